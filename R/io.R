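TRIAL_COLUMNS <- c("participant_id", "trial_index", "block", "phase",
                   "trial_type", "rotation_deg", "feedback",
                   "hand_angle_deg")

#' Read a trial table from delimited text
#'
#' Reads a comma-delimited trial table with a header, validates the
#' required columns and basic schedule constraints, and returns a data
#' frame. Angles are degrees, counter-clockwise positive, target at 0.
#'
#' @param path path to a CSV file.
#' @param col_map optional named character vector mapping the file's column
#'   names to the required ones, e.g. `c(subject = "participant_id")`.
#' @return a validated trial table.
#' @export
read_trials <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("empty trial table: ", path, call. = FALSE)
  if (!is.null(col_map)) {
    m <- match(names(col_map), names(tab))
    names(tab)[m[!is.na(m)]] <- col_map[!is.na(m)]
  }
  miss <- setdiff(TRIAL_COLUMNS, names(tab))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in c("rotation_deg", "hand_angle_deg")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0)
      stop(sprintf("non-numeric or non-finite '%s' at row %d", col, bad[1L]),
           call. = FALSE)
    tab[[col]] <- v
  }
  if (is.null(tab$excluded)) tab$excluded <- FALSE
  meas <- tab$trial_type == "measured"
  levels_seen <- unique(tab$rotation_deg[meas])
  odd <- setdiff(levels_seen, c(0, -2, 2, -4, 4))
  if (length(odd) > 0)
    warning("unexpected rotation level(s) on measured trials: ",
            paste(odd, collapse = ", "), call. = FALSE)
  if (any(tab$rotation_deg[tab$trial_type == "null"] != 0))
    warning("null trials with non-zero rotation found", call. = FALSE)
  tab
}

#' Write a trial table to delimited text
#'
#' Writes the table as comma-delimited UTF-8 with a deterministic column
#' order (required columns first) and full numeric precision, so that
#' write-then-read is the identity.
#'
#' @param trials a trial table.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_trials <- function(trials, path) {
  check_trials(trials)
  ord <- c(intersect(TRIAL_COLUMNS, names(trials)),
           setdiff(names(trials), TRIAL_COLUMNS))
  utils::write.csv(trials[, ord], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# plain-text provenance sidecar written next to every CLI output
write_sidecar <- function(path, fields) {
  side <- paste0(path, ".provenance.txt")
  lines <- c(sprintf("package: piece %s",
                     as.character(utils::packageVersion("piece"))),
             sprintf("written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             vapply(names(fields), function(nm)
               sprintf("%s: %s", nm, paste(fields[[nm]], collapse = " ")),
               character(1)))
  writeLines(lines, side)
  invisible(side)
}
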