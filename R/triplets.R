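#' Flag outlier reaches by per-participant z-score
#'
#' Flags trials whose reach angle lies more than `z_threshold` SDs from that
#' participant's mean reach angle. Flagged trials are excluded from triplet
#' extraction and all downstream analyses.
#'
#' @param trials a trial table.
#' @param z_threshold absolute z-score cutoff.
#' @return the trial table with the `excluded` column updated.
#' @export
exclude_outliers <- function(trials, z_threshold = 3.5) {
  check_trials(trials)
  if (is.null(trials$excluded)) trials$excluded <- FALSE
  for (pid in unique(trials$participant_id)) {
    idx <- trials$participant_id == pid
    x <- trials$hand_angle_deg[idx]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      warning(sprintf(
        "participant %s: zero reach-angle variance, no trials excluded",
        pid), call. = FALSE)
      next
    }
    trials$excluded[idx] <- abs(x - mean(x)) / s > z_threshold
  }
  trials
}

#' Extract measured-trial triplets
#'
#' One triplet per measured trial that is flanked by null trials, with none
#' of the three trials excluded. The externally generated error (EGE) is
#' the rotation on the measured trial; the internally generated error (IGE)
#' is the hand angle on the measured trial; single-trial adaptation is the
#' hand-angle change from the preceding null to the following null,
#' `hand[t+1] - hand[t-1]`, which keeps the outcome measure free of its
#' putative predictor. Target-jump trials are never used.
#'
#' @param trials a trial table, ideally after [exclude_outliers()].
#' @return a data frame with `participant_id`, `center_index`, `EGE`,
#'   `IGE`, `adaptation`; malformed or excluded triplets are skipped and
#'   their count is reported via a message.
#' @export
extract_triplets <- function(trials) {
  check_trials(trials)
  if (is.null(trials$excluded)) trials$excluded <- FALSE
  res <- list()
  n_skipped <- 0L
  for (pid in unique(trials$participant_id)) {
    tr <- trials[trials$participant_id == pid, ]
    tr <- tr[order(tr$trial_index), ]
    i <- which(tr$trial_type == "measured")
    ok_pos <- i > 1L & i < nrow(tr)
    n_skipped <- n_skipped + sum(!ok_pos)
    i <- i[ok_pos]
    flanked <- tr$trial_type[i - 1L] == "null" & tr$trial_type[i + 1L] == "null"
    clean <- !(tr$excluded[i - 1L] | tr$excluded[i] | tr$excluded[i + 1L])
    n_skipped <- n_skipped + sum(!flanked)
    keep <- flanked & clean
    i <- i[keep]
    res[[pid]] <- data.frame(
      participant_id = rep(pid, length(i)),
      center_index = tr$trial_index[i],
      EGE = tr$rotation_deg[i],
      IGE = tr$hand_angle_deg[i],
      adaptation = tr$hand_angle_deg[i + 1L] - tr$hand_angle_deg[i - 1L],
      stringsAsFactors = FALSE)
  }
  if (n_skipped > 0L)
    message(sprintf("extract_triplets: skipped %d measured trial(s) without null neighbours",
                    n_skipped))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# ordinary least squares y ~ x with normal-theory CIs, via lm
reg_summary <- function(y, x, xname = "x") {
  fit <- stats::lm(y ~ x)
  ci <- stats::confint(fit)
  s <- summary(fit)
  r2 <- s$r.squared
  if (stats::var(y) < 1e-24) r2 <- 0   # constant response carries no variance
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2,
       ci_low = ci[2L, 1L], ci_high = ci[2L, 2L],
       n = length(y), predictor = xname)
}

#' Binned adaptation regressions on EGE and IGE
#'
#' For each participant, triplets are split by the five EGE levels and,
#' within each level, binned into `n_ige_bins` quantile bins of IGE
#' (boundary ties broken by stable rank on trial order), giving a
#' 5 x `n_ige_bins` grid of mean adaptation. Sensitivity to EGE (IGE) is
#' the OLS slope of the bin means on the bin's EGE (mean IGE). At the group
#' level the grid cells are first averaged across participants, then
#' regressed.
#'
#' @param triplets a triplet table from [extract_triplets()].
#' @param n_ige_bins number of IGE bins per EGE level.
#' @return a list with `bins` (per-participant bin means), `group_bins`,
#'   `ege` and `ige` (group-level regression summaries) and `participant`
#'   (per-participant slopes).
#' @export
binned_regression <- function(triplets, n_ige_bins = 5) {
  if (nrow(triplets) < 25)
    stop("need at least 25 triplets", call. = FALSE)
  rows <- list()
  for (pid in unique(triplets$participant_id)) {
    tp <- triplets[triplets$participant_id == pid, ]
    for (lev in sort(unique(tp$EGE))) {
      cell <- tp[tp$EGE == lev, ]
      cell <- cell[order(cell$center_index), ]
      rk <- rank(cell$IGE, ties.method = "first")
      bin <- ceiling(rk * n_ige_bins / nrow(cell))
      for (bn in seq_len(n_ige_bins)) {
        sel <- bin == bn
        if (!any(sel)) {
          warning(sprintf(
            "participant %s, EGE %g: empty IGE bin %d dropped", pid, lev, bn),
            call. = FALSE)
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pid, ege_level = lev, ige_bin = bn,
          mean_adapt = mean(cell$adaptation[sel]),
          mean_ige = mean(cell$IGE[sel]), n = sum(sel),
          stringsAsFactors = FALSE)
      }
    }
  }
  bins <- do.call(rbind, rows)

  # per-participant slopes
  pp <- lapply(split(bins, bins$participant_id), function(b) {
    data.frame(participant_id = b$participant_id[1L],
               ege_slope = reg_summary(b$mean_adapt, b$ege_level)$slope,
               ige_slope = reg_summary(b$mean_adapt, b$mean_ige)$slope,
               stringsAsFactors = FALSE)
  })
  pp <- do.call(rbind, pp)
  rownames(pp) <- NULL

  # group level: average each grid cell across participants, then regress
  gb <- stats::aggregate(cbind(mean_adapt, mean_ige) ~ ege_level + ige_bin,
                         data = bins, FUN = mean)
  list(bins = bins, group_bins = gb,
       ege = reg_summary(gb$mean_adapt, gb$ege_level, "EGE"),
       ige = reg_summary(gb$mean_adapt, gb$mean_ige, "IGE"),
       participant = pp)
}

#' Bivariate regression of unbinned adaptation on EGE and IGE
#'
#' Per participant, OLS of single-trial adaptation on EGE and IGE jointly.
#' Coefficients are reported sign-flipped, so a positive value means
#' adaptation opposing the error.
#'
#' @param triplets a triplet table from [extract_triplets()].
#' @return a data frame with one row per participant: sign-flipped
#'   `ege_coef` and `ige_coef`, their confidence intervals, `r_squared`
#'   and `n`.
#' @export
bivariate_regression <- function(triplets) {
  out <- lapply(split(triplets, triplets$participant_id), function(tp) {
    if (nrow(tp) < 3)
      stop("need at least 3 triplets per participant", call. = FALSE)
    X <- cbind(1, tp$EGE, tp$IGE)
    if (qr(X)$rank < 3L)
      stop("EGE and IGE are collinear; bivariate regression is undefined",
           call. = FALSE)
    fit <- stats::lm(adaptation ~ EGE + IGE, data = tp)
    ci <- stats::confint(fit)
    data.frame(participant_id = tp$participant_id[1L],
               ege_coef = -unname(stats::coef(fit)["EGE"]),
               ige_coef = -unname(stats::coef(fit)["IGE"]),
               ege_ci_low = -ci["EGE", 2L], ege_ci_high = -ci["EGE", 1L],
               ige_ci_low = -ci["IGE", 2L], ige_ci_high = -ci["IGE", 1L],
               r_squared = summary(fit)$r.squared, n = nrow(tp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Group-level tests of the regression coefficients
#'
#' Paired t-test of the EGE versus IGE coefficients across participants,
#' one-sample t-tests of each against zero, and bootstrap percentile CIs of
#' the means (resampling participants with replacement).
#'
#' @param coefs a per-participant coefficient table from
#'   [bivariate_regression()] (columns `ege_coef`, `ige_coef`).
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed for the bootstrap.
#' @return a list with `paired`, `ege`, `ige` (each: estimate, t, df, p,
#'   bootstrap `ci`), and `n`.
#' @export
group_stats <- function(coefs, n_boot = 10000, seed = 1) {
  n <- nrow(coefs)
  if (n < 2) stop("need at least 2 participants", call. = FALSE)
  d <- coefs$ege_coef - coefs$ige_coef

  one_sample <- function(x) {
    if (stats::sd(x) < 1e-12) {
      # undefined-variance guard: degenerate sample, t undefined
      return(list(estimate = mean(x), t = NA_real_, df = n - 1,
                  p = if (abs(mean(x)) < 1e-12) 1 else NA_real_))
    }
    tt <- stats::t.test(x)
    list(estimate = unname(tt$estimate), t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value)
  }

  set.seed(as.integer(seed))
  boot_idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  boot_ci <- function(x) {
    m <- rowMeans(matrix(x[boot_idx], nrow = n_boot))
    unname(stats::quantile(m, c(0.025, 0.975)))
  }

  res <- list(paired = one_sample(d),
              ege = one_sample(coefs$ege_coef),
              ige = one_sample(coefs$ige_coef),
              n = n)
  res$paired$ci <- boot_ci(d)
  res$ege$ci <- boot_ci(coefs$ege_coef)
  res$ige$ci <- boot_ci(coefs$ige_coef)
  res
}

#' Residual adaptation two trials after a perturbation
#'
#' Regresses the hand-angle change from the pre-perturbation null to the
#' trial two positions after the perturbation (`hand[t+2] - hand[t-1]`,
#' restricted to schedules where trial `t+2` is a null) onto the EGE at
#' trial `t`. Under the no-memory assumption the slope is near zero; a
#' carried-over update produces a negative slope (residual adaptation in
#' the compensatory direction).
#'
#' @param trials a trial table, ideally after [exclude_outliers()].
#' @return a regression summary (slope is the residual-memory estimate), or
#'   `NULL` with a warning if too few eligible trials exist.
#' @export
lag2_residual <- function(trials) {
  check_trials(trials)
  if (is.null(trials$excluded)) trials$excluded <- FALSE
  ys <- xs <- numeric(0)
  for (pid in unique(trials$participant_id)) {
    tr <- trials[trials$participant_id == pid, ]
    tr <- tr[order(tr$trial_index), ]
    i <- which(tr$trial_type == "measured")
    i <- i[i > 1L & i + 2L <= nrow(tr)]
    keep <- tr$trial_type[i + 2L] == "null" &
      !(tr$excluded[i - 1L] | tr$excluded[i] | tr$excluded[i + 2L])
    i <- i[keep]
    ys <- c(ys, tr$hand_angle_deg[i + 2L] - tr$hand_angle_deg[i - 1L])
    xs <- c(xs, tr$rotation_deg[i])
  }
  if (length(ys) < 10 || length(unique(xs)) < 2) {
    warning("too few eligible trials for the lag-2 residual analysis",
            call. = FALSE)
    return(NULL)
  }
  reg_summary(ys, xs, "EGE (lag 2)")
}

check_trials <- function(trials) {
  req <- c("participant_id", "trial_index", "trial_type", "rotation_deg",
           "hand_angle_deg")
  miss <- setdiff(req, names(trials))
  if (length(miss) > 0)
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}
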