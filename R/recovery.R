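#' Parameter recovery for the causal-inference observer
#'
#' Simulates synthetic participants at each row of a generating-parameter
#' grid, refits the observer to each simulated dataset, and reports the
#' recovered estimates next to the generating values.
#'
#' @param grid a data frame whose columns are a subset of
#'   `sigma_r`, `sigma_combined`, `bias`; one row per generating point.
#' @param n_rep simulated datasets per grid point.
#' @param seed integer seed; all protocol, simulation and fitting seeds are
#'   derived from it.
#' @param protocol optional fixed protocol; by default each replicate gets
#'   a freshly randomized schedule.
#' @param n_starts optimization starts per fit.
#' @param base_params fixed observer settings (`sigma_h`, `alpha`, `beta`)
#'   shared by all grid points.
#' @return a list with `estimates` (one row per replicate: generating and
#'   recovered values) and `summary` (per grid point: median absolute bias
#'   error and median relative `sigma_r` error).
#' @export
parameter_recovery <- function(grid, n_rep = 20, seed = 1, protocol = NULL,
                               n_starts = 10,
                               base_params = piece_params()) {
  set.seed(as.integer(seed))
  total <- nrow(grid) * n_rep
  seeds <- matrix(sample.int(2^31 - 1, 3 * total), ncol = 3)
  rows <- vector("list", total)
  r <- 0L
  for (g in seq_len(nrow(grid))) {
    gen <- base_params
    for (nm in intersect(names(grid), c("sigma_r", "sigma_combined", "bias")))
      gen[[nm]] <- grid[[nm]][g]
    gen <- do.call(piece_params, gen[setdiff(names(gen), "model")])
    for (rep_i in seq_len(n_rep)) {
      r <- r + 1L
      prot <- if (is.null(protocol))
        build_protocol(seed = seeds[r, 1]) else protocol
      sim <- simulate_participant(gen, prot, seed = seeds[r, 2],
                                  participant_id = sprintf("G%dR%d", g, rep_i))
      fit <- fit_adaptation(sim, "piece", n_starts = n_starts,
                            seed = seeds[r, 3],
                            alpha = gen$alpha, beta = gen$beta)
      est <- coef(fit)
      rows[[r]] <- data.frame(
        grid_point = g, rep = rep_i,
        sigma_r_true = gen$sigma_r, sigma_r_est = est[["sigma_r"]],
        sigma_combined_true = gen$sigma_combined,
        sigma_combined_est = est[["sigma_combined"]],
        bias_true = gen$bias, bias_est = est[["bias"]])
    }
  }
  est <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(est, est$grid_point), function(e)
    data.frame(grid_point = e$grid_point[1L],
               sigma_r_true = e$sigma_r_true[1L],
               bias_true = e$bias_true[1L],
               med_abs_bias_err = stats::median(abs(e$bias_est - e$bias_true)),
               med_rel_sigma_r_err = stats::median(
                 abs(e$sigma_r_est - e$sigma_r_true) / e$sigma_r_true))))
  rownames(summ) <- NULL
  list(estimates = est, summary = summ)
}

#' Model recovery by BIC across all four models
#'
#' Simulates synthetic participants from each generating model, fits all
#' four models to every simulated dataset, and tabulates the BIC winners as
#' a confusion matrix (generating model in rows, winning model in columns).
#' Successful recovery shows up as diagonal dominance.
#'
#' @param n_rep simulated participants per generating model.
#' @param seed integer seed; all derived seeds flow from it.
#' @param gen_params named list of generating `adapt_params`, one per model;
#'   defaults to the package's study-condition defaults.
#' @param protocol optional fixed protocol; defaults to fresh randomized
#'   schedules.
#' @param n_starts optimization starts per fit.
#' @return a list with `confusion` (counts matrix), `details` (per dataset:
#'   generating model, winner, BICs) and `gen_params`.
#' @export
model_recovery <- function(n_rep = 10, seed = 1, gen_params = NULL,
                           protocol = NULL, n_starts = 10) {
  models <- c("piece", "premo", "pea", "rem")
  if (is.null(gen_params))
    gen_params <- stats::setNames(lapply(models, default_params), models)
  stopifnot(all(models %in% names(gen_params)))
  set.seed(as.integer(seed))
  total <- length(models) * n_rep
  seeds <- matrix(sample.int(2^31 - 1, total * (2 + length(models))),
                  nrow = total)
  confusion <- matrix(0L, length(models), length(models),
                      dimnames = list(generating = models, winner = models))
  details <- vector("list", total)
  r <- 0L
  for (gm in models) {
    for (rep_i in seq_len(n_rep)) {
      r <- r + 1L
      prot <- if (is.null(protocol))
        build_protocol(seed = seeds[r, 1]) else protocol
      sim <- simulate_participant(gen_params[[gm]], prot,
                                  seed = seeds[r, 2],
                                  participant_id = sprintf("%s%02d", gm, rep_i))
      bics <- stats::setNames(numeric(length(models)), models)
      for (j in seq_along(models)) {
        fit <- fit_adaptation(sim, models[j], n_starts = n_starts,
                              seed = seeds[r, 2 + j])
        bics[models[j]] <- fit$bic
      }
      win <- names(which.min(bics))
      confusion[gm, win] <- confusion[gm, win] + 1L
      details[[r]] <- data.frame(generating = gm, rep = rep_i, winner = win,
                                 t(bics))
    }
  }
  list(confusion = confusion, details = do.call(rbind, details),
       gen_params = gen_params)
}
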