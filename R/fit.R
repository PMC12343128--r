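# internal: assemble the likelihood ingredients for one participant
prepare_fit_data <- function(trials, z_threshold = 3.5) {
  check_trials(trials)
  if (length(unique(trials$participant_id)) != 1L)
    stop("fit one participant at a time (split the table first)",
         call. = FALSE)
  trials <- exclude_outliers(trials, z_threshold)
  trips <- extract_triplets(trials)
  if (nrow(trips) < 10)
    stop("too few triplets to fit (need >= 10)", call. = FALSE)
  # observed response on the trial following each measured trial
  tr <- trials[order(trials$trial_index), ]
  pos <- match(trips$center_index, tr$trial_index)
  list(trials = trials,
       trips = trips,
       hand_next = tr$hand_angle_deg[pos + 1L],
       hand_prev = tr$hand_angle_deg[pos - 1L],
       sigma_h = baseline_sigma(trials),
       bias0 = baseline_bias(trials))
}

nll_from_data <- function(params, fd, likelihood = "response",
                          include_nulls = FALSE) {
  mu <- predict_trial(params, fd$trips$EGE, fd$trips$IGE)
  if (any(!is.finite(mu)))
    stop(sprintf("non-finite prediction at triplet center trial %d",
                 fd$trips$center_index[which(!is.finite(mu))[1L]]),
         call. = FALSE)
  nll <- if (likelihood == "response") {
    -sum(stats::dnorm(fd$hand_next, mu, params$sigma_h, log = TRUE))
  } else {
    # adaptation target: hand[t+1] - hand[t-1] ~ N(mu - b, 2 * sigma_h^2)
    -sum(stats::dnorm(fd$hand_next - fd$hand_prev, mu - params$bias,
                      sqrt(2) * params$sigma_h, log = TRUE))
  }
  if (include_nulls) {
    tr <- fd$trials[order(fd$trials$trial_index), ]
    main <- which(tr$phase == "main" & tr$trial_type == "null" &
                    !tr$excluded)
    # only nulls not already used as the response to a measured trial
    prev_measured <- main > 1L & tr$trial_type[pmax(main - 1L, 1L)] == "measured"
    nulls <- tr$hand_angle_deg[main[!prev_measured]]
    nll <- nll - sum(stats::dnorm(nulls, params$bias, params$sigma_h,
                                  log = TRUE))
  }
  nll
}

#' Negative log-likelihood of a trial table under a model
#'
#' For every measured-trial triplet (all rotation levels, including zero),
#' the observed reach on the following trial is scored under a Gaussian
#' centred on the model's deterministic single-trial prediction with SD
#' `sigma_h` (fixed from baseline). Trials are treated as independent and
#' the log-likelihoods summed.
#'
#' @param params an `adapt_params` object (its `sigma_h` is overridden by
#'   the baseline estimate from the data).
#' @param trials a single participant's trial table.
#' @param likelihood `"response"` scores the following trial's reach;
#'   `"adaptation"` scores the triplet difference `hand[t+1] - hand[t-1]`
#'   with SD `sqrt(2) * sigma_h`.
#' @param include_nulls if `TRUE`, null-trial reaches not already serving
#'   as a measured trial's response contribute `N(bias, sigma_h^2)` terms.
#' @return the negative log-likelihood (a single number).
#' @export
negative_log_likelihood <- function(params, trials,
                                    likelihood = c("response", "adaptation"),
                                    include_nulls = FALSE) {
  likelihood <- match.arg(likelihood)
  fd <- prepare_fit_data(trials)
  params$sigma_h <- fd$sigma_h
  nll_from_data(params, fd, likelihood, include_nulls)
}

#' Fit an adaptation model to one participant by maximum likelihood
#'
#' Multi-start bounded maximum-likelihood estimation of a single-trial
#' adaptation model on one participant's trial table. The response noise
#' `sigma_h` is fixed to the SD of the final 50 baseline reaches (and, for
#' the perceptual-error model, the reach bias is fixed to the baseline
#' mean); only the model's free parameters are estimated. Start points are
#' drawn by Latin-hypercube sampling within the bounds and each is refined
#' with bounded quasi-Newton (`L-BFGS-B`); the best converged start is
#' returned. Fitting is deterministic given the data, seed, bounds and
#' number of starts.
#'
#' @param trials a single participant's trial table.
#' @param model one of `"piece"`, `"premo"`, `"pea"`, `"rem"`.
#' @param n_starts number of optimization starts.
#' @param bounds optional data frame with columns `name`, `lower`, `upper`
#'   overriding the model's default box (see [free_param_info()]).
#' @param seed integer seed for start sampling (required).
#' @param likelihood,include_nulls see [negative_log_likelihood()].
#' @param alpha,beta visual-uncertainty coefficients for the models that
#'   use them (fixed, not fitted).
#' @param z_threshold outlier cutoff passed to [exclude_outliers()].
#' @return an object of class `adapt_fit`; see [coef.adapt_fit()],
#'   [logLik.adapt_fit()], [predict.adapt_fit()], [simulate.adapt_fit()].
#'   Its `bic` element equals `k * log(n) + 2 * nll` with `n` the number of
#'   triplets scored.
#' @export
fit_adaptation <- function(trials, model = c("piece", "premo", "pea", "rem"),
                           n_starts = 20, bounds = NULL, seed = 1,
                           likelihood = c("response", "adaptation"),
                           include_nulls = FALSE, alpha = 1, beta = 0.3,
                           z_threshold = 3.5) {
  model <- match.arg(model)
  likelihood <- match.arg(likelihood)
  cl <- match.call()
  fd <- prepare_fit_data(trials, z_threshold)

  base <- switch(model,
    piece = piece_params(sigma_h = fd$sigma_h, alpha = alpha, beta = beta),
    premo = premo_params(sigma_h = fd$sigma_h),
    pea = pea_params(sigma_h = fd$sigma_h, bias = fd$bias0, alpha = alpha,
                     beta = beta),
    rem = rem_params(sigma_h = fd$sigma_h))
  info <- free_param_info(base)
  if (!is.null(bounds)) {
    m <- match(info$name, bounds$name)
    ok <- !is.na(m)
    info$lower[ok] <- bounds$lower[m[ok]]
    info$upper[ok] <- bounds$upper[m[ok]]
    if (any(info$lower >= info$upper))
      stop("invalid bounds: lower >= upper", call. = FALSE)
  }
  k <- nrow(info)

  obj <- function(theta) {
    p <- set_free_params(base, stats::setNames(theta, info$name))
    nll_from_data(p, fd, likelihood, include_nulls)
  }

  set.seed(as.integer(seed))
  starts <- lhs::randomLHS(n_starts, k)
  starts <- sweep(starts, 2, info$upper - info$lower, "*")
  starts <- sweep(starts, 2, info$lower, "+")
  # keep the bias start near its baseline estimate where bias is free
  if ("bias" %in% info$name) {
    j <- match("bias", info$name)
    starts[1L, j] <- min(max(fd$bias0, info$lower[j]), info$upper[j])
  }

  best <- NULL
  n_conv <- 0L
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      stats::optim(starts[s, ], obj, method = "L-BFGS-B",
                   lower = info$lower, upper = info$upper,
                   control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0L) n_conv <- n_conv + 1L else next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      best$start <- s
    }
  }
  if (is.null(best))
    stop(sprintf(
      "no optimization start converged (%d starts, model '%s')",
      n_starts, model), call. = FALSE)

  H <- tryCatch(
    stats::optimHess(best$par, obj), error = function(e) NULL)
  se <- rep(NA_real_, k)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      d <- diag(V)
      se[d > 0] <- sqrt(d[d > 0])
    }
  }

  mle <- stats::setNames(best$par, info$name)
  n <- nrow(fd$trips)
  structure(list(
    model = model,
    participant_id = fd$trips$participant_id[1L],
    coefficients = mle,
    se = stats::setNames(se, info$name),
    params = set_free_params(base, mle),
    fixed = list(sigma_h = fd$sigma_h,
                 bias0 = fd$bias0,
                 alpha = alpha, beta = beta,
                 likelihood = likelihood,
                 include_nulls = include_nulls),
    nll = best$value,
    n = n, k = k,
    bic = k * log(n) + 2 * best$value,
    converged = TRUE,
    n_starts = n_starts, n_converged = n_conv, best_start = best$start,
    bounds = info,
    trials = fd$trials,
    triplets = fd$trips,
    hand_next = fd$hand_next,
    call = cl), class = "adapt_fit")
}

#' Compare fitted models by BIC
#'
#' Tabulates BIC scores across models (and participants), benchmarks each
#' model's BIC against a reference model, and reports the per-participant
#' BIC winner.
#'
#' @param fits a list of `adapt_fit` objects covering one or more
#'   participants; each participant must have every model fitted.
#' @param reference model name the deltas are benchmarked to.
#' @return a list with `table` (one row per participant x model, columns
#'   `bic`, `delta_bic`, `winner`) and `winners` (named count of wins per
#'   model).
#' @export
bic_compare <- function(fits, reference = "premo") {
  stopifnot(all(vapply(fits, inherits, logical(1), "adapt_fit")))
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(participant_id = f$participant_id, model = f$model,
               nll = f$nll, k = f$k, n = f$n, bic = f$bic,
               stringsAsFactors = FALSE)))
  models <- sort(unique(tab$model))
  if (!reference %in% models)
    stop(sprintf("reference model '%s' has no fits", reference),
         call. = FALSE)
  out <- list()
  for (pid in unique(tab$participant_id)) {
    tp <- tab[tab$participant_id == pid, ]
    if (!all(models %in% tp$model))
      stop(sprintf("participant %s is missing fits for: %s", pid,
                   paste(setdiff(models, tp$model), collapse = ", ")),
           call. = FALSE)
    tp$delta_bic <- tp$bic - tp$bic[tp$model == reference]
    tp$winner <- tp$model == tp$model[which.min(tp$bic)]
    out[[pid]] <- tp
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  winners <- table(factor(tab$model[tab$winner], levels = models))
  list(table = tab, winners = winners)
}

#' Posterior predictive check of a fitted model
#'
#' Simulates the participant's own schedule at the maximum-likelihood
#' estimates and runs the bivariate (and, when enough triplets exist,
#' binned) analyses on the observed and simulated data side by side. A
#' model that captures error parsing should reproduce both the EGE
#' sensitivity and the near-zero IGE sensitivity of the observed data.
#'
#' @param fit an `adapt_fit` object.
#' @param seed integer seed for the simulation.
#' @param protocol optional protocol; defaults to the schedule of the
#'   fitted data.
#' @return an object of class `adapt_ppc`: coefficient tables for observed
#'   and simulated data plus the simulated trial table.
#' @export
posterior_predictive_check <- function(fit, seed, protocol = NULL) {
  stopifnot(inherits(fit, "adapt_fit"))
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (is.null(protocol)) {
    protocol <- fit$trials[order(fit$trials$trial_index),
                           c("trial_index", "block", "phase", "trial_type",
                             "rotation_deg", "feedback")]
  }
  sim <- simulate_participant(fit$params, protocol, seed = seed,
                              participant_id = fit$participant_id)
  sim <- exclude_outliers(sim)
  sim_trips <- extract_triplets(sim)
  obs <- bivariate_regression(fit$triplets)
  # noiseless simulations have constant IGE, leaving the bivariate
  # regression undefined; report NULL coefficients in that case
  simc <- tryCatch(bivariate_regression(sim_trips),
                   error = function(e) NULL)
  structure(list(model = fit$model,
                 participant_id = fit$participant_id,
                 observed = obs, simulated = simc,
                 sim_trials = sim, sim_triplets = sim_trips,
                 seed = seed),
            class = "adapt_ppc")
}

#' @export
print.adapt_ppc <- function(x, ...) {
  cat(sprintf("Posterior predictive check: %s, participant %s\n",
              model_label(x$model), x$participant_id))
  if (is.null(x$simulated)) {
    cat("simulated data degenerate (constant IGE); no coefficients\n")
  } else {
    tab <- rbind(observed = c(x$observed$ege_coef, x$observed$ige_coef),
                 simulated = c(x$simulated$ege_coef, x$simulated$ige_coef))
    colnames(tab) <- c("EGE coef", "IGE coef")
    print(round(tab, 3))
  }
  cat("(coefficients sign-flipped: positive = adaptation opposing error)\n")
  invisible(x)
}
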