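#' Visual uncertainty as a function of target error
#'
#' The SD of the visual cue grows linearly with the distance of the feedback
#' cursor from the target: `sigma_v = alpha + beta * e`.
#'
#' @param e absolute cursor-to-target error in degrees (vectorized, must be
#'   non-negative).
#' @param params a [piece_params()] (or [pea_params()]) object supplying
#'   `alpha` and `beta`.
#' @return visual SD in degrees, strictly positive.
#' @export
visual_uncertainty <- function(e, params) {
  if (any(!is.finite(e)) || any(e < 0))
    stop("target error 'e' must be finite and non-negative", call. = FALSE)
  params$alpha + params$beta * e
}

#' Bundle the observer's cues on one trial
#'
#' @param x_v visual measurement of the cursor angle (degrees).
#' @param x_c combined internal measurement of hand angle (degrees);
#'   proprioception fused with the motor prediction.
#' @param e absolute cursor-to-target error (degrees), used to set the
#'   visual SD; ignored when `sigma_v` is given directly.
#' @param params a [piece_params()] object (needed when `sigma_v` is derived
#'   from `e`).
#' @param sigma_v optional visual SD (degrees) overriding the linear rule.
#' @return a `cue_set` list with elements `x_v`, `x_c`, `e`, `sigma_v`.
#' @export
cue_set <- function(x_v, x_c, e = NULL, params = NULL, sigma_v = NULL) {
  if (is.null(sigma_v)) {
    if (is.null(e) || is.null(params))
      stop("supply either 'sigma_v' or both 'e' and 'params'", call. = FALSE)
    sigma_v <- visual_uncertainty(e, params)
  } else if (any(sigma_v <= 0)) {
    stop("'sigma_v' must be strictly positive", call. = FALSE)
  }
  if (is.null(e)) e <- rep(NA_real_, length(x_v))
  structure(list(x_v = x_v, x_c = x_c, e = e, sigma_v = sigma_v),
            class = "cue_set")
}

# Log marginal likelihoods of the cue pair (x_v, x_c) under the unperturbed
# and perturbed world states, with hand position (and the rotation, in the
# perturbed case) integrated out analytically. Both are bivariate Gaussian
# in (x_v, x_c) with means (b, b), Cov = sigma_h^2, Var(x_c) = sigma_h^2 +
# sigma_combined^2 and Var(x_v) = sigma_h^2 + sigma_v^2 (+ sigma_r^2 when
# perturbed). Vectorized over cues.
marginal_loglik <- function(x_v, x_c, sigma_v, params) {
  if (any(sigma_v <= 0)) stop("'sigma_v' must be positive", call. = FALSE)
  vh <- params$sigma_h^2
  vc <- vh + params$sigma_combined^2
  dv <- x_v - params$bias
  dc <- x_c - params$bias
  bvn <- function(var_v) {
    det <- var_v * vc - vh * vh
    q <- (vc * dv * dv - 2 * vh * dv * dc + var_v * dc * dc) / det
    -log(2 * pi) - 0.5 * log(det) - 0.5 * q
  }
  list(nopert = bvn(vh + sigma_v^2),
       pert = bvn(vh + sigma_v^2 + params$sigma_r^2))
}

#' Marginal likelihoods of the cues under each world state
#'
#' Computes the likelihood of the visual and combined internal cues under
#' the unperturbed hypothesis (hand position marginalized out) and the
#' perturbed hypothesis (hand position and rotation magnitude marginalized
#' out). Both marginals are available in closed form because every node in
#' the generative model is Gaussian.
#'
#' @param cues a [cue_set()].
#' @param params a [piece_params()] object.
#' @return a list with numeric vectors `nopert` and `pert` (densities,
#'   floored at `1e-300`).
#' @export
marginal_likelihoods <- function(cues, params) {
  ll <- marginal_loglik(cues$x_v, cues$x_c, cues$sigma_v, params)
  list(nopert = pmax(exp(ll$nopert), 1e-300),
       pert = pmax(exp(ll$pert), 1e-300))
}

#' Posterior belief that the feedback was perturbed
#'
#' Combines the prior on the causal node with the marginal likelihoods of
#' the cues and normalizes. All arithmetic is done in log space, so the
#' posterior is well defined even for extreme cue values.
#'
#' @inheritParams marginal_likelihoods
#' @return a list of numeric vectors `p_pert` and `p_nopert`, summing to 1.
#' @export
causal_posterior <- function(cues, params) {
  ll <- marginal_loglik(cues$x_v, cues$x_c, cues$sigma_v, params)
  lp <- log(params$p_pert_prior) + ll$pert
  ln <- log1p(-params$p_pert_prior) + ll$nopert
  p_pert <- 1 / (1 + exp(ln - lp))
  list(p_pert = p_pert, p_nopert = 1 - p_pert)
}

#' Learning rate from precision weighting
#'
#' The fraction of the observed perturbation corrected on a trial, obtained
#' by optimally combining the measurement (precision `1/sigma_v^2`) with the
#' prior on rotation magnitude (precision `1/sigma_r^2`).
#'
#' @param sigma_v visual SD on the trial (degrees).
#' @param sigma_r prior SD on the rotation magnitude (degrees).
#' @return the gain, strictly inside (0, 1); decreasing in `sigma_v` and
#'   increasing in `sigma_r`.
#' @examples
#' kalman_gain(2, 2)  # equal precisions: 0.5
#' @export
kalman_gain <- function(sigma_v, sigma_r) {
  if (any(!is.finite(sigma_v)) || any(sigma_v <= 0) ||
      any(!is.finite(sigma_r)) || any(sigma_r <= 0))
    stop("'sigma_v' and 'sigma_r' must be positive and finite",
         call. = FALSE)
  sigma_r^2 / (sigma_r^2 + sigma_v^2)
}

#' Overall state estimate of the perturbation
#'
#' The perturbation estimate is a belief-weighted linear combination of the
#' state estimates under the two world states; the unperturbed state
#' contributes zero, so `r_hat = p_pert * K * z`.
#'
#' @param z observation of the perturbation (degrees).
#' @param gain_K learning rate from [kalman_gain()].
#' @param posterior a list with element `p_pert` (as returned by
#'   [causal_posterior()]) or a numeric vector of perturbed-state beliefs.
#' @return a list with `gain_K`, `z` and the estimate `r_hat`.
#' @export
estimate_perturbation <- function(z, gain_K, posterior) {
  p_pert <- if (is.list(posterior)) posterior$p_pert else posterior
  if (any(p_pert < 0 | p_pert > 1))
    stop("'p_pert' must lie in [0, 1]", call. = FALSE)
  list(gain_K = gain_K, z = z, r_hat = p_pert * gain_K * z)
}

# Deterministic single-trial machinery shared by prediction and simulation:
# cues at their experimenter-visible values (x_v = hand + r, x_c = hand,
# z = r, e = |hand + r|). Returns the posterior, gain and estimate.
piece_machinery <- function(params, rotation, hand) {
  e <- abs(hand + rotation)
  sigma_v <- params$alpha + params$beta * e
  post <- causal_posterior(
    cue_set(x_v = hand + rotation, x_c = hand, sigma_v = sigma_v), params)
  K <- kalman_gain(sigma_v, params$sigma_r)
  list(sigma_v = sigma_v, p_pert = post$p_pert, gain_K = K,
       r_hat = post$p_pert * K * rotation)
}

#' @export
predict_trial.piece_params <- function(params, rotation, hand,
                                       feedback = "full", ...) {
  n <- max(length(rotation), length(hand))
  rotation <- rep_len(rotation, n)
  hand <- rep_len(hand, n)
  mu <- params$bias - piece_machinery(params, rotation, hand)$r_hat
  if (!identical(feedback, "full")) {
    feedback <- rep_len(feedback, n)
    mu[feedback == "none"] <- params$bias
  }
  mu
}

#' Predicted or simulated response to one trial
#'
#' Given the rotation and the measured hand angle on the current trial,
#' returns the model's reach angle on the next trial. In deterministic mode
#' the cues are set at their experimenter-visible values (`x_v = hand + r`,
#' `x_c = hand`, `z = r`) and the mean response `-r_hat + b` is returned;
#' this is the prediction used for likelihood evaluation. In stochastic mode
#' the observer's cues are sampled from their generative distributions
#' (`x_v ~ N(hand + r, sigma_v)`, `x_c ~ N(hand, sigma_combined)`,
#' `z ~ N(r, sigma_v)`) and motor noise `N(0, sigma_h^2)` is added to the
#' response. On feedback-absent trials there is nothing to learn from and
#' the response mean is the bias.
#'
#' @param rotation rotation (degrees) on the current trial; vectorized.
#' @param hand measured hand angle (degrees) on the current trial.
#' @param params a [piece_params()] object.
#' @param mode `"deterministic"` (mean response) or `"stochastic"`
#'   (sampled response; requires `seed`).
#' @param feedback `"full"` or `"none"`, vectorized.
#' @param seed integer seed, required in stochastic mode for
#'   reproducibility.
#' @return next-trial hand angle(s) in degrees.
#' @export
piece_predict <- function(rotation, hand, params,
                          mode = c("deterministic", "stochastic"),
                          feedback = "full", seed = NULL) {
  mode <- match.arg(mode)
  n <- max(length(rotation), length(hand))
  rotation <- rep_len(rotation, n)
  hand <- rep_len(hand, n)
  feedback <- rep_len(feedback, n)
  if (mode == "deterministic")
    return(predict_trial(params, rotation, hand, feedback = feedback))
  if (is.null(seed))
    stop("stochastic mode requires an explicit 'seed'", call. = FALSE)
  set.seed(as.integer(seed))
  e <- abs(hand + rotation)
  sigma_v <- params$alpha + params$beta * e
  x_v <- stats::rnorm(n, hand + rotation, sigma_v)
  x_c <- stats::rnorm(n, hand, params$sigma_combined)
  z <- stats::rnorm(n, rotation, sigma_v)
  post <- causal_posterior(cue_set(x_v = x_v, x_c = x_c, sigma_v = sigma_v),
                           params)
  r_hat <- post$p_pert * kalman_gain(sigma_v, params$sigma_r) * z
  mu <- params$bias - r_hat
  mu[feedback == "none"] <- params$bias
  mu + stats::rnorm(n, 0, params$sigma_h)
}

#' Mean causal posterior as a function of rotation size
#'
#' Simulates the observer over a protocol, records the posterior belief in a
#' perturbation on every measured trial, and aggregates it by rotation
#' level. With zero bias the curve is symmetric in the rotation sign, and
#' the belief is strictly positive even at a rotation of zero: some
#' credence goes to the perturbed hypothesis on unperturbed trials.
#'
#' @param params a [piece_params()] object.
#' @param protocol a protocol from [build_protocol()].
#' @param seed integer seed.
#' @param cue_mode `"stochastic"` (sampled cues; default) or
#'   `"deterministic"`.
#' @return a data frame with `rotation_deg`, `mean_p_pert`, `n`.
#' @export
posterior_curve <- function(params, protocol, seed,
                            cue_mode = c("stochastic", "deterministic")) {
  cue_mode <- match.arg(cue_mode)
  stopifnot(inherits(params, "piece_params"))
  trials <- simulate_participant(params, protocol, seed = seed,
                                 cue_mode = cue_mode)
  meas <- trials[trials$trial_type == "measured", ]
  agg <- stats::aggregate(meas$p_pert, by = list(rotation_deg = meas$rotation_deg),
                          FUN = mean)
  names(agg)[2] <- "mean_p_pert"
  agg$n <- as.vector(table(meas$rotation_deg)[as.character(agg$rotation_deg)])
  agg
}

#' Deterministic adaptation as a function of rotation size
#'
#' Evaluates the mean single-trial adaptive response `-r_hat(r)` over a grid
#' of rotations, with the hand at the bias. Because the learning rate falls
#' as visual uncertainty grows with error size, the response saturates (and
#' for suitable `sigma_r`/`beta` becomes non-monotonic) at large rotations.
#'
#' @param params a [piece_params()] object.
#' @param rotations numeric vector of rotations (degrees).
#' @return a data frame with `rotation_deg` and `adaptation` (degrees).
#' @export
sensitivity_sweep <- function(params, rotations) {
  if (any(!is.finite(rotations)))
    stop("'rotations' must be finite", call. = FALSE)
  mech <- piece_machinery(params, rotations, rep(params$bias,
                                                 length(rotations)))
  data.frame(rotation_deg = rotations, adaptation = -mech$r_hat)
}
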