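#' Single-trial prediction interface shared by all models
#'
#' Every model exposes the same contract: given the rotation and the
#' measured hand angle on the current trial, return the mean reach angle on
#' the next trial. This is the prediction the likelihood is evaluated on and
#' the update rule the simulator applies after each measured trial.
#'
#' @param params an `adapt_params` object; dispatch selects the model.
#' @param rotation rotation (degrees) on the current trial; vectorized.
#' @param hand measured hand angle (degrees) on the current trial.
#' @param ... further arguments (e.g. `feedback`) passed to methods.
#' @return mean next-trial hand angle(s) in degrees.
#' @export
predict_trial <- function(params, rotation, hand, ...) {
  UseMethod("predict_trial")
}

#' Predict a trial under a model chosen by name
#'
#' Convenience wrapper around [predict_trial()] that checks the parameter
#' object matches the requested model.
#'
#' @param model one of `"piece"`, `"premo"`, `"pea"`, `"rem"`.
#' @param rotation,hand as in [predict_trial()].
#' @param params matching `adapt_params` object.
#' @return mean next-trial hand angle(s) in degrees.
#' @export
model_predict <- function(model, rotation, hand, params) {
  model <- match.arg(model, c("piece", "premo", "pea", "rem"))
  if (!identical(params$model, model))
    stop(sprintf("parameter object is for model '%s', not '%s'",
                 params$model, model), call. = FALSE)
  predict_trial(params, rotation, hand)
}

# smooth saturating shift: odd, slope 1 at 0, bounded by +/- s
sat_shift <- function(x, s) s * tanh(x / s)

#' Proprioceptive re-alignment prediction
#'
#' The seen cursor is drawn toward the felt hand and the felt hand toward
#' the seen cursor, both through saturating shifts; adaptation then reduces
#' the saturated error between the perceived hand and the target. The
#' perceived hand contains the actual hand position, so the prediction is a
#' function of the total cursor error and responds to internally generated
#' error even when the rotation is zero.
#'
#' @param rotation,hand current-trial rotation and hand angle (degrees).
#' @param params a [premo_params()] object.
#' @return mean next-trial hand angle(s) in degrees.
#' @export
premo_predict <- function(rotation, hand, params) {
  if (!inherits(params, "premo_params"))
    stop("'params' must be a premo_params object", call. = FALSE)
  predict_trial(params, rotation, hand)
}

#' @export
predict_trial.premo_params <- function(params, rotation, hand,
                                       feedback = "full", ...) {
  n <- max(length(rotation), length(hand))
  rotation <- rep_len(rotation, n)
  hand <- rep_len(hand, n)
  cursor <- hand + rotation
  v_hat <- cursor + params$beta_v * sat_shift(hand - cursor, params$shift_sat)
  p_hat <- hand + params$beta_p * sat_shift(v_hat - hand, params$shift_sat)
  mu <- params$bias - params$eta * sat_shift(p_hat, params$err_sat)
  if (!identical(feedback, "full"))
    mu[rep_len(feedback, n) == "none"] <- params$bias
  mu
}

#' Perceptual-error adaptation prediction
#'
#' The perceived hand is the precision-weighted fusion of the visual cursor,
#' the proprioceptive cue (centred on the actual hand) and a motor
#' prediction centred on the target; adaptation is proportional to the
#' perceived hand error. Responds to internally generated error through the
#' visual and proprioceptive cues.
#'
#' @inheritParams premo_predict
#' @param params a [pea_params()] object.
#' @return mean next-trial hand angle(s) in degrees.
#' @export
pea_predict <- function(rotation, hand, params) {
  if (!inherits(params, "pea_params"))
    stop("'params' must be a pea_params object", call. = FALSE)
  predict_trial(params, rotation, hand)
}

#' @export
predict_trial.pea_params <- function(params, rotation, hand,
                                     feedback = "full", ...) {
  n <- max(length(rotation), length(hand))
  rotation <- rep_len(rotation, n)
  hand <- rep_len(hand, n)
  cursor <- hand + rotation
  sigma_v <- params$alpha + params$beta * abs(cursor)
  w_v <- 1 / sigma_v^2
  w_p <- 1 / params$sigma_p^2
  w_u <- 1 / params$sigma_u^2
  x_hat <- (w_v * cursor + w_p * hand) / (w_v + w_p + w_u)
  mu <- params$bias - params$eta * x_hat
  if (!identical(feedback, "full"))
    mu[rep_len(feedback, n) == "none"] <- params$bias
  mu
}

#' Relevance-estimation prediction
#'
#' The cursor-to-target error is weighted by the posterior probability that
#' it is relevant to the hand (narrow zero-centred source) rather than
#' irrelevant (broad source), and a fraction of the weighted error is
#' corrected. The relevance weight declines monotonically for large,
#' implausible errors.
#'
#' @inheritParams premo_predict
#' @param params a [rem_params()] object.
#' @return mean next-trial hand angle(s) in degrees.
#' @export
rem_predict <- function(rotation, hand, params) {
  if (!inherits(params, "rem_params"))
    stop("'params' must be a rem_params object", call. = FALSE)
  predict_trial(params, rotation, hand)
}

#' @export
predict_trial.rem_params <- function(params, rotation, hand,
                                     feedback = "full", ...) {
  n <- max(length(rotation), length(hand))
  rotation <- rep_len(rotation, n)
  hand <- rep_len(hand, n)
  err <- hand + rotation
  w <- rem_relevance(err, params)
  mu <- params$bias - params$eta * w * err
  if (!identical(feedback, "full"))
    mu[rep_len(feedback, n) == "none"] <- params$bias
  mu
}

# posterior relevance weight, computed in log space
rem_relevance <- function(err, params) {
  lr <- log(params$p_rel) + stats::dnorm(err, 0, params$sigma_rel, log = TRUE)
  li <- log1p(-params$p_rel) + stats::dnorm(err, 0, params$sigma_irr,
                                            log = TRUE)
  1 / (1 + exp(li - lr))
}

#' Simulate a synthetic participant from any model
#'
#' Shared simulation harness: sequential trial-by-trial simulation of a
#' protocol with response noise `N(0, sigma_h^2)`, reproducible given the
#' seed. Equivalent to [simulate_participant()]; provided under this name
#' for symmetry with the rival-model interface.
#'
#' @param model one of `"piece"`, `"premo"`, `"pea"`, `"rem"`.
#' @param params matching `adapt_params` object.
#' @param protocol a protocol from [build_protocol()].
#' @param seed integer seed (required).
#' @param ... passed to [simulate_participant()].
#' @return a trial table (data frame), one row per trial.
#' @export
rival_simulate <- function(model, params, protocol, seed, ...) {
  model <- match.arg(model, c("piece", "premo", "pea", "rem"))
  if (!identical(params$model, model))
    stop(sprintf("parameter object is for model '%s', not '%s'",
                 params$model, model), call. = FALSE)
  simulate_participant(params, protocol, seed = seed, ...)
}
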