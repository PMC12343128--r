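#' Parameters of the Bayesian error-parsing observer
#'
#' Constructs the parameter set of the causal-inference observer used
#' throughout the package. The observer receives a visual cue of the cursor,
#' a combined internal cue (proprioception fused with the motor prediction,
#' both centred on the true hand position), infers whether the feedback was
#' perturbed, and corrects for a precision-weighted estimate of the
#' perturbation. All angles are in degrees, counter-clockwise positive, with
#' the target at 0.
#'
#' The three free parameters in fitting are `sigma_r`, `sigma_combined` and
#' `bias`; `sigma_h` is fixed from baseline reaches (see [baseline_sigma()]),
#' and `alpha`/`beta` are fixed configuration inputs. The shipped
#' `alpha`/`beta` defaults are documented placeholders for the visual
#' uncertainty function, not empirical estimates; substitute task-appropriate
#' values when fitting real data.
#'
#' @param sigma_r prior SD (degrees) on the rotation magnitude; the range of
#'   perturbation sizes the observer believes plausible.
#' @param sigma_combined SD (degrees) of the fused proprioceptive +
#'   motor-prediction cue.
#' @param bias intrinsic reach bias `b` (degrees).
#' @param sigma_h intrinsic motor variability (degrees); also the SD of the
#'   observer's prior on hand position. Fixed, not a free parameter.
#' @param alpha,beta intercept (degrees) and slope (dimensionless) of the
#'   visual uncertainty function `sigma_v = alpha + beta * e`, where `e` is
#'   the absolute cursor-to-target error.
#' @param p_pert_prior prior probability that a trial is perturbed; the task
#'   statistics are symmetric so the default is flat (0.5).
#' @return an object of class `c("piece_params", "adapt_params")`.
#' @seealso [premo_params()], [pea_params()], [rem_params()],
#'   [predict_trial()], [fit_adaptation()]
#' @examples
#' p <- piece_params(sigma_r = 4, sigma_combined = 0.7, bias = 0.5)
#' predict_trial(p, rotation = c(-4, 0, 4), hand = c(0.5, 0.5, 0.5))
#' @export
piece_params <- function(sigma_r = 4, sigma_combined = 0.7, bias = 0.5,
                         sigma_h = 2, alpha = 1, beta = 0.3,
                         p_pert_prior = 0.5) {
  check_positive(sigma_r = sigma_r, sigma_combined = sigma_combined)
  check_nonneg(sigma_h = sigma_h)
  check_number(bias = bias, alpha = alpha, beta = beta)
  if (alpha < 0 || beta < 0)
    stop("'alpha' and 'beta' must be non-negative", call. = FALSE)
  if (alpha <= 0 && beta <= 0)
    stop("at least one of 'alpha', 'beta' must be positive", call. = FALSE)
  if (!is.numeric(p_pert_prior) || p_pert_prior <= 0 || p_pert_prior >= 1)
    stop("'p_pert_prior' must lie strictly within (0, 1)", call. = FALSE)
  structure(
    list(model = "piece", sigma_r = sigma_r, sigma_combined = sigma_combined,
         bias = bias, sigma_h = sigma_h, alpha = alpha, beta = beta,
         p_pert_prior = p_pert_prior),
    class = c("piece_params", "adapt_params"))
}

#' Parameters of the proprioceptive re-alignment model
#'
#' Single-trial form of the proprioceptive re-alignment account of implicit
#' adaptation: cross-sensory recalibration shifts the seen cursor toward the
#' felt hand and the felt hand toward the seen cursor (both shifts saturate),
#' and adaptation drives the perceived hand back to the target. Because the
#' perceived hand contains the actual hand position, the model responds to
#' internally generated error. Six free parameters.
#'
#' @param eta adaptation rate (dimensionless).
#' @param beta_v rate of the visual shift toward the felt hand, in `[0, 1]`.
#' @param beta_p rate of the proprioceptive shift toward the seen cursor,
#'   in `[0, 1]`.
#' @param shift_sat saturation (degrees) of the cross-sensory shifts.
#' @param err_sat saturation (degrees) of the perceptual error that drives
#'   adaptation.
#' @param bias intrinsic reach bias (degrees).
#' @param sigma_h fixed motor variability (degrees), as in [piece_params()].
#' @return an object of class `c("premo_params", "adapt_params")`.
#' @export
premo_params <- function(eta = 0.9, beta_v = 0.1, beta_p = 0.9,
                         shift_sat = 3, err_sat = 3, bias = 0.5,
                         sigma_h = 2) {
  check_positive(shift_sat = shift_sat, err_sat = err_sat)
  check_nonneg(sigma_h = sigma_h)
  check_number(eta = eta, beta_v = beta_v, beta_p = beta_p, bias = bias)
  if (eta < 0) stop("'eta' must be non-negative", call. = FALSE)
  if (beta_v < 0 || beta_v > 1 || beta_p < 0 || beta_p > 1)
    stop("'beta_v' and 'beta_p' must lie in [0, 1]", call. = FALSE)
  structure(
    list(model = "premo", eta = eta, beta_v = beta_v, beta_p = beta_p,
         shift_sat = shift_sat, err_sat = err_sat, bias = bias,
         sigma_h = sigma_h),
    class = c("premo_params", "adapt_params"))
}

#' Parameters of the perceptual-error adaptation model
#'
#' Single-trial form of the perceptual-error account: the perceived hand
#' position is the precision-weighted fusion of the visual cursor (whose
#' uncertainty grows linearly with cursor-to-target error, sharing
#' `alpha`/`beta` with [piece_params()]), the proprioceptive cue centred on
#' the actual hand, and a motor prediction centred on the target. Adaptation
#' is proportional to the perceived hand error. Three free parameters
#' (`eta`, `sigma_p`, `sigma_u`); the reach bias is fixed from baseline, as
#' `sigma_h` is.
#'
#' @param eta adaptation rate (dimensionless).
#' @param sigma_p SD (degrees) of the proprioceptive cue.
#' @param sigma_u SD (degrees) of the motor prediction centred on the target.
#' @param bias fixed reach bias (degrees), estimated from baseline reaches.
#' @param sigma_h fixed motor variability (degrees).
#' @param alpha,beta visual uncertainty function, shared with
#'   [piece_params()].
#' @return an object of class `c("pea_params", "adapt_params")`.
#' @export
pea_params <- function(eta = 1, sigma_p = 2, sigma_u = 5, bias = 0.5,
                       sigma_h = 2, alpha = 1, beta = 0.3) {
  check_positive(sigma_p = sigma_p, sigma_u = sigma_u)
  check_nonneg(sigma_h = sigma_h)
  check_number(eta = eta, bias = bias, alpha = alpha, beta = beta)
  if (eta < 0) stop("'eta' must be non-negative", call. = FALSE)
  if (alpha < 0 || beta < 0)
    stop("'alpha' and 'beta' must be non-negative", call. = FALSE)
  structure(
    list(model = "pea", eta = eta, sigma_p = sigma_p, sigma_u = sigma_u,
         bias = bias, sigma_h = sigma_h, alpha = alpha, beta = beta),
    class = c("pea_params", "adapt_params"))
}

#' Parameters of the relevance-estimation model
#'
#' Single-trial form of the relevance-estimation account: the cursor error is
#' judged either relevant to the hand (drawn from a narrow zero-centred
#' distribution reflecting normal motor variability) or irrelevant (a broad
#' distribution), and adaptation corrects a fraction of the error weighted by
#' the posterior relevance. The error signal is the cursor-to-target error,
#' so the model responds to internally generated error. Four free parameters
#' (`eta`, `sigma_rel`, `p_rel`, `bias`); the irrelevant-source SD is fixed.
#'
#' @param eta adaptation rate (dimensionless).
#' @param sigma_rel SD (degrees) of errors deemed relevant.
#' @param p_rel prior probability that an error is relevant, in `(0, 1)`.
#' @param bias intrinsic reach bias (degrees).
#' @param sigma_irr fixed SD (degrees) of the irrelevant error source.
#' @param sigma_h fixed motor variability (degrees).
#' @return an object of class `c("rem_params", "adapt_params")`.
#' @export
rem_params <- function(eta = 0.6, sigma_rel = 2, p_rel = 0.8, bias = 0.5,
                       sigma_irr = 30, sigma_h = 2) {
  check_positive(sigma_rel = sigma_rel, sigma_irr = sigma_irr)
  check_nonneg(sigma_h = sigma_h)
  check_number(eta = eta, bias = bias)
  if (eta < 0) stop("'eta' must be non-negative", call. = FALSE)
  if (!is.numeric(p_rel) || p_rel <= 0 || p_rel >= 1)
    stop("'p_rel' must lie strictly within (0, 1)", call. = FALSE)
  structure(
    list(model = "rem", eta = eta, sigma_rel = sigma_rel, p_rel = p_rel,
         bias = bias, sigma_irr = sigma_irr, sigma_h = sigma_h),
    class = c("rem_params", "adapt_params"))
}

#' Default parameter sets by model name
#'
#' Returns the package's documented default parameter object for a model.
#' These defaults are the study conditions used by the simulation examples
#' and the recovery harnesses; see the methods vignette for the rationale
#' behind each value.
#'
#' @param model one of `"piece"`, `"premo"`, `"pea"`, `"rem"`.
#' @param ... overrides passed to the model's constructor.
#' @return an `adapt_params` object.
#' @export
default_params <- function(model = c("piece", "premo", "pea", "rem"), ...) {
  model <- match.arg(model)
  switch(model,
         piece = piece_params(...),
         premo = premo_params(...),
         pea = pea_params(...),
         rem = rem_params(...))
}

#' @export
print.adapt_params <- function(x, ...) {
  cat(sprintf("<%s parameters>\n", model_label(x$model)))
  vals <- unlist(x[setdiff(names(x), "model")])
  print(round(vals, 4))
  info <- free_param_info(x)
  cat("free parameters:", paste(info$name, collapse = ", "), "\n")
  invisible(x)
}

model_label <- function(model) {
  switch(model,
         piece = "causal-inference error-parsing observer (PIECE)",
         premo = "proprioceptive re-alignment model (PReMo)",
         pea   = "perceptual-error adaptation model (PEA)",
         rem   = "relevance estimation model (REM)",
         model)
}

# --- free-parameter bookkeeping used by the fitter -------------------------

#' Free parameters and default fitting bounds of a model
#'
#' @param params an `adapt_params` object.
#' @return a data frame with columns `name`, `lower`, `upper`, one row per
#'   free parameter, in the order the fitter uses.
#' @export
free_param_info <- function(params) UseMethod("free_param_info")

#' @export
free_param_info.piece_params <- function(params) {
  data.frame(name = c("sigma_r", "sigma_combined", "bias"),
             lower = c(0.1, 0.01, -10), upper = c(50, 20, 10))
}

#' @export
free_param_info.premo_params <- function(params) {
  data.frame(name = c("eta", "beta_v", "beta_p", "shift_sat", "err_sat",
                      "bias"),
             lower = c(0, 0, 0, 0.5, 0.5, -10),
             upper = c(2, 1, 1, 30, 30, 10))
}

#' @export
free_param_info.pea_params <- function(params) {
  data.frame(name = c("eta", "sigma_p", "sigma_u"),
             lower = c(0, 0.01, 0.01), upper = c(2, 20, 20))
}

#' @export
free_param_info.rem_params <- function(params) {
  data.frame(name = c("eta", "sigma_rel", "p_rel", "bias"),
             lower = c(0, 0.1, 0.01, -10), upper = c(2, 50, 0.99, 10))
}

# replace free parameters by a named or positional numeric vector
set_free_params <- function(params, theta) {
  info <- free_param_info(params)
  if (is.null(names(theta))) names(theta) <- info$name
  params[names(theta)] <- as.list(unname(theta))
  params
}

# --- input checking helpers ------------------------------------------------

check_positive <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm),
           call. = FALSE)
  }
  invisible(TRUE)
}

check_nonneg <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("'%s' must be a single non-negative finite number", nm),
           call. = FALSE)
  }
  invisible(TRUE)
}

check_number <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
  }
  invisible(TRUE)
}
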