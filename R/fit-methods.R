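#' @export
print.adapt_fit <- function(x, ...) {
  cat(sprintf("Maximum-likelihood fit: %s\n", model_label(x$model)))
  cat(sprintf("participant %s, %d triplets\n", x$participant_id, x$n))
  cat("\nCoefficients:\n")
  print(round(x$coefficients, 4))
  cat(sprintf("\nnll = %.3f, k = %d, BIC = %.2f\n", x$nll, x$k, x$bic))
  invisible(x)
}

#' Extract fitted model coefficients
#'
#' @param object an `adapt_fit` object.
#' @param ... unused.
#' @return named numeric vector of maximum-likelihood estimates.
#' @export
coef.adapt_fit <- function(object, ...) object$coefficients

#' @export
logLik.adapt_fit <- function(object, ...) {
  structure(-object$nll, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
summary.adapt_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               Lower = object$bounds$lower, Upper = object$bounds$upper)
  structure(list(fit = object, coef_table = tab),
            class = "summary.adapt_fit")
}

#' @export
print.summary.adapt_fit <- function(x, ...) {
  f <- x$fit
  cat(sprintf("Maximum-likelihood fit: %s\n", model_label(f$model)))
  cat(sprintf("participant %s, %d triplets, %d/%d starts converged (best: %d)\n",
              f$participant_id, f$n, f$n_converged, f$n_starts,
              f$best_start))
  cat("\nCoefficients (with fitting box):\n")
  print(round(x$coef_table, 4))
  cat(sprintf("\nFixed: sigma_h = %.3f", f$fixed$sigma_h))
  if (f$model == "pea") cat(sprintf(", bias = %.3f", f$fixed$bias0))
  if (f$model %in% c("piece", "pea"))
    cat(sprintf(", alpha = %.2f, beta = %.2f", f$fixed$alpha, f$fixed$beta))
  cat(sprintf("\nnll = %.3f, BIC = %.2f (k = %d, n = %d)\n",
              f$nll, f$bic, f$k, f$n))
  invisible(x)
}

#' Predicted single-trial responses from a fitted model
#'
#' @param object an `adapt_fit` object.
#' @param newdata optional data frame with columns `rotation_deg` and
#'   `hand_angle_deg`; by default the fitted triplets are used.
#' @param ... unused.
#' @return mean next-trial hand angles in degrees.
#' @export
predict.adapt_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    return(predict_trial(object$params, object$triplets$EGE,
                         object$triplets$IGE))
  predict_trial(object$params, newdata$rotation_deg, newdata$hand_angle_deg)
}

#' @export
residuals.adapt_fit <- function(object, ...) {
  object$hand_next - predict.adapt_fit(object)
}

#' Simulate trial tables from a fitted model
#'
#' @param object an `adapt_fit` object.
#' @param nsim number of simulated participants.
#' @param seed integer seed (required).
#' @param protocol optional protocol; defaults to the fitted schedule.
#' @param ... unused.
#' @return a list of `nsim` trial tables.
#' @export
simulate.adapt_fit <- function(object, nsim = 1, seed = NULL,
                               protocol = NULL, ...) {
  if (is.null(seed)) stop("'seed' is required", call. = FALSE)
  if (is.null(protocol)) {
    protocol <- object$trials[order(object$trials$trial_index),
                              c("trial_index", "block", "phase",
                                "trial_type", "rotation_deg", "feedback")]
  }
  set.seed(as.integer(seed))
  seeds <- sample.int(2^31 - 1, nsim)
  lapply(seq_len(nsim), function(i)
    simulate_participant(object$params, protocol, seed = seeds[i],
                         participant_id = sprintf("%s_sim%02d",
                                                  object$participant_id, i)))
}

#' Diagnostic plot of a fitted model
#'
#' Two panels: single-trial adaptation against EGE and against IGE, with
#' the fitted model's predicted adaptation overlaid.
#'
#' @param x an `adapt_fit` object.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.adapt_fit <- function(x, ...) {
  tp <- x$triplets
  pred <- predict.adapt_fit(x) - x$params$bias
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(tp$EGE, tp$adaptation, pch = 16,
                 col = grDevices::adjustcolor("grey40", 0.4),
                 xlab = "EGE (deg)", ylab = "adaptation (deg)", ...)
  o <- order(tp$EGE)
  graphics::lines(stats::lowess(tp$EGE[o], pred[o]), col = "red3", lwd = 2)
  graphics::plot(tp$IGE, tp$adaptation, pch = 16,
                 col = grDevices::adjustcolor("grey40", 0.4),
                 xlab = "IGE (deg)", ylab = "adaptation (deg)", ...)
  o <- order(tp$IGE)
  graphics::lines(stats::lowess(tp$IGE[o], pred[o]), col = "red3", lwd = 2)
  invisible(x)
}
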