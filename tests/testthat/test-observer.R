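test_that("visual uncertainty is linear in target error and rejects negative error", {
  p <- piece_params(alpha = 1, beta = 0.5)
  expect_equal(visual_uncertainty(0, p), 1)
  expect_equal(visual_uncertainty(4, p), 3)
  e <- seq(0, 50, by = 0.5)
  expect_true(all(diff(visual_uncertainty(e, p)) >= 0))
  expect_error(visual_uncertainty(-0.1, p), "non-negative")
})

test_that("closed-form cue marginals match quadrature and obey symmetries", {
  p <- piece_params(sigma_r = 3, sigma_combined = 0.8, bias = 0.7,
                    sigma_h = 2)
  cues <- cue_set(x_v = c(1.5, -3, 6), x_c = c(0.4, -1, 0.2), sigma_v = 1.8)
  got <- marginal_likelihoods(cues, p)
  for (i in seq_along(cues$x_v)) {
    want <- quad_marginals(cues$x_v[i], cues$x_c[i], 1.8, p)
    expect_equal(got$nopert[i], want[["nopert"]], tolerance = 1e-8)
    expect_equal(got$pert[i], want[["pert"]], tolerance = 1e-8)
  }
  # reflecting the cues about the bias leaves both densities unchanged
  refl <- marginal_likelihoods(
    cue_set(x_v = 2 * p$bias - cues$x_v, x_c = 2 * p$bias - cues$x_c,
            sigma_v = 1.8), p)
  expect_equal(refl$nopert, got$nopert, tolerance = 1e-12)
  expect_equal(refl$pert, got$pert, tolerance = 1e-12)
  # a vanishing rotation prior collapses the perturbed onto the unperturbed
  p0 <- piece_params(sigma_r = 1e-8, sigma_combined = 0.8, bias = 0.7,
                     sigma_h = 2)
  m0 <- marginal_likelihoods(cues, p0)
  expect_equal(m0$pert, m0$nopert, tolerance = 1e-10)
})

test_that("causal posterior is normalized, monotone in visual offset, stable at extremes", {
  p <- piece_params(beta = 0)
  # equal evidence under a flat prior: find the visual offset where the two
  # marginals cross (the broader perturbed marginal is lower at the centre)
  dens_gap <- function(xv) {
    m <- marginal_likelihoods(cue_set(x_v = xv, x_c = p$bias, sigma_v = 1), p)
    m$pert - m$nopert
  }
  xv_eq <- uniroot(dens_gap, c(p$bias, p$bias + 20), tol = 1e-12)$root
  expect_equal(causal_posterior(cue_set(x_v = xv_eq, x_c = p$bias,
                                        sigma_v = 1), p)$p_pert, 0.5,
               tolerance = 1e-9)
  # with a degenerate rotation prior the world states are indistinguishable
  pdeg <- piece_params(sigma_r = 1e-9, beta = 0)
  expect_equal(causal_posterior(cue_set(x_v = 1.3, x_c = -0.4,
                                        sigma_v = 1), pdeg)$p_pert, 0.5,
               tolerance = 1e-6)
  # belief in a perturbation grows with the distance of the visual cue
  xv <- p$bias + seq(0, 30, by = 0.25)
  post <- causal_posterior(cue_set(x_v = xv, x_c = p$bias, sigma_v = 1), p)
  expect_true(all(diff(post$p_pert) >= -1e-12))
  expect_true(all(abs(post$p_pert + post$p_nopert - 1) < 1e-12))
  # a huge visual-internal discrepancy makes the perturbation certain,
  # without NaN even at extreme cue values
  far <- causal_posterior(cue_set(x_v = 1e3, x_c = 0, sigma_v = 1), p)
  expect_false(is.nan(far$p_pert))
  expect_gt(far$p_pert, 1 - 1e-6)
})

test_that("learning-rate gain has the precision-weighting limits and monotonicity", {
  expect_equal(kalman_gain(2, 2), 0.5)
  expect_equal(kalman_gain(2, 1), 0.2)
  expect_equal(kalman_gain(1, 1e8), 1, tolerance = 1e-12)
  sv <- seq(0.2, 10, by = 0.2)
  expect_true(all(diff(kalman_gain(sv, 3)) < 0))
  sr <- seq(0.2, 10, by = 0.2)
  expect_true(all(diff(kalman_gain(3, sr)) > 0))
  g <- kalman_gain(runif(50, 0.1, 20), runif(50, 0.1, 20))
  expect_true(all(g > 0 & g < 1))
  expect_error(kalman_gain(0, 1), "positive")
})

test_that("state estimate weights the observation by belief and gain", {
  expect_equal(estimate_perturbation(4, 0.5, list(p_pert = 0.5))$r_hat, 1)
  expect_equal(estimate_perturbation(7, 0.9, 0)$r_hat, 0)
  z <- runif(30, -10, 10)
  r_hat <- estimate_perturbation(z, 0.7, runif(30))$r_hat
  expect_true(all(sign(r_hat) == sign(z) | r_hat == 0))
})

test_that("deterministic response is bias at zero observation and antisymmetric", {
  p <- piece_params()
  expect_equal(piece_predict(0, p$bias, p), p$bias)
  # rotation-free trials never produce adaptation, whatever the hand did
  hand <- seq(-6, 6, by = 0.5)
  expect_equal(piece_predict(rep(0, length(hand)), hand, p),
               rep(p$bias, length(hand)))
  # with zero bias the generative model is odd in (rotation, hand)
  p0 <- piece_params(bias = 0)
  r <- c(-4, -2, 2, 4); h <- c(1.3, -0.4, 2.2, -3)
  expect_equal(piece_predict(r, h, p0), -piece_predict(-r, -h, p0),
               tolerance = 1e-12)
  # with nearly constant visual uncertainty, bigger rotations adapt more
  ps <- piece_params(beta = 0.02)
  a2 <- abs(piece_predict(2, ps$bias, ps) - ps$bias)
  a4 <- abs(piece_predict(4, ps$bias, ps) - ps$bias)
  expect_gt(a4, a2)
  # feedback-absent trials carry no update
  expect_equal(piece_predict(4, 2, p, feedback = "none"), p$bias)
})

test_that("stochastic mode needs a seed and is bit-reproducible", {
  p <- piece_params()
  expect_error(piece_predict(4, 0, p, mode = "stochastic"), "seed")
  a <- piece_predict(rep(2, 10), 0, p, mode = "stochastic", seed = 7)
  b <- piece_predict(rep(2, 10), 0, p, mode = "stochastic", seed = 7)
  expect_identical(a, b)
  expect_gt(stats::sd(a), 0)
})

test_that("posterior curve rises with rotation size and is positive at zero", {
  prot <- small_protocol(3)
  p0 <- piece_params(bias = 0)
  curve <- posterior_curve(p0, prot, seed = 11)
  at <- function(r) curve$mean_p_pert[curve$rotation_deg == r]
  expect_gte(at(4), at(0))
  expect_gte(at(-4), at(0))
  expect_gt(at(0), 0)      # residual belief in a perturbation on null trials
  expect_lt(abs(at(2) - at(-2)), 0.1)   # symmetry up to Monte-Carlo error
})

test_that("adaptation saturates for large rotations when visual noise grows fast", {
  p0 <- piece_params(bias = 0)
  sweep0 <- sensitivity_sweep(p0, c(-40, -4, 0, 4, 40))
  expect_equal(sweep0$adaptation[sweep0$rotation_deg == 0], 0)
  expect_equal(sweep0$adaptation, -rev(sweep0$adaptation))  # odd function
  pbig <- piece_params(bias = 0, beta = 1)
  sw <- sensitivity_sweep(pbig, c(4, 40))
  expect_lt(abs(sw$adaptation[2]), 10 * abs(sw$adaptation[1]))
})
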