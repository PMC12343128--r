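test_that("the likelihood reduces to the Gaussian normalizer at its mode", {
  # baseline alternates so sigma_h is exactly 1; every response sits on the
  # inert model's prediction (the bias, 0)
  tab <- manual_trials(0)
  inert <- rem_params(eta = 0, bias = 0, sigma_rel = 2)
  n <- nrow(extract_triplets(tab))
  expect_equal(negative_log_likelihood(inert, tab), n * 0.5 * log(2 * pi),
               tolerance = 1e-10)
})

test_that("the likelihood matches direct density summation on noisy data", {
  sim <- small_participant("rem", seed = 31)
  par <- rem_params(eta = 0.4, sigma_rel = 3, p_rel = 0.7, bias = 0.2)
  got <- negative_log_likelihood(par, sim)
  # independent oracle: walk the table and sum Gaussian log-densities
  tr <- exclude_outliers(sim)
  tp <- extract_triplets(tr)
  tr <- tr[order(tr$trial_index), ]
  pos <- match(tp$center_index, tr$trial_index)
  par$sigma_h <- baseline_sigma(sim)
  want <- 0
  for (k in seq_len(nrow(tp))) {
    mu <- rem_predict(tp$EGE[k], tp$IGE[k], par)
    want <- want - dnorm(tr$hand_angle_deg[pos[k] + 1], mu, par$sigma_h,
                         log = TRUE)
  }
  expect_equal(got, want, tolerance = 1e-10)
  # the adaptation-target variant uses the widened SD, sqrt(2) * sigma_h
  got_a <- negative_log_likelihood(par, sim, likelihood = "adaptation")
  want_a <- 0
  for (k in seq_len(nrow(tp))) {
    mu <- rem_predict(tp$EGE[k], tp$IGE[k], par) - par$bias
    want_a <- want_a - dnorm(tp$adaptation[k], mu, sqrt(2) * par$sigma_h,
                             log = TRUE)
  }
  expect_equal(got_a, want_a, tolerance = 1e-10)
})

test_that("profile likelihood centres the bias on the observed responses", {
  # without rotations the observer predicts its bias on every trial, so the
  # MLE of the bias is the mean of the scored responses
  quiet <- build_protocol(seed = 9, n_blocks = 4, rotations = 0,
                          trials_per_level = 120)
  sim <- simulate_participant(piece_params(bias = 1), quiet, seed = 14)
  fit <- fit_adaptation(sim, "piece", n_starts = 6, seed = 3)
  tp <- fit$triplets
  expect_lt(abs(coef(fit)[["bias"]] - mean(fit$hand_next)), 0.02)
})

test_that("fitting is deterministic, self-consistent, and respects wider boxes", {
  sim <- small_participant("piece", seed = 41)
  f1 <- fit_adaptation(sim, "piece", n_starts = 8, seed = 5)
  f2 <- fit_adaptation(sim, "piece", n_starts = 8, seed = 5)
  expect_identical(coef(f1), coef(f2))
  expect_true(f1$converged)
  # evaluating the likelihood at the reported MLE reproduces the nll
  expect_equal(negative_log_likelihood(f1$params, sim), f1$nll,
               tolerance = 1e-8)
  # a narrower feasible box can never beat the wider one it sits inside
  narrow <- data.frame(name = "sigma_r", lower = 0.5, upper = 3)
  fn <- fit_adaptation(sim, "piece", n_starts = 8, seed = 5, bounds = narrow)
  expect_lte(f1$nll, fn$nll + 1e-6)
  expect_error(fit_adaptation(sim, "piece", seed = 1,
                              bounds = data.frame(name = "sigma_r",
                                                  lower = 5, upper = 2)),
               "bounds")
})

test_that("BIC bookkeeping follows k log(n) + 2 nll and benchmarks to the reference", {
  sim <- small_participant("piece", seed = 51)
  f <- fit_adaptation(sim, "piece", n_starts = 4, seed = 7)
  expect_equal(f$bic, f$k * log(f$n) + 2 * f$nll, tolerance = 1e-9)
  expect_equal(BIC(f), f$bic, tolerance = 1e-9)
  expect_equal(f$k, 3)

  fake <- function(model, nll, k, n = 100, pid = "X") {
    structure(list(model = model, participant_id = pid, nll = nll,
                   k = k, n = n, bic = k * log(n) + 2 * nll),
              class = "adapt_fit")
  }
  # equal evidence and complexity: all deltas vanish
  same <- lapply(c("piece", "premo", "pea", "rem"), fake, nll = 50, k = 3)
  cmp <- bic_compare(same)
  expect_true(all(cmp$table$delta_bic == 0))
  expect_equal(fake("m", 50, 3)$bic, 3 * log(100) + 100, tolerance = 1e-4)
  # a missing model is an error
  expect_error(bic_compare(same[1:3]), NA)
  expect_error(bic_compare(c(same, list(fake("piece", 10, 3, pid = "Y")))),
               "missing")
})

test_that("free-parameter counts match the model classes", {
  expect_equal(nrow(free_param_info(piece_params())), 3)
  expect_equal(nrow(free_param_info(premo_params())), 6)
  expect_equal(nrow(free_param_info(pea_params())), 3)
  expect_equal(nrow(free_param_info(rem_params())), 4)
})

test_that("fit methods expose coefficients, predictions, residuals, simulation", {
  sim <- small_participant("piece", seed = 61)
  f <- fit_adaptation(sim, "piece", n_starts = 6, seed = 9)
  expect_named(coef(f), c("sigma_r", "sigma_combined", "bias"))
  expect_equal(length(predict(f)), f$n)
  nd <- data.frame(rotation_deg = c(0, 4), hand_angle_deg = c(0, 0))
  pr <- predict(f, nd)
  expect_equal(pr[1], coef(f)[["bias"]])
  expect_equal(residuals(f), f$hand_next - predict(f))
  ll <- logLik(f)
  expect_equal(attr(ll, "df"), 3)
  sims <- simulate(f, nsim = 2, seed = 3)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]]$hand_angle_deg, sims[[2]]$hand_angle_deg))
  expect_output(print(f), "triplets")
  expect_output(print(summary(f)), "starts converged")
})

test_that("posterior predictive checks close the loop and degenerate cleanly", {
  sim <- small_participant("piece", seed = 71)
  f <- fit_adaptation(sim, "piece", n_starts = 6, seed = 11)
  ppc <- posterior_predictive_check(f, seed = 4)
  expect_s3_class(ppc, "adapt_ppc")
  # the refitted observer reproduces the observed EGE sensitivity
  expect_lt(abs(ppc$simulated$ege_coef - ppc$observed$ege_coef), 0.2)
  expect_output(print(ppc), "EGE coef")
  # without motor noise the check is deterministic across seeds
  f0 <- f
  f0$params$sigma_h <- 0
  a <- posterior_predictive_check(f0, seed = 1)
  b <- posterior_predictive_check(f0, seed = 2)
  expect_identical(a$sim_trials$hand_angle_deg, b$sim_trials$hand_angle_deg)
})
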