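test_that("outlier exclusion flags extreme reaches per participant", {
  tab <- manual_trials(0)
  tab$hand_angle_deg[tab$phase == "main"] <- 0
  expect_warning(out <- exclude_outliers(tab[tab$phase == "main", ]),
                 "zero")
  expect_equal(sum(out$excluded), 0)
  # a single wild reach among 99 calm ones is the only trial flagged
  tab2 <- tab[tab$phase == "main", ][1:100, ]
  tab2$hand_angle_deg <- c(rep(0, 50), 100, rep(0, 49)) +
    rep_len(c(0.01, -0.01), 100)            # avoid exact zero variance
  out2 <- exclude_outliers(tab2)
  expect_equal(which(out2$excluded), 51L)
  # on standard normal reaches, the 3.5-SD rule removes almost nothing
  set.seed(42)
  tab3 <- tab2[rep(1, 20000), ]
  tab3$trial_index <- seq_len(20000)
  tab3$hand_angle_deg <- rnorm(20000)
  frac <- mean(exclude_outliers(tab3)$excluded)
  expect_lt(frac, 0.002)
})

test_that("triplets carry EGE, IGE and flanking-null adaptation", {
  prot <- small_protocol(1)
  tab <- manual_trials(0, prot)
  i <- which(tab$trial_type == "measured")[1]
  tab$hand_angle_deg[i - 1] <- 1
  tab$hand_angle_deg[i] <- 0.3
  tab$hand_angle_deg[i + 1] <- -2
  tp <- extract_triplets(tab)
  row <- tp[tp$center_index == tab$trial_index[i], ]
  expect_equal(row$adaptation, -3)
  expect_equal(row$IGE, 0.3)
  expect_equal(row$EGE, tab$rotation_deg[i])
  # equal flanks give zero adaptation
  tab$hand_angle_deg[i + 1] <- 1
  expect_equal(extract_triplets(tab)$adaptation[1], 0)
  # excluding one flank removes exactly that triplet
  tab$excluded[i + 1] <- TRUE
  expect_equal(nrow(extract_triplets(tab)), nrow(tp) - 1)
  # a measured trial without a null neighbour is skipped with a note
  tab2 <- manual_trials(0, prot)
  j <- which(tab2$trial_type == "measured")[2]
  tab2$trial_type[j - 1] <- "measured"
  expect_message(tp2 <- extract_triplets(tab2), "skipped")
  # one extra measured trial appears, but both it and its neighbour lose
  # their null flank, so the net count drops by one
  expect_equal(nrow(tp2), nrow(tp) - 1)
})

test_that("binned regression recovers constructed linear structure exactly", {
  set.seed(3)
  trip <- data.frame(
    participant_id = "A", center_index = 1:500,
    EGE = rep(c(-4, -2, 0, 2, 4), each = 100),
    IGE = rnorm(500, 0, 2))
  trip$adaptation <- -0.6 * trip$EGE
  br <- suppressWarnings(binned_regression(trip))  # noiseless: perfect fit
  expect_equal(br$ege$slope, -0.6, tolerance = 1e-10)
  expect_equal(br$ege$r_squared, 1, tolerance = 1e-10)
  expect_lt(abs(br$ige$slope), 0.05)
  expect_equal(nrow(br$group_bins), 25)
  # constant adaptation: flat slopes, no variance explained
  trip$adaptation <- 1.7
  brc <- suppressWarnings(binned_regression(trip))
  expect_equal(brc$ege$slope, 0, tolerance = 1e-12)
  expect_equal(brc$ige$slope, 0, tolerance = 1e-12)
  expect_equal(brc$ege$r_squared, 0)
  expect_error(binned_regression(trip[1:10, ]), "25")
})

test_that("bivariate regression recovers noiseless coefficients, sign-flipped", {
  set.seed(4)
  trip <- data.frame(
    participant_id = "A", center_index = 1:200,
    EGE = rep(c(-4, -2, 0, 2, 4), each = 40),
    IGE = rnorm(200, 0.5, 2))
  trip$adaptation <- -0.5 * trip$EGE - 0.1 * trip$IGE
  bv <- suppressWarnings(bivariate_regression(trip))
  expect_equal(bv$ege_coef, 0.5, tolerance = 1e-10)
  expect_equal(bv$ige_coef, 0.1, tolerance = 1e-10)
  # permutation invariance
  bv2 <- suppressWarnings(bivariate_regression(trip[sample(nrow(trip)), ]))
  expect_equal(bv2$ege_coef, bv$ege_coef, tolerance = 1e-12)
  expect_equal(bv2$ige_coef, bv$ige_coef, tolerance = 1e-12)
  # collinear predictors are rejected
  trip$IGE <- 2 * trip$EGE
  expect_error(bivariate_regression(trip), "collinear")
})

test_that("regressions agree with a hand-rolled normal-equations oracle", {
  set.seed(5)
  for (rep_i in 1:5) {
    x <- rnorm(40); y <- 0.3 * x + rnorm(40)
    got <- piece:::reg_summary(y, x)
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(got$intercept, beta[1], tolerance = 1e-10)
    expect_equal(got$slope, beta[2], tolerance = 1e-10)
    z <- rnorm(40); y2 <- 0.3 * x - 0.2 * z + rnorm(40)
    trip <- data.frame(participant_id = "A", center_index = 1:40,
                       EGE = x, IGE = z, adaptation = y2)
    bv <- bivariate_regression(trip)
    X2 <- cbind(1, x, z)
    b2 <- solve(t(X2) %*% X2, t(X2) %*% y2)
    expect_equal(c(bv$ege_coef, bv$ige_coef), c(-b2[2], -b2[3]),
                 tolerance = 1e-10)
  }
})

test_that("group statistics test coefficients with guards and bootstrap CIs", {
  coefs <- data.frame(ege_coef = rep(0.6, 5), ige_coef = rep(0.6, 5))
  gs <- suppressWarnings(group_stats(coefs, n_boot = 200, seed = 1))
  expect_equal(gs$paired$estimate, 0)
  expect_equal(gs$paired$p, 1)
  expect_error(group_stats(coefs[1, , drop = FALSE]), "2 participants")

  set.seed(6)
  coefs2 <- data.frame(ege_coef = rnorm(16, 0.6, 0.05),
                       ige_coef = rnorm(16, 0.0, 0.05))
  gs2 <- group_stats(coefs2, n_boot = 2000, seed = 2)
  expect_lt(gs2$paired$p, 0.001)
  expect_true(gs2$ege$ci[1] <= mean(coefs2$ege_coef) &&
                mean(coefs2$ege_coef) <= gs2$ege$ci[2])
  # a strong mean effect is detected at alpha = 0.001 essentially always
  hits <- 0
  for (k in 1:100) {
    x <- rnorm(16, 0.6, 0.05)
    if (stats::t.test(x)$p.value < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 99)
})
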