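# shared fixtures, built in code at test time

# a short protocol: 4 blocks x 100 trials, 30 measured trials per level
small_protocol <- function(seed = 1) {
  build_protocol(seed = seed, n_blocks = 4, trials_per_level = 30)
}

# a single simulated participant on a short protocol
small_participant <- function(model = "piece", seed = 1, ...) {
  simulate_participant(default_params(model, ...), small_protocol(seed),
                       seed = seed + 100)
}

# a hand-built trial table: baseline with exact SD 1 around 0, then a main
# phase whose hand angles can be assigned directly
manual_trials <- function(main_hand, protocol = small_protocol(1)) {
  tab <- as.data.frame(protocol)
  tab$participant_id <- "M01"
  nb <- sum(tab$phase == "baseline")
  a <- sqrt(49 / 50)                      # alternating +/-a has sample SD 1
  tab$hand_angle_deg <- c(rep(c(a, -a), length.out = nb),
                          rep_len(main_hand, nrow(tab) - nb))
  tab$cursor_angle_deg <- ifelse(tab$feedback == "full",
                                 tab$hand_angle_deg + tab$rotation_deg,
                                 NA_real_)
  tab$excluded <- FALSE
  tab
}

# brute-force quadrature oracle for the cue marginals: integrates the
# generative densities over hand position (and rotation) numerically,
# independently of the closed form under test
quad_marginals <- function(x_v, x_c, sigma_v, par) {
  f_h <- function(h, r = 0) {
    stats::dnorm(x_v, h + r, sigma_v) *
      stats::dnorm(x_c, h, par$sigma_combined) *
      stats::dnorm(h, par$bias, par$sigma_h)
  }
  # the h-integrand is a product of Gaussians: its bump lies between the
  # component centres with width at most the narrowest component SD
  h_lim <- function(r) {
    ctr <- c(x_v - r, x_c, par$bias)
    hw <- 14 * min(sigma_v, par$sigma_combined, par$sigma_h) + 0.5
    c(min(ctr) - hw, max(ctr) + hw)
  }
  hl0 <- h_lim(0)
  nopert <- stats::integrate(f_h, hl0[1], hl0[2], rel.tol = 1e-10,
                             abs.tol = 0, subdivisions = 500L)$value
  inner <- function(r) {
    vapply(r, function(ri) {
      hl <- h_lim(ri)
      stats::integrate(function(h) f_h(h, ri), hl[1], hl[2],
                       rel.tol = 1e-10, abs.tol = 0,
                       subdivisions = 500L)$value
    }, numeric(1))
  }
  # the integrand in r is a product of Gaussians: its bump sits between the
  # prior centre (0) and the measurement-implied centres, with width no
  # larger than the smallest contributing scale
  centers <- c(0, x_v - x_c, x_v - par$bias)
  hw <- 14 * min(par$sigma_r,
                 sigma_v + par$sigma_h + par$sigma_combined) + 1
  pert <- stats::integrate(function(r) inner(r) * stats::dnorm(r, 0, par$sigma_r),
                           min(centers) - hw, max(centers) + hw,
                           rel.tol = 1e-9, abs.tol = 0,
                           subdivisions = 1000L)$value
  c(nopert = nopert, pert = pert)
}
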