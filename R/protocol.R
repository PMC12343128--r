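#' Build a randomized rotation-triplet reaching protocol
#'
#' Generates the trial schedule of the randomized visuomotor-rotation
#' paradigm: a baseline block of unperturbed reaches with veridical
#' feedback, followed by experimental blocks in which measured
#' (possibly rotated) trials are interleaved with null trials so that every
#' measured trial is immediately preceded and followed by a null trial.
#' Rotation levels are assigned to measured slots at random under the seed;
#' measured slots left over after all rotation (and optional target-jump)
#' trials are placed revert to null trials. Half of the null trials,
#' selected at random, carry no visual feedback.
#'
#' @param seed integer seed; the schedule is reproducible given the seed.
#' @param n_blocks number of experimental blocks.
#' @param block_length trials per experimental block (even).
#' @param n_baseline number of baseline trials.
#' @param rotations rotation levels in degrees.
#' @param trials_per_level measured trials per rotation level.
#' @param p_feedback_absent probability that a null trial has no visual
#'   feedback.
#' @param target_jump if `TRUE`, also schedule target-jump trials (excluded
#'   from all analyses by the analysis functions).
#' @param jump_sizes,jumps_per_level target-jump sizes (degrees) and count
#'   per size; used only when `target_jump = TRUE`.
#' @return a data frame of class `adapt_protocol` with columns
#'   `trial_index`, `block` (0 = baseline), `phase`, `trial_type`,
#'   `rotation_deg`, `feedback`.
#' @examples
#' prot <- build_protocol(seed = 1)
#' table(prot$trial_type)
#' @export
build_protocol <- function(seed, n_blocks = 18, block_length = 100,
                           n_baseline = 70,
                           rotations = c(-4, -2, 0, 2, 4),
                           trials_per_level = 100,
                           p_feedback_absent = 0.5,
                           target_jump = FALSE,
                           jump_sizes = c(-4, -2, 2, 4),
                           jumps_per_level = 50) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (block_length %% 2L != 0L || block_length < 4L)
    stop("'block_length' must be an even number >= 4", call. = FALSE)
  set.seed(as.integer(seed))

  # measured slots sit at even within-block positions 2..(block_length - 2),
  # so each is flanked by null trials, including across block boundaries
  slots_per_block <- (block_length - 2L) %/% 2L
  n_slots <- n_blocks * slots_per_block
  labels <- rep(as.character(rotations), each = trials_per_level)
  if (target_jump)
    labels <- c(labels, rep(paste0("jump", jump_sizes), each = jumps_per_level))
  if (length(labels) > n_slots)
    stop(sprintf(
      "infeasible schedule: %d measured trials requested but only %d slots",
      length(labels), n_slots), call. = FALSE)
  labels <- c(labels, rep("nullfill", n_slots - length(labels)))
  labels <- sample(labels)

  n_main <- n_blocks * block_length
  block <- rep(seq_len(n_blocks), each = block_length)
  pos <- rep(seq_len(block_length), times = n_blocks)
  slot <- pos %% 2L == 0L & pos < block_length

  trial_type <- rep("null", n_main)
  rotation <- rep(0, n_main)
  lab <- labels[cumsum(slot)[slot]]
  is_jump <- startsWith(lab, "jump")
  type_at_slot <- ifelse(lab == "nullfill", "null",
                         ifelse(is_jump, "target_jump", "measured"))
  rot_at_slot <- ifelse(lab %in% as.character(rotations),
                        suppressWarnings(as.numeric(lab)), 0)
  trial_type[slot] <- type_at_slot
  rotation[slot] <- rot_at_slot

  feedback <- rep("full", n_main)
  is_null <- trial_type == "null"
  feedback[is_null] <- ifelse(
    stats::runif(sum(is_null)) < p_feedback_absent, "none", "full")

  out <- data.frame(
    trial_index = seq_len(n_baseline + n_main),
    block = c(rep(0L, n_baseline), block),
    phase = c(rep("baseline", n_baseline), rep("main", n_main)),
    trial_type = c(rep("null", n_baseline), trial_type),
    rotation_deg = c(rep(0, n_baseline), rotation),
    feedback = c(rep("full", n_baseline), feedback),
    stringsAsFactors = FALSE)
  class(out) <- c("adapt_protocol", "data.frame")
  out
}

#' Simulate one synthetic participant over a protocol
#'
#' Sequential trial-by-trial simulation of any model. Each reach is the
#' model's mean response plus Gaussian motor noise `N(0, sigma_h^2)`.
#' Because the perturbation schedule is randomized, trial effects are
#' assumed independent with no memory across trials: only the trial
#' immediately following a measured (rotated, full-feedback) trial carries
#' that trial's update; all other reaches are centred on the bias. For the
#' causal-inference observer, `cue_mode = "stochastic"` samples the
#' observer's cues from their generative distributions when forming the
#' update, while `"deterministic"` uses mean cues (the setting matched by
#' the fitted likelihood). The posterior belief in a perturbation is
#' recorded for every measured trial (`NA` for models without one).
#'
#' @param params an `adapt_params` object for any model.
#' @param protocol a protocol from [build_protocol()].
#' @param seed integer seed (required; simulation is bit-reproducible).
#' @param participant_id participant label.
#' @param cue_mode `"deterministic"` or `"stochastic"` (observer cue noise;
#'   only used by the causal-inference observer).
#' @return a trial table: the protocol columns plus `participant_id`,
#'   `hand_angle_deg`, `cursor_angle_deg` (`NA` without feedback), `p_pert`
#'   and `excluded`.
#' @export
simulate_participant <- function(params, protocol, seed,
                                 participant_id = "P01",
                                 cue_mode = c("deterministic",
                                              "stochastic")) {
  cue_mode <- match.arg(cue_mode)
  if (missing(seed) || is.null(seed))
    stop("'seed' is required for simulation", call. = FALSE)
  stopifnot(inherits(params, "adapt_params"))
  set.seed(as.integer(seed))
  n <- nrow(protocol)
  eps <- stats::rnorm(n, 0, params$sigma_h)
  is_piece <- inherits(params, "piece_params")
  stochastic <- is_piece && cue_mode == "stochastic"

  hand <- numeric(n)
  p_pert <- rep(NA_real_, n)
  mu_next <- params$bias      # pending mean for the upcoming trial
  for (t in seq_len(n)) {
    hand[t] <- mu_next + eps[t]
    mu_next <- params$bias
    if (protocol$trial_type[t] == "measured" &&
        protocol$feedback[t] == "full") {
      r <- protocol$rotation_deg[t]
      if (is_piece) {
        if (stochastic) {
          e <- abs(hand[t] + r)
          sv <- params$alpha + params$beta * e
          x_v <- stats::rnorm(1, hand[t] + r, sv)
          x_c <- stats::rnorm(1, hand[t], params$sigma_combined)
          z <- stats::rnorm(1, r, sv)
          post <- causal_posterior(
            cue_set(x_v = x_v, x_c = x_c, sigma_v = sv), params)
          p_pert[t] <- post$p_pert
          mu_next <- params$bias -
            post$p_pert * kalman_gain(sv, params$sigma_r) * z
        } else {
          mech <- piece_machinery(params, r, hand[t])
          p_pert[t] <- mech$p_pert
          mu_next <- params$bias - mech$r_hat
        }
      } else {
        mu_next <- predict_trial(params, r, hand[t])
      }
    }
  }

  out <- as.data.frame(protocol)
  out$participant_id <- participant_id
  out$hand_angle_deg <- hand
  out$cursor_angle_deg <- ifelse(out$feedback == "full",
                                 hand + out$rotation_deg, NA_real_)
  out$p_pert <- p_pert
  out$excluded <- FALSE
  out[, c("participant_id", setdiff(names(out), "participant_id"))]
}

#' Simulate a cohort of synthetic participants
#'
#' Draws per-participant reach biases from `N(bias, bias_sd^2)` around the
#' supplied parameter set and simulates each participant on an
#' independently randomized protocol.
#'
#' @param n_participants number of synthetic participants.
#' @param params an `adapt_params` object providing the population values.
#' @param seed integer seed; per-participant seeds are derived from it.
#' @param bias_sd SD (degrees) of the between-participant bias spread.
#' @param protocol optional fixed protocol shared by all participants;
#'   by default each participant gets a freshly randomized schedule.
#' @param cue_mode passed to [simulate_participant()].
#' @return a single trial table with all participants stacked.
#' @export
simulate_cohort <- function(n_participants, params, seed, bias_sd = 0.5,
                            protocol = NULL,
                            cue_mode = c("deterministic", "stochastic")) {
  cue_mode <- match.arg(cue_mode)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  set.seed(as.integer(seed))
  biases <- stats::rnorm(n_participants, params$bias, bias_sd)
  sub_seeds <- sample.int(2^31 - 1, 2 * n_participants)
  tabs <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    p_i <- params
    p_i$bias <- biases[i]
    prot <- if (is.null(protocol))
      build_protocol(seed = sub_seeds[2 * i - 1]) else protocol
    tabs[[i]] <- simulate_participant(
      p_i, prot, seed = sub_seeds[2 * i],
      participant_id = sprintf("P%02d", i), cue_mode = cue_mode)
  }
  do.call(rbind, tabs)
}

#' Motor variability from baseline reaches
#'
#' Sample SD of the hand angle over the final `n_last` baseline trials;
#' used as the fixed response-noise parameter `sigma_h` in fitting.
#'
#' @param trials a trial table containing a `baseline` phase.
#' @param n_last number of final baseline trials to use.
#' @return SD in degrees.
#' @export
baseline_sigma <- function(trials, n_last = 50) {
  b <- trials[trials$phase == "baseline", ]
  if (nrow(b) < n_last)
    stop(sprintf("need at least %d baseline trials, found %d",
                 n_last, nrow(b)), call. = FALSE)
  b <- b[order(b$trial_index), ]
  stats::sd(utils::tail(b$hand_angle_deg, n_last))
}

# mean of the final baseline reaches; fixed bias for models that do not
# fit it (and the centre of the bias search box otherwise)
baseline_bias <- function(trials, n_last = 50) {
  b <- trials[trials$phase == "baseline", ]
  if (nrow(b) < n_last)
    stop(sprintf("need at least %d baseline trials, found %d",
                 n_last, nrow(b)), call. = FALSE)
  b <- b[order(b$trial_index), ]
  mean(utils::tail(b$hand_angle_deg, n_last))
}
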