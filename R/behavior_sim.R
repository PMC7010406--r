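#' Generative behavior parameters, keyed by movement
#'
#' The agent is described by per-movement (ordered from-target, to-target
#' pair) parameters: the probability of a predictive response, truncated
#' -normal response-time distributions for predictive and cue-driven
#' responses, a movement-time distribution, isotropic endpoint noise, an
#' undershoot/overshoot bias along the movement direction, and the
#' probabilities of a direction error and of a missed response. Scalars are
#' expanded to all 25 ordered pairs; `overrides` adjusts individual
#' movements.
#'
#' Predictive responses have support strictly below the 150 ms cutoff
#' (anticipations may start up to 400 ms before the cue, the repeating-task
#' cue delay); cue-driven responses lie in the 150-800 ms response window.
#'
#' @param p_predictive probability that a repeating-task response is
#'   predictive rather than cue-driven.
#' @param rt_pred_mean,rt_pred_sd location/scale (ms) of the predictive RT
#'   distribution, truncated to (-400, 150).
#' @param rt_cued_mean,rt_cued_sd location/scale (ms) of the cue-driven RT
#'   distribution, truncated to (150, 800).
#' @param mt_mean,mt_sd location/scale (ms) of movement time.
#' @param endpoint_sigma isotropic endpoint noise scale (screen units).
#' @param undershoot_bias signed displacement of the endpoint along the
#'   movement direction (screen units; negative = undershoot).
#' @param p_direction_error probability that the aim is replaced by the
#'   nearest target on the opposite side of the origin.
#' @param p_no_hit probability of no registered touch within the window.
#' @param p_fast_guess random-task probability of a fast anticipatory
#'   response at a guessed target (such trials are excluded downstream).
#' @param dwell_ms minimum hold time on a target before release (ms).
#' @param overrides optional data frame with columns `param`, `from`, `to`,
#'   `value` adjusting single movements.
#' @return an object of class `agent_params`: a list of 5 x 5 matrices
#'   (rows = from, cols = to) plus scalars `p_fast_guess`, `dwell_ms`.
#' @export
agent_params <- function(p_predictive = 0.92,
                         rt_pred_mean = 50, rt_pred_sd = 60,
                         rt_cued_mean = 350, rt_cued_sd = 90,
                         mt_mean = 200, mt_sd = 35,
                         endpoint_sigma = 13,
                         undershoot_bias = 0,
                         p_direction_error = 0.002,
                         p_no_hit = 0.005,
                         p_fast_guess = 0.02,
                         dwell_ms = 50,
                         overrides = NULL) {
  mat_params <- c("p_predictive", "rt_pred_mean", "rt_pred_sd",
                  "rt_cued_mean", "rt_cued_sd", "mt_mean", "mt_sd",
                  "endpoint_sigma", "undershoot_bias",
                  "p_direction_error", "p_no_hit")
  vals <- mget(mat_params)
  mats <- lapply(vals, function(v) matrix(as.numeric(v), 5, 5))
  if (!is.null(overrides)) {
    for (i in seq_len(nrow(overrides))) {
      p <- as.character(overrides$param[i])
      if (!p %in% mat_params) stop("unknown agent parameter: ", p)
      mats[[p]][overrides$from[i], overrides$to[i]] <- overrides$value[i]
    }
  }
  for (p in c("p_predictive", "p_direction_error", "p_no_hit"))
    if (any(mats[[p]] < 0 | mats[[p]] > 1))
      stop(p, " must lie in [0, 1]")
  if (any(mats$p_predictive + mats$p_no_hit > 1))
    stop("p_predictive + p_no_hit must not exceed 1")
  for (p in c("rt_pred_sd", "rt_cued_sd", "mt_sd", "endpoint_sigma"))
    if (any(mats[[p]] < 0)) stop(p, " must be >= 0")
  structure(c(mats, list(p_fast_guess = p_fast_guess, dwell_ms = dwell_ms)),
            class = "agent_params")
}

#' Injection effect scenario
#'
#' Per-phase perturbation of the agent's generative parameters. Scenarios
#' encode the pharmacology: anisomycin (protein-synthesis inhibition)
#' degrades only memory-guided performance, so its scope is the repeating
#' task; muscimol silences M1 output and degrades both tasks; saline changes
#' nothing. Deltas apply to generative parameters, never to derived
#' statistics, so parameter-recovery checks are non-circular.
#'
#' @param scenario `"anisomycin"`, `"muscimol"` or `"saline"`.
#' @param d_p_predictive subtractive shift of the predictive probability.
#' @param sigma_multiplier multiplicative endpoint-noise scale.
#' @param d_undershoot_bias additive endpoint bias shift (screen units).
#' @param d_p_direction_error additive direction-error probability shift.
#' @param d_rt_ms additive shift of the cue-driven RT location (ms).
#' @param d_mt_ms additive shift of the movement-time location (ms).
#' @param overrides optional data frame (`param`, `from`, `to`, `value`)
#'   adjusting single movements.
#' @return an object of class `injection_effect` with delta matrices, the
#'   scenario and its scope (`"repeating_only"`, `"both_tasks"`, `"none"`).
#' @export
injection_effect <- function(scenario = c("anisomycin", "muscimol", "saline"),
                             d_p_predictive = 0,
                             sigma_multiplier = 1,
                             d_undershoot_bias = 0,
                             d_p_direction_error = 0,
                             d_rt_ms = 0, d_mt_ms = 0,
                             overrides = NULL) {
  scenario <- match.arg(scenario)
  scope <- switch(scenario,
                  anisomycin = "repeating_only",
                  muscimol = "both_tasks",
                  saline = "none")
  mat_params <- c("d_p_predictive", "sigma_multiplier", "d_undershoot_bias",
                  "d_p_direction_error", "d_rt_ms", "d_mt_ms")
  vals <- mget(mat_params)
  neutral <- c(d_p_predictive = 0, sigma_multiplier = 1,
               d_undershoot_bias = 0, d_p_direction_error = 0,
               d_rt_ms = 0, d_mt_ms = 0)
  mats <- lapply(vals, function(v) matrix(as.numeric(v), 5, 5))
  if (!is.null(overrides)) {
    for (i in seq_len(nrow(overrides))) {
      p <- as.character(overrides$param[i])
      if (!p %in% mat_params) stop("unknown effect parameter: ", p)
      mats[[p]][overrides$from[i], overrides$to[i]] <- overrides$value[i]
    }
  }
  if (scenario == "saline") {
    for (p in mat_params)
      if (any(mats[[p]] != neutral[p]))
        stop("saline is a no-effect control: all deltas must be neutral")
  }
  structure(c(mats, list(scenario = scenario, scope = scope)),
            class = "injection_effect")
}

# Agent parameters effective for one (phase, task mode): POST-phase deltas
# are applied only within the effect's scope.
effective_agent <- function(agent, effect, phase, mode) {
  if (is.null(effect) || phase != "post" || effect$scope == "none")
    return(agent)
  if (effect$scope == "repeating_only" && mode != "repeating")
    return(agent)
  clamp01 <- function(m) pmin(pmax(m, 0), 1)
  agent$p_predictive <- clamp01(agent$p_predictive - effect$d_p_predictive)
  agent$endpoint_sigma <- agent$endpoint_sigma * effect$sigma_multiplier
  agent$undershoot_bias <- agent$undershoot_bias + effect$d_undershoot_bias
  agent$p_direction_error <-
    clamp01(agent$p_direction_error + effect$d_p_direction_error)
  agent$rt_cued_mean <- agent$rt_cued_mean + effect$d_rt_ms
  agent$mt_mean <- agent$mt_mean + effect$d_mt_ms
  agent
}

# Nearest target strictly on the opposite side of the origin, or NA when
# none exists (origin 1 moving right has no leftward neighbour etc.).
opposite_target <- function(from, to) {
  if (is.na(from) || is.na(to) || from == to) return(NA_integer_)
  cand <- if (to > from) from - 1L else from + 1L
  if (cand >= 1L && cand <= 5L) cand else NA_integer_
}

#' Generate a reach endpoint
#'
#' The endpoint is the aimed target's center, displaced by the movement's
#' undershoot/overshoot bias along the origin-to-aim direction, plus
#' isotropic Gaussian noise. Accuracy errors arise emergently when bias and
#' noise push the endpoint outside the correct target; direction errors
#' arise upstream, when the aim itself is replaced by the opposite-side
#' target.
#'
#' @param from origin target ID (`NA` at a block start: bias is skipped).
#' @param aim aimed target ID.
#' @param layout a [target_layout()].
#' @param endpoint_sigma,undershoot_bias movement parameters (screen units).
#' @return numeric `c(x, y)`.
#' @export
generate_touch <- function(from, aim, layout, endpoint_sigma,
                           undershoot_bias) {
  ctr <- layout$centers[aim, ]
  if (!is.na(from) && from != aim && undershoot_bias != 0) {
    dir <- layout$centers[aim, ] - layout$centers[from, ]
    dir <- dir / sqrt(sum(dir^2))
    ctr <- ctr + undershoot_bias * dir
  }
  ctr + endpoint_sigma * stats::rnorm(2)
}

#' Simulate one behavioral session
#'
#' Generates a full session of alternating random/repeating blocks under
#' the task engine's scheduling rules, a generative agent, and an optional
#' injection effect. Block lengths are drawn uniformly from `block_range`;
#' repeating blocks cycle through `sequences`. The same seed yields an
#' identical log. Per-trial generative ground truth (predictive draw,
#' direction-error draw, fast-guess draw, aimed target) is attached as
#' `attr(, "truth")` for parameter-recovery testing.
#'
#' @param n_trials total trials in the session.
#' @param agent an [agent_params()].
#' @param effect an [injection_effect()] or `NULL`.
#' @param phase `"pre"` or `"post"`; POST applies the effect within its
#'   scope.
#' @param seed integer seed; all randomness flows from it.
#' @param layout a [target_layout()].
#' @param sequences list of repeating-task sequences used in the session.
#' @param block_range inclusive block-length bounds (trials).
#' @param start_mode mode of the first block.
#' @param monkey_id,session_id,treatment,day_offset session metadata.
#' @return a `session_log` with truth sidecar attributes.
#' @examples
#' s <- simulate_session(400, agent_params(), seed = 1)
#' s
#' @export
simulate_session <- function(n_trials, agent, effect = NULL,
                             phase = c("pre", "post"), seed,
                             layout = target_layout(),
                             sequences = list(c(5L, 3L, 1L), c(1L, 2L, 4L)),
                             block_range = c(200L, 500L),
                             start_mode = c("random", "repeating"),
                             monkey_id = "sim", session_id = "s1",
                             treatment = NULL, day_offset = NULL) {
  phase <- match.arg(phase)
  start_mode <- match.arg(start_mode)
  stopifnot(n_trials > 0, inherits(agent, "agent_params"))
  if (!is.null(effect) && !inherits(effect, "injection_effect"))
    stop("effect must be an injection_effect or NULL")
  if (is.null(treatment))
    treatment <- if (is.null(effect)) "none" else effect$scenario
  if (is.null(day_offset)) day_offset <- if (phase == "post") 1L else -1L

  cfg_random <- task_config("random")
  cfg_repeating <- lapply(sequences, function(s)
    task_config("repeating", sequence = s))
  ag <- list(random = effective_agent(agent, effect, phase, "random"),
             repeating = effective_agent(agent, effect, phase, "repeating"))

  with_seed(seed, {
    # block plan
    lens <- integer(0)
    while (sum(lens) < n_trials)
      lens <- c(lens, sample(block_range[1]:block_range[2], 1L))
    lens[length(lens)] <- n_trials - sum(lens[-length(lens)])
    pair <- if (start_mode == "random") c("random", "repeating")
            else c("repeating", "random")
    modes <- rep(pair, length.out = length(lens))
    sim_trial_stream(lens, modes, cfg_random, cfg_repeating, ag, layout)
  }) -> sim

  trials <- tibble::as_tibble(sim$trials)
  log <- session_log(trials, layout, monkey_id = monkey_id,
                     session_id = session_id, phase = phase,
                     treatment = treatment, day_offset = day_offset,
                     seed = seed)
  attr(log, "truth") <- tibble::as_tibble(sim$truth)
  attr(log, "generative_params") <- ag
  log
}

# Inner per-trial loop shared by simulate_session; returns plain vectors.
# The scheduling, endpoint and assignment rules are inlined copies of the
# task_engine / metrics primitives (a Monte-Carlo stage simulates millions
# of trials, so the loop avoids per-trial function-call overhead); a replay
# test checks the stream against next_cue()/assign_touch_to_target().
sim_trial_stream <- function(lens, modes, cfg_random, cfg_repeating,
                             ag, layout) {
  runif <- stats::runif; qnorm <- stats::qnorm
  pnorm <- stats::pnorm; rnorm <- stats::rnorm
  cx <- layout$centers[, "x"]; cy <- layout$centers[, "y"]
  hw2 <- layout$half_width^2
  n <- sum(lens)
  trial_index <- seq_len(n)
  block_id <- rep(seq_along(lens), lens)
  task_mode <- rep(modes, lens)
  cue_target <- integer(n); cue_onset <- numeric(n)
  release <- rep(NA_real_, n); touch <- rep(NA_real_, n)
  touch_x <- rep(NA_real_, n); touch_y <- rep(NA_real_, n)
  raw_outcome <- character(n)
  g_pred <- rep(NA, n); g_dir <- rep(NA, n); g_fast <- rep(NA, n)
  g_aim <- rep(NA_integer_, n)

  anchor <- 0          # time reference for the next cue
  hand <- NA_integer_  # target currently under the hand
  rep_cycle <- 0L      # which repeating config comes next
  i <- 0L
  for (b in seq_along(lens)) {
    mode <- modes[b]
    repeating <- mode == "repeating"
    if (repeating) {
      rep_cycle <- rep_cycle %% length(cfg_repeating) + 1L
      cfg <- cfg_repeating[[rep_cycle]]
      seqv <- cfg$sequence; pos <- 1L; cue <- seqv[1L]
    } else {
      cfg <- cfg_random
      cue <- sample.int(5L, 1L)
    }
    delay <- cfg$cue_delay_ms; win <- cfg$response_window_ms
    lo_rt <- max(-400, -delay + 1)
    pars <- ag[[mode]]
    Ppred <- pars$p_predictive; Pdir <- pars$p_direction_error
    Pnh <- pars$p_no_hit; Sig <- pars$endpoint_sigma
    Bias <- pars$undershoot_bias
    Mpr <- pars$rt_pred_mean; Spr <- pars$rt_pred_sd
    Mcu <- pars$rt_cued_mean; Scu <- pars$rt_cued_sd
    Mmt <- pars$mt_mean; Smt <- pars$mt_sd
    p_fast <- pars$p_fast_guess; dwell <- pars$dwell_ms
    outcome <- ""
    for (k in seq_len(lens[b])) {
      i <- i + 1L
      if (outcome == "correct") {
        if (repeating) {
          pos <- pos %% length(seqv) + 1L
          cue <- seqv[pos]
        } else {
          cue <- ((1:5)[-cue])[sample.int(4L, 1L)]
        }
      }  # error / no_hit: trial repeated, cue unchanged
      cue_target[i] <- cue
      onset <- anchor + delay
      cue_onset[i] <- onset
      fi <- if (is.na(hand)) cue else hand  # param row for block starts
      if (runif(1) < Pnh[fi, cue]) {
        raw_outcome[i] <- "no_hit"
        anchor <- onset + win
        outcome <- "no_hit"
        next
      }
      aim <- cue; fast <- FALSE; pred <- FALSE; dir_err <- FALSE
      if (repeating) {
        pred <- runif(1) < Ppred[fi, cue]
      } else if (runif(1) < p_fast) {
        fast <- TRUE
        guessable <- if (is.na(hand)) 1:5 else (1:5)[-hand]
        aim <- guessable[sample.int(length(guessable), 1L)]
      }
      if (!fast && runif(1) < Pdir[fi, cue]) {
        opp <- opposite_target(hand, cue)
        if (!is.na(opp)) { aim <- opp; dir_err <- TRUE }
      }
      if (pred || fast) {
        m <- Mpr[fi, cue]; s <- Spr[fi, cue]
        rt <- qnorm(runif(1, pnorm(lo_rt, m, s), pnorm(149, m, s)), m, s)
        rt <- min(149, max(lo_rt, round(rt)))
      } else {
        m <- Mcu[fi, cue]; s <- Scu[fi, cue]
        rt <- qnorm(runif(1, pnorm(150, m, s), pnorm(win, m, s)), m, s)
        rt <- min(win, max(150, round(rt)))
      }
      t_touch <- onset + rt
      # endpoint: aim center + bias along movement direction + noise
      px <- cx[aim]; py <- cy[aim]
      bias <- Bias[fi, cue]
      if (!is.na(hand) && hand != aim && bias != 0) {
        dx <- cx[aim] - cx[hand]; dy <- cy[aim] - cy[hand]
        nrm <- sqrt(dx * dx + dy * dy)
        px <- px + bias * dx / nrm; py <- py + bias * dy / nrm
      }
      noise <- rnorm(2L, 0, Sig[fi, cue])
      # 2-decimal screen coordinates: the trial-log format's precision
      px <- round(px + noise[1L], 2); py <- round(py + noise[2L], 2)
      # nearest-center assignment (ties toward the lower target ID)
      d2 <- (cx - px)^2 + (cy - py)^2
      tgt <- which.min(d2)
      # movement time and release
      m <- Mmt[fi, cue]; s <- Smt[fi, cue]
      mt <- qnorm(runif(1, pnorm(10, m, s), 1), m, s)
      mt <- max(10, round(mt))
      release[i] <- min(t_touch, max(anchor + dwell, t_touch - mt))
      touch[i] <- t_touch
      touch_x[i] <- px; touch_y[i] <- py
      raw_outcome[i] <- "hit"
      g_pred[i] <- pred; g_dir[i] <- dir_err; g_fast[i] <- fast
      g_aim[i] <- aim
      outcome <- if (tgt == cue && d2[tgt] <= hw2) "correct" else "error"
      hand <- tgt
      anchor <- t_touch
    }
  }
  list(
    trials = list(trial_index = trial_index, block_id = block_id,
                  task_mode = task_mode, cue_target = cue_target,
                  cue_onset_ms = cue_onset, release_prev_ms = release,
                  touch_ms = touch, touch_x = touch_x, touch_y = touch_y,
                  raw_outcome = raw_outcome),
    truth = list(trial_index = trial_index,
                 gen_predictive = g_pred, gen_direction_error = g_dir,
                 gen_fast_guess = g_fast, gen_aim = g_aim)
  )
}
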