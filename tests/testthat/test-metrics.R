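test_that("RT and MT follow their task-specific definitions", {
  # repeating: inter-touch interval minus the 400 ms delay (may be negative)
  r <- derive_rt_mt(touch_ms = 1250, cue_onset_ms = 1400,
                    release_prev_ms = 1100, prev_touch_ms = 1000,
                    mode = "repeating")
  expect_equal(r$rt_ms, -150)
  expect_equal(r$mt_ms, 150)
  # random: cue onset to touch
  r <- derive_rt_mt(touch_ms = 1400, cue_onset_ms = 1100,
                    release_prev_ms = 1150, prev_touch_ms = 1000,
                    mode = "random")
  expect_equal(r$rt_ms, 300)
  expect_equal(r$mt_ms, 250)
  # vectorised over mixed modes, NA release leaves MT undefined
  r <- derive_rt_mt(touch_ms = c(500, 900), cue_onset_ms = c(100, 500),
                    release_prev_ms = c(NA, 650), prev_touch_ms = c(0, 400),
                    mode = c("random", "repeating"))
  expect_equal(r$rt_ms, c(400, 100))
  expect_equal(r$mt_ms, c(NA_real_, 250))
})

test_that("the predictive cutoff is strict and admits negative RTs", {
  expect_true(classify_predictive(100))
  expect_false(classify_predictive(150))
  expect_true(classify_predictive(149.9))
  expect_true(classify_predictive(-50))
})

test_that("touch assignment picks the nearest center, ties to the lower ID", {
  lay <- target_layout()
  a <- assign_touch_to_target(200, 0, lay)
  expect_equal(a$target, 3L); expect_true(a$inside)
  a <- assign_touch_to_target(205, 4, lay)
  expect_equal(a$target, 3L); expect_true(a$inside)
  # exactly midway between targets 2 and 3
  a <- assign_touch_to_target(150, 0, lay)
  expect_equal(a$target, 2L); expect_false(a$inside)
  # brute-force oracle over random points
  pts <- withr::with_seed(8, cbind(runif(200, -80, 480), runif(200, -60, 60)))
  got <- assign_touch_to_target(pts[, 1], pts[, 2], lay)
  for (i in seq_len(nrow(pts))) {
    d <- sqrt((lay$centers[, "x"] - pts[i, 1])^2 +
                (lay$centers[, "y"] - pts[i, 2])^2)
    expect_equal(got$target[i], which.min(d))
    expect_equal(got$inside[i], min(d) <= lay$half_width)
  }
})

# hand-built two-block session exercising every response class
tiny_session <- function() {
  lay <- target_layout()
  # repeating block, sequence 5-3-1; then one random block
  trials <- tibble::tibble(
    trial_index = 1:9,
    block_id = c(rep(1L, 7), 2L, 2L),
    task_mode = c(rep("repeating", 7), "random", "random"),
    cue_target = c(5L, 3L, 1L, 5L, 5L, 3L, 1L, 2L, 4L),
    cue_onset_ms = c(400, 1100, 1600, 2300, 3100, 3800, 4500, 4900, 5500),
    release_prev_ms = c(NA, 1100, 1800, 2600, 3300, 4000, 4700, 5300, 5700),
    touch_ms = c(700, 1200, 1900, 2700, 3400, 4100, 4800, 5400, 5800),
    touch_x = c(400, 200, 0, 330, 400, 200, 0, 100, 340),
    touch_y = c(0, 0, 0, 0, 0, 0, 0, 0, 0),
    raw_outcome = "hit")
  session_log(trials, lay, phase = "pre")
}

test_that("response classes cover the error taxonomy", {
  cl <- classify_trials(tiny_session())
  expect_equal(cl$response_class[1:7],
               c("correct",          # block start, on target
                 "correct",          # 3 from 5
                 "correct",          # 1 from 3
                 "accuracy_error",   # toward 5 but short: x=330 is nearest
                                     # target 4, outside target 5
                 "corrective",       # correct 5 after the error
                 "correct",          # 3
                 "correct"))         # 1
  # trial 8 (random, cue 2 from 1, rt=500): correct
  expect_equal(cl$response_class[8], "correct")
  # trial 9: cue 4 from 2, touch at x=340: toward 4 but outside it
  expect_equal(cl$response_class[9], "accuracy_error")
  expect_equal(cl$assigned_target[c(4, 9)], c(4L, 4L))
  expect_false(any(cl$inside_target[c(4, 9)] &
                     cl$cue_target[c(4, 9)] == cl$assigned_target[c(4, 9)]))
  # movements derive from the hand's actual position
  expect_equal(cl$from_target[5], 4L)  # hand landed on 4 after the error
  expect_true(is.na(cl$from_target[1]))
  expect_true(is.na(cl$from_target[8]))  # block start
  # repeating RT: inter-touch minus 400 (trial 2: 1200 - 700 - 400)
  expect_equal(cl$rt_ms[2], 100)
})

test_that("a leftward touch opposite the movement is a direction error", {
  lay <- target_layout()
  trials <- tibble::tibble(
    trial_index = 1:3,
    block_id = 1L,
    task_mode = "repeating",
    cue_target = c(2L, 4L, 4L),
    cue_onset_ms = c(400, 1400, 2400),
    release_prev_ms = c(NA, 1200, 2200),
    touch_ms = c(600, 1600, 2600),
    touch_x = c(100, 5, 300),
    touch_y = c(0, 0, 0),
    raw_outcome = "hit")
  cl <- classify_trials(session_log(trials, lay, phase = "pre"))
  # move 2 -> 4 touched at x=5 (assigned target 1): direction error
  expect_equal(cl$response_class[2], "direction_error")
  expect_equal(cl$assigned_target[2], 1L)
  # the following correct response is corrective
  expect_equal(cl$response_class[3], "corrective")
})

test_that("exactly the three stated exclusions are applied", {
  cl <- classify_trials(tiny_session())
  # corrective trial excluded
  expect_false(cl$included[5])
  expect_equal(cl$exclusion_reason[5], "corrective")
  # everything else in the repeating block included (fast RTs allowed)
  expect_true(all(cl$included[c(2:4, 6:7)]))
  # repeating RT may be far below 150 and stays included / predictive
  expect_lt(cl$rt_ms[2], 150)
  expect_true(cl$predictive[2])

  # fast random trials are excluded, slow ones kept
  lay <- target_layout()
  trials <- tibble::tibble(
    trial_index = 1:3, block_id = 1L, task_mode = "random",
    cue_target = c(2L, 4L, 1L),
    cue_onset_ms = c(100, 700, 1400),
    release_prev_ms = c(NA, 550, 1250),
    touch_ms = c(600, 820, 1700),
    touch_x = c(100, 300, 0), touch_y = 0, raw_outcome = "hit")
  cl2 <- classify_trials(session_log(trials, lay, phase = "pre"))
  expect_equal(cl2$rt_ms, c(500, 120, 300))
  expect_equal(cl2$included, c(TRUE, FALSE, TRUE))
  expect_equal(cl2$exclusion_reason[2], "fast_random")

  # a no-hit trial is excluded and the following correct is corrective
  trials$raw_outcome[2] <- "no_hit"
  trials$touch_ms[2] <- NA; trials$touch_x[2] <- NA
  trials$touch_y[2] <- NA; trials$release_prev_ms[2] <- NA
  cl3 <- classify_trials(session_log(trials, lay, phase = "pre"))
  expect_equal(cl3$response_class[2], "no_hit")
  expect_equal(cl3$exclusion_reason[2], "no_hit")
  expect_equal(cl3$response_class[3], "corrective")
})

test_that("movement summaries satisfy the count identities", {
  ps <- scenario_preset("anisomycin_session2_N")
  s <- simulate_session(1500, ps$agent, ps$effect, phase = "post", seed = 77,
                        sequences = ps$sequences)
  sm <- suppressWarnings(summarize_by_movement(classify_trials(s)))
  expect_true(all(sm$n_included == sm$n_correct + sm$n_accuracy_err +
                    sm$n_direction_err + sm$n_other_err))
  expect_true(all(sm$n_predictive + sm$n_nonpredictive == sm$n_correct))
  # counting example: a small hand-made summary
  counts <- make_classified(
    data.frame(from = 5, to = 3, n_correct = 8, n_acc = 2, n_pred = 6),
    phase = "pre")
  sm2 <- summarize_by_movement(counts)
  expect_equal(sm2$n_correct, 8)
  expect_equal(sm2$n_predictive, 6)
  expect_equal(sm2$n_accuracy_err, 2)
  expect_equal(sm2$n_included, 10)
})

test_that("partition: every trial has one class; included + excluded = total", {
  ps <- scenario_preset("anisomycin_session2_N")
  for (seed in c(3, 14)) {
    s <- simulate_session(800, ps$agent, ps$effect,
                          phase = if (seed %% 2) "post" else "pre",
                          seed = seed, sequences = ps$sequences)
    cl <- classify_trials(s)
    expect_true(all(cl$response_class %in%
                      c("correct", "accuracy_error", "direction_error",
                        "other_error", "no_hit", "corrective")))
    expect_equal(sum(cl$included) + sum(!cl$included), nrow(cl))
    expect_true(all(is.na(cl$exclusion_reason[cl$included])))
    expect_true(all(!is.na(cl$exclusion_reason[!cl$included])))
  }
})

test_that("raising the predictive threshold never decreases predictive counts", {
  ps <- scenario_preset("anisomycin_session2_N")
  s <- simulate_session(1000, ps$agent, NULL, phase = "pre", seed = 55,
                        sequences = ps$sequences)
  thresholds <- c(50, 100, 150, 250, 400)
  counts <- vapply(thresholds, function(th) {
    cl <- classify_trials(s, predictive_threshold_ms = th)
    sum(cl$predictive[cl$included])
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("error rates recover the generative probabilities", {
  # direction-error probability p is recovered within 3 binomial SEs
  p <- 0.15
  ag <- agent_params(endpoint_sigma = 4, p_direction_error = p,
                     p_no_hit = 0, p_fast_guess = 0)
  s <- simulate_session(3000, ag, seed = 23, start_mode = "repeating",
                        sequences = list(c(2L, 3L, 4L)))
  sm <- summarize_by_movement(classify_trials(s))
  # moves with an opposite-side target available: 3->4 (left of 3), 4->2,
  # 3->2; the wrap move 4->...; pool repeating movements of the sequence
  rs <- sm[sm$task_mode == "repeating" &
             sm$movement %in% c("2-3", "3-4", "4-2"), ]
  n <- sum(rs$n_included)
  p_hat <- sum(rs$n_direction_err) / n
  expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("summary counts match the simulator's ground-truth tallies", {
  ps <- scenario_preset("anisomycin_session2_N")
  s <- simulate_session(1200, ps$agent, ps$effect, phase = "post", seed = 61,
                        sequences = ps$sequences)
  cl <- classify_trials(s)
  tru <- attr(s, "truth")
  keep <- cl$included & !is.na(cl$from_target)
  # classified predictive-correct trials are exactly the predictive
  # generative draws among included correct responses
  expect_equal(
    sum(cl$predictive[keep] & cl$response_class[keep] == "correct"),
    sum(tru$gen_predictive[keep] & cl$response_class[keep] == "correct",
        na.rm = TRUE))
})
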