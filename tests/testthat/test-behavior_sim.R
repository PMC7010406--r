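test_that("identical seeds give byte-identical session logs", {
  ps <- scenario_preset("anisomycin_session2_N")
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  a <- simulate_session(500, ps$agent, ps$effect, phase = "post", seed = 7,
                        sequences = ps$sequences)
  b <- simulate_session(500, ps$agent, ps$effect, phase = "post", seed = 7,
                        sequences = ps$sequences)
  write_session(a, f1); write_session(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed gives a different log
  c3 <- simulate_session(500, ps$agent, ps$effect, phase = "post", seed = 8,
                         sequences = ps$sequences)
  expect_false(identical(a$trials$touch_x, c3$trials$touch_x))
})

test_that("a noiseless agent touches every cued target center and makes no errors", {
  s <- simulate_session(600, noiseless_agent(), seed = 4)
  cl <- classify_trials(s)
  lay <- s$layout
  expect_true(all(s$trials$raw_outcome == "hit"))
  expect_equal(s$trials$touch_x, unname(lay$centers[s$trials$cue_target, "x"]))
  expect_equal(s$trials$touch_y, unname(lay$centers[s$trials$cue_target, "y"]))
  expect_equal(sum(cl$response_class %in%
                     c("accuracy_error", "direction_error", "other_error")), 0)
})

test_that("every trial appears once with monotone timestamps", {
  ps <- scenario_preset("anisomycin_session2_N")
  s <- simulate_session(1000, ps$agent, ps$effect, phase = "post", seed = 21,
                        sequences = ps$sequences)
  tr <- s$trials
  expect_equal(tr$trial_index, seq_len(1000))
  t_ok <- !is.na(tr$touch_ms)
  expect_true(all(diff(tr$touch_ms[t_ok]) > 0))
  expect_true(all(diff(tr$cue_onset_ms) > 0))
  expect_true(all(tr$release_prev_ms[t_ok] <= tr$touch_ms[t_ok]))
})

test_that("the simulated cue stream obeys the task engine's scheduling", {
  ps <- scenario_preset("anisomycin_session2_N")
  s <- simulate_session(1500, ps$agent, ps$effect, phase = "post", seed = 31,
                        sequences = ps$sequences)
  cl <- classify_trials(s)
  outcome <- ifelse(cl$raw_outcome == "no_hit", "no_hit",
                    ifelse(!is.na(cl$assigned_target) &
                             cl$assigned_target == cl$cue_target &
                             cl$inside_target, "correct", "error"))
  for (b in unique(cl$block_id)) {
    i <- which(cl$block_id == b)
    mode <- cl$task_mode[i[1]]
    for (k in i[-1]) {
      if (outcome[k - 1] != "correct") {
        # error/miss: trial repeated with the same cue
        expect_identical(cl$cue_target[k], cl$cue_target[k - 1])
      } else if (mode == "random") {
        # random never re-cues the just-hit target
        expect_false(cl$cue_target[k] == cl$assigned_target[k - 1] &&
                       cl$inside_target[k - 1])
      }
    }
    if (mode == "repeating") {
      # the deduplicated correct-cue stream cycles one of the sequences
      cues <- cl$cue_target[i][outcome[i] == "correct"]
      seqs <- ps$sequences
      match_any <- any(vapply(seqs, function(sq) {
        start <- match(cues[1], sq)
        !is.na(start) &&
          all(cues == sq[(start + seq_along(cues) - 2) %% 3 + 1])
      }, logical(1)))
      expect_true(match_any)
    }
  }
})

test_that("generative response classes round-trip through the metrics layer", {
  ps <- scenario_preset("anisomycin_session2_N")
  s <- simulate_session(2000, ps$agent, ps$effect, phase = "post", seed = 13,
                        sequences = ps$sequences)
  cl <- classify_trials(s)
  tru <- attr(s, "truth")
  hit <- cl$raw_outcome == "hit"
  prev_hit <- c(FALSE, hit[-nrow(cl)])  # RT needs a previous touch
  rep_hit <- hit & prev_hit & cl$task_mode == "repeating" &
    !is.na(cl$from_target) & cl$included
  # predictive generative draws always derive RT < 150; cued draws >= 150
  expect_true(all(cl$rt_ms[rep_hit & tru$gen_predictive] < 150))
  expect_true(all(cl$rt_ms[rep_hit & !tru$gen_predictive] >= 150))
  # direction-error draws are classified as direction errors
  dir_trials <- rep_hit & tru$gen_direction_error
  expect_gt(sum(dir_trials), 0)
  expect_true(mean(cl$response_class[dir_trials] == "direction_error") > 0.95)
})

test_that("predictive fraction is recovered within Monte-Carlo error", {
  ag <- agent_params(p_predictive = 0.9, endpoint_sigma = 5)
  s <- simulate_session(2000, ag, seed = 17, start_mode = "repeating")
  sm <- summarize_by_movement(classify_trials(s))
  rep_sm <- sm[sm$task_mode == "repeating", ]
  p_hat <- sum(rep_sm$n_predictive) / sum(rep_sm$n_correct)
  se <- sqrt(0.9 * 0.1 / sum(rep_sm$n_correct))
  expect_lt(abs(p_hat - 0.9), 3 * se)
})

test_that("endpoint generation reproduces the error taxonomy geometry", {
  lay <- target_layout()
  hw <- lay$half_width
  # no noise, no bias: exactly the aimed center
  expect_equal(withr::with_seed(1, generate_touch(1L, 4L, lay, 0, 0)),
               lay$centers[4L, ])
  # undershoot of 1.2 half-widths on 1 -> 5 with small noise lands nearest
  # target 5 region boundary; a large undershoot lands nearest target 4
  xy <- withr::with_seed(2, generate_touch(1L, 5L, lay, 1, -1.2 * hw))
  a <- assign_touch_to_target(xy[1], xy[2], lay)
  expect_false(a$target == 5L && a$inside)  # an accuracy error downstream
  xy2 <- withr::with_seed(3, generate_touch(1L, 5L, lay, 1, -60))
  expect_equal(assign_touch_to_target(xy2[1], xy2[2], lay)$target, 4L)
  # direction-error branch on 2 -> 4 flips the aim to target 1
  ag <- noiseless_agent(p_direction_error = 1)
  s <- simulate_session(50, ag, seed = 5, start_mode = "repeating",
                        sequences = list(c(1L, 2L, 4L)),
                        block_range = c(50L, 50L))
  cl <- classify_trials(s)
  m24 <- !is.na(cl$from_target) & cl$from_target == 2 & cl$to_target == 4
  expect_gt(sum(m24), 0)
  expect_true(all(cl$assigned_target[m24] == 1L))
  expect_true(all(cl$response_class[m24] == "direction_error"))
  # ...but is skipped when no opposite-side target exists (move 4 -> 1 has
  # no target right of 4 only when origin is 5; origin 1 moving right)
  s2 <- simulate_session(50, ag, seed = 6, start_mode = "repeating",
                         sequences = list(c(1L, 5L, 3L)),
                         block_range = c(50L, 50L))
  cl2 <- classify_trials(s2)
  m15 <- !is.na(cl2$from_target) & cl2$from_target == 1 & cl2$to_target == 5
  expect_true(all(cl2$response_class[m15] == "correct" |
                    cl2$response_class[m15] == "corrective"))
})

test_that("injection scopes are honored and validated", {
  expect_error(injection_effect("saline", d_rt_ms = 5), "neutral")
  expect_equal(injection_effect("anisomycin")$scope, "repeating_only")
  expect_equal(injection_effect("muscimol")$scope, "both_tasks")
  ps <- scenario_preset("anisomycin_session2_N")
  post <- simulate_session(300, ps$agent, ps$effect, phase = "post",
                           seed = 9, sequences = ps$sequences)
  gp <- attr(post, "generative_params")
  # repeating-only scope: random-task generative parameters untouched
  expect_identical(gp$random$p_predictive, ps$agent$p_predictive)
  expect_identical(gp$random$endpoint_sigma, ps$agent$endpoint_sigma)
  # repeating parameters shifted
  expect_lt(gp$repeating$p_predictive[5, 3], ps$agent$p_predictive[5, 3])
  mus <- scenario_preset("muscimol")
  postm <- simulate_session(300, mus$agent, mus$effect, phase = "post",
                            seed = 10, sequences = mus$sequences)
  gpm <- attr(postm, "generative_params")
  expect_gt(gpm$random$endpoint_sigma[1, 2], mus$agent$endpoint_sigma[1, 2])
})

test_that("agent parameter invariants are validated", {
  expect_error(agent_params(p_predictive = 1.2), "\\[0, 1\\]")
  expect_error(agent_params(p_predictive = 0.999, p_no_hit = 0.01),
               "exceed 1")
  expect_error(agent_params(rt_pred_sd = -1), ">= 0")
  expect_error(agent_params(overrides = data.frame(
    param = "nonsense", from = 1, to = 2, value = 0)), "unknown")
})
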