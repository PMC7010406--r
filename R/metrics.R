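#' Assign a touch to the nearest target
#'
#' Touches between targets are counted as touches to the closest target
#' center; a tie is broken toward the lower target ID. The `inside` flag
#' records whether the touch fell within the target's acceptance radius —
#' only touches inside the correct target count as correct responses.
#'
#' @param x,y touch coordinates (vectors of equal length, screen units).
#' @param layout a [target_layout()].
#' @return a list with integer vector `target` and logical vector `inside`.
#' @examples
#' lay <- target_layout()
#' assign_touch_to_target(205, 4, lay)  # target 3, inside
#' @export
assign_touch_to_target <- function(x, y, layout) {
  stopifnot(inherits(layout, "target_layout"))
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  # n x 5 squared distances to each center
  d2 <- outer(x, layout$centers[, "x"], "-")^2 +
        outer(y, layout$centers[, "y"], "-")^2
  target <- max.col(-d2, ties.method = "first")  # ties -> lower ID
  dmin2 <- d2[cbind(seq_len(n), target)]
  inside <- dmin2 <= layout$half_width^2
  target[is.na(x) | is.na(y)] <- NA_integer_
  inside[is.na(x) | is.na(y)] <- NA
  list(target = as.integer(target), inside = inside)
}

#' Derive response time and movement time for a trial
#'
#' Movement time (MT) is the interval from release of contact on the
#' previous target to touch of the next. Response time (RT) is mode
#' specific: in the random task it runs from cue onset to touch; in the
#' repeating task it is the inter-touch interval minus the 400 ms cue delay,
#' which is negative when the animal moves before the cue appears.
#'
#' @param touch_ms,cue_onset_ms,release_prev_ms,prev_touch_ms timestamps
#'   (vectors, ms; `NA` where undefined).
#' @param mode `"random"` or `"repeating"` (vector or scalar).
#' @param cue_delay_ms repeating-task cue delay subtracted from the
#'   inter-touch interval (default 400).
#' @return list with numeric vectors `rt_ms` and `mt_ms`.
#' @examples
#' derive_rt_mt(touch_ms = 1250, cue_onset_ms = 1400, release_prev_ms = 1100,
#'              prev_touch_ms = 1000, mode = "repeating")  # rt = -150
#' @export
derive_rt_mt <- function(touch_ms, cue_onset_ms, release_prev_ms,
                         prev_touch_ms, mode, cue_delay_ms = 400) {
  n <- length(touch_ms)
  mode <- rep_len(mode, n)
  rt <- ifelse(mode == "random",
               touch_ms - cue_onset_ms,
               (touch_ms - prev_touch_ms) - cue_delay_ms)
  mt <- touch_ms - release_prev_ms
  list(rt_ms = as.numeric(rt), mt_ms = as.numeric(mt))
}

#' Predictive-response cutoff
#'
#' A correct response with RT strictly below the threshold is predictive:
#' too fast to be a simple reaction to the visual cue, so the animal must
#' have anticipated the target. Negative RTs (movement before cue onset)
#' are predictive.
#'
#' @param rt_ms response times (ms).
#' @param threshold_ms strict cutoff (default 150 ms).
#' @return logical vector.
#' @export
classify_predictive <- function(rt_ms, threshold_ms = 150) {
  rt_ms < threshold_ms
}

# Horizontal-direction response taxonomy for one vector of trials.
# Direction is judged on the x-axis only: the targets sit in a horizontal
# row, so "opposite direction" means the touch moved the wrong way along it.
classify_response_vec <- function(assigned, inside, touch_x,
                                  from, to, layout, no_hit) {
  x_from <- layout$centers[, "x"][from]
  x_to <- layout$centers[, "x"][to]
  s_move <- sign(x_to - x_from)
  s_touch <- sign(touch_x - x_from)
  cls <- rep(NA_character_, length(assigned))
  cls[no_hit] <- "no_hit"
  hit <- !no_hit & !is.na(assigned)
  ok <- hit & assigned == to & inside
  cls[ok] <- "correct"
  err <- hit & !ok
  cls[err & s_touch == s_move & s_touch != 0] <- "accuracy_error"
  cls[err & s_touch == -s_move & s_touch != 0] <- "direction_error"
  cls[err & (s_touch == 0 | s_move == 0) & is.na(cls)] <- "other_error"
  cls[err & is.na(cls)] <- "other_error"
  cls
}

#' Classify every trial of a session
#'
#' Turns a raw session log into analysis-ready classified trials:
#' derives the movement (the ordered pair previous-target to cued-target),
#' RT and MT, assigns each touch to its nearest target, labels the response
#' class (correct / accuracy error / direction error / other error / no
#' hit), relabels correct responses that immediately follow an error as
#' corrective, flags predictive responses, and applies the three exclusion
#' rules (see [apply_exclusions()]).
#'
#' The movement origin is where the hand actually was: the previous trial's
#' assigned touch target, carried over a missed response. The first trial of
#' each block has no defined movement and is dropped from movement-level
#' analyses.
#'
#' @param session a `session_log` (see [simulate_session()],
#'   [read_session()]).
#' @param predictive_threshold_ms strict predictive cutoff (ms).
#' @param repeating_cue_delay_ms delay subtracted in the repeating-task RT
#'   definition (ms).
#' @return a tibble of classified trials, one row per trial, with columns
#'   `from_target`, `to_target`, `rt_ms`, `mt_ms`, `assigned_target`,
#'   `inside_target`, `response_class`, `predictive`, `included`,
#'   `exclusion_reason` added to the raw trial fields.
#' @export
classify_trials <- function(session,
                            predictive_threshold_ms = 150,
                            repeating_cue_delay_ms = 400) {
  tr <- as_trial_tibble(session)
  layout <- session_layout(session)
  n <- nrow(tr)
  if (n == 0L) stop("session has no trials")

  asg <- assign_touch_to_target(tr$touch_x, tr$touch_y, layout)
  no_hit <- tr$raw_outcome == "no_hit"
  assigned <- asg$target
  assigned[no_hit] <- NA_integer_

  # hand position before each trial: last assigned target of the block,
  # carried across missed responses; NA for the first trial of a block
  hand <- assigned
  hand[no_hit] <- NA_integer_
  from <- lag_fill_by_block(hand, tr$block_id)
  prev_touch <- lag_fill_by_block(tr$touch_ms, tr$block_id)
  to <- tr$cue_target

  tm <- derive_rt_mt(tr$touch_ms, tr$cue_onset_ms, tr$release_prev_ms,
                     prev_touch, tr$task_mode,
                     cue_delay_ms = repeating_cue_delay_ms)

  cls <- rep(NA_character_, n)
  movement_ok <- !is.na(from)
  cls[movement_ok] <- classify_response_vec(
    assigned[movement_ok], asg$inside[movement_ok], tr$touch_x[movement_ok],
    from[movement_ok], to[movement_ok], layout, no_hit[movement_ok])
  # first trial of a block still gets a class (no movement direction, so
  # errors there are 'other'); summaries drop it via the NA movement
  cls[!movement_ok] <- ifelse(
    no_hit[!movement_ok], "no_hit",
    ifelse(!is.na(assigned[!movement_ok]) &
             assigned[!movement_ok] == to[!movement_ok] &
             asg$inside[!movement_ok], "correct", "other_error"))

  # corrective relabel: a correct response immediately following any error
  # or miss (the erroneous trial is repeated, so its target is predictable)
  prev_cls <- c(NA_character_, cls[-n])
  prev_err <- !is.na(prev_cls) & prev_cls != "correct" & prev_cls != "corrective"
  # a corrective itself counts as correct for the following trial
  cls[cls == "correct" & prev_err] <- "corrective"

  predictive <- !is.na(tm$rt_ms) &
    classify_predictive(tm$rt_ms, predictive_threshold_ms) &
    cls %in% c("correct", "corrective")

  out <- tr
  out$from_target <- from
  out$to_target <- to
  out$rt_ms <- tm$rt_ms
  out$mt_ms <- tm$mt_ms
  out$assigned_target <- assigned
  out$inside_target <- asg$inside
  out$response_class <- cls
  out$predictive <- predictive
  out <- apply_exclusions(out, predictive_threshold_ms = predictive_threshold_ms)
  attr(out, "layout") <- layout
  attr(out, "meta") <- session_meta(session)
  out
}

# last observation carried forward
locf <- function(v) {
  idx <- ifelse(is.na(v), 0L, seq_along(v))
  last <- cummax(idx)
  out <- v
  out[last > 0L] <- v[last[last > 0L]]
  out
}

# previous non-NA value within each block (NA at each block start)
lag_fill_by_block <- function(x, block) {
  f <- factor(block, levels = unique(block))
  unsplit(lapply(split(x, f), function(v) locf(c(NA, v[-length(v)]))), f)
}

#' Apply the analysis exclusion rules
#'
#' Exactly three kinds of trials are excluded from analysis:
#' corrective responses (the repeated target is predictable), no-hit
#' responses (attributable to lapses of motivation), and random-task trials
#' with RT under the predictive threshold (possible carry-over of repeating
#' -task anticipation). Everything else is included.
#'
#' @param classified a classified-trial tibble (see [classify_trials()]).
#' @param predictive_threshold_ms cutoff used for the fast-random rule (ms).
#' @return the tibble with logical `included` and character
#'   `exclusion_reason` (`NA` when included) columns set.
#' @export
apply_exclusions <- function(classified, predictive_threshold_ms = 150) {
  reason <- rep(NA_character_, nrow(classified))
  reason[classified$response_class == "corrective"] <- "corrective"
  reason[classified$response_class == "no_hit"] <- "no_hit"
  fast_random <- classified$task_mode == "random" &
    !is.na(classified$rt_ms) &
    classified$rt_ms < predictive_threshold_ms &
    is.na(reason)
  reason[fast_random] <- "fast_random"
  classified$included <- is.na(reason)
  classified$exclusion_reason <- reason
  classified
}

#' Per-movement summaries of classified trials
#'
#' Aggregates included trials by movement (ordered from-to target pair),
#' task mode and phase: response-class counts, predictive counts among
#' correct responses, and mean RT/MT over correct responses. Movements with
#' no included trials are omitted with a warning; trials without a defined
#' movement (first of each block) are dropped.
#'
#' @param classified a classified-trial tibble, or a list of them (rows are
#'   pooled, e.g. pre-injection baseline days).
#' @return a tibble with one row per (movement, task_mode, phase) and
#'   columns `n_included`, `n_correct`, `n_accuracy_err`, `n_direction_err`,
#'   `n_other_err`, `n_predictive`, `n_nonpredictive`, `mean_rt_ms`,
#'   `mean_mt_ms`. Identities `n_included = n_correct + n_accuracy_err +
#'   n_direction_err + n_other_err` and `n_predictive + n_nonpredictive =
#'   n_correct` hold by construction.
#' @export
summarize_by_movement <- function(classified) {
  if (is.data.frame(classified)) classified <- list(classified)
  tr <- dplyr::bind_rows(lapply(classified, function(x) {
    x$phase <- attr(x, "meta")$phase %||% x$phase %||% NA_character_
    x
  }))
  keep <- tr$included & !is.na(tr$from_target)
  excl <- !keep & !is.na(tr$from_target)
  dropped_movements <- if (any(excl))
    unique(paste0(tr$from_target[excl], "-", tr$to_target[excl]))
  else character(0)
  tr <- tr[keep, , drop = FALSE]
  out <- tr |>
    dplyr::group_by(.data$from_target, .data$to_target, .data$task_mode,
                    .data$phase) |>
    dplyr::summarise(
      n_included = dplyr::n(),
      n_correct = sum(.data$response_class == "correct"),
      n_accuracy_err = sum(.data$response_class == "accuracy_error"),
      n_direction_err = sum(.data$response_class == "direction_error"),
      n_other_err = sum(.data$response_class == "other_error"),
      n_predictive = sum(.data$predictive & .data$response_class == "correct"),
      n_nonpredictive = sum(!.data$predictive & .data$response_class == "correct"),
      mean_rt_ms = mean(.data$rt_ms[.data$response_class == "correct"]),
      mean_mt_ms = mean(.data$mt_ms[.data$response_class == "correct"],
                        na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(movement = paste0(.data$from_target, "-", .data$to_target),
                  .before = 1L)
  absent <- setdiff(dropped_movements, out$movement)
  absent <- absent[!grepl("NA", absent)]
  if (length(absent) > 0)
    warning("movements with zero included trials omitted: ",
            paste(absent, collapse = ", "))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
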