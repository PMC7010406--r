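#' Geometry of the five-target touch row
#'
#' The task presents five targets in a horizontal row, numbered 1 to 5 from
#' left to right. A touch counts as inside a target when its distance from
#' the target center is at most `half_width`.
#'
#' @param centers_x numeric vector of 5 strictly increasing horizontal
#'   center coordinates (screen units).
#' @param centers_y vertical center coordinates; a scalar is recycled.
#' @param half_width acceptance radius around each center (screen units).
#' @return an object of class `target_layout` with elements `centers`
#'   (5 x 2 matrix) and `half_width`.
#' @examples
#' layout <- target_layout()
#' layout$centers
#' @export
target_layout <- function(centers_x = seq(0, 400, by = 100),
                          centers_y = 0,
                          half_width = 30) {
  centers_x <- as.numeric(centers_x)
  centers_y <- rep_len(as.numeric(centers_y), length(centers_x))
  if (length(centers_x) != 5L)
    stop("a target layout has exactly 5 targets, got ", length(centers_x))
  if (any(diff(centers_x) <= 0))
    stop("target x-coordinates must be strictly increasing (IDs 1..5 left to right)")
  if (!is.finite(half_width) || half_width <= 0)
    stop("half_width must be a positive number")
  if (any(diff(centers_x) <= 2 * half_width))
    stop("targets overlap: inter-center spacing must exceed 2 * half_width")
  structure(
    list(centers = cbind(x = centers_x, y = centers_y), half_width = half_width),
    class = "target_layout"
  )
}

#' @export
print.target_layout <- function(x, ...) {
  cat("<target_layout> 5 targets, half_width =", x$half_width, "\n")
  print(x$centers)
  invisible(x)
}

#' Task configuration for one block mode
#'
#' The Random task cues a pseudo-random admissible target 100 ms after each
#' correct touch; the Repeating task cycles a fixed three-element sequence
#' with a 400 ms cue delay, long enough for the animal to anticipate the next
#' element. Responses must land within `response_window_ms` of cue onset, and
#' correct responses with response time under `predictive_threshold_ms` are
#' scored as predictive.
#'
#' @param mode `"random"` or `"repeating"`.
#' @param sequence integer triple of target IDs (repeating mode only); the
#'   standard sequences are `c(5, 3, 1)`, `c(1, 2, 4)` and `c(2, 3, 4)`.
#' @param cue_delay_ms delay from previous touch to next cue onset. Defaults
#'   to 100 (random) / 400 (repeating).
#' @param response_window_ms response deadline after cue onset (ms).
#' @param predictive_threshold_ms strict upper RT bound for a predictive
#'   response (ms).
#' @return an object of class `task_config`.
#' @examples
#' task_config("repeating", sequence = c(5, 3, 1))
#' @export
task_config <- function(mode = c("random", "repeating"),
                        sequence = NULL,
                        cue_delay_ms = NULL,
                        response_window_ms = 800,
                        predictive_threshold_ms = 150) {
  mode <- match.arg(mode)
  if (is.null(cue_delay_ms))
    cue_delay_ms <- if (mode == "random") 100 else 400
  if (cue_delay_ms < 0) stop("cue_delay_ms must be >= 0")
  if (mode == "repeating") {
    if (is.null(sequence))
      stop("repeating mode requires a target sequence")
    sequence <- as.integer(sequence)
    if (!all(sequence %in% 1:5))
      stop("sequence entries must be target IDs in 1..5")
    if (any(sequence == c(sequence[-1], sequence[1])))
      stop("no two consecutive sequence entries (cyclically) may be equal")
  } else if (!is.null(sequence)) {
    stop("random mode takes no sequence")
  }
  structure(
    list(mode = mode, sequence = sequence,
         cue_delay_ms = cue_delay_ms,
         response_window_ms = response_window_ms,
         predictive_threshold_ms = predictive_threshold_ms),
    class = "task_config"
  )
}

#' Initial task state for a block
#'
#' @param config a [task_config()].
#' @param start_target first cued target; defaults to the first sequence
#'   element (repeating) or a draw from the current RNG stream (random).
#' @return an object of class `task_state` with the current cue and, for
#'   repeating mode, the sequence position.
#' @export
new_task_state <- function(config, start_target = NULL) {
  if (config$mode == "repeating") {
    if (is.null(start_target)) start_target <- config$sequence[1L]
    pos <- match(start_target, config$sequence)
    if (is.na(pos))
      stop("start_target must be an element of the sequence")
  } else {
    if (is.null(start_target)) start_target <- sample.int(5L, 1L)
    pos <- NA_integer_
  }
  structure(
    list(current_cued_target = as.integer(start_target),
         previous_correct_target = NA_integer_,
         sequence_position = pos),
    class = "task_state"
  )
}

#' Advance the cue schedule by one trial
#'
#' Implements the task's error-handling rule: after an error or a missed
#' response the same target is cued again; after a correct response the
#' repeating task advances cyclically through its sequence, while the random
#' task draws uniformly from the four targets other than the one just hit
#' (an immediate repeat would define a zero-length movement). Random draws
#' come from the session RNG stream, so the cue sequence is reproducible
#' from the seed.
#'
#' @param state a [new_task_state()] object.
#' @param config the matching [task_config()].
#' @param last_outcome `"correct"`, `"error"` or `"no_hit"`.
#' @return list with elements `state` (updated) and `target` (next cue ID).
#' @examples
#' cfg <- task_config("repeating", sequence = c(5, 3, 1))
#' st <- new_task_state(cfg)
#' next_cue(st, cfg, "correct")$target  # 3 follows 5
#' @export
next_cue <- function(state, config,
                     last_outcome = c("correct", "error", "no_hit")) {
  last_outcome <- match.arg(last_outcome)
  if (config$mode == "repeating" && is.na(state$sequence_position))
    stop("state was not initialised for a repeating-mode config")
  if (last_outcome != "correct") {
    # trial repeated: cue unchanged
    return(list(state = state, target = state$current_cued_target))
  }
  hit <- state$current_cued_target
  if (config$mode == "repeating") {
    pos <- state$sequence_position %% length(config$sequence) + 1L
    target <- config$sequence[pos]
    state$sequence_position <- pos
  } else {
    admissible <- setdiff(1:5, hit)
    target <- admissible[sample.int(4L, 1L)]
  }
  state$previous_correct_target <- hit
  state$current_cued_target <- as.integer(target)
  list(state = state, target = as.integer(target))
}

#' Cue onset time after a touch
#'
#' New targets are cued a fixed delay after contact of the previous target:
#' 100 ms in the random task, 400 ms in the repeating task.
#'
#' @param previous_touch_ms timestamp of the previous touch (ms).
#' @param config a [task_config()].
#' @return cue onset timestamp (ms).
#' @export
cue_onset_time <- function(previous_touch_ms, config) {
  stopifnot(is.finite(previous_touch_ms))
  previous_touch_ms + config$cue_delay_ms
}

#' Is a touch within the response window?
#'
#' True when the touch lands no later than `response_window_ms` after cue
#' onset. Touches before cue onset (anticipations of the next sequence
#' element) are within the window; they give rise to negative response times
#' in the repeating task.
#'
#' @param cue_onset_ms,touch_ms timestamps (ms).
#' @param config a [task_config()].
#' @return logical.
#' @export
is_within_window <- function(cue_onset_ms, touch_ms, config) {
  stopifnot(is.finite(cue_onset_ms), is.finite(touch_ms))
  touch_ms <= cue_onset_ms + config$response_window_ms
}
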