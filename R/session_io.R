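#' Construct a session log
#'
#' A session log bundles one behavioral session: per-trial records, the
#' target layout, and session metadata (animal, phase relative to an
#' injection, treatment, day offset).
#'
#' @param trials tibble with columns `trial_index`, `block_id`, `task_mode`,
#'   `cue_target`, `cue_onset_ms`, `release_prev_ms`, `touch_ms`, `touch_x`,
#'   `touch_y`, `raw_outcome` (`"hit"`/`"no_hit"`).
#' @param layout a [target_layout()].
#' @param monkey_id,session_id labels.
#' @param phase `"pre"` or `"post"` (relative to injection).
#' @param treatment `"anisomycin"`, `"muscimol"`, `"saline"` or `"none"`.
#' @param day_offset signed days from the injection day.
#' @param seed generating seed, if simulated (recorded for provenance).
#' @return an object of class `session_log`.
#' @export
session_log <- function(trials, layout,
                        monkey_id = "sim", session_id = "s1",
                        phase = c("pre", "post"),
                        treatment = c("none", "anisomycin", "muscimol", "saline"),
                        day_offset = 0L, seed = NA_integer_) {
  phase <- match.arg(phase)
  treatment <- match.arg(treatment)
  trials <- tibble::as_tibble(trials)
  validate_trials(trials, layout)
  structure(
    list(meta = list(monkey_id = monkey_id, session_id = session_id,
                     phase = phase, treatment = treatment,
                     day_offset = as.integer(day_offset),
                     seed = seed),
         layout = layout, trials = trials),
    class = "session_log"
  )
}

trial_columns <- c("trial_index", "block_id", "task_mode", "cue_target",
                   "cue_onset_ms", "release_prev_ms", "touch_ms",
                   "touch_x", "touch_y", "raw_outcome")

validate_trials <- function(trials, layout) {
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols) > 0)
    stop("trial table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(trials) == 0) stop("no trials")
  if (any(diff(trials$trial_index) <= 0))
    stop("trial_index must be strictly increasing; violated at row ",
         which(diff(trials$trial_index) <= 0)[1] + 1L)
  bad_target <- which(!(trials$cue_target %in% 1:5))
  if (length(bad_target) > 0)
    stop("unknown cue target ID at row ", bad_target[1])
  bad_mode <- which(!(trials$task_mode %in% c("random", "repeating")))
  if (length(bad_mode) > 0)
    stop("unknown task_mode at row ", bad_mode[1])
  both <- !is.na(trials$release_prev_ms) & !is.na(trials$touch_ms)
  bad_rel <- which(both & trials$release_prev_ms > trials$touch_ms)
  if (length(bad_rel) > 0)
    stop("release_prev_ms exceeds touch_ms at row ", bad_rel[1])
  bad_out <- which(!(trials$raw_outcome %in% c("hit", "no_hit")))
  if (length(bad_out) > 0)
    stop("raw_outcome must be 'hit' or 'no_hit' at row ", bad_out[1])
  n_modes <- tapply(trials$task_mode, trials$block_id,
                    function(m) length(unique(m)))
  if (any(n_modes > 1))
    stop("task_mode must be constant within a block; violated in block ",
         names(n_modes)[which(n_modes > 1)[1]])
  invisible(trials)
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> %s/%s %s %s day %+d: %d trials, %d blocks\n",
              x$meta$monkey_id, x$meta$session_id, x$meta$treatment,
              x$meta$phase, x$meta$day_offset, nrow(x$trials),
              length(unique(x$trials$block_id))))
  invisible(x)
}

as_trial_tibble <- function(session) {
  if (inherits(session, "session_log")) session$trials
  else tibble::as_tibble(session)
}

session_layout <- function(session) {
  if (inherits(session, "session_log")) session$layout
  else attr(session, "layout")
}

session_meta <- function(session) {
  if (inherits(session, "session_log")) session$meta
  else attr(session, "meta")
}

fmt_num <- function(x, digits) {
  out <- formatC(x, format = "f", digits = digits)
  out[is.na(x)] <- "NA"
  out
}

#' Write a session log as tab-separated text
#'
#' The format is a commented header block of `# key: value` metadata lines
#' (including the target layout and a `format_version`), a tab-separated
#' column header, and one row per trial. Output is deterministic: fixed
#' column order, integer timestamps, coordinates with two fixed decimals —
#' writing the same log twice yields identical bytes.
#'
#' @param session a `session_log`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "session_log"))
  m <- session$meta
  lay <- session$layout
  hdr <- c(
    "# format_version: 1",
    paste0("# monkey_id: ", m$monkey_id),
    paste0("# session_id: ", m$session_id),
    paste0("# phase: ", m$phase),
    paste0("# treatment: ", m$treatment),
    paste0("# day_offset: ", m$day_offset),
    paste0("# seed: ", m$seed),
    paste0("# layout_x: ", paste(fmt_num(lay$centers[, "x"], 2), collapse = ",")),
    paste0("# layout_y: ", paste(fmt_num(lay$centers[, "y"], 2), collapse = ",")),
    paste0("# half_width: ", fmt_num(lay$half_width, 2))
  )
  tr <- session$trials[trial_columns]
  body <- paste(
    tr$trial_index, tr$block_id, tr$task_mode, tr$cue_target,
    ifelse(is.na(tr$cue_onset_ms), "NA", format(tr$cue_onset_ms, scientific = FALSE, trim = TRUE)),
    ifelse(is.na(tr$release_prev_ms), "NA", format(tr$release_prev_ms, scientific = FALSE, trim = TRUE)),
    ifelse(is.na(tr$touch_ms), "NA", format(tr$touch_ms, scientific = FALSE, trim = TRUE)),
    fmt_num(tr$touch_x, 2), fmt_num(tr$touch_y, 2), tr$raw_outcome,
    sep = "\t")
  writeLines(c(hdr, paste(trial_columns, collapse = "\t"), body), path)
  invisible(path)
}

#' Read a session log written by [write_session()]
#'
#' Fully validates the file: the column schema, strictly increasing trial
#' indices, target IDs, and release-before-touch ordering; malformed rows
#' are reported by row number.
#'
#' @param path file path.
#' @return a `session_log`.
#' @export
read_session <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta_lines <- lines[is_meta & seq_along(lines) <= which(!is_meta)[1]]
  kv <- sub("^#\\s*", "", meta_lines)
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  meta <- stats::setNames(as.list(vals), keys)
  if (!identical(meta$format_version, "1"))
    stop("unsupported or missing format_version in header")
  layout <- target_layout(
    centers_x = as.numeric(strsplit(meta$layout_x, ",")[[1]]),
    centers_y = as.numeric(strsplit(meta$layout_y, ",")[[1]]),
    half_width = as.numeric(meta$half_width))
  data_lines <- lines[!is_meta]
  if (length(data_lines) < 2) stop("no trials")
  header <- strsplit(data_lines[1], "\t", fixed = TRUE)[[1]]
  missing_cols <- setdiff(trial_columns, header)
  if (length(missing_cols) > 0)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  tr <- utils::read.delim(textConnection(data_lines), sep = "\t",
                          na.strings = "NA", stringsAsFactors = FALSE)
  tr <- tibble::as_tibble(tr)[trial_columns]
  tr$trial_index <- as.integer(tr$trial_index)
  tr$block_id <- as.integer(tr$block_id)
  tr$cue_target <- as.integer(tr$cue_target)
  for (col in c("cue_onset_ms", "release_prev_ms", "touch_ms",
                "touch_x", "touch_y"))
    tr[[col]] <- as.numeric(tr[[col]])
  session_log(tr, layout,
              monkey_id = meta$monkey_id, session_id = meta$session_id,
              phase = meta$phase, treatment = meta$treatment,
              day_offset = as.integer(meta$day_offset),
              seed = suppressWarnings(as.integer(meta$seed)))
}

#' Import a deposited source-data spreadsheet export
#'
#' Adapter for externally deposited trial tables (e.g. CSV exports of the
#' published source-data spreadsheets). Their internal schema is not fixed,
#' so the column mapping is supplied by the caller rather than hard-coded:
#' `mapping` names this package's trial columns and gives the corresponding
#' source column for each. Unmapped optional timing columns are filled with
#' `NA`.
#'
#' @param path CSV file path.
#' @param mapping named character vector, names from
#'   `c("trial_index", "block_id", "task_mode", "cue_target",
#'   "cue_onset_ms", "release_prev_ms", "touch_ms", "touch_x", "touch_y",
#'   "raw_outcome")`, values the source file's column names. `trial_index`,
#'   `task_mode`, `cue_target` are required.
#' @param layout a [target_layout()] describing the deposited geometry.
#' @param mode_labels named character vector translating the source file's
#'   task-mode labels to `"random"`/`"repeating"`.
#' @param ... metadata passed on to [session_log()].
#' @return a `session_log`.
#' @export
read_source_data <- function(path, mapping, layout,
                             mode_labels = c(Random = "random",
                                             Repeating = "repeating"),
                             ...) {
  required <- c("trial_index", "task_mode", "cue_target")
  if (!all(required %in% names(mapping)))
    stop("mapping must provide: ", paste(required, collapse = ", "))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  absent <- setdiff(unname(mapping), names(raw))
  if (length(absent) > 0)
    stop("source file lacks mapped column(s): ", paste(absent, collapse = ", "))
  tr <- tibble::tibble(trial_index = as.integer(raw[[mapping["trial_index"]]]))
  pick <- function(col, default) {
    if (col %in% names(mapping)) raw[[mapping[col]]] else default
  }
  n <- nrow(raw)
  mode_raw <- as.character(pick("task_mode", NULL))
  tr$task_mode <- unname(mode_labels[mode_raw])
  # blocks default to runs of constant task mode
  mode_runs <- cumsum(c(TRUE, tr$task_mode[-1] != tr$task_mode[-n]))
  tr$block_id <- as.integer(pick("block_id", mode_runs))
  tr$cue_target <- as.integer(pick("cue_target", NULL))
  tr$cue_onset_ms <- as.numeric(pick("cue_onset_ms", rep(NA_real_, n)))
  tr$release_prev_ms <- as.numeric(pick("release_prev_ms", rep(NA_real_, n)))
  tr$touch_ms <- as.numeric(pick("touch_ms", rep(NA_real_, n)))
  tr$touch_x <- as.numeric(pick("touch_x", rep(NA_real_, n)))
  tr$touch_y <- as.numeric(pick("touch_y", rep(NA_real_, n)))
  out_raw <- pick("raw_outcome", rep("hit", n))
  tr$raw_outcome <- ifelse(is.na(tr$touch_ms) & is.na(tr$touch_x),
                           "no_hit", tolower(as.character(out_raw)))
  session_log(tr, layout, ...)
}
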