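#' Pearson chi-square on a 2x2 pre/post table
#'
#' Tests whether a success proportion changed between phases. By default
#' this is the Pearson statistic without continuity correction (df = 1); the
#' correction is exposed as an option. A zero margin leaves the test
#' undefined and yields a not-computable result (`NA` statistic and p).
#'
#' @param pre,post integer pairs `c(successes, failures)`.
#' @param correct apply the Yates continuity correction.
#' @return list with `statistic`, `df`, `p`.
#' @examples
#' chi2_2x2(c(90, 10), c(50, 50))
#' @export
chi2_2x2 <- function(pre, post, correct = FALSE) {
  stopifnot(length(pre) == 2, length(post) == 2,
            all(pre >= 0), all(post >= 0))
  tab <- rbind(pre, post)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(statistic = NA_real_, df = 1L, p = NA_real_))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), df = 1L, p = unname(ht$p.value))
}

#' Holm-Bonferroni step-down rejections
#'
#' Controls the family-wise error rate: p-values are sorted ascending and
#' p(i) is compared against alpha / (m - i + 1); rejection stops at the
#' first failure. Flags are returned in input order. Holm rejects a
#' superset of plain Bonferroni and a subset of uncorrected alpha-level
#' tests.
#'
#' @param p_values numeric vector of p-values in `[0, 1]` (`NA` allowed for
#'   not-computable tests; never rejected, and not counted in the family
#'   size).
#' @param alpha family-wise error rate.
#' @return logical rejection flags in input order.
#' @examples
#' holm_bonferroni(c(0.010, 0.030, 0.040), alpha = 0.05)
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) stop("p_values must be nonempty")
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  rej <- rep(FALSE, length(p_values))
  rej[ok] <- stats::p.adjust(p_values[ok], method = "holm") <= alpha
  rej
}

#' Welch two-sample t-test on per-trial durations
#'
#' Two-sided, unequal-variance comparison of pre- versus post-injection
#' RT or MT values. Degenerate samples (n < 2 or zero variance in both
#' groups) are not computable.
#'
#' @param pre_values,post_values numeric vectors (ms).
#' @return list with `statistic`, `df`, `p` (all `NA` when not computable).
#' @export
ttest_two_sample <- function(pre_values, post_values) {
  pre_values <- pre_values[!is.na(pre_values)]
  post_values <- post_values[!is.na(post_values)]
  if (length(pre_values) < 2 || length(post_values) < 2 ||
      (stats::var(pre_values) == 0 && stats::var(post_values) == 0)) {
    if (length(pre_values) >= 2 && identical(pre_values, post_values))
      return(list(statistic = 0, df = 2 * length(pre_values) - 2, p = 1))
    return(list(statistic = NA_real_, df = NA_real_, p = NA_real_))
  }
  ht <- stats::t.test(pre_values, post_values, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Paired t-test on session-level differences
#'
#' One-sample two-sided t-test of the differences against zero, df = n - 1.
#' Used for population contrasts across injection sessions (e.g. six
#' sessions give df = 5). Zero-variance differences are not computable.
#'
#' @param diffs numeric vector of paired differences.
#' @return list with `statistic`, `df`, `p`.
#' @examples
#' ttest_paired(1:6)  # t = 4.583, df = 5
#' @export
ttest_paired <- function(diffs) {
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) < 2)
    return(list(statistic = NA_real_, df = NA_real_, p = NA_real_))
  if (stats::var(diffs) == 0) {
    if (all(diffs == 0))
      return(list(statistic = 0, df = length(diffs) - 1, p = 1))
    return(list(statistic = NA_real_, df = NA_real_, p = NA_real_))
  }
  ht <- stats::t.test(diffs, mu = 0)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Pre/post statistical contrasts for one session
#'
#' For every movement observed in both phases of a task (with at least
#' `min_n` included trials in each), runs the four contrasts: a 2x2
#' chi-square on correct versus error counts, a 2x2 chi-square on
#' predictive versus non-predictive counts among correct responses, and
#' Welch t-tests on per-trial RT and MT of correct responses.
#' Holm-Bonferroni correction is applied within each family, defined as the
#' movements of one test kind in one task mode.
#'
#' The session effect ranks repeating-task movements by their post-minus-pre
#' error-rate change: the strongest effect is the largest increase, the
#' weakest the smallest (ties broken toward the lower movement in from-to
#' order).
#'
#' @param pre,post classified-trial tibbles (see [classify_trials()]) for
#'   the baseline and post-injection phases.
#' @param alpha family-wise error rate.
#' @param min_n minimum included trials per phase for a movement to enter
#'   the analysis (screens out sparsely visited error-recovery movements).
#' @param chi2_correct passed to [chi2_2x2()].
#' @return list with `tests` (tibble: movement, task_mode, test_kind,
#'   statistic, df, p_raw, significant_adjusted, alpha), `effect` (tibble of
#'   per-movement deltas plus `strongest_movement`/`weakest_movement`
#'   attributes), and `summaries` (the per-movement pre/post summaries).
#' @export
session_contrast <- function(pre, post, alpha = 0.05, min_n = 20,
                             chi2_correct = FALSE) {
  s_pre <- summarize_by_movement(pre)
  s_post <- summarize_by_movement(post)
  s_pre$phase <- "pre"; s_post$phase <- "post"
  key <- c("movement", "task_mode")
  merged <- dplyr::inner_join(
    dplyr::filter(s_pre, .data$n_included >= min_n),
    dplyr::filter(s_post, .data$n_included >= min_n),
    by = key, suffix = c("_pre", "_post"))
  skipped <- setdiff(unique(c(paste(s_pre$movement, s_pre$task_mode),
                              paste(s_post$movement, s_post$task_mode))),
                     paste(merged$movement, merged$task_mode))
  if (length(skipped) > 0)
    warning("movements without enough data in both phases skipped: ",
            paste(skipped, collapse = "; "))
  if (nrow(merged) == 0) stop("no movement has enough data in both phases")

  trial_rt <- function(trials, mv, mode) {
    i <- trials$included & !is.na(trials$from_target) &
      paste0(trials$from_target, "-", trials$to_target) == mv &
      trials$task_mode == mode & trials$response_class == "correct"
    trials[i, c("rt_ms", "mt_ms")]
  }

  rows <- lapply(seq_len(nrow(merged)), function(i) {
    m <- merged[i, ]
    err_pre <- c(m$n_correct_pre,
                 m$n_included_pre - m$n_correct_pre)
    err_post <- c(m$n_correct_post,
                  m$n_included_post - m$n_correct_post)
    ce <- chi2_2x2(err_pre, err_post, correct = chi2_correct)
    cp <- chi2_2x2(c(m$n_predictive_pre, m$n_nonpredictive_pre),
                   c(m$n_predictive_post, m$n_nonpredictive_post),
                   correct = chi2_correct)
    dpre <- trial_rt(pre, m$movement, m$task_mode)
    dpost <- trial_rt(post, m$movement, m$task_mode)
    trt <- ttest_two_sample(dpre$rt_ms, dpost$rt_ms)
    tmt <- ttest_two_sample(dpre$mt_ms, dpost$mt_ms)
    tibble::tibble(
      movement = m$movement, task_mode = m$task_mode,
      test_kind = c("chi2_error", "chi2_predictive", "ttest_rt", "ttest_mt"),
      statistic = c(ce$statistic, cp$statistic, trt$statistic, tmt$statistic),
      df = c(ce$df, cp$df, trt$df, tmt$df),
      p_raw = c(ce$p, cp$p, trt$p, tmt$p))
  })
  tests <- dplyr::bind_rows(rows)
  tests <- tests |>
    dplyr::group_by(.data$task_mode, .data$test_kind) |>
    dplyr::mutate(significant_adjusted = holm_bonferroni(.data$p_raw, alpha),
                  alpha = alpha) |>
    dplyr::ungroup()

  eff <- merged |>
    dplyr::mutate(
      d_error_rate = (1 - .data$n_correct_post / .data$n_included_post) -
        (1 - .data$n_correct_pre / .data$n_included_pre),
      d_predictive_rate =
        .data$n_predictive_post / .data$n_correct_post -
        .data$n_predictive_pre / .data$n_correct_pre,
      d_mean_rt_ms = .data$mean_rt_ms_post - .data$mean_rt_ms_pre,
      d_mean_mt_ms = .data$mean_mt_ms_post - .data$mean_mt_ms_pre) |>
    dplyr::select(dplyr::all_of(key), dplyr::starts_with("d_"))
  rep_eff <- eff[eff$task_mode == "repeating", ]
  rep_eff <- rep_eff[order(rep_eff$movement), ]
  strongest <- if (nrow(rep_eff)) rep_eff$movement[which.max(rep_eff$d_error_rate)]
               else NA_character_
  weakest <- if (nrow(rep_eff)) rep_eff$movement[which.min(rep_eff$d_error_rate)]
             else NA_character_
  attr(eff, "strongest_movement") <- strongest
  attr(eff, "weakest_movement") <- weakest
  list(tests = tests, effect = eff,
       summaries = dplyr::bind_rows(s_pre, s_post))
}

#' Population aggregation across injection sessions
#'
#' For each session, takes its strongest- and weakest-effect repeating-task
#' movements (largest/smallest post-minus-pre error-rate increase) and the
#' same movement identities in the random task, then averages pre/post
#' error rates and predictive percentages across sessions (mean and
#' standard error) and runs paired t-tests of post versus pre.
#'
#' Note the strongest/weakest movements are selected on the same data they
#' are then tested on; under a null generator this selection inflates the
#' strongest-movement rejection rate above alpha, which is a property of
#' the procedure, not a bug.
#'
#' @param contrasts named list of [session_contrast()] results (one per
#'   session; at least two).
#' @return list with `table` (tibble: task_mode, selection, measure, pre/post
#'   mean and SE, paired t statistic, df, p, n_sessions) and `per_session`
#'   (the session-level rates entering the aggregates).
#' @export
population_summary <- function(contrasts) {
  if (length(contrasts) < 2)
    stop("population aggregation needs at least 2 sessions")
  per <- dplyr::bind_rows(lapply(seq_along(contrasts), function(i) {
    ct <- contrasts[[i]]
    sid <- names(contrasts)[i] %||% as.character(i)
    sm <- ct$summaries
    sel <- tibble::tibble(
      selection = c("strongest", "weakest"),
      movement = c(attr(ct$effect, "strongest_movement"),
                   attr(ct$effect, "weakest_movement")))
    dplyr::bind_rows(lapply(seq_len(nrow(sel)), function(j) {
      mv <- sel$movement[j]
      rows <- sm[sm$movement == mv, ]
      if (nrow(rows) == 0) return(NULL)
      rows |>
        dplyr::mutate(session_id = sid, selection = sel$selection[j],
                      error_rate = 1 - .data$n_correct / .data$n_included,
                      predictive_pct =
                        100 * .data$n_predictive / .data$n_correct) |>
        dplyr::select("session_id", "selection", "movement", "task_mode",
                      "phase", "error_rate", "predictive_pct")
    }))
  }))
  se <- function(x) stats::sd(x) / sqrt(length(x))
  long <- per |>
    tidyr::pivot_longer(c("error_rate", "predictive_pct"),
                        names_to = "measure", values_to = "value") |>
    tidyr::pivot_wider(names_from = "phase", values_from = "value")
  tab <- long |>
    dplyr::group_by(.data$task_mode, .data$selection, .data$measure) |>
    dplyr::summarise(
      n_sessions = dplyr::n(),
      pre_mean = mean(.data$pre), pre_se = se(.data$pre),
      post_mean = mean(.data$post), post_se = se(.data$post),
      t = ttest_paired(.data$post - .data$pre)$statistic,
      df = ttest_paired(.data$post - .data$pre)$df,
      p = ttest_paired(.data$post - .data$pre)$p,
      .groups = "drop")
  list(table = tab, per_session = per)
}
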