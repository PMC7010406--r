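# Shared fixtures: all built in code at test time.

# An agent with no noise, no bias, no lapses: every reach lands dead center
# on the cued target.
noiseless_agent <- function(...) {
  args <- list(endpoint_sigma = 0, undershoot_bias = 0,
               p_direction_error = 0, p_no_hit = 0, p_fast_guess = 0)
  user <- list(...)
  args[names(user)] <- user
  do.call(agent_params, args)
}

# Hand-built classified-trial tibble from per-movement counts, for driving
# the statistics layer with exactly known tables.
make_classified <- function(counts, phase, task_mode = "repeating",
                            rt_mean = 300, mt_mean = 200) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    cls <- c(rep("correct", r$n_correct),
             rep("accuracy_error", r$n_acc %||0% 0),
             rep("direction_error", r$n_dir %||0% 0))
    n <- length(cls)
    tibble::tibble(
      task_mode = task_mode,
      from_target = r$from, to_target = r$to,
      response_class = cls,
      predictive = c(rep(TRUE, r$n_pred %||0% 0),
                     rep(FALSE, n - (r$n_pred %||0% 0))) &
        cls == "correct",
      rt_ms = rt_mean + seq_len(n),
      mt_ms = mt_mean + seq_len(n),
      included = TRUE)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "meta") <- list(phase = phase)
  out
}

`%||0%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

# Closed-form Pearson chi-square oracle for a 2x2 table, independent of the
# implementation under test.
chi2_closed_form <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  (a * d - b * c)^2 * n / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Brute-force Holm step-down enumeration.
holm_brute <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  reject_sorted <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= alpha / (m - i + 1)) reject_sorted[i] <- TRUE
    else break
  }
  out <- logical(m)
  out[ord] <- reject_sorted
  out
}
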