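#!/usr/bin/env Rscript
# Per-session pre/post statistical contrasts: chi-square tests on error and
# predictive-response proportions and Welch t-tests on RT/MT per movement,
# Holm-corrected within each test family. Writes one test table per session
# and prints the per-movement picture for the exemplar anisomycin session.

suppressPackageStartupMessages(library(seqreach))

in_dir <- "results/sessions"
out_dir <- "results/contrasts"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
pre_files <- list.files(in_dir, pattern = "_pre\\.tsv$", full.names = TRUE)
if (length(pre_files) == 0) stop("run analysis/01_simulate_sessions.R first")

for (f in pre_files) {
  id <- sub("_pre\\.tsv$", "", basename(f))
  pre <- classify_trials(read_session(f))
  post <- classify_trials(read_session(sub("_pre", "_post", f)))
  ct <- suppressWarnings(session_contrast(pre, post))
  write.csv(ct$tests, file.path(out_dir, paste0(id, "_tests.csv")),
            row.names = FALSE)
  n_sig <- function(mode, kind) {
    t <- ct$tests
    sum(t$significant_adjusted[t$task_mode == mode & t$test_kind == kind],
        na.rm = TRUE)
  }
  cat(sprintf(
    "%-12s repeating: %d/%d moves sig. error incr., %d sig. predictive drop | random: %d sig. error\n",
    id, n_sig("repeating", "chi2_error"),
    sum(ct$tests$task_mode == "repeating" &
          ct$tests$test_kind == "chi2_error"),
    n_sig("repeating", "chi2_predictive"), n_sig("random", "chi2_error")))
  cat(sprintf("             strongest effect: move %s, weakest: move %s\n",
              attr(ct$effect, "strongest_movement"),
              attr(ct$effect, "weakest_movement")))
}

cat("\nExemplar session (aniso_N1), per-movement detail:\n")
pre <- classify_trials(read_session(file.path(in_dir, "aniso_N1_pre.tsv")))
post <- classify_trials(read_session(file.path(in_dir, "aniso_N1_post.tsv")))
ct <- suppressWarnings(session_contrast(pre, post))
t <- ct$tests
for (mode in c("random", "repeating")) {
  cat(sprintf(" %s task, error-rate chi-square (df = 1):\n", mode))
  tt <- t[t$task_mode == mode & t$test_kind == "chi2_error" &
            t$movement %in% c("5-3", "3-1", "1-5", "1-2", "2-4", "4-1"), ]
  for (i in order(tt$movement)) {
    cat(sprintf("   move %s: chi2 = %7.2f, p = %.3g%s\n", tt$movement[i],
                tt$statistic[i], tt$p_raw[i],
                if (isTRUE(tt$significant_adjusted[i])) " *" else ""))
  }
}
cat("\nThe memory-guided (repeating) task degrades; the visually guided\n")
cat("(random) task does not: the anisomycin scenario is task-selective.\n")
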