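#!/usr/bin/env Rscript
# Simulate the full injection-experiment dataset: six anisomycin sessions
# (four for monkey N on sequences 5-3-1 / 1-2-4, two for monkey R on
# sequence 2-3-4), two muscimol sessions and one saline control, each as a
# pre-injection baseline plus a post-injection test session. Trial logs are
# written under results/sessions/.

suppressPackageStartupMessages(library(seqreach))

seed <- 20260929L
out_dir <- "results/sessions"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
n_trials <- 2400L

ps_N <- scenario_preset("anisomycin_session2_N")

# Monkey R practiced one sequence (2-3-4). The published effect sizes
# describe monkey N's exemplar session, so monkey R's degradation is an
# interpolated scenario built with the same closed-form calibration:
# moderate error increases on all three of its movements.
seq_R <- list(c(2L, 3L, 4L))
pre_sigma <- ps_N$agent$endpoint_sigma[1, 1]
degrade <- function(from, to, p_correct) {
  s_post <- sigma_for_correct((1 + p_correct) / 2)
  rbind(
    data.frame(param = "sigma_multiplier", from = from, to = to,
               value = s_post / pre_sigma),
    data.frame(param = "d_undershoot_bias", from = from, to = to,
               value = -bias_for_correct(p_correct, s_post)))
}
effect_R <- injection_effect(
  "anisomycin", d_p_predictive = 0.45, d_mt_ms = 45.82,
  overrides = rbind(degrade(2, 3, 0.60), degrade(3, 4, 0.75),
                    degrade(4, 2, 0.65)))

plan <- list()
for (s in 1:4)
  plan[[length(plan) + 1]] <- list(monkey = "N", id = sprintf("aniso_N%d", s),
                                   agent = ps_N$agent, effect = ps_N$effect,
                                   sequences = ps_N$sequences)
for (s in 1:2)
  plan[[length(plan) + 1]] <- list(monkey = "R", id = sprintf("aniso_R%d", s),
                                   agent = ps_N$agent, effect = effect_R,
                                   sequences = seq_R)
mus <- scenario_preset("muscimol")
for (s in 1:2)
  plan[[length(plan) + 1]] <- list(monkey = "N", id = sprintf("musc_N%d", s),
                                   agent = mus$agent, effect = mus$effect,
                                   sequences = mus$sequences)
sal <- scenario_preset("saline")
plan[[length(plan) + 1]] <- list(monkey = "N", id = "saline_N1",
                                 agent = sal$agent, effect = sal$effect,
                                 sequences = sal$sequences)

for (i in seq_along(plan)) {
  p <- plan[[i]]
  for (ph in c("pre", "post")) {
    s <- simulate_session(
      n_trials, p$agent, p$effect, phase = ph,
      seed = (seed + 211 * i + (ph == "post")) %% 2147483647,
      sequences = p$sequences, monkey_id = p$monkey, session_id = p$id)
    f <- file.path(out_dir, sprintf("%s_%s.tsv", p$id, ph))
    write_session(s, f)
    cat(sprintf("%-22s %4d trials, %2d blocks -> %s\n", p$id,
                nrow(s$trials), length(unique(s$trials$block_id)), f))
  }
}
cat("\nSimulated", length(plan), "injection sessions (pre + post each):",
    "6 anisomycin, 2 muscimol, 1 saline.\n")
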