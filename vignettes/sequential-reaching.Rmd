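---
title: "Simulating and analyzing memory-guided sequential reaching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing memory-guided sequential reaching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqreach)
```

## The behavioral paradigm

`seqreach` models a touchscreen reaching paradigm used to dissociate
memory-guided from visually guided sequential movements in non-human
primates. Five targets sit in a horizontal row (IDs 1–5, left to right).
In the **Random task** the next target is drawn pseudo-randomly and cued
100 ms after the previous touch: every reach is visually guided. In the
**Repeating task** targets follow a fixed three-element sequence (the
standard sequences are 5-3-1, 1-2-4 and 2-3-4) and the cue appears only
400 ms after the previous touch, so a practiced animal can move from
memory *before* the cue. Responses must land within 800 ms of cue onset;
errors and misses repeat the trial. Alternating blocks of 200–500 trials
of each task make up a session of up to a few thousand trials.

The analysis quantities are:

* **MT** (movement time): release of one target to touch of the next.
* **RT** (response time): cue onset to touch in the Random task; in the
  Repeating task the inter-touch interval minus the 400 ms delay, which is
  *negative* when the hand moves before the cue.
* **Predictive response**: a correct response with RT < 150 ms — too fast
  to be a reaction to the cue, hence generated from memory. The cutoff is
  strict (`RT = 150` is non-predictive).
* **Accuracy error**: a reach in the correct direction ending outside the
  correct target. **Direction error**: a reach in the direction opposite
  to the correct target. Touches between targets count toward the nearest
  center (ties to the lower ID), but a *correct* response must land inside
  the correct target's acceptance radius.

Three trial types are excluded from analysis: corrective responses
(correct responses following an error — the repeated target is
predictable), no-hit trials (attributable to lapses of motivation), and
Random-task trials with RT < 150 ms (possible carry-over of anticipatory
responding). Pre/post injection contrasts use per-movement 2×2 chi-square
tests (error vs correct; predictive vs non-predictive among correct) and
per-trial Welch t-tests on RT and MT, with Holm–Bonferroni correction.

## The generative agent

The simulator exists so that every pipeline stage can be exercised, and
its estimators validated, against known ground truth. Behavior is
parameterized per movement (ordered from→to target pair):

| parameter | meaning | default |
|---|---|---|
| `p_predictive` | probability a Repeating-task response is predictive | 0.92 |
| `rt_pred_mean`, `rt_pred_sd` | predictive RT location/scale (ms), truncated to (−400, 150) | 50, 60 |
| `rt_cued_mean`, `rt_cued_sd` | cue-driven RT location/scale (ms), truncated to (150, 800) | 350, 90 |
| `mt_mean`, `mt_sd` | movement time (ms) | 200, 35 |
| `endpoint_sigma` | isotropic endpoint noise (screen units) | 13 |
| `undershoot_bias` | signed endpoint shift along the movement direction | 0 |
| `p_direction_error` | probability the aim flips to the opposite-side neighbor | 0.002 |
| `p_no_hit` | probability of no registered touch | 0.005 |
| `p_fast_guess` | Random-task probability of a fast anticipatory guess | 0.02 |
| `dwell_ms` | minimum hold before release | 50 |

RT distributions are truncated Gaussians; only the 150 ms cutoff and mean
shifts are empirically constrained, so locations and scales are the
package's own choices of plausible primate reaction times. Predictive
draws are truncated strictly below the cutoff and cued draws at or above
it, so generative labels and derived classifications round-trip exactly
(a property the test suite asserts). Draw timestamps are integers (ms);
the predictive draw is capped at 149 ms after rounding to preserve the
round trip.

A direction error replaces the aim by the nearest target on the *opposite*
side of the origin (e.g. a leftward reach from target 2 when target 4 was
cued); when no opposite-side target exists (an outward reach from an end
target) the branch is skipped rather than redirected — end targets cannot
produce direction errors. Accuracy errors are *emergent*: they arise from
`endpoint_sigma` and `undershoot_bias`, not from a dedicated probability.

Release times are derived as `touch − MT`, clipped so release never
precedes the previous touch plus the dwell time; the paradigm defines MT
but not dwell, so dwell is a simulator convention. After a missed
response the clock resumes from the end of the response window.

### Endpoint calibration in closed form

With isotropic noise σ and the aim offset a distance *d* from the target
center, the squared center distance over σ² is noncentral chi-square with
2 df and noncentrality (d/σ)², so

P(hit) = `pchisq(r²/σ², df = 2, ncp = (d/σ)²)`,

with *r* the acceptance radius. `sigma_for_correct()` and
`bias_for_correct()` invert this, which lets scenario presets hit stated
correct rates exactly rather than by trial and error. The
`anisomycin_session2_N` preset is calibrated this way: pre-injection
correct rates of 96% (move 1-5), 93% (move 2-4) and 95% elsewhere;
post-injection, within the Repeating task only, predictive probability on
move 5-3 falls 92.4% → 35.3%, move 1-5 falls to 55% correct with an
undershoot bias (accuracy-error dominated), move 2-4 gains an 18%
direction-error rate, moves 4-1 and 1-2 degrade to 65% and 85%, move 3-1
is untouched, and MT slows by 45.82 ms. Each degraded movement's loss is
split between noise and bias: the post noise level alone would leave the
correct rate at the midpoint between one and the target, and the bias
accounts for the remainder. Only two movements' pre-injection error
compositions are empirically pinned down; the remaining rates are
interpolations, and the preset says so in its `notes`.

The ~140 ms mean-RT increase in the Repeating task is *not* an explicit
delta: it emerges from the predictive→cued composition shift. A drop of
0.45 in predictive probability moves that much probability mass from the
predictive RT mean (≈ 44 ms after truncation) to the cued mean
(≈ 353 ms), a shift of ≈ 0.45 × 309 ≈ 139 ms. The injection deltas apply
to *generative* parameters, never to derived statistics, so parameter
recovery is non-circular.

The effect scopes encode the pharmacology: anisomycin
(protein-synthesis inhibition, disrupting stored sequence information)
affects only the Repeating task; muscimol (inactivation of motor output)
affects both tasks; saline affects neither, and its constructor rejects
non-neutral deltas.

## Design choices where the paradigm is open

* **Random scheduling.** The pseudo-random order is i.i.d. uniform over
  the four targets other than the one just hit: an immediate repeat would
  define a zero-length movement, and analyses are stratified by nonzero
  movements. The first cue of a block defaults to the first sequence
  element (Repeating) or a seeded draw (Random).
* **Movement origin.** The origin of a movement is where the hand
  actually is — the previous trial's assigned touch target, carried over
  missed responses — not the previously *cued* target. After an error the
  repeated trial is therefore a different movement (e.g. 4→5 after an
  undershoot on 1→5), which is how corrective and recovery reaches enter
  the data.
* **Direction sign.** Direction is judged on the horizontal axis only
  (the targets are collinear); a touch with zero horizontal displacement
  from the origin is an "other" error, outside the accuracy/direction
  dichotomy.
* **Corrective relabeling** looks back exactly one trial and is applied
  before exclusions, because an erroneous trial is repeated immediately.
  A correct response after a *no-hit* is also treated as corrective (the
  repeated target is equally predictable); this is an assumption the
  paradigm's description implies but does not state.
* **First trial of a block** has no defined movement and is dropped from
  movement-level analyses.
* **Anticipations in the Random task** are permitted by the engine (the
  response window has no lower edge) and excluded by the metrics layer,
  which is why `p_fast_guess` exists: it generates the excluded class so
  the exclusion rule is exercised.
* **Chi-square without continuity correction** (df = 1 Pearson), **Welch**
  rather than pooled-variance t-tests, and **two-sided** tests throughout;
  all three choices are exposed as options. RT/MT t-tests use per-trial
  values, not block means.
* **Holm family** = the movements of one test kind within one task and
  session. The family definition is not empirically constrained; this is
  the narrowest defensible choice and is applied uniformly.
* **Strongest/weakest selection** ranks Repeating-task movements by
  post-minus-pre error-rate increase, ties broken toward the lower
  movement in from→to order, and only considers movements with at least
  20 included trials in both phases — off-sequence recovery movements
  (visited a handful of times after errors) would otherwise dominate the
  argmax. Note the selection is made on the same data that the paired
  population tests then use: under a null generator the strongest-movement
  rejection rate exceeds the nominal α by construction. The package
  characterizes this rather than hiding it.

## What the tests do and do not establish

The test suite checks the statistics against independent oracles (the
closed-form 2×2 chi-square, brute-force Holm step-down, hand-computed
t values), asserts the classification invariants (partition into response
classes, count identities, threshold monotonicity) on randomly drawn
agents, verifies the simulator against the task engine's scheduling rules,
and runs two Monte-Carlo campaigns at the trial counts of a real injection
session (2,400 trials per phase, roughly 200 included trials per Repeating
movement): a null calibration of the error chi-square under the saline
preset (500 session pairs; per-test type-I error within 0.05 ± 0.02) and
blind parameter recovery under the anisomycin preset (200 replicates;
pooled recovered rates within 3 binomial SEs of generative truth,
repeating-task contrasts rejecting at p < 0.001 in >99% of replicates,
random-task contrasts Holm-clean in ≥90%).

The generator emulates the *stationary* structure of the task: scheduling,
timing, endpoint noise, error taxonomy, and injection effects as step
changes between phases. It does not model learning dynamics across
training days, within-session drift (fatigue, satiety), kinematic
trajectories between touches, or reward-schedule effects on motivation
(reward timing is log metadata only). Passing recovery tests therefore
show that the pipeline correctly measures what this generative family
produces — not that real sessions lack the unmodeled structure. The
format adapter `read_source_data()` exists so deposited trial tables can
be mapped into the same pipeline when available; its column mapping is
caller-supplied because deposited schemas vary.

## Reproducibility

Every stochastic function takes an explicit integer seed and restores the
caller's RNG state. `run_pipeline()` splits one root seed per session and
writes an MD5 manifest of every artifact; identical configurations yield
identical bytes. The trial-log format is fixed-precision text (integer
millisecond timestamps, two-decimal coordinates), so write → read → write
is byte-idempotent.
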