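---
title: "Phenotyping endogenous pain modulation from continuous VAS ratings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping endogenous pain modulation from continuous VAS ratings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painmod)
```

## The problem

Healthy people differ strikingly in how their nervous system modulates
pain. Under three classic psychophysical paradigms — placebo analgesia
(an inert "lidocaine" cream the participant believes is analgesic),
conditioned pain modulation (CPM: a remote tonic muscle-pain stimulus
applied while a test heat stimulus is rated) and offset analgesia (a
disproportionate pain drop after a small 1 °C decrease of a noxious
temperature) — some individuals report much less pain (*inhibitors*),
some report no change (*nonresponders*), and some report more
(*facilitators*).

`painmod` implements the behavioural analysis of such experiments. Each
participant contributes two recording series of eight noxious heat blocks
each, rated continuously on a 0–100 visual analogue scale (VAS) sampled
every 0.5 s: a control series, then a modulated series (placebo cream /
concurrent conditioning pain / offset temperature profile). The package

1. reduces each continuous trace to eight per-block mean VAS values,
2. classifies each subject with a bootstrapped resampling test, and
3. computes cohort statistics: label proportions, paired effect sizes,
   percent pain change, rating variability, normality-gated group
   comparisons and questionnaire ANOVAs.

Because raw human data from these paradigms are not publicly deposited,
the package ships a synthetic-cohort generator that reproduces the
statistical structure the analysis assumes, making every stage testable
end to end.

## Paradigm timing

`paradigm_timing()` encodes the fixed schedules. Placebo and CPM use
15 s stimulus blocks (with 2.5 s thermode ramps at 4 °C/s counted inside
the block) and 15 s inter-stimulus intervals (ISI). Offset analgesia uses
a fast thermode: 14.4 s blocks, 14.4 s ISIs, and within each block of the
*offset* series the profile T1 = 4 s at the moderate temperature,
T2 = 4 s raised by 1 °C, T3 = 6.4 s back down.

The analysed windows per paradigm are:

* placebo / CPM — the full 15 s block, both series (ramps included,
  because the block mean is defined over the whole pain period);
* offset — the T3 window of the offset series against the time-matched
  last 6.4 s of each control block.

All windows are half-open `[start, end)`: a sample on a boundary belongs
to the later window, so consecutive windows never double-count. Sampling
is anchored at each segment onset, and a segment of duration `d` holds
`floor(d / 0.5)` samples. For 15 s blocks this is the plain 0.5 s grid
(30 samples); for 14.4 s offset blocks it gives 28 in-block samples and
exactly 8/8/12 samples in T1/T2/T3. This convention is needed because
14.4 s is not an integer multiple of the whole-series grid; its
consequence — timestamps are uniformly spaced within a segment but not
across segment boundaries in the offset paradigm — is deliberate and
asserted in the tests.

## The responder classifier

For each subject the two series yield 8 + 8 block means. The test:

1. draw `B = 10000` bootstrap resamples of the mean from each series
   independently (each resample = mean of 8 draws with replacement);
2. pair the two streams by replicate index and form
   `d_b = test_mean_b − control_mean_b`;
3. `p_inhibit = #(d_b ≥ 0)/B` and `p_facilitate = #(d_b ≤ 0)/B`,
   one-tailed;
4. label *inhibitor* if `p_inhibit < α`, else *facilitator* if
   `p_facilitate < α`, else *nonresponder*, with `α = 0.05` one-tailed.

Design choices worth making explicit:

* **Resampling of block means, not raw samples.** The unit of evidence
  is the stimulus block; the eight block means are what the test
  resamples.
* **Paired-difference reading.** The two bootstrap streams are
  independent and compared replicate-by-replicate; a
  permutation-of-pooled-values scheme was rejected because each series is
  explicitly resampled "with replacement" on its own.
* **Ties count toward both tails.** `p_inhibit + p_facilitate ≥ 1`
  always, so with `α < 0.5` the inhibitor and facilitator calls are
  mutually exclusive, and two identical constant series are labelled
  nonresponder (both p-values equal 1) rather than erroring.
* **Plain tail proportions.** No +1 continuity correction, mirroring the
  stated B-sample procedure; the exact oracle below quantifies the
  granularity this induces.
* **Per-subject RNG streams.** Each subject's resampling stream is
  derived from the master seed and the subject id by a stable string
  hash, so classifications are reproducible and independent of cohort
  order. Because the two streams are drawn in argument order, swapping
  control and test mirrors the p-values within Monte-Carlo tolerance
  (the mirror is exact for the enumeration oracle).

### The exact-enumeration oracle

A bootstrap mean of 8 draws from 8 values has only `C(15,7) = 6435`
distinct multisets. `exact_bootstrap_p()` enumerates them for both series
with their multinomial probabilities and returns the exact
`P(d ≥ 0)` and `P(d ≤ 0)` under independent pairing — the population
limit of the Monte-Carlo test. It is used three ways: as a correctness
oracle (the B = 10000 estimate must sit within binomial error of it), as
a fast deterministic classifier in power/calibration studies, and to
separate Monte-Carlo noise from properties of the test itself.

### Calibration

A bootstrap-of-means test on n = 8 block means is not exactly calibrated:
the acceptance script measures the fraction of exchangeable (null)
subjects receiving a non-nonresponder label and it exceeds the nominal
`2α = 10 %`. The package treats this as a property of the procedure
itself, faithfully reproduced — not something to correct silently.
What *is* asserted is internal consistency: the Monte-Carlo labelling
rate tracks the exact oracle's rate to within two percentage points, and
both are stable across seeds. Anyone comparing inhibitor proportions
across studies should keep this anticonservatism in mind.

## The synthetic cohort generator

`simulate_cohort()` draws, per subject: a true class (inhibitor /
nonresponder / facilitator), a moderate-pain baseline, a modulation
effect added to every block of series 2, noise scales, covariates and
questionnaire scores, then renders both continuous traces.

**Noise model.** Within a stimulus block the latent level is
`baseline (+ delta for series 2) + b_k`, with `b_k ~ N(0, σ_block)` per
block, plus `N(0, σ_within)` jitter per 0.5 s sample; everything is
clamped to [0, 100]. ISI ratings decay linearly to zero over the first
5 s of the ISI (the ISI temperature is non-painful); no analysed window
overlaps the ISI, so the decay shape is immaterial. The induced variance
of a block mean is

\[ \mathrm{Var}(\bar{y}_k) = \sigma_\text{block}^2 +
   \sigma_\text{within}^2 / m, \]

with `m` the samples per block (30 for placebo/CPM), and the SD of the
eight block means converges to the square root of that quantity — a
property the test-suite checks against direct resampling of this
generative law.

**Defaults as study conditions.** The defaults encode the magnitudes
reported for these paradigms: class effects `N(−12.4, 4.8)` /
`0` / `N(+13.3, 7.0)` VAS points; per-subject between-block SD drawn from
`N(7, 2)` truncated at 0.5 (placing most series variability in the
4–12 VAS-point range); within-block jitter SD `N(2, 0.5)`; baselines
uniform on the moderate-pain target 40–50; calibrated thermode
temperatures on the 44–48.5 °C grid in 0.5 °C steps, centred near
46.8 °C; a default class mix of 49/34/17 %. Dispositional optimism
(LOT-R) is generated mildly class-dependent (inhibitors most
optimistic, means 15.6/14.1/12.0, SD 4.4), the other instruments
class-independent, so the questionnaire ANOVA stage has realistic inputs.

**Allocation and reproducibility.** Class labels are assigned by a
deterministic sequential quota rule (each subject takes the class with
the largest running deficit `mix · i − count`), which satisfies quota —
100 subjects at mix (0.49, 0.34, 0.17) give exactly 49/34/17 — and is
prefix-stable: enlarging a cohort never relabels earlier subjects. Every
subject's profile and traces are drawn in an RNG stream sub-seeded from
the spec seed and the subject id, so cohorts are byte-reproducible and
subjects mutually independent. Emitted values are quantised to 10⁻⁴
(far below rating-device resolution), which makes the CSV serialisation
lossless: simulate → write → read → analyse reproduces the in-memory
analysis bit for bit.

**What the generator does not emulate.** Real VAS traces carry slider
kinematics (finite movement speed, touch latency), serial correlation
within blocks, habituation/sensitisation drift across blocks, and
occasional non-compliance — none of which are modelled. Passing tests
therefore demonstrate the correctness and calibration of the *analysis*
under the stated generative law, not robustness of the paradigms to
messy human rating behaviour.

## Cohort statistics

* `paired_effect()` — mean, sample SD (n−1), paired Cohen's
  `D = |mean|/SD`, `t = mean/(SD/√n)`, two-sided p on n−1 df. The
  two-sided convention applies to group-level effect summaries; the
  one-tailed rule belongs to subject classification only. A zero-SD
  vector yields a flagged degenerate result instead of a number.
  `prescribed_diffs()` constructs a vector with exact sample moments, so
  reported effect summaries can be recomputed from their n/mean/SD moments.
* `percent_change()` — per-subject `100·(test−control)/control`,
  summarised as mean ± SEM across subjects (the per-subject-then-average
  convention; a ratio of group means would weight subjects unequally).
* `two_proportion_test()` — pooled two-proportion z, two-sided; a pooled
  proportion of 0 or 1 returns `z = 0, p = 1` (no evidence of a
  difference) by documented convention.
* `normality_gate()` — Lilliefors-corrected Kolmogorov–Smirnov per group
  (parameters estimated from the sample, critical values via
  `nortest::lillie.test`); any departure at 0.05, a zero-variance group,
  or a group below the test's n ≥ 5 requirement routes the whole family
  of pairwise comparisons to Mann–Whitney U (`stats::wilcox.test`: exact
  for small untied samples, normal approximation with tie correction
  otherwise). Otherwise pooled-variance two-sample t-tests are used.
* `compare_groups()` — all pairwise contrasts among the three labels,
  Bonferroni-corrected with family size 3 (the three pairwise contrasts
  per measure per paradigm), capped at 1.
* `anova_with_posthoc()` — one-way fixed-effects ANOVA; if p < 0.05, all
  pairwise pooled-variance t-tests, uncorrected. Zero within-group
  variance yields a flagged degenerate F.

## Numerical conventions and edge cases

* Window membership uses an absolute 10⁻⁹ s tolerance on the half-open
  boundaries, robust to floating-point drift in offset timestamps.
* Missing samples inside an analysed window are an error, never imputed.
* Exact-enumeration means are compared after rounding resample sums to
  9 decimals so that identical rational means tie correctly across the
  two series; the final probabilities are clamped to [0, 1] against
  accumulated floating error in the multinomial weights.
* Sub-seeds are produced by a polynomial string hash modulo 2³¹−1, kept
  exactly representable in doubles.

## Problem sizes

The test-suite and the acceptance script run, by the package's own
choice: 2000 exchangeable subjects for the calibration comparison
(B = 10000 against the exact oracle), 50 random series pairs for
Monte-Carlo/oracle agreement, a 300-subject cohort for mix recovery,
and a few hundred replicate subjects for noise-model convergence. These
sizes put Monte-Carlo error well below the tolerances being asserted
while keeping a full run under a few minutes.

## Limitations

* The classifier is exactly the field's standard procedure; no studentised or
  bias-corrected bootstrap variant is offered, and the measured
  anticonservatism on 8-block series is reported, not repaired.
* The Bonferroni family size, the pooled-variance post hoc choice and
  the Lilliefors reading of "KS normality test" are documented
  interpretations where the verbal description of the analysis is
  underdetermined; each is switchable at the function interface.
* Offset analgesia cohorts are analysed arm-only (the paradigm is not
  run on the face), and conditioning-site effects are carried as
  covariates, not modelled.
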