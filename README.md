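# painmod

Responder phenotyping for endogenous pain-modulation experiments.

Healthy people split into reproducible phenotypes under the classic
pain-modulation paradigms — placebo analgesia, conditioned pain modulation
(CPM) and offset analgesia: **inhibitors** whose pain ratings drop under the
modulation, **nonresponders**, and **facilitators** whose ratings rise.
`painmod` is an R package for the behavioural analysis of such experiments,
for psychophysicists and pain researchers who collect continuous 0–100
visual-analogue-scale (VAS) ratings over repeated noxious heat stimuli.

Each participant contributes two series of eight 15 s heat blocks
(14.4 s for offset analgesia), rated continuously at 0.5 s resolution: a
control series, then a modulated one. The package:

* reduces each trace to eight per-block mean VAS values using the
  paradigm's analysis windows (full block for placebo/CPM; the T3 window
  of the offset series vs the last 6.4 s of each control block);
* classifies every subject with a **bootstrapped resampling test**: B =
  10,000 resampled means per series (8 draws with replacement each),
  paired differences `d_b = test_b − control_b`, one-tailed tail
  proportions

  `p_inhibit = #(d_b ≥ 0)/B`,  `p_facilitate = #(d_b ≤ 0)/B`,

  labelling a subject *inhibitor* if `p_inhibit < 0.05`, *facilitator* if
  `p_facilitate < 0.05`, else *nonresponder* — plus an
  **exact-enumeration oracle** (all C(15,7) = 6435 resample multisets per
  series with multinomial weights) giving the same probabilities without
  Monte-Carlo error;
* computes cohort statistics: label proportions, paired effect summaries
  (Cohen's `D = |m̄|/s_d`, `t = m̄/(s_d/√n)`), percent pain change,
  rating variability (SD of the eight block means), pooled two-proportion
  z tests, Lilliefors-gated t / Mann–Whitney group comparisons with
  Bonferroni correction, and one-way ANOVA with post hoc t-tests for
  questionnaire scores;
* ships a **synthetic cohort generator** (hierarchical Gaussian rating
  noise, clamped to [0, 100], reproducible per-subject RNG streams) so the
  whole pipeline is testable without human data.

## Worked example

```r
library(painmod)

spec <- cohort_spec(40, seed = 2026)            # default placebo-like cohort
coh  <- simulate_cohort(spec)
bm   <- cohort_block_means(coh$traces, paradigm_timing("placebo"))
cls  <- classify_cohort(bm, bootstrap_config(10000, seed = 11), coh$metadata)
summary(cls)
```

```
Bootstrap responder classification of 40 subjects
  10000 resamples per series, one-tailed alpha = 0.050, seed 11
        label  n percent
    inhibitor 18    45.0
 nonresponder 13    32.5
  facilitator  9    22.5
...
Mean VAS change (series 2 - series 1): -1.75 (range -19.03 to 31.38)
```

The cohort was generated with a true class mix of 49/34/17 %; the
classifier recovers 45/32.5/22.5 % at n = 40 — within binomial noise of
the truth, with the excess facilitators coming from null subjects that a
one-tailed 5 % test mislabels at a known rate (see the vignette on
calibration). The paired effect among labelled inhibitors:

```r
paired_effect(cls$results$mean_diff[cls$results$label == "inhibitor"],
              group = "inhibitors")
#> <effect_summary> inhibitors (n = 18): mean -10.51, SD 4.55, D = 2.31,
#>   t(17) = -9.80, p = 2.08e-08
```

i.e. labelled inhibitors show a mean pain decrease of 10.5 VAS points
(Cohen's D = 2.31, a large effect, as expected after selecting on
significance). The exact oracle for one clearly inhibiting subject:

```r
exact_bootstrap_p(c(44, 47, 43, 46, 45, 48, 44, 46),
                  c(33, 36, 31, 35, 34, 37, 32, 35))
#> $p_inhibit    [1] 0
#> $p_facilitate [1] 1
```

The full pipeline — simulate (or ingest a ratings CSV), window, classify,
summarise, write CSVs and a JSON report — runs via `run_pipeline()`, or
from a shell through the thin wrapper `inst/scripts/painmod.R`:

```sh
Rscript inst/scripts/painmod.R all --spec cohort.json --out results/ --seed 17
Rscript inst/scripts/painmod.R classify --ratings ratings.csv --paradigm cpm --out results/
```

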