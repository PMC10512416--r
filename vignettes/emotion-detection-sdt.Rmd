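---
title: "Rating-scale signal detection for auditory emotion detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rating-scale signal detection for auditory emotion detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emoroc)
```

## The experimental problem

Listeners hear short emotional speech clips embedded in Gaussian white
noise and decide, in each of four sessions, whether the clip carries that
session's target emotion (Happy, Neutral, Fear or Disgust), then rate
their confidence from 1 (least) to 6 (most). The scientific question is
whether trait anxiety — measured by the 20-item STAI trait subscale and
split at the conventional cutoff of 39 — modulates perceptual
*sensitivity* to specific emotions, separately from any response bias.
`emoroc` implements the full chain from trial design to group inference,
plus a synthetic-observer generator so the chain can be tested end to end
without human data.

## The detection model and its scoring

### Gaussian evidence model

Each trial yields a scalar "evidence" value: `Normal(0, 1)` on non-target
trials and `Normal(d', sigma_signal)` on target trials. The observer
responds "target" when evidence exceeds a decision criterion `c`, and
reports confidence `1 + #(cuts exceeded by |evidence - c|)`, with five
equally spaced cuts, capped at 6. The model is the *simulator's*
assumption only — the scoring below is nonparametric and never relies on
it. With the default equal-variance model (`sigma_signal = 1`), the area
under the smooth ROC is `pnorm(d'/sqrt(2))` (`theoretical_auc()`), the
closed form used as the oracle in recovery tests.

### Corrected rates, rating ROC, eAUC

Counts of "target" judgments at each confidence level are accumulated from
the most confident level downward; at each of the six thresholds the hit
and false-alarm rates use the loglinear correction
`(count + 0.5) / (n + 1)`, which keeps every operating point strictly
inside the unit square even for perfect or empty counts. The correction is
applied at every threshold with the same denominators. The six points plus
the anchors (0,0) and (1,1) form the empirical ROC; cumulative construction
makes it monotone by construction, and `eauc()` integrates it with the
trapezoidal rule. The construction is cumulative because a non-cumulative
reading of "rates per confidence level" produces non-monotone point sets
that do not bound an ROC area.

Participants whose eAUC is not *strictly* above 0.50 in all four emotions
are excluded (`apply_exclusion()`), mirroring the attrition rule of
at-chance performers.

### Discretization bias of the six-point trapezoid

Because operating points exist only where the observer actually places
response thresholds, the six-point trapezoid is a *biased* estimator of
the smooth-curve area: chords under a concave ROC lose area wherever the
points leave wide gaps. `expected_eauc()` gives the population value of
the trapezoid in closed form, so the bias
`theoretical_auc(d) - expected_eauc(d, ...)` can be inspected directly:

```{r bias}
d <- c(0, 0.5, 1, 2)
conservative <- theoretical_auc(d) -
  sapply(d, expected_eauc, criterion = 0.35, conf_spacing = 0.4)
covering <- theoretical_auc(d) -
  sapply(d, expected_eauc, criterion = -0.65, conf_spacing = 0.55)
round(rbind(conservative, covering), 4)
```

Two consequences shape the package's tests:

* With the *default* observer (criterion 0.35, cut spacing 0.4 — a
  plausibly conservative listener), the thresholds sample only the upper
  shoulder of the ROC and the bias reaches ~0.03. This is a property of
  the statistic itself, not an implementation error, and the same bias is
  present in any study using this construction.
* Recovery tests that compare the empirical eAUC against `pnorm(d'/sqrt(2))`
  to within 0.01 therefore use a *full-coverage* configuration
  (criterion −0.65, spacing 0.55), chosen from the closed form so the six
  thresholds straddle both shoulders; its worst-case bias over
  d' ∈ {0, 0.5, 1, 2} is 0.0068. Against `expected_eauc()` itself,
  convergence holds for *any* configuration.

At the session scale (30 + 30 trials) the corrections additionally shrink
eAUC toward 0.5; the test suite quantifies this small-sample shrinkage
rather than assuming unbiasedness.

## The synthetic cohort

`cohort_config()` fixes the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_low`, `n_high` | 15, 13 | group sizes after exclusion |
| `low_range`, `high_range` | 33–39, 40–47 | discrete-uniform trait-score ranges on either side of the cutoff |
| `base_dprime` | HA 0.77, NE 0.65, FE 1.12, DI 1.03 | baseline evidence separation |
| `high_deficit` | FE 0.46, DI 0.37 (0 elsewhere) | sensitivity loss in the High group |
| `decision_criterion` | 0.35 | evidence threshold for "target" |
| `conf_spacing` | 0.4 | confidence cut spacing (evidence units) |

The baselines and deficits were solved from `expected_eauc()` so that (a)
the pooled population eAUCs of a 15 + 13 cohort land inside the observed
0.65–0.72 band and (b) the population Low − High eAUC gaps equal 0.107
(Fear) and 0.088 (Disgust), the reported mean differences. Trait scores
are sampled uniformly within each range; anxiety acts *only* through the
group-level d′ deficit — there is no per-trial state modulation, no
reaction-time, lapse or fatigue model. Passing tests therefore show the
pipeline recovers a group-by-emotion sensitivity structure when one
exists; they say nothing about the mechanism behind such a structure in
real listeners.

## Design and stimulus conventions

* **Stimulus reuse.** Each emotion's 30 selected stimuli all serve as
  targets in their own session and are partitioned into three disjoint
  5F/5M sets of 10 for the three sessions where the emotion is a
  non-target, so every stimulus occurs exactly twice per experiment. This
  is the only assignment satisfying all stated composition counts
  (30 targets; 10 non-targets per other emotion, 5 per speaker sex; no
  repeats within a session).
* **Randomization.** One master seed per participant; session order, set
  partitioning, trial order and fixation jitter each use an independently
  derived sub-stream, so changing one consumer never perturbs the others.
* **Fixation jitter** is continuous uniform on [300, 500] ms, rounded to
  integer milliseconds.
* **Noise scaling.** The masking noise variance is the *population* value
  `P_signal / 10^(SNR/10)` from the measured mean-square power of the full
  clip; a finite realization deviates slightly, which `realized_snr()`
  quantifies (about ±0.02 dB SD for 3 s at 44.1 kHz). Power is measured
  before trimming; masking precedes trimming to 3,000 ms. No loudness
  normalization is applied across stimuli.
* **Screening stimuli.** The antiphase probe is an exact polarity
  inversion (200 Hz default); the Huggins probe phase-shifts a ±6 % band
  around 600 Hz by π in one channel of a shared noise. Their scoring
  protocols are out of scope.

## Inference choices

* **Mixed ANOVA** (`mixed_anova()`) uses the classical split-plot
  decomposition: the group effect tested against subjects-within-group,
  emotion and interaction against the emotion-by-subject residual; with
  complete within-subject data the sequential and marginal sums of squares
  coincide even at unequal group sizes (verified against `stats::aov` in
  the tests). Reported df are uncorrected — sphericity is checked by
  `mauchly_sphericity()` (first-order Box chi-square approximation; W
  matches `stats::mauchly.test` exactly, p to ~1e-3) but not used to
  adjust df, matching the convention of reporting uncorrected df after a
  non-significant Mauchly test. Partial η² uses each effect's own error
  term.
* **Simple main effects** are per-emotion two-sample contrasts with
  pooled-variance SEM, Bonferroni-corrected over the family of four.
* **Mann–Whitney** (`mann_whitney()`) uses midranks, tie-corrected normal
  variance and *no* continuity correction — with complete separation at
  n = 15/13 this yields |z| = 97.5/√(15·13·29/12) ≈ 4.49. The p-value is
  exact (via the null distribution of U) when there are no ties and
  n ≤ 50, else normal. Two effect sizes are always reported, rank-biserial
  `1 − 2U/(n1·n2)` and `|z|/√N`, because published r values for such
  comparisons are often not reproducible from either standard definition.
* **Effect-size conversion.** `eta2_to_f()` implements
  `f = sqrt(eta2/(1 − eta2))` only; note that η² = 0.40 gives f = 0.8165,
  while f = 0.44 corresponds to η² ≈ 0.163 — both directions can be
  inspected, nothing is silently reconciled.
* **Power.** `required_sample_size()` inverts the analytic noncentral-F
  power of the within–between interaction
  (λ = N·f²·m·ε/(1 − ρ)), validated against a Monte-Carlo simulation of
  the split-plot design in the tests. α = 0.05, two-tailed, throughout.

## Numerical and degenerate-input conventions

* `corrected_rate` errors on counts outside [0, n]; `measure_power` and
  `mix_noise_at_snr` reject empty and all-zero clips (SNR scaling is
  undefined); `realized_snr` returns `Inf` for a zero residual.
* `trim_clip` errors on short clips unless zero-padding is requested, and
  is idempotent at the target duration.
* ROC points are sorted by false-alarm rate then hit rate; coincident
  points contribute zero width to the trapezoid.
* `split_by_cutoff` sends a score of exactly 39 to the Low group; an empty
  group is an error naming the deficiency.
* Exactly-at-threshold eAUC (0.50) is *excluded* — the rule is strict
  inequality.

## Problem sizes used in the test suite

Property tests run at sizes chosen to make Monte-Carlo error a small
fraction of each tolerance: 1,000 random curves for the polygon-area
oracle; 24 replicates of 5,000 + 5,000 trials per d′ for AUC recovery;
1,000 replicate cohorts for the interaction type-I calibration (28
observers, 30 + 30 trials per emotion each); 10,000 trials for the
fixation-jitter mean; 400 replicates for the analytic-vs-simulated power
comparison.

## Known limitations

* The generator emulates group structure, not individuals: real data show
  attention lapses, fatigue over the ~90-minute task, criterion drift and
  heterogeneous confidence usage, none of which are modeled.
* The six-point eAUC inherits the coverage-dependent bias described
  above; comparisons *between* groups scored identically are unaffected to
  first order, but absolute eAUC values should not be read as Φ(d′/√2).
* The headline inferential statistics of any one study (F, p, mean
  differences) depend on its raw behavioral data; with synthetic cohorts
  the package reproduces design-determined quantities (df, trial counts,
  SNR, chance level) exactly and effect patterns only in distribution.
* The Lilliefors p-value uses the Dallal–Wilkinson approximation; the
  plain K-S p against a fitted normal is conservative and provided only
  because that usage is common in the literature.
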