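---
title: "Cross-study generalizability of passive symptom prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-study generalizability of passive symptom prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Passive mobile sensing studies collect day-level behavioral streams
(activity, conversation, location, phone use, sleep) alongside brief
in-the-moment symptom self-reports (ecological momentary assessments,
EMAs). Prediction models trained inside a single study rarely face the
question that matters for deployment: do they generalize to subjects
from a *different* study — different population, devices, schedules and
response scales? `crossgen` implements a complete, testable pipeline for
that question:

1. **Harmonization** of two heterogeneous studies into one canonical
   schema: 44 features per EMA response (8 sensing variables x 5
   daily/epoch summaries + 3 sleep features + 1 missing-day counter),
   outcomes normalized to a common 0–3 severity scale.
2. **Leave-one-subject-out cross-validation (LOSO-CV)** over a declared
   grid of 432 configurations of a Huber-loss gradient-boosted
   regression tree (GBRT), comparing *single-study* versus *combined*
   training, with optional SMOTE oversampling and k-nearest-neighbor
   personalization.
3. **Domain distance**: the Proxy-A distance PAD = 2(1 − 2ε), where ε
   is the cross-validated error of a linear SVM separating training
   rows from a held-out subject's rows.
4. **Evaluation statistics**: per-subject MAE deltas, one-sided
   Wilcoxon signed-rank tests (exact by sign enumeration for small n),
   the Rosner–Glynn–Lee clustered variant, rank-biserial correlations,
   Cramér's V, Benjamini–Hochberg multiplicity control, severity
   classification metrics, and the within-subject association between
   ΔPAD and ΔMAE estimated by both a Gaussian exchangeable GEE with
   sandwich errors and a random-intercept linear mixed model.
5. A **synthetic two-study generator** standing in for the original
   public datasets, so every stage is testable offline.

## Harmonization conventions

* Days are calendar days on a single study-local clock; the four 6-hour
  epochs are half-open, so a value stamped exactly at 6AM belongs to
  the 6AM–12PM epoch (deterministic bucketing).
* Durations and distances are summed within epochs; event counts are
  counted; sleep onset/wake/duration are day-level only. This is forced
  by the feature count: 43 = 8 x 5 + 3.
* The 19-hour coverage rule drops low-coverage days only in studies
  flagged `raw_derived` — studies whose public release already contains
  curated day-level features pass through.
* Each EMA response is paired with the mean of each feature over the
  three days up to and including the response day; a 44th feature
  counts the missing days in that window. Sleep features missing for
  the whole window are filled with the subject's own mean observed
  sleep value. This fill never crosses subjects, so it cannot leak
  information across LOSO folds (which split by subject); it does use
  the subject's full observation period, a deliberate simplification.
* Response scales: the 4-category sleep-quality item (1 = very good …
  4 = very bad) maps through x → 4 − x so higher always means better
  sleep; the 5-label stress item is reordered into its unique
  severity-monotone order and mapped affinely onto [0, 3], snapped to
  the integer grid (0, 1, 2, 2, 3). Multiple responses to one item on
  one day are kept as separate instances sharing the day's features.
* "Severe" means the two categories at the severe end of the
  normalized scale: sleep 0–1, stress 2–3.

## Modeling conventions

* GBRT: depth-limited regression trees fitted to Huber pseudo-residuals
  (transition point at the 0.9 quantile of absolute residuals each
  iteration) with per-leaf Huber updates; no row or feature
  subsampling, so fits are deterministic and an ensemble truncated to
  its first m trees equals a fit with m trees — the grid's 20/100/1000
  tree counts are read off one staged fit.
* Pipeline order per fold: build → personalize → standardize → SMOTE →
  fit. Personalization defines the relevant neighborhood first; SMOTE
  then balances within it. Standardization, personalization and SMOTE
  are all computed from the training fold only.
* SMOTE classes are the outcome categories after rounding to
  {0, 1, 2, 3} (the common grid across studies); k = 5 neighbors in
  standardized space, a class smaller than k + 1 reduces k to its size
  minus one, singleton classes are duplicated with a warning.
* Predictions are clipped to [0, 3].
* Baselines predict the mean outcome of the *same* prepared training
  set (mode, personalization and SMOTE included), so each configuration
  is compared with its own constant predictor.
* Proxy-A distance: ε is estimated by 5-fold stratified
  cross-validation of a squared-hinge linear SVM (C = 1) after
  subsampling the majority side to the minority size; with 0/1 labels
  the misclassification rate equals the classifier's MAE. Negative PAD
  estimates are preserved, not clamped.

## Statistical conventions

* Signed-rank tests drop zero differences and midrank ties; for n ≤ 12
  the one-sided p-value is exact by enumeration of all 2^n sign
  assignments (valid under ties), otherwise a tie-corrected normal
  approximation with continuity correction is used.
* The clustered variant is the Rosner–Glynn–Lee form: with S_i the sum
  of signed ranks inside cluster i, Z = ΣS_i / sqrt(ΣS_i²). Its level
  is verified by simulation (type-I error within [0.04, 0.06] at
  α = 0.05 under cluster-correlated nulls) rather than by formula
  citation; the unclustered test on the same data is demonstrably
  anti-conservative, which motivates the clustered variant.
* Severity binarization of regression outputs uses the scale midpoint:
  predicted severe iff the prediction falls in the severe half
  (≤ 1.5 for sleep, ≥ 1.5 for stress). This is the unique midpoint rule
  consistent with two-category severe sets.
* Table-style summary percentages are rounded to integers.
* The ΔPAD→ΔMAE association controls for the outcome item and the
  personalization neighbor count, clusters on subject, and reports both
  a population-averaged GEE (exchangeable working correlation, robust
  sandwich errors, moment estimate of the correlation) and a
  random-intercept LMM via `lme4`, fitted on the identical row set with
  Wald 95% intervals.

## What the synthetic generator emulates — and what it does not

No public generative model exists for these data; the generator is a
documented stand-in that reproduces the *statistical structure* the
analysis assumes:

* Heavy-tailed, non-negative sensing marginals: log-normal hourly
  values for durations and distances, negative-binomial counts, shaped
  by a diurnal profile; per-subject log-normal level multipliers create
  between-subject heterogeneity; a per-subject latent intercept creates
  within-subject outcome correlation.
* EMA schedules: a fixed Mon/Wed/Fri cadence with a non-response
  probability for the CrossCheck-like study; per-day Bernoulli
  selection (mean period ~2.5 days) for the StudentLife-like study.
* Outcomes: a weighted sum of standardized noiseless 3-day trailing
  means of the daily summaries (so harmonization can recover the signal
  exactly), plus the subject intercept and Gaussian noise, passed
  through a linear/threshold/saturating link and discretized onto the
  0–3 grid. Cutpoints are Monte-Carlo calibrated on a config-seeded
  substream so the study's marginal category frequencies match a
  configured prior — severe categories under-represented at roughly the
  observed 20–45%.
* Missingness: whole subject-days dropped independently at a
  configured rate, after outcomes are generated.
* Seeding: one master seed expands into per-subject substreams drawn
  up-front, so subject s's data do not change when the subject count
  does.

**Shared links across studies.** A design question the build surfaced:
if study B's link were calibrated against B's own *shifted* feature
moments, the raw-feature→symptom conditional would differ between
studies even with a "shared" link, and combining data would always hurt
(pure negative transfer). `generate_paired_studies(shared_link = TRUE)`
therefore copies study A's calibration (standardization moments and
grid cutpoints) into B, making the conditional identical on the raw
feature scale; B's outcome marginals then *emerge* from its feature
shift, mirroring how the real studies report different severe
fractions. With `shared_link = FALSE` each study calibrates its own
links, which may be opposed (negative transfer by construction).

A related numerical observation worth knowing when configuring shifts:
daily sums of log-normal hourly values have large mean-to-sd ratios, so
even a 10% scale shift on a link-weighted variable moves the
standardized latent by about one standard deviation and can empty an
outcome category entirely. Scenario configurations that want comparable
outcome marginals across studies should place marginal shifts on
variables *outside* the link.

What a green test does **not** establish: the generator makes no claim
about the real datasets' effect sizes, so the package's directional
tests (combined-beats-single, PAD monotonicity, SMOTE
sensitivity/specificity trade-off) verify that the pipeline reproduces
the qualitative phenomena in a world where they are true by
construction — they are integration tests of the machinery, not
replications of the real-data values, which would require downloading
the original studies.

## Tunable parameters that matter

| Parameter | Default | Units / meaning |
|---|---|---|
| `window` | 3 | days averaged per EMA response |
| `min_coverage` | 19 | hours of data required to keep a raw-derived day |
| `min_ema` | 30 | responses required to enter validation |
| `alpha` | 0.05 | per-test significance level |
| `fdr` | 0.25 | Benjamini–Hochberg false discovery rate |
| grid | 432 configs | lr {0.001, 0.01, 0.1, 1} x trees {20, 100, 1000} x depth {3, 7, 10} x SMOTE {on, off} x k {5, 10, 50, 100, 500, all} |
| `noise_sd` | 0.8 | latent noise of a link (outcome scale SD) |
| `subject_sd` | 0.35 | SD of per-subject log-level multipliers |
| `n_cal` | 1500 | Monte-Carlo size for link calibration |

## Known limitations

* The sleep-from-phone-lock estimator (longest locked interval in the
  9PM–noon window) is a documented stand-in for the original
  undescribed method; onset/wake are reported in hours since midnight
  of the night-start day to avoid wrap-around.
* Whether SMOTE preceded personalization in the original analysis is
  unknown; the personalize-then-SMOTE order is recorded in provenance.
* Baseline means are computed per prepared training set (per mode);
  whether the original analysis shared one baseline across modes is
  unknown.
* The ε-estimation protocol for the Proxy-A distance (5-fold stratified
  CV, C = 1, majority subsampling) is this package's choice of a
  standard estimator, not an inference about the original protocol.
* The unpaired rank-biserial correlation is computed as 2U/(n₁n₂) − 1
  for between-study comparisons even though the cited formulation is
  usually stated for paired data; the paired (rank-sum proportion) form
  is used for paired deltas.
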