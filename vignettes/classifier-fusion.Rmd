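---
title: "Fusing AFib detectors: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing AFib detectors: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afcf)
```

## The problem

Atrial fibrillation (AFib) is the most common sustained arrhythmia and a
major stroke risk, yet it is under-diagnosed because it is often
asymptomatic and intermittent. Consumer single-lead ECG devices record
short (~30 s) strips at a scale of hundreds of thousands per day, which
turns even small differences in false-positive rate into a large daily
review burden for clinicians. Many independent AFib classifiers exist,
each with different strengths; `afcf` implements a *meta-level* approach:
treat the outputs of several strong base classifiers (plus a set of
RR-interval features) as features for a second-stage learner, rank them by
how much they contribute, and fuse the best of them with a random forest
whose majority vote becomes the final call.

The package implements the full pipeline on three inputs: a votes table
(per-record outputs of base algorithms — categorical rhythm calls in
{AFib, non-AFib, noisy} and/or continuous scores in [0,1]), a labels table
(expert rhythm label per record), and optionally raw RR-interval series
from which it computes 24 heart-rate-variability (HRV) features. Because
the original base algorithms and datasets are not redistributable, the
package also ships seeded synthetic generators for both kinds of input, so
every stage is exercised offline.

## RR-interval features

All features operate on the beat-to-beat (RR) interval sequence in
milliseconds, with heart rate defined per beat as 60000/RR and standard
deviations using the n−1 denominator.

* **Time domain** — mean/min/max RR, SDNN (sample SD of RR), mean and
  median heart rate, and pNN50, the percentage of successive-difference
  magnitudes exceeding 50 ms. (One published gloss defines pNN50 as the
  percentage of *intervals* larger than 50 ms; that reading is a typo —
  every RR interval exceeds 50 ms — so the standard successive-difference
  definition is used.)
* **RMSSD family** — root mean (or median: RMeSSD) of squared lag-k RR
  differences, k ∈ {1, 2, 3}: successive, every-other, every-third
  interval. The Li-style `RMSSD` and Kardia-style `RMSSD1` are the same
  statistic; in the original setting they differed only through different
  upstream QRS detectors, which are out of scope here, so on one RR stream
  they coincide (asserted in tests).
* **Spectral** — low-frequency (0.04–0.15 Hz) and high-frequency
  (0.15–0.40 Hz) band powers of the tachogram. The RR series is unevenly
  sampled in time, so band powers come from a classical Lomb–Scargle
  periodogram on the (onset time, RR) pairs — no interpolation artifacts.
  Both raw band powers and normalized fractions LFn = LF/(LF+HF) are
  returned; the full feature vector reports the normalized fractions
  (summing to one) plus the LF/HF ratio, with an `NA` sentinel when
  HF = 0. Series shorter than 30 intervals or 60 s are flagged
  unreliable.
* **COSEn** — the coefficient of sample entropy,
  SampEn(m, r) + ln(2r) − ln(mean RR), with SampEn = −ln(A/B) counting
  Chebyshev template matches at lengths m and m+1 (self-matches excluded,
  matches at distance ≤ r, the first n−m templates at both lengths).
  Defaults m = 1, r = 30 ms — the established convention for short
  AF-screening RR records; both are exposed. A = 0 or B = 0 leaves the
  entropy undefined and yields `NA` with a diagnostic rather than ±Inf.
* **NFEn** — normalized fuzzy entropy: the series is divided by its mean
  (removing scale), templates are baseline-removed, and match counting is
  replaced by the soft membership exp(−(d/r)^2) with r = 0.2 × SD of the
  normalized series. Zero-variance series make the default tolerance
  degenerate and return the `NA` sentinel.
* **MAD** — over 3-beat windows of per-beat heart rate, the SD within
  each window; MAD is the median of these window SDs. The source
  description of this feature is ambiguous ("variation in the absolute
  standard deviation from the mean of heart rate in three adjacent RR
  segments"); this package fixes the sliding-window reading and offers
  disjoint windows behind `sliding = FALSE`.
* **AFEv** — a Lorenz-plot evidence score: successive RR-difference pairs
  (ΔRR_i, ΔRR_{i−1}) are quantized to 40 ms bins;
  AFEv = (# distinct occupied non-origin bins) − (# points in the origin
  zone, |ΔRR| < 80 ms on both axes) − 2 × (# occupied bins in the
  opposite-sign near-antidiagonal zone, the alternating signature of
  ectopy/bigeminy). The exact segment geometry of the original
  implantable-monitor detector is not published; the mask here is our own
  documented rendition that preserves its three ingredients (irregularity
  rewards, origin and ectopy penalties). Scattered fibrillatory dynamics
  score high; regular rhythms score negative; bigeminy is penalized
  relative to plain irregularity.

The two trained-network features (`CNNout`, `RNNout`) cannot be derived
from RR intervals; they are stand-ins, absent unless supplied by the user
or a simulation.

## Ranking and fusion

Votes are one-hot encoded — each categorical vote becomes the indicator
pair (is_AFib, is_noisy), with non-AFib as (0,0) — so that a forest
sampling a *single* feature per split can still isolate either class
signal from one vote. Records labeled `noisy` are removed before ranking
and training: the meta-problem is binary.

**Ranking.** One random forest (default 500 trees, ⌊√p⌋ features per
split, full-size bootstrap with replacement, cross-entropy splits, trees
grown to purity) is fit, and each meta-feature is scored by classic
per-tree out-of-bag permutation importance: within each tree's
out-of-bag records, the feature's encoded column block is permuted (a
vote's indicator pair jointly, with one permutation) and the increase in
that tree's error recorded; the importance is the mean increase over
trees. Ties are broken by feature name, and the tree-growing and
permutation RNG streams are derived independently from one master seed,
so a ranking is exactly reproducible.

**Fusion forest.** The combiner is the same forest configured for
maximal decorrelation: exactly **one** uniformly sampled feature
considered per split. Each of the 500 trees votes; the AFib probability
is the vote ratio (so every probability is a multiple of 1/500) and the
default call threshold is 0.5, with the exact tie going to AFib — in a
screening context the costlier error is the missed case. Unsplittable
impure nodes (identical encoded features, mixed labels) become
majority-label leaves, again with ties to AFib.

**How many features to fuse.** `select_k()` evaluates a grid of k
(number of top-ranked features) under repeated stratified
cross-validation (default 5 × 10; per-fold class counts within one record
of proportional) and picks the *smallest* k whose mean F1 is within one
standard deviation of the best mean — an argmax over statistically
indistinguishable k values is unstable, and the parsimony rule makes the
choice reproducible. Folds that come out single-class are redrawn under
a logged sub-seed.

The forest core is implemented in C++ (as the field's forest packages do)
with hand-rolled bounded-integer draws over a Mersenne-Twister stream, so
results are bit-identical across platforms and standard libraries. The
established `randomForest` package is used in the test suite as an
independent cross-check of discrimination and importance ranking — never
as the implementation, since it offers neither cross-entropy splits nor
group-wise permutation of encoded vote blocks.

## Evaluation and screening burden

AFib is the positive class everywhere. `metrics()` reports sensitivity,
specificity, PPV, NPV and F1 at full precision (rounded to 3 decimals
only for display), with `NA` sentinels for zero denominators. ROC curves
sweep "call AFib when score ≥ t" over the distinct scores plus a +∞
sentinel; the trapezoidal AUC then equals the pairwise concordance
probability P(s⁺ > s⁻) + ½P(s⁺ = s⁻), which the tests verify against a
brute-force O(n²) oracle. Categorical-only algorithms contribute a single
operating point.

`compare_workload()` turns a daily volume, a prevalence and two
algorithms' error rates into daily false positives/negatives. Each
algorithm's count is rounded half away from zero *before* differencing;
this per-term convention is the one that keeps the differences consistent
with the individually quoted counts (e.g. 99500 × 0.027 = 2686.5 → 2687
and 99500 × 0.031 = 3084.5 → 3085, difference 398 — rounding after
differencing would disagree with the quoted per-algorithm figures at some
prevalences). Prevalence strings must carry an explicit `%` suffix;
a bare number ≥ 1 is rejected rather than guessed at.

## What the synthetic generators emulate — and what they do not

`gen_rr()` emulates the *feature-level* contrast between rhythms:

* sinus rhythm: 800 ms mean RR modulated by respiration (0.25 Hz, 30 ms)
  and by the slower baroreflex Mayer wave (0.10 Hz, 50 ms) plus 10 ms
  white jitter. Both oscillations are standard constituents of sinus HRV;
  the slow component is what makes consecutive beats strongly correlated
  (with only the 0.25 Hz component at 75 bpm, the lag-1 autocorrelation
  of RR is bounded by cos(2π·0.2) ≈ 0.31 no matter the amplitude).
* AFib: i.i.d. log-normal intervals, CV 0.25 around 700 ms — irregularly
  irregular and serially uncorrelated. `slow_afib` rescales to a mean of
  1100 ms so the ventricular rate (60000/mean RR) is below 60 bpm by
  construction. `noisy_afib` corrupts the stream with spurious
  detections (split intervals) and missed beats (merged intervals) at a
  5% per-beat rate.

This is deliberately *not* a physiological simulator: there is no
atrioventricular-node conduction model, no ectopy in sinus rhythm, no
flutter/SVT confusers, and no waveform level at all. Passing tests show
that the features separate caricatured rhythm classes with the right
ordering — not that they match clinical effect sizes.

`gen_ensemble()` emulates the shape of the meta-table: exact class counts
when requested (so fixtures match stated distributions verbatim, e.g.
2317/137/78 and 777/3867), six categorical voters with per-class skills
in the range of strong published detectors, and one continuous scorer
with class-conditional Beta scores. Voter errors are correlated through a
shared per-record latent difficulty acting on the logit of each voter's
correctness probability — a single interpretable knob
(`difficulty_weight`) rather than an explicit error-covariance matrix.
`gen_complementary_experts()` is the scenario behind the fusion-beats-best
property: seven voters, each near-perfect (0.98) on its own seventh of
the records and mediocre (0.70) elsewhere, so no single voter can win
overall while a combiner that learns when to trust whom can.

## Numerical choices and degenerate inputs

* Sample-entropy matches use d ≤ r; implementation and test oracle state
  the same convention explicitly.
* Forest splits maximize information gain with midpoint thresholds; ties
  between candidate features break toward the lower feature index, and a
  node whose sampled feature is constant falls back to the remaining
  non-constant candidates before becoming a leaf.
* Probabilities, thresholds: call = AFib iff p ≥ threshold; with an even
  number of trees the exact 0.5 tie is possible and documented to go to
  AFib.
* Zero-denominator ratios are `NA` sentinels throughout, never `NaN` or
  infinities; per-feature failures in `extract_all()` degrade only that
  feature.
* Model persistence is versioned JSON text (`afcf-fusion-forest/1`) of the
  tree arrays plus configuration; a round trip restores bit-identical
  predictions.

## Scale of the shipped checks

The test suite exercises the pipeline at sizes chosen to make the
stochastic properties sharp while keeping a full run in the low minutes
on one core: entropy oracles to n = 200 (exact count equality),
label-copy ranking at n = 1000 over 100 seeded forests of 500 trees,
fusion-versus-experts at n = 2000 over 50 seeds, and study-sized
ensembles (2532/4644 records) for class-count and end-to-end checks.
The acceptance script (`scripts/acceptance.R`) repeats the headline
computations from scratch under a caller-supplied seed.

## Known limitations

* The two network stand-ins carry no signal unless supplied; nothing in
  the package can reproduce the original trained networks.
* AFEv's segment mask is a faithful-by-construction rendition, not the
  published implantable-monitor constants; absolute AFEv values are not
  comparable to that detector's, only the ordering properties are.
* The published training-time results (the 62-feature ranking order, the
  choice of seven, per-fold F1) depend on the original base-algorithm
  outputs, which are not available; the package reproduces the
  *procedure* and validates it on synthetic ensembles, and can replay the
  published test-set supplementary files when the user downloads them.
* `select_k()` retrains one forest per fold per candidate k; on large
  grids this is the slowest step of the pipeline.
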