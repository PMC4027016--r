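---
title: "Wavelet packet fractal dimension analysis of sustained vowels"
author: "wavefrac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet packet fractal dimension analysis of sustained vowels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavefrac)
```

## The problem

Listening-based (auscultatory) assessment of voice quality is
qualitative and depends on the examiner.  `wavefrac` implements an
objective pipeline for three-class voice studies: a healthy control
group (H) and two clinical groups with characteristically *weak,
breathy* (Q) and *hoarse, dry* (Y) voices, each contributing a ~1 s
sustained /a:/ phonation sampled at 16 kHz.  The pipeline turns every
recording into 62 numbers — the box-counting fractal dimension of each
wavelet packet subband — compares groups per subband with age-adjusted
linear models, and classifies subjects with pairwise-tuned RBF support
vector machines.

## Wavelet packet subbands

The wavelet packet transform splits *both* the approximation and the
detail branch at every level, so level $i$ tiles $[0, f_s/2]$ into
$2^i$ equal bands of width $(f_s/2)/2^i$: 4 kHz at level 1 down to
250 Hz at level 5 for $f_s = 16$ kHz.  We use the orthonormal `db4`
filter bank.  Two conventions matter:

* **Frequency ordering.**  The natural (Paley) order of the filter
  bank does not follow frequency, because high-pass decimation
  mirrors the spectrum of its branch.  Public node indices are
  therefore permuted by the inverse Gray code so that node $n$ at
  level $i$ always covers $[n\,\Delta f, (n+1)\Delta f)$, with the
  Nyquist edge assigned to the last node.  `nodeFrequencyBand(3, 4,
  16000)` is the 4–5 kHz band, and a band-center tone always
  maximizes the coefficient energy of the node that names its band
  (this is tested at every level).

* **Boundary handling.**  Analysis uses zero extension and keeps
  every coefficient whose analysis filter overlaps the signal
  support.  With an orthonormal filter bank this makes the transform
  an exact isometry: subband energies at any level sum to the signal
  energy to machine precision, and summing all single-node
  reconstructions recovers the input exactly.  We preferred this over
  the more common symmetric extension precisely because symmetric
  padding trades exact energy conservation for slightly smaller edge
  transients, and downstream statistics lean on per-band energies
  being an exact partition.

The tree is built to the depth requested (up to 7); features default
to levels 1–5, i.e. $2+4+8+16+32 = 62$ subbands, which is where the
band structure is informative for speech at this sampling rate —
deeper levels leave too few coefficients per node for stable
dimension estimates.

## Box-counting dimension of a sampled curve

Each subband coefficient sequence is treated as a curve.  It is peak
normalized, $v = (x/\max|x| + 1)/2$, time is mapped to $[0,1]$, and
the unit square is covered with dyadic grids of side $s = 2^{-1},
\dots, 2^{-M}$ with $M = \min(\lfloor \log_2 L\rfloor, 8)$ — the grid
is never finer than the sampling density, because sub-sample grids
collapse the count growth and bias the estimate.  $N(s)$ counts the
cells intersected by the *polyline* joining consecutive samples
(linear interpolation; a points-only mode exists for sensitivity
checks), with half-open cells $[a, a+s)\times[b, b+s)$ and the
closing edges at 1 included.  The dimension estimate is the
least-squares slope of $\log N(s)$ against $\log(1/s)$, computed by
the closed-form normal-equation expression (natural logarithms; the
slope is base-invariant).

Numerical conventions worth stating:

* All-zero sequences are an error, not dimension 1 by fiat: peak
  normalization is undefined there.
* A boundary-crossing value is *approached* but not attained inside
  the column to its left.  This only matters when the crossing sits
  exactly on a horizontal grid line; handling it explicitly makes a
  grid-aligned diagonal occupy exactly $1/s$ cells, as it should.
* The estimate is invariant to amplitude gain and sign flips by
  construction, and the implementation is verified cell-for-cell
  against a brute-force rasterization oracle on short curves.

### What the estimate does — and does not — guarantee

For bounded sampled signals the estimate lives essentially in
$[1, 2]$: smooth slowly-varying curves sit near 1, white noise near
2.  Two finite-scale effects are worth knowing.  First, a sustained
tone with many cycles across the analysis window is *space-filling*
at the grid resolutions used (total vertical travel exceeds the cell
budget), so its estimate saturates at 2 even though the underlying
curve is smooth; "smooth" for this estimator means few oscillations
relative to the 256-column finest grid.  Second, the least-squares
slope can undershoot 1 by a few percent on spiky, near-flat
sequences — e.g. the near-silent leakage of a pure tone into a
distant subband — because covering counts there refine at less than
$2\times$ per scale halving at the finest grids.  Polyline counting
guarantees $N(s) \ge 1/s$, but that bounds the counts, not the
fitted slope.  Full-signal estimates of tones, noise and vowels stay
inside $[1, 2]$; the undershoot appears only for degenerate
subband sequences, and we report it rather than trimming scales to
hide it.

A related consequence for interpretation: the dimension of a
*subband coefficient sequence* depends on where a narrowband
component aliases within its band after decimation, not merely on
its presence.  Subband dimensions are a texture measure, not an
energy detector — which is exactly why they complement energy
features in voice work.

## Age-adjusted subband comparisons

For every node the model is `dimension ~ group + age`, an
ANCOVA-style linear model with treatment-coded groups.  Pairwise
p-values (H–Y, H–Q, Y–Q) come from contrasts of the fitted
coefficients using the model covariance (two-sided $t$ tests on the
residual df); the arithmetic is verified against `emmeans` contrasts.
The age covariate matters because control cohorts are typically
younger than clinical ones; the synthetic cohort reproduces that
imbalance (H mean 26.3 y vs Q 45.2 y, Y 53.5 y) so the adjustment is
exercised, and a simulation test confirms that a shared age trend
combined with different age distributions inflates unadjusted
comparisons but not adjusted ones.

Reported group means and SDs are deliberately *raw* (the conventional
presentation); only the p-values are adjusted.  No multiple-testing
correction is applied by default — the reference analysis reports raw
$P < 0.05$ over 62 bands — but `adjustP = "BH"` provides
Benjamini–Hochberg control as a documented deviation.  Significance
is computed per stratum (`all`, `male`, `female`); stratification is
stateless, i.e. identical to running the pipeline on the filtered
cohort.

## One-vs-one SVM classification

Three binary RBF-SVM classifiers (H–Y, H–Q, Y–Q; $k(k-1)/2$ for $k$
classes) are combined by majority vote, ties broken by the largest
summed absolute decision value, then by fixed class order (Q, Y, H).
Each binary classifier gets

* **its own feature subset**: the nodes whose pairwise age-adjusted
  p-value is below $\alpha = 0.05$ on the *training rows only* (an
  empty subset falls back to all 62 features, with a message);
* **its own kernel parameters**: $C \in 2^{-5}, 2^{-3}, \dots,
  2^{15}$ and $\gamma \in 2^{-15}, \dots, 2^{3}$, chosen by
  stratified inner 5-fold cross-validation, ties toward smaller $C$
  then smaller $\gamma$ (the standard libsvm-style grid; the
  reference analysis names no grid);
* **its own standardization**: per-feature z-scores with parameters
  from training rows.

Evaluation is stratified 3-fold cross-validation in which the *whole*
training pipeline — feature selection, standardization, grid search,
fitting — runs inside each fold.  Selecting features on the full
dataset before cross-validating (a select-then-validate ordering
still common in applied work) leaks information; we default to
fold-internal selection and expose the other ordering as
`globalSelection = TRUE` for comparison.  A dedicated test corrupts one
subject's features and checks that its own fold's model is unchanged.
Sex-stratified evaluation trains fully separate male and female
models and combines their overall accuracies weighted by subject
proportion, rounded to two decimals.

## The synthetic cohort

No recordings ship with the package, so a source-filter simulator
provides cohorts with known structure: a glottal pulse train at $f_0$
(male 120 Hz, female 210 Hz on average) with cycle-to-cycle jitter
and shimmer, shaped by a zero-mean soft pulse kernel, filtered
through cascaded two-pole resonators at /a:/ formants (700, 1100,
2600, 3300 Hz; 10 % higher for female voices), plus aspiration noise
mixed at a target harmonic-to-noise ratio with a separately
controlled high-band (4–8 kHz) component.  Group effects follow the
clinical pictures: Q (weak, breathy) lowers HNR to ~10 dB and raises
the high-band noise share to ~0.35; Y (hoarse) raises jitter to
~2.6 % and shimmer to ~10 % with HNR ~17 dB; H is the baseline
(~24 dB, jitter ~0.6 %).  Composition defaults to the reference
three-class design: 43 H / 49 Y / 137 Q, 68 male / 161 female, with
the group age distributions above truncated to 18–90 y.  All
randomness flows from one master seed through per-subject derived
seeds, so cohorts are reproducible piecewise.

What the simulator does *not* emulate: physiological glottal-flow
detail, vocal-tract interaction, room acoustics, or inter-speaker
formant variability beyond the sex scaling.  Passing tests on this
cohort therefore demonstrates that the pipeline recovers *planted*
spectral-texture differences through the full chain — not that the
clinical effect sizes or accuracies of any particular study are
reproduced.  Accuracies on synthetic cohorts (typically around 90 %
overall at the default separations) should be read as pipeline
checks, not clinical claims.

## Problem sizes and determinism

Default test and acceptance runs use: 100-signal dimension suites
(1 s at 16 kHz each), 1000 simulated null nodes at $n = 50$ per group
for calibration, 200 replicates for power, and ten full 229-subject
cohorts for end-to-end recovery, each with 3-fold outer and 5-fold
inner cross-validation over the 110-point grid.  These sizes keep a
complete run in the tens of minutes on one core while leaving the
statistical checks well-powered.  Every stochastic step takes an
explicit seed; fixed seeds give bitwise-identical features, fold
assignments, model selections and reports.

## Known limitations

* Estimates are tied to the stated scale set; comparing dimensions
  across sequence lengths mixes different $M$.
* The $[1, 2]$ range is a property of full-signal estimates;
  near-silent subband sequences can undershoot 1 by a few percent
  (see above).
* The ANCOVA model assumes a common linear age effect across groups;
  no interaction or nonparametric alternative is provided.
* The classifier is deliberately faithful to the one-vs-one
  RBF design: no probability calibration, no other kernels, no
  one-vs-rest.
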