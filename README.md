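# wavefrac

Objective voice analysis for three-class auscultation studies.
`wavefrac` quantifies a sustained /a:/ phonation by the **box-counting
fractal dimension of its wavelet packet subbands**, compares diagnostic
groups per subband with age-adjusted linear models, and classifies
subjects with one-vs-one RBF support vector machines whose feature
subsets and kernel parameters are tuned per binary problem.

It is aimed at voice/biosignal researchers studying cohorts of a
healthy group (H) and two clinical groups with weak/breathy (Q) and
hoarse/dry (Y) voices, and at anyone who needs a well-tested
box-dimension estimator for 1-D sampled curves.

## The method

1. **Subbands.** Each ~1 s, 16 kHz recording is decomposed with an
   orthonormal `db4` wavelet packet filter bank.  Level *i* tiles
   [0, 8 kHz] into 2^*i* equal bands; public node indices are
   frequency-ordered (inverse Gray code), so node *n* at level *i*
   covers [*n*·Δf, (*n*+1)·Δf) with Δf = 8000/2^*i* Hz.
2. **Dimension.** Every subband coefficient sequence (levels 1–5,
   62 nodes) is normalized into the unit square and covered with
   dyadic grids of side *s*; N(*s*) counts grid cells intersected by
   the sample polyline.  The box dimension D_B is the least-squares
   slope of log N(*s*) vs log(1/*s*) — near 1 for smooth curves, near
   2 for noise-like ones.
3. **Statistics.** Per node, `D_B ~ group + age` with pairwise group
   contrasts (raw means ± SD reported; p-values age-adjusted).
4. **Classification.** Three pairwise RBF-SVMs (libsvm via e1071),
   each with its own significant-subband feature subset and
   grid-searched (C, γ) from nested cross-validation, combined by
   majority vote; evaluation by stratified 3-fold CV, optionally with
   fully separate male/female models whose accuracies combine by
   subject proportion.

Because no clinical recordings are distributable, the package includes
a source-filter vowel simulator (`generateCohort()`) that reproduces
the reference cohort composition (43 H / 49 Y / 137 Q; 68 male /
161 female, group-specific age distributions) with group-dependent
jitter, shimmer, harmonic-to-noise ratio and high-band aspiration
noise, so the entire pipeline is testable end to end.

## Worked example

```r
library(wavefrac)

## a small synthetic cohort (use defaults for the full 229-subject one)
cfg <- defaultCohortConfig()
cfg$counts <- list(H = c(male = 4, female = 6),
                   Y = c(male = 4, female = 6),
                   Q = c(male = 6, female = 10))
coh <- generateCohort(cfg, seed = 11)

ffs <- buildFeatureTable(coh)      # 62 nodes x 36 subjects
st  <- significanceTable(ffs)      # age-adjusted per-subband contrasts
st
#> SubbandStats (all subjects, alpha = 0.05): 62 nodes, 26 with >=1 significant pair

rep <- crossValidate(ffs, folds = 3, seed = 1)
rep
#> EvalReport: overall accuracy 69.44% (n = 36, seed 1)
#>   group Q:  75.00%  (n = 16)
#>   group Y:  60.00%  (n = 10)
#>   group H:  70.00%  (n = 10)
```

On this deliberately tiny cohort the classifier already beats the 33 %
chance level; the full default 229-subject cohort reaches roughly
90 % overall — the planted group signatures (high-band aspiration for
Q, jitter/shimmer for Y) are recovered through the whole chain.
Single-signal building blocks are exported too:

```r
sig  <- synthVowel(vowelParams(f0 = 210), seed = 1)
tree <- wpDecompose(sig, maxLevel = 5)
nodeFrequencyBand(3, 4, 16000)    # 4000-5000 Hz
boxDimension(nodeCoefficients(tree, 3, 4))
#> [1] 1.794365
weightedAccuracy(c(male = 72.07, female = 91.95),
                 c(male = 68, female = 161))
#> [1] 86.05
```

A command-line pipeline mirroring these steps is installed at
`system.file("scripts", "wpfd", package = "wavefrac")`
(`wpfd simulate|extract|stats|classify|all`).

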