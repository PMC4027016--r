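## Shared fixtures, built once per test run.

.fixtureCache <- new.env(parent = emptyenv())

memoFixture <- function(name, build) {
  if (!exists(name, .fixtureCache)) assign(name, build(), .fixtureCache)
  get(name, .fixtureCache)
}

## a 1 s 16 kHz tone
toneSignal <- function(freq, n = 16000, rate = 16000, amp = 1) {
  AudioSignal(amp * sin(2 * pi * freq * seq.int(0, n - 1) / rate), rate)
}

## small synthetic cohort config (fast; keeps Table-like imbalance)
smallCohortConfig <- function() {
  cfg <- defaultCohortConfig()
  cfg$counts <- list(H = c(male = 4, female = 6),
                     Y = c(male = 4, female = 6),
                     Q = c(male = 6, female = 10))
  cfg
}

smallCohort <- function() {
  memoFixture("smallCohort", function() generateCohort(smallCohortConfig(),
                                                       seed = 11))
}

smallFeatures <- function() {
  memoFixture("smallFeatures", function() buildFeatureTable(smallCohort()))
}

## Gaussian feature set with three separated classes, for classifier
## and stats tests that do not need audio
gaussianFeatureSet <- function(nPer = c(Q = 20, Y = 14, H = 12),
                               shift = 2, seed = 1, nFeat = 62) {
  set.seed(seed)
  groups <- rep(names(nPer), nPer)
  n <- length(groups)
  mat <- matrix(rnorm(nFeat * n), nFeat, n)
  ## class structure in the first six features
  centers <- list(Q = c(0, 0), Y = c(shift, 0), H = c(0, shift))
  for (i in seq_len(n)) {
    mat[1:3, i] <- mat[1:3, i] + centers[[groups[i]]][1]
    mat[4:6, i] <- mat[4:6, i] + centers[[groups[i]]][2]
  }
  meta <- data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    group = groups,
    sex = rep_len(c("male", "female"), n),
    age = round(runif(n, 20, 80), 1))
  fractalFeatureSet(mat + 1.6, meta)   # offset into the plausible range
}

## brute-force rasterized box counting oracle (independent of the
## implementation): sample each polyline segment densely and assign
## every attained point to its half-open cell
bruteBoxCount <- function(curve, s, K = 3000) {
  t <- curve$t
  v <- curve$v
  m <- round(1 / s)
  keys <- character(0)
  for (i in seq_len(length(t) - 1L)) {
    a <- seq(0, 1, length.out = K)
    tt <- t[i] + (t[i + 1] - t[i]) * a
    vv <- v[i] + (v[i + 1] - v[i]) * a
    col <- pmin(floor(tt / s), m - 1)
    row <- pmin(floor(vv / s), m - 1)
    keys <- c(keys, unique(paste(col, row)))
  }
  length(unique(keys))
}

smallSvmGrid <- function() list(cost = 2^c(-1, 3, 7), gamma = 2^c(-7, -3))
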