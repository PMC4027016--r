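## Source-filter synthesis of sustained /a:/ vowels with group- and
## sex-dependent parameters, so the whole pipeline can be exercised on
## cohorts shaped like a three-class clinical study.
##
## The voice source is a glottal pulse train at f0 with cycle-to-cycle
## frequency perturbation (jitter, %) and amplitude perturbation
## (shimmer, %), shaped by a soft pulse kernel; the vocal tract is a
## cascade of two-pole formant resonators; aspiration noise is white
## noise with an extra high-band (>4 kHz) component controlled by
## `highbandNoiseGain`, mixed at the target harmonic-to-noise ratio.

#' Vowel synthesis parameters
#'
#' @param f0 Fundamental frequency in Hz.
#' @param jitter Cycle-to-cycle f0 perturbation, percent.
#' @param shimmer Cycle-to-cycle amplitude perturbation, percent.
#' @param formants Matrix/data.frame with columns `center` and
#'   `bandwidth` (Hz); defaults are /a:/ formants F1-F4.
#' @param hnrDb Harmonic-to-noise ratio in dB.
#' @param highbandNoiseGain Fraction of the noise budget placed in the
#'   4-8 kHz band (0..1): breathy/weak voices put more aspiration
#'   energy there.
#' @param duration Seconds.
#' @param samplingRate Hz.
#' @return A validated parameter list of class `"VowelParams"`.
#' @export
vowelParams <- function(f0 = 120, jitter = 0.6, shimmer = 3,
                        formants = cbind(center = c(700, 1100, 2600, 3300),
                                         bandwidth = c(80, 90, 120, 150)),
                        hnrDb = 22, highbandNoiseGain = 0.1,
                        duration = 1.2, samplingRate = 16000) {
  p <- list(f0 = f0, jitter = jitter, shimmer = shimmer,
            formants = as.matrix(formants), hnrDb = hnrDb,
            highbandNoiseGain = highbandNoiseGain, duration = duration,
            samplingRate = samplingRate)
  if (f0 < 60 || f0 > 400) stop("f0 must lie in [60, 400] Hz")
  if (any(p$formants[, "center"] >= samplingRate / 2))
    stop("formant centers must lie below Nyquist")
  if (duration <= 0) stop("duration must be positive")
  if (jitter < 0 || shimmer < 0) stop("jitter/shimmer must be >= 0")
  if (highbandNoiseGain < 0 || highbandNoiseGain > 1)
    stop("highbandNoiseGain must lie in [0, 1]")
  class(p) <- "VowelParams"
  p
}

## two-pole resonator applied in cascade
.formantFilter <- function(x, center, bandwidth, rate) {
  r <- exp(-pi * bandwidth / rate)
  theta <- 2 * pi * center / rate
  a <- c(1, -2 * r * cos(theta), r^2)
  b <- (1 - r) * sqrt(1 - 2 * r * cos(2 * theta) + r^2)
  as.numeric(signal::filter(b, a, x))
}

#' Synthesize a sustained vowel
#'
#' Deterministic for a fixed `(params, seed)` pair.  The returned
#' signal is peak-normalized to `[-1, 1]`.
#'
#' @param params A [vowelParams()] list.
#' @param seed Integer seed for the perturbation and noise draws.
#' @param subjectId,group,sex,age Metadata for the returned signal.
#' @return An [AudioSignal] of `round(duration * samplingRate)`
#'   samples.
#' @examples
#' sig <- synthVowel(vowelParams(f0 = 210), seed = 1)
#' length(sig)
#' @export
synthVowel <- function(params, seed = 1L, subjectId = NA_character_,
                       group = NA_character_, sex = NA_character_,
                       age = NA_real_) {
  stopifnot(inherits(params, "VowelParams"))
  rate <- params$samplingRate
  n <- as.integer(round(params$duration * rate))
  x <- .withSeed(seed, function() {
    ## glottal pulse train with jitter/shimmer
    src <- numeric(n)
    pos <- 1
    while (pos <= n) {
      period <- rate / (params$f0 *
                          (1 + params$jitter / 100 * rnorm(1)))
      period <- max(8, period)
      amp <- 1 + params$shimmer / 100 * rnorm(1)
      src[round(pos)] <- amp
      pos <- pos + period
    }
    ## soft glottal pulse kernel (~ -12 dB/oct source tilt)
    klen <- max(8L, round(0.4 * rate / params$f0))
    tt <- seq(0, 1, length.out = klen)
    kernel <- tt^2 * (1 - tt)
    kernel <- kernel - mean(kernel)   # zero-mean source (no DC buildup)
    src <- .conv(src, kernel)[seq_len(n)]
    voiced <- src
    for (i in seq_len(nrow(params$formants)))
      voiced <- .formantFilter(voiced, params$formants[i, "center"],
                               params$formants[i, "bandwidth"], rate)
    ## aspiration: broadband + extra high-band (>4 kHz) component
    wn <- rnorm(n)
    bf <- signal::butter(4, 4000 / (rate / 2), type = "high")
    hb <- as.numeric(signal::filter(bf, rnorm(n)))
    noise <- (1 - params$highbandNoiseGain) * wn / sd(wn) +
      params$highbandNoiseGain * hb / sd(hb)
    gain <- sqrt(mean(voiced^2) / mean(noise^2)) *
      10^(-params$hnrDb / 20)
    voiced + gain * noise
  })
  x <- x / max(abs(x))
  AudioSignal(samples = x, samplingRate = rate, subjectId = subjectId,
              group = group, sex = sex, age = age)
}

#' Default synthetic cohort configuration
#'
#' Composition follows the reference three-class, two-sex design:
#' 43 H (10 male / 33 female), 49 Y (11/38), 137 Q (47/90), with group
#' age distributions (mean, sd) of (26.3, 6.2) for H, (53.5, 10.6) for
#' Y and (45.2, 12.5) for Q, truncated to 18-90 years.  Group voice
#' parameters encode the clinical pictures: Q (weak, breathy voice) has
#' a markedly lower harmonic-to-noise ratio and more high-band
#' aspiration; Y (hoarse, dry voice) has raised jitter and shimmer and
#' a moderately lowered HNR; H is the healthy baseline.  Sex sets the
#' mean f0 (male 120 Hz, female 210 Hz) and scales the formants.
#'
#' @return Nested list: `counts[[group]][[sex]]`, `age[[group]]`
#'   (mean/sd), and `voice[[group]]` parameter means and spreads.
#' @export
defaultCohortConfig <- function() {
  list(
    samplingRate = 16000,
    duration = 1.2,
    counts = list(
      H = c(male = 10, female = 33),
      Y = c(male = 11, female = 38),
      Q = c(male = 47, female = 90)
    ),
    age = list(H = c(mean = 26.3, sd = 6.2),
               Y = c(mean = 53.5, sd = 10.6),
               Q = c(mean = 45.2, sd = 12.5)),
    f0 = list(male = c(mean = 120, sd = 10),
              female = c(mean = 210, sd = 15)),
    voice = list(
      H = list(jitter = c(0.6, 0.15), shimmer = c(3, 0.8),
               hnrDb = c(24, 2), highband = c(0.08, 0.02)),
      Y = list(jitter = c(2.6, 0.5), shimmer = c(10, 2),
               hnrDb = c(17, 2), highband = c(0.12, 0.03)),
      Q = list(jitter = c(1.2, 0.3), shimmer = c(5, 1.2),
               hnrDb = c(10, 2), highband = c(0.35, 0.07))
    )
  )
}

## truncated normal by resampling
.rtrunc <- function(n, mean, sd, lo, hi) {
  out <- rnorm(n, mean, sd)
  bad <- out < lo | out > hi
  while (any(bad)) {
    out[bad] <- rnorm(sum(bad), mean, sd)
    bad <- out < lo | out > hi
  }
  out
}

#' Draw vowel parameters for a group/sex cell
#'
#' @param group `"Q"`, `"Y"`, or `"H"`.
#' @param sex `"male"` or `"female"`.
#' @param config Cohort configuration (default
#'   [defaultCohortConfig()]).
#' @param seed Seed for the draw.
#' @return A [vowelParams()] list.
#' @export
groupParams <- function(group, sex, config = defaultCohortConfig(),
                        seed = 1L) {
  if (!group %in% .GROUPS) stop("unknown group: ", group)
  if (!sex %in% .SEXES) stop("unknown sex: ", sex)
  v <- config$voice[[group]]
  f0c <- config$f0[[sex]]
  .withSeed(seed, function() {
    pos <- function(p) max(p[1] + p[2] * rnorm(1), 0.01)
    fScale <- if (sex == "female") 1.1 else 1
    vowelParams(
      f0 = min(400, max(60, rnorm(1, f0c["mean"], f0c["sd"]))),
      jitter = pos(v$jitter), shimmer = pos(v$shimmer),
      formants = cbind(center = c(700, 1100, 2600, 3300) * fScale,
                       bandwidth = c(80, 90, 120, 150)),
      hnrDb = v$hnrDb[1] + v$hnrDb[2] * rnorm(1),
      highbandNoiseGain = min(1, pos(v$highband)),
      duration = config$duration, samplingRate = config$samplingRate)
  })
}

#' Reference suite of bounded test signals
#'
#' A fixed-composition set of 1 s, 16 kHz signals used to probe the
#' dimension estimator across signal classes: 50 pure tones with
#' frequencies log-spaced on 50-4000 Hz, 30 white-noise signals at
#' three amplitudes (0.1, 1, 10), and 20 default synthetic vowels
#' cycling through the group/sex cells.  Signal `i` uses seed
#' `seeds[i]`.
#'
#' @param seeds Integer vector of per-signal seeds (its length fixes
#'   the suite size; default 1:100).
#' @param samplingRate Hz.
#' @return List of [AudioSignal] objects, `length(seeds)` long.
#' @export
referenceSignalSuite <- function(seeds = 1:100, samplingRate = 16000) {
  n <- length(seeds)
  nTone <- round(0.5 * n)
  nNoise <- round(0.3 * n)
  nVowel <- n - nTone - nNoise
  freqs <- exp(seq(log(50), log(4000), length.out = max(nTone, 1L)))
  amps <- rep_len(c(0.1, 1, 10), max(nNoise, 1L))
  cells <- expand.grid(group = .GROUPS, sex = .SEXES,
                       stringsAsFactors = FALSE)
  out <- vector("list", n)
  tt <- seq.int(0L, samplingRate - 1L) / samplingRate
  for (i in seq_len(n)) {
    out[[i]] <- if (i <= nTone) {
      AudioSignal(sin(2 * pi * freqs[i] * tt), samplingRate,
                  subjectId = sprintf("tone_%04.0f", freqs[i]))
    } else if (i <= nTone + nNoise) {
      j <- i - nTone
      .withSeed(seeds[i], function()
        AudioSignal(amps[j] * rnorm(samplingRate), samplingRate,
                    subjectId = sprintf("noise_%g_%d", amps[j], j)))
    } else {
      j <- (i - nTone - nNoise - 1L) %% nrow(cells) + 1L
      p <- groupParams(cells$group[j], cells$sex[j],
                       seed = seeds[i])
      p$duration <- 1
      p$samplingRate <- samplingRate
      synthVowel(p, seed = seeds[i],
                 subjectId = sprintf("vowel_%s_%s_%d", cells$group[j],
                                     cells$sex[j], i),
                 group = cells$group[j], sex = cells$sex[j])
    }
  }
  out
}

#' Generate a synthetic cohort
#'
#' Synthesizes every subject of the configured composition.  All
#' randomness flows from `seed` through per-subject derived seeds, so
#' cohorts are reproducible piecewise and two different master seeds
#' share the composition but not the waveforms.
#'
#' @param config Cohort configuration (default
#'   [defaultCohortConfig()]).
#' @param seed Master seed.
#' @param writeWavTo Optional directory; when given, WAV files and a
#'   `manifest.csv` in the [readManifest()] dialect are written there.
#' @return List with `manifest` (`data.frame`: subject_id, group, sex,
#'   age, and `path` when written) and `signals` (list of
#'   [AudioSignal]).
#' @examples
#' \donttest{
#' cfg <- defaultCohortConfig()
#' cfg$counts <- lapply(cfg$counts, function(x) pmax(1, x %/% 10))
#' coh <- generateCohort(cfg, seed = 1)
#' table(coh$manifest$group)
#' }
#' @export
generateCohort <- function(config = defaultCohortConfig(), seed = 1L,
                           writeWavTo = NULL) {
  cells <- expand.grid(group = .GROUPS, sex = .SEXES,
                       stringsAsFactors = FALSE)
  rows <- list()
  signals <- list()
  k <- 0L
  for (i in seq_len(nrow(cells))) {
    g <- cells$group[i]
    s <- cells$sex[i]
    nGS <- config$counts[[g]][[s]]
    if (is.null(nGS) || nGS < 1L) next
    for (j in seq_len(nGS)) {
      k <- k + 1L
      subSeed <- (as.integer(seed) %% 100000L) * 20011L + k * 7919L
      id <- sprintf("%s_%s_%03d", g, substr(s, 1, 1), j)
      age <- .withSeed(subSeed + 1L, function()
        .rtrunc(1, config$age[[g]]["mean"], config$age[[g]]["sd"],
                18, 90))
      params <- groupParams(g, s, config, seed = subSeed + 2L)
      signals[[k]] <- synthVowel(params, seed = subSeed + 3L,
                                 subjectId = id, group = g, sex = s,
                                 age = round(age, 1))
      rows[[k]] <- data.frame(subject_id = id, group = g, sex = s,
                              age = round(age, 1))
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(writeWavTo)) {
    dir.create(writeWavTo, recursive = TRUE, showWarnings = FALSE)
    manifest$path <- paste0(manifest$subject_id, ".wav")
    for (k in seq_along(signals))
      writeWav(signals[[k]], path = file.path(writeWavTo,
                                              manifest$path[k]))
    write.csv(manifest[, c("subject_id", "path", "group", "sex", "age")],
              file.path(writeWavTo, "manifest.csv"), row.names = FALSE,
              quote = FALSE)
  }
  list(manifest = manifest, signals = signals)
}
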