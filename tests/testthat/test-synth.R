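test_that("default cohort reproduces the reference composition", {
  cfg <- defaultCohortConfig()
  total <- sum(unlist(cfg$counts))
  expect_equal(total, 229)
  expect_equal(sum(cfg$counts$H), 43)
  expect_equal(sum(cfg$counts$Y), 49)
  expect_equal(sum(cfg$counts$Q), 137)
  expect_equal(unname(cfg$counts$Q["male"]), 47)
  expect_equal(unname(cfg$counts$Y["female"]), 38)
  expect_equal(unname(cfg$counts$H["male"]), 10)
})

test_that("vowel synthesis is deterministic and spectrally plausible", {
  p <- vowelParams(f0 = 150, duration = 1, samplingRate = 16000)
  s1 <- synthVowel(p, seed = 42)
  s2 <- synthVowel(p, seed = 42)
  expect_identical(samples(s1), samples(s2))
  expect_length(s1, 16000)
  expect_lte(max(abs(samples(s1))), 1)
  s3 <- synthVowel(p, seed = 43)
  expect_false(identical(samples(s1), samples(s3)))

  ## spectral peak of the periodic part at a harmonic of f0
  clean <- vowelParams(f0 = 150, jitter = 0, shimmer = 0, hnrDb = 60,
                       duration = 1, samplingRate = 16000)
  sp <- Mod(stats::fft(samples(synthVowel(clean, seed = 1))))[1:4000]
  peakHz <- which.max(sp) - 1
  expect_lt(min(abs(peakHz - 150 * (1:8))), 2)
})

test_that("parameter validation rejects out-of-range voices", {
  expect_error(vowelParams(f0 = 30), "f0")
  expect_error(vowelParams(formants = cbind(center = 9000,
                                            bandwidth = 100)), "Nyquist")
  expect_error(vowelParams(duration = 0), "duration")
  expect_error(groupParams("Z", "male"), "unknown group")
  expect_error(groupParams("Q", "other"), "unknown sex")
})

test_that("group parameter draws encode the clinical contrasts", {
  cfg <- defaultCohortConfig()
  draw <- function(g, s, i) groupParams(g, s, cfg, seed = i)
  qh <- vapply(1:25, function(i) draw("Q", "male", i)$hnrDb, numeric(1))
  hh <- vapply(1:25, function(i) draw("H", "male", i)$hnrDb, numeric(1))
  expect_lt(mean(qh), mean(hh))
  yj <- vapply(1:25, function(i) draw("Y", "female", i)$jitter,
               numeric(1))
  hj <- vapply(1:25, function(i) draw("H", "female", i)$jitter,
               numeric(1))
  expect_gt(mean(yj), mean(hj))
  qg <- vapply(1:25, function(i) draw("Q", "female", i)$highbandNoiseGain,
               numeric(1))
  hg <- vapply(1:25, function(i) draw("H", "female", i)$highbandNoiseGain,
               numeric(1))
  expect_gt(mean(qg), mean(hg))
  ## reproducible draws
  expect_identical(draw("Y", "male", 5), draw("Y", "male", 5))
  ## sex sets the f0 register
  fm <- vapply(1:25, function(i) draw("H", "male", i)$f0, numeric(1))
  ff <- vapply(1:25, function(i) draw("H", "female", i)$f0, numeric(1))
  expect_lt(mean(fm), 160)
  expect_gt(mean(ff), 180)
})

test_that("cohort generation respects counts, ages, and seeding", {
  coh <- smallCohort()
  m <- coh$manifest
  cfg <- smallCohortConfig()
  for (g in c("Q", "Y", "H"))
    for (s in c("male", "female"))
      expect_equal(sum(m$group == g & m$sex == s),
                   unname(cfg$counts[[g]][s]),
                   label = paste(g, s))
  expect_false(anyDuplicated(m$subject_id) > 0)
  expect_true(all(m$age >= 18 & m$age <= 90))
  ## H is the youngest group by construction
  expect_lt(mean(m$age[m$group == "H"]), mean(m$age[m$group == "Q"]))

  ## same seed: identical; different seed: same shape, new waveforms
  cohB <- generateCohort(cfg, seed = 11)
  expect_identical(samples(coh$signals[[1]]), samples(cohB$signals[[1]]))
  cohC <- generateCohort(cfg, seed = 12)
  expect_identical(cohC$manifest[, c("subject_id", "group", "sex")],
                   m[, c("subject_id", "group", "sex")])
  expect_false(identical(samples(coh$signals[[1]]),
                         samples(cohC$signals[[1]])))
})

test_that("reference signal suite has the documented composition", {
  suite <- referenceSignalSuite(seeds = 1:20)
  expect_length(suite, 20L)
  ids <- vapply(suite, subjectId, character(1))
  expect_equal(sum(startsWith(ids, "tone")), 10L)
  expect_equal(sum(startsWith(ids, "noise")), 6L)
  expect_equal(sum(startsWith(ids, "vowel")), 4L)
  expect_true(all(vapply(suite, length, integer(1)) == 16000L))
})
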