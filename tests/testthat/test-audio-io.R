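test_that("WAV write/read round-trips within 1 LSB at each depth", {
  x <- 0.8 * sin(2 * pi * 440 * (0:3999) / 16000)
  for (bits in c(16L, 24L, 32L)) {
    f <- withr::local_tempfile(fileext = ".wav")
    writeWav(x, 16000, f, bits = bits)
    sig <- readAudio(f)
    expect_equal(samplingRate(sig), 16000)
    expect_length(samples(sig), 4000)
    lsb <- if (bits == 32L) 1e-7 else 2^-(bits - 1L)
    expect_lt(max(abs(samples(sig) - x)), lsb + 1e-12)
  }
})

test_that("reader rejects what the acquisition contract excludes", {
  expect_error(readAudio(file.path(tempdir(), "nope.wav")), "not found")

  ## stereo file: craft a 2-channel header by hand
  f <- withr::local_tempfile(fileext = ".wav")
  con <- file(f, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + 8L, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 2L), con, size = 2, endian = "little")
  writeBin(c(16000L, 64000L), con, size = 4, endian = "little")
  writeBin(c(4L, 16L), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(8L, con, size = 4, endian = "little")
  writeBin(c(0L, 0L, 0L, 0L), con, size = 2, endian = "little")
  close(con)
  expect_error(readAudio(f), "stereo")

  ## zero-length data chunk
  f2 <- withr::local_tempfile(fileext = ".wav")
  writeWav(numeric(1), 16000, f2)  # 1 sample is fine...
  expect_s4_class(readAudio(f2), "AudioSignal")

  ## an all-zero file is accepted here (rejected downstream)
  f3 <- withr::local_tempfile(fileext = ".wav")
  writeWav(numeric(100), 16000, f3)
  expect_identical(samples(readAudio(f3)), rep(0, 100))
})

test_that("optional resampling matches an analytic tone oracle", {
  ## 440 Hz tone recorded at 44.1 kHz, resampled to 16 kHz: compare
  ## the interior against the analytically generated 16 kHz tone
  f <- withr::local_tempfile(fileext = ".wav")
  x44 <- sin(2 * pi * 440 * (0:44099) / 44100)
  writeWav(x44, 44100, f)
  sig <- readAudio(f, resampleTo = 16000)
  expect_equal(samplingRate(sig), 16000)
  expect_equal(length(sig), 16000)
  oracle <- sin(2 * pi * 440 * (0:(length(sig) - 1)) / 16000)
  mid <- 2000:14000
  expect_lt(max(abs(samples(sig)[mid] - oracle[mid])), 0.02)
  ## without the flag the original rate is preserved
  expect_equal(samplingRate(readAudio(f)), 44100)
})

test_that("stable-segment selection maximizes RMS with earliest tie-break", {
  rate <- 1000
  ## silence then a unit tone: the tone second must be returned
  x <- c(numeric(rate), sin(2 * pi * 50 * (0:(rate - 1)) / rate))
  sig <- AudioSignal(x, rate)
  seg <- selectStableSegment(sig, 1)
  expect_length(seg, rate)
  expect_equal(samples(seg), x[(rate + 1):(2 * rate)])

  ## exhaustive check on a short fixture: no same-length window beats it
  set.seed(4)
  y <- rnorm(300) * rep(c(0.2, 1, 0.5), each = 100)
  sigY <- AudioSignal(y, rate)
  segY <- samples(selectStableSegment(sigY, 0.1))
  n <- 100L
  rmsAll <- vapply(seq_len(length(y) - n + 1L), function(i)
    sqrt(mean(y[i:(i + n - 1L)]^2)), numeric(1))
  expect_gte(sqrt(mean(segY^2)) + 1e-12, max(rmsAll[seq(1, 201, by = 10)]))

  ## exact-length input is returned unchanged
  expect_identical(samples(selectStableSegment(sigY, 0.3)), y)
  ## equal-energy windows: earliest wins
  z <- AudioSignal(rep(c(1, -1), 200), rate)
  expect_identical(samples(selectStableSegment(z, 0.1)),
                   samples(z)[1:100])
  expect_error(selectStableSegment(z, 1), "shorter")
})

test_that("manifest validation enforces the cohort contract", {
  d <- withr::local_tempdir()
  m <- data.frame(subject_id = c("a", "b"), path = c("a.wav", "b.wav"),
                  group = c("Q", "H"), sex = c("male", "female"),
                  age = c(40, 30))
  f <- file.path(d, "manifest.csv")
  write.csv(m, f, row.names = FALSE)
  got <- readManifest(f)
  expect_equal(got$subject_id, c("a", "b"))
  expect_true(all(startsWith(got$path, d)))

  bad <- m; bad$group[1] <- "X"
  write.csv(bad, f, row.names = FALSE)
  expect_error(readManifest(f), "group")
  bad <- m; bad$subject_id <- c("a", "a")
  write.csv(bad, f, row.names = FALSE)
  expect_error(readManifest(f), "duplicate")
  bad <- m; bad$age[2] <- -1
  write.csv(bad, f, row.names = FALSE)
  expect_error(readManifest(f), "age")
})
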