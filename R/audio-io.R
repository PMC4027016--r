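## WAV I/O and pre-segmentation.
##
## The reader handles the formats the acquisition contract promises:
## mono RIFF/WAVE, PCM 16- or 24-bit, or IEEE float32.  Stereo input is
## rejected outright (channel averaging would change the amplitude
## statistics feeding the fractal estimator).

.readChunks <- function(con) {
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file")
  chunks <- list()
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(size) == 0L) break
    data <- readBin(con, "raw", size)
    chunks[[id]] <- data
    if (size %% 2L == 1L) readBin(con, "raw", 1)  # chunk padding
    if (!is.null(chunks[["fmt "]]) && !is.null(chunks[["data"]])) break
  }
  chunks
}

#' Read a mono WAV file
#'
#' Reads a mono PCM (16- or 24-bit) or IEEE float32 WAV file and
#' returns an [AudioSignal] with amplitudes scaled to `[-1, 1]`.
#'
#' @param path Path to a WAV file.
#' @param subjectId,group,sex,age Optional metadata attached to the
#'   returned signal.
#' @param resampleTo If non-`NULL`, a target sampling rate in Hz; files
#'   at a different rate are polyphase-resampled.  When `NULL`
#'   (default) a file at any rate is returned unchanged.
#' @return An [AudioSignal].
#' @examples
#' f <- tempfile(fileext = ".wav")
#' writeWav(sin(2 * pi * 440 * (0:15999) / 16000), 16000, f)
#' sig <- readAudio(f)
#' samplingRate(sig)
#' @seealso [writeWav()], [selectStableSegment()]
#' @export
readAudio <- function(path, subjectId = NA_character_,
                      group = NA_character_, sex = NA_character_,
                      age = NA_real_, resampleTo = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  chunks <- .readChunks(con)
  fmt <- chunks[["fmt "]]
  dat <- chunks[["data"]]
  if (is.null(fmt) || is.null(dat)) stop("missing fmt/data chunk: ", path)
  audioFormat <- readBin(fmt[1:2], "integer", 1, size = 2, endian = "little",
                         signed = FALSE)
  nChannels <- readBin(fmt[3:4], "integer", 1, size = 2, endian = "little",
                       signed = FALSE)
  rate <- readBin(fmt[5:8], "integer", 1, size = 4, endian = "little")
  bits <- readBin(fmt[15:16], "integer", 1, size = 2, endian = "little",
                  signed = FALSE)
  if (nChannels != 1L)
    stop("stereo/multichannel input rejected (", nChannels, " channels): ",
         path)
  x <- if (audioFormat == 1L && bits == 16L) {
    readBin(dat, "integer", length(dat) %/% 2L, size = 2,
            endian = "little") / 32768
  } else if (audioFormat == 1L && bits == 24L) {
    n <- length(dat) %/% 3L
    b <- matrix(as.integer(dat[seq_len(3L * n)]), nrow = 3L)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else if (audioFormat == 3L && bits == 32L) {
    readBin(dat, "numeric", length(dat) %/% 4L, size = 4,
            endian = "little")
  } else {
    stop("unsupported WAV encoding (format ", audioFormat, ", ", bits,
         " bit): ", path)
  }
  if (length(x) == 0L) stop("zero-length audio: ", path)
  if (!is.null(resampleTo) && resampleTo != rate) {
    x <- .resampleTo(x, rate, resampleTo)
    rate <- resampleTo
  }
  AudioSignal(samples = as.numeric(x), samplingRate = rate,
              subjectId = subjectId, group = group, sex = sex, age = age)
}

## zero-phase anti-alias lowpass (when downsampling) + interpolation
.resampleTo <- function(x, rate, target) {
  if (target < rate) {
    b <- signal::butter(8, 0.9 * target / rate)
    x <- signal::filtfilt(b, x)
  }
  n <- round(length(x) * target / rate)
  stats::approx(seq.int(0L, length(x) - 1L) / rate,
                x, xout = seq.int(0L, n - 1L) / target, rule = 2)$y
}

#' Write a mono WAV file
#'
#' @param x Numeric amplitudes in `[-1, 1]` (values are clipped) or an
#'   [AudioSignal].
#' @param rate Sampling rate in Hz (ignored when `x` is an
#'   [AudioSignal]).
#' @param path Output path.
#' @param bits Encoding: 16 or 24 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
writeWav <- function(x, rate, path, bits = 16L) {
  if (is(x, "AudioSignal")) {
    rate <- samplingRate(x)
    x <- samples(x)
  }
  stopifnot(bits %in% c(16L, 24L, 32L))
  x <- pmin(1, pmax(-1, x))
  bytesPer <- bits %/% 8L
  dataSize <- length(x) * bytesPer
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(if (bits == 32L) 3L else 1L, 1L), con, size = 2,
           endian = "little")
  writeBin(as.integer(c(rate, rate * bytesPer)), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(bytesPer, bits)), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, size = 4, endian = "little")
  if (bits == 16L) {
    v <- as.integer(round(pmin(32767, x * 32768)))
    writeBin(v, con, size = 2, endian = "little")
  } else if (bits == 24L) {
    v <- round(pmin(8388607, x * 8388608))
    v <- ifelse(v < 0, v + 16777216, v)
    b <- rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256)
    writeBin(as.raw(b), con)
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Select the most stable segment of a phonation
#'
#' Returns the contiguous window of the requested duration with maximal
#' RMS energy, scanned at a 10 ms hop.  Ties are broken by taking the
#' earliest window, so the result is deterministic.
#'
#' @param signal An [AudioSignal].
#' @param duration Window length in seconds (default 1, the nominal
#'   length of a sustained phonation).
#' @return An [AudioSignal] of exactly `round(duration * rate)`
#'   samples, metadata preserved.
#' @export
selectStableSegment <- function(signal, duration = 1) {
  x <- samples(signal)
  rate <- samplingRate(signal)
  n <- as.integer(round(duration * rate))
  if (n < 1L) stop("duration too short")
  if (n > length(x))
    stop("signal shorter than requested duration")
  if (n == length(x)) return(signal)
  hop <- max(1L, as.integer(round(0.010 * rate)))
  starts <- seq.int(1L, length(x) - n + 1L, by = hop)
  cs <- c(0, cumsum(x^2))
  energy <- cs[starts + n] - cs[starts]
  best <- starts[which.max(energy)]   # which.max takes the first maximum
  initialize(signal, samples = x[best:(best + n - 1L)])
}

#' Read a cohort manifest
#'
#' Reads a CSV manifest with header
#' `subject_id,path,group,sex,age` and validates it: subject ids must
#' be unique, groups in `{Q, Y, H}`, ages non-negative.
#'
#' @param path Path to the manifest CSV.
#' @param baseDir Directory that relative audio paths are resolved
#'   against (defaults to the manifest's directory).
#' @return A `data.frame` with the validated records.
#' @export
readManifest <- function(path, baseDir = dirname(path)) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "group", "sex", "age")
  if (!all(need %in% colnames(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(m$subject_id))
    stop("duplicate subject ids in manifest")
  if (!all(m$group %in% .GROUPS))
    stop("groups must be one of: ", paste(.GROUPS, collapse = ", "))
  if (!all(m$sex %in% .SEXES))
    stop("sex must be 'male' or 'female'")
  if (!all(is.finite(m$age) & m$age >= 0))
    stop("ages must be finite and non-negative")
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(baseDir, m$path[rel])
  m
}
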