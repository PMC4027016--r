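## Wavelet packet decomposition (orthonormal Daubechies filter bank).
##
## Analysis uses zero extension with full-overlap coefficient
## retention: every inner product of the signal with a translated
## analysis filter that overlaps the support is kept, so the transform
## is an exact isometry (energy conserved) and synthesis inverts it
## exactly.  Public node indices are frequency (sequency) ordered; the
## natural Paley order of the filter bank is permuted by the inverse
## Gray code.

## Orthonormal scaling filters (synthesis lowpass h, sum = sqrt(2)).
.SCALING_FILTERS <- list(
  haar = c(0.70710678118654757, 0.70710678118654757),
  db1 = c(0.70710678118654757, 0.70710678118654757),
  db2 = c(0.48296291314453416, 0.83651630373780794, 0.22414386804201339,
          -0.12940952255126037),
  db4 = c(0.23037781330889651, 0.71484657055291567, 0.63088076792985892,
          -0.027983769416859854, -0.18703481171909309,
          0.030841381835560764, 0.032883011666885197,
          -0.010597401785069032),
  db8 = c(0.054415842243104008, 0.31287159091429995, 0.67563073629728976,
          0.58535468365420673, -0.015829105256349306,
          -0.28401554296154691, 0.00047248457391328279,
          0.12874742662047847, -0.017369301001807547,
          -0.044088253930794755, 0.013981027917398282,
          0.0087460940474057766, -0.0048703529934515741,
          -0.00039174037337694705, 0.00067544940645056933,
          -0.00011747678412476953),
  sym4 = c(0.032223100604042702, -0.012603967262037833,
           -0.099219543576847216, 0.29785779560527736,
           0.80373875180591614, 0.49761866763201545,
           -0.02963552764599851, -0.075765714789273325)
)

.waveletFilters <- function(name) {
  h <- .SCALING_FILTERS[[name]]
  if (is.null(h)) stop("unknown wavelet: ", name, " (available: ",
                       paste(names(.SCALING_FILTERS), collapse = ", "), ")")
  decLo <- rev(h)
  recHi <- decLo * (-1)^(seq_along(h) - 1L)
  list(decLo = decLo, decHi = rev(recHi), recLo = h, recHi = recHi,
       length = length(h))
}

## full linear convolution (direct; filters here are short)
.conv <- function(x, f) {
  nf <- length(f)
  padded <- c(numeric(nf - 1L), x, numeric(nf - 1L))
  y <- stats::filter(padded, f, method = "convolution", sides = 1L)
  as.numeric(y[seq.int(nf, length.out = length(x) + nf - 1L)])
}

.dwtStep <- function(x, filt) {
  lo <- .conv(x, filt$decLo)
  hi <- .conv(x, filt$decHi)
  keep <- seq.int(2L, length(lo), by = 2L)
  list(a = lo[keep], d = hi[keep])
}

.idwtStep <- function(a, d, filt, outLen) {
  up <- function(c) {
    u <- numeric(2L * length(c))
    u[seq.int(1L, length(u), by = 2L)] <- c
    u
  }
  r <- .conv(up(a), filt$recLo) + .conv(up(d), filt$recHi)
  r[seq.int(filt$length - 1L, length.out = outLen)]
}

## natural (Paley) index p -> frequency position: inverse Gray code
.freqOfNatural <- function(p) {
  f <- 0L
  while (p > 0L) {
    f <- bitwXor(f, p)
    p <- bitwShiftR(p, 1L)
  }
  f
}

## frequency position f -> natural index: Gray code
.naturalOfFreq <- function(f) bitwXor(f, bitwShiftR(f, 1L))

.checkNode <- function(tree, level, index) {
  if (level < 0L || level > tree@maxLevel)
    stop("level must lie in 0..", tree@maxLevel)
  if (index < 0L || index >= 2^level)
    stop("node index must lie in 0..", 2^level - 1L, " at level ", level)
  invisible(TRUE)
}

#' Wavelet packet decomposition of a signal
#'
#' Performs a full wavelet packet decomposition to `maxLevel` with an
#' orthonormal Daubechies-family filter bank (default `"db4"`).  Both
#' the approximation and detail branches are split at every level, so
#' level `i` holds `2^i` equal-bandwidth subbands.  Nodes are exposed
#' in frequency order (see [nodeFrequencyBand()]).
#'
#' @param signal An [AudioSignal] or a numeric vector.
#' @param waveletName Wavelet identifier; one of `haar`/`db1`, `db2`,
#'   `db4`, `db8`, `sym4`.
#' @param maxLevel Decomposition depth (`>= 1`; `0` returns a trivial
#'   tree whose only node is the input).
#' @param samplingRate Sampling rate in Hz, required when `signal` is a
#'   bare numeric vector.
#' @return A [WaveletPacketTree].
#' @examples
#' x <- sin(2 * pi * 440 * (0:4095) / 16000)
#' tree <- wpDecompose(x, maxLevel = 3, samplingRate = 16000)
#' tree
#' length(nodeCoefficients(tree, 3, 0))
#' @export
wpDecompose <- function(signal, waveletName = "db4", maxLevel = 5L,
                        samplingRate = NULL) {
  if (is(signal, "AudioSignal")) {
    x <- samples(signal)
    rate <- samplingRate(signal)
  } else {
    x <- as.numeric(signal)
    rate <- if (is.null(samplingRate)) NA_real_ else samplingRate
  }
  maxLevel <- as.integer(maxLevel)
  if (maxLevel < 0L) stop("maxLevel must be >= 0")
  if (length(x) < 2^maxLevel)
    stop("signal too short (", length(x), " samples) for a level-",
         maxLevel, " decomposition")
  filt <- .waveletFilters(waveletName)
  nodes <- vector("list", maxLevel)
  lengths <- integer(maxLevel + 1L)
  lengths[1L] <- length(x)
  natural <- list(x)
  for (lev in seq_len(maxLevel)) {
    children <- vector("list", 2L * length(natural))
    for (p in seq_along(natural)) {
      ad <- .dwtStep(natural[[p]], filt)
      children[[2L * p - 1L]] <- ad$a
      children[[2L * p]] <- ad$d
    }
    natural <- children
    lengths[lev + 1L] <- length(natural[[1L]])
    ## permute natural -> frequency order
    freq <- vector("list", length(natural))
    for (p in seq_along(natural))
      freq[[.freqOfNatural(p - 1L) + 1L]] <- natural[[p]]
    nodes[[lev]] <- freq
  }
  WaveletPacketTree(
    waveletName = waveletName, maxLevel = maxLevel, nodes = nodes,
    lengths = lengths, originalLength = length(x), original = x,
    samplingRate = as.numeric(rate)
  )
}

#' Frequency band of a wavelet packet node
#'
#' In frequency order, node `n` at level `i` covers
#' `[n * df, (n + 1) * df)` Hz with `df = (samplingRate / 2) / 2^i`;
#' the Nyquist frequency is assigned to the last node (half-open bands,
#' closed at the top edge).
#'
#' @param level Decomposition level (`>= 1`).
#' @param index Frequency-ordered node index in `0:(2^level - 1)`.
#' @param samplingRate Sampling rate in Hz.
#' @return Named numeric vector `c(low = , high = )` in Hz.
#' @examples
#' nodeFrequencyBand(1, 1, 16000)  # 4-8 kHz
#' nodeFrequencyBand(3, 4, 16000)  # 4-5 kHz
#' @export
nodeFrequencyBand <- function(level, index, samplingRate) {
  if (level < 1L) stop("level must be >= 1")
  if (index < 0L || index >= 2^level)
    stop("node index out of range at level ", level)
  df <- (samplingRate / 2) / 2^level
  c(low = index * df, high = (index + 1) * df)
}

#' Reconstruct the time-domain content of one subband
#'
#' Inverts the filter bank with all other nodes zeroed, yielding a
#' sequence of the original length that contains only the chosen
#' subband's contribution.  Summing the reconstructions of all nodes of
#' any level recovers the original signal exactly.
#'
#' @param tree A [WaveletPacketTree].
#' @param level Level of the node.
#' @param index Frequency-ordered node index.
#' @return Numeric vector of length `tree@originalLength`.
#' @export
reconstructNode <- function(tree, level, index) {
  .checkNode(tree, level, index)
  if (level == 0L) return(tree@original)
  filt <- .waveletFilters(tree@waveletName)
  p <- .naturalOfFreq(as.integer(index))
  coef <- tree@nodes[[level]][[index + 1L]]
  for (lev in seq.int(level, 1L)) {
    bit <- p %% 2L
    p <- p %/% 2L
    zero <- numeric(length(coef))
    coef <- if (bit == 0L)
      .idwtStep(coef, zero, filt, tree@lengths[lev])
    else
      .idwtStep(zero, coef, filt, tree@lengths[lev])
  }
  coef
}

#' Per-node energies of a decomposition level
#'
#' @param tree A [WaveletPacketTree].
#' @param level Level to summarize.
#' @return Numeric vector of sums of squared coefficients, frequency
#'   order.
#' @export
nodeEnergies <- function(tree, level) {
  if (level < 1L || level > tree@maxLevel)
    stop("level must lie in 1..", tree@maxLevel)
  vapply(tree@nodes[[level]], function(v) sum(v^2), numeric(1))
}

#' Serialize tree metadata to JSON
#'
#' Writes (or returns) a JSON summary of a decomposition: wavelet,
#' depth, per-level coefficient lengths, and per-node energies with
#' band limits.
#'
#' @param tree A [WaveletPacketTree].
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
treeMetadataJSON <- function(tree, path = NULL) {
  levels <- lapply(seq_len(tree@maxLevel), function(lev) {
    idx <- 0:(2^lev - 1L)
    bands <- t(vapply(idx, nodeFrequencyBand, numeric(2), level = lev,
                      samplingRate = tree@samplingRate))
    list(level = lev, coefficients = tree@lengths[lev + 1L],
         nodes = data.frame(index = idx, low_hz = bands[, 1L],
                            high_hz = bands[, 2L],
                            energy = nodeEnergies(tree, lev)))
  })
  out <- jsonlite::toJSON(
    list(wavelet = tree@waveletName, max_level = tree@maxLevel,
         original_length = tree@originalLength,
         sampling_rate = tree@samplingRate, levels = levels),
    auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}
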