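# Recording-level acoustic descriptors.
#
# Each recording is summarised by an 88-dimensional vector of acoustic
# functionals: 22 frame-level descriptors (pitch, voicing, energy, spectral
# balance and voice-quality proxies) x 4 functionals (mean, sd, 20th and
# 80th percentile). Pitch is expressed in semitones above 27.5 Hz, the
# convention used by standardised paralinguistic feature sets.

#' Extract the 88 acoustic functionals of a recording
#'
#' Frame-level analysis (25 ms Hanning window, 10 ms hop): fundamental
#' frequency by FFT-based autocorrelation (55-500 Hz search range,
#' semitones above 27.5 Hz), voicing probability, RMS energy (dB),
#' zero-crossing rate, spectral centroid/spread/skewness/entropy/crest,
#' rolloff (0.85), flux, slope, alpha ratio (50-1000 Hz vs 1-5 kHz energy),
#' Hammarberg index, four band energies, autocorrelation peak height
#' (harmonicity), and jitter/shimmer proxies (frame-to-frame F0 and
#' amplitude perturbation). Each descriptor contributes its mean, standard
#' deviation and 20th/80th percentiles over frames. Deterministic.
#'
#' @param w a \linkS4class{Waveform} of at least 1 s.
#' @return named numeric vector of length 88.
#' @export
extractFunctionals <- function(w) {
  stopifnot(methods::is(w, "Waveform"))
  sr <- w@sampleRate
  x <- w@samples
  if (length(x) / sr < 1) {
    stop("invalid input: recording must be at least 1 s for functionals")
  }
  win <- max(32L, round(0.025 * sr))
  hop <- max(16L, round(0.010 * sr))
  nFrames <- ((length(x) - win) %/% hop) + 1L
  idx <- outer(seq_len(win), (seq_len(nFrames) - 1L) * hop, "+")
  frames <- matrix(x[idx], win, nFrames)
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1L) / (win - 1L))
  wf <- frames * hann

  # magnitude spectra
  nfft <- 2L^ceiling(log2(win))
  pad <- rbind(wf, matrix(0, nfft - win, nFrames))
  spec <- abs(stats::mvfft(pad))[seq_len(nfft %/% 2L), , drop = FALSE]
  freqs <- (seq_len(nfft %/% 2L) - 1L) * sr / nfft
  specPow <- spec^2
  totPow <- colSums(specPow) + 1e-12

  rms <- sqrt(colMeans(frames^2))
  rmsDb <- 20 * log10(pmax(rms, 1e-8))
  zcr <- colMeans(abs(diff(sign(frames))) > 0)

  centroid <- colSums(spec * freqs) / (colSums(spec) + 1e-12)
  fc <- matrix(freqs, length(freqs), nFrames) -
    matrix(centroid, length(freqs), nFrames, byrow = TRUE)
  spread <- sqrt(colSums(specPow * fc^2) / totPow)
  skewness <- colSums(specPow * fc^3) / (totPow * pmax(spread, 1e-6)^3)
  pSpec <- sweep(specPow, 2L, totPow, "/")
  entropy <- -colSums(pSpec * log(pSpec + 1e-12))
  crest <- apply(spec, 2L, max) / (colMeans(spec) + 1e-12)

  cum <- apply(specPow, 2L, cumsum)
  rolloff <- freqs[pmax(1L, apply(cum >= 0.85 * rep(totPow, each = nrow(cum)),
                                  2L, function(z) which(z)[1L]))]
  flux <- c(0, sqrt(colSums((spec[, -1L, drop = FALSE] -
                               spec[, -nFrames, drop = FALSE])^2)))
  # least-squares slope of magnitude on frequency
  fd <- freqs - mean(freqs)
  slope <- colSums(spec * fd) / sum(fd^2)

  bandE <- function(lo, hi) {
    sel <- freqs >= lo & freqs < hi
    10 * log10(colSums(specPow[sel, , drop = FALSE]) + 1e-12)
  }
  alphaRatio <- bandE(50, 1000) - bandE(1000, 5000)
  hammarberg <- {
    sel1 <- freqs >= 0 & freqs < 2000
    sel2 <- freqs >= 2000 & freqs < 5000
    20 * log10((apply(spec[sel1, , drop = FALSE], 2L, max) + 1e-12) /
                 (apply(spec[sel2, , drop = FALSE], 2L, max) + 1e-12))
  }

  # F0 by FFT-based autocorrelation
  lagMin <- max(2L, floor(sr / 500))
  lagMax <- min(win - 1L, ceiling(sr / 55))
  pad2 <- rbind(wf, matrix(0, nrow(wf), nFrames))
  F2 <- stats::mvfft(pad2)
  ac <- Re(stats::mvfft(F2 * Conj(F2), inverse = TRUE)) / nrow(pad2)
  ac0 <- pmax(ac[1L, ], 1e-12)
  acn <- sweep(ac[(lagMin + 1L):(lagMax + 1L), , drop = FALSE], 2L, ac0, "/")
  peakRel <- apply(acn, 2L, max)
  peakLag <- (lagMin:lagMax)[apply(acn, 2L, which.max)]
  f0hz <- sr / peakLag
  voiced <- peakRel > 0.45 & rms > 0.5 * mean(rms)
  f0st <- ifelse(voiced, 12 * log2(pmax(f0hz, 1) / 27.5), NA_real_)
  voicingProb <- as.numeric(voiced)
  jitter <- abs(c(0, diff(ifelse(is.na(f0st), 0, f0st)))) * voicingProb
  shimmer <- abs(c(0, diff(rmsDb)))

  descriptors <- list(
    F0semitone = f0st[voiced],
    voicingProb = voicingProb,
    loudnessDb = rmsDb,
    zcr = zcr,
    spectralCentroid = centroid,
    spectralRolloff = rolloff,
    spectralFlux = flux,
    spectralSlope = slope,
    spectralEntropy = entropy,
    alphaRatio = alphaRatio,
    hammarbergIndex = hammarberg,
    bandEnergy0to500 = bandE(0, 500),
    bandEnergy500to1000 = bandE(500, 1000),
    bandEnergy1000to2000 = bandE(1000, 2000),
    bandEnergy2000to4000 = bandE(2000, 4000),
    harmonicity = peakRel,
    jitterProxy = jitter,
    shimmerProxy = shimmer,
    logEnergy = log(colSums(frames^2) + 1e-12),
    spectralSpread = spread,
    spectralSkewness = skewness,
    spectralCrest = crest
  )
  out <- numeric(0)
  for (nm in names(descriptors)) {
    v <- descriptors[[nm]]
    v <- v[is.finite(v)]
    if (length(v) == 0L) v <- 0
    qs <- stats::quantile(v, c(0.2, 0.8), names = FALSE, type = 7)
    f <- c(mean(v), stats::sd(c(v, if (length(v) == 1L) v)), qs[1L], qs[2L])
    f[!is.finite(f)] <- 0
    names(f) <- paste0(nm, c("_mean", "_sd", "_p20", "_p80"))
    out <- c(out, f)
  }
  stopifnot(length(out) == 88L)
  out
}

#' Linear 88-to-256 acoustic projection parameters
#'
#' @param seed initialisation seed.
#' @param dIn input dimensionality (default 88).
#' @param dOut projected dimensionality (default 256).
#' @return list with weight matrix \code{W} (dOut x dIn) and bias \code{b}.
#' @export
makeAcousticProjection <- function(seed = 1L, dIn = 88L, dOut = 256L) {
  .withSeed(seed, list(W = .rmat(dOut, dIn), b = matrix(0, dOut, 1L)))
}

#' Project an acoustic vector and tile it across the token sequence
#'
#' Applies the learnable linear map to the 88-dimensional functional vector
#' and repeats the projected vector N times, so the acoustic stream has one
#' (identical) row per text token.
#'
#' @param a numeric vector of length \code{ncol(proj$W)}.
#' @param N number of rows to tile.
#' @param proj projection parameters from \code{\link{makeAcousticProjection}}.
#' @return numeric matrix N x \code{nrow(proj$W)} with all rows equal.
#' @export
projectAndTile <- function(a, N, proj) {
  v <- as.numeric(proj$W %*% matrix(a, ncol = 1L) + proj$b)
  matrix(v, N, length(v), byrow = TRUE)
}
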