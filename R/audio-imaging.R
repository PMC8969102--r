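# Audio -> 3-channel spectrogram image.
#
# The image encoder consumes one image per recording: channel 1 is the
# log-Mel spectrogram in dB, channels 2 and 3 are its first and second
# temporal derivatives (delta and delta-delta, "acceleration"), each resized
# to 224 x 224 by bilinear interpolation. Defaults: 224 Mel bands, hop 1024
# samples, Hanning window, n_fft 2048, dB relative to per-recording maximum
# power with an -80 dB floor.

#' Mel-scaled spectrogram matrix
#'
#' @slot values numeric matrix (dB), n_mels rows x n_frames columns.
#' @slot nMels number of Mel bands.
#' @slot hopLength hop length in samples.
#' @slot window window function name.
#' @slot sampleRate sampling rate of the source waveform (Hz).
#' @export
setClass("MelMatrix",
         representation(values = "matrix", nMels = "integer",
                        hopLength = "integer", window = "character",
                        sampleRate = "numeric"))

setValidity("MelMatrix", function(object) {
  if (nrow(object@values) != object@nMels) return("nrow(values) != nMels")
  if (ncol(object@values) < 1L) return("need at least one frame")
  if (!all(is.finite(object@values))) return("non-finite entries")
  TRUE
})

#' @rdname MelMatrix-class
#' @param x a \code{MelMatrix} or \code{SpectrogramImage}.
#' @export
setGeneric("melValues", function(x) standardGeneric("melValues"))

#' @rdname MelMatrix-class
#' @export
setMethod("melValues", "MelMatrix", function(x) x@values)

setMethod("show", "MelMatrix", function(object) {
  cat(sprintf("MelMatrix: %d Mel bands x %d frames (hop %d, %s window)\n",
              object@nMels, ncol(object@values), object@hopLength,
              object@window))
})

#' Three-channel spectrogram image
#'
#' Channels are (log-Mel, delta, delta-delta), each 224 x 224 after bilinear
#' resizing; \code{normalization} records the per-channel affine transform
#' applied after min-max scaling.
#'
#' @slot channels list of 3 matrices, each size x size.
#' @slot channelRoles character vector naming the channels.
#' @slot normalization list with elements \code{applied}, \code{mean},
#'   \code{sd} describing the normalization.
#' @export
setClass("SpectrogramImage",
         representation(channels = "list", channelRoles = "character",
                        normalization = "list"))

setValidity("SpectrogramImage", function(object) {
  if (length(object@channels) != 3L) return("exactly 3 channels required")
  dims <- dim(object@channels[[1L]])
  for (ch in object@channels) {
    if (!is.matrix(ch) || !identical(dim(ch), dims)) {
      return("all channels must be matrices of identical size")
    }
    if (!all(is.finite(ch))) return("non-finite image entries")
  }
  TRUE
})

#' @rdname SpectrogramImage-class
#' @param x a \code{SpectrogramImage}.
#' @export
setGeneric("imageChannels", function(x) standardGeneric("imageChannels"))

#' @rdname SpectrogramImage-class
#' @export
setMethod("imageChannels", "SpectrogramImage", function(x) x@channels)

setMethod("show", "SpectrogramImage", function(object) {
  d <- dim(object@channels[[1L]])
  cat(sprintf("SpectrogramImage: 3 x %d x %d (%s)%s\n", d[1L], d[2L],
              paste(object@channelRoles, collapse = ", "),
              if (isTRUE(object@normalization$applied)) ", normalized" else ""))
})

# Mel scale (HTK convention)
.hzToMel <- function(f) 2595 * log10(1 + f / 700)
.melToHz <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel filterbank matrix
#'
#' Triangular filters, peak 1, on HTK-Mel-spaced center frequencies.
#'
#' @param nMels number of Mel bands.
#' @param nFft FFT size (filters span \code{nFft/2} bins, DC..below Nyquist,
#'   matching the STFT layout used by \code{computeLogMel}).
#' @param sampleRate sampling rate in Hz.
#' @param fmin,fmax frequency range covered by the filterbank.
#' @return list with \code{weights} (nMels x nFft/2) and \code{centers}
#'   (Hz center frequency per band).
#' @export
melFilterbank <- function(nMels, nFft, sampleRate, fmin = 0,
                          fmax = sampleRate / 2) {
  nBins <- nFft %/% 2L
  binFreqs <- (0:(nBins - 1L)) * sampleRate / nFft
  pts <- .melToHz(seq(.hzToMel(fmin), .hzToMel(fmax), length.out = nMels + 2L))
  W <- matrix(0, nMels, nBins)
  for (i in seq_len(nMels)) {
    lo <- pts[i]; ce <- pts[i + 1L]; hi <- pts[i + 2L]
    up <- (binFreqs - lo) / (ce - lo)
    dn <- (hi - binFreqs) / (hi - ce)
    W[i, ] <- pmax(0, pmin(up, dn))
  }
  list(weights = W, centers = pts[2:(nMels + 1L)])
}

#' Log-Mel spectrogram of a waveform
#'
#' Short-time Fourier power spectrogram (Hanning window, no center padding)
#' projected onto a Mel filterbank and converted to dB relative to the
#' per-recording maximum power, floored at \code{floorDb}.
#'
#' @param w a \linkS4class{Waveform}.
#' @param nMels number of Mel bands (default 224).
#' @param hopLength hop length in samples (default 1024).
#' @param window window function name; only \code{"hanning"} is supported.
#' @param nFft FFT size (default 2048).
#' @param floorDb dB floor (default -80).
#' @return A \linkS4class{MelMatrix} in dB.
#' @export
computeLogMel <- function(w, nMels = 224L, hopLength = 1024L,
                          window = "hanning", nFft = 2048L, floorDb = -80) {
  stopifnot(methods::is(w, "Waveform"))
  x <- w@samples
  if (length(x) == 0L) stop("invalid input: empty waveform")
  if (!all(is.finite(x))) stop("invalid input: non-finite samples")
  if (nMels < 1L) stop("nMels must be >= 1")
  if (!identical(window, "hanning")) stop("unsupported window: ", window)
  if (length(x) < nFft) x <- c(x, numeric(nFft - length(x)))
  sg <- signal::specgram(x, n = nFft, Fs = w@sampleRate,
                         window = signal::hanning(nFft),
                         overlap = nFft - hopLength)
  P <- Mod(sg$S)^2 # nFft/2 x nFrames
  fb <- melFilterbank(nMels, nFft, w@sampleRate)
  M <- fb$weights %*% P
  ref <- max(M)
  if (ref <= 0) ref <- 1
  db <- 10 * log10(pmax(M / ref, 10^(floorDb / 10)))
  methods::new("MelMatrix", values = db, nMels = as.integer(nMels),
               hopLength = as.integer(hopLength), window = window,
               sampleRate = w@sampleRate)
}

#' Temporal delta and delta-delta of a Mel matrix
#'
#' First-order local regression along time over a \code{width}-frame window
#' (replicated-edge padding); the delta-delta is the delta of the delta.
#'
#' @param m a \linkS4class{MelMatrix} or plain matrix (bands x frames).
#' @param width odd regression window width in frames (default 9).
#' @return list with matrices \code{delta} and \code{deltaDelta}, same shape
#'   as the input.
#' @export
computeDeltas <- function(m, width = 9L) {
  vals <- if (methods::is(m, "MelMatrix")) m@values else as.matrix(m)
  if (width < 3L || width %% 2L == 0L) stop("width must be odd and >= 3")
  if (ncol(vals) < width) {
    stop("invalid input: need at least ", width, " frames, got ", ncol(vals))
  }
  d1 <- .regressionDelta(vals, width)
  d2 <- .regressionDelta(d1, width)
  list(delta = d1, deltaDelta = d2)
}

.regressionDelta <- function(x, width) {
  half <- (width - 1L) %/% 2L
  nT <- ncol(x)
  # replicate edges
  xp <- x[, c(rep(1L, half), seq_len(nT), rep(nT, half)), drop = FALSE]
  denom <- 2 * sum((1:half)^2)
  out <- matrix(0, nrow(x), nT)
  for (n in seq_len(half)) {
    out <- out + n * (xp[, (half + n) + seq_len(nT), drop = FALSE] -
                        xp[, (half - n) + seq_len(nT), drop = FALSE])
  }
  out / denom
}

#' Resize a matrix by bilinear interpolation
#'
#' @param x numeric matrix.
#' @param nr,nc target number of rows / columns.
#' @return resized matrix.
#' @export
resizeBilinear <- function(x, nr, nc) {
  EBImage::resize(x, w = nr, h = nc, filter = "bilinear")
}

#' Build the 3-channel spectrogram image
#'
#' Computes the delta and delta-delta of a log-Mel matrix, stacks the three
#' channels in the fixed order (log-Mel, delta, delta-delta), resizes each
#' channel to \code{size} x \code{size} by bilinear interpolation, and
#' optionally applies per-channel min-max scaling to [0, 1] followed by a
#' (mean, sd) affine normalization.
#'
#' @param m a \linkS4class{MelMatrix}.
#' @param size output side length (default 224).
#' @param normalize apply per-channel normalization (default TRUE).
#' @param mean,sd normalization parameters applied after min-max scaling.
#' @param deltaWidth delta regression window (default 9).
#' @return A \linkS4class{SpectrogramImage}.
#' @export
buildSpectrogramImage <- function(m, size = 224L, normalize = TRUE,
                                  mean = 0.5, sd = 0.5, deltaWidth = 9L) {
  stopifnot(methods::is(m, "MelMatrix"))
  d <- computeDeltas(m, width = deltaWidth)
  chans <- list(m@values, d$delta, d$deltaDelta)
  chans <- lapply(chans, resizeBilinear, nr = size, nc = size)
  if (normalize) {
    chans <- lapply(chans, function(ch) {
      rng <- range(ch)
      if (rng[2L] > rng[1L]) ch <- (ch - rng[1L]) / (rng[2L] - rng[1L])
      else ch <- ch * 0
      (ch - mean) / sd
    })
  }
  methods::new("SpectrogramImage", channels = chans,
               channelRoles = c("log_mel", "delta", "delta_delta"),
               normalization = list(applied = normalize, mean = mean, sd = sd))
}

#' Full audio-to-image preprocessing
#'
#' Convenience wrapper: waveform -> log-Mel -> 3-channel image with the
#' package defaults (224 bands, hop 1024, Hanning, 224 x 224 output).
#'
#' @param w a \linkS4class{Waveform}.
#' @param ... passed to \code{\link{buildSpectrogramImage}}.
#' @return A \linkS4class{SpectrogramImage}.
#' @export
audioToImage <- function(w, ...) {
  buildSpectrogramImage(computeLogMel(w), ...)
}
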