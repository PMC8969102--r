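#' Waveform container
#'
#' A mono audio signal with its sampling rate. Amplitudes are dimensionless
#' reals, typically in [-1, 1] after PCM decoding.
#'
#' @slot samples numeric vector of amplitudes.
#' @slot sampleRate sampling rate in Hz.
#' @export
setClass("Waveform",
         representation(samples = "numeric", sampleRate = "numeric"))

setValidity("Waveform", function(object) {
  if (length(object@samples) == 0L) return("waveform must be non-empty")
  if (!all(is.finite(object@samples))) return("waveform samples must be finite")
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0) {
    return("sampleRate must be a single positive number")
  }
  TRUE
})

#' Construct a Waveform
#'
#' @param samples numeric vector of amplitudes.
#' @param sampleRate sampling rate in Hz.
#' @return A \linkS4class{Waveform}.
#' @export
Waveform <- function(samples, sampleRate) {
  methods::new("Waveform", samples = as.numeric(samples),
               sampleRate = as.numeric(sampleRate))
}

#' @describeIn Waveform amplitude samples.
#' @param object,x a \code{Waveform}.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname Waveform
#' @export
setMethod("samples", "Waveform", function(x) x@samples)

#' @rdname Waveform
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname Waveform
#' @export
setMethod("sampleRate", "Waveform", function(x) x@sampleRate)

setMethod("show", "Waveform", function(object) {
  cat(sprintf("Waveform: %d samples @ %g Hz (%.2f s)\n",
              length(object@samples), object@sampleRate,
              length(object@samples) / object@sampleRate))
})

#' Read a PCM WAV file
#'
#' Reads 8/16/32-bit integer or 32/64-bit float PCM. Multi-channel audio is
#' mixed down to mono by averaging. Optionally resamples on load.
#'
#' @param path path to a RIFF/WAVE file.
#' @param targetRate if non-NULL, resample the signal to this rate (Hz).
#'   The package convention is 16 kHz.
#' @return A \linkS4class{Waveform}.
#' @export
readWav <- function(path, targetRate = 16000) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)
  fmt <- NULL
  dat <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audioFormat = sum(as.integer(raw[1:2]) * c(1, 256)),
        nChannels = sum(as.integer(raw[3:4]) * c(1, 256)),
        sampleRate = sum(as.integer(raw[5:8]) * c(1, 256, 65536, 16777216)),
        bitsPerSample = sum(as.integer(raw[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      dat <- readBin(con, "raw", sz)
      break
    } else {
      invisible(readBin(con, "raw", sz + (sz %% 2L)))
    }
  }
  if (is.null(fmt) || is.null(dat)) stop("malformed WAV file: ", path)
  bps <- fmt$bitsPerSample
  if (fmt$audioFormat == 3L) { # IEEE float
    x <- readBin(dat, "double", length(dat) %/% (bps / 8), bps / 8,
                 endian = "little")
  } else if (bps == 16L) {
    x <- readBin(dat, "integer", length(dat) %/% 2L, 2L, signed = TRUE,
                 endian = "little") / 32768
  } else if (bps == 32L) {
    x <- readBin(dat, "integer", length(dat) %/% 4L, 4L,
                 endian = "little") / 2147483648
  } else if (bps == 8L) {
    x <- (readBin(dat, "integer", length(dat), 1L, signed = FALSE) - 128) / 128
  } else {
    stop("unsupported bit depth: ", bps)
  }
  if (fmt$nChannels > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$nChannels))
  }
  w <- Waveform(x, fmt$sampleRate)
  if (!is.null(targetRate) && targetRate != fmt$sampleRate) {
    w <- resampleWav(w, targetRate)
  }
  w
}

#' Write a 16-bit PCM WAV file
#'
#' @param w a \linkS4class{Waveform}; amplitudes are clipped to [-1, 1].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeWav <- function(w, path) {
  stopifnot(methods::is(w, "Waveform"))
  x <- pmax(pmin(w@samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  nBytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nBytes), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(1L, con, 2L, endian = "little") # PCM
  writeBin(1L, con, 2L, endian = "little") # mono
  sr <- as.integer(round(w@sampleRate))
  writeBin(sr, con, 4L, endian = "little")
  writeBin(sr * 2L, con, 4L, endian = "little") # byte rate
  writeBin(2L, con, 2L, endian = "little") # block align
  writeBin(16L, con, 2L, endian = "little") # bits
  writeChar("data", con, eos = NULL)
  writeBin(nBytes, con, 4L, endian = "little")
  writeBin(pcm, con, 2L, endian = "little")
  invisible(path)
}

#' Resample a waveform
#'
#' Rational-factor polyphase resampling (via \code{signal::resample}).
#'
#' @param w a \linkS4class{Waveform}.
#' @param targetRate new sampling rate in Hz.
#' @return A resampled \linkS4class{Waveform}.
#' @export
resampleWav <- function(w, targetRate) {
  if (targetRate == w@sampleRate) return(w)
  frac <- .simplifyRatio(targetRate, w@sampleRate)
  y <- signal::resample(w@samples, frac[1L], frac[2L])
  Waveform(as.numeric(y), targetRate)
}

.simplifyRatio <- function(p, q) {
  p <- as.integer(round(p)); q <- as.integer(round(q))
  g <- .gcd(p, q)
  c(p %/% g, q %/% g)
}

.gcd <- function(a, b) if (b == 0L) a else .gcd(b, a %% b)
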