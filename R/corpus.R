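# Synthetic corpus generator.
#
# Emulates the *structure* of a balanced dementia speech corpus - one WAV
# recording and one CHAT transcript per subject, balanced AD/HC groups,
# MMSE scores tied to group (25-30 normal, below 25 impaired) - with a
# controllable group signal: AD subjects pause more, speak slower, repeat
# themselves and draw from a shrunken vocabulary, with intensity scaled by
# a per-subject severity in [0, 1]. It is artifact plumbing for development
# and testing, not a speech synthesizer, and carries no clinical validity.

#' Specification of a synthetic corpus
#'
#' @param nSubjects number of subjects.
#' @param adFraction fraction of subjects in the AD group.
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @param pauseRateDelta extra pauses per utterance for a fully severe AD
#'   subject (also scales the audio silence fraction).
#' @param speechRateDelta change in words per utterance-second for severe AD
#'   (negative = slower).
#' @param vocabularyShrink fraction of the vocabulary unavailable to a fully
#'   severe AD subject.
#' @param durationS target recording duration in seconds.
#' @param sampleRate audio sampling rate in Hz.
#' @return list of class \code{corpusSpec}.
#' @export
corpusSpec <- function(nSubjects = 24L, adFraction = 0.5, seed = 1L,
                       pauseRateDelta = 1.5, speechRateDelta = -0.8,
                       vocabularyShrink = 0.5, durationS = 8,
                       sampleRate = 16000) {
  if (nSubjects < 0L) stop("nSubjects must be >= 0")
  stopifnot(adFraction >= 0, adFraction <= 1, durationS > 1)
  structure(list(nSubjects = as.integer(nSubjects), adFraction = adFraction,
                 seed = as.integer(seed), pauseRateDelta = pauseRateDelta,
                 speechRateDelta = speechRateDelta,
                 vocabularyShrink = vocabularyShrink, durationS = durationS,
                 sampleRate = sampleRate),
            class = "corpusSpec")
}

# picture-description vocabulary (subject / verb / object / filler pools)
.corpusVocab <- function() {
  list(
    subj = c("the boy", "the girl", "the mother", "the woman", "the child",
             "the little boy", "his sister", "the lady"),
    verb = c("is taking", "is reaching for", "is washing", "is drying",
             "is climbing on", "is falling off", "is standing on",
             "is looking at", "is handing over", "is ignoring"),
    obj = c("the cookie jar", "the stool", "the dishes", "the sink",
            "the water", "the plate", "the cupboard", "the window",
            "the curtains", "the garden", "the counter", "the floor"),
    comment = c("and the water is overflowing", "outside the window",
                "in the kitchen", "without noticing", "very carefully",
                "while the sink runs over", "behind her", "right there")
  )
}

.makeUtterance <- function(vocab, severity, spec) {
  shrink <- function(x) {
    keep <- max(2L, round(length(x) * (1 - spec$vocabularyShrink * severity)))
    x[seq_len(keep)]
  }
  s <- sample(shrink(vocab$subj), 1L)
  v <- sample(shrink(vocab$verb), 1L)
  o <- sample(shrink(vocab$obj), 1L)
  parts <- c(s, v, o)
  if (stats::runif(1) < 0.4) {
    parts <- c(parts, sample(shrink(vocab$comment), 1L))
  }
  # retracing: repeat the opening noun phrase, marked as a CHAT retrace;
  # intensity rides the vocabulary dial so zeroed dials mean no group signal
  if (stats::runif(1) < min(0.85, 1.7 * spec$vocabularyShrink * severity)) {
    parts <- c(paste0("<", s, "> [/]"), parts)
  }
  # silent-pause codes between phrases
  nPause <- stats::rpois(1L, spec$pauseRateDelta * severity)
  if (nPause > 0) {
    at <- sample(seq_along(parts), min(nPause, length(parts)), replace = FALSE)
    parts[at] <- paste(parts[at], "(.)")
  }
  paste(c(parts, "."), collapse = " ")
}

.writeCha <- function(path, id, utts) {
  lines <- c("@UTF8", "@Begin", "@Languages:\teng",
             "@Participants:\tPAR Participant, INV Investigator",
             sprintf("@ID:\teng|synthetic|PAR|||||Participant|||"),
             sprintf("@ID:\teng|synthetic|INV|||||Investigator|||"),
             "*INV:\tplease tell me what you see in this picture .",
             paste0("*PAR:\t", utts),
             "@End")
  writeLines(lines, path, useBytes = TRUE)
}

# one vowel-like syllable: harmonic stack under a raised-cosine envelope
.synthSyllable <- function(sr, dur, f0) {
  n <- max(8L, round(sr * dur))
  tt <- (seq_len(n) - 1L) / sr
  env <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
  x <- 0.6 * sin(2 * pi * f0 * tt) + 0.3 * sin(2 * pi * 2 * f0 * tt) +
    0.15 * sin(2 * pi * 3 * f0 * tt)
  0.3 * x * env
}

.synthRecording <- function(spec, severity) {
  sr <- spec$sampleRate
  target <- round(spec$durationS * sr)
  # pause probability rises with severity scaled by the pause-rate dial
  pPause <- min(0.8, 0.12 + 0.18 * severity * spec$pauseRateDelta)
  sylDur <- 0.14 - 0.04 * spec$speechRateDelta * severity / 0.8
  out <- vector("list", 0L)
  len <- 0L
  while (len < target) {
    syl <- .synthSyllable(sr, sylDur * stats::runif(1, 0.8, 1.2),
                          stats::runif(1, 100, 180))
    gap <- if (stats::runif(1) < pPause) {
      numeric(round(sr * stats::runif(1, 0.4, 0.8)))
    } else {
      numeric(round(sr * stats::runif(1, 0.04, 0.1)))
    }
    out[[length(out) + 1L]] <- syl
    out[[length(out) + 1L]] <- gap
    len <- len + length(syl) + length(gap)
  }
  x <- unlist(out)[seq_len(target)]
  Waveform(x, sr)
}

#' Generate a synthetic corpus
#'
#' Writes one WAV (16 kHz PCM) and one CHAT transcript per subject plus a
#' \code{metadata.csv} (columns \code{id,label,mmse}; label 1 = AD) under
#' \code{outDir}. Deterministic given the spec. HC subjects get MMSE 25-30;
#' AD subjects get MMSE below 25, decreasing with severity.
#'
#' @param spec a \code{\link{corpusSpec}}.
#' @param outDir output directory (created if needed).
#' @return data.frame with columns id, label (0/1), group, mmse, severity,
#'   wav, cha; also written as \code{metadata.csv} (id, label, mmse).
#' @export
generateCorpus <- function(spec, outDir) {
  stopifnot(inherits(spec, "corpusSpec"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  n <- spec$nSubjects
  nAd <- round(n * spec$adFraction)
  vocab <- .corpusVocab()
  .withSeed(spec$seed, {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      isAd <- i <= nAd
      id <- sprintf("S%03d", i)
      severity <- if (isAd) stats::runif(1, 0.5, 1) else stats::runif(1, 0, 0.12)
      mmse <- if (isAd) {
        as.integer(round(24 - 18 * (severity - 0.5) / 0.5))
      } else {
        sample(25:30, 1L)
      }
      mmse <- max(0L, min(30L, mmse))
      nUtts <- max(3L, round(8 + spec$speechRateDelta * severity * 2 +
                               stats::rnorm(1, 0, 0.5)))
      utts <- vapply(seq_len(nUtts), function(u) {
        .makeUtterance(vocab, severity, spec)
      }, character(1L))
      wavPath <- file.path(outDir, paste0(id, ".wav"))
      chaPath <- file.path(outDir, paste0(id, ".cha"))
      writeWav(.synthRecording(spec, severity), wavPath)
      .writeCha(chaPath, id, utts)
      rows[[i]] <- data.frame(id = id, label = as.integer(isAd),
                              group = if (isAd) "AD" else "HC",
                              mmse = mmse, severity = severity,
                              wav = wavPath, cha = chaPath,
                              stringsAsFactors = FALSE)
    }
    meta <- do.call(rbind, rows)
    if (is.null(meta)) {
      meta <- data.frame(id = character(0), label = integer(0),
                         group = character(0), mmse = integer(0),
                         severity = numeric(0), wav = character(0),
                         cha = character(0))
    }
    utils::write.csv(meta[, c("id", "label", "mmse")],
                     file.path(outDir, "metadata.csv"), row.names = FALSE,
                     quote = FALSE)
    meta
  })
}
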