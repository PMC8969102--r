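# End-to-end preparation: raw WAV + CHAT -> the per-sample inputs the
# fusion architectures consume. The frozen encoders run once per subject;
# training then operates on the cached embeddings.

#' Prepare one subject's multimodal inputs
#'
#' Reads and encodes one recording/transcript pair: parses the CHAT file,
#' token-encodes it and runs the frozen text encoder (X, N x d); converts
#' the audio to the 3-channel spectrogram image and runs the image encoder
#' (Y, T x d, plus the pooled class vector); optionally extracts the 88
#' acoustic functionals.
#'
#' @param wavPath path to the WAV recording.
#' @param chaPath path to the CHAT transcript.
#' @param enc an \linkS4class{EncoderBundle}.
#' @param speakers CHAT tiers to keep (default participant only).
#' @param withAcoustic also extract the 88 acoustic functionals.
#' @return list with \code{X}, \code{Y}, \code{pooled}, \code{acoustic}
#'   (or NULL), \code{mask} (pad mask), \code{encoding}.
#' @export
prepareSubject <- function(wavPath, chaPath, enc, speakers = "PAR",
                           withAcoustic = TRUE) {
  tr <- parseChat(chaPath, speakers = speakers)
  encTxt <- encodeText(tr, maxLen = enc@N, vocabSize = enc@vocabSize)
  X <- encodeTokens(enc, encTxt)
  w <- readWav(wavPath)
  img <- audioToImage(w, size = enc@imageSize)
  imgEmb <- encodeImage(enc, img)
  list(X = X, Y = imgEmb$values, pooled = imgEmb$pooled,
       acoustic = if (withAcoustic) extractFunctionals(w) else NULL,
       mask = encTxt@padMask, encoding = encTxt)
}

#' Prepare a whole corpus
#'
#' @param meta data.frame as returned by \code{\link{generateCorpus}} (or
#'   with columns id, label, mmse, wav, cha).
#' @param enc an \linkS4class{EncoderBundle}.
#' @param speakers CHAT tiers to keep.
#' @param withAcoustic also extract acoustic functionals per subject.
#' @return list with \code{samples} (list of prepared samples), \code{ids},
#'   \code{labels} (0/1), \code{mmse}.
#' @export
prepareCorpus <- function(meta, enc, speakers = "PAR", withAcoustic = TRUE) {
  samples <- lapply(seq_len(nrow(meta)), function(i) {
    prepareSubject(meta$wav[i], meta$cha[i], enc, speakers = speakers,
                   withAcoustic = withAcoustic)
  })
  list(samples = samples, ids = meta$id, labels = meta$label,
       mmse = meta$mmse)
}
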