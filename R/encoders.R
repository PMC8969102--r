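# Text and image encoders behind a uniform contract.
#
# Both encoders emit token-by-feature matrices sharing one hidden size d:
# the text encoder maps a length-N token encoding to N x d, the image
# encoder maps a 3-channel square image to T x d (T-1 patches + a prepended
# class token whose final state is the pooled representation). The package
# ships the "tiny" grade: small randomly initialised transformer encoders,
# reproducible from a seed, suitable for desk-scale training and testing.
# At the published scale the same contract holds with d = 768, N = 512 and
# T = 197 (224 x 224 input, 16 x 16 patches).

#' Encoder bundle
#'
#' Holds the text- and image-encoder parameters and the shared dimensions.
#'
#' @slot textParams named list of parameter matrices of the text encoder.
#' @slot imageParams named list of parameter matrices of the image encoder.
#' @slot d shared hidden size.
#' @slot N text sequence length.
#' @slot T image sequence length (patches + class token).
#' @slot vocabSize tokenizer vocabulary size.
#' @slot imageSize expected image side length.
#' @slot patchSize patch side length.
#' @slot nLayers transformer layers per encoder.
#' @slot grade \code{"tiny"} (randomly initialised) by construction.
#' @slot seed initialisation seed.
#' @export
setClass("EncoderBundle",
         representation(textParams = "list", imageParams = "list",
                        d = "integer", N = "integer", T = "integer",
                        vocabSize = "integer", imageSize = "integer",
                        patchSize = "integer", nLayers = "integer",
                        grade = "character", seed = "integer"))

setValidity("EncoderBundle", function(object) {
  if (object@d < 1L || object@N < 1L || object@T < 1L) {
    return("dims must be positive")
  }
  g <- sqrt(object@T - 1L)
  if (g != round(g)) return("T - 1 must be a perfect square (patch grid)")
  TRUE
})

setMethod("show", "EncoderBundle", function(object) {
  cat(sprintf(
    "EncoderBundle (%s): d=%d, N=%d, T=%d (%dx%d image, %dx%d patches), seed=%d\n",
    object@grade, object@d, object@N, object@T, object@imageSize,
    object@imageSize, object@patchSize, object@patchSize, object@seed))
})

#' @rdname EncoderBundle-class
#' @param x an \code{EncoderBundle}.
#' @export
setGeneric("encoderDims", function(x) standardGeneric("encoderDims"))

#' @rdname EncoderBundle-class
#' @export
setMethod("encoderDims", "EncoderBundle", function(x) {
  c(d = x@d, N = x@N, T = x@T)
})

# run expr under a temporary RNG seed, restoring global RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

.rmat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

.transformerLayerParams <- function(d, prefix) {
  ff <- 2L * d
  p <- list(
    Wq = .rmat(d, d), bq = matrix(0, 1L, d),
    Wk = .rmat(d, d), bk = matrix(0, 1L, d),
    Wv = .rmat(d, d), bv = matrix(0, 1L, d),
    Wo = .rmat(d, d), bo = matrix(0, 1L, d),
    W1 = .rmat(d, ff), b1 = matrix(0, 1L, ff),
    W2 = .rmat(ff, d), b2 = matrix(0, 1L, d),
    g1 = matrix(1, 1L, d), n1 = matrix(0, 1L, d),
    g2 = matrix(1, 1L, d), n2 = matrix(0, 1L, d)
  )
  names(p) <- paste0(prefix, ".", names(p))
  p
}

#' Build tiny randomly-initialised encoders
#'
#' Constructs a desk-scale \linkS4class{EncoderBundle}: a transformer text
#' encoder (token + position embeddings, self-attention with pad-key
#' masking) and a transformer image encoder (linear patch projection, class
#' token, position embeddings). Reproducible from \code{seed}.
#'
#' @param d hidden size shared by both encoders.
#' @param N text sequence length.
#' @param T image sequence length; \code{T - 1} must be a perfect square.
#' @param seed initialisation seed.
#' @param vocabSize tokenizer vocabulary size (default 2000).
#' @param imageSize image side length the image encoder expects
#'   (default 224); the patch side is \code{imageSize / sqrt(T - 1)}.
#' @param nLayers transformer layers per encoder (default 1).
#' @return An \linkS4class{EncoderBundle}.
#' @export
buildTinyEncoders <- function(d, N, T, seed = 1L, vocabSize = 2000L,
                              imageSize = 224L, nLayers = 1L) {
  stopifnot(d >= 1L, N >= 1L, T >= 2L)
  g <- sqrt(T - 1L)
  if (g != round(g)) stop("T - 1 must be a perfect square")
  if (imageSize %% g != 0L) stop("imageSize must be divisible by sqrt(T - 1)")
  patch <- as.integer(imageSize / g)
  .withSeed(seed, {
    txt <- c(list(emb = .rmat(vocabSize, d), pos = .rmat(N, d)),
             do.call(c, lapply(seq_len(nLayers), function(l) {
               .transformerLayerParams(d, paste0("l", l))
             })))
    patchDim <- 3L * patch * patch
    img <- c(list(patch = .rmat(patchDim, d), pbias = matrix(0, 1L, d),
                  cls = .rmat(1L, d), pos = .rmat(T, d)),
             do.call(c, lapply(seq_len(nLayers), function(l) {
               .transformerLayerParams(d, paste0("l", l))
             })))
    methods::new("EncoderBundle", textParams = txt, imageParams = img,
                 d = as.integer(d), N = as.integer(N), T = as.integer(T),
                 vocabSize = as.integer(vocabSize),
                 imageSize = as.integer(imageSize), patchSize = patch,
                 nLayers = as.integer(nLayers), grade = "tiny",
                 seed = as.integer(seed))
  })
}

# map a named list of matrices onto tape nodes (leaves if trainable)
.agParamNodes <- function(tape, params, trainable = FALSE, prefix = "") {
  out <- vector("list", length(params))
  names(out) <- names(params)
  for (nm in names(params)) {
    out[[nm]] <- if (trainable) {
      agLeaf(tape, params[[nm]], paste0(prefix, nm))
    } else {
      agConst(tape, params[[nm]])
    }
  }
  out
}

# one post-norm transformer layer on the tape; attnBias is NULL or a 1 x n
# constant node added to every attention-score row (pad-key masking)
.agTransformerLayer <- function(x, p, prefix, d, attnBias = NULL) {
  nm <- function(s) p[[paste0(prefix, ".", s)]]
  q <- agAdd(agMM(x, nm("Wq")), nm("bq"))
  k <- agAdd(agMM(x, nm("Wk")), nm("bk"))
  v <- agAdd(agMM(x, nm("Wv")), nm("bv"))
  scores <- agScale(agMM(q, agT(k)), 1 / sqrt(d))
  if (!is.null(attnBias)) scores <- agAdd(scores, attnBias)
  att <- agMM(agSoftmaxRows(scores), v)
  att <- agAdd(agMM(att, nm("Wo")), nm("bo"))
  x <- agLayerNormRows(agAdd(x, att), nm("g1"), nm("n1"))
  ff <- agMM(agRelu(agAdd(agMM(x, nm("W1")), nm("b1"))), nm("W2"))
  ff <- agAdd(ff, nm("b2"))
  agLayerNormRows(agAdd(x, ff), nm("g2"), nm("n2"))
}

# tape forward of the text encoder from an input-embedding node (N x d)
.agTextLayers <- function(x, p, nLayers, d, attnBias = NULL) {
  for (l in seq_len(nLayers)) {
    x <- .agTransformerLayer(x, p, paste0("l", l), d, attnBias)
  }
  x
}

.agTextForward <- function(tape, p, enc, ids, mask) {
  x <- agAdd(agRows(p$emb, ids), p$pos)
  bias <- agConst(tape, matrix(ifelse(mask, 0, -1e9), 1L))
  .agTextLayers(x, p, enc@nLayers, enc@d, bias)
}

# split a 3-channel image into flattened patch vectors ((T-1) x patchDim)
.patchify <- function(img, grid, patch) {
  chans <- if (methods::is(img, "SpectrogramImage")) img@channels else img
  out <- matrix(0, grid * grid, 3L * patch * patch)
  k <- 0L
  for (gr in seq_len(grid)) {
    for (gc in seq_len(grid)) {
      k <- k + 1L
      rows <- ((gr - 1L) * patch + 1L):(gr * patch)
      cols <- ((gc - 1L) * patch + 1L):(gc * patch)
      out[k, ] <- c(chans[[1L]][rows, cols], chans[[2L]][rows, cols],
                    chans[[3L]][rows, cols])
    }
  }
  out
}

.agImageForward <- function(tape, p, enc, patchMat) {
  x <- agAdd(agMM(agConst(tape, patchMat), p$patch), p$pbias)
  x <- agAdd(agRbind(p$cls, x), p$pos)
  for (l in seq_len(enc@nLayers)) {
    x <- .agTransformerLayer(x, p, paste0("l", l), enc@d)
  }
  x
}

#' Encode a token sequence to contextual embeddings
#'
#' Runs the bundle's text encoder; position i of the result is the
#' contextual representation of token i. Pad positions are excluded from
#' attention (masked keys), so the embeddings at real-token positions do not
#' depend on the pad region.
#'
#' @param enc an \linkS4class{EncoderBundle}.
#' @param x a \linkS4class{TextEncoding} of length \code{N}.
#' @return numeric matrix N x d.
#' @export
encodeTokens <- function(enc, x) {
  stopifnot(methods::is(enc, "EncoderBundle"), methods::is(x, "TextEncoding"))
  if (x@maxLen != enc@N) {
    stop("shape error: encoding length ", x@maxLen,
         " does not match encoder N = ", enc@N)
  }
  tape <- agTape()
  p <- .agParamNodes(tape, enc@textParams)
  agValue(.agTextForward(tape, p, enc, x@tokenIds, x@padMask))
}

#' Encode a spectrogram image to patch embeddings
#'
#' Runs the bundle's image encoder: linear patch projection, prepended class
#' token, position embeddings, transformer layers. The pooled vector is the
#' final state of the class token (row 1 of \code{values}).
#'
#' @param enc an \linkS4class{EncoderBundle}.
#' @param img a \linkS4class{SpectrogramImage} (or list of 3 matrices) whose
#'   side length matches the encoder.
#' @return list with \code{values} (T x d) and \code{pooled} (1 x d).
#' @export
encodeImage <- function(enc, img) {
  stopifnot(methods::is(enc, "EncoderBundle"))
  chans <- if (methods::is(img, "SpectrogramImage")) img@channels else img
  if (length(chans) != 3L || nrow(chans[[1L]]) != enc@imageSize ||
      ncol(chans[[1L]]) != enc@imageSize) {
    stop("shape error: image must be 3 x ", enc@imageSize, " x ",
         enc@imageSize)
  }
  grid <- as.integer(sqrt(enc@T - 1L))
  pm <- .patchify(chans, grid, enc@patchSize)
  tape <- agTape()
  p <- .agParamNodes(tape, enc@imageParams)
  vals <- agValue(.agImageForward(tape, p, enc, pm))
  list(values = vals, pooled = vals[1L, , drop = FALSE])
}
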