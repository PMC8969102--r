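# Multimodal shifting gate: attention-gated non-verbal shift of word
# embeddings, fed to a second (trainable) text encoder.
#
# For token i with frozen word embedding e(i), tiled visual vector h_v(i)
# and tiled acoustic vector h_a(i):
#   w_v(i) = sigmoid(W_hv [h_v(i); e(i)] + b_v)         (visual gate)
#   w_a(i) = sigmoid(W_ha [h_a(i); e(i)] + b_a)         (acoustic gate)
#   h_m(i) = w_v(i) * (W_v h_v(i)) + w_a(i) * (W_a h_a(i)) + b_m
#   alpha  = min(beta * ||e(i)|| / (||h_m(i)|| + eps), 1)
#   e_m(i) = e(i) + alpha * h_m(i)
# then layer normalization, dropout 0.4, and a second text encoder whose
# class-token output feeds the task head (after dropout 0.2). Variants drop
# the visual or acoustic term. Gates are length-d vectors (the element-wise
# product in the shift forces gate length = shift-space dimension).

#' Shifting-gate parameters
#'
#' Defaults follow the published configuration: beta = 0.01 for the
#' acoustic and combined variants, beta = 0.001 for the visual variant.
#' Includes the trainable acoustic projection (88 -> 256), the gate and
#' projection maps, layer-norm parameters, a trainable copy of the bundle's
#' text encoder (the second encoder, initialised from the same weights and
#' given its own position embeddings), and the task head.
#'
#' @param enc an \linkS4class{EncoderBundle} (supplies d, N and the second
#'   encoder's initial weights).
#' @param variant \code{"acoustic"}, \code{"visual"} or \code{"both"}.
#' @param task \code{"classification"} or \code{"regression"}.
#' @param beta shift-scale hyperparameter; default set by variant.
#' @param epsilon guard added to the shift norm in alpha (default 1e-9).
#' @param dAcoustic projected acoustic dimensionality (default 256).
#' @param seed initialisation seed.
#' @return named list of parameter matrices plus settings.
#' @export
shiftGateParams <- function(enc, variant = c("both", "acoustic", "visual"),
                            task = "classification", beta = NULL,
                            epsilon = 1e-9, dAcoustic = 256L, seed = 1L) {
  variant <- match.arg(variant)
  if (is.null(beta)) beta <- if (variant == "visual") 0.001 else 0.01
  d <- enc@d
  .withSeed(seed, {
    p <- list()
    if (variant %in% c("visual", "both")) {
      p$Whv <- .rmat(2L * d, d, 0.05)
      p$bv <- matrix(0, 1L, d)
      p$Wv <- .rmat(d, d, 0.05)
    }
    if (variant %in% c("acoustic", "both")) {
      p$Wha <- .rmat(dAcoustic + d, d, 0.05)
      p$ba <- matrix(0, 1L, d)
      p$Wa <- .rmat(dAcoustic, d, 0.05)
      p$projW <- .rmat(88L, dAcoustic, 0.05)
      p$projb <- matrix(0, 1L, dAcoustic)
    }
    p$bm <- matrix(0, 1L, d)
    p$lnG <- matrix(1, 1L, d)
    p$lnB <- matrix(0, 1L, d)
    # second text encoder: same initial layer weights, own position table
    enc2 <- enc@textParams[setdiff(names(enc@textParams), "emb")]
    names(enc2) <- paste0("enc2.", names(enc2))
    p <- c(p, enc2, .headParams(d, task))
    attr(p, "settings") <- list(variant = variant, beta = beta,
                                epsilon = epsilon, dAcoustic = dAcoustic)
    p
  })
}

#' Attention gate over a concatenated modality/word vector
#'
#' \code{sigmoid(W' [h_mod; e] + b)} applied row-wise: each row of
#' \code{hMod} and \code{e} is one token.
#'
#' @param hMod modality vectors, N x dMod.
#' @param e word embeddings, N x d.
#' @param W weight matrix, (dMod + d) x d.
#' @param b bias, 1 x d.
#' @return gate matrix N x d with entries strictly in (0, 1).
#' @export
computeGates <- function(hMod, e, W, b) {
  if (ncol(hMod) + ncol(e) != nrow(W)) {
    stop("shape error: W must have ", ncol(hMod) + ncol(e), " rows")
  }
  z <- cbind(hMod, e) %*% W
  1 / (1 + exp(-sweep(z, 2L, b[1L, ], "+")))
}

#' Non-verbal shift vector
#'
#' Element-wise gated sum of the projected modality vectors plus a shared
#' bias: \code{h_m = w_v * (h_v W_v) + w_a * (h_a W_a) + b_m}. The variant
#' decides which terms are present.
#'
#' @param hV visual vectors N x d (or NULL).
#' @param hA acoustic vectors N x dAcoustic (or NULL).
#' @param gatesV,gatesA gate matrices N x d from \code{\link{computeGates}}.
#' @param params parameter list from \code{\link{shiftGateParams}}.
#' @return shift matrix N x d.
#' @export
computeShiftVector <- function(hV, hA, gatesV, gatesA, params) {
  s <- attr(params, "settings")
  variant <- s$variant
  d <- ncol(params$bm)
  n <- if (!is.null(hV)) nrow(hV) else nrow(hA)
  hm <- matrix(params$bm[1L, ], n, d, byrow = TRUE)
  if (variant %in% c("visual", "both")) {
    if (is.null(hV)) stop("configuration error: variant needs visual input")
    hm <- hm + gatesV * (hV %*% params$Wv)
  }
  if (variant %in% c("acoustic", "both")) {
    if (is.null(hA)) stop("configuration error: variant needs acoustic input")
    hm <- hm + gatesA * (hA %*% params$Wa)
  }
  hm
}

#' Scale and shift word embeddings
#'
#' Per token: \code{alpha = min(beta * ||e|| / (||h_m|| + epsilon), 1)} and
#' \code{e_m = e + alpha * h_m}. Layer normalization and dropout are applied
#' afterwards by the model forward, not here.
#'
#' @param e word embeddings N x d.
#' @param hm shift vectors N x d.
#' @param beta shift-scale hyperparameter (> 0).
#' @param epsilon guard for the zero-shift case.
#' @return list with \code{alpha} (length-N vector in (0, 1]) and \code{em}
#'   (N x d).
#' @export
scaleAndShift <- function(e, hm, beta, epsilon = 1e-9) {
  stopifnot(beta > 0)
  ne <- sqrt(rowSums(e^2))
  nh <- sqrt(rowSums(hm^2))
  alpha <- pmin(beta * ne / (nh + epsilon), 1)
  list(alpha = alpha, em = e + alpha * hm)
}

# tape forward. sample: X (N x d frozen embeddings), pooled (1 x d),
# acoustic (length 88). enc supplies dims and nLayers for the second pass.
.agShiftGateForward <- function(tape, p, sample, enc, task, train,
                                settings, dropShift = 0.4, dropCls = 0.2) {
  variant <- settings$variant
  N <- nrow(sample$X)
  d <- ncol(sample$X)
  E <- agConst(tape, sample$X)
  ones <- agConst(tape, matrix(1, N, 1L))
  terms <- NULL
  if (variant %in% c("visual", "both")) {
    if (is.null(sample$pooled)) {
      stop("configuration error: variant '", variant, "' needs an image")
    }
    Hv <- agMM(ones, agConst(tape, sample$pooled)) # tiled N x d
    gv <- agSigmoid(agAdd(agMM(agCbind(Hv, E), p$Whv), p$bv))
    terms <- agMul(gv, agMM(Hv, p$Wv))
  }
  if (variant %in% c("acoustic", "both")) {
    if (is.null(sample$acoustic)) {
      stop("configuration error: variant '", variant, "' needs audio")
    }
    aRow <- agMM(agConst(tape, matrix(sample$acoustic, 1L)), p$projW)
    aRow <- agAdd(aRow, p$projb)
    Ha <- agMM(ones, aRow)                          # tiled N x 256
    ga <- agSigmoid(agAdd(agMM(agCbind(Ha, E), p$Wha), p$ba))
    tA <- agMul(ga, agMM(Ha, p$Wa))
    terms <- if (is.null(terms)) tA else agAdd(terms, tA)
  }
  hm <- agAdd(terms, p$bm)
  eNorm <- agSqrt(agRowSums(agSquare(E)))           # N x 1
  hNorm <- agSqrt(agAddConst(agRowSums(agSquare(hm)), settings$epsilon^2))
  alpha <- agMinConst(agScale(agDiv(eNorm, agAddConst(hNorm, settings$epsilon)),
                              settings$beta), 1)
  em <- agAdd(E, agMul(alpha, hm))
  em <- agLayerNormRows(em, p$lnG, p$lnB)
  em <- agDropout(em, dropShift, train)
  # second text encoder: e_m as input embeddings + its own positions
  x <- agAdd(em, p$`enc2.pos`)
  bias <- agConst(tape, matrix(ifelse(sample$mask, 0, -1e9), 1L))
  for (l in seq_len(enc@nLayers)) {
    x <- .agTransformerLayer(x, p, paste0("enc2.l", l), d, bias)
  }
  cls <- agRows(x, 1L)
  cls <- agDropout(cls, dropCls, train)
  .agHead(cls, p, task, train, hiddenDrop = 0)
}
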