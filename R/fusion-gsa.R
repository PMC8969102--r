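# Gated self-attention fusion over the concatenated text+image sequence.
#
# Z = [X; Y] (text rows first, m = N + T), Q = K = V = Z. A learned gate
#   M = sigmoid(FC_g(FC_qg(Q) * FC_kg(K)))          (m x 2)
# yields two per-position masks in (0,1), tiled across the feature axis and
# applied multiplicatively to queries and keys before scaled dot-product
# attention:
#   A_g = softmax((Q * Mq~)(K * Mk~)' / sqrt(d)),   H = A_g V
# H is mean-pooled over the m positions, passed through dropout 0.3, a
# 128-unit ReLU layer, and the task head. The layer captures inter- and
# intra-modal interactions (text-text, image-image, text-image) in one map.

#' Gated self-attention parameters
#'
#' @param d shared hidden size.
#' @param dG gate hidden size (default 64).
#' @param task \code{"classification"} or \code{"regression"}.
#' @param seed initialisation seed.
#' @return named list of parameter matrices.
#' @export
gsaParams <- function(d, dG = 64L, task = "classification", seed = 1L) {
  .withSeed(seed, c(
    list(FCqg = .rmat(d, dG, 0.05), bqg = matrix(0, 1L, dG),
         FCkg = .rmat(d, dG, 0.05), bkg = matrix(0, 1L, dG),
         FCg = .rmat(dG, 2L, 0.05), bg = matrix(0, 1L, 2L)),
    .headParams(d, task)
  ))
}

#' Concatenate the modality sequences
#'
#' Row-wise concatenation, text rows first; the result serves as query, key
#' and value of the self-attention.
#'
#' @param X text embeddings N x d.
#' @param Y image embeddings T x d.
#' @return matrix m x d with m = N + T.
#' @export
concatModalities <- function(X, Y) {
  if (is.null(dim(Y)) || nrow(Y) == 0L || is.null(dim(X)) || nrow(X) == 0L) {
    stop("degenerate input: both modalities must contribute at least one row")
  }
  if (ncol(X) != ncol(Y)) stop("shape error: X and Y must share d")
  rbind(X, Y)
}

#' Gate masks for queries and keys
#'
#' \code{M = sigmoid(FC_g(FC_qg(Q) * FC_kg(K)))} (m x 2); the two columns
#' are tiled across the d feature columns.
#'
#' @param Q,K matrices m x d.
#' @param params list from \code{\link{gsaParams}}.
#' @return list with \code{M} (m x 2), \code{MqTiled} and \code{MkTiled}
#'   (each m x d).
#' @export
computeMasks <- function(Q, K, params) {
  if (!identical(dim(Q), dim(K))) stop("shape error: Q and K must match")
  pq <- sweep(Q %*% params$FCqg, 2L, params$bqg[1L, ], "+")
  pk <- sweep(K %*% params$FCkg, 2L, params$bkg[1L, ], "+")
  z <- sweep((pq * pk) %*% params$FCg, 2L, params$bg[1L, ], "+")
  M <- 1 / (1 + exp(-z))
  d <- ncol(Q)
  list(M = M,
       MqTiled = matrix(M[, 1L], nrow(Q), d),
       MkTiled = matrix(M[, 2L], nrow(Q), d))
}

#' Mask-gated scaled dot-product self-attention
#'
#' @param Q,K,V matrices m x d.
#' @param MqTiled,MkTiled tiled masks m x d.
#' @param d scale dimension (attention logits are divided by sqrt(d)).
#' @return list with \code{Ag} (m x m, rows are probability distributions)
#'   and \code{H} (m x d).
#' @export
gatedAttention <- function(Q, K, V, MqTiled, MkTiled, d = ncol(Q)) {
  if (!identical(dim(Q), dim(K)) || !identical(dim(K), dim(V))) {
    stop("shape error: Q, K, V must match")
  }
  logits <- (Q * MqTiled) %*% t(K * MkTiled) / sqrt(d)
  mx <- apply(logits, 1L, max)
  e <- exp(logits - mx)
  Ag <- e / rowSums(e)
  list(Ag = Ag, H = Ag %*% V)
}

# tape forward. sample: X (N x d), Y (T x d)
.agGsaForward <- function(tape, p, sample, task, train, dropPool = 0.3) {
  Z <- agConst(tape, rbind(sample$X, sample$Y))
  d <- ncol(sample$X)
  m <- nrow(sample$X) + nrow(sample$Y)
  pq <- agAdd(agMM(Z, p$FCqg), p$bqg)
  pk <- agAdd(agMM(Z, p$FCkg), p$bkg)
  M <- agSigmoid(agAdd(agMM(agMul(pq, pk), p$FCg), p$bg))
  ones <- agConst(tape, matrix(1, 1L, d))
  MqT <- agMM(agPick(M, rep(1L, m)), ones)  # m x 1 -> m x d tiling
  MkT <- agMM(agPick(M, rep(2L, m)), ones)
  Qm <- agMul(Z, MqT)
  Km <- agMul(Z, MkT)
  Ag <- agSoftmaxRows(agScale(agMM(Qm, agT(Km)), 1 / sqrt(d)))
  H <- agMM(Ag, Z)
  pooled <- agMeanRows(H)
  pooled <- agDropout(pooled, dropPool, train)
  .agHead(pooled, p, task, train, hiddenDrop = 0)
}
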