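# Co-attention fusion: simultaneous word/patch attention over the text and
# image embeddings through an affinity matrix, fused by concatenation.
#
# With C (d x N) the token embeddings and S (d x T) the patch embeddings:
#   F   = tanh(C' W_l S)                         (affinity, N x T)
#   H_s = tanh(W_s S + (W_c C) F)                (image attention map, k x T)
#   H_c = tanh(W_c C + (W_s S) F')               (text attention map,  k x N)
#   a_s = softmax(w_hs' H_s), a_c = softmax(w_hc' H_c)
#   s^  = sum_i a_s[i] s_i,   c^  = sum_j a_c[j] c_j
#   p   = [s^ ; c^]                              (1 x 2d)
# followed by dropout 0.4, a 128-unit ReLU layer, dropout 0.2 and the task
# head (2 logits, or 1 ReLU unit for MMSE regression).

# shared prediction-head parameters
.headParams <- function(dIn, task, hidden = 128L) {
  nOut <- if (task == "classification") 2L else 1L
  list(hW1 = .rmat(dIn, hidden, 0.05), hb1 = matrix(0, 1L, hidden),
       hW2 = .rmat(hidden, nOut, 0.05),
       hb2 = matrix(if (task == "regression") 15 else 0, 1L, nOut))
}

# tape head: x (1 x dIn) -> logits / ReLU scalar; dropout after the hidden
# layer only when hiddenDrop > 0
.agHead <- function(x, p, task, train, hiddenDrop = 0) {
  h <- agRelu(agAdd(agMM(x, p$hW1), p$hb1))
  if (hiddenDrop > 0) h <- agDropout(h, hiddenDrop, train)
  out <- agAdd(agMM(h, p$hW2), p$hb2)
  if (task == "regression") out <- agRelu(out)
  out
}

#' Co-attention parameters
#'
#' @param d shared hidden size of the encoders.
#' @param k attention hidden size (default 40).
#' @param task \code{"classification"} or \code{"regression"}.
#' @param seed initialisation seed.
#' @return named list of parameter matrices.
#' @export
coattentionParams <- function(d, k = 40L, task = "classification", seed = 1L) {
  .withSeed(seed, c(
    list(Wl = .rmat(d, d, 0.05), Ws = .rmat(k, d, 0.05),
         Wc = .rmat(k, d, 0.05), whs = .rmat(k, 1L, 0.05),
         whc = .rmat(k, 1L, 0.05)),
    .headParams(2L * d, task)
  ))
}

#' Affinity matrix between token and patch embeddings
#'
#' \code{F = tanh(C' W_l S)}; every entry lies in (-1, 1).
#'
#' @param C text embeddings, d x N (tokens as columns).
#' @param S image embeddings, d x T (patches as columns).
#' @param Wl learnable d x d matrix.
#' @return affinity matrix N x T.
#' @export
computeAffinity <- function(C, S, Wl) {
  if (nrow(C) != nrow(S) || any(dim(Wl) != nrow(C))) {
    stop("shape error: C, S and Wl must share the hidden size d")
  }
  tanh(t(C) %*% Wl %*% S)
}

#' Co-attention maps and attention distributions
#'
#' \code{H_s = tanh(W_s S + (W_c C) F)}, \code{H_c = tanh(W_c C + (W_s S) F')};
#' the distributions are softmaxes of \code{w_hs' H_s} and \code{w_hc' H_c}
#' over the patch and token axes respectively.
#'
#' @param C,S embeddings as in \code{\link{computeAffinity}}.
#' @param F affinity matrix N x T.
#' @param params list with \code{Ws}, \code{Wc}, \code{whs}, \code{whc}.
#' @return list with \code{Hs} (k x T), \code{Hc} (k x N), \code{as} (1 x T),
#'   \code{ac} (1 x N); each distribution sums to 1.
#' @export
computeAttentionDistributions <- function(C, S, F, params) {
  if (nrow(F) != ncol(C) || ncol(F) != ncol(S)) {
    stop("shape error: F must be N x T")
  }
  Hs <- tanh(params$Ws %*% S + (params$Wc %*% C) %*% F)
  Hc <- tanh(params$Wc %*% C + (params$Ws %*% S) %*% t(F))
  as_ <- .softmaxRow(t(params$whs) %*% Hs)
  ac_ <- .softmaxRow(t(params$whc) %*% Hc)
  list(Hs = Hs, Hc = Hc, as = as_, ac = ac_)
}

.softmaxRow <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Attend and fuse the two modalities
#'
#' \code{s^ = sum_i a_s[i] s_i}, \code{c^ = sum_j a_c[j] c_j};
#' \code{p = [s^ ; c^]}.
#'
#' @param C,S embeddings as in \code{\link{computeAffinity}}.
#' @param as_,ac_ attention distributions (1 x T and 1 x N).
#' @return list with \code{sHat} (1 x d), \code{cHat} (1 x d), \code{p}
#'   (1 x 2d).
#' @export
attendAndFuse <- function(C, S, as_, ac_) {
  sHat <- as_ %*% t(S)
  cHat <- ac_ %*% t(C)
  list(sHat = sHat, cHat = cHat, p = cbind(sHat, cHat))
}

# tape forward: sample has X (N x d) and Y (T x d); returns output node
.agCoattentionForward <- function(tape, p, sample, task, train,
                                  drop1 = 0.4, drop2 = 0.2) {
  Ct <- agConst(tape, sample$X)            # N x d = C'
  St <- agConst(tape, t(sample$Y))         # d x T
  FF <- agTanh(agMM(agMM(Ct, p$Wl), St))   # N x T
  C <- agT(Ct)
  Hs <- agTanh(agAdd(agMM(p$Ws, St), agMM(agMM(p$Wc, C), FF)))
  Hc <- agTanh(agAdd(agMM(p$Wc, C), agMM(agMM(p$Ws, St), agT(FF))))
  as_ <- agSoftmaxRows(agMM(agT(p$whs), Hs))
  ac_ <- agSoftmaxRows(agMM(agT(p$whc), Hc))
  sHat <- agMM(as_, agT(St))                # 1 x d
  cHat <- agMM(ac_, Ct)                     # 1 x d
  pvec <- agCbind(sHat, cHat)
  pvec <- agDropout(pvec, drop1, train)
  .agHead(pvec, p, task, train, hiddenDrop = drop2)
}
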