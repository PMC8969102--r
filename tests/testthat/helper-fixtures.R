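# Shared fixtures (memoised) and independent reference implementations used
# as oracles. Reference code here is deliberately loop-based and written
# against the published equations, not against the package internals.

.fx <- new.env()

fxEnc <- function() {
  if (is.null(.fx$enc)) .fx$enc <- buildTinyEncoders(d = 32, N = 64, T = 17,
                                                     seed = 3)
  .fx$enc
}

fxCorpus <- function() {
  if (is.null(.fx$meta)) {
    dir <- file.path(tempdir(), "fx-corpus")
    .fx$meta <- generateCorpus(corpusSpec(nSubjects = 24, seed = 7), dir)
  }
  .fx$meta
}

fxPrep <- function() {
  if (is.null(.fx$prep)) .fx$prep <- prepareCorpus(fxCorpus(), fxEnc())
  .fx$prep
}

fxSine <- function(freq = 440, dur = 2, sr = 16000) {
  Waveform(sin(2 * pi * freq * (0:(dur * sr - 1)) / sr), sr)
}

fxChaFile <- function() {
  path <- file.path(tempdir(), "fixture.cha")
  writeLines(c(
    "@UTF8", "@Begin", "@Languages:\teng",
    "@Participants:\tPAR Participant, INV Investigator",
    "@ID:\teng|test|PAR|||||Participant|||",
    "*INV:\twhat do you see here ?",
    "*PAR:\tthe boy [/] the boy falls .",
    "%mor:\tdet|the n|boy v|fall-3S .",
    "*PAR:\tthe water (.) is overflowing .",
    "@End"), path, useBytes = TRUE)
  path
}

# ---- reference (oracle) implementations ------------------------------------

refSoftmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# co-attention equations by explicit loops
refCoattention <- function(C, S, Wl, Ws, Wc, whs, whc) {
  d <- nrow(C); N <- ncol(C); T <- ncol(S); k <- nrow(Ws)
  F <- matrix(0, N, T)
  for (i in 1:N) for (j in 1:T) {
    acc <- 0
    for (a in 1:d) for (b in 1:d) acc <- acc + C[a, i] * Wl[a, b] * S[b, j]
    F[i, j] <- tanh(acc)
  }
  Hs <- matrix(0, k, T); Hc <- matrix(0, k, N)
  WsS <- Ws %*% S; WcC <- Wc %*% C
  for (r in 1:k) for (j in 1:T) {
    acc <- WsS[r, j]
    for (i in 1:N) acc <- acc + WcC[r, i] * F[i, j]
    Hs[r, j] <- tanh(acc)
  }
  for (r in 1:k) for (i in 1:N) {
    acc <- WcC[r, i]
    for (j in 1:T) acc <- acc + WsS[r, j] * F[i, j]
    Hc[r, i] <- tanh(acc)
  }
  as_ <- refSoftmax(as.numeric(t(whs) %*% Hs))
  ac_ <- refSoftmax(as.numeric(t(whc) %*% Hc))
  sHat <- numeric(d); cHat <- numeric(d)
  for (j in 1:T) sHat <- sHat + as_[j] * S[, j]
  for (i in 1:N) cHat <- cHat + ac_[i] * C[, i]
  list(F = F, Hs = Hs, Hc = Hc, as = as_, ac = ac_, sHat = sHat,
       cHat = cHat, p = c(sHat, cHat))
}

# shifting-gate equations by explicit per-token loops
refShiftGate <- function(E, Hv, Ha, p, beta, epsilon, variant = "both") {
  N <- nrow(E); d <- ncol(E)
  em <- matrix(0, N, d); alpha <- numeric(N)
  for (i in 1:N) {
    e <- E[i, ]
    hm <- as.numeric(p$bm)
    if (variant %in% c("visual", "both")) {
      wv <- 1 / (1 + exp(-(as.numeric(c(Hv[i, ], e) %*% p$Whv) + p$bv[1, ])))
      hm <- hm + wv * as.numeric(Hv[i, ] %*% p$Wv)
    }
    if (variant %in% c("acoustic", "both")) {
      wa <- 1 / (1 + exp(-(as.numeric(c(Ha[i, ], e) %*% p$Wha) + p$ba[1, ])))
      hm <- hm + wa * as.numeric(Ha[i, ] %*% p$Wa)
    }
    a <- min(beta * sqrt(sum(e^2)) / (sqrt(sum(hm^2)) + epsilon), 1)
    alpha[i] <- a
    em[i, ] <- e + a * hm
  }
  list(alpha = alpha, em = em)
}

# gated self-attention (and, with unit masks, vanilla attention) by loops
refGatedAttention <- function(Q, K, V, Mq, Mk, d) {
  m <- nrow(Q)
  Ag <- matrix(0, m, m)
  for (i in 1:m) {
    logits <- numeric(m)
    for (j in 1:m) {
      logits[j] <- sum((Q[i, ] * Mq[i, ]) * (K[j, ] * Mk[j, ])) / sqrt(d)
    }
    Ag[i, ] <- refSoftmax(logits)
  }
  list(Ag = Ag, H = Ag %*% V)
}

refGsaMasks <- function(Q, K, p) {
  m <- nrow(Q)
  M <- matrix(0, m, 2)
  for (i in 1:m) {
    pq <- as.numeric(Q[i, ] %*% p$FCqg) + p$bqg[1, ]
    pk <- as.numeric(K[i, ] %*% p$FCkg) + p$bkg[1, ]
    M[i, ] <- 1 / (1 + exp(-(as.numeric((pq * pk) %*% p$FCg) + p$bg[1, ])))
  }
  M
}

# plain-R forward of one package transformer layer (post-norm), used to
# cross-check tape forwards
refLayerNorm <- function(x, g, b, eps = 1e-5) {
  t(apply(x, 1L, function(r) {
    (r - mean(r)) / sqrt(mean((r - mean(r))^2) + eps) * g + b
  }))
}

refTransformerLayer <- function(x, p, prefix, d, maskBias = NULL) {
  nm <- function(s) p[[paste0(prefix, ".", s)]]
  q <- sweep(x %*% nm("Wq"), 2L, nm("bq")[1L, ], "+")
  k <- sweep(x %*% nm("Wk"), 2L, nm("bk")[1L, ], "+")
  v <- sweep(x %*% nm("Wv"), 2L, nm("bv")[1L, ], "+")
  sc <- q %*% t(k) / sqrt(d)
  if (!is.null(maskBias)) sc <- sweep(sc, 2L, maskBias, "+")
  A <- t(apply(sc, 1L, refSoftmax))
  att <- sweep((A %*% v) %*% nm("Wo"), 2L, nm("bo")[1L, ], "+")
  x <- refLayerNorm(x + att, nm("g1")[1L, ], nm("n1")[1L, ])
  ff <- pmax(sweep(x %*% nm("W1"), 2L, nm("b1")[1L, ], "+"), 0) %*% nm("W2")
  ff <- sweep(ff, 2L, nm("b2")[1L, ], "+")
  refLayerNorm(x + ff, nm("g2")[1L, ], nm("n2")[1L, ])
}

refHead <- function(x, p, task) {
  h <- pmax(as.numeric(x %*% p$hW1) + p$hb1[1L, ], 0)
  out <- as.numeric(h %*% p$hW2) + p$hb2[1L, ]
  if (task == "regression") out <- pmax(out, 0)
  out
}
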