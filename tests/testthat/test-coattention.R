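test_that("zero weights give a zero affinity and uniform attention", {
  d <- 4; N <- 3; T <- 5; k <- 2
  set.seed(1)
  C <- matrix(rnorm(d * N), d, N)
  S <- matrix(rnorm(d * T), d, T)
  F <- computeAffinity(C, S, matrix(0, d, d))
  expect_true(all(F == 0))
  params <- list(Ws = matrix(0, k, d), Wc = matrix(0, k, d),
                 whs = matrix(rnorm(k)), whc = matrix(rnorm(k)))
  att <- computeAttentionDistributions(C, S, F, params)
  expect_equal(as.numeric(att$as), rep(1 / T, T))
  expect_equal(as.numeric(att$ac), rep(1 / N, N))
})

test_that("affinity entries live in (-1, 1) and swap with column swaps", {
  set.seed(2)
  d <- 3; N <- 4; T <- 2
  C <- matrix(rnorm(d * N), d, N)
  S <- matrix(rnorm(d * T), d, T)
  Wl <- matrix(rnorm(d * d), d, d)
  F <- computeAffinity(C, S, Wl)
  expect_true(all(F > -1 & F < 1))
  Csw <- C[, c(2, 1, 3, 4)]
  expect_equal(computeAffinity(Csw, S, Wl), F[c(2, 1, 3, 4), ])
})

test_that("the equation block matches the explicit-loop oracle", {
  set.seed(3)
  for (rep in 1:20) {
    d <- sample(2:5, 1); N <- sample(2:5, 1); T <- sample(2:5, 1)
    k <- sample(2:5, 1)
    C <- matrix(rnorm(d * N), d, N)
    S <- matrix(rnorm(d * T), d, T)
    params <- list(Wl = matrix(rnorm(d * d), d, d),
                   Ws = matrix(rnorm(k * d), k, d),
                   Wc = matrix(rnorm(k * d), k, d),
                   whs = matrix(rnorm(k)), whc = matrix(rnorm(k)))
    ref <- refCoattention(C, S, params$Wl, params$Ws, params$Wc,
                          params$whs, params$whc)
    F <- computeAffinity(C, S, params$Wl)
    att <- computeAttentionDistributions(C, S, F, params)
    fuse <- attendAndFuse(C, S, att$as, att$ac)
    expect_lt(max(abs(F - ref$F)), 1e-6)
    expect_lt(max(abs(att$Hs - ref$Hs)), 1e-6)
    expect_lt(max(abs(att$Hc - ref$Hc)), 1e-6)
    expect_lt(max(abs(as.numeric(att$as) - ref$as)), 1e-6)
    expect_lt(max(abs(as.numeric(att$ac) - ref$ac)), 1e-6)
    expect_lt(max(abs(as.numeric(fuse$p) - ref$p)), 1e-6)
    expect_equal(sum(att$as), 1, tolerance = 1e-6)
    expect_equal(sum(att$ac), 1, tolerance = 1e-6)
  }
})

test_that("attention logits are shift-invariant", {
  set.seed(4)
  k <- 3; T <- 4
  H <- matrix(rnorm(k * T), k, T)
  w <- matrix(rnorm(k))
  ns <- asNamespace("demfusion")
  a1 <- ns$.softmaxRow(t(w) %*% H)
  a2 <- ns$.softmaxRow(t(w) %*% H + 13.7)
  expect_lt(max(abs(a1 - a2)), 1e-6)
})

test_that("attended vectors are convex combinations of the embeddings", {
  set.seed(5)
  d <- 4; N <- 6; T <- 5
  C <- matrix(rnorm(d * N), d, N)
  S <- matrix(rnorm(d * T), d, T)
  params <- coattentionParams(d, k = 3, seed = 6)
  F <- computeAffinity(C, S, params$Wl)
  att <- computeAttentionDistributions(C, S, F, params)
  fuse <- attendAndFuse(C, S, att$as, att$ac)
  expect_true(all(fuse$sHat >= apply(S, 1, min) - 1e-9))
  expect_true(all(fuse$sHat <= apply(S, 1, max) + 1e-9))
  expect_true(all(fuse$cHat >= apply(C, 1, min) - 1e-9))
  expect_true(all(fuse$cHat <= apply(C, 1, max) + 1e-9))
  # uniform weights give the column mean; one-hot selects a column
  uni <- attendAndFuse(C, S, matrix(1 / T, 1, T), matrix(1 / N, 1, N))
  expect_equal(as.numeric(uni$sHat), rowMeans(S))
  oh <- matrix(0, 1, T); oh[3] <- 1
  expect_equal(as.numeric(attendAndFuse(C, S, oh, matrix(1 / N, 1, N))$sHat),
               S[, 3])
})

test_that("model forward obeys the head contract and is deterministic", {
  enc <- fxEnc()
  s <- fxPrep()$samples[[1]]
  mc <- buildModel("coattention", enc, "classification", seed = 8)
  o1 <- modelForward(mc, s)
  expect_length(o1, 2L)
  expect_identical(o1, modelForward(mc, s))
  mr <- buildModel("coattention", enc, "regression", seed = 8)
  expect_gte(modelForward(mr, s)[1], 0)
})

test_that("the full forward equals the composition of the exported ops", {
  enc <- fxEnc()
  s <- fxPrep()$samples[[2]]
  m <- buildModel("coattention", enc, "classification", seed = 9)
  p <- modelParams(m)
  C <- t(s$X); S <- t(s$Y)
  F <- computeAffinity(C, S, p$Wl)
  att <- computeAttentionDistributions(C, S, F, p)
  fuse <- attendAndFuse(C, S, att$as, att$ac)
  manual <- refHead(fuse$p, p, "classification")
  expect_lt(max(abs(modelForward(m, s) - manual)), 1e-5)
})

test_that("one optimisation step moves every co-attention parameter", {
  enc <- fxEnc()
  prep <- fxPrep()
  m <- buildModel("coattention", enc, "classification", seed = 10)
  cfg <- trainConfig(lr = 1e-2, epochs = 1, batchSize = 4,
                     earlyStopPatience = Inf, lrPatience = Inf, seed = 1)
  fit <- trainModel(m, prep$samples[1:4], prep$labels[1:4],
                    prep$samples[5:6], prep$labels[5:6], cfg)
  for (nm in c("Wl", "Ws", "Wc", "whs", "whc")) {
    expect_gt(max(abs(modelParams(fit$finalModel)[[nm]] - modelParams(m)[[nm]])), 0)
  }
})
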