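test_that("gates are sigmoid-affine in the concatenated vector", {
  set.seed(1)
  N <- 4; dMod <- 3; d <- 3
  hMod <- matrix(rnorm(N * dMod), N, dMod)
  e <- matrix(rnorm(N * d), N, d)
  # zero map: every entry sigma(0) = 0.5
  g0 <- computeGates(hMod, e, matrix(0, dMod + d, d), matrix(0, 1, d))
  expect_true(all(g0 == 0.5))
  # saturating bias
  gs <- computeGates(hMod, e, matrix(0, dMod + d, d), matrix(20, 1, d))
  expect_true(all(gs > 0.999999))
  # explicit-loop oracle
  W <- matrix(rnorm((dMod + d) * d), dMod + d, d)
  b <- matrix(rnorm(d), 1, d)
  g <- computeGates(hMod, e, W, b)
  for (i in 1:N) {
    ref <- 1 / (1 + exp(-(as.numeric(c(hMod[i, ], e[i, ]) %*% W) + b[1, ])))
    expect_lt(max(abs(g[i, ] - ref)), 1e-6)
  }
  expect_true(all(g > 0 & g < 1))
})

test_that("the shift vector honours the variant and the zero projections", {
  enc <- buildTinyEncoders(d = 4, N = 3, T = 5, seed = 2, imageSize = 4)
  pBoth <- shiftGateParams(enc, "both", seed = 3)
  N <- 3; d <- 4
  hV <- matrix(rnorm(N * d), N, d)
  hA <- matrix(rnorm(N * 256), N, 256)
  gV <- matrix(runif(N * d), N, d)
  gA <- matrix(runif(N * d), N, d)
  pZero <- pBoth
  pZero$Wv <- pZero$Wv * 0; pZero$Wa <- pZero$Wa * 0; pZero$bm <- pZero$bm * 0
  expect_true(all(computeShiftVector(hV, hA, gV, gA, pZero) == 0))

  pVis <- shiftGateParams(enc, "visual", seed = 3)
  h1 <- computeShiftVector(hV, hA, gV, gA, pVis)
  h2 <- computeShiftVector(hV, hA + 5, gV, gA, pVis)
  expect_identical(h1, h2) # acoustic input ignored under the visual variant
  expect_error(computeShiftVector(NULL, hA, gV, gA, pVis), "configuration")
})

test_that("alpha follows the norm-ratio formula with its cap", {
  e <- matrix(c(4, 0, 0), 1, 3)   # ||e|| = 4
  hm <- matrix(c(0, 2, 0), 1, 3)  # ||hm|| = 2
  res <- scaleAndShift(e, hm, beta = 0.25)
  expect_equal(res$alpha, 0.5, tolerance = 1e-9)
  # zero shift: cap active and e_m = e exactly
  res0 <- scaleAndShift(e, hm * 0, beta = 0.25)
  expect_equal(res0$alpha, 1)
  expect_identical(res0$em, e)
  # huge beta: cap active, full shift
  resBig <- scaleAndShift(e, hm, beta = 1e6)
  expect_equal(resBig$alpha, 1)
  expect_equal(resBig$em, e + hm)
})

test_that("the shift magnitude is bounded on both branches of the cap", {
  set.seed(4)
  for (rep in 1:50) {
    d <- sample(2:4, 1)
    e <- matrix(rnorm(d), 1, d)
    hm <- matrix(rnorm(d), 1, d)
    beta <- runif(1, 0.001, 2)
    res <- scaleAndShift(e, hm, beta)
    shift <- sqrt(sum((res$em - e)^2))
    if (res$alpha < 1) {
      expect_lte(shift, beta * sqrt(sum(e^2)) + 1e-9)
    } else {
      expect_lte(shift, sqrt(sum(hm^2)) + 1e-9)
    }
  }
})

test_that("the maximal shift vanishes monotonically as beta decreases", {
  set.seed(5)
  E <- matrix(rnorm(20), 5, 4)
  Hm <- matrix(rnorm(20), 5, 4)
  betas <- 10^seq(0, -6, by = -1)
  maxShift <- vapply(betas, function(b) {
    max(sqrt(rowSums((scaleAndShift(E, Hm, b)$em - E)^2)))
  }, numeric(1))
  expect_true(all(diff(maxShift) <= 1e-12))
  expect_lt(maxShift[length(maxShift)], 1e-4)
})

test_that("gate/shift equations match the per-token loop oracle", {
  set.seed(6)
  enc <- buildTinyEncoders(d = 4, N = 3, T = 5, seed = 7, imageSize = 4)
  for (variant in c("acoustic", "visual", "both")) {
    p <- shiftGateParams(enc, variant, seed = 8)
    st <- attr(p, "settings")
    N <- 3; d <- 4
    E <- matrix(rnorm(N * d), N, d)
    Hv <- matrix(rnorm(N * d), N, d)
    Ha <- matrix(rnorm(N * 256), N, 256)
    gV <- if (!is.null(p$Whv)) computeGates(Hv, E, p$Whv, p$bv) else NULL
    gA <- if (!is.null(p$Wha)) computeGates(Ha, E, p$Wha, p$ba) else NULL
    hm <- computeShiftVector(Hv, Ha, gV, gA, p)
    res <- scaleAndShift(E, hm, st$beta, st$epsilon)
    ref <- refShiftGate(E, Hv, Ha, p, st$beta, st$epsilon, variant)
    expect_lt(max(abs(res$em - ref$em)), 1e-6)
    expect_lt(max(abs(res$alpha - ref$alpha)), 1e-6)
  }
})

test_that("beta defaults follow the variant", {
  enc <- buildTinyEncoders(d = 4, N = 3, T = 5, seed = 2, imageSize = 4)
  expect_equal(attr(shiftGateParams(enc, "acoustic"), "settings")$beta, 0.01)
  expect_equal(attr(shiftGateParams(enc, "visual"), "settings")$beta, 0.001)
  expect_equal(attr(shiftGateParams(enc, "both"), "settings")$beta, 0.01)
})

test_that("with zeroed gates the forward reduces to the plain second-encoder pass", {
  enc <- fxEnc()
  s <- fxPrep()$samples[[3]]
  m <- buildModel("multimodal_bert", enc, "classification", seed = 11)
  p <- m@params
  for (nm in c("Whv", "bv", "Wv", "Wha", "ba", "Wa", "projW", "projb", "bm")) {
    p[[nm]] <- p[[nm]] * 0
  }
  m@params <- p
  # manual reference: e_m = e, layer-normalised, second encoder, head
  x <- refLayerNorm(s$X, p$lnG[1, ], p$lnB[1, ]) + p$`enc2.pos`
  bias <- ifelse(s$mask, 0, -1e9)
  x <- refTransformerLayer(x, p, "enc2.l1", enc@d, bias)
  manual <- refHead(x[1, , drop = FALSE], p, "classification")
  expect_lt(max(abs(modelForward(m, s) - manual)), 1e-5)
})

test_that("forward is deterministic in evaluation mode and tiles the image row", {
  enc <- fxEnc()
  s <- fxPrep()$samples[[1]]
  m <- buildModel("multimodal_bert", enc, "classification", seed = 12)
  expect_identical(modelForward(m, s), modelForward(m, s))
  # gates computed from identical tiled rows are identical across tokens
  Hv <- matrix(s$pooled, enc@N, enc@d, byrow = TRUE)
  g <- computeGates(Hv, matrix(1, enc@N, enc@d), m@params$Whv, m@params$bv)
  expect_true(all(g == matrix(g[1, ], enc@N, enc@d, byrow = TRUE)))
})

test_that("training updates the second encoder but never the frozen bundle", {
  enc <- fxEnc()
  prep <- fxPrep()
  before <- enc@textParams
  m <- buildModel("multimodal_bert", enc, "classification", seed = 13)
  cfg <- trainConfig(lr = 1e-2, epochs = 2, batchSize = 4,
                     earlyStopPatience = Inf, lrPatience = Inf, seed = 2)
  fit <- trainModel(m, prep$samples[1:4], prep$labels[1:4],
                    prep$samples[5:6], prep$labels[5:6], cfg)
  expect_identical(fit$finalModel@enc@textParams, before)
  moved <- vapply(grep("^enc2\\.", names(m@params), value = TRUE), function(nm) {
    max(abs(fit$finalModel@params[[nm]] - m@params[[nm]]))
  }, numeric(1))
  expect_true(all(moved > 0))
})
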