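test_that("concatenation is text-rows-first with m = N + T", {
  X <- matrix(rnorm(512 * 4), 512, 4)
  Y <- matrix(rnorm(197 * 4), 197, 4)
  Z <- concatModalities(X, Y)
  expect_equal(nrow(Z), 709L)
  expect_equal(Z[1, ], X[1, ])
  expect_equal(Z[513, ], Y[1, ])
  expect_error(concatModalities(X, Y[0, , drop = FALSE]), "degenerate")
  expect_error(concatModalities(X, matrix(0, 3, 5)), "shape")
})

test_that("masks are sigmoid gates; zero input exposes the gate bias", {
  d <- 3; dG <- 2; m <- 4
  params <- gsaParams(d, dG = dG, seed = 1)
  Z0 <- matrix(0, m, d)
  mk <- computeMasks(Z0, Z0, params)
  expect_true(all(mk$M == 0.5)) # zero-initialised biases
  params$bg <- matrix(c(1, -1), 1, 2)
  mk2 <- computeMasks(Z0, Z0, params)
  expect_equal(unique(mk2$M[, 1]), 1 / (1 + exp(-1)))
  expect_equal(unique(mk2$M[, 2]), 1 / (1 + exp(1)))
  # tiling repeats each mask entry across the d columns
  set.seed(2)
  Z <- matrix(rnorm(m * d), m, d)
  mk3 <- computeMasks(Z, Z, params)
  for (i in 1:m) {
    expect_true(all(mk3$MqTiled[i, ] == mk3$M[i, 1]))
    expect_true(all(mk3$MkTiled[i, ] == mk3$M[i, 2]))
  }
  expect_true(all(mk3$M > 0 & mk3$M < 1))
})

test_that("the mask equation matches the explicit-loop oracle", {
  set.seed(3)
  for (rep in 1:20) {
    m <- sample(2:6, 1); d <- sample(2:4, 1); dG <- sample(2:3, 1)
    params <- gsaParams(d, dG = dG, seed = rep)
    params$bqg <- matrix(rnorm(dG), 1); params$bkg <- matrix(rnorm(dG), 1)
    params$bg <- matrix(rnorm(2), 1)
    Z <- matrix(rnorm(m * d), m, d)
    M <- computeMasks(Z, Z, params)$M
    expect_lt(max(abs(M - refGsaMasks(Z, Z, params))), 1e-6)
  }
})

test_that("unit masks reduce gated attention to vanilla self-attention", {
  set.seed(4)
  m <- 5; d <- 3
  Z <- matrix(rnorm(m * d), m, d)
  ones <- matrix(1, m, d)
  got <- gatedAttention(Z, Z, Z, ones, ones, d)
  ref <- refGatedAttention(Z, Z, Z, ones, ones, d)
  expect_lt(max(abs(got$Ag - ref$Ag)), 1e-6)
  expect_lt(max(abs(got$H - ref$H)), 1e-6)
  expect_equal(rowSums(got$Ag), rep(1, m), tolerance = 1e-6)
  expect_true(all(got$Ag >= 0))
})

test_that("gated attention matches the loop oracle on random instances", {
  set.seed(5)
  for (rep in 1:20) {
    m <- sample(2:6, 1); d <- sample(2:4, 1); dG <- sample(2:3, 1)
    params <- gsaParams(d, dG = dG, seed = 100 + rep)
    Z <- matrix(rnorm(m * d), m, d)
    mk <- computeMasks(Z, Z, params)
    got <- gatedAttention(Z, Z, Z, mk$MqTiled, mk$MkTiled, d)
    ref <- refGatedAttention(Z, Z, Z, mk$MqTiled, mk$MkTiled, d)
    expect_lt(max(abs(got$Ag - ref$Ag)), 1e-6)
    expect_lt(max(abs(got$H - ref$H)), 1e-6)
  }
})

test_that("identical rows attend uniformly and reproduce the common row", {
  d <- 4; m <- 6
  row <- rnorm(d)
  Z <- matrix(row, m, d, byrow = TRUE)
  params <- gsaParams(d, seed = 6)
  mk <- computeMasks(Z, Z, params)
  got <- gatedAttention(Z, Z, Z, mk$MqTiled, mk$MkTiled, d)
  expect_equal(got$Ag, matrix(1 / m, m, m), tolerance = 1e-9)
  for (i in 1:m) expect_equal(got$H[i, ], row, tolerance = 1e-9)
})

test_that("a saturated gate bias converges to vanilla attention", {
  set.seed(7)
  m <- 5; d <- 3
  Z <- matrix(rnorm(m * d), m, d)
  params <- gsaParams(d, seed = 8)
  params$bg <- matrix(20, 1, 2)
  mk <- computeMasks(Z, Z, params)
  got <- gatedAttention(Z, Z, Z, mk$MqTiled, mk$MkTiled, d)
  ones <- matrix(1, m, d)
  ref <- refGatedAttention(Z, Z, Z, ones, ones, d)
  expect_lt(max(abs(got$Ag - ref$Ag)), 1e-4)
})

test_that("permuting the sequence permutes H and leaves the pooled mean unchanged", {
  set.seed(9)
  m <- 6; d <- 3
  Z <- matrix(rnorm(m * d), m, d)
  params <- gsaParams(d, seed = 10)
  run <- function(Zp) {
    mk <- computeMasks(Zp, Zp, params)
    gatedAttention(Zp, Zp, Zp, mk$MqTiled, mk$MkTiled, d)
  }
  a <- run(Z)
  perm <- sample(m)
  b <- run(Z[perm, , drop = FALSE])
  expect_lt(max(abs(b$H - a$H[perm, , drop = FALSE])), 1e-9)
  expect_lt(max(abs(b$Ag - a$Ag[perm, perm])), 1e-9)
  expect_lt(max(abs(colMeans(b$H) - colMeans(a$H))), 1e-9)
})

test_that("the model forward composes the ops, pools by the mean and is deterministic", {
  enc <- fxEnc()
  s <- fxPrep()$samples[[4]]
  m <- buildModel("gsa", enc, "classification", seed = 11)
  expect_identical(modelForward(m, s), modelForward(m, s))
  p <- modelParams(m)
  Z <- concatModalities(s$X, s$Y)
  mk <- computeMasks(Z, Z, p)
  att <- gatedAttention(Z, Z, Z, mk$MqTiled, mk$MkTiled, ncol(Z))
  pooled <- matrix(colMeans(att$H), 1)
  manual <- refHead(pooled, p, "classification")
  expect_lt(max(abs(modelForward(m, s) - manual)), 1e-5)
  mr <- buildModel("gsa", enc, "regression", seed = 11)
  expect_gte(modelForward(mr, s)[1], 0)
})
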