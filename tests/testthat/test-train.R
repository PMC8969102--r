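test_that("splits hit the stated fractions with half-up rounding on the train side", {
  ids <- sprintf("P%03d", 1:100)
  sp <- splitDataset(ids, seed = 1)
  expect_length(sp$train, 65L)
  expect_length(sp$validation, 35L)
  ids108 <- sprintf("P%03d", 1:108)
  sp108 <- splitDataset(ids108, seed = 2)
  expect_length(sp108$train, 70L) # 0.65 * 108 = 70.2 -> 70
  expect_length(sp108$validation, 38L)
  expect_setequal(c(sp108$train, sp108$validation), ids108)
  expect_length(intersect(sp108$train, sp108$validation), 0L)
})

test_that("splits are reproducible and stratification balances the groups", {
  ids <- sprintf("P%03d", 1:108)
  labels <- rep(c(0, 1), each = 54)
  a <- splitDataset(ids, seed = 5, labels = labels)
  b <- splitDataset(ids, seed = 5, labels = labels)
  expect_identical(a, b)
  expect_length(a$train, 70L)
  trLab <- labels[match(a$train, ids)]
  expect_equal(sum(trLab == 0), 35L)
  expect_equal(sum(trLab == 1), 35L)
  expect_error(splitDataset("only-one"), "at least 2")
})

test_that("missing MMSE drops subjects for regression only", {
  meta <- data.frame(id = sprintf("P%d", 1:108),
                     mmse = c(NA, sample(5:30, 107, replace = TRUE)))
  expect_equal(nrow(dropMissingMmse(meta, "regression")), 107L)
  expect_equal(nrow(dropMissingMmse(meta, "classification")), 108L)
  full <- data.frame(id = "a", mmse = 25)
  expect_identical(dropMissingMmse(full, "regression"), full)
})

test_that("classification metrics reproduce the hand-computed confusion matrix", {
  m <- evaluateClassification(c(1, 0, 0, 0), c(1, 1, 0, 0))
  expect_equal(unname(m["precision"]), 100)
  expect_equal(unname(m["recall"]), 50)
  expect_equal(unname(m["f1"]), 200 / 3, tolerance = 1e-9)
  expect_equal(unname(m["accuracy"]), 75)
  expect_equal(unname(m["specificity"]), 100)

  perfect <- evaluateClassification(c(1, 0, 1), c(1, 0, 1))
  expect_true(all(perfect == 100))

  w <- capture_warnings(neg <- evaluateClassification(c(0, 0, 0, 0),
                                                      c(1, 1, 0, 0)))
  expect_true(any(grepl("precision", w)))
  expect_equal(unname(neg["recall"]), 0)
  expect_equal(unname(neg["specificity"]), 100)
})

test_that("metrics match a brute-force implementation on random cases", {
  set.seed(31)
  for (rep in 1:200) {
    n <- sample(3:40, 1)
    truth <- rbinom(n, 1, 0.5)
    pred <- rbinom(n, 1, runif(1, 0.2, 0.8))
    got <- suppressWarnings(evaluateClassification(pred, truth))
    tab <- table(factor(pred, c(0, 1)), factor(truth, c(0, 1)))
    tp <- tab["1", "1"]; tn <- tab["0", "0"]
    fp <- tab["1", "0"]; fn <- tab["0", "1"]
    div <- function(a, b) if (b == 0) 0 else a / b
    prec <- div(tp, tp + fp); rec <- div(tp, tp + fn)
    expect_equal(unname(got["accuracy"]), 100 * (tp + tn) / n)
    expect_equal(unname(got["precision"]), 100 * prec)
    expect_equal(unname(got["recall"]), 100 * rec)
    expect_equal(unname(got["f1"]),
                 100 * div(2 * prec * rec, prec + rec))
    expect_equal(unname(got["specificity"]), 100 * div(tn, tn + fp))
    preds <- runif(n, 0, 30); targ <- runif(n, 0, 30)
    expect_equal(evaluateRegression(preds, targ),
                 sqrt(sum((preds - targ)^2) / n))
  }
})

test_that("RMSE worked examples and the shift law hold", {
  expect_equal(evaluateRegression(c(28, 20), c(30, 20)), sqrt(2))
  expect_equal(evaluateRegression(1:5, 1:5), 0)
  expect_equal(evaluateRegression(1:5 + 2.5, 1:5), 2.5)
  expect_error(evaluateRegression(numeric(0), numeric(0)), "empty")
})

test_that("run aggregation reports the mean and population standard deviation", {
  agg <- aggregateRuns(data.frame(accuracy = c(80, 90), f1 = c(70, 70)))
  expect_equal(agg["mean", "accuracy"], 85)
  expect_equal(agg["sd", "accuracy"], 5) # population convention
  expect_equal(agg["sd", "f1"], 0)
  one <- aggregateRuns(data.frame(rmse = 3.2))
  expect_equal(one["mean", "rmse"], 3.2)
  expect_equal(one["sd", "rmse"], 0)
})

test_that("the plateau scheduler decays 1e-5 to 1e-6 after a 3-epoch plateau", {
  ns <- asNamespace("demfusion")
  st <- ns$.plateauInit(1e-5, 0.1, 3L)
  st <- ns$.plateauUpdate(st, 1.0) # improvement (best was Inf)
  for (i in 1:2) st <- ns$.plateauUpdate(st, 1.0)
  expect_equal(st$lr, 1e-5) # only 2 flat epochs so far
  st <- ns$.plateauUpdate(st, 1.0)
  expect_equal(st$lr, 1e-6)
})

test_that("early stopping fires after exactly six non-improving epochs", {
  ns <- asNamespace("demfusion")
  st <- ns$.earlyStopInit(6L)
  st <- ns$.earlyStopUpdate(st, 0.5)
  for (i in 1:5) {
    st <- ns$.earlyStopUpdate(st, 0.5)
    expect_false(st$stop)
  }
  st <- ns$.earlyStopUpdate(st, 0.5)
  expect_true(st$stop)
  # an improvement resets the counter
  st2 <- ns$.earlyStopInit(6L)
  st2 <- ns$.earlyStopUpdate(st2, 0.5)
  for (i in 1:5) st2 <- ns$.earlyStopUpdate(st2, 0.5)
  st2 <- ns$.earlyStopUpdate(st2, 0.4)
  expect_false(st2$stop)
  expect_equal(st2$wait, 0L)
})

test_that("a frozen run halts at the exact early-stopping epoch with decayed lr", {
  enc <- fxEnc()
  prep <- fxPrep()
  m <- buildModel("coattention", enc, "classification", seed = 21)
  cfg <- trainConfig(lr = 0, epochs = 30, batchSize = 4, seed = 3)
  fit <- trainModel(m, prep$samples[1:6], prep$labels[1:6],
                    prep$samples[7:9], prep$labels[7:9], cfg)
  # epoch 1 improves on Inf; epochs 2..7 are flat -> stop at epoch 7
  expect_true(fit$stoppedEarly)
  expect_equal(nrow(fit$history), 7L)
  expect_identical(fit$finalModel@params, m@params) # lr 0 moves nothing
})

test_that("training reduces the loss on a separable corpus", {
  enc <- fxEnc()
  prep <- fxPrep()
  m <- buildModel("gsa", enc, "classification", seed = 22)
  cfg <- trainConfig(lr = 1e-2, epochs = 8, batchSize = 8,
                     earlyStopPatience = Inf, lrPatience = Inf, seed = 4)
  fit <- trainModel(m, prep$samples[1:16], prep$labels[1:16],
                    prep$samples[17:24], prep$labels[17:24], cfg)
  expect_lt(fit$history$trainLoss[8], fit$history$trainLoss[1])
})
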