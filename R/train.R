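# Training protocol: stratified 65/35 split, Adam, reduce-on-plateau,
# early stopping keyed on validation loss, multi-run aggregation.

#' Training configuration
#'
#' Defaults follow the published protocol: Adam with learning rate 1e-5,
#' reduce-on-plateau (factor 0.1, patience 3), early stopping (patience 6),
#' both keyed on validation loss, and 5 repetitions. The desk-scale (tiny
#' encoder) runs in the package's own tests use \code{lr = 1e-2} and
#' \code{earlyStopPatience = Inf}; see the methods vignette.
#'
#' @param lr Adam learning rate.
#' @param epochs maximum epochs.
#' @param batchSize minibatch size.
#' @param lrFactor plateau decay factor.
#' @param lrPatience epochs of non-decreasing validation loss before decay.
#' @param earlyStopPatience epochs of non-decreasing validation loss before
#'   stopping (may be \code{Inf}).
#' @param repetitions number of repeated runs for aggregation.
#' @param seed RNG seed for shuffling, dropout and initialisation.
#' @return list of class \code{trainConfig}.
#' @export
trainConfig <- function(lr = 1e-5, epochs = 50L, batchSize = 8L,
                        lrFactor = 0.1, lrPatience = 3L,
                        earlyStopPatience = 6L, repetitions = 5L, seed = 1L) {
  structure(list(lr = lr, epochs = epochs, batchSize = batchSize,
                 lrFactor = lrFactor, lrPatience = lrPatience,
                 earlyStopPatience = earlyStopPatience,
                 repetitions = repetitions, seed = seed),
            class = "trainConfig")
}

#' Split subjects into train and validation sets
#'
#' Disjoint, exhaustive split at the stated fractions (default 65/35), with
#' the train size rounded half-up. For classification the split is
#' stratified by label so small corpora keep both groups in each part.
#'
#' @param ids subject identifiers.
#' @param fractions train/validation fractions summing to 1.
#' @param seed RNG seed; the split is reproducible.
#' @param labels optional group labels for stratification.
#' @return list with \code{train} and \code{validation} id vectors.
#' @export
splitDataset <- function(ids, fractions = c(0.65, 0.35), seed = 1L,
                         labels = NULL) {
  n <- length(ids)
  if (n < 2L) stop("need at least 2 subjects to split")
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  nTrain <- floor(fractions[1L] * n + 0.5) # round half-up on the train side
  .withSeed(seed, {
    if (is.null(labels)) {
      tr <- ids[sample.int(n, nTrain)]
    } else {
      tr <- ids[0]
      groups <- split(seq_along(ids), labels)
      want <- vapply(groups, function(g) {
        floor(fractions[1L] * length(g) + 0.5)
      }, numeric(1L))
      # reconcile per-group rounding with the overall train size
      excess <- sum(want) - nTrain
      ord <- order(vapply(groups, length, numeric(1L)), decreasing = TRUE)
      i <- 1L
      while (excess != 0) {
        g <- ord[(i - 1L) %% length(groups) + 1L]
        want[g] <- want[g] - sign(excess)
        excess <- excess - sign(excess)
        i <- i + 1L
      }
      for (gi in seq_along(groups)) {
        g <- groups[[gi]]
        tr <- c(tr, ids[g[sample.int(length(g), want[gi])]])
      }
    }
    list(train = ids[ids %in% tr], validation = ids[!ids %in% tr])
  })
}

#' Drop subjects without an MMSE score (regression task only)
#'
#' @param metadata data.frame with at least \code{id} and \code{mmse}.
#' @param task \code{"regression"} removes rows with missing MMSE;
#'   \code{"classification"} returns the table untouched.
#' @return filtered data.frame.
#' @export
dropMissingMmse <- function(metadata, task = "regression") {
  if (task != "regression") return(metadata)
  metadata[!is.na(metadata$mmse), , drop = FALSE]
}

# ---- plateau scheduler / early stopping state machines ---------------------
# both count consecutive epochs without strict improvement of the monitored
# (validation) loss

.plateauInit <- function(lr, factor = 0.1, patience = 3L) {
  list(lr = lr, factor = factor, patience = patience, best = Inf, wait = 0L)
}

.plateauUpdate <- function(state, loss) {
  if (loss < state$best - 1e-12) {
    state$best <- loss
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) {
      state$lr <- state$lr * state$factor
      state$wait <- 0L
    }
  }
  state
}

.earlyStopInit <- function(patience = 6L) {
  list(patience = patience, best = Inf, wait = 0L, stop = FALSE)
}

.earlyStopUpdate <- function(state, loss) {
  if (loss < state$best - 1e-12) {
    state$best <- loss
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) state$stop <- TRUE
  }
  state
}

# mean evaluation-mode loss over samples
.evalLoss <- function(model, samples, targets) {
  if (model@task == "classification") {
    tot <- 0
    for (i in seq_along(samples)) {
      o <- modelForward(model, samples[[i]])
      lp <- o - (max(o) + log(sum(exp(o - max(o)))))
      tot <- tot - lp[targets[i] + 1L]
    }
    tot / length(samples)
  } else {
    preds <- vapply(samples, function(s) modelForward(model, s)[1L],
                    numeric(1L))
    sqrt(mean((preds - targets)^2))
  }
}

#' Train a fusion model
#'
#' Minimises cross-entropy (classification) or RMSE (regression) with Adam;
#' the learning rate decays by \code{lrFactor} after \code{lrPatience}
#' epochs without validation-loss improvement and training stops after
#' \code{earlyStopPatience} such epochs. The frozen encoder bundle is never
#' touched. Returns the best-validation parameter set alongside the final
#' one and the loss history.
#'
#' @param model a \linkS4class{FusionModel}.
#' @param trainSamples,trainTargets prepared training samples and labels
#'   (0/1) or MMSE scores.
#' @param valSamples,valTargets validation samples and targets.
#' @param config a \code{\link{trainConfig}}.
#' @param verbose print per-epoch losses.
#' @return list with \code{model} (best-validation checkpoint),
#'   \code{finalModel}, \code{history} (data.frame epoch/trainLoss/valLoss/
#'   lr), and \code{stoppedEarly}.
#' @export
trainModel <- function(model, trainSamples, trainTargets, valSamples,
                       valTargets, config = trainConfig(), verbose = FALSE) {
  params <- model@params
  opt <- adamInit(params)
  sched <- .plateauInit(config$lr, config$lrFactor, config$lrPatience)
  stopper <- .earlyStopInit(config$earlyStopPatience)
  bestParams <- params
  bestVal <- Inf
  hist <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                     valLoss = numeric(0), lr = numeric(0))
  n <- length(trainSamples)
  .withSeed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      epochLoss <- 0
      nb <- 0L
      for (start in seq(1L, n, by = config$batchSize)) {
        sel <- ord[start:min(start + config$batchSize - 1L, n)]
        model@params <- params
        bl <- .batchLoss(model, trainSamples[sel], trainTargets[sel],
                         train = TRUE)
        lv <- agValue(bl$loss)[1L]
        if (!is.finite(lv)) stop("training diverged: non-finite loss")
        grads <- agBackward(bl$loss)
        step <- adamStep(params, grads, opt, sched$lr)
        params <- step$params
        opt <- step$state
        epochLoss <- epochLoss + lv
        nb <- nb + 1L
      }
      model@params <- params
      valLoss <- .evalLoss(model, valSamples, valTargets)
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     trainLoss = epochLoss / nb,
                                     valLoss = valLoss, lr = sched$lr))
      if (verbose) {
        message(sprintf("epoch %d: train %.4f val %.4f lr %.2g", epoch,
                        epochLoss / nb, valLoss, sched$lr))
      }
      if (valLoss < bestVal) {
        bestVal <- valLoss
        bestParams <- params
      }
      sched <- .plateauUpdate(sched, valLoss)
      stopper <- .earlyStopUpdate(stopper, valLoss)
      if (stopper$stop) break
    }
  })
  best <- model
  best@params <- bestParams
  final <- model
  final@params <- params
  list(model = best, finalModel = final, history = hist,
       stoppedEarly = stopper$stop)
}

#' Aggregate metrics over repeated runs
#'
#' Per-metric mean and population standard deviation over repetitions.
#'
#' @param runs data.frame or matrix, one row per run, one column per metric.
#' @return data.frame with rows \code{mean} and \code{sd}.
#' @export
aggregateRuns <- function(runs) {
  runs <- as.data.frame(runs)
  stopifnot(nrow(runs) >= 1L)
  popSd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- rbind(vapply(runs, mean, numeric(1L)),
               vapply(runs, popSd, numeric(1L)))
  rownames(out) <- c("mean", "sd")
  as.data.frame(out)
}
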