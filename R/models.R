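# Model container and forward dispatch for the three fusion architectures.

#' Fusion model
#'
#' Bundles an architecture name, task, trainable parameters and the (frozen)
#' encoder bundle. Parameters live in a named list and are updated in place
#' by the trainer.
#'
#' @slot name one of \code{"coattention"}, \code{"multimodal_bert"},
#'   \code{"gsa"}.
#' @slot task \code{"classification"} or \code{"regression"}.
#' @slot variant shifting-gate variant (\code{"both"}, \code{"acoustic"},
#'   \code{"visual"}); empty for the other architectures.
#' @slot params named list of trainable parameter matrices.
#' @slot enc the frozen \linkS4class{EncoderBundle}.
#' @slot settings architecture settings (beta, epsilon, dropout rates, ...).
#' @export
setClass("FusionModel",
         representation(name = "character", task = "character",
                        variant = "character", params = "list",
                        enc = "EncoderBundle", settings = "list"))

setValidity("FusionModel", function(object) {
  if (!object@name %in% c("coattention", "multimodal_bert", "gsa")) {
    return("unknown architecture name")
  }
  if (!object@task %in% c("classification", "regression")) {
    return("task must be classification or regression")
  }
  TRUE
})

setMethod("show", "FusionModel", function(object) {
  v <- if (nzchar(object@variant)) paste0(" (", object@variant, ")") else ""
  cat(sprintf("FusionModel '%s'%s, task=%s, %d parameter matrices (%s values)\n",
              object@name, v, object@task, length(object@params),
              format(sum(vapply(object@params, length, numeric(1))),
                     big.mark = ",")))
})

#' @rdname FusionModel-class
#' @param x a \code{FusionModel}.
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))

#' @rdname FusionModel-class
#' @export
setMethod("modelParams", "FusionModel", function(x) x@params)

#' Build a fusion model
#'
#' @param name architecture: \code{"coattention"} (affinity co-attention
#'   over token and patch embeddings), \code{"multimodal_bert"} (shifting
#'   gate + second text encoder), or \code{"gsa"} (gated self-attention over
#'   the concatenated sequence).
#' @param enc an \linkS4class{EncoderBundle}.
#' @param task \code{"classification"} (AD vs HC) or \code{"regression"}
#'   (MMSE score).
#' @param variant shifting-gate variant, default \code{"both"}.
#' @param seed parameter-initialisation seed.
#' @param k co-attention hidden size (default 40).
#' @param dG gate hidden size for gated self-attention (default 64).
#' @param beta shifting-gate scale; default by variant (0.01 acoustic/both,
#'   0.001 visual).
#' @return A \linkS4class{FusionModel}.
#' @export
buildModel <- function(name = c("coattention", "multimodal_bert", "gsa"),
                       enc, task = c("classification", "regression"),
                       variant = "both", seed = 1L, k = 40L, dG = 64L,
                       beta = NULL) {
  name <- match.arg(name)
  task <- match.arg(task)
  d <- enc@d
  if (name == "coattention") {
    params <- coattentionParams(d, k = k, task = task, seed = seed)
    settings <- list(k = k, drop1 = 0.4, drop2 = 0.2)
    variant <- ""
  } else if (name == "multimodal_bert") {
    params <- shiftGateParams(enc, variant = variant, task = task,
                              beta = beta, seed = seed)
    settings <- c(attr(params, "settings"),
                  list(dropShift = 0.4, dropCls = 0.2))
    attr(params, "settings") <- NULL
  } else {
    params <- gsaParams(d, dG = dG, task = task, seed = seed)
    settings <- list(dG = dG, dropPool = 0.3)
    variant <- ""
  }
  methods::new("FusionModel", name = name, task = task, variant = variant,
               params = params, enc = enc, settings = settings)
}

# forward pass with pre-built parameter nodes (shared across a batch)
.modelForwardNodes <- function(model, p, tape, sample, train = FALSE) {
  st <- model@settings
  switch(model@name,
    coattention = .agCoattentionForward(tape, p, sample, model@task, train,
                                        st$drop1, st$drop2),
    multimodal_bert = {
      settings <- list(variant = st$variant, beta = st$beta,
                       epsilon = st$epsilon)
      .agShiftGateForward(tape, p, sample, model@enc, model@task, train,
                          settings, st$dropShift, st$dropCls)
    },
    gsa = .agGsaForward(tape, p, sample, model@task, train, st$dropPool)
  )
}

# forward pass on a fresh tape; returns list(out = node, tape = tape)
.modelForward <- function(model, sample, train = FALSE, trainable = TRUE) {
  tape <- agTape()
  p <- .agParamNodes(tape, model@params, trainable = trainable)
  list(out = .modelForwardNodes(model, p, tape, sample, train), tape = tape)
}

# mean batch loss on one tape: cross-entropy for classification, mean
# squared error for regression (the RMSE minimiser; validation loss is
# reported on the RMSE scale by .evalLoss). Returns list(loss, tape).
.batchLoss <- function(model, samples, targets, train = TRUE) {
  tape <- agTape()
  p <- .agParamNodes(tape, model@params, trainable = TRUE)
  acc <- NULL
  for (i in seq_along(samples)) {
    out <- .modelForwardNodes(model, p, tape, samples[[i]], train)
    li <- if (model@task == "classification") {
      agScale(agPick(agLogSoftmaxRows(out), targets[i] + 1L), -1)
    } else {
      agSquare(agAddConst(out, -targets[i]))
    }
    acc <- if (is.null(acc)) li else agAdd(acc, li)
  }
  list(loss = agScale(acc, 1 / length(samples)), tape = tape)
}

#' Run a model forward in evaluation mode
#'
#' @param model a \linkS4class{FusionModel}.
#' @param sample prepared sample (see \code{\link{prepareSubject}}).
#' @return for classification a length-2 logit vector; for regression a
#'   single non-negative value.
#' @export
modelForward <- function(model, sample) {
  as.numeric(agValue(.modelForward(model, sample, train = FALSE,
                                   trainable = FALSE)$out))
}

#' Predict labels or scores for prepared samples
#'
#' Classification uses argmax over the two logits (1 = AD); regression
#' returns the ReLU output unit, hence predictions are always >= 0.
#'
#' @param model a \linkS4class{FusionModel}.
#' @param samples list of prepared samples.
#' @return numeric vector of 0/1 labels or MMSE predictions.
#' @export
predictModel <- function(model, samples) {
  vapply(samples, function(s) {
    o <- modelForward(model, s)
    if (model@task == "classification") which.max(o) - 1 else o[1L]
  }, numeric(1L))
}

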