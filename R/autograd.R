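# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every value on the tape is a numeric matrix (scalars are 1x1). A forward
# pass appends nodes to the tape in topological order; backward() walks the
# tape in reverse, accumulating gradients. Leaves registered with a name are
# the trainable parameters; constants never receive gradients.
#
# The engine is deliberately small: only the operations the fusion
# architectures, the tiny transformer encoders and the loss functions need.

agTape <- function() {
  e <- new.env(parent = emptyenv())
  e$vals <- list()
  e$parents <- list()
  e$bw <- list()
  e$n <- 0L
  e$leaves <- list() # name -> node id
  e
}

.agPush <- function(tape, val, parents = integer(0), bw = NULL) {
  i <- tape$n + 1L
  tape$n <- i
  tape$vals[[i]] <- val
  tape$parents[[i]] <- parents
  tape$bw[i] <- list(bw)
  structure(list(tape = tape, id = i), class = "agNode")
}

agValue <- function(a) a$tape$vals[[a$id]]

agConst <- function(tape, x) {
  .agPush(tape, as.matrix(x))
}

agLeaf <- function(tape, x, name) {
  node <- .agPush(tape, as.matrix(x))
  tape$leaves[[name]] <- node$id
  node
}

# broadcast b (1x1, 1xn or mx1) up to dims; and collapse a gradient back down
.agExpand <- function(x, dims) {
  dx <- dim(x)
  if (identical(dx, dims)) return(x)
  if (all(dx == c(1L, 1L))) return(matrix(x[1L], dims[1L], dims[2L]))
  if (dx[1L] == 1L && dx[2L] == dims[2L]) {
    return(matrix(x, dims[1L], dims[2L], byrow = TRUE))
  }
  if (dx[2L] == 1L && dx[1L] == dims[1L]) {
    return(matrix(x, dims[1L], dims[2L], byrow = FALSE))
  }
  stop("cannot broadcast shape (", dx[1L], ",", dx[2L], ") to (",
       dims[1L], ",", dims[2L], ")")
}

.agCollapse <- function(g, dims) {
  dg <- dim(g)
  if (identical(dg, dims)) return(g)
  if (all(dims == c(1L, 1L))) return(matrix(sum(g), 1L, 1L))
  if (dims[1L] == 1L) return(matrix(colSums(g), 1L, dg[2L]))
  if (dims[2L] == 1L) return(matrix(rowSums(g), dg[1L], 1L))
  stop("cannot collapse gradient")
}

.agBroadDims <- function(a, b) {
  da <- dim(a); db <- dim(b)
  c(max(da[1L], db[1L]), max(da[2L], db[2L]))
}

agAdd <- function(a, b) {
  A <- agValue(a); B <- agValue(b)
  dims <- .agBroadDims(A, B)
  val <- .agExpand(A, dims) + .agExpand(B, dims)
  da <- dim(A); db <- dim(B)
  .agPush(a$tape, val, c(a$id, b$id), function(g) {
    list(.agCollapse(g, da), .agCollapse(g, db))
  })
}

agSub <- function(a, b) {
  A <- agValue(a); B <- agValue(b)
  dims <- .agBroadDims(A, B)
  val <- .agExpand(A, dims) - .agExpand(B, dims)
  da <- dim(A); db <- dim(B)
  .agPush(a$tape, val, c(a$id, b$id), function(g) {
    list(.agCollapse(g, da), .agCollapse(-g, db))
  })
}

agMul <- function(a, b) {
  A <- agValue(a); B <- agValue(b)
  dims <- .agBroadDims(A, B)
  Ae <- .agExpand(A, dims); Be <- .agExpand(B, dims)
  da <- dim(A); db <- dim(B)
  .agPush(a$tape, Ae * Be, c(a$id, b$id), function(g) {
    list(.agCollapse(g * Be, da), .agCollapse(g * Ae, db))
  })
}

agDiv <- function(a, b) {
  A <- agValue(a); B <- agValue(b)
  dims <- .agBroadDims(A, B)
  Ae <- .agExpand(A, dims); Be <- .agExpand(B, dims)
  da <- dim(A); db <- dim(B)
  .agPush(a$tape, Ae / Be, c(a$id, b$id), function(g) {
    list(.agCollapse(g / Be, da), .agCollapse(-g * Ae / (Be * Be), db))
  })
}

agScale <- function(a, s) {
  A <- agValue(a)
  .agPush(a$tape, A * s, a$id, function(g) list(g * s))
}

agAddConst <- function(a, c) {
  A <- agValue(a)
  .agPush(a$tape, A + c, a$id, function(g) list(g))
}

agMM <- function(a, b) {
  A <- agValue(a); B <- agValue(b)
  .agPush(a$tape, A %*% B, c(a$id, b$id), function(g) {
    list(g %*% t(B), t(A) %*% g)
  })
}

agT <- function(a) {
  A <- agValue(a)
  .agPush(a$tape, t(A), a$id, function(g) list(t(g)))
}

agTanh <- function(a) {
  v <- tanh(agValue(a))
  .agPush(a$tape, v, a$id, function(g) list(g * (1 - v * v)))
}

agSigmoid <- function(a) {
  v <- 1 / (1 + exp(-agValue(a)))
  .agPush(a$tape, v, a$id, function(g) list(g * v * (1 - v)))
}

agRelu <- function(a) {
  A <- agValue(a)
  v <- pmax(A, 0)
  .agPush(a$tape, v, a$id, function(g) list(g * (A > 0)))
}

agSquare <- function(a) {
  A <- agValue(a)
  .agPush(a$tape, A * A, a$id, function(g) list(2 * g * A))
}

agSqrt <- function(a) {
  v <- sqrt(agValue(a))
  .agPush(a$tape, v, a$id, function(g) list(g / (2 * v)))
}

agMinConst <- function(a, cap) {
  A <- agValue(a)
  .agPush(a$tape, pmin(A, cap), a$id, function(g) list(g * (A < cap)))
}

agSoftmaxRows <- function(a) {
  A <- agValue(a)
  mx <- apply(A, 1L, max)
  ex <- exp(A - mx)
  P <- ex / rowSums(ex)
  .agPush(a$tape, P, a$id, function(g) {
    s <- rowSums(g * P)
    list((g - s) * P)
  })
}

agLogSoftmaxRows <- function(a) {
  A <- agValue(a)
  mx <- apply(A, 1L, max)
  lse <- mx + log(rowSums(exp(A - mx)))
  v <- A - lse
  .agPush(a$tape, v, a$id, function(g) {
    list(g - rowSums(g) * exp(v))
  })
}

agRowSums <- function(a) {
  A <- agValue(a)
  nc <- ncol(A)
  .agPush(a$tape, matrix(rowSums(A), ncol = 1L), a$id, function(g) {
    list(matrix(g, nrow(g), nc))
  })
}

agSum <- function(a) {
  A <- agValue(a)
  dims <- dim(A)
  .agPush(a$tape, matrix(sum(A), 1L, 1L), a$id, function(g) {
    list(matrix(g[1L], dims[1L], dims[2L]))
  })
}

agMean <- function(a) {
  A <- agValue(a)
  dims <- dim(A)
  n <- length(A)
  .agPush(a$tape, matrix(mean(A), 1L, 1L), a$id, function(g) {
    list(matrix(g[1L] / n, dims[1L], dims[2L]))
  })
}

agMeanRows <- function(a) {
  A <- agValue(a)
  m <- nrow(A)
  .agPush(a$tape, matrix(colMeans(A), 1L), a$id, function(g) {
    list(matrix(g / m, m, ncol(A), byrow = TRUE))
  })
}

agRbind <- function(a, b) {
  A <- agValue(a); B <- agValue(b)
  na <- nrow(A)
  .agPush(a$tape, rbind(A, B), c(a$id, b$id), function(g) {
    list(g[seq_len(na), , drop = FALSE], g[-seq_len(na), , drop = FALSE])
  })
}

agCbind <- function(a, b) {
  A <- agValue(a); B <- agValue(b)
  na <- ncol(A)
  .agPush(a$tape, cbind(A, B), c(a$id, b$id), function(g) {
    list(g[, seq_len(na), drop = FALSE], g[, -seq_len(na), drop = FALSE])
  })
}

agRows <- function(a, idx) {
  A <- agValue(a)
  dims <- dim(A)
  .agPush(a$tape, A[idx, , drop = FALSE], a$id, function(g) {
    out <- matrix(0, dims[1L], dims[2L])
    for (r in seq_along(idx)) {
      out[idx[r], ] <- out[idx[r], ] + g[r, ]
    }
    list(out)
  })
}

# entry (i, j[i]) for each row -> column vector
agPick <- function(a, j) {
  A <- agValue(a)
  dims <- dim(A)
  sel <- cbind(seq_len(dims[1L]), j)
  .agPush(a$tape, matrix(A[sel], ncol = 1L), a$id, function(g) {
    out <- matrix(0, dims[1L], dims[2L])
    out[sel] <- g
    list(out)
  })
}

# row-wise layer normalization with learnable gain/bias (1 x d nodes)
agLayerNormRows <- function(a, gamma, beta, eps = 1e-5) {
  A <- agValue(a)
  G <- agValue(gamma); B <- agValue(beta)
  d <- ncol(A)
  mu <- rowMeans(A)
  xc <- A - mu
  va <- rowMeans(xc * xc)
  sd <- sqrt(va + eps)
  xhat <- xc / sd
  val <- sweep(xhat, 2L, G[1L, ], "*")
  val <- sweep(val, 2L, B[1L, ], "+")
  .agPush(a$tape, val, c(a$id, gamma$id, beta$id), function(g) {
    dgamma <- matrix(colSums(g * xhat), 1L)
    dbeta <- matrix(colSums(g), 1L)
    dxhat <- sweep(g, 2L, G[1L, ], "*")
    t1 <- rowSums(dxhat)
    t2 <- rowSums(dxhat * xhat)
    dx <- (dxhat - t1 / d - xhat * t2 / d) / sd
    list(dx, dgamma, dbeta)
  })
}

# inverted dropout; identity in evaluation mode
agDropout <- function(a, rate, train) {
  if (!train || rate <= 0) return(a)
  A <- agValue(a)
  mask <- matrix((stats::runif(length(A)) >= rate) / (1 - rate),
                 nrow(A), ncol(A))
  .agPush(a$tape, A * mask, a$id, function(g) list(g * mask))
}

# Backpropagate from a scalar loss node; returns named list of gradients for
# every registered leaf (zeros for leaves the loss does not depend on).
agBackward <- function(loss) {
  tape <- loss$tape
  stopifnot(all(dim(agValue(loss)) == c(1L, 1L)))
  grads <- vector("list", tape$n)
  grads[[loss$id]] <- matrix(1, 1L, 1L)
  for (i in rev(seq_len(loss$id))) {
    g <- grads[[i]]
    if (is.null(g)) next
    bw <- tape$bw[[i]]
    if (is.null(bw)) next
    pg <- bw(g)
    ps <- tape$parents[[i]]
    for (k in seq_along(ps)) {
      j <- ps[k]
      if (is.null(grads[[j]])) grads[[j]] <- pg[[k]] else {
        grads[[j]] <- grads[[j]] + pg[[k]]
      }
    }
  }
  out <- list()
  for (nm in names(tape$leaves)) {
    id <- tape$leaves[[nm]]
    g <- grads[[id]]
    if (is.null(g)) g <- matrix(0, nrow(tape$vals[[id]]), ncol(tape$vals[[id]]))
    out[[nm]] <- g
  }
  out
}

# ---- Adam optimizer over a named list of parameter matrices ----------------

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
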