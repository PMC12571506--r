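# Minimal neural-network primitives: activations, grouped softmax
# helpers, a recursive Adam optimizer over nested parameter lists.
# Gradients throughout the package are analytic and are verified against
# finite differences in the test suite.

leakyRelu <- function(x, slope = 0.2) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  x
}

leakyReluGrad <- function(x, slope = 0.2) {
  g <- array(1, dim = dim(x) %||% length(x))
  g[x < 0] <- slope
  g
}

eluFun <- function(x) {
  neg <- x < 0
  x[neg] <- exp(x[neg]) - 1
  x
}

eluGrad <- function(x) {
  g <- array(1, dim = dim(x) %||% length(x))
  neg <- x < 0
  g[neg] <- exp(x[neg])
  g
}

sigmoidFun <- function(x) stats::plogis(x)

# numerically stable mean binary cross-entropy on logits
bceWithLogits <- function(logits, y) {
  sp <- pmax(logits, 0) + log1p(exp(-abs(logits)))
  mean(sp - y * logits)
}

bceGrad <- function(logits, y) {
  (stats::plogis(logits) - y) / length(logits)
}

# sum of v over groups g, returned as a length-n vector (zeros for
# groups not present); v may be a vector or a matrix (row groups)
groupSum <- function(v, g, n) {
  r <- rowsum(v, g)
  idx <- as.integer(rownames(r))
  if (is.matrix(v)) {
    out <- matrix(0, n, ncol(v))
    out[idx, ] <- r
  } else {
    out <- numeric(n)
    out[idx] <- r
  }
  out
}

groupMax <- function(v, g, n) {
  t <- tapply(v, g, max)
  out <- rep(-Inf, n)
  out[as.integer(names(t))] <- t
  out
}

# affine layer
denseForward <- function(x, W, b) sweep(x %*% W, 2L, b, `+`)

denseBackward <- function(x, W, dOut) {
  list(dX = dOut %*% t(W), dW = crossprod(x, dOut), db = colSums(dOut))
}

# Glorot-uniform initialization
glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

glorotVec <- function(d) {
  lim <- sqrt(6 / (d + 1))
  runif(d, -lim, lim)
}

# ---- Adam over nested lists of numeric arrays ----

adamInit <- function(params) {
  zeroLike <- function(p) {
    if (is.list(p)) lapply(p, zeroLike) else p * 0
  }
  list(m = zeroLike(params), v = zeroLike(params), t = 0L)
}

adamStep <- function(params, grads, state, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      nm <- names(p)
      byName <- !is.null(nm) && all(nzchar(nm))
      for (k in if (byName) nm else seq_along(p)) {
        gk <- g[[k]]
        if (is.null(gk)) next  # tower not touched this step
        res <- walk(p[[k]], gk, m[[k]], v[[k]])
        p[[k]] <- res$p; m[[k]] <- res$m; v[[k]] <- res$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    p <- p - lr * mhat / (sqrt(vhat) + eps)
    list(p = p, m = m, v = v)
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = t))
}

# elementwise sum of two parameter/gradient trees
gradAdd <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) return(mapply(gradAdd, a, b, SIMPLIFY = FALSE))
  a + b
}
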