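# Graph attention layer (additive attention): per head h and edge j -> i,
#   e_ij = leaky_relu(a1 . W x_i + a2 . W x_j)
#   alpha_ij = softmax over j in N(i) u {i}
#   out_i = sum_j alpha_ij W x_j
# Heads are concatenated (layer 1) or single (layer 2); a per-layer bias
# is added after concatenation. Self-loops must be present in `edges`.
# Implemented edge-list sparse; a dense per-node reference used in tests.

#' @importFrom Matrix sparseMatrix
NULL

addSelfLoops <- function(edges, n) {
  list(dst = c(edges$dst, seq_len(n)), src = c(edges$src, seq_len(n)))
}

# layerParams: list(heads = list(list(W, a1, a2), ...), bias)
gatForward <- function(X, edges, layerParams, slope = 0.2) {
  n <- nrow(X)
  dst <- edges$dst; src <- edges$src
  heads <- layerParams$heads
  outs <- vector("list", length(heads))
  caches <- vector("list", length(heads))
  for (h in seq_along(heads)) {
    hp <- heads[[h]]
    H <- X %*% hp$W
    c1 <- drop(H %*% hp$a1)
    c2 <- drop(H %*% hp$a2)
    eRaw <- c1[dst] + c2[src]
    e <- leakyRelu(eRaw, slope)
    mx <- groupMax(e, dst, n)
    ex <- exp(e - mx[dst])
    den <- groupSum(ex, dst, n)
    alpha <- ex / den[dst]
    A <- sparseMatrix(i = dst, j = src, x = alpha, dims = c(n, n))
    outs[[h]] <- as.matrix(A %*% H)
    caches[[h]] <- list(H = H, eRaw = eRaw, alpha = alpha, A = A)
  }
  out <- do.call(cbind, outs)
  out <- sweep(out, 2L, layerParams$bias, `+`)
  list(out = out, cache = list(X = X, edges = edges, heads = caches,
                               slope = slope))
}

gatBackward <- function(layerParams, cache, dOut) {
  X <- cache$X
  dst <- cache$edges$dst; src <- cache$edges$src
  n <- nrow(X)
  slope <- cache$slope
  dX <- matrix(0, n, ncol(X))
  headGrads <- vector("list", length(layerParams$heads))
  dHead <- ncol(dOut) / length(layerParams$heads)
  for (h in seq_along(layerParams$heads)) {
    hp <- layerParams$heads[[h]]
    ch <- cache$heads[[h]]
    cols <- ((h - 1L) * dHead + 1L):(h * dHead)
    dO <- dOut[, cols, drop = FALSE]
    H <- ch$H; alpha <- ch$alpha; eRaw <- ch$eRaw; A <- ch$A
    dH <- as.matrix(Matrix::crossprod(A, dO))
    dalpha <- rowSums(dO[dst, , drop = FALSE] * H[src, , drop = FALSE])
    sg <- groupSum(alpha * dalpha, dst, n)
    de <- alpha * (dalpha - sg[dst])
    deRaw <- de * ifelse(eRaw > 0, 1, slope)
    dc1 <- groupSum(deRaw, dst, n)
    dc2 <- groupSum(deRaw, src, n)
    dH <- dH + outer(dc1, hp$a1) + outer(dc2, hp$a2)
    da1 <- drop(crossprod(H, dc1))
    da2 <- drop(crossprod(H, dc2))
    dW <- crossprod(X, dH)
    dX <- dX + dH %*% t(hp$W)
    headGrads[[h]] <- list(W = dW, a1 = da1, a2 = da2)
  }
  list(dX = dX, grads = list(heads = headGrads, bias = colSums(dOut)))
}

# dense reference implementation used as an independent oracle in tests:
# materializes the full attention matrix with explicit per-node loops
gatForwardDense <- function(X, edges, layerParams, slope = 0.2) {
  n <- nrow(X)
  nbrs <- lapply(seq_len(n), function(i)
    sort(unique(c(i, edges$src[edges$dst == i]))))
  outs <- lapply(layerParams$heads, function(hp) {
    H <- X %*% hp$W
    out <- matrix(0, n, ncol(H))
    for (i in seq_len(n)) {
      js <- nbrs[[i]]
      e <- vapply(js, function(j) {
        v <- sum(hp$a1 * H[i, ]) + sum(hp$a2 * H[j, ])
        if (v < 0) slope * v else v
      }, numeric(1L))
      a <- exp(e - max(e)); a <- a / sum(a)
      for (k in seq_along(js)) out[i, ] <- out[i, ] + a[k] * H[js[k], ]
    }
    out
  })
  sweep(do.call(cbind, outs), 2L, layerParams$bias, `+`)
}

# two-layer GAT tower: ELU between layers, linear output before fusion
gatTowerForward <- function(X, edges, params, slope = 0.2) {
  l1 <- gatForward(X, edges, params$gat1, slope)
  a1 <- eluFun(l1$out)
  l2 <- gatForward(a1, edges, params$gat2, slope)
  list(out = l2$out,
       cache = list(l1 = l1, a1pre = l1$out, l2 = l2))
}

gatTowerBackward <- function(params, cache, dOut) {
  b2 <- gatBackward(params$gat2, cache$l2$cache, dOut)
  dA1 <- b2$dX * eluGrad(cache$a1pre)
  b1 <- gatBackward(params$gat1, cache$l1$cache, dA1)
  list(dX = b1$dX, grads = list(gat1 = b1$grads, gat2 = b2$grads))
}
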