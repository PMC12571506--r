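# The multimodal classifier: a two-layer GAT tower over the protein
# family network, a three-layer signature encoder, and a fusion MLP with
# per-term sigmoid outputs. Five ablation modes share one forward pass:
#   LLM      embeddings -> fusion MLP
#   BPV      signature encoder -> fusion MLP
#   BPV_GNN  GAT run with binary signature rows as node features
#   LLM_BPV  concat(raw embedding, encoded signatures) -> fusion MLP
#   FULL     concat(GAT(embeddings), encoded signatures) -> fusion MLP

.MODEL_MODES <- c("LLM", "BPV", "BPV_GNN", "LLM_BPV", "FULL")

#' Model configuration
#'
#' Architecture settings for the multimodal protein function classifier.
#' Defaults follow the published architecture: three attention heads with
#' hidden width 128 in the first GAT layer, a single 512-wide head in the
#' second, a three-layer LeakyReLU signature encoder reducing to 512, and
#' LeakyReLU attention slope 0.2. `mode` selects which towers are active.
#'
#' @param mode one of `"LLM"`, `"BPV"`, `"BPV_GNN"`, `"LLM_BPV"`, `"FULL"`.
#' @param inputDim width of the embedding vectors (1536 for the usual
#'   protein language-model provider).
#' @param vocabSize width of the binary signature vectors (training
#'   vocabulary size).
#' @param nLabels number of GO term labels (one namespace).
#' @param gatHeads attention heads in GAT layer 1 (default 3).
#' @param gatHidden per-head hidden width of GAT layer 1 (default 128).
#' @param gatOut output width of the single-head GAT layer 2 (default 512).
#' @param sigLatent output width of the signature encoder (default 512).
#' @param fusionHidden hidden width of the fusion MLP (default 1024).
#' @param attentionSlope LeakyReLU slope inside attention (default 0.2).
#' @param dropout dropout rate on the fusion hidden layer during training
#'   (default 0.2).
#' @param seed integer seed keying parameter initialization.
#' @return A validated list of class `"ModelConfig"`.
#' @export
modelConfig <- function(mode = "FULL", inputDim = 1536L, vocabSize = 1L,
                        nLabels = 1L, gatHeads = 3L, gatHidden = 128L,
                        gatOut = 512L, sigLatent = 512L,
                        fusionHidden = 1024L, attentionSlope = 0.2,
                        dropout = 0.2, seed = 1L) {
  if (!mode %in% .MODEL_MODES)
    stopf("mode must be one of %s", paste(.MODEL_MODES, collapse = ", "))
  dims <- c(inputDim = inputDim, vocabSize = vocabSize, nLabels = nLabels,
            gatHeads = gatHeads, gatHidden = gatHidden, gatOut = gatOut,
            sigLatent = sigLatent, fusionHidden = fusionHidden)
  if (any(dims < 1L)) stopf("all dimensions must be >= 1")
  if (dropout < 0 || dropout >= 1) stopf("dropout must be in [0, 1)")
  structure(list(mode = mode, inputDim = as.integer(inputDim),
                 vocabSize = as.integer(vocabSize),
                 nLabels = as.integer(nLabels),
                 gatHeads = as.integer(gatHeads),
                 gatHidden = as.integer(gatHidden),
                 gatOut = as.integer(gatOut),
                 sigLatent = as.integer(sigLatent),
                 fusionHidden = as.integer(fusionHidden),
                 attentionSlope = attentionSlope, dropout = dropout,
                 seed = as.integer(seed)),
            class = "ModelConfig")
}

#' @export
print.ModelConfig <- function(x, ...) {
  cat(sprintf(
    "ModelConfig [%s] input=%d vocab=%d labels=%d gat=%dx%d->%d sig->%d fusion=%d\n",
    x$mode, x$inputDim, x$vocabSize, x$nLabels, x$gatHeads, x$gatHidden,
    x$gatOut, x$sigLatent, x$fusionHidden))
  invisible(x)
}

# which towers a mode needs
.modeUsesGraph <- function(mode) mode %in% c("FULL", "BPV_GNN")
.modeUsesSig <- function(mode) mode %in% c("BPV", "LLM_BPV", "FULL")
.modeUsesEmb <- function(mode) mode %in% c("LLM", "LLM_BPV", "FULL")

# width of the fusion MLP input per mode
.fusionInDim <- function(config) {
  switch(config$mode,
    FULL = config$gatOut + config$sigLatent,
    LLM = config$inputDim,
    BPV = config$sigLatent,
    BPV_GNN = config$gatOut,
    LLM_BPV = config$inputDim + config$sigLatent)
}

# intermediate widths of the 3-layer signature encoder: geometric
# interpolation from the vocabulary size down to sigLatent
.sigDims <- function(vocabSize, sigLatent) {
  d0 <- max(vocabSize, 1L); d3 <- sigLatent
  d1 <- max(round(d0^(2 / 3) * d3^(1 / 3)), d3)
  d2 <- max(round(d0^(1 / 3) * d3^(2 / 3)), d3)
  c(d0, d1, d2, d3)
}

#' Initialize model parameters
#'
#' Variance-scaled (Glorot) uniform initialization, deterministic given
#' `config$seed`.
#'
#' @param config a [modelConfig()] object.
#' @return Nested list of weight matrices and bias vectors.
#' @export
initModelParams <- function(config) {
  withSeed(config$seed, {
    params <- list()
    gatIn <- if (config$mode == "BPV_GNN") config$vocabSize else config$inputDim
    if (.modeUsesGraph(config$mode)) {
      params$gat1 <- list(
        heads = lapply(seq_len(config$gatHeads), function(h)
          list(W = glorot(gatIn, config$gatHidden),
               a1 = glorotVec(config$gatHidden),
               a2 = glorotVec(config$gatHidden))),
        bias = numeric(config$gatHeads * config$gatHidden))
      params$gat2 <- list(
        heads = list(list(
          W = glorot(config$gatHeads * config$gatHidden, config$gatOut),
          a1 = glorotVec(config$gatOut),
          a2 = glorotVec(config$gatOut))),
        bias = numeric(config$gatOut))
    }
    if (.modeUsesSig(config$mode)) {
      d <- .sigDims(config$vocabSize, config$sigLatent)
      params$sig <- list(
        W1 = glorot(d[1L], d[2L]), b1 = numeric(d[2L]),
        W2 = glorot(d[2L], d[3L]), b2 = numeric(d[3L]),
        W3 = glorot(d[3L], d[4L]), b3 = numeric(d[4L]))
    }
    fin <- .fusionInDim(config)
    params$head <- list(
      W1 = glorot(fin, config$fusionHidden),
      b1 = numeric(config$fusionHidden),
      W2 = glorot(config$fusionHidden, config$nLabels),
      b2 = numeric(config$nLabels))
    params
  })
}

# signature encoder: three affine layers, LeakyReLU after the first two
sigEncForward <- function(rows, sig, slope = 0.2) {
  z1 <- denseForward(rows, sig$W1, sig$b1); a1 <- leakyRelu(z1, slope)
  z2 <- denseForward(a1, sig$W2, sig$b2); a2 <- leakyRelu(z2, slope)
  z3 <- denseForward(a2, sig$W3, sig$b3)
  list(out = z3, cache = list(rows = rows, z1 = z1, a1 = a1, z2 = z2,
                              a2 = a2, slope = slope))
}

sigEncBackward <- function(sig, cache, dOut) {
  s <- cache$slope
  b3 <- denseBackward(cache$a2, sig$W3, dOut)
  d2 <- b3$dX * leakyReluGrad(cache$z2, s)
  b2 <- denseBackward(cache$a1, sig$W2, d2)
  d1 <- b2$dX * leakyReluGrad(cache$z1, s)
  b1 <- denseBackward(cache$rows, sig$W1, d1)
  list(dRows = b1$dX,
       grads = list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db,
                    W3 = b3$dW, b3 = b3$db))
}

#' Forward pass of the multimodal classifier
#'
#' @param params parameters from [initModelParams()] (or trained).
#' @param config a [modelConfig()].
#' @param batch list with components as required by `config$mode`:
#'   `edges` (list of integer vectors `dst`, `src`, indices into the node
#'   universe, self-loops added internally), `nodeFeatures` (universe x
#'   input matrix for the GAT tower), `seedIdx` (rows of the universe that
#'   are scored), `sigRows` (seeds x vocabulary binary matrix), `embRows`
#'   (seeds x inputDim embedding matrix).
#' @param training if TRUE, dropout is applied on the fusion hidden layer.
#' @param zeroGraphTower diagnostic switch: if TRUE the GAT tower output
#'   is replaced by zeros before fusion (used to verify ablation nesting).
#' @return list with `scores` (sigmoid, in \[0,1\]), `logits` and `cache`.
#' @export
modelForward <- function(params, config, batch, training = FALSE,
                         zeroGraphTower = FALSE) {
  mode <- config$mode
  cache <- list(mode = mode)
  pieces <- list()
  if (.modeUsesGraph(mode)) {
    if (is.null(batch$nodeFeatures) || is.null(batch$edges) ||
        is.null(batch$seedIdx))
      stopf("mode %s requires nodeFeatures, edges and seedIdx", mode)
    n <- nrow(batch$nodeFeatures)
    edges <- addSelfLoops(batch$edges, n)
    tw <- gatTowerForward(batch$nodeFeatures, edges, params,
                          config$attentionSlope)
    G <- tw$out[batch$seedIdx, , drop = FALSE]
    if (zeroGraphTower) G <- G * 0
    cache$gat <- tw$cache
    cache$seedIdx <- batch$seedIdx
    cache$nUniverse <- n
    cache$zeroGraph <- zeroGraphTower
    pieces$G <- G
  }
  if (.modeUsesSig(mode)) {
    if (is.null(batch$sigRows)) stopf("mode %s requires sigRows", mode)
    if (ncol(batch$sigRows) != config$vocabSize)
      stopf("signature row width %d != vocabulary size %d",
            ncol(batch$sigRows), config$vocabSize)
    se <- sigEncForward(batch$sigRows, params$sig, config$attentionSlope)
    cache$sig <- se$cache
    pieces$S <- se$out
  }
  if (mode %in% c("LLM", "LLM_BPV")) {
    if (is.null(batch$embRows)) stopf("mode %s requires embRows", mode)
    if (ncol(batch$embRows) != config$inputDim)
      stopf("embedding width %d != inputDim %d",
            ncol(batch$embRows), config$inputDim)
    pieces$E <- batch$embRows
  }
  Z <- switch(mode,
    FULL = cbind(pieces$G, pieces$S),
    LLM = pieces$E,
    BPV = pieces$S,
    BPV_GNN = pieces$G,
    LLM_BPV = cbind(pieces$E, pieces$S))
  z1 <- denseForward(Z, params$head$W1, params$head$b1)
  a1 <- leakyRelu(z1, config$attentionSlope)
  if (training && config$dropout > 0) {
    keep <- 1 - config$dropout
    mask <- matrix(runif(length(a1)) < keep, nrow(a1)) / keep
    a1 <- a1 * mask
    cache$dropMask <- mask
  }
  logits <- denseForward(a1, params$head$W2, params$head$b2)
  cache$Z <- Z; cache$z1 <- z1; cache$a1 <- a1
  list(scores = sigmoidFun(logits), logits = logits, cache = cache)
}

# backward pass: returns gradient tree matching params
modelBackward <- function(params, config, cache, dLogits) {
  grads <- list()
  bh2 <- denseBackward(cache$a1, params$head$W2, dLogits)
  dA1 <- bh2$dX
  if (!is.null(cache$dropMask)) dA1 <- dA1 * cache$dropMask
  dZ1 <- dA1 * leakyReluGrad(cache$z1, config$attentionSlope)
  bh1 <- denseBackward(cache$Z, params$head$W1, dZ1)
  grads$head <- list(W1 = bh1$dW, b1 = bh1$db, W2 = bh2$dW, b2 = bh2$db)
  dZ <- bh1$dX
  mode <- cache$mode
  dG <- dS <- NULL
  if (mode == "FULL") {
    gw <- config$gatOut
    dG <- dZ[, seq_len(gw), drop = FALSE]
    dS <- dZ[, (gw + 1L):ncol(dZ), drop = FALSE]
  } else if (mode == "BPV_GNN") dG <- dZ
  else if (mode == "BPV") dS <- dZ
  else if (mode == "LLM_BPV")
    dS <- dZ[, (config$inputDim + 1L):ncol(dZ), drop = FALSE]
  if (!is.null(dS)) {
    bs <- sigEncBackward(params$sig, cache$sig, dS)
    grads$sig <- bs$grads
  }
  if (!is.null(dG)) {
    if (isTRUE(cache$zeroGraph)) dG <- dG * 0
    dOutFull <- matrix(0, cache$nUniverse, ncol(dG))
    dOutFull[cache$seedIdx, ] <- dG
    bt <- gatTowerBackward(params, cache$gat, dOutFull)
    grads$gat1 <- bt$grads$gat1
    grads$gat2 <- bt$grads$gat2
  }
  grads
}
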