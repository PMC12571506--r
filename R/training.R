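# Per-subontology supervised training: two-hop neighborhood sampling on
# the PFN, Adam with a reduce-on-plateau learning-rate scheduler, early
# stopping on validation loss, best-checkpoint return, seeded multi-run
# summaries.

#' Optimizer / loop settings
#'
#' @param lr initial Adam learning rate (default 1e-3).
#' @param maxEpochs epoch cap (default 100).
#' @param batchSize seed proteins per minibatch (default 64).
#' @param fanouts two-element integer vector: neighbors sampled per node
#'   at hop 1 and hop 2; the second hop draws a smaller subset, so
#'   `fanouts[1] >= fanouts[2]` is enforced (default c(25, 10)).
#' @param patience early-stopping patience in epochs (default 5).
#' @param schedulerFactor multiplicative LR decay on plateau (default 0.5).
#' @param schedulerPatience epochs without improvement before decay
#'   (default 2).
#' @param monitor `"loss"` (validation loss, default) or `"fmax"`
#'   (validation Fmax; requires labels aligned with a DAG-free grid).
#' @param allowFanoutOverride set TRUE to permit fanouts[1] < fanouts[2].
#' @return list of class `"OptSettings"`.
#' @export
optSettings <- function(lr = 1e-3, maxEpochs = 100L, batchSize = 64L,
                        fanouts = c(25L, 10L), patience = 5L,
                        schedulerFactor = 0.5, schedulerPatience = 2L,
                        monitor = c("loss", "fmax"),
                        allowFanoutOverride = FALSE) {
  monitor <- match.arg(monitor)
  if (length(fanouts) != 2L)
    stopf("fanouts must have exactly two entries")
  if (any(fanouts < 1L)) stopf("fanouts must be >= 1")
  if (fanouts[1L] < fanouts[2L] && !allowFanoutOverride)
    stopf("fanouts[1] must be >= fanouts[2] (second hop is a smaller subset)")
  structure(list(lr = lr, maxEpochs = as.integer(maxEpochs),
                 batchSize = as.integer(batchSize),
                 fanouts = as.integer(fanouts),
                 patience = as.integer(patience),
                 schedulerFactor = schedulerFactor,
                 schedulerPatience = as.integer(schedulerPatience),
                 monitor = monitor),
            class = "OptSettings")
}

#' Sample a two-hop neighborhood around seed nodes
#'
#' Uniform sampling without replacement, per node per hop: up to
#' `fanouts[1]` neighbors of each seed, then up to `fanouts[2]` neighbors
#' of each sampled first-hop node. When a node's degree does not exceed
#' the fanout, all its neighbors are taken. Deterministic given `rngSeed`.
#'
#' @param pfn a [ProteinFamilyNetwork-class].
#' @param seeds character vector of seed accessions (must be nodes).
#' @param fanouts two-element integer vector, `fanouts[1] >= fanouts[2]`.
#' @param rngSeed integer seed.
#' @param allowFanoutOverride permit increasing fanouts (see [optSettings()]).
#' @return list with `seedNodes`, `layerEdges` (list of per-hop
#'   data.frames with columns dst, src as accessions), `nodeUniverse`.
#' @export
sampleNeighborhood <- function(pfn, seeds, fanouts = c(25L, 10L),
                               rngSeed = 1L, allowFanoutOverride = FALSE) {
  if (length(fanouts) != 2L || any(fanouts < 1L))
    stopf("fanouts must be two integers >= 1")
  if (fanouts[1L] < fanouts[2L] && !allowFanoutOverride)
    stopf("fanouts[1] must be >= fanouts[2] (second hop is a smaller subset)")
  bad <- setdiff(seeds, pfn@nodes)
  if (length(bad))
    stopf("seeds not in graph: %s", paste(head(bad, 5L), collapse = ", "))
  adj <- .adjacencyList(pfn)
  sIdx <- match(seeds, pfn@nodes)
  withSeed(rngSeed, {
    hop <- function(targets, fan) {
      dst <- integer(); src <- integer()
      for (t in targets) {
        nb <- adj[[t]]
        if (!length(nb)) next
        pick <- if (length(nb) <= fan) nb else sample(nb, fan)
        dst <- c(dst, rep.int(t, length(pick)))
        src <- c(src, pick)
      }
      list(dst = dst, src = src)
    }
    h1 <- hop(sIdx, fanouts[1L])
    frontier <- unique(c(sIdx, h1$src))
    h2 <- hop(frontier, fanouts[2L])
    universe <- unique(c(sIdx, h1$src, h2$src, h2$dst))
    nm <- pfn@nodes
    list(
      seedNodes = seeds,
      layerEdges = list(
        data.frame(dst = nm[h1$dst], src = nm[h1$src],
                   stringsAsFactors = FALSE),
        data.frame(dst = nm[h2$dst], src = nm[h2$src],
                   stringsAsFactors = FALSE)),
      nodeUniverse = nm[universe])
  })
}

# convert a sampled subgraph into the integer edge structure used by the
# model (indices into nodeUniverse; both hops merged, deduplicated)
.subgraphBatchEdges <- function(sub) {
  uni <- sub$nodeUniverse
  dst <- c(sub$layerEdges[[1L]]$dst, sub$layerEdges[[2L]]$dst)
  src <- c(sub$layerEdges[[1L]]$src, sub$layerEdges[[2L]]$src)
  key <- !duplicated(paste(dst, src))
  list(dst = match(dst[key], uni), src = match(src[key], uni))
}

# full (un-sampled) directed edge structure for inference: every stored
# undirected edge in both directions, indices into pfn nodes
.fullEdges <- function(pfn) {
  if (!nrow(pfn@edges)) return(list(dst = integer(), src = integer()))
  i <- match(pfn@edges[, 1L], pfn@nodes)
  j <- match(pfn@edges[, 2L], pfn@nodes)
  list(dst = c(i, j), src = c(j, i))
}

# binary target matrix: proteins x labels
.targetMatrix <- function(ann, proteinIds, labelIds) {
  y <- matrix(0, length(proteinIds), length(labelIds),
              dimnames = list(proteinIds, labelIds))
  for (i in seq_along(proteinIds)) {
    ts <- intersect(ann@annotations[[proteinIds[i]]], labelIds)
    if (length(ts)) y[i, match(ts, labelIds)] <- 1
  }
  y
}

# one early-stopping / scheduler bookkeeping step; pure so the halting
# arithmetic is testable in isolation. Lower monitored value = better.
earlyStopUpdate <- function(state, value, opt) {
  improved <- value < state$best - 1e-12
  if (improved) {
    state$best <- value
    state$bestEpoch <- state$epoch
    state$sinceImprove <- 0L
    state$sinceSched <- 0L
  } else {
    state$sinceImprove <- state$sinceImprove + 1L
    state$sinceSched <- state$sinceSched + 1L
    if (state$sinceSched >= opt$schedulerPatience) {
      state$lr <- state$lr * opt$schedulerFactor
      state$sinceSched <- 0L
    }
  }
  state$halt <- state$sinceImprove >= opt$patience
  state
}

#' Train the multimodal classifier on one namespace
#'
#' Minimizes mean per-label binary cross-entropy on the training proteins
#' with Adam; minibatches use sampled two-hop neighborhoods in the graph
#' modes. After every epoch the validation loss (or Fmax) is monitored:
#' the learning rate halves after `schedulerPatience` epochs without
#' improvement and training stops after `patience` epochs without
#' improvement, returning the best-validation parameters.
#'
#' @param data list with components `pfn` ([ProteinFamilyNetwork-class]),
#'   `embeddings` ([EmbeddingMatrix-class]), `binary` (protein x
#'   vocabulary 0/1 matrix with rownames), `labels` (character vector of
#'   term labels), `annotations` (propagated [AnnotationSet-class]),
#'   `splits` (named character vector protein -> train/valid/test).
#' @param config a [modelConfig()].
#' @param opt an [optSettings()].
#' @param seed integer seed for sampling, dropout and shuffling.
#' @param quiet suppress per-epoch messages (default TRUE).
#' @return list with `params` (best checkpoint), `state` (final train
#'   state), `history` (per-epoch data.frame), `config`, `labels`.
#' @export
trainModel <- function(data, config, opt = optSettings(), seed = 1L,
                       quiet = TRUE) {
  trainIds <- names(data$splits)[data$splits == "train"]
  validIds <- names(data$splits)[data$splits == "valid"]
  if (!length(trainIds) || !length(validIds))
    stopf("empty train or validation split")
  # the data are authoritative for the interface widths
  config$vocabSize <- ncol(data$binary)
  config$nLabels <- length(data$labels)
  if (!is.null(data$embeddings))
    config$inputDim <- ncol(data$embeddings@values)
  labelIds <- data$labels
  yTrain <- .targetMatrix(data$annotations, trainIds, labelIds)
  yValid <- .targetMatrix(data$annotations, validIds, labelIds)
  useGraph <- .modeUsesGraph(config$mode)
  embVals <- if (!is.null(data$embeddings)) data$embeddings@values else NULL
  binVals <- data$binary
  nodeFeat <- NULL
  if (useGraph)
    nodeFeat <- if (config$mode == "BPV_GNN") binVals else embVals

  params <- initModelParams(config)
  adam <- adamInit(params)
  state <- list(epoch = 0L, best = Inf, bestEpoch = 0L, sinceImprove = 0L,
                sinceSched = 0L, lr = opt$lr, halt = FALSE, seed = seed)
  bestParams <- params
  hist <- list()

  evalSplit <- function(p, ids, y) {
    batch <- .inferenceBatch(config, data, ids, nodeFeat)
    fw <- modelForward(p, config, batch, training = FALSE)
    bceWithLogits(fw$logits, y)
  }

  withSeed(seed, {
    for (epoch in seq_len(opt$maxEpochs)) {
      state$epoch <- epoch
      ord <- sample(trainIds)
      nb <- ceiling(length(ord) / opt$batchSize)
      epochLoss <- 0
      for (b in seq_len(nb)) {
        ids <- ord[((b - 1L) * opt$batchSize + 1L):min(b * opt$batchSize,
                                                       length(ord))]
        if (useGraph) {
          sub <- sampleNeighborhood(data$pfn, ids, opt$fanouts,
                                    rngSeed = sample.int(2^30, 1L))
          uni <- sub$nodeUniverse
          batch <- list(
            edges = .subgraphBatchEdges(sub),
            nodeFeatures = nodeFeat[uni, , drop = FALSE],
            seedIdx = match(ids, uni))
        } else {
          batch <- list()
        }
        if (.modeUsesSig(config$mode))
          batch$sigRows <- binVals[ids, , drop = FALSE]
        if (config$mode %in% c("LLM", "LLM_BPV"))
          batch$embRows <- embVals[ids, , drop = FALSE]
        fw <- modelForward(params, config, batch, training = TRUE)
        y <- yTrain[ids, , drop = FALSE]
        loss <- bceWithLogits(fw$logits, y)
        if (!is.finite(loss)) stopf("non-finite training loss at epoch %d", epoch)
        grads <- modelBackward(params, config, fw$cache, bceGrad(fw$logits, y))
        upd <- adamStep(params, grads, adam, state$lr)
        params <- upd$params
        adam <- upd$state
        epochLoss <- epochLoss + loss * length(ids)
      }
      epochLoss <- epochLoss / length(trainIds)
      valLoss <- evalSplit(params, validIds, yValid)
      monitored <- valLoss
      state <- earlyStopUpdate(state, monitored, opt)
      if (state$sinceImprove == 0L) bestParams <- params
      hist[[epoch]] <- data.frame(epoch = epoch, trainLoss = epochLoss,
                                  valLoss = valLoss, lr = state$lr)
      if (!quiet)
        message(sprintf("epoch %3d  train %.5f  valid %.5f  lr %.2e",
                        epoch, epochLoss, valLoss, state$lr))
      if (state$halt) break
    }
  })
  list(params = bestParams, state = state, history = do.call(rbind, hist),
       config = config, labels = labelIds)
}

# assemble a full-neighborhood inference batch for the given proteins
.inferenceBatch <- function(config, data, ids, nodeFeat = NULL) {
  if (is.null(nodeFeat) && .modeUsesGraph(config$mode))
    nodeFeat <- if (config$mode == "BPV_GNN") data$binary
                else data$embeddings@values
  batch <- list()
  if (.modeUsesGraph(config$mode)) {
    pfn <- data$pfn
    batch$edges <- .fullEdges(pfn)
    batch$nodeFeatures <- nodeFeat[pfn@nodes, , drop = FALSE]
    batch$seedIdx <- match(ids, pfn@nodes)
    if (anyNA(batch$seedIdx))
      stopf("proteins missing from the network: %s",
            paste(head(ids[is.na(batch$seedIdx)], 5L), collapse = ", "))
  }
  if (.modeUsesSig(config$mode))
    batch$sigRows <- data$binary[ids, , drop = FALSE]
  if (config$mode %in% c("LLM", "LLM_BPV"))
    batch$embRows <- data$embeddings@values[ids, , drop = FALSE]
  batch
}

#' Predict term scores for proteins
#'
#' Deterministic inference pass: graph modes use the full (un-sampled)
#' neighborhood structure and dropout is disabled, so repeated calls give
#' identical matrices.
#'
#' @param fit result of [trainModel()] (or a list with `params`, `config`,
#'   `labels`).
#' @param proteinIds ordered accessions to score.
#' @param data the same data list used for training (or one with the same
#'   vocabulary / network containing the requested proteins).
#' @return A [PredictionMatrix-class].
#' @export
predictScores <- function(fit, proteinIds, data) {
  config <- fit$config
  known <- rownames(data$binary) %||% data$pfn@nodes
  bad <- setdiff(proteinIds, known)
  if (length(bad))
    stopf("unknown proteins: %s", paste(head(bad, 5L), collapse = ", "))
  batch <- .inferenceBatch(config, data, proteinIds)
  fw <- modelForward(fit$params, config, batch, training = FALSE)
  sc <- fw$scores
  dimnames(sc) <- list(proteinIds, fit$labels)
  new("PredictionMatrix", proteins = proteinIds, labels = fit$labels,
      scores = sc)
}

#' Label-prevalence baseline predictor
#'
#' Scores every protein with each label's training-split prevalence; the
#' strongest structure-free baseline for protein-centric Fmax.
#'
#' @param ann propagated [AnnotationSet-class] of the training split.
#' @param trainIds training protein accessions.
#' @param labelIds ordered labels.
#' @param proteinIds proteins to score.
#' @return A [PredictionMatrix-class].
#' @export
prevalenceBaseline <- function(ann, trainIds, labelIds, proteinIds) {
  y <- .targetMatrix(ann, trainIds, labelIds)
  prev <- colMeans(y)
  sc <- matrix(rep(prev, each = length(proteinIds)),
               length(proteinIds), length(labelIds),
               dimnames = list(proteinIds, labelIds))
  new("PredictionMatrix", proteins = proteinIds, labels = labelIds,
      scores = sc)
}

#' Summarize metrics over multiple seeded runs
#'
#' Mean and standard deviation of Fmax, Smin and AUPRC across a list of
#' [EvaluationReport-class] objects, the conventional way multi-seed
#' results are reported.
#'
#' @param reports list of [EvaluationReport-class].
#' @return data.frame with one row per metric: mean, sd, n runs.
#' @export
summarizeRuns <- function(reports) {
  g <- function(f) vapply(reports, f, numeric(1L))
  m <- rbind(fmax = g(function(r) r@fmax),
             smin = g(function(r) r@smin),
             auprc = g(function(r) r@auprc))
  data.frame(metric = rownames(m),
             mean = rowMeans(m),
             sd = apply(m, 1L, sd),
             runs = length(reports),
             row.names = NULL)
}
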