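# fixture builders shared across test files; everything is generated in
# code, no stored data

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a small OBO file from stanza fields; returns the path
writeTestOBO <- function(stanzas, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("obofix")
    dir.create(dir)
  }
  path <- file.path(dir, "test.obo")
  lines <- c("format-version: 1.2")
  for (st in stanzas) lines <- c(lines, "", "[Term]", st)
  writeLines(lines, path)
  path
}

# two-term chain: B is_a A
chainOBO <- function() {
  writeTestOBO(list(
    c("id: GO:0000001", "name: a", "namespace: molecular_function"),
    c("id: GO:0000002", "name: b", "namespace: molecular_function",
      "is_a: GO:0000001 ! a")))
}

# a propagated AnnotationSet from a plain list
annSet <- function(lst, propagated = FALSE) {
  new("AnnotationSet", annotations = lst,
      evidence = data.frame(protein = character(), term = character(),
                            evidence = character()),
      propagated = propagated)
}

# random catalog: nP proteins, nS signatures, each protein draws 1..maxK
randomCatalog <- function(nP, nS, maxK = 4L, types = c("FAMILY", "DOMAIN",
                                                       "MOTIF")) {
  prot <- sprintf("P%03d", seq_len(nP))
  sigs <- sprintf("S%03d", seq_len(nS))
  pr <- character(); sg <- character()
  for (p in prot) {
    k <- sample.int(maxK, 1L)
    s <- sigs[sample.int(nS, min(k, nS))]
    pr <- c(pr, rep(p, length(s))); sg <- c(sg, s)
  }
  tp <- setNames(sample(types, nS, replace = TRUE), sigs)
  pfnet:::newSignatureCatalog(pr, sg, tp)
}

# small model config for desk-scale tests
tinyConfig <- function(mode = "FULL", inputDim = 8L, vocabSize = 6L,
                       nLabels = 4L, seed = 1L) {
  modelConfig(mode = mode, inputDim = inputDim, vocabSize = vocabSize,
              nLabels = nLabels, gatHeads = 2L, gatHidden = 5L,
              gatOut = 7L, sigLatent = 6L, fusionHidden = 9L,
              dropout = 0, seed = seed)
}

# random batch compatible with tinyConfig on a random graph
tinyBatch <- function(config, nNodes = 6L, nSeeds = 3L, pEdge = 0.5) {
  edges <- list(dst = integer(), src = integer())
  for (i in seq_len(nNodes)) for (j in seq_len(nNodes)) {
    if (i != j && runif(1) < pEdge) {
      edges$dst <- c(edges$dst, i); edges$src <- c(edges$src, j)
    }
  }
  list(edges = edges,
       nodeFeatures = matrix(rnorm(nNodes * config$inputDim), nNodes),
       seedIdx = seq_len(nSeeds),
       sigRows = matrix(rbinom(nSeeds * config$vocabSize, 1L, 0.4), nSeeds),
       embRows = matrix(rnorm(nSeeds * config$inputDim), nSeeds))
}

# the default-conditions synthetic world pipeline, trained FULL model,
# cached so acceptance tests don't recompute it per block
.accCache <- new.env(parent = emptyenv())

acceptanceRuns <- function() {
  if (!is.null(.accCache$runs)) return(.accCache$runs)
  world <- generateWorld(seed = 20260921L)
  data <- worldPipelineData(world)
  cfg <- modelConfig(mode = "FULL", inputDim = 64L, gatHeads = 3L,
                     gatHidden = 32L, gatOut = 64L, sigLatent = 64L,
                     fusionHidden = 128L)
  opt <- optSettings(lr = 3e-3, maxEpochs = 40L)
  res <- multiSeedRun(data, cfg, opt, seeds = 1:5)
  trainIds <- names(data$splits)[data$splits == "train"]
  testIds <- names(data$splits)[data$splits == "test"]
  base <- prevalenceBaseline(subsetAnnotations(data$annotations, trainIds),
                             trainIds, data$labels, testIds)
  baseReport <- evaluatePredictions(
    base, subsetAnnotations(data$annotations, testIds), data$dag, data$ic)
  .accCache$runs <- list(world = world, data = data, config = cfg,
                         opt = opt, res = res, baseReport = baseReport)
  .accCache$runs
}
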