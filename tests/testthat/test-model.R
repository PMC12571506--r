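# graph attention layer and the multimodal forward/backward pass

test_that("sparse attention equals the dense per-node reference", {
  withr::local_seed(21)
  for (rep in 1:5) {
    n <- 5L; din <- 4L
    edges <- list(dst = integer(), src = integer())
    for (i in 1:n) for (j in 1:n)
      if (i != j && runif(1) < 0.5) {
        edges$dst <- c(edges$dst, i); edges$src <- c(edges$src, j)
      }
    edges <- pfnet:::addSelfLoops(edges, n)
    lp <- list(heads = list(
      list(W = matrix(rnorm(din * 3L), din), a1 = rnorm(3L), a2 = rnorm(3L)),
      list(W = matrix(rnorm(din * 3L), din), a1 = rnorm(3L), a2 = rnorm(3L))),
      bias = rnorm(6L))
    X <- matrix(rnorm(n * din), n)
    sparse <- pfnet:::gatForward(X, edges, lp)$out
    dense <- pfnet:::gatForwardDense(X, edges, lp)
    expect_equal(sparse, dense, tolerance = 1e-6)
  }
})

test_that("an isolated node reduces to a linear map of its own features", {
  withr::local_seed(2)
  din <- 4L
  lp <- list(heads = list(list(W = matrix(rnorm(din * 3L), din),
                               a1 = rnorm(3L), a2 = rnorm(3L))),
             bias = rnorm(3L))
  X <- matrix(rnorm(2L * din), 2L)
  # only node 2 has a neighbor; node 1 is self-loop only
  edges <- pfnet:::addSelfLoops(list(dst = 2L, src = 1L), 2L)
  out <- pfnet:::gatForward(X, edges, lp)$out
  expect_equal(out[1L, ], drop(X[1L, ] %*% lp$heads[[1L]]$W) + lp$bias,
               tolerance = 1e-12)
})

test_that("identical neighbor features give uniform attention", {
  withr::local_seed(4)
  din <- 3L
  lp <- list(heads = list(list(W = matrix(rnorm(din * 2L), din),
                               a1 = rnorm(2L), a2 = rnorm(2L))),
             bias = numeric(2L))
  x <- rnorm(din)
  X <- rbind(x, x, x)  # all nodes identical
  edges <- pfnet:::addSelfLoops(list(dst = c(1L, 1L), src = c(2L, 3L)), 3L)
  fw <- pfnet:::gatForward(X, edges, lp)
  # attention over node 1's neighborhood {1,2,3} is exactly uniform
  alpha1 <- unname(fw$cache$heads[[1L]]$alpha[c(edges$dst == 1L)])
  expect_equal(alpha1, rep(1 / 3, 3L), tolerance = 1e-12)
  expect_equal(fw$out[1L, ], drop(x %*% lp$heads[[1L]]$W),
               tolerance = 1e-12)
})

test_that("analytic gradients match finite differences in every mode", {
  withr::local_seed(31)
  for (mode in c("FULL", "BPV", "LLM", "BPV_GNN", "LLM_BPV")) {
    config <- tinyConfig(mode)
    if (mode == "BPV_GNN") {
      batch <- tinyBatch(config)
      batch$nodeFeatures <- matrix(
        rbinom(nrow(batch$nodeFeatures) * config$vocabSize, 1L, 0.4),
        nrow(batch$nodeFeatures))
    } else batch <- tinyBatch(config)
    params <- initModelParams(config)
    y <- matrix(rbinom(3L * config$nLabels, 1L, 0.5), 3L)
    lossAt <- function(p) {
      fw <- modelForward(p, config, batch)
      pfnet:::bceWithLogits(fw$logits, y)
    }
    fw <- modelForward(params, config, batch)
    grads <- pfnet:::modelBackward(params, config, fw$cache,
                                   pfnet:::bceGrad(fw$logits, y))
    # probe a handful of coordinates in selected parameter leaves
    eps <- 1e-6
    bump <- function(tree, path, i, delta) {
      sel <- paste0("tree", paste(sprintf("[['%s']]", path), collapse = ""),
                    sprintf("[%d]", i))
      eval(parse(text = paste0(sel, " <- ", sel, " + delta")))
      tree
    }
    checkLeaf <- function(path) {
      g <- grads
      for (k in path) g <- g[[k]]
      p <- params
      for (k in path) p <- p[[k]]
      for (i in sample(length(p), min(3L, length(p)))) {
        fd <- (lossAt(bump(params, path, i, eps)) -
               lossAt(bump(params, path, i, -eps))) / (2 * eps)
        expect_equal(g[i], fd, tolerance = 1e-4,
                     label = paste(mode, paste(path, collapse = "/"), i))
      }
    }
    leafPaths <- switch(mode,
      FULL = list(c("head", "W1"), c("head", "b2"), c("sig", "W2"),
                  c("gat2", "bias")),
      BPV = list(c("head", "W1"), c("sig", "W1"), c("sig", "b3")),
      LLM = list(c("head", "W1"), c("head", "b1")),
      BPV_GNN = list(c("head", "W2"), c("gat2", "bias")),
      LLM_BPV = list(c("head", "W1"), c("sig", "W3")))
    for (pp in leafPaths) checkLeaf(pp)
    # GAT head leaves need numeric indices; check one explicitly
    if (mode %in% c("FULL", "BPV_GNN")) {
      g <- grads$gat1$heads[[1L]]$W
      for (i in sample(length(g), 3L)) {
        plus <- params; minus <- params
        plus$gat1$heads[[1L]]$W[i] <- plus$gat1$heads[[1L]]$W[i] + eps
        minus$gat1$heads[[1L]]$W[i] <- minus$gat1$heads[[1L]]$W[i] - eps
        fd <- (lossAt(plus) - lossAt(minus)) / (2 * eps)
        expect_equal(g[i], fd, tolerance = 1e-4,
                     label = paste(mode, "gat1 W", i))
      }
      ga <- grads$gat1$heads[[2L]]$a1
      for (i in sample(length(ga), 2L)) {
        plus <- params; minus <- params
        plus$gat1$heads[[2L]]$a1[i] <- plus$gat1$heads[[2L]]$a1[i] + eps
        minus$gat1$heads[[2L]]$a1[i] <- minus$gat1$heads[[2L]]$a1[i] - eps
        fd <- (lossAt(plus) - lossAt(minus)) / (2 * eps)
        expect_equal(ga[i], fd, tolerance = 1e-4,
                     label = paste(mode, "gat1 a1", i))
      }
    }
  }
})

test_that("scores are sigmoid-bounded in every mode", {
  withr::local_seed(12)
  for (mode in c("FULL", "BPV", "LLM", "BPV_GNN", "LLM_BPV")) {
    config <- tinyConfig(mode)
    batch <- tinyBatch(config)
    if (mode == "BPV_GNN")
      batch$nodeFeatures <- matrix(
        rbinom(nrow(batch$nodeFeatures) * config$vocabSize, 1L, 0.4),
        nrow(batch$nodeFeatures))
    fw <- modelForward(initModelParams(config), config, batch)
    expect_true(all(fw$scores >= 0 & fw$scores <= 1))
  }
})

test_that("inactive towers cannot influence the output", {
  withr::local_seed(13)
  configL <- tinyConfig("LLM")
  batch <- tinyBatch(configL)
  pL <- initModelParams(configL)
  a <- modelForward(pL, configL, batch)$scores
  batch2 <- batch
  batch2$sigRows <- 1 - batch2$sigRows
  batch2$edges <- list(dst = integer(), src = integer())
  expect_identical(modelForward(pL, configL, batch2)$scores, a)

  configB <- tinyConfig("BPV")
  pB <- initModelParams(configB)
  b <- modelForward(pB, configB, batch)$scores
  batch3 <- batch
  batch3$embRows <- batch3$embRows * 10
  batch3$nodeFeatures <- batch3$nodeFeatures * -1
  expect_identical(modelForward(pB, configB, batch3)$scores, b)
})

test_that("the graph tower is permutation-equivariant", {
  withr::local_seed(14)
  config <- tinyConfig("FULL")
  n <- 6L
  batch <- tinyBatch(config, nNodes = n, nSeeds = n, pEdge = 0.4)
  batch$sigRows <- matrix(rbinom(n * config$vocabSize, 1L, 0.4), n)
  params <- initModelParams(config)
  out <- modelForward(params, config, batch)$scores
  perm <- sample(n)
  inv <- order(perm)
  pb <- list(
    edges = list(dst = inv[batch$edges$dst], src = inv[batch$edges$src]),
    nodeFeatures = batch$nodeFeatures[perm, , drop = FALSE],
    seedIdx = inv[batch$seedIdx],
    sigRows = batch$sigRows)  # seeds scored in the same protein order
  out2 <- modelForward(params, config, pb)$scores
  expect_equal(out2, out, tolerance = 1e-6)
})

test_that("outputs depend only on the two-hop neighborhood", {
  withr::local_seed(15)
  config <- tinyConfig("FULL")
  # path graph 1-2-3-4-5: node 5 is 3 hops from node 2 (the seed)
  n <- 5L
  edges <- list(dst = c(1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L),
                src = c(2L, 1L, 3L, 2L, 4L, 3L, 5L, 4L))
  batch <- list(edges = edges,
                nodeFeatures = matrix(rnorm(n * config$inputDim), n),
                seedIdx = 2L,
                sigRows = matrix(rbinom(config$vocabSize, 1L, 0.5), 1L))
  params <- initModelParams(config)
  a <- modelForward(params, config, batch)$scores
  batch$nodeFeatures[5L, ] <- rnorm(config$inputDim)
  b <- modelForward(params, config, batch)$scores
  expect_identical(a, b)
  # a 2-hop node does change the output
  batch$nodeFeatures[4L, ] <- rnorm(config$inputDim)
  expect_false(identical(modelForward(params, config, batch)$scores, a))
})

test_that("zeroing the graph tower reproduces the pure signature pathway", {
  withr::local_seed(16)
  config <- tinyConfig("FULL")
  batch <- tinyBatch(config)
  params <- initModelParams(config)
  z <- modelForward(params, config, batch, zeroGraphTower = TRUE)
  # manual pathway: [0, sigEnc(rows)] through the fusion head
  se <- pfnet:::sigEncForward(batch$sigRows, params$sig,
                              config$attentionSlope)
  Z <- cbind(matrix(0, nrow(se$out), config$gatOut), se$out)
  a1 <- pfnet:::leakyRelu(
    pfnet:::denseForward(Z, params$head$W1, params$head$b1),
    config$attentionSlope)
  logits <- pfnet:::denseForward(a1, params$head$W2, params$head$b2)
  expect_equal(z$logits, logits, tolerance = 1e-6)
})

test_that("signature encoder honors its architectural contract", {
  withr::local_seed(17)
  config <- tinyConfig("BPV", vocabSize = 10L)
  params <- initModelParams(config)
  rows <- matrix(rbinom(30L, 1L, 0.3), 3L)
  enc <- pfnet:::sigEncForward(rows, params$sig)
  expect_equal(ncol(enc$out), config$sigLatent)
  # identical rows give identical outputs
  same <- rbind(rows[1L, ], rows[1L, ])
  enc2 <- pfnet:::sigEncForward(same, params$sig)
  expect_equal(enc2$out[1L, ], enc2$out[2L, ])
  # all-zero input passes only biases through the layers
  z <- pfnet:::sigEncForward(matrix(0, 1L, 10L), params$sig)
  manual <- pfnet:::leakyRelu(matrix(params$sig$b1, 1L), 0.2) %*%
    params$sig$W2
  manual <- pfnet:::leakyRelu(sweep(manual, 2L, params$sig$b2, `+`), 0.2) %*%
    params$sig$W3
  manual <- sweep(manual, 2L, params$sig$b3, `+`)
  expect_equal(z$out, manual, tolerance = 1e-12)
  expect_error(pfnet:::sigEncForward(matrix(0, 1L, 4L), params$sig))
})

test_that("configuration is validated", {
  expect_error(modelConfig(mode = "NOPE"), "mode")
  expect_error(modelConfig(nLabels = 0L), "dimensions")
  expect_error(modelConfig(dropout = 1), "dropout")
  config <- tinyConfig("FULL")
  batch <- tinyBatch(config)
  batch$sigRows <- NULL
  expect_error(modelForward(initModelParams(config), config, batch),
               "sigRows")
})
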