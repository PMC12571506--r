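# the CAFA metric stack: score propagation, precision/recall, Fmax,
# Smin, AUPRC, grouped evaluation

# two-protein worked example used throughout:
#   P1 truth {a,b}, scores {a: 0.8}
#   P2 truth {a},   scores {a: 0.8, b: 0.6}
toyScores <- function() {
  m <- rbind(P1 = c(a = 0.8, b = 0), P2 = c(a = 0.8, b = 0.6))
  m
}
toyTruth <- function() rbind(P1 = c(a = 1, b = 1), P2 = c(a = 1, b = 0))

test_that("score propagation applies the descendant-max rule", {
  dag <- parseOBO(chainOBO())  # GO:0000002 is_a GO:0000001
  pm <- new("PredictionMatrix", proteins = "P1",
            labels = c("GO:0000001", "GO:0000002"),
            scores = matrix(c(0.5, 0.9), 1L,
                            dimnames = list("P1", NULL)))
  prop <- propagateScores(pm, dag)
  expect_equal(unname(scores(prop)[1L, ]), c(0.9, 0.9))
  again <- propagateScores(prop, dag)
  expect_identical(scores(again), scores(prop))
  bad <- new("PredictionMatrix", proteins = "P1", labels = "GO:0099999",
             scores = matrix(0.5, 1L))
  expect_error(propagateScores(bad, dag), "absent")
})

test_that("score propagation equals a brute-force descendant-max oracle", {
  withr::local_seed(23)
  for (rep in 1:4) {
    parents <- oracleRandomParents(12L)
    dag <- dagFromParents(parents)
    ids <- names(parents)
    sc <- matrix(runif(5L * 12L), 5L, dimnames = list(sprintf("P%d", 1:5),
                                                      ids))
    pm <- new("PredictionMatrix", proteins = rownames(sc), labels = ids,
              scores = sc)
    got <- scores(propagateScores(pm, dag))
    want <- sc
    for (t in ids) {
      # descendants of t: terms whose closure contains t
      desc <- ids[vapply(ids, function(x) t %in% oracleClosure(parents, x),
                         logical(1L))]
      want[, t] <- apply(sc[, desc, drop = FALSE], 1L, max)
    }
    expect_equal(got, want, tolerance = 1e-12)
    # parent >= child everywhere
    for (t in ids) for (p in parents[[t]])
      expect_true(all(got[, p] >= got[, t]))
  }
})

test_that("precision and recall reproduce the worked two-protein example", {
  prm <- precisionRecallAtTau(toyScores(), toyTruth(), 0.6)
  expect_equal(prm$pr, 0.75)
  expect_equal(prm$rc, 0.75)
  expect_equal(prm$m, 2L)
  # below every score: perfect recall, precision diluted by b for P1
  low <- precisionRecallAtTau(toyTruth(), toyTruth(), 0.5)
  expect_equal(low$pr, 1)
  expect_equal(low$rc, 1)
  expect_equal(low$m, 2L)
  # above every score: nothing predicted
  high <- precisionRecallAtTau(toyScores(), toyTruth(), 0.95)
  expect_true(is.na(high$pr))
  expect_equal(high$rc, 0)
  expect_equal(high$m, 0L)
})

test_that("Fmax on the worked example is 6/7 by exhaustive thresholds", {
  fm <- fmaxCurve(toyScores(), toyTruth())
  expect_equal(fm$fmax, 6 / 7, tolerance = 1e-12)
  # attained where only the two a-predictions survive
  expect_true(fm$tauStar > 0.6 && fm$tauStar <= 0.8)
  expect_equal(nrow(fm$curve), 101L)
  expect_error(fmaxCurve(toyScores(), toyTruth(), grid = numeric()),
               "grid")
})

test_that("degenerate identities hold exactly", {
  perfect <- fmaxCurve(toyTruth(), toyTruth())
  expect_equal(perfect$fmax, 1)
  none <- fmaxCurve(toyTruth() * 0, toyTruth())
  expect_equal(none$fmax, 0)
  expect_equal(auprc(toyTruth(), toyTruth()), 1)
  icv <- c(a = 1, b = 0.5)
  ic <- new("ICTable", ic = icv, logBase = exp(1))
  sp <- sminCurve(toyTruth(), toyTruth(), ic)
  expect_equal(sp$smin, 0)
})

test_that("Smin evaluates the toy cases analytically", {
  ic <- new("ICTable", ic = c(c = log(2)), logBase = exp(1))
  # one protein, truth {c}, no predictions: ru = ln 2 at every threshold
  sc <- matrix(0, 1L, 1L, dimnames = list("P1", "c"))
  tr <- matrix(1, 1L, 1L, dimnames = list("P1", "c"))
  sm <- sminCurve(sc, tr, ic)
  expect_equal(sm$smin, log(2), tolerance = 1e-12)
  # no truth, one false positive with ic 1: high thresholds empty Pi
  ic2 <- new("ICTable", ic = c(p = 1), logBase = exp(1))
  sc2 <- matrix(0.5, 1L, 1L, dimnames = list("P1", "p"))
  tr2 <- matrix(0, 1L, 1L, dimnames = list("P1", "p"))
  sm2 <- sminCurve(sc2, tr2, ic2)
  expect_equal(sm2$smin, 0)
  expect_error(sminCurve(sc2, tr2,
                         new("ICTable", ic = c(q = 1), logBase = exp(1))),
               "missing")
})

test_that("AUPRC behaves on ranked and random data", {
  # all positives above all negatives
  sc <- matrix(c(0.9, 0.8, 0.2, 0.1), 2L)
  tr <- matrix(c(1, 1, 0, 0), 2L)
  expect_equal(auprc(sc, tr), 1)
  # a single positive ranked first
  sc2 <- matrix(seq(1, 0.1, length.out = 10L), 2L)
  tr2 <- matrix(0, 2L, 5L); tr2[1L, 1L] <- 1
  expect_equal(auprc(sc2, tr2), 1)
  expect_error(auprc(sc2, tr2 * 0), "positives")
  # random scores: micro AUPRC approaches prevalence
  withr::local_seed(77)
  sc3 <- matrix(runif(1e4), 100L)
  tr3 <- matrix(rbinom(1e4, 1L, 0.1), 100L)
  expect_equal(auprc(sc3, tr3), 0.1, tolerance = 0.02)
})

test_that("micro and macro AUPRC agree with the explicit-sweep oracle", {
  withr::local_seed(41)
  sc <- matrix(runif(60L), 10L)
  tr <- matrix(rbinom(60L, 1L, 0.3), 10L)
  tr[1L, ] <- 1  # guarantee positives
  expect_equal(auprc(sc, tr), oracleAUPRC(sc, tr), tolerance = 1e-12)
  mac <- auprc(sc, tr, average = "macro")
  want <- mean(vapply(seq_len(ncol(sc)), function(j)
    oracleAUPRC(sc[, j, drop = FALSE], tr[, j, drop = FALSE]),
    numeric(1L)))
  expect_equal(mac, want, tolerance = 1e-12)
})

test_that("recall never increases with the threshold", {
  withr::local_seed(55)
  for (rep in 1:5) {
    sc <- matrix(runif(40L), 8L)
    tr <- matrix(rbinom(40L, 1L, 0.4), 8L)
    tr[rowSums(tr) == 0L, 1L] <- 1
    fm <- fmaxCurve(sc, tr)
    expect_true(all(diff(fm$curve$rc) <= 1e-12))
  }
})

test_that("grid refinement never loses the optimum", {
  withr::local_seed(66)
  sc <- matrix(runif(30L), 6L)
  tr <- matrix(rbinom(30L, 1L, 0.4), 6L)
  tr[rowSums(tr) == 0L, 1L] <- 1
  ic <- new("ICTable",
            ic = setNames(runif(5L, 0.1, 2), colnames(sc) <- colnames(tr) <-
                            sprintf("t%d", 1:5)),
            logBase = exp(1))
  coarse <- seq(0, 1, by = 0.02)
  fine <- seq(0, 1, by = 0.01)
  expect_gte(fmaxCurve(sc, tr, fine)$fmax, fmaxCurve(sc, tr, coarse)$fmax)
  expect_lte(sminCurve(sc, tr, ic, fine)$smin,
             sminCurve(sc, tr, ic, coarse)$smin)
})

test_that("the full evaluator matches the brute-force CAFA oracle", {
  withr::local_seed(88)
  for (rep in 1:6) {
    nP <- sample(2:5, 1L); nL <- sample(3:6, 1L)
    labels <- sprintf("t%d", seq_len(nL))
    sc <- matrix(round(runif(nP * nL), 2L), nP,
                 dimnames = list(sprintf("P%d", seq_len(nP)), labels))
    tr <- matrix(rbinom(nP * nL, 1L, 0.4), nP,
                 dimnames = dimnames(sc))
    tr[rowSums(tr) == 0L, sample(nL, 1L)] <- 1
    icv <- setNames(runif(nL, 0.05, 3), labels)
    grid <- defaultTauGrid()
    truthList <- apply(tr, 1L, function(r) labels[r > 0],
                       simplify = FALSE)
    want <- oracleCafa(sc, truthList, labels, icv, grid)
    fm <- fmaxCurve(sc, tr, grid)
    sm <- sminCurve(sc, tr, new("ICTable", ic = icv, logBase = exp(1)),
                    grid)
    expect_equal(fm$fmax, want$fmax, tolerance = 1e-9)
    expect_equal(fm$tauStar, want$tauStar, tolerance = 1e-9)
    expect_equal(sm$smin, want$smin, tolerance = 1e-9)
    expect_equal(fm$curve$pr, want$curve$pr, tolerance = 1e-9)
    expect_equal(fm$curve$rc, want$curve$rc, tolerance = 1e-9)
    expect_equal(fm$curve$m, want$curve$m)
    expect_equal(sm$curve$ru, want$curve$ru, tolerance = 1e-9)
    expect_equal(sm$curve$mi, want$curve$mi, tolerance = 1e-9)
  }
})

test_that("evaluatePredictions assembles a consistent report", {
  dag <- parseOBO(chainOBO())
  child <- "GO:0000002"
  truth <- annSet(list(P1 = c("GO:0000001", child),
                       P2 = c("GO:0000001", child)), propagated = TRUE)
  pm <- new("PredictionMatrix", proteins = c("P1", "P2"), labels = child,
            scores = matrix(c(0.9, 0.8), 2L,
                            dimnames = list(c("P1", "P2"), child)))
  ic <- estimateIC(truth, dag)
  rep <- evaluatePredictions(pm, truth, dag, ic)
  expect_s4_class(rep, "EvaluationReport")
  expect_equal(rep@fmax, 1)
  expect_equal(rep@smin, 0)
  expect_equal(rep@auprc, 1)
  expect_equal(nrow(rep@curve), 101L)
  expect_equal(rep@n, 2L)
  expect_equal(rep@namespace, "MFO")
})

test_that("namespace mixtures are rejected", {
  path <- writeTestOBO(list(
    c("id: GO:0000001", "namespace: molecular_function"),
    c("id: GO:0000002", "namespace: biological_process")))
  dag <- parseOBO(path)
  pm <- new("PredictionMatrix", proteins = "P1",
            labels = c("GO:0000001", "GO:0000002"),
            scores = matrix(c(0.4, 0.6), 1L))
  truth <- annSet(list(P1 = c("GO:0000001", "GO:0000002")),
                  propagated = TRUE)
  ic <- new("ICTable", ic = c("GO:0000001" = 0, "GO:0000002" = 0),
            logBase = exp(1))
  expect_error(evaluatePredictions(pm, truth, dag, ic), "namespaces")
})

test_that("grouped evaluation partitions the overall protein count", {
  withr::local_seed(30)
  world <- generateWorld(nProteins = 60L, nTerms = 20L, nSignatures = 8L,
                         seed = 9L)
  d <- worldPipelineData(world, embeddingDim = 8L, minProteins = 3L)
  ids <- names(d$splits)[d$splits == "test"]
  truth <- subsetAnnotations(d$annotations, ids)
  sc <- matrix(runif(length(ids) * length(d$labels)), length(ids),
               dimnames = list(ids, d$labels))
  pm <- new("PredictionMatrix", proteins = ids, labels = d$labels,
            scores = sc)
  whole <- evaluatePredictions(pm, truth, d$dag, d$ic)
  one <- evaluateByGroup(pm, truth, d$dag, d$ic,
                         setNames(rep("all", length(ids)), ids))
  expect_equal(one$all@fmax, whole@fmax)
  expect_equal(one$all@n, whole@n)
  two <- evaluateByGroup(pm, truth, d$dag, d$ic, d$taxa[ids])
  expect_equal(sum(vapply(two, function(r) r@n, integer(1L))), whole@n)
  expect_error(evaluateByGroup(pm, truth, d$dag, d$ic,
                               d$taxa[ids][-1L]), "groupMap")
})
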