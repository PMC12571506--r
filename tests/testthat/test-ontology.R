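# GO DAG parsing, evidence filtering, true-path propagation, label
# selection and information content

test_that("parseOBO reads the minimal chain and maps structure", {
  dag <- parseOBO(chainOBO())
  expect_setequal(goTerms(dag), c("GO:0000001", "GO:0000002"))
  expect_equal(parentsOf(dag)[["GO:0000002"]], "GO:0000001")
  expect_equal(rootsOf(dag), "GO:0000001")
  expect_equal(unname(namespaceOf(dag)["GO:0000002"]), "MFO")
})

test_that("parseOBO drops obsolete terms and maps alt ids", {
  path <- writeTestOBO(list(
    c("id: GO:0000001", "name: a", "namespace: molecular_function"),
    c("id: GO:0000002", "name: b", "namespace: molecular_function",
      "is_a: GO:0000001", "alt_id: GO:0009999"),
    c("id: GO:0000003", "name: gone", "namespace: molecular_function",
      "is_a: GO:0000001", "is_obsolete: true")))
  dag <- parseOBO(path)
  expect_false("GO:0000003" %in% goTerms(dag))
  expect_equal(resolveAltIds(dag, "GO:0009999"), "GO:0000002")
})

test_that("parseOBO rejects malformed stanzas and cycles", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.obo")
  writeLines(c("format-version: 1.2", "", "[Term]", "id: GO:0000001",
               "garbage line without separator"), bad)
  expect_error(parseOBO(bad), "malformed")
  cyc <- writeTestOBO(list(
    c("id: GO:0000001", "namespace: molecular_function",
      "is_a: GO:0000002"),
    c("id: GO:0000002", "namespace: molecular_function",
      "is_a: GO:0000001")), dir)
  expect_error(parseOBO(cyc), "cycle")
})

test_that("cross-namespace parent links are dropped", {
  path <- writeTestOBO(list(
    c("id: GO:0000001", "namespace: molecular_function"),
    c("id: GO:0000010", "namespace: biological_process"),
    c("id: GO:0000011", "namespace: biological_process",
      "is_a: GO:0000010", "is_a: GO:0000001")))
  dag <- parseOBO(path)
  expect_equal(parentsOf(dag)[["GO:0000011"]], "GO:0000010")
})

test_that("relationship links define parenthood only when configured", {
  path <- writeTestOBO(list(
    c("id: GO:0000001", "namespace: molecular_function"),
    c("id: GO:0000002", "namespace: molecular_function",
      "relationship: part_of GO:0000001")))
  expect_equal(parentsOf(parseOBO(path))[["GO:0000002"]], character())
  dag <- parseOBO(path, relations = "part_of")
  expect_equal(parentsOf(dag)[["GO:0000002"]], "GO:0000001")
})

test_that("filterEvidence applies presets", {
  raw <- data.frame(
    protein = c("P1", "P1", "P2", "P3"),
    term = c("GO:1", "GO:2", "GO:1", "GO:3"),
    evidence = c("IDA", "IEA", "HDA", "EXP"))
  expA <- filterEvidence(raw, "EXPERIMENTAL")
  expect_setequal(names(annotationsOf(expA)), c("P1", "P3"))
  expect_equal(annotationsOf(expA)$P1, "GO:1")  # IEA dropped
  expB <- filterEvidence(raw, "EXTENDED")
  expect_true("P2" %in% names(annotationsOf(expB)))  # HDA kept
  expect_error(filterEvidence(raw, "SOMETHING"), "preset")
  empty <- filterEvidence(raw[0, ], "EXPERIMENTAL")
  expect_length(annotationsOf(empty), 0L)
})

test_that("propagation closes annotation sets and is idempotent", {
  dag <- parseOBO(chainOBO())
  ann <- annSet(list(P1 = "GO:0000002"))
  prop <- propagateAnnotations(ann, dag)
  expect_setequal(annotationsOf(prop)$P1, c("GO:0000001", "GO:0000002"))
  expect_true(isPropagated(prop))
  again <- propagateAnnotations(prop, dag)
  expect_identical(annotationsOf(again), annotationsOf(prop))
})

test_that("propagation equals the brute-force closure oracle", {
  withr::local_seed(42)
  for (rep in 1:5) {
    parents <- oracleRandomParents(30L)
    dag <- dagFromParents(parents)
    ids <- names(parents)
    ann <- annSet(lapply(setNames(nm = sprintf("P%02d", 1:12)), function(p)
      ids[sample.int(30L, sample.int(4L, 1L))]))
    prop <- propagateAnnotations(ann, dag)
    for (p in names(annotationsOf(ann))) {
      want <- sort(unique(unlist(lapply(annotationsOf(ann)[[p]],
                                        oracleClosure, parents = parents))))
      expect_equal(sort(annotationsOf(prop)[[p]]), want)
    }
  }
})

test_that("annotations to unknown terms error unless lenient", {
  dag <- parseOBO(chainOBO())
  ann <- annSet(list(P1 = c("GO:0000002", "GO:0099999")))
  expect_error(propagateAnnotations(ann, dag), "GO:0099999")
  prop <- propagateAnnotations(ann, dag, lenient = TRUE)
  expect_setequal(annotationsOf(prop)$P1, c("GO:0000001", "GO:0000002"))
})

test_that("label filter keeps terms at the protein threshold, drops roots", {
  dag <- parseOBO(chainOBO())
  # 10 proteins on the child, 9 on a hypothetical second term
  lst <- setNames(rep(list("GO:0000002"), 10L), sprintf("P%02d", 1:10))
  prop <- propagateAnnotations(annSet(lst), dag)
  labs <- filterLabels(prop, dag, minProteins = 10L)
  expect_equal(labs$MFO, "GO:0000002")  # root excluded, child kept at 10
  lst9 <- lst[1:9]
  prop9 <- propagateAnnotations(annSet(lst9), dag)
  expect_length(filterLabels(prop9, dag, minProteins = 10L), 0L)
  expect_equal(filterLabels(prop, dag, minProteins = 1L)$MFO, "GO:0000002")
  expect_error(filterLabels(prop, dag, minProteins = 0L), "minProteins")
  expect_length(filterLabels(annSet(list(), propagated = TRUE), dag), 0L)
})

test_that("raising minProteins never adds labels", {
  withr::local_seed(7)
  parents <- oracleRandomParents(25L)
  dag <- dagFromParents(parents)
  ids <- names(parents)
  ann <- annSet(lapply(setNames(nm = sprintf("P%02d", 1:40)), function(p)
    ids[sample.int(25L, sample.int(3L, 1L))]))
  prop <- propagateAnnotations(ann, dag)
  prev <- NULL
  for (k in c(1L, 3L, 6L, 12L)) {
    cur <- filterLabels(prop, dag, minProteins = k)$MFO %||% character()
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("information content matches the analytic toy", {
  dag <- parseOBO(chainOBO())
  lst <- c(setNames(rep(list(c("GO:0000001", "GO:0000002")), 5L),
                    sprintf("P%02d", 1:5)),
           setNames(rep(list("GO:0000001"), 5L), sprintf("P%02d", 6:10)))
  prop <- annSet(lst, propagated = TRUE)
  ic <- estimateIC(prop, dag)
  expect_equal(unname(icValues(ic)["GO:0000002"]), log(2), tolerance = 1e-12)
  expect_equal(unname(icValues(ic)["GO:0000001"]), 0)
  ic2 <- estimateIC(prop, dag, logBase = 2)
  expect_equal(unname(icValues(ic2)["GO:0000002"]), 1, tolerance = 1e-12)
})

test_that("information content matches a counting oracle on random corpora", {
  withr::local_seed(11)
  parents <- oracleRandomParents(15L, maxParents = 1L)
  dag <- dagFromParents(parents)
  ids <- names(parents)
  lst <- lapply(setNames(nm = sprintf("P%02d", 1:20)), function(p)
    oracleClosure(parents, ids[sample.int(15L, 1L)]))
  prop <- annSet(lst, propagated = TRUE)
  ic <- estimateIC(prop, dag)
  counts <- oracleTermCounts(lst)
  nCorpus <- length(lst)
  for (t in ids) {
    par <- parents[[t]]
    nx <- if (t %in% names(counts)) counts[[t]] else 0L
    np <- if (!length(par)) nCorpus
          else if (par %in% names(counts)) counts[[par]] else 0L
    pr <- if (nx == 0L || np == 0L) 1 / (nCorpus + 1) else nx / np
    expect_equal(unname(icValues(ic)[t]), -log(pr), tolerance = 1e-12,
                 label = t)
  }
  expect_true(all(icValues(ic) >= 0))
})

test_that("estimateIC refuses unpropagated or empty corpora", {
  dag <- parseOBO(chainOBO())
  expect_error(estimateIC(annSet(list(P1 = "GO:0000002")), dag),
               "propagated")
  expect_error(estimateIC(annSet(list(), propagated = TRUE), dag), "empty")
})
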