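#' @import methods
#' @importFrom stats rnorm runif rbinom rpois setNames sd median quantile
#' @importFrom utils head read.delim write.table
NULL

#' Gene Ontology DAG restricted to one or more namespaces
#'
#' Holds the non-obsolete terms of a GO release (or a synthetic ontology),
#' their namespace assignment (BPO, CCO or MFO), direct parent links within
#' the same namespace, alternative-id mappings and the namespace roots.
#'
#' @slot terms character vector of canonical term identifiers.
#' @slot namespaces named character vector, term -> one of "BPO","CCO","MFO".
#' @slot parents named list, term -> character vector of direct parents
#'   (same namespace; empty for roots).
#' @slot altIds named character vector, alternative id -> canonical id.
#' @slot roots character vector of terms with no parents.
#'
#' @seealso [parseOBO()], [ancestorsOf()], [propagateAnnotations()]
#' @export
setClass("OntologyDAG",
  representation(
    terms = "character",
    namespaces = "character",
    parents = "list",
    altIds = "character",
    roots = "character"
  )
)

setValidity("OntologyDAG", function(object) {
  msg <- character()
  trm <- object@terms
  if (anyDuplicated(trm)) msg <- c(msg, "duplicate term identifiers")
  if (!setequal(names(object@namespaces), trm))
    msg <- c(msg, "namespaces must be named by exactly the terms")
  if (!setequal(names(object@parents), trm))
    msg <- c(msg, "parents must be named by exactly the terms")
  bad <- setdiff(unlist(object@parents, use.names = FALSE), trm)
  if (length(bad))
    msg <- c(msg, paste0("parent links to unknown terms: ",
                         paste(head(bad, 5L), collapse = ", ")))
  if (length(object@altIds) &&
      !all(object@altIds %in% trm))
    msg <- c(msg, "altIds must map onto member terms")
  npar <- lengths(object@parents[trm])
  if (!setequal(object@roots, trm[npar == 0L]))
    msg <- c(msg, "roots must be exactly the terms with no parents")
  # acyclicity: cheap edge-count guard here, full check in parse/generate
  if (length(msg)) msg else TRUE
})

#' Protein-to-term annotation set
#'
#' Maps protein accessions to sets of GO terms, with the evidence code of
#' each (protein, term) assignment and a flag recording whether the set has
#' been closed under the true-path rule (every annotated term implies all
#' of its ancestors).
#'
#' @slot annotations named list, protein accession -> character vector of
#'   term ids.
#' @slot evidence data.frame with columns protein, term, evidence (one row
#'   per asserted annotation; propagation does not add rows here).
#' @slot propagated logical scalar; TRUE once ancestor-closed.
#'
#' @seealso [filterEvidence()], [propagateAnnotations()], [filterLabels()]
#' @export
setClass("AnnotationSet",
  representation(
    annotations = "list",
    evidence = "data.frame",
    propagated = "logical"
  ),
  prototype(propagated = FALSE)
)

setValidity("AnnotationSet", function(object) {
  msg <- character()
  if (length(object@propagated) != 1L || is.na(object@propagated))
    msg <- c(msg, "propagated must be TRUE or FALSE")
  if (length(object@annotations) && is.null(names(object@annotations)))
    msg <- c(msg, "annotations must be named by protein accession")
  if (length(msg)) msg else TRUE
})

#' Per-term information content table
#'
#' Information content IC(x) = -log Pr(x | parents(x)) estimated from an
#' annotation corpus, in a configurable logarithm base.
#'
#' @slot ic named non-negative numeric vector, term -> information content.
#' @slot logBase base of the logarithm used (> 1; default natural log).
#' @export
setClass("ICTable",
  representation(ic = "numeric", logBase = "numeric")
)

setValidity("ICTable", function(object) {
  msg <- character()
  if (length(object@ic) && is.null(names(object@ic)))
    msg <- c(msg, "ic must be named by term")
  if (any(object@ic < 0 | !is.finite(object@ic)))
    msg <- c(msg, "ic values must be finite and non-negative")
  if (length(object@logBase) != 1L || object@logBase <= 1)
    msg <- c(msg, "logBase must be a single value > 1")
  if (length(msg)) msg else TRUE
})

#' Catalog of InterPro-style protein signatures
#'
#' Mutually consistent protein -> signatures and signature -> members maps,
#' plus the entry type of each signature (FAMILY, DOMAIN, MOTIF, SITE or
#' OTHER). Signatures with no members are not stored.
#'
#' @slot signaturesOf named list, protein -> character vector of signatures.
#' @slot membersOf named list, signature -> character vector of proteins.
#' @slot typeOf named character vector, signature -> entry type.
#' @seealso [parseInterProScan()], [buildPFN()], [binarySignatureMatrix()]
#' @export
setClass("SignatureCatalog",
  representation(
    signaturesOf = "list",
    membersOf = "list",
    typeOf = "character"
  )
)

setValidity("SignatureCatalog", function(object) {
  msg <- character()
  sigs <- names(object@membersOf)
  if (!setequal(names(object@typeOf), sigs))
    msg <- c(msg, "typeOf must be named by exactly the signatures")
  if (any(lengths(object@membersOf) == 0L))
    msg <- c(msg, "empty signatures are not allowed")
  ok <- c("FAMILY", "DOMAIN", "MOTIF", "SITE", "OTHER")
  if (length(object@typeOf) && !all(object@typeOf %in% ok))
    msg <- c(msg, "typeOf values must be FAMILY/DOMAIN/MOTIF/SITE/OTHER")
  # inverse consistency (checked on a sample for speed on big catalogs)
  pr <- names(object@signaturesOf)
  take <- head(pr, 50L)
  for (p in take) {
    for (s in object@signaturesOf[[p]]) {
      if (!s %in% sigs || !p %in% object@membersOf[[s]]) {
        msg <- c(msg, "signaturesOf/membersOf are not mutual inverses")
        break
      }
    }
    if (length(msg)) break
  }
  if (length(msg)) msg else TRUE
})

#' Protein family network
#'
#' Undirected simple graph over protein accessions in which two proteins
#' are adjacent iff they share at least one qualifying signature (family,
#' domain or motif by default). Self-loops are never stored; the model adds
#' them transiently before attention.
#'
#' @slot nodes ordered character vector of protein accessions.
#' @slot edges two-column character matrix; each row an unordered pair
#'   stored with the lexicographically smaller accession first.
#' @slot sharedCount integer vector parallel to edges: number of distinct
#'   qualifying signatures shared by the pair (metadata only; edges are
#'   unweighted for message passing).
#' @seealso [buildPFN()], [graphStats()], [sampleNeighborhood()]
#' @export
setClass("ProteinFamilyNetwork",
  representation(
    nodes = "character",
    edges = "matrix",
    sharedCount = "integer"
  )
)

setValidity("ProteinFamilyNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (ncol(e) != 2L && nrow(e) > 0L)
    msg <- c(msg, "edges must have two columns")
  if (nrow(e)) {
    if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self-loops are not stored")
    if (!all(e %in% object@nodes)) msg <- c(msg, "edge endpoints must be nodes")
    if (any(e[, 1L] > e[, 2L]))
      msg <- c(msg, "edges must be stored smaller-endpoint first")
    key <- paste(e[, 1L], e[, 2L])
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges")
  }
  if (length(object@sharedCount) != nrow(e))
    msg <- c(msg, "sharedCount must parallel edges")
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate nodes")
  if (length(msg)) msg else TRUE
})

#' Fixed-width per-protein embedding matrix
#'
#' Real-valued node features for the graph tower: either loaded from a
#' precomputed protein language-model embedding file (mean-pooled encoder
#' states, default width 1536) or generated deterministically by
#' [syntheticEmbeddings()].
#'
#' @slot proteins ordered accessions (rownames of `values`).
#' @slot values numeric matrix proteins x dim, all entries finite.
#' @slot providerTag free-text provenance string.
#' @export
setClass("EmbeddingMatrix",
  representation(
    proteins = "character",
    values = "matrix",
    providerTag = "character"
  )
)

setValidity("EmbeddingMatrix", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@proteins))
    msg <- c(msg, "values must have one row per protein")
  if (length(object@proteins) && anyDuplicated(object@proteins))
    msg <- c(msg, "duplicate protein accessions")
  if (length(object@values) && !all(is.finite(object@values)))
    msg <- c(msg, "embedding values must be finite")
  if (length(msg)) msg else TRUE
})

#' Per-protein per-term prediction scores
#'
#' @slot proteins ordered accessions (rows).
#' @slot labels ordered term identifiers (columns).
#' @slot scores numeric matrix in \[0, 1\].
#' @seealso [predictScores()], [propagateScores()], [evaluatePredictions()]
#' @export
setClass("PredictionMatrix",
  representation(
    proteins = "character",
    labels = "character",
    scores = "matrix"
  )
)

setValidity("PredictionMatrix", function(object) {
  msg <- character()
  if (nrow(object@scores) != length(object@proteins) ||
      ncol(object@scores) != length(object@labels))
    msg <- c(msg, "scores dimensions must match proteins x labels")
  if (length(object@scores) &&
      (any(!is.finite(object@scores)) ||
       any(object@scores < 0) || any(object@scores > 1)))
    msg <- c(msg, "scores must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' CAFA-style evaluation report for one namespace
#'
#' @slot n number of evaluated proteins (those with non-empty ground truth).
#' @slot fmax maximum protein-centric F1 over the threshold grid.
#' @slot tauStar smallest threshold attaining fmax.
#' @slot smin minimum over the grid of sqrt(ru^2 + mi^2) where ru is mean
#'   remaining uncertainty and mi mean misinformation, both IC-weighted.
#' @slot auprc micro-averaged area under the precision-recall curve over
#'   all (protein, term) pairs.
#' @slot curve data.frame with one row per threshold: tau, pr, rc, m, ru,
#'   mi (pr is NA where no protein predicts any term).
#' @slot namespace "BPO", "CCO" or "MFO".
#' @export
setClass("EvaluationReport",
  representation(
    n = "integer",
    fmax = "numeric",
    tauStar = "numeric",
    smin = "numeric",
    auprc = "numeric",
    curve = "data.frame",
    namespace = "character"
  )
)

setValidity("EvaluationReport", function(object) {
  msg <- character()
  if (object@fmax < 0 || object@fmax > 1) msg <- c(msg, "fmax out of [0,1]")
  if (object@smin < 0) msg <- c(msg, "smin must be >= 0")
  if (!is.na(object@auprc) && (object@auprc < 0 || object@auprc > 1))
    msg <- c(msg, "auprc out of [0,1]")
  need <- c("tau", "pr", "rc", "m", "ru", "mi")
  if (!all(need %in% names(object@curve)))
    msg <- c(msg, "curve must carry tau, pr, rc, m, ru, mi")
  if (length(msg)) msg else TRUE
})

#' A complete synthetic benchmark world
#'
#' Bundles everything the pipeline consumes: a random ontology DAG, a
#' signature catalog with planted signature-to-term rules, true-path
#' propagated annotations, chronological-style train/valid/test splits and
#' taxon assignments. With both noise rates at zero a protein's annotation
#' set is exactly the propagated union of its signatures' rule terms.
#'
#' @slot dag [OntologyDAG-class] for one namespace.
#' @slot catalog [SignatureCatalog-class].
#' @slot rules named list, signature -> character vector of planted terms.
#' @slot annotations propagated [AnnotationSet-class].
#' @slot splits named character vector, protein -> "train"/"valid"/"test".
#' @slot taxa named character vector, protein -> taxon id.
#' @slot latentClass named character vector, protein -> latent class used
#'   to give synthetic embeddings signal.
#' @slot params list of generator settings (see [generateWorld()]).
#' @export
setClass("SyntheticWorld",
  representation(
    dag = "OntologyDAG",
    catalog = "SignatureCatalog",
    rules = "list",
    annotations = "AnnotationSet",
    splits = "character",
    taxa = "character",
    latentClass = "character",
    params = "list"
  )
)

setValidity("SyntheticWorld", function(object) {
  msg <- character()
  if (!object@annotations@propagated)
    msg <- c(msg, "world annotations must be propagated")
  if (!all(object@splits %in% c("train", "valid", "test")))
    msg <- c(msg, "splits must be train/valid/test")
  if (length(msg)) msg else TRUE
})
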