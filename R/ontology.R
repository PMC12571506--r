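# GO DAG parsing, evidence filtering, true-path propagation, label
# selection and information-content estimation.

.NAMESPACE_MAP <- c(
  biological_process = "BPO",
  cellular_component = "CCO",
  molecular_function = "MFO"
)

.EVIDENCE_PRESETS <- list(
  EXPERIMENTAL = c("EXP", "IDA", "IMP", "IPI", "IGI", "IEP", "TAS", "IC"),
  EXTENDED = c("EXP", "IDA", "IMP", "IPI", "IGI", "IEP", "TAS", "IC",
               "HTP", "HDA", "HMP", "HGI", "HEP")
)

#' Evidence-code presets for annotation filtering
#'
#' `"EXPERIMENTAL"` keeps the eight classic experimental evidence codes
#' (EXP, IDA, IMP, IPI, IGI, IEP, TAS, IC); `"EXTENDED"` additionally keeps
#' the high-throughput family (HTP, HDA, HMP, HGI, HEP).
#'
#' @param preset `"EXPERIMENTAL"` or `"EXTENDED"`.
#' @return Character vector of evidence codes.
#' @export
evidencePreset <- function(preset) {
  if (!is.character(preset) || length(preset) != 1L ||
      !preset %in% names(.EVIDENCE_PRESETS))
    stopf("unknown evidence preset '%s' (use %s)", paste(preset)[1L],
          paste(names(.EVIDENCE_PRESETS), collapse = " or "))
  .EVIDENCE_PRESETS[[preset]]
}

# internal constructor used by the parser and the synthetic generator
newOntologyDAG <- function(terms, namespaces, parents, altIds = character()) {
  parents <- parents[terms]
  names(parents) <- terms
  parents <- lapply(parents, function(p) if (is.null(p)) character() else p)
  roots <- terms[lengths(parents) == 0L]
  dag <- new("OntologyDAG", terms = terms,
             namespaces = namespaces[terms],
             parents = parents, altIds = altIds, roots = roots)
  dag
}

# find one directed cycle by DFS; returns character vector or NULL
.findCycle <- function(parents) {
  color <- setNames(integer(length(parents)), names(parents))
  stackTrace <- character()
  cyc <- NULL
  visit <- function(t) {
    if (!is.null(cyc)) return()
    color[[t]] <<- 1L
    stackTrace <<- c(stackTrace, t)
    for (p in parents[[t]]) {
      if (is.null(cyc) && !is.na(color[p]) && color[[p]] == 1L) {
        i <- match(p, stackTrace)
        cyc <<- c(stackTrace[i:length(stackTrace)], p)
      } else if (is.null(cyc) && !is.na(color[p]) && color[[p]] == 0L) {
        visit(p)
      }
    }
    color[[t]] <<- 2L
    stackTrace <<- stackTrace[-length(stackTrace)]
  }
  for (t in names(parents)) if (color[[t]] == 0L && is.null(cyc)) visit(t)
  cyc
}

#' Parse a Gene Ontology OBO file
#'
#' Stanza-based reader for OBO 1.2/1.4 text honoring `id`, `name`,
#' `namespace`, `is_a`, `relationship`, `is_obsolete` and `alt_id` tags.
#' Obsolete terms are dropped. Parenthood defaults to `is_a` links only;
#' `part_of` (or other relationship types) can be added via `relations`.
#' Parent links crossing namespaces are dropped, since models are trained
#' per subontology.
#'
#' @param path path to an OBO file.
#' @param relations character vector of relationship types that define
#'   parenthood in addition to `is_a` (e.g. `"part_of"`); default none.
#' @return An [OntologyDAG-class].
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("format-version: 1.2", "", "[Term]", "id: GO:0000001",
#'   "name: root", "namespace: molecular_function", "", "[Term]",
#'   "id: GO:0000002", "name: child", "namespace: molecular_function",
#'   "is_a: GO:0000001 ! root"), obo)
#' dag <- parseOBO(obo)
#' rootsOf(dag)
#' @export
parseOBO <- function(path, relations = character()) {
  if (!file.exists(path)) stopf("OBO file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  inTerm <- FALSE
  cur <- NULL
  stanzas <- list()
  flush <- function() {
    if (!is.null(cur)) stanzas[[length(stanzas) + 1L]] <<- cur
    cur <<- NULL
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, "[")) {
      flush()
      inTerm <- identical(ln, "[Term]")
      if (inTerm) cur <- list(line = i)
      next
    }
    if (!inTerm) next
    m <- regexpr(":", ln, fixed = TRUE)
    if (m < 0L) stopf("malformed stanza line %d: '%s'", i, ln)
    key <- substr(ln, 1L, m - 1L)
    val <- trimws(substr(ln, m + 1L, nchar(ln)))
    val <- sub("\\s*!.*$", "", val)          # strip trailing comment
    cur[[length(cur) + 1L]] <- c(key, val)
  }
  flush()

  ids <- character(); nss <- character(); parents <- list()
  altIds <- character()
  for (st in stanzas) {
    kv <- unname(st[-1L])
    keys <- vapply(kv, `[`, "", 1L)
    vals <- vapply(kv, `[`, "", 2L)
    if (!"id" %in% keys) stopf("term stanza at line %d has no id", st$line)
    id <- vals[match("id", keys)]
    if (any(keys == "is_obsolete" & vals == "true")) next
    ns <- if ("namespace" %in% keys) vals[match("namespace", keys)] else NA
    pset <- vals[keys == "is_a"]
    for (rel in vals[keys == "relationship"]) {
      bits <- strsplit(rel, "\\s+")[[1L]]
      if (length(bits) >= 2L && bits[1L] %in% relations)
        pset <- c(pset, bits[2L])
    }
    ids <- c(ids, id)
    nss[id] <- if (!is.na(ns) && ns %in% names(.NAMESPACE_MAP))
      .NAMESPACE_MAP[[ns]] else if (!is.na(ns) && ns %in% .NAMESPACE_MAP)
      ns else "MFO"
    parents[[id]] <- unique(pset)
    for (a in vals[keys == "alt_id"]) altIds[a] <- id
  }
  if (!length(ids)) stopf("no terms found in %s", path)
  # drop links to unknown (e.g. obsolete) or cross-namespace parents
  parents <- lapply(ids, function(t) {
    p <- parents[[t]]
    p <- p[p %in% ids]
    p[nss[p] == nss[[t]]]
  })
  names(parents) <- ids
  altIds <- altIds[altIds %in% ids]
  cyc <- .findCycle(parents)
  if (!is.null(cyc))
    stopf("ontology contains a cycle: %s", paste(cyc, collapse = " -> "))
  newOntologyDAG(ids, nss, parents, altIds)
}

#' Ancestor closure of terms within a DAG
#'
#' Returns, for each requested term, the set of the term itself plus all
#' of its ancestors under the DAG's parent links (the true-path closure).
#'
#' @param dag an [OntologyDAG-class].
#' @param termIds character vector of term ids (alt ids are resolved).
#' @return Named list, term -> character vector including the term.
#' @export
ancestorsOf <- function(dag, termIds) {
  memo <- new.env(parent = emptyenv())
  close1 <- function(t) {
    got <- memo[[t]]
    if (!is.null(got)) return(got)
    res <- t
    for (p in dag@parents[[t]]) res <- union(res, close1(p))
    memo[[t]] <- res
    res
  }
  termIds <- resolveAltIds(dag, termIds)
  out <- lapply(termIds, close1)
  names(out) <- termIds
  out
}

#' @rdname ancestorsOf
#' @export
resolveAltIds <- function(dag, termIds) {
  hit <- termIds %in% names(dag@altIds)
  termIds[hit] <- dag@altIds[termIds[hit]]
  termIds
}

#' Read a protein-term annotation table
#'
#' TSV with columns protein_accession, go_term, evidence_code and
#' optionally taxon_id (a GAF-subset dialect). Lines starting with `!` are
#' comments; a header row is detected and skipped.
#'
#' @param path path to the TSV.
#' @return data.frame with columns protein, term, evidence, taxon.
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(protein = character(), term = character(),
                      evidence = character(), taxon = character()))
  if (grepl("protein", lines[1L], ignore.case = TRUE)) lines <- lines[-1L]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc < 3L))
    stopf("annotation row %d has %d columns (need >= 3)",
          which(nc < 3L)[1L], min(nc))
  data.frame(
    protein = vapply(parts, `[`, "", 1L),
    term = vapply(parts, `[`, "", 2L),
    evidence = vapply(parts, `[`, "", 3L),
    taxon = vapply(parts, function(p) if (length(p) >= 4L) p[4L] else NA_character_, ""),
    stringsAsFactors = FALSE
  )
}

#' Filter annotation rows by evidence code
#'
#' Keeps only rows whose evidence code belongs to `codes`, which may be a
#' preset name (`"EXPERIMENTAL"` or `"EXTENDED"`) or an explicit character
#' vector of codes.
#'
#' @param raw data.frame with columns protein, term, evidence (as returned
#'   by [readAnnotations()]).
#' @param codes preset name or character vector of evidence codes.
#' @return An unpropagated [AnnotationSet-class].
#' @export
filterEvidence <- function(raw, codes = "EXPERIMENTAL") {
  knownCodes <- unique(c(unlist(.EVIDENCE_PRESETS, use.names = FALSE),
                         "IEA", "ISS", "ISO", "ISA", "ISM", "IGC", "IBA",
                         "IBD", "IKR", "IRD", "RCA", "NAS", "ND"))
  if (length(codes) == 1L && codes %in% names(.EVIDENCE_PRESETS))
    codes <- evidencePreset(codes)
  else if (length(codes) == 1L && !codes %in% knownCodes)
    stopf("unknown evidence preset '%s'", codes)
  keep <- raw$evidence %in% codes
  kept <- raw[keep, , drop = FALSE]
  kept <- kept[!duplicated(kept[c("protein", "term")]), , drop = FALSE]
  ann <- if (nrow(kept)) split(kept$term, kept$protein) else
    setNames(list(), character())
  ann <- lapply(ann, unique)
  new("AnnotationSet",
      annotations = ann,
      evidence = data.frame(protein = kept$protein, term = kept$term,
                            evidence = kept$evidence,
                            stringsAsFactors = FALSE),
      propagated = FALSE)
}

#' Propagate annotations by the true-path rule
#'
#' Replaces each protein's term set by its ancestor closure within the
#' DAG: annotation to a term implies annotation to every ancestor.
#' Idempotent.
#'
#' @param ann an [AnnotationSet-class].
#' @param dag the companion [OntologyDAG-class].
#' @param lenient if TRUE, annotations to terms missing from the DAG are
#'   silently dropped; otherwise they raise an error listing the ids.
#' @return A propagated [AnnotationSet-class].
#' @export
propagateAnnotations <- function(ann, dag, lenient = FALSE) {
  allTerms <- unique(unlist(ann@annotations, use.names = FALSE))
  allTerms <- resolveAltIds(dag, allTerms)
  unknown <- setdiff(allTerms, dag@terms)
  if (length(unknown)) {
    if (!lenient)
      stopf("annotations to unknown terms: %s",
            paste(head(unknown, 10L), collapse = ", "))
    allTerms <- setdiff(allTerms, unknown)
  }
  clo <- ancestorsOf(dag, allTerms)
  prop <- lapply(ann@annotations, function(ts) {
    ts <- resolveAltIds(dag, ts)
    ts <- ts[ts %in% dag@terms]
    unique(unlist(clo[ts], use.names = FALSE)) %||% character()
  })
  new("AnnotationSet", annotations = prop, evidence = ann@evidence,
      propagated = TRUE)
}

#' Select the label set per namespace
#'
#' Returns, for each namespace present, the sorted vector of non-root
#' terms annotated (after propagation) to at least `minProteins` proteins.
#'
#' @param ann a propagated [AnnotationSet-class] (typically restricted to
#'   the training split).
#' @param dag the companion [OntologyDAG-class].
#' @param minProteins minimum number of annotated proteins per kept term
#'   (default 10).
#' @return Named list, namespace -> sorted character vector of labels.
#' @export
filterLabels <- function(ann, dag, minProteins = 10L) {
  if (!isTRUE(ann@propagated)) stopf("filterLabels needs propagated annotations")
  if (minProteins < 1L) stopf("minProteins must be >= 1")
  counts <- table(unlist(ann@annotations, use.names = FALSE))
  kept <- names(counts)[counts >= minProteins]
  kept <- setdiff(kept, dag@roots)
  kept <- kept[kept %in% dag@terms]
  if (!length(kept)) return(setNames(list(), character()))
  byNs <- split(kept, dag@namespaces[kept])
  lapply(byNs, function(x) sort(x))
}

#' Estimate per-term information content
#'
#' IC(x) = -log Pr(x | parents(x)), with the conditional probability
#' estimated from annotation counts as n(x) / n(parents(x)), where n(x)
#' is the number of proteins annotated with x and n(parents(x)) the number
#' annotated with all direct parents of x (the whole corpus for roots).
#' Zero or undefined ratios are clamped to 1/(corpus size + 1) before the
#' log so IC stays finite.
#'
#' @param ann a propagated [AnnotationSet-class]; estimate on the training
#'   split only to avoid leakage into evaluation.
#' @param dag the companion [OntologyDAG-class].
#' @param logBase logarithm base (default natural log).
#' @return An [ICTable-class] covering every DAG term.
#' @export
estimateIC <- function(ann, dag, logBase = exp(1)) {
  if (!isTRUE(ann@propagated)) stopf("estimateIC needs propagated annotations")
  nCorpus <- length(ann@annotations)
  if (nCorpus == 0L) stopf("empty annotation corpus")
  termsOfProt <- ann@annotations
  counts <- table(unlist(termsOfProt, use.names = FALSE))
  nOf <- setNames(integer(length(dag@terms)), dag@terms)
  nOf[names(counts)] <- as.integer(counts)
  # n(parents): proteins carrying ALL direct parents. For a single parent
  # this is just its count; for multiple parents, count the intersection.
  protSets <- lapply(termsOfProt, identity)
  byTerm <- new.env(parent = emptyenv())
  for (p in names(protSets)) for (t in protSets[[p]])
    byTerm[[t]] <- c(byTerm[[t]], p)
  clampP <- 1 / (nCorpus + 1)
  ic <- vapply(dag@terms, function(t) {
    par <- dag@parents[[t]]
    nPar <- if (!length(par)) {
      nCorpus
    } else if (length(par) == 1L) {
      nOf[[par]]
    } else {
      common <- byTerm[[par[1L]]] %||% character()
      for (q in par[-1L]) common <- intersect(common, byTerm[[q]] %||% character())
      length(common)
    }
    pr <- if (nOf[[t]] == 0L || nPar == 0L) clampP else nOf[[t]] / nPar
    pr <- min(max(pr, clampP), 1)
    -log(pr) / log(logBase)
  }, numeric(1L))
  new("ICTable", ic = ic, logBase = logBase)
}

#' Restrict an annotation set to a subset of proteins
#'
#' @param ann an [AnnotationSet-class].
#' @param keep character vector of protein accessions.
#' @return The restricted [AnnotationSet-class] (propagation flag kept).
#' @export
subsetAnnotations <- function(ann, keep) {
  sel <- intersect(names(ann@annotations), keep)
  ev <- ann@evidence
  new("AnnotationSet",
      annotations = ann@annotations[sel],
      evidence = ev[ev$protein %in% keep, , drop = FALSE],
      propagated = ann@propagated)
}
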