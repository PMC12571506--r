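#' @name accessors
#' @title Accessors for pfnet classes
#'
#' @description Small read-only accessors so user code never touches slots.
#'
#' @param x an object of the documented class.
#' @return The corresponding component.
NULL

#' @rdname accessors
#' @export
setGeneric("goTerms", function(x) standardGeneric("goTerms"))

#' @rdname accessors
#' @export
setGeneric("namespaceOf", function(x) standardGeneric("namespaceOf"))

#' @rdname accessors
#' @export
setGeneric("parentsOf", function(x) standardGeneric("parentsOf"))

#' @rdname accessors
#' @export
setGeneric("rootsOf", function(x) standardGeneric("rootsOf"))

#' @rdname accessors
#' @export
setGeneric("annotationsOf", function(x) standardGeneric("annotationsOf"))

#' @rdname accessors
#' @export
setGeneric("isPropagated", function(x) standardGeneric("isPropagated"))

#' @rdname accessors
#' @export
setGeneric("icValues", function(x) standardGeneric("icValues"))

#' @rdname accessors
#' @export
setGeneric("signaturesOf", function(x) standardGeneric("signaturesOf"))

#' @rdname accessors
#' @export
setGeneric("membersOf", function(x) standardGeneric("membersOf"))

#' @rdname accessors
#' @export
setGeneric("signatureTypes", function(x) standardGeneric("signatureTypes"))

#' @rdname accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname accessors
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' @rdname accessors
#' @export
setGeneric("termLabels", function(x) standardGeneric("termLabels"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("embeddingValues", function(x) standardGeneric("embeddingValues"))

#' @rdname accessors
#' @export
setMethod("goTerms", "OntologyDAG", function(x) x@terms)

#' @rdname accessors
#' @export
setMethod("namespaceOf", "OntologyDAG", function(x) x@namespaces)

#' @rdname accessors
#' @export
setMethod("parentsOf", "OntologyDAG", function(x) x@parents)

#' @rdname accessors
#' @export
setMethod("rootsOf", "OntologyDAG", function(x) x@roots)

#' @rdname accessors
#' @export
setMethod("annotationsOf", "AnnotationSet", function(x) x@annotations)

#' @rdname accessors
#' @export
setMethod("isPropagated", "AnnotationSet", function(x) x@propagated)

#' @rdname accessors
#' @export
setMethod("icValues", "ICTable", function(x) x@ic)

#' @rdname accessors
#' @export
setMethod("signaturesOf", "SignatureCatalog", function(x) x@signaturesOf)

#' @rdname accessors
#' @export
setMethod("membersOf", "SignatureCatalog", function(x) x@membersOf)

#' @rdname accessors
#' @export
setMethod("signatureTypes", "SignatureCatalog", function(x) x@typeOf)

#' @rdname accessors
#' @export
setMethod("nodes", "ProteinFamilyNetwork", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("edges", "ProteinFamilyNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("proteins", "EmbeddingMatrix", function(x) x@proteins)

#' @rdname accessors
#' @export
setMethod("proteins", "PredictionMatrix", function(x) x@proteins)

#' @rdname accessors
#' @export
setMethod("termLabels", "PredictionMatrix", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("scores", "PredictionMatrix", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("embeddingValues", "EmbeddingMatrix", function(x) x@values)

setMethod("show", "OntologyDAG", function(object) {
  ns <- table(object@namespaces)
  cat("OntologyDAG with", length(object@terms), "terms (",
      paste(names(ns), as.integer(ns), collapse = ", "), ")\n")
  cat("  roots:", paste(head(object@roots, 3L), collapse = ", "),
      if (length(object@roots) > 3L) "..." else "", "\n")
  cat("  alt ids:", length(object@altIds), "\n")
})

setMethod("show", "AnnotationSet", function(object) {
  cat("AnnotationSet:", length(object@annotations), "proteins,",
      sum(lengths(object@annotations)), "protein-term pairs;",
      if (object@propagated) "propagated" else "unpropagated", "\n")
})

setMethod("show", "ICTable", function(object) {
  cat("ICTable over", length(object@ic), "terms, log base",
      format(object@logBase, digits = 4), "\n")
})

setMethod("show", "SignatureCatalog", function(object) {
  cat("SignatureCatalog:", length(object@signaturesOf), "proteins,",
      length(object@membersOf), "signatures\n")
  if (length(object@typeOf))
    print(table(object@typeOf))
})

setMethod("show", "ProteinFamilyNetwork", function(object) {
  s <- graphStats(object)
  cat("ProteinFamilyNetwork:", s$nodes, "nodes,", s$edges,
      "edges, mean degree", format(s$meanDegree, digits = 4),
      ",", s$isolated, "isolated\n")
})

setMethod("show", "EmbeddingMatrix", function(object) {
  cat("EmbeddingMatrix:", nrow(object@values), "proteins x",
      ncol(object@values), "dims [", object@providerTag, "]\n")
})

setMethod("show", "PredictionMatrix", function(object) {
  cat("PredictionMatrix:", length(object@proteins), "proteins x",
      length(object@labels), "labels\n")
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf(
    "EvaluationReport [%s] n=%d  Fmax=%.4f (tau*=%.2f)  Smin=%.4f  AUPRC=%s\n",
    object@namespace, object@n, object@fmax, object@tauStar, object@smin,
    ifelse(is.na(object@auprc), "NA", sprintf("%.4f", object@auprc))))
})

setMethod("show", "SyntheticWorld", function(object) {
  p <- object@params
  cat("SyntheticWorld:", length(object@splits), "proteins,",
      length(goTerms(object@dag)), "terms,",
      length(membersOf(object@catalog)), "signatures; seed",
      p$seed, "\n")
  print(table(object@splits))
})
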