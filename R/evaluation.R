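# CAFA-style evaluation: hierarchical score propagation, protein-centric
# precision/recall over a threshold grid, Fmax, IC-weighted remaining
# uncertainty / misinformation and Smin, micro-averaged AUPRC, and
# per-group (e.g. per-taxon) breakdowns.
#
# Conventions: predictions are max-propagated up the DAG before scoring;
# root terms are excluded from both predicted and truth sets; precision
# at a threshold averages over only the m(tau) proteins predicting at
# least one term, recall over all n proteins with non-empty truth;
# proteins with empty truth are excluded from n.

#' Default CAFA threshold grid
#'
#' 101 thresholds 0.00, 0.01, ..., 1.00.
#' @return numeric vector.
#' @export
defaultTauGrid <- function() seq(0, 1, by = 0.01)

#' Propagate prediction scores up the ontology
#'
#' Replaces each term's score by the maximum over itself and all of its
#' descendants present in the label set, so parent scores never fall
#' below child scores. Idempotent.
#'
#' @param preds a [PredictionMatrix-class].
#' @param dag the companion [OntologyDAG-class].
#' @return A hierarchically consistent [PredictionMatrix-class].
#' @export
propagateScores <- function(preds, dag) {
  lab <- preds@labels
  missing <- setdiff(lab, dag@terms)
  if (length(missing))
    stopf("labels absent from the DAG: %s",
          paste(head(missing, 5L), collapse = ", "))
  anc <- ancestorsOf(dag, lab)
  sc <- preds@scores
  out <- sc
  for (k in seq_along(lab)) {
    up <- intersect(setdiff(anc[[lab[k]]], lab[k]), lab)
    if (length(up)) {
      j <- match(up, lab)
      out[, j] <- pmax(out[, j, drop = FALSE],
                       matrix(sc[, k], nrow(sc), length(j)))
    }
  }
  new("PredictionMatrix", proteins = preds@proteins, labels = lab,
      scores = out)
}

# build the truth 0/1 matrix aligned to preds; drops root terms and
# proteins with empty truth. Returns list(P=score matrix, T=truth matrix).
.alignTruth <- function(preds, truth, dag = NULL, lenient = FALSE) {
  if (!isTRUE(truth@propagated))
    stopf("evaluation needs propagated ground truth")
  lab <- preds@labels
  if (!is.null(dag)) lab <- setdiff(lab, dag@roots)
  prot <- preds@proteins
  missing <- setdiff(prot, names(truth@annotations))
  if (length(missing)) {
    if (!lenient)
      stopf("proteins missing from ground truth: %s",
            paste(head(missing, 5L), collapse = ", "))
    prot <- setdiff(prot, missing)
  }
  tm <- .targetMatrix(truth, prot, lab)
  keep <- rowSums(tm) > 0
  prot <- prot[keep]
  sc <- preds@scores[match(prot, preds@proteins), match(lab, preds@labels),
                     drop = FALSE]
  list(scores = sc, truth = tm[keep, , drop = FALSE], proteins = prot,
       labels = lab)
}

#' Protein-centric precision and recall at one threshold
#'
#' A protein's predicted set at threshold `tau` is every label scoring
#' `>= tau`, except that a score of exactly 0 never counts as a
#' prediction (the CAFA convention: an unscored term was not submitted,
#' so the tau = 0 grid point evaluates "all submitted predictions").
#' Precision averages the per-protein precision over only the
#' `m` proteins with a non-empty predicted set; recall averages over all
#' `n` proteins (all of which have non-empty truth). Returns `pr = NA`
#' when `m = 0`.
#'
#' @param scores numeric matrix proteins x labels.
#' @param truthMat 0/1 matrix of the same shape.
#' @param tau threshold in \[0, 1\].
#' @return list with pr, rc, m.
#' @export
precisionRecallAtTau <- function(scores, truthMat, tau) {
  P <- scores >= tau & scores > 0
  tp <- rowSums(P & (truthMat > 0))
  predN <- rowSums(P)
  truthN <- rowSums(truthMat > 0)
  hasPred <- predN > 0
  m <- sum(hasPred)
  pr <- if (m == 0L) NA_real_ else mean(tp[hasPred] / predN[hasPred])
  rc <- mean(ifelse(truthN > 0, tp / truthN, 0))
  list(pr = pr, rc = rc, m = m)
}

#' Fmax over a threshold grid
#'
#' F(tau) is the harmonic mean of precision and recall where both are
#' defined and positive, else 0; Fmax is the maximum over the grid and
#' tauStar the smallest threshold attaining it.
#'
#' @param scores,truthMat as in [precisionRecallAtTau()].
#' @param grid threshold grid (default [defaultTauGrid()]).
#' @return list with fmax, tauStar, curve (data.frame tau, pr, rc, f, m).
#' @export
fmaxCurve <- function(scores, truthMat, grid = defaultTauGrid()) {
  if (!length(grid)) stopf("empty threshold grid")
  rows <- lapply(grid, function(tau) {
    prm <- precisionRecallAtTau(scores, truthMat, tau)
    f <- if (is.na(prm$pr) || (prm$pr + prm$rc) <= 0) 0
         else 2 * prm$pr * prm$rc / (prm$pr + prm$rc)
    data.frame(tau = tau, pr = prm$pr, rc = prm$rc, f = f, m = prm$m)
  })
  curve <- do.call(rbind, rows)
  best <- which.max(curve$f)
  list(fmax = curve$f[best], tauStar = curve$tau[best], curve = curve)
}

#' Smin over a threshold grid
#'
#' Remaining uncertainty ru(tau) is the mean total information content of
#' truth terms not predicted; misinformation mi(tau) the mean total IC of
#' predicted terms not in the truth. Smin is the minimum Euclidean norm
#' sqrt(ru^2 + mi^2) over the grid.
#'
#' @param scores,truthMat as in [precisionRecallAtTau()].
#' @param ic an [ICTable-class] (terms missing from the table get the
#'   clamped maximum IC of the estimation corpus via [estimateIC()]; here
#'   absent labels simply error).
#' @param grid threshold grid.
#' @return list with smin, tauStar, curve (data.frame tau, ru, mi, s).
#' @export
sminCurve <- function(scores, truthMat, ic, grid = defaultTauGrid()) {
  lab <- colnames(scores)
  icv <- icValues(ic)[lab]
  if (anyNA(icv))
    stopf("IC missing for labels: %s",
          paste(head(lab[is.na(icv)], 5L), collapse = ", "))
  if (any(icv < 0)) stopf("negative IC values")
  rows <- lapply(grid, function(tau) {
    P <- scores >= tau & scores > 0
    Tm <- truthMat > 0
    ru <- mean((Tm & !P) %*% icv)
    mi <- mean((P & !Tm) %*% icv)
    data.frame(tau = tau, ru = ru, mi = mi, s = sqrt(ru^2 + mi^2))
  })
  curve <- do.call(rbind, rows)
  best <- which.min(curve$s)
  list(smin = curve$s[best], tauStar = curve$tau[best], curve = curve)
}

#' Micro-averaged area under the precision-recall curve
#'
#' All (protein, label) pairs are pooled into one ranking; the area is
#' the step-wise sum (average precision): sum over distinct thresholds of
#' (recall increment) x (precision at that threshold), with no
#' interpolation. Macro averaging over labels is available via `average`.
#'
#' @param scores numeric matrix proteins x labels.
#' @param truthMat 0/1 matrix of the same shape.
#' @param average `"micro"` (default) or `"macro"` (mean AP over labels
#'   with at least one positive).
#' @return numeric scalar in \[0, 1\].
#' @export
auprc <- function(scores, truthMat, average = c("micro", "macro")) {
  average <- match.arg(average)
  ap <- function(s, y) {
    if (sum(y) == 0) stopf("AUPRC undefined with zero positives")
    ord <- order(s, decreasing = TRUE)
    s <- s[ord]; y <- y[ord]
    tp <- cumsum(y); fp <- cumsum(1 - y)
    # evaluate at the last index of each distinct score (threshold)
    lastOfTie <- c(diff(s) != 0, TRUE)
    tp <- tp[lastOfTie]; fp <- fp[lastOfTie]
    prec <- tp / (tp + fp)
    rec <- tp / sum(y)
    dRec <- diff(c(0, rec))
    sum(dRec * prec)
  }
  if (average == "micro") {
    ap(as.vector(scores), as.vector(truthMat > 0) * 1)
  } else {
    pos <- colSums(truthMat > 0) > 0
    mean(vapply(which(pos), function(j)
      ap(scores[, j], truthMat[, j] * 1), numeric(1L)))
  }
}

#' Full CAFA evaluation of a prediction matrix
#'
#' Max-propagates scores up the DAG, drops root terms and proteins with
#' empty truth, and computes the Fmax curve, Smin curve and micro AUPRC
#' in one report. All labels must belong to a single namespace.
#'
#' @param preds a [PredictionMatrix-class].
#' @param truth a propagated [AnnotationSet-class].
#' @param dag the companion [OntologyDAG-class].
#' @param ic an [ICTable-class] (training-split estimate).
#' @param grid threshold grid (default [defaultTauGrid()]).
#' @param lenient drop proteins missing from the truth instead of erroring.
#' @return An [EvaluationReport-class].
#' @export
evaluatePredictions <- function(preds, truth, dag, ic,
                                grid = defaultTauGrid(), lenient = FALSE) {
  ns <- unique(dag@namespaces[intersect(preds@labels, dag@terms)])
  if (length(ns) > 1L)
    stopf("labels span multiple namespaces: %s", paste(ns, collapse = ", "))
  preds <- propagateScores(preds, dag)
  al <- .alignTruth(preds, truth, dag, lenient = lenient)
  if (!length(al$proteins))
    stopf("no proteins with non-empty ground truth to evaluate")
  fm <- fmaxCurve(al$scores, al$truth, grid)
  sm <- sminCurve(al$scores, al$truth, ic, grid)
  au <- auprc(al$scores, al$truth)
  curve <- cbind(fm$curve, ru = sm$curve$ru, mi = sm$curve$mi)
  new("EvaluationReport",
      n = length(al$proteins), fmax = fm$fmax, tauStar = fm$tauStar,
      smin = sm$smin, auprc = au, curve = curve,
      namespace = if (length(ns)) ns else NA_character_)
}

#' Per-group evaluation breakdown
#'
#' Computes an independent [EvaluationReport-class] for each group of
#' proteins (e.g. taxa). Groups that end up with no evaluable protein are
#' omitted with a warning.
#'
#' @param preds,truth,dag,ic,grid as in [evaluatePredictions()].
#' @param groupMap named character vector, protein -> group id.
#' @param lenient proteins absent from `groupMap` are bucketed as
#'   "unassigned" when TRUE; otherwise they raise an error.
#' @return Named list, group id -> [EvaluationReport-class].
#' @export
evaluateByGroup <- function(preds, truth, dag, ic, groupMap,
                            grid = defaultTauGrid(), lenient = FALSE) {
  grp <- groupMap[preds@proteins]
  if (anyNA(grp)) {
    if (!lenient)
      stopf("proteins missing from groupMap: %s",
            paste(head(preds@proteins[is.na(grp)], 5L), collapse = ", "))
    grp[is.na(grp)] <- "unassigned"
  }
  out <- list()
  for (g in unique(grp)) {
    ids <- preds@proteins[grp == g]
    sub <- new("PredictionMatrix", proteins = ids, labels = preds@labels,
               scores = preds@scores[match(ids, preds@proteins), ,
                                     drop = FALSE])
    rep <- tryCatch(
      evaluatePredictions(sub, truth, dag, ic, grid, lenient = TRUE),
      error = function(e) NULL)
    if (is.null(rep)) warning(sprintf("group '%s' omitted: no evaluable proteins", g))
    else out[[g]] <- rep
  }
  out
}

#' Write / read CAFA-style prediction files
#'
#' Three tab-separated columns: protein accession, term id, score.
#'
#' @param preds a [PredictionMatrix-class].
#' @param path destination / source file.
#' @param minScore rows with scores below this are not written (default 0,
#'   write everything).
#' @return `readPredictions` returns a [PredictionMatrix-class].
#' @export
writePredictions <- function(preds, path, minScore = 0) {
  sc <- preds@scores
  idx <- which(sc >= minScore, arr.ind = TRUE)
  lines <- sprintf("%s\t%s\t%.6f",
                   preds@proteins[idx[, 1L]], preds@labels[idx[, 2L]],
                   sc[idx])
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writePredictions
#' @export
readPredictions <- function(path) {
  d <- read.delim(path, header = FALSE,
                  col.names = c("protein", "term", "score"),
                  stringsAsFactors = FALSE)
  prot <- unique(d$protein); lab <- sort(unique(d$term))
  sc <- matrix(0, length(prot), length(lab),
               dimnames = list(prot, lab))
  sc[cbind(match(d$protein, prot), match(d$term, lab))] <- d$score
  new("PredictionMatrix", proteins = prot, labels = lab, scores = sc)
}
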