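# independent brute-force oracles; deliberately written with explicit
# loops and set operations, never sharing code paths with the package

# transitive ancestor closure by repeated parent expansion
oracleClosure <- function(parents, term) {
  out <- term
  repeat {
    grown <- unique(c(out, unlist(parents[out], use.names = FALSE)))
    if (length(grown) == length(out)) return(sort(out))
    out <- grown
  }
}

# per-term protein counts by explicit enumeration
oracleTermCounts <- function(annList) {
  counts <- list()
  for (p in names(annList)) for (t in annList[[p]])
    counts[[t]] <- c(counts[[t]], p)
  vapply(counts, function(x) length(unique(x)), integer(1L))
}

# O(n^2) pairwise shared-signature edges
oraclePFNEdges <- function(sigOf, proteins, qualifying) {
  edges <- character()
  for (i in seq_along(proteins)) for (j in seq_len(i - 1L)) {
    a <- proteins[j]; b <- proteins[i]
    shared <- intersect(intersect(sigOf[[a]], sigOf[[b]]), qualifying)
    if (length(shared)) {
      e <- sort(c(a, b))
      edges <- c(edges, paste(e[1L], e[2L]))
    }
  }
  sort(edges)
}

# CAFA metrics with every Pi(tau) materialized as an explicit set
oracleCafa <- function(scores, truthList, labels, icv, grid) {
  n <- nrow(scores)
  rows <- data.frame()
  for (tau in grid) {
    prs <- c(); tps <- 0
    m <- 0L; rcSum <- 0; ruSum <- 0; miSum <- 0
    for (i in seq_len(n)) {
      Pi <- labels[scores[i, ] >= tau & scores[i, ] > 0]
      Ti <- truthList[[i]]
      if (length(Pi) > 0L) {
        m <- m + 1L
        prs <- c(prs, length(intersect(Pi, Ti)) / length(Pi))
      }
      rcSum <- rcSum + length(intersect(Pi, Ti)) / length(Ti)
      ruSum <- ruSum + sum(icv[setdiff(Ti, Pi)])
      miSum <- miSum + sum(icv[setdiff(Pi, Ti)])
    }
    pr <- if (m == 0L) NA_real_ else mean(prs)
    rc <- rcSum / n
    f <- if (is.na(pr) || pr + rc <= 0) 0 else 2 * pr * rc / (pr + rc)
    rows <- rbind(rows, data.frame(
      tau = tau, pr = pr, rc = rc, f = f, m = m,
      ru = ruSum / n, mi = miSum / n,
      s = sqrt((ruSum / n)^2 + (miSum / n)^2)))
  }
  list(curve = rows, fmax = max(rows$f),
       tauStar = rows$tau[which.max(rows$f)],
       smin = min(rows$s))
}

# micro AUPRC by explicit threshold sweep with direct counting
oracleAUPRC <- function(scores, truthMat) {
  s <- as.vector(scores); y <- as.vector(truthMat > 0)
  thr <- sort(unique(s), decreasing = TRUE)
  nPos <- sum(y)
  prevRec <- 0; area <- 0
  for (t in thr) {
    pred <- s >= t
    tp <- sum(pred & y)
    prec <- tp / sum(pred)
    rec <- tp / nPos
    area <- area + (rec - prevRec) * prec
    prevRec <- rec
  }
  area
}

# random small DAG as a bare parent list (term ids T01..)
oracleRandomParents <- function(nTerms, maxParents = 2L) {
  ids <- sprintf("T%02d", seq_len(nTerms))
  parents <- list()
  parents[[ids[1L]]] <- character()
  for (k in seq_len(nTerms)[-1L]) {
    np <- sample.int(min(maxParents, k - 1L), 1L)
    parents[[ids[k]]] <- ids[sample.int(k - 1L, np)]
  }
  parents
}

# wrap a bare parent list into an OntologyDAG (single namespace)
dagFromParents <- function(parents, namespace = "MFO") {
  ids <- names(parents)
  pfnet:::newOntologyDAG(ids, stats::setNames(rep(namespace, length(ids)),
                                              ids), parents)
}
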