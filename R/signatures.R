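# InterProScan parsing, binary signature vectors and the protein family
# network (PFN): proteins sharing a family, domain or motif signature are
# linked by an edge (clique expansion per signature).

.SIG_TYPES <- c("FAMILY", "DOMAIN", "MOTIF", "SITE", "OTHER")

# internal constructor from a two-column (protein, signature) frame
newSignatureCatalog <- function(protein, signature, type = NULL) {
  d <- data.frame(protein = protein, signature = signature,
                  stringsAsFactors = FALSE)
  d <- d[!duplicated(d), , drop = FALSE]
  sigOf <- lapply(split(d$signature, d$protein), unique)
  memOf <- lapply(split(d$protein, d$signature), unique)
  tp <- setNames(rep("OTHER", length(memOf)), names(memOf))
  if (!is.null(type) && length(type)) {
    type <- type[names(type) %in% names(memOf)]
    tp[names(type)] <- ifelse(type %in% .SIG_TYPES, type, "OTHER")
  }
  new("SignatureCatalog", signaturesOf = sigOf, membersOf = memOf,
      typeOf = tp)
}

#' Parse InterProScan tabular output
#'
#' Reads the InterProScan TSV dialect: >= 13 tab-separated columns with the
#' protein accession in column 1, member database in column 4, member
#' signature accession in column 5, integrated InterPro accession in
#' column 12 ("-" when unintegrated) and description in column 13. An
#' optional 14th column carrying an entry type (FAMILY/DOMAIN/MOTIF/SITE)
#' is honored when present; otherwise signatures get type OTHER.
#'
#' One catalog entry is kept per distinct (protein, signature); multiple
#' match locations collapse silently.
#'
#' @param path path to the TSV file.
#' @param useIntegrated when TRUE (default) the signature id is the
#'   integrated InterPro accession where available, falling back to the
#'   member-database id; when FALSE the member id is always used.
#' @return A [SignatureCatalog-class].
#' @export
parseInterProScan <- function(path, useIntegrated = TRUE) {
  if (!file.exists(path)) stopf("InterProScan file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(newSignatureCatalog(character(), character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc < 13L))
    stopf("InterProScan row %d has %d columns (need >= 13)",
          which(nc < 13L)[1L], min(nc))
  prot <- vapply(parts, `[`, "", 1L)
  memberId <- vapply(parts, `[`, "", 5L)
  iprId <- vapply(parts, `[`, "", 12L)
  sig <- if (useIntegrated) ifelse(iprId == "-" | iprId == "", memberId, iprId)
         else memberId
  type <- vapply(parts, function(p)
    if (length(p) >= 14L && p[14L] %in% .SIG_TYPES) p[14L] else "OTHER", "")
  # first-seen type wins per signature
  tp <- tapply(type, sig, `[`, 1L)
  newSignatureCatalog(prot, sig, setNames(as.character(tp), names(tp)))
}

#' Binary protein-signature matrix
#'
#' 0/1 matrix with one row per requested protein and one column per
#' vocabulary signature; entry (i, j) is 1 iff protein i carries signature
#' j. The vocabulary should be frozen from the training catalog; proteins
#' absent from the catalog get all-zero rows and signatures outside the
#' vocabulary are ignored.
#'
#' @param catalog a [SignatureCatalog-class].
#' @param proteinIds ordered accessions (no duplicates).
#' @param vocabulary ordered signature ids.
#' @return numeric matrix with dimnames (proteinIds, vocabulary).
#' @export
binarySignatureMatrix <- function(catalog, proteinIds, vocabulary) {
  if (anyDuplicated(proteinIds)) stopf("duplicate protein accessions")
  m <- matrix(0, length(proteinIds), length(vocabulary),
              dimnames = list(proteinIds, vocabulary))
  sOf <- catalog@signaturesOf
  for (i in seq_along(proteinIds)) {
    s <- sOf[[proteinIds[i]]]
    if (length(s)) {
      j <- match(intersect(s, vocabulary), vocabulary)
      if (length(j)) m[i, j] <- 1
    }
  }
  m
}

#' Build the protein family network
#'
#' For every signature of a qualifying entry type, all pairs of member
#' proteins (restricted to `proteinIds`) are connected; the number of
#' distinct shared qualifying signatures is kept per edge as metadata.
#' Proteins without qualifying signatures become isolated nodes.
#'
#' @param catalog a [SignatureCatalog-class].
#' @param proteinIds ordered node accessions.
#' @param qualifyingTypes signature entry types that induce edges
#'   (default FAMILY, DOMAIN, MOTIF).
#' @param maxGroupSize optional cap: signatures with more members than
#'   this are skipped, guarding against clique explosion from promiscuous
#'   signatures (default NULL = no cap).
#' @return A [ProteinFamilyNetwork-class].
#' @export
buildPFN <- function(catalog, proteinIds,
                     qualifyingTypes = c("FAMILY", "DOMAIN", "MOTIF"),
                     maxGroupSize = NULL) {
  qual <- names(catalog@typeOf)[catalog@typeOf %in% qualifyingTypes]
  allA <- character(0); allB <- character(0)
  protSet <- proteinIds
  for (s in qual) {
    mem <- intersect(catalog@membersOf[[s]], protSet)
    k <- length(mem)
    if (k < 2L) next
    if (!is.null(maxGroupSize) && k > maxGroupSize) next
    mem <- sort(mem)
    idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    allA <- c(allA, mem[idx[, 1L]])
    allB <- c(allB, mem[idx[, 2L]])
  }
  if (length(allA)) {
    key <- paste(allA, allB, sep = "\r")
    cnt <- table(key)
    uk <- names(cnt)
    bits <- strsplit(uk, "\r", fixed = TRUE)
    e <- cbind(vapply(bits, `[`, "", 1L), vapply(bits, `[`, "", 2L))
    ord <- order(e[, 1L], e[, 2L])
    e <- e[ord, , drop = FALSE]
    sc <- as.integer(cnt)[ord]
  } else {
    e <- matrix(character(), 0L, 2L)
    sc <- integer()
  }
  new("ProteinFamilyNetwork", nodes = proteinIds, edges = e,
      sharedCount = sc)
}

#' Write / read a binary signature matrix in sparse coordinate form
#'
#' Text format: a `# proteins:` and a `# vocabulary:` header line, then
#' one `i<TAB>j` row per nonzero entry (1-based indices).
#'
#' @param m 0/1 matrix with dimnames as from [binarySignatureMatrix()].
#' @param path destination / source file.
#' @return `readBinaryMatrix` returns the matrix.
#' @export
writeBinaryMatrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# proteins: ", paste(rownames(m), collapse = ",")), con)
  writeLines(paste0("# vocabulary: ", paste(colnames(m), collapse = ",")),
             con)
  idx <- which(m != 0, arr.ind = TRUE)
  if (nrow(idx))
    writeLines(paste(idx[, 1L], idx[, 2L], sep = "\t"), con)
  invisible(path)
}

#' @rdname writeBinaryMatrix
#' @export
readBinaryMatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(tag) strsplit(sub(paste0("^# ", tag, ": "), "",
                                     lines[startsWith(lines,
                                                      paste0("# ", tag))][1L]),
                                 ",", fixed = TRUE)[[1L]]
  prot <- grab("proteins"); vocab <- grab("vocabulary")
  m <- matrix(0, length(prot), length(vocab),
              dimnames = list(prot, vocab))
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    i <- as.integer(vapply(parts, `[`, "", 1L))
    j <- as.integer(vapply(parts, `[`, "", 2L))
    m[cbind(i, j)] <- 1
  }
  m
}

#' Summary statistics of a protein family network
#'
#' @param pfn a [ProteinFamilyNetwork-class].
#' @return list with nodes, edges, meanDegree (2E/N) and isolated count.
#' @export
graphStats <- function(pfn) {
  nN <- length(pfn@nodes)
  nE <- nrow(pfn@edges)
  if (nN == 0L)
    return(list(nodes = 0L, edges = 0L, meanDegree = 0, isolated = 0L))
  touched <- unique(as.vector(pfn@edges))
  list(nodes = nN, edges = nE,
       meanDegree = 2 * nE / nN,
       isolated = nN - length(touched))
}

#' Write / read a PFN edge list
#'
#' Two-column TSV of edges plus a `# nodes:` header line preserving
#' isolated nodes.
#'
#' @param pfn a [ProteinFamilyNetwork-class].
#' @param path destination / source file.
#' @return `readPFN` returns the [ProteinFamilyNetwork-class].
#' @export
writePFN <- function(pfn, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# nodes: ", paste(pfn@nodes, collapse = ",")), con)
  if (nrow(pfn@edges))
    writeLines(paste(pfn@edges[, 1L], pfn@edges[, 2L],
                     pfn@sharedCount, sep = "\t"), con)
  invisible(path)
}

#' @rdname writePFN
#' @export
readPFN <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "# nodes: ")]
  nodes <- strsplit(sub("^# nodes: ", "", hdr[1L]), ",", fixed = TRUE)[[1L]]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    e <- cbind(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
    sc <- as.integer(vapply(parts, `[`, "", 3L))
  } else {
    e <- matrix(character(), 0L, 2L); sc <- integer()
  }
  new("ProteinFamilyNetwork", nodes = nodes, edges = e, sharedCount = sc)
}

# adjacency list (integer indices) used by sampling and inference
.adjacencyList <- function(pfn) {
  n <- length(pfn@nodes)
  if (!nrow(pfn@edges)) return(rep(list(integer()), n))
  i <- match(pfn@edges[, 1L], pfn@nodes)
  j <- match(pfn@edges[, 2L], pfn@nodes)
  unname(split(c(j, i), factor(c(i, j), levels = seq_len(n))))
}
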