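# Fixed-width per-protein feature vectors: load precomputed protein
# language-model embeddings (mean-pooled encoder states, typically 1536-d)
# or generate deterministic synthetic stand-ins with optional class signal.

#' Load per-protein embeddings
#'
#' Two on-disk forms are supported and detected by extension: a TSV (one
#' row per protein, accession in the first column followed by the
#' embedding values, no header) and a keyed binary container (`.rds`
#' holding a named list accession -> numeric vector). Rows are returned
#' in the order of `proteinIds` and widths are checked for consistency.
#'
#' @param path path to the embedding file.
#' @param proteinIds ordered accessions to extract.
#' @param normalize if TRUE, rows are L2-normalized (default FALSE).
#' @return An [EmbeddingMatrix-class].
#' @export
loadEmbeddings <- function(path, proteinIds, normalize = FALSE) {
  if (!file.exists(path)) stopf("embedding file not found: %s", path)
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    store <- readRDS(path)
    missing <- setdiff(proteinIds, names(store))
    if (length(missing))
      stopf("embeddings missing for: %s",
            paste(head(missing, 10L), collapse = ", "))
    widths <- unique(lengths(store[proteinIds]))
    if (length(widths) > 1L)
      stopf("ragged embedding widths: %s", paste(widths, collapse = ", "))
    vals <- do.call(rbind, store[proteinIds])
    if (any(!is.finite(vals))) stopf("non-finite embedding values in %s", path)
    if (normalize) {
      nrm <- sqrt(rowSums(vals^2))
      vals <- vals / pmax(nrm, .Machine$double.eps)
    }
    rownames(vals) <- proteinIds
    return(new("EmbeddingMatrix", proteins = proteinIds, values = vals,
               providerTag = sprintf("rds:%s", basename(path))))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(parts) - 1L
  if (length(unique(widths)) > 1L)
    stopf("ragged embedding widths: %s", paste(unique(widths), collapse = ", "))
  acc <- vapply(parts, `[`, "", 1L)
  missing <- setdiff(proteinIds, acc)
  if (length(missing))
    stopf("embeddings missing for: %s",
          paste(head(missing, 10L), collapse = ", "))
  idx <- match(proteinIds, acc)
  vals <- t(vapply(parts[idx], function(p) as.numeric(p[-1L]),
                   numeric(widths[1L])))
  if (any(!is.finite(vals))) stopf("non-finite embedding values in %s", path)
  if (normalize) {
    nrm <- sqrt(rowSums(vals^2))
    vals <- vals / pmax(nrm, .Machine$double.eps)
  }
  rownames(vals) <- proteinIds
  new("EmbeddingMatrix", proteins = proteinIds, values = vals,
      providerTag = sprintf("file:%s", basename(path)))
}

#' Write embeddings in a form read by [loadEmbeddings()]
#'
#' A `.rds` destination writes the keyed binary container; anything else
#' writes the TSV dialect.
#'
#' @param emb an [EmbeddingMatrix-class].
#' @param path destination file.
#' @export
writeEmbeddings <- function(emb, path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    store <- lapply(seq_along(emb@proteins), function(i)
      unname(emb@values[i, ]))
    names(store) <- emb@proteins
    saveRDS(store, path)
    return(invisible(path))
  }
  rows <- apply(emb@values, 1L, function(v)
    paste(format(v, digits = 8, scientific = FALSE, trim = TRUE),
          collapse = "\t"))
  writeLines(paste(emb@proteins, rows, sep = "\t"), path)
  invisible(path)
}

#' Deterministic synthetic protein embeddings
#'
#' Stand-in for a protein language-model encoder. Each protein's vector is
#' unit-variance Gaussian noise keyed by a hash of its accession and the
#' seed (so the matrix is identical regardless of request order), plus an
#' optional class-specific offset so downstream learning has signal: all
#' proteins of the same latent class share one offset vector of the given
#' magnitude.
#'
#' @param proteinIds ordered accessions.
#' @param dim embedding width (>= 1).
#' @param seed integer seed; same inputs and seed give bitwise-identical
#'   matrices.
#' @param signal optional named character vector, protein -> latent class.
#' @param offsetMagnitude L2 length of each class offset (default 3).
#' @return An [EmbeddingMatrix-class].
#' @export
syntheticEmbeddings <- function(proteinIds, dim = 1536L, seed = 1L,
                                signal = NULL, offsetMagnitude = 3) {
  if (dim < 1L) stopf("embedding dim must be >= 1")
  vals <- matrix(0, length(proteinIds), dim,
                 dimnames = list(proteinIds, NULL))
  for (i in seq_along(proteinIds)) {
    h <- stringHash(proteinIds[i], seed)
    vals[i, ] <- withSeed(h, rnorm(dim))
  }
  if (!is.null(signal)) {
    cls <- signal[proteinIds]
    for (cl in unique(cls[!is.na(cls)])) {
      off <- withSeed(stringHash(paste0("class::", cl), seed), rnorm(dim))
      off <- off / sqrt(sum(off^2)) * offsetMagnitude
      rows <- which(cls == cl)
      vals[rows, ] <- sweep(vals[rows, , drop = FALSE], 2L, off, `+`)
    }
  }
  new("EmbeddingMatrix", proteins = proteinIds, values = vals,
      providerTag = sprintf("synthetic:dim=%d,seed=%d", dim, as.integer(seed)))
}
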