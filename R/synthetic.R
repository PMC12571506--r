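# Synthetic benchmark worlds: a random ontology DAG, a signature catalog
# with planted signature-to-term rules, true-path propagated annotations,
# deterministic embeddings with class signal, chronological-style splits
# and taxon assignments. Every reader in the package round-trips the
# files this module writes.

#' Generate a random ontology DAG
#'
#' Grows a single-root DAG mixing recency-biased and uniform attachment,
#' so the graph has both the long specialization chains and the branching
#' of real GO namespaces: term k attaches its primary parent to one of
#' the six most recently created terms with probability 0.5 (uniformly
#' over all earlier terms otherwise), and with probability 0.15 gains a
#' second uniformly chosen parent when `maxParents >= 2`. Acyclic by
#' construction (parents always precede children in creation order).
#'
#' @param nTerms number of terms (>= 1).
#' @param namespace "BPO", "CCO" or "MFO" (default "MFO").
#' @param maxParents maximum direct parents per term (default 2).
#' @param seed integer seed.
#' @param idOffset first numeric id (default 1), handy for disjoint DAGs.
#' @return An [OntologyDAG-class].
#' @export
generateDAG <- function(nTerms, namespace = "MFO", maxParents = 2L,
                        seed = 1L, idOffset = 1L) {
  if (nTerms < 1L) stopf("nTerms must be >= 1")
  if (maxParents < 1L) stopf("maxParents must be >= 1")
  ids <- sprintf("GO:%07d", seq.int(idOffset, length.out = nTerms))
  parents <- withSeed(seed, {
    p <- vector("list", nTerms)
    p[[1L]] <- character()
    for (k in seq_len(nTerms)[-1L]) {
      lo <- max(1L, k - 6L)
      prim <- if (runif(1L) < 0.5) sample(lo:(k - 1L), 1L)
              else sample.int(k - 1L, 1L)
      ps <- ids[prim]
      if (maxParents >= 2L && k > 2L && runif(1L) < 0.15)
        ps <- union(ps, ids[sample.int(k - 1L, 1L)])
      p[[k]] <- ps
    }
    p
  })
  names(parents) <- ids
  nss <- setNames(rep(namespace, nTerms), ids)
  newOntologyDAG(ids, nss, parents)
}

# depth of each term (root = 0), used to pick "leaf-ish" rule targets
.termDepths <- function(dag) {
  memo <- new.env(parent = emptyenv())
  depth <- function(t) {
    got <- memo[[t]]
    if (!is.null(got)) return(got)
    p <- dag@parents[[t]]
    d <- if (!length(p)) 0L else 1L + max(vapply(p, depth, integer(1L)))
    memo[[t]] <- d
    d
  }
  setNames(vapply(dag@terms, depth, integer(1L)), dag@terms)
}

#' Generate a complete synthetic world
#'
#' Builds, deterministically per seed: a DAG ([generateDAG()]); a
#' signature catalog where every protein draws `signaturesPerProtein`
#' signatures uniformly without replacement (entry types cycle through
#' FAMILY/DOMAIN/MOTIF so all signatures qualify for network edges);
#' planted rules mapping each signature to one or two leaf terms;
#' annotations
#' as the true-path propagated union of each protein's rule terms, with
#' each planted term dropped with probability `ruleNoise` and
#' Poisson(`labelNoise`) spurious terms added per protein; taxa assigned
#' round-robin over three model organisms; and a chronological-style
#' 70/15/15 split by protein index.
#'
#' With both noise rates zero, a protein's annotation set is exactly the
#' propagated union of its signatures' rule terms.
#'
#' @param nProteins,nTerms,nSignatures world dimensions (defaults 300,
#'   60, 30).
#' @param signaturesPerProtein signatures drawn per protein (default 2).
#' @param ruleNoise per-term drop probability (default 0.05).
#' @param labelNoise expected spurious terms per protein (default 0.05).
#' @param namespace single namespace for the DAG (default "MFO").
#' @param seed integer seed.
#' @return A [SyntheticWorld-class].
#' @export
generateWorld <- function(nProteins = 300L, nTerms = 60L,
                          nSignatures = 30L, signaturesPerProtein = 2L,
                          ruleNoise = 0.05, labelNoise = 0.05,
                          namespace = "MFO", seed = 1L) {
  if (min(nProteins, nTerms, nSignatures) < 1L)
    stopf("world dimensions must be >= 1")
  if (signaturesPerProtein > nSignatures)
    stopf("signaturesPerProtein exceeds nSignatures")
  if (ruleNoise < 0 || ruleNoise > 1 || labelNoise < 0)
    stopf("noise rates must be valid probabilities / rates")
  dag <- generateDAG(nTerms, namespace, maxParents = 2L, seed = seed)
  ids <- dag@terms
  prot <- sprintf("P%05d", seq_len(nProteins))
  sigs <- sprintf("IPR%06d", seq_len(nSignatures))
  sigTypes <- setNames(rep(c("FAMILY", "DOMAIN", "MOTIF"),
                           length.out = nSignatures), sigs)
  world <- withSeed(seed + 1L, {
    # rules point at leaves so annotation sets are long distinct ancestor
    # chains, not a shared shallow core
    hasChild <- unique(unlist(dag@parents, use.names = FALSE))
    leaves <- setdiff(ids, hasChild)
    if (!length(leaves)) leaves <- ids[length(ids)]
    rules <- lapply(sigs, function(s)
      sort(sample(leaves, min(sample.int(2L, 1L), length(leaves)))))
    names(rules) <- sigs  # 1-2 leaves per signature
    sigOf <- lapply(prot, function(p)
      sort(sigs[sample.int(nSignatures, signaturesPerProtein)]))
    names(sigOf) <- prot
    asserted <- lapply(prot, function(p) {
      planted <- unique(unlist(rules[sigOf[[p]]], use.names = FALSE))
      if (ruleNoise > 0 && length(planted))
        planted <- planted[runif(length(planted)) >= ruleNoise]
      extra <- if (labelNoise > 0) {
        k <- rpois(1L, labelNoise)
        if (k > 0L) sample(ids, min(k, length(ids))) else character()
      } else character()
      unique(c(planted, extra))
    })
    names(asserted) <- prot
    list(rules = rules, sigOf = sigOf, asserted = asserted)
  })
  catalog <- newSignatureCatalog(
    rep(prot, lengths(world$sigOf)),
    unlist(world$sigOf, use.names = FALSE),
    sigTypes)
  ev <- withSeed(seed + 2L, {
    codes <- evidencePreset("EXPERIMENTAL")
    data.frame(
      protein = rep(prot, lengths(world$asserted)),
      term = unlist(world$asserted, use.names = FALSE),
      evidence = sample(codes, sum(lengths(world$asserted)), replace = TRUE),
      stringsAsFactors = FALSE)
  })
  annRaw <- new("AnnotationSet", annotations = world$asserted,
                evidence = ev, propagated = FALSE)
  ann <- propagateAnnotations(annRaw, dag)
  nTr <- floor(0.70 * nProteins)
  nVa <- floor(0.15 * nProteins)
  splits <- setNames(rep("test", nProteins), prot)
  splits[seq_len(nTr)] <- "train"
  if (nVa > 0L) splits[nTr + seq_len(nVa)] <- "valid"
  taxa <- setNames(rep(c("9606", "10090", "3702"),
                       length.out = nProteins), prot)
  latent <- vapply(world$sigOf, `[`, "", 1L)
  new("SyntheticWorld", dag = dag, catalog = catalog, rules = world$rules,
      annotations = ann, splits = splits, taxa = taxa,
      latentClass = latent,
      params = list(nProteins = nProteins, nTerms = nTerms,
                    nSignatures = nSignatures,
                    signaturesPerProtein = signaturesPerProtein,
                    ruleNoise = ruleNoise, labelNoise = labelNoise,
                    namespace = namespace, seed = seed))
}

.OBO_NS <- c(BPO = "biological_process", CCO = "cellular_component",
             MFO = "molecular_function")

#' Write a DAG as OBO text
#'
#' Emits the subset of OBO 1.2 used by [parseOBO()]: id, name, namespace
#' and is_a tags.
#'
#' @param dag an [OntologyDAG-class].
#' @param path destination file.
#' @export
writeOBO <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in dag@terms) {
    writeLines("", con)
    writeLines("[Term]", con)
    writeLines(paste0("id: ", t), con)
    writeLines(paste0("name: synthetic term ", t), con)
    writeLines(paste0("namespace: ", .OBO_NS[[dag@namespaces[[t]]]]), con)
    for (p in dag@parents[[t]])
      writeLines(paste0("is_a: ", p, " ! parent"), con)
  }
  invisible(path)
}

# InterProScan-dialect row for one (protein, signature) pair; 14 columns
# with the entry type in the last
.ipsRow <- function(protein, signature, type) {
  paste(protein, "0000000000000000", "100", "SYNDB", signature,
        "synthetic signature", "1", "100", "1e-10", "T", "01-01-2026",
        signature, "synthetic signature", type, sep = "\t")
}

#' Write all fixture files for a synthetic world
#'
#' Emits, into `directory`: `ontology.obo`, `interproscan.tsv` (the
#' 14-column dialect of [parseInterProScan()]), `annotations.tsv`
#' (asserted annotations with experimental evidence codes),
#' `embeddings.tsv` (deterministic synthetic embeddings keyed to each
#' protein's latent class) and `splits.tsv`. All files round-trip through
#' the package readers.
#'
#' @param world a [SyntheticWorld-class].
#' @param directory output directory (created if needed).
#' @param embeddingDim width of the written embeddings (default 64).
#' @return Named character vector of file paths, invisibly.
#' @export
writeFixtures <- function(world, directory, embeddingDim = 64L) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  f <- c(obo = file.path(directory, "ontology.obo"),
         ips = file.path(directory, "interproscan.tsv"),
         ann = file.path(directory, "annotations.tsv"),
         emb = file.path(directory, "embeddings.tsv"),
         splits = file.path(directory, "splits.tsv"))
  writeOBO(world@dag, f[["obo"]])
  sOf <- world@catalog@signaturesOf
  tp <- world@catalog@typeOf
  rows <- unlist(lapply(names(sOf), function(p)
    vapply(sOf[[p]], function(s) .ipsRow(p, s, tp[[s]]), "")),
    use.names = FALSE)
  writeLines(rows, f[["ips"]])
  ev <- world@annotations@evidence
  writeLines(c("protein_accession\tgo_term\tevidence_code\ttaxon_id",
               paste(ev$protein, ev$term, ev$evidence,
                     world@taxa[ev$protein], sep = "\t")), f[["ann"]])
  prot <- names(world@splits)
  emb <- syntheticEmbeddings(prot, dim = embeddingDim,
                             seed = world@params$seed,
                             signal = world@latentClass)
  writeEmbeddings(emb, f[["emb"]])
  writeLines(c("protein\tsplit",
               paste(prot, world@splits, sep = "\t")), f[["splits"]])
  invisible(f)
}

#' Read a split manifest written by [writeFixtures()]
#'
#' @param path path to splits.tsv.
#' @return named character vector, protein -> split.
#' @export
readSplits <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  setNames(d$split, d$protein)
}
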