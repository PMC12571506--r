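# End-to-end orchestration: assemble pipeline data from a synthetic
# world or from files, run build -> train -> predict -> evaluate per
# seed, summarize across seeds, and back the command-line entry points.

#' Assemble pipeline data from a synthetic world
#'
#' Builds everything [trainModel()] consumes: the PFN over all proteins
#' (transductive: test proteins attach through their signatures), the
#' binary signature matrix on the training-frozen vocabulary, synthetic
#' embeddings keyed to the world's latent classes, the label set
#' (training split, min 10 proteins by default) and the training IC
#' table.
#'
#' @param world a [SyntheticWorld-class].
#' @param embeddingDim width of the synthetic embeddings (default 64).
#' @param minProteins label filter threshold (default 10).
#' @return list with pfn, embeddings, binary, labels, annotations,
#'   splits, dag, ic, taxa, vocabulary.
#' @export
worldPipelineData <- function(world, embeddingDim = 64L, minProteins = 10L) {
  prot <- names(world@splits)
  trainIds <- prot[world@splits == "train"]
  # vocabulary frozen on the training catalog
  vocab <- sort(unique(unlist(world@catalog@signaturesOf[trainIds],
                              use.names = FALSE)))
  binary <- binarySignatureMatrix(world@catalog, prot, vocab)
  pfn <- buildPFN(world@catalog, prot)
  emb <- syntheticEmbeddings(prot, dim = embeddingDim,
                             seed = world@params$seed,
                             signal = world@latentClass)
  trainAnn <- subsetAnnotations(world@annotations, trainIds)
  labelsByNs <- filterLabels(trainAnn, world@dag, minProteins)
  ns <- world@params$namespace
  labels <- labelsByNs[[ns]] %||% character()
  ic <- estimateIC(trainAnn, world@dag)
  list(pfn = pfn, embeddings = emb, binary = binary, labels = labels,
       annotations = world@annotations, splits = world@splits,
       dag = world@dag, ic = ic, taxa = world@taxa, vocabulary = vocab)
}

#' Assemble pipeline data from files
#'
#' File-based twin of [worldPipelineData()]: reads the OBO ontology, the
#' InterProScan TSV, the annotation table (filtered by evidence preset
#' and true-path propagated), the embedding TSV and the split manifest.
#'
#' @param oboPath,ipsPath,annPath,embPath,splitsPath input files.
#' @param namespace namespace to model ("BPO", "CCO" or "MFO").
#' @param evidence evidence preset or code vector (default EXPERIMENTAL).
#' @param minProteins label filter threshold (default 10).
#' @param useIntegrated passed to [parseInterProScan()].
#' @return as [worldPipelineData()].
#' @export
filePipelineData <- function(oboPath, ipsPath, annPath, embPath,
                             splitsPath, namespace,
                             evidence = "EXPERIMENTAL",
                             minProteins = 10L, useIntegrated = TRUE) {
  dag <- parseOBO(oboPath)
  catalog <- parseInterProScan(ipsPath, useIntegrated = useIntegrated)
  raw <- readAnnotations(annPath)
  ann <- propagateAnnotations(filterEvidence(raw, evidence), dag)
  splits <- readSplits(splitsPath)
  prot <- names(splits)
  trainIds <- prot[splits == "train"]
  vocab <- sort(unique(unlist(catalog@signaturesOf[trainIds],
                              use.names = FALSE)))
  binary <- binarySignatureMatrix(catalog, prot, vocab)
  pfn <- buildPFN(catalog, prot)
  emb <- loadEmbeddings(embPath, prot)
  trainAnn <- subsetAnnotations(ann, trainIds)
  labels <- filterLabels(trainAnn, dag, minProteins)[[namespace]] %||%
    character()
  ic <- estimateIC(trainAnn, dag)
  taxa <- setNames(raw$taxon[!duplicated(raw$protein)],
                   raw$protein[!duplicated(raw$protein)])
  list(pfn = pfn, embeddings = emb, binary = binary, labels = labels,
       annotations = ann, splits = splits, dag = dag, ic = ic,
       taxa = taxa, vocabulary = vocab)
}

#' Train, predict and evaluate for one seed
#'
#' @param data pipeline data list (see [worldPipelineData()]).
#' @param config a [modelConfig()]; `vocabSize` and `nLabels` are filled
#'   in from the data when left at 1.
#' @param opt an [optSettings()].
#' @param seed integer seed.
#' @param evalSplit which split to evaluate (default "test").
#' @return list with fit, predictions ([PredictionMatrix-class]) and
#'   report ([EvaluationReport-class]).
#' @export
runPipeline <- function(data, config, opt = optSettings(), seed = 1L,
                        evalSplit = "test") {
  if (!length(data$labels)) stopf("empty label set")
  config$vocabSize <- ncol(data$binary)
  config$nLabels <- length(data$labels)
  config$inputDim <- ncol(data$embeddings@values)
  config$seed <- as.integer(seed)
  fit <- trainModel(data, config, opt, seed = seed)
  ids <- names(data$splits)[data$splits == evalSplit]
  preds <- predictScores(fit, ids, data)
  truth <- subsetAnnotations(data$annotations, ids)
  report <- evaluatePredictions(preds, truth, data$dag, data$ic)
  list(fit = fit, predictions = preds, report = report)
}

#' Multi-seed pipeline runs with a mean/sd summary
#'
#' @param data,config,opt as [runPipeline()].
#' @param seeds integer vector of seeds.
#' @return list with `runs` (per-seed results), `reports`, and `summary`
#'   (mean and standard deviation per metric, from [summarizeRuns()]).
#' @export
multiSeedRun <- function(data, config, opt = optSettings(),
                         seeds = 1:5) {
  if (!length(seeds)) stopf("seeds must be non-empty")
  runs <- lapply(seeds, function(s) runPipeline(data, config, opt, seed = s))
  reports <- lapply(runs, `[[`, "report")
  names(reports) <- paste0("seed", seeds)
  list(runs = runs, reports = reports, summary = summarizeRuns(reports))
}

# serialize an EvaluationReport as a JSON-ready list
reportToList <- function(report) {
  list(namespace = report@namespace, n = report@n, fmax = report@fmax,
       tau_star = report@tauStar, smin = report@smin,
       auprc = report@auprc)
}

#' Write an evaluation report as JSON plus a per-threshold curve CSV
#'
#' @param report an [EvaluationReport-class].
#' @param jsonPath,curvePath output files (curvePath optional).
#' @export
writeReport <- function(report, jsonPath, curvePath = NULL) {
  jsonlite::write_json(reportToList(report), jsonPath, auto_unbox = TRUE,
                       digits = NA, na = "null")
  if (!is.null(curvePath))
    utils::write.csv(report@curve, curvePath, row.names = FALSE)
  invisible(jsonPath)
}

#' Validate a run configuration
#'
#' A run configuration (typically from YAML) must name exactly one
#' namespace and a non-empty seed list; paths are required unless
#' `synthetic` is set.
#'
#' @param cfg list with fields namespace, seeds, mode, and either
#'   `synthetic: yes` or the input paths (obo, interproscan, annotations,
#'   embeddings, splits); optional model/training sub-lists.
#' @return The validated config (with defaults filled), or an error.
#' @export
validateRunConfig <- function(cfg) {
  if (is.null(cfg$namespace) || length(cfg$namespace) != 1L)
    stopf("config error: exactly one namespace per run")
  if (!cfg$namespace %in% c("BPO", "CCO", "MFO"))
    stopf("config error: namespace must be BPO, CCO or MFO")
  if (is.null(cfg$seeds) || !length(cfg$seeds))
    stopf("config error: seeds must be non-empty")
  cfg$mode <- cfg$mode %||% "FULL"
  if (!cfg$mode %in% .MODEL_MODES)
    stopf("config error: mode must be one of %s",
          paste(.MODEL_MODES, collapse = ", "))
  if (!isTRUE(cfg$synthetic)) {
    for (p in c("obo", "interproscan", "annotations", "embeddings",
                "splits")) {
      if (is.null(cfg[[p]]))
        stopf("config error: missing required path '%s'", p)
      if (!file.exists(cfg[[p]]))
        stopf("config error: input file not found: %s", cfg[[p]])
    }
  }
  cfg
}

#' End-to-end command: train and evaluate for every configured seed
#'
#' Reads a YAML configuration (or takes the equivalent list), assembles
#' the pipeline data, runs every seed, and writes per-seed artifacts
#' (predictions TSV, report JSON, curve CSV, checkpoint RDS) plus a
#' cross-seed `summary.json` into the output directory.
#'
#' @param config path to a YAML file or a config list
#'   (see [validateRunConfig()]).
#' @param outputDir output directory (default from config, else "runs").
#' @return Invisibly, the multi-seed result list.
#' @export
cmdRun <- function(config, outputDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validateRunConfig(config)
  outputDir <- outputDir %||% cfg$output %||% "runs"
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  message("resolved config: ", jsonlite::toJSON(cfg, auto_unbox = TRUE))
  data <- if (isTRUE(cfg$synthetic)) {
    wp <- cfg$world %||% list()
    world <- do.call(generateWorld, c(wp, list(
      namespace = cfg$namespace,
      seed = as.integer(cfg$seeds[[1L]]))))
    worldPipelineData(world,
                      embeddingDim = cfg$embeddingDim %||% 64L)
  } else {
    filePipelineData(cfg$obo, cfg$interproscan, cfg$annotations,
                     cfg$embeddings, cfg$splits, cfg$namespace)
  }
  mc <- do.call(modelConfig, c(list(mode = cfg$mode), cfg$model %||% list()))
  oc <- do.call(optSettings, cfg$training %||% list())
  res <- multiSeedRun(data, mc, oc, seeds = as.integer(unlist(cfg$seeds)))
  for (i in seq_along(res$runs)) {
    tag <- names(res$reports)[i]
    writePredictions(res$runs[[i]]$predictions,
                     file.path(outputDir, paste0("predictions_", tag, ".tsv")),
                     minScore = 0.01)
    writeReport(res$runs[[i]]$report,
                file.path(outputDir, paste0("report_", tag, ".json")),
                file.path(outputDir, paste0("curve_", tag, ".csv")))
    saveRDS(list(params = res$runs[[i]]$fit$params,
                 config = res$runs[[i]]$fit$config,
                 labels = res$runs[[i]]$fit$labels,
                 vocabularyHash = stringHash(paste(data$vocabulary,
                                                   collapse = ","))),
            file.path(outputDir, paste0("checkpoint_", tag, ".rds")))
  }
  perSeed <- lapply(res$reports, reportToList)
  jsonlite::write_json(
    list(seeds = perSeed,
         summary = res$summary),
    file.path(outputDir, "summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null")
  invisible(res)
}

#' Generate and write a synthetic fixture set
#'
#' Wraps [generateWorld()] + [writeFixtures()] and prints a manifest.
#'
#' @param directory output directory.
#' @param seed integer seed.
#' @param ... further arguments to [generateWorld()].
#' @return Named character vector of file paths, invisibly.
#' @export
cmdSimulate <- function(directory, seed = 1L, ...) {
  world <- generateWorld(seed = seed, ...)
  files <- writeFixtures(world, directory)
  message("wrote ", length(files), " fixture files to ", directory, ":")
  for (f in files) message("  ", f)
  invisible(files)
}

#' Load a model checkpoint written by [cmdRun()]
#'
#' Refuses checkpoints whose signature vocabulary differs from the
#' current data's.
#'
#' @param path checkpoint RDS path.
#' @param vocabulary current signature vocabulary (optional check).
#' @return list with params, config, labels.
#' @export
loadCheckpoint <- function(path, vocabulary = NULL) {
  ck <- readRDS(path)
  if (!is.null(vocabulary)) {
    h <- stringHash(paste(vocabulary, collapse = ","))
    if (!identical(h, ck$vocabularyHash))
      stopf("checkpoint vocabulary hash mismatch")
  }
  ck
}
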