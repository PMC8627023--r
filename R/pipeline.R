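# Pipeline module: one call wiring catalog -> features -> TCA -> model,
# with every tunable echoed into a JSON run manifest so a run can be
# reproduced bit-identically.  A thin command-line wrapper around these
# functions ships in inst/scripts/microtca.R.

#' Assemble a pipeline run configuration
#'
#' Inputs come either from files (`indels`, `exons`, `conservation`,
#' `residues`) or, when `scenario` is given, from the synthetic generator;
#' the synthetic route bypasses feature extraction and feeds the generated
#' 25-feature domains straight into scaling, TCA and the classifier.
#'
#' @param indels path to a microindel VCF/TSV (labeled source records).
#' @param exons path to a microexon TSV (unlabeled target records).
#' @param conservation path to a flat conservation track TSV
#'   (`chrom`, `pos`, `score`).
#' @param residues path to a per-residue annotation TSV.
#' @param scenario optional [shiftScenario()]; replaces the four inputs.
#' @param outDir output directory (created if absent).
#' @param nWindow flank size for feature windows (default 2).
#' @param kernel a [kernelSpec()] for TCA (default linear).
#' @param m number of transfer components (default 8).
#' @param mu TCA ridge regularizer (default 0.1).
#' @param cost,svmKernel classifier hyperparameters.
#' @param threshold probability threshold for functional calls
#'   (default 0.5).
#' @param k neighbor count of the KNN fallback catalog (default 5).
#' @param nFolds cross-validation folds (default 10).
#' @param seed master RNG seed.
#' @return list with class `"RunConfig"`; unset values keep the defaults
#'   shown here, and every effective value is echoed into the run manifest.
#' @export
runConfig <- function(indels = NULL, exons = NULL, conservation = NULL,
                      residues = NULL, scenario = NULL,
                      outDir = tempfile("microtca_run_"), nWindow = 2L,
                      kernel = kernelSpec("linear"), m = 8L, mu = 0.1,
                      cost = 1, svmKernel = "radial", threshold = 0.5,
                      k = 5L, nFolds = 10L, seed = 20211126L) {
  if (is.null(scenario) && (is.null(indels) || is.null(exons)))
    .stopf("either 'scenario' or both 'indels' and 'exons' must be given")
  structure(list(indels = indels, exons = exons,
                 conservation = conservation, residues = residues,
                 scenario = scenario, outDir = outDir,
                 nWindow = as.integer(nWindow), kernel = kernel,
                 m = as.integer(m), mu = mu, cost = cost,
                 svmKernel = svmKernel, threshold = threshold,
                 k = as.integer(k), nFolds = as.integer(nFolds),
                 seed = as.integer(seed)),
            class = "RunConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full prediction pipeline
#'
#' Stages: read and NFS-filter the catalogs, extract the 25 features (or
#' generate synthetic domains), impute and standardize with source-fitted
#' parameters, fit the TCA projection, cross-validate the classifier on the
#' transferred source components, train on all of them, and label the
#' target records at the configured threshold.  Artifacts written to
#' `outDir`: `source_features.tsv`, `target_features.tsv`,
#' `cv_report.tsv`, `predictions.tsv` and `manifest.json` (config echo,
#' package version, input checksums).
#'
#' @param config a [runConfig()].
#' @return (invisibly) list with the fitted `projection`, the `report`
#'   ([EvaluationReport-class]), the `predictions` data.frame, the
#'   reference `catalog` ([ReferenceCatalog-class]) and the `manifest`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$scenario)) {
    dom <- .stage("simulate", generateDomains(config$scenario))
    src <- dom$source; tgt <- dom$target
    srcRaw <- featureMatrix(src); tgtRaw <- featureMatrix(tgt)
    srcLabels <- domainLabels(src)
  } else {
    indels <- .stage("read", readMicroindels(config$indels))
    exons <- .stage("read", readMicroexons(config$exons))
    indels <- .stage("filter", filterNFSMicroindels(indels))
    exons <- .stage("filter", filterNFSMicroexons(exons))
    if (is.null(config$conservation) || is.null(config$residues))
      .stopf("pipeline stage 'extract' failed: conservation track and residue annotations are required")
    provider <- .stage("extract",
      trackProvider(utils::read.delim(config$conservation)))
    residues <- .stage("extract", utils::read.delim(config$residues))
    srcRaw <- .stage("extract",
      extractFeatures(indels, provider, residues, config$nWindow))
    tgtRaw <- .stage("extract",
      extractFeatures(exons, provider, residues, config$nWindow))
    srcLabels <- as.integer(mcols(indels)$label == "functional")
  }

  scaler <- .stage("standardize", featureScaler(srcRaw))
  srcStd <- scaleFeatures(srcRaw, scaler)
  tgtStd <- scaleFeatures(tgtRaw, scaler)

  proj <- .stage("tca",
    fitTCA(srcStd, tgtStd, kernel = config$kernel, m = config$m,
           mu = config$mu))
  Es <- sourceEmbedding(proj); Et <- targetEmbedding(proj)
  rownames(Es) <- rownames(srcRaw); rownames(Et) <- rownames(tgtRaw)

  report <- .stage("evaluate",
    crossValidate(Es, srcLabels, nFolds = config$nFolds,
                  seed = config$seed, threshold = config$threshold,
                  cost = config$cost, kernel = config$svmKernel))
  model <- .stage("train",
    trainClassifier(Es, srcLabels, cost = config$cost,
                    kernel = config$svmKernel, seed = config$seed))
  predictions <- .stage("predict",
    predictTarget(model, Et, threshold = config$threshold))
  catalog <- .stage("predict",
    referenceCatalog(tgtRaw, predictions$probability,
                     labels = as.integer(predictions$label == "functional"),
                     scaler = scaler))

  writeFeatureTable(srcRaw, file.path(config$outDir, "source_features.tsv"),
                    labels = srcLabels)
  writeFeatureTable(tgtRaw, file.path(config$outDir, "target_features.tsv"))
  utils::write.table(as.data.frame(report),
                     file.path(config$outDir, "cv_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(predictions,
                     file.path(config$outDir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  inputs <- Filter(Negate(is.null),
                   config[c("indels", "exons", "conservation", "residues")])
  manifest <- list(
    package = "microTCA",
    version = as.character(utils::packageVersion("microTCA")),
    config = .manifestConfig(config),
    input_checksums = if (length(inputs))
      as.list(tools::md5sum(unlist(inputs))) else list(),
    n_source = nrow(srcRaw), n_target = nrow(tgtRaw),
    pre_tca_mmd = mmdDistance(srcStd, tgtStd, kernelSpec("linear")),
    post_tca_mmd = projectedMMD(proj),
    n_functional = countAtThreshold(predictions, config$threshold))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(projection = proj, report = report,
                 predictions = predictions, catalog = catalog,
                 manifest = manifest))
}

.manifestConfig <- function(config) {
  cfg <- unclass(config)
  cfg$kernel <- unclass(cfg$kernel)
  if (!is.null(cfg$scenario)) cfg$scenario <- unclass(cfg$scenario)
  cfg
}
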