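#' Default pipeline configuration
#'
#' A plain nested list covering every stage: window scheme, dynamics-model
#' settings, binarization density, null-model settings, prediction horizon
#' and classifier settings, all driven by one master seed. A YAML file read
#' with [readPipelineConfig()] overrides these defaults field by field.
#'
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @return nested configuration list.
#' @export
pipelineDefaults <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    window = list(length = 6L, step = 5L),
    ndcn = list(hiddenDim = 16L, odeSolver = "rk4", stepSize = 0.2,
                epochs = 300L, learningRate = 0.02, weightDecay = 1e-4,
                lossNorm = "l1"),
    coupling = list(density = 0.15),
    binarize = list(density = 0.15),
    nullModel = list(nRandom = 20L, nSwapsPerEdge = 10L),
    predict = list(outHorizon = 70L),
    classify = list(classifier = "svm", nFolds = 5L)
  )
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline configuration file
#'
#' YAML with the same structure as [pipelineDefaults()]; unspecified fields
#' keep their defaults. Every field is validated before any stage runs.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @param seed master seed used when the file does not set one.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path = NULL, seed = 1L) {
  cfg <- pipelineDefaults(seed)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- .mergeConfig(cfg, yaml::read_yaml(path))
  }
  validatePipelineConfig(cfg)
  cfg
}

#' @rdname readPipelineConfig
#' @param cfg configuration list to validate.
#' @export
validatePipelineConfig <- function(cfg) {
  stopifnot(cfg$window$length >= 1, cfg$window$step >= 1)
  stopifnot(cfg$coupling$density > 0, cfg$coupling$density <= 1)
  stopifnot(cfg$binarize$density > 0, cfg$binarize$density <= 1)
  stopifnot(cfg$nullModel$nRandom >= 1, cfg$predict$outHorizon >= 0)
  stopifnot(cfg$classify$nFolds >= 2)
  # constructing the model config runs its own validity checks
  invisible(.ndcnConfigFrom(cfg))
}

.ndcnConfigFrom <- function(cfg) {
  ndcnConfig(hiddenDim = cfg$ndcn$hiddenDim, odeSolver = cfg$ndcn$odeSolver,
             stepSize = cfg$ndcn$stepSize, epochs = cfg$ndcn$epochs,
             learningRate = cfg$ndcn$learningRate,
             weightDecay = cfg$ndcn$weightDecay, seed = cfg$seed,
             lossNorm = cfg$ndcn$lossNorm)
}

#' Run the full per-subject pipeline
#'
#' Windowed snapshots -> coupling graph -> continuous-time model fit ->
#' per-volume in-snapshots and extrapolated out-snapshots -> small-world
#' validation -> clustering-coefficient feature vector.
#'
#' @param series an [RoiTimeSeries-class].
#' @param cfg configuration from [pipelineDefaults()] /
#'   [readPipelineConfig()].
#' @param smallWorldOn which snapshot sets get small-world analysis
#'   (any of "observed", "in", "out"; analysis of every in-snapshot is the
#'   expensive part).
#' @return list with snapshots, coupling, model, inSnaps, outSnaps,
#'   smallWorld (list per analyzed set), features (in+out concatenated),
#'   featuresIn, featuresOut, and the resolved config.
#' @export
runSubject <- function(series, cfg = pipelineDefaults(),
                       smallWorldOn = "observed") {
  validatePipelineConfig(cfg)
  scheme <- windowScheme(cfg$window$length, cfg$window$step)
  snaps <- buildObservedSnapshots(series, scheme)
  coupling <- buildCouplingGraph(snaps, cfg$coupling$density)
  model <- fitNdcn(snaps, coupling, .ndcnConfigFrom(cfg))
  inSnaps <- predictInSnapshots(model, subjectId = series@subjectId)
  outSnaps <- predictOutSnapshots(model, cfg$predict$outHorizon,
                                  subjectId = series@subjectId)
  sw <- list()
  sets <- list(observed = snaps, `in` = inSnaps, out = outSnaps)
  for (nm in intersect(smallWorldOn, names(sets))) {
    if (length(sets[[nm]]) > 0L)
      sw[[nm]] <- smallWorldFraction(sets[[nm]], cfg$binarize$density,
                                     cfg$nullModel$nRandom, seed = cfg$seed)
  }
  fin <- extractFeatures(inSnaps, NULL, cfg$binarize$density)
  fout <- if (length(outSnaps) > 0L)
    extractFeatures(outSnaps, NULL, cfg$binarize$density) else numeric()
  list(snapshots = snaps, coupling = coupling, model = model,
       inSnaps = inSnaps, outSnaps = outSnaps, smallWorld = sw,
       features = c(fin, fout), featuresIn = fin, featuresOut = fout,
       config = cfg)
}

#' Write per-subject pipeline outputs to a directory
#'
#' Flushes every stage (snapshots, model, predictions, small-world CSV,
#' features) plus an echo of the resolved configuration, so each output
#' directory is self-describing.
#'
#' @param result list from [runSubject()].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeSubjectOutputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeSnapshots(result$snapshots, file.path(dir, "observed"))
  writeSnapshots(result$inSnaps, file.path(dir, "in"))
  if (length(result$outSnaps) > 0L)
    writeSnapshots(result$outSnaps, file.path(dir, "out"))
  saveNdcnModel(result$model, file.path(dir, "model.json"))
  for (nm in names(result$smallWorld))
    write.table(result$smallWorld[[nm]]$table,
                file.path(dir, paste0("smallworld_", nm, ".csv")),
                sep = ",", quote = FALSE, row.names = FALSE)
  feats <- data.frame(index = seq_along(result$features),
                      segment = c(rep("in", length(result$featuresIn)),
                                  rep("out", length(result$featuresOut))),
                      clustering = result$features)
  write.table(feats, file.path(dir, "features.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  yaml::write_yaml(result$config, file.path(dir, "config_echo.yaml"))
  invisible(dir)
}

#' Run the pipeline over a manifest and classify two groups
#'
#' @param manifestPath manifest TSV (subject_id, group, path).
#' @param groupA,groupB groups to contrast (A = disease class).
#' @param cfg pipeline configuration.
#' @param featureSet "both", "in" or "out".
#' @return list with the feature table and the classification report.
#' @export
runCohortClassification <- function(manifestPath, groupA, groupB,
                                    cfg = pipelineDefaults(),
                                    featureSet = "both") {
  man <- readManifest(manifestPath)
  feats <- list()
  for (r in seq_len(nrow(man))) {
    series <- readRoiSeries(man$path[r], subjectId = man$subject_id[r])
    res <- runSubject(series, cfg, smallWorldOn = character())
    feats[[man$subject_id[r]]] <- switch(featureSet,
      both = res$features, `in` = res$featuresIn, out = res$featuresOut,
      stop("featureSet must be both/in/out"))
  }
  groups <- setNames(man$group, man$subject_id)
  tab <- buildFeatureTable(feats, groups)
  report <- classifyGroups(tab, groupA, groupB, cfg$classify$classifier,
                           cfg$classify$nFolds, seed = cfg$seed)
  list(featureTable = tab, report = report)
}

#' Windowed-baseline feature table for a manifest
#'
#' Clustering-coefficient features computed directly from the observed
#' windowed snapshots (no dynamics model) — the conventional
#' sliding-window baseline, also the fast path for large cohorts.
#'
#' @param manifestPath manifest TSV.
#' @param cfg pipeline configuration.
#' @return feature table data.frame.
#' @export
windowedFeatureTable <- function(manifestPath, cfg = pipelineDefaults()) {
  man <- readManifest(manifestPath)
  scheme <- windowScheme(cfg$window$length, cfg$window$step)
  feats <- list()
  for (r in seq_len(nrow(man))) {
    series <- readRoiSeries(man$path[r], subjectId = man$subject_id[r])
    snaps <- buildObservedSnapshots(series, scheme)
    feats[[man$subject_id[r]]] <- extractFeatures(snaps, NULL,
                                                  cfg$binarize$density)
  }
  buildFeatureTable(feats, setNames(man$group, man$subject_id))
}
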