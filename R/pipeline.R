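## End-to-end orchestration: simulate -> split -> normalize -> screen ->
## train -> stack -> evaluate -> report, with per-stage seeds and a
## reproducible output bundle.

#' Run the full analysis pipeline
#'
#' Executes every stage on a synthetic cohort (or a cohort read from TSV):
#' simulation, stratified splitting, bridging normalization of the
#' screening batch, univariate screening, per-class base-learner training,
#' stacking, evaluation in discovery and validation, and permutation
#' importance. All stage seeds derive deterministically from `seed`, so an
#' identical `(config, seed)` pair yields an identical bundle.
#'
#' @param config a [cohortConfig()] object, a YAML file path holding the
#'   pipeline configuration, or `NULL` for defaults.
#' @param seed integer master seed.
#' @param outDir output directory (created); `NULL` skips file output.
#' @param cohortFile optional TSV to load instead of simulating.
#' @param subsampling subsampling mode for all learners.
#' @param predictionMode meta-input convention for the stack.
#' @param subsetSizes RFE subset-size grid (default: the full grid; pass a
#'   short grid to trade resolution for speed).
#' @param candidates candidate features (default: clinical + all markers).
#' @param nBoot bootstrap resamples for the evaluation summaries.
#' @param importance compute permutation importance (slowest stage).
#' @param comparators character subset of `c("rfe_glm", "random_forest",
#'   "gradient_boosted_trees")` to train as baselines.
#' @param nParamDraws hyperparameter draws for tree comparators.
#' @return (invisibly) a list: `cohort`, `split`, `screen`, `learners`,
#'   `stack`, `evaluation` (discovery/validation [RocSummary-class]),
#'   `importance`, `comparators`, `files`.
#' @examples
#' \donttest{
#' cfg <- cohortConfig(nPerClass = c(Healthy = 20, "Liver Disease" = 20),
#'                     nCases = 12)
#' res <- runPipeline(cfg, seed = 1, outDir = NULL,
#'                    subsetSizes = c(1, 2, 4), nBoot = 200,
#'                    candidates = c("CA19-9", "VWF", "CRP", "Age"))
#' res$evaluation$validation
#' }
#' @export
runPipeline <- function(config = NULL, seed = 1L, outDir = NULL,
                        cohortFile = NULL, subsampling = "over",
                        predictionMode = "insample", subsetSizes = NULL,
                        candidates = NULL, nBoot = 2000L,
                        importance = FALSE, comparators = character(0),
                        nParamDraws = 25L) {
  if (is.character(config)) config <- configFromYaml(config)
  config <- config %||% cohortConfig()
  files <- list()
  emit <- function(name, writer) {
    if (!is.null(outDir)) {
      path <- file.path(outDir, name)
      writer(path)
      files[[name]] <<- path
    }
  }
  if (!is.null(outDir)) dir.create(outDir, recursive = TRUE,
                                   showWarnings = FALSE)

  ## 1. cohort
  cohort <- if (!is.null(cohortFile)) readCohort(cohortFile)
  else simulateCohort(config, seed = childSeed(seed, 1L))
  emit("cohort.tsv", function(p) writeCohort(cohort, p))

  ## 2. bridging normalization of the screening batch (when present)
  cd <- colData(cohort)
  if (all(c("B1", "B2") %in% cd$batch) &&
      !is.null(metadata(cohort)$batch_offsets)) {
    nBridge <- config$batchModel$nBridge
    if (nBridge >= 2L) {
      pairs <- generateBridgePairs(cohort, nBridge,
                                   seed = childSeed(seed, 2L))
      ref <- cohort[, cd$batch == "B1"]
      new <- cohort[, cd$batch == "B2"]
      new <- bridgeNormalize(ref, new, pairs)
      m <- markerData(cohort)
      m[, cd$batch == "B2"] <- markerData(new)
      assay(cohort, "npx") <- m
    }
  }

  ## 3. split
  split <- assignSplit(cohort, seed = childSeed(seed, 3L))
  emit("split.tsv", function(p) writeSplit(split, p))
  discovery <- splitArm(cohort, split, "discovery")
  validation <- splitArm(cohort, split, "validation")

  ## 4. univariate screen (discovery only; validation scored, not refit)
  candidates <- candidates %||% candidateFeatures(cohort)
  screen <- screenFeatures(discovery, candidates, validation = validation)
  emit("screen.tsv", function(p)
    write.table(screen, p, sep = "\t", quote = FALSE, row.names = FALSE))

  ## 5. base learners, one per control class present in discovery
  classes <- intersect(controlClasses(),
                       unique(diagnosisClasses(discovery)[!isCase(discovery)]))
  learners <- lapply(seq_along(classes), function(k)
    trainBaseLearner(discovery, classes[k], candidates = candidates,
                     subsampling = subsampling,
                     seed = childSeed(seed, 10L + k),
                     subsetSizes = subsetSizes))
  names(learners) <- classes

  ## 6. stack
  stack <- fitStack(learners, discovery, predictionMode = predictionMode,
                    seed = childSeed(seed, 4L))
  emit("stack.json", function(p) writeStack(stack, p))
  emit("stack-coefficients.tsv",
       function(p) writeStackCoefficients(stack, p))

  ## 7. evaluation
  evalArm <- function(arm, k) {
    rocSummary(predict(stack, arm), isCase(arm), nBoot = nBoot,
               seed = childSeed(seed, 5L + k))
  }
  evaluation <- list(discovery = evalArm(discovery, 0L),
                     validation = evalArm(validation, 1L))

  ## 8. comparators
  comp <- list()
  if ("rfe_glm" %in% comparators)
    comp$rfe_glm <- trainRfeGlmWhole(discovery, candidates = candidates,
                                     subsampling = subsampling,
                                     seed = childSeed(seed, 20L),
                                     subsetSizes = subsetSizes)
  for (fam in intersect(comparators,
                        c("random_forest", "gradient_boosted_trees")))
    comp[[fam]] <- trainTreeComparator(discovery, fam,
                                       nParamDraws = nParamDraws,
                                       candidates = candidates,
                                       subsampling = subsampling,
                                       cvFolds = 10L,
                                       seed = childSeed(seed, 21L))

  ## 9. importance
  imp <- NULL
  if (importance) {
    imp <- aggregateImportance(learners, discovery,
                               seed = childSeed(seed, 30L))
    emit("importance.tsv", function(p) writeImportance(imp, p))
  }

  ## 10. summary
  summary <- list(
    seed = as.integer(seed),
    n_samples = ncol(cohort),
    n_discovery = ncol(discovery), n_validation = ncol(validation),
    n_base_learners = length(learners),
    n_meta_coefficients = length(metaCoefficients(stack)),
    discovery = .rocToList(evaluation$discovery),
    validation = .rocToList(evaluation$validation))
  emit("summary.json", function(p)
    jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                         na = "null"))

  invisible(list(cohort = cohort, split = split, screen = screen,
                 learners = learners, stack = stack,
                 evaluation = evaluation, importance = imp,
                 comparators = comp, files = files))
}

.rocToList <- function(r) {
  list(auc = r@auc, sens = r@sens, ppv = r@ppv, npv = r@npv,
       threshold = r@threshold, specificity = r@specificity,
       ci = list(auc = unname(r@ci["auc", ]), sens = unname(r@ci["sens", ]),
                 ppv = unname(r@ci["ppv", ]), npv = unname(r@ci["npv", ])),
       n_cases = r@nCases, n_controls = r@nControls)
}

#' Read / write a simulation config as YAML
#'
#' @param path YAML file path.
#' @param config a [cohortConfig()] object.
#' @return `configFromYaml()` returns a validated config.
#' @export
configToYaml <- function(config, path) {
  x <- unclass(config)
  x$nPerClass <- as.list(x$nPerClass)
  x$stageDist <- as.list(x$stageDist)
  x$effectMap <- as.list(x$effectMap)
  x$symptomModel <- lapply(x$symptomModel, as.list)
  x$covariateModel <- lapply(x$covariateModel, function(m) {
    m$ethnicity <- as.list(m$ethnicity); m
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname configToYaml
#' @export
configFromYaml <- function(path) {
  x <- yaml::read_yaml(path)
  args <- list(
    nPerClass = unlist(x$nPerClass),
    nCases = x$nCases,
    stageDist = unlist(x$stageDist),
    noiseSd = x$noiseSd %||% 1.0,
    baseline = x$baseline %||% 5.0,
    missingRate = x$missingRate %||% 0)
  if (!is.null(x$markerPanel)) args$markerPanel <- unlist(x$markerPanel)
  if (!is.null(x$effectMap))
    args$effectMap <- data.frame(marker = unlist(x$effectMap$marker),
                                 group = unlist(x$effectMap$group),
                                 shift = unlist(x$effectMap$shift))
  if (!is.null(x$symptomModel))
    args$symptomModel <- lapply(x$symptomModel, unlist)
  if (!is.null(x$qcancerModel)) args$qcancerModel <- x$qcancerModel
  if (!is.null(x$batchModel)) args$batchModel <- x$batchModel
  if (!is.null(x$covariateModel))
    args$covariateModel <- lapply(x$covariateModel, function(m) {
      m$ethnicity <- unlist(m$ethnicity); m
    })
  do.call(cohortConfig, args)
}
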