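## Central S4 classes and the controlled vocabularies they rely on.

# promote the S3 generics we define S4 methods for, so the standardGeneric
# is bound in this namespace (not just the imported S3 function)
#' @importFrom stats coef predict
setGeneric("coef")
setGeneric("predict")

#' Controlled vocabularies for cohort construction
#'
#' `controlClasses()` returns the 16 control diagnosis classes (15 benign /
#' symptomatic classes plus the screening-derived "Healthy" class),
#' `caseClass()` the case label ("PDAC"), `tumourStages()` the admissible
#' stage codes, `defaultSymptoms()` the 12 presenting-symptom flags, and
#' `elisaMarkers()` the five single-plex ELISA markers measured alongside
#' the multiplex NPX panel.
#'
#' @return A character vector.
#' @examples
#' controlClasses()
#' elisaMarkers()
#' @export
controlClasses <- function() {
  c("Sphincter of Oddi dysfunction", "Pancreatic Cyst", "Other Cancer",
    "Other Biliary Duct Disease", "No Relevant Diagnosis", "Liver Disease",
    "Irritable Bowel Syndrome", "IgG4 Disease", "Gastritis/Reflux Disease",
    "Gallstone Disease", "Familial Pancreatic Cancer", "Chronic Pancreatitis",
    "Acute Pancreatitis", "Isolated LFT Derangement",
    "Non-specific Abdominal Pain", "Healthy")
}

#' @rdname controlClasses
#' @export
caseClass <- function() "PDAC"

#' @rdname controlClasses
#' @export
tumourStages <- function() c("I", "II", "III", "IV", "unknown")

#' @rdname controlClasses
#' @export
defaultSymptoms <- function() {
  c("Jaundice", "Weight Loss", "Abdominal Pain", "Back Pain",
    "Change in Bowel Habit", "Asymptomatic LFT Derangement", "Vomiting",
    "Rectal Bleeding", "Reflux", "Bloating", "Heartburn", "Anaemia")
}

#' @rdname controlClasses
#' @export
elisaMarkers <- function() c("CA19-9", "IL6ST", "VWF", "PKM2", "THBS2")

#' @rdname controlClasses
#' @export
clinicalCovariates <- function() c("Age", "Gender", "BMI", "Diabetes", "Ethnicity")

# required per-sample metadata columns (symptom flags live in sym_* columns)
.COHORT_COLS <- c("sample_id", "source_cohort", "diagnosis_class", "stage",
                  "label", "age", "gender", "bmi", "diabetes", "ethnicity",
                  "qcancer", "batch")

#' PdacCohort: a serum-proteomics case-control cohort
#'
#' A `SummarizedExperiment` subclass holding one cohort: a markers-by-samples
#' matrix on the NPX log2 scale (assay `"npx"`; the five ELISA markers are
#' kept on the log2 scale too) plus per-sample clinical metadata in
#' `colData`: diagnosis class (16 control classes or PDAC), tumour stage for
#' cases, case/control label, age, gender, BMI, diabetes, ethnicity, an
#' optional QCancer percent-risk score, a batch identifier, and 12 binary
#' symptom flags stored in columns prefixed `sym_`. Screening-source samples
#' (e.g. trial-derived healthy controls) carry `NA` symptoms and QCancer,
#' mirroring cohorts where that information was never collected.
#'
#' @slot .. inherited from `SummarizedExperiment`.
#' @seealso [PdacCohort()], [simulateCohort()], [readCohort()]
#' @aliases PdacCohort-class
#' @exportClass PdacCohort
setClass("PdacCohort", contains = "SummarizedExperiment")

setValidity("PdacCohort", function(object) {
  cd <- colData(object)
  miss <- setdiff(.COHORT_COLS, colnames(cd))
  if (length(miss))
    return(paste("missing colData column(s):", paste(miss, collapse = ", ")))
  if (!"npx" %in% assayNames(object))
    return("assay 'npx' is required")
  dc <- as.character(cd$diagnosis_class)
  bad <- setdiff(unique(dc), c(controlClasses(), caseClass()))
  if (length(bad))
    return(paste("unknown diagnosis class:", paste(bad, collapse = ", ")))
  lab <- as.character(cd$label)
  if (!all(lab %in% c("case", "control")))
    return("label must be 'case' or 'control'")
  if (!all((dc == caseClass()) == (lab == "case")))
    return("label = case must coincide with diagnosis_class = PDAC")
  st <- as.character(cd$stage)
  if (any(lab == "case" & (is.na(st) | !st %in% tumourStages())))
    return("cases must carry a stage in I/II/III/IV/unknown")
  if (any(lab == "control" & !is.na(st)))
    return("controls must not carry a stage")
  age <- cd$age
  if (any(!is.finite(age)) || any(age < 18 | age > 100))
    return("age must be finite and within [18, 100]")
  npx <- assay(object, "npx")
  if (!all(is.finite(npx) | is.na(npx)))
    return("marker values must be finite (NA allowed only as configured missingness)")
  scr <- cd$source_cohort == "screening"
  symCols <- grep("^sym_", colnames(cd), value = TRUE)
  if (any(scr)) {
    if (length(symCols) &&
        !all(is.na(as.matrix(cd[scr, symCols, drop = FALSE]))))
      return("screening-source samples must have NA symptom flags")
    if (!all(is.na(cd$qcancer[scr])))
      return("screening-source samples must have NA qcancer")
  }
  TRUE
})

#' Construct a PdacCohort
#'
#' @param markers numeric matrix, markers in rows, samples in columns
#'   (NPX log2 scale).
#' @param sampleData `data.frame`/`DataFrame` of per-sample metadata with the
#'   required columns (`sample_id`, `source_cohort`, `diagnosis_class`,
#'   `stage`, `label`, `age`, `gender`, `bmi`, `diabetes`, `ethnicity`,
#'   `qcancer`, `batch`) plus binary symptom flags in `sym_*` columns.
#' @return A [PdacCohort-class] object.
#' @examples
#' cohort <- simulateCohort(cohortConfig(nPerClass = c(Healthy = 10),
#'                                       nCases = 5), seed = 1)
#' cohort
#' @export
PdacCohort <- function(markers, sampleData) {
  sampleData <- DataFrame(sampleData, check.names = FALSE)
  rownames(sampleData) <- sampleData$sample_id
  colnames(markers) <- sampleData$sample_id
  new("PdacCohort", SummarizedExperiment(
    assays = list(npx = markers), colData = sampleData))
}

setMethod("show", "PdacCohort", function(object) {
  cd <- colData(object)
  cat(sprintf("PdacCohort: %d samples x %d markers\n",
              ncol(object), nrow(object)))
  cat(sprintf("  cases (PDAC): %d | controls: %d across %d diagnosis classes\n",
              sum(cd$label == "case"), sum(cd$label == "control"),
              length(unique(cd$diagnosis_class[cd$label == "control"]))))
  cat(sprintf("  sources: %s | batches: %s\n",
              paste(unique(cd$source_cohort), collapse = ", "),
              paste(unique(cd$batch), collapse = ", ")))
})

#' FirthFit: a Firth bias-reduced logistic regression fit
#'
#' Holds the penalized-likelihood optimum of a logistic regression with
#' Jeffreys-prior (Firth) penalty: coefficients on the log-odds scale, odds
#' ratios, profile penalized-likelihood confidence limits, penalized
#' likelihood-ratio p-values, hat diagonals, and convergence diagnostics.
#' The design matrix and outcome are retained so that intervals and nested
#' tests can be profiled after the fit.
#'
#' @slot coefficients named numeric, includes `(Intercept)`.
#' @slot ci numeric matrix (terms x 2) of profile CI bounds on the log-odds
#'   scale (may contain `Inf` when one-sided).
#' @slot p named numeric of penalized-LRT p-values per term.
#' @slot logLik penalized log-likelihood at the optimum.
#' @slot hat numeric hat diagonals.
#' @slot iter,converged diagnostics.
#' @slot X,y the design matrix and 0/1 outcome used.
#' @slot level CI level.
#' @aliases FirthFit-class
#' @exportClass FirthFit
setClass("FirthFit", representation(
  coefficients = "numeric", ci = "matrix", p = "numeric",
  logLik = "numeric", hat = "numeric", iter = "integer",
  converged = "logical", X = "matrix", y = "numeric", level = "numeric"))

setMethod("show", "FirthFit", function(object) {
  cat(sprintf("FirthFit: %d terms, n = %d, penalized logLik = %.4f (%s)\n",
              length(object@coefficients), length(object@y), object@logLik,
              if (object@converged) "converged" else "NOT converged"))
  tab <- data.frame(
    beta = object@coefficients,
    OR = exp(object@coefficients),
    CI_low = exp(object@ci[, 1]), CI_high = exp(object@ci[, 2]),
    p = object@p, check.names = FALSE)
  print(round(tab, 4))
})

#' @describeIn FirthFit-class coefficient vector (log-odds scale).
#' @param object,... standard S4 method arguments.
#' @export
setMethod("coef", "FirthFit", function(object, ...) object@coefficients)

#' Odds ratios, intervals and p-values of a fit
#'
#' @param object a [FirthFit-class].
#' @return `oddsRatios`: named numeric of `exp(beta)`. `firthSummary`: a
#'   `data.frame` with term, beta, OR, profile CI bounds (OR scale) and
#'   penalized-LRT p-value.
#' @export
oddsRatios <- function(object) exp(object@coefficients)

#' @rdname oddsRatios
#' @export
firthSummary <- function(object) {
  data.frame(term = names(object@coefficients),
             beta = unname(object@coefficients),
             OR = unname(exp(object@coefficients)),
             CI_low = unname(exp(object@ci[, 1])),
             CI_high = unname(exp(object@ci[, 2])),
             p = unname(object@p),
             row.names = NULL, check.names = FALSE)
}

#' SplitAssignment: a stratified discovery/validation allocation
#'
#' @slot assignment data.frame with columns `sample_id`, `stratum_id`, `arm`
#'   (`discovery`/`validation`).
#' @slot seed integer seed used for the randomized rounding.
#' @aliases SplitAssignment-class
#' @exportClass SplitAssignment
setClass("SplitAssignment",
         representation(assignment = "data.frame", seed = "integer"))

setMethod("show", "SplitAssignment", function(object) {
  tb <- table(object@assignment$arm)
  cat(sprintf("SplitAssignment: %d samples, %d strata (discovery %d / validation %d)\n",
              nrow(object@assignment),
              length(unique(object@assignment$stratum_id)),
              tb[["discovery"]], tb[["validation"]]))
})

#' BaseLearner: one diagnosis-class-vs-PDAC classifier
#'
#' A logistic classifier contrasting the controls of a single diagnosis
#' class against the shared PDAC cases, trained by recursive feature
#' elimination under leave-one-out cross-validation with in-fold
#' subsampling.
#'
#' @slot diagnosisClass the control class the learner specializes in.
#' @slot features selected feature names.
#' @slot coefficients named numeric, `(Intercept)` plus selected features,
#'   on the standardized-feature scale.
#' @slot center,scale standardization parameters from the final training
#'   data, named by feature.
#' @slot cvProfile data.frame `size`, `auc`: pooled-LOOCV AUC per subset size.
#' @slot oofProb named numeric: held-out LOOCV probability (at the winning
#'   size) per training-subset sample.
#' @slot subsampling one of `"over"`, `"under"`, `"smote"`, `"none"`.
#' @slot candidates candidate feature names offered to RFE.
#' @slot firth logical: whether the final fit required Firth penalization.
#' @slot seed integer.
#' @aliases BaseLearner-class
#' @exportClass BaseLearner
setClass("BaseLearner", representation(
  diagnosisClass = "character", features = "character",
  coefficients = "numeric", center = "numeric", scale = "numeric",
  cvProfile = "data.frame", oofProb = "numeric", subsampling = "character",
  candidates = "character", firth = "logical", seed = "integer"))

setValidity("BaseLearner", function(object) {
  if (!all(object@features %in% object@candidates))
    return("selected features must be a subset of candidates")
  if (length(object@coefficients) != length(object@features) + 1L)
    return("coefficient dimension must be |features| + 1")
  TRUE
})

setMethod("show", "BaseLearner", function(object) {
  cat(sprintf("BaseLearner['%s']: %d/%d features (%s subsampling%s)\n",
              object@diagnosisClass, length(object@features),
              length(object@candidates), object@subsampling,
              if (object@firth) ", Firth final fit" else ""))
  cat("  features:", paste(object@features, collapse = ", "), "\n")
  best <- object@cvProfile[which.max(object@cvProfile$auc), ]
  cat(sprintf("  pooled-LOOCV AUC %.3f at size %d\n", best$auc, best$size))
})

#' @describeIn BaseLearner-class selected feature names.
#' @param object a `BaseLearner`.
#' @export
selectedFeatures <- function(object) object@features

#' @describeIn BaseLearner-class LOOCV profile (subset size vs pooled AUC).
#' @export
cvProfile <- function(object) object@cvProfile

#' StackModel: logistic stack of diagnosis-specific base learners
#'
#' @slot learners list of [BaseLearner-class], named by diagnosis class.
#' @slot metaCoef named numeric: intercept plus one coefficient per learner
#'   applied to clipped logits of base probabilities.
#' @slot metaP named numeric: per-learner meta-coefficient p-values.
#' @slot predictionMode `"insample"` or `"out_of_fold"` (how meta-inputs
#'   were produced on the training set).
#' @slot metaFirth logical: meta-fit used Firth penalization.
#' @slot seed integer.
#' @aliases StackModel-class
#' @exportClass StackModel
setClass("StackModel", representation(
  learners = "list", metaCoef = "numeric", metaP = "numeric",
  predictionMode = "character", metaFirth = "logical", seed = "integer"))

setValidity("StackModel", function(object) {
  if (length(object@metaCoef) != length(object@learners) + 1L)
    return("meta coefficient count must be learner count + 1")
  TRUE
})

setMethod("show", "StackModel", function(object) {
  cat(sprintf("StackModel: %d base learners, %s meta-inputs%s\n",
              length(object@learners), object@predictionMode,
              if (object@metaFirth) " (Firth meta-fit)" else ""))
  print(round(data.frame(beta = object@metaCoef,
                         p = c(NA, object@metaP)[seq_along(object@metaCoef)]),
              4))
})

#' @describeIn StackModel-class the base-learner list.
#' @param object a `StackModel`.
#' @export
baseLearners <- function(object) object@learners

#' @describeIn StackModel-class meta-coefficients (intercept first).
#' @export
metaCoefficients <- function(object) object@metaCoef

#' RocSummary: ROC performance with stratified-bootstrap intervals
#'
#' AUC plus sensitivity, positive and negative predictive value at a fixed
#' specificity (default 90%), each with a stratified percentile-bootstrap
#' confidence interval.
#'
#' @slot auc,sens,ppv,npv point estimates.
#' @slot ci numeric matrix (metric x 2) of bootstrap CI bounds.
#' @slot threshold operating threshold achieving the target specificity.
#' @slot specificity target specificity.
#' @slot nCases,nControls,nBoot,seed bookkeeping.
#' @slot level CI level.
#' @slot stable FALSE when the evaluated subset was too small for intervals.
#' @aliases RocSummary-class
#' @exportClass RocSummary
setClass("RocSummary", representation(
  auc = "numeric", sens = "numeric", ppv = "numeric", npv = "numeric",
  ci = "matrix", threshold = "numeric", specificity = "numeric",
  nCases = "integer", nControls = "integer", nBoot = "integer",
  seed = "integer", level = "numeric", stable = "logical"))

setMethod("show", "RocSummary", function(object) {
  cat(sprintf("RocSummary (%d cases / %d controls)%s\n", object@nCases,
              object@nControls,
              if (!object@stable) " [unstable: CIs suppressed]" else ""))
  fmt <- function(metric, v) {
    ci <- object@ci[metric, ]
    if (all(is.finite(ci)))
      sprintf("%.3f (%d%% CI %.3f-%.3f)", v, round(100 * object@level),
              ci[1], ci[2])
    else sprintf("%.3f", v)
  }
  cat(sprintf("  AUC  %s\n", fmt("auc", object@auc)))
  cat(sprintf("  at %.0f%% specificity (threshold %.4g):\n",
              100 * object@specificity, object@threshold))
  cat(sprintf("    Sens %s\n", fmt("sens", object@sens)))
  cat(sprintf("    PPV  %s\n", fmt("ppv", object@ppv)))
  cat(sprintf("    NPV  %s\n", fmt("npv", object@npv)))
})

#' @describeIn RocSummary-class AUC point estimate.
#' @param object a `RocSummary`.
#' @export
auc <- function(object) object@auc

#' @describeIn RocSummary-class CI matrix (rows auc/sens/ppv/npv).
#' @export
rocCi <- function(object) object@ci
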