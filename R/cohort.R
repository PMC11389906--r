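## Cohort accessors, feature encoding, TSV I/O, stratified splitting and
## reference-sample bridging normalization.

#' Cohort accessors
#'
#' `markerData()` returns the markers-by-samples NPX matrix, `markerNames()`
#' the panel, `isCase()` a logical case indicator, `diagnosisClasses()` the
#' per-sample diagnosis class, `symptomFlags()` the samples-by-symptoms 0/1
#' matrix (NA for screening-source samples), and `qcancerScore()` the
#' percent-risk score.
#'
#' @param x a [PdacCohort-class].
#' @return See details above.
#' @export
markerData <- function(x) assay(x, "npx")

#' @rdname markerData
#' @export
markerNames <- function(x) rownames(x)

#' @rdname markerData
#' @export
isCase <- function(x) colData(x)$label == "case"

#' @rdname markerData
#' @export
diagnosisClasses <- function(x) as.character(colData(x)$diagnosis_class)

#' @rdname markerData
#' @export
symptomFlags <- function(x) {
  cd <- colData(x)
  cols <- grep("^sym_", colnames(cd), value = TRUE)
  m <- as.matrix(as.data.frame(cd[, cols, drop = FALSE]))
  colnames(m) <- sub("^sym_", "", cols)
  rownames(m) <- cd$sample_id
  m
}

#' @rdname markerData
#' @export
qcancerScore <- function(x) setNames(colData(x)$qcancer, colData(x)$sample_id)

#' Candidate features and the numeric design they induce
#'
#' Model features are the marker panel plus five clinical covariates (Age,
#' Gender, BMI, Diabetes, Ethnicity). `featureMatrix()` encodes them as a
#' samples-by-features numeric matrix: markers on the NPX scale, Age and BMI
#' in their native units, Gender as male = 1, Diabetes as yes = 1, and
#' Ethnicity one-vs-rest against a reference category (default Caucasian,
#' with unknown treated as non-reference).
#'
#' @param x a [PdacCohort-class].
#' @param features character; defaults to all candidates.
#' @param ethnicityRef reference category for the one-vs-rest encoding.
#' @return `candidateFeatures`: character. `featureMatrix`: numeric matrix.
#' @export
candidateFeatures <- function(x) c(clinicalCovariates(), markerNames(x))

#' @rdname candidateFeatures
#' @export
featureMatrix <- function(x, features = candidateFeatures(x),
                          ethnicityRef = "Caucasian") {
  cd <- colData(x)
  n <- ncol(x)
  enc <- function(f) {
    switch(f,
      Age = as.numeric(cd$age),
      Gender = as.numeric(cd$gender == "male"),
      BMI = as.numeric(cd$bmi),
      Diabetes = as.numeric(cd$diabetes == "yes"),
      Ethnicity = as.numeric(cd$ethnicity == ethnicityRef),
      {
        if (!f %in% rownames(x)) stopf("feature '%s' not found in cohort", f)
        as.numeric(assay(x, "npx")[f, ])
      })
  }
  m <- vapply(features, enc, numeric(n))
  if (n == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, features))
  rownames(m) <- cd$sample_id
  m
}

## ---------------------------------------------------------------- I/O ----

#' Read / write a cohort as a plain-text TSV
#'
#' The on-disk layout has one row per sample: metadata columns, the 12
#' symptom flags (`sym_` prefix), `qcancer`, `batch`, then one column per
#' marker. ELISA markers (see [elisaMarkers()]) are written on the linear
#' concentration scale when `elisaLinear = TRUE` (the default, mirroring
#' vendor exports) and log2-transformed back on load.
#'
#' @param path file path.
#' @param x a [PdacCohort-class].
#' @param elisaLinear logical; store/read ELISA markers on the linear scale.
#' @return `readCohort()` returns a [PdacCohort-class]; `writeCohort()`
#'   returns `path` invisibly.
#' @examples
#' cohort <- simulateCohort(cohortConfig(nPerClass = c(Healthy = 8),
#'                                       nCases = 4), seed = 1)
#' tf <- tempfile(fileext = ".tsv")
#' writeCohort(cohort, tf)
#' cohort2 <- readCohort(tf)
#' @export
writeCohort <- function(x, path, elisaLinear = TRUE) {
  cd <- as.data.frame(colData(x), check.names = FALSE)
  mk <- t(markerData(x))
  if (elisaLinear) {
    el <- intersect(elisaMarkers(), colnames(mk))
    mk[, el] <- 2 ^ mk[, el, drop = FALSE]
  }
  df <- cbind(cd, as.data.frame(mk, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path, elisaLinear = TRUE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   fileEncoding = "UTF-8")
  symCols <- grep("^sym_", colnames(df), value = TRUE)
  miss <- setdiff(.COHORT_COLS, colnames(df))
  if (length(miss))
    stopf("cohort file lacks required column(s): %s",
          paste(miss, collapse = ", "))
  metaCols <- c(.COHORT_COLS, symCols)
  markerCols <- setdiff(colnames(df), metaCols)
  mk <- as.matrix(df[, markerCols, drop = FALSE])
  if (!is.numeric(mk)) {
    bad <- which(!vapply(df[markerCols], is.numeric, logical(1)))[1]
    row <- which(is.na(suppressWarnings(as.numeric(df[[markerCols[bad]]]))))[1]
    stopf("non-numeric marker value in column '%s' (row %d)",
          markerCols[bad], row)
  }
  if (elisaLinear) {
    el <- intersect(elisaMarkers(), colnames(mk))
    mk[, el] <- log2(mk[, el, drop = FALSE])
  }
  df$stage <- as.character(df$stage)
  df$stage[df$stage %in% c("", "NA")] <- NA_character_
  PdacCohort(t(mk), df[, metaCols, drop = FALSE])
}

## -------------------------------------------------- stratified split ----

#' Age bins used for split stratification
#'
#' Half-open decade bins: (18,28], (28,38], ..., (68,78], and 79+.
#' @param age numeric vector of ages in years.
#' @return character bin labels.
#' @export
ageBin <- function(age) {
  as.character(cut(age, breaks = c(18, 28, 38, 48, 58, 68, 78, Inf),
                   labels = c("(18,28]", "(28,38]", "(38,48]", "(48,58]",
                              "(58,68]", "(68,78]", "79+"),
                   include.lowest = TRUE, right = TRUE))
}

#' Stratified 2/3 vs 1/3 discovery/validation split
#'
#' Samples are stratified on age bin, diabetes status, case/control label
#' and control diagnosis class; tumour stage is added to the stratum for
#' cases. Within each stratum two thirds are allocated to discovery, with
#' the rounding direction randomized so that neither arm is systematically
#' inflated; the realized count never deviates from `round(2n/3)` by more
#' than one. Screening-source controls may instead carry a fixed external
#' assignment (mirroring reuse of a split inherited from a prior study).
#'
#' @param cohort a [PdacCohort-class].
#' @param seed integer.
#' @param external optional named character vector `sample_id -> arm` fixing
#'   the assignment of screening-source samples.
#' @return A [SplitAssignment-class].
#' @export
assignSplit <- function(cohort, seed, external = NULL) {
  cd <- colData(cohort)
  if (ncol(cohort) == 0L) stopf("cannot split an empty cohort")
  stratum <- paste(ageBin(cd$age), cd$diabetes, cd$label, cd$diagnosis_class,
                   ifelse(cd$label == "case", as.character(cd$stage), "-"),
                   sep = "|")
  ids <- cd$sample_id
  arm <- setNames(rep(NA_character_, length(ids)), ids)
  fixed <- character(0)
  if (!is.null(external)) {
    fixed <- intersect(names(external), ids[cd$source_cohort == "screening"])
    arm[fixed] <- external[fixed]
  }
  withSeed(seed, {
    for (s in unique(stratum)) {
      members <- setdiff(ids[stratum == s], fixed)
      n <- length(members)
      if (!n) next
      target <- 2 * n / 3
      nd <- floor(target) + (runif(1) < (target - floor(target)))
      disc <- if (nd > 0) sample(members, nd) else character(0)
      arm[members] <- ifelse(members %in% disc, "discovery", "validation")
    }
  })
  new("SplitAssignment",
      assignment = data.frame(sample_id = ids, stratum_id = stratum,
                              arm = unname(arm[ids]),
                              stringsAsFactors = FALSE),
      seed = as.integer(seed))
}

#' @rdname assignSplit
#' @param split a [SplitAssignment-class].
#' @param arm `"discovery"` or `"validation"`.
#' @export
splitArm <- function(cohort, split, arm = c("discovery", "validation")) {
  arm <- match.arg(arm)
  keep <- split@assignment$sample_id[split@assignment$arm == arm]
  cohort[, colData(cohort)$sample_id %in% keep]
}

#' @rdname assignSplit
#' @param path output file path (TSV: sample_id, stratum_id, arm).
#' @export
writeSplit <- function(split, path) {
  write.table(split@assignment, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

## ------------------------------------------------ bridging normalization ----

#' Reference-sample bridging normalization between batches
#'
#' Aligns a new batch to a reference batch using bridge samples measured in
#' both: for each assay, the median over bridge pairs of (new - reference)
#' is subtracted from every sample of the new batch. After correction the
#' per-assay median bridge difference is exactly zero. This is the standard
#' reference-sample bridging adjustment used for multiplex NPX panels.
#'
#' @param batchRef,batchNew [PdacCohort-class] objects with identical marker
#'   panels.
#' @param bridgePairs a list as produced by [generateBridgePairs()], with
#'   markers-by-bridge matrices `ref` and `new`.
#' @return `batchNew` with the per-assay offsets removed; the estimated
#'   offsets are attached as `metadata(x)$bridge_offsets`.
#' @export
bridgeNormalize <- function(batchRef, batchNew, bridgePairs) {
  if (!identical(rownames(batchRef), rownames(batchNew)))
    stopf("marker panels of the two batches differ")
  if (is.null(bridgePairs$ref) || ncol(bridgePairs$ref) < 2L)
    stopf(paste("need at least 2 bridge pairs to estimate batch offsets;",
                "re-run the bridging experiment with more shared samples"))
  if (!identical(rownames(bridgePairs$ref), rownames(batchNew)))
    stopf("bridge pair panel does not match the batches")
  offsets <- apply(bridgePairs$new - bridgePairs$ref, 1L, median)
  assay(batchNew, "npx") <- assay(batchNew, "npx") - offsets
  metadata(batchNew)$bridge_offsets <- offsets
  batchNew
}
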