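## Synthetic cohort generation: emulates the statistical structure of a
## symptomatic secondary-care case-control study (serum NPX marker panel,
## clinical covariates, symptom flags, QCancer score, batch structure with
## bridge samples) so that every downstream stage is testable without any
## patient-level data.

#' Default marker panel: 92 multiplex NPX analytes plus 5 ELISA markers
#'
#' The multiplex portion mimics an oncology-focused 92-plex panel (cancer
#' antigens, growth factors, receptors, adhesion regulators); the five
#' single-plex ELISA markers are CA19-9, IL6ST, VWF, PKM2 and THBS2.
#'
#' @return character vector of 97 marker names.
#' @export
defaultMarkerPanel <- function() {
  olink <- c(
    "ICOSLG", "GPNMB", "ESM1", "DLL1", "ERBB2", "FCRLB", "CEACAM5", "EGF",
    "CTSV", "FASLG", "CPE", "CA9", "CD207", "CRP", "CDKN1A", "EPHA2",
    "ITGAV", "MUC16", "CXCL13", "ERBB3", "FOLR1", "FADD", "ERBB4", "CD27",
    "AREG", "ADAMTS15", "ABL1", "ANXA1", "CXCL17", "CD70", "CEACAM1",
    "CD48", "CD160", "CYR61", "CRNN", "ADAM8", "FOLR3", "GZMB", "SYND1",
    "PPY", "TGFA", "VEGFA", "Creatinine", "TBIL",
    "KLK8", "KLK11", "KLK13", "KLK14", "MSLN", "MDK", "SPARC", "WFDC2",
    "GPC1", "RET", "SEZ6L", "WISP1", "TNFRSF6B", "TNFRSF4", "TNFSF13",
    "IFNGR1", "CD69", "LY9", "TCL1A", "ITGB5", "TLR3", "NECTIN4", "LYPD3",
    "S100A4", "S100A11", "TXLNA", "RSPO3", "VIM", "MIA", "TFPI2", "PODXL",
    "SCAMP3", "MAD1L1", "HGF", "IGF1R", "WIF1", "FGFBP1", "GZMH",
    "TNFSF10", "CXCL9", "IL6", "MMP7", "MMP12", "CTSD", "PVR", "DKK1",
    "EPHB4", "LRIG1")
  c(olink, elisaMarkers())
}

#' Default per-class sample counts
#'
#' 421 symptomatic controls spread over the 15 benign diagnosis classes
#' plus 72 screening-derived healthy controls (all female, no symptom or
#' QCancer information), matching the marginal totals of the cohort the
#' generator emulates: 493 controls and 46 PDAC cases.
#'
#' @return named integer vector over [controlClasses()].
#' @export
defaultClassCounts <- function() {
  c("Gallstone Disease" = 60L, "Gastritis/Reflux Disease" = 50L,
    "Non-specific Abdominal Pain" = 45L, "Liver Disease" = 40L,
    "Chronic Pancreatitis" = 35L, "Pancreatic Cyst" = 35L,
    "Irritable Bowel Syndrome" = 30L, "Other Biliary Duct Disease" = 25L,
    "Acute Pancreatitis" = 25L, "No Relevant Diagnosis" = 20L,
    "Isolated LFT Derangement" = 18L, "Other Cancer" = 15L,
    "Familial Pancreatic Cancer" = 10L, "IgG4 Disease" = 8L,
    "Sphincter of Oddi dysfunction" = 5L, "Healthy" = 72L)
}

#' Default planted marker effects
#'
#' Mean NPX log2 shifts per (marker, group). PDAC carries elevated CA19-9
#' and a panel of tumour-associated markers; several benign classes carry
#' confounding shifts (e.g. CA19-9 elevation in biliary obstruction and
#' pancreatitis, CRP in inflammatory conditions), which is what makes the
#' diagnosis-specific ensemble design meaningful.
#'
#' @return data.frame with columns `marker`, `group`, `shift`.
#' @export
defaultEffectMap <- function() {
  rbind(
    data.frame(marker = c("CA19-9", "VWF", "CPE", "CTSV", "CEACAM1",
                          "CD160", "IL6ST", "THBS2", "PKM2", "MUC16",
                          "CEACAM5", "ESM1", "DLL1", "EGF", "ERBB2",
                          "GPNMB", "ICOSLG", "FASLG", "CRP"),
               group = "PDAC",
               shift = c(1.8, 1.0, 0.8, 0.8, 0.7, 0.6, 0.6, 0.6, 0.5, 0.5,
                         0.5, 0.4, 0.4, 0.4, 0.4, 0.4, 0.4, 0.3, 0.5)),
    data.frame(marker = c("CA19-9", "CRP", "PKM2"),
               group = "Chronic Pancreatitis", shift = c(0.7, 0.6, 0.3)),
    data.frame(marker = c("CRP", "CA19-9"),
               group = "Acute Pancreatitis", shift = c(1.0, 0.5)),
    data.frame(marker = c("CA19-9", "CRP", "TBIL"),
               group = "Other Biliary Duct Disease", shift = c(0.9, 0.4, 1.0)),
    data.frame(marker = "CA19-9", group = "Gallstone Disease", shift = 0.5),
    data.frame(marker = c("VWF", "CRP", "TBIL"),
               group = "Liver Disease", shift = c(0.5, 0.4, 0.8)),
    data.frame(marker = "CRP", group = "IgG4 Disease", shift = 0.5),
    data.frame(marker = c("CEACAM5", "MUC16", "CA19-9"),
               group = "Other Cancer", shift = c(0.6, 0.5, 0.3)),
    data.frame(marker = "CA19-9", group = "Pancreatic Cyst", shift = 0.4))
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-cohort generator with defaults
#' emulating the marginal structure of a 539-sample symptomatic cohort
#' (46 PDAC cases staged 4/15/10/16/1 across I/II/III/IV/unknown, 421
#' symptomatic controls over 15 benign classes, 72 screening-derived
#' healthy controls): class-specific marker shifts, age/gender/diabetes/
#' BMI/ethnicity case-control structure, per-symptom prevalences, a
#' logistic-linked QCancer percent-risk score, and per-assay batch offsets
#' with bridge samples.
#'
#' @param nPerClass named counts over (a subset of) [controlClasses()].
#' @param nCases number of PDAC cases.
#' @param stageDist named counts over [tumourStages()] summing to `nCases`;
#'   when `NULL`, the default stage mix is allocated proportionally.
#' @param markerPanel character marker names.
#' @param effectMap data.frame (`marker`, `group`, `shift`): mean NPX shift
#'   for that marker in that group; groups are `"PDAC"` or control classes.
#' @param covariateModel list with elements `case`, `control`, `screening`,
#'   each a list of `ageMean`, `ageSd`, `maleP`, `diabetesP`, `bmiMean`,
#'   `bmiSd`, `ethnicity` (named category probabilities).
#' @param symptomModel list with numeric vectors `case` and `control`:
#'   per-symptom prevalence (names = symptom flags).
#' @param qcancerModel list: `rate` (fraction of symptomatic-source samples
#'   carrying a score), coefficients `intercept`, `age`, `male`, `symptom`,
#'   `case` of the logistic link, and `noiseSd` (logit-scale noise).
#' @param batchModel list: `offsetSd` (per-assay batch offset SD, NPX),
#'   `nBridge` (bridge samples per batch pair).
#' @param noiseSd residual per-assay NPX SD.
#' @param baseline baseline NPX level (single value or named per marker).
#' @param missingRate fraction of marker values set missing (default 0).
#' @return a validated config list of class `pdac_sim_config`.
#' @examples
#' cfg <- cohortConfig(nPerClass = c(Healthy = 20, "Liver Disease" = 15),
#'                     nCases = 10)
#' cohort <- simulateCohort(cfg, seed = 7)
#' @export
cohortConfig <- function(nPerClass = defaultClassCounts(),
                         nCases = 46L,
                         stageDist = NULL,
                         markerPanel = defaultMarkerPanel(),
                         effectMap = defaultEffectMap(),
                         covariateModel = NULL,
                         symptomModel = NULL,
                         qcancerModel = NULL,
                         batchModel = NULL,
                         noiseSd = 1.0,
                         baseline = 5.0,
                         missingRate = 0) {
  # when the caller overrides the panel but not the effect map, restrict
  # the default planted effects to the markers actually present
  if (missing(effectMap))
    effectMap <- effectMap[effectMap$marker %in% markerPanel, , drop = FALSE]
  if (is.null(stageDist)) {
    ref <- c(I = 4, II = 15, III = 10, IV = 16, unknown = 1)
    raw <- ref / sum(ref) * nCases
    stageDist <- floor(raw)
    rem <- nCases - sum(stageDist)
    if (rem > 0) {
      ord <- order(raw - floor(raw), decreasing = TRUE)
      stageDist[ord[seq_len(rem)]] <- stageDist[ord[seq_len(rem)]] + 1
    }
  }
  covDefaults <- list(
    case = list(ageMean = 69.7, ageSd = 10, maleP = 31 / 46,
                diabetesP = 10 / 46, bmiMean = 24.8, bmiSd = 4,
                ethnicity = c(Caucasian = 0.457, unknown = 0.457,
                              Asian = 0.065, Other = 0.021,
                              "Afro/Caribbean" = 0)),
    control = list(ageMean = 57.4, ageSd = 15, maleP = 180 / 421,
                   diabetesP = 75 / 421, bmiMean = 25.3, bmiSd = 4,
                   ethnicity = c(Caucasian = 0.691, unknown = 0.143,
                                 Asian = 0.071, Other = 0.043,
                                 "Afro/Caribbean" = 0.052)),
    screening = list(ageMean = 62.9, ageSd = 6, maleP = 0,
                     diabetesP = 3 / 72, bmiMean = 26.5, bmiSd = 4,
                     ethnicity = c(unknown = 1)))
  covariateModel <- modifyList(covDefaults, covariateModel %||% list())
  symDefaults <- list(
    case = c("Jaundice" = 0.50, "Weight Loss" = 0.55, "Abdominal Pain" = 0.55,
             "Back Pain" = 0.20, "Change in Bowel Habit" = 0.15,
             "Asymptomatic LFT Derangement" = 0.15, "Vomiting" = 0.15,
             "Rectal Bleeding" = 0.02, "Reflux" = 0.05, "Bloating" = 0.08,
             "Heartburn" = 0.05, "Anaemia" = 0.05),
    control = c("Jaundice" = 0.06, "Weight Loss" = 0.18,
                "Abdominal Pain" = 0.45, "Back Pain" = 0.15,
                "Change in Bowel Habit" = 0.13,
                "Asymptomatic LFT Derangement" = 0.10, "Vomiting" = 0.10,
                "Rectal Bleeding" = 0.04, "Reflux" = 0.15, "Bloating" = 0.18,
                "Heartburn" = 0.12, "Anaemia" = 0.04))
  symptomModel <- modifyList(symDefaults, symptomModel %||% list())
  qcancerModel <- modifyList(
    list(rate = 0.3, intercept = -3.2, age = 0.04, male = 0.3,
         symptom = 0.35, case = 1.5, noiseSd = 0.5),
    qcancerModel %||% list())
  batchModel <- modifyList(list(offsetSd = 0.3, nBridge = 16L),
                           batchModel %||% list())
  cfg <- structure(list(
    nPerClass = nPerClass, nCases = as.integer(nCases),
    stageDist = stageDist, markerPanel = markerPanel,
    effectMap = effectMap, covariateModel = covariateModel,
    symptomModel = symptomModel, qcancerModel = qcancerModel,
    batchModel = batchModel, noiseSd = noiseSd, baseline = baseline,
    missingRate = missingRate), class = "pdac_sim_config")
  validateConfig(cfg)
  cfg
}

#' @rdname cohortConfig
#' @param config a config list to validate.
#' @export
validateConfig <- function(config) {
  with(config, {
    if (any(nPerClass < 0) || nCases < 0 || any(stageDist < 0))
      stopf("all counts must be non-negative")
    bad <- setdiff(names(nPerClass), controlClasses())
    if (length(bad))
      stopf("unknown diagnosis class in nPerClass: %s",
            paste(bad, collapse = ", "))
    if (sum(stageDist) != nCases)
      stopf("stageDist must sum to nCases")
    if (!all(names(stageDist) %in% tumourStages()))
      stopf("unknown stage in stageDist")
    if (noiseSd <= 0) stopf("noiseSd must be > 0")
    if (missingRate < 0 || missingRate > 1)
      stopf("missingRate must be in [0, 1]")
    if (nrow(effectMap)) {
      if (!all(effectMap$marker %in% markerPanel))
        stopf("effectMap references unknown marker(s): %s",
              paste(setdiff(effectMap$marker, markerPanel), collapse = ", "))
      okGroups <- c(caseClass(), controlClasses())
      if (!all(effectMap$group %in% okGroups))
        stopf("effectMap references unknown group(s): %s",
              paste(setdiff(effectMap$group, okGroups), collapse = ", "))
    }
    probs <- c(unlist(symptomModel), qcancerModel$rate,
               vapply(covariateModel, function(m)
                 c(m$maleP, m$diabetesP), numeric(2)))
    if (any(probs < 0 | probs > 1)) stopf("probabilities must be in [0, 1]")
  })
  invisible(TRUE)
}

.drawArm <- function(n, model) {
  age <- pmin(pmax(rnorm(n, model$ageMean, model$ageSd), 18), 100)
  eth <- if (length(model$ethnicity) == 1L) {
    rep(names(model$ethnicity), n)
  } else {
    sample(names(model$ethnicity), n, replace = TRUE, prob = model$ethnicity)
  }
  data.frame(
    age = round(age, 1),
    gender = ifelse(runif(n) < model$maleP, "male", "female"),
    bmi = round(pmax(rnorm(n, model$bmiMean, model$bmiSd), 13), 1),
    diabetes = ifelse(runif(n) < model$diabetesP, "yes", "no"),
    ethnicity = eth, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Generate a synthetic cohort
#'
#' Draws a full [PdacCohort-class] under `config`: marker values are
#' baseline + (marker, group) shift + per-assay batch offset + Gaussian
#' noise on the NPX log2 scale; clinical covariates, symptom flags and the
#' QCancer score follow the configured case/control models. Symptomatic-
#' source samples are assigned to the reference batch, screening-source
#' ("Healthy") samples to a second batch whose per-assay offsets are drawn
#' with SD `batchModel$offsetSd`. The realized batch offsets and noise SD
#' are recorded in `metadata()` so bridge pairs can be measured afterwards.
#' Identical `(config, seed)` give a bit-identical cohort.
#'
#' @param config a [cohortConfig()] object.
#' @param seed integer.
#' @return a [PdacCohort-class].
#' @export
simulateCohort <- function(config, seed) {
  validateConfig(config)
  withSeed(seed, {
    classes <- rep(names(config$nPerClass), config$nPerClass)
    stages <- rep(names(config$stageDist), config$stageDist)
    nCtrl <- length(classes)
    nCase <- config$nCases
    n <- nCtrl + nCase
    diagnosis <- c(classes, rep(caseClass(), nCase))
    label <- c(rep("control", nCtrl), rep("case", nCase))
    stage <- c(rep(NA_character_, nCtrl), stages)
    source <- ifelse(diagnosis == "Healthy", "screening", "symptomatic")

    armOf <- ifelse(label == "case", "case",
                    ifelse(source == "screening", "screening", "control"))
    cov <- data.frame(age = numeric(n), gender = character(n),
                      bmi = numeric(n), diabetes = character(n),
                      ethnicity = character(n), stringsAsFactors = FALSE)
    for (a in unique(armOf)) {
      idx <- which(armOf == a)
      cov[idx, ] <- .drawArm(length(idx), config$covariateModel[[a]])
    }

    symNames <- names(config$symptomModel$case)
    sym <- matrix(NA_integer_, n, length(symNames),
                  dimnames = list(NULL, paste0("sym_", symNames)))
    sympt <- source == "symptomatic"
    for (j in seq_along(symNames)) {
      pCase <- config$symptomModel$case[[j]]
      pCtrl <- config$symptomModel$control[[j]]
      p <- ifelse(label == "case", pCase, pCtrl)
      sym[sympt, j] <- rbinom(sum(sympt), 1L, p[sympt])
    }

    qm <- config$qcancerModel
    qc <- rep(NA_real_, n)
    hasQ <- sympt & runif(n) < qm$rate
    if (any(hasQ)) {
      nsym <- rowSums(sym[, , drop = FALSE], na.rm = TRUE)
      lin <- qm$intercept + qm$age * (cov$age - 60) +
        qm$male * (cov$gender == "male") + qm$symptom * nsym +
        qm$case * (label == "case")
      qc[hasQ] <- round(100 * plogis(lin[hasQ] +
                                       rnorm(sum(hasQ), 0, qm$noiseSd)), 2)
    }

    batch <- ifelse(source == "screening", "B2", "B1")
    p <- length(config$markerPanel)
    offsets <- matrix(0, p, 2,
                      dimnames = list(config$markerPanel, c("B1", "B2")))
    offsets[, "B2"] <- rnorm(p, 0, config$batchModel$offsetSd)

    base <- if (length(config$baseline) == 1L)
      setNames(rep(config$baseline, p), config$markerPanel)
    else config$baseline[config$markerPanel]
    shifts <- matrix(0, p, n, dimnames = list(config$markerPanel, NULL))
    if (nrow(config$effectMap)) {
      for (k in seq_len(nrow(config$effectMap))) {
        e <- config$effectMap[k, ]
        shifts[e$marker, diagnosis == e$group] <-
          shifts[e$marker, diagnosis == e$group] + e$shift
      }
    }
    npx <- base + shifts + offsets[, batch] +
      matrix(rnorm(p * n, 0, config$noiseSd), p, n)
    if (config$missingRate > 0)
      npx[runif(p * n) < config$missingRate] <- NA_real_

    sampleData <- cbind(
      data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                 source_cohort = source, diagnosis_class = diagnosis,
                 stage = stage, label = label, stringsAsFactors = FALSE),
      cov, as.data.frame(sym),
      data.frame(qcancer = qc, batch = batch, stringsAsFactors = FALSE))
    sampleData <- sampleData[, c("sample_id", "source_cohort",
                                 "diagnosis_class", "stage", "label", "age",
                                 "gender", "bmi", "diabetes", "ethnicity",
                                 colnames(sym), "qcancer", "batch")]
    cohort <- PdacCohort(npx, sampleData)
    metadata(cohort)$batch_offsets <- offsets
    metadata(cohort)$noise_sd <- config$noiseSd
    metadata(cohort)$config_seed <- as.integer(seed)
    cohort
  })
}

#' Measure bridge samples under two batch conditions
#'
#' Selects `nBridge` samples and re-measures their underlying marker values
#' under the reference and the new batch's per-assay offsets (each with
#' fresh measurement noise), emulating the shared "bridge" samples plated
#' together when two batches must be aligned.
#'
#' @param cohort a simulated [PdacCohort-class] (its `metadata()` carries
#'   the realized batch offsets and noise SD).
#' @param nBridge number of bridge samples (default 16).
#' @param seed integer.
#' @param batches length-2 character: reference and new batch names.
#' @return list with markers-by-bridge matrices `ref` and `new`, and
#'   `sample_id` of the bridged samples.
#' @export
generateBridgePairs <- function(cohort, nBridge = 16L, seed = 1L,
                                batches = c("B1", "B2")) {
  off <- metadata(cohort)$batch_offsets
  if (is.null(off)) stopf("cohort carries no batch offset metadata")
  cd <- colData(cohort)
  pool <- which(cd$batch == batches[1])
  if (!length(pool)) pool <- seq_len(ncol(cohort))
  if (nBridge > length(pool))
    stopf("nBridge (%d) exceeds batch size (%d)", nBridge, length(pool))
  p <- nrow(cohort)
  if (nBridge == 0L) {
    empty <- matrix(numeric(0), p, 0, dimnames = list(rownames(cohort), NULL))
    return(list(ref = empty, new = empty, sample_id = character(0)))
  }
  withSeed(seed, {
    pick <- sort(sample(pool, nBridge))
    underlying <- markerData(cohort)[, pick, drop = FALSE] -
      off[, cd$batch[pick[1]]]
    noiseSd <- metadata(cohort)$noise_sd %||% 0
    ref <- underlying + off[, batches[1]] +
      matrix(rnorm(p * nBridge, 0, noiseSd), p, nBridge)
    new <- underlying + off[, batches[2]] +
      matrix(rnorm(p * nBridge, 0, noiseSd), p, nBridge)
    list(ref = ref, new = new, sample_id = cd$sample_id[pick])
  })
}
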