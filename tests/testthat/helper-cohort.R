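# shared fixtures: all cohorts are generated in code at test time

# minimal marker panels keep LOOCV loops fast
smallPanel <- function(extra = character(0)) {
  unique(c("CA19-9", "VWF", "CRP", "EGF", extra, elisaMarkers()))
}

noEffects <- function() {
  data.frame(marker = character(0), group = character(0),
             shift = numeric(0))
}

# a small two-class cohort with a planted PDAC signal on CA19-9
smallCohort <- function(seed = 1, nCtrl = 20, nCase = 12, shift = 2) {
  cfg <- cohortConfig(
    nPerClass = c("Liver Disease" = nCtrl),
    nCases = nCase, markerPanel = smallPanel(),
    effectMap = data.frame(marker = "CA19-9", group = "PDAC",
                           shift = shift))
  simulateCohort(cfg, seed = seed)
}

# hand-built PdacCohort from a marker matrix (markers x samples)
manualCohort <- function(npx, label = NULL, diagnosis = NULL,
                         batch = "B1", age = 60) {
  n <- ncol(npx)
  if (is.null(label)) label <- rep(c("case", "control"), length.out = n)
  if (is.null(diagnosis))
    diagnosis <- ifelse(label == "case", "PDAC", "Liver Disease")
  sd <- data.frame(
    sample_id = sprintf("X%03d", seq_len(n)),
    source_cohort = "symptomatic", diagnosis_class = diagnosis,
    stage = ifelse(label == "case", "II", NA_character_),
    label = label, age = rep_len(age, n), gender = "male", bmi = 25,
    diabetes = "no", ethnicity = "Caucasian",
    sym_Jaundice = 0L, qcancer = NA_real_,
    batch = rep_len(batch, n), stringsAsFactors = FALSE)
  PdacCohort(npx, sd)
}

# brute-force AUC oracle: explicit pair counting with half-credit ties
pairCountAuc <- function(scores, labels) {
  cs <- scores[as.logical(labels)]
  ct <- scores[!as.logical(labels)]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# brute-force Youden oracle: exhaustive search over candidate thresholds
bruteYouden <- function(scores, labels) {
  labels <- as.logical(labels)
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1, u)
  max(vapply(cand, function(t)
    mean(scores[labels] >= t) + mean(scores[!labels] < t) - 1,
    numeric(1)))
}
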