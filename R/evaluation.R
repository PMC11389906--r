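## ROC/AUC computation, fixed-specificity operating metrics, stratified
## bootstrap confidence intervals and one-sided bootstrap AUC comparisons.

#' ROC area under the curve
#'
#' Mann-Whitney formulation: the proportion of (case, control) pairs in
#' which the case scores higher, with ties credited one half. Computed via
#' midranks, so it equals exhaustive pair counting exactly.
#'
#' @param scores numeric predictor values (higher = more case-like).
#' @param labels binary labels (1/TRUE = case).
#' @return AUC in [0, 1].
#' @examples
#' rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Operating metrics at a fixed specificity
#'
#' The operating threshold is the smallest observed score value achieving
#' at least the target specificity when samples scoring at or above the
#' threshold are called positive (no interpolation between observed
#' scores). Sensitivity, PPV and NPV are computed at that threshold using
#' the evaluated set's own prevalence. If no observed score reaches the
#' target specificity, the threshold is reported above the maximum score
#' and sensitivity is zero.
#'
#' @inheritParams rocAuc
#' @param spec target specificity (default 0.90).
#' @return list with `sens`, `ppv`, `npv`, `spec` (realized), `threshold`.
#' @export
metricsAtSpecificity <- function(scores, labels, spec = 0.90) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stopf("both classes must be present")
  ctrl <- scores[!labels]
  cand <- sort(unique(scores))
  specAt <- vapply(cand, function(t) mean(ctrl < t), numeric(1))
  ok <- which(specAt >= spec)
  if (!length(ok)) {
    thr <- max(scores) + 1
  } else {
    thr <- cand[ok[1L]]
  }
  pos <- scores >= thr
  tp <- sum(pos & labels); fp <- sum(pos & !labels)
  tn <- sum(!pos & !labels); fn <- sum(!pos & labels)
  list(sens = tp / (tp + fn),
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       spec = tn / (tn + fp),
       threshold = thr)
}

#' Stratified percentile-bootstrap confidence interval
#'
#' Cases and controls are resampled separately with replacement; the metric
#' is recomputed on each resample and the percentile interval returned.
#' Resamples on which the metric is undefined (e.g. no positive calls) are
#' redrawn, with the redraw count reported.
#'
#' @param metric function `(scores, labels) -> numeric(1)`.
#' @inheritParams rocAuc
#' @param nBoot number of bootstrap resamples (default 2000).
#' @param level confidence level.
#' @param seed integer.
#' @return list `lower`, `upper`, `level`, `nBoot`, `nRedrawn`, `seed`.
#' @export
stratifiedBootstrapCi <- function(metric, scores, labels, nBoot = 2000L,
                                  level = 0.95, seed = 1L) {
  labels <- as.logical(labels)
  ic <- which(labels); i0 <- which(!labels)
  vals <- numeric(nBoot)
  redrawn <- 0L
  withSeed(seed, {
    for (b in seq_len(nBoot)) {
      repeat {
        idx <- c(sample(ic, length(ic), replace = TRUE),
                 sample(i0, length(i0), replace = TRUE))
        v <- tryCatch(metric(scores[idx], labels[idx]),
                      error = function(e) NA_real_)
        if (is.finite(v)) break
        redrawn <- redrawn + 1L
        if (redrawn > 100L * nBoot)
          stopf("metric undefined on essentially all resamples")
      }
      vals[b] <- v
    }
  })
  a <- (1 - level) / 2
  q <- unname(quantile(vals, c(a, 1 - a), type = 7))
  list(lower = q[1], upper = q[2], level = level, nBoot = as.integer(nBoot),
       nRedrawn = redrawn, seed = as.integer(seed))
}

#' Full ROC summary with stratified-bootstrap intervals
#'
#' AUC plus sensitivity/PPV/NPV at the target specificity, each with a
#' stratified percentile-bootstrap CI (the operating threshold is
#' re-derived on every resample). When the evaluated subset has fewer than
#' two cases or two controls the summary is flagged unstable and intervals
#' are suppressed.
#'
#' @inheritParams rocAuc
#' @param spec target specificity.
#' @param nBoot,level,seed bootstrap settings.
#' @return a [RocSummary-class].
#' @export
rocSummary <- function(scores, labels, spec = 0.90, nBoot = 2000L,
                       level = 0.95, seed = 1L) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present")
  m <- metricsAtSpecificity(scores, labels, spec)
  a <- rocAuc(scores, labels)
  ci <- matrix(NA_real_, 4L, 2L,
               dimnames = list(c("auc", "sens", "ppv", "npv"),
                               c("lower", "upper")))
  stable <- n1 >= 2L && n0 >= 2L
  if (stable && nBoot > 0L) {
    mk <- function(extract) function(s, l) {
      v <- extract(s, l)
      if (is.null(v) || !is.finite(v)) NA_real_ else v
    }
    fns <- list(
      auc = mk(function(s, l) rocAuc(s, l)),
      sens = mk(function(s, l) metricsAtSpecificity(s, l, spec)$sens),
      ppv = mk(function(s, l) metricsAtSpecificity(s, l, spec)$ppv),
      npv = mk(function(s, l) metricsAtSpecificity(s, l, spec)$npv))
    for (k in seq_along(fns)) {
      b <- stratifiedBootstrapCi(fns[[k]], scores, labels, nBoot, level,
                                 seed = childSeed(seed, k))
      ci[k, ] <- c(b$lower, b$upper)
    }
  }
  new("RocSummary", auc = a, sens = m$sens,
      ppv = if (is.finite(m$ppv)) m$ppv else NA_real_,
      npv = if (is.finite(m$npv)) m$npv else NA_real_,
      ci = ci, threshold = m$threshold, specificity = spec,
      nCases = as.integer(n1), nControls = as.integer(n0),
      nBoot = as.integer(nBoot), seed = as.integer(seed), level = level,
      stable = stable)
}

#' One-sided bootstrap comparison of two paired predictors
#'
#' Both score vectors must be computed on the same samples. Cases and
#' controls are resampled jointly (paired, stratified); the bootstrap
#' distribution of the metric difference is standardized and the one-sided
#' p-value for H1: metric(a) > metric(b) is the upper normal tail of
#' observed difference / bootstrap SD (the halved two-sided convention).
#' The metric defaults to AUC; sensitivity at fixed specificity is also
#' supported.
#'
#' @param scoresA,scoresB paired score vectors.
#' @inheritParams rocAuc
#' @param nBoot resamples (default 10000).
#' @param metric `"auc"` or `"sens"` (sensitivity at `spec`).
#' @param spec specificity for `metric = "sens"`.
#' @param seed integer.
#' @return list `deltaObs`, `p`, `aucA`, `aucB`, `nBoot`, `seed`, `metric`.
#' @export
compareAucBootstrap <- function(scoresA, scoresB, labels, nBoot = 10000L,
                                metric = c("auc", "sens"), spec = 0.90,
                                seed = 1L) {
  metric <- match.arg(metric)
  if (length(scoresA) != length(scoresB) ||
      length(scoresA) != length(labels))
    stopf("scoresA, scoresB and labels must have equal length")
  labels <- as.logical(labels)
  fn <- if (metric == "auc") rocAuc else
    function(s, l) metricsAtSpecificity(s, l, spec)$sens
  mA <- fn(scoresA, labels); mB <- fn(scoresB, labels)
  deltaObs <- mA - mB
  ic <- which(labels); i0 <- which(!labels)
  deltas <- numeric(nBoot)
  withSeed(seed, {
    for (b in seq_len(nBoot)) {
      idx <- c(sample(ic, length(ic), replace = TRUE),
               sample(i0, length(i0), replace = TRUE))
      deltas[b] <- fn(scoresA[idx], labels[idx]) -
        fn(scoresB[idx], labels[idx])
    }
  })
  sdB <- sd(deltas)
  p <- if (sdB == 0) {
    if (deltaObs > 0) 0 else if (deltaObs < 0) 1 else 0.5
  } else {
    pnorm(deltaObs / sdB, lower.tail = FALSE)
  }
  list(deltaObs = deltaObs, p = p, aucA = mA, aucB = mB,
       nBoot = as.integer(nBoot), seed = as.integer(seed), metric = metric)
}

#' Evaluate a trained model on a symptom-defined subset
#'
#' No refitting: per-sample probabilities from the already-trained model
#' are concatenated across the discovery and validation arms, restricted to
#' symptomatic-source samples presenting the given symptom, and summarized
#' as a [RocSummary-class]. Subsets with fewer than two cases or controls
#' are flagged unstable (intervals suppressed).
#'
#' @param model a [StackModel-class] or [BaseLearner-class].
#' @param discovery,validation [PdacCohort-class] arms.
#' @param symptom symptom name (one of [defaultSymptoms()]).
#' @param ... passed to [rocSummary()].
#' @return a [RocSummary-class].
#' @export
evaluateSymptomSubset <- function(model, discovery, validation, symptom,
                                  ...) {
  score <- function(cohort) {
    keep <- colData(cohort)$source_cohort == "symptomatic"
    cohort <- cohort[, keep]
    flags <- symptomFlags(cohort)
    if (!symptom %in% colnames(flags))
      stopf("symptom '%s' not recorded in cohort", symptom)
    sel <- !is.na(flags[, symptom]) & flags[, symptom] == 1
    list(p = predict(model, cohort[, sel]), y = isCase(cohort[, sel]))
  }
  d <- score(discovery); v <- score(validation)
  scores <- c(d$p, v$p); y <- c(d$y, v$y)
  if (!any(y) || all(y))
    stopf("symptom subset contains a single class; cannot evaluate")
  rocSummary(scores, y, ...)
}

#' Evaluate the model against the QCancer score across risk thresholds
#'
#' Restricted to samples carrying a QCancer percent-risk score, evaluates
#' (a) the model's probability and (b) the raw QCancer score as predictors
#' of PDAC, overall and above each risk threshold, and reports the Pearson
#' correlation between the QCancer score and the model's log-odds with its
#' t-test p-value.
#'
#' @param model a [StackModel-class] or [BaseLearner-class].
#' @param cohort a [PdacCohort-class] (typically discovery + validation).
#' @param thresholds QCancer percent thresholds (default 2, 2.5, 3).
#' @param nBoot,seed bootstrap settings for the per-threshold summaries.
#' @return list with `correlation` (`r`, `p`, `n`), and per-threshold lists
#'   of [RocSummary-class] for the model and for the QCancer score.
#' @export
qcancerAnalysis <- function(model, cohort, thresholds = c(2, 2.5, 3),
                            nBoot = 2000L, seed = 1L) {
  q <- qcancerScore(cohort)
  keep <- !is.na(q)
  if (!any(keep)) stopf("no samples carry a QCancer score")
  cohort <- cohort[, keep]; q <- q[keep]
  prob <- predict(model, cohort)
  y <- isCase(cohort)
  logOdds <- clippedLogit(prob)
  r <- cor(q, logOdds)
  n <- length(q)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  pcor <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  evalAt <- function(scores, sel, k) {
    if (sum(y[sel]) < 1L || sum(!y[sel]) < 1L) return(NULL)
    rocSummary(scores[sel], y[sel], nBoot = nBoot,
               seed = childSeed(seed, k))
  }
  cuts <- c(0, thresholds)
  names(cuts) <- c("all", paste0(">", thresholds))
  modelRoc <- lapply(seq_along(cuts), function(i)
    evalAt(prob, q > cuts[i] | cuts[i] == 0, i))
  qRoc <- lapply(seq_along(cuts), function(i)
    evalAt(q, q > cuts[i] | cuts[i] == 0, 100 + i))
  names(modelRoc) <- names(qRoc) <- names(cuts)
  list(correlation = list(r = r, p = pcor, n = n),
       model = modelRoc, qcancer = qRoc)
}
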