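## Univariate screening: per-feature Firth association with PDAC, single-
## feature model performance in discovery and validation, Youden cutoffs,
## and symptom associations.

#' Youden's J optimal cutoff
#'
#' The threshold maximizing sensitivity + specificity - 1, with samples at
#' or above the threshold called positive. Candidate thresholds are the
#' midpoints between adjacent distinct observed scores (plus one below the
#' minimum and one above the maximum); ties in J are broken toward the
#' midpoint between adjacent observed scores closest to the overall
#' median.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels binary labels (1 = case).
#' @return list `threshold`, `J`, `sens`, `spec`.
#' @export
youdenCutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stopf("both classes must be present")
  u <- sort(unique(scores))
  cand <- if (length(u) == 1L) u else
    c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  j <- vapply(cand, function(t) {
    mean(scores[labels] >= t) + mean(scores[!labels] < t) - 1
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.min(abs(cand[best] - median(scores)))]
  t <- cand[pick]
  list(threshold = t, J = max(j),
       sens = mean(scores[labels] >= t),
       spec = mean(scores[!labels] < t))
}

#' Univariate feature screen against PDAC status
#'
#' For each feature: a Firth logistic association fit on the discovery
#' arm (OR, profile CI, penalized-LRT p), a single-feature logistic model
#' trained on discovery and scored on both arms (ROC summaries), and the
#' discovery Youden cutoff. Rows are sorted by association p-value.
#' Constant features are flagged and assigned p = 1 by convention. An
#' optional Benjamini-Hochberg column is appended for reporting; selection
#' downstream uses raw p-values.
#'
#' @param discovery a [PdacCohort-class].
#' @param features feature names (default: all candidates).
#' @param validation optional [PdacCohort-class] scored with the
#'   discovery-fit single-feature models (no refit).
#' @param nBoot bootstrap resamples for the ROC summaries (0 disables CIs).
#' @param seed integer.
#' @return data.frame: feature, OR, CI_low, CI_high, p, p_adj, auc_disc,
#'   sens90_disc, youden_cutoff, and (if validation given) auc_valid,
#'   sens90_valid.
#' @export
screenFeatures <- function(discovery, features = candidateFeatures(discovery),
                           validation = NULL, nBoot = 0L, seed = 1L) {
  missing <- setdiff(features,
                     c(clinicalCovariates(), markerNames(discovery)))
  if (length(missing))
    stopf("feature(s) not present: %s", paste(missing, collapse = ", "))
  X <- featureMatrix(discovery, features)
  y <- as.numeric(isCase(discovery))
  Xv <- if (!is.null(validation)) featureMatrix(validation, features)
  yv <- if (!is.null(validation)) as.numeric(isCase(validation))
  rows <- lapply(features, function(f) {
    v <- X[, f]
    if (sd(v) == 0) {
      row <- data.frame(feature = f, OR = NA_real_, CI_low = NA_real_,
                        CI_high = NA_real_, p = 1, constant = TRUE,
                        auc_disc = NA_real_, sens90_disc = NA_real_,
                        youden_cutoff = NA_real_)
      if (!is.null(validation)) {
        row$auc_valid <- NA_real_; row$sens90_valid <- NA_real_
      }
      return(row)
    }
    fit <- firthFit(matrix(v, ncol = 1, dimnames = list(NULL, f)), y)
    score <- plogis(coef(fit)[1L] + coef(fit)[2L] * v)
    m <- metricsAtSpecificity(score, y)
    yc <- youdenCutoff(v, y)
    row <- data.frame(feature = f, OR = unname(exp(coef(fit)[2L])),
                      CI_low = unname(exp(fit@ci[2L, 1L])),
                      CI_high = unname(exp(fit@ci[2L, 2L])),
                      p = unname(fit@p[2L]), constant = FALSE,
                      auc_disc = rocAuc(score, y), sens90_disc = m$sens,
                      youden_cutoff = yc$threshold)
    if (!is.null(validation)) {
      sv <- plogis(coef(fit)[1L] + coef(fit)[2L] * Xv[, f])
      mv <- metricsAtSpecificity(sv, yv)
      row$auc_valid <- rocAuc(sv, yv)
      row$sens90_valid <- mv$sens
    }
    row
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out[order(out$p, out$feature), , drop = FALSE]
}

#' Per-symptom Firth association with PDAC
#'
#' Restricted to symptomatic-source samples (screening-derived controls
#' carry no symptom information and are excluded). Each recorded symptom
#' flag is tested against PDAC status with a Firth logistic model.
#' Symptoms absent from every sample are skipped with a warning.
#'
#' @param cohort a [PdacCohort-class].
#' @return data.frame: symptom, n_yes, OR, CI_low, CI_high, p.
#' @export
symptomAssociation <- function(cohort) {
  keep <- colData(cohort)$source_cohort == "symptomatic"
  cohort <- cohort[, keep]
  flags <- symptomFlags(cohort)
  if (!ncol(flags)) stopf("cohort carries no symptom flags")
  y <- as.numeric(isCase(cohort))
  rows <- lapply(colnames(flags), function(s) {
    v <- flags[, s]
    ok <- !is.na(v)
    if (!any(v[ok] == 1)) {
      warnf("symptom '%s' present in zero samples; skipped", s)
      return(NULL)
    }
    if (sd(v[ok]) == 0) {
      warnf("symptom '%s' constant; skipped", s)
      return(NULL)
    }
    fit <- firthFit(matrix(v[ok], ncol = 1, dimnames = list(NULL, s)), y[ok])
    data.frame(symptom = s, n_yes = sum(v[ok] == 1),
               OR = unname(exp(coef(fit)[2L])),
               CI_low = unname(exp(fit@ci[2L, 1L])),
               CI_high = unname(exp(fit@ci[2L, 2L])),
               p = unname(fit@p[2L]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no testable symptom flags")
  out[order(out$p), , drop = FALSE]
}
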