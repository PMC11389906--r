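## Diagnosis-specific base learners: controls of one diagnosis class vs the
## shared PDAC cases, trained by recursive feature elimination (RFE) with
## logistic regression under leave-one-out cross-validation (LOOCV).
## Standardization, subsampling and RFE are all recomputed inside every
## fold, so the held-out row never leaks into feature selection.

# lightly ridge-penalized logistic IRLS (intercept unpenalized); the small
# default ridge only stabilizes tiny, nearly separable folds
.ridgeLogistic <- function(Z, y, lambda = 1e-4, maxIter = 25L, tol = 1e-8,
                           start = NULL) {
  X <- cbind(1, Z)
  p1 <- ncol(X)
  beta <- if (is.null(start)) numeric(p1) else start
  pen <- c(0, rep(lambda, p1 - 1L))
  for (it in seq_len(maxIter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    XtWX <- crossprod(X * sqrt(w))
    diag(XtWX) <- diag(XtWX) + pen
    z <- w * eta + (y - mu)
    betaNew <- tryCatch(drop(solve(XtWX, crossprod(X, z))),
                        error = function(e) NULL)
    if (is.null(betaNew)) {
      diag(XtWX) <- diag(XtWX) + 1e-6
      betaNew <- drop(solve(XtWX, crossprod(X, z)))
    }
    if (max(abs(betaNew - beta)) < tol) { beta <- betaNew; break }
    beta <- betaNew
  }
  setNames(beta, c("(Intercept)", colnames(Z)))
}

#' Recursive feature elimination ranking with logistic regression
#'
#' Iteratively refits a ridge-stabilized logistic model and drops the
#' feature with the smallest absolute (standardized-scale) coefficient;
#' ties are broken lexicographically by feature name (the alphabetically
#' earlier name survives). The returned ranking lists features from most
#' to least important (last-removed first). Fitted coefficient vectors are
#' recorded at each requested subset size along the elimination path.
#'
#' @param Z standardized feature matrix (columns named).
#' @param y binary labels (1 = case).
#' @param sizes subset sizes at which to keep the fitted model.
#' @param lambda ridge penalty of the elimination fits.
#' @return list `ranking` (character) and `fits` (named list, one
#'   coefficient vector per requested size).
#' @export
rfeRank <- function(Z, y, sizes = ncol(Z), lambda = 1e-4) {
  remaining <- colnames(Z)
  if (is.null(remaining)) stopf("feature matrix must have column names")
  sizes <- sort(unique(pmin(sizes, ncol(Z))))
  fits <- vector("list", length(sizes))
  names(fits) <- as.character(sizes)
  removed <- character(0)
  warm <- NULL
  repeat {
    beta <- .ridgeLogistic(Z[, remaining, drop = FALSE], y, lambda,
                           start = warm)
    sz <- length(remaining)
    if (sz %in% sizes) fits[[as.character(sz)]] <- beta
    if (sz == 1L) break
    ab <- abs(beta[-1L])
    # among ties at the minimum, drop the lexicographically later name
    minNames <- names(ab)[ab <= min(ab) + 1e-6]
    drop <- sort(minNames, decreasing = TRUE)[1L]
    removed <- c(removed, drop)
    remaining <- setdiff(remaining, drop)
    warm <- beta[c("(Intercept)", remaining)]
  }
  list(ranking = c(remaining, rev(removed)), fits = fits)
}

.standardizeParams <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

.applyStandardize <- function(X, sp) {
  sweep(sweep(X, 2L, sp$center), 2L, sp$scale, "/")
}

.defaultSubsetSizes <- function(p) {
  unique(pmin(c(1:10, 15, 20, 30, 45, 60, p), p))
}

# final (unpenalized) logistic fit with a Firth fallback under separation
.finalLogistic <- function(Z, y) {
  sepWarn <- FALSE
  fit <- withCallingHandlers(
    glm.fit(cbind(1, Z), y, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sepWarn <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- setNames(fit$coefficients, c("(Intercept)", colnames(Z)))
  if (sepWarn || !fit$converged || any(!is.finite(beta)) ||
      any(abs(beta) > 15)) {
    warnf("separation in final fit; switching to Firth penalization")
    eng <- .firthEngine(cbind("(Intercept)" = 1, Z), y)
    beta <- eng$coefficients
    list(beta = beta, firth = TRUE)
  } else {
    list(beta = beta, firth = FALSE)
  }
}

#' Train one diagnosis-specific base learner
#'
#' The training subset is the discovery controls of `diagnosisClass` plus
#' all discovery PDAC cases (PDAC coded 1). An outer LOOCV runs over the
#' subset rows; inside each fold the features are standardized by the
#' fold-training statistics, the training slice is balanced by the chosen
#' subsampling mode, an RFE ranking is computed, a logistic model is fitted
#' at each candidate subset size, and the held-out row is scored. The
#' subset size with the best pooled-LOOCV AUC (smallest size on ties) wins;
#' the final model is refit on the full subset (standardize, subsample,
#' fit) restricted to the winning feature set, with a Firth fallback under
#' complete separation.
#'
#' @param discovery a [PdacCohort-class] (discovery arm).
#' @param diagnosisClass one of [controlClasses()].
#' @param candidates candidate feature names (default: clinical covariates
#'   plus all markers).
#' @param subsampling `"over"` (default), `"under"`, `"smote"` or `"none"`.
#' @param seed integer.
#' @param subsetSizes candidate feature-set sizes (default
#'   1..10, 15, 20, 30, 45, 60, all).
#' @param lambda ridge penalty used inside RFE.
#' @return a [BaseLearner-class].
#' @examples
#' cfg <- cohortConfig(nPerClass = c("Liver Disease" = 15), nCases = 10,
#'                     markerPanel = c("CA19-9", "VWF", "CRP", "EGF"),
#'                     effectMap = data.frame(marker = "CA19-9",
#'                                            group = "PDAC", shift = 2))
#' cohort <- simulateCohort(cfg, seed = 3)
#' bl <- trainBaseLearner(cohort, "Liver Disease",
#'                        candidates = c("CA19-9", "VWF", "CRP", "EGF"),
#'                        seed = 3, subsetSizes = c(1, 2, 4))
#' selectedFeatures(bl)
#' @export
trainBaseLearner <- function(discovery, diagnosisClass,
                             candidates = candidateFeatures(discovery),
                             subsampling = c("over", "under", "smote", "none"),
                             seed = 1L, subsetSizes = NULL, lambda = 1e-4) {
  subsampling <- match.arg(subsampling)
  dc <- diagnosisClasses(discovery)
  keep <- (dc == diagnosisClass & !isCase(discovery)) | isCase(discovery)
  if (!any(dc == diagnosisClass))
    stopf("diagnosis class '%s' absent from discovery set", diagnosisClass)
  sub <- discovery[, keep]
  y <- as.numeric(isCase(sub))
  if (sum(y == 0) < 3L)
    stopf("need at least 3 '%s' controls in discovery", diagnosisClass)
  if (sum(y == 1) < 1L) stopf("no PDAC cases in discovery")
  X <- featureMatrix(sub, candidates)
  n <- nrow(X)
  sizes <- subsetSizes %||% .defaultSubsetSizes(length(candidates))
  sizes <- sort(unique(pmin(sizes, length(candidates))))

  oof <- matrix(NA_real_, n, length(sizes),
                dimnames = list(rownames(X), as.character(sizes)))
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
    sp <- .standardizeParams(Xtr)
    Ztr <- .applyStandardize(Xtr, sp)
    bal <- applySubsampling(Ztr, ytr, subsampling, childSeed(seed, i))
    rfe <- rfeRank(bal$X, bal$y, sizes = sizes, lambda = lambda)
    zHold <- .applyStandardize(X[i, , drop = FALSE], sp)
    for (s in names(rfe$fits)) {
      beta <- rfe$fits[[s]]
      feats <- names(beta)[-1L]
      oof[i, s] <- plogis(beta[1L] +
                            sum(zHold[1L, feats] * beta[-1L]))
    }
  }
  aucs <- vapply(colnames(oof), function(s) rocAuc(oof[, s], y), numeric(1))
  profile <- data.frame(size = as.integer(colnames(oof)),
                        auc = unname(aucs))
  best <- profile$size[which.max(profile$auc)]

  sp <- .standardizeParams(X)
  Z <- .applyStandardize(X, sp)
  bal <- applySubsampling(Z, y, subsampling, childSeed(seed, 0L))
  rfe <- rfeRank(bal$X, bal$y, sizes = best, lambda = lambda)
  feats <- rfe$ranking[seq_len(best)]
  fin <- .finalLogistic(bal$X[, feats, drop = FALSE], bal$y)
  new("BaseLearner", diagnosisClass = diagnosisClass, features = feats,
      coefficients = fin$beta, center = sp$center[feats],
      scale = sp$scale[feats], cvProfile = profile,
      oofProb = setNames(oof[, as.character(best)], rownames(X)),
      subsampling = subsampling, candidates = candidates,
      firth = fin$firth, seed = as.integer(seed))
}

#' Predict PDAC probabilities from a base learner
#'
#' Features are standardized by the learner's stored training parameters;
#' probabilities are defined for any sample regardless of its diagnosis
#' class.
#'
#' @param object a [BaseLearner-class].
#' @param newdata a [PdacCohort-class].
#' @return named numeric probabilities in (0, 1).
#' @export
setMethod("predict", "BaseLearner", function(object, newdata) {
  X <- featureMatrix(newdata, object@features)
  Z <- .applyStandardize(X, list(center = object@center,
                                 scale = object@scale))
  eta <- drop(object@coefficients[1L] + Z %*% object@coefficients[-1L])
  setNames(plogis(eta), rownames(X))
})
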