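## Non-ensemble baselines trained on the whole discovery set: a single
## RFE-logistic model (no division of controls into diagnosis classes) and
## tree-based models (random forest, gradient boosted trees) with random
## hyperparameter search. All comparators consume exactly the same
## candidate features and splits as the ensemble.

#' Whole-discovery RFE logistic comparator
#'
#' Identical machinery to [trainBaseLearner()] but contrasting all
#' discovery controls against all discovery cases, yielding a single model
#' instead of one per diagnosis class. Returned as a [BaseLearner-class]
#' with `diagnosisClass = "ALL"` so the same prediction and importance
#' tooling applies.
#'
#' @inheritParams trainBaseLearner
#' @return a [BaseLearner-class].
#' @export
trainRfeGlmWhole <- function(discovery,
                             candidates = candidateFeatures(discovery),
                             subsampling = c("over", "under", "smote", "none"),
                             seed = 1L, subsetSizes = NULL, lambda = 1e-4) {
  subsampling <- match.arg(subsampling)
  y <- as.numeric(isCase(discovery))
  if (sum(y == 0) < 3L || sum(y == 1) < 1L)
    stopf("discovery set too small for the whole-cohort comparator")
  X <- featureMatrix(discovery, candidates)
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
      oof[i, s] <- plogis(beta[1L] + sum(zHold[1L, feats] * beta[-1L]))
    }
  }
  aucs <- vapply(colnames(oof), function(s) rocAuc(oof[, s], y), numeric(1))
  profile <- data.frame(size = as.integer(colnames(oof)), auc = unname(aucs))
  best <- profile$size[which.max(profile$auc)]
  sp <- .standardizeParams(X)
  Z <- .applyStandardize(X, sp)
  bal <- applySubsampling(Z, y, subsampling, childSeed(seed, 0L))
  rfe <- rfeRank(bal$X, bal$y, sizes = best, lambda = lambda)
  feats <- rfe$ranking[seq_len(best)]
  fin <- .finalLogistic(bal$X[, feats, drop = FALSE], bal$y)
  new("BaseLearner", diagnosisClass = "ALL", features = feats,
      coefficients = fin$beta, center = sp$center[feats],
      scale = sp$scale[feats], cvProfile = profile,
      oofProb = setNames(oof[, as.character(best)], rownames(X)),
      subsampling = subsampling, candidates = candidates,
      firth = fin$firth, seed = as.integer(seed))
}

# declared random-search grids for the tree families
.treeGrid <- function(family, nDraws, p, seed) {
  withSeed(seed, {
    if (family == "random_forest") {
      data.frame(
        num.trees = sample(c(100L, 250L, 500L), nDraws, replace = TRUE),
        mtry = pmax(1L, round(runif(nDraws, 0.1, 0.9) * p)),
        min.node.size = sample(1:5, nDraws, replace = TRUE))
    } else {
      data.frame(
        nrounds = sample(c(25L, 50L, 100L), nDraws, replace = TRUE),
        max_depth = sample(2:6, nDraws, replace = TRUE),
        eta = runif(nDraws, 0.05, 0.4),
        subsample = runif(nDraws, 0.6, 1))
    }
  })
}

.fitTree <- function(family, X, y, par, seed) {
  if (family == "random_forest") {
    ranger::ranger(
      x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
      probability = TRUE, num.trees = par$num.trees, mtry = par$mtry,
      min.node.size = par$min.node.size, seed = seed, num.threads = 1L)
  } else {
    xgboost::xgboost(
      data = X, label = y, nrounds = par$nrounds,
      params = list(objective = "binary:logistic", max_depth = par$max_depth,
                    eta = par$eta, subsample = par$subsample,
                    nthread = 1L, seed = seed),
      verbose = 0)
  }
}

.predictTree <- function(family, model, X) {
  if (family == "random_forest") {
    predict(model, data = as.data.frame(X), num.threads = 1L)$predictions[, "1"]
  } else {
    predict(model, X)
  }
}

#' Tree-based comparators with random hyperparameter search
#'
#' Fits a random forest or gradient boosted trees on the whole discovery
#' set; `nParamDraws` random hyperparameter combinations from a declared
#' grid are scored by pooled cross-validated AUC with in-fold subsampling,
#' and the best configuration is refit on the full (subsampled) discovery
#' data. Cross-validation is leave-one-out by default; a k-fold downgrade
#' is available for speed.
#'
#' @param discovery a [PdacCohort-class].
#' @param family `"random_forest"` or `"gradient_boosted_trees"`.
#' @param nParamDraws number of random hyperparameter draws.
#' @param candidates candidate features.
#' @param subsampling in-fold subsampling mode.
#' @param cvFolds `NULL` for LOOCV or an integer number of folds.
#' @param seed integer.
#' @return list with `model`, `family`, `best` (chosen hyperparameters),
#'   `searchTrace` (data.frame of draws and pooled CV AUC), `features`,
#'   and a `predictFun(cohort)` closure.
#' @export
trainTreeComparator <- function(discovery,
                                family = c("random_forest",
                                           "gradient_boosted_trees"),
                                nParamDraws = 1000L,
                                candidates = candidateFeatures(discovery),
                                subsampling = "over", cvFolds = NULL,
                                seed = 1L) {
  family <- match.arg(family)
  if (nParamDraws < 1L) stopf("nParamDraws must be >= 1")
  X <- featureMatrix(discovery, candidates)
  y <- as.numeric(isCase(discovery))
  n <- nrow(X)
  folds <- if (is.null(cvFolds)) seq_len(n) else withSeed(seed, {
    f <- integer(n)
    for (cl in c(0, 1)) {
      idx <- sample(which(y == cl))
      f[idx] <- rep_len(seq_len(cvFolds), length(idx))
    }
    f
  })
  grid <- .treeGrid(family, nParamDraws, ncol(X), seed)
  cvAuc <- numeric(nParamDraws)
  for (g in seq_len(nParamDraws)) {
    pr <- numeric(n)
    for (k in unique(folds)) {
      tr <- folds != k
      bal <- applySubsampling(X[tr, , drop = FALSE], y[tr], subsampling,
                              childSeed(seed, 1000L * g + k))
      fit <- .fitTree(family, bal$X, bal$y, grid[g, ],
                      childSeed(seed, 7L * g + k))
      pr[!tr] <- .predictTree(family, fit, X[!tr, , drop = FALSE])
    }
    cvAuc[g] <- rocAuc(pr, y)
  }
  bestIdx <- which.max(cvAuc)
  bal <- applySubsampling(X, y, subsampling, childSeed(seed, 0L))
  model <- .fitTree(family, bal$X, bal$y, grid[bestIdx, ],
                    childSeed(seed, 1L))
  trace <- cbind(grid, cv_auc = cvAuc)
  list(model = model, family = family, best = grid[bestIdx, ],
       searchTrace = trace, features = candidates,
       predictFun = function(cohort)
         .predictTree(family, model, featureMatrix(cohort, candidates)))
}
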