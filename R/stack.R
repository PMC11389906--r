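## Logistic stacking of diagnosis-specific base learners, recursive
## base-learner elimination, reduced-signature construction and JSON
## serialization of fitted models.

# meta design: one column per learner holding clipped logits of base
# probabilities on `cohort`; in out_of_fold mode a learner's own LOOCV
# held-out probabilities replace its in-sample ones where available.
.metaDesign <- function(learners, cohort, predictionMode = "insample") {
  ids <- colData(cohort)$sample_id
  M <- vapply(learners, function(bl) {
    p <- predict(bl, cohort)
    if (predictionMode == "out_of_fold") {
      oofIds <- intersect(names(bl@oofProb), ids)
      p[oofIds] <- bl@oofProb[oofIds]
    }
    clippedLogit(p)
  }, numeric(length(ids)))
  if (length(ids) == 1L)
    M <- matrix(M, nrow = 1L,
                dimnames = list(ids, names(learners)))
  colnames(M) <- names(learners)
  rownames(M) <- ids
  M
}

#' Stack base learners with a logistic meta-model
#'
#' The meta design holds, per learner, the clipped logit of its PDAC
#' probability on the discovery samples (`insample`, the default) or its
#' LOOCV held-out probability where one exists (`out_of_fold`, the
#' leakage-safe alternative). A logistic regression of PDAC status on the
#' meta design gives the stack; Firth penalization is used when the meta
#' problem is separable. Constant meta-columns are dropped with a warning.
#' Per-learner meta-coefficient p-values are reported (Wald, or penalized
#' LRT under the Firth fallback).
#'
#' @param learners list of [BaseLearner-class] (named by diagnosis class;
#'   names are derived when absent).
#' @param discovery a [PdacCohort-class].
#' @param predictionMode `"insample"` or `"out_of_fold"`.
#' @param seed integer (recorded).
#' @return a [StackModel-class].
#' @export
fitStack <- function(learners, discovery,
                     predictionMode = c("insample", "out_of_fold"),
                     seed = 1L) {
  predictionMode <- match.arg(predictionMode)
  if (length(learners) < 2L) stopf("need at least 2 base learners")
  if (is.null(names(learners)))
    names(learners) <- vapply(learners, function(b) b@diagnosisClass, "")
  M <- .metaDesign(learners, discovery, predictionMode)
  y <- as.numeric(isCase(discovery))
  keep <- apply(M, 2L, function(col) sd(col) > 0)
  if (!all(keep)) {
    warnf("dropping constant meta-column(s): %s",
          paste(colnames(M)[!keep], collapse = ", "))
    M <- M[, keep, drop = FALSE]
    learners <- learners[keep]
  }
  # collinear meta-columns (e.g. two learners emitting identical clipped
  # logits) are unidentifiable: fit on an independent basis and give the
  # redundant learners meta-coefficient 0, leaving predictions unchanged
  X1 <- cbind("(Intercept)" = 1, M)
  qrX <- qr(X1)
  indep <- sort(qrX$pivot[seq_len(qrX$rank)])
  useCols <- setdiff(indep, 1L) - 1L
  Mi <- M[, useCols, drop = FALSE]
  fin <- .finalLogistic(Mi, y)
  pvI <- setNames(rep(NA_real_, ncol(Mi)), colnames(Mi))
  if (!fin$firth) {
    # Wald p-values from the unpenalized meta-fit
    Xi <- cbind(1, Mi)
    eta <- drop(Xi %*% fin$beta)
    w <- plogis(eta) * (1 - plogis(eta))
    V <- tryCatch(solve(crossprod(Xi * sqrt(w))), error = function(e) NULL)
    if (!is.null(V)) {
      se <- sqrt(diag(V))[-1L]
      pvI[] <- 2 * pnorm(abs(fin$beta[-1L]) / se, lower.tail = FALSE)
    }
  } else {
    ff <- firthFit(Mi, y)
    pvI[] <- ff@p[-1L]
    fin$beta <- coef(ff)
  }
  beta <- setNames(numeric(ncol(M) + 1L), c("(Intercept)", colnames(M)))
  beta[c("(Intercept)", colnames(Mi))] <- fin$beta
  pv <- setNames(rep(NA_real_, ncol(M)), colnames(M))
  pv[names(pvI)] <- pvI
  new("StackModel", learners = learners, metaCoef = beta, metaP = pv,
      predictionMode = predictionMode, metaFirth = fin$firth,
      seed = as.integer(seed))
}

#' Predict PDAC probability and odds from a stack
#'
#' @param object a [StackModel-class].
#' @param newdata a [PdacCohort-class].
#' @return named numeric probabilities in (0, 1); see [stackOdds()] for
#'   the odds scale.
#' @export
setMethod("predict", "StackModel", function(object, newdata) {
  M <- .metaDesign(object@learners, newdata, "insample")
  eta <- drop(object@metaCoef[1L] + M %*% object@metaCoef[-1L])
  setNames(plogis(eta), rownames(M))
})

#' @rdname stackOdds
#' @export
stackProbability <- function(stack, cohort) predict(stack, cohort)

#' Stack output on the odds scale
#'
#' @param stack a [StackModel-class].
#' @param cohort a [PdacCohort-class].
#' @return named numeric odds `p / (1 - p)`.
#' @export
stackOdds <- function(stack, cohort) {
  p <- predict(stack, cohort)
  p / (1 - p)
}

#' Recursive base-learner elimination
#'
#' Greedy backward elimination on the discovery arm only: at each step the
#' learner whose removal least degrades (or most improves) the metric is
#' dropped. The metric is a grouped k-fold cross-validated AUC of the
#' logistic meta-fit on the discovery meta design (stratified by case
#' status), so the validation arm is never consulted. Returns the full
#' elimination trace and the best subset encountered.
#'
#' @param stack a fitted [StackModel-class].
#' @param discovery a [PdacCohort-class].
#' @param nFolds folds of the meta-level CV metric.
#' @param seed integer.
#' @return list `trace` (data.frame: step, removed, metric after removal),
#'   `best` (character: learner names of the best subset), `metricFull`
#'   (metric of the full set).
#' @export
recursiveLearnerElimination <- function(stack, discovery, nFolds = 5L,
                                        seed = 1L) {
  M <- .metaDesign(stack@learners, discovery, stack@predictionMode)
  y <- as.numeric(isCase(discovery))
  folds <- withSeed(seed, {
    f <- integer(length(y))
    for (cl in c(0, 1)) {
      idx <- sample(which(y == cl))
      f[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
    f
  })
  cvAuc <- function(cols) {
    pr <- numeric(length(y))
    for (k in seq_len(nFolds)) {
      tr <- folds != k
      beta <- .ridgeLogistic(M[tr, cols, drop = FALSE], y[tr])
      pr[!tr] <- plogis(beta[1L] +
                          M[!tr, cols, drop = FALSE] %*% beta[-1L])
    }
    rocAuc(pr, y)
  }
  current <- colnames(M)
  metricFull <- cvAuc(current)
  trace <- data.frame(step = integer(0), removed = character(0),
                      metric = numeric(0))
  bestSet <- current; bestMetric <- metricFull
  step <- 0L
  while (length(current) > 1L) {
    step <- step + 1L
    scores <- vapply(current, function(l) cvAuc(setdiff(current, l)),
                     numeric(1))
    drop <- names(scores)[which.max(scores)]
    current <- setdiff(current, drop)
    trace <- rbind(trace, data.frame(step = step, removed = drop,
                                     metric = unname(max(scores))))
    if (max(scores) > bestMetric) {
      bestMetric <- max(scores); bestSet <- current
    }
  }
  list(trace = trace, best = bestSet, metricFull = metricFull)
}

#' Build a reduced-signature stack
#'
#' Re-runs the full diagnosis-specific ensemble protocol restricted to a
#' reduced candidate feature list. The default list is the 8-feature
#' reduced signature (CA19-9, VWF, CPE, CTSV, CEACAM1, CD160, Diabetes,
#' Age).
#'
#' @param discovery a [PdacCohort-class].
#' @param features candidate features of the reduced signature.
#' @param classes control classes to build base learners for (default: all
#'   classes present in discovery).
#' @param subsampling,seed,subsetSizes passed to [trainBaseLearner()].
#' @param predictionMode passed to [fitStack()].
#' @return a [StackModel-class].
#' @export
reducedSignatureFeatures <- function() {
  c("CA19-9", "VWF", "CPE", "CTSV", "CEACAM1", "CD160", "Diabetes", "Age")
}

#' @rdname reducedSignatureFeatures
#' @export
buildReducedSignature <- function(discovery,
                                  features = reducedSignatureFeatures(),
                                  classes = NULL, subsampling = "over",
                                  seed = 1L, subsetSizes = NULL,
                                  predictionMode = "insample") {
  if (!length(features)) stopf("feature list must not be empty")
  dc <- diagnosisClasses(discovery)
  classes <- classes %||%
    intersect(controlClasses(), unique(dc[!isCase(discovery)]))
  learners <- lapply(seq_along(classes), function(k)
    trainBaseLearner(discovery, classes[k], candidates = features,
                     subsampling = subsampling,
                     seed = childSeed(seed, k), subsetSizes = subsetSizes))
  names(learners) <- classes
  fitStack(learners, discovery, predictionMode = predictionMode, seed = seed)
}

## ------------------------------------------------------ serialization ----

#' Serialize / restore fitted models as JSON
#'
#' Round-trips reproduce predictions exactly (coefficients are written at
#' full double precision).
#'
#' @param object a [BaseLearner-class] or [StackModel-class].
#' @param path file path.
#' @return `readStack()`/`readLearner()` return the restored object.
#' @export
writeLearner <- function(object, path) {
  jsonlite::write_json(.learnerToList(object), path, auto_unbox = TRUE,
                       digits = I(17), null = "null", na = "null")
  invisible(path)
}

.learnerToList <- function(bl) {
  list(type = "BaseLearner", diagnosis_class = bl@diagnosisClass,
       features = as.list(bl@features),
       coefficients = as.list(bl@coefficients),
       center = as.list(bl@center), scale = as.list(bl@scale),
       cv_profile = list(size = bl@cvProfile$size, auc = bl@cvProfile$auc),
       oof_prob = as.list(bl@oofProb), subsampling = bl@subsampling,
       candidates = as.list(bl@candidates), firth = bl@firth,
       seed = bl@seed)
}

.learnerFromList <- function(x) {
  num <- function(v) unlist(v)
  new("BaseLearner", diagnosisClass = x$diagnosis_class,
      features = unlist(x$features), coefficients = num(x$coefficients),
      center = num(x$center), scale = num(x$scale),
      cvProfile = data.frame(size = unlist(x$cv_profile$size),
                             auc = unlist(x$cv_profile$auc)),
      oofProb = num(x$oof_prob), subsampling = x$subsampling,
      candidates = unlist(x$candidates), firth = isTRUE(x$firth),
      seed = as.integer(x$seed))
}

#' @rdname writeLearner
#' @export
readLearner <- function(path) {
  .learnerFromList(jsonlite::read_json(path))
}

#' @rdname writeLearner
#' @export
writeStack <- function(object, path) {
  x <- list(type = "StackModel",
            learners = lapply(object@learners, .learnerToList),
            meta_coef = as.list(object@metaCoef),
            meta_p = as.list(object@metaP),
            prediction_mode = object@predictionMode,
            meta_firth = object@metaFirth, seed = object@seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname writeLearner
#' @export
readStack <- function(path) {
  x <- jsonlite::read_json(path)
  learners <- lapply(x$learners, .learnerFromList)
  names(learners) <- vapply(learners, function(b) b@diagnosisClass, "")
  metaP <- vapply(x$meta_p, function(v) if (is.null(v)) NA_real_ else v,
                  numeric(1))
  names(metaP) <- names(x$meta_p)
  new("StackModel", learners = learners, metaCoef = unlist(x$meta_coef),
      metaP = metaP, predictionMode = x$prediction_mode,
      metaFirth = isTRUE(x$meta_firth), seed = as.integer(x$seed))
}

#' Write the stack meta-coefficients as a TSV
#'
#' One row per base learner: learner name, meta coefficient (log-odds per
#' unit base-logit) and p-value, preceded by the intercept row.
#'
#' @param stack a [StackModel-class].
#' @param path output path.
#' @export
writeStackCoefficients <- function(stack, path) {
  df <- data.frame(learner = names(stack@metaCoef),
                   beta = unname(stack@metaCoef),
                   p = c(NA_real_, unname(stack@metaP)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
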