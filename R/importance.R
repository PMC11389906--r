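## Model-agnostic permutation feature importance per base learner, per-
## learner scaling to [0, 100], and cross-learner aggregation.

#' Permutation importance of a base learner's features
#'
#' Importance of a feature is the mean drop in AUC over `nRepeats`
#' independent permutations of that feature's column, evaluated on `data`
#' with the already-trained learner. Features the learner did not select
#' score exactly zero without computation.
#'
#' @param learner a [BaseLearner-class].
#' @param data a [PdacCohort-class] to evaluate on.
#' @param nRepeats permutations per feature (default 20).
#' @param seed integer.
#' @return named numeric raw importance over `candidates` of the learner.
#' @export
permutationImportance <- function(learner, data, nRepeats = 20L, seed = 1L) {
  X <- featureMatrix(data, learner@features)
  y <- as.numeric(isCase(data))
  if (length(unique(y)) < 2L) stopf("metric undefined: single-class data")
  sp <- list(center = learner@center, scale = learner@scale)
  prob <- function(Xi) {
    Z <- .applyStandardize(Xi, sp)
    plogis(drop(learner@coefficients[1L] + Z %*% learner@coefficients[-1L]))
  }
  baseAuc <- rocAuc(prob(X), y)
  imp <- setNames(numeric(length(learner@candidates)), learner@candidates)
  for (f in learner@features) {
    # per-feature seed derived from the feature name, so the result is
    # invariant to feature declaration order
    fseed <- childSeed(seed, sum(utf8ToInt(f)))
    imp[f] <- withSeed(fseed, {
      mean(vapply(seq_len(nRepeats), function(r) {
        Xp <- X
        Xp[, f] <- X[sample.int(nrow(X)), f]
        baseAuc - rocAuc(prob(Xp), y)
      }, numeric(1)))
    })
  }
  imp
}

#' Aggregate scaled importance across base learners
#'
#' Raw permutation importances are scaled within each learner so the
#' largest equals 100 (features the learner never selected stay exactly
#' 0); the aggregate column is the mean of scaled importances over all
#' learners, zeros included. Rows are sorted by decreasing aggregate
#' importance, ties broken lexicographically.
#'
#' @param learners list of [BaseLearner-class].
#' @param data a [PdacCohort-class] to evaluate on.
#' @param nRepeats,seed passed to [permutationImportance()].
#' @return list with `matrix` (feature x learner scaled importance),
#'   `aggregate` (data.frame: feature, mean scaled importance, rank).
#' @export
aggregateImportance <- function(learners, data, nRepeats = 20L, seed = 1L) {
  if (!length(learners)) stopf("need at least one learner")
  if (is.null(names(learners)))
    names(learners) <- vapply(learners, function(b) b@diagnosisClass, "")
  feats <- sort(unique(unlist(lapply(learners, function(b) b@candidates))))
  M <- matrix(0, length(feats), length(learners),
              dimnames = list(feats, names(learners)))
  for (k in seq_along(learners)) {
    raw <- permutationImportance(learners[[k]], data, nRepeats,
                                 seed = childSeed(seed, k))
    mx <- max(raw)
    scaled <- if (mx > 0) 100 * pmax(raw, 0) / mx else raw * 0
    M[names(scaled), k] <- scaled
  }
  agg <- rowMeans(M)
  ord <- order(-agg, feats)
  df <- data.frame(feature = feats[ord], importance = unname(agg[ord]),
                   rank = seq_along(ord))
  list(matrix = M[ord, , drop = FALSE], aggregate = df)
}

#' Write the per-learner importance table
#'
#' Long-format TSV: feature, learner, scaled importance.
#'
#' @param importance result of [aggregateImportance()].
#' @param path output path.
#' @export
writeImportance <- function(importance, path) {
  M <- importance$matrix
  df <- data.frame(feature = rep(rownames(M), ncol(M)),
                   learner = rep(colnames(M), each = nrow(M)),
                   scaled_importance = as.vector(M))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
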