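## Class-imbalance subsampling. These operate on plain (X, y) slices and
## are applied strictly inside cross-validation training folds; held-out
## rows are never touched.

.classSplit <- function(y) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stopf("both classes must be present")
  tab <- table(y)
  minority <- as.numeric(names(tab)[which.min(tab)])
  list(min = which(y == minority), maj = which(y != minority))
}

#' Balance classes by random oversampling of the minority class
#'
#' Minority rows are duplicated by sampling with replacement until both
#' classes have equal counts; majority rows are unchanged.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y binary labels.
#' @param seed integer.
#' @return list `X`, `y` with balanced classes.
#' @export
oversampleMinority <- function(X, y, seed = 1L) {
  cs <- .classSplit(y)
  need <- length(cs$maj) - length(cs$min)
  if (need == 0L) return(list(X = X, y = y))
  withSeed(seed, {
    extra <- sample(cs$min, need, replace = TRUE)
    keep <- c(seq_len(nrow(X)), extra)
    list(X = X[keep, , drop = FALSE], y = y[keep])
  })
}

#' Balance classes by random undersampling of the majority class
#'
#' Majority rows are subsampled without replacement down to the minority
#' count.
#'
#' @inheritParams oversampleMinority
#' @return list `X`, `y` with balanced classes.
#' @export
undersampleMajority <- function(X, y, seed = 1L) {
  cs <- .classSplit(y)
  if (length(cs$maj) == length(cs$min)) return(list(X = X, y = y))
  withSeed(seed, {
    keepMaj <- sample(cs$maj, length(cs$min))
    keep <- sort(c(cs$min, keepMaj))
    list(X = X[keep, , drop = FALSE], y = y[keep])
  })
}

#' Balance classes by SMOTE
#'
#' Synthetic minority points are interpolated between a minority point and
#' one of its k nearest minority neighbours (Euclidean distance on
#' features standardized by the input slice's own statistics):
#' `x_new = x_i + u (x_nn - x_i)`, `u ~ U(0, 1)`. Points are generated
#' until classes balance. With fewer than two minority rows, falls back to
#' [oversampleMinority()] with a warning.
#'
#' @inheritParams oversampleMinority
#' @param k number of nearest neighbours (default 5; capped at minority
#'   count minus one).
#' @return list `X`, `y` with balanced classes (synthetic rows appended).
#' @export
smote <- function(X, y, k = 5L, seed = 1L) {
  cs <- .classSplit(y)
  need <- length(cs$maj) - length(cs$min)
  if (need == 0L) return(list(X = X, y = y))
  if (length(cs$min) < 2L) {
    warnf("fewer than 2 minority rows; falling back to oversampling")
    return(oversampleMinority(X, y, seed))
  }
  k <- min(k, length(cs$min) - 1L)
  mu <- colMeans(X)
  sg <- apply(X, 2L, sd); sg[!is.finite(sg) | sg == 0] <- 1
  Z <- sweep(sweep(X[cs$min, , drop = FALSE], 2L, mu), 2L, sg, "/")
  D <- as.matrix(dist(Z))
  diag(D) <- Inf
  ord <- apply(D, 1L, function(d) order(d)[seq_len(k)])
  nn <- if (k == 1L) matrix(ord, ncol = 1L) else t(ord)
  minLab <- y[cs$min[1L]]
  withSeed(seed, {
    base <- sample(seq_along(cs$min), need, replace = TRUE)
    pick <- vapply(base, function(i) nn[i, sample.int(k, 1L)], integer(1))
    u <- runif(need)
    Xm <- X[cs$min, , drop = FALSE]
    synth <- Xm[base, , drop = FALSE] +
      u * (Xm[pick, , drop = FALSE] - Xm[base, , drop = FALSE])
    list(X = rbind(X, synth), y = c(y, rep(minLab, need)))
  })
}

# dispatcher used by the learners
applySubsampling <- function(X, y, mode, seed) {
  switch(mode,
         over = oversampleMinority(X, y, seed),
         under = undersampleMajority(X, y, seed),
         smote = smote(X, y, seed = seed),
         none = list(X = X, y = y),
         stopf("unknown subsampling mode '%s'", mode))
}
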