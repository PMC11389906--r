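## Firth bias-reduced logistic regression with profile penalized-likelihood
## confidence intervals and tests, implemented from first principles.
##
## The estimator maximizes the penalized log-likelihood
##   l*(beta) = l(beta) + 1/2 log det I(beta),
## where I is the Fisher information; the Jeffreys-prior penalty keeps
## estimates finite under complete separation and, for a single binary
## covariate, reduces exactly to the add-1/2 cross-product odds ratio.
## The modified score is U*(beta) = X' (y - pi + h (1/2 - pi)) with h the
## hat diagonals, solved by Newton iterations with step-halving on any
## decrease of l*.

# core engine: X includes the intercept column; `fixed`/`fixedValues`
# constrain coordinates (used for profiling and per-term LRTs).
# Columns are scaled (not centred) internally so that covariates of very
# different magnitudes condition the Newton solve equally; coefficients
# are returned on the original scale.
.firthEngine <- function(X, y, fixed = integer(0), fixedValues = numeric(0),
                         tol = 1e-8, maxIter = 50L, start = NULL) {
  p <- ncol(X)
  scl <- apply(X, 2L, function(col) {
    s <- sd(col)
    if (!is.finite(s) || s == 0) 1 else s
  })
  scl[1L] <- 1  # intercept untouched
  Xs <- sweep(X, 2L, scl, "/")
  free <- setdiff(seq_len(p), fixed)
  beta <- if (is.null(start)) numeric(p) else start * scl
  beta[fixed] <- fixedValues * scl[fixed]

  # det I on the original scale = det I(scaled) * prod(scl)^2; the Jacobian
  # term keeps the reported value the true penalized log-likelihood so
  # that fits on different designs remain comparable
  logJac <- sum(log(scl))
  pll <- function(beta) {
    eta <- drop(Xs %*% beta)
    ll <- -sum(log1p(exp(-(2 * y - 1) * eta)))
    w <- plogis(eta) * (1 - plogis(eta))
    info <- crossprod(Xs * sqrt(w))
    ll + 0.5 * as.numeric(determinant(info, logarithm = TRUE)$modulus) +
      logJac
  }

  cur <- pll(beta)
  converged <- FALSE
  hat <- numeric(length(y))
  iter <- 0L
  for (iter in seq_len(maxIter)) {
    eta <- drop(Xs %*% beta)
    pi <- plogis(eta)
    w <- pi * (1 - pi)
    XW <- Xs * sqrt(w)
    info <- crossprod(XW)
    infoInv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(infoInv)) {
      # ridge rescue for a numerically singular information matrix
      infoInv <- solve(info + diag(1e-8, p))
    }
    hat <- rowSums((XW %*% infoInv) * XW)
    Ustar <- drop(crossprod(Xs, y - pi + hat * (0.5 - pi)))
    if (max(abs(Ustar[free])) < tol) { converged <- TRUE; break }
    delta <- numeric(p)
    delta[free] <- tryCatch(
      drop(solve(info[free, free, drop = FALSE], Ustar[free])),
      error = function(e)
        drop(solve(info[free, free, drop = FALSE] +
                     diag(1e-6, length(free)), Ustar[free])))
    step <- 1
    moved <- FALSE
    repeat {
      cand <- beta + step * delta
      new <- pll(cand)
      if (is.finite(new) && new >= cur - 1e-12) {
        beta <- cand; cur <- new; moved <- TRUE; break
      }
      step <- step / 2
      if (step < 1e-10) break
    }
    if (!moved) break  # stalled: no ascent direction left
  }
  list(coefficients = setNames(beta / scl, colnames(X)), logLik = cur,
       hat = hat, iter = iter, converged = converged)
}

.checkDesign <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("design is rank deficient; collinear column(s): %s",
          paste(drop, collapse = ", "))
  }
}

#' Firth bias-reduced logistic regression
#'
#' Fits `outcome ~ covariates` by maximizing the Jeffreys-penalized
#' log-likelihood (Firth's bias reduction): Newton iterations on the
#' modified score with responses adjusted by hat values, step-halving on
#' any decrease of the penalized log-likelihood. Per-term p-values are
#' penalized likelihood-ratio tests (the coefficient profiled to zero) and
#' confidence intervals are profile penalized-likelihood intervals, so both
#' remain valid when contingency tables are asymmetric or contain zeros.
#'
#' @param x numeric covariate matrix (no intercept column; one is added),
#'   or a numeric vector for a single covariate.
#' @param y binary outcome (0/1 or logical), 1 = case.
#' @param tol convergence tolerance on the maximum modified-score component.
#' @param maxIter maximum Newton iterations.
#' @param level CI level.
#' @param inference compute profile CIs and LRT p-values (set `FALSE` to
#'   return only the point fit, e.g. in tight loops).
#' @return a [FirthFit-class].
#' @examples
#' # 2x2 table: 31/15 exposed/unexposed cases, 180/241 controls
#' fit <- firthTable2x2(31, 15, 180, 241)
#' firthSummary(fit)
#' @export
firthFit <- function(x, y, tol = 1e-8, maxIter = 50L, level = 0.95,
                     inference = TRUE) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L, dimnames = list(NULL, "x"))
  x <- as.matrix(x)
  if (ncol(x) > 0L && is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stopf("outcome must be binary 0/1")
  X <- cbind("(Intercept)" = 1, x)
  .checkDesign(X)
  if (length(unique(y)) < 2L)
    warnf("outcome contains a single class; fit is penalization-driven")
  eng <- .firthEngine(X, y, tol = tol, maxIter = maxIter)
  if (!eng$converged)
    warnf("Firth fit did not converge in %d iterations", maxIter)
  p <- ncol(X)
  ci <- matrix(NA_real_, p, 2L,
               dimnames = list(colnames(X), c("lower", "upper")))
  pv <- setNames(rep(NA_real_, p), colnames(X))
  fit <- new("FirthFit", coefficients = eng$coefficients, ci = ci, p = pv,
             logLik = eng$logLik, hat = eng$hat, iter = as.integer(eng$iter),
             converged = eng$converged, X = X, y = y, level = level)
  if (inference) {
    for (j in seq_len(p)) {
      fit@ci[j, ] <- firthProfileCI(fit, j, level = level)
      prof0 <- .firthEngine(X, y, fixed = j, fixedValues = 0,
                            tol = tol, maxIter = maxIter)
      stat <- max(0, 2 * (eng$logLik - prof0$logLik))
      fit@p[j] <- pchisq(stat, df = 1L, lower.tail = FALSE)
    }
  }
  fit
}

#' @rdname firthFit
#' @param caseExposed,caseUnexposed,controlExposed,controlUnexposed cell
#'   counts of a 2x2 exposure-by-outcome table; `firthTable2x2()` expands
#'   them into unit records and fits the single-covariate model.
#' @export
firthTable2x2 <- function(caseExposed, caseUnexposed,
                          controlExposed, controlUnexposed) {
  y <- rep(c(1, 1, 0, 0),
           c(caseExposed, caseUnexposed, controlExposed, controlUnexposed))
  x <- rep(c(1, 0, 1, 0),
           c(caseExposed, caseUnexposed, controlExposed, controlUnexposed))
  firthFit(matrix(x, ncol = 1, dimnames = list(NULL, "exposure")), y)
}

# profile penalized log-likelihood of term j held at `value` (original
# scale); warm-started at the unconstrained optimum for stability
.profilePll <- function(fit, j, value, tol = 1e-8, maxIter = 100L) {
  start <- fit@coefficients
  .firthEngine(fit@X, fit@y, fixed = j, fixedValues = value,
               tol = tol, maxIter = maxIter, start = start)$logLik
}

#' Profile penalized-likelihood confidence interval
#'
#' Bounds are the values of the coefficient where twice the drop of the
#' profile penalized log-likelihood from its maximum equals the chi-square
#' (1 d.f.) quantile at `level`, with all other coefficients re-optimized
#' at each candidate value. Roots are bracketed by doubling steps from the
#' point estimate and solved by `uniroot`; when no root lies within a wide
#' bound the interval is one-sided and the bound is reported infinite.
#'
#' @param fit a [FirthFit-class].
#' @param term index or name of the coefficient (1 = intercept).
#' @param level confidence level.
#' @return numeric `c(lower, upper)` on the log-odds scale (exponentiate
#'   for the OR scale).
#' @export
firthProfileCI <- function(fit, term, level = 0.95) {
  j <- if (is.character(term)) match(term, colnames(fit@X)) else term
  if (is.na(j) || j < 1 || j > ncol(fit@X)) stopf("unknown term")
  bhat <- fit@coefficients[j]
  target <- fit@logLik - qchisq(level, 1L) / 2
  f <- function(b) {
    v <- tryCatch(.profilePll(fit, j, b), error = function(e) NA_real_)
    if (!is.finite(v)) return(-qchisq(level, 1L))  # treat as far past bound
    v - target
  }
  se <- {
    eta <- drop(fit@X %*% fit@coefficients)
    w <- plogis(eta) * (1 - plogis(eta))
    v <- tryCatch(solve(crossprod(fit@X * sqrt(w)))[j, j],
                  error = function(e) NA_real_)
    if (is.finite(v) && v > 0) sqrt(v) else 1
  }
  oneSide <- function(dir) {
    step <- se
    lo <- bhat
    repeat {
      hi <- bhat + dir * step
      if (f(hi) < 0)
        return(uniroot(f, sort(c(lo, hi)), tol = 1e-7)$root)
      lo <- hi
      step <- step * 2
      if (step > 200 * se + 100) return(dir * Inf)
    }
  }
  c(lower = oneSide(-1), upper = oneSide(1))
}

#' Penalized likelihood-ratio test between nested Firth fits
#'
#' The terms of the full design absent from the reduced design are
#' profiled to zero *within the full design* (so both likelihoods carry
#' the same Jeffreys penalty — comparing two separately-penalized fits is
#' not calibrated), and twice the penalized log-likelihood drop is
#' referred to a chi-square with d.f. equal to the number of dropped
#' terms.
#'
#' @param fitFull,fitReduced [FirthFit-class] objects on the same samples;
#'   the reduced design's columns must be a subset of the full design's.
#' @return list with `statistic`, `df`, `p`.
#' @export
firthLRT <- function(fitFull, fitReduced) {
  if (length(fitFull@y) != length(fitReduced@y) ||
      any(fitFull@y != fitReduced@y))
    stopf("fits are not on the same outcome")
  redCols <- colnames(fitReduced@X)
  if (!all(redCols %in% colnames(fitFull@X)))
    stopf("models are not nested (reduced terms missing from full design)")
  dropped <- setdiff(colnames(fitFull@X), redCols)
  df <- length(dropped)
  if (df == 0L) return(list(statistic = 0, df = 0L, p = 1))
  j <- match(dropped, colnames(fitFull@X))
  prof <- .firthEngine(fitFull@X, fitFull@y, fixed = j,
                       fixedValues = rep(0, df), maxIter = 100L)
  stat <- max(0, 2 * (fitFull@logLik - prof$logLik))
  list(statistic = stat, df = df,
       p = pchisq(stat, df = df, lower.tail = FALSE))
}
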