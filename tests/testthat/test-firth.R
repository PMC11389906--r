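test_that("2x2 Firth fits equal the add-half cross-product odds ratio", {
  set.seed(42)
  for (i in 1:20) {
    cells <- sample(0:40, 4, replace = TRUE)
    # ensure both outcome classes exist
    if (cells[1] + cells[2] == 0) cells[1] <- 3
    if (cells[3] + cells[4] == 0) cells[4] <- 5
    fit <- firthTable2x2(cells[1], cells[2], cells[3], cells[4])
    oracle <- log(((cells[1] + 0.5) * (cells[4] + 0.5)) /
                    ((cells[2] + 0.5) * (cells[3] + 0.5)))
    expect_equal(unname(coef(fit)[2]), oracle, tolerance = 1e-6)
  }
})

test_that("estimates stay finite under complete separation and match a grid oracle", {
  x <- c(0, 0, 1, 1); y <- c(0, 0, 1, 1)
  fit <- firthFit(x, y)
  expect_true(all(is.finite(coef(fit))))

  # independent oracle: two-stage dense grid over the penalized likelihood
  pll <- function(b0, b1) {
    eta <- b0 + b1 * x
    p <- plogis(eta); w <- p * (1 - p)
    X <- cbind(1, x)
    info <- crossprod(X * sqrt(w))
    sum(y * eta - log1p(exp(eta))) +
      0.5 * log(info[1, 1] * info[2, 2] - info[1, 2]^2)
  }
  best <- c(0, 0); span <- 6; stepn <- 60
  for (refine in 1:4) {
    b0s <- seq(best[1] - span, best[1] + span, length.out = stepn)
    b1s <- seq(best[2] - span, best[2] + span, length.out = stepn)
    vals <- outer(b0s, b1s, Vectorize(pll))
    ix <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    best <- c(b0s[ix[1]], b1s[ix[2]])
    span <- span / 10
  }
  expect_equal(unname(coef(fit)), best, tolerance = 1e-3)
})

test_that("profile intervals match a one-dimensional grid of the profile likelihood", {
  fit <- firthTable2x2(12, 5, 20, 30)
  ci <- firthProfileCI(fit, 2)
  # oracle: profile out the intercept on a fine grid of the covariate term
  x <- fit@X[, 2]; y <- fit@y
  prof <- function(b1) {
    optimize(function(b0) {
      eta <- b0 + b1 * x
      p <- plogis(eta); w <- p * (1 - p)
      X <- cbind(1, x)
      info <- crossprod(X * sqrt(w))
      -(sum(y * eta - log1p(exp(eta))) +
          0.5 * log(info[1, 1] * info[2, 2] - info[1, 2]^2))
    }, c(-20, 20))$objective * -1
  }
  target <- fit@logLik - qchisq(0.95, 1) / 2
  grid <- seq(coef(fit)[2] - 3, coef(fit)[2] + 3, by = 0.002)
  pv <- vapply(grid, prof, numeric(1))
  inside <- grid[pv >= target]
  expect_lt(abs(unname(ci["lower"]) - min(inside)), 5e-3)
  expect_lt(abs(unname(ci["upper"]) - max(inside)), 5e-3)
  # interval brackets the point estimate
  expect_lt(ci["lower"], coef(fit)[2])
  expect_gt(ci["upper"], coef(fit)[2])
})

test_that("flipping outcome labels negates non-intercept coefficients", {
  set.seed(7)
  X <- cbind(a = rnorm(40), b = rnorm(40))
  y <- rbinom(40, 1, 0.4)
  f1 <- firthFit(X, y, inference = FALSE)
  f2 <- firthFit(X, 1 - y, inference = FALSE)
  expect_equal(unname(coef(f1)[-1]), -unname(coef(f2)[-1]),
               tolerance = 1e-6)
})

test_that("covariate rescaling rescales the estimate and its profile interval", {
  set.seed(11)
  x <- rnorm(60); y <- rbinom(60, 1, plogis(0.8 * x))
  f1 <- firthFit(cbind(z = x), y, inference = FALSE)
  f2 <- firthFit(cbind(z = x / 10), y, inference = FALSE)
  expect_equal(unname(coef(f1)[2]) * 10, unname(coef(f2)[2]),
               tolerance = 1e-5)
  ci1 <- firthProfileCI(f1, 2)
  ci2 <- firthProfileCI(f2, 2)
  expect_equal(unname(ci1) * 10, unname(ci2), tolerance = 1e-3)
})

test_that("null data with a balanced covariate yields an interval containing OR 1", {
  # exactly balanced 2x2 (all cells 15): the OR is 1 by construction
  x <- rep(c(0, 1), each = 30)
  y <- rep(rep(c(0, 1), each = 15), 2)
  fit <- firthFit(cbind(g = x), y)
  expect_lt(exp(fit@ci[2, 1]), 1)
  expect_gt(exp(fit@ci[2, 2]), 1)
})

test_that("penalized LRT: identical models give p = 1 and the null is calibrated", {
  x <- c(0, 1, 0, 1, 1, 0); y <- c(0, 0, 1, 1, 0, 1)
  f <- firthFit(cbind(x = x), y, inference = FALSE)
  expect_equal(firthLRT(f, f)$p, 1)
  r <- firthFit(matrix(numeric(0), nrow = 6, ncol = 0), y,
                inference = FALSE)
  expect_error(firthLRT(r, f), "nested")

  # Monte-Carlo type-I error of the per-term penalized LRT
  set.seed(19)
  rej <- vapply(1:1000, function(i) {
    xx <- rnorm(60)
    yy <- rbinom(60, 1, 0.3)
    full <- firthFit(cbind(x = xx), yy, inference = FALSE)
    red <- firthFit(matrix(numeric(0), nrow = 60, ncol = 0), yy,
                    inference = FALSE)
    firthLRT(full, red)$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("degenerate designs are rejected with informative errors", {
  expect_error(firthFit(cbind(a = rep(1, 10)), rep(c(0, 1), 5)),
               "collinear")
  expect_error(firthFit(rnorm(6), c(0, 1, 2, 0, 1, 0)), "binary")
  expect_warning(firthFit(rnorm(8), rep(0, 8), inference = FALSE),
                 "single class")
})
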