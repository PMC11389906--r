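test_that("rocAuc equals exhaustive pair counting on random instances", {
  set.seed(13)
  for (i in 1:100) {
    n1 <- sample(2:15, 1); n0 <- sample(2:15, 1)
    # rounding forces ties
    s <- round(rnorm(n1 + n0), 1)
    y <- c(rep(1, n1), rep(0, n0))
    expect_identical(rocAuc(s, y), pairCountAuc(s, y))
  }
  expect_equal(rocAuc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(rocAuc(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(rocAuc(1:5, rep(1, 5)), "both classes")
})

test_that("rocAuc agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  for (i in 1:10) {
    s <- round(rnorm(40), 1)
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(rocAuc(s, y), ref)
  }
})

test_that("fixed-specificity metrics follow direct enumeration", {
  s <- c(1:9, 10); y <- c(rep(0, 9), 1)
  m <- metricsAtSpecificity(s, y, 0.90)
  expect_equal(m$sens, 1)
  expect_gte(m$spec, 0.90)
  # perfect separation
  mp <- metricsAtSpecificity(c(1, 2, 8, 9), c(0, 0, 1, 1), 0.90)
  expect_equal(mp$sens, 1); expect_equal(mp$ppv, 1)
  # all-tied scores cannot attain the specificity: zero sensitivity
  mt <- metricsAtSpecificity(rep(3, 10), rep(c(0, 1), 5), 0.90)
  expect_equal(mt$sens, 0)
  expect_gt(mt$threshold, 3)
  # monotonicity: requiring more specificity never raises sensitivity
  set.seed(15)
  s2 <- rnorm(60); y2 <- rbinom(60, 1, 0.4)
  sens <- vapply(c(0.5, 0.7, 0.9, 0.95), function(sp)
    metricsAtSpecificity(s2, y2, sp)$sens, numeric(1))
  expect_true(all(diff(sens) <= 0))
})

test_that("stratified bootstrap CIs are deterministic, bounded and honest about constants", {
  set.seed(16)
  s <- rnorm(50); y <- rbinom(50, 1, 0.5)
  a <- stratifiedBootstrapCi(rocAuc, s, y, nBoot = 200, seed = 9)
  b <- stratifiedBootstrapCi(rocAuc, s, y, nBoot = 200, seed = 9)
  expect_identical(a[c("lower", "upper")], b[c("lower", "upper")])
  expect_gte(a$lower, 0); expect_lte(a$upper, 1)
  cst <- stratifiedBootstrapCi(function(...) 0.7, s, y, nBoot = 50,
                               seed = 1)
  expect_equal(cst$lower, 0.7); expect_equal(cst$upper, 0.7)
})

test_that("paired bootstrap AUC comparison behaves at the null and under separation", {
  set.seed(17)
  y <- rep(c(1, 0), each = 30)
  s <- rnorm(60)
  eq <- compareAucBootstrap(s, s, y, nBoot = 500, seed = 3)
  expect_equal(eq$p, 0.5, tolerance = 1e-6)
  # perfect vs uninformative
  sa <- y + rnorm(60, 0, 0.01); sb <- rnorm(60)
  cmp <- compareAucBootstrap(sa, sb, y, nBoot = 2000, seed = 4)
  expect_lt(cmp$p, 0.001)
  # antisymmetry under the normal-tail convention
  ab <- compareAucBootstrap(sa, sb, y, nBoot = 500, seed = 5)
  ba <- compareAucBootstrap(sb, sa, y, nBoot = 500, seed = 5)
  expect_equal(ab$p + ba$p, 1, tolerance = 1e-9)
  expect_error(compareAucBootstrap(sa[-1], sb, y), "equal length")
})

test_that("rocSummary composes the metrics and flags unstable subsets", {
  set.seed(18)
  s <- c(rnorm(40, 1.2), rnorm(40)); y <- rep(c(1, 0), each = 40)
  r <- rocSummary(s, y, nBoot = 200, seed = 2)
  expect_equal(auc(r), rocAuc(s, y))
  ci <- rocCi(r)
  expect_true(all(ci[, 1] <= ci[, 2]))
  expect_true(ci["auc", 1] <= auc(r) && auc(r) <= ci["auc", 2])
  # one case only: flagged, intervals suppressed
  r1 <- rocSummary(c(5, rnorm(10)), c(1, rep(0, 10)), nBoot = 200, seed = 2)
  expect_false(r1@stable)
  expect_true(all(is.na(rocCi(r1))))
})

test_that("Youden cutoff equals exhaustive search and handles degeneracy", {
  set.seed(19)
  for (i in 1:50) {
    s <- round(rnorm(20), 1)
    y <- rbinom(20, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(youdenCutoff(s, y)$J, bruteYouden(s, y), tolerance = 1e-12)
  }
  # perfect separation: J = 1, threshold between the groups
  ps <- youdenCutoff(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))
  expect_equal(ps$J, 1)
  expect_gt(ps$threshold, 3); expect_lte(ps$threshold, 10)
  # identical scores: no discrimination, J = 0
  expect_equal(youdenCutoff(rep(4, 8), rep(c(0, 1), 4))$J, 0)
  expect_error(youdenCutoff(1:4, rep(1, 4)), "both classes")
})

test_that("AUC is invariant to monotone score transforms; Youden J likewise", {
  set.seed(20)
  s <- rnorm(40); y <- rbinom(40, 1, 0.5)
  expect_equal(rocAuc(s, y), rocAuc(exp(s), y))
  expect_equal(youdenCutoff(s, y)$J, youdenCutoff(plogis(s), y)$J)
})
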