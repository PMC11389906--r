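# two tiny hand-built learners over a shared candidate set
mkLearner <- function(class, feat, beta, candidates = c("CA19-9", "VWF")) {
  cf <- setNames(c(-0.2, beta), c("(Intercept)", feat))
  new("BaseLearner", diagnosisClass = class, features = feat,
      coefficients = cf, center = setNames(5, feat),
      scale = setNames(1, feat),
      cvProfile = data.frame(size = 1L, auc = 0.8), oofProb = numeric(0),
      subsampling = "over", candidates = candidates, firth = FALSE,
      seed = 1L)
}

stackCohort <- function(seed = 27, n = 40) {
  set.seed(seed)
  y <- rep(c("case", "control"), length.out = n)
  npx <- matrix(rnorm(2 * n, 5), nrow = 2,
                dimnames = list(c("CA19-9", "VWF"), NULL))
  npx["CA19-9", y == "case"] <- npx["CA19-9", y == "case"] + 2
  manualCohort(npx, label = y)
}

test_that("two identical learners leave the stack ROC unchanged", {
  co <- stackCohort()
  l1 <- mkLearner("Healthy", "CA19-9", 1.5)
  l2 <- mkLearner("Liver Disease", "CA19-9", 1.5)
  st <- suppressWarnings(fitStack(list(Healthy = l1, `Liver Disease` = l2),
                                  co))
  expect_equal(length(metaCoefficients(st)), 3)
  expect_equal(rocAuc(predict(st, co), isCase(co)),
               rocAuc(predict(l1, co), isCase(co)))
})

test_that("a perfect learner among noise learners keeps discovery separable", {
  co <- stackCohort(seed = 28)
  # make CA19-9 truly separated so one base learner is perfect
  npx <- assay(co, "npx")
  npx["CA19-9", ] <- ifelse(isCase(co), 9, 1) + 0.01 * npx["VWF", ]
  assay(co, "npx") <- npx
  sep <- mkLearner("Healthy", "CA19-9", 40)   # saturating discriminant
  noise <- mkLearner("Liver Disease", "VWF", 0.01)
  st <- suppressWarnings(fitStack(list(Healthy = sep,
                                       `Liver Disease` = noise), co))
  expect_equal(rocAuc(predict(st, co), isCase(co)), 1)
})

test_that("stack output reduces to the meta-intercept when all base logits are zero", {
  co <- stackCohort(seed = 29)
  flat1 <- mkLearner("Healthy", "CA19-9", 0)
  flat2 <- mkLearner("Liver Disease", "VWF", 0)
  flat1@coefficients[1] <- 0; flat2@coefficients[1] <- 0
  st <- new("StackModel",
            learners = list(Healthy = flat1, `Liver Disease` = flat2),
            metaCoef = c("(Intercept)" = 0.3, Healthy = 2,
                         `Liver Disease` = -1),
            metaP = c(Healthy = NA_real_, `Liver Disease` = NA_real_),
            predictionMode = "insample", metaFirth = FALSE, seed = 1L)
  p <- predict(st, co)
  expect_equal(unname(p), rep(plogis(0.3), ncol(co)))
  # odds transform
  expect_equal(unname(stackOdds(st, co)),
               rep(plogis(0.3) / (1 - plogis(0.3)), ncol(co)))
})

test_that("stack probability is monotone in a positive-weight learner's output", {
  co <- stackCohort(seed = 30)
  l1 <- mkLearner("Healthy", "CA19-9", 1)
  l2 <- mkLearner("Liver Disease", "VWF", 1)
  st <- suppressWarnings(fitStack(list(Healthy = l1, `Liver Disease` = l2),
                                  co))
  w <- metaCoefficients(st)["Healthy"]
  npx <- assay(co, "npx")
  npx["CA19-9", 1] <- npx["CA19-9", 1] + 0.5   # raises l1's probability only
  co2 <- co; assay(co2, "npx") <- npx
  dp <- predict(st, co2)[1] - predict(st, co)[1]
  expect_equal(sign(unname(dp)), sign(unname(w)))
})

test_that("serialization round-trips learners and stacks bit-exactly", {
  co <- smallCohort(seed = 31, nCtrl = 14, nCase = 10)
  bl <- suppressWarnings(
    trainBaseLearner(co, "Liver Disease", candidates = c("CA19-9", "VWF"),
                     seed = 4, subsetSizes = c(1, 2)))
  fl <- tempfile(fileext = ".json")
  writeLearner(bl, fl)
  bl2 <- readLearner(fl)
  expect_identical(predict(bl2, co), predict(bl, co))

  l2 <- suppressWarnings(
    trainBaseLearner(co, "Liver Disease", candidates = c("CRP", "EGF"),
                     seed = 5, subsetSizes = c(1, 2)))
  l2@diagnosisClass <- "Healthy"
  st <- suppressWarnings(fitStack(list(`Liver Disease` = bl, Healthy = l2),
                                  co, seed = 6))
  fs <- tempfile(fileext = ".json")
  writeStack(st, fs)
  st2 <- readStack(fs)
  expect_identical(predict(st2, co), predict(st, co))
  expect_equal(metaCoefficients(st2), metaCoefficients(st))
})

test_that("recursive learner elimination drops an injected noise learner first", {
  mk <- c("S1", "S2", "NZ", elisaMarkers())
  cfg <- cohortConfig(
    nPerClass = c("Liver Disease" = 12, "Pancreatic Cyst" = 12,
                  Healthy = 12),
    nCases = 10, markerPanel = mk,
    effectMap = data.frame(marker = c("S1", "S2"), group = "PDAC",
                           shift = 2))
  co <- simulateCohort(cfg, seed = 33)
  # two informative learners on disjoint markers plus one pure-noise learner
  good1 <- suppressWarnings(trainBaseLearner(co, "Liver Disease",
    candidates = "S1", seed = 1, subsetSizes = 1))
  good2 <- suppressWarnings(trainBaseLearner(co, "Pancreatic Cyst",
    candidates = "S2", seed = 2, subsetSizes = 1))
  pure <- suppressWarnings(trainBaseLearner(co, "Healthy",
    candidates = "NZ", seed = 3, subsetSizes = 1))
  st <- suppressWarnings(fitStack(
    list(`Liver Disease` = good1, `Pancreatic Cyst` = good2,
         Healthy = pure), co, seed = 4))
  rle <- suppressWarnings(recursiveLearnerElimination(st, co, seed = 5))
  expect_equal(nrow(rle$trace), 2)
  expect_equal(rle$trace$removed[1], "Healthy")

  # two learners -> a single elimination step
  st2 <- suppressWarnings(fitStack(
    list(`Liver Disease` = good1, `Pancreatic Cyst` = good2), co, seed = 6))
  rle2 <- suppressWarnings(recursiveLearnerElimination(st2, co, seed = 7))
  expect_equal(nrow(rle2$trace), 1)
})

test_that("the reduced-signature builder is the full protocol on a restricted panel", {
  expect_setequal(reducedSignatureFeatures(),
                  c("CA19-9", "VWF", "CPE", "CTSV", "CEACAM1", "CD160",
                    "Diabetes", "Age"))
  mk <- c("S1", "S2", elisaMarkers())
  cfg <- cohortConfig(
    nPerClass = c("Liver Disease" = 15, Healthy = 15), nCases = 12,
    markerPanel = mk,
    effectMap = data.frame(marker = c("S1", "S2"), group = "PDAC",
                           shift = 2))
  co <- simulateCohort(cfg, seed = 34)
  cls <- c("Liver Disease", "Healthy")
  full <- suppressWarnings(buildReducedSignature(
    co, features = c("S1", "S2", "VWF"), classes = cls, seed = 7,
    subsetSizes = c(1, 2)))
  # identity: the same call is exactly reproducible
  full2 <- suppressWarnings(buildReducedSignature(
    co, features = c("S1", "S2", "VWF"), classes = cls, seed = 7,
    subsetSizes = c(1, 2)))
  expect_identical(predict(full2, co), predict(full, co))
  # removing the planted signal cannot improve the discovery AUC
  red <- suppressWarnings(buildReducedSignature(
    co, features = "VWF", classes = cls, seed = 7, subsetSizes = 1))
  y <- isCase(co)
  expect_lte(rocAuc(predict(red, co), y), rocAuc(predict(full, co), y))
  expect_error(buildReducedSignature(co, features = character(0)),
               "empty")
})
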