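test_that("identical config and seed give a bit-identical cohort", {
  cfg <- cohortConfig(nPerClass = c(Healthy = 15, "Liver Disease" = 10),
                      nCases = 8, markerPanel = smallPanel())
  a <- simulateCohort(cfg, seed = 5)
  b <- simulateCohort(cfg, seed = 5)
  expect_identical(markerData(a), markerData(b))
  expect_identical(as.data.frame(colData(a)), as.data.frame(colData(b)))
  c <- simulateCohort(cfg, seed = 6)
  expect_false(identical(markerData(a), markerData(c)))
})

test_that("row counts match the configuration exactly, per class and stage", {
  co <- simulateCohort(cohortConfig(), seed = 1)
  expect_equal(ncol(co), 539)
  expect_equal(sum(isCase(co)), 46)
  expect_equal(sum(!isCase(co)), 493)
  st <- table(colData(co)$stage[isCase(co)])
  expect_equal(unname(st[c("I", "II", "III", "IV", "unknown")]),
               c(4, 15, 10, 16, 1), ignore_attr = TRUE)
  cls <- table(diagnosisClasses(co)[!isCase(co)])
  expect_equal(unname(cls["Healthy"]), 72, ignore_attr = TRUE)
  expect_equal(sum(cls), 493)
  # cohort-level structural invariants
  cd <- colData(co)
  expect_true(all(cd$age >= 18 & cd$age <= 100))
  scr <- cd$source_cohort == "screening"
  expect_true(all(is.na(cd$qcancer[scr])))
  expect_true(all(is.na(symptomFlags(co)[scr, ])))
  expect_true(all(diagnosisClasses(co)[scr] == "Healthy"))
})

test_that("unknown classes, negative counts and bad probabilities are rejected", {
  expect_error(cohortConfig(nPerClass = c(Narnia = 5)), "unknown diagnosis")
  expect_error(cohortConfig(nCases = -1), "non-negative")
  expect_error(cohortConfig(noiseSd = 0), "noiseSd")
  expect_error(
    cohortConfig(markerPanel = smallPanel(),
                 effectMap = data.frame(marker = "NOPE", group = "PDAC",
                                        shift = 1)),
    "unknown marker")
  expect_error(
    cohortConfig(markerPanel = smallPanel(),
                 effectMap = data.frame(marker = "CRP", group = "Narnia",
                                        shift = 1)),
    "unknown group")
})

test_that("a planted shift is recovered within three standard errors", {
  cfg <- cohortConfig(nPerClass = c("Liver Disease" = 40), nCases = 40,
                      markerPanel = smallPanel(),
                      effectMap = data.frame(marker = "CA19-9",
                                             group = "PDAC", shift = 1.5))
  co <- simulateCohort(cfg, seed = 21)
  v <- markerData(co)["CA19-9", ]
  d <- mean(v[isCase(co)]) - mean(v[!isCase(co)])
  se <- sqrt(var(v[isCase(co)]) / 40 + var(v[!isCase(co)]) / 40)
  expect_lt(abs(d - 1.5), 3 * se)
})

test_that("with no planted effects marker AUCs stay in the null band", {
  cfg <- cohortConfig(nPerClass = c("Liver Disease" = 30), nCases = 30,
                      markerPanel = smallPanel(), effectMap = noEffects(),
                      batchModel = list(offsetSd = 0))
  seAuc <- sqrt((30 + 30 + 1) / (12 * 30 * 30))  # Hanley-McNeil null SE
  inBand <- vapply(1:30, function(s) {
    co <- simulateCohort(cfg, seed = 100 + s)
    a <- rocAuc(markerData(co)["CRP", ], isCase(co))
    abs(a - 0.5) <= 1.96 * seAuc
  }, logical(1))
  expect_gte(sum(inBand), 25)
})

test_that("bridge pairs reproduce the planted batch offset", {
  cfg <- cohortConfig(nPerClass = c(Healthy = 20, "Liver Disease" = 20),
                      nCases = 6, markerPanel = smallPanel(),
                      effectMap = noEffects(), noiseSd = 0.05,
                      batchModel = list(offsetSd = 0, nBridge = 16))
  co <- simulateCohort(cfg, seed = 31)
  off <- metadata(co)$batch_offsets
  off[, "B2"] <- 0
  off["CRP", "B2"] <- 0.8
  metadata(co)$batch_offsets <- off
  pairs <- generateBridgePairs(co, 16, seed = 2)
  d <- rowMeans(pairs$new - pairs$ref)
  expect_equal(unname(d["CRP"]), 0.8, tolerance = 0.1)
  expect_lt(max(abs(d[setdiff(names(d), "CRP")])), 0.1)
  # degenerate requests
  expect_equal(ncol(generateBridgePairs(co, 0, seed = 1)$ref), 0)
  expect_error(generateBridgePairs(co, 10000, seed = 1), "exceeds")
})

test_that("QCancer scores stochastically dominate in cases and missingness is honored", {
  cfg <- cohortConfig(nPerClass = c("Liver Disease" = 120), nCases = 80,
                      markerPanel = smallPanel(),
                      qcancerModel = list(rate = 1))
  co <- simulateCohort(cfg, seed = 41)
  q <- qcancerScore(co)
  expect_gt(mean(q[isCase(co)]), mean(q[!isCase(co)]))

  cfgM <- cohortConfig(nPerClass = c("Liver Disease" = 20), nCases = 5,
                       markerPanel = smallPanel(), missingRate = 0.1)
  com <- simulateCohort(cfgM, seed = 42)
  frac <- mean(is.na(markerData(com)))
  expect_gt(frac, 0.05); expect_lt(frac, 0.15)
})
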