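test_that("TSV round trip preserves the cohort", {
  co <- smallCohort(seed = 2)
  tf <- tempfile(fileext = ".tsv")
  # exact round trip on the NPX scale
  writeCohort(co, tf, elisaLinear = FALSE)
  rt <- readCohort(tf, elisaLinear = FALSE)
  expect_equal(markerData(rt), markerData(co))
  expect_equal(as.data.frame(colData(rt))$diagnosis_class,
               as.data.frame(colData(co))$diagnosis_class)
  # default (vendor-style linear ELISA) round trip is exact to float noise
  writeCohort(co, tf)
  rt2 <- readCohort(tf)
  expect_equal(markerData(rt2), markerData(co), tolerance = 1e-10)
  # a 539-row file reads back as 539 samples
  big <- tempfile(fileext = ".tsv")
  writeCohort(simulateCohort(cohortConfig(), seed = 1), big)
  expect_equal(ncol(readCohort(big)), 539)
})

test_that("schema violations are reported with the offending column", {
  co <- smallCohort(seed = 3)
  tf <- tempfile(fileext = ".tsv")
  writeCohort(co, tf)
  df <- read.delim(tf, check.names = FALSE)
  df$diagnosis_class[2] <- "Planet X"
  bad <- tempfile(fileext = ".tsv")
  write.table(df, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readCohort(bad), "unknown diagnosis class")

  df2 <- read.delim(tf, check.names = FALSE)
  df2$age <- NULL
  write.table(df2, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readCohort(bad), "age")
})

test_that("age bins follow the half-open decade convention", {
  expect_equal(ageBin(c(19, 28, 28.5, 38, 48.01, 79, 95)),
               c("(18,28]", "(18,28]", "(28,38]", "(28,38]", "(48,58]",
                 "79+", "79+"))
})

test_that("stratified split honors the two-thirds rule in every stratum", {
  # forced rounding: 3 samples in one stratum -> 2 discovery / 1 validation
  m <- matrix(rnorm(3 * 2), nrow = 2,
              dimnames = list(c("A", "B"), NULL))
  co3 <- manualCohort(m, label = rep("control", 3),
                      diagnosis = rep("Gastritis/Reflux Disease", 3))
  s3 <- assignSplit(co3, seed = 1)
  expect_equal(sum(s3@assignment$arm == "discovery"), 2)

  # one 100-sample stratum -> 66 or 67 discovery
  m100 <- matrix(rnorm(100), nrow = 1, dimnames = list("A", NULL))
  co100 <- manualCohort(m100, label = rep("control", 100),
                        diagnosis = rep("Liver Disease", 100))
  nd <- vapply(1:20, function(s)
    sum(assignSplit(co100, seed = s)@assignment$arm == "discovery"),
    numeric(1))
  expect_true(all(nd %in% c(66, 67)))
  expect_true(length(unique(nd)) > 1)  # rounding direction is randomized

  # full synthetic cohort: every stratum within one of round(2n/3),
  # every sample assigned exactly once, deterministic given seed
  co <- simulateCohort(cohortConfig(), seed = 9)
  sp <- assignSplit(co, seed = 4)
  a <- sp@assignment
  expect_setequal(a$sample_id, colData(co)$sample_id)
  expect_false(any(is.na(a$arm)))
  dev <- vapply(split(a$arm, a$stratum_id), function(x)
    abs(sum(x == "discovery") - round(2 * length(x) / 3)), numeric(1))
  expect_lte(max(dev), 1)
  expect_identical(assignSplit(co, seed = 4)@assignment, a)
  expect_error(assignSplit(co[, 0], seed = 1), "empty")
})

test_that("screening samples can keep an externally fixed assignment", {
  cfg <- cohortConfig(nPerClass = c(Healthy = 12, "Liver Disease" = 12),
                      nCases = 6, markerPanel = smallPanel())
  co <- simulateCohort(cfg, seed = 10)
  scr <- colData(co)$sample_id[colData(co)$source_cohort == "screening"]
  ext <- setNames(rep(c("discovery", "validation"), length.out = length(scr)),
                  scr)
  sp <- assignSplit(co, seed = 1, external = ext)
  got <- with(sp@assignment, setNames(arm, sample_id))[scr]
  expect_identical(got, ext)
})

test_that("bridging normalization subtracts the per-assay median pair difference", {
  set.seed(5)
  mk <- c("A", "B", "C")
  base <- matrix(rnorm(3 * 10, 5), nrow = 3, dimnames = list(mk, NULL))
  ref <- manualCohort(base, label = rep("control", 10), batch = "B1")
  offs <- c(A = 0.8, B = -0.5, C = 0)
  newm <- matrix(rnorm(3 * 8, 5), nrow = 3, dimnames = list(mk, NULL)) + offs
  new <- manualCohort(newm, label = rep("control", 8), batch = "B2")
  bm <- matrix(rnorm(3 * 16, 5), nrow = 3, dimnames = list(mk, NULL))
  pairs <- list(ref = bm, new = bm + offs)  # noise-free bridge pairs

  corrected <- bridgeNormalize(ref, new, pairs)
  est <- metadata(corrected)$bridge_offsets
  expect_equal(unname(est), unname(offs))  # each assay independently
  expect_equal(unname(markerData(corrected)), unname(newm - offs))
  # post-correction the median bridge difference is exactly zero
  expect_equal(unname(apply((pairs$new - est) - pairs$ref, 1, median)),
               c(0, 0, 0))

  # idempotence: re-bridging an aligned batch changes nothing
  pairs2 <- list(ref = bm, new = bm)
  again <- bridgeNormalize(ref, corrected, pairs2)
  expect_equal(markerData(again), markerData(corrected))

  # shift equivariance: a constant added to an assay of the new batch is
  # removed, leaving corrected values unchanged
  shifted <- new
  assay(shifted, "npx")["A", ] <- assay(shifted, "npx")["A", ] + 3
  pairsS <- list(ref = bm, new = pairs$new)
  pairsS$new["A", ] <- pairsS$new["A", ] + 3
  corr2 <- bridgeNormalize(ref, shifted, pairsS)
  expect_equal(markerData(corr2), markerData(corrected))

  # refusal and mismatch guards
  expect_error(bridgeNormalize(ref, new,
                               list(ref = bm[, 1, drop = FALSE],
                                    new = bm[, 1, drop = FALSE])),
               "at least 2 bridge pairs")
  refBad <- ref[c("A", "B"), ]
  expect_error(bridgeNormalize(refBad, new, pairs), "panels")
})
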