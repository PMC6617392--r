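test_that("median centering and quantile normalization behave as defined", {
  m <- matrix(c(1, 2, 3, 3, 2, 1), 3, 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  cen <- normalizeAndCenter(m, "median_center")
  expect_true(all(apply(cen, 1, stats::median) == 0))
  const <- matrix(5, 3, 2)
  expect_true(all(normalizeAndCenter(const, "median_center") == 0))
  # columns that are permutations of each other share sorted values after
  # quantile normalization
  q <- normalizeAndCenter(m, "quantile_log")
  expect_equal(unname(sort(q[, 1])), unname(sort(q[, 2])))
  expect_error(normalizeAndCenter(matrix(0, 2, 2)), "all-zero")
})

test_that("centroid assignment recovers exact and noisy centroid samples", {
  cen <- syntheticCentroids(200, c("CMS1", "CMS2", "CMS3", "CMS4"))
  call <- assignCentroidSubtype(cen[, "CMS2"], cen)
  expect_identical(subtypeLabel(call), "CMS2")
  expect_equal(unname(subtypeScores(call)["CMS2"]), 1)
  expect_identical(callConfidence(call), "high")
  expect_identical(callMethod(call), "centroid_correlation")
})

test_that("pure-noise and equicorrelated samples are low confidence", {
  cen <- syntheticCentroids(786, c("CMS1", "CMS2", "CMS3", "CMS4"))
  noise <- withr::with_seed(99,
    stats::setNames(stats::rnorm(nrow(cen)), rownames(cen)))
  nc <- assignCentroidSubtype(noise, cen)
  expect_identical(callConfidence(nc), "low")
  expect_lt(max(subtypeScores(nc)), 0.15)
  # a sample halfway between two centroids has a top-two gap below 0.06
  mixed <- (cen[, "CMS2"] + cen[, "CMS4"]) / 2
  mc <- assignCentroidSubtype(mixed, cen)
  r <- sort(subtypeScores(mc), decreasing = TRUE)
  expect_lt(r[1] - r[2], 0.06)
  expect_identical(callConfidence(mc), "low")
})

test_that("centroid assignment is invariant to positive affine transforms", {
  cen <- syntheticCentroids(300, c("A", "B", "C"))
  x <- cen[, "B"] + withr::with_seed(5, stats::rnorm(300, sd = 0.5))
  names(x) <- rownames(cen)
  base <- assignCentroidSubtype(x, cen)
  shifted <- assignCentroidSubtype(2.5 * x + 7, cen)
  expect_identical(subtypeLabel(shifted), subtypeLabel(base))
  expect_equal(subtypeScores(shifted), subtypeScores(base))
})

test_that("insufficient centroid gene overlap is an error naming genes", {
  cen <- syntheticCentroids(100, c("A", "B"))
  x <- stats::setNames(stats::rnorm(30), rownames(cen)[1:30])
  expect_error(assignCentroidSubtype(x, cen), "30/100")
})

test_that("label recovery on simulated cohorts meets the noise benchmark", {
  cen <- syntheticCentroids(300, c("CMS1", "CMS2", "CMS3", "CMS4"))
  truth <- rep(colnames(cen), length.out = 24)
  expr <- simulateExpressionCohort(cen, truth, 0.5, seed = 17)
  got <- vapply(seq_len(ncol(expr)), function(i)
    subtypeLabel(assignCentroidSubtype(expr[, i], cen)), character(1))
  expect_gte(mean(got == truth), 0.95)
  clean <- simulateExpressionCohort(cen, truth, 0, seed = 18)
  cleanCalls <- lapply(seq_len(ncol(clean)), function(i)
    assignCentroidSubtype(clean[, i], cen))
  expect_identical(vapply(cleanCalls, subtypeLabel, character(1)), truth)
  expect_true(all(vapply(cleanCalls, callConfidence, character(1)) == "high"))
})

test_that("nearest-template prediction calls planted samples confidently", {
  templates <- list(CMS2 = sprintf("g%03d", 1:25),
                    CMS4 = sprintf("g%03d", 26:50),
                    CMS1 = sprintf("g%03d", 51:75))
  x <- stats::setNames(c(rep(2, 25), rep(0, 50)), sprintf("g%03d", 1:75))
  x <- x + withr::with_seed(3, stats::rnorm(75, sd = 0.05))
  call <- assignNearestTemplate(x, templates, nPermutations = 1000, seed = 9)
  expect_identical(subtypeLabel(call), "CMS2")
  expect_lte(qvalue(call), 0.001)
  expect_identical(callConfidence(call), "high")
  # identical input and seed give identical q
  again <- assignNearestTemplate(x, templates, nPermutations = 1000, seed = 9)
  expect_identical(qvalue(again), qvalue(call))
})

test_that("shuffled samples are low confidence under permutation", {
  templates <- list(A = sprintf("g%03d", 1:25), B = sprintf("g%03d", 26:50))
  shuffled <- withr::with_seed(31, stats::setNames(
    stats::rnorm(50), sprintf("g%03d", 1:50)))
  call <- assignNearestTemplate(shuffled, templates, nPermutations = 500,
                                seed = 4)
  expect_gt(qvalue(call), 0.01)
  expect_identical(callConfidence(call), "low")
  expect_error(assignNearestTemplate(
    stats::setNames(rep(1, 50), sprintf("g%03d", 1:50)), templates),
    "zero-variance")
})

test_that("permutation q-values are near-uniform on null inputs", {
  templates <- list(A = sprintf("g%02d", 1:20), B = sprintf("g%02d", 21:40),
                    C = sprintf("g%02d", 41:60))
  qs <- vapply(1:500, function(i) {
    x <- withr::with_seed(1000 + i, stats::setNames(
      stats::rnorm(60), sprintf("g%02d", 1:60)))
    qvalue(assignNearestTemplate(x, templates, nPermutations = 99, seed = i))
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(qs, "punif"))
  expect_gt(ks$p.value, 1e-3)
  expect_equal(mean(qs), 0.5, tolerance = 0.08)
})

test_that("subtype switches flag the CMS2>4 and TA>SL transitions", {
  mk <- function(label, all = c("CMS1", "CMS2", "CMS3", "CMS4")) {
    scores <- stats::setNames(rep(0.2, length(all)), all)
    scores[label] <- 0.9
    new("SubtypeCall", label = label, scores = scores, confidence = "high",
        method = "centroid_correlation")
  }
  sw <- detectSubtypeSwitch(mk("CMS2"), mk("CMS4"))
  expect_true(sw$switched)
  expect_true(sw$is_cms2_to_4)
  expect_false(sw$is_ta_to_sl)
  same <- detectSubtypeSwitch(mk("CMS2"), mk("CMS2"))
  expect_false(same$switched)
  tasl <- detectSubtypeSwitch(mk("TA", c("TA", "SL")), mk("SL", c("TA", "SL")))
  expect_true(tasl$is_ta_to_sl)
  ntp <- new("SubtypeCall", label = "CMS2",
             scores = c(CMS2 = 0.1, CMS4 = 0.5), confidence = "high",
             method = "nearest_template", qvalue = 0.001)
  expect_error(detectSubtypeSwitch(mk("CMS2"), ntp), "different methods")
})

test_that("the cpm filter applies the 10/L threshold", {
  # L = 10 million -> threshold 1 cpm -> 10 reads in the smallest library
  lib <- c(1e7, 2e7)
  counts <- matrix(c(
    10, 20,   # 1.0 / 1.0 cpm -> kept (boundary inclusive)
    9, 18,    # 0.9 cpm everywhere -> dropped
    0, 0,     # zero everywhere -> dropped
    100, 5,   # passes in one sample only -> dropped under all-samples rule
    50, 100), # comfortably above -> kept
    ncol = 2, byrow = TRUE,
    dimnames = list(c("boundary", "below", "zero", "straddle", "high"), NULL))
  kept <- cpmGeneFilter(counts, lib)
  expect_identical(kept, c("boundary", "high"))
  # with the one-sample criterion the straddler survives
  expect_true("straddle" %in% cpmGeneFilter(counts, lib, minSamples = 1))
  expect_error(cpmGeneFilter(counts, c(0, 1e7)), "library sizes")
})
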