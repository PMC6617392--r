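test_that("estimateCcf matches direct substitution into the CCF formula", {
  expect_equal(ccf(estimateCcf(0.5, 1, 2)), 1)
  expect_equal(ccf(estimateCcf(0.25, 1, 2)), 0.5)
  expect_equal(ccf(estimateCcf(0.4, 1, 1)), 0.8 / 1.4) # 0.5714
  expect_equal(ccf(estimateCcf(0, 1, 2)), 0)
})

test_that("estimateCcf caps noisy values above 1 and flags them", {
  est <- estimateCcf(0.6, 1, 2) # raw 1.2/1.0 = 1.2
  expect_equal(ccf(est), 1)
  expect_true(ccfCapped(est))
  expect_false(ccfCapped(estimateCcf(0.5, 1, 2)))
})

test_that("estimateCcf rejects inconsistent copy states", {
  # denominator m + 2V - Vt <= 0: V = 0.9, m = 1, t = 4 -> 1 + 1.8 - 3.6 < 0
  expect_error(estimateCcf(0.9, 1, 4), "inconsistent copy state")
  expect_error(estimateCcf(0.5, 0, 2), "copiesMutated")
  expect_error(estimateCcf(0.5, 3, 2), "copiesTotal")
})

test_that("expectedClonalVaf inverts estimateCcf across the valid domain", {
  expect_equal(expectedClonalVaf(1, 1, 2), 0.5)
  expect_equal(expectedClonalVaf(2 / 3.5, 1, 2), 1 / 3.5) # denom reduces to 2
  for (t in 1:8) {
    for (m in 1:t) {
      # keep VAF below the level where raw CCF would exceed 1
      vmax <- expectedClonalVaf(1, m, t)
      v <- seq(0.01, vmax - 0.005, length.out = 25)
      v <- v[v > 0]
      back <- expectedClonalVaf(ccf(estimateCcf(v, m, t)), m, t)
      expect_lt(max(abs(back - v)), 1e-12)
    }
  }
})

test_that("estimateCcf is monotone increasing in VAF for a fixed copy state", {
  for (t in c(1, 2, 4, 8)) {
    vmax <- expectedClonalVaf(1, 1, t)
    v <- seq(0.001, vmax, length.out = 50)
    expect_true(all(diff(ccf(estimateCcf(v, 1, t))) > 0))
  }
})

test_that("TP53-anchored ctDNA purity follows the formula literally", {
  expect_equal(purity(estimateCtdnaPurity(0.4, 1, 1)), 0.8 / 1.4)
  # pure ctDNA, clonal, LOH: the formula's fixed two normal copies give 2/3
  expect_equal(purity(estimateCtdnaPurity(0.5, 1, 1)), 2 / 3)
  expect_error(estimateCtdnaPurity(numeric(0), 1, 1), "anchor")
})

test_that("two TP53 mutations are pooled by summed VAFs and copies", {
  pur <- estimateCtdnaPurity(c(0.2, 0.1), c(4, 2), c(4, 2))
  expect_equal(purity(pur), 0.6 / (6 + 0.6 - 1.8)) # 0.125
  expect_true(pur@combined)
  expect_false(estimateCtdnaPurity(0.4, 1, 1)@combined)
})

test_that("driverFraction divides observed by expected clonal VAF", {
  pur <- estimateCtdnaPurity(0.4, 1, 1) # 0.5714
  expect_equal(as.numeric(driverFraction(0.05, pur, 2)), 0.175)
  vExp <- expectedClonalVaf(purity(pur), 1, 2)
  expect_equal(as.numeric(driverFraction(vExp, pur, 2)), 1)
  expect_equal(as.numeric(driverFraction(0, pur, 2)), 0)
  expect_error(driverFraction(0.05, 0, 2), "purity is 0")
})

test_that("driverFraction at diploid loci reduces to 2*VAF/CCF_sample", {
  for (p in c(0.2, 0.5, 0.9)) {
    v <- seq(0.01, p / 2, length.out = 10)
    expect_equal(as.numeric(driverFraction(v, p, 2)), 2 * v / p)
  }
})

test_that("resistanceGap sums driver fractions with a cap at 1", {
  expect_equal(gap(resistanceGap(numeric(0))), 1)
  expect_equal(gap(resistanceGap(0.175)), 0.825)
  rg <- resistanceGap(c(0.7, 0.6))
  expect_equal(totalDriverFraction(rg), 1)
  expect_equal(gap(rg), 0)
  expect_true(rg@capped)
  expect_equal(gap(rg) + totalDriverFraction(rg), 1)
})

test_that("cancer cell content is 2x the median VAF with a 10% exclusion", {
  res <- estimateCancerCellContent(c(0.2, 0.25, 0.3))
  expect_equal(res$content, 0.5)
  expect_true(res$included)
  low <- estimateCancerCellContent(rep(0.04, 5))
  expect_equal(low$content, 0.08)
  expect_false(low$included)
  expect_equal(estimateCancerCellContent(0.6)$content, 1) # capped
  expect_error(estimateCancerCellContent(numeric(0)), "at least one")
})

test_that("mutation multiplicity recovers allele counts from VAF and purity", {
  expect_equal(mutationMultiplicity(0.5, 1, 2), 1)
  expect_equal(mutationMultiplicity(0.25, 0.5, 2), 1)
  expect_equal(mutationMultiplicity(0.4, 0.5, 3), 2)
  expect_error(mutationMultiplicity(0.5, 0, 2), "purity")
})

test_that("clonal status comes from whether the binomial CI of CCF reaches 1", {
  expect_equal(clonalStatus(assignClonalStatus(estimateCcf(0.5, 1, 2), 1000)),
               "clonal")
  expect_equal(clonalStatus(assignClonalStatus(estimateCcf(0.1, 1, 2), 1000)),
               "subclonal")
  # CCF 0.95 at depth 30: VAF 0.475, alt = 14; the exact binomial CI upper
  # bound (oracle below) maps to a CCF above 1, so the call is clonal
  vObs <- expectedClonalVaf(0.95, 1, 2)
  hi <- stats::binom.test(round(vObs * 30), 30)$conf.int[2]
  expect_gt(2 * hi / (1 + 2 * hi - 2 * hi), 1)
  est <- estimateCcf(vObs, 1, 2)
  expect_equal(clonalStatus(assignClonalStatus(est, 30)), "clonal")
  expect_equal(clonalStatus(assignClonalStatus(est, 0)), "unassigned")
})
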