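test_that("exome SNV thresholds are inclusive at their boundaries", {
  boundary <- data.frame(tumor_depth = 20, tumor_alt = 1,
                         normal_depth = 50, normal_alt = 2)
  expect_true(filterExomeSnvs(boundary)$retained)
  below <- data.frame(tumor_depth = 1000, tumor_alt = 49,
                      normal_depth = 50, normal_alt = 0) # VAF 4.9%
  expect_false(filterExomeSnvs(below)$retained)
})

test_that("the SNV fixture reproduces its hand-enumerated retention set", {
  fix <- snvFixture()
  out <- filterExomeSnvs(fix)
  expect_identical(sum(out$retained), 7L)
  expect_identical(out$id[!out$retained],
                   c("lowvaf", "lowdepth", "normalalt"))
  expect_identical(out$retained, snvOracle(fix))
  # the filter annotates without mutating or dropping observations
  expect_identical(out[names(fix)], fix)
})

test_that("SNV filtering demands matched-normal counts", {
  calls <- data.frame(id = "v1", tumor_depth = 100, tumor_alt = 30,
                      normal_depth = NA, normal_alt = NA)
  expect_error(filterExomeSnvs(calls), "v1")
})

test_that("exome SNV rules are order-independent pure predicates", {
  fix <- snvFixture()
  perm <- fix[rev(seq_len(nrow(fix))), ]
  out <- filterExomeSnvs(perm)
  expect_identical(out$retained, rev(filterExomeSnvs(fix)$retained))
})

test_that("indel retention honors flags, genotype and depth floors", {
  base <- data.frame(filter = "PASS", normal_gt = "0/0", normal_depth = 10,
                     tumor_depth = 20, tumor_alt = 5)
  expect_true(filterExomeIndels(base)$retained) # all boundaries inclusive
  flagged <- transform(base, filter = "badReads")
  expect_false(filterExomeIndels(flagged)$retained)
  het <- transform(base, normal_gt = "0/1")
  expect_false(filterExomeIndels(het)$retained)
  multi <- transform(base, filter = "strandBias;alleleBias")
  expect_false(filterExomeIndels(multi)$retained)
  benign <- transform(base, filter = "alleleBias") # not in the excluded set
  expect_true(filterExomeIndels(benign)$retained)
  expect_error(filterExomeIndels(transform(base, filter = NA)), "FILTER")
})

test_that("cross-normal filter applies the 2% flag and 5% cohort rules", {
  calls <- data.frame(chrom = "chr1", pos = 100, alt = "T")
  cohortOf <- function(altReads) data.frame(chrom = "chr1", pos = 100,
    alt = "T", normal_sample = paste0("N", seq_along(altReads)),
    depth = 100, alt_reads = altReads)
  # one normal at exactly 2.0% flags, but 1/40 = 2.5% < 5% -> retained
  one <- crossNormalFilter(calls, cohortOf(c(2, rep(0, 39))), 40)
  expect_true(one$retained)
  expect_identical(one$cohort_flag_count, 1L)
  # flagged in 2/40 = 5.0% of normals -> rejected ("5% or more")
  two <- crossNormalFilter(calls, cohortOf(c(2, 3, rep(0, 38))), 40)
  expect_false(two$retained)
  # no flagging normals -> retained
  none <- crossNormalFilter(calls, cohortOf(rep(1, 40)), 40) # all below 2%
  expect_true(none$retained)
})

test_that("cohort members without locus coverage count as not flagging", {
  calls <- data.frame(chrom = "chr1", pos = c(100, 200), alt = "T")
  cohort <- data.frame(chrom = "chr1", pos = 100, alt = "T",
    normal_sample = paste0("N", 1:10), depth = 100, alt_reads = 0)
  expect_message(out <- crossNormalFilter(calls, cohort, 40), "not flagging")
  expect_true(all(out$retained))
  expect_identical(out$cohort_flag_count, c(0L, 0L))
})

test_that("planted recurrent artifacts are removed exactly", {
  # 30 loci; loci 1-5 are artifacts present at >= 2% in >= 5% of 40 normals
  nNormals <- 40
  calls <- data.frame(chrom = "chr1", pos = 1:30 * 10, alt = "A")
  cohort <- do.call(rbind, lapply(1:30, function(i) {
    nFlag <- if (i <= 5) 2 else if (i <= 10) 1 else 0
    data.frame(chrom = "chr1", pos = i * 10, alt = "A",
      normal_sample = paste0("N", 1:nNormals), depth = 200,
      alt_reads = c(rep(5, nFlag), rep(0, nNormals - nFlag)))
  }))
  out <- crossNormalFilter(calls, cohort, nNormals)
  expect_identical(which(!out$retained), 1:5)
})

test_that("amplicon calling needs 0.5% VAF and 3 supporting reads", {
  rc <- data.frame(pos = 1:3, depth = c(2000, 2000, 200),
                   alt_reads = c(12, 2, 3))
  out <- callAmpliconMutations(rc)
  expect_identical(out$pos, c(1L, 3L)) # 0.6% w/ 12 reads; 1.5% w/ 3 reads
  expect_error(callAmpliconMutations(data.frame(depth = 0, alt_reads = 0)),
               "depth")
})

test_that("ctDNA hotspot calls need 2 reads and a catalogued change", {
  cat <- data.frame(gene = c("KRAS", "KRAS", "BRAF"),
                    pos = c(25398284, 25398281, 140453136),
                    aa_change = c("G12D", "G13D", "V600E"))
  rc <- data.frame(
    gene = c("KRAS", "KRAS", "NRAS", "KRAS"),
    pos = c(25398284, 25398284, 115258747, 25398284),
    depth = 1e4, alt_reads = c(2, 1, 5, 3),
    aa_change = c("G12D", "G12D", "Q61K", NA))
  expect_message(out <- callCtdnaHotspots(rc, cat), "untranslatable")
  # 2 reads of a catalogued change called; 1 read not; non-catalog not
  expect_identical(nrow(out), 1L)
  expect_identical(out$alt_reads, 2)
  expect_error(callCtdnaHotspots(rc, cat[0, ]), "empty")
})

test_that("non-catalogued amino-acid changes are never called", {
  cat <- data.frame(gene = "KRAS", pos = 25398284, aa_change = "G12D")
  rc <- data.frame(gene = "KRAS", pos = 25398284, depth = 1e4,
                   alt_reads = 50, aa_change = "G12V")
  expect_identical(nrow(callCtdnaHotspots(rc, cat)), 0L)
})
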