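test_that("germline variant retention applies the five printed conditions", {
  base <- data.frame(chrom = "chr1", pos = 100, ref = "A", alt = "G",
    filter = "PASS", gq = 10, gt = "0/1", depth = 10, alt_reads = 1)
  expect_identical(nrow(filterGermlineVariants(base)), 1L) # all inclusive
  reject <- function(...) {
    expect_identical(nrow(filterGermlineVariants(transform(base, ...))), 0L)
  }
  reject(gq = 9)
  reject(filter = "LowQual")
  reject(gt = "0/0")
  reject(depth = 9)
  reject(alt_reads = 0)
})

test_that("multi-allelic sites keep only the highest-frequency alt", {
  rec <- data.frame(chrom = "chr1", pos = c(100, 100), ref = "A",
    alt = c("G", "T"), filter = "PASS", gq = 30, gt = c("0/1", "0/2"),
    depth = 100, alt_reads = c(30, 20))
  out <- filterGermlineVariants(rec)
  expect_identical(out$alt, "G") # AF 0.3 beats 0.2
})

test_that("segmental-duplication regions and malformed genotypes drop out", {
  rec <- data.frame(chrom = "chr1", pos = c(100, 5000), ref = "A", alt = "G",
    filter = "PASS", gq = 30, gt = c("0/1", "0/1"), depth = 50,
    alt_reads = 20)
  dup <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4000, 6000))
  out <- filterGermlineVariants(rec, exclusionRegions = dup)
  expect_identical(out$pos, 100)
  badGt <- transform(rec[1, ], gt = "not-a-genotype")
  expect_message(out2 <- filterGermlineVariants(badGt), "malformed")
  expect_identical(nrow(out2), 0L)
})

test_that("overlap resolution prefers somatic, then leftmost", {
  sameSite <- data.frame(pos = c(5, 5), ref = "A", alt = c("T", "G"),
                         origin = c("germline", "somatic"))
  expect_message(kept <- resolveOverlaps(sameSite), "somatic")
  expect_identical(kept$origin, "somatic")
  # two overlapping germline deletions: leftmost wins
  dels <- data.frame(pos = c(10, 12), ref = c("ACGTA", "GTACG"),
                     alt = c("A", "G"), origin = "germline")
  expect_message(kept2 <- resolveOverlaps(dels), "germline")
  expect_identical(kept2$pos, 10)
  # disjoint variants pass through untouched
  clean <- data.frame(pos = c(3, 20), ref = "A", alt = "G",
                      origin = c("germline", "somatic"))
  expect_identical(resolveOverlaps(clean), clean)
})

test_that("germline and tumor CDS are built in phase, right to left", {
  cds <- "ATGGCTTGGTAA"
  none <- buildSequences(cds, data.frame(pos = integer(0), ref = character(0),
    alt = character(0), origin = character(0)))
  expect_identical(none$germline, cds)
  expect_identical(none$tumor, cds)
  missense <- data.frame(pos = 4, ref = "G", alt = "C", origin = "somatic")
  out <- buildSequences(cds, missense)
  expect_identical(out$germline, cds)
  expect_identical(out$tumor, "ATGCCTTGGTAA")
  # germline SNV plus downstream somatic frameshift, hand-built expectation
  both <- data.frame(pos = c(4, 8), ref = c("G", "G"),
                     alt = c("C", "GA"), origin = c("germline", "somatic"))
  out2 <- buildSequences(cds, both)
  expect_identical(out2$germline, "ATGCCTTGGTAA")
  expect_identical(out2$tumor, "ATGCCTTGAGTAA")
  expect_error(
    buildSequences(cds, data.frame(pos = 4, ref = "T", alt = "C",
                                   origin = "somatic"), transcript = "tx9"),
    "tx9")
})

test_that("translation runs to the first stop, or sequence end without one", {
  expect_identical(translateCds("ATGGCTTAA"), "MA")
  expect_identical(translateCds("ATGGCTGGG"), "MAG") # no stop: to the end
  expect_identical(translateCds("ATGGCTGGGT"), "MAG") # partial codon dropped
  expect_identical(translateCds("ATGTAAGCT"), "M") # mid-CDS stop truncates
  expect_error(translateCds("AT"), "codon")
})

test_that("neopeptide counts match the window-enumeration oracle exactly", {
  germ <- withr::with_seed(1, randomProtein(30))
  expect_length(enumerateNeopeptides(germ, germ), 0)
  # single interior substitution in a length-30 protein: 8+9+10+11 windows
  pos <- 15
  tum <- paste0(substr(germ, 1, pos - 1),
                if (substr(germ, pos, pos) == "A") "C" else "A",
                substr(germ, pos + 1, 30))
  neo <- enumerateNeopeptides(tum, germ)
  expect_length(neo, 38)
  expect_setequal(neo, neoOracle(tum, germ))
  # substitution at the first residue: one window per length
  tumFirst <- paste0(if (substr(germ, 1, 1) == "A") "C" else "A",
                     substr(germ, 2, 30))
  expect_length(enumerateNeopeptides(tumFirst, germ), 4)
})

test_that("every neopeptide differs from germline or sits past a frameshift", {
  toy <- makeToyTranscriptome(16, c(20, 40), seed = 23)
  for (tx in unique(toy$variants$transcript)) {
    v <- resolveOverlaps(
      toy$variants[toy$variants$transcript == tx, , drop = FALSE])
    seqs <- buildSequences(as.character(toy$cds[[tx]]), v)
    sG <- translateCds(seqs$germline)
    sT <- translateCds(seqs$tumor)
    if (nchar(sG) == 0 || nchar(sT) == 0) next
    neo <- enumerateNeopeptides(sT, sG)
    expect_setequal(neo, neoOracle(sT, sG))
    # none of the neopeptides occurs anywhere in the germline protein
    if (length(neo))
      expect_false(any(vapply(neo, grepl, logical(1), x = sG,
                              fixed = TRUE)))
  }
})

test_that("the toy predictor is deterministic and shortens some cores", {
  a <- toyRankPredictor("SIINFEKLAW", "HLA-A*02:01")
  b <- toyRankPredictor("SIINFEKLAW", "HLA-A*02:01")
  expect_identical(a, b)
  expect_true(a$rank >= 0 && a$rank < 100)
  peps <- vapply(1:300, function(i)
    withr::with_seed(i, randomProtein(10)), "")
  cores <- vapply(peps, function(p) toyRankPredictor(p, "H")$core, "")
  shortened <- mean(nchar(cores) < nchar(peps))
  expect_gt(shortened, 0.02)
  expect_lt(shortened, 0.3)
})

test_that("binder counting keeps best rank per core and excludes wild type", {
  germ <- paste(rep("Q", 30), collapse = "")
  predictor <- function(peptide, hla) {
    switch(peptide,
      AAAAAAAA = list(core = "AAAAAAAA",
                      rank = if (hla == "H2") 0.4 else 50),
      QQQQQQQQ = list(core = "QQQQQQQQ", rank = 0.1), # wild-type window
      CCCCCCCC = list(core = "CCCCCCCC", rank = 50),
      NULL)
  }
  out <- countBinders(c("AAAAAAAA", "QQQQQQQQ", "CCCCCCCC"),
                      c("H1", "H2"), predictor, germ)
  expect_identical(out$count, 1L)
  rec <- out$records
  expect_equal(rec$best_rank[rec$core == "AAAAAAAA"], 0.4)
  expect_true(rec$binder[rec$core == "AAAAAAAA"])
  # rank 0.1 but identical to a germline window: excluded
  expect_false(rec$binder[rec$core == "QQQQQQQQ"])
  expect_false(rec$contains_mutated_residue[rec$core == "QQQQQQQQ"])
  # below-threshold rank in no context: not a binder
  expect_false(rec$binder[rec$core == "CCCCCCCC"])
  # a failing predictor response skips the peptide with a log entry
  expect_message(countBinders("WWWWWWWW", "H1", predictor, germ), "skipped")
})

test_that("adding HLA contexts can only lower best ranks per core", {
  germ <- paste(rep("Q", 30), collapse = "")
  peps <- vapply(1:20, function(i) withr::with_seed(100 + i,
                                                    randomProtein(9)), "")
  one <- countBinders(peps, "HLA-A*01:01", toyRankPredictor, germ)
  two <- countBinders(peps, c("HLA-A*01:01", "HLA-B*07:02"),
                      toyRankPredictor, germ)
  shared <- intersect(one$records$core, two$records$core)
  r1 <- stats::setNames(one$records$best_rank, one$records$core)
  r2 <- stats::setNames(two$records$best_rank, two$records$core)
  expect_true(all(r2[shared] <= r1[shared]))
  b1 <- one$records$core[one$records$binder]
  expect_true(all(b1 %in% two$records$core[two$records$binder]))
})

test_that("the TSV predictor adapter answers from its table only", {
  tab <- data.frame(peptide = "AAAAAAAA", hla = "H1", core = "AAAAAAAA",
                    rank = 0.2)
  pred <- tsvRankPredictor(tab)
  expect_equal(pred("AAAAAAAA", "H1")$rank, 0.2)
  expect_null(pred("AAAAAAAA", "H2"))
})
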