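# Shared fixture builders; everything is generated in code.

# Exome SNV fixture: 7 clean calls and 3 violating exactly one rule each.
snvFixture <- function() {
  clean <- data.frame(
    id = sprintf("ok%02d", 1:7),
    tumor_depth = c(20, 50, 100, 200, 40, 30, 60),
    tumor_alt = c(1, 10, 20, 40, 10, 6, 30),
    normal_depth = 50, normal_alt = c(2, 0, 1, 2, 0, 1, 0))
  bad <- data.frame(
    id = c("lowvaf", "lowdepth", "normalalt"),
    tumor_depth = c(100, 19, 100),
    tumor_alt = c(4, 10, 30),     # 4% VAF; fine VAF; fine VAF
    normal_depth = 50, normal_alt = c(0, 0, 3))
  rbind(clean, bad)
}

# Independent re-statement of the exome SNV rules, for oracle comparison.
snvOracle <- function(calls) {
  (calls$tumor_alt / calls$tumor_depth >= 0.05) &
    calls$tumor_depth >= 20 & calls$normal_alt <= 2
}

# Random copy-number segment set on one chromosome.
randomSegments <- function(n, seed) {
  withr::with_seed(seed, {
    bounds <- sort(sample(1:1e6, n + 1))
    cnAbs <- stats::runif(n, 0, 8)
    copySegments("chr1", head(bounds, n) + 1, bounds[-1],
                 cnAbsolute = cnAbs, cnTotal = round(cnAbs))
  })
}

# Synthetic centroid matrix: uncorrelated unit-variance subtype profiles.
syntheticCentroids <- function(nGenes = 786, subtypes = c("CMS1", "CMS2",
                               "CMS3", "CMS4", "CMS5"), seed = 42) {
  withr::with_seed(seed,
    matrix(stats::rnorm(nGenes * length(subtypes)), nGenes,
           length(subtypes),
           dimnames = list(sprintf("g%04d", seq_len(nGenes)), subtypes)))
}

# Brute-force k-mer set-difference oracle for neopeptide enumeration.
neoOracle <- function(sTum, sGerm, lengths = 8:11) {
  windows <- function(s, k) {
    n <- nchar(s)
    if (n < k) return(character(0))
    vapply(seq_len(n - k + 1), function(i) substr(s, i, i + k - 1), "")
  }
  tum <- unique(unlist(lapply(lengths, windows, s = sTum)))
  germ <- unique(unlist(lapply(lengths, windows, s = sGerm)))
  tum[!tum %in% germ]
}

# Naive loop re-implementation of the single-sample GSEA running sum.
ssgseaOracle <- function(sample, geneSet, alpha = 0.25) {
  n <- length(sample)
  r <- rank(sample, ties.method = "average")
  ord <- order(sample, decreasing = TRUE)
  inSet <- names(sample)[ord] %in% geneSet
  w <- unname(abs(r[ord])^alpha)
  sumW <- sum(w[inSet])
  nOut <- sum(!inSet)
  pin <- 0; pout <- 0; es <- 0
  for (i in seq_len(n)) {
    if (inSet[i]) pin <- pin + w[i] / sumW else pout <- pout + 1 / nOut
    es <- es + (pin - pout)
  }
  es
}

randomProtein <- function(n, seed = NULL) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(aa, n, replace = TRUE), collapse = "")
}
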