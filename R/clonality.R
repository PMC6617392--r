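## Copy-number-aware CCF algebra: ctDNA purity anchoring, per-driver
## cancer-cell fractions and the per-sample resistance gap.

#' Estimate the cancer cell fraction of a mutation from its VAF
#'
#' Converts a variant allele fraction into the fraction of cancer cells
#' carrying the mutation, correcting for the local copy-number state:
#' \deqn{CCF = \frac{2\,VAF}{C_{mut} + 2\,VAF - VAF \cdot C_{tot}}}
#' where \eqn{C_{mut}} is the number of copies carrying the mutation and
#' \eqn{C_{tot}} the absolute local copy number. The denominator assumes two
#' copies of the locus in admixed normal cells. Raw values above 1 (sampling
#' noise) are capped at 1 and flagged.
#'
#' All arguments are recycled to a common length, so a whole variant table can
#' be converted in one call.
#'
#' @param vaf numeric, variant allele fraction(s) in [0, 1].
#' @param copiesMutated integer, copies carrying the mutation (>= 1).
#' @param copiesTotal integer, local total copy number (>= copiesMutated).
#' @return A [CcfEstimate-class] with one element per input variant and
#'   status \code{"unassigned"} (see [assignClonalStatus()]).
#' @examples
#' ccf(estimateCcf(0.5, 1, 2))   # clonal heterozygous diploid -> 1
#' ccf(estimateCcf(0.25, 1, 2))  # half the cancer cells -> 0.5
#' @seealso [expectedClonalVaf()] for the inverse map,
#'   [mutationMultiplicity()] for the purity-based allele count.
#' @export
estimateCcf <- function(vaf, copiesMutated, copiesTotal) {
  n <- max(length(vaf), length(copiesMutated), length(copiesTotal))
  vaf <- rep_len(vaf, n)
  m <- rep_len(copiesMutated, n)
  t <- rep_len(copiesTotal, n)
  assertProb(vaf, "vaf")
  if (!all(isWholeNumber(m)) || any(m < 1))
    stop("'copiesMutated' must be integer >= 1")
  if (!all(isWholeNumber(t)) || any(t < m))
    stop("'copiesTotal' must be integer >= copiesMutated")
  denom <- m + 2 * vaf - vaf * t
  if (any(denom <= 0))
    stop("inconsistent copy state: CCF denominator <= 0 ",
         "(VAF too high for the given copy numbers)")
  raw <- 2 * vaf / denom
  raw[vaf == 0] <- 0
  capped <- raw > 1
  new("CcfEstimate", ccf = pmin(raw, 1), capped = capped,
      copiesMutated = as.integer(m), copiesTotal = as.integer(t),
      sourceVaf = vaf, status = rep("unassigned", n))
}

#' Expected VAF of a fully clonal mutation at a given sample CCF
#'
#' The algebraic inverse of [estimateCcf()]:
#' \deqn{VAF = \frac{CCF \cdot C_{mut}}{CCF \cdot C_{tot} + 2 - 2\,CCF}}
#' Used to predict the allele fraction a 100\%-clonal mutation would show in a
#' sample whose cancer-cell (or ctDNA) fraction is \code{ccf}, given its local
#' copy-number state.
#'
#' @param ccf numeric, cancer cell fraction(s) in [0, 1].
#' @param copiesMutated integer, copies carrying the mutation (>= 1).
#' @param copiesTotal integer, local total copy number (>= copiesMutated).
#' @return numeric VAF values in [0, 1].
#' @examples
#' expectedClonalVaf(1, 1, 2)  # 0.5
#' @export
expectedClonalVaf <- function(ccf, copiesMutated, copiesTotal) {
  n <- max(length(ccf), length(copiesMutated), length(copiesTotal))
  ccf <- rep_len(ccf, n)
  m <- rep_len(copiesMutated, n)
  t <- rep_len(copiesTotal, n)
  assertProb(ccf, "ccf")
  if (!all(isWholeNumber(m)) || any(m < 1))
    stop("'copiesMutated' must be integer >= 1")
  if (!all(isWholeNumber(t)) || any(t < m))
    stop("'copiesTotal' must be integer >= copiesMutated")
  denom <- ccf * t + 2 - 2 * ccf
  if (any(denom <= 0)) stop("inconsistent copy state: denominator <= 0")
  ccf * m / denom
}

#' Anchor ctDNA purity on truncal TP53 mutations
#'
#' Estimates the fraction of cell-free DNA of cancer-cell origin from the
#' VAF(s) of the sample's truncal TP53 mutation(s) and the TP53 locus
#' copy-number state taken from the matched biopsy. Under TP53 loss of
#' heterozygosity the mutated and total copies are equal. When a tumor
#' carries two TP53 mutations (biallelic inactivation through two events),
#' the VAFs are summed and the summed mutated / chromosome-17p total copies
#' are used; the result carries a \code{combined} flag.
#'
#' @param tp53Vaf numeric, VAF of each TP53 mutation in the ctDNA sample.
#' @param copiesMutated integer, per mutation, biopsy copies carrying it.
#' @param copiesTotal integer, per mutation, total copies of its locus.
#' @return A [CtdnaPurity-class]; extract the purity with [purity()].
#' @examples
#' purity(estimateCtdnaPurity(0.4, 1, 1))  # TP53 LOH anchor -> 0.5714
#' @export
estimateCtdnaPurity <- function(tp53Vaf, copiesMutated, copiesTotal) {
  if (length(tp53Vaf) < 1L)
    stop("purity anchor unavailable: no TP53 variant supplied")
  n <- length(tp53Vaf)
  copiesMutated <- rep_len(copiesMutated, n)
  copiesTotal <- rep_len(copiesTotal, n)
  combined <- n > 1L
  est <- if (combined) {
    estimateCcf(sum(tp53Vaf), sum(copiesMutated), sum(copiesTotal))
  } else {
    estimateCcf(tp53Vaf, copiesMutated, copiesTotal)
  }
  new("CtdnaPurity", ccfSample = ccf(est), anchorVafs = tp53Vaf,
      combined = combined, capped = ccfCapped(est))
}

#' Fraction of sampled cancer cells carrying a resistance driver
#'
#' Divides a driver mutation's observed VAF by the VAF expected for a
#' mutation that is 100\% clonal given the ctDNA purity and the driver
#' locus copy number, assuming the driver is mutated on a single copy
#' (\eqn{C_{mut} = 1}; resistance drivers act dominantly, and this choice
#' maximizes the estimated driver-bearing fraction, making the resulting
#' resistance gap conservative). Fractions above 1 are capped.
#'
#' @param vaf numeric, observed driver VAF(s).
#' @param purity a [CtdnaPurity-class] or the purity value itself.
#' @param copiesTotal integer, total copy number at each driver locus
#'   (biopsy-matched integer state).
#' @return numeric fractions in [0, 1], with attribute \code{"capped"}
#'   (logical vector) marking raw values above 1.
#' @examples
#' driverFraction(0.05, estimateCtdnaPurity(0.4, 1, 1), 2)  # 0.175
#' @export
driverFraction <- function(vaf, purity, copiesTotal) {
  p <- if (is(purity, "CtdnaPurity")) purity@ccfSample else purity
  assertProb(p, "purity")
  if (p == 0) stop("undefined driver fraction: ctDNA purity is 0")
  assertProb(vaf, "vaf")
  expect <- expectedClonalVaf(p, 1L, copiesTotal)
  raw <- vaf / expect
  out <- pmin(raw, 1)
  attr(out, "capped") <- raw > 1
  out
}

#' Sum driver fractions and compute the resistance gap
#'
#' The maximum fraction of cancer cells harboring any detected resistance
#' driver is estimated as the sum of the per-driver fractions, capped at 1;
#' the resistance gap is its complement -- the fraction of sampled cancer
#' cells with no detectable resistance mechanism. A sample without detected
#' drivers has a gap of 1.
#'
#' @param fractions numeric, per-driver cancer-cell fractions in [0, 1]
#'   (e.g. from [driverFraction()]); may be empty and may be named.
#' @return A [ResistanceGapResult-class]; extract with [gap()],
#'   [totalDriverFraction()] and [driverFractions()].
#' @examples
#' gap(resistanceGap(c(KRAS_G12D = 0.175)))  # 0.825
#' gap(resistanceGap(numeric(0)))            # no drivers detected -> 1
#' @export
resistanceGap <- function(fractions) {
  fractions <- as.numeric2(fractions)
  assertProb(fractions, "fractions")
  total <- sum(fractions)
  capped <- total > 1
  total <- min(total, 1)
  new("ResistanceGapResult", driverFractions = fractions,
      totalDriverFraction = total, gap = 1 - total, capped = capped)
}

## strips attributes (e.g. the 'capped' attr from driverFraction) but keeps
## names, so ResistanceGapResult slots validate cleanly
#' @noRd
as.numeric2 <- function(x) {
  out <- as.vector(x, mode = "numeric")
  names(out) <- names(x)
  out
}

#' Approximate a sample's cancer cell content from somatic VAFs
#'
#' Most somatic mutations are heterozygous and thus present in half of the
#' cancer cells' DNA copies, so twice the VAF approximates the fraction of
#' cancer cells in the sample. The per-sample summary aggregates over
#' mutations with the median (robust to the subclonal tail) and caps at 1.
#' Samples below 10\% estimated content are flagged for exclusion because
#' typical sequencing depth is insufficient to detect their mutations
#' reliably.
#'
#' @param vafs numeric, somatic mutation VAFs of one sample (>= 1 value).
#' @param minContent numeric(1), exclusion threshold (default 0.10).
#' @return list with \code{content} (capped at 1), \code{included} (logical:
#'   content >= \code{minContent}) and \code{threshold}.
#' @examples
#' estimateCancerCellContent(c(0.2, 0.25, 0.3))$content  # 0.5
#' @export
estimateCancerCellContent <- function(vafs, minContent = 0.10) {
  if (length(vafs) < 1L) stop("at least one somatic VAF is required")
  assertProb(vafs, "vafs")
  content <- min(2 * stats::median(vafs), 1)
  list(content = content, included = content >= minContent,
       threshold = minContent)
}

#' Mutation copy number (multiplicity) from VAF, purity and local copies
#'
#' The unrounded number of alleles per cancer cell carrying a mutation:
#' \deqn{mult = VAF \cdot \frac{purity \cdot C_{tot} + 2 (1 - purity)}{purity}}
#' A truncal heterozygous diploid mutation in a pure sample has multiplicity
#' 1; values near 2 indicate mutation of both copies or amplification of the
#' mutant allele.
#'
#' @param vaf numeric, variant allele fraction(s).
#' @param purity numeric(1), tumor purity in (0, 1].
#' @param copiesTotal integer, local total copy number (>= 1).
#' @return numeric multiplicities (unrounded allele counts).
#' @examples
#' mutationMultiplicity(0.25, 0.5, 2)  # 1
#' @export
mutationMultiplicity <- function(vaf, purity, copiesTotal) {
  assertProb(vaf, "vaf")
  if (length(purity) != 1L || purity <= 0 || purity > 1)
    stop("'purity' must be a single value in (0, 1]")
  if (!all(isWholeNumber(copiesTotal)) || any(copiesTotal < 1))
    stop("'copiesTotal' must be integer >= 1")
  vaf * (purity * copiesTotal + 2 * (1 - purity)) / purity
}

#' Assign clonal / subclonal status from a binomial confidence interval
#'
#' A variant is called clonal when the 95\% binomial confidence interval of
#' its CCF includes 1, i.e. when the read counts cannot exclude full
#' clonality; otherwise subclonal. The interval is obtained by computing the
#' exact (Clopper-Pearson) binomial interval on the VAF at the observed depth
#' and mapping its endpoints through the CCF transform, which is monotone
#' increasing in VAF for a fixed copy state. Zero depth yields
#' \code{"unassigned"}.
#'
#' This is a deliberate simplification of full phylogenetic CCF-clustering
#' machinery: adequate for deep targeted data and synthetic validation.
#'
#' @param est a [CcfEstimate-class].
#' @param depth integer, per-variant read depth used for the interval.
#' @param conf numeric(1), confidence level (default 0.95).
#' @return The input [CcfEstimate-class] with \code{clonalStatus()} filled in.
#' @examples
#' clonalStatus(assignClonalStatus(estimateCcf(0.5, 1, 2), 1000))
#' @export
assignClonalStatus <- function(est, depth, conf = 0.95) {
  stopifnot(is(est, "CcfEstimate"))
  n <- length(est@ccf)
  depth <- rep_len(depth, n)
  status <- character(n)
  for (i in seq_len(n)) {
    if (is.na(depth[i]) || depth[i] < 1) {
      status[i] <- "unassigned"
      next
    }
    alt <- round(est@sourceVaf[i] * depth[i])
    ciHi <- stats::binom.test(alt, depth[i],
                              conf.level = conf)$conf.int[2]
    m <- est@copiesMutated[i]
    t <- est@copiesTotal[i]
    ## map upper VAF bound to CCF; monotone in VAF while denominator > 0
    denom <- m + 2 * ciHi - ciHi * t
    ccfHi <- if (denom <= 0) Inf else 2 * ciHi / denom
    status[i] <- if (ccfHi >= 1) "clonal" else "subclonal"
  }
  est@status <- status
  validObject(est)
  est
}
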