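## Ploidy and copy-number-aberration calling on segmented allele-specific
## copy number, and acquired-amplification detection between paired biopsies.
## Segments live in a GRanges with metadata columns cnAbsolute (unrounded
## total copies), cnTotal (nearest-integer total) and cnMinor (integer minor
## allele copies). Coordinates are 1-based inclusive.

#' Build a copy-number segment GRanges
#'
#' @param chrom character, chromosome per segment.
#' @param start,end integer, 1-based inclusive segment bounds.
#' @param cnAbsolute numeric, unrounded total copy number.
#' @param cnTotal integer, nearest-integer total copies; defaults to
#'   \code{round(cnAbsolute)} (half-to-even).
#' @param cnMinor integer, minor-allele copies; defaults to NA. Must satisfy
#'   \code{cnMinor <= cnTotal - cnMinor}.
#' @return GRanges with mcols \code{cnAbsolute}, \code{cnTotal},
#'   \code{cnMinor}.
#' @examples
#' copySegments("chr17", 1, 1e6, cnAbsolute = 1.1, cnMinor = 0L)
#' @export
copySegments <- function(chrom, start, end, cnAbsolute,
                         cnTotal = round(cnAbsolute), cnMinor = NA_integer_) {
  if (any(end < start)) stop("segment end must be >= start")
  if (any(cnTotal < 0)) stop("copy number must be >= 0")
  ok <- is.na(cnMinor) | cnMinor <= cnTotal - cnMinor
  if (!all(ok)) stop("'cnMinor' must not exceed cnTotal - cnMinor")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  S4Vectors::mcols(gr)$cnAbsolute <- cnAbsolute
  S4Vectors::mcols(gr)$cnTotal <- as.integer(cnTotal)
  S4Vectors::mcols(gr)$cnMinor <- as.integer(cnMinor)
  gr
}

#' @noRd
segmentsFromDataFrame <- function(df) {
  copySegments(df$chrom, df$start, df$end, df$cnAbsolute,
               if (is.null(df$cnTotal)) round(df$cnAbsolute) else df$cnTotal,
               if (is.null(df$cnMinor)) NA_integer_ else df$cnMinor)
}

#' Length-weighted mean copy number (ploidy) of a segmented sample
#'
#' \deqn{Ploidy = \frac{\sum_s CN_{abs}(s) \cdot len(s)}{\sum_s len(s)}}
#' where the sums run over segments, \eqn{CN_{abs}} is the unrounded absolute
#' copy number and \eqn{len} the segment length in bp. Invariant under
#' splitting any segment into pieces with the same copy number.
#'
#' @param segments GRanges from [copySegments()] (or a data.frame with
#'   \code{chrom}, \code{start}, \code{end}, \code{cnAbsolute}).
#' @return A [PloidyEstimate-class].
#' @examples
#' seg <- copySegments("chr1", c(1, 101), c(100, 200), c(2, 4))
#' ploidy(computePloidy(seg))  # 3
#' @export
computePloidy <- function(segments) {
  if (is.data.frame(segments)) segments <- segmentsFromDataFrame(segments)
  if (length(segments) == 0L)
    stop("cannot compute ploidy from an empty segment list")
  w <- as.numeric(GenomicRanges::width(segments))
  cn <- S4Vectors::mcols(segments)$cnAbsolute
  new("PloidyEstimate", ploidy = sum(cn * w) / sum(w))
}

#' Classify segments as amplification, loss, homozygous deletion or neutral
#'
#' An amplification is a 3-fold or greater increase on the sample's ploidy
#' (integer copy number at or above \code{round(3 * ploidy)}), a substantial
#' loss a 3-fold or greater decrease (\code{round(ploidy / 3)} or below, but
#' above zero), and a homozygous deletion CN = 0. Thresholds are rounded to
#' the nearest integer copy state with half-to-even tie handling.
#'
#' @param cnTotal integer vector of segment (or gene) total copy numbers, or
#'   a GRanges from [copySegments()].
#' @param ploidy a [PloidyEstimate-class] or the ploidy value itself.
#' @return character vector: \code{"amplification"},
#'   \code{"substantial_loss"}, \code{"homozygous_deletion"} or
#'   \code{"neutral"}.
#' @examples
#' classifyCna(c(6, 2, 0), 2)  # amplification, neutral, homozygous_deletion
#' @export
classifyCna <- function(cnTotal, ploidy) {
  if (is(cnTotal, "GRanges")) cnTotal <- S4Vectors::mcols(cnTotal)$cnTotal
  p <- if (is(ploidy, "PloidyEstimate")) ploidy@ploidy else ploidy
  if (any(cnTotal < 0, na.rm = TRUE)) stop("negative copy number")
  ampAt <- roundHalfEven(3 * p)
  lossAt <- roundHalfEven(p / 3)
  out <- rep("neutral", length(cnTotal))
  out[cnTotal <= lossAt] <- "substantial_loss"
  out[cnTotal >= ampAt] <- "amplification"
  out[cnTotal == 0] <- "homozygous_deletion"
  out[is.na(cnTotal)] <- NA_character_
  out
}

#' Gene-level integer copy number from overlapping segments
#'
#' Genes can straddle segment breakpoints; the gene-level state is the
#' length-weighted mode of the overlapping segments' integer copy numbers.
#' Genes not covered by any segment get NA (uncallable), never 0.
#'
#' @param segments GRanges from [copySegments()].
#' @param genes named GRanges of gene intervals (names = gene symbols).
#' @return named integer vector of per-gene copy number (NA = uncallable).
#' @export
geneCopyNumber <- function(segments, genes) {
  hits <- GenomicRanges::findOverlaps(genes, segments)
  ov <- GenomicRanges::pintersect(
    genes[S4Vectors::queryHits(hits)], segments[S4Vectors::subjectHits(hits)])
  w <- GenomicRanges::width(ov)
  cn <- S4Vectors::mcols(segments)$cnTotal[S4Vectors::subjectHits(hits)]
  out <- rep(NA_integer_, length(genes))
  names(out) <- names(genes)
  for (i in unique(S4Vectors::queryHits(hits))) {
    sel <- S4Vectors::queryHits(hits) == i
    tab <- tapply(w[sel], cn[sel], sum)
    out[i] <- as.integer(names(tab)[which.max(tab)])
  }
  out
}

#' Acquired amplifications between baseline and progression biopsies
#'
#' Compares a baseline (BL) and a progression (PD) copy-number profile from
#' one patient and reports genes that are amplified at PD but not at BL,
#' each sample classified against its own ploidy. Genes without segment
#' coverage in either sample are reported as uncallable rather than
#' non-amplified.
#'
#' @param baseline,progression GRanges from [copySegments()].
#' @param genes named GRanges of gene intervals.
#' @return data.frame with per-gene BL/PD copy number and class,
#'   \code{callable}, and logical \code{acquired_amp}; acquired genes are
#'   \code{gene[acquired_amp]}.
#' @examples
#' bl <- copySegments("chr7", 1, 2e6, 2)
#' pd <- copySegments("chr7", 1, 2e6, 60)
#' genes <- GenomicRanges::GRanges("chr7",
#'   IRanges::IRanges(5e5, 6e5, names = "EGFR"))
#' detectAcquiredAmps(bl, pd, genes)
#' @export
detectAcquiredAmps <- function(baseline, progression, genes) {
  blP <- computePloidy(baseline)
  pdP <- computePloidy(progression)
  blCn <- geneCopyNumber(baseline, genes)
  pdCn <- geneCopyNumber(progression, genes)
  blClass <- classifyCna(blCn, blP)
  pdClass <- classifyCna(pdCn, pdP)
  callable <- !is.na(blCn) & !is.na(pdCn)
  data.frame(gene = names(genes), bl_cn = blCn, pd_cn = pdCn,
    bl_class = blClass, pd_class = pdClass, callable = callable,
    acquired_amp = callable & pdClass == "amplification" &
      blClass != "amplification",
    row.names = NULL)
}

#' Harmonize a genome-doubled biopsy pair
#'
#' When one sample of a BL/PD pair has close to double the ploidy of the
#' other and the copy-number profiles are highly similar after doubling the
#' lower profile (suggestive of a genome-doubling event), the lower sample's
#' integer copy numbers are doubled so changes between the two timepoints can
#' be compared directly. Similarity is the length-weighted Pearson
#' correlation of integer copy number over the disjoint bins shared by both
#' profiles; zero-variance profiles fall back to the exact-agreement
#' fraction.
#'
#' @param first,second GRanges from [copySegments()], one biopsy pair.
#' @param ratioWindow numeric(2), admissible higher/lower ploidy ratio
#'   (default \code{c(1.8, 2.2)}).
#' @param corThreshold numeric(1), minimum doubled-profile similarity
#'   (default 0.9).
#' @return list with elements \code{first}, \code{second} (adjusted
#'   segments), \code{doubled} (\code{"first"}, \code{"second"} or
#'   \code{NA}) and \code{flag} (logical).
#' @export
harmonizeGenomeDoubling <- function(first, second,
                                    ratioWindow = c(1.8, 2.2),
                                    corThreshold = 0.9) {
  p1 <- ploidy(computePloidy(first))
  p2 <- ploidy(computePloidy(second))
  lowIsFirst <- p1 <= p2
  ratio <- max(p1, p2) / min(p1, p2)
  out <- list(first = first, second = second, doubled = NA_character_,
              flag = FALSE)
  if (ratio < ratioWindow[1] || ratio > ratioWindow[2]) return(out)
  low <- if (lowIsFirst) first else second
  high <- if (lowIsFirst) second else first
  ## integer CN of both profiles over shared disjoint bins
  bins <- GenomicRanges::disjoin(c(GenomicRanges::granges(low),
                                   GenomicRanges::granges(high)))
  cnAt <- function(segs) {
    hit <- GenomicRanges::findOverlaps(bins, segs, select = "first")
    S4Vectors::mcols(segs)$cnTotal[hit]
  }
  cnLow <- cnAt(low)
  cnHigh <- cnAt(high)
  keep <- !is.na(cnLow) & !is.na(cnHigh)
  if (!any(keep)) return(out)
  w <- as.numeric(GenomicRanges::width(bins))[keep]
  x <- 2 * cnLow[keep]
  y <- cnHigh[keep]
  sim <- weightedSimilarity(x, y, w)
  if (sim < corThreshold) return(out)
  S4Vectors::mcols(low)$cnTotal <- 2L * S4Vectors::mcols(low)$cnTotal
  S4Vectors::mcols(low)$cnAbsolute <- 2 * S4Vectors::mcols(low)$cnAbsolute
  if (!all(is.na(S4Vectors::mcols(low)$cnMinor)))
    S4Vectors::mcols(low)$cnMinor <- 2L * S4Vectors::mcols(low)$cnMinor
  if (lowIsFirst) out$first <- low else out$second <- low
  out$doubled <- if (lowIsFirst) "first" else "second"
  out$flag <- TRUE
  out
}

## Length-weighted Pearson correlation; exact-agreement fraction when either
## profile has zero weighted variance.
#' @noRd
weightedSimilarity <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx < 1e-12 || vy < 1e-12) return(sum(w * (x == y)))
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}
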