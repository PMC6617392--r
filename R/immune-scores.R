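## Per-sample immune infiltrate metrics and paired BL/PD comparisons.

#' Cytolytic activity (CYT)
#'
#' The geometric mean of the normalized expression of GZMA and PRF1, each
#' offset by 1: \code{sqrt((gzma + 1) * (prf1 + 1))}. With nonnegative
#' expression the score is bounded below by 1. Symmetric and monotone in
#' both arguments.
#'
#' @param gzma,prf1 numeric, normalized expression values (>= 0); recycled.
#' @return numeric CYT score(s).
#' @examples
#' cytolyticActivity(3, 8)  # 6
#' @export
cytolyticActivity <- function(gzma, prf1) {
  if (any(gzma < 0) || any(prf1 < 0))
    stop("normalized expression must be >= 0")
  sqrt((gzma + 1) * (prf1 + 1))
}

#' Mean-expression signature score
#'
#' The arithmetic mean of the normalized expression of the signature genes
#' present in the sample (the BATF3-dendritic-cell signature is scored this
#' way). The fraction of signature genes present is attached as the
#' \code{"coverage"} attribute.
#'
#' @param sample named numeric expression vector.
#' @param genes character, signature gene identifiers.
#' @return numeric(1) score with attribute \code{coverage}.
#' @examples
#' x <- c(BATF3 = 2, XCR1 = 4, CLEC9A = 6)
#' signatureMean(x, c("BATF3", "XCR1", "CLEC9A"))  # 4
#' @export
signatureMean <- function(sample, genes) {
  present <- intersect(genes, names(sample))
  if (length(present) == 0L)
    stop("no signature gene present in the sample")
  out <- mean(sample[present])
  attr(out, "coverage") <- length(present) / length(genes)
  out
}

#' Single-sample GSEA enrichment score
#'
#' Barbie-style single-sample enrichment: genes are ordered by decreasing
#' expression; at each position the running difference between the weighted
#' in-set empirical distribution (weight = rank value to the power
#' \code{alpha}, where the highest-expressed gene has rank N) and the
#' unweighted out-of-set distribution is accumulated, and the enrichment
#' score is the total of that running sum. \code{alpha = 0.25} is the
#' conventional default. Scores are single-sample quantities; no cohort-wide
#' rescaling is applied.
#'
#' @param sample named numeric expression vector (>= 2 distinct values).
#' @param geneSet character, gene identifiers (>= 1 present in the sample).
#' @param alpha numeric(1), rank weight exponent (default 0.25).
#' @return numeric(1) enrichment score.
#' @examples
#' x <- stats::setNames(seq(10, 1), paste0("g", 1:10))
#' ssgseaScore(x, paste0("g", 1:3)) > 0  # top-expressed set enriches
#' @export
ssgseaScore <- function(sample, geneSet, alpha = 0.25) {
  if (length(unique(sample)) < 2L)
    stop("sample needs at least 2 distinct expression values")
  inSet <- names(sample) %in% geneSet
  if (!any(inSet)) stop("no gene-set member present in the sample")
  n <- length(sample)
  r <- rank(sample, ties.method = "average") # N for the most expressed
  ord <- order(sample, decreasing = TRUE)
  w <- abs(r[ord])^alpha
  inOrd <- inSet[ord]
  stepIn <- w * inOrd
  pIn <- cumsum(stepIn) / sum(stepIn)
  nOut <- n - sum(inOrd)
  pOut <- if (nOut == 0) rep(0, n) else cumsum(!inOrd) / nOut
  sum(pIn - pOut)
}

#' Marker-gene mean abundance
#'
#' Generic cell-population abundance score: the mean of \code{log2(x + 1)}
#' over the marker genes present in the sample. Serves as the package's
#' plumbing for marker-based abundance estimates (e.g. fibroblast markers).
#'
#' @param sample named numeric expression vector (linear scale, >= 0).
#' @param markers character, marker gene identifiers (>= 1 present).
#' @return numeric(1) abundance score.
#' @examples
#' markerMeanAbundance(c(ACTA2 = 3, FAP = 3), c("ACTA2", "FAP"))  # 2
#' @export
markerMeanAbundance <- function(sample, markers) {
  present <- intersect(markers, names(sample))
  if (length(present) == 0L) stop("no marker gene present in the sample")
  mean(log2(sample[present] + 1))
}

#' Paired BL/PD score comparisons
#'
#' Compares per-score values between baseline and progression samples.
#' \code{"paired_t"} applies the paired Student's t-test per score;
#' \code{"mann_whitney_fdr"} applies the Mann-Whitney (Wilcoxon rank-sum)
#' test per score followed by Benjamini-Hochberg FDR correction, with
#' significance at q <= 0.1. Identical paired vectors (zero variance of the
#' differences) are reported with p = 1 and flagged; a constant nonzero
#' shift with zero variance is reported at the smallest representable p and
#' flagged.
#'
#' @param bl,pd numeric matrices, scores x samples, equal dimnames; columns
#'   are patient-aligned pairs.
#' @param method \code{"paired_t"} or \code{"mann_whitney_fdr"}.
#' @param maxQ numeric(1), significance threshold on q (default 0.1).
#' @return data.frame per score: \code{statistic}, \code{p}, \code{flag};
#'   plus \code{q} and \code{significant} for the FDR method.
#' @examples
#' bl <- matrix(rnorm(20), 2, 10, dimnames = list(c("CYT", "DC"), NULL))
#' pairedChangeTests(bl, bl + 1, method = "paired_t")
#' @export
pairedChangeTests <- function(bl, pd,
    method = c("paired_t", "mann_whitney_fdr"), maxQ = 0.1) {
  method <- match.arg(method)
  stopifnot(is.matrix(bl), is.matrix(pd), all(dim(bl) == dim(pd)))
  if (ncol(bl) < 2L) stop("at least 2 BL/PD pairs are required")
  scores <- rownames(bl) %||% paste0("score", seq_len(nrow(bl)))
  res <- lapply(seq_len(nrow(bl)), function(i) {
    x <- bl[i, ]
    y <- pd[i, ]
    if (method == "paired_t") {
      d <- y - x
      ## tolerance catches exact constant shifts whose differences carry
      ## floating-point residue (t.test would abort on them)
      if (stats::sd(d) <= sqrt(.Machine$double.eps) * (abs(mean(d)) + 1)) {
        if (all(d == 0))
          return(data.frame(statistic = 0, p = 1, flag = "zero_variance"))
        return(data.frame(statistic = sign(mean(d)) * Inf,
                          p = .Machine$double.xmin,
                          flag = "zero_variance_shift"))
      }
      tt <- stats::t.test(y, x, paired = TRUE)
      data.frame(statistic = unname(tt$statistic), p = tt$p.value,
                 flag = "")
    } else {
      wt <- suppressWarnings(stats::wilcox.test(y, x))
      data.frame(statistic = unname(wt$statistic), p = wt$p.value,
                 flag = "")
    }
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(score = scores), out)
  if (method == "mann_whitney_fdr") {
    out$q <- stats::p.adjust(out$p, method = "BH")
    out$significant <- out$q <= maxQ
  }
  rownames(out) <- NULL
  out
}
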