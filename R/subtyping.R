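## Transcriptomic subtype assignment: centroid correlation (CRCassigner
## style) and nearest-template prediction with permutation confidence (CMS
## style), plus switch detection between paired biopsies and the low-count
## gene filter.

#' Quantile-normalize and/or row-median-center an expression matrix
#'
#' \code{"quantile_log"} applies \code{limma::normalizeQuantiles(log2(x +
#' 0.25))} so all columns share a common quantile distribution;
#' \code{"median_center"} subtracts each gene row's median so every row has
#' median 0. The subtyping pipeline applies both in that order, matching the
#' preprocessing expected by published centroid signatures.
#'
#' @param expr numeric matrix, genes x samples.
#' @param mode character, any of \code{"quantile_log"},
#'   \code{"median_center"}; applied in the given order.
#' @return The transformed matrix.
#' @examples
#' m <- matrix(c(1, 2, 3, 3, 2, 1), 3, 2)
#' normalizeAndCenter(m, "median_center")
#' @export
normalizeAndCenter <- function(expr,
    mode = c("quantile_log", "median_center")) {
  stopifnot(is.matrix(expr))
  if (all(expr == 0)) stop("all-zero expression matrix")
  mode <- match.arg(mode, c("quantile_log", "median_center"),
                    several.ok = TRUE)
  for (m in mode) {
    expr <- switch(m,
      quantile_log = {
        if (any(expr < 0)) stop("'quantile_log' needs nonnegative counts")
        limma::normalizeQuantiles(log2(expr + 0.25))
      },
      median_center = expr - apply(expr, 1, stats::median))
  }
  expr
}

#' Assign a subtype by highest centroid correlation
#'
#' Computes the Pearson correlation of a sample's expression with each
#' subtype centroid over the genes shared between sample and centroid matrix
#' and assigns the subtype with the highest correlation. The call is low
#' confidence when the best correlation is below 0.15 or its lead over the
#' second best is below 0.06. Requires at least \code{minOverlap} of the
#' centroid genes to be present. Correlation ties are broken toward the
#' lexicographically smallest label (logged).
#'
#' @param sample named numeric vector of (normalized, centered) expression.
#' @param centroids numeric matrix, genes x subtypes, with dimnames.
#' @param minOverlap numeric(1), minimum fraction of centroid genes present
#'   (default 0.5).
#' @param minCor,minGap confidence thresholds (defaults 0.15 and 0.06).
#' @return A [SubtypeCall-class] with \code{method = "centroid_correlation"}.
#' @examples
#' cen <- matrix(rnorm(100), 50, 2,
#'   dimnames = list(paste0("g", 1:50), c("TA", "SL")))
#' call <- assignCentroidSubtype(cen[, "TA"], cen)
#' subtypeLabel(call); callConfidence(call)
#' @export
assignCentroidSubtype <- function(sample, centroids, minOverlap = 0.5,
                                  minCor = 0.15, minGap = 0.06) {
  stopifnot(is.matrix(centroids), !is.null(rownames(centroids)))
  shared <- intersect(names(sample), rownames(centroids))
  if (length(shared) < minOverlap * nrow(centroids)) {
    miss <- setdiff(rownames(centroids), names(sample))
    stop("only ", length(shared), "/", nrow(centroids), " centroid genes ",
         "present; missing e.g. ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  r <- apply(centroids[shared, , drop = FALSE], 2,
             function(cen) stats::cor(sample[shared], cen))
  ord <- order(-r, names(r)) # ties -> lexicographically smallest label
  best <- names(r)[ord[1]]
  if (sum(r == r[ord[1]]) > 1L)
    message("correlation tie broken toward '", best, "'")
  low <- r[ord[1]] < minCor || (r[ord[1]] - r[ord[2]]) < minGap
  new("SubtypeCall", label = best, scores = r,
      confidence = if (low) "low" else "high",
      method = "centroid_correlation")
}

#' Assign a subtype by nearest-template prediction with permutation q-value
#'
#' Builds, for each subtype, a template indicator vector over the union of
#' all template genes (1 for the subtype's markers, 0 elsewhere), computes
#' the cosine distance (1 - cosine similarity) between the sample and each
#' template, and assigns the subtype with the shortest distance. Confidence
#' comes from permuting the sample's gene labels \code{nPermutations} times:
#' the q-value is the empirical tail probability \eqn{(1 + b) / (1 + n)} of
#' observing a distance at most as small as the real one; the call is low
#' confidence when q exceeds 0.01.
#'
#' @param sample named numeric vector of (normalized, centered) expression.
#' @param templates named list of character vectors, marker genes per
#'   subtype.
#' @param nPermutations integer(1), permutation count (default 1000).
#' @param seed integer(1), seed for the permutation stream.
#' @param minOverlap numeric(1), required fraction of each template's genes
#'   present in the sample (default 0.5).
#' @param maxQ numeric(1), low-confidence threshold (default 0.01).
#' @return A [SubtypeCall-class] with \code{method = "nearest_template"} and
#'   the permutation q in \code{qvalue()}; \code{subtypeScores()} holds the
#'   per-subtype distances.
#' @examples
#' templates <- list(CMS2 = paste0("g", 1:20), CMS4 = paste0("g", 21:40))
#' x <- stats::setNames(c(rep(2, 20), rep(0, 20)), paste0("g", 1:40))
#' call <- assignNearestTemplate(x, templates, nPermutations = 200, seed = 5)
#' subtypeLabel(call)
#' @export
assignNearestTemplate <- function(sample, templates, nPermutations = 1000L,
                                  seed = 1L, minOverlap = 0.5,
                                  maxQ = 0.01) {
  stopifnot(length(templates) >= 1L, !is.null(names(templates)))
  if (stats::sd(sample) == 0) stop("zero-variance sample")
  union <- unique(unlist(templates))
  covered <- vapply(templates, function(g) mean(g %in% names(sample)),
                    numeric(1))
  if (any(covered < minOverlap))
    stop("sample covers < ", minOverlap * 100, "% of template gene(s) for: ",
         paste(names(templates)[covered < minOverlap], collapse = ", "))
  genes <- intersect(union, names(sample))
  x <- sample[genes]
  dist1 <- function(v) {
    vapply(templates, function(g) {
      ind <- as.numeric(genes %in% g)
      1 - sum(v * ind) / (sqrt(sum(v^2)) * sqrt(sum(ind^2)))
    }, numeric(1))
  }
  d <- dist1(x)
  best <- which.min(d)
  obs <- d[best]
  hits <- withSeed(deriveSeed(seed, "ntp"), {
    sum(vapply(seq_len(nPermutations), function(i) {
      min(dist1(base::sample(x))) <= obs
    }, logical(1)))
  })
  q <- (1 + hits) / (1 + nPermutations)
  new("SubtypeCall", label = names(templates)[best], scores = d,
      confidence = if (q > maxQ) "low" else "high",
      method = "nearest_template", qvalue = q)
}

#' Detect a subtype switch between baseline and progression
#'
#' Compares the subtype calls of a patient's baseline (BL) and progression
#' (PD) biopsies, which must come from the same classification method, and
#' flags the two transitions of particular interest: CMS2 to CMS4 (loss of
#' the therapy-sensitive canonical subtype) and transit-amplifying (TA) to
#' stem-like (SL).
#'
#' @param bl,pd [SubtypeCall-class] objects for the BL and PD biopsies.
#' @return list with \code{from}, \code{to}, \code{switched},
#'   \code{is_cms2_to_4}, \code{is_ta_to_sl}, and the BL/PD confidences.
#' @examples
#' # detectSubtypeSwitch(blCall, pdCall)$is_cms2_to_4
#' @export
detectSubtypeSwitch <- function(bl, pd) {
  stopifnot(is(bl, "SubtypeCall"), is(pd, "SubtypeCall"))
  if (callMethod(bl) != callMethod(pd))
    stop("BL and PD calls come from different methods: ",
         callMethod(bl), " vs ", callMethod(pd))
  from <- subtypeLabel(bl)
  to <- subtypeLabel(pd)
  list(from = from, to = to, switched = from != to,
       is_cms2_to_4 = from == "CMS2" && to == "CMS4",
       is_ta_to_sl = from == "TA" && to == "SL",
       bl_confidence = callConfidence(bl),
       pd_confidence = callConfidence(pd))
}

#' Filter lowly expressed genes by a library-size-scaled cpm threshold
#'
#' A gene is retained when its counts-per-million reach \code{10 / L} in at
#' least \code{minSamples} samples, where \code{L} is the minimum library
#' size in millions -- i.e. roughly 10 raw reads in the smallest library.
#'
#' @param counts integer matrix, genes x samples, with rownames.
#' @param librarySizes numeric, reads per sample (default column sums).
#' @param minSamples integer(1), number of samples that must pass (default:
#'   all samples).
#' @return character vector of retained gene names.
#' @examples
#' counts <- matrix(c(100, 0, 100, 2), 2, 2,
#'   dimnames = list(c("kept", "dropped"), NULL))
#' cpmGeneFilter(counts, librarySizes = c(1e7, 1e7))
#' @export
cpmGeneFilter <- function(counts, librarySizes = colSums(counts),
                          minSamples = ncol(counts)) {
  if (any(librarySizes <= 0)) stop("library sizes must be > 0")
  L <- min(librarySizes) / 1e6
  threshold <- 10 / L
  cpm <- t(t(counts) / librarySizes) * 1e6
  keep <- rowSums(cpm >= threshold) >= minSamples
  rownames(counts)[keep]
}
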