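#' @import methods
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom stats setNames
NULL

## ---- PloidyEstimate ---------------------------------------------------------

#' Length-weighted mean copy number of a segmented genome
#'
#' Holds the ploidy of one sample, defined as the segment-length-weighted mean
#' of the unrounded absolute copy number, together with a flag recording
#' whether the profile was adjusted to a genome-doubled state when harmonizing
#' a biopsy pair.
#'
#' @slot ploidy numeric(1), mean copy number in copies; positive for any
#'   non-empty segment set.
#' @slot genomeDoubled logical(1), \code{TRUE} if the integer profile was
#'   doubled during pair harmonization.
#'
#' @seealso [computePloidy()], [harmonizeGenomeDoubling()]
#' @export
setClass("PloidyEstimate",
  representation(ploidy = "numeric", genomeDoubled = "logical"),
  prototype(genomeDoubled = FALSE))

setValidity("PloidyEstimate", function(object) {
  if (length(object@ploidy) != 1L || is.na(object@ploidy))
    return("'ploidy' must be a single non-missing number")
  if (object@ploidy <= 0)
    return("'ploidy' must be positive")
  TRUE
})

## ---- CcfEstimate ------------------------------------------------------------

#' Cancer cell fraction estimates with their copy-number inputs
#'
#' A vector-like container: all slots are parallel vectors, one element per
#' variant. The CCF is the fraction of cancer cells (for ctDNA: of
#' tumor-derived fragments' cells of origin) carrying a mutation, corrected
#' for the local copy-number state. Raw values above 1, which arise from
#' sampling noise, are capped at 1 with the \code{capped} flag set.
#'
#' @slot ccf numeric, capped CCF values in [0, 1].
#' @slot capped logical, \code{TRUE} where the raw value exceeded 1.
#' @slot copiesMutated integer, alleles carrying the mutation (>= 1).
#' @slot copiesTotal integer, local total copy number (>= copiesMutated).
#' @slot sourceVaf numeric, the variant allele fraction the estimate came from.
#' @slot status character, one of \code{"clonal"}, \code{"subclonal"},
#'   \code{"unassigned"}.
#'
#' @seealso [estimateCcf()], [assignClonalStatus()]
#' @export
setClass("CcfEstimate",
  representation(ccf = "numeric", capped = "logical",
    copiesMutated = "integer", copiesTotal = "integer",
    sourceVaf = "numeric", status = "character"))

setValidity("CcfEstimate", function(object) {
  n <- length(object@ccf)
  if (!all(lengths(list(object@capped, object@copiesMutated,
                        object@copiesTotal, object@sourceVaf,
                        object@status)) == n))
    return("all slots must have equal length")
  if (any(object@ccf < 0 | object@ccf > 1))
    return("'ccf' must lie in [0, 1] (raw values above 1 are capped)")
  if (any(object@copiesMutated < 1L))
    return("'copiesMutated' must be >= 1")
  if (any(object@copiesMutated > object@copiesTotal))
    return("'copiesMutated' must not exceed 'copiesTotal'")
  if (!all(object@status %in% c("clonal", "subclonal", "unassigned")))
    return("'status' must be clonal, subclonal or unassigned")
  TRUE
})

## ---- CtdnaPurity ------------------------------------------------------------

#' Fraction of cell-free DNA of cancer-cell origin
#'
#' The ctDNA "purity" of a plasma sample, anchored on the VAF of truncal TP53
#' mutations and the TP53 locus copy-number state from the matched biopsy.
#' When a tumor carries two TP53 mutations (biallelic inactivation through
#' distinct events) the VAFs are summed and the summed chromosome 17p copies
#' used, recorded by the \code{combined} flag.
#'
#' @slot ccfSample numeric(1), fraction of ctDNA of cancer-cell origin in
#'   [0, 1].
#' @slot anchorVafs numeric, VAF(s) of the anchoring TP53 variant(s).
#' @slot combined logical(1), \code{TRUE} if several TP53 mutations were
#'   pooled.
#' @slot capped logical(1), \code{TRUE} if the raw estimate exceeded 1.
#'
#' @seealso [estimateCtdnaPurity()], [driverFraction()]
#' @export
setClass("CtdnaPurity",
  representation(ccfSample = "numeric", anchorVafs = "numeric",
    combined = "logical", capped = "logical"),
  prototype(combined = FALSE, capped = FALSE))

setValidity("CtdnaPurity", function(object) {
  if (length(object@ccfSample) != 1L)
    return("'ccfSample' must be a single value")
  if (object@ccfSample < 0 || object@ccfSample > 1)
    return("'ccfSample' must lie in [0, 1]")
  if (length(object@anchorVafs) < 1L)
    return("at least one anchoring TP53 VAF is required")
  TRUE
})

## ---- ResistanceGapResult ----------------------------------------------------

#' Summed driver cancer-cell fractions and the resistance gap
#'
#' For one sample: the per-driver fractions of cancer cells carrying each
#' detected resistance driver mutation, their sum capped at 1, and the gap
#' \code{1 - total} -- the maximum fraction of cancer cells with no detected
#' resistance mechanism.
#'
#' @slot driverFractions numeric, per-driver fractions in [0, 1], possibly
#'   named by driver.
#' @slot totalDriverFraction numeric(1), capped sum of the fractions.
#' @slot gap numeric(1), \code{1 - totalDriverFraction}.
#' @slot capped logical(1), \code{TRUE} if the raw sum exceeded 1.
#'
#' @seealso [resistanceGap()], [driverFraction()]
#' @export
setClass("ResistanceGapResult",
  representation(driverFractions = "numeric", totalDriverFraction = "numeric",
    gap = "numeric", capped = "logical"))

setValidity("ResistanceGapResult", function(object) {
  if (any(object@driverFractions < 0 | object@driverFractions > 1))
    return("driver fractions must lie in [0, 1]")
  if (abs(object@gap + object@totalDriverFraction - 1) > 1e-12)
    return("'gap' + 'totalDriverFraction' must equal 1")
  TRUE
})

## ---- SubtypeCall ------------------------------------------------------------

#' A per-sample transcriptomic subtype assignment
#'
#' Produced either by Pearson correlation against subtype centroids (the
#' CRCassigner approach) or by nearest-template prediction with a permutation
#' q-value (the CMS approach). The confidence rules differ by method: for
#' centroid correlation a call is low confidence when the best correlation is
#' below 0.15 or its lead over the runner-up is below 0.06; for nearest
#' template, when the permutation q-value exceeds 0.01.
#'
#' @slot label character(1), the assigned subtype.
#' @slot scores named numeric, per-subtype Pearson correlations
#'   (centroid method) or template distances (nearest template).
#' @slot confidence character(1), \code{"high"} or \code{"low"}.
#' @slot method character(1), \code{"centroid_correlation"} or
#'   \code{"nearest_template"}.
#' @slot qvalue numeric(1), permutation q-value (NA for the centroid method).
#'
#' @seealso [assignCentroidSubtype()], [assignNearestTemplate()],
#'   [detectSubtypeSwitch()]
#' @export
setClass("SubtypeCall",
  representation(label = "character", scores = "numeric",
    confidence = "character", method = "character", qvalue = "numeric"),
  prototype(qvalue = NA_real_))

setValidity("SubtypeCall", function(object) {
  if (length(object@label) != 1L) return("'label' must be a single subtype")
  if (!object@confidence %in% c("high", "low"))
    return("'confidence' must be 'high' or 'low'")
  if (!object@method %in% c("centroid_correlation", "nearest_template"))
    return("unknown 'method'")
  if (is.null(names(object@scores)) || !object@label %in% names(object@scores))
    return("'scores' must be named and include the assigned label")
  TRUE
})

## ---- ClonalArchitecture -----------------------------------------------------

#' Ground-truth clonal composition of a simulated tumor
#'
#' Defines a tumor as a set of clones (the truncal clone at cancer-cell
#' fraction 1 plus subclones), the mutations assigned to each clone with their
#' local copy-number state, and the sample purity -- the fraction of sampled
#' DNA of cancer-cell origin. This is the ground truth that the simulators
#' turn into read counts and that parameter-recovery tests compare against.
#'
#' @slot purity numeric(1), fraction of sampled DNA of cancer origin, [0, 1].
#' @slot clones data.frame with columns \code{clone} (id) and \code{ccf}
#'   (cancer cell fraction in [0, 1]); the truncal clone has ccf 1.
#' @slot mutations data.frame with columns \code{id}, \code{clone},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{copiesMutated},
#'   \code{copiesTotal}; each mutation belongs to exactly one clone and
#'   \code{copiesMutated <= copiesTotal}.
#' @slot segments GRanges of allele-specific copy-number segments with
#'   metadata columns \code{cnAbsolute}, \code{cnTotal}, \code{cnMinor}
#'   (may be empty when only locus-level copy states are needed).
#'
#' @seealso [ClonalArchitecture()], [simulateCtdnaCohort()]
#' @export
setClass("ClonalArchitecture",
  representation(purity = "numeric", clones = "data.frame",
    mutations = "data.frame", segments = "GRanges"))

setValidity("ClonalArchitecture", function(object) {
  if (length(object@purity) != 1L || object@purity < 0 || object@purity > 1)
    return("'purity' must be one value in [0, 1]")
  cl <- object@clones
  if (!all(c("clone", "ccf") %in% names(cl)))
    return("'clones' needs columns 'clone' and 'ccf'")
  if (anyDuplicated(cl$clone)) return("clone ids must be unique")
  if (any(cl$ccf < 0 | cl$ccf > 1)) return("clone CCFs must lie in [0, 1]")
  if (!any(abs(cl$ccf - 1) < 1e-12))
    return("a truncal clone with cancer-cell fraction 1 is required")
  mu <- object@mutations
  need <- c("id", "clone", "copiesMutated", "copiesTotal")
  if (!all(need %in% names(mu)))
    return(paste("'mutations' needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(mu$id)) return("mutation ids must be unique")
  if (!all(mu$clone %in% cl$clone))
    return("every mutation must be assigned to a declared clone")
  if (any(mu$copiesMutated < 1L) || any(mu$copiesMutated > mu$copiesTotal))
    return("1 <= copiesMutated <= copiesTotal must hold for every mutation")
  TRUE
})

## ---- show methods -----------------------------------------------------------

setMethod("show", "PloidyEstimate", function(object) {
  cat(sprintf("PloidyEstimate: %.4f copies%s\n", object@ploidy,
    if (object@genomeDoubled) " (genome-doubling adjusted)" else ""))
})

setMethod("show", "CcfEstimate", function(object) {
  n <- length(object@ccf)
  cat(sprintf("CcfEstimate of %d variant%s\n", n, if (n == 1L) "" else "s"))
  k <- min(n, 5L)
  for (i in seq_len(k))
    cat(sprintf("  CCF %.4f (VAF %.4f, m=%d, t=%d, %s%s)\n",
      object@ccf[i], object@sourceVaf[i], object@copiesMutated[i],
      object@copiesTotal[i], object@status[i],
      if (object@capped[i]) ", capped" else ""))
  if (n > k) cat(sprintf("  ... and %d more\n", n - k))
})

setMethod("show", "CtdnaPurity", function(object) {
  cat(sprintf(
    "CtdnaPurity: %.4f of ctDNA of cancer-cell origin (anchor VAF%s %s%s%s)\n",
    object@ccfSample, if (length(object@anchorVafs) > 1L) "s" else "",
    paste(sprintf("%.4f", object@anchorVafs), collapse = " + "),
    if (object@combined) ", pooled TP53 mutations" else "",
    if (object@capped) ", capped" else ""))
})

setMethod("show", "ResistanceGapResult", function(object) {
  cat(sprintf("ResistanceGapResult: %d driver%s, total fraction %.4f%s\n",
    length(object@driverFractions),
    if (length(object@driverFractions) == 1L) "" else "s",
    object@totalDriverFraction, if (object@capped) " (capped)" else ""))
  cat(sprintf("  resistance gap: %.4f\n", object@gap))
})

setMethod("show", "SubtypeCall", function(object) {
  cat(sprintf("SubtypeCall: %s (%s confidence, %s)\n", object@label,
    object@confidence, object@method))
  what <- if (object@method == "centroid_correlation") "r" else "distance"
  sc <- sort(object@scores,
             decreasing = object@method == "centroid_correlation")
  cat("  ", paste(sprintf("%s %s=%.3f", names(sc), what, sc),
                  collapse = ", "), "\n", sep = "")
  if (!is.na(object@qvalue))
    cat(sprintf("  permutation q = %.4g\n", object@qvalue))
})

setMethod("show", "ClonalArchitecture", function(object) {
  cat(sprintf(
    "ClonalArchitecture: purity %.3f, %d clone%s, %d mutation%s\n",
    object@purity, nrow(object@clones),
    if (nrow(object@clones) == 1L) "" else "s", nrow(object@mutations),
    if (nrow(object@mutations) == 1L) "" else "s"))
  for (i in seq_len(nrow(object@clones))) {
    cl <- object@clones$clone[i]
    cat(sprintf("  clone %s (CCF %.3f): %d mutation(s)\n", cl,
      object@clones$ccf[i], sum(object@mutations$clone == cl)))
  }
})
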