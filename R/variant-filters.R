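## Post-caller somatic variant retention rules for the three assays, plus the
## panel-of-normals (cross-normal) artifact filter. Each filter annotates its
## input table with `retained` and `reject_reason` rather than dropping rows,
## so every threshold decision stays auditable.

## Platypus FILTER flags that disqualify an indel call.
.INDEL_EXCLUDED_FLAGS <- c("GOF", "badReads", "hp10", "MQ", "strandBias",
                           "QualDepth", "REFCALL")

#' @noRd
vafFromCounts <- function(calls) {
  if (is.null(calls$vaf)) calls$tumor_alt / calls$tumor_depth else calls$vaf
}

#' @noRd
annotateRetention <- function(calls, ok, reason) {
  calls$retained <- ok
  calls$reject_reason <- ifelse(ok, "", reason)
  calls
}

#' Exome SNV retention filter
#'
#' Retains a single-nucleotide variant call iff its variant allele fraction
#' is at least 5\%, the depth in the called tumor sample is at least 20
#' reads, and the matched normal shows at most 2 variant-supporting reads.
#' All thresholds are inclusive.
#'
#' @param calls data.frame with columns \code{tumor_depth}, \code{tumor_alt},
#'   \code{normal_depth}, \code{normal_alt} (and optionally a precomputed
#'   \code{vaf}; otherwise \code{tumor_alt / tumor_depth} is used). An
#'   \code{id} column, if present, is used in error messages.
#' @param minVaf,minDepth,maxNormalAlt the printed thresholds; defaults 0.05,
#'   20 and 2.
#' @return The input data.frame with logical \code{retained} and character
#'   \code{reject_reason} columns appended.
#' @examples
#' calls <- data.frame(tumor_depth = c(20, 100), tumor_alt = c(1, 30),
#'                     normal_depth = 40, normal_alt = c(2, 3))
#' filterExomeSnvs(calls)$retained  # first fails VAF, second normal_alt
#' @export
filterExomeSnvs <- function(calls, minVaf = 0.05, minDepth = 20,
                            maxNormalAlt = 2) {
  if (is.null(calls$normal_depth) || is.null(calls$normal_alt))
    stop("matched-normal read counts missing for all variants")
  bad <- is.na(calls$normal_depth) | is.na(calls$normal_alt)
  if (any(bad)) {
    ids <- if (!is.null(calls$id)) calls$id else seq_len(nrow(calls))
    stop("matched-normal read counts missing for variant(s): ",
         paste(ids[bad], collapse = ", "))
  }
  vaf <- vafFromCounts(calls)
  okVaf <- vaf >= minVaf
  okDepth <- calls$tumor_depth >= minDepth
  okNormal <- calls$normal_alt <= maxNormalAlt
  reason <- paste0(ifelse(okVaf, "", "vaf_below_min;"),
                   ifelse(okDepth, "", "tumor_depth_below_min;"),
                   ifelse(okNormal, "", "normal_alt_above_max;"))
  annotateRetention(calls, okVaf & okDepth & okNormal,
                    sub(";$", "", reason))
}

#' Exome indel retention filter
#'
#' Retains an indel call iff none of the disqualifying caller FILTER flags
#' (GOF, badReads, hp10, MQ, strandBias, QualDepth, REFCALL) is present, the
#' normal genotype is homozygous reference (0/0), the normal depth is at
#' least 10, the tumor depth at least 20, and at least 5 variant reads
#' support the call in the tumor.
#'
#' @param calls data.frame with columns \code{filter} (flag string,
#'   semicolon/comma-separated; \code{"PASS"} or \code{""} means no flags),
#'   \code{normal_gt}, \code{normal_depth}, \code{tumor_depth},
#'   \code{tumor_alt}. An absent or NA \code{filter} field is an error, never
#'   a pass.
#' @return The input data.frame with \code{retained} / \code{reject_reason}.
#' @examples
#' calls <- data.frame(filter = c("PASS", "badReads"), normal_gt = "0/0",
#'   normal_depth = 10, tumor_depth = 20, tumor_alt = 5)
#' filterExomeIndels(calls)$retained  # TRUE FALSE
#' @export
filterExomeIndels <- function(calls) {
  if (is.null(calls$filter) || any(is.na(calls$filter)))
    stop("indel calls must carry a FILTER field; absent/NA is an error, ",
         "not a pass")
  flagged <- vapply(strsplit(as.character(calls$filter), "[;,]\\s*"),
    function(f) any(f %in% .INDEL_EXCLUDED_FLAGS), logical(1))
  okGt <- calls$normal_gt %in% c("0/0", "0|0")
  okNd <- calls$normal_depth >= 10
  okTd <- calls$tumor_depth >= 20
  okTa <- calls$tumor_alt >= 5
  reason <- paste0(ifelse(flagged, "excluded_filter_flag;", ""),
                   ifelse(okGt, "", "normal_not_homref;"),
                   ifelse(okNd, "", "normal_depth_below_min;"),
                   ifelse(okTd, "", "tumor_depth_below_min;"),
                   ifelse(okTa, "", "tumor_alt_below_min;"))
  annotateRetention(calls, !flagged & okGt & okNd & okTd & okTa,
                    sub(";$", "", reason))
}

#' Panel-of-normals (cross-normal) artifact filter
#'
#' A cohort normal sample flags a variant when its variant-supporting reads
#' reach 2\% or more of its total reads at the call locus; a call is rejected
#' when 5\% or more of the cohort normals flag it. Removes recurrent
#' alignment artifacts and systematically noisy positions. A cohort member
#' with no read counts at a locus counts as not flagging (logged).
#'
#' @param calls data.frame of candidate calls with \code{chrom}, \code{pos}
#'   (and \code{alt}, matched when the cohort table also carries \code{alt}).
#' @param cohort data.frame of per-(locus, normal sample) read counts:
#'   \code{chrom}, \code{pos}, \code{normal_sample}, \code{depth}, \code{alt_reads}
#'   (optionally \code{alt}).
#' @param cohortSize integer(1), number of normals in the cohort (>= 1);
#'   the denominator of the 5\% rule, which may exceed the number of samples
#'   present in \code{cohort} when some normals lack coverage everywhere.
#' @param flagVafMin,rejectFracMin the printed thresholds (0.02 and 0.05).
#' @return \code{calls} with \code{cohort_flag_count}, \code{retained} and
#'   \code{reject_reason} appended.
#' @examples
#' calls <- data.frame(chrom = "chr1", pos = 100, alt = "T")
#' cohort <- data.frame(chrom = "chr1", pos = 100, alt = "T",
#'   normal_sample = paste0("N", 1:40), depth = 100,
#'   alt_reads = c(2, rep(0, 39)))
#' crossNormalFilter(calls, cohort, 40)$retained  # 1/40 = 2.5% < 5% -> TRUE
#' @export
crossNormalFilter <- function(calls, cohort, cohortSize,
                              flagVafMin = 0.02, rejectFracMin = 0.05) {
  if (cohortSize < 1) stop("'cohortSize' must be >= 1")
  useAlt <- !is.null(calls$alt) && !is.null(cohort$alt)
  key <- function(d) if (useAlt) paste(d$chrom, d$pos, d$alt)
    else paste(d$chrom, d$pos)
  cohort$flags <- with(cohort, ifelse(depth > 0,
                                      alt_reads / depth >= flagVafMin, FALSE))
  flagCount <- tapply(cohort$flags, key(cohort), sum)
  seen <- tapply(rep(TRUE, nrow(cohort)), key(cohort), length)
  k <- key(calls)
  calls$cohort_flag_count <- as.integer(ifelse(is.na(flagCount[k]), 0L,
                                               flagCount[k]))
  nSeen <- ifelse(is.na(seen[k]), 0L, seen[k])
  if (any(nSeen < cohortSize))
    message(sum(nSeen < cohortSize), " call locus/loci missing from some ",
            "cohort normals; absent members count as not flagging")
  rejected <- calls$cohort_flag_count / cohortSize >= rejectFracMin
  annotateRetention(calls, !rejected, "cross_normal_artifact")
}

#' Deep-amplicon mutation calling rule
#'
#' Emits a call at a position iff the variant allele fraction is at least
#' 0.5\% and at least 3 reads support the variant, the calling floor of the
#' deep amplicon assay.
#'
#' @param readcounts data.frame with \code{depth} and \code{alt_reads}
#'   (plus any identifying columns, carried through).
#' @param minVaf,minAlt thresholds; defaults 0.005 and 3.
#' @return The rows of \code{readcounts} that are called, with a \code{vaf}
#'   column added.
#' @examples
#' rc <- data.frame(pos = 1:2, depth = 2000, alt_reads = c(12, 2))
#' callAmpliconMutations(rc)$pos  # only position 1 (VAF 0.6%, 12 reads)
#' @export
callAmpliconMutations <- function(readcounts, minVaf = 0.005, minAlt = 3) {
  if (any(readcounts$depth <= 0)) stop("'depth' must be > 0 at evaluated ",
                                       "positions")
  readcounts$vaf <- readcounts$alt_reads / readcounts$depth
  out <- readcounts[readcounts$vaf >= minVaf & readcounts$alt_reads >= minAlt,
                    , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' ctDNA hotspot calling rule
#'
#' Calls a variant from ultra-deep ctDNA read counts iff at least 2
#' independent variant reads are observed at a catalogued mutational hotspot
#' position and the encoded amino-acid change is in that gene's recurrent
#' set. Positions with an untranslatable allele (NA amino-acid change) are
#' skipped with a log message.
#'
#' @param readcounts data.frame with \code{gene}, \code{pos}, \code{depth},
#'   \code{alt_reads}, \code{aa_change}.
#' @param catalog hotspot catalog: data.frame with \code{gene}, \code{pos},
#'   \code{aa_change} (one row per recurrent change); positions unique per
#'   gene-change pair.
#' @param minAlt integer(1), minimum independent variant reads (default 2).
#' @return Called rows with a \code{vaf} column added.
#' @examples
#' cat <- data.frame(gene = "KRAS", pos = 25398284, aa_change = "G12D")
#' rc <- data.frame(gene = "KRAS", pos = 25398284, depth = 10000,
#'                  alt_reads = 2, aa_change = "G12D")
#' nrow(callCtdnaHotspots(rc, cat))  # 1
#' @export
callCtdnaHotspots <- function(readcounts, catalog, minAlt = 2) {
  if (nrow(catalog) < 1L) stop("hotspot catalog is empty")
  untranslatable <- is.na(readcounts$aa_change)
  if (any(untranslatable)) {
    message(sum(untranslatable), " position(s) with untranslatable allele ",
            "skipped")
    readcounts <- readcounts[!untranslatable, , drop = FALSE]
  }
  inCatalog <- paste(readcounts$gene, readcounts$pos, readcounts$aa_change) %in%
    paste(catalog$gene, catalog$pos, catalog$aa_change)
  out <- readcounts[inCatalog & readcounts$alt_reads >= minAlt, ,
                    drop = FALSE]
  out$vaf <- out$alt_reads / out$depth
  rownames(out) <- NULL
  out
}
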