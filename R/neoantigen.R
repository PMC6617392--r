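## Neoantigen enumeration: germline variant retention, in-phase germline and
## tumor CDS construction, translation, 8-11-mer neopeptide set difference,
## and core-peptide best-rank binder counting behind a pluggable predictor.

#' Germline variant retention for neoantigen phasing
#'
#' Retains a germline variant call iff its FILTER is PASS, genotype quality
#' GQ is at least 10, the genotype differs from 0/0, germline coverage is at
#' least 10 and at least one read supports the variant allele; variants in
#' exclusion regions (e.g. segmental duplications) are removed. When several
#' alternative alleles at a site qualify, only the one with the highest
#' allele frequency is kept. Records with a malformed genotype are skipped
#' with a log message.
#'
#' @param records data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{filter}, \code{gq}, \code{gt},
#'   \code{depth}, \code{alt_reads}, and \code{af} (allele frequency used to
#'   pick among multi-allelic alts; defaults to \code{alt_reads / depth}).
#' @param exclusionRegions optional GRanges; variants overlapping are
#'   removed.
#' @return The retained rows.
#' @examples
#' rec <- data.frame(chrom = "chr1", pos = 1, ref = "A", alt = "G",
#'   filter = "PASS", gq = 10, gt = "0/1", depth = 10, alt_reads = 1)
#' nrow(filterGermlineVariants(rec))  # 1: all boundaries inclusive
#' @export
filterGermlineVariants <- function(records, exclusionRegions = NULL) {
  malformed <- !grepl("^[0-9.]+[/|][0-9.]+$", records$gt)
  if (any(malformed)) {
    message(sum(malformed), " record(s) with malformed genotype skipped")
    records <- records[!malformed, , drop = FALSE]
  }
  if (is.null(records$af)) records$af <- records$alt_reads / records$depth
  ok <- records$filter == "PASS" & records$gq >= 10 &
    !records$gt %in% c("0/0", "0|0") & records$depth >= 10 &
    records$alt_reads >= 1
  records <- records[ok, , drop = FALSE]
  if (!is.null(exclusionRegions) && nrow(records)) {
    pos <- GenomicRanges::GRanges(records$chrom,
      IRanges::IRanges(records$pos,
                       records$pos + nchar(records$ref) - 1L))
    hit <- GenomicRanges::findOverlaps(pos, exclusionRegions)
    inDup <- seq_len(nrow(records)) %in% S4Vectors::queryHits(hit)
    records <- records[!inDup, , drop = FALSE]
  }
  if (nrow(records) > 1L) {
    ## multi-allelic: keep the highest-AF qualifying alt per site
    siteKey <- paste(records$chrom, records$pos)
    keep <- unlist(lapply(split(seq_len(nrow(records)), siteKey),
      function(i) i[which.max(records$af[i])]))
    records <- records[sort(keep), , drop = FALSE]
  }
  rownames(records) <- NULL
  records
}

#' Resolve overlapping variants on a transcript
#'
#' When the positions of two variants overlap only one is retained: somatic
#' variants take priority over germline, then the leftmost wins; each
#' dropped variant is logged. Variant footprints are \code{[pos, pos +
#' nchar(ref) - 1]} in CDS coordinates.
#'
#' @param variants data.frame with \code{pos}, \code{ref}, \code{alt},
#'   \code{origin} (\code{"somatic"} or \code{"germline"}).
#' @return An overlap-free subset, sorted by position.
#' @examples
#' v <- data.frame(pos = c(5, 5), ref = "A", alt = c("T", "G"),
#'                 origin = c("germline", "somatic"))
#' resolveOverlaps(v)$origin  # somatic wins
#' @export
resolveOverlaps <- function(variants) {
  if (nrow(variants) < 2L) return(variants)
  variants <- variants[order(variants$pos), , drop = FALSE]
  ends <- variants$pos + nchar(variants$ref) - 1L
  ## cluster transitively overlapping footprints
  cluster <- cumsum(c(1L, as.integer(
    variants$pos[-1L] > cummax(ends)[-nrow(variants)])))
  keep <- unlist(lapply(split(seq_len(nrow(variants)), cluster),
    function(i) {
      if (length(i) == 1L) return(i)
      som <- i[variants$origin[i] == "somatic"]
      win <- if (length(som)) som[1L] else i[1L]
      message("overlap at CDS position ", variants$pos[win], ": kept ",
              variants$origin[win], " variant, dropped ",
              length(i) - 1L, " other(s)")
      win
    }))
  out <- variants[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build germline and tumor CDS sequences from in-phase variants
#'
#' Applies variants to a reference CDS assuming all germline and somatic
#' variants are in phase: the germline transcript carries the germline
#' variants only, the tumor transcript carries germline plus somatic
#' variants. Variants are applied right-to-left so earlier positions stay
#' valid under indels. A mismatch between a variant's \code{ref} and the
#' sequence is an annotation inconsistency and raises an error naming the
#' transcript.
#'
#' @param cds character(1) or [Biostrings::DNAString], the reference CDS.
#' @param variants overlap-free data.frame (\code{pos}, \code{ref},
#'   \code{alt}, \code{origin}), e.g. from [resolveOverlaps()].
#' @param transcript character(1), id used in error messages.
#' @return list with character elements \code{germline} and \code{tumor}.
#' @examples
#' v <- data.frame(pos = 4, ref = "G", alt = "C", origin = "somatic")
#' buildSequences("ATGGCTTAA", v)$tumor  # "ATGCCTTAA"
#' @export
buildSequences <- function(cds, variants, transcript = "transcript") {
  cds <- as.character(cds)
  apply1 <- function(seq, vars) {
    if (nrow(vars) == 0L) return(seq)
    vars <- vars[order(-vars$pos), , drop = FALSE]
    for (i in seq_len(nrow(vars))) {
      p <- vars$pos[i]
      ref <- vars$ref[i]
      found <- substr(seq, p, p + nchar(ref) - 1L)
      if (found != ref)
        stop("annotation inconsistency in ", transcript, " at CDS position ",
             p, ": expected '", ref, "', sequence has '", found, "'")
      seq <- paste0(substr(seq, 1L, p - 1L), vars$alt[i],
                    substr(seq, p + nchar(ref), nchar(seq)))
    }
    seq
  }
  germVars <- variants[variants$origin == "germline", , drop = FALSE]
  list(germline = apply1(cds, germVars), tumor = apply1(cds, variants))
}

#' Translate a CDS to protein
#'
#' Standard-genetic-code translation from the first position to the first
#' in-frame stop codon; when no stop is reached (frameshifted or stop-lost
#' sequences) translation runs to the last complete codon and any trailing
#' 1-2 nucleotides are ignored.
#'
#' @param cds character(1) or [Biostrings::DNAString], length >= 3.
#' @return character(1) amino-acid sequence (no stop symbol).
#' @examples
#' translateCds("ATGGCTTAA")  # "MA"
#' @export
translateCds <- function(cds) {
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  if (n < 3L) stop("CDS shorter than one codon")
  nCodon <- n %/% 3L
  codons <- substring(cds, 3L * seq_len(nCodon) - 2L, 3L * seq_len(nCodon))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X" # ambiguous bases
  stopAt <- which(aa == "*")
  if (length(stopAt)) aa <- aa[seq_len(stopAt[1] - 1L)]
  paste(aa, collapse = "")
}

#' @noRd
kmers <- function(protein, k) {
  n <- nchar(protein)
  if (n < k) return(character(0))
  unique(substring(protein, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

#' Enumerate neopeptides as a tumor-vs-germline k-mer set difference
#'
#' Generates all peptides of length 8-11 from the tumor protein and removes
#' every peptide also generated by the germline protein; what remains are
#' the neopeptides attributable to the somatic variants. Duplicates are
#' collapsed.
#'
#' @param sTum,sGerm character(1), tumor and germline protein sequences.
#' @param lengths integer, peptide lengths (default 8:11).
#' @return character vector of neopeptides (possibly empty).
#' @examples
#' length(enumerateNeopeptides(paste(rep("A", 30), collapse = ""),
#'                             paste(rep("A", 30), collapse = "")))  # 0
#' @export
enumerateNeopeptides <- function(sTum, sGerm, lengths = 8:11) {
  if (nchar(sTum) == 0L || nchar(sGerm) == 0L)
    stop("protein sequences must be nonempty")
  tum <- unlist(lapply(lengths, kmers, protein = sTum))
  germ <- unlist(lapply(lengths, kmers, protein = sGerm))
  setdiff(tum, germ)
}

#' Deterministic toy binding-rank predictor
#'
#' A reproducible stand-in for an MHC binding predictor, for tests and
#' synthetic pipelines: the percentage rank is a hash of (peptide, HLA)
#' scaled to [0, 100), and for ~10\% of peptides (again by hash) the
#' reported interaction core is the central (k-1)-mer rather than the full
#' peptide, exercising the shortened-core code path. Real predictor output
#' is ingested with [tsvRankPredictor()].
#'
#' @param peptide character(1), the queried peptide.
#' @param hla character(1), the HLA allele context.
#' @return list with \code{core} (character) and \code{rank} (numeric
#'   percentage rank in [0, 100)).
#' @examples
#' toyRankPredictor("SIINFEKL", "HLA-A*02:01")
#' @export
toyRankPredictor <- function(peptide, hla) {
  h <- fnv1a32(paste(peptide, hla, sep = "|"))
  core <- if (h %% 10 == 0 && nchar(peptide) > 8L) {
    k <- nchar(peptide)
    substr(peptide, 2L, k - (k %% 2L == 1L))  # central (k-1)-mer
  } else peptide
  list(core = core, rank = (h %% 100000) / 1000)
}

#' Predictor backed by a table of precomputed ranks
#'
#' Adapts a table of externally computed binding predictions (columns
#' \code{peptide}, \code{hla}, \code{core}, \code{rank}) to the predictor
#' interface used by [countBinders()]. Queries not present in the table
#' return NULL, and the corresponding peptide is skipped with a log entry.
#'
#' @param table data.frame or path to a TSV with the four columns above.
#' @return function(peptide, hla) -> list(core, rank) or NULL.
#' @export
tsvRankPredictor <- function(table) {
  if (is.character(table))
    table <- utils::read.delim(table, stringsAsFactors = FALSE)
  stopifnot(all(c("peptide", "hla", "core", "rank") %in% names(table)))
  key <- paste(table$peptide, table$hla)
  function(peptide, hla) {
    i <- match(paste(peptide, hla), key)
    if (is.na(i)) return(NULL)
    list(core = table$core[i], rank = table$rank[i])
  }
}

#' Count core-peptide high binders among neopeptides
#'
#' Queries the predictor for every (neopeptide, HLA allele) combination,
#' keeps for each distinct interaction core only the best (lowest)
#' percentage rank seen in the sample, and counts as binders the cores with
#' best rank below 0.5 that do not correspond to wild-type peptide windows
#' (cores occurring as substrings of the germline protein are excluded:
#' shortened cores can be devoid of mutated residues). Predictor failures
#' (NULL returns) skip the peptide with a log entry.
#'
#' @param neopeptides character, neopeptides from [enumerateNeopeptides()].
#' @param hlas character, HLA alleles of the sample.
#' @param predictor function(peptide, hla) -> list(core, rank) or NULL;
#'   e.g. [toyRankPredictor()] or [tsvRankPredictor()].
#' @param sGerm character(1), germline protein used for the wild-type-core
#'   exclusion.
#' @param maxRank numeric(1), binder threshold on the percentage rank
#'   (default 0.5).
#' @return list with \code{count} (the neoantigen burden contribution) and
#'   \code{records}: data.frame per core with \code{core}, \code{peptide}
#'   (a peptide achieving the best rank), \code{best_rank},
#'   \code{contains_mutated_residue}, \code{binder}.
#' @examples
#' countBinders("QQQQWQQQ", "HLA-A*01:01", toyRankPredictor,
#'              paste(rep("Q", 20), collapse = ""))$count
#' @export
countBinders <- function(neopeptides, hlas, predictor, sGerm,
                         maxRank = 0.5) {
  best <- list()
  skipped <- 0L
  for (pep in neopeptides) {
    for (hla in hlas) {
      hit <- predictor(pep, hla)
      if (is.null(hit)) {
        skipped <- skipped + 1L
        next
      }
      cur <- best[[hit$core]]
      if (is.null(cur) || hit$rank < cur$rank)
        best[[hit$core]] <- list(peptide = pep, rank = hit$rank)
    }
  }
  if (skipped > 0L)
    message(skipped, " (peptide, HLA) quer(ies) without prediction skipped")
  if (length(best) == 0L)
    return(list(count = 0L,
                records = data.frame(core = character(0),
                  peptide = character(0), best_rank = numeric(0),
                  contains_mutated_residue = logical(0),
                  binder = logical(0))))
  cores <- names(best)
  ranks <- vapply(best, function(b) b$rank, numeric(1))
  peps <- vapply(best, function(b) b$peptide, character(1))
  wildtype <- vapply(cores, function(cp) grepl(cp, sGerm, fixed = TRUE),
                     logical(1))
  binder <- ranks < maxRank & !wildtype
  records <- data.frame(core = cores, peptide = peps, best_rank = ranks,
    contains_mutated_residue = !wildtype, binder = binder,
    row.names = NULL)
  list(count = sum(binder), records = records)
}

#' Per-sample neoantigen burden from transcripts and variants
#'
#' End-to-end convenience wrapper: for each transcript carrying at least one
#' non-synonymous somatic variant, resolves overlaps, builds germline and
#' tumor CDS, translates, enumerates neopeptides and counts core-peptide
#' high binders; the sample burden is the total binder count.
#'
#' @param cds named character vector or [Biostrings::DNAStringSet] of
#'   reference CDS.
#' @param variants data.frame with \code{transcript}, \code{pos},
#'   \code{ref}, \code{alt}, \code{origin}, \code{class} (e.g. from
#'   [makeToyTranscriptome()]).
#' @param hlas character, HLA alleles.
#' @param predictor predictor function (default [toyRankPredictor]).
#' @return list with \code{burden} (total binder count), \code{perTranscript}
#'   data.frame (\code{transcript}, \code{n_neopeptides}, \code{n_binders})
#'   and \code{records} (all core-peptide records).
#' @export
neoantigenBurden <- function(cds, variants, hlas,
                             predictor = toyRankPredictor) {
  cds <- stats::setNames(as.character(cds), names(cds))
  res <- list()
  recs <- list()
  for (tx in unique(variants$transcript)) {
    v <- variants[variants$transcript == tx, , drop = FALSE]
    hasSomatic <- any(v$origin == "somatic" & v$class != "synonymous")
    if (!hasSomatic) next # synonymous-only transcripts excluded
    v <- resolveOverlaps(v)
    seqs <- buildSequences(cds[[tx]], v, transcript = tx)
    sGerm <- translateCds(seqs$germline)
    sTum <- translateCds(seqs$tumor)
    if (nchar(sGerm) == 0L || nchar(sTum) == 0L) next # start lost to nothing
    neo <- enumerateNeopeptides(sTum, sGerm)
    bound <- countBinders(neo, hlas, predictor, sGerm)
    res[[tx]] <- data.frame(transcript = tx, n_neopeptides = length(neo),
                            n_binders = bound$count)
    if (nrow(bound$records)) {
      bound$records$transcript <- tx
      recs[[tx]] <- bound$records
    }
  }
  perTranscript <- if (length(res)) do.call(rbind, res) else
    data.frame(transcript = character(0), n_neopeptides = integer(0),
               n_binders = integer(0))
  rownames(perTranscript) <- NULL
  list(burden = sum(perTranscript$n_binders), perTranscript = perTranscript,
       records = if (length(recs)) do.call(rbind, recs) else NULL)
}
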