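## Ground-truth cohort generators. These define the study conditions under
## which the inference layer is validated: binomial read noise at
## assay-typical depths, Gaussian expression noise around subtype centroids,
## and toy transcriptomes with planted variants.

#' Construct a ground-truth clonal architecture
#'
#' Convenience constructor for [ClonalArchitecture-class]. A truncal clone at
#' cancer-cell fraction 1 must be present; every mutation belongs to exactly
#' one clone and carries its local copy-number state.
#'
#' @param purity numeric(1), fraction of sampled DNA of cancer origin.
#' @param clones data.frame with columns \code{clone}, \code{ccf}.
#' @param mutations data.frame with columns \code{id}, \code{clone},
#'   \code{copiesMutated}, \code{copiesTotal}; optional \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt} are filled with placeholders.
#' @param segments optional GRanges of copy-number segments (mcols
#'   \code{cnAbsolute}, \code{cnTotal}, \code{cnMinor}).
#' @return A validated [ClonalArchitecture-class].
#' @examples
#' arch <- ClonalArchitecture(0.571,
#'   clones = data.frame(clone = c("truncal", "res1"), ccf = c(1, 0.175)),
#'   mutations = data.frame(id = c("TP53_R175H", "KRAS_G12D"),
#'     clone = c("truncal", "res1"),
#'     copiesMutated = c(1L, 1L), copiesTotal = c(1L, 2L)))
#' purity(arch)
#' @export
ClonalArchitecture <- function(purity, clones, mutations,
                               segments = GenomicRanges::GRanges()) {
  defaults <- list(chrom = "chr1", ref = "A", alt = "T")
  for (col in names(defaults))
    if (is.null(mutations[[col]])) mutations[[col]] <- defaults[[col]]
  if (is.null(mutations$pos)) mutations$pos <- seq_len(nrow(mutations)) * 1000L
  new("ClonalArchitecture", purity = purity, clones = clones,
      mutations = mutations, segments = segments)
}

#' Simulate ctDNA read counts for a clonal architecture
#'
#' For each mutation, the expected variant allele fraction is
#' \deqn{E[VAF] = \frac{purity \cdot CCF \cdot C_{mut}}
#'                     {purity \cdot C_{tot} + 2 (1 - purity)}}
#' evaluated against the mutation's clone, and the variant read count is
#' drawn as Binomial(depth, E[VAF]). Read noise is purely binomial (no
#' overdispersion) and every variant is observed at the same fixed depth.
#' Optionally, truncal heterozygous-diploid passenger mutations and germline
#' heterozygous sites (expected VAF 0.5 regardless of purity) are appended.
#'
#' @param architecture a [ClonalArchitecture-class].
#' @param depth numeric(1), per-variant read depth (>= 1).
#' @param seed integer(1), global seed; the generator derives its own stream.
#' @param nPassengers integer(1), extra truncal het diploid passengers.
#' @param nGermline integer(1), extra germline het sites at expected VAF 0.5.
#' @return data.frame with one row per variant: \code{id}, \code{clone},
#'   \code{origin}, \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{copiesMutated}, \code{copiesTotal}, \code{expected_vaf},
#'   \code{depth}, \code{alt_reads}, \code{vaf}.
#' @examples
#' arch <- ClonalArchitecture(1,
#'   clones = data.frame(clone = "truncal", ccf = 1),
#'   mutations = data.frame(id = "m1", clone = "truncal",
#'     copiesMutated = 1L, copiesTotal = 2L))
#' rc <- simulateCtdnaCohort(arch, depth = 1048, seed = 7)
#' rc$expected_vaf  # 0.5
#' @export
simulateCtdnaCohort <- function(architecture, depth, seed,
                                nPassengers = 0L, nGermline = 0L) {
  stopifnot(is(architecture, "ClonalArchitecture"))
  validObject(architecture)
  if (depth < 1) stop("'depth' must be >= 1")
  depth <- round(depth)
  p <- architecture@purity
  mu <- architecture@mutations
  cloneCcf <- stats::setNames(architecture@clones$ccf,
                              architecture@clones$clone)
  tab <- data.frame(id = as.character(mu$id), clone = as.character(mu$clone),
    origin = "somatic", chrom = mu$chrom, pos = mu$pos, ref = mu$ref,
    alt = mu$alt, copiesMutated = as.integer(mu$copiesMutated),
    copiesTotal = as.integer(mu$copiesTotal),
    stringsAsFactors = FALSE)
  tab$ccf <- unname(cloneCcf[tab$clone])
  if (nPassengers > 0L) {
    pas <- data.frame(id = sprintf("passenger_%03d", seq_len(nPassengers)),
      clone = "truncal", origin = "somatic", chrom = "chr2",
      pos = seq_len(nPassengers) * 997L, ref = "C", alt = "G",
      copiesMutated = 1L, copiesTotal = 2L, ccf = 1)
    tab <- rbind(tab, pas)
  }
  ## somatic expected VAF under the admixture model
  tab$expected_vaf <- p * tab$ccf * tab$copiesMutated /
    (p * tab$copiesTotal + 2 * (1 - p))
  if (nGermline > 0L) {
    germ <- data.frame(id = sprintf("germline_%03d", seq_len(nGermline)),
      clone = NA_character_, origin = "germline", chrom = "chr3",
      pos = seq_len(nGermline) * 1009L, ref = "G", alt = "A",
      copiesMutated = 1L, copiesTotal = 2L, ccf = NA_real_,
      expected_vaf = 0.5)
    tab <- rbind(tab, germ)
  }
  bad <- !is.finite(tab$expected_vaf) | tab$expected_vaf < 0 |
    tab$expected_vaf > 1
  if (any(bad))
    stop("invalid architecture: expected VAF outside [0, 1] for ",
         paste(tab$id[bad], collapse = ", "))
  tab$depth <- depth
  tab$alt_reads <- withSeed(deriveSeed(seed, "ctdna"),
    stats::rbinom(nrow(tab), depth, tab$expected_vaf))
  tab$vaf <- tab$alt_reads / tab$depth
  tab$ccf <- NULL
  rownames(tab) <- NULL
  tab
}

#' Simulate an expression cohort around subtype centroids
#'
#' Each sample's column is its assigned subtype centroid plus i.i.d. Gaussian
#' noise of standard deviation \code{noiseSd} (in the units of the centroid
#' matrix, typically log2 expression).
#'
#' @param centroids numeric matrix, genes x subtypes, with row and column
#'   names.
#' @param assignments character, subtype label per sample; must all be
#'   centroid column names.
#' @param noiseSd numeric(1) >= 0, additive noise standard deviation.
#' @param seed integer(1), global seed.
#' @return numeric matrix genes x samples with \code{true_subtype} attribute.
#' @examples
#' cen <- matrix(rnorm(40), 20, 2,
#'   dimnames = list(paste0("g", 1:20), c("CMS2", "CMS4")))
#' expr <- simulateExpressionCohort(cen, c("CMS2", "CMS4"), 0.5, seed = 3)
#' @export
simulateExpressionCohort <- function(centroids, assignments, noiseSd, seed) {
  stopifnot(is.matrix(centroids), !is.null(colnames(centroids)),
            !is.null(rownames(centroids)))
  if (noiseSd < 0) stop("'noiseSd' must be >= 0")
  unknown <- setdiff(assignments, colnames(centroids))
  if (length(unknown))
    stop("unknown subtype label(s): ", paste(unknown, collapse = ", "))
  n <- length(assignments)
  base <- centroids[, assignments, drop = FALSE]
  noise <- withSeed(deriveSeed(seed, "expression"),
    matrix(stats::rnorm(nrow(centroids) * n, sd = noiseSd),
           nrow(centroids), n))
  out <- base + noise
  colnames(out) <- sprintf("S%03d", seq_len(n))
  rownames(out) <- rownames(centroids)
  attr(out, "true_subtype") <- assignments
  out
}

## Codon pools used when assembling toy CDS sequences. NOSTOP excludes the
## three stop codons so interior codons never terminate translation early.
.CODONS <- apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                             c("T", "C", "A", "G")), 1, paste, collapse = "")
.STOPS <- c("TAA", "TAG", "TGA")
.NOSTOP <- setdiff(.CODONS, .STOPS)

#' Generate a toy transcriptome with planted variants
#'
#' Builds random coding sequences (start codon, random non-stop interior
#' codons, terminal stop) and plants one somatic variant per transcript,
#' cycling through the supported consequence classes; optionally each
#' transcript additionally receives a germline interior missense SNV. The
#' reference is adjusted before recording variants so every planted variant's
#' \code{ref} matches the sequence. Indels use VCF-style anchor-base
#' representation.
#'
#' @param nTranscripts integer(1), number of transcripts.
#' @param cdsLengthRange integer(2), CDS length range in codons (including
#'   start and stop; >= 12 so interior planting never touches the ends).
#' @param seed integer(1), global seed.
#' @param classes character, somatic consequence classes to cycle through;
#'   subset of \code{missense, synonymous, stop_gained, frameshift,
#'   inframe_del, inframe_ins, start_lost, stop_lost}.
#' @param germlineProb numeric(1), probability that a transcript also gets a
#'   germline missense SNV.
#' @return list with \code{cds} (a [Biostrings::DNAStringSet]) and
#'   \code{variants} (data.frame: \code{transcript}, \code{pos} (CDS 1-based),
#'   \code{ref}, \code{alt}, \code{origin}, \code{class}).
#' @examples
#' toy <- makeToyTranscriptome(2, c(20, 30), seed = 11)
#' toy$variants
#' @export
makeToyTranscriptome <- function(nTranscripts, cdsLengthRange = c(20L, 60L),
    seed = 1L,
    classes = c("missense", "synonymous", "stop_gained", "frameshift",
                "inframe_del", "inframe_ins", "start_lost", "stop_lost"),
    germlineProb = 0.5) {
  classes <- match.arg(classes, several.ok = TRUE)
  if (min(cdsLengthRange) < 12L)
    stop("'cdsLengthRange' must be >= 12 codons")
  withSeed(deriveSeed(seed, "transcriptome"), {
    seqs <- character(nTranscripts)
    vars <- vector("list", nTranscripts)
    for (i in seq_len(nTranscripts)) {
      L <- sample(seq(cdsLengthRange[1], cdsLengthRange[2]), 1L)
      codons <- c("ATG", sample(.NOSTOP, L - 2L, replace = TRUE), "TAA")
      cls <- classes[(i - 1L) %% length(classes) + 1L]
      ## interior codon indices kept clear of start, stop and each other
      ci <- sample(4:(L - 3L), 1L)
      gi <- sample(setdiff(4:(L - 3L), (ci - 1L):(ci + 1L)), 1L)
      planted <- plantVariant(codons, ci, cls, L)
      codons <- planted$codons
      v <- planted$variant
      v$origin <- "somatic"
      if (stats::runif(1) < germlineProb) {
        codons[gi] <- "AAA" # Lys; A->G at first base gives Glu (missense)
        g <- data.frame(pos = (gi - 1L) * 3L + 1L, ref = "A", alt = "G",
                        class = "missense", origin = "germline")
        v <- rbind(v, g)
      }
      v$transcript <- sprintf("tx%03d", i)
      vars[[i]] <- v
      seqs[i] <- paste(codons, collapse = "")
    }
    cds <- Biostrings::DNAStringSet(seqs)
    names(cds) <- sprintf("tx%03d", seq_len(nTranscripts))
    variants <- do.call(rbind, vars)
    variants <- variants[, c("transcript", "pos", "ref", "alt", "origin",
                             "class")]
    rownames(variants) <- NULL
    list(cds = cds, variants = variants)
  })
}

## Adjust the reference codons so the requested consequence class is realized
## by a single planted variant, and return that variant record.
#' @noRd
plantVariant <- function(codons, ci, cls, L) {
  var <- switch(cls,
    missense = {
      codons[ci] <- "GCT" # Ala; G->C gives CCT (Pro)
      data.frame(pos = (ci - 1L) * 3L + 1L, ref = "G", alt = "C",
                 class = cls)
    },
    synonymous = {
      codons[ci] <- "GCT" # Ala; T->C gives GCC (Ala)
      data.frame(pos = ci * 3L, ref = "T", alt = "C", class = cls)
    },
    stop_gained = {
      codons[ci] <- "TAC" # Tyr; C->A gives TAA (stop)
      data.frame(pos = ci * 3L, ref = "C", alt = "A", class = cls)
    },
    frameshift = {
      anchor <- substr(codons[ci], 1L, 1L)
      data.frame(pos = (ci - 1L) * 3L + 1L, ref = anchor,
                 alt = paste0(anchor, "A"), class = cls)
    },
    inframe_ins = {
      anchor <- substr(codons[ci], 3L, 3L)
      data.frame(pos = ci * 3L, ref = anchor,
                 alt = paste0(anchor, "GCT"), class = cls)
    },
    inframe_del = {
      ## delete codon ci+1, anchored on the last base of codon ci
      anchor <- substr(codons[ci], 3L, 3L)
      data.frame(pos = ci * 3L, ref = paste0(anchor, codons[ci + 1L]),
                 alt = anchor, class = cls)
    },
    start_lost = data.frame(pos = 1L, ref = "A", alt = "G", class = cls),
    stop_lost = {
      ## terminal stop is TAA; T->C gives CAA (Gln)
      data.frame(pos = (L - 1L) * 3L + 1L, ref = "T", alt = "C",
                 class = cls)
    },
    stop("unsupported variant class: ", cls))
  list(codons = codons, variant = var)
}
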