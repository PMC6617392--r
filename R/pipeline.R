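## Cohort-level orchestration on synthetic data, plus the small reporting
## statistics (fold enrichment with Fisher's exact test, non-silent mutation
## burden with a two-sample t-test).

#' Validate a cohort manifest
#'
#' A manifest lists one row per sample: \code{sample}, \code{patient},
#' \code{timepoint} (\code{"BL"} or \code{"PD"}) and \code{group}
#' (\code{"prolonged_benefit"} or \code{"primary_progression"}). Every PD
#' sample must have a BL sample from the same patient, and no sample id may
#' appear twice.
#'
#' @param manifest data.frame as above.
#' @return The manifest, invisibly, if valid; otherwise an error.
#' @export
validateManifest <- function(manifest) {
  need <- c("sample", "patient", "timepoint", "group")
  if (!all(need %in% names(manifest)))
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(manifest$sample))
    stop("duplicate sample id(s) in manifest")
  if (!all(manifest$timepoint %in% c("BL", "PD")))
    stop("timepoint must be 'BL' or 'PD'")
  pdPat <- manifest$patient[manifest$timepoint == "PD"]
  blPat <- manifest$patient[manifest$timepoint == "BL"]
  orphan <- setdiff(pdPat, blPat)
  if (length(orphan))
    stop("orphan PD sample(s) without a BL pair for patient(s): ",
         paste(orphan, collapse = ", "))
  invisible(manifest)
}

#' Fold enrichment of a label between two response groups with Fisher's test
#'
#' Builds the 2x2 contingency table of (has target label) x (group) and
#' reports the fold enrichment -- the label rate in the first group divided
#' by the rate in the second -- together with the two-sided Fisher's exact
#' p-value. A zero rate in the second group yields an infinite fold with a
#' flag.
#'
#' @param labels character, per-sample label (e.g. subtype).
#' @param groups character, per-sample group; exactly two distinct values.
#' @param target character(1), the label whose enrichment is tested.
#' @return list with \code{table}, \code{fold}, \code{p},
#'   \code{infinite_fold}.
#' @examples
#' enrichmentTable(rep(c("CMS2", "CMS4"), each = 5),
#'                 rep(c("A", "B"), each = 5), "CMS2")$p  # 0.0079
#' @export
enrichmentTable <- function(labels, groups, target) {
  g <- sort(unique(groups))
  if (length(g) != 2L) stop("exactly two groups are required")
  tab <- table(factor(labels == target, levels = c(TRUE, FALSE)),
               factor(groups, levels = g))
  rateA <- tab[1, 1] / sum(tab[, 1])
  rateB <- tab[1, 2] / sum(tab[, 2])
  fold <- if (rateB == 0) Inf else rateA / rateB
  p <- stats::fisher.test(tab)$p.value
  list(table = tab, fold = fold, p = p, infinite_fold = !is.finite(fold))
}

#' Non-silent mutation burden per sample and group comparison
#'
#' Counts the non-silent retained calls per sample, reports per-group
#' medians and a two-sample Student's t-test between the groups.
#'
#' @param calls data.frame with \code{sample} and logical \code{silent}.
#' @param groups named character, group per sample (names = sample ids).
#' @return list with \code{perSample} (data.frame sample/count/group),
#'   \code{medians} (per group) and \code{p} (t-test; NA when a group has
#'   fewer than 2 samples).
#' @export
mutationBurden <- function(calls, groups) {
  samples <- names(groups)
  counts <- vapply(samples, function(s)
    sum(calls$sample == s & !calls$silent), numeric(1))
  perSample <- data.frame(sample = samples, count = counts,
                          group = unname(groups), row.names = NULL)
  medians <- tapply(perSample$count, perSample$group, stats::median)
  p <- tryCatch(
    stats::t.test(count ~ group, data = perSample)$p.value,
    error = function(e) NA_real_)
  list(perSample = perSample, medians = medians, p = p)
}

#' @noRd
defaultConfig <- function() {
  list(seed = 1L, nPatients = 6L, depth = 1048L, noiseSd = 0.5,
    nGenes = 200L, nPermutations = 200L, nTranscripts = 8L,
    hlas = c("HLA-A*01:01", "HLA-A*02:01"))
}

#' Run the synthetic end-to-end analysis pipeline
#'
#' Generates a synthetic BL/PD cohort with known ground truth, then runs
#' every inference stage: ctDNA read-count simulation, TP53-anchored purity,
#' per-driver fractions and resistance gap; expression simulation, centroid
#' subtype calls and switch detection; immune scores with paired tests;
#' toy-transcriptome neoantigen burden; non-silent mutation burden and
#' subtype-by-group enrichment. All stage outputs are written as TSV plus a
#' JSON report with provenance (config hash, seed, package version). The
#' run is deterministic: the same config and seed produce byte-identical
#' outputs.
#'
#' @param outDir output directory (created if needed).
#' @param config named list overriding entries of the default configuration
#'   (\code{seed}, \code{nPatients}, \code{depth}, \code{noiseSd},
#'   \code{nGenes}, \code{nPermutations}, \code{nTranscripts}, \code{hlas}).
#' @param manifest optional cohort manifest; defaults to a generated one.
#'   Validated before any stage runs.
#' @return Invisibly, a list with the report (as written to
#'   \code{report.json}) and the per-stage tables.
#' @examples
#' \donttest{
#' res <- runPipeline(file.path(tempdir(), "demo"), config = list(seed = 7))
#' res$report$headline$median_resistance_gap
#' }
#' @export
runPipeline <- function(outDir, config = list(), manifest = NULL) {
  cfg <- utils::modifyList(defaultConfig(), config)
  seed <- cfg$seed
  nP <- cfg$nPatients
  if (is.null(manifest)) {
    manifest <- data.frame(
      sample = c(sprintf("P%02dBL", seq_len(nP)),
                 sprintf("P%02dPD", seq_len(nP))),
      patient = rep(sprintf("P%02d", seq_len(nP)), 2L),
      timepoint = rep(c("BL", "PD"), each = nP),
      group = rep(rep(c("prolonged_benefit", "primary_progression"),
                      length.out = nP), 2L))
  }
  validateManifest(manifest)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  ## ---- ground truth ---------------------------------------------------
  truth <- withSeed(deriveSeed(seed, "pipeline-truth"), {
    lapply(seq_len(nP), function(i) {
      nDrivers <- sample(0:2, 1L)
      list(patient = sprintf("P%02d", i),
        purityBl = stats::runif(1, 0.3, 0.7),
        purityPd = stats::runif(1, 0.3, 0.7),
        driverFrac = if (nDrivers > 0) stats::runif(nDrivers, 0.05, 0.4)
                     else numeric(0))
    })
  })

  ## ---- ctDNA stage: readcounts, purity, driver fractions, gap ---------
  driverGenes <- c("KRAS", "NRAS", "BRAF", "EGFR", "MAP2K1")
  allCounts <- list()
  gapRows <- list()
  for (i in seq_len(nP)) {
    tr <- truth[[i]]
    for (tp in c("BL", "PD")) {
      sampleId <- paste0(tr$patient, tp)
      fr <- if (tp == "PD") tr$driverFrac else numeric(0)
      pur <- if (tp == "PD") tr$purityPd else tr$purityBl
      clonesDf <- data.frame(clone = "truncal", ccf = 1)
      mutDf <- data.frame(id = "TP53", clone = "truncal",
                          copiesMutated = 1L, copiesTotal = 1L)
      if (length(fr)) {
        clonesDf <- rbind(clonesDf,
          data.frame(clone = sprintf("res%d", seq_along(fr)), ccf = fr))
        mutDf <- rbind(mutDf, data.frame(
          id = driverGenes[seq_along(fr)],
          clone = sprintf("res%d", seq_along(fr)),
          copiesMutated = 1L, copiesTotal = 2L))
      }
      arch <- ClonalArchitecture(pur, clonesDf, mutDf)
      rc <- simulateCtdnaCohort(arch, cfg$depth,
        deriveSeed(seed, paste0("rc-", sampleId)),
        nPassengers = 4L)
      rc$sample <- sampleId
      allCounts[[sampleId]] <- rc
      tp53 <- rc[rc$id == "TP53", ]
      purHat <- estimateCtdnaPurity(tp53$vaf, 1L, 1L)
      drv <- rc[rc$id %in% driverGenes & rc$alt_reads >= 2L, ]
      fracs <- if (nrow(drv))
        driverFraction(drv$vaf, purHat, drv$copiesTotal) else numeric(0)
      rg <- resistanceGap(fracs)
      gapRows[[sampleId]] <- data.frame(sample = sampleId,
        patient = tr$patient, timepoint = tp,
        purity_hat = purity(purHat), n_drivers = nrow(drv),
        total_driver_fraction = totalDriverFraction(rg), gap = gap(rg))
    }
  }
  readcounts <- do.call(rbind, allCounts)
  gapTable <- do.call(rbind, gapRows)
  rownames(readcounts) <- rownames(gapTable) <- NULL
  writeTsv(readcounts, file.path(outDir, "readcounts.tsv"))
  writeTsv(gapTable, file.path(outDir, "resistance_gap.tsv"))

  ## ---- expression stage: subtype calls and switches -------------------
  subtypes <- c("CMS1", "CMS2", "CMS3", "CMS4")
  centroids <- withSeed(deriveSeed(seed, "pipeline-centroids"),
    matrix(stats::rnorm(cfg$nGenes * length(subtypes)), cfg$nGenes,
           length(subtypes),
           dimnames = list(sprintf("g%04d", seq_len(cfg$nGenes)),
                           subtypes)))
  ## BL tumors are CMS2; on progression, primary-progression patients
  ## switch to CMS4
  blType <- rep("CMS2", nP)
  pdType <- ifelse(manifest$group[manifest$timepoint == "PD"] ==
                     "primary_progression", "CMS4", "CMS2")
  expr <- simulateExpressionCohort(centroids, c(blType, pdType),
                                   cfg$noiseSd,
                                   deriveSeed(seed, "pipeline-expr"))
  colnames(expr) <- manifest$sample[order(manifest$timepoint)]
  exprN <- normalizeAndCenter(expr, "median_center")
  calls <- lapply(colnames(exprN), function(s)
    assignCentroidSubtype(exprN[, s], centroids))
  names(calls) <- colnames(exprN)
  callTable <- data.frame(sample = names(calls),
    label = vapply(calls, subtypeLabel, character(1)),
    confidence = vapply(calls, callConfidence, character(1)),
    best_r = vapply(calls, function(cl) max(subtypeScores(cl)), numeric(1)),
    row.names = NULL)
  writeTsv(callTable, file.path(outDir, "subtype_calls.tsv"))
  switches <- do.call(rbind, lapply(seq_len(nP), function(i) {
    pat <- sprintf("P%02d", i)
    sw <- detectSubtypeSwitch(calls[[paste0(pat, "BL")]],
                              calls[[paste0(pat, "PD")]])
    data.frame(patient = pat, from = sw$from, to = sw$to,
               switched = sw$switched, is_cms2_to_4 = sw$is_cms2_to_4)
  }))
  writeTsv(switches, file.path(outDir, "subtype_switches.tsv"))

  ## ---- immune stage ----------------------------------------------------
  immuneGenes <- c("GZMA", "PRF1", "BATF3", "XCR1", "CLEC9A", "THBD")
  immuneExpr <- withSeed(deriveSeed(seed, "pipeline-immune"),
    matrix(stats::rexp(length(immuneGenes) * nrow(manifest), rate = 0.2),
      length(immuneGenes), nrow(manifest),
      dimnames = list(immuneGenes, manifest$sample)))
  cyt <- cytolyticActivity(immuneExpr["GZMA", ], immuneExpr["PRF1", ])
  dc <- apply(immuneExpr, 2, signatureMean,
              genes = c("BATF3", "XCR1", "CLEC9A", "THBD"))
  scoreTable <- data.frame(sample = manifest$sample, cyt = unname(cyt),
                           batf3_dc = unname(dc), row.names = NULL)
  writeTsv(scoreTable, file.path(outDir, "immune_scores.tsv"))
  blS <- rbind(CYT = cyt[sprintf("P%02dBL", seq_len(nP))],
               BATF3_DC = dc[sprintf("P%02dBL", seq_len(nP))])
  pdS <- rbind(CYT = cyt[sprintf("P%02dPD", seq_len(nP))],
               BATF3_DC = dc[sprintf("P%02dPD", seq_len(nP))])
  paired <- pairedChangeTests(blS, pdS, method = "paired_t")
  writeTsv(paired, file.path(outDir, "paired_tests.tsv"))

  ## ---- neoantigen stage ------------------------------------------------
  toy <- makeToyTranscriptome(cfg$nTranscripts, c(20L, 40L),
                              seed = deriveSeed(seed, "pipeline-toy"))
  burden <- neoantigenBurden(toy$cds, toy$variants, cfg$hlas)
  writeTsv(burden$perTranscript,
           file.path(outDir, "neoantigen_per_transcript.tsv"))

  ## ---- burden and enrichment reporting --------------------------------
  somatic <- readcounts[readcounts$origin == "somatic" &
                          readcounts$alt_reads >= 3L, ]
  ## passengers alternate silent / non-silent; drivers and TP53 non-silent
  somatic$silent <- grepl("passenger_0*[02468]$", somatic$id)
  groups <- stats::setNames(manifest$group, manifest$sample)
  burdenStats <- mutationBurden(somatic, groups)
  writeTsv(burdenStats$perSample, file.path(outDir, "mutation_burden.tsv"))
  pdCalls <- callTable[grepl("PD$", callTable$sample), ]
  enr <- enrichmentTable(pdCalls$label,
    groups[pdCalls$sample], "CMS4")

  report <- list(
    provenance = list(
      package = "clonalgap",
      version = as.character(utils::packageVersion("clonalgap")),
      seed = seed,
      config_hash = fnv1a32(paste(deparse(cfg), collapse = ""))),
    files = list.files(outDir, pattern = "\\.tsv$"),
    headline = list(
      median_resistance_gap_pd =
        stats::median(gapTable$gap[gapTable$timepoint == "PD"]),
      n_cms2_to_4_switches = sum(switches$is_cms2_to_4),
      n_patients = nP,
      neoantigen_burden = burden$burden,
      cms4_enrichment_fold = if (is.finite(enr$fold)) enr$fold else "Inf",
      cms4_enrichment_p = enr$p,
      burden_t_p = burdenStats$p))
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(report = report, gapTable = gapTable,
                 callTable = callTable, switches = switches,
                 immune = scoreTable, paired = paired,
                 burden = burdenStats, readcounts = readcounts))
}
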