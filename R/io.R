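## Plain-text I/O helpers. All tables are tab-separated with a header, no
## quoting and no row names, so repeated runs produce byte-identical files.

#' Read / write the package's TSV dialect
#'
#' @param path file path.
#' @param x data.frame to write.
#' @return \code{readTsv} returns a data.frame.
#' @rdname tsv-io
#' @export
readTsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname tsv-io
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated: name, description, then
#' gene identifiers.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  if (any(lengths(sets) == 0L)) stop("empty gene set(s) in GMT")
  sets
}

#' Read a BED-like segment TSV into a copy-number GRanges
#'
#' Expects columns \code{chrom}, \code{start}, \code{end} (1-based
#' inclusive), \code{cnAbsolute} and optionally \code{cnTotal},
#' \code{cnMinor}.
#'
#' @param path TSV file path.
#' @return GRanges as from [copySegments()].
#' @export
readSegments <- function(path) {
  segmentsFromDataFrame(readTsv(path))
}

#' @noRd
segmentsToDataFrame <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    cnAbsolute = S4Vectors::mcols(gr)$cnAbsolute,
    cnTotal = S4Vectors::mcols(gr)$cnTotal,
    cnMinor = S4Vectors::mcols(gr)$cnMinor)
}
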