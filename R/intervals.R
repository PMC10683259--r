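# Genomic interval handling. Intervals are 0-based half-open on disk
# (BED) and in the coordinate tables; in memory they are GRanges
# (1-based closed), converted at the boundary.

#' Build a GRanges from 0-based half-open records
#'
#' @param chrom,start,end vectors in BED convention (`start < end`,
#'   0-based half-open).
#' @param name optional interval names.
#' @return A [GenomicRanges::GRanges] object, sorted within chromosome.
#' @export
interval_set <- function(chrom, start, end, name = NULL) {
  if (any(start >= end)) {
    stop_methrisk("interval start must be < end (0-based half-open)",
                  "methrisk_invalid_input")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end)
  )
  if (!is.null(name)) names(gr) <- name
  GenomicRanges::sort(gr)
}

#' Read / write BED interval files
#'
#' Thin wrappers over [rtracklayer::import.bed]/[rtracklayer::export.bed]
#' so all interval I/O keeps the BED 0-based half-open convention.
#'
#' @param path BED file path.
#' @param gr a `GRanges`.
#' @return A `GRanges` (reader); `path`, invisibly (writer).
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' @rdname read_bed
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Map CpG sites to genomic intervals
#'
#' Each CpG at 0-based position `pos` becomes the 0-based half-open
#' interval `[pos - flank, pos + flank + 1)`; with the default
#' `flank = 0` this is the single-base CpG footprint.
#'
#' @param cpg_ids character vector of CpG identifiers.
#' @param coords coordinate table (`cpg`, `chrom`, `start`, `end`),
#'   e.g. the `coords` slot of a [methylation_matrix()].
#' @param flank non-negative integer flank in base pairs.
#' @return A `GRanges` named by CpG id.
#' @export
map_cpgs_to_intervals <- function(cpg_ids, coords, flank = 0L) {
  stopifnot(is_count(flank))
  idx <- match(cpg_ids, coords$cpg)
  if (anyNA(idx)) {
    stop_methrisk(paste0("CpGs without coordinates: ",
                         paste(cpg_ids[is.na(idx)], collapse = ", ")),
                  "methrisk_unknown_cpg")
  }
  pos <- coords$start[idx]
  gr <- GenomicRanges::GRanges(
    seqnames = coords$chrom[idx],
    ranges = IRanges::IRanges(start = pmax(pos - flank, 0L) + 1L,
                              end = pos + flank + 1L)
  )
  names(gr) <- cpg_ids
  gr
}
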