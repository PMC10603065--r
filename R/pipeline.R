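#' Run the read-level pipeline: quality filter, demultiplex, annotate
#'
#' Convenience wrapper chaining [quality_filter()], [demultiplex()] and
#' [annotate_reads()] with the standard settings. Read conservation
#' holds: every input read is exactly one of retained-and-assigned,
#' unassigned, quality-rejected, or annotation-rejected.
#'
#' @param reads read table (e.g. from [read_fastq()], barcodes still
#'   attached).
#' @param barcodes a [barcode_spec()].
#' @param scaffolds list of [scaffold_ref()].
#' @param min_phred quality threshold, default 40.
#' @param fraction_required fraction of bases required at `min_phred`,
#'   default 1.
#' @param identity_floor scaffold-call floor, default 0.70.
#' @return list: `clones`, `read_map`, `rejects` (annotation),
#'   `unassigned` (demultiplexing), `n_quality_rejected`, `n_input`.
#' @export
process_reads <- function(reads, barcodes, scaffolds, min_phred = 40L,
                          fraction_required = 1.0, identity_floor = 0.70) {
  n_input <- nrow(reads)
  kept <- quality_filter(reads, min_phred, fraction_required)
  dm <- demultiplex(kept, barcodes)
  ann <- annotate_reads(dm$assigned, scaffolds, identity_floor)
  c(ann, list(unassigned = dm$unassigned,
              n_quality_rejected = n_input - nrow(kept),
              n_input = n_input))
}
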