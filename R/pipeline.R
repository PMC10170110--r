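#' Run the full quantification pipeline
#'
#' Decode -> exact alignment -> feature assignment -> UMI collapse ->
#' weighted expression matrix -> per-cell and run-level QC. Accepts file
#' paths or pre-loaded objects for every input, so the same entry point
#' serves FASTQ runs and in-memory simulations.
#'
#' @param fastq Read FASTQ path, or a character vector of read sequences.
#' @param reference FASTA path, `DNAStringSet`, or an existing
#'   [build_index()].
#' @param annotations GFF3/BED path or an annotation `data.frame`.
#' @param whitelist Whitelist path or character vector.
#' @param barcode_fastq Index-read FASTQ path or sequence vector (for the
#'   separate-index-read layout).
#' @param layout A [read_layout()].
#' @param umi_mismatch UMI adjacency tolerance (default 1).
#' @param priority Biotype priority for feature assignment.
#' @return A list with `decoded` (full decode table), `counters`,
#'   `hits` (annotated hit table), `molecules` (read-level records),
#'   `quant` (list of `matrix`, `features`, `molecules`), `qc`
#'   (per-cell stats), and `run` (run-level stats).
#' @export
run_pipeline <- function(fastq, reference, annotations, whitelist,
                         barcode_fastq = NULL, layout = read_layout(),
                         umi_mismatch = 1L, priority = biotype_priority()) {
  if (length(whitelist) == 1L && file.exists(whitelist)) {
    whitelist <- read_whitelist(whitelist)
  }
  if (length(fastq) == 1L && file.exists(fastq)) {
    dm <- demultiplex(fastq, layout, whitelist, barcode_fastq)
  } else {
    bc <- barcode_fastq
    if (!is.null(bc) && length(bc) == 1L && file.exists(bc)) {
      bc <- .read_fastq(bc)$seqs
    }
    decoded <- parse_reads(fastq, layout, barcode_seqs = bc,
                           whitelist = whitelist)
    statuses <- c("ok", "no_adapter5", "no_adapter3", "bad_length",
                  "barcode_unassigned")
    counters <- vapply(statuses, function(s) sum(decoded$status == s), 0L)
    dm <- list(reads = decoded[decoded$status == "ok", , drop = FALSE],
               decoded = decoded,
               counters = c(counters, total = nrow(decoded)))
  }
  index <- if (inherits(reference, "exact_index")) reference
           else build_index(reference)
  ann <- if (is.data.frame(annotations)) annotations
         else read_annotations(annotations)
  hits <- align_inserts(dm$reads$insert, index)
  assigned <- assign_hits(hits, ann, priority)
  mols <- build_molecules(dm$reads, assigned)
  quant <- weight_and_sum(mols, umi_mismatch)
  qc <- if (nrow(mols)) {
    cell_qc(quant, mols, dm$decoded)
  } else {
    NULL
  }
  list(decoded = dm$decoded, counters = dm$counters, hits = assigned,
       molecules = mols, quant = quant, qc = qc, run = run_stats(dm$decoded))
}
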