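#' Sequencing saturation
#'
#' `saturation = 1 - N_deduped_reads / N_total_reads`, where
#' `N_deduped_reads` is the total UMI count in the cell and
#' `N_total_reads` the total mapped small RNA read count. Approaches 1 as
#' re-sequencing of already-seen molecules dominates.
#'
#' @param n_deduped Total UMI counts per cell (may be fractional after
#'   multimapper weighting).
#' @param n_total Total mapped small RNA read counts per cell.
#' @return Numeric saturation in `[0, 1]` (vectorised).
#' @examples
#' saturation(20, 200)  # 0.9
#' @export
saturation <- function(n_deduped, n_total) {
  if (any(n_total == 0)) stop("saturation undefined for N_total_reads == 0")
  if (any(n_deduped < 0) || any(n_total < 0)) stop("negative read counts")
  if (any(n_deduped > n_total)) {
    stop("N_deduped_reads cannot exceed N_total_reads")
  }
  1 - n_deduped / n_total
}

#' Per-cell small RNA ratio
#'
#' For a barcoded single-cell run:
#' `(small_rna_reads / total_reads_cell) *
#'  (reads_with_cell_barcodes / total_sequenced_reads)`.
#'
#' @param small_rna_reads Small RNA (mapped, length-filtered) reads of the
#'   cell.
#' @param total_reads_cell All reads carrying the cell's barcode.
#' @param reads_with_cell_barcodes Run-level reads with a valid barcode.
#' @param total_sequenced_reads Run-level total sequenced reads.
#' @return Numeric ratio in `[0, 1]`.
#' @export
small_rna_ratio_cell <- function(small_rna_reads, total_reads_cell,
                                 reads_with_cell_barcodes,
                                 total_sequenced_reads) {
  if (any(total_reads_cell == 0) || total_sequenced_reads == 0) {
    stop("zero denominator in small RNA ratio")
  }
  (small_rna_reads / total_reads_cell) *
    (reads_with_cell_barcodes / total_sequenced_reads)
}

#' Bulk small RNA ratio
#'
#' `small_rna_reads / total_sequenced_reads`, the definition used for
#' non-barcoded libraries.
#'
#' @param small_rna_reads Small RNA read count.
#' @param total_sequenced_reads Total sequenced reads.
#' @return Numeric ratio.
#' @export
small_rna_ratio_bulk <- function(small_rna_reads, total_sequenced_reads) {
  if (any(total_sequenced_reads == 0)) {
    stop("zero denominator in small RNA ratio")
  }
  small_rna_reads / total_sequenced_reads
}

#' Pairwise Jaccard reproducibility of detected species
#'
#' `Intersect(set1, set2) / Union(set1, set2)` over every unordered pair
#' of cells; the mean over pairs summarises the run. A pair of two empty
#' sets is defined as 0 (with a warning).
#'
#' @param x Either a features x cells matrix (detected = value >
#'   `threshold`) or a list of per-cell character vectors of detected
#'   species.
#' @param threshold Detection threshold on the weighted count (default 0:
#'   any evidence counts).
#' @return A list with `matrix` (symmetric Jaccard matrix, unit diagonal)
#'   and `mean` (average over unordered pairs; `NA` for < 2 cells).
#' @export
reproducibility <- function(x, threshold = 0) {
  sets <- if (is.list(x) && !is.data.frame(x)) {
    lapply(x, unique)
  } else {
    stopifnot(!is.null(rownames(x)))
    s <- lapply(seq_len(ncol(x)), function(j) rownames(x)[x[, j] > threshold])
    names(s) <- colnames(x)
    s
  }
  n <- length(sets)
  J <- matrix(1, n, n, dimnames = list(names(sets), names(sets)))
  warned <- FALSE
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        u <- length(union(sets[[i]], sets[[j]]))
        if (u == 0) {
          if (!warned) {
            warning("pair(s) of empty detection sets: Jaccard defined as 0")
            warned <- TRUE
          }
          J[i, j] <- J[j, i] <- 0
        } else {
          J[i, j] <- J[j, i] <- length(intersect(sets[[i]], sets[[j]])) / u
        }
      }
    }
  }
  list(matrix = J,
       mean = if (n >= 2) mean(J[upper.tri(J)]) else NA_real_)
}

#' Per-cell quality statistics
#'
#' Combines the decode table, annotated hits and the quantified matrix
#' into one row per cell: mapped reads, deduplicated (weighted UMI)
#' totals, saturation, species counts, and the miRNA molecule fraction.
#' Cells with no mapped reads get `NA` saturation with a warning.
#'
#' @param quant Result of [weight_and_sum()].
#' @param molecules Molecule records from [build_molecules()] (read
#'   level, pre-collapse).
#' @param decoded Full decode table (all statuses) from [demultiplex()].
#' @return `data.frame` with columns `cell_barcode`, `n_total_reads`,
#'   `n_deduped_reads`, `saturation`, `small_rna_reads`,
#'   `total_reads_cell`, `n_species`, `n_mirna_species`, `mirna_fraction`.
#' @export
cell_qc <- function(quant, molecules, decoded) {
  m <- quant$matrix
  cells <- colnames(m)
  mols <- data.table::as.data.table(molecules)
  ## mapped reads per cell: distinct reads with >= 1 hit
  mapped <- mols[, list(n_total_reads = length(unique(read_id))),
                 by = "cell_barcode"]
  n_total <- mapped$n_total_reads[match(cells, mapped$cell_barcode)]
  n_total[is.na(n_total)] <- 0L
  n_deduped <- Matrix::colSums(m)
  sat <- rep(NA_real_, length(cells))
  pos <- n_total > 0
  if (any(!pos)) warning("cell(s) with no mapped reads: saturation is NA")
  sat[pos] <- saturation(n_deduped[pos], n_total[pos])
  mir <- quant$features$feature_id[quant$features$biotype == "miRNA"]
  mir_mass <- if (length(mir)) {
    Matrix::colSums(m[rownames(m) %in% mir, , drop = FALSE])
  } else {
    rep(0, length(cells))
  }
  total_cell <- table(decoded$corrected_barcode)[cells]
  total_cell <- as.integer(ifelse(is.na(total_cell), 0L, total_cell))
  data.frame(
    cell_barcode = cells,
    n_total_reads = n_total,
    n_deduped_reads = as.numeric(n_deduped),
    saturation = sat,
    small_rna_reads = n_total,
    total_reads_cell = total_cell,
    n_species = as.integer(Matrix::colSums(m > 0)),
    n_mirna_species = as.integer(
      Matrix::colSums(m[rownames(m) %in% mir, , drop = FALSE] > 0)
    ),
    mirna_fraction = ifelse(n_deduped > 0, mir_mass / n_deduped, NA_real_),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Run-level statistics
#'
#' @param decoded Full decode table from [demultiplex()].
#' @return List with `total_sequenced_reads` and
#'   `reads_with_cell_barcodes` (reads whose barcode corrected to a
#'   whitelist entry).
#' @export
run_stats <- function(decoded) {
  list(
    total_sequenced_reads = nrow(decoded),
    reads_with_cell_barcodes = sum(!is.na(decoded$corrected_barcode))
  )
}

#' Downsampling sensitivity curve
#'
#' Randomly samples reads without replacement at each requested depth
#' (before decoding), re-runs decode, alignment and quantification, and
#' reports the mean number of miRNA species detected per cell — the
#' sequencing-depth sensitivity curve.
#'
#' @param seqs Character vector of raw read sequences.
#' @param barcode_seqs Matching index-read sequences (or `NULL`).
#' @param depths Integer vector of read depths.
#' @param seed RNG seed (required; sampling is the only randomness).
#' @param layout,whitelist,index,annotations Pipeline inputs.
#' @param umi_mismatch UMI adjacency tolerance.
#' @return `data.frame` with `depth` and `mean_mirna_species`. Depths
#'   exceeding the available reads are skipped with a warning; depth 0
#'   reports 0 species.
#' @export
downsample_curve <- function(seqs, barcode_seqs = NULL, depths, seed,
                             layout = read_layout(), whitelist, index,
                             annotations, umi_mismatch = 1L) {
  stopifnot(!missing(seed))
  n <- length(seqs)
  keep <- depths <= n
  if (any(!keep)) {
    warning("depth(s) exceeding available reads skipped: ",
            paste(depths[!keep], collapse = ", "))
  }
  depths <- depths[keep]
  set.seed(seed)
  out <- lapply(depths, function(d) {
    if (d == 0) {
      return(data.frame(depth = 0L, mean_mirna_species = 0))
    }
    idx <- sample.int(n, d)
    dec <- parse_reads(seqs[idx], layout,
                       barcode_seqs = if (is.null(barcode_seqs)) NULL
                                      else barcode_seqs[idx],
                       whitelist = whitelist)
    ok <- dec[dec$status == "ok", , drop = FALSE]
    if (!nrow(ok)) {
      return(data.frame(depth = d, mean_mirna_species = 0))
    }
    hits <- align_inserts(ok$insert, index)
    assigned <- assign_hits(hits, annotations)
    mols <- build_molecules(ok, assigned)
    quant <- weight_and_sum(mols, umi_mismatch)
    mir <- quant$features$feature_id[quant$features$biotype == "miRNA"]
    spp <- Matrix::colSums(
      quant$matrix[rownames(quant$matrix) %in% mir, , drop = FALSE] > 0
    )
    data.frame(depth = d, mean_mirna_species = mean(spp))
  })
  do.call(rbind, out)
}
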