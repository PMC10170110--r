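#' UMI connected components at one-mismatch adjacency
#'
#' Reads with the same index tag, or tags adjacent at Hamming distance
#' <= `max_mismatch`, belong to one molecule: components of the graph
#' whose nodes are the distinct observed UMIs and whose edges join pairs
#' within the mismatch tolerance. Edges are found by neighbour generation
#' (every single-position substitution is looked up in the UMI set) and
#' merged with union-find, so no pairwise distance matrix is formed.
#'
#' @param umis Character vector of equal-length UMIs (one entry per read).
#' @param max_mismatch Adjacency tolerance in bases (default 1).
#' @return Integer component id per input element, numbered from 1 in
#'   order of first appearance.
#' @export
umi_components <- function(umis, max_mismatch = 1L) {
  u <- unique(umis)
  k <- length(u)
  if (k == 0L) return(integer(0))
  if (k == 1L || max_mismatch == 0L) {
    comp <- if (max_mismatch == 0L) seq_len(k) else rep.int(1L, k)
    return(comp[match(umis, u)])
  }
  if (max_mismatch > 1L) {
    stop("max_mismatch > 1 is not supported")
  }
  L <- unique(nchar(u))
  if (length(L) != 1L) stop("UMIs must share one length")
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  idx <- seq_len(k)
  for (pos in seq_len(L)) {
    cur <- substr(u, pos, pos)
    for (b in c("A", "C", "G", "T")) {
      variant <- u
      substr(variant, pos, pos) <- b
      j <- match(variant, u)
      hit <- which(!is.na(j) & cur != b & j > idx)
      for (h in hit) {
        ri <- find(h)
        rj <- find(j[h])
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(idx, find, integer(1))
  comp <- match(roots, unique(roots))
  comp[match(umis, u)]
}

#' Count deduplicated molecules in one (cell, feature) group
#'
#' @inheritParams umi_components
#' @return Integer number of UMI components (0 for an empty group).
#' @examples
#' collapse_umis(c("AAAAAAAA", "AAAAAAAT", "TTTTTTTT"))  # 2
#' @export
collapse_umis <- function(umis, max_mismatch = 1L) {
  if (!length(umis)) return(0L)
  max(umi_components(umis, max_mismatch))
}

#' Expand decoded reads into per-feature molecule records
#'
#' Joins accepted decoded reads with their annotated alignment hits. A
#' read hitting `n_hits` genomic loci receives, for each feature, weight
#' `n_loci(feature) / n_hits`, so its weights over features sum to 1.
#'
#' @param decoded Decode table of `ok` reads (see [parse_reads()]).
#' @param assigned Annotated hit table from [assign_hits()].
#' @return A `data.table` with one row per (read, feature):
#'   `read_id`, `cell_barcode`, `umi`, `insert`, `feature_id`, `biotype`,
#'   `n_hits`, `weight`.
#' @export
build_molecules <- function(decoded, assigned) {
  reads <- data.table::as.data.table(
    decoded[, c("read_id", "corrected_barcode", "umi", "insert")]
  )
  data.table::setnames(reads, "corrected_barcode", "cell_barcode")
  hits <- data.table::as.data.table(
    assigned[, c("insert", "feature_id", "biotype", "n_hits")]
  )
  ## per (insert, feature): number of loci backing the feature
  feat <- hits[, list(n_loci = .N, n_hits = n_hits[1L]),
               by = c("insert", "feature_id", "biotype")]
  feat[, weight := n_loci / n_hits]
  mols <- merge(reads, feat, by = "insert", allow.cartesian = TRUE)
  data.table::setorderv(mols, c("cell_barcode", "feature_id", "insert", "umi"))
  mols[, c("read_id", "cell_barcode", "umi", "insert", "feature_id",
           "biotype", "n_hits", "weight"), with = FALSE]
}

#' Collapse UMIs per (cell, feature) and sum weighted molecules
#'
#' Within each (cell, feature) group, reads are collapsed into molecules
#' by [umi_components()]; each molecule contributes its multimapping
#' weight (1/`n_hits` per locus) to the matrix entry. When a component
#' merges reads of different inserts, it takes the weight of its first
#' read in deterministic (insert, umi) order.
#'
#' @param molecules Molecule records from [build_molecules()].
#' @param umi_mismatch UMI adjacency tolerance (default 1).
#' @param cells Optional cell barcodes fixing column order; defaults to
#'   the sorted observed barcodes.
#' @return A list: `matrix` (sparse dgCMatrix, features x cells of
#'   weighted UMI counts), `features` (data.frame of `feature_id`,
#'   `biotype`), `molecules` (data.table of per-molecule records with
#'   `cell_barcode`, `feature_id`, `comp`, `weight`, `read_support`).
#' @export
weight_and_sum <- function(molecules, umi_mismatch = 1L, cells = NULL) {
  mols <- data.table::as.data.table(molecules)
  if (!nrow(mols)) {
    feats <- data.frame(feature_id = character(0), biotype = character(0))
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(0L, length(cells)),
                              dimnames = list(NULL, cells))
    return(list(matrix = m, features = feats,
                molecules = data.table::data.table()))
  }
  data.table::setorderv(mols, c("cell_barcode", "feature_id", "insert", "umi"))
  mols[, comp := umi_components(umi, umi_mismatch),
       by = c("cell_barcode", "feature_id")]
  dedup <- mols[, list(weight = weight[1L], read_support = .N,
                       biotype = biotype[1L]),
                by = c("cell_barcode", "feature_id", "comp")]
  counts <- dedup[, list(count = sum(weight)),
                  by = c("cell_barcode", "feature_id", "biotype")]
  feats <- unique(counts[, c("feature_id", "biotype"), with = FALSE])
  data.table::setorderv(feats, "feature_id")
  if (is.null(cells)) cells <- sort(unique(counts$cell_barcode))
  m <- Matrix::sparseMatrix(
    i = match(counts$feature_id, feats$feature_id),
    j = match(counts$cell_barcode, cells),
    x = counts$count,
    dims = c(nrow(feats), length(cells)),
    dimnames = list(feats$feature_id, cells)
  )
  list(matrix = m, features = as.data.frame(feats), molecules = dedup)
}

#' Write a sparse expression matrix directory
#'
#' 10x-style triplet layout: `matrix.mtx` (MatrixMarket), `barcodes.tsv`
#' (one cell barcode per line) and `features.tsv` (`feature_id`,
#' `biotype`).
#'
#' @param quant Result of [weight_and_sum()] (or a list with `matrix` and
#'   `features`).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_matrix_dir <- function(quant, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(quant$matrix, file.path(dir, "matrix.mtx"))
  writeLines(colnames(quant$matrix), file.path(dir, "barcodes.tsv"))
  utils::write.table(quant$features, file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a sparse expression matrix directory
#'
#' @param dir Directory written by [write_matrix_dir()].
#' @return A list with `matrix` (dgCMatrix with dimnames) and `features`.
#' @export
read_matrix_dir <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  features <- utils::read.delim(file.path(dir, "features.tsv"),
                                stringsAsFactors = FALSE)
  dimnames(m) <- list(features$feature_id, barcodes)
  list(matrix = m, features = features)
}
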