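#' Simulation configuration
#'
#' Bundles every parameter of the synthetic data generator. Defaults
#' emulate a small but realistic nanowell single-cell small RNA run: one
#' 100-kb contig carrying ~200 non-overlapping small RNA loci dominated
#' by miRNAs, 50 cells at 300 molecules each, and a power-law expression
#' skew (exponent 1.2) under which the ten most abundant features carry
#' more than half of a cell's molecules — the hallmark of cultured-cell
#' miRNA profiles.
#'
#' @param seed Integer seed; identical configurations reproduce
#'   byte-identical outputs. Mandatory.
#' @param n_contigs,contig_length Reference geometry.
#' @param n_features Named integer vector of loci per biotype.
#' @param feature_length Named list of `c(min, max)` mature lengths (nt)
#'   per biotype; all within the 16-39 nt insert window.
#' @param n_cells Cells (barcodes actually used).
#' @param molecules_per_cell Molecules per cell: a single integer or a
#'   vector of length `n_cells`.
#' @param skew Power-law exponent of expression over feature ranks
#'   (0 = uniform).
#' @param duplication Reads sequenced per molecule (PCR/optical
#'   duplication factor D), a positive integer.
#' @param error_rate Per-base substitution error rate applied i.i.d. to
#'   every emitted read (no indels: the pipeline matches adapters and
#'   aligns inserts exactly, so indels only create rejects).
#' @param layout A [read_layout()].
#' @param n_barcodes Whitelist size; pairwise Hamming distance is kept at
#'   least `min_barcode_dist` so 2-error correction stays unambiguous.
#' @param min_barcode_dist Minimum pairwise whitelist distance.
#' @param multimap_copies Number of miRNA loci planted a second time with
#'   an identical sequence, to exercise multimapper weighting (default 0).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_contigs = 1L,
                       contig_length = 100000L,
                       n_features = c(miRNA = 120L, tRNA = 30L, rRNA = 20L,
                                      snRNA = 10L, snoRNA = 10L, CDS = 10L),
                       feature_length = list(
                         miRNA = c(21L, 23L), tRNA = c(28L, 36L),
                         rRNA = c(25L, 39L), snRNA = c(20L, 30L),
                         snoRNA = c(20L, 30L), CDS = c(18L, 35L),
                         other = c(16L, 39L)),
                       n_cells = 50L,
                       molecules_per_cell = 300L,
                       skew = 1.2,
                       duplication = 1L,
                       error_rate = 0,
                       layout = read_layout(),
                       n_barcodes = 96L,
                       min_barcode_dist = 5L,
                       multimap_copies = 0L) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(
    is.numeric(seed), length(seed) == 1L,
    n_contigs >= 1, contig_length >= 1000,
    all(n_features >= 0), sum(n_features) >= 1,
    all(names(n_features) %in% biotype_priority()),
    n_cells >= 1, all(molecules_per_cell >= 0),
    length(molecules_per_cell) %in% c(1L, n_cells),
    skew >= 0, duplication >= 1,
    error_rate >= 0, error_rate <= 1,
    inherits(layout, "read_layout"),
    n_barcodes >= n_cells, min_barcode_dist >= 1,
    multimap_copies >= 0, multimap_copies <= n_features[["miRNA"]]
  )
  structure(list(
    seed = as.integer(seed), n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length),
    n_features = n_features, feature_length = feature_length,
    n_cells = as.integer(n_cells),
    molecules_per_cell = as.integer(molecules_per_cell),
    skew = skew, duplication = as.integer(duplication),
    error_rate = error_rate, layout = layout,
    n_barcodes = as.integer(n_barcodes),
    min_barcode_dist = as.integer(min_barcode_dist),
    multimap_copies = as.integer(multimap_copies)
  ), class = "sim_config")
}

## contiguous fixed run of the 3' adapter (its anchoring substring)
.adapter3_anchor <- function(layout) {
  runs <- regmatches(layout$adapter3,
                     gregexpr("[ACGT]+", layout$adapter3))[[1]]
  runs[which.max(nchar(runs))]
}

## A mature sequence is decodable without ambiguity iff it neither
## contains the 3'-adapter anchor nor ends with one of its prefixes long
## enough (>= 6 nt here) that a shifted anchor window could match across
## the insert/adapter boundary.
.insert_decodable <- function(x, anchor) {
  if (grepl(anchor, x, fixed = TRUE)) return(FALSE)
  for (k in 6:min(nchar(anchor) - 1L, nchar(x))) {
    if (substr(x, nchar(x) - k + 1L, nchar(x)) == substr(anchor, 1L, k)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Simulate a reference genome, annotations and barcode whitelist
#'
#' Generates random contigs, plants non-overlapping small RNA loci per
#' biotype (random strand; minus-strand mature sequences are the reverse
#' complement of the locus), and draws a whitelist of distinct barcodes
#' at pairwise Hamming distance >= `min_barcode_dist`. Planted mature
#' sequences are resampled until they are unique and free of the
#' 3'-adapter anchor, so that decoding is unambiguous by construction.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; when given, writes
#'   `reference.fa`, `annotations.gff3` and `whitelist.txt`.
#' @return A list with `genome` (DNAStringSet), `annotations`
#'   (data.frame as in [read_annotations()], plus `mature` sequence),
#'   `whitelist`, and file `paths` when `dir` was given.
#' @export
simulate_reference <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  anchor <- .adapter3_anchor(config$layout)

  ## feature roster (base features + multimapper copies)
  biot <- rep(names(config$n_features), config$n_features)
  ids <- unlist(lapply(names(config$n_features), function(b) {
    sprintf("%s-%04d", tolower(b), seq_len(config$n_features[[b]]))
  }))
  copy_of <- rep(NA_integer_, length(ids))
  if (config$multimap_copies > 0) {
    src <- which(biot == "miRNA")[seq_len(config$multimap_copies)]
    biot <- c(biot, biot[src])
    ids <- c(ids, paste0(ids[src], "-copy"))
    copy_of <- c(copy_of, src)
  }
  n_tot <- length(ids)

  ## genome as mutable per-contig character vectors
  genome <- lapply(seq_len(config$n_contigs), function(i) {
    sample(c("A", "C", "G", "T"), config$contig_length, replace = TRUE)
  })
  contig_names <- sprintf("contig%02d", seq_len(config$n_contigs))

  ## slot placement: features round-robin over contigs, one slot each
  contig_of <- rep(seq_len(config$n_contigs), length.out = n_tot)
  max_len <- max(vapply(config$feature_length, max, 0L))
  ann <- data.frame(feature_id = ids, biotype = biot,
                    contig = contig_names[contig_of],
                    start = NA_integer_, end = NA_integer_,
                    strand = NA_character_, mature = NA_character_,
                    stringsAsFactors = FALSE)
  for (ci in seq_len(config$n_contigs)) {
    rows <- which(contig_of == ci)
    n_slots <- length(rows)
    if (!n_slots) next
    slot_w <- config$contig_length %/% n_slots
    if (slot_w < max_len + 2L) {
      stop("requested features do not fit the contig: need slots of >= ",
           max_len + 2L, " bp, have ", slot_w)
    }
    for (k in seq_along(rows)) {
      r <- rows[k]
      lenr <- config$feature_length[[ann$biotype[r]]]
      flen <- if (lenr[1] == lenr[2]) lenr[1] else
        sample(seq(lenr[1], lenr[2]), 1)
      start0 <- (k - 1L) * slot_w + sample.int(slot_w - flen + 1L, 1) - 1L
      strand <- sample(c("+", "-"), 1)
      if (!is.na(copy_of[r])) {
        ## multimapper copy: plant the source's mature sequence verbatim
        src <- copy_of[r]
        mature <- ann$mature[src]
        flen <- nchar(mature)
        start0 <- (k - 1L) * slot_w + sample.int(slot_w - flen + 1L, 1) - 1L
        strand <- ann$strand[src]
        region <- strsplit(if (strand == "+") mature else revcomp(mature),
                           "")[[1]]
        genome[[ci]][(start0 + 1L):(start0 + flen)] <- region
      } else {
        repeat {
          region <- sample(c("A", "C", "G", "T"), flen, replace = TRUE)
          mature <- paste(region, collapse = "")
          if (strand == "-") mature <- revcomp(mature)
          if (.insert_decodable(mature, anchor) &&
              !mature %in% ann$mature) break
        }
        genome[[ci]][(start0 + 1L):(start0 + flen)] <- region
      }
      ann$start[r] <- start0
      ann$end[r] <- start0 + flen
      ann$strand[r] <- strand
      ann$mature[r] <- mature
    }
  }

  genome_set <- Biostrings::DNAStringSet(
    vapply(genome, paste, character(1), collapse = "")
  )
  names(genome_set) <- contig_names

  ## whitelist: rejection sampling at pairwise distance >= min_barcode_dist
  wl <- character(0)
  wl_mat <- NULL
  L <- config$layout$barcode_length
  while (length(wl) < config$n_barcodes) {
    cand <- .random_dna(1, L)
    ch <- strsplit(cand, "")[[1]]
    if (is.null(wl_mat) ||
        min(rowSums(wl_mat != matrix(ch, nrow(wl_mat), L, byrow = TRUE))) >=
          config$min_barcode_dist) {
      wl <- c(wl, cand)
      wl_mat <- rbind(wl_mat, ch)
    }
  }

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "reference.fa")
    gff <- file.path(dir, "annotations.gff3")
    wlf <- file.path(dir, "whitelist.txt")
    Biostrings::writeXStringSet(genome_set, fa)
    gr <- GenomicRanges::GRanges(
      ann$contig, IRanges::IRanges(ann$start + 1L, ann$end),
      strand = ann$strand, type = ann$biotype, ID = ann$feature_id,
      phase = ifelse(ann$biotype == "CDS", 0L, NA_integer_)
    )
    rtracklayer::export(gr, gff, format = "gff3")
    writeLines(wl, wlf)
    paths <- list(reference = fa, annotations = gff, whitelist = wlf)
  }
  list(genome = genome_set, annotations = ann, whitelist = wl, paths = paths)
}

#' Simulate per-cell molecule truth
#'
#' Each cell draws its molecules from a multinomial over features with
#' probabilities proportional to `rank^(-skew)` under a fixed (seeded)
#' random rank permutation shared by all cells; molecule UMIs are drawn
#' uniformly over all 4^L tags (collisions are accepted, not resolved —
#' they are part of what deduplication statistics quantify).
#'
#' @param config A [sim_config()].
#' @param reference Result of [simulate_reference()].
#' @return A list with `molecules` (data.frame: `molecule_id`,
#'   `cell_barcode`, `feature_id`, `umi`, `insert`) and `truth_counts`
#'   (features x cells integer matrix of true molecule counts).
#' @export
simulate_cells <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  ann <- reference$annotations
  base <- ann[!grepl("-copy$", ann$feature_id), , drop = FALSE]
  nf <- nrow(base)
  ranks <- sample.int(nf)
  probs <- ranks^(-config$skew)
  probs <- probs / sum(probs)
  cells <- reference$whitelist[seq_len(config$n_cells)]
  per_cell <- rep(config$molecules_per_cell, length.out = config$n_cells)

  counts <- vapply(seq_len(config$n_cells), function(i) {
    as.integer(stats::rmultinom(1, per_cell[i], probs))
  }, integer(nf))
  counts <- matrix(counts, nrow = nf,
                   dimnames = list(base$feature_id, cells))

  total <- sum(counts)
  if (total == 0) {
    mols <- data.frame(molecule_id = character(0), cell_barcode = character(0),
                       feature_id = character(0), umi = character(0),
                       insert = character(0), stringsAsFactors = FALSE)
    return(list(molecules = mols, truth_counts = counts))
  }
  cell_idx <- rep(seq_len(config$n_cells), times = Matrix::colSums(counts))
  feat_idx <- unlist(lapply(seq_len(config$n_cells), function(i) {
    rep(seq_len(nf), times = counts[, i])
  }))
  mols <- data.frame(
    molecule_id = sprintf("mol%07d", seq_len(total)),
    cell_barcode = cells[cell_idx],
    feature_id = base$feature_id[feat_idx],
    umi = .random_dna(total, config$layout$umi_length),
    insert = base$mature[feat_idx],
    stringsAsFactors = FALSE
  )
  list(molecules = mols, truth_counts = counts)
}

## render an adapter pattern for a vector of UMIs, consuming UMI bases at
## the N positions starting at `offset`; returns the rendered strings and
## the number of UMI bases consumed
.render_pattern <- function(pattern, umis, offset = 0L) {
  ch <- strsplit(pattern, "", fixed = TRUE)[[1]]
  parts <- list()
  consumed <- 0L
  buf <- ""
  for (c0 in ch) {
    if (c0 == "N") {
      if (nzchar(buf)) {
        parts[[length(parts) + 1L]] <- buf
        buf <- ""
      }
      consumed <- consumed + 1L
      pos <- offset + consumed
      parts[[length(parts) + 1L]] <- substr(umis, pos, pos)
    } else {
      buf <- paste0(buf, c0)
    }
  }
  if (nzchar(buf)) parts[[length(parts) + 1L]] <- buf
  list(rendered = do.call(paste0, parts), consumed = consumed)
}

#' Emit sequencing reads (FASTQ) from molecule truth
#'
#' Every molecule is sequenced `duplication` times. Each read is the 5'
#' adapter (UMI bases at its N positions) + insert + 3' adapter (remaining
#' UMI bases), with the cell barcode either appended downstream or written
#' to a separate index FASTQ, per the layout. Substitution errors are
#' applied i.i.d. per base at `error_rate`; the provenance table records
#' the error counts per read region and the decode status they predict.
#'
#' @param truth Result of [simulate_cells()].
#' @param config A [sim_config()].
#' @param dir Optional directory for `reads.fastq` (+ `barcodes.fastq`).
#' @return A list with `seqs`, `barcode_seqs` (or `NULL`), `provenance`
#'   (data.frame incl. `expected_status`), and `paths` when written.
#' @export
simulate_reads <- function(truth, config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  lay <- config$layout
  mols <- truth$molecules
  D <- config$duplication
  n <- nrow(mols) * D
  if (n == 0) {
    return(list(seqs = character(0), barcode_seqs = NULL,
                provenance = data.frame(), paths = NULL))
  }
  idx <- rep(seq_len(nrow(mols)), each = D)
  umi <- mols$umi[idx]
  insert <- mols$insert[idx]
  barcode <- mols$cell_barcode[idx]
  r5 <- .render_pattern(lay$adapter5, umi, 0L)
  r3 <- .render_pattern(lay$adapter3, umi, r5$consumed)
  downstream <- lay$barcode_source == "downstream_of_adapter3"
  seqs <- if (downstream) {
    paste0(r5$rendered, insert, r3$rendered, barcode)
  } else {
    paste0(r5$rendered, insert, r3$rendered)
  }
  bc_seqs <- if (downstream) NULL else barcode

  p5 <- .pattern_info(lay$adapter5)
  p3 <- .pattern_info(lay$adapter3)
  ins_len <- nchar(insert)

  ## classify every read position once errors land there
  classify <- function(pos, L) {
    ifelse(pos <= p5$len,
           ifelse(pos %in% p5$fixed, "adapter5_fixed", "umi"),
    ifelse(pos <= p5$len + L, "insert",
    ifelse(pos <= p5$len + L + p3$len,
           ifelse((pos - p5$len - L) %in% p3$fixed, "adapter3_fixed", "umi"),
           "barcode")))
  }

  err <- matrix(0L, n, 5,
                dimnames = list(NULL, c("adapter5_fixed", "adapter3_fixed",
                                        "umi", "insert", "barcode")))
  if (config$error_rate > 0) {
    lens <- nchar(seqs)
    n_err <- stats::rbinom(n, lens, config$error_rate)
    for (i in which(n_err > 0)) {
      pos <- sample.int(lens[i], n_err[i])
      for (p in pos) {
        old <- substr(seqs[i], p, p)
        substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
        cls <- classify(p, ins_len[i])
        err[i, cls] <- err[i, cls] + 1L
      }
    }
    if (!downstream) {
      n_err2 <- stats::rbinom(n, nchar(bc_seqs), config$error_rate)
      for (i in which(n_err2 > 0)) {
        pos <- sample.int(nchar(bc_seqs[i]), n_err2[i])
        for (p in pos) {
          old <- substr(bc_seqs[i], p, p)
          substr(bc_seqs[i], p, p) <-
            sample(setdiff(c("A", "C", "G", "T"), old), 1)
        }
        err[i, "barcode"] <- err[i, "barcode"] + n_err2[i]
      }
    }
  }

  expected_status <- ifelse(
    err[, "adapter5_fixed"] > 0, "no_adapter5",
    ifelse(err[, "adapter3_fixed"] > 0, "no_adapter3",
           ifelse(err[, "barcode"] > lay$max_barcode_errors,
                  "barcode_unassigned", "ok")))

  prov <- data.frame(
    read_id = sprintf("sim%08d", seq_len(n)),
    molecule_id = mols$molecule_id[idx],
    cell_barcode = barcode,
    feature_id = mols$feature_id[idx],
    umi = umi,
    err_adapter5_fixed = err[, "adapter5_fixed"],
    err_adapter3_fixed = err[, "adapter3_fixed"],
    err_umi = err[, "umi"],
    err_insert = err[, "insert"],
    err_barcode = err[, "barcode"],
    expected_status = expected_status,
    expected_maps = err[, "insert"] == 0L,
    stringsAsFactors = FALSE
  )

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fq <- file.path(dir, "reads.fastq")
    .write_fastq(prov$read_id, seqs, fq)
    paths <- list(reads = fq)
    if (!downstream) {
      fq2 <- file.path(dir, "barcodes.fastq")
      .write_fastq(prov$read_id, bc_seqs, fq2)
      paths$barcodes <- fq2
    }
  }
  list(seqs = seqs, barcode_seqs = bc_seqs, provenance = prov, paths = paths)
}

.write_fastq <- function(ids, seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                    strrep("I", nchar(seqs))), con)
}

#' Simulate a complete dataset
#'
#' Runs [simulate_reference()], [simulate_cells()] and [simulate_reads()]
#' in sequence and, when `dir` is given, writes every input the pipeline
#' consumes (FASTA, GFF3, whitelist, FASTQ) plus the truth tables and the
#' resolved configuration for provenance.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory.
#' @return A list with `reference`, `truth`, `reads` and `config`.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  reference <- simulate_reference(config, dir)
  truth <- simulate_cells(config, reference)
  reads <- simulate_reads(truth, config, dir)
  if (!is.null(dir)) {
    utils::write.table(truth$molecules, file.path(dir, "truth_molecules.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tc <- as.data.frame(as.table(truth$truth_counts),
                        stringsAsFactors = FALSE)
    names(tc) <- c("feature_id", "cell_barcode", "count")
    utils::write.table(tc[tc$count > 0, ],
                       file.path(dir, "truth_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(reads$provenance, file.path(dir, "provenance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cfg <- config
    cfg$layout <- unclass(cfg$layout)
    jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(reference = reference, truth = truth, reads = reads, config = config)
}

#' Simulate a clustered expression matrix with planted markers
#'
#' Generates raw counts for `n_clusters` cell groups over a common
#' feature background (Poisson counts around gamma-distributed feature
#' means); each cluster overexpresses its own disjoint marker set
#' `fold`-fold. Used to exercise marker calling with known truth.
#'
#' @param seed RNG seed.
#' @param n_clusters,cells_per_cluster,n_features Dataset geometry.
#' @param markers_per_cluster Planted markers per cluster.
#' @param fold Overexpression factor of a marker in its own cluster.
#' @param base_mean Mean of the gamma-distributed background feature
#'   means.
#' @return A list with `counts` (features x cells), `clusters` (label per
#'   cell) and `marker_sets` (named list of planted feature ids).
#' @export
simulate_clustered_matrix <- function(seed, n_clusters = 3L,
                                      cells_per_cluster = 30L,
                                      n_features = 200L,
                                      markers_per_cluster = 10L,
                                      fold = 8, base_mean = 5) {
  stopifnot(n_clusters * markers_per_cluster <= n_features)
  set.seed(seed)
  feat <- sprintf("feat-%04d", seq_len(n_features))
  lambda <- stats::rgamma(n_features, shape = 2, scale = base_mean / 2)
  marker_sets <- lapply(seq_len(n_clusters), function(k) {
    feat[((k - 1) * markers_per_cluster + 1):(k * markers_per_cluster)]
  })
  names(marker_sets) <- paste0("cluster", seq_len(n_clusters))
  ## planted markers share one fixed baseline so every cluster adds the
  ## same expected total: clusters stay exchangeable and non-marker
  ## features remain uniform after per-cell normalization
  planted <- unlist(marker_sets)
  lambda[match(planted, feat)] <- base_mean
  clusters <- rep(names(marker_sets), each = cells_per_cluster)
  counts <- sapply(seq_along(clusters), function(i) {
    lam <- lambda
    k <- match(clusters[i], names(marker_sets))
    lam[match(marker_sets[[k]], feat)] <-
      lam[match(marker_sets[[k]], feat)] * fold
    stats::rpois(n_features, lam)
  })
  dimnames(counts) <- list(feat, sprintf("cell-%03d", seq_along(clusters)))
  list(counts = counts, clusters = clusters, marker_sets = marker_sets)
}
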