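test_that("reference simulation plants non-overlapping features and a spaced whitelist", {
  cfg <- sim_config(seed = 101, n_cells = 10,
                    n_features = c(miRNA = 50),
                    feature_length = list(miRNA = c(22L, 22L)),
                    contig_length = 100000)
  sim <- simulate_reference(cfg)
  ann <- sim$annotations
  expect_equal(sum(ann$biotype == "miRNA"), 50L)
  expect_true(all(ann$end - ann$start == 22L))
  ## no overlaps within a contig
  for (ctg in unique(ann$contig)) {
    a <- ann[ann$contig == ctg, ]
    a <- a[order(a$start), ]
    expect_true(all(head(a$end, -1) <= tail(a$start, -1)))
  }
  ## planted mature sequences sit in the genome (strand-adjusted)
  g <- as.character(sim$genome[[1]])
  for (i in sample(nrow(ann), 10)) {
    sub <- substring(g, ann$start[i] + 1, ann$end[i])
    if (ann$strand[i] == "-") {
      sub <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(sub)))
    }
    expect_equal(sub, ann$mature[i])
  }
  ## whitelist: 96 barcodes, all pairwise Hamming distances >= 5
  wl <- sim$whitelist
  expect_equal(length(wl), 96L)
  mat <- do.call(rbind, strsplit(wl, ""))
  dmin <- min(vapply(seq_len(95), function(i) {
    min(vapply((i + 1):96, function(j) sum(mat[i, ] != mat[j, ]), 0))
  }, 0))
  expect_gte(dmin, 5)
})

test_that("identical configurations reproduce byte-identical outputs", {
  cfg <- sim_config(seed = 103, n_cells = 4, molecules_per_cell = 30,
                    n_features = c(miRNA = 20, tRNA = 5),
                    contig_length = 10000, error_rate = 0.01,
                    duplication = 2)
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulate_dataset(cfg, d1)
  s2 <- simulate_dataset(cfg, d2)
  for (f in c("reference.fa", "annotations.gff3", "whitelist.txt",
              "reads.fastq", "barcodes.fastq", "truth_molecules.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("expression skew concentrates molecules in the top features", {
  ## default skew: the 10 most abundant features carry > half the
  ## molecules of a cell on average
  cfg <- sim_config(seed = 107, n_cells = 20, molecules_per_cell = 300)
  ref <- simulate_reference(cfg)
  truth <- simulate_cells(cfg, ref)
  counts <- truth$truth_counts
  top10 <- names(sort(rowSums(counts), decreasing = TRUE))[1:10]
  share <- mean(colSums(counts[top10, ]) / colSums(counts))
  expect_gt(share, 0.5)
})

test_that("zero skew gives uniform expected expression", {
  rejections <- 0
  for (s in 1:10) {
    cfg <- sim_config(seed = 200 + s, n_cells = 10,
                      molecules_per_cell = 400, skew = 0,
                      n_features = c(miRNA = 50), contig_length = 50000)
    ref <- simulate_reference(cfg)
    truth <- simulate_cells(cfg, ref)
    p <- suppressWarnings(
      stats::chisq.test(rowSums(truth$truth_counts))$p.value)
    if (p < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 1)
})

test_that("zero molecules yield an empty truth", {
  cfg <- sim_config(seed = 109, n_cells = 3, molecules_per_cell = 0,
                    n_features = c(miRNA = 10), contig_length = 10000)
  ref <- simulate_reference(cfg)
  truth <- simulate_cells(cfg, ref)
  expect_equal(nrow(truth$molecules), 0L)
  expect_equal(sum(truth$truth_counts), 0L)
})

test_that("read emission conserves molecules and respects the layout", {
  cfg <- sim_config(seed = 113, n_cells = 5, molecules_per_cell = 40,
                    duplication = 3, error_rate = 0,
                    n_features = c(miRNA = 20), contig_length = 20000)
  sim <- simulate_dataset(cfg)
  expect_equal(length(sim$reads$seqs),
               nrow(sim$truth$molecules) * cfg$duplication)
  ## error-free reads decode to their provenance exactly
  dec <- parse_reads(sim$reads$seqs, cfg$layout,
                     barcode_seqs = sim$reads$barcode_seqs,
                     whitelist = sim$reference$whitelist)
  expect_true(all(dec$status == "ok"))
  expect_identical(dec$umi, sim$reads$provenance$umi)
  expect_identical(dec$corrected_barcode,
                   sim$reads$provenance$cell_barcode)
})

test_that("errors planted in fixed adapter bases are rejected as predicted", {
  cfg <- sim_config(seed = 127, n_cells = 6, molecules_per_cell = 50,
                    duplication = 2, error_rate = 0.03,
                    n_features = c(miRNA = 25, tRNA = 5),
                    contig_length = 20000)
  sim <- simulate_dataset(cfg)
  dec <- parse_reads(sim$reads$seqs, cfg$layout,
                     barcode_seqs = sim$reads$barcode_seqs,
                     whitelist = sim$reference$whitelist)
  prov <- sim$reads$provenance
  expect_identical(dec$status, prov$expected_status)
  ## specifically: every read with a fixed 5'-adapter error is no_adapter5
  expect_true(all(dec$status[prov$err_adapter5_fixed > 0] == "no_adapter5"))
  expect_true(all(dec$status[prov$err_adapter5_fixed == 0 &
                             prov$err_adapter3_fixed > 0] == "no_adapter3"))
})

test_that("simulation parameters are recovered end to end under noise", {
  for (s in 1:5) {
    cfg <- sim_config(seed = 300 + s, n_cells = 8, molecules_per_cell = 120,
                      duplication = 3, error_rate = 0.005,
                      n_features = c(miRNA = 60, tRNA = 10, rRNA = 5),
                      contig_length = 30000)
    sim <- simulate_dataset(cfg)
    res <- run_pipeline(sim$reads$seqs, sim$reference$genome,
                        sim$reference$annotations[, 1:6],
                        sim$reference$whitelist,
                        barcode_fastq = sim$reads$barcode_seqs)
    truth <- sim$truth$truth_counts
    cells <- colnames(truth)
    rec <- res$quant$matrix
    rec_tot <- Matrix::colSums(rec)[cells]
    true_tot <- colSums(truth)
    expect_true(all(abs(rec_tot - true_tot) / true_tot < 0.05))
    for (cell in cells) {
      shared <- intersect(rownames(truth), rownames(rec))
      rho <- suppressWarnings(
        cor(truth[shared, cell], as.numeric(rec[shared, cell]),
            method = "spearman"))
      expect_gt(rho, 0.95)
    }
  }
})
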