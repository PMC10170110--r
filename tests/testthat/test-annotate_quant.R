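ann_fixture <- function() {
  data.frame(
    feature_id = c("mir-1", "cds-1", "trna-1"),
    biotype = c("miRNA", "CDS", "tRNA"),
    contig = "c1",
    start = c(100L, 110L, 400L),
    end = c(122L, 190L, 430L),
    strand = c("+", "+", "-"),
    stringsAsFactors = FALSE
  )
}

test_that("hits are assigned to same-strand features by biotype priority", {
  ann <- ann_fixture()
  hit <- data.frame(insert = "X", contig = "c1", start = 102L, end = 120L,
                    strand = "+", n_hits = 1L, stringsAsFactors = FALSE)
  res <- assign_hits(hit, ann)
  expect_equal(res$feature_id, "mir-1")   # miRNA beats the overlapping CDS
  expect_equal(res$biotype, "miRNA")

  ## overlap only with the CDS
  hit2 <- transform(hit, start = 150L, end = 170L)
  expect_equal(assign_hits(hit2, ann)$feature_id, "cds-1")

  ## antisense to the only overlapping feature: unannotated 'other'
  hit3 <- data.frame(insert = "X", contig = "c1", start = 405L, end = 425L,
                     strand = "+", n_hits = 1L, stringsAsFactors = FALSE)
  res3 <- assign_hits(hit3, ann)
  expect_match(res3$feature_id, "^unann:")
  expect_equal(res3$biotype, "other")
})

test_that("GFF3 round trip preserves coordinates and biotypes", {
  cfg <- sim_config(seed = 2, n_cells = 2, molecules_per_cell = 10,
                    n_features = c(miRNA = 10, tRNA = 3), contig_length = 5000)
  dir <- tempfile()
  sim <- simulate_reference(cfg, dir)
  ann <- read_annotations(sim$paths$annotations)
  want <- sim$annotations[order(sim$annotations$feature_id),
                          c("feature_id", "biotype", "contig", "start",
                            "end", "strand")]
  got <- ann[order(ann$feature_id), names(want)]
  rownames(want) <- rownames(got) <- NULL
  expect_equal(got, want)
})

test_that("UMI collapse counts connected components at one mismatch", {
  expect_equal(collapse_umis(rep("AAAAAAAA", 3)), 1L)
  expect_equal(collapse_umis(c("AAAAAAAA", "AAAAAAAT")), 1L)
  ## chain joined through the middle tag
  expect_equal(collapse_umis(c("AAAAAAAA", "AAAAAATT", "AAAAAAAT")), 1L)
  expect_equal(collapse_umis(c("AAAAAAAA", "TTTTTTTT")), 2L)
  expect_equal(collapse_umis(character(0)), 0L)
  ## zero tolerance: distinct tags never merge
  expect_equal(collapse_umis(c("AAAAAAAA", "AAAAAAAT"), max_mismatch = 0), 2L)
})

test_that("UMI collapse agrees with the brute-force components oracle", {
  skip_if_not_installed("igraph")
  set.seed(13)
  for (rep in 1:60) {
    k <- sample(1:200, 1)
    ## a narrow alphabet portion makes adjacency common
    umis <- vapply(seq_len(k), function(i) paste(
      sample(c("A", "C", "G", "T"), 8, replace = TRUE,
             prob = c(0.55, 0.25, 0.15, 0.05)), collapse = ""), character(1))
    expect_equal(collapse_umis(umis), oracle_umi_count(umis))
  }
})

test_that("multimapper molecules split their unit mass over loci", {
  ## one read, one hit
  dec <- data.frame(read_id = "r1", corrected_barcode = "CELL1",
                    umi = "AAAAAAAA", insert = "I1",
                    stringsAsFactors = FALSE)
  assigned <- data.frame(insert = "I1", contig = "c1", start = 0L, end = 20L,
                         strand = "+", n_hits = 1L, feature_id = "f1",
                         biotype = "miRNA", stringsAsFactors = FALSE)
  q <- weight_and_sum(build_molecules(dec, assigned))
  expect_equal(as.numeric(q$matrix["f1", "CELL1"]), 1.0)

  ## one molecule hitting 4 loci in 4 features: 0.25 each, total 1
  assigned4 <- data.frame(
    insert = "I1", contig = "c1", start = c(0L, 100L, 200L, 300L),
    end = c(20L, 120L, 220L, 320L), strand = "+", n_hits = 4L,
    feature_id = paste0("f", 1:4), biotype = "miRNA",
    stringsAsFactors = FALSE)
  q4 <- weight_and_sum(build_molecules(dec, assigned4))
  expect_equal(as.numeric(q4$matrix[paste0("f", 1:4), "CELL1"]),
               rep(0.25, 4))
  expect_equal(sum(q4$matrix), 1.0)

  ## two loci collapsed into the same feature: 0.5 + 0.5 = 1 to it
  assigned2 <- transform(assigned4[1:2, ], n_hits = 2L, feature_id = "f1")
  q2 <- weight_and_sum(build_molecules(dec, assigned2))
  expect_equal(as.numeric(q2$matrix["f1", "CELL1"]), 1.0)
})

test_that("error-free simulations are recovered exactly and deterministically", {
  skip_if_not_installed("igraph")
  cfg <- sim_config(seed = 17, n_cells = 6, molecules_per_cell = 80,
                    duplication = 2, error_rate = 0,
                    n_features = c(miRNA = 40, tRNA = 10, rRNA = 5),
                    contig_length = 30000)
  sim <- simulate_dataset(cfg)
  run <- function() run_pipeline(
    sim$reads$seqs, sim$reference$genome,
    sim$reference$annotations[, 1:6], sim$reference$whitelist,
    barcode_fastq = sim$reads$barcode_seqs)
  res <- run()
  ## expected matrix: truth molecules collapsed by the independent oracle
  cells <- colnames(res$quant$matrix)
  feats <- rownames(res$quant$matrix)
  want <- oracle_truth_matrix(sim$truth$molecules, feats, cells)
  expect_identical(as.matrix(res$quant$matrix), want)
  ## byte-identical on a repeated run
  res2 <- run()
  expect_identical(as.matrix(res$quant$matrix), as.matrix(res2$quant$matrix))
})

test_that("matrix directory round trip preserves the sparse triplet", {
  cfg <- sim_config(seed = 23, n_cells = 4, molecules_per_cell = 40,
                    n_features = c(miRNA = 20, tRNA = 5),
                    contig_length = 15000)
  sim <- simulate_dataset(cfg)
  res <- run_pipeline(sim$reads$seqs, sim$reference$genome,
                      sim$reference$annotations[, 1:6],
                      sim$reference$whitelist,
                      barcode_fastq = sim$reads$barcode_seqs)
  dir <- tempfile()
  write_matrix_dir(res$quant, dir)
  back <- read_matrix_dir(dir)
  expect_equal(as.matrix(back$matrix), as.matrix(res$quant$matrix))
  expect_equal(back$features, res$quant$features)
})
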