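test_that("normalization scales cells to the target total then log-transforms", {
  m <- matrix(c(5, 5), nrow = 2, dimnames = list(c("f1", "f2"), "c1"))
  out <- normalize_log(m, scale_total = 10)
  expect_equal(as.numeric(out), rep(log1p(5), 2))

  ## a zero cell stays zero, with a warning
  m2 <- cbind(m, c2 = c(0, 0))
  expect_warning(out2 <- normalize_log(m2, scale_total = 10))
  expect_equal(as.numeric(out2[, "c2"]), c(0, 0))

  ## pre-log totals equal the scale factor for non-empty cells
  set.seed(8)
  m3 <- matrix(rpois(60, 4), nrow = 10)
  rownames(m3) <- paste0("f", 1:10)
  out3 <- normalize_log(m3, scale_total = 1e4)
  expect_equal(colSums(expm1(as.matrix(out3))), rep(1e4, ncol(m3)))
})

test_that("Spearman correlation to the reference matches rank arithmetic", {
  set.seed(19)
  feats <- paste0("f", 1:20)
  ref <- matrix(rnorm(20 * 5), 20, 5,
                dimnames = list(feats, paste0("s", 1:5)))
  q <- setNames(rnorm(20), feats)

  rho <- spearman_to_reference(q, ref)
  want <- apply(ref, 2, function(col) {
    stats::cor(rank(q[feats]), rank(col))  # rank-then-Pearson
  })
  expect_equal(rho, want)

  ## perfect agreement and perfect reversal
  q2 <- setNames(ref[, "s1"], feats)
  expect_equal(unname(spearman_to_reference(q2, ref)["s1"]), 1.0)
  expect_equal(unname(spearman_to_reference(-q2, ref)["s1"]), -1.0)

  expect_error(spearman_to_reference(setNames(1:2, c("f1", "f2")), ref))
})

test_that("ontology scores are invariant under monotone query transforms", {
  set.seed(27)
  feats <- paste0("f", 1:30)
  ref <- matrix(rexp(30 * 8), 30, 8, dimnames = list(feats, paste0("s", 1:8)))
  membership <- list(term1 = c("s1", "s2", "s3"), term2 = c("s4", "s5"))
  q <- setNames(runif(30), feats)
  a <- ontology_score(spearman_to_reference(q, ref), membership)
  b <- ontology_score(spearman_to_reference(exp(3 * q) + 2, ref), membership)
  expect_equal(a, b)
})

test_that("the modified t statistic follows its displayed equations", {
  ## 10 reference samples; members correlate visibly better than average
  rho <- setNames(c(0.9, 0.8, 0.7, 0.1, 0.15, 0.2, 0.05, 0.0, 0.12, 0.3),
                  paste0("s", 1:10))
  membership <- list(myterm = c("s1", "s2", "s3"))
  sc <- ontology_score(rho, membership)

  ## independent direct evaluation
  m <- mean(c(0.9, 0.8, 0.7)); s <- sd(c(0.9, 0.8, 0.7)); n <- 3
  M <- mean(rho); S <- sd(rho)
  t_want <- (m - M) / sqrt(s^2 / n + S^2 / n)
  df_want <- (n - 1) * (s^2 + S^2)^2 / (s^4 + S^4)
  expect_equal(sc$t, t_want)
  expect_equal(sc$df, df_want)
  expect_equal(sc$p, pt(t_want, df_want, lower.tail = FALSE))

  ## m == M makes t vanish regardless of the spreads
  rho2 <- setNames(c(0.2, 0.4, 0.1, 0.3, 0.2, 0.6), paste0("s", 1:6))
  mem2 <- list(t0 = c("s1", "s2"))   # mean 0.3 == overall mean 0.3
  expect_equal(ontology_score(rho2, mem2)$t, 0)

  ## s == S collapses df to 2(n - 1), to machine precision
  y <- sqrt(0.02)
  rho3 <- setNames(c(-0.1, 0.1, -y, y), paste0("s", 1:4))
  mem3 <- list(teq = c("s1", "s2"))  # member sd == full-set sd
  sc3 <- ontology_score(rho3, mem3)
  expect_equal(sc3$df, 2 * (sc3$n - 1), tolerance = 1e-12)

  ## degenerate spread is skipped with a warning
  rho4 <- setNames(rep(0.5, 4), paste0("s", 1:4))
  expect_warning(sc4 <- ontology_score(rho4, list(z = c("s1", "s2"))))
  expect_equal(nrow(sc4), 0L)
})

test_that("Wilcoxon marker p-values match exhaustive enumeration on 6 vs 6", {
  set.seed(41)
  for (rep in 1:5) {
    x <- round(runif(6, 0, 10), 3)
    y <- round(runif(6, 0, 10) + 2, 3)
    if (anyDuplicated(c(x, y))) next
    got <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
    expect_equal(got, oracle_wilcox_p(x, y))
  }
})

test_that("markers are called for separated features and not for uniform ones", {
  set.seed(55)
  n <- 40
  clusters <- rep(c("A", "B"), each = 20)
  norm <- rbind(
    sep = c(rnorm(20, 5, 0.3), rnorm(20, 1, 0.3)),  # high only in A
    unif = rnorm(n, 3, 0.5)
  )
  colnames(norm) <- paste0("c", 1:n)
  mk <- find_markers(norm, clusters)
  expect_true(mk$is_marker[mk$feature_id == "sep" & mk$cluster == "A"])
  expect_false(mk$is_marker[mk$feature_id == "sep" & mk$cluster == "B"])
  expect_false(any(mk$is_marker[mk$feature_id == "unif"]))

  ## tiny clusters are excluded with a warning
  cl2 <- c(rep("A", 20), rep("B", 18), "C", "C")
  expect_warning(mk2 <- find_markers(norm, cl2))
  expect_false("C" %in% mk2$cluster)
})

test_that("planted cluster markers are recovered from simulated counts", {
  sim <- simulate_clustered_matrix(seed = 61)
  norm <- normalize_log(sim$counts)
  mk <- find_markers(norm, sim$clusters)
  for (cl in names(sim$marker_sets)) {
    hit <- mk$feature_id[mk$cluster == cl & mk$is_marker]
    recall <- mean(sim$marker_sets[[cl]] %in% hit)
    expect_gte(recall, 0.9)
  }
  uniform <- setdiff(rownames(sim$counts), unlist(sim$marker_sets))
  expect_false(any(mk$is_marker[mk$feature_id %in% uniform]))
})

test_that("ontology reference files round-trip through the readers", {
  dir <- tempfile(); dir.create(dir)
  prof <- data.frame(feature_id = paste0("f", 1:5),
                     s1 = runif(5), s2 = runif(5), s3 = runif(5))
  write.table(prof, file.path(dir, "prof.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  terms <- data.frame(term = c("t1", "t1", "t2"),
                      sample = c("s1", "s2", "s3"))
  write.table(terms, file.path(dir, "terms.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ref <- read_ontology_reference(file.path(dir, "prof.tsv"),
                                 file.path(dir, "terms.tsv"))
  expect_equal(dim(ref$profiles), c(5L, 3L))
  expect_equal(ref$membership$t1, c("s1", "s2"))
})
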