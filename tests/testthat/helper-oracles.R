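## Independent oracles and fixture builders. Everything here is written
## against the contracts, not the package internals: naive scans,
## exhaustive enumeration, and literal read construction.

rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

## literal read construction for the default layout:
## AAA u1u2 AAA u3u4 AAA u5u6 + insert + u7u8 + CTGTAGGCAC [+ barcode]
make_read <- function(insert, umi, barcode = NULL) {
  u <- strsplit(umi, "")[[1]]
  stopifnot(length(u) == 8)
  paste0("AAA", u[1], u[2], "AAA", u[3], u[4], "AAA", u[5], u[6],
         insert, u[7], u[8], "CTGTAGGCAC",
         if (is.null(barcode)) "" else barcode)
}

## inserts for which anchored decoding is unambiguous: no 3'-adapter
## anchor inside, and no suffix equal to an anchor prefix of >= 6 nt
decodable_insert <- function(x, anchor = "CTGTAGGCAC") {
  vapply(x, function(s) {
    if (grepl(anchor, s, fixed = TRUE)) return(FALSE)
    for (k in 6:min(nchar(anchor) - 1L, nchar(s))) {
      if (substr(s, nchar(s) - k + 1L, nchar(s)) == substr(anchor, 1L, k)) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

rand_decodable_inserts <- function(n, lens) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    drawn <- if (length(lens) == 1L) rep(lens, need)
             else sample(lens, need, replace = TRUE)
    cand <- vapply(drawn,
                   function(L) paste(sample(c("A", "C", "G", "T"), L,
                                            replace = TRUE), collapse = ""),
                   character(1))
    out <- c(out, cand[decodable_insert(cand)])
  }
  out[seq_len(n)]
}

write_fastq_file <- function(ids, seqs, path) {
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                    strrep("I", nchar(seqs))), path)
}

## brute-force both-strand exact aligner: sliding window over every
## contig, string equality per window
oracle_align <- function(queries, refs) {
  qs <- unique(queries)
  rows <- list()
  for (w in unique(nchar(qs))) {
    grp <- qs[nchar(qs) == w]
    grp_rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(grp)))
    for (cn in names(refs)) {
      s <- refs[[cn]]
      L <- nchar(s)
      if (L < w) next
      starts <- seq_len(L - w + 1L)
      windows <- substring(s, starts, starts + w - 1L)
      for (k in seq_along(grp)) {
        for (p in starts[windows == grp[k]]) {
          rows[[length(rows) + 1L]] <- data.frame(
            insert = grp[k], contig = cn, start = p - 1L, end = p - 1L + w,
            strand = "+", stringsAsFactors = FALSE)
        }
        for (p in starts[windows == grp_rc[k]]) {
          rows[[length(rows) + 1L]] <- data.frame(
            insert = grp[k], contig = cn, start = p - 1L, end = p - 1L + w,
            strand = "-", stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(insert = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), n_hits = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$insert, out$contig, out$start, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out$n_hits <- as.integer(table(out$insert)[out$insert])
  out
}

## connected components of the <=1-mismatch UMI graph via igraph on a
## pairwise Hamming distance matrix
oracle_umi_count <- function(umis) {
  u <- unique(umis)
  k <- length(u)
  if (k == 0) return(0L)
  if (k == 1) return(1L)
  m <- do.call(rbind, strsplit(u, ""))
  d <- matrix(0L, k, k)
  for (col in seq_len(ncol(m))) {
    d <- d + outer(m[, col], m[, col], "!=")
  }
  g <- igraph::graph_from_adjacency_matrix(d <= 1, mode = "undirected",
                                           diag = FALSE)
  as.integer(igraph::components(g)$no)
}

## per-(cell, feature) expected molecule counts from simulator truth,
## applying the same <=1-mismatch collapse with the independent oracle
oracle_truth_matrix <- function(molecules, features, cells) {
  key <- paste(molecules$cell_barcode, molecules$feature_id, sep = "\r")
  counts <- vapply(split(molecules$umi, key), oracle_umi_count, integer(1))
  parts <- strsplit(names(counts), "\r", fixed = TRUE)
  m <- matrix(0, length(features), length(cells),
              dimnames = list(features, cells))
  for (i in seq_along(counts)) {
    m[parts[[i]][2], parts[[i]][1]] <- counts[i]
  }
  m
}

## exhaustive rank-sum enumeration for a two-sided Wilcoxon p-value
## (tie-free samples)
oracle_wilcox_p <- function(x, y) {
  stopifnot(!anyDuplicated(c(x, y)))
  m <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(pooled), m)
  w_all <- apply(combos, 2, function(id) sum(r[id]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}
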