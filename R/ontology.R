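#' Per-cell normalization and log transform
#'
#' Each cell's counts are divided by the cell total, scaled to
#' `scale_total` (default 10,000) and transformed with the natural
#' `log(1 + x)` — the convention of the standard single-cell toolkits.
#' Cells with zero total counts are left as zeros with a warning.
#'
#' @param m Features x cells matrix (dense or sparse), entries >= 0.
#' @param scale_total Per-cell scale factor after normalization.
#' @return Matrix of the same class/shape with normalized log values.
#' @examples
#' normalize_log(matrix(c(5, 5), 2, 1), scale_total = 10)
#' @export
normalize_log <- function(m, scale_total = 1e4) {
  if (any(m < 0)) stop("expression entries must be non-negative")
  tot <- Matrix::colSums(m)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero total counts left as zeros")
    tot[zero] <- 1
  }
  scaled <- m %*% Matrix::Diagonal(x = scale_total / tot)
  colnames(scaled) <- colnames(m)
  log1p(scaled)
}

#' Read an ontology reference (profiles + term membership)
#'
#' The reference atlas is a features x samples expression TSV (first
#' column: feature ids) plus a two-column TSV mapping each ontology term
#' to its member samples.
#'
#' @param profile_tsv Path to the profile matrix TSV.
#' @param terms_tsv Path to the term-membership TSV (columns `term`,
#'   `sample`).
#' @return List with `profiles` (numeric matrix, rownames = features) and
#'   `membership` (named list: term -> character vector of samples).
#' @export
read_ontology_reference <- function(profile_tsv, terms_tsv) {
  prof <- utils::read.delim(profile_tsv, check.names = FALSE,
                            stringsAsFactors = FALSE)
  rn <- prof[[1]]
  prof <- as.matrix(prof[, -1, drop = FALSE])
  rownames(prof) <- rn
  terms <- utils::read.delim(terms_tsv, stringsAsFactors = FALSE)
  membership <- split(terms$sample, terms$term)
  for (term in names(membership)) {
    mem <- membership[[term]]
    if (!length(mem) || length(unique(mem)) >= ncol(prof)) {
      stop("term '", term, "' must name a non-empty strict subset of samples")
    }
  }
  list(profiles = prof, membership = membership)
}

#' Spearman correlation of a query profile to reference samples
#'
#' Restricted to the features shared between query and reference (at
#' least 3 required); ties receive average ranks. Constant vectors yield
#' `NA` for the affected pair.
#'
#' @param query Named numeric vector (names = feature ids).
#' @param profiles Reference features x samples matrix with rownames.
#' @return Named numeric vector of Spearman rho per reference sample.
#' @export
spearman_to_reference <- function(query, profiles) {
  shared <- intersect(names(query), rownames(profiles))
  if (length(shared) < 3) {
    stop("need >= 3 shared features between query and reference, got ",
         length(shared))
  }
  suppressWarnings(
    stats::cor(query[shared], profiles[shared, , drop = FALSE],
               method = "spearman")[1, ]
  )
}

#' Score cell-ontology terms by a modified t-test
#'
#' For each ontology term, the mean `m` and standard deviation `s` of the
#' Spearman correlations over the term's `n` member samples are compared
#' with the mean `M` and standard deviation `S` over all samples:
#' \deqn{t = (m - M) / \sqrt{s^2/n + S^2/n}}
#' \deqn{df = (n - 1) (s^2 + S^2)^2 / (s^4 + S^4)}
#' The p-value is the upper tail of Student's t with `df` degrees of
#' freedom (one-sided: enrichment means member samples correlate better
#' than average). Terms with fewer than 2 scored members, or with
#' `s == S == 0`, are skipped with a warning.
#'
#' @param correlations Named numeric vector of per-sample Spearman rho
#'   (e.g. from [spearman_to_reference()]); `NA` entries are dropped.
#' @param membership Named list: term -> member sample names.
#' @return `data.frame` with `term`, `m`, `s`, `n`, `M`, `S`, `t`, `df`,
#'   `p`, sorted by increasing `p`.
#' @export
ontology_score <- function(correlations, membership) {
  rho <- correlations[!is.na(correlations)]
  M <- mean(rho)
  S <- stats::sd(rho)
  rows <- lapply(names(membership), function(term) {
    mem <- intersect(membership[[term]], names(rho))
    n <- length(mem)
    if (n < 2) {
      warning("term '", term, "' has fewer than 2 scored members: skipped")
      return(NULL)
    }
    m <- mean(rho[mem])
    s <- stats::sd(rho[mem])
    if (s == 0 && S == 0) {
      warning("term '", term, "' has zero spread (s == S == 0): skipped")
      return(NULL)
    }
    t_stat <- (m - M) / sqrt(s^2 / n + S^2 / n)
    df <- (n - 1) * (s^2 + S^2)^2 / (s^4 + S^4)
    data.frame(term = term, m = m, s = s, n = n, M = M, S = S,
               t = t_stat, df = df,
               p = stats::pt(t_stat, df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(0), m = numeric(0), s = numeric(0),
                      n = integer(0), M = numeric(0), S = numeric(0),
                      t = numeric(0), df = numeric(0), p = numeric(0)))
  }
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
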