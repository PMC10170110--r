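#' Call cluster marker features by Wilcoxon rank-sum test
#'
#' For every feature and every cluster, tests the cluster's cells against
#' all remaining cells with the Wilcoxon rank-sum test (exact for small
#' tie-free groups, otherwise the normal approximation with tie and
#' continuity correction, via [stats::wilcox.test()]). Log fold change is
#' the difference of mean log-expression (cluster minus rest), and the
#' in-cluster detection fraction is the share of cluster cells with
#' non-zero expression. A feature is a marker when
#' `corrected_p < 0.01`, `fraction_in_cluster > 0.2` and
#' `log_fold_change > 1`.
#'
#' @param norm Normalized log-expression matrix (features x cells), e.g.
#'   from [normalize_log()].
#' @param clusters Cluster label per cell (externally produced, e.g. by a
#'   graph clustering of the same matrix).
#' @param correction Multiple-testing correction, `"bonferroni"`
#'   (default, applied per cluster over all features) or any
#'   [stats::p.adjust()] method such as `"BH"`.
#' @param alpha,min_fraction,min_lfc Marker thresholds (defaults 0.01,
#'   0.2, 1).
#' @return `data.frame` with one row per (feature, cluster):
#'   `feature_id`, `cluster`, `log_fold_change`, `fraction_in_cluster`,
#'   `raw_p`, `corrected_p`, `is_marker`. Clusters with fewer than 3
#'   cells are excluded with a warning.
#' @export
find_markers <- function(norm, clusters, correction = "bonferroni",
                         alpha = 0.01, min_fraction = 0.2, min_lfc = 1) {
  stopifnot(ncol(norm) == length(clusters))
  clusters <- as.character(clusters)
  sizes <- table(clusters)
  small <- names(sizes)[sizes < 3]
  if (length(small)) {
    warning("cluster(s) with < 3 cells excluded: ",
            paste(small, collapse = ", "))
  }
  use <- setdiff(names(sizes), small)
  if (length(use) < 2) stop("need >= 2 clusters with >= 3 cells")
  dense <- as.matrix(norm)
  out <- lapply(use, function(cl) {
    in_cl <- clusters == cl
    ## rest = all other cells, including those of excluded tiny clusters
    raw_p <- apply(dense, 1, function(v) {
      x <- v[in_cl]
      y <- v[!in_cl]
      if (length(unique(c(x, y))) == 1L) return(1)
      suppressWarnings(stats::wilcox.test(x, y)$p.value)
    })
    lfc <- rowMeans(dense[, in_cl, drop = FALSE]) -
           rowMeans(dense[, !in_cl, drop = FALSE])
    frac <- rowMeans(dense[, in_cl, drop = FALSE] > 0)
    corrected <- stats::p.adjust(raw_p, method = correction)
    data.frame(
      feature_id = rownames(dense), cluster = cl,
      log_fold_change = lfc, fraction_in_cluster = frac,
      raw_p = raw_p, corrected_p = corrected,
      is_marker = corrected < alpha & frac > min_fraction & lfc > min_lfc,
      row.names = NULL, stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
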