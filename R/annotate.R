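#' Small RNA biotypes, highest priority first
#'
#' When a hit overlaps several same-strand features, the feature whose
#' biotype comes first in this order wins; within a biotype, the smaller
#' interval, then the lexicographically first `feature_id`.
#'
#' @return Character vector of biotypes.
#' @export
biotype_priority <- function() {
  c("miRNA", "tRNA", "rRNA", "snRNA", "snoRNA", "CDS", "other")
}

#' Load small RNA annotations
#'
#' Reads a GFF3 (1-based inclusive, converted to the package's 0-based
#' half-open convention at this boundary) or a 6-column BED. The biotype
#' is taken from the GFF `type` column (or a `biotype`/`gene_biotype`
#' attribute when `type` is generic), or from a sidecar TSV
#' (`feature_id`, `biotype`) for BED input. Biotypes outside the closed
#' set from [biotype_priority()] are coerced to `"other"` with a warning;
#' zero-width intervals are dropped with a warning.
#'
#' @param path GFF3 or BED file.
#' @param biotype_tsv Optional sidecar TSV mapping feature ids to biotypes.
#' @return A `data.frame` with `feature_id`, `biotype`, `contig`, `start`
#'   (0-based), `end` (half-open), `strand`.
#' @export
read_annotations <- function(path, biotype_tsv = NULL) {
  fmt <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  mc <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(mc)) as.character(mc$ID)
        else if ("Name" %in% names(mc)) as.character(mc$Name)
        else if ("name" %in% names(mc)) as.character(mc$name)
        else sprintf("feature%05d", seq_along(gr))
  bt <- rep(NA_character_, length(gr))
  for (col in c("biotype", "gene_biotype", "type")) {
    if (col %in% names(mc)) {
      cand <- as.character(mc[[col]])
      bt[is.na(bt) & cand %in% biotype_priority()] <-
        cand[is.na(bt) & cand %in% biotype_priority()]
    }
  }
  if (!is.null(biotype_tsv)) {
    map <- utils::read.delim(biotype_tsv, header = TRUE,
                             stringsAsFactors = FALSE)
    bt2 <- map$biotype[match(id, map$feature_id)]
    bt[!is.na(bt2)] <- bt2[!is.na(bt2)]
  }
  if (anyNA(bt) || any(!bt %in% biotype_priority())) {
    bad <- is.na(bt) | !bt %in% biotype_priority()
    if (any(bad)) {
      warning(sum(bad), " feature(s) with unknown biotype coerced to 'other'")
      bt[bad] <- "other"
    }
  }
  ann <- data.frame(
    feature_id = id, biotype = bt,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,      # 1-based -> 0-based
    end = GenomicRanges::end(gr),               # inclusive -> half-open
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  zero <- ann$start >= ann$end
  if (any(zero)) {
    warning(sum(zero), " annotation interval(s) with start >= end dropped")
    ann <- ann[!zero, , drop = FALSE]
  }
  if (anyDuplicated(ann$feature_id)) stop("feature ids are not unique")
  rownames(ann) <- NULL
  ann
}

#' Assign alignment hits to annotated features
#'
#' Each hit is labelled with the overlapping (>= 1 bp, same strand)
#' feature of highest-priority biotype; ties within a biotype are broken
#' by the smaller feature interval, then lexicographic `feature_id`. Hits
#' overlapping no feature are labelled as unannotated loci
#' (`feature_id = "unann:<contig>:<start>:<strand>"`, biotype `"other"`),
#' so that novel small RNA loci still count as species.
#'
#' @param hits Hit `data.frame` from [align_inserts()].
#' @param annotations Annotation `data.frame` from [read_annotations()]
#'   (or built in code with the same columns).
#' @param priority Biotype priority order (highest first).
#' @return `hits` with `feature_id` and `biotype` columns appended.
#' @export
assign_hits <- function(hits, annotations, priority = biotype_priority()) {
  if (!nrow(hits)) {
    hits$feature_id <- character(0)
    hits$biotype <- character(0)
    return(hits)
  }
  stopifnot(all(annotations$biotype %in% priority))
  hit_gr <- GenomicRanges::GRanges(
    hits$contig,
    IRanges::IRanges(start = hits$start + 1L, end = hits$end),
    strand = hits$strand
  )
  ann_gr <- GenomicRanges::GRanges(
    annotations$contig,
    IRanges::IRanges(start = annotations$start + 1L, end = annotations$end),
    strand = annotations$strand
  )
  ov <- GenomicRanges::findOverlaps(hit_gr, ann_gr, ignore.strand = FALSE)
  feature_id <- sprintf("unann:%s:%d:%s", hits$contig, hits$start, hits$strand)
  biotype <- rep("other", nrow(hits))
  if (length(ov)) {
    cand <- data.frame(
      hit = S4Vectors::queryHits(ov),
      feature_id = annotations$feature_id[S4Vectors::subjectHits(ov)],
      biotype = annotations$biotype[S4Vectors::subjectHits(ov)],
      width = annotations$end[S4Vectors::subjectHits(ov)] -
              annotations$start[S4Vectors::subjectHits(ov)],
      stringsAsFactors = FALSE
    )
    cand$rank <- match(cand$biotype, priority)
    cand <- cand[order(cand$hit, cand$rank, cand$width, cand$feature_id), ,
                 drop = FALSE]
    best <- cand[!duplicated(cand$hit), , drop = FALSE]
    feature_id[best$hit] <- best$feature_id
    biotype[best$hit] <- best$biotype
  }
  hits$feature_id <- feature_id
  hits$biotype <- biotype
  hits
}

#' @rdname assign_hits
#' @param hit A single-hit list or one-row data.frame.
#' @export
assign_annotation <- function(hit, annotations, priority = biotype_priority()) {
  hit <- as.data.frame(hit, stringsAsFactors = FALSE)
  stopifnot(nrow(hit) == 1L)
  res <- assign_hits(hit, annotations, priority)
  res[, c("feature_id", "biotype")]
}
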