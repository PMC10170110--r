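#' Build an exact-match index over a reference genome
#'
#' Loads a (optionally gzipped) FASTA, uppercases soft-masked bases, and
#' returns the per-contig sequence store queried by [align_exact()].
#' Reference `N` bases never match a query.
#'
#' @param reference Path to a FASTA file, or a named
#'   [Biostrings::DNAStringSet].
#' @return An object of class `exact_index` with elements `seqs`
#'   (DNAStringSet) and `contigs` (data.frame of names and lengths).
#' @export
build_index <- function(reference) {
  seqs <- if (is.character(reference)) {
    Biostrings::readDNAStringSet(reference)
  } else if (methods::is(reference, "DNAStringSet")) {
    reference
  } else {
    stop("reference must be a FASTA path or a DNAStringSet")
  }
  if (!length(seqs)) stop("reference contains no sequences")
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("reference contigs must be named")
  }
  if (anyDuplicated(names(seqs))) stop("duplicate contig names in reference")
  ## uppercase soft-masked bases
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  structure(list(
    seqs = seqs,
    contigs = data.frame(contig = names(seqs),
                         length = Biostrings::width(seqs),
                         stringsAsFactors = FALSE)
  ), class = "exact_index")
}

#' @export
print.exact_index <- function(x, ...) {
  cat("exact_index: ", nrow(x$contigs), " contig(s), ",
      sum(x$contigs$length), " bp total\n", sep = "")
  invisible(x)
}

#' Align inserts to the reference with zero mismatches
#'
#' Enumerates every exact occurrence of each insert on both strands.
#' Minus-strand hits are matches of the insert's reverse complement on the
#' forward reference, reported in forward coordinates (0-based, half-open).
#' Queries are batched per length through a `PDict` for speed. Inserts
#' containing non-ACGT characters cannot match exactly and yield no hits.
#'
#' @param inserts Character vector of insert sequences.
#' @param index An [build_index()] result.
#' @return A `data.frame` with columns `insert`, `contig`, `start`, `end`,
#'   `strand`, `n_hits` (total hits of that insert, constant across its
#'   rows), sorted by `(insert, contig, start, strand)`. Unmapped inserts
#'   contribute no rows.
#' @export
align_inserts <- function(inserts, index) {
  stopifnot(inherits(index, "exact_index"))
  uq <- unique(inserts)
  uq <- uq[!is.na(uq)]
  valid <- grepl("^[ACGT]+$", uq)
  out <- list()
  widths <- nchar(uq)
  contig_names <- names(index$seqs)
  for (w in sort(unique(widths[valid]))) {
    grp <- uq[valid & widths == w]
    fwd <- Biostrings::DNAStringSet(grp)
    pd_f <- Biostrings::PDict(fwd)
    pd_r <- Biostrings::PDict(Biostrings::reverseComplement(fwd))
    for (ci in seq_along(index$seqs)) {
      subj <- index$seqs[[ci]]
      for (str in c("+", "-")) {
        pd <- if (str == "+") pd_f else pd_r
        st <- Biostrings::startIndex(Biostrings::matchPDict(pd, subj))
        nh <- lengths(st)
        if (!sum(nh)) next
        out[[length(out) + 1L]] <- data.frame(
          insert = rep(grp, nh),
          contig = contig_names[ci],
          start = unlist(st, use.names = FALSE) - 1L,
          end = unlist(st, use.names = FALSE) - 1L + w,
          strand = str,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(insert = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), n_hits = integer(0),
                      stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$insert, hits$contig, hits$start, hits$strand), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits$n_hits <- as.integer(table(hits$insert)[hits$insert])
  hits
}

#' Align one insert
#'
#' Scalar form of [align_inserts()] honouring the 16-39 nt insert
#' contract.
#'
#' @param insert A single insert sequence (16-39 nt).
#' @param index An [build_index()] result.
#' @return Hit `data.frame` (possibly empty); see [align_inserts()].
#' @export
align_exact <- function(insert, index) {
  stopifnot(length(insert) == 1L)
  if (nchar(insert) < 16 || nchar(insert) > 39) {
    stop("insert length must be within 16-39 nt, got ", nchar(insert))
  }
  hits <- align_inserts(insert, index)
  hits[, setdiff(names(hits), "insert"), drop = FALSE]
}
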