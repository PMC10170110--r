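#' Decode raw reads into (insert, UMI, barcode) triples
#'
#' Vectorised parser for the adapter architecture described by a
#' [read_layout()]. The fixed positions of the 5' adapter must match the
#' read prefix; the 3' adapter is then located downstream (leftmost match
#' wins, as in standard adapter trimming). The UMI is the concatenation of
#' the bases at the adapters' N positions, 5' adapter first. Reads failing
#' a stage carry the first failing status:
#' `no_adapter5`, `no_adapter3`, `bad_length`, `barcode_unassigned`, else
#' `ok`.
#'
#' @param seqs Character vector of read sequences.
#' @param layout A [read_layout()].
#' @param barcode_seqs Character vector of index-read sequences (required
#'   when `layout$barcode_source == "separate_index_read"` and barcode
#'   assignment is wanted).
#' @param whitelist Character vector of valid barcodes, or `NULL` to skip
#'   correction (then `corrected_barcode` is `NA` and status stops at
#'   length filtering).
#' @param read_ids Optional read identifiers.
#' @return A `data.frame` with columns `read_id`, `status`, `insert`,
#'   `umi`, `raw_barcode`, `corrected_barcode`. Fields downstream of the
#'   failing stage are `NA`.
#' @examples
#' lay <- read_layout(barcode_source = "downstream_of_adapter3")
#' read <- paste0("AAACGAAATTAAAGG", "TGAGGTAGTAGGTTGTATAGTT",
#'                "AACTGTAGGCAC", "ACGTACGTACGT")
#' parse_reads(read, lay, whitelist = "ACGTACGTACGT")
#' @export
parse_reads <- function(seqs, layout = read_layout(), barcode_seqs = NULL,
                        whitelist = NULL, read_ids = NULL) {
  stopifnot(is.character(seqs))
  n <- length(seqs)
  if (is.null(read_ids)) read_ids <- sprintf("read%06d", seq_len(n))
  p5 <- .pattern_info(layout$adapter5)
  p3 <- .pattern_info(layout$adapter3)
  len <- nchar(seqs)

  ## stage 1: 5' adapter anchored at the read prefix
  mm5 <- rep.int(0L, n)
  for (i in p5$fixed) {
    mm5 <- mm5 + (substr(seqs, i, i) != p5$chars[i])
  }
  ok5 <- len >= p5$len & mm5 <= layout$max_adapter_mismatch

  ## stage 2: leftmost downstream position whose fixed 3'-adapter bases match
  a3off <- rep.int(NA_integer_, n)   # insert length candidate
  max_off <- max(len) - p5$len - p3$len
  if (is.finite(max_off) && max_off >= 0) {
    pending <- which(ok5)
    for (o in 0:max_off) {
      if (!length(pending)) break
      cand <- pending[len[pending] >= p5$len + o + p3$len]
      if (!length(cand)) { pending <- integer(0); break }
      mm <- rep.int(0L, length(cand))
      for (i in p3$fixed) {
        pos <- p5$len + o + i
        mm <- mm + (substr(seqs[cand], pos, pos) != p3$chars[i])
      }
      hit <- cand[mm <= layout$max_adapter_mismatch]
      a3off[hit] <- o
      pending <- setdiff(pending, hit)
    }
  }
  ok3 <- ok5 & !is.na(a3off)

  status <- rep.int("ok", n)
  status[!ok5] <- "no_adapter5"
  status[ok5 & !ok3] <- "no_adapter3"

  ## stage 3: insert length filter
  ins_len <- a3off
  badlen <- ok3 & (ins_len < layout$min_insert | ins_len > layout$max_insert)
  status[badlen] <- "bad_length"
  keep <- ok3 & !badlen

  insert <- rep.int(NA_character_, n)
  insert[keep] <- substr(seqs[keep], p5$len + 1, p5$len + ins_len[keep])

  ## UMI: adapter-5 free bases then adapter-3 free bases, left to right
  umi <- rep.int(NA_character_, n)
  if (any(keep)) {
    parts <- vector("list", length(p5$free) + length(p3$free))
    k <- 0L
    for (i in p5$free) {
      k <- k + 1L
      parts[[k]] <- substr(seqs[keep], i, i)
    }
    for (i in p3$free) {
      k <- k + 1L
      pos <- p5$len + ins_len[keep] + i
      parts[[k]] <- substr(seqs[keep], pos, pos)
    }
    umi[keep] <- if (k) do.call(paste0, parts) else ""
  }

  ## stage 4: barcode extraction + whitelist correction
  raw_bc <- rep.int(NA_character_, n)
  if (layout$barcode_source == "separate_index_read") {
    if (!is.null(barcode_seqs)) {
      stopifnot(length(barcode_seqs) == n)
      from <- layout$barcode_offset + 1L
      raw_bc <- substr(barcode_seqs, from, from + layout$barcode_length - 1L)
    }
  } else {
    from <- p5$len + ins_len + p3$len + layout$barcode_offset + 1L
    raw_bc[keep] <- substr(seqs[keep], from[keep],
                           from[keep] + layout$barcode_length - 1L)
  }
  raw_bc[!is.na(raw_bc) & nchar(raw_bc) < layout$barcode_length] <- NA_character_

  corrected <- rep.int(NA_character_, n)
  if (!is.null(whitelist)) {
    idx <- which(keep & !is.na(raw_bc))
    if (length(idx)) {
      corrected[idx] <- correct_barcodes(raw_bc[idx], whitelist,
                                         layout$max_barcode_errors)
    }
    unass <- keep & is.na(corrected)
    status[unass] <- "barcode_unassigned"
    keep <- keep & !unass
  }

  data.frame(read_id = read_ids, status = status, insert = insert, umi = umi,
             raw_barcode = raw_bc, corrected_barcode = corrected,
             stringsAsFactors = FALSE)
}

#' Decode a single read
#'
#' Convenience scalar wrapper around [parse_reads()].
#'
#' @inheritParams parse_reads
#' @param seq A single read sequence.
#' @param barcode_seq Optional index-read sequence.
#' @return A one-row decode `data.frame` (see [parse_reads()]).
#' @export
parse_read <- function(seq, layout = read_layout(), barcode_seq = NULL,
                       whitelist = NULL) {
  stopifnot(length(seq) == 1L, nchar(seq) > 0)
  parse_reads(seq, layout, barcode_seqs = barcode_seq, whitelist = whitelist)
}

#' Insert length filter
#'
#' Small RNA inserts are retained when their length lies within the
#' inclusive 16-39 nt window (after adapter removal).
#'
#' @param insert Character vector of insert sequences.
#' @param min_len,max_len Inclusive bounds in nt.
#' @return Logical vector: `TRUE` = pass.
#' @export
filter_length <- function(insert, min_len = 16L, max_len = 39L) {
  n <- nchar(insert)
  n >= min_len & n <= max_len
}

#' Correct observed cell barcodes against a whitelist
#'
#' Each observed barcode is assigned to the unique whitelist entry at
#' minimal Hamming distance `d <= max_errors`. Observations with no entry
#' within tolerance, or with two or more entries tied at the minimal
#' distance, are left unassigned (`NA`): ties are discarded rather than
#' resolved arbitrarily, to avoid cross-cell contamination. Non-ACGT bases
#' mismatch every entry base.
#'
#' @param observed Character vector of observed barcodes (whitelist
#'   barcode length each).
#' @param whitelist Character vector of distinct, equal-length barcodes.
#' @param max_errors Maximum tolerated Hamming distance (default 2).
#' @return Character vector: the corrected entry or `NA_character_`.
#' @examples
#' correct_barcodes(c("AAAACCCCGGGG", "AAAACCCCGGTT"),
#'                  whitelist = c("AAAACCCCGGGG", "TTTTCCCCGGGG"))
#' @export
correct_barcodes <- function(observed, whitelist, max_errors = 2L) {
  stopifnot(length(whitelist) >= 1, !anyDuplicated(whitelist))
  L <- nchar(whitelist[1])
  stopifnot(all(nchar(whitelist) == L), all(nchar(observed) == L))
  wl_mat <- .char_matrix(whitelist)
  uq <- unique(observed)
  uq_mat <- .char_matrix(uq)
  assigned <- vapply(seq_along(uq), function(i) {
    d <- rowSums(wl_mat != matrix(uq_mat[i, ], nrow(wl_mat), L, byrow = TRUE))
    dmin <- min(d)
    if (dmin > max_errors || sum(d == dmin) > 1L) NA_character_
    else whitelist[which.min(d)]
  }, character(1))
  assigned[match(observed, uq)]
}

#' @rdname correct_barcodes
#' @export
correct_barcode <- function(observed, whitelist, max_errors = 2L) {
  stopifnot(length(observed) == 1L)
  correct_barcodes(observed, whitelist, max_errors)
}

#' Read a barcode whitelist
#'
#' Plain text, one barcode per line. Entries must be distinct, equal
#' length, and ACGT-only.
#'
#' @param path File path.
#' @return Character vector of barcodes.
#' @export
read_whitelist <- function(path) {
  x <- readLines(path)
  x <- x[nzchar(x)]
  if (!length(x)) stop("whitelist is empty: ", path)
  if (anyDuplicated(x)) stop("whitelist entries are not distinct: ", path)
  if (length(unique(nchar(x))) != 1L) stop("whitelist entries differ in length")
  if (!all(grepl("^[ACGT]+$", x))) stop("whitelist entries must be ACGT-only")
  x
}

## FASTQ reader: Biostrings handles plain and gzipped files
.read_fastq <- function(path) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) stop("failed to parse FASTQ '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- sub("\\s.*$", "", names(x))
  list(ids = ids, seqs = as.character(x))
}

#' Demultiplex a FASTQ run
#'
#' Streams a FASTQ (optionally with a separate barcode/index FASTQ),
#' decodes every read with [parse_reads()], and returns the accepted reads
#' together with per-status counters. The counters partition the input:
#' their sum always equals the number of reads.
#'
#' @param fastq Path to the read FASTQ(.gz).
#' @param layout A [read_layout()].
#' @param whitelist Character vector of barcodes or a whitelist file path.
#' @param barcode_fastq Path to the index-read FASTQ(.gz) when the layout
#'   uses a separate index read.
#' @return A list with `reads` (decode table of `ok` reads only),
#'   `decoded` (full decode table), and `counters` (named integer vector
#'   over statuses, plus `total`).
#' @export
demultiplex <- function(fastq, layout = read_layout(), whitelist,
                        barcode_fastq = NULL) {
  if (length(whitelist) == 1L && file.exists(whitelist)) {
    whitelist <- read_whitelist(whitelist)
  }
  r1 <- .read_fastq(fastq)
  bc <- NULL
  if (layout$barcode_source == "separate_index_read") {
    if (is.null(barcode_fastq)) {
      stop("layout expects a separate index read: supply barcode_fastq")
    }
    r2 <- .read_fastq(barcode_fastq)
    if (length(r2$seqs) != length(r1$seqs)) {
      stop("read FASTQ and barcode FASTQ differ in record count (",
           length(r1$seqs), " vs ", length(r2$seqs), ")")
    }
    bc <- r2$seqs
  }
  decoded <- parse_reads(r1$seqs, layout, barcode_seqs = bc,
                         whitelist = whitelist, read_ids = r1$ids)
  statuses <- c("ok", "no_adapter5", "no_adapter3", "bad_length",
                "barcode_unassigned")
  counters <- vapply(statuses, function(s) sum(decoded$status == s), 0L)
  counters <- c(counters, total = nrow(decoded))
  list(reads = decoded[decoded$status == "ok", , drop = FALSE],
       decoded = decoded, counters = counters)
}
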