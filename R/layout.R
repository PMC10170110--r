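#' Read layout: adapter architecture, UMI and barcode geometry
#'
#' Describes how a raw read is assembled: a 5' adapter pattern, the small
#' RNA insert, a 3' adapter pattern, and the cell barcode. Fixed (non-N)
#' adapter positions anchor parsing; N positions are free bases whose
#' concatenation (5' adapter N's first, left to right, then 3' adapter N's)
#' forms the unique molecular index (UMI). The defaults encode the
#' nanowell single-cell small RNA protocol: `AAANNAAANNAAANN` + insert +
#' `NNCTGTAGGCAC`, an 8-nt UMI, and a 12-nt cell barcode tolerating two
#' sequencing errors.
#'
#' @param adapter5,adapter3 Adapter patterns over `A`,`C`,`G`,`T`,`N`.
#' @param umi_length UMI length in nt; must equal the number of N positions
#'   in the two adapter patterns combined.
#' @param barcode_length Cell barcode length in nt.
#' @param barcode_source Where the barcode is sequenced:
#'   `"separate_index_read"` (a second FASTQ, the default) or
#'   `"downstream_of_adapter3"` (same read, after the 3' adapter).
#' @param barcode_offset Bases to skip before the barcode at its source.
#' @param max_barcode_errors Maximum Hamming distance tolerated when
#'   correcting a barcode against the whitelist.
#' @param max_adapter_mismatch Mismatches tolerated at fixed adapter
#'   positions (default 0: exact anchoring).
#' @param min_insert,max_insert Inclusive insert length bounds (nt).
#' @return An object of class `read_layout`.
#' @examples
#' layout <- read_layout()
#' layout$umi_length
#' @export
read_layout <- function(adapter5 = "AAANNAAANNAAANN",
                        adapter3 = "NNCTGTAGGCAC",
                        umi_length = 8L,
                        barcode_length = 12L,
                        barcode_source = c("separate_index_read",
                                           "downstream_of_adapter3"),
                        barcode_offset = 0L,
                        max_barcode_errors = 2L,
                        max_adapter_mismatch = 0L,
                        min_insert = 16L,
                        max_insert = 39L) {
  barcode_source <- match.arg(barcode_source)
  stopifnot(
    grepl("^[ACGTN]+$", adapter5), grepl("^[ACGTN]+$", adapter3),
    umi_length >= 0, barcode_length > 0,
    max_barcode_errors >= 0, max_barcode_errors < barcode_length,
    max_adapter_mismatch >= 0, barcode_offset >= 0,
    min_insert >= 1, max_insert >= min_insert
  )
  n_free <- sum(strsplit(paste0(adapter5, adapter3), "")[[1]] == "N")
  if (n_free != umi_length) {
    stop("number of N positions in the adapters (", n_free,
         ") must equal umi_length (", umi_length, ")")
  }
  structure(list(
    adapter5 = adapter5, adapter3 = adapter3,
    umi_length = as.integer(umi_length),
    barcode_length = as.integer(barcode_length),
    barcode_source = barcode_source,
    barcode_offset = as.integer(barcode_offset),
    max_barcode_errors = as.integer(max_barcode_errors),
    max_adapter_mismatch = as.integer(max_adapter_mismatch),
    min_insert = as.integer(min_insert),
    max_insert = as.integer(max_insert)
  ), class = "read_layout")
}

#' @export
print.read_layout <- function(x, ...) {
  cat("read_layout:\n")
  cat("  5' adapter : ", x$adapter5, "\n", sep = "")
  cat("  3' adapter : ", x$adapter3, "\n", sep = "")
  cat("  UMI        : ", x$umi_length, " nt (adapter N positions)\n", sep = "")
  cat("  barcode    : ", x$barcode_length, " nt from ", x$barcode_source,
      ", <=", x$max_barcode_errors, " errors\n", sep = "")
  cat("  insert     : ", x$min_insert, "-", x$max_insert, " nt\n", sep = "")
  invisible(x)
}

## split an adapter pattern into fixed / free position bookkeeping
.pattern_info <- function(pattern) {
  ch <- strsplit(pattern, "", fixed = TRUE)[[1]]
  list(chars = ch, len = length(ch),
       fixed = which(ch != "N"), free = which(ch == "N"))
}
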