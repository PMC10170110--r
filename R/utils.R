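#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Hamming distance between equal-length strings
#'
#' Positions holding any differing characters count as mismatches, so a
#' non-ACGT base mismatches every ACGT base.
#'
#' @param a,b Character scalars of equal length.
#' @return Integer mismatch count.
#' @export
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

## character matrix (n x L) from equal-length strings
.char_matrix <- function(x) {
  if (!length(x)) return(matrix(character(0), 0, 0))
  L <- nchar(x[1])
  stopifnot(all(nchar(x) == L))
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = L, byrow = TRUE)
}

.random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}
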