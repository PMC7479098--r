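#' Pairwise sequence identity from global alignment
#'
#' Aligns two nucleotide sequences globally with an affine gap penalty
#' (match +1, mismatch -1, gap open -2, gap extension -1 per position) and
#' returns the fraction of identical alignment columns. Terminal gap columns
#' (leading/trailing runs where either sequence is gapped) are excluded from
#' both numerator and denominator, so a short sequence nested in a longer one
#' is scored only over the overlapping region. The traceback uses a fixed
#' preference order on ties, making the value deterministic.
#'
#' @param a,b non-empty nucleotide strings.
#' @param band optional DP band half-width around the main diagonal; `NULL`
#'   (default) runs the full unbanded alignment. A band is exact whenever the
#'   optimal alignment stays within it (always true for substitution-only
#'   divergence) and is used by the clustering fast paths.
#' @param details if `TRUE` return a list with the aligned strings, score,
#'   match and column counts in addition to the identity.
#' @return identity in `[0, 1]`, or a list when `details = TRUE`.
#' @examples
#' pairwise_identity("ACGTACGT", "ACGTACGT")        # 1
#' pairwise_identity("ACGTACGT", "ACGAACGT")        # 7/8
#' @export
pairwise_identity <- function(a, b, band = NULL, details = FALSE) {
  if (!is.character(a) || !is.character(b) || length(a) != 1L || length(b) != 1L)
    stop("'a' and 'b' must be single character strings")
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("sequences must be non-empty")
  r <- .cpp_nw_align(a, b, band = if (is.null(band)) -1L else as.integer(band))
  if (details) r else r$identity
}

#' Pairwise identity matrix for equal-length ungapped sequences
#'
#' Gapless identity `1 - hamming/L` for a set of sequences sharing one length.
#' For substitution-only divergence this equals [pairwise_identity()].
#'
#' @param seqs character vector of equal-length sequences.
#' @return symmetric identity matrix with unit diagonal.
#' @export
identity_matrix <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  m <- .cpp_hamming_identity_matrix(seqs)
  dimnames(m) <- list(names(seqs), names(seqs))
  m
}
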