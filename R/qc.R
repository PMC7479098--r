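# Read quality control: ambiguous-base removal, positional trimming, length
# bounds, and a reference-based bimera screen.

new_filter_report <- function(sample_ids) {
  data.frame(sample_id = sample_ids,
             input = 0L, removed_ambiguous = 0L, removed_length = 0L,
             removed_chimera = 0L, retained = 0L, stringsAsFactors = FALSE)
}

#' Quality-filter and trim reads
#'
#' Drops reads containing any non-ACGT symbol, truncates survivors to the
#' positional window `trim_window` (1-based, inclusive; default 10--1490, the
#' standard near-full-length 16S window), then drops reads whose post-trim
#' length falls outside `[min_len, max_len]`. Read order is preserved.
#'
#' @param reads a `read_set` data.frame.
#' @param min_len,max_len post-trim length bounds (default 1000 and 1600).
#' @param trim_window `c(start, end)`, `start < end`.
#' @return list with `reads` (filtered, trimmed) and `report` (a per-sample
#'   `FilterReport`: input = removed_ambiguous + removed_length + retained).
#' @export
quality_filter <- function(reads, min_len = 1000, max_len = 1600,
                           trim_window = c(10, 1490)) {
  if (trim_window[1] >= trim_window[2]) stop("trim window start must be < end")
  samples <- unique(reads$sample_id)
  rep_ <- new_filter_report(samples)
  rep_$input <- as.integer(table(factor(reads$sample_id, levels = samples)))

  ambiguous <- grepl("[^ACGT]", reads$sequence)
  rep_$removed_ambiguous <- as.integer(
    table(factor(reads$sample_id[ambiguous], levels = samples)))
  reads <- reads[!ambiguous, , drop = FALSE]

  reads$sequence <- substr(reads$sequence, trim_window[1], trim_window[2])
  len <- nchar(reads$sequence)
  bad_len <- len < min_len | len > max_len
  rep_$removed_length <- as.integer(
    table(factor(reads$sample_id[bad_len], levels = samples)))
  reads <- reads[!bad_len, , drop = FALSE]

  rep_$retained <- as.integer(table(factor(reads$sample_id, levels = samples)))
  rownames(reads) <- NULL
  list(reads = reads, report = rep_)
}

#' Reference-based bimera (chimera) filter
#'
#' A read is flagged bimeric when some two-parent model (left segment copied
#' from reference A, right from reference B, breakpoint scanned on a
#' `grid`-nt grid) explains it better than any single reference: flagged when
#' best two-parent identity minus best single-parent identity is `>= margin`
#' (default 0.02). Flagged reads are removed. Reads and references must share
#' one length (apply the same trim window to both); the scan uses gapless
#' segment identities.
#'
#' @param reads a `read_set` (post [quality_filter()]).
#' @param references character vector of reference sequences (same length as
#'   the reads).
#' @param margin required identity gain of the two-parent model.
#' @param grid breakpoint grid spacing in nt.
#' @param report optionally a `FilterReport` from [quality_filter()] to update.
#' @return list with `reads`, `report`, and `flags` (logical per input read).
#' @export
chimera_filter <- function(reads, references, margin = 0.02, grid = 50,
                           report = NULL) {
  if (length(references) == 0) stop("references must be non-empty")
  if (nrow(reads) == 0) {
    return(list(reads = reads, report = report, flags = logical(0)))
  }
  sc <- .cpp_chimera_scan(reads$sequence, unname(references), grid = grid)
  flags <- (sc[, 2] - sc[, 1]) >= margin
  samples <- unique(reads$sample_id)
  if (is.null(report)) {
    report <- new_filter_report(samples)
    report$input <- as.integer(table(factor(reads$sample_id, levels = samples)))
  }
  rm_ <- table(factor(reads$sample_id[flags], levels = report$sample_id))
  report$removed_chimera <- report$removed_chimera + as.integer(rm_)
  out <- reads[!flags, , drop = FALSE]
  report$retained <- as.integer(
    table(factor(out$sample_id, levels = report$sample_id)))
  rownames(out) <- NULL
  list(reads = out, report = report, flags = flags)
}
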