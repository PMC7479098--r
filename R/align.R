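# Multiple alignment of reference sequences (center-star progressive scheme)
# with profile-constrained query mapping, and the conservation column filter.

insertion_profile <- function(aligned_center) {
  # number of inserted columns before each center residue (and trailing)
  s <- strsplit(aligned_center, "", fixed = TRUE)[[1]]
  Lc <- sum(s != "-")
  ins <- integer(Lc + 1L)
  pos <- 1L; run <- 0L
  for (ch in s) {
    if (ch == "-") run <- run + 1L
    else { ins[pos] <- run; run <- 0L; pos <- pos + 1L }
  }
  ins[Lc + 1L] <- run
  ins
}

project_row <- function(aligned_center, aligned_seq, master_ins) {
  # rebuild one row on the master column system defined by `master_ins`
  ac <- strsplit(aligned_center, "", fixed = TRUE)[[1]]
  as_ <- strsplit(aligned_seq, "", fixed = TRUE)[[1]]
  out <- character(0)
  pos <- 1L; buf <- character(0)
  flush <- function(buf, width) c(buf, rep("-", width - length(buf)))
  for (k in seq_along(ac)) {
    if (ac[k] == "-") {
      buf <- c(buf, as_[k])
    } else {
      out <- c(out, flush(buf, master_ins[pos]), as_[k])
      buf <- character(0); pos <- pos + 1L
    }
  }
  out <- c(out, flush(buf, master_ins[pos]))
  paste(out, collapse = "")
}

#' Align references and map queries onto the fixed profile
#'
#' References are multiply aligned by a center-star progressive scheme: the
#' reference with the highest summed pairwise identity is the center, every
#' other reference is aligned to it globally (same scoring as
#' [pairwise_identity()]), and the pairwise alignments are merged under
#' "once a gap, always a gap". Queries never alter the reference columns:
#' each query is aligned to its highest-identity reference and projected onto
#' that reference's columns, dropping query insertions relative to the profile
#' (reference-constrained mapping). When every input has one common length the
#' gapless alignment is returned directly (the substitution-only fast path).
#'
#' @param references named character vector (>= 2) of ACGT sequences.
#' @param queries optional named character vector mapped onto the profile.
#' @return object of class `aligned_matrix`: `rows` (named equal-length
#'   strings, references first), `mask` (all TRUE), `reference_ids`,
#'   `query_ids`.
#' @export
align_profiles <- function(references, queries = NULL) {
  if (length(references) < 2) stop("need at least 2 references")
  all_seq <- c(references, queries)
  if (any(grepl("[^ACGT]", all_seq)))
    stop("sequences must contain only A/C/G/T (run quality_filter first)")
  if (is.null(names(references)) || (length(queries) && is.null(names(queries))))
    stop("sequences must be named")

  if (length(unique(nchar(all_seq))) == 1L) {
    rows <- all_seq
  } else {
    ids <- names(references)
    n <- length(ids)
    idm <- matrix(1, n, n)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      v <- pairwise_identity(references[[i]], references[[j]])
      idm[i, j] <- v; idm[j, i] <- v
    }
    center <- which.max(rowSums(idm))
    pairs <- vector("list", n)
    for (i in seq_len(n)) {
      if (i == center) next
      a <- .cpp_nw_align(references[[center]], references[[i]])
      pairs[[i]] <- list(ac = a$aligned_a, as = a$aligned_b)
    }
    Lc <- nchar(references[[center]])
    master <- integer(Lc + 1L)
    for (i in seq_len(n)) if (!is.null(pairs[[i]]))
      master <- pmax(master, insertion_profile(pairs[[i]]$ac))
    rows <- character(n); names(rows) <- ids
    rows[center] <- project_row(references[[center]], references[[center]], master)
    for (i in seq_len(n)) if (!is.null(pairs[[i]]))
      rows[i] <- project_row(pairs[[i]]$ac, pairs[[i]]$as, master)

    if (length(queries)) {
      ref_rows <- rows
      qrows <- character(length(queries)); names(qrows) <- names(queries)
      for (q in seq_along(queries)) {
        best <- which.max(vapply(references, function(r)
          pairwise_identity(r, queries[[q]]), 0))
        a <- .cpp_nw_align(references[[best]], queries[[q]])
        # map query residues onto the best reference's master columns
        rr <- strsplit(ref_rows[[best]], "", fixed = TRUE)[[1]]
        ar <- strsplit(a$aligned_a, "", fixed = TRUE)[[1]]
        aq <- strsplit(a$aligned_b, "", fixed = TRUE)[[1]]
        qchar_at_ref_pos <- aq[ar != "-"]  # query char aligned to each ref residue
        out <- rep("-", length(rr))
        out[rr != "-"] <- qchar_at_ref_pos
        qrows[q] <- paste(out, collapse = "")
      }
      rows <- c(ref_rows, qrows)
    }
  }
  structure(list(rows = rows,
                 mask = rep(TRUE, nchar(rows[[1L]])),
                 reference_ids = names(references),
                 query_ids = names(queries) %||% character(0)),
            class = "aligned_matrix")
}

#' Conservation column filter
#'
#' Keeps an alignment column iff the modal residue frequency among its non-gap
#' entries is at least `min_conservation` (30% by default, the standard
#' conservational filter for 16S phylogenetic reconstruction) and its non-gap
#' fraction is at least `min_nongap`. Only the mask changes; the alignment
#' data are untouched.
#'
#' @param aln an `aligned_matrix`.
#' @param min_conservation modal-residue frequency floor in `[0, 1]`.
#' @param min_nongap non-gap fraction floor.
#' @return the `aligned_matrix` with an updated `mask`.
#' @export
conservation_mask <- function(aln, min_conservation = 0.30, min_nongap = 0.5) {
  stopifnot(inherits(aln, "aligned_matrix"))
  if (length(aln$rows) == 0) stop("alignment is empty")
  m <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  keep <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    nongap <- col[col %in% c("A", "C", "G", "T")]
    frac_nongap <- length(nongap) / length(col)
    if (frac_nongap < min_nongap) next
    modal <- max(table(nongap)) / length(nongap)
    keep[j] <- modal >= min_conservation
  }
  if (!any(keep)) stop("conservation filter masked every column")
  aln$mask <- keep
  aln
}
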