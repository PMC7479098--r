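# Greedy centroid OTU clustering at the species-discrimination identity
# threshold, with abundance-ranked processing and deterministic tie-breaks.

#' Cluster reads into OTUs by greedy centroid clustering
#'
#' Unique sequences are processed in decreasing multiplicity (ties broken by
#' lexicographic sequence order). Each sequence joins the first existing
#' centroid, in founding order, whose identity to it is at or above
#' `threshold` (98.7%, the 16S species-discrimination threshold, by default);
#' otherwise it founds a new centroid. Identity is [pairwise_identity()]; for
#' equal-length pairs the gapless value is used directly, with a
#' dynamic-programming confirmation when it falls within `slack` below the
#' threshold (see the methods vignette).
#'
#' @param reads a `read_set` data.frame.
#' @param threshold identity threshold in (0, 1]; joining is inclusive
#'   (`>= threshold`) unless `inclusive = FALSE`.
#' @param inclusive whether identity exactly at the threshold joins.
#' @param slack,band fast-path parameters passed to the clustering core.
#' @return object of class `otu_set`: `map` (read_id, sample_id, otu_id),
#'   `otus` (otu_id, representative, size, founded order), `threshold`.
#' @export
greedy_cluster <- function(reads, threshold = 0.987, inclusive = TRUE,
                           slack = 0.02, band = 64) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (nrow(reads) == 0) stop("no reads to cluster")
  useq <- unique(reads$sequence)
  idx <- match(reads$sequence, useq)
  mult <- tabulate(idx, nbins = length(useq))
  ord <- order(-mult, useq)
  eff_threshold <- if (inclusive) threshold else threshold + 1e-12
  assign_sorted <- .cpp_greedy_cluster(useq[ord], eff_threshold,
                                       slack = slack, band = as.integer(band))
  cent_of_unique <- integer(length(useq))
  cent_of_unique[ord] <- assign_sorted
  otu_ids <- sprintf("OTU%05d", cent_of_unique[idx])

  map <- data.frame(read_id = reads$read_id, sample_id = reads$sample_id,
                    otu_id = otu_ids, stringsAsFactors = FALSE)
  reps <- vapply(split(reads$sequence, otu_ids), pick_representative, "")
  sizes <- table(otu_ids)
  otus <- data.frame(otu_id = names(reps), representative = unname(reps),
                     size = as.integer(sizes[names(reps)]),
                     stringsAsFactors = FALSE)
  otus <- otus[order(otus$otu_id), , drop = FALSE]
  rownames(otus) <- NULL
  structure(list(map = map, otus = otus, threshold = threshold),
            class = "otu_set")
}

#' Representative sequence of an OTU
#'
#' The member sequence with the highest read multiplicity; ties broken by the
#' lexicographically smallest sequence.
#'
#' @param sequences member sequences, one entry per read (duplicates encode
#'   multiplicity), or unique sequences with `multiplicity` supplied.
#' @param multiplicity optional integer vector matching `sequences`.
#' @return the representative sequence.
#' @export
pick_representative <- function(sequences, multiplicity = NULL) {
  if (length(sequences) == 0) stop("OTU must be non-empty")
  if (is.null(multiplicity)) {
    tab <- table(sequences)
    u <- names(tab); m <- as.integer(tab)
  } else {
    u <- sequences; m <- as.integer(multiplicity)
  }
  u[order(-m, u)][1L]
}
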