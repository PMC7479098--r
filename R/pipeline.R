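# End-to-end orchestration: reads -> OTUs -> placement -> OPU/SLP calls ->
# abundance, prevalence and typing layers; plus truth-based evaluation
# helpers for synthetic runs.

trim_sequences <- function(seqs, trim_window) {
  substr(seqs, trim_window[1], trim_window[2])
}

#' Run the full metataxonomic pipeline
#'
#' Quality filter and trim, reference-based bimera removal, greedy OTU
#' clustering at the species threshold, alignment and conservation masking,
#' Jukes-Cantor/neighbor-joining reference tree, least-squares placement of
#' OTU representatives, OPU delineation and categorization, and the SLP x
#' sample abundance table with prevalence strata.
#'
#' @param db the emitted (visible) `reference_db`.
#' @param reads a `read_set`.
#' @param trim_window,min_len,max_len see [quality_filter()].
#' @param chimera_margin see [chimera_filter()]; `NULL` disables the screen.
#' @param otu_threshold OTU identity threshold (default 0.987).
#' @param min_conservation conservation filter (default 0.30).
#' @param species_threshold classified-species identity bound.
#' @return list: `report`, `otus`, `aln`, `dist`, `tree`, `opus`,
#'   `slp_table`, `prevalence`, `groups`, `trimmed_refs`.
#' @export
run_pipeline <- function(db, reads, trim_window = c(10, 1490),
                         min_len = 1000, max_len = 1600,
                         chimera_margin = 0.02,
                         otu_threshold = 0.987,
                         min_conservation = 0.30,
                         species_threshold = 0.987) {
  qc <- quality_filter(reads, min_len = min_len, max_len = max_len,
                       trim_window = trim_window)
  refs_trimmed <- trim_sequences(db$sequences, trim_window)
  work <- qc
  if (!is.null(chimera_margin)) {
    cf <- chimera_filter(qc$reads, refs_trimmed[names(refs_trimmed) != db$outgroup_id],
                         margin = chimera_margin, report = qc$report)
    work <- cf
  }
  otus <- greedy_cluster(work$reads, threshold = otu_threshold)
  reps <- setNames(otus$otus$representative, otus$otus$otu_id)
  aln <- align_profiles(refs_trimmed, reps)
  aln <- conservation_mask(aln, min_conservation = min_conservation)
  d <- masked_jc_matrix(aln)
  ref_ids <- names(refs_trimmed)
  tree <- nj_tree(d[ref_ids, ref_ids], db$outgroup_id)
  sizes <- setNames(otus$otus$size, otus$otus$otu_id)
  tree <- place_queries(tree, d, names(reps), sizes)
  opus <- call_opus(tree, otus, db, ref_seqs = refs_trimmed,
                    species_threshold = species_threshold)
  slp <- build_slp_table(otus$map, opus$otu_to_opu)
  prev <- prevalence(slp)
  groups <- stratify(prev$prevalence)
  names(groups) <- names(prev$prevalence)
  list(report = work$report, otus = otus, aln = aln, dist = d, tree = tree,
       opus = opus, slp_table = slp, prevalence = prev, groups = groups,
       trimmed_refs = refs_trimmed)
}

#' Majority true source taxon per OPU
#'
#' Maps every OPU to the most frequent true source taxon among its member
#' reads (chimeric reads excluded). Only meaningful on synthetic read sets
#' carrying provenance.
#'
#' @param result a [run_pipeline()] result.
#' @param reads the original `read_set` with truth columns.
#' @return data.frame: opu_id, truth_taxon (NA when all members are
#'   chimeric), purity (fraction of non-chimeric member reads from the
#'   majority taxon).
#' @export
opu_truth <- function(result, reads) {
  src <- setNames(reads$source_taxon_id, reads$read_id)
  map <- result$otus$map
  map$opu_id <- result$opus$otu_to_opu[map$otu_id]
  map$truth <- src[map$read_id]
  out <- lapply(split(map, map$opu_id), function(grp) {
    tt <- grp$truth[!is.na(grp$truth)]
    if (length(tt) == 0)
      return(data.frame(opu_id = grp$opu_id[1L], truth_taxon = NA_character_,
                        purity = NA_real_, stringsAsFactors = FALSE))
    tab <- sort(table(tt), decreasing = TRUE)
    data.frame(opu_id = grp$opu_id[1L], truth_taxon = names(tab)[1L],
               purity = as.numeric(tab[1L]) / length(tt),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

planted_category <- c(classified = "classified_species",
                      new_species = "potential_new_species",
                      new_genus = "potential_new_taxon")

#' Evaluate parameter recovery of a synthetic run
#'
#' Compares OPU calls against the planted truth: the fraction of OPUs whose
#' category matches the planted one (classified / new species / new taxon),
#' the fraction of classified OPUs assigned the true species name, and the
#' fraction of community taxa whose prevalence stratum matches the planted
#' tier. OPUs with no non-chimeric reads are excluded.
#'
#' @param result a [run_pipeline()] result.
#' @param reads the synthetic `read_set`.
#' @param profiles the `community_profiles` that generated the reads.
#' @return list of recovery fractions and supporting tables.
#' @export
evaluate_recovery <- function(result, reads, profiles) {
  truth <- opu_truth(result, reads)
  rec <- merge(result$opus$records, truth, by = "opu_id")
  rec <- rec[!is.na(rec$truth_taxon), , drop = FALSE]
  planted <- setNames(profiles$novelty$planted, profiles$novelty$taxon_id)
  rec$planted <- planted_category[planted[rec$truth_taxon]]
  rec$category_ok <- rec$category == rec$planted
  cls <- rec[rec$planted == "classified_species" &
               rec$category == "classified_species", , drop = FALSE]
  cls_ok <- cls$species == cls$truth_taxon

  # tier recovery: recovered stratum of each taxon's (largest) OPU vs planted
  tier_map <- c(low = "low", medium = "medium", high = "high")
  rec_major <- rec[order(-rec$size), ]
  rec_major <- rec_major[!duplicated(rec_major$truth_taxon), ]
  recovered_group <- result$groups[rec_major$opu_id]
  planted_tier <- profiles$tiers[rec_major$truth_taxon]
  tier_ok <- recovered_group == tier_map[planted_tier]

  list(category_accuracy = mean(rec$category_ok),
       species_name_accuracy = if (nrow(cls)) mean(cls_ok) else NA_real_,
       tier_recovery = mean(tier_ok, na.rm = TRUE),
       n_opus = nrow(rec),
       n_classified = nrow(cls),
       n_taxa_scored = sum(!is.na(tier_ok)),
       records = rec)
}

#' Adjusted Rand index between two labelings
#'
#' Standard chance-corrected agreement between partitions; 1 means identical
#' up to label permutation, 0 is the chance level.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
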