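# OPU delineation and categorization: smallest monophyletic clades anchoring
# queries to references, three-way species-level calls, and the SLP table.

#' Smallest anchored clade containing a query leaf
#'
#' Walks rootward from the query and returns the first (minimal) node whose
#' leaf set contains at least one reference leaf.
#'
#' @param tree rooted `phylo` containing the query.
#' @param query_leaf query tip label.
#' @param reference_ids tip labels that count as references.
#' @return internal node number of the clade.
#' @export
smallest_anchored_clade <- function(tree, query_leaf, reference_ids) {
  if (!any(tree$tip.label %in% reference_ids))
    stop("tree contains no reference leaves")
  tipn <- match(query_leaf, tree$tip.label)
  if (is.na(tipn)) stop("query leaf not found in tree")
  anc <- phangorn::Ancestors(tree, tipn, type = "all")
  for (node in anc) {
    tips <- tree$tip.label[phangorn::Descendants(tree, node, type = "tips")[[1L]]]
    if (any(tips %in% reference_ids)) return(node)
  }
  stop("no anchored clade found")  # unreachable on a tree with references
}

#' Group placed queries into OPUs
#'
#' Each query's smallest anchored clade is computed; queries whose clades
#' coincide are merged, as are queries whose clades nest (one contains the
#' other) while sharing the same reference leaves -- the outer clade then
#' adds only further queries, so the nearest reference anchor is unchanged.
#' Nested clades that recruit additional references stay separate OPUs.
#' Every query belongs to exactly one OPU.
#'
#' @param tree rooted `phylo` with queries placed.
#' @param query_ids query tip labels.
#' @param reference_ids reference tip labels.
#' @return data.frame: query_id, clade_node (per query), opu_id, opu_clade
#'   (the maximal clade node of the OPU).
#' @export
delineate_opus <- function(tree, query_ids, reference_ids) {
  nodes <- vapply(query_ids, function(q)
    smallest_anchored_clade(tree, q, reference_ids), 0L)
  n <- length(query_ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  node_anc <- lapply(nodes, function(nd)
    phangorn::Ancestors(tree, nd, type = "all"))
  node_refs <- lapply(nodes, function(nd) sort(intersect(
    tree$tip.label[phangorn::Descendants(tree, nd, type = "tips")[[1L]]],
    reference_ids)))
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      nested <- nodes[i] %in% node_anc[[j]] || nodes[j] %in% node_anc[[i]]
      merge_ <- nodes[i] == nodes[j] ||
        (nested && identical(node_refs[[i]], node_refs[[j]]))
      if (merge_) parent[find(j)] <- find(i)
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  # maximal clade per component = the node closest to the root (fewest ancestors)
  depth <- vapply(nodes, function(nd)
    length(phangorn::Ancestors(tree, nd, type = "all")), 0L)
  opu_clade <- vapply(comp, function(cc) {
    members <- which(comp == cc)
    members_nodes <- nodes[members]
    members_nodes[which.min(depth[members])]
  }, 0L)
  comp_ids <- match(comp, unique(comp))
  data.frame(query_id = query_ids,
             clade_node = unname(nodes),
             opu_id = sprintf("OPU%04d", comp_ids),
             opu_clade = unname(opu_clade),
             stringsAsFactors = FALSE)
}

rank_below <- c(genus = "species", family = "genus", order = "family",
                class = "order", phylum = "class")

#' Categorize one OPU
#'
#' The anchor is the clade reference closest to the OPU representative
#' (type strains preferred). Categories: (i) anchor is a type strain with
#' identity strictly above `species_threshold` -> `classified_species`;
#' otherwise the finest rank is sought at which all clade references share
#' one lineage label *and* the anchor identity reaches the canonical rank
#' identity floor (genus 94.5%, family 86.5%, order 82%, class 78.5%, phylum
#' 75%): agreement at genus gives `potential_new_species` within that genus,
#' agreement only at a coarser rank gives `potential_new_taxon` at the rank
#' one below it.
#'
#' @param clade_node OPU clade node in `tree`.
#' @param tree rooted `phylo`.
#' @param db `reference_db` providing lineages and reference sequences.
#' @param representative_seq the OPU representative sequence.
#' @param ref_seqs optional named reference sequences to score identity
#'   against (defaults to `db$sequences`; pass trimmed references when the
#'   representative is trimmed).
#' @param species_threshold strict lower bound for a classified species call.
#' @param rank_floors named rank identity floors.
#' @param identity_band DP band half-width for the anchor identity (64 covers
#'   any plausible 16S indel load; `NULL` = unbanded).
#' @return one-row data.frame: anchor_ref_id, anchor_identity, category,
#'   new_taxon_rank, and the six lineage columns (NA below the resolved rank).
#' @export
categorize_opu <- function(clade_node, tree, db, representative_seq,
                           ref_seqs = NULL,
                           species_threshold = 0.987,
                           rank_floors = RANK_IDENTITY_FLOORS,
                           identity_band = 64) {
  ref_seqs <- ref_seqs %||% db$sequences
  tips <- tree$tip.label[phangorn::Descendants(tree, clade_node, type = "tips")[[1L]]]
  refs <- intersect(tips, db$taxa$id)
  if (length(refs) == 0) stop("clade contains no reference leaves")
  tx <- db$taxa[match(refs, db$taxa$id), , drop = FALSE]
  if (anyNA(tx$genus)) stop("missing lineage for: ",
                            paste(refs[is.na(tx$genus)], collapse = ", "))

  cand <- if (any(tx$is_type_strain)) refs[tx$is_type_strain] else refs
  idents <- vapply(cand, function(r)
    pairwise_identity(ref_seqs[[r]], representative_seq, band = identity_band), 0)
  anchor <- cand[order(-idents, cand)][1L]
  anchor_identity <- idents[[anchor]]
  anchor_tx <- tx[match(anchor, refs), ]

  lineage <- rep(NA_character_, 6L); names(lineage) <- RANKS
  if (anchor_tx$is_type_strain && anchor_identity > species_threshold) {
    lineage[] <- unlist(anchor_tx[RANKS])
    out <- data.frame(anchor_ref_id = anchor, anchor_identity = anchor_identity,
                      category = "classified_species",
                      new_taxon_rank = NA_character_, stringsAsFactors = FALSE)
    return(cbind(out, as.data.frame(as.list(lineage), stringsAsFactors = FALSE)))
  }
  for (r in c("genus", "family", "order", "class", "phylum")) {
    homogeneous <- length(unique(tx[[r]])) == 1L
    if (homogeneous && anchor_identity >= rank_floors[[r]]) {
      upto <- seq_len(match(r, RANKS))
      lineage[upto] <- unlist(anchor_tx[RANKS[upto]])
      if (r == "genus") {
        out <- data.frame(anchor_ref_id = anchor,
                          anchor_identity = anchor_identity,
                          category = "potential_new_species",
                          new_taxon_rank = NA_character_,
                          stringsAsFactors = FALSE)
      } else {
        out <- data.frame(anchor_ref_id = anchor,
                          anchor_identity = anchor_identity,
                          category = "potential_new_taxon",
                          new_taxon_rank = rank_below[[r]],
                          stringsAsFactors = FALSE)
      }
      return(cbind(out, as.data.frame(as.list(lineage), stringsAsFactors = FALSE)))
    }
  }
  out <- data.frame(anchor_ref_id = anchor, anchor_identity = anchor_identity,
                    category = "potential_new_taxon", new_taxon_rank = "phylum",
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(as.list(lineage), stringsAsFactors = FALSE))
}

#' Delineate and categorize all OPUs on a placed tree
#'
#' @param tree rooted `phylo` with queries placed.
#' @param otus an `otu_set` (provides representatives and sizes; its OTU ids
#'   must be the query tip labels).
#' @param db `reference_db`.
#' @param ref_seqs optional (e.g. trimmed) reference sequences for identity.
#' @param species_threshold,rank_floors,identity_band see [categorize_opu()].
#' @return list with `records` (one row per OPU: opu_id, members, size,
#'   anchor, identity, category, rank, lineage) and `otu_to_opu` (named map).
#' @export
call_opus <- function(tree, otus, db, ref_seqs = NULL,
                      species_threshold = 0.987,
                      rank_floors = RANK_IDENTITY_FLOORS,
                      identity_band = 64) {
  query_ids <- intersect(tree$tip.label, otus$otus$otu_id)
  del <- delineate_opus(tree, query_ids, db$taxa$id)
  sizes <- setNames(otus$otus$size, otus$otus$otu_id)
  reps <- setNames(otus$otus$representative, otus$otus$otu_id)
  rec <- lapply(split(del, del$opu_id), function(grp) {
    members <- grp$query_id
    rep_member <- members[order(-sizes[members], members)][1L]
    cat_ <- categorize_opu(grp$opu_clade[1L], tree, db, reps[[rep_member]],
                           ref_seqs = ref_seqs,
                           species_threshold = species_threshold,
                           rank_floors = rank_floors,
                           identity_band = identity_band)
    cbind(data.frame(opu_id = grp$opu_id[1L],
                     members = paste(members, collapse = ","),
                     n_otus = length(members),
                     size = sum(sizes[members]),
                     representative_otu = rep_member,
                     stringsAsFactors = FALSE),
          cat_)
  })
  records <- do.call(rbind, rec)
  rownames(records) <- NULL
  otu_to_opu <- setNames(del$opu_id, del$query_id)
  list(records = records, otu_to_opu = otu_to_opu)
}

#' Build the SLP x sample abundance table
#'
#' Counts retained reads per OPU (species-level phylotype) and sample. Rows
#' are ordered by total abundance, descending.
#'
#' @param otu_map data.frame read_id/sample_id/otu_id (from an `otu_set`).
#' @param otu_to_opu named character map OTU id -> OPU id.
#' @return integer matrix, rows = SLP (OPU) ids, columns = sample ids; column
#'   sums equal retained reads per sample.
#' @export
build_slp_table <- function(otu_map, otu_to_opu) {
  opu <- otu_to_opu[otu_map$otu_id]
  if (anyNA(opu)) {
    missing <- unique(otu_map$otu_id[is.na(opu)])
    stop("unmapped OTUs: ", paste(missing, collapse = ", "))
  }
  tab <- table(opu, otu_map$sample_id)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m[order(-rowSums(m)), , drop = FALSE]
}
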