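# Synthetic-data module: reference databases with rank-calibrated 16S
# divergence, planted two-type community profiles, and error-bearing read sets.

local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_positions <- function(seq, n_mut) {
  if (n_mut <= 0L) return(seq)
  bases <- c("A", "C", "G", "T")
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(s), min(n_mut, length(s)))
  for (p in pos) {
    s[p] <- sample(setdiff(bases, s[p]), 1L)
  }
  paste(s, collapse = "")
}

# Evolve k descendant sequences from a common ancestor within one rank.
# Descendants sit at divergence depth D (fraction of sites) below the ancestor;
# internal splits of the random topology occur at depths drawn from
# [split_lo, split_hi], so any two descendants differ by mutations on
# 2*(D - split_depth) of sites. Depths are sorted so that splits nest properly.
evolve_group <- function(seq, k, D, split_lo, split_hi, L) {
  if (k == 1L) return(list(mutate_positions(seq, round(D * L))))
  depths <- sort(runif(k - 1L, split_lo, split_hi))
  recurse <- function(seq, depth_now, k, depths) {
    if (k == 1L) return(list(mutate_positions(seq, round((D - depth_now) * L))))
    d <- depths[1L]
    seq_d <- mutate_positions(seq, round(max(0, d - depth_now) * L))
    k1 <- sample(seq_len(k - 1L), 1L)
    k2 <- k - k1
    rest <- depths[-1L]
    if (length(rest) > 0L && k1 > 1L) {
      take <- sort(sample(length(rest), k1 - 1L))
      d1 <- rest[take]; d2 <- rest[-take]
    } else {
      d1 <- numeric(0); d2 <- rest
    }
    c(recurse(seq_d, d, k1, d1), recurse(seq_d, d, k2, d2))
  }
  recurse(seq, 0, k, depths)
}

default_divergence <- function() {
  list(
    phylum  = list(depth = 0.050, split = c(0.000, 0.020)),
    class   = list(depth = 0.020, split = c(0.000, 0.008)),
    order   = list(depth = 0.020, split = c(0.000, 0.008)),
    family  = list(depth = 0.040, split = c(0.000, 0.020)),
    genus   = list(depth = 0.0625, split = c(0.020, 0.036)),
    species = list(depth = 0.025, split = c(0.000, 0.015)),
    outgroup = 0.35
  )
}

default_bands <- function() {
  # realized pairwise identity bands the generated database must satisfy:
  # congeneric species straddle (but stay below) the 98.7% species threshold,
  # confamilial genera sit between the family and genus identity floors.
  list(genus = c(0.92, 0.987), family = c(0.86, 0.92))
}

#' Generate a hierarchical 16S reference database
#'
#' Simulates type-strain 16S rRNA sequences along a six-rank taxonomy
#' (phylum, class, order, family, genus, species) by accumulating random
#' substitutions down the hierarchy. Divergence is rank-calibrated so that
#' realized pairwise identities straddle the canonical species threshold:
#' congeneric species fall inside `bands$genus` (default 92--98.7% identity)
#' and genera within a family inside `bands$family` (default 86--92%).
#' Identities are measured with the package's own gapless identity (the
#' substitution-only model produces no indels) and the generator aborts,
#' naming the offending band, if a parameter set cannot realize them.
#' A divergent outgroup taxon is always included for tree rooting.
#'
#' @param n_phyla,classes_per_phylum,orders_per_class,families_per_order,
#'   genera_per_family,species_per_genus taxonomy shape; all `>= 1`.
#' @param seq_length sequence length in nt (default 1443, a typical
#'   near-full-length 16S amplicon).
#' @param seed integer seed; identical inputs and seed give byte-identical
#'   output.
#' @param divergence per-rank divergence depths and split-depth ranges
#'   (fractions of sites); see `metataxa:::default_divergence()`.
#' @param bands realized-identity bands to validate, or `NULL` to skip.
#' @return an object of class `reference_db`: a list with `taxa`
#'   (data.frame: id, the six rank columns, `is_type_strain`), `sequences`
#'   (named character), and `outgroup_id`.
#' @export
build_reference_db <- function(n_phyla = 2, classes_per_phylum = 1,
                               orders_per_class = 1, families_per_order = 2,
                               genera_per_family = 3, species_per_genus = 6,
                               seq_length = 1443, seed = 1,
                               divergence = default_divergence(),
                               bands = default_bands()) {
  counts <- c(n_phyla, classes_per_phylum, orders_per_class,
              families_per_order, genera_per_family, species_per_genus)
  if (any(counts < 1)) stop("all taxonomy counts must be >= 1")
  L <- as.integer(seq_length)
  local_seed(seed, {
    root <- random_sequence(L)
    taxa <- list(); seqs <- character(0)
    dv <- divergence
    phyla <- evolve_group(root, n_phyla, dv$phylum$depth,
                          dv$phylum$split[1], dv$phylum$split[2], L)
    for (ip in seq_along(phyla)) {
      p_lab <- sprintf("p%02d", ip)
      classes <- evolve_group(phyla[[ip]], classes_per_phylum, dv$class$depth,
                              dv$class$split[1], dv$class$split[2], L)
      for (ic in seq_along(classes)) {
        c_lab <- sprintf("%s_c%02d", p_lab, ic)
        orders <- evolve_group(classes[[ic]], orders_per_class, dv$order$depth,
                               dv$order$split[1], dv$order$split[2], L)
        for (io in seq_along(orders)) {
          o_lab <- sprintf("%s_o%02d", c_lab, io)
          fams <- evolve_group(orders[[io]], families_per_order, dv$family$depth,
                               dv$family$split[1], dv$family$split[2], L)
          for (ifa in seq_along(fams)) {
            f_lab <- sprintf("%s_f%02d", o_lab, ifa)
            gens <- evolve_group(fams[[ifa]], genera_per_family, dv$genus$depth,
                                 dv$genus$split[1], dv$genus$split[2], L)
            for (ig in seq_along(gens)) {
              g_lab <- sprintf("%s_g%02d", f_lab, ig)
              sps <- evolve_group(gens[[ig]], species_per_genus, dv$species$depth,
                                  dv$species$split[1], dv$species$split[2], L)
              for (is in seq_along(sps)) {
                s_lab <- sprintf("%s_s%02d", g_lab, is)
                taxa[[length(taxa) + 1L]] <- data.frame(
                  id = s_lab, phylum = p_lab, class = c_lab, order = o_lab,
                  family = f_lab, genus = g_lab, species = s_lab,
                  is_type_strain = TRUE, stringsAsFactors = FALSE)
                seqs[s_lab] <- sps[[is]]
              }
            }
          }
        }
      }
    }
    og <- mutate_positions(root, round(dv$outgroup * L))
    taxa[[length(taxa) + 1L]] <- data.frame(
      id = "outgroup", phylum = "og_p", class = "og_c", order = "og_o",
      family = "og_f", genus = "og_g", species = "outgroup",
      is_type_strain = TRUE, stringsAsFactors = FALSE)
    seqs["outgroup"] <- og
    db <- structure(list(taxa = do.call(rbind, taxa), sequences = seqs,
                         outgroup_id = "outgroup", seq_length = L,
                         seed = seed),
                    class = "reference_db")
    if (!is.null(bands)) validate_divergence_bands(db, bands)
    db
  })
}

validate_divergence_bands <- function(db, bands) {
  tx <- db$taxa[db$taxa$id != db$outgroup_id, ]
  ids <- tx$id
  idm <- identity_matrix(db$sequences[ids])
  fail <- function(band, lo, hi, val, a, b) {
    stop(sprintf(
      "divergence band '%s' cannot be realized: identity(%s, %s) = %.4f outside (%.3f, %.3f)",
      band, a, b, val, lo, hi), call. = FALSE)
  }
  n <- length(ids)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      same_genus <- tx$genus[i] == tx$genus[j]
      same_family <- tx$family[i] == tx$family[j]
      v <- idm[i, j]
      if (same_genus) {
        if (v <= bands$genus[1] || v >= bands$genus[2])
          fail("genus (congeneric species)", bands$genus[1], bands$genus[2],
               v, ids[i], ids[j])
      } else if (same_family) {
        if (v <= bands$family[1] || v >= bands$family[2])
          fail("family (confamilial genera)", bands$family[1], bands$family[2],
               v, ids[i], ids[j])
      }
    }
  }
  invisible(TRUE)
}

#' Simulate two-type community profiles
#'
#' Draws per-sample expected compositions for a cohort split into two planted
#' community types, P and B, each dominated by its own taxon. Every non-dominant
#' taxon is fixed into a prevalence tier (low/medium/high) that determines its
#' per-sample Bernoulli occurrence probability; abundances of present taxa are
#' log-normal with a tier-specific mean (sigma = 1), shifted by a fixed
#' per-taxon type effect (drawn once per community type, uniform on
#' `[-type_effect_range, type_effect_range]`) so that the two types differ as
#' coordinated guilds rather than in the dominant taxon alone -- the bounded
#' draw keeps every guild taxon below the dominant in expectation -- and
#' renormalized to sum to 1.
#' Optionally plants novelty: `n_new_species` species withheld from the
#' emitted reference set (their congeners remain) and `n_new_genera` genera
#' withheld entirely, with one community member each.
#'
#' @param db a `reference_db`.
#' @param n_samples number of samples.
#' @param frac_type_P fraction of samples labeled P; each type needs >= 1.
#' @param tier_fractions length-3 fractions (low, medium, high) summing to 1.
#' @param n_classified number of visible reference species to include in the
#'   community (`NULL` = all visible).
#' @param n_new_species,n_new_genera planted novelty counts.
#' @param occurrence per-tier per-sample occurrence probabilities.
#' @param log_mean per-tier log-abundance means; `dominant_log_mean` for the
#'   type's dominant taxon; `sigma` the common log-sd.
#' @param type_effect_range half-width of the fixed per-taxon, per-type
#'   uniform log-abundance offsets that differentiate the two community
#'   types.
#' @param occurrence_effect_range half-width of the fixed per-taxon uniform
#'   logit-occurrence shift applied antisymmetrically to the two types
#'   (taxa are more prevalent in one type and correspondingly less in the
#'   other; cohort-level prevalence, and hence the planted tier, is
#'   approximately preserved).
#' @param seed integer seed.
#' @return object of class `community_profiles`: `samples` (sample_id,
#'   type_label), `composition` (taxa x samples expected relative abundance,
#'   columns sum to 1), `tiers`, `novelty`, `dominants`, `reference_ids`
#'   (taxa to be emitted as the downstream reference database).
#' @export
simulate_communities <- function(db, n_samples, frac_type_P = 0.5,
                                 tier_fractions = c(low = 0.3, medium = 0.4, high = 0.3),
                                 n_classified = NULL,
                                 n_new_species = 0, n_new_genera = 0,
                                 occurrence = c(low = 0.04, medium = 0.35, high = 0.90),
                                 log_mean = c(low = 0, medium = 1, high = 2),
                                 dominant_log_mean = 5, sigma = 1,
                                 type_effect_range = 2.5,
                                 occurrence_effect_range = 1.75,
                                 seed = 1) {
  stopifnot(inherits(db, "reference_db"), n_samples >= 2)
  if (frac_type_P < 0 || frac_type_P > 1) stop("frac_type_P must be in [0, 1]")
  if (abs(sum(tier_fractions) - 1) > 1e-9) stop("tier_fractions must sum to 1")
  n_P <- round(frac_type_P * n_samples)
  n_B <- n_samples - n_P
  if (n_P < 1 || n_B < 1)
    stop("each community type needs at least one sample (frac_type_P * n_samples < 1)")

  local_seed(seed, {
    tx <- db$taxa[db$taxa$id != db$outgroup_id, ]

    withheld_genus_taxa <- character(0); novel_genus_reps <- character(0)
    if (n_new_genera > 0) {
      fam_gen <- unique(tx[, c("family", "genus")])
      fam_sizes <- table(fam_gen$family)
      donors <- names(fam_sizes)[fam_sizes >= 3]
      if (length(donors) < n_new_genera)
        stop("not enough families with >= 3 genera to plant novel genera")
      don_f <- sample(donors, n_new_genera)
      for (f in don_f) {
        g <- sample(fam_gen$genus[fam_gen$family == f], 1)
        members <- tx$id[tx$genus == g]
        withheld_genus_taxa <- c(withheld_genus_taxa, members)
        novel_genus_reps <- c(novel_genus_reps, sample(members, 1))
      }
    }
    pool <- tx[!(tx$id %in% withheld_genus_taxa), ]

    novel_species <- character(0)
    if (n_new_species > 0) {
      # withhold species while their genus keeps >= 1 visible congener
      remaining <- table(pool$genus)
      for (k in seq_len(n_new_species)) {
        cand_gen <- names(remaining)[remaining >= 2]
        if (length(cand_gen) == 0)
          stop("not enough genera with >= 2 species to plant novel species")
        g <- sample(cand_gen, 1)
        pick <- sample(setdiff(pool$id[pool$genus == g], novel_species), 1)
        novel_species <- c(novel_species, pick)
        remaining[g] <- remaining[g] - 1
      }
    }
    visible <- setdiff(pool$id, novel_species)
    classified <- if (is.null(n_classified)) visible else {
      if (n_classified > length(visible))
        stop("n_classified exceeds the number of visible reference species")
      sample(visible, n_classified)
    }
    taxa_ids <- c(classified, novel_species, novel_genus_reps)

    # dominants: one classified taxon per type, from different phyla if possible
    phy <- tx$phylum[match(classified, tx$id)]
    dom_P <- classified[1L]
    alt <- classified[phy != phy[1L]]
    dom_B <- if (length(alt) > 0) alt[1L] else classified[2L]
    dominants <- c(P = dom_P, B = dom_B)

    others <- setdiff(taxa_ids, dominants)
    ntier <- c(low = 0L, medium = 0L, high = 0L)
    ntier["low"] <- round(tier_fractions[1] * length(others))
    ntier["medium"] <- round(tier_fractions[2] * length(others))
    ntier["high"] <- length(others) - ntier["low"] - ntier["medium"]
    if (ntier["high"] < 0) { ntier["medium"] <- ntier["medium"] + ntier["high"]; ntier["high"] <- 0L }
    tier_of <- setNames(rep(c("low", "medium", "high"), times = ntier),
                        sample(others))
    tier_of[dominants] <- "high"
    # planted novelty must surface in the reads: keep it out of the low tier
    novel_ids <- c(novel_species, novel_genus_reps)
    tier_of[novel_ids][tier_of[novel_ids] == "low"] <- "medium"
    tier_of <- tier_of[taxa_ids]

    samples <- data.frame(
      sample_id = sprintf("S%03d", seq_len(n_samples)),
      type_label = c(rep("P", n_P), rep("B", n_B)),
      stringsAsFactors = FALSE)

    # fixed per-taxon community-type effects (guild structure of the types)
    type_effect <- rbind(
      P = runif(length(taxa_ids), -type_effect_range, type_effect_range),
      B = runif(length(taxa_ids), -type_effect_range, type_effect_range))
    colnames(type_effect) <- taxa_ids
    type_effect[, dominants] <- 0
    occ_shift <- runif(length(taxa_ids), -occurrence_effect_range,
                       occurrence_effect_range)
    occ_shift[tier_of == "low"] <- 0  # rare taxa are transient, not type-bound
    occ_effect <- rbind(P = occ_shift, B = -occ_shift)
    colnames(occ_effect) <- taxa_ids
    occ_effect[, dominants] <- 0

    comp <- matrix(0, nrow = length(taxa_ids), ncol = n_samples,
                   dimnames = list(taxa_ids, samples$sample_id))
    for (s in seq_len(n_samples)) {
      ty <- samples$type_label[s]
      dom <- dominants[[ty]]
      occ <- plogis(qlogis(occurrence[tier_of]) + occ_effect[ty, ])
      present <- runif(length(taxa_ids)) < occ
      names(present) <- taxa_ids
      present[dom] <- TRUE
      mu <- log_mean[tier_of] + type_effect[ty, ]
      names(mu) <- taxa_ids
      mu[dom] <- dominant_log_mean
      ab <- ifelse(present, rlnorm(length(taxa_ids), meanlog = mu, sdlog = sigma), 0)
      comp[, s] <- ab / sum(ab)
    }

    novelty <- data.frame(
      taxon_id = taxa_ids,
      planted = ifelse(taxa_ids %in% novel_genus_reps, "new_genus",
                ifelse(taxa_ids %in% novel_species, "new_species", "classified")),
      stringsAsFactors = FALSE)

    structure(list(
      samples = samples, composition = comp,
      tiers = tier_of, novelty = novelty, dominants = dominants,
      reference_ids = c(visible, db$outgroup_id),
      seed = seed), class = "community_profiles")
  })
}

#' Restrict a reference database to the taxa visible downstream
#'
#' Drops the planted-novelty taxa recorded in a `community_profiles` object, so
#' the emitted reference FASTA/taxonomy never contains a withheld taxon.
#'
#' @param db a `reference_db`.
#' @param profiles a `community_profiles`.
#' @return a `reference_db` containing only `profiles$reference_ids`.
#' @export
emit_references <- function(db, profiles) {
  stopifnot(inherits(db, "reference_db"), inherits(profiles, "community_profiles"))
  keep <- profiles$reference_ids
  out <- db
  out$taxa <- db$taxa[db$taxa$id %in% keep, , drop = FALSE]
  rownames(out$taxa) <- NULL
  out$sequences <- db$sequences[out$taxa$id]
  out
}

#' Simulate error-bearing full-length 16S reads
#'
#' Allocates `depth` reads per sample multinomially by the sample's expected
#' composition, copies each read from its source sequence with i.i.d. per-base
#' substitutions at `error_rate` (default 0.159%, a typical CCS error rate),
#' and, with probability `chimera_rate`, replaces a read by a two-parent splice
#' at a single uniform breakpoint between positions 300 and 1200. True
#' provenance (source taxon, chimera parents) is recorded per read.
#'
#' @param db a `reference_db` (the full database: withheld taxa must still be
#'   sampled from).
#' @param profiles a `community_profiles`.
#' @param depth reads per sample (>= 1).
#' @param error_rate,chimera_rate rates in `[0, 1)`.
#' @param breakpoint_range two integers, the uniform chimera breakpoint range.
#' @param seed integer seed.
#' @return a `read_set` data.frame: sample_id, read_id, sequence,
#'   source_taxon_id (NA for chimeras), is_chimera, chimera_parents.
#' @export
sample_reads <- function(db, profiles, depth = 2000, error_rate = 0.00159,
                         chimera_rate = 0, breakpoint_range = c(300, 1200),
                         seed = 1) {
  stopifnot(inherits(db, "reference_db"), inherits(profiles, "community_profiles"))
  if (depth < 1) stop("depth must be >= 1")
  if (error_rate < 0 || error_rate >= 1 || chimera_rate < 0 || chimera_rate >= 1)
    stop("rates must be in [0, 1)")
  if (ncol(profiles$composition) == 0) stop("empty profile set")
  L <- db$seq_length
  bp_lo <- max(1L, breakpoint_range[1]); bp_hi <- min(L - 1L, breakpoint_range[2])
  local_seed(seed, {
    out <- vector("list", nrow(profiles$samples))
    for (s in seq_len(nrow(profiles$samples))) {
      sid <- profiles$samples$sample_id[s]
      p <- profiles$composition[, sid]
      counts <- as.integer(rmultinom(1, depth, p))
      src <- rep(rownames(profiles$composition), counts)
      src <- sample(src)  # shuffle read order within the sample
      chim <- runif(depth) < chimera_rate
      seqs <- unname(db$sequences[src])
      parents <- rep(NA_character_, depth)
      if (any(chim)) {
        for (i in which(chim)) {
          p2 <- sample(rownames(profiles$composition), 1, prob = p)
          b <- sample(seq(bp_lo, bp_hi), 1)
          seqs[i] <- paste0(substr(db$sequences[[src[i]]], 1, b),
                            substr(db$sequences[[p2]], b + 1, L))
          parents[i] <- paste(src[i], p2, sep = "|")
        }
      }
      seqs <- as.character(.cpp_mutate_seqs(seqs, error_rate))
      out[[s]] <- data.frame(
        sample_id = sid,
        read_id = sprintf("%s_r%05d", sid, seq_len(depth)),
        sequence = seqs,
        source_taxon_id = ifelse(chim, NA_character_, src),
        is_chimera = chim,
        chimera_parents = parents,
        stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    class(res) <- c("read_set", "data.frame")
    res
  })
}
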