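test_that("reference generation respects the rank divergence bands", {
  db <- build_reference_db(n_phyla = 1, classes_per_phylum = 1,
                           orders_per_class = 1, families_per_order = 1,
                           genera_per_family = 1, species_per_genus = 2,
                           seed = 7)
  sp <- db$taxa$id[db$taxa$id != db$outgroup_id]
  expect_length(sp, 2)
  id <- pairwise_identity(db$sequences[[sp[1]]], db$sequences[[sp[2]]])
  expect_gt(id, 0.92)
  expect_lt(id, 0.987)
  # a sequence is always identical to itself (duplication with 0 mutations)
  expect_equal(pairwise_identity(db$sequences[[sp[1]]], db$sequences[[sp[1]]]), 1)
})

test_that("generation is deterministic per seed and validates its bands", {
  d1 <- build_reference_db(species_per_genus = 3, seed = 99)
  d2 <- build_reference_db(species_per_genus = 3, seed = 99)
  expect_identical(d1$sequences, d2$sequences)
  expect_identical(d1$taxa, d2$taxa)
  d3 <- build_reference_db(species_per_genus = 3, seed = 100)
  expect_false(identical(d1$sequences, d3$sequences))
  # sequences too short to realize the divergence bands are rejected loudly
  expect_error(build_reference_db(seq_length = 30, seed = 1),
               "divergence band")
  expect_error(build_reference_db(n_phyla = 0), "counts")
})

test_that("lineages have six non-empty ranks and unique ids", {
  db <- build_reference_db(seed = 5)
  ranks <- c("phylum", "class", "order", "family", "genus", "species")
  expect_true(all(ranks %in% names(db$taxa)))
  expect_false(any(db$taxa[ranks] == ""))
  expect_false(anyDuplicated(db$taxa$id) > 0)
  expect_true(all(grepl("^[ACGT]+$", db$sequences)))
})

test_that("community simulation allocates types and tiers as configured", {
  db <- build_reference_db(seed = 21)
  prof <- simulate_communities(db, n_samples = 10, frac_type_P = 0.5, seed = 3)
  expect_equal(sum(prof$samples$type_label == "P"), 5)
  expect_equal(sum(prof$samples$type_label == "B"), 5)
  expect_equal(unname(colSums(prof$composition)), rep(1, 10), tolerance = 1e-9)
  # exactly one dominant per type, present in every sample of its type
  for (ty in c("P", "B")) {
    dom <- prof$dominants[[ty]]
    s <- prof$samples$sample_id[prof$samples$type_label == ty]
    expect_true(all(prof$composition[dom, s] > 0))
  }
  # all-low tier fractions put every non-dominant taxon in the low tier
  prof2 <- simulate_communities(db, n_samples = 6, tier_fractions = c(1, 0, 0),
                                seed = 4)
  others <- setdiff(names(prof2$tiers), prof2$dominants)
  expect_true(all(prof2$tiers[others] == "low"))
  expect_error(simulate_communities(db, n_samples = 10, frac_type_P = 0.01),
               "at least one sample")
})

test_that("high-tier occurrence implies >60% prevalence with near certainty", {
  # a taxon present with probability 0.9 per sample: at n = 40 the chance of
  # realized prevalence > 60% (i.e. > 24 samples) is essentially 1
  expect_gt(1 - pbinom(24, 40, 0.9), 0.99)
  db <- build_reference_db(seed = 22)
  prof <- simulate_communities(db, n_samples = 40, seed = 23)
  high <- names(prof$tiers)[prof$tiers == "high"]
  realized <- rowMeans(prof$composition[high, , drop = FALSE] > 0)
  expect_gt(mean(realized > 0.6), 0.9)
})

test_that("planted novelty is withheld from the emitted references only", {
  db <- build_reference_db(species_per_genus = 4, seed = 31)
  prof <- simulate_communities(db, n_samples = 6, n_new_species = 3,
                               n_new_genera = 1, seed = 32)
  vis <- emit_references(db, prof)
  withheld <- prof$novelty$taxon_id[prof$novelty$planted != "classified"]
  expect_length(withheld, 4)
  expect_false(any(withheld %in% vis$taxa$id))
  # withheld taxa still appear in the reads
  reads <- sample_reads(db, prof, depth = 3000, seed = 33)
  expect_true(all(withheld %in% reads$source_taxon_id))
  # ...and every congener genus of a planted new species is still visible
  new_sp <- prof$novelty$taxon_id[prof$novelty$planted == "new_species"]
  gen <- db$taxa$genus[match(new_sp, db$taxa$id)]
  expect_true(all(gen %in% vis$taxa$genus))
})

test_that("read simulation reproduces composition, error and chimera rates", {
  db <- build_reference_db(n_phyla = 1, genera_per_family = 2,
                           species_per_genus = 3, seed = 41)
  prof <- simulate_communities(db, n_samples = 2, seed = 42)

  # error_rate = 0: every non-chimeric read equals its source
  r0 <- sample_reads(db, prof, depth = 50, error_rate = 0, seed = 43)
  expect_true(all(r0$sequence == db$sequences[r0$source_taxon_id]))

  # mean mismatches per read ~ L * e = 1443 * 0.00159 = 2.29 (+-10%)
  r1 <- sample_reads(db, prof, depth = 600, error_rate = 0.00159, seed = 44)
  mm <- mapply(function(s, src) .cpp_hamming(s, db$sequences[[src]])[1],
               r1$sequence, r1$source_taxon_id)
  expect_equal(mean(mm), 1443 * 0.00159, tolerance = 0.1)

  # chimera count within 3 binomial sigmas of depth * rate
  r2 <- sample_reads(db, prof, depth = 1000, chimera_rate = 0.05, seed = 45)
  expected <- 2000 * 0.05
  sigma <- sqrt(2000 * 0.05 * 0.95)
  expect_lt(abs(sum(r2$is_chimera) - expected), 3 * sigma)
  expect_true(all(!is.na(r2$chimera_parents[r2$is_chimera])))

  # determinism
  expect_identical(r1, sample_reads(db, prof, depth = 600,
                                    error_rate = 0.00159, seed = 44))
  expect_error(sample_reads(db, prof, depth = 0), "depth")
})

test_that("multinomial allocation converges to the composition at high depth", {
  db <- build_reference_db(n_phyla = 1, genera_per_family = 2,
                           species_per_genus = 3, seed = 51)
  prof <- simulate_communities(db, n_samples = 2, seed = 52)
  reads <- sample_reads(db, prof, depth = 1e5, error_rate = 0, seed = 53)
  s1 <- prof$samples$sample_id[1]
  tab <- table(reads$source_taxon_id[reads$sample_id == s1]) / 1e5
  frac <- setNames(rep(0, nrow(prof$composition)), rownames(prof$composition))
  frac[names(tab)] <- as.numeric(tab)
  expect_lt(max(abs(frac - prof$composition[, s1])), 0.02)
})
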