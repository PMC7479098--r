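# Shared synthetic runs, generated once per test session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# small end-to-end run: 8 samples, shallow depth, some planted novelty
small_run <- function() {
  memo("small", {
    db <- build_reference_db(n_phyla = 2, families_per_order = 2,
                             genera_per_family = 3, species_per_genus = 4,
                             seed = 7)
    prof <- simulate_communities(db, n_samples = 8, frac_type_P = 0.5,
                                 n_new_species = 2, n_new_genera = 1,
                                 seed = 11)
    reads <- sample_reads(db, prof, depth = 150, chimera_rate = 0.01,
                          seed = 13)
    vis <- emit_references(db, prof)
    res <- run_pipeline(vis, reads)
    list(db = db, prof = prof, reads = reads, vis = vis, res = res)
  })
}

# study-scale run: 40 samples (25 P / 15 B), depth 2000, 60 classified +
# 10 planted novel species + 4 planted novel genera, error 0.159%
study_run <- function() {
  memo("study", {
    db <- build_reference_db(n_phyla = 2, families_per_order = 2,
                             genera_per_family = 3, species_per_genus = 9,
                             seed = 101)
    prof <- simulate_communities(db, n_samples = 40, frac_type_P = 0.625,
                                 n_classified = 60, n_new_species = 10,
                                 n_new_genera = 4, seed = 102)
    reads <- sample_reads(db, prof, depth = 2000, error_rate = 0.00159,
                          chimera_rate = 0.01, seed = 103)
    vis <- emit_references(db, prof)
    res <- run_pipeline(vis, reads)
    list(db = db, prof = prof, reads = reads, vis = vis, res = res)
  })
}
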