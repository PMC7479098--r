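stub_db <- function(ids, genus, family = "fam1", is_type = TRUE, seqs = NULL) {
  taxa <- data.frame(id = ids, phylum = "phy1", class = "cls1", order = "ord1",
                     family = family, genus = genus, species = ids,
                     is_type_strain = is_type, stringsAsFactors = FALSE)
  structure(list(taxa = taxa,
                 sequences = seqs %||% setNames(rep("ACGT", length(ids)), ids),
                 outgroup_id = "none", seq_length = 4, seed = NA),
            class = "reference_db")
}

clade_tips <- function(tree, node)
  tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]]

test_that("smallest anchored clade is the first rootward anchored node", {
  tr <- ape::read.tree(text = "((q:1,T:1):1,(x:1,y:1):1);")
  nd <- smallest_anchored_clade(tr, "q", c("T", "x", "y"))
  expect_setequal(clade_tips(tr, nd), c("q", "T"))

  # an inner clade of non-type references beats the outer type-strain clade
  tr2 <- ape::read.tree(text = "(((q:1,(n1:1,n2:1):1):1,n3:1):1,T:1);")
  nd2 <- smallest_anchored_clade(tr2, "q", c("n1", "n2", "n3", "T"))
  expect_setequal(clade_tips(tr2, nd2), c("q", "n1", "n2"))

  expect_error(smallest_anchored_clade(tr, "q", "absent"), "no reference")
})

test_that("minimal clades agree with brute-force enumeration on random trees", {
  set.seed(111)
  for (i in 1:25) {
    ntip <- sample(6:16, 1)
    tr <- ape::rtree(ntip)
    tips <- tr$tip.label
    queries <- sample(tips, sample(2:4, 1))
    refs <- setdiff(tips, queries)
    for (q in queries) {
      expect_equal(smallest_anchored_clade(tr, q, refs),
                   clade_oracle(tr, q, refs))
    }
    got <- delineate_opus(tr, queries, refs)
    want <- opu_partition_oracle(tr, queries, refs)
    expect_setequal(unname(lapply(split(got$query_id, got$opu_id), sort)),
                    unname(lapply(want, sort)))
  }
})

test_that("queries sharing an anchor merge; distinct anchors stay separate", {
  tr <- ape::read.tree(text = "(((q1:1,q2:1):1,T:1):1,(x:1,o:1):1);")
  del <- delineate_opus(tr, c("q1", "q2"), c("T", "x", "o"))
  expect_equal(length(unique(del$opu_id)), 1)

  tr2 <- ape::read.tree(text = "((q1:1,T1:1):1,(q2:1,T2:1):1);")
  del2 <- delineate_opus(tr2, c("q1", "q2"), c("T1", "T2"))
  expect_equal(length(unique(del2$opu_id)), 2)
})

test_that("categorization follows identity and clade homogeneity", {
  set.seed(112)
  base <- rand_seq(1000)
  # classified species: type-strain anchor, identity 0.99
  db <- stub_db("T", genus = "G", seqs = c(T = base))
  tr <- ape::read.tree(text = "(q:1,T:1);")
  rep99 <- substitute_at(base, sample(1000, 10))
  out <- categorize_opu(ape::Ntip(tr) + 1L, tr, db, rep99)
  expect_equal(out$category, "classified_species")
  expect_equal(out$species, "T")
  expect_equal(out$anchor_identity, 0.99)

  # identity 0.95 within a single-genus clade: potential new species in G
  rep95 <- substitute_at(base, sample(1000, 50))
  out2 <- categorize_opu(ape::Ntip(tr) + 1L, tr, db, rep95)
  expect_equal(out2$category, "potential_new_species")
  expect_equal(out2$genus, "G")
  expect_true(is.na(out2$species))

  # clade spanning two genera of one family: new taxon at genus rank
  db3 <- stub_db(c("A", "B"), genus = c("G1", "G2"),
                 seqs = c(A = base, B = substitute_at(base, sample(1000, 60))))
  tr3 <- ape::read.tree(text = "((q:1,(A:1,B:1):1):1,C:1);")
  rep90 <- substitute_at(base, sample(1000, 100))
  nd <- smallest_anchored_clade(tr3, "q", c("A", "B"))
  out3 <- categorize_opu(nd, tr3, db3, rep90)
  expect_equal(out3$category, "potential_new_taxon")
  expect_equal(out3$new_taxon_rank, "genus")
  expect_equal(out3$family, "fam1")

  # boundary: identity 0.9871 is strictly above 0.987 -> still classified
  base10k <- rand_seq(10000)
  db4 <- stub_db("T", genus = "G", seqs = c(T = base10k))
  rep9871 <- substitute_at(base10k, sample(10000, 129))
  out4 <- categorize_opu(3L, ape::read.tree(text = "(q:1,T:1);"), db4, rep9871)
  expect_equal(out4$anchor_identity, 0.9871)
  expect_equal(out4$category, "classified_species")
})

test_that("raising the species threshold only declassifies, never the reverse", {
  set.seed(113)
  base <- rand_seq(1000)
  db <- stub_db("T", genus = "G", seqs = c(T = base))
  tr <- ape::read.tree(text = "(q:1,T:1);")
  reps <- lapply(c(2, 8, 14, 40), function(k)
    substitute_at(base, sample(1000, k)))
  for (rep_ in reps) {
    lo <- categorize_opu(3L, tr, db, rep_, species_threshold = 0.987)$category
    hi <- categorize_opu(3L, tr, db, rep_, species_threshold = 0.992)$category
    if (lo == "potential_new_species") expect_equal(hi, "potential_new_species")
    if (hi == "classified_species") expect_equal(lo, "classified_species")
  }
})

test_that("the SLP table tallies reads per OPU and sample", {
  otu_map <- data.frame(
    read_id = sprintf("r%02d", 1:10),
    sample_id = rep(c("S1", "S2"), times = c(6, 4)),
    otu_id = c("o1", "o1", "o2", "o2", "o2", "o3", "o1", "o3", "o3", "o3"),
    stringsAsFactors = FALSE)
  map <- c(o1 = "OPU1", o2 = "OPU2", o3 = "OPU3")
  tab <- build_slp_table(otu_map, map)
  want <- matrix(c(1L, 3L, 3L, 0L, 2L, 1L), nrow = 3, byrow = TRUE,
                 dimnames = list(c("OPU3", "OPU2", "OPU1"), c("S1", "S2")))
  expect_equal(tab[rownames(want), ], want)
  # rows ordered by total abundance, descending
  expect_true(all(diff(rowSums(tab)) <= 0))
  expect_equal(colSums(tab), c(S1 = 6L, S2 = 4L))

  one <- build_slp_table(data.frame(read_id = sprintf("r%d", 1:10),
                                    sample_id = "S1", otu_id = "o1"),
                         c(o1 = "OPU1"))
  expect_equal(as.integer(one), 10L)
  expect_error(build_slp_table(otu_map, map[-1]), "unmapped")
})
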