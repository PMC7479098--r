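test_that("multiplicative zero replacement preserves unit row sums", {
  m <- matrix(c(0L, 10L, 5L, 5L), nrow = 2, byrow = TRUE)
  out <- replace_zeros(m)
  # row (0, 10): delta = 0.65/10 = 0.065; the non-zero entry shrinks to 0.935
  expect_equal(out[1, ], c(0.065, 0.935))
  expect_true(all(out > 0))
  # a zero-free matrix is returned as plain proportions, unchanged
  m2 <- matrix(c(2L, 6L, 1L, 1L), nrow = 2, byrow = TRUE)
  expect_equal(replace_zeros(m2), m2 / rowSums(m2))
  set.seed(131)
  for (i in 1:25) {
    m3 <- matrix(rpois(60, 1), 6, 10)
    m3[, 1] <- m3[, 1] + 1; m3[1, ] <- m3[1, ] + 1
    expect_equal(unname(rowSums(replace_zeros(m3))), rep(1, 6),
                 tolerance = 1e-12)
  }
  expect_error(replace_zeros(matrix(c(0L, 0L, 1L, 2L), 2, byrow = TRUE)),
               "all-zero")
})

test_that("CLR closed forms, zero row sums and scale invariance", {
  expect_equal(clr(matrix(c(1, 1, 1, 1), 1)), matrix(0, 1, 4))
  x <- clr(matrix(c(1, 10), 1))
  expect_equal(as.numeric(x), c(-log(sqrt(10)), log(sqrt(10))),
               tolerance = 1e-12)
  set.seed(132)
  m <- matrix(rlnorm(40), 5, 8)
  expect_equal(unname(rowSums(clr(m))), rep(0, 5), tolerance = 1e-9)
  expect_equal(clr(3.7 * m), clr(m), tolerance = 1e-12)
  expect_error(clr(matrix(c(1, 0), 1)), "positive")
})

test_that("Aitchison distance matches its closed form and axioms", {
  a <- clr(matrix(c(1, 10, 10, 1), 2, byrow = TRUE))
  d <- aitchison_distance(a)
  expect_equal(d[1, 2], 2 * sqrt(2) * log(sqrt(10)), tolerance = 1e-9)
  expect_equal(d[1, 2], 3.2562, tolerance = 1e-4)
  expect_equal(unname(diag(d)), c(0, 0))
  # invariance to per-sample rescaling of the raw compositions
  raw <- matrix(rlnorm(30), 3, 10)
  d1 <- aitchison_distance(clr(raw))
  d2 <- aitchison_distance(clr(raw * c(2, 0.1, 7)))
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("ward typing separates planted groups and scores silhouettes", {
  set.seed(133)
  g1 <- matrix(rnorm(20 * 4, 0, 0.2), 20, 4)
  g2 <- matrix(rnorm(15 * 4, 6, 0.2), 15, 4)
  d <- as.matrix(dist(rbind(g1, g2)))
  ty <- ward_cluster(d, k = 2)
  expect_equal(adjusted_rand_index(ty$labels, rep(1:2, c(20, 15))), 1)
  expect_gt(ty$mean_silhouette, 0.9)

  # four 1-D points {0, 0.1, 10, 10.1}: pairs cluster, mean silhouette 0.990
  d4 <- as.matrix(dist(c(0, 0.1, 10, 10.1)))
  ty4 <- ward_cluster(d4, k = 2)
  expect_equal(sort(as.integer(table(ty4$labels))), c(2L, 2L))
  expect_equal(ty4$mean_silhouette, 0.99, tolerance = 1e-3)

  # degenerate cut k = n: silhouette 0 by convention
  expect_equal(ward_cluster(d4, k = 4)$mean_silhouette, 0)
  expect_error(ward_cluster(d4, k = 5), "exceed")
})

test_that("silhouettes agree with the cluster package on random data", {
  set.seed(134)
  x <- matrix(rnorm(60), 20, 3)
  d <- as.matrix(dist(x))
  ty <- ward_cluster(d, k = 3)
  ref <- cluster::silhouette(ty$labels, dmatrix = d)
  expect_equal(unname(ty$silhouette), unname(ref[, "sil_width"]),
               tolerance = 1e-12)
})

test_that("ordination: collinear variance, distance round-trip, PCoA~PCA", {
  pts <- cbind(c(0, 1, 2), c(0, 2, 4))
  ord <- ordinate(as.matrix(dist(pts)), k = 2)
  expect_equal(ord$explained[1], 1, tolerance = 1e-9)

  set.seed(135)
  x <- clr(matrix(rlnorm(48), 6, 8))
  d <- aitchison_distance(x)
  ord2 <- ordinate(d, k = 5)
  expect_equal(unname(as.matrix(dist(ord2$coordinates))), unname(d),
               tolerance = 1e-9)
  # PCoA coordinates match PCA scores up to per-axis sign
  pca <- ordinate(x, k = 2, method = "pca")
  for (ax in 1:2) {
    expect_equal(unname(abs(ord2$coordinates[, ax])),
                 unname(abs(pca$coordinates[, ax])), tolerance = 1e-6)
  }
})

test_that("permanova matches adonis2 and its permutation conventions", {
  set.seed(136)
  x <- matrix(rnorm(20 * 5), 20, 5)
  x[11:20, 1] <- x[11:20, 1] + 3
  d <- as.matrix(dist(x))
  f <- rep(c("a", "b"), each = 10)
  got <- permanova(d, f, n_perm = 199, seed = 42)
  ref <- vegan::adonis2(as.dist(d) ~ f, permutations = 199)
  expect_equal(got$pseudo_F, ref$F[1], tolerance = 1e-9)
  expect_equal(got$R2, ref$R2[1], tolerance = 1e-9)
  # widely separated groups reach the permutation floor 1/(n_perm+1)
  x2 <- x; x2[11:20, ] <- x2[11:20, ] + 100
  got2 <- permanova(as.matrix(dist(x2)), f, n_perm = 199, seed = 42)
  expect_equal(got2$p_value, 1 / 200)
  expect_error(permanova(d, rep("a", 20)), "constant")
  # seeded permutations are reproducible
  expect_equal(permanova(d, f, n_perm = 99, seed = 9)$p_value,
               permanova(d, f, n_perm = 99, seed = 9)$p_value)
})

test_that("permanova adjusts multiple factors as one BH family", {
  set.seed(137)
  x <- matrix(rnorm(18 * 4), 18, 4)
  d <- as.matrix(dist(x))
  fs <- data.frame(f1 = rep(c("a", "b"), 9), f2 = rep(c("u", "v", "w"), 6))
  got <- permanova(d, fs, n_perm = 99, seed = 3)
  expect_equal(nrow(got), 2)
  expect_equal(got$p_adjusted, p.adjust(got$p_value, "BH"))
  expect_true(all(got$p_adjusted >= got$p_value))
})

test_that("differential abundance flags planted shifts with |effect| >= 1", {
  set.seed(138)
  p <- rep(1 / 15, 15)
  p2 <- p; p2[1] <- p2[1] * 8; p2 <- p2 / sum(p2)
  counts <- cbind(
    vapply(1:20, function(i) rmultinom(1, 2000, p)[, 1], integer(15)),
    vapply(1:20, function(i) rmultinom(1, 2000, p2)[, 1], integer(15)))
  rownames(counts) <- sprintf("slp%02d", 1:15)
  groups <- rep(c("g1", "g2"), each = 20)
  da <- dirichlet_mc_da(counts, groups, n_mc = 64, seed = 11)
  expect_true(da$significant[1])
  expect_gte(abs(da$effect[1]), 1)
  # the flag is exactly (fdr < 0.05) | (|effect| >= 1)
  expect_equal(da$significant, da$fdr < 0.05 | abs(da$effect) >= 1)
  expect_true(all(da$bh_welch >= da$p_welch - 1e-12))
  expect_true(all(da$bh_wilcoxon >= da$p_wilcoxon - 1e-12))
  # effect sizes flip sign when the group labels swap
  da_rev <- dirichlet_mc_da(counts, factor(groups, levels = c("g2", "g1")),
                            n_mc = 64, seed = 11)
  expect_equal(da$effect, -da_rev$effect, tolerance = 1e-12)
  expect_error(dirichlet_mc_da(counts[, 1:3], c("a", "a", "b")), "2 samples")
})

test_that("label permutations of one dataset yield no discoveries", {
  set.seed(139)
  p <- rlnorm(12); p <- p / sum(p)
  counts <- vapply(1:24, function(i) rmultinom(1, 2000, p)[, 1], integer(12))
  rownames(counts) <- sprintf("slp%02d", 1:12)
  flags <- vapply(1:6, function(s) {
    g <- sample(rep(c("a", "b"), each = 12))
    sum(dirichlet_mc_da(counts, g, n_mc = 16, seed = s)$fdr < 0.05)
  }, 0)
  expect_lte(mean(flags > 0), 0.2)
})

test_that("proportionality rho obeys its closed forms and bounds", {
  set.seed(140)
  x <- rnorm(30)
  m <- cbind(a = x, b = x, c = -x, d = rnorm(30))
  rho <- proportionality_rho(m)
  expect_equal(rho["a", "b"], 1)
  expect_equal(rho["a", "c"], -1)
  expect_true(all(abs(rho) <= 1 + 1e-12, na.rm = TRUE))
  # zero-variance SLPs are reported as missing
  m2 <- cbind(m, e = rep(1, 30))
  rho2 <- proportionality_rho(m2)
  expect_true(all(is.na(rho2["e", ])))
  expect_error(proportionality_rho(m[1:2, ]), "3 samples")
  # independent columns: mean off-diagonal rho near zero
  big <- matrix(rnorm(1000 * 8), 1000, 8)
  rb <- proportionality_rho(big)
  expect_lt(abs(mean(rb[upper.tri(rb)])), 0.05)
})

test_that("the proportionality network thresholds edges and finds modules", {
  # two disconnected triangles: 2 modules, Q = 0.5 by the e_ii - a_i^2 sum
  rho <- diag(6)
  within <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))
  rho[within] <- 0.8; rho[within[, 2:1]] <- 0.8
  dimnames(rho) <- list(letters[1:6], letters[1:6])
  net <- build_network(rho, cutoff = 0.3)
  expect_equal(igraph::ecount(net$graph), 6)
  expect_equal(length(unique(net$modules)), 2)
  expect_equal(net$modularity, 0.5, tolerance = 1e-9)
  # an impossible cutoff leaves no edges
  expect_equal(nrow(build_network(rho, cutoff = 1)$edges), 0)
  # negative associations also draw edges, with signed weights kept
  rho["a", "d"] <- -0.6; rho["d", "a"] <- -0.6
  net2 <- build_network(rho, cutoff = 0.3)
  expect_true(any(net2$edges$rho < 0))
})

test_that("planted two-block rho structure is recovered as modules", {
  set.seed(141)
  f1 <- rnorm(60); f2 <- rnorm(60)
  m <- cbind(sapply(1:4, function(i) f1 + rnorm(60, 0, 0.5)),
             sapply(1:4, function(i) f2 + rnorm(60, 0, 0.5)))
  colnames(m) <- sprintf("v%d", 1:8)
  net <- build_network(proportionality_rho(m), cutoff = 0.3)
  expect_equal(length(unique(net$modules)), 2)
  expect_equal(length(unique(net$modules[1:4])), 1)
  expect_equal(length(unique(net$modules[5:8])), 1)
})
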