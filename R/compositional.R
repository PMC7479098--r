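# Compositional statistics: multiplicative zero replacement, CLR, Aitchison
# distance, Ward typing with silhouettes, ordination, perMANOVA, Dirichlet
# Monte-Carlo differential abundance, and proportionality networks.

#' Multiplicative (count-zero) replacement
#'
#' On the proportion scale, zeros in sample `s` are replaced by
#' `delta_s = 0.65 / total_s` (total_s = the sample's read total) and the
#' non-zero proportions are multiplicatively shrunk so each row still sums
#' to 1.
#'
#' @param counts non-negative integer matrix, rows = samples, columns = SLPs;
#'   no all-zero row or column.
#' @param frac replacement fraction of a single count (default 0.65).
#' @return strictly positive proportion matrix with unit row sums.
#' @export
replace_zeros <- function(counts, frac = 0.65) {
  if (any(rowSums(counts) == 0)) stop("all-zero sample row")
  if (any(colSums(counts) == 0)) stop("all-zero SLP column")
  tot <- rowSums(counts)
  prop <- counts / tot
  out <- prop
  for (i in seq_len(nrow(counts))) {
    z <- prop[i, ] == 0
    if (!any(z)) next
    delta <- frac / tot[i]
    out[i, z] <- delta
    out[i, !z] <- prop[i, !z] * (1 - delta * sum(z))
  }
  out
}

#' Centered log-ratio transform
#'
#' Row-wise `x -> log(x) - mean(log(x))`; renders compositions scale
#' invariant. Rows sum to zero.
#'
#' @param x strictly positive matrix, rows = samples.
#' @return CLR matrix with zero row sums.
#' @export
clr <- function(x) {
  if (any(x <= 0)) stop("CLR requires strictly positive entries")
  lx <- log(x)
  sweep(lx, 1, rowMeans(lx), "-")
}

#' Aitchison distance matrix
#'
#' Euclidean distance between CLR-transformed rows (samples).
#'
#' @param clr_matrix a CLR matrix (rows = samples).
#' @return symmetric distance matrix with zero diagonal.
#' @export
aitchison_distance <- function(clr_matrix) {
  as.matrix(dist(clr_matrix, method = "euclidean"))
}

silhouette_widths <- function(d, labels) {
  n <- length(labels)
  ks <- unique(labels)
  if (length(ks) == n || length(ks) == 1L) return(rep(0, n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(ks, labels[i]), function(k)
      mean(d[i, labels == k]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

#' Ward clustering of samples with silhouette validation
#'
#' Hierarchical clustering with the ward.D2 convention (distances squared
#' internally by `hclust`, heights on the distance scale), cut at `k`
#' clusters. Per-sample and mean silhouette widths are computed from the same
#' distance matrix; a sample alone in its cluster, or a degenerate k = n cut,
#' has silhouette 0 by convention.
#'
#' @param dist_matrix symmetric distance matrix (e.g. Aitchison).
#' @param k number of clusters (2 by default, the two community types).
#' @return object of class `typing_result`: `labels`, `tree` (hclust),
#'   `silhouette` (per sample), `mean_silhouette`, `k`.
#' @export
ward_cluster <- function(dist_matrix, k = 2) {
  d <- as.matrix(dist_matrix)
  n <- nrow(d)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k cannot exceed the number of samples")
  hc <- hclust(as.dist(d), method = "ward.D2")
  labels <- cutree(hc, k = k)
  sil <- silhouette_widths(d, labels)
  structure(list(labels = labels, tree = hc, silhouette = sil,
                 mean_silhouette = mean(sil), k = k),
            class = "typing_result")
}

#' Ordination: principal coordinates or principal components
#'
#' PCoA is classical metric scaling of a distance matrix (eigendecomposition
#' of the double-centered Gram matrix, `cmdscale`); PCA is the
#' eigendecomposition of the CLR covariance (`prcomp`). On Aitchison
#' distances the two agree up to sign/rotation. A warning is raised when
#' negative eigenvalue mass exceeds 5% of the total (non-Euclidean input).
#'
#' @param x distance matrix (`method = "pcoa"`) or CLR matrix
#'   (`method = "pca"`).
#' @param k number of axes to keep.
#' @param method `"pcoa"` or `"pca"`.
#' @return list with `coordinates`, `eig` (or `sdev`), and
#'   `explained` (fraction of positive eigenvalue mass per kept axis).
#' @export
ordinate <- function(x, k = 2, method = c("pcoa", "pca")) {
  method <- match.arg(method)
  if (method == "pcoa") {
    mds <- cmdscale(as.dist(as.matrix(x)), k = k, eig = TRUE)
    neg <- sum(abs(mds$eig[mds$eig < 0]))
    if (neg > 0.05 * sum(abs(mds$eig)))
      warning("negative eigenvalue mass exceeds 5%: input is non-Euclidean")
    pos <- mds$eig[mds$eig > 0]
    list(coordinates = mds$points, eig = mds$eig,
         explained = mds$eig[seq_len(k)] / sum(pos))
  } else {
    pc <- prcomp(x, center = TRUE, scale. = FALSE)
    kk <- min(k, ncol(pc$x))
    list(coordinates = pc$x[, seq_len(kk), drop = FALSE], sdev = pc$sdev,
         explained = pc$sdev[seq_len(kk)]^2 / sum(pc$sdev^2))
  }
}

permanova_F <- function(d2, labels) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(labels)) {
    i <- which(labels == g)
    if (length(i) > 1)
      ss_within <- ss_within + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
  }
  a <- length(unique(labels))
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

#' Permutational multivariate analysis of variance (one-way, per factor)
#'
#' Anderson's pseudo-F from between/within sums of squared distances, with a
#' seeded label-permutation null; `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#' When several factors are supplied each is tested marginally and the
#' p-values are Benjamini-Hochberg adjusted as one family.
#'
#' @param dist_matrix symmetric distance matrix.
#' @param factors a factor/character vector, or a data.frame of them
#'   (rows = samples in matrix order).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutations.
#' @return data.frame: factor, pseudo_F, R2, p_value, p_adjusted.
#' @export
permanova <- function(dist_matrix, factors, n_perm = 1000, seed = 1) {
  d <- as.matrix(dist_matrix)
  d2 <- d^2
  if (!is.data.frame(factors)) factors <- data.frame(factor = factors)
  n <- nrow(d)
  local_seed(seed, {
    res <- lapply(names(factors), function(fn) {
      f <- as.character(factors[[fn]])
      if (length(unique(f)) < 2) stop("factor '", fn, "' is constant")
      f_obs <- permanova_F(d2, f)
      a <- length(unique(f))
      ss_total <- sum(d2[upper.tri(d2)]) / n
      # recover R2 from the F decomposition
      ssw <- ss_total / (1 + f_obs * (a - 1) / (n - a))
      r2 <- 1 - ssw / ss_total
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        fp <- f[sample.int(n)]
        if (permanova_F(d2, fp) >= f_obs) exceed <- exceed + 1L
      }
      data.frame(factor = fn, pseudo_F = f_obs, R2 = r2,
                 p_value = (1 + exceed) / (1 + n_perm),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$p_adjusted <- p.adjust(out$p_value, method = "BH")
    out
  })
}

welch_p <- function(x_mat, g1, g2) {
  # vectorized Welch t-test p-values across rows (SLPs)
  m1 <- rowMeans(x_mat[, g1, drop = FALSE]); m2 <- rowMeans(x_mat[, g2, drop = FALSE])
  v1 <- apply(x_mat[, g1, drop = FALSE], 1, var)
  v2 <- apply(x_mat[, g2, drop = FALSE], 1, var)
  n1 <- length(g1); n2 <- length(g2)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  p[se2 == 0] <- 1
  p
}

wilcoxon_p <- function(x_mat, g1, g2) {
  # rank-sum with normal approximation, tie correction, continuity correction
  n1 <- length(g1); n2 <- length(g2); n <- n1 + n2
  apply(x_mat, 1, function(x) {
    r <- rank(c(x[g1], x[g2]))
    w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 == 0) return(1)
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    2 * pnorm(-abs(z))
  })
}

#' Dirichlet Monte-Carlo differential abundance
#'
#' For every sample, `n_mc` Dirichlet(counts + 0.5) draws are taken and
#' CLR-transformed, propagating count uncertainty. Per SLP and instance a
#' Welch t-test and a Wilcoxon rank-sum test compare the two groups; p-values
#' are averaged over instances and then BH-adjusted (each test family
#' separately). The effect size is the median over instances of
#' (median between-group CLR difference) / (max of the two within-group
#' IQRs); the reported `fdr` is the consensus `max(BH_welch, BH_wilcoxon)`,
#' and an SLP is flagged when `fdr < 0.05` or `|effect| >= 1`.
#'
#' @param counts count matrix, rows = SLPs, columns = samples.
#' @param groups two-level factor over samples, each level with >= 2 samples.
#' @param n_mc number of Monte-Carlo instances (default 256).
#' @param seed integer seed.
#' @return data.frame per SLP: expected CLR per group, median difference,
#'   effect size, raw and BH p-values for both tests, `fdr`, `significant`.
#' @export
dirichlet_mc_da <- function(counts, groups, n_mc = 256, seed = 1) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
  g1 <- which(groups == levels(groups)[1L])
  g2 <- which(groups == levels(groups)[2L])
  ns <- ncol(counts); nt <- nrow(counts)
  local_seed(seed, {
    pw <- matrix(0, nt, n_mc); pt_ <- matrix(0, nt, n_mc)
    eff <- matrix(0, nt, n_mc); dlt <- matrix(0, nt, n_mc)
    e1 <- matrix(0, nt, n_mc); e2 <- matrix(0, nt, n_mc)
    for (b in seq_len(n_mc)) {
      # Dirichlet(counts + 0.5) per sample, then CLR
      gmat <- matrix(rgamma(nt * ns, shape = counts + 0.5), nt, ns)
      lx <- log(gmat)
      x <- sweep(lx, 2, colMeans(lx), "-")  # CLR per sample (columns)
      pt_[, b] <- welch_p(x, g1, g2)
      pw[, b] <- wilcoxon_p(x, g1, g2)
      med1 <- apply(x[, g1, drop = FALSE], 1, median)
      med2 <- apply(x[, g2, drop = FALSE], 1, median)
      iqr1 <- apply(x[, g1, drop = FALSE], 1, function(v) diff(quantile(v, c(0.25, 0.75))))
      iqr2 <- apply(x[, g2, drop = FALSE], 1, function(v) diff(quantile(v, c(0.25, 0.75))))
      dlt[, b] <- med2 - med1
      eff[, b] <- (med2 - med1) / pmax(pmax(iqr1, iqr2), .Machine$double.eps)
      e1[, b] <- rowMeans(x[, g1, drop = FALSE])
      e2[, b] <- rowMeans(x[, g2, drop = FALSE])
    }
    p_welch <- rowMeans(pt_); p_wilcox <- rowMeans(pw)
    bh_welch <- p.adjust(p_welch, "BH"); bh_wilcox <- p.adjust(p_wilcox, "BH")
    effect <- apply(eff, 1, median)
    fdr <- pmax(bh_welch, bh_wilcox)
    out <- data.frame(
      slp_id = rownames(counts) %||% as.character(seq_len(nt)),
      clr_group1 = rowMeans(e1), clr_group2 = rowMeans(e2),
      diff_btw = apply(dlt, 1, median), effect = effect,
      p_welch = p_welch, p_wilcoxon = p_wilcox,
      bh_welch = bh_welch, bh_wilcoxon = bh_wilcox,
      fdr = fdr,
      significant = fdr < 0.05 | abs(effect) >= 1,
      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Proportionality (rho) between SLPs
#'
#' `rho(x, y) = 1 - var(x - y) / (var(x) + var(y))` across samples on CLR
#' values; the compositionally valid substitute for correlation. Values lie
#' in `[-1, 1]`; pairs involving a zero-variance SLP are `NA`.
#'
#' @param clr_matrix CLR matrix, rows = samples, columns = SLPs (>= 3
#'   samples).
#' @return symmetric rho matrix with unit diagonal.
#' @export
proportionality_rho <- function(clr_matrix) {
  if (nrow(clr_matrix) < 3) stop("need at least 3 samples")
  v <- stats::cov(clr_matrix)
  dv <- diag(v)
  denom <- outer(dv, dv, "+")
  rho <- 2 * v / denom
  rho[denom == 0] <- NA
  zero <- dv == 0
  rho[zero, ] <- NA; rho[, zero] <- NA
  diag(rho)[!zero] <- 1
  rho
}

#' Proportionality network with greedy modularity modules
#'
#' Edges connect SLP pairs with `rho > cutoff` or `rho < -cutoff`
#' (default 0.3), weighted by rho; node size is overall relative abundance.
#' Modules are found by fast-greedy modularity optimization on absolute
#' weights and the modularity Q of that partition is reported.
#'
#' @param rho symmetric rho matrix.
#' @param abundance named overall relative abundances per SLP.
#' @param cutoff edge threshold on `|rho|` (strict).
#' @return list: `graph` (igraph, edge attribute `rho`), `edges` data.frame,
#'   `modules` (named membership), `modularity`.
#' @export
build_network <- function(rho, abundance = NULL, cutoff = 0.3) {
  ids <- rownames(rho) %||% as.character(seq_len(nrow(rho)))
  adj <- rho
  adj[is.na(adj)] <- 0
  adj[abs(adj) <= cutoff] <- 0
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(abs(adj), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$name <- ids
  # signed rho stored per edge
  el <- igraph::as_edgelist(g)
  rho_e <- if (nrow(el)) rho[cbind(el[, 1], el[, 2])] else numeric(0)
  igraph::E(g)$rho <- rho_e
  if (!is.null(abundance)) igraph::V(g)$size <- as.numeric(abundance[ids])
  if (igraph::ecount(g) > 0) {
    comm <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
    modules <- setNames(igraph::membership(comm), ids)
    q <- igraph::modularity(comm)
  } else {
    modules <- setNames(seq_along(ids), ids)
    q <- NA_real_
  }
  edges <- data.frame(from = el[, 1], to = el[, 2], rho = rho_e,
                      stringsAsFactors = FALSE)
  list(graph = g, edges = edges, modules = modules, modularity = q)
}
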