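# Reference phylogeny: Jukes-Cantor distances on masked columns,
# neighbor-joining with outgroup rooting, and least-squares query insertion
# into the fixed reference topology.

#' Jukes-Cantor distance
#'
#' `d = -(3/4) * log(1 - 4p/3)` for a mismatch fraction `p`; the standard
#' one-parameter correction for multiple substitutions.
#'
#' @param p_mismatch mismatch fraction(s) in `[0, 0.75)`.
#' @return corrected distance(s).
#' @export
jc_distance <- function(p_mismatch) {
  bad <- !is.na(p_mismatch) & (p_mismatch < 0 | p_mismatch >= 0.75)
  if (any(bad))
    stop(sprintf("Jukes-Cantor saturation: mismatch fraction %.4f >= 0.75 (pair %s)",
                 p_mismatch[bad][1L],
                 paste(which(bad)[1L])))
  -0.75 * log(1 - 4 * p_mismatch / 3)
}

#' Jukes-Cantor distance matrix over masked alignment columns
#'
#' Mismatch fractions are computed per sequence pair over columns that pass
#' the mask and where both sequences are ungapped, then Jukes-Cantor
#' corrected. Saturated pairs (p >= 0.75) raise an error naming the pair.
#'
#' @param aln an `aligned_matrix` (after [conservation_mask()]).
#' @return symmetric distance matrix over all rows.
#' @export
masked_jc_matrix <- function(aln) {
  stopifnot(inherits(aln, "aligned_matrix"))
  mm <- .cpp_masked_mismatch(unname(aln$rows), aln$mask)
  p <- mm$p
  if (anyNA(p)) {
    idx <- which(is.na(p), arr.ind = TRUE)[1L, ]
    stop(sprintf("no shared unmasked columns between '%s' and '%s'",
                 names(aln$rows)[idx[1L]], names(aln$rows)[idx[2L]]))
  }
  sat <- p >= 0.75
  if (any(sat)) {
    idx <- which(sat, arr.ind = TRUE)[1L, ]
    stop(sprintf("Jukes-Cantor saturation between '%s' and '%s' (p = %.3f)",
                 names(aln$rows)[idx[1L]], names(aln$rows)[idx[2L]], p[idx[1L], idx[2L]]))
  }
  d <- jc_distance(p)
  dimnames(d) <- list(names(aln$rows), names(aln$rows))
  d
}

#' Neighbor-joining tree rooted on an outgroup
#'
#' Canonical Saitou-Nei neighbor joining (as implemented in \pkg{ape}) on a
#' symmetric distance matrix; negative branch lengths are clamped to zero and
#' the tree is rooted on the outgroup edge.
#'
#' @param dist_matrix symmetric matrix with zero diagonal, >= 3 taxa.
#' @param outgroup_id a row/column name of `dist_matrix`.
#' @return a rooted `phylo` tree.
#' @export
nj_tree <- function(dist_matrix, outgroup_id) {
  if (!is.matrix(dist_matrix) || anyNA(dist_matrix) || any(!is.finite(dist_matrix)))
    stop("distance matrix must be finite with no missing values")
  if (!isTRUE(all.equal(dist_matrix, t(dist_matrix), tolerance = 1e-12)))
    stop("distance matrix must be symmetric")
  if (any(diag(dist_matrix) != 0)) stop("distance matrix diagonal must be zero")
  if (nrow(dist_matrix) < 3) stop("need at least 3 taxa")
  if (!(outgroup_id %in% rownames(dist_matrix)))
    stop("outgroup not present in the distance matrix")
  tr <- ape::nj(as.dist(dist_matrix))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr <- ape::root(tr, outgroup = outgroup_id, resolve.root = TRUE)
  tr
}

# least-squares cost of attaching a query on a given edge; dq holds the
# query's distances to all current leaves. Returns list(cost, x, pendant).
ls_attach_edge <- function(nd, edge_u, edge_v, edge_len, side_v, dq, tips) {
  r <- dq - nd[edge_u, tips]          # residual vs the u endpoint
  s <- ifelse(side_v, -1, 1)          # v-side leaves get distance nd[u,i] - x
  n <- length(r)
  # minimize sum (r - p - s*x)^2 over p >= 0, 0 <= x <= len
  sum_s <- sum(s); sum_r <- sum(r); sum_sr <- sum(s * r)
  den <- n * n - sum_s * sum_s
  if (den > 1e-12) {
    x <- (n * sum_sr - sum_s * sum_r) / den
    p <- (sum_r - sum_s * x) / n
  } else {
    x <- 0; p <- sum_r / n
  }
  x <- min(max(x, 0), edge_len)
  p <- max(p, 0)
  # re-optimize p for clamped x
  p <- max(sum(r - s * x) / n, 0)
  cost <- sum((r - p - s * x)^2)
  list(cost = cost, x = x, pendant = p)
}

#' Insert a query into a fixed reference tree
#'
#' Attaches the query leaf by subdividing the edge that minimizes the
#' least-squares discrepancy between the query's (masked, Jukes-Cantor)
#' distances to all current leaves and the path lengths induced by the
#' attachment; the reference topology is otherwise unchanged. The attachment
#' point along the edge and the pendant length are optimized in closed form
#' and clamped to be non-negative.
#'
#' @param tree a rooted `phylo`.
#' @param query_label leaf label to add.
#' @param dist_to_leaves named distances from the query to every current tip.
#' @return the tree with the query attached.
#' @export
parsimony_insert <- function(tree, query_label, dist_to_leaves) {
  tips <- tree$tip.label
  if (!all(tips %in% names(dist_to_leaves)))
    stop("dist_to_leaves must cover every tip")
  if (anyNA(dist_to_leaves[tips]))
    stop("query has undefined distance to some leaf (all-gap masked row?)")
  dq <- dist_to_leaves[tips]
  nd <- ape::dist.nodes(tree)
  ntip <- length(tips)
  best <- NULL
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]
    len <- tree$edge.length[e]
    below <- phangorn::Descendants(tree, v, type = "tips")[[1L]]
    side_v <- seq_len(ntip) %in% below
    fit <- ls_attach_edge(nd, u, v, len, side_v, dq, seq_len(ntip))
    if (is.null(best) || fit$cost < best$cost - 1e-12) {
      best <- c(fit, list(edge = e, v = v, len = len))
    }
  }
  # bind.tip positions are measured from the child end of the edge
  phytools::bind.tip(tree, query_label,
                     edge.length = best$pendant,
                     where = best$v,
                     position = best$len - best$x)
}

#' Remove a query leaf from a tree
#'
#' Inverse of [parsimony_insert()]: drops the tip and collapses the leftover
#' degree-2 node, restoring the original edge.
#' @param tree a `phylo`.
#' @param query_label tip to drop.
#' @return the tree without the query.
#' @export
drop_query <- function(tree, query_label) {
  ape::drop.tip(tree, query_label, collapse.singles = TRUE)
}

#' Place a set of queries on the reference tree
#'
#' Queries are inserted one at a time in decreasing OTU size (ties by label),
#' each seeing the tree with all previously inserted queries.
#'
#' @param tree rooted reference `phylo`.
#' @param dist_matrix distance matrix over references and queries (from
#'   [masked_jc_matrix()]).
#' @param query_ids queries to insert.
#' @param sizes named OTU sizes driving the insertion order.
#' @return the tree with all queries attached.
#' @export
place_queries <- function(tree, dist_matrix, query_ids, sizes = NULL) {
  ord <- if (is.null(sizes)) sort(query_ids)
         else query_ids[order(-sizes[query_ids], query_ids)]
  for (q in ord) {
    tree <- parsimony_insert(tree, q, dist_matrix[q, ])
  }
  tree
}
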