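# Independent oracles, written from the definitions rather than from the
# package implementation, plus small sequence/tree fixtures built in code.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

substitute_at <- function(seq, pos) {
  s <- strsplit(seq, "")[[1]]
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  paste(s, collapse = "")
}

# ---------------------------------------------------------------------------
# Pure-R affine-gap Needleman-Wunsch, written directly from the recurrence
# (M/X/Y states; gap of length k costs open + k*ext; tie preference M > X > Y).
# Returns the identity over columns with terminal gap runs excluded.
nw_oracle <- function(a, b, match = 1, mismatch = -1, open = 2, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  tM <- matrix(0L, n + 1, m + 1); tX <- tM; tY <- tM
  M[1, 1] <- 0
  for (i in seq_len(n)) { X[i + 1, 1] <- -(open + i * ext); tX[i + 1, 1] <- 1L }
  for (j in seq_len(m)) { Y[1, j + 1] <- -(open + j * ext); tY[1, j + 1] <- 2L }
  pick <- function(m_, x_, y_) {         # preference M > X > Y
    w <- which.max(c(m_, x_, y_))        # which.max takes the first maximum
    c(max(m_, x_, y_), w - 1L)
  }
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (A[i] == B[j]) match else mismatch
    pr <- pick(M[i, j], X[i, j], Y[i, j])
    if (pr[1] > NEG / 2) { M[i + 1, j + 1] <- pr[1] + s; tM[i + 1, j + 1] <- pr[2] }
    pr <- pick(M[i, j + 1] - (open + ext), X[i, j + 1] - ext,
               Y[i, j + 1] - (open + ext))
    if (pr[1] > NEG / 2) { X[i + 1, j + 1] <- pr[1]; tX[i + 1, j + 1] <- pr[2] }
    pr <- pick(M[i + 1, j] - (open + ext), X[i + 1, j] - (open + ext),
               Y[i + 1, j] - ext)
    if (pr[1] > NEG / 2) { Y[i + 1, j + 1] <- pr[1]; tY[i + 1, j + 1] <- pr[2] }
  }
  st <- pick(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  state <- st[2]
  ra <- character(0); rb <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (state == 0) {
      ra <- c(A[i], ra); rb <- c(B[j], rb)
      state <- tM[i + 1, j + 1]; i <- i - 1; j <- j - 1
    } else if (state == 1) {
      ra <- c(A[i], ra); rb <- c("-", rb)
      state <- tX[i + 1, j + 1]; i <- i - 1
    } else {
      ra <- c("-", ra); rb <- c(B[j], rb)
      state <- tY[i + 1, j + 1]; j <- j - 1
    }
  }
  gap <- ra == "-" | rb == "-"
  keep <- which(!gap)
  if (length(keep) == 0) return(list(identity = NaN, score = st[1]))
  span <- seq(min(keep), max(keep))
  list(identity = sum(ra[span] == rb[span]) / length(span),
       score = st[1], aligned_a = paste(ra, collapse = ""),
       aligned_b = paste(rb, collapse = ""))
}

# ---------------------------------------------------------------------------
# Exhaustive sum-of-pairs optimal alignment of three sequences (3D DP).
# Pairwise column scores: match +1, mismatch -1, residue-vs-gap -3
# (a length-1 gap under the package's affine costs), gap-vs-gap 0.
msa3_oracle <- function(s1, s2, s3) {
  S <- list(strsplit(s1, "")[[1]], strsplit(s2, "")[[1]], strsplit(s3, "")[[1]])
  L <- vapply(S, length, 0L)
  colscore <- function(c1, c2, c3) {
    sc <- 0
    ch <- c(c1, c2, c3)
    for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
      x <- ch[p[1]]; y <- ch[p[2]]
      sc <- sc + if (x == "-" && y == "-") 0
        else if (x == "-" || y == "-") -3
        else if (x == y) 1 else -1
    }
    sc
  }
  D <- array(-Inf, dim = L + 1L)
  D[1, 1, 1] <- 0
  moves <- as.matrix(expand.grid(0:1, 0:1, 0:1))[-1, ]
  for (i in 0:L[1]) for (j in 0:L[2]) for (k in 0:L[3]) {
    if (i + j + k == 0) next
    best <- -Inf
    for (mv in seq_len(nrow(moves))) {
      d <- moves[mv, ]
      pi <- i - d[1]; pj <- j - d[2]; pk <- k - d[3]
      if (pi < 0 || pj < 0 || pk < 0) next
      prev <- D[pi + 1, pj + 1, pk + 1]
      if (!is.finite(prev)) next
      c1 <- if (d[1]) S[[1]][i] else "-"
      c2 <- if (d[2]) S[[2]][j] else "-"
      c3 <- if (d[3]) S[[3]][k] else "-"
      best <- max(best, prev + colscore(c1, c2, c3))
    }
    D[i + 1, j + 1, k + 1] <- best
  }
  D[L[1] + 1, L[2] + 1, L[3] + 1]
}

# score an existing 3-row alignment with the same sum-of-pairs function
sp_score3 <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  tot <- 0
  for (j in seq_len(ncol(m))) {
    ch <- m[, j]
    for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
      x <- ch[p[1]]; y <- ch[p[2]]
      tot <- tot + if (x == "-" && y == "-") 0
        else if (x == "-" || y == "-") -3
        else if (x == y) 1 else -1
    }
  }
  tot
}

# ---------------------------------------------------------------------------
# Brute-force smallest anchored clade: enumerate every internal node, keep
# those whose tip set contains the query and at least one reference, return
# the one with the fewest tips.
clade_oracle <- function(tree, query, reference_ids) {
  ntip <- length(tree$tip.label)
  nodes <- (ntip + 1):(ntip + tree$Nnode)
  best <- NULL; best_size <- Inf
  for (nd in nodes) {
    tips <- tree$tip.label[phangorn::Descendants(tree, nd, type = "tips")[[1]]]
    if (!(query %in% tips)) next
    if (!any(tips %in% reference_ids)) next
    if (length(tips) < best_size) { best <- nd; best_size <- length(tips) }
  }
  best
}

# Brute-force OPU partition: minimal anchored clades from clade_oracle, then
# transitive closure of "merge iff clades coincide, or nest with identical
# reference leaf sets".
opu_partition_oracle <- function(tree, query_ids, reference_ids) {
  nd <- vapply(query_ids, clade_oracle, 0, tree = tree,
               reference_ids = reference_ids)
  tipsets <- lapply(nd, function(x)
    sort(tree$tip.label[phangorn::Descendants(tree, x, type = "tips")[[1]]]))
  refsets <- lapply(tipsets, function(ts) sort(intersect(ts, reference_ids)))
  n <- length(query_ids)
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    nested <- all(tipsets[[i]] %in% tipsets[[j]]) ||
      all(tipsets[[j]] %in% tipsets[[i]])
    adj[i, j] <- nd[i] == nd[j] ||
      (nested && identical(refsets[[i]], refsets[[j]]))
  }
  # transitive closure
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) { cid <- cid + 1L; comp[adj[i, ]] <- cid }
  }
  split(query_ids, comp)
}

# ---------------------------------------------------------------------------
# Greedy clustering oracle: replay the documented insertion order with
# identities recomputed through pairwise_identity (full DP).
greedy_oracle <- function(sequences, threshold) {
  useq <- unique(sequences)
  mult <- vapply(useq, function(u) sum(sequences == u), 0L)
  ord <- order(-mult, useq)
  useq <- useq[ord]
  centroids <- character(0)
  assign <- integer(length(useq))
  for (i in seq_along(useq)) {
    hit <- 0L
    for (ci in seq_along(centroids)) {
      if (pairwise_identity(centroids[ci], useq[i]) >= threshold) {
        hit <- ci; break
      }
    }
    if (hit == 0L) { centroids <- c(centroids, useq[i]); hit <- length(centroids) }
    assign[i] <- hit
  }
  setNames(assign, useq)
}

# random rooted tree with strictly positive branch lengths (for additivity)
random_metric_tree <- function(ntips) {
  tr <- ape::rtree(ntips, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.05, 1)
  tr
}
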