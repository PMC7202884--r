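# Independent brute-force oracles, kept deliberately naive: each works from
# explicit root-to-tip branch paths, never through the package's
# branch-incidence machinery.

# edges (rows of tree$edge) on the path from the root to `tip` (a label)
root_path_edges <- function(tree, tip) {
  node <- match(tip, tree$tip.label)
  path <- integer(0)
  repeat {
    row <- which(tree$edge[, 2L] == node)
    if (!length(row)) break
    path <- c(path, row)
    node <- tree$edge[row, 1L]
  }
  path
}

# branch set (edge row indices) spanned by a set of tips, root paths unioned
oracle_branch_set <- function(tree, tips) {
  unique(unlist(lapply(tips, root_path_edges, tree = tree)))
}

oracle_pd <- function(tree, tips) {
  sum(tree$edge.length[oracle_branch_set(tree, tips)])
}

oracle_phylosor <- function(tree, tips_i, tips_j) {
  bi <- oracle_branch_set(tree, tips_i)
  bj <- oracle_branch_set(tree, tips_j)
  bl_ij <- sum(tree$edge.length[intersect(bi, bj)])
  bl_i <- sum(tree$edge.length[bi])
  bl_j <- sum(tree$edge.length[bj])
  1 - bl_ij / (0.5 * (bl_i + bl_j))
}

oracle_unifrac <- function(tree, tips_i, tips_j) {
  bi <- oracle_branch_set(tree, tips_i)
  bj <- oracle_branch_set(tree, tips_j)
  shared <- sum(tree$edge.length[intersect(bi, bj)])
  total <- sum(tree$edge.length[union(bi, bj)])
  1 - shared / total
}

# naive double-loop silhouette on a dissimilarity matrix
oracle_silhouette <- function(m, labels) {
  n <- nrow(m)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(m[i, own])
    b <- Inf
    for (g in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(m[i, labels == g]))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  s
}

# naive IndVal over explicit site counting, one (unit, combo) at a time
oracle_indval_cell <- function(occ, labels, unit, combo) {
  pres <- occ[, unit] > 0
  in_combo <- labels %in% combo
  A <- sum(pres & in_combo) / sum(pres)
  B <- sum(pres & in_combo) / sum(in_combo)
  c(A = A, B = B, stat = sqrt(A * B))
}

# random fixtures ----------------------------------------------------------

random_fixture_tree <- function(n_tips, seed) {
  set.seed(seed)
  tree <- ape::rtree(n_tips)
  tree$tip.label <- sprintf("t%02d", seq_len(n_tips))
  tree
}

random_occupancy <- function(tree, n_sites, seed, p = 0.4) {
  set.seed(seed)
  repeat {
    occ <- matrix(rbinom(n_sites * length(tree$tip.label), 1, p),
                  n_sites, length(tree$tip.label),
                  dimnames = list(sprintf("s%02d", seq_len(n_sites)),
                                  tree$tip.label))
    if (all(rowSums(occ) > 0) && all(colSums(occ) >= 0)) return(occ)
  }
}

occ_to_long <- function(occ) as_assemblages(occ)

# planted block dissimilarity: `sizes` block sizes, within ~0, between ~1
block_dissim <- function(sizes, noise = 0, seed = 1) {
  set.seed(seed)
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  m <- 1 - outer(lab, lab, "==")
  if (noise > 0) {
    e <- matrix(runif(n * n, 0, noise), n, n)
    e <- (e + t(e)) / 2
    m <- pmin(pmax(m + e - noise / 2, 0), 1)
  }
  diag(m) <- 0
  dimnames(m) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
  list(d = m, labels = setNames(lab, rownames(m)))
}
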