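#' Phylogenetic dissimilarity between assemblages
#'
#' `phylosor_complement()` computes the one-complement of the PhyloSor index
#' for every pair of sites,
#' \deqn{d_{ij} = 1 - \frac{BL_{ij}}{0.5\,(BL_i + BL_j)},}
#' where \eqn{BL_{ij}} is the summed length of branches with at least one
#' descendant tip in both sites and \eqn{BL_i} is the (rooted) PD of site
#' \eqn{i}. `unifrac_complement()` is the Jaccard-type analogue: unique
#' branch length over union branch length. Both are 0 for identical tip
#' sets; PhyloSor reaches 1 exactly when the two assemblages are
#' reciprocally monophyletic and share no branches.
#'
#' All pairs are computed from one branch-incidence pass
#' ([branch_incidence()]) and dense matrix products, never by extracting
#' per-pair subtrees.
#'
#' @param assemblages Long assemblage tibble (see [as_assemblages()]); every
#'   genus must be on the tree and every site must retain at least one genus
#'   (use [align_to_tree()] first).
#' @param tree A `phylo` object with branch lengths.
#' @return An object of class `evo_dissim`: the symmetric site-by-site
#'   dissimilarity matrix with attributes `metric` and `site_pd` (per-site
#'   rooted PD). Use [as.matrix()], [as.dist()], or [generics::tidy()].
#' @seealso [pd_total()], [cluster_assemblages()]
#' @export
phylosor_complement <- function(assemblages, tree) {
  bi <- dissim_incidence(assemblages, tree)
  wl <- sweep(bi$incidence, 2L, bi$lengths, `*`)
  bl_i <- drop(wl %*% rep(1, ncol(wl)))
  bl_ij <- tcrossprod(wl, bi$incidence)          # shared branch length
  d <- 1 - bl_ij / (0.5 * outer(bl_i, bl_i, `+`))
  new_evo_dissim(d, "phylosor", bl_i)
}

#' @rdname phylosor_complement
#' @export
unifrac_complement <- function(assemblages, tree) {
  bi <- dissim_incidence(assemblages, tree)
  wl <- sweep(bi$incidence, 2L, bi$lengths, `*`)
  bl_i <- drop(wl %*% rep(1, ncol(wl)))
  bl_ij <- tcrossprod(wl, bi$incidence)
  union_bl <- outer(bl_i, bl_i, `+`) - bl_ij
  d <- 1 - bl_ij / union_bl
  new_evo_dissim(d, "unifrac", bl_i)
}

# shared setup + validation for the two metrics
dissim_incidence <- function(assemblages, tree) {
  occ <- occupancy_matrix(assemblages)
  bi <- branch_incidence(tree, occ)
  bl_i <- drop((bi$incidence %*% bi$lengths))
  empty <- rownames(occ)[bl_i <= 0]
  if (length(empty)) {
    stop("Sites with zero branch length on the tree (PD undefined): ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  bi
}

new_evo_dissim <- function(d, metric, site_pd) {
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d[d < 0] <- 0
  d[d > 1] <- 1
  structure(d, class = c("evo_dissim", "matrix"), metric = metric,
            site_pd = site_pd)
}

#' @method print evo_dissim
#' @export
print.evo_dissim <- function(x, ...) {
  cat(sprintf("<evo_dissim> %s complement, %d sites\n", attr(x, "metric"), nrow(x)))
  cat(sprintf("  range %.3f-%.3f, mean %.3f\n",
              min(x[upper.tri(x)]), max(x[upper.tri(x)]), mean(x[upper.tri(x)])))
  invisible(x)
}

#' @method as.matrix evo_dissim
#' @export
as.matrix.evo_dissim <- function(x, ...) {
  structure(unclass(x), metric = NULL, site_pd = NULL)
}

#' @export
as.dist.evo_dissim <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(as.matrix(m), diag = diag, upper = upper)
}

#' Tidy a dissimilarity matrix into site pairs
#'
#' @param x An `evo_dissim` object.
#' @param ... Unused.
#' @return Tibble with columns `site1`, `site2`, `dissimilarity` (unordered
#'   pairs, upper triangle).
#' @export
tidy.evo_dissim <- function(x, ...) {
  m <- as.matrix(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(
    site1 = rownames(m)[idx[, 1L]],
    site2 = colnames(m)[idx[, 2L]],
    dissimilarity = m[idx]
  )
}

#' Write a dissimilarity matrix as square CSV
#'
#' @param x An `evo_dissim` object (or square matrix with dimnames).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dissim <- function(x, path) {
  m <- as.matrix(x)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
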