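#' Site-by-branch weighted matrix
#'
#' Entry (i, b) is `present(i, b) * length(b)`: the branch length of b when
#' at least one tip descending branch b occurs at site i, else 0. Branches
#' are ordered by the tree's edge table (one column per non-root branch).
#' This is the evolutionary-unit analogue of a site-by-species matrix: each
#' branch is a "lineage unit" weighted by its duration.
#'
#' @param assemblages Long assemblage tibble (aligned to the tree).
#' @param tree A `phylo` object.
#' @return Numeric sites x branches matrix; attribute `"branches"` holds a
#'   tibble (branch, child_node, length, clade_label).
#' @export
site_by_branch_matrix <- function(assemblages, tree) {
  occ <- occupancy_matrix(assemblages)
  bi <- branch_incidence(tree, occ)
  w <- sweep(bi$incidence, 2L, bi$lengths, `*`)
  rownames(w) <- rownames(occ)
  colnames(w) <- paste0("b", seq_len(ncol(w)))
  attr(w, "branches") <- branch_table(tree)
  w
}

# branch metadata: child node, length, readable clade label (tip name for
# terminal branches, "first..last" descendant tips for internal ones)
branch_table <- function(tree) {
  desc <- node_descendant_tips(tree)
  child <- tree$edge[, 2L]
  ntip <- length(tree$tip.label)
  lab <- vapply(child, function(nd) {
    tl <- tree$tip.label[desc[, nd]]
    if (length(tl) == 1L) tl else paste0(tl[1L], "..", tl[length(tl)], " (", length(tl), ")")
  }, character(1))
  tibble::tibble(branch = paste0("b", seq_along(child)), child_node = child,
                 length = tree$edge.length, n_tips = colSums(desc)[child],
                 clade_label = lab)
}

#' Evolutionary principal components analysis
#'
#' PCA of the Hellinger-transformed site-by-branch matrix: each site's
#' branch-length profile is square-root transformed after dividing by its
#' row total, columns are centred, and the centred matrix decomposed by SVD.
#' Site scores spread lineage composition along orthogonal axes; branch
#' (clade) loadings say which parts of the tree drive each axis. On a star
#' tree with unit branch lengths this reduces exactly to a centred PCA of
#' the Hellinger-transformed genus occupancy matrix.
#'
#' @param assemblages Long assemblage tibble (aligned to the tree).
#' @param tree A `phylo` object.
#' @param n_axes Number of axes to keep (default 5).
#' @return An `evopca` object: list with `site_scores` (tibble), `loadings`
#'   (tibble: branch metadata + one column per axis), `eigenvalues`,
#'   `var_explained`, `total_variance`, `n_axes`.
#' @export
evopca <- function(assemblages, tree, n_axes = 5) {
  w <- site_by_branch_matrix(assemblages, tree)
  if (nrow(w) < 3L) stop("evopca needs at least 3 sites.", call. = FALSE)
  rs <- rowSums(w)
  if (any(rs <= 0)) {
    stop("Sites with empty branch profiles: ",
         paste(rownames(w)[rs <= 0], collapse = ", "), call. = FALSE)
  }
  y <- sqrt(sweep(w, 1L, rs, `/`))
  yc <- scale(y, center = TRUE, scale = FALSE)
  sv <- svd(yc)
  pos <- sv$d > max(sv$d) * 1e-12
  d <- sv$d[pos]
  n_axes <- min(n_axes, length(d))
  u <- sv$u[, seq_len(n_axes), drop = FALSE]
  v <- sv$v[, seq_len(n_axes), drop = FALSE]
  d_k <- d[seq_len(n_axes)]
  # sign convention: the largest-magnitude loading on each axis is positive
  for (a in seq_len(n_axes)) {
    s <- sign(v[which.max(abs(v[, a])), a])
    if (s < 0) { v[, a] <- -v[, a]; u[, a] <- -u[, a] }
  }
  scores <- u %*% diag(d_k, n_axes)
  axis_names <- paste0("axis", seq_len(n_axes))
  site_scores <- tibble::as_tibble(stats::setNames(as.data.frame(scores), axis_names))
  site_scores <- dplyr::bind_cols(tibble::tibble(site = rownames(w)), site_scores)
  loadings <- dplyr::bind_cols(
    attr(w, "branches"),
    tibble::as_tibble(stats::setNames(as.data.frame(v), axis_names))
  )
  eig <- d^2 / nrow(yc)
  structure(
    list(site_scores = site_scores, loadings = loadings,
         eigenvalues = eig[seq_len(n_axes)],
         var_explained = (d_k^2) / sum(d^2),
         total_variance = sum(d^2) / nrow(yc),
         n_axes = n_axes),
    class = "evopca"
  )
}

#' @method print evopca
#' @export
print.evopca <- function(x, ...) {
  cat(sprintf("<evopca> %d axes, variance explained: %s\n", x$n_axes,
              paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", ")))
  invisible(x)
}

#' Tidy evoPCA results
#'
#' @param x An `evopca` object.
#' @param matrix Which part to return: `"scores"` (site scores, default),
#'   `"loadings"` (per-branch clade loadings), or `"eigenvalues"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.evopca <- function(x, matrix = c("scores", "loadings", "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = x$site_scores,
    loadings = x$loadings,
    eigenvalues = tibble::tibble(axis = seq_along(x$eigenvalues),
                                 eigenvalue = x$eigenvalues,
                                 var_explained = x$var_explained)
  )
}

#' @rdname tidy.evopca
#' @export
glance.evopca <- function(x, ...) {
  tibble::tibble(n_axes = x$n_axes, total_variance = x$total_variance,
                 var_axis1 = x$var_explained[1L],
                 var_axis2 = if (x$n_axes >= 2L) x$var_explained[2L] else NA_real_)
}

#' Ordination scatter of site scores
#'
#' @param object An `evopca` object.
#' @param axes Two axes to plot (default `c(1, 2)`).
#' @param colour Optional named vector (site -> group) to colour points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evopca <- function(object, axes = c(1, 2), colour = NULL, ...) {
  sc <- object$site_scores
  xvar <- paste0("axis", axes[1L]); yvar <- paste0("axis", axes[2L])
  if (!is.null(colour)) sc$group <- factor(colour[sc$site])
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data[[xvar]], y = .data[[yvar]])) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", xvar, 100 * object$var_explained[axes[1L]]),
      y = sprintf("%s (%.1f%%)", yvar, 100 * object$var_explained[axes[2L]])
    )
  if (!is.null(colour)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  } else {
    p + ggplot2::geom_point()
  }
}
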