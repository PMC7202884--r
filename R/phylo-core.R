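#' Read a rooted, dated phylogeny from Newick
#'
#' Thin validating wrapper around [ape::read.tree()]. The tree is the unit
#' all downstream computations consume: tips are genus names, branch lengths
#' are in millions of years. Polytomies are kept as-is.
#'
#' @param source Path to a Newick file, or a Newick string (anything
#'   containing `"("` and `";"` is treated as text).
#' @return An object of class `phylo`.
#' @details Validation beyond `ape`'s parser: tip labels must be unique and
#'   non-empty, every non-root edge must carry a non-negative branch length.
#'   A root edge (`root.edge`), when present, is ignored by all diversity
#'   sums in this package.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' sum(tr$edge.length)
read_newick <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  tree <- if (grepl("\\(", source) && grepl(";", source)) {
    tryCatch(ape::read.tree(text = source),
             error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE))
  } else {
    if (!file.exists(source)) stop("No such file: ", source, call. = FALSE)
    tryCatch(ape::read.tree(source),
             error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE))
  }
  if (is.null(tree)) stop("Newick parse error: no tree found in input.", call. = FALSE)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  validate_phylogeny(tree)
  tree
}

#' Write a phylogeny to Newick
#'
#' @param tree A `phylo` object.
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @return The path (invisibly) or the Newick string.
#' @export
write_newick <- function(tree, path = NULL) {
  validate_phylogeny(tree)
  if (is.null(path)) {
    return(ape::write.tree(tree, digits = 15))
  }
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

#' @keywords internal
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a `phylo` object.", call. = FALSE)
  labs <- tree$tip.label
  if (anyNA(labs) || any(!nzchar(labs))) {
    stop("Tip labels must be non-empty strings.", call. = FALSE)
  }
  dup <- unique(labs[duplicated(labs)])
  if (length(dup)) {
    stop("Duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("Tree has no branch lengths; a dated phylogeny is required.", call. = FALSE)
  }
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("All branch lengths must be present and non-negative.", call. = FALSE)
  }
  invisible(tree)
}

#' Normalize genus names for tree/assemblage reconciliation
#'
#' Exact matching after trimming whitespace and treating underscores and
#' spaces as equivalent (both collapse to `_`).
#' @param x Character vector of genus names.
#' @return Normalized character vector.
#' @export
normalize_genus <- function(x) {
  x <- trimws(as.character(x))
  gsub("[ ]+", "_", x)
}

# Tips (by index) descending each node of the tree, as a tips x nodes logical
# matrix over ALL nodes (tips and internal), column j = node j.
node_descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  desc <- matrix(FALSE, nrow = ntip, ncol = nnode)
  desc[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    p <- eo[k, 1L]; ch <- eo[k, 2L]
    desc[, p] <- desc[, p] | desc[, ch]
  }
  desc
}

#' Branch-by-assemblage incidence
#'
#' For every branch of the tree (identified by its child node) and every
#' assemblage, flags whether at least one tip descending the branch occurs in
#' the assemblage. One post-order pass gives the shared-branch bookkeeping
#' that PhyloSor, UniFrac, PD, and the site-by-branch matrices all reuse.
#'
#' @param tree A `phylo` object.
#' @param occupancy A sites x genera binary matrix (row names = site ids,
#'   column names = genus names), or a list of character vectors of tip
#'   names (one per assemblage).
#' @return A list with elements `incidence` (sites x branches 0/1 matrix,
#'   branches in `tree$edge` order), `lengths` (branch lengths), and
#'   `child` (child node id of each branch).
#' @export
branch_incidence <- function(tree, occupancy) {
  validate_phylogeny(tree)
  if (is.list(occupancy) && !is.matrix(occupancy)) {
    sets <- occupancy
    nm <- names(sets)
    if (is.null(nm)) nm <- paste0("site", seq_along(sets))
    genera <- sort(unique(unlist(sets)))
    occupancy <- matrix(0L, length(sets), length(genera),
                        dimnames = list(nm, genera))
    for (i in seq_along(sets)) occupancy[i, match(sets[[i]], genera)] <- 1L
  }
  if (nrow(occupancy) < 1L) stop("At least one assemblage is required.", call. = FALSE)
  genera <- normalize_genus(colnames(occupancy))
  tips <- normalize_genus(tree$tip.label)
  miss <- setdiff(genera, tips)
  if (length(miss)) {
    stop("Genera absent from the tree: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  tip_idx <- match(genera, tips)
  desc <- node_descendant_tips(tree)              # tips x nodes
  tipbr <- desc[tip_idx, tree$edge[, 2L], drop = FALSE]  # matrix tips-in-data x branches
  inc <- (occupancy > 0) %*% (tipbr * 1)          # counts of descendant tips present
  inc <- (inc > 0) * 1
  dimnames(inc) <- list(rownames(occupancy), NULL)
  list(incidence = inc, lengths = tree$edge.length, child = tree$edge[, 2L])
}

#' Phylogenetic diversity of a tip set
#'
#' Faith's PD, rooted to the global root: the summed branch length of the
#' minimal subtree connecting the tips and the root of `tree`. The root edge
#' itself (when present in the Newick) is excluded, so PD is invariant to a
#' zero-length root stalk. Units follow the branch lengths (Myr).
#'
#' @param tree A `phylo` object.
#' @param tips Character vector of tip names (an assemblage).
#' @return A single non-negative number.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' pd_total(tr, c("A", "B"))  # 3
pd_total <- function(tree, tips) {
  validate_phylogeny(tree)
  tips <- unique(normalize_genus(tips))
  if (!length(tips)) stop("`tips` must be non-empty.", call. = FALSE)
  labs <- normalize_genus(tree$tip.label)
  miss <- setdiff(tips, labs)
  if (length(miss)) {
    stop("Tips not on tree: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  desc <- node_descendant_tips(tree)
  present <- labs %in% tips
  on_path <- colSums(desc[present, tree$edge[, 2L], drop = FALSE]) > 0
  sum(tree$edge.length[on_path])
}
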