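#' Indicator value analysis over group combinations
#'
#' For every genus and every candidate combination of groups (all non-empty
#' proper subsets, as in the multipatt approach), computes
#' specificity `A` = P(site belongs to the combination | genus present),
#' fidelity `B` = P(genus present | site in the combination), and the
#' indicator statistic `sqrt(A * B)`. The combination maximizing the
#' statistic is reported per genus; ties break toward the smaller, then
#' lexicographically earlier, combination. Specificity is the unweighted
#' (site-count) version matching the probability definitions; the
#' group-size-corrected variant is available via `correct_group_size`.
#'
#' @param assemblages Long assemblage tibble.
#' @param labels Named vector of group labels (site -> group).
#' @param allow_combos Consider multi-group combinations (default TRUE).
#'   With FALSE only singleton groups are candidates.
#' @param all_combos Return the full per-genus-per-combination table instead
#'   of only each genus's best row.
#' @param correct_group_size Use the group-size-corrected specificity
#'   (mean per-group incidence rates instead of raw site counts).
#' @return Tibble: `unit`, `combo` (group names joined by `+`), `A`, `B`,
#'   `stat`, sorted by decreasing `stat`. Genera absent everywhere are
#'   excluded.
#' @export
indval_genera <- function(assemblages, labels, allow_combos = TRUE,
                          all_combos = FALSE, correct_group_size = FALSE) {
  occ <- occupancy_matrix(assemblages)
  indval_matrix(occ, labels, allow_combos = allow_combos,
                all_combos = all_combos, correct_group_size = correct_group_size)
}

# core IndVal on any sites x units binary matrix
indval_matrix <- function(occ, labels, allow_combos = TRUE, all_combos = FALSE,
                          correct_group_size = FALSE) {
  labels <- align_labels(labels, rownames(occ))
  groups <- sort(unique(as.character(labels)))
  k <- length(groups)
  if (k < 2L) stop("Indicator analysis needs at least 2 groups.", call. = FALSE)
  if (k > 5L) stop("Group combinations are capped at 5 groups.", call. = FALSE)
  sizes <- tabulate(factor(labels, groups), k)
  if (any(sizes == 0L)) stop("Every group needs at least one site.", call. = FALSE)
  combos <- group_combinations(k, allow_combos)
  member <- outer(as.character(labels), groups, `==`) * 1   # sites x groups
  n_pres_group <- t(member) %*% (occ > 0)                   # groups x units
  n_pres_total <- colSums(occ > 0)
  keep <- n_pres_total > 0
  units <- colnames(occ)[keep]
  rows <- vector("list", length(combos))
  for (ci in seq_along(combos)) {
    cset <- combos[[ci]]
    in_combo <- colSums(n_pres_group[cset, keep, drop = FALSE])
    if (correct_group_size) {
      rates <- n_pres_group[, keep, drop = FALSE] / sizes
      a <- colSums(rates[cset, , drop = FALSE]) / colSums(rates)
    } else {
      a <- in_combo / n_pres_total[keep]
    }
    b <- in_combo / sum(sizes[cset])
    rows[[ci]] <- tibble::tibble(
      unit = units,
      combo = paste(groups[cset], collapse = "+"),
      combo_size = length(cset),
      A = unname(a), B = unname(b), stat = sqrt(unname(a) * unname(b))
    )
  }
  tab <- dplyr::bind_rows(rows)
  if (all_combos) {
    return(dplyr::arrange(dplyr::select(tab, -"combo_size"),
                          dplyr::desc(.data$stat), .data$unit))
  }
  best <- dplyr::arrange(tab, .data$unit, dplyr::desc(.data$stat),
                         .data$combo_size, .data$combo)
  best <- dplyr::distinct(best, .data$unit, .keep_all = TRUE)
  dplyr::arrange(dplyr::select(best, -"combo_size"),
                 dplyr::desc(.data$stat), .data$unit)
}

# all non-empty proper subsets of 1..k (indices), smallest first
group_combinations <- function(k, allow_combos) {
  if (!allow_combos || k == 2L) {
    return(lapply(seq_len(k), identity))
  }
  sizes <- seq_len(k - 1L)
  unlist(lapply(sizes, function(s) {
    cmb <- utils::combn(k, s, simplify = FALSE)
    cmb
  }), recursive = FALSE)
}

#' Site-by-node presence/absence matrix
#'
#' One column per internal node of the tree (including the root): a node is
#' present at a site when at least one of its descendant tips occurs there.
#'
#' @param assemblages Long assemblage tibble (aligned to the tree).
#' @param tree A `phylo` object.
#' @return Integer 0/1 matrix, sites x internal nodes; columns named
#'   `nd<node id>`; attribute `"nodes"` is a tibble (node, n_tips,
#'   clade_label).
#' @export
site_by_node_matrix <- function(assemblages, tree) {
  occ <- occupancy_matrix(assemblages)
  genera <- colnames(occ)
  tips <- normalize_genus(tree$tip.label)
  miss <- setdiff(genera, tips)
  if (length(miss)) {
    stop("Genera absent from the tree: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  ntip <- length(tree$tip.label)
  nodes <- ntip + seq_len(tree$Nnode)
  desc <- node_descendant_tips(tree)
  tipnode <- desc[match(genera, tips), nodes, drop = FALSE] * 1
  m <- ((occ %*% tipnode) > 0) * 1L
  colnames(m) <- paste0("nd", nodes)
  lab <- vapply(nodes, function(nd) {
    tl <- tree$tip.label[desc[, nd]]
    paste0(tl[1L], "..", tl[length(tl)], " (", length(tl), ")")
  }, character(1))
  attr(m, "nodes") <- tibble::tibble(node = nodes, n_tips = colSums(desc[, nodes, drop = FALSE]),
                                     clade_label = lab)
  m
}

#' Indicator clades: non-nested high-stat nodes per group
#'
#' Runs the indicator analysis on the site-by-node matrix, then greedily
#' walks nodes in order of decreasing statistic, keeping a node only when it
#' is neither an ancestor nor a descendant of an already-kept node. The
#' result is an antichain of indicator clades: the independent lineages most
#' strongly associated with each group (or group combination).
#'
#' @inheritParams indval_genera
#' @param tree A `phylo` object.
#' @param min_stat Drop nodes below this statistic before selection
#'   (default 0, keep all).
#' @return List with `selected` (tibble: node, clade_label, n_tips, combo,
#'   A, B, stat) and `full` (the unpruned per-node best-combo table).
#' @export
indicator_nodes <- function(assemblages, tree, labels, allow_combos = TRUE,
                            min_stat = 0) {
  m <- site_by_node_matrix(assemblages, tree)
  nodes_meta <- attr(m, "nodes")
  tab <- indval_matrix(m, labels, allow_combos = allow_combos)
  tab$node <- as.integer(sub("^nd", "", tab$unit))
  tab <- dplyr::left_join(tab, nodes_meta, by = "node")
  full <- dplyr::select(tab, "node", "clade_label", "n_tips", "combo", "A", "B", "stat")
  cand <- dplyr::filter(full, .data$stat >= min_stat)
  # order: stat desc, then larger (higher-level) clades, then node id
  cand <- dplyr::arrange(cand, dplyr::desc(.data$stat),
                         dplyr::desc(.data$n_tips), .data$node)
  desc <- node_descendant_tips(tree)
  ntip <- length(tree$tip.label)
  tipsets <- lapply(cand$node, function(nd) which(desc[, nd]))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    nested <- FALSE
    for (j in which(keep)) {
      a <- tipsets[[i]]; b <- tipsets[[j]]
      if (all(a %in% b) || all(b %in% a)) { nested <- TRUE; break }
    }
    keep[i] <- !nested
  }
  list(selected = cand[keep, , drop = FALSE], full = full)
}
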