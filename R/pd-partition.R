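#' Partition phylogenetic diversity into group-restricted and shared parts
#'
#' For each group or group combination with indicator genera, the restricted
#' PD is the branch length lost when the genera whose specificity `A` for
#' that combination exceeds `threshold` are pruned from the phylogeny:
#' `restricted_g = PD(all present genera) - PD(present genera without g's
#' high-specificity indicators)`. The PD shared across all groups is what no
#' combination claims: `shared_all = total_pd - sum(restricted)`, an exact
#' identity by construction. Each genus belongs to at most one pruning set
#' (its best combination in the indicator table), so components never double
#' count. PD is rooted (see [pd_total()]) and computed over the genera
#' present anywhere in the data, so genera absent from all sites never
#' inflate the totals.
#'
#' @param assemblages Long assemblage tibble (aligned to the tree).
#' @param tree A `phylo` object.
#' @param indicators Indicator table from [indval_genera()] (best-combo
#'   rows; computed with combinations enabled). When `NULL` it is computed
#'   from `labels`.
#' @param labels Named group labels (site -> group); only needed when
#'   `indicators` is `NULL`.
#' @param threshold Specificity cutoff (default 0.6): genera with
#'   `A > threshold` for their best combination are pruned for it.
#' @return A `pd_partition` object: list with `components` (tibble: combo,
#'   n_pruned, restricted_pd), `total_pd`, `shared_all`, `threshold`.
#' @export
partition_pd <- function(assemblages, tree, indicators = NULL, labels = NULL,
                         threshold = 0.6) {
  a <- as_assemblages(assemblages)
  combos <- NULL
  if (is.null(indicators)) {
    if (is.null(labels)) stop("Provide `indicators` or `labels`.", call. = FALSE)
    indicators <- indval_genera(a, labels, allow_combos = TRUE)
  }
  if (!is.null(labels)) {
    groups <- sort(unique(as.character(labels)))
    combos <- vapply(group_combinations(length(groups), TRUE),
                     function(ix) paste(groups[ix], collapse = "+"),
                     character(1))
  }
  present <- sort(unique(a$genus))
  total_pd <- pd_total(tree, present)
  sets <- dplyr::filter(indicators, .data$A > threshold, .data$unit %in% present)
  # combos claimed by the indicator table, padded to every candidate
  # combination when the group labels are known
  combos <- sort(unique(c(combos, indicators$combo)))
  comp <- lapply(combos, function(cb) {
    prune <- sets$unit[sets$combo == cb]
    if (!length(prune)) {
      return(tibble::tibble(combo = cb, n_pruned = 0L, restricted_pd = 0))
    }
    rest <- setdiff(present, prune)
    if (!length(rest)) {
      stop("Pruning for combination '", cb, "' removes every genus.", call. = FALSE)
    }
    tibble::tibble(combo = cb, n_pruned = length(prune),
                   restricted_pd = total_pd - pd_total(tree, rest))
  })
  comp <- dplyr::bind_rows(comp)
  structure(
    list(components = comp, total_pd = total_pd,
         shared_all = total_pd - sum(comp$restricted_pd),
         threshold = threshold),
    class = "pd_partition"
  )
}

#' @method print pd_partition
#' @export
print.pd_partition <- function(x, ...) {
  cat(sprintf("<pd_partition> total PD = %.4g, shared across all groups = %.4g (%.1f%%)\n",
              x$total_pd, x$shared_all, 100 * x$shared_all / x$total_pd))
  print(x$components, n = nrow(x$components))
  invisible(x)
}

#' Tidy a PD partition
#'
#' @param x A `pd_partition` object.
#' @param ... Unused.
#' @return Tibble with one row per component (`combo`, `n_pruned`,
#'   `restricted_pd`, `fraction`) plus a final `shared` row.
#' @export
tidy.pd_partition <- function(x, ...) {
  comp <- dplyr::mutate(x$components, fraction = .data$restricted_pd / x$total_pd)
  dplyr::bind_rows(
    comp,
    tibble::tibble(combo = "(shared)", n_pruned = NA_integer_,
                   restricted_pd = x$shared_all,
                   fraction = x$shared_all / x$total_pd)
  )
}

#' @rdname tidy.pd_partition
#' @export
glance.pd_partition <- function(x, ...) {
  tibble::tibble(total_pd = x$total_pd, shared_all = x$shared_all,
                 shared_fraction = x$shared_all / x$total_pd,
                 threshold = x$threshold,
                 n_components = nrow(x$components))
}

#' Export a PD partition for Euler/Venn rendering
#'
#' Writes the machine-readable set components (not a drawing): total PD,
#' threshold, one entry per combination with its restricted PD, and the
#' shared remainder.
#'
#' @param x A `pd_partition` object.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_pd_partition <- function(x, path) {
  jsonlite::write_json(
    list(total_pd = x$total_pd, threshold = x$threshold,
         components = x$components[, c("combo", "restricted_pd")],
         shared_all = x$shared_all),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Bar chart of PD-partition components
#'
#' @param object A `pd_partition` object.
#' @param ... Unused.
#' @return A ggplot of restricted and shared PD fractions.
#' @export
autoplot.pd_partition <- function(object, ...) {
  td <- tidy(object)
  td$combo <- factor(td$combo, levels = td$combo)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$combo, y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "group / combination", y = "fraction of total PD")
}
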