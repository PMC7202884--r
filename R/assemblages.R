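#' Coerce assemblage data to the canonical long form
#'
#' The package's canonical assemblage container is a tibble with one row per
#' (site, genus) presence: columns `site` and `genus`, both character. Wide
#' site-by-genus matrices or data frames (first column or row names = site
#' ids, remaining columns = genera, entries binarized at `> 0`) and long
#' data frames with `site`/`genus` columns are both accepted.
#'
#' @param x A long data frame with `site` and `genus` columns, a wide
#'   site-by-genus matrix/data frame, or the result of a previous call.
#' @return A tibble with columns `site`, `genus`, one row per presence.
#' @export
as_assemblages <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      stop("A wide matrix needs site row names and genus column names.", call. = FALSE)
    }
    df <- as.data.frame(x, check.names = FALSE)
    df$site <- rownames(x)
    x <- df
  }
  x <- tibble::as_tibble(x)
  if (all(c("site", "genus") %in% names(x))) {
    out <- dplyr::distinct(dplyr::transmute(
      x,
      site = as.character(.data$site),
      genus = normalize_genus(.data$genus)
    ))
  } else {
    if (!"site" %in% names(x)) {
      names(x)[1L] <- "site"
    }
    out <- tidyr::pivot_longer(x, -"site", names_to = "genus", values_to = "n")
    out <- dplyr::transmute(
      dplyr::filter(out, .data$n > 0),
      site = as.character(.data$site),
      genus = normalize_genus(.data$genus)
    )
    out <- dplyr::distinct(out)
  }
  if (anyNA(out$site) || anyNA(out$genus) || any(!nzchar(out$genus))) {
    stop("Sites and genera must be non-missing, non-empty.", call. = FALSE)
  }
  dplyr::arrange(out, .data$site, .data$genus)
}

#' Build the binary site-by-genus occupancy matrix
#'
#' @param assemblages Long assemblage tibble (see [as_assemblages()]).
#' @return Integer 0/1 matrix, sites in rows (sorted), genera in columns.
#' @export
occupancy_matrix <- function(assemblages) {
  a <- as_assemblages(assemblages)
  sites <- sort(unique(a$site))
  genera <- sort(unique(a$genus))
  m <- matrix(0L, length(sites), length(genera), dimnames = list(sites, genera))
  m[cbind(match(a$site, sites), match(a$genus, genera))] <- 1L
  m
}

#' Drop sites with too few genera
#'
#' Sites carrying fewer than `min_genera` distinct genera are removed; genus
#' columns left with no occurrences disappear with them. This mirrors the
#' minimum-information filter applied before any regionalization: sparse
#' sites cannot be placed reliably in ordinations or clusterings.
#'
#' @param assemblages Long assemblage tibble.
#' @param min_genera Minimum number of distinct genera per site (default 5).
#' @return Filtered assemblage tibble. A report (tibble of per-site genus
#'   counts and a `kept` flag) is attached as attribute `"filter_report"`.
#' @export
filter_min_genera <- function(assemblages, min_genera = 5) {
  a <- as_assemblages(assemblages)
  counts <- dplyr::summarise(dplyr::group_by(a, .data$site),
                             n_genera = dplyr::n_distinct(.data$genus),
                             .groups = "drop")
  counts$kept <- counts$n_genera >= min_genera
  out <- dplyr::semi_join(a, dplyr::filter(counts, .data$kept), by = "site")
  if (!nrow(out)) warning("No site has >= ", min_genera, " genera; result is empty.")
  attr(out, "filter_report") <- counts
  out
}

#' Restrict assemblages to genera present on the phylogeny
#'
#' Genera that cannot be reconciled with the tree's tip labels (exact match
#' after whitespace/underscore normalization) are dropped, with a report of
#' what was lost and the per-site retained fraction. Sites losing all their
#' genera are removed with a warning.
#'
#' @param assemblages Long assemblage tibble.
#' @param tree A `phylo` object.
#' @return Aligned assemblage tibble with attribute `"alignment_report"`, a
#'   list with `dropped_genera`, `n_dropped`, and `site_retention` (tibble:
#'   site, n_before, n_after, retained_fraction).
#' @export
align_to_tree <- function(assemblages, tree) {
  a <- as_assemblages(assemblages)
  validate_phylogeny(tree)
  tips <- normalize_genus(tree$tip.label)
  on_tree <- a$genus %in% tips
  dropped <- sort(unique(a$genus[!on_tree]))
  before <- dplyr::count(a, .data$site, name = "n_before")
  out <- a[on_tree, , drop = FALSE]
  after <- dplyr::count(out, .data$site, name = "n_after")
  ret <- dplyr::left_join(before, after, by = "site")
  ret$n_after[is.na(ret$n_after)] <- 0L
  ret$retained_fraction <- ret$n_after / ret$n_before
  lost_sites <- ret$site[ret$n_after == 0L]
  if (length(lost_sites)) {
    warning("Sites dropped (no genus left on the tree): ",
            paste(lost_sites, collapse = ", "))
  }
  if (length(dropped)) {
    message(length(dropped), " genera not on the tree were dropped.")
  }
  attr(out, "alignment_report") <- list(
    dropped_genera = dropped,
    n_dropped = length(dropped),
    site_retention = ret
  )
  out
}

#' Read assemblages from delimited text
#'
#' Accepts the two on-disk layouts: a wide site-by-genus 0/1 table (header of
#' genus names, first column site ids) or a long table with `site,genus`
#' columns. The layout is detected from the header.
#'
#' @param path CSV/TSV file path.
#' @param sep Field separator (default `,`).
#' @return Long assemblage tibble.
#' @export
read_assemblages <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  as_assemblages(df)
}

#' Read per-site covariates
#'
#' Covariates are keyed by site id; expected columns are any of `lat`,
#' `lon`, `elevation`, `MAT`, `MAP`, `TS`, `CWD`, `continent`, plus binary
#' delimitation flags (e.g. `freezing`).
#'
#' @param path CSV file path.
#' @param sep Field separator.
#' @return Tibble with a character `site` column.
#' @export
read_covariates <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"site" %in% names(df)) names(df)[1L] <- "site"
  df$site <- as.character(df$site)
  if (anyDuplicated(df$site)) stop("Duplicate site ids in covariates.", call. = FALSE)
  tibble::as_tibble(df)
}
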