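#' K-means grouping of assemblages from a phylogenetic dissimilarity matrix
#'
#' Runs Lloyd's algorithm `n_init` times on a feature representation of the
#' dissimilarity matrix and keeps the run with the lowest total
#' within-cluster sum of squares (TSS). The default representation feeds the
#' rows of the symmetric matrix to k-means (what `stats::kmeans()` does when
#' handed a dissimilarity matrix coerced to a matrix); `"pcoa"` uses a
#' classical principal-coordinates embedding instead.
#'
#' Empty clusters are re-seeded deterministically from the point farthest
#' from its centroid, so every group is non-empty. With `seed` fixed the
#' result is reproducible.
#'
#' @param d An `evo_dissim` object or symmetric dissimilarity matrix with
#'   site ids as dimnames.
#' @param k Number of groups (2 <= k < number of sites).
#' @param seed Integer seed controlling all restarts (required: no hidden
#'   global RNG state is used).
#' @param n_init Number of random restarts (default 25).
#' @param representation `"rows"` (default) or `"pcoa"`.
#' @param n_axes Number of PCoA axes when `representation = "pcoa"`.
#' @return An `evo_clusters` object: a list with `k`, `labels` (named
#'   integer vector, site -> group), `tss`, `silhouette` (tibble site,
#'   group, width), `centers`, `seed`, `n_init`. `tidy()` returns the
#'   per-site tibble; `glance()` the one-row summary.
#' @export
cluster_assemblages <- function(d, k, seed, n_init = 25,
                                representation = c("rows", "pcoa"),
                                n_axes = 10) {
  representation <- match.arg(representation)
  m <- as.matrix(d)
  n <- nrow(m)
  if (k < 2) stop("`k` must be at least 2.", call. = FALSE)
  if (k >= n) stop("`k` must be smaller than the number of sites.", call. = FALSE)
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  feats <- switch(representation,
    rows = m,
    pcoa = {
      e <- stats::cmdscale(stats::as.dist(m), k = min(n_axes, n - 1), eig = FALSE)
      e
    }
  )
  fit <- lloyd_best(feats, k, seed = seed, n_init = n_init)
  labels <- stats::setNames(fit$labels, rownames(m))
  sil <- silhouette_widths(m, labels)
  structure(
    list(k = k, labels = labels, tss = fit$tss, silhouette = sil,
         centers = fit$centers, seed = seed, n_init = n_init,
         representation = representation),
    class = "evo_clusters"
  )
}

# Best-of-n_init Lloyd's algorithm; private RNG stream, deterministic.
lloyd_best <- function(x, k, seed, n_init, max_iter = 100L) {
  best <- NULL
  rng <- local_rng(seed)
  for (run in seq_len(n_init)) {
    init <- rng$sample(nrow(x), k)
    fit <- lloyd_once(x, k, init, max_iter)
    if (is.null(best) || fit$tss < best$tss) best <- fit
  }
  best
}

lloyd_once <- function(x, k, init, max_iter) {
  centers <- x[init, , drop = FALSE]
  labels <- integer(nrow(x))
  for (it in seq_len(max_iter)) {
    dd <- point_center_dist2(x, centers)
    new_labels <- max.col(-dd, ties.method = "first")
    # re-seed any empty cluster from the point farthest from its centroid
    repeat {
      empties <- which(tabulate(new_labels, k) == 0L)
      if (!length(empties)) break
      g <- empties[1L]
      own <- dd[cbind(seq_len(nrow(x)), new_labels)]
      own[tabulate(new_labels, k)[new_labels] == 1L] <- -Inf  # keep singletons
      far <- which.max(own)
      new_labels[far] <- g
      centers[g, ] <- x[far, , drop = FALSE]
      dd[, g] <- point_center_dist2(x, centers[g, , drop = FALSE])[, 1L]
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    centers <- do.call(rbind, lapply(seq_len(k), function(g) {
      colMeans(x[labels == g, , drop = FALSE])
    }))
  }
  within <- x - centers[labels, , drop = FALSE]
  list(labels = labels, centers = centers, tss = sum(within^2))
}

point_center_dist2 <- function(x, centers) {
  # squared Euclidean distances, n x k
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, `+`) - 2 * tcrossprod(x, centers)
}

# A small private RNG so package functions never disturb the global stream.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(
    sample = function(n, size) with_state(function() sample.int(n, size)),
    runif = function(n, ...) with_state(function() stats::runif(n, ...)),
    rnorm = function(n, ...) with_state(function() stats::rnorm(n, ...))
  )
}

#' Silhouette widths on the original dissimilarities
#'
#' Classical silhouette \eqn{s(i) = (b_i - a_i)/\max(a_i, b_i)} where
#' \eqn{a_i} is the mean dissimilarity of site \eqn{i} to its own group
#' (excluding itself) and \eqn{b_i} the smallest mean dissimilarity to any
#' other group. Members of singleton groups get width 0 by convention, as do
#' sites with \eqn{a_i = b_i = 0}. Computed on the phylogenetic
#' dissimilarities themselves, not on the k-means feature space.
#'
#' @param d Dissimilarity matrix (or `evo_dissim`).
#' @param labels Named (or site-ordered) group labels.
#' @return Tibble with columns `site`, `group`, `width`.
#' @export
silhouette_widths <- function(d, labels) {
  m <- as.matrix(d)
  n <- nrow(m)
  labels <- align_labels(labels, rownames(m))
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop("Silhouette needs at least 2 groups.", call. = FALSE)
  # mean dissimilarity from every site to every group
  member <- outer(labels, groups, `==`) * 1           # n x G
  sums <- m %*% member
  sizes <- colSums(member)
  width <- numeric(n)
  for (i in seq_len(n)) {
    g <- match(labels[i], groups)
    if (sizes[g] == 1L) { width[i] <- 0; next }
    a <- sums[i, g] / (sizes[g] - 1L)
    b <- min(sums[i, -g] / sizes[-g])
    width[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  tibble::tibble(site = rownames(m), group = labels, width = width)
}

align_labels <- function(labels, sites) {
  if (!is.null(names(labels))) {
    if (!all(sites %in% names(labels))) {
      stop("Labels are missing for some sites.", call. = FALSE)
    }
    labels <- labels[sites]
  } else if (length(labels) != length(sites)) {
    stop("Label vector does not match the sites.", call. = FALSE)
  }
  unname(labels)
}

#' Choose the number of groups: Elbow (TSS) and average silhouette curves
#'
#' Fits k-means for every `k` in `k_range` and records the total
#' within-cluster sum of squares and mean silhouette width. The elbow is
#' formalized as the interior `k` maximizing the discrete second difference
#' `tss(k-1) - 2 tss(k) + tss(k+1)`; the silhouette choice is the `k` with
#' the highest average width. Both curves are returned for inspection —
#' the formal elbow is a summary of a visual judgement, not a substitute
#' for it.
#'
#' @inheritParams cluster_assemblages
#' @param k_range Candidate numbers of groups (default 2:10).
#' @return A `k_selection` object: list with `curve` (tibble k, tss,
#'   avg_silhouette), `elbow_k`, `silhouette_k`, and `fits` (the
#'   `evo_clusters` per k).
#' @export
select_k <- function(d, k_range = 2:10, seed, n_init = 25,
                     representation = c("rows", "pcoa"), n_axes = 10) {
  representation <- match.arg(representation)
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  fits <- lapply(k_range, function(k) {
    cluster_assemblages(d, k, seed = seed + k, n_init = n_init,
                        representation = representation, n_axes = n_axes)
  })
  names(fits) <- paste0("k", k_range)
  curve <- tibble::tibble(
    k = k_range,
    tss = vapply(fits, `[[`, numeric(1), "tss"),
    avg_silhouette = vapply(fits, function(f) mean(f$silhouette$width), numeric(1))
  )
  structure(
    list(curve = curve,
         elbow_k = elbow_select(stats::setNames(curve$tss, curve$k)),
         silhouette_k = curve$k[which.max(curve$avg_silhouette)],
         fits = fits),
    class = "k_selection"
  )
}

#' Elbow of a TSS curve
#'
#' @param tss_curve Named numeric vector: names are k, values the total
#'   within-cluster sum of squares.
#' @return The interior k maximizing the discrete second difference. A flat
#'   (no positive curvature) or non-monotone curve triggers a warning; the
#'   smallest interior k is returned when no elbow stands out.
#' @export
elbow_select <- function(tss_curve) {
  ks <- as.integer(names(tss_curve))
  if (is.null(names(tss_curve)) || anyNA(ks)) {
    stop("`tss_curve` must be named by k.", call. = FALSE)
  }
  o <- order(ks)
  ks <- ks[o]; tss <- as.numeric(tss_curve[o])
  if (length(ks) < 3L) stop("Need at least 3 points to find an elbow.", call. = FALSE)
  if (any(diff(tss) > 0)) warning("TSS curve is not monotone non-increasing.")
  interior <- 2:(length(ks) - 1L)
  d2 <- tss[interior - 1L] - 2 * tss[interior] + tss[interior + 1L]
  if (max(d2) <= 0 || diff(range(d2)) < 1e-12 * max(abs(tss))) {
    warning("No clear elbow; returning the smallest interior k.")
    return(ks[interior[1L]])
  }
  ks[interior[which.max(d2)]]
}

#' @method print evo_clusters
#' @export
print.evo_clusters <- function(x, ...) {
  cat(sprintf("<evo_clusters> k = %d, %d sites, TSS = %.4g, mean silhouette = %.3f\n",
              x$k, length(x$labels), x$tss, mean(x$silhouette$width)))
  print(table(group = x$labels))
  invisible(x)
}

#' @method print k_selection
#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("<k_selection> elbow k = %d, silhouette k = %d\n",
              x$elbow_k, x$silhouette_k))
  print(x$curve, n = nrow(x$curve))
  invisible(x)
}

#' Tidy clustering results
#'
#' @param x An `evo_clusters` object.
#' @param ... Unused.
#' @return Per-site tibble: `site`, `group`, `silhouette`.
#' @export
tidy.evo_clusters <- function(x, ...) {
  tibble::tibble(site = names(x$labels), group = unname(x$labels),
                 silhouette = x$silhouette$width)
}

#' @rdname tidy.evo_clusters
#' @return `glance()`: one-row tibble with `k`, `tss`, `avg_silhouette`,
#'   `n_sites`, `seed`.
#' @export
glance.evo_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, tss = x$tss,
                 avg_silhouette = mean(x$silhouette$width),
                 n_sites = length(x$labels), seed = x$seed)
}

#' @export
tidy.k_selection <- function(x, ...) x$curve

#' Diagnostic plot for k selection
#'
#' @param object A `k_selection` object.
#' @param ... Unused.
#' @return A ggplot: TSS and mean silhouette against k.
#' @export
autoplot.k_selection <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curve, -"k",
                              names_to = "criterion", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::labs(x = "number of groups (k)", y = NULL)
}

#' Silhouette plot of a clustering solution
#'
#' @param object An `evo_clusters` object.
#' @param ... Unused.
#' @return A ggplot: per-site silhouette widths sorted within groups.
#' @export
autoplot.evo_clusters <- function(object, ...) {
  sil <- dplyr::arrange(object$silhouette, .data$group,
                        dplyr::desc(.data$width))
  sil$rank <- seq_len(nrow(sil))
  ggplot2::ggplot(sil, ggplot2::aes(x = .data$rank, y = .data$width,
                                    fill = factor(.data$group))) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "silhouette width", fill = "group")
}
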