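#' Simulate a dated genus-level phylogeny
#'
#' Pure-birth (Yule) tree with branch lengths in millions of years. At the
#' default birth rate of 0.05 per Myr a 150-genus tree has an expected root
#' age near 100 Myr (root age grows like log(n)/lambda), on the order of a
#' dated angiosperm genus phylogeny.
#'
#' @param n_genera Number of tips (>= 10).
#' @param birth_rate Speciation rate per lineage per Myr.
#' @param seed Integer seed.
#' @return A `phylo` object with tips `g001`, `g002`, ...
#' @export
simulate_tree <- function(n_genera = 150, birth_rate = 0.05, seed) {
  if (n_genera < 10) stop("`n_genera` must be at least 10.", call. = FALSE)
  if (birth_rate <= 0) stop("`birth_rate` must be positive.", call. = FALSE)
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  tree <- with_seed(seed, ape::rphylo(n_genera, birth = birth_rate, death = 0))
  tree$tip.label <- sprintf("g%03d", seq_len(n_genera))
  tree
}

#' Simulate phylogenetically conserved niche traits
#'
#' Two independent Brownian-motion traits evolve along the tree: a cold
#' tolerance and a drought tolerance. Under Brownian motion the covariance
#' of two tips equals `sigma2` times their shared root-to-tip path length,
#' so close relatives inherit similar tolerances — the operational meaning
#' of phylogenetic niche conservatism.
#'
#' @param tree A `phylo` object (typically from [simulate_tree()]).
#' @param sigma2 Brownian variance accumulated per Myr (default 0.01: tip
#'   variance ~1 on a 100-Myr-deep tree).
#' @param seed Integer seed.
#' @return Tibble: `genus`, `cold_tol`, `drought_tol` (root state 0).
#' @export
simulate_niches <- function(tree, sigma2 = 0.01, seed) {
  if (sigma2 < 0) stop("`sigma2` must be non-negative.", call. = FALSE)
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  s <- sqrt(sigma2)
  tr <- with_seed(seed, list(
    cold = ape::rTraitCont(tree, model = "BM", sigma = s, root.value = 0),
    dry = ape::rTraitCont(tree, model = "BM", sigma = s, root.value = 0)
  ))
  tibble::tibble(genus = tree$tip.label,
                 cold_tol = unname(tr$cold[tree$tip.label]),
                 drought_tol = unname(tr$dry[tree$tip.label]))
}

#' Assemble sites under niche-conserved or dispersal-limited community assembly
#'
#' Generates a landscape of sites (latitude, longitude, elevation and the
#' derived climate: minimum temperature, MAT, MAP, TS, CWD, a freezing flag
#' and a continent), then fills each site with genera according to the
#' scenario:
#'
#' * `niche_conservatism` — frost is a hard physiological filter. Genera are
#'   split by their (standardized) cold-tolerance trait into a tropical-only
#'   band, a generalist band, and a cold-specialist band occurring only
#'   where it freezes (the band widths are `generalist_fraction` and
#'   `specialist_fraction` of genera). Within the allowed sites, occupancy
#'   probability follows a Gaussian niche on the drought axis with breadth
#'   `filter_width` (standard deviations of the standardized drought
#'   gradient). Geography plays no role.
#' * `dispersal_limitation` — genera belong to phylogenetically clustered
#'   continental pools (a third Brownian trait thresholded at its median);
#'   occurrence outside the home continent has probability `leak`. Climate
#'   plays no role beyond the drought niche.
#' * `mixed` — both constraints apply.
#'
#' A non-finite `filter_width` switches all environmental filtering off
#' (uniform occupancy at `base_prob`), giving the structureless null.
#' Sites ending up with fewer than `min_genera` genera are redrawn (up to
#' 100 times), so the generated matrix is valid pipeline input while the
#' minimum-genera filter is still exercised upstream of it.
#'
#' @param tree A `phylo` object.
#' @param niches Tibble from [simulate_niches()].
#' @param n_sites Number of sites.
#' @param scenario One of `"niche_conservatism"`, `"dispersal_limitation"`,
#'   `"mixed"`.
#' @param freezing_fraction Fraction of sites below freezing (default 0.3).
#' @param filter_width Drought-niche breadth (default 0.9).
#' @param specialist_fraction Fraction of genera in the cold-specialist
#'   band (default 0.12, planting roughly a tenth of the phylogeny's
#'   diversity in the extratropics).
#' @param generalist_fraction Fraction of genera tolerating both regimes
#'   (default 0.23).
#' @param base_prob Occupancy probability at a perfect niche match
#'   (default 0.6).
#' @param leak Off-continent occurrence probability factor under dispersal
#'   limitation (default 0.02).
#' @param min_genera Minimum realized genera per site (default 5).
#' @param seed Integer seed.
#' @return A list: `assemblages` (long tibble), `covariates` (tibble with
#'   site, lat, lon, elevation, MAT, MAP, TS, CWD, continent, freezing),
#'   `true_labels` (named character), `bands` (per-genus tibble),
#'   `true_restricted_fraction` (planted fraction of PD restricted to the
#'   cold pool; `NA` under pure dispersal limitation).
#' @export
assemble_sites <- function(tree, niches, n_sites = 400,
                           scenario = c("niche_conservatism",
                                        "dispersal_limitation", "mixed"),
                           freezing_fraction = 0.3, filter_width = 0.9,
                           specialist_fraction = 0.12,
                           generalist_fraction = 0.23,
                           base_prob = 0.6, leak = 0.02,
                           min_genera = 5, seed) {
  scenario <- match.arg(scenario)
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  stopifnot(freezing_fraction > 0, freezing_fraction < 1,
            specialist_fraction > 0, generalist_fraction >= 0,
            specialist_fraction + generalist_fraction < 1)
  n_genera <- nrow(niches)
  out <- with_seed(seed, {
    ## landscape ------------------------------------------------------------
    lat <- stats::runif(n_sites, -47, 49)
    lon <- stats::runif(n_sites, -120, -35)
    elevation <- 4000 * stats::runif(n_sites)^1.6
    min_temp <- 20 - 0.4 * abs(lat) - 0.007 * elevation + stats::rnorm(n_sites, 0, 2)
    min_temp <- min_temp - stats::quantile(min_temp, freezing_fraction)
    freezing <- min_temp < 0
    MAT <- min_temp + 14 + stats::rnorm(n_sites, 0, 1)
    TS <- pmax(200, 2500 + 110 * abs(lat) + stats::rnorm(n_sites, 0, 600))
    dryness <- stats::runif(n_sites)
    MAP <- pmax(150, 3200 - 2500 * dryness + stats::rnorm(n_sites, 0, 200))
    CWD <- pmin(0, -(30 + 850 * dryness) + stats::rnorm(n_sites, 0, 40))
    continent <- ifelse(lon >= -80, "South", "NorthCentral")
    env_dry <- as.numeric(scale(dryness))

    ## genus niche bands ----------------------------------------------------
    z_cold <- as.numeric(scale(niches$cold_tol))
    z_dry <- as.numeric(scale(niches$drought_tol))
    q_lo <- stats::quantile(z_cold, 1 - specialist_fraction - generalist_fraction)
    q_hi <- stats::quantile(z_cold, 1 - specialist_fraction)
    band <- cut(z_cold, c(-Inf, q_lo, q_hi, Inf),
                labels = c("tropical", "generalist", "extratropical"))
    geo_trait <- ape::rTraitCont(tree, model = "BM", sigma = 1, root.value = 0)
    geo_trait <- geo_trait[niches$genus]
    home <- ifelse(geo_trait > stats::median(geo_trait), "South", "NorthCentral")

    ## occupancy probabilities (sites x genera) ------------------------------
    filtering <- is.finite(filter_width)
    if (filtering) {
      gauss <- exp(-outer(env_dry, z_dry, `-`)^2 / (2 * filter_width^2))
      p <- base_prob * gauss
      if (scenario %in% c("niche_conservatism", "mixed")) {
        allowed_cold <- outer(freezing, band == "tropical",
                              function(f, tr) !(f & tr)) &
          outer(freezing, band == "extratropical",
                function(f, ex) !(!f & ex))
        p <- p * allowed_cold
      }
      if (scenario %in% c("dispersal_limitation", "mixed")) {
        match_cont <- outer(continent, home, `==`)
        p <- p * ifelse(match_cont, 1, leak)
      }
    } else {
      p <- matrix(base_prob, n_sites, n_genera)
    }

    ## draw occupancy, redrawing information-poor sites -----------------------
    occ <- matrix(stats::rbinom(length(p), 1L, p), n_sites, n_genera)
    for (i in seq_len(n_sites)) {
      tries <- 0L
      while (sum(occ[i, ]) < min_genera) {
        tries <- tries + 1L
        if (tries > 100L) {
          stop("Site ", i, " cannot reach ", min_genera,
               " genera; the niche filter is too narrow.", call. = FALSE)
        }
        occ[i, ] <- stats::rbinom(n_genera, 1L, p[i, ])
      }
    }
    site_ids <- sprintf("s%04d", seq_len(n_sites))
    dimnames(occ) <- list(site_ids, niches$genus)

    covariates <- tibble::tibble(
      site = site_ids, lat = lat, lon = lon, elevation = elevation,
      min_temp = min_temp, MAT = MAT, MAP = MAP, TS = TS, CWD = CWD,
      continent = continent, freezing = freezing
    )
    true_labels <- stats::setNames(
      if (scenario == "dispersal_limitation") continent
      else ifelse(freezing, "extratropical", "tropical"),
      site_ids
    )
    bands <- tibble::tibble(genus = niches$genus, band = as.character(band),
                            home_continent = home,
                            z_cold = z_cold, z_dry = z_dry)
    present <- colnames(occ)[colSums(occ) > 0]
    pool <- intersect(niches$genus[band == "extratropical"], present)
    restricted_fraction <- if (scenario == "dispersal_limitation" || !filtering) {
      NA_real_
    } else if (length(pool) && length(pool) < length(present)) {
      total <- pd_total(tree, present)
      (total - pd_total(tree, setdiff(present, pool))) / total
    } else {
      0
    }
    list(assemblages = as_assemblages(occ), covariates = covariates,
         true_labels = true_labels, bands = bands,
         true_restricted_fraction = restricted_fraction)
  })
  out
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper chaining [simulate_tree()], [simulate_niches()] and
#' [assemble_sites()] with seeds derived from one master seed.
#'
#' @param n_genera,birth_rate Tree parameters (see [simulate_tree()]).
#' @param sigma2 Trait variance rate (see [simulate_niches()]).
#' @param seed Master integer seed.
#' @param ... Passed to [assemble_sites()] (`n_sites`, `scenario`, ...).
#' @return An `evo_sim` list: `tree`, `niches`, plus everything
#'   [assemble_sites()] returns, and `seed`.
#' @export
simulate_dataset <- function(n_genera = 150, birth_rate = 0.05, sigma2 = 0.01,
                             seed, ...) {
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  tree <- simulate_tree(n_genera, birth_rate, seed = seed)
  niches <- simulate_niches(tree, sigma2, seed = seed + 1L)
  parts <- assemble_sites(tree, niches, seed = seed + 2L, ...)
  structure(c(list(tree = tree, niches = niches, seed = seed), parts),
            class = "evo_sim")
}

#' @method print evo_sim
#' @export
print.evo_sim <- function(x, ...) {
  cat(sprintf("<evo_sim> %d genera, %d sites, seed %d\n",
              length(x$tree$tip.label), nrow(x$covariates), x$seed))
  if (!is.na(x$true_restricted_fraction)) {
    cat(sprintf("  planted cold-restricted PD fraction: %.3f\n",
                x$true_restricted_fraction))
  }
  invisible(x)
}

#' Write a synthetic dataset as standard pipeline inputs
#'
#' Emits the Newick tree, the wide site-by-genus 0/1 CSV, the covariates
#' CSV, and a truth JSON (labels, planted restricted fraction, scenario
#' metadata).
#'
#' @param x An `evo_sim` object from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             matrix = file.path(dir, "assemblages.csv"),
             covariates = file.path(dir, "covariates.csv"),
             truth = file.path(dir, "truth.json"))
  write_newick(x$tree, paths[["tree"]])
  occ <- occupancy_matrix(x$assemblages)
  utils::write.csv(data.frame(site = rownames(occ), occ, check.names = FALSE),
                   paths[["matrix"]], row.names = FALSE)
  utils::write.csv(x$covariates, paths[["covariates"]], row.names = FALSE)
  jsonlite::write_json(
    list(true_labels = as.list(x$true_labels),
         true_restricted_fraction = x$true_restricted_fraction,
         seed = x$seed),
    paths[["truth"]], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
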