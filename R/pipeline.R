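#' Run the full evolutionary-regionalization pipeline
#'
#' Orchestrates the stages — simulate (or load), filter, dissimilarity,
#' clustering with K selection, evoPCA, indicator genera and clades, PD
#' partition, and the climate-versus-geography classification — writing
#' each stage's outputs under `output_dir` together with a manifest of
#' parameters, input checksums and runtimes. A rerun with unchanged inputs
#' and configuration reuses cached stage outputs; a corrupted cache file is
#' detected by its checksum and refused.
#'
#' @param config A named list (or path to a JSON/YAML file readable by
#'   [jsonlite::read_json()]). Recognized entries:
#'   \describe{
#'     \item{tree, matrix, covariates}{Input file paths, or}
#'     \item{simulation}{List of [simulate_dataset()] arguments (must
#'       include `seed`).}
#'     \item{min_genera}{Site filter threshold (default 5).}
#'     \item{k_range}{Candidate K values (default 2:6).}
#'     \item{k}{K values to report labels for (default `c(2, 4)`).}
#'     \item{n_init, seed}{Clustering restarts (default 25) and seed
#'       (required).}
#'     \item{n_axes}{evoPCA axes (default 5).}
#'     \item{specificity_threshold}{PD-partition cutoff (default 0.6).}
#'     \item{n_trees}{Random-forest size (default 500).}
#'   }
#'   Unknown entries are rejected.
#' @param output_dir Directory for stage outputs and the manifest.
#' @param force Rerun every stage even on cache hits.
#' @return A `pipeline_run` list with the in-memory results of every stage
#'   and the manifest tibble.
#' @export
run_pipeline <- function(config, output_dir, force = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  known <- c("tree", "matrix", "covariates", "simulation", "min_genera",
             "k_range", "k", "n_init", "seed", "n_axes",
             "specificity_threshold", "n_trees")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("Unknown config entries: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(config$seed)) stop("`config$seed` is required.", call. = FALSE)
  cfg <- utils::modifyList(
    list(min_genera = 5, k_range = 2:6, k = c(2, 4), n_init = 25,
         n_axes = 5, specificity_threshold = 0.6, n_trees = 500),
    config
  )
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(output_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path) && !force) {
    jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  } else {
    list()
  }
  runs <- list()

  stage <- function(name, params, outputs, fun) {
    entry <- manifest[[name]]
    key <- jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA)
    paths <- file.path(output_dir, outputs)
    if (!force && !is.null(entry) && identical(as.character(entry$key), as.character(key)) &&
        all(file.exists(paths))) {
      sums <- unname(tools::md5sum(paths))
      if (!identical(sums, as.character(unlist(entry$md5)))) {
        stop("Stage '", name, "' cache is corrupted (checksum mismatch); ",
             "delete ", output_dir, " or rerun with force = TRUE.", call. = FALSE)
      }
      runs[[name]] <<- list(cached = TRUE, runtime = 0)
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    fun(paths)
    manifest[[name]] <<- list(key = key,
                              md5 = as.list(unname(tools::md5sum(paths))),
                              runtime = proc.time()[["elapsed"]] - t0)
    runs[[name]] <<- list(cached = FALSE,
                          runtime = manifest[[name]]$runtime)
    invisible(NULL)
  }

  ## inputs -------------------------------------------------------------
  if (!is.null(cfg$simulation)) {
    sim_args <- cfg$simulation
    sim <- do.call(simulate_dataset, sim_args)
    stage("simulate", sim_args,
          c("tree.nwk", "assemblages.csv", "covariates.csv", "truth.json"),
          function(paths) write_dataset(sim, output_dir))
    tree <- sim$tree
    assemblages <- sim$assemblages
    covariates <- sim$covariates
  } else {
    if (is.null(cfg$tree) || is.null(cfg$matrix)) {
      stop("Config needs `tree` and `matrix` paths or a `simulation` block.",
           call. = FALSE)
    }
    tree <- read_newick(cfg$tree)
    assemblages <- read_assemblages(cfg$matrix)
    covariates <- if (!is.null(cfg$covariates)) read_covariates(cfg$covariates)
  }

  ## filter -------------------------------------------------------------
  assemblages <- align_to_tree(assemblages, tree)
  assemblages <- filter_min_genera(assemblages, cfg$min_genera)
  report <- attr(assemblages, "filter_report")
  stage("filter", list(min_genera = cfg$min_genera, n = nrow(report)),
        "filter_report.csv", function(paths) {
    utils::write.csv(report, paths[1L], row.names = FALSE)
  })

  ## dissimilarity --------------------------------------------------------
  d <- phylosor_complement(assemblages, tree)
  stage("dissim", list(metric = "phylosor", n = nrow(d)), "dissimilarity.csv",
        function(paths) write_dissim(d, paths[1L]))

  ## clustering -----------------------------------------------------------
  ks <- select_k(d, k_range = cfg$k_range, seed = cfg$seed, n_init = cfg$n_init)
  labels_tab <- tibble::tibble(site = rownames(d))
  for (k in cfg$k) {
    fit <- ks$fits[[paste0("k", k)]]
    if (is.null(fit)) {
      fit <- cluster_assemblages(d, k, seed = cfg$seed + k, n_init = cfg$n_init)
    }
    labels_tab[[paste0("K", k)]] <- unname(fit$labels[labels_tab$site])
  }
  stage("cluster", list(k_range = cfg$k_range, k = cfg$k, seed = cfg$seed,
                        n_init = cfg$n_init),
        c("labels.csv", "k_selection.json"), function(paths) {
    utils::write.csv(labels_tab, paths[1L], row.names = FALSE)
    jsonlite::write_json(
      list(curve = ks$curve, elbow_k = ks$elbow_k,
           silhouette_k = ks$silhouette_k),
      paths[2L], auto_unbox = TRUE, digits = NA)
  })

  ## ordination -----------------------------------------------------------
  pca <- evopca(assemblages, tree, n_axes = cfg$n_axes)
  stage("evopca", list(n_axes = cfg$n_axes),
        c("site_scores.csv", "clade_loadings.csv", "eigenvalues.csv"),
        function(paths) {
    utils::write.csv(pca$site_scores, paths[1L], row.names = FALSE)
    utils::write.csv(pca$loadings, paths[2L], row.names = FALSE)
    utils::write.csv(tidy(pca, "eigenvalues"), paths[3L], row.names = FALSE)
  })

  ## indicators + PD partition (primary K = first of cfg$k) ---------------
  k0 <- cfg$k[1L]
  labels <- stats::setNames(labels_tab[[paste0("K", k0)]], labels_tab$site)
  ind <- indval_genera(assemblages, labels, allow_combos = TRUE)
  nodes <- indicator_nodes(assemblages, tree, labels, allow_combos = TRUE)
  part <- partition_pd(assemblages, tree, indicators = ind,
                       threshold = cfg$specificity_threshold)
  stage("indicators", list(k = k0), c("indicator_genera.csv",
                                      "indicator_clades.csv"),
        function(paths) {
    utils::write.csv(ind, paths[1L], row.names = FALSE)
    utils::write.csv(nodes$selected, paths[2L], row.names = FALSE)
  })
  stage("pdpartition", list(k = k0, threshold = cfg$specificity_threshold),
        c("pd_partition.json", "pd_partition.csv"), function(paths) {
    write_pd_partition(part, paths[1L])
    utils::write.csv(tidy(part), paths[2L], row.names = FALSE)
  })

  ## classification --------------------------------------------------------
  comparison <- NULL
  if (!is.null(covariates)) {
    comparison <- compare_classifiers(covariates, labels, seed = cfg$seed,
                                      n_trees = cfg$n_trees)
    stage("classify", list(k = k0, seed = cfg$seed, n_trees = cfg$n_trees),
          c("classification.json", "importances.csv"), function(paths) {
      jsonlite::write_json(
        list(climate_accuracy = comparison$climate$accuracy,
             geography_accuracy = comparison$geography$accuracy,
             n_sites = comparison$n_sites),
        paths[1L], auto_unbox = TRUE, digits = NA)
      utils::write.csv(tidy(comparison), paths[2L], row.names = FALSE)
    })
  }

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  structure(
    list(tree = tree, assemblages = assemblages, covariates = covariates,
         dissimilarity = d, k_selection = ks, labels = labels_tab,
         evopca = pca, indicator_genera = ind, indicator_clades = nodes,
         pd_partition = part, classification = comparison,
         manifest = runs, output_dir = output_dir),
    class = "pipeline_run"
  )
}

#' @method print pipeline_run
#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>", x$output_dir, "\n")
  for (nm in names(x$manifest)) {
    cat(sprintf("  %-12s %s (%.2fs)\n", nm,
                if (x$manifest[[nm]]$cached) "cached" else "run",
                x$manifest[[nm]]$runtime))
  }
  invisible(x)
}
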