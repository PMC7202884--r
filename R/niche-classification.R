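#' Climate versus geography as predictors of evolutionary group
#'
#' Fits two random-forest classifiers of group membership: a climatic model
#' (MAT, MAP, TS, CWD) and a geographic model (continent, latitude,
#' longitude). Out-of-bag accuracy operationalizes "proportion of
#' assemblages correctly categorized"; variable importances are mean
#' decreases in Gini impurity. Sites without a continent assignment are
#' excluded from both models so the two accuracies are comparable.
#'
#' @param covariates Per-site covariate tibble (see [read_covariates()]).
#' @param labels Named group labels (site -> group), e.g. from
#'   [cluster_assemblages()].
#' @param seed Integer seed (forests are stochastic).
#' @param n_trees Trees per forest (default 500).
#' @return A `classifier_comparison` object: list with `climate` and
#'   `geography`, each holding `accuracy`, `per_class_accuracy`,
#'   `importance` (tibble), `confusion`; plus `n_sites`, `seed`.
#' @export
compare_classifiers <- function(covariates, labels, seed, n_trees = 500) {
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  climate_vars <- c("MAT", "MAP", "TS", "CWD")
  geo_vars <- c("continent", "lat", "lon")
  need <- c("site", climate_vars, geo_vars)
  miss <- setdiff(need, names(covariates))
  if (length(miss)) {
    stop("Missing covariate columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  cov <- covariates[match(names(labels), covariates$site), , drop = FALSE]
  if (anyNA(cov$site)) stop("Covariates missing for some labelled sites.", call. = FALSE)
  ok <- !is.na(cov$continent) & stats::complete.cases(cov[, c(climate_vars, "lat", "lon")])
  cov <- cov[ok, , drop = FALSE]
  y <- factor(unname(labels)[ok])
  fit_one <- function(vars, s) {
    x <- as.data.frame(cov[, vars, drop = FALSE])
    x$continent <- if ("continent" %in% vars) factor(cov$continent) else NULL
    set.seed(s)
    rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees, importance = FALSE)
    conf <- rf$confusion[, levels(y), drop = FALSE]
    list(
      accuracy = 1 - rf$err.rate[n_trees, "OOB"][[1L]],
      per_class_accuracy = diag(conf) / rowSums(conf),
      importance = tibble::tibble(
        variable = rownames(randomForest::importance(rf)),
        mean_decrease_gini = randomForest::importance(rf)[, "MeanDecreaseGini"]
      ),
      confusion = conf
    )
  }
  structure(
    list(climate = fit_one(climate_vars, seed),
         geography = fit_one(geo_vars, seed + 1L),
         n_sites = length(y), n_trees = n_trees, seed = seed),
    class = "classifier_comparison"
  )
}

#' @method print classifier_comparison
#' @export
print.classifier_comparison <- function(x, ...) {
  cat(sprintf("<classifier_comparison> %d sites, %d trees\n", x$n_sites, x$n_trees))
  cat(sprintf("  climate OOB accuracy:   %.1f%%\n", 100 * x$climate$accuracy))
  cat(sprintf("  geography OOB accuracy: %.1f%%\n", 100 * x$geography$accuracy))
  invisible(x)
}

#' Tidy a classifier comparison
#'
#' @param x A `classifier_comparison` object.
#' @param ... Unused.
#' @return Tibble: one row per model x variable with the Gini importance
#'   and the model's overall accuracy.
#' @export
tidy.classifier_comparison <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$climate$importance, model = "climate",
                  accuracy = x$climate$accuracy),
    dplyr::mutate(x$geography$importance, model = "geography",
                  accuracy = x$geography$accuracy)
  )[, c("model", "variable", "mean_decrease_gini", "accuracy")]
}

#' @rdname tidy.classifier_comparison
#' @export
glance.classifier_comparison <- function(x, ...) {
  tibble::tibble(climate_accuracy = x$climate$accuracy,
                 geography_accuracy = x$geography$accuracy,
                 advantage = x$climate$accuracy - x$geography$accuracy,
                 n_sites = x$n_sites, n_trees = x$n_trees, seed = x$seed)
}

#' Rank climatic variables for a binary within-region split
#'
#' For each candidate variable (MAT, MAP, TS, CWD) fits a binomial
#' regression of the binary label on the standardized variable with a
#' varying intercept per 1-degree grid cell (`floor(lat) x floor(lon)`),
#' absorbing spatial autocorrelation, and ranks the variables by AIC. When
#' the grid is essentially one site per cell the random intercept is not
#' estimable and a plain binomial GLM is used instead (with a message).
#'
#' @param covariates Per-site covariate tibble (`lat`, `lon` and the
#'   candidate variables required).
#' @param labels Named binary labels (site -> one of exactly two values),
#'   e.g. tropical moist vs dry sites.
#' @param variables Candidate variables (default MAT, MAP, TS, CWD).
#' @param grid Cell size in degrees (default 1).
#' @return Tibble sorted by AIC: `variable`, `aic`, `delta_aic`,
#'   `estimate` (slope on the standardized variable), `method`.
#' @export
rank_climate_variables <- function(covariates, labels,
                                   variables = c("MAT", "MAP", "TS", "CWD"),
                                   grid = 1) {
  miss <- setdiff(c("site", "lat", "lon", variables), names(covariates))
  if (length(miss)) {
    stop("Missing covariate columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  cov <- covariates[match(names(labels), covariates$site), , drop = FALSE]
  if (anyNA(cov$site)) stop("Covariates missing for some labelled sites.", call. = FALSE)
  lv <- unique(unname(labels))
  if (length(lv) != 2L) stop("Exactly 2 label values are required.", call. = FALSE)
  y <- as.integer(unname(labels) == lv[2L])
  cell <- factor(paste(floor(cov$lat / grid), floor(cov$lon / grid), sep = ":"))
  use_glmm <- nlevels(cell) < 0.9 * length(y)
  if (!use_glmm) message("Grid cells are nearly all singletons; using plain binomial GLM.")
  rows <- lapply(variables, function(v) {
    z <- cov[[v]]
    if (stats::sd(z) == 0) {
      warning("Variable ", v, " is constant; skipped.")
      return(NULL)
    }
    z <- as.numeric(scale(z))
    df <- data.frame(y = y, z = z, cell = cell)
    if (use_glmm) {
      fit <- suppressWarnings(suppressMessages(
        lme4::glmer(y ~ z + (1 | cell), data = df, family = stats::binomial)
      ))
      tibble::tibble(variable = v, aic = stats::AIC(fit),
                     estimate = lme4::fixef(fit)[["z"]], method = "glmm")
    } else {
      fit <- stats::glm(y ~ z, data = df, family = stats::binomial)
      tibble::tibble(variable = v, aic = stats::AIC(fit),
                     estimate = stats::coef(fit)[["z"]], method = "glm")
    }
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$aic)
  dplyr::mutate(out, delta_aic = .data$aic - min(.data$aic),
                .after = "aic")
}

#' Correspondence between a two-group clustering and tropics delimitations
#'
#' Compares K = 2 cluster labels against binary tropical/extratropical
#' delimitations: the latitudinal definition (C1, |lat| <= 23.4 degrees) is
#' computed internally; any other delimitation is consumed as a logical
#' covariate column flagging *tropical* sites (e.g. `freezing = FALSE`
#' regimes are tropical under the freezing-line definition C4, so the flag
#' column should mark the tropical side: see `flags`). The match fraction is
#' maximized over the two possible cluster-to-class mappings, so it is
#' always at least 0.5.
#'
#' @param covariates Per-site covariate tibble with `lat` and any flag
#'   columns.
#' @param labels Named K = 2 cluster labels.
#' @param flags Character vector of covariate column names holding logical
#'   delimitations (TRUE = tropical side). Default: every logical column.
#' @param latitudinal Include the computed |lat| <= 23.4 delimitation as
#'   `"C1_latitude"` (default TRUE).
#' @return Tibble: `delimitation`, `match_fraction`, `tropical_cluster`
#'   (the cluster label mapped to the tropical side).
#' @export
delimitation_correspondence <- function(covariates, labels, flags = NULL,
                                        latitudinal = TRUE) {
  cov <- covariates[match(names(labels), covariates$site), , drop = FALSE]
  if (anyNA(cov$site)) stop("Covariates missing for some labelled sites.", call. = FALSE)
  gl <- unique(unname(labels))
  if (length(gl) != 2L) stop("K = 2 labels are required.", call. = FALSE)
  if (is.null(flags)) {
    flags <- names(cov)[vapply(cov, is.logical, logical(1))]
  }
  delims <- list()
  if (latitudinal) {
    if (!"lat" %in% names(cov)) stop("`lat` column required for C1.", call. = FALSE)
    delims$C1_latitude <- abs(cov$lat) <= 23.4
  }
  for (f in flags) {
    if (!f %in% names(cov)) {
      warning("Delimitation flag '", f, "' not found; skipped.")
      next
    }
    delims[[f]] <- as.logical(cov[[f]])
  }
  lab <- unname(labels)
  rows <- lapply(names(delims), function(nm) {
    tropical <- delims[[nm]]
    m1 <- mean((lab == gl[1L]) == tropical)
    m2 <- mean((lab == gl[2L]) == tropical)
    tibble::tibble(delimitation = nm,
                   match_fraction = max(m1, m2),
                   tropical_cluster = as.character(if (m1 >= m2) gl[1L] else gl[2L]))
  })
  dplyr::bind_rows(rows)
}
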