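sim_cov <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    site = sprintf("s%03d", seq_len(n)),
    lat = runif(n, -40, 45), lon = runif(n, -110, -40),
    elevation = runif(n, 0, 3000),
    MAT = rnorm(n, 18, 8), MAP = runif(n, 200, 3200),
    TS = runif(n, 300, 9000), CWD = -runif(n, 0, 900),
    continent = sample(c("South", "NorthCentral"), n, replace = TRUE)
  )
}

test_that("labels independent of all features give near-chance OOB accuracy", {
  cov <- sim_cov(240, 1)
  set.seed(2)
  labels <- setNames(sample(c("x", "y"), 240, replace = TRUE), cov$site)
  cc <- compare_classifiers(cov, labels, seed = 3, n_trees = 300)
  base <- max(table(labels)) / length(labels)
  expect_lt(abs(cc$climate$accuracy - base), 0.12)
  expect_lt(abs(cc$geography$accuracy - base), 0.12)
  expect_true(all(tidy(cc)$mean_decrease_gini >= 0))
})

test_that("missing covariate columns are named in the error", {
  cov <- sim_cov(30, 4)
  labels <- setNames(rep(c("x", "y"), 15), cov$site)
  expect_error(compare_classifiers(cov[, -match("CWD", names(cov))], labels,
                                   seed = 1), "CWD")
})

test_that("the classifier comparison is seed-reproducible", {
  cov <- sim_cov(120, 5)
  labels <- setNames(ifelse(cov$MAT > 18, "warm", "cool"), cov$site)
  c1 <- compare_classifiers(cov, labels, seed = 11, n_trees = 200)
  c2 <- compare_classifiers(cov, labels, seed = 11, n_trees = 200)
  expect_identical(glance(c1), glance(c2))
})

test_that("labels generated from MAP alone rank MAP first by AIC", {
  cov <- sim_cov(250, 6)
  set.seed(7)
  p <- plogis(3 * as.numeric(scale(cov$MAP)))
  labels <- setNames(ifelse(rbinom(250, 1, p) == 1, "moist", "dry"), cov$site)
  suppressMessages(tab <- rank_climate_variables(cov, labels))
  expect_equal(tab$variable[1], "MAP")
  expect_gt(tab$delta_aic[2], 10)
})

test_that("pure-noise labels produce no runaway AIC winner", {
  cov <- sim_cov(150, 8)
  set.seed(9)
  labels <- setNames(sample(c("u", "v"), 150, replace = TRUE), cov$site)
  suppressMessages(tab <- rank_climate_variables(cov, labels))
  expect_lt(max(tab$delta_aic), 10)
})

test_that("AIC ranking is invariant to affine rescaling and exact for duplicates", {
  cov <- sim_cov(150, 10)
  set.seed(11)
  p <- plogis(2 * as.numeric(scale(cov$CWD)))
  labels <- setNames(ifelse(rbinom(150, 1, p) == 1, "a", "b"), cov$site)
  cov2 <- dplyr::mutate(cov, MAT = 9 / 5 * MAT + 32)   # different units
  suppressMessages(t1 <- rank_climate_variables(cov, labels))
  suppressMessages(t2 <- rank_climate_variables(cov2, labels))
  expect_equal(t1$aic[t1$variable == "MAT"], t2$aic[t2$variable == "MAT"],
               tolerance = 1e-8)
  # perfectly collinear duplicate variable gets an identical AIC
  cov3 <- dplyr::mutate(cov, MAT = 2 * CWD + 5)
  suppressMessages(t3 <- rank_climate_variables(cov3, labels))
  expect_equal(t3$aic[t3$variable == "MAT"], t3$aic[t3$variable == "CWD"],
               tolerance = 1e-6)
  # constant variables are skipped with a warning
  cov4 <- dplyr::mutate(cov, TS = 1000)
  suppressMessages(expect_warning(t4 <- rank_climate_variables(cov4, labels),
                                  "constant"))
  expect_false("TS" %in% t4$variable)
})

test_that("the grid-cell random intercept engages when cells hold several sites", {
  cov <- sim_cov(200, 12)
  cov$lat <- round(cov$lat / 8) * 8 + runif(200, 0, 0.9)
  cov$lon <- round(cov$lon / 8) * 8 + runif(200, 0, 0.9)
  set.seed(13)
  p <- plogis(2.5 * as.numeric(scale(cov$MAP)))
  labels <- setNames(ifelse(rbinom(200, 1, p) == 1, "m", "d"), cov$site)
  tab <- rank_climate_variables(cov, labels)
  expect_true(all(tab$method == "glmm"))
  expect_equal(tab$variable[1], "MAP")
})

test_that("delimitation matches are maximized over the two label mappings", {
  cov <- sim_cov(100, 14)
  cov$freezing <- cov$MAT < 12
  labels <- setNames(ifelse(cov$freezing, 1L, 2L), cov$site)
  dm <- delimitation_correspondence(cov, labels)
  expect_equal(dm$match_fraction[dm$delimitation == "freezing"], 1)
  # flipped labels give the same match by the mapping maximization
  dm2 <- delimitation_correspondence(cov, setNames(3L - labels, names(labels)))
  expect_equal(dm2$match_fraction[dm2$delimitation == "freezing"], 1)
  # independent balanced flag sits near one half, never below it
  set.seed(15)
  cov$random_flag <- sample(c(TRUE, FALSE), 100, replace = TRUE)
  dm3 <- delimitation_correspondence(cov, labels)
  mf <- dm3$match_fraction[dm3$delimitation == "random_flag"]
  expect_gte(mf, 0.5)
  expect_lt(mf, 0.7)
  # C1 latitudinal band is computed from latitude
  expect_true("C1_latitude" %in% dm3$delimitation)
  expect_warning(delimitation_correspondence(cov, labels, flags = "nope"),
                 "nope")
})
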