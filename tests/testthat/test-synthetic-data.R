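test_that("simulated trees have the requested size and are seed-reproducible", {
  tr <- simulate_tree(10, seed = 1)
  expect_length(tr$tip.label, 10L)
  expect_equal(tr$Nnode, 9L)
  expect_identical(write_newick(simulate_tree(40, seed = 5)),
                   write_newick(simulate_tree(40, seed = 5)))
  expect_false(identical(write_newick(simulate_tree(40, seed = 5)),
                         write_newick(simulate_tree(40, seed = 6))))
  expect_error(simulate_tree(5, seed = 1), "at least 10")
})

test_that("expected root age grows with the number of genera", {
  ages <- function(n) {
    mean(vapply(1:60, function(s) {
      max(ape::node.depth.edgelength(simulate_tree(n, 0.1, seed = s * 7)))
    }, numeric(1)))
  }
  a20 <- ages(20); a80 <- ages(80)
  expect_gt(a80, a20)
  # pure-birth root age scales like log(n)/lambda
  expect_equal(a80 - a20, log(80 / 20) / 0.1, tolerance = 0.35)
})

test_that("niche traits follow Brownian covariance along the tree", {
  tree <- simulate_tree(12, 0.1, seed = 3)
  # sigma2 = 0 collapses every tip to the root state
  flat <- simulate_niches(tree, sigma2 = 0, seed = 1)
  expect_true(all(flat$cold_tol == 0))
  # Monte-Carlo tip covariance vs the closed-form shared path length
  sigma2 <- 0.5
  reps <- vapply(1:400, function(s) {
    simulate_niches(tree, sigma2, seed = 1000 + s)$cold_tol
  }, numeric(12))
  emp <- cov(t(reps))
  theo <- sigma2 * ape::vcv(tree)[tree$tip.label, tree$tip.label]
  expect_equal(unname(emp), unname(theo), tolerance = 0.2)
  # phylogenetic signal: close relatives diverge less than distant pairs
  d_tree <- ape::cophenetic.phylo(tree)[tree$tip.label, tree$tip.label]
  sqdiff <- matrix(0, 12, 12)
  for (r in seq_len(ncol(reps))) {
    sqdiff <- sqdiff + outer(reps[, r], reps[, r], `-`)^2
  }
  sqdiff <- sqdiff / ncol(reps)
  near <- d_tree < median(d_tree[upper.tri(d_tree)])
  ut <- upper.tri(d_tree)
  expect_lt(mean(sqdiff[near & ut]), mean(sqdiff[!near & ut]))
})

test_that("assembled datasets are deterministic and structurally valid", {
  s1 <- simulate_dataset(n_genera = 40, n_sites = 50, seed = 9)
  s2 <- simulate_dataset(n_genera = 40, n_sites = 50, seed = 9)
  expect_identical(s1$assemblages, s2$assemblages)
  expect_identical(s1$covariates, s2$covariates)
  cov <- s1$covariates
  expect_true(all(cov$CWD <= 0))
  expect_true(all(table(s1$assemblages$site) >= 5))
  # freezing flag is the below-zero side of the minimum-temperature proxy
  expect_equal(cov$freezing, cov$min_temp < 0)
  expect_equal(mean(cov$freezing), 0.3, tolerance = 0.05)
  # labels follow the scenario
  expect_equal(unname(s1$true_labels[cov$site]),
               ifelse(cov$freezing, "extratropical", "tropical"))
  disp <- simulate_dataset(n_genera = 40, n_sites = 50, seed = 9,
                           scenario = "dispersal_limitation")
  expect_equal(unname(disp$true_labels[disp$covariates$site]),
               disp$covariates$continent)
})

test_that("cold specialists occur only in freezing sites and plant restricted PD", {
  sim <- simulate_dataset(n_genera = 60, n_sites = 80, seed = 23)
  occ <- occupancy_matrix(sim$assemblages)
  specialists <- sim$bands$genus[sim$bands$band == "extratropical"]
  specialists <- intersect(specialists, colnames(occ))
  freezing <- sim$covariates$freezing[match(rownames(occ), sim$covariates$site)]
  expect_true(all(occ[!freezing, specialists] == 0))
  tropical_only <- intersect(sim$bands$genus[sim$bands$band == "tropical"],
                             colnames(occ))
  expect_true(all(occ[freezing, tropical_only] == 0))
  expect_gt(sim$true_restricted_fraction, 0)
  expect_lt(sim$true_restricted_fraction, 0.35)
})

test_that("an infinite niche breadth removes community structure", {
  sim <- simulate_dataset(n_genera = 50, n_sites = 60, seed = 31,
                          filter_width = Inf, base_prob = 0.4)
  d <- phylosor_complement(sim$assemblages, sim$tree)
  cl <- cluster_assemblages(d, 2, seed = 1, n_init = 10)
  expect_lt(mean(cl$silhouette$width), 0.15)
  expect_true(is.na(sim$true_restricted_fraction))
})

test_that("an infeasibly narrow filter errors instead of looping", {
  tree <- simulate_tree(20, seed = 2)
  niches <- simulate_niches(tree, 0.01, seed = 3)
  expect_error(
    assemble_sites(tree, niches, n_sites = 10, seed = 4,
                   filter_width = 0.01, base_prob = 0.01, min_genera = 10),
    "too narrow"
  )
})

test_that("written datasets round-trip through the standard readers", {
  sim <- simulate_dataset(n_genera = 30, n_sites = 30, seed = 77)
  dir <- file.path(tempdir(), "evoreg_ds")
  paths <- write_dataset(sim, dir)
  tr <- read_newick(paths[["tree"]])
  expect_equal(sort(tr$tip.label), sort(sim$tree$tip.label))
  a <- read_assemblages(paths[["matrix"]])
  expect_equal(as.data.frame(a), as.data.frame(sim$assemblages))
  cv <- read_covariates(paths[["covariates"]])
  expect_equal(cv$site, sim$covariates$site)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$true_restricted_fraction, sim$true_restricted_fraction,
               tolerance = 1e-9)
  unlink(dir, recursive = TRUE)
})
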