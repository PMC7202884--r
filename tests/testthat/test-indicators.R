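two_group_fixture <- function(n1 = 4, n2 = 4) {
  sites <- sprintf("s%02d", seq_len(n1 + n2))
  labels <- setNames(rep(c("a", "b"), c(n1, n2)), sites)
  list(sites = sites, labels = labels)
}

test_that("a genus confined to one full group is a perfect indicator", {
  fx <- two_group_fixture()
  a <- data.frame(site = fx$sites,
                  genus = rep(c("only_a", "only_b"), c(4, 4)))
  a <- rbind(a, data.frame(site = fx$sites, genus = "everywhere"))
  tab <- indval_genera(a, fx$labels)
  row <- tab[tab$unit == "only_a", ]
  expect_equal(row$combo, "a")
  expect_equal(row$A, 1)
  expect_equal(row$B, 1)
  expect_equal(row$stat, 1)
})

test_that("an uninformative genus ties across combos and the smallest wins", {
  sites <- sprintf("s%02d", 1:9)
  labels <- setNames(rep(c("a", "b", "c"), each = 3), sites)
  a <- data.frame(site = sites, genus = "ubiquitous")
  a <- rbind(a, data.frame(site = sites[c(1, 4, 7)], genus = "filler"))
  tab <- indval_genera(a, labels, allow_combos = TRUE)
  row <- tab[tab$unit == "ubiquitous", ]
  # all combos give B = 1 and A = |combo|/3; best stat is the 2-group combo,
  # tie between a+b, a+c, b+c broken lexicographically
  expect_equal(row$combo, "a+b")
})

test_that("A, B and stat match brute-force contingency counting", {
  set.seed(33)
  for (rep in 1:6) {
    tree <- random_fixture_tree(10, rep + 200)
    occ <- random_occupancy(tree, 9, rep + 300, p = 0.45)
    labels <- setNames(sample(c("a", "b", "c"), 9, replace = TRUE), rownames(occ))
    while (length(unique(labels)) < 3) {
      labels <- setNames(sample(c("a", "b", "c"), 9, replace = TRUE), rownames(occ))
    }
    tab <- indval_genera(occ_to_long(occ), labels, all_combos = TRUE)
    groups <- c("a", "b", "c")
    for (r in sample(nrow(tab), 20)) {
      combo <- strsplit(tab$combo[r], "+", fixed = TRUE)[[1]]
      ref <- oracle_indval_cell(occ, unname(labels[rownames(occ)]),
                                tab$unit[r], combo)
      expect_equal(tab$A[r], ref[["A"]], tolerance = 1e-12)
      expect_equal(tab$B[r], ref[["B"]], tolerance = 1e-12)
      expect_equal(tab$stat[r], ref[["stat"]], tolerance = 1e-12)
    }
  }
})

test_that("stat^2 equals A*B and the full group set is never a candidate", {
  tree <- random_fixture_tree(12, 401)
  occ <- random_occupancy(tree, 12, 402)
  labels <- setNames(rep(c("a", "b", "c"), each = 4), rownames(occ))
  tab <- indval_genera(occ_to_long(occ), labels, all_combos = TRUE)
  expect_equal(tab$stat^2, tab$A * tab$B, tolerance = 1e-12)
  expect_false(any(tab$combo == "a+b+c"))
})

test_that("stat values are invariant to site reordering and label renaming", {
  tree <- random_fixture_tree(10, 403)
  occ <- random_occupancy(tree, 8, 404)
  labels <- setNames(rep(c("a", "b"), each = 4), rownames(occ))
  t1 <- indval_genera(occ_to_long(occ), labels)
  perm <- sample(8)
  t2 <- indval_genera(occ_to_long(occ[perm, ]), labels[perm])
  expect_equal(dplyr::arrange(t1, unit)$stat,
               dplyr::arrange(t2, unit)$stat, tolerance = 1e-12)
  relabeled <- setNames(c(a = "z", b = "y")[labels], names(labels))
  t3 <- indval_genera(occ_to_long(occ), relabeled)
  expect_equal(dplyr::arrange(t1, unit)$stat,
               dplyr::arrange(t3, unit)$stat, tolerance = 1e-12)
})

test_that("a group with zero sites is rejected", {
  occ <- random_occupancy(random_fixture_tree(6, 405), 4, 406)
  labels <- setNames(rep("a", 4), rownames(occ))
  expect_error(indval_genera(occ_to_long(occ), labels), "2 groups")
})

test_that("the site-by-node matrix is the OR of descendant tip columns", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  a <- data.frame(site = c("s1", "s1", "s2", "s3"),
                  genus = c("A", "C", "B", "D"))
  m <- site_by_node_matrix(a, tr)
  nodes <- attr(m, "nodes")
  # root present wherever any genus is
  root_col <- paste0("nd", nodes$node[which.max(nodes$n_tips)])
  expect_true(all(m[, root_col] == 1))
  # cherry (A,B) present iff A or B present
  ab <- nodes$node[nodes$n_tips == 2 & grepl("^A", nodes$clade_label)]
  expect_equal(unname(m[, paste0("nd", ab)]), c(1, 1, 0))
  for (seed in 1:5) {
    tree <- random_fixture_tree(10, seed + 500)
    occ <- random_occupancy(tree, 6, seed + 600)
    m <- site_by_node_matrix(occ_to_long(occ), tree)
    nd <- attr(m, "nodes")
    desc <- ape::prop.part(tree)
    for (j in seq_along(nd$node)) {
      tips <- tree$tip.label[desc[[j]]]
      expect_equal(unname(m[, paste0("nd", nd$node[j])]),
                   unname((rowSums(occ[, tips, drop = FALSE]) > 0) * 1L))
    }
  }
})

test_that("indicator clades are non-nested and catch perfect group-restricted clades", {
  # clade (A,B,C) occurs only in group a sites and fills them
  tr <- read_newick("(((A:1,B:1):1,C:2):1,((D:1,E:1):1,F:2):1);")
  sites <- sprintf("s%02d", 1:6)
  labels <- setNames(rep(c("a", "b"), each = 3), sites)
  a <- rbind(
    data.frame(site = rep(sites[1:3], each = 3), genus = c("A", "B", "C")),
    data.frame(site = rep(sites[4:6], each = 3), genus = c("D", "E", "F"))
  )
  res <- indicator_nodes(a, tr, labels)
  sel <- res$selected
  # the ABC and DEF clade MRCAs are selected with stat 1; their descendant
  # cherries (also perfect) are suppressed by the non-nesting rule
  perfect <- sel[sel$stat == 1, ]
  expect_equal(sort(perfect$n_tips), c(3, 3))
  expect_setequal(perfect$combo, c("a", "b"))
  # no selected node is an ancestor or descendant of another
  desc <- ape::prop.part(tr)
  tipsets <- lapply(sel$node, function(nd) desc[[nd - length(tr$tip.label)]])
  for (i in seq_along(tipsets)) for (j in seq_along(tipsets)) {
    if (i != j) {
      expect_false(all(tipsets[[i]] %in% tipsets[[j]]))
    }
  }
})

test_that("greedy antichain selection matches an independent naive implementation", {
  for (seed in 1:6) {
    tree <- random_fixture_tree(12, seed + 700)
    occ <- random_occupancy(tree, 8, seed + 800)
    labels <- setNames(rep(c("a", "b"), each = 4), rownames(occ))
    res <- indicator_nodes(occ_to_long(occ), tree, labels)
    # naive reference: sort full table, keep non-nested by explicit tip sets
    full <- res$full[order(-res$full$stat, -res$full$n_tips, res$full$node), ]
    desc <- ape::prop.part(tree)
    ntip <- length(tree$tip.label)
    chosen <- list(); keep <- integer(0)
    for (r in seq_len(nrow(full))) {
      ts <- desc[[full$node[r] - ntip]]
      nested <- any(vapply(chosen, function(o) {
        all(ts %in% o) || all(o %in% ts)
      }, logical(1)))
      if (!nested) { chosen <- c(chosen, list(ts)); keep <- c(keep, r) }
    }
    expect_equal(res$selected$node, full$node[keep])
  }
})
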