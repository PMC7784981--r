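ph4 <- toy_phenotypes(letters[1:4],
                      c("resistant", "resistant", "permissive", "permissive"))
ph6 <- toy_phenotypes(c("r1", "r2", "n1", "n2", "p1", "p2"),
                      rep(c("resistant", "nonpermissive", "permissive"),
                          each = 2))

test_that("Newick parsing attaches groups and preserves polytomies", {
  t1 <- parse_labeled_tree("((a,b),(c,d));", ph4)
  expect_identical(sort(t1$tree$tip.label), letters[1:4])
  expect_identical(t1$tree$Nnode, 3L)
  expect_identical(unname(t1$groups[c("a", "d")]),
                   c("resistant", "permissive"))
  star <- parse_labeled_tree("(a,b,c,d);", ph4)
  expect_identical(star$tree$Nnode, 1L)
  expect_error(parse_labeled_tree("((a,b),(c,x));", ph4),
               class = "panphen_lookup_error", regexp = "x")
  expect_error(parse_labeled_tree("((a,b),(c,d)", ph4),
               class = "panphen_format_error")
})

test_that("split compatibility handles binary trees and polytomies", {
  t1 <- parse_labeled_tree("((a,b),(c,d));", ph4)
  expect_true(split_compatible(t1, c("a", "b")))
  expect_false(split_compatible(
    parse_labeled_tree("((a,c),(b,d));", ph4), c("a", "b")))
  # a star can always be resolved to display any split
  expect_true(split_compatible(parse_labeled_tree("(a,b,c,d);", ph4),
                               c("a", "b")))
  expect_error(split_compatible(t1, letters[1:4]),
               class = "panphen_argument_error")
  expect_error(split_compatible(t1, character(0)),
               class = "panphen_argument_error")
})

test_that("split compatibility is symmetric in the bipartition", {
  set.seed(5)
  tips <- paste0("t", 1:7)
  phx <- toy_phenotypes(tips, rep("permissive", 7))
  for (i in 1:40) {
    tree <- random_polytomous_tree(tips)
    t <- parse_labeled_tree(tree, phx)
    taxa <- sample(tips, sample(1:6, 1))
    expect_identical(split_compatible(t, taxa),
                     split_compatible(t, setdiff(tips, taxa)))
  }
})

test_that("split compatibility agrees with refinement enumeration", {
  set.seed(8)
  phx <- toy_phenotypes(paste0("t", 1:8), rep("permissive", 8))
  for (i in 1:60) {
    n <- sample(4:7, 1)
    tips <- paste0("t", 1:n)
    tree <- random_polytomous_tree(tips)
    t <- parse_labeled_tree(tree, phx)
    taxa <- sample(tips, sample(seq_len(n - 1), 1))
    expect_identical(split_compatible(t, taxa),
                     oracle_split_compatible(tree, taxa),
                     label = paste("instance", i))
  }
})

test_that("constraint matching reproduces the reference cases", {
  t_sister <- parse_labeled_tree("(((r1,r2),(n1,n2)),(p1,p2));", ph6)
  expect_true(matches_constraint(t_sister, "R_SISTER_NP"))
  expect_true(matches_constraint(t_sister, "ALL_MONO"))

  t_mono <- parse_labeled_tree("((r1,r2),((n1,n2),(p1,p2)));", ph6)
  expect_true(matches_constraint(t_mono, "ALL_MONO"))
  expect_false(matches_constraint(t_mono, "R_SISTER_NP"))

  t_none <- parse_labeled_tree("((r1,n1),(r2,p1),(n2,p2));", ph6)
  expect_false(matches_constraint(t_none, "ALL_MONO"))
  expect_false(matches_constraint(t_none, "R_SISTER_NP"))
  expect_false(oracle_matches(t_none$tree, t_none$groups, "ALL_MONO"))

  ph2 <- toy_phenotypes(c("p1", "p2", "n1", "n2"),
                        c("permissive", "permissive",
                          "nonpermissive", "nonpermissive"))
  expect_true(matches_constraint(
    parse_labeled_tree("((p1,p2),(n1,n2));", ph2), "P_NP_SPLIT"))
  expect_false(matches_constraint(
    parse_labeled_tree("((p1,n1),(p2,n2));", ph2), "P_NP_SPLIT"))
  expect_error(matches_constraint(
    parse_labeled_tree("((p1,p2),(n1,n2));", ph2), "ALL_MONO"),
    class = "panphen_argument_error")
})

test_that("constraint matching agrees with refinement enumeration", {
  set.seed(12)
  n_checked <- 0
  for (i in 1:120) {
    n <- sample(5:7, 1)
    tips <- paste0("t", 1:n)
    groups <- sample(c("resistant", "nonpermissive", "permissive"), n,
                     replace = TRUE)
    if (length(unique(groups)) < 3) next
    phx <- toy_phenotypes(tips, groups)
    tree <- random_polytomous_tree(tips)
    t <- parse_labeled_tree(tree, phx)
    for (con in c("ALL_MONO", "R_SISTER_NP")) {
      expect_identical(matches_constraint(t, con),
                       oracle_matches(tree, t$groups, con),
                       label = paste(con, "instance", i))
    }
    expect_true(!matches_constraint(t, "R_SISTER_NP") ||
                  matches_constraint(t, "ALL_MONO"))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 60)
})

test_that("star trees match every applicable constraint", {
  star3 <- parse_labeled_tree("(r1,r2,n1,n2,p1,p2);", ph6)
  expect_true(matches_constraint(star3, "ALL_MONO"))
  expect_true(matches_constraint(star3, "R_SISTER_NP"))
  scr <- screen_trees(list(star3))
  expect_identical(tidy(scr)$matched, "R_SISTER_NP")
  expect_identical(tidy(scr)$n_internal_edges, 0L)
})

test_that("screening classifies most-specific-first and recovers planted trees", {
  gt <- simulate_gene_trees(tree_sim_config(n_trees = 50,
                                            concordant_fraction = 0.2,
                                            seed = 17))
  scr <- screen_trees(gt$trees)
  res <- tidy(scr)
  planted <- gt$truth$cluster_id[gt$truth$concordant]
  expect_true(all(res$matched[res$cluster_id %in% planted] == "R_SISTER_NP"))
  g <- glance(scr)
  expect_identical(g$n_trees, 50L)
  expect_gte(g$R_SISTER_NP, length(planted))
})

test_that("ALL_MONO is invariant under permuting the group labels", {
  set.seed(23)
  for (i in 1:25) {
    tips <- paste0("t", 1:6)
    groups <- c("resistant", "resistant", "nonpermissive", "nonpermissive",
                "permissive", "permissive")
    tree <- random_polytomous_tree(tips)
    t0 <- parse_labeled_tree(tree, toy_phenotypes(tips, groups))
    perm <- sample(c("resistant", "nonpermissive", "permissive"))
    t1 <- parse_labeled_tree(tree, toy_phenotypes(
      tips, perm[match(groups, c("resistant", "nonpermissive",
                                 "permissive"))]))
    expect_identical(matches_constraint(t0, "ALL_MONO"),
                     matches_constraint(t1, "ALL_MONO"))
  }
})

test_that("non-single-copy clusters are skipped with a warning", {
  counts <- matrix(c(2L, 1L, 1L, 1L), 2, 2,
                   dimnames = list(c("a", "b"), c("cX", "cY")))
  m <- gene_cluster_matrix(counts)
  phab <- toy_phenotypes(c("a", "b"), c("permissive", "nonpermissive"))
  t_bad <- parse_labeled_tree("(a,b);", phab, cluster_id = "cX")
  t_ok <- parse_labeled_tree("(a,b);", phab, cluster_id = "cY")
  expect_warning(scr <- screen_trees(list(t_bad, t_ok), m = m),
                 regexp = "not single-copy")
  expect_identical(tidy(scr)$cluster_id, "cY")
})

test_that("empty collections screen to an empty report with a warning", {
  expect_warning(scr <- screen_trees(list()), regexp = "Empty")
  expect_identical(nrow(tidy(scr)), 0L)
})
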