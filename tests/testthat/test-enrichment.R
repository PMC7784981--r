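# The published enrichment table for the 23-genome pangenome (groups of
# 10 resistant / 3 nonpermissive / 10 permissive) is the package's anchor:
# feeding each row's observation fractions to the score must reproduce the
# printed score to printed precision.
published_scores <- c(
  mur_ligase = 23, acyl_coa_dehydrogenase = 13.78,
  glcnac_pi_deacetylase = 13.48, butirosin_biosynthesis_h = 13.08,
  phage_terminase_small = 16.74, sam_synthetase_n = 14.6,
  duf4391 = 12.42, pectate_lyase = 10.03, hsdm_n_terminal = 9.19,
  rmuc_family = 15.68, ctp_synthase = 11.98, tpm_domain = 10.55)

test_that("published observation fractions reproduce the printed scores", {
  obs <- score_observations()
  for (nm in names(published_scores)) {
    got <- obs$score[obs$slug == nm]
    expect_equal(round(got, nchar(sub("^[0-9]+\\.?", "", published_scores[[nm]]))),
                 published_scores[[nm]], tolerance = 1e-9,
                 label = paste("score for", nm))
  }
  # every perfect-association row attains the genome count
  perfect <- obs$score[obs$section %in% c("resistant", "susceptible")]
  expect_true(all(abs(perfect - 23) < 1e-12))
})

test_that("enrichment score is the Pearson chi-square on the 2 x G table", {
  expect_equal(enrichment_score(c(10, 0, 0), c(10, 3, 10)), 23)
  expect_equal(round(enrichment_score(c(2, 1, 10), c(10, 3, 10)), 2), 13.78)
  expect_equal(round(enrichment_score(c(1, 3, 0), c(10, 3, 10)), 2), 16.74)
  expect_identical(enrichment_score(c(10, 3, 10), c(10, 3, 10)), 0)
  expect_identical(enrichment_score(c(0, 0, 0), c(10, 3, 10)), 0)
})

test_that("score agrees with the observed/expected loop on random tables", {
  set.seed(101)
  for (i in 1:1000) {
    g <- sample(2:4, 1)
    nt <- sample(1:12, g, replace = TRUE)
    np <- vapply(nt, function(n) sample(0:n, 1), integer(1))
    got <- enrichment_score(np, nt)
    expect_equal(got, oracle_chisq(np, nt), tolerance = 1e-10)
    # and with the textbook test where it is defined
    if (sum(np) > 0 && sum(np) < sum(nt)) {
      tab <- rbind(np, nt - np)
      ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      expect_equal(got, unname(ref$statistic), tolerance = 1e-10)
    }
  }
})

test_that("score is maximal iff presence coincides with a group boundary", {
  set.seed(55)
  nt <- c(10, 3, 10)
  n <- sum(nt)
  for (i in 1:200) {
    np <- vapply(nt, function(k) sample(0:k, 1), integer(1))
    s <- enrichment_score(np, nt)
    expect_lte(s, n + 1e-9)
    boundary <- all(np == 0 | np == nt) && sum(np) > 0 && sum(np) < n
    expect_identical(abs(s - n) < 1e-9, boundary)
  }
})

test_that("score is invariant under group reordering", {
  set.seed(77)
  for (i in 1:50) {
    nt <- sample(1:10, 3, replace = TRUE)
    np <- vapply(nt, function(n) sample(0:n, 1), integer(1))
    perm <- sample(3)
    expect_equal(enrichment_score(np, nt),
                 enrichment_score(np[perm], nt[perm]))
  }
})

test_that("score argument errors", {
  expect_error(enrichment_score(1, 2), class = "panphen_argument_error")
  expect_error(enrichment_score(c(1, 0), c(2, 0)),
               class = "panphen_argument_error")
  expect_error(enrichment_score(c(3, 0), c(2, 2)),
               class = "panphen_argument_error")
})

test_that("p-values are the chi-square upper tail", {
  expect_identical(enrichment_pvalue(0, 3), 1)
  # df = 2 has the closed-form tail exp(-x/2)
  expect_equal(enrichment_pvalue(23, 3), exp(-11.5), tolerance = 1e-12)
  dens <- function(x) stats::dchisq(x, df = 2)
  num <- stats::integrate(dens, 13.78, Inf)$value
  expect_equal(enrichment_pvalue(13.78, 3), num, tolerance = 1e-5)
  expect_error(enrichment_pvalue(1, 1), class = "panphen_argument_error")
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), class = "panphen_argument_error")
  set.seed(202)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))^2
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone along sorted p
  }
})

test_that("associated groups use the inclusive majority rule", {
  expect_identical(
    associated_groups(c(resistant = 1, nonpermissive = 0, permissive = 0)),
    "resistant")
  expect_identical(
    associated_groups(c(resistant = 0.9, nonpermissive = 1,
                        permissive = 0.1)),
    c("resistant", "nonpermissive"))
  # boundary: exactly half counts as associated
  expect_identical(
    associated_groups(c(resistant = 0.5, nonpermissive = 1, permissive = 0)),
    c("resistant", "nonpermissive"))
  expect_length(associated_groups(c(a = 0.2, b = 0.4)), 0)
})

test_that("a genome has a function if any annotated cluster carries it", {
  counts <- matrix(c(1L, 0L, 0L, 1L, 1L, 1L), 2, 3,
                   dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  fns <- tibble::tibble(gene_cluster_id = c("c1", "c2"),
                        accession = c("PF1", "PF1"),
                        annotation = c("fn one", "fn one"))
  m <- gene_cluster_matrix(counts, fns)
  ph <- toy_phenotypes(c("g1", "g2"), c("resistant", "permissive"))
  prof <- function_presence(m, ph)
  # g2 lacks c1 but carries c2, so it has PF1; unannotated c3 contributes
  # to no profile
  expect_identical(nrow(prof), 2L)
  expect_identical(prof$n_present, c(1L, 1L))
  no_ann <- gene_cluster_matrix(counts)
  expect_warning(empty <- function_presence(no_ann, ph),
                 regexp = "No functional annotations")
  expect_identical(nrow(empty), 0L)
})

test_that("a planted group-exclusive function ranks first with maximal score", {
  sim <- simulate_pangenome(pangenome_sim_config(
    n_core = 30, n_exclusive = c(resistant = 1), n_noise = 150,
    theta = 0.4, multi_copy_prob = 0, seed = 9))
  enr <- run_enrichment(sim$matrix, sim$phenotypes)
  rec <- tidy(enr)
  planted <- sim$truth$accession[sim$truth$target == "resistant"]
  expect_identical(rec$accession[1], planted)
  expect_equal(rec$score[1], 23)
  expect_identical(rec$associated_groups[1], "resistant")
  expect_true(all(diff(rec$score) <= 1e-12))
  g <- glance(enr)
  expect_identical(g$n_genomes, 23L)
  expect_identical(g$n_groups, 3L)
})

test_that("enrichment is invariant to relabeling genomes within groups", {
  sim <- simulate_pangenome(pangenome_sim_config(
    n_core = 10, n_exclusive = c(susceptible = 3), n_noise = 80,
    theta = 0.3, seed = 21))
  m <- sim$matrix
  ph <- sim$phenotypes
  # swap the repertoires of two genomes in the same group: same data under
  # permuted within-group labels
  counts3 <- m$counts
  perm_rows <- counts3[c("P01", "P02"), ]
  counts3["P01", ] <- perm_rows["P02", ]
  counts3["P02", ] <- perm_rows["P01", ]
  m3 <- gene_cluster_matrix(counts3, m$functions)
  r1 <- tidy(run_enrichment(m, ph))
  r3 <- tidy(run_enrichment(m3, ph))
  expect_equal(r1, r3)
})

test_that("null pangenomes yield almost no q < 0.05 calls", {
  sim <- simulate_pangenome(pangenome_sim_config(
    n_core = 0, n_exclusive = c(resistant = 0), n_noise = 600,
    theta = 0.5, annotation_rate = 1, seed = 3))
  rec <- tidy(run_enrichment(sim$matrix, sim$phenotypes))
  expect_lt(mean(rec$q_value < 0.05), 0.01)
})

test_that("q-values are computed over the full universe and order is stable", {
  sim <- simulate_pangenome(pangenome_sim_config(
    n_core = 5, n_exclusive = c(resistant = 2, susceptible = 2),
    n_noise = 60, theta = 0.3, seed = 4))
  enr <- run_enrichment(sim$matrix, sim$phenotypes)
  rec <- tidy(enr)
  expect_equal(rec$q_value, bh_fdr(rec$p_value), tolerance = 1e-12)
  expect_true(all(rec$q_value >= rec$p_value - 1e-12))
  ties <- rec[rec$score == 23, ]
  expect_identical(ties$accession, sort(ties$accession))
  top <- tidy(run_enrichment(sim$matrix, sim$phenotypes, top_n = 3))
  expect_identical(nrow(top), 3L)
  expect_identical(top$accession, rec$accession[1:3])
})
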