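# Independent oracles used to cross-check the package's algorithms.
# These deliberately re-derive every quantity with the most literal method
# available (explicit loops, exhaustive enumeration) and never call the
# package functions they check.

# ---- set algebra ----------------------------------------------------------

oracle_core <- function(counts, genome_set) {
  out <- character(0)
  for (cl in colnames(counts)) {
    ok <- TRUE
    for (g in genome_set) if (counts[g, cl] < 1) ok <- FALSE
    if (ok) out <- c(out, cl)
  }
  sort(out)
}

oracle_exclusive <- function(counts, in_group, out_group) {
  out <- character(0)
  for (cl in colnames(counts)) {
    ok <- TRUE
    for (g in in_group) if (counts[g, cl] < 1) ok <- FALSE
    for (g in out_group) if (counts[g, cl] != 0) ok <- FALSE
    if (ok) out <- c(out, cl)
  }
  sort(out)
}

oracle_single_copy <- function(counts, genome_set) {
  out <- character(0)
  for (cl in colnames(counts)) {
    ok <- TRUE
    for (g in genome_set) if (counts[g, cl] != 1) ok <- FALSE
    if (ok) out <- c(out, cl)
  }
  sort(out)
}

random_count_matrix <- function(n_genomes, n_clusters, max_count = 3) {
  m <- matrix(sample(0:max_count, n_genomes * n_clusters, replace = TRUE,
                     prob = c(0.35, rep(0.65 / max_count, max_count))),
              n_genomes, n_clusters,
              dimnames = list(sprintf("g%02d", seq_len(n_genomes)),
                              sprintf("c%03d", seq_len(n_clusters))))
  empty <- which(colSums(m) == 0)
  m[cbind(sample.int(n_genomes, length(empty), replace = TRUE), empty)] <- 1L
  storage.mode(m) <- "integer"
  m
}

# ---- chi-square -----------------------------------------------------------

# textbook sum over observed/expected cells of the 2 x G table
oracle_chisq <- function(n_present, n_total) {
  O <- rbind(present = n_present, absent = n_total - n_present)
  if (sum(O["present", ]) == 0 || sum(O["absent", ]) == 0) return(0)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  total <- 0
  for (i in 1:2) for (j in seq_along(n_total)) {
    total <- total + (O[i, j] - E[i, j])^2 / E[i, j]
  }
  unname(total)
}

# hand-executed Benjamini-Hochberg step-up rule
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    val <- Inf
    for (j in i:m) val <- min(val, p[ord[j]] * m / j)
    q[ord[i]] <- min(1, val)
  }
  q
}

# ---- tree refinement enumeration ------------------------------------------

# bitmask helpers (tips indexed 1..n, n <= 9)
mask_of <- function(idx) sum(2^(idx - 1))
popcount <- function(mask) sum(bitwAnd(mask, 2^(0:9)) > 0)

# non-trivial unrooted splits of a tree, as bitmasks over `labels` order,
# normalised to exclude tip 1
tree_split_masks <- function(tree, labels) {
  n <- length(labels)
  full <- mask_of(seq_len(n))
  tipmask <- setNames(2^(match(tree$tip.label, labels) - 1), tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")$edge
  node_mask <- numeric(length(tree$tip.label) + tree$Nnode)
  node_mask[seq_along(tree$tip.label)] <- tipmask[tree$tip.label]
  for (k in seq_len(nrow(post))) {
    node_mask[post[k, 1]] <- node_mask[post[k, 1]] + node_mask[post[k, 2]]
  }
  masks <- node_mask[tree$edge[, 2]]
  masks <- vapply(masks, function(mk) {
    if (bitwAnd(mk, 1) == 1) full - mk else mk
  }, numeric(1))
  masks <- masks[vapply(masks, popcount, numeric(1)) >= 2 &
                   vapply(masks, function(mk) popcount(full - mk), numeric(1)) >= 2]
  unique(masks)
}

normalise_mask <- function(mask, n) {
  full <- mask_of(seq_len(n))
  if (bitwAnd(mask, 1) == 1) full - mask else mask
}

is_trivial_mask <- function(mask, n) {
  k <- popcount(normalise_mask(mask, n))
  k <= 1 || k >= n - 1
}

# cache of all binary unrooted topologies per leaf count, as split-mask sets
.oracle_tree_cache <- new.env(parent = emptyenv())

all_binary_split_sets <- function(n) {
  key <- as.character(n)
  if (!is.null(.oracle_tree_cache[[key]])) return(.oracle_tree_cache[[key]])
  labels <- paste0("t", seq_len(n))
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = labels)
  sets <- lapply(trees, tree_split_masks, labels = labels)
  .oracle_tree_cache[[key]] <- sets
  sets
}

# TRUE iff some binary refinement of `tree` displays every mask in
# `required_masks` (all masks over sorted(tree$tip.label) indexing)
oracle_refinement_displays <- function(tree, required_masks) {
  labels <- sort(tree$tip.label)
  n <- length(labels)
  t_masks <- tree_split_masks(tree, labels)
  req <- vapply(required_masks, normalise_mask, numeric(1), n = n)
  req <- req[!vapply(req, is_trivial_mask, logical(1), n = n)]
  if (length(req) == 0 && length(t_masks) == 0) return(TRUE)
  for (cand in all_binary_split_sets(n)) {
    if (all(t_masks %in% cand) && all(req %in% cand)) return(TRUE)
  }
  FALSE
}

oracle_split_compatible <- function(tree, taxa) {
  labels <- sort(tree$tip.label)
  oracle_refinement_displays(tree, mask_of(match(taxa, labels)))
}

# attach a pseudo-leaf at the root so rooted monophyly questions become
# unrooted split questions
augment_with_root_tip <- function(tree) {
  nwk <- ape::write.tree(tree)
  core <- sub(";$", "", nwk)
  ape::read.tree(text = paste0("(", core, ",ZZROOT);"))
}

# exhaustive check of the rooted constraint semantics
oracle_matches <- function(tree, groups, constraint) {
  leaves_of <- function(g) names(groups)[groups == g]
  if (constraint == "P_NP_SPLIT") {
    return(oracle_split_compatible(tree, leaves_of("permissive")))
  }
  aug <- augment_with_root_tip(tree)
  labels <- sort(aug$tip.label)
  need <- list(leaves_of("resistant"), leaves_of("permissive"),
               leaves_of("nonpermissive"))
  if (constraint == "R_SISTER_NP") {
    need <- c(need, list(c(leaves_of("resistant"), leaves_of("nonpermissive"))))
  }
  masks <- vapply(need, function(tp) mask_of(match(tp, labels)), numeric(1))
  oracle_refinement_displays(aug, masks)
}

# random rooted tree with polytomies over given tips
random_polytomous_tree <- function(tips, collapse_prob = 0.4) {
  tree <- ape::rtree(length(tips), tip.label = sample(tips))
  internal <- which(tree$edge[, 2] > length(tips))
  hit <- internal[runif(length(internal)) < collapse_prob]
  if (length(hit) > 0) {
    tree$edge.length[hit] <- 0
    tree <- ape::di2multi(tree, tol = 1e-12)
  }
  tree
}

# ---- misc ----------------------------------------------------------------

toy_matrix <- function() {
  gene_cluster_matrix(
    matrix(c(1L, 1L, 1L, 1L, 2L, 0L), nrow = 2, byrow = TRUE,
           dimnames = list(c("g1", "g2"), c("c1", "c2", "c3"))))
}

toy_phenotypes <- function(genomes, groups) {
  phenotype_map(tibble::tibble(genome_name = genomes, group = groups))
}
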