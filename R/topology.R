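#' Topology constraints for gene-tree screening
#'
#' Three constraint topologies relate sequence variants of a core gene to the
#' host-phenotype groups:
#'
#' * `ALL_MONO` (three-group trees): every phenotype group can be made
#'   monophyletic, with the relationships among the three clades left free.
#' * `R_SISTER_NP` (three-group trees): `ALL_MONO`, and additionally the
#'   resistant and nonpermissive clades are sisters (their union can be made
#'   monophyletic on the same rooted tree).
#' * `P_NP_SPLIT` (two-group trees over the susceptible genomes): some edge
#'   of a refinement separates the permissive from the nonpermissive leaves.
#'
#' Polytomies are read as unspecified hierarchy: a constraint is satisfied if
#' *some* resolution of the polytomies displays the required clades, so
#' under-resolved trees (including star trees) match permissively.
#'
#' @export
topology_constraints <- c("R_SISTER_NP", "ALL_MONO", "P_NP_SPLIT")

#' Parse a Newick gene tree and attach phenotype groups to its leaves
#'
#' @param newick Newick string (or an `ape::phylo` object).
#' @param ph A [phenotype_map()]; every leaf name must be labeled.
#' @param cluster_id Optional gene-cluster id carried along for reporting.
#' @return An object of class `labeled_gene_tree`: list with `cluster_id`,
#'   `tree` (an `ape::phylo`, polytomies preserved, rooted as parsed), and
#'   `groups` (named character vector, leaf -> group).
#' @export
parse_labeled_tree <- function(newick, ph, cluster_id = NA_character_) {
  if (inherits(newick, "phylo")) {
    tree <- newick
  } else {
    tree <- tryCatch(
      ape::read.tree(text = newick),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(tree)) {
      abort("Unparseable Newick string.", class = "panphen_format_error")
    }
  }
  unlabeled <- setdiff(tree$tip.label, ph$genome_name)
  if (length(unlabeled) > 0) {
    abort(paste0("Leaf/leaves with no phenotype label: ",
                 paste(unlabeled, collapse = ", ")),
          class = "panphen_lookup_error")
  }
  groups <- setNames(ph$group[match(tree$tip.label, ph$genome_name)],
                     tree$tip.label)
  structure(list(cluster_id = cluster_id, tree = tree, groups = groups),
            class = "labeled_gene_tree")
}

#' @export
print.labeled_gene_tree <- function(x, ...) {
  cat("<labeled_gene_tree> cluster ", x$cluster_id, ": ",
      length(x$tree$tip.label), " leaves (",
      paste(names(table(x$groups)), table(x$groups),
            sep = "=", collapse = ", "),
      "), ", n_internal_edges(x$tree), " internal edges\n", sep = "")
  invisible(x)
}

n_internal_edges <- function(tree) {
  sum(tree$edge[, 2] > length(tree$tip.label))
}

# For each edge of the (arbitrarily rooted) tree, the set of tips below it,
# as a list of logical vectors over tip indices, in postorder.
edge_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  below <- matrix(FALSE, nrow = nnode, ncol = ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  post <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(post))) {
    below[post[k, 1], ] <- below[post[k, 1], ] | below[post[k, 2], ]
  }
  below
}

#' Can a tree be refined to display a split?
#'
#' Tests whether the bipartition `taxa | complement` is compatible with the
#' tree read as *unrooted*: whether some resolution of its polytomies has an
#' edge whose removal separates `taxa` from the remaining leaves.
#' Equivalently, the minimal connecting subtree of `taxa` and that of its
#' complement share at most one vertex (no edge lies in both). On fully
#' binary trees this reduces to exact edge display.
#'
#' @param t A [parse_labeled_tree()] result, or an `ape::phylo`.
#' @param taxa Character vector of leaf names; must be a nonempty proper
#'   subset of the leaves.
#' @return Logical scalar.
#' @export
#' @examples
#' ph <- phenotype_map(data.frame(
#'   genome_name = letters[1:4],
#'   group = c("resistant", "resistant", "permissive", "permissive")))
#' t1 <- parse_labeled_tree("((a,b),(c,d));", ph)
#' split_compatible(t1, c("a", "b"))  # TRUE
#' split_compatible(t1, c("a", "c"))  # FALSE
#' split_compatible(parse_labeled_tree("(a,b,c,d);", ph), c("a", "b")) # TRUE
split_compatible <- function(t, taxa) {
  tree <- if (inherits(t, "labeled_gene_tree")) t$tree else t
  tips <- tree$tip.label
  if (length(taxa) == 0 || !all(taxa %in% tips) || length(taxa) >= length(tips)) {
    abort("`taxa` must be a nonempty proper subset of the leaves.",
          class = "panphen_argument_error")
  }
  in_s <- tips %in% taxa
  below <- edge_tip_sets(tree)
  # an edge lies on the Steiner subtree of S iff S has leaves on both of its
  # sides; compatibility fails iff some edge carries both S and its
  # complement on both sides
  for (k in seq_len(nrow(tree$edge))) {
    b <- below[tree$edge[k, 2], ]
    s_below <- sum(in_s & b); s_above <- sum(in_s) - s_below
    c_below <- sum(!in_s & b); c_above <- sum(!in_s) - c_below
    if (s_below > 0 && s_above > 0 && c_below > 0 && c_above > 0) {
      return(FALSE)
    }
  }
  TRUE
}

# On a rooted tree with polytomies, the leaf set `tips_in` can be made
# monophyletic by some resolution iff every child subtree of its MRCA lies
# entirely inside or entirely outside the set (refinement can then group the
# inside children under a new node).
can_be_monophyletic <- function(tree, tips_in) {
  tips <- tree$tip.label
  if (length(tips_in) <= 1 || length(tips_in) >= length(tips)) return(TRUE)
  below <- edge_tip_sets(tree)
  target <- tips %in% tips_in
  # MRCA: smallest node whose below-set contains all of tips_in
  covers_all <- rowSums(below[, target, drop = FALSE]) == sum(target)
  sizes <- rowSums(below)
  mrca <- which(covers_all)[which.min(sizes[covers_all])]
  children <- tree$edge[tree$edge[, 1] == mrca, 2]
  for (ch in children) {
    n_in <- sum(below[ch, ] & target)
    if (n_in > 0 && n_in < sum(below[ch, ])) return(FALSE)
  }
  TRUE
}

root_tree <- function(tree, rooting = c("as-parsed", "midpoint", "outgroup"),
                      outgroup = NULL) {
  rooting <- match.arg(rooting)
  switch(rooting,
    "as-parsed" = tree,
    "midpoint" = phangorn::midpoint(tree),
    "outgroup" = {
      if (is.null(outgroup)) {
        abort("`outgroup` required for outgroup rooting.",
              class = "panphen_argument_error")
      }
      ape::root(tree, outgroup = outgroup, resolve.root = FALSE)
    })
}

#' Does a gene tree match a constraint topology?
#'
#' `P_NP_SPLIT` is evaluated on the unrooted tree via [split_compatible()]
#' for the permissive (equivalently nonpermissive) leaf set. `ALL_MONO` and
#' `R_SISTER_NP` are evaluated on the rooted tree under the chosen rooting:
#' `ALL_MONO` requires that each group's leaf set can be made monophyletic by
#' some resolution of the polytomies, and `R_SISTER_NP` additionally requires
#' the resistant + nonpermissive union to be simultaneously monophyletic.
#' The groups' clusters are pairwise disjoint or nested, so per-set
#' refinements at each set's MRCA compose into a single resolution displaying
#' all of them; this is cross-checked against exhaustive enumeration of
#' binary refinements in the package's test battery.
#'
#' @param t A [parse_labeled_tree()] result.
#' @param constraint One of `"ALL_MONO"`, `"R_SISTER_NP"`, `"P_NP_SPLIT"`.
#' @param rooting `"as-parsed"` (default: the orientation the tree file
#'   records), `"midpoint"`, or `"outgroup"`.
#' @param outgroup Leaf name(s) for `rooting = "outgroup"`.
#' @return Logical scalar.
#' @export
matches_constraint <- function(t, constraint = topology_constraints,
                               rooting = c("as-parsed", "midpoint", "outgroup"),
                               outgroup = NULL) {
  constraint <- match.arg(constraint)
  rooting <- match.arg(rooting)
  stopifnot(inherits(t, "labeled_gene_tree"))
  present <- unique(unname(t$groups))
  needed <- switch(constraint,
    P_NP_SPLIT = c("permissive", "nonpermissive"),
    c("resistant", "permissive", "nonpermissive"))
  if (!all(needed %in% present)) {
    abort(paste0("Constraint ", constraint, " references group(s) absent ",
                 "from the tree: ",
                 paste(setdiff(needed, present), collapse = ", ")),
          class = "panphen_argument_error")
  }
  leaves_of <- function(g) names(t$groups)[t$groups == g]
  if (constraint == "P_NP_SPLIT") {
    perm <- leaves_of("permissive")
    if (length(perm) == length(t$tree$tip.label)) return(TRUE)
    return(split_compatible(t, perm))
  }
  tree <- root_tree(t$tree, rooting, outgroup)
  mono_all <- all(vapply(c("resistant", "permissive", "nonpermissive"),
                         function(g) can_be_monophyletic(tree, leaves_of(g)),
                         logical(1)))
  if (constraint == "ALL_MONO") return(mono_all)
  mono_all && can_be_monophyletic(
    tree, c(leaves_of("resistant"), leaves_of("nonpermissive")))
}

#' Screen gene trees for phenotype-separating topologies
#'
#' Classifies each single-copy-core gene tree against the constraint
#' topologies applicable to its groups: three-group trees are tested for
#' `R_SISTER_NP` first and then `ALL_MONO` (most specific wins), two-group
#' permissive/nonpermissive trees for `P_NP_SPLIT`. Trees whose cluster is
#' not single-copy in the genomes its leaves span are skipped with a warning
#' when a matrix is supplied. Matched results carry the cluster's functional
#' annotations and the number of internal edges, so downstream users can
#' filter under-resolved (trivially matching) trees.
#'
#' @param trees List of [parse_labeled_tree()] results.
#' @param m Optional [gene_cluster_matrix()] used to verify the single-copy
#'   precondition and to attach functions.
#' @inheritParams matches_constraint
#' @return An object of class `panphen_screen`; [tidy()] returns one row per
#'   tree (`cluster_id`, `n_leaves`, `n_internal_edges`, `matched`,
#'   `functions`), [glance()] the per-constraint counts.
#' @export
screen_trees <- function(trees, m = NULL,
                         rooting = c("as-parsed", "midpoint", "outgroup"),
                         outgroup = NULL) {
  rooting <- match.arg(rooting)
  if (length(trees) == 0) {
    warn("Empty tree collection; nothing to screen.")
  }
  rows <- purrr::map_dfr(trees, function(t) {
    stopifnot(inherits(t, "labeled_gene_tree"))
    leaves <- t$tree$tip.label
    if (!is.null(m) && !is.na(t$cluster_id) &&
        t$cluster_id %in% m$clusters) {
      counts <- m$counts[intersect(leaves, m$genomes), t$cluster_id]
      if (length(counts) < length(leaves) || any(counts != 1L)) {
        warn(paste0("Cluster ", t$cluster_id,
                    " is not single-copy across its leaf genomes; skipped."))
        return(NULL)
      }
    }
    present <- unique(unname(t$groups))
    matched <- "none"
    if (all(c("resistant", "permissive", "nonpermissive") %in% present)) {
      if (matches_constraint(t, "R_SISTER_NP", rooting, outgroup)) {
        matched <- "R_SISTER_NP"
      } else if (matches_constraint(t, "ALL_MONO", rooting, outgroup)) {
        matched <- "ALL_MONO"
      }
    } else if (setequal(present, c("permissive", "nonpermissive"))) {
      if (matches_constraint(t, "P_NP_SPLIT", rooting, outgroup)) {
        matched <- "P_NP_SPLIT"
      }
    }
    fns <- if (!is.null(m)) {
      sub <- m$functions[m$functions$gene_cluster_id %in% t$cluster_id, ]
      paste(stats::na.omit(unique(sub$annotation)), collapse = "; ")
    } else ""
    tibble(cluster_id = t$cluster_id,
           n_leaves = length(leaves),
           n_internal_edges = n_internal_edges(t$tree),
           matched = matched,
           functions = fns)
  })
  if (is.null(rows) || nrow(rows) == 0) {
    rows <- tibble(cluster_id = character(), n_leaves = integer(),
                   n_internal_edges = integer(), matched = character(),
                   functions = character())
  }
  structure(list(results = rows, rooting = rooting),
            class = "panphen_screen")
}

#' @export
print.panphen_screen <- function(x, ...) {
  cat("<panphen_screen> ", nrow(x$results), " trees screened (rooting: ",
      x$rooting, ")\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @rdname screen_trees
#' @param x A `panphen_screen` object.
#' @param ... Unused.
#' @method tidy panphen_screen
#' @export
tidy.panphen_screen <- function(x, ...) x$results

#' @rdname screen_trees
#' @method glance panphen_screen
#' @export
glance.panphen_screen <- function(x, ...) {
  counts <- table(factor(x$results$matched,
                         levels = c(topology_constraints, "none")))
  out <- as_tibble(as.list(counts))
  out$n_trees <- nrow(x$results)
  out
}
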