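#' Gene-cluster copy-count matrix
#'
#' A `gene_cluster_matrix` holds the genomes-by-clusters copy-count matrix of
#' a pangenome together with the functional annotations attached to each gene
#' cluster. Counts record how many genes of a cluster each genome carries;
#' presence/absence views collapse these to `count >= 1`.
#'
#' @param counts Integer matrix, genomes in rows, gene clusters in columns.
#'   Row and column names are required and must be unique. Every count must be
#'   a non-negative integer and every cluster must be present in at least one
#'   genome.
#' @param functions Tibble with columns `gene_cluster_id`, `accession`,
#'   `annotation` mapping clusters to zero or more functions. May be empty.
#'
#' @return An object of class `gene_cluster_matrix` with fields `genomes`,
#'   `clusters`, `counts`, and `functions`.
#' @export
#' @examples
#' m <- gene_cluster_matrix(
#'   matrix(c(1L, 1L, 1L, 2L, 1L, 0L), nrow = 2, byrow = TRUE,
#'          dimnames = list(c("g1", "g2"), c("c1", "c2", "c3"))))
#' m
gene_cluster_matrix <- function(counts, functions = empty_functions()) {
  if (!is.matrix(counts)) {
    abort("`counts` must be a matrix.", class = "panphen_argument_error")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have genome row names and cluster column names.",
          class = "panphen_argument_error")
  }
  if (anyDuplicated(rownames(counts))) {
    abort("Genome names must be unique.", class = "panphen_format_error")
  }
  if (anyDuplicated(colnames(counts))) {
    abort("Gene-cluster ids must be unique.", class = "panphen_format_error")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Counts must be non-negative integers.",
          class = "panphen_format_error")
  }
  empty <- colSums(counts >= 1) == 0
  if (any(empty)) {
    abort(
      paste0("Clusters with no member genome: ",
             paste(head(colnames(counts)[empty], 5), collapse = ", ")),
      class = "panphen_format_error")
  }
  storage.mode(counts) <- "integer"
  functions <- as_tibble(functions)
  stopifnot(all(c("gene_cluster_id", "accession", "annotation") %in%
                  names(functions)))
  unknown <- setdiff(functions$gene_cluster_id, colnames(counts))
  if (length(unknown) > 0) {
    abort(
      paste0("Annotations reference unknown clusters: ",
             paste(head(unknown, 5), collapse = ", ")),
      class = "panphen_format_error")
  }
  structure(
    list(
      genomes  = rownames(counts),
      clusters = colnames(counts),
      counts   = counts,
      functions = dplyr::distinct(functions)
    ),
    class = "gene_cluster_matrix")
}

empty_functions <- function() {
  tibble(gene_cluster_id = character(), accession = character(),
         annotation = character())
}

#' @export
print.gene_cluster_matrix <- function(x, ...) {
  cat("<gene_cluster_matrix> ", length(x$genomes), " genomes x ",
      length(x$clusters), " gene clusters\n", sep = "")
  cat("  gene calls: ", sum(x$counts), "; annotated clusters: ",
      length(unique(x$functions$gene_cluster_id)), "\n", sep = "")
  invisible(x)
}

#' @export
dim.gene_cluster_matrix <- function(x) dim(x$counts)

#' @rdname gene_cluster_matrix
#' @param x A `gene_cluster_matrix`.
#' @param ... Unused.
#' @method as_tibble gene_cluster_matrix
#' @export
as_tibble.gene_cluster_matrix <- function(x, ...) {
  counts <- x$counts
  out <- tibble(
    genome_name = rep(rownames(counts), times = ncol(counts)),
    gene_cluster_id = rep(colnames(counts), each = nrow(counts)),
    n_genes = as.integer(counts))
  dplyr::filter(out, .data$n_genes > 0)
}

# Default column-name dialect: the header of an anvi'o pangenome gene-cluster
# summary. Only the first three are required.
default_dialect <- function() {
  list(gene_id = "gene_callers_id",
       genome  = "genome_name",
       cluster = "gene_cluster_id",
       accession = "accession",
       annotation = "function")
}

#' Read a gene-cluster membership table
#'
#' Reads a tab-separated table with one row per gene (gene id, genome name,
#' gene-cluster id, optional function accession/annotation) and aggregates it
#' into a [gene_cluster_matrix()]. Genomes and clusters are ordered
#' lexicographically so loading is independent of row order.
#'
#' @param path Path to a UTF-8, tab-separated file with a header row.
#' @param dialect Named list mapping the roles `gene_id`, `genome`, `cluster`,
#'   `accession`, `annotation` to column names in the file. Defaults to the
#'   anvi'o summary header (`gene_callers_id`, `genome_name`,
#'   `gene_cluster_id`, `accession`, `function`). Unknown extra columns are
#'   ignored.
#'
#' @return A [gene_cluster_matrix()].
#' @export
read_gene_clusters <- function(path, dialect = default_dialect()) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "panphen_format_error")
  }
  dialect <- modifyList(default_dialect(), dialect)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (nrow(df) == 0) {
    abort(paste0("Empty gene-cluster table: ", path),
          class = "panphen_format_error")
  }
  for (role in c("gene_id", "genome", "cluster")) {
    if (!dialect[[role]] %in% names(df)) {
      abort(paste0("Missing required column `", dialect[[role]],
                   "` (", role, ") in ", path),
            class = "panphen_format_error")
    }
  }
  if (anyDuplicated(df[[dialect$gene_id]])) {
    dup <- df[[dialect$gene_id]][duplicated(df[[dialect$gene_id]])]
    abort(paste0("Duplicate gene id(s): ",
                 paste(head(unique(dup), 5), collapse = ", ")),
          class = "panphen_format_error")
  }
  long <- tibble(
    genome_name = df[[dialect$genome]],
    gene_cluster_id = df[[dialect$cluster]])
  gcm_from_long(long, functions_from_table(df, dialect))
}

functions_from_table <- function(df, dialect) {
  have_acc <- dialect$accession %in% names(df)
  have_ann <- dialect$annotation %in% names(df)
  if (!have_acc && !have_ann) return(empty_functions())
  fns <- tibble(
    gene_cluster_id = df[[dialect$cluster]],
    accession = if (have_acc) df[[dialect$accession]] else NA_character_,
    annotation = if (have_ann) df[[dialect$annotation]] else NA_character_)
  fns <- dplyr::filter(fns, !(is.na(.data$accession) & is.na(.data$annotation)),
                       .data$accession != "" | is.na(.data$accession))
  dplyr::distinct(fns)
}

# Build the matrix from a long (genome, cluster[, n]) tibble with
# deterministic lexicographic ordering.
gcm_from_long <- function(long, functions = empty_functions()) {
  genomes <- sort(unique(long$genome_name))
  clusters <- sort(unique(long$gene_cluster_id))
  counts <- matrix(0L, nrow = length(genomes), ncol = length(clusters),
                   dimnames = list(genomes, clusters))
  tab <- if ("n_genes" %in% names(long)) {
    dplyr::count(long, .data$genome_name, .data$gene_cluster_id,
                 wt = .data$n_genes, name = "n")
  } else {
    dplyr::count(long, .data$genome_name, .data$gene_cluster_id, name = "n")
  }
  counts[cbind(match(tab$genome_name, genomes),
               match(tab$gene_cluster_id, clusters))] <- as.integer(tab$n)
  gene_cluster_matrix(counts, functions)
}

check_genomes <- function(m, genome_set) {
  unknown <- setdiff(genome_set, m$genomes)
  if (length(unknown) > 0) {
    abort(paste0("Unknown genome(s): ", paste(unknown, collapse = ", ")),
          class = "panphen_lookup_error")
  }
  if (length(genome_set) == 0) {
    abort("`genome_set` must be nonempty.", class = "panphen_argument_error")
  }
  invisible(genome_set)
}

#' Core, exclusive-core, and single-copy-core gene-cluster sets
#'
#' `core_clusters()` returns the clusters present (count >= 1) in at least a
#' fraction `min_presence` of the given genomes (default: all of them).
#' `exclusive_core()` returns the clusters present in every in-group genome
#' and absent from every out-group genome. `single_copy_core()` returns the
#' clusters with exactly one gene in every given genome, the set suitable for
#' gene-tree building.
#'
#' @param m A [gene_cluster_matrix()].
#' @param genome_set Character vector of genome names (default: all genomes).
#' @param min_presence Fraction of `genome_set` a cluster must be present in
#'   to count as core. The default 1 is strict presence-in-all; values below 1
#'   tolerate genes missing from incomplete assemblies.
#' @return Sorted character vector of gene-cluster ids.
#' @export
#' @examples
#' m <- gene_cluster_matrix(
#'   matrix(c(1L, 1L, 1L, 2L, 1L, 0L), nrow = 2, byrow = TRUE,
#'          dimnames = list(c("g1", "g2"), c("c1", "c2", "c3"))))
#' core_clusters(m)        # c1 c2
#' single_copy_core(m)     # c1
core_clusters <- function(m, genome_set = m$genomes, min_presence = 1) {
  check_genomes(m, genome_set)
  stopifnot(min_presence > 0, min_presence <= 1)
  sub <- m$counts[genome_set, , drop = FALSE] >= 1L
  hit <- colSums(sub) >= min_presence * length(genome_set)
  sort(m$clusters[hit])
}

#' @rdname core_clusters
#' @param in_group,out_group Disjoint, nonempty character vectors of genome
#'   names.
#' @export
exclusive_core <- function(m, in_group, out_group) {
  check_genomes(m, in_group)
  check_genomes(m, out_group)
  if (length(intersect(in_group, out_group)) > 0) {
    abort("`in_group` and `out_group` must be disjoint.",
          class = "panphen_argument_error")
  }
  inside <- colSums(m$counts[in_group, , drop = FALSE] >= 1L) ==
    length(in_group)
  outside <- colSums(m$counts[out_group, , drop = FALSE]) == 0L
  sort(m$clusters[inside & outside])
}

#' @rdname core_clusters
#' @export
single_copy_core <- function(m, genome_set = m$genomes) {
  check_genomes(m, genome_set)
  sub <- m$counts[genome_set, , drop = FALSE]
  sort(m$clusters[colSums(sub == 1L) == length(genome_set)])
}

#' Summarise the classic pangenome partitions for labeled genomes
#'
#' Convenience wrapper computing, for a phenotype-labeled pangenome, the
#' all-genomes core, each group's exclusive core (against all other labeled
#' genomes), the susceptible (permissive + nonpermissive) exclusive core, and
#' the single-copy cores of the full and susceptible genome sets.
#'
#' @inheritParams core_clusters
#' @param ph A [phenotype_map()].
#' @return Tibble with columns `set`, `size`, and a list-column `clusters`.
#' @export
core_set_summary <- function(m, ph) {
  ph <- validate_phenotypes(m, ph)
  groups <- split(ph$genome_name, ph$group)
  susceptible <- sort(c(groups$permissive, groups$nonpermissive))
  sets <- list(
    core_all = core_clusters(m, ph$genome_name),
    single_copy_core_all = single_copy_core(m, ph$genome_name),
    single_copy_core_susceptible = single_copy_core(m, susceptible))
  for (g in names(groups)) {
    sets[[paste0("exclusive_", g)]] <-
      exclusive_core(m, groups[[g]], setdiff(ph$genome_name, groups[[g]]))
  }
  sets$exclusive_susceptible <-
    exclusive_core(m, susceptible, setdiff(ph$genome_name, susceptible))
  tibble(set = names(sets),
         size = lengths(sets),
         clusters = unname(sets))
}
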