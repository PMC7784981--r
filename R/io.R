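#' Write and re-read the package's file dialects
#'
#' Writers emit exactly the dialects the readers consume, so every format
#' round-trips: the gene-cluster TSV (anvi'o-style header, one row per
#' gene), the phenotype TSV, per-cluster Newick files, the passage CSV, and
#' the enrichment/screen report TSVs. Numeric report columns carry full
#' precision; per-group observations are also rendered as "x/y" strings.
#'
#' @param m A [gene_cluster_matrix()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @name panphen_io
NULL

#' @rdname panphen_io
#' @export
write_gene_cluster_table <- function(m, path) {
  stopifnot(inherits(m, "gene_cluster_matrix"))
  long <- as_tibble(m)
  long <- tidyr::uncount(long, .data$n_genes)
  long <- dplyr::arrange(long, .data$genome_name, .data$gene_cluster_id)
  long$gene_callers_id <- sprintf("gene_%06d", seq_len(nrow(long)))
  fns <- dplyr::summarise(
    dplyr::group_by(m$functions, .data$gene_cluster_id),
    accession = paste(.data$accession, collapse = "|"),
    annotation = paste(.data$annotation, collapse = "|"),
    .groups = "drop")
  long <- dplyr::left_join(long, fns, by = "gene_cluster_id")
  out <- long[c("gene_callers_id", "genome_name", "gene_cluster_id",
                "accession", "annotation")]
  names(out)[5] <- "function"
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname panphen_io
#' @param ph A [phenotype_map()].
#' @export
write_phenotype_map <- function(ph, path) {
  readr::write_tsv(ph[c("genome_name", "group")], path, progress = FALSE)
  invisible(path)
}

#' @rdname panphen_io
#' @param trees List of [parse_labeled_tree()] objects.
#' @param dir Directory receiving one `<cluster_id>.nwk` file per tree.
#' @export
write_gene_trees <- function(trees, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (t in trees) {
    stopifnot(inherits(t, "labeled_gene_tree"))
    ape::write.tree(t$tree, file.path(dir, paste0(t$cluster_id, ".nwk")))
  }
  invisible(dir)
}

#' @rdname panphen_io
#' @export
read_gene_trees <- function(dir, ph) {
  files <- sort(list.files(dir, pattern = "\\.nwk$", full.names = TRUE))
  purrr::map(files, function(f) {
    parse_labeled_tree(paste(readLines(f), collapse = ""), ph,
                       cluster_id = sub("\\.nwk$", "", basename(f)))
  })
}

#' @rdname panphen_io
#' @param df Passage tibble (see [read_passage_series()]).
#' @export
write_passage_csv <- function(df, path) {
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname panphen_io
#' @param enr A `panphen_enrichment` object.
#' @export
write_enrichment_tsv <- function(enr, path) {
  stopifnot(inherits(enr, "panphen_enrichment"))
  rec <- enr$records
  for (g in enr$groups) {
    rec[[paste0("observation_", g)]] <-
      paste0(rec[[paste0("n_present_", g)]], "/",
             rec[[paste0("n_total_", g)]])
  }
  readr::write_tsv(rec, path, progress = FALSE)
  invisible(path)
}

#' @rdname panphen_io
#' @export
read_enrichment_tsv <- function(path) {
  readr::read_tsv(path, progress = FALSE,
                  col_types = readr::cols(.default = "c")) |>
    dplyr::mutate(dplyr::across(c("score", "p_value", "q_value"), as.numeric),
                  dplyr::across(dplyr::starts_with("n_"), as.integer),
                  associated_groups = dplyr::coalesce(.data$associated_groups,
                                                      ""))
}

#' @rdname panphen_io
#' @param scr A `panphen_screen` object.
#' @export
write_screen_tsv <- function(scr, path) {
  stopifnot(inherits(scr, "panphen_screen"))
  readr::write_tsv(scr$results, path, progress = FALSE)
  invisible(path)
}

#' @rdname panphen_io
#' @param sets Result of [core_set_summary()].
#' @export
write_cluster_sets <- function(sets, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_len(nrow(sets))) {
    writeLines(sets$clusters[[i]],
               file.path(dir, paste0(sets$set[i], ".txt")))
  }
  readr::write_tsv(sets[c("set", "size")],
                   file.path(dir, "set_sizes.tsv"), progress = FALSE)
  invisible(dir)
}

#' @rdname panphen_io
#' @param x List (truth record, run manifest, ...) to serialise as JSON.
#' @export
write_truth_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
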