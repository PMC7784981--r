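#' Published per-group observation fractions for enriched Pfam functions
#'
#' The per-group presence counts ("observation in-group" fractions) of the
#' top enriched Pfam functions across a 23-genome *Actinomyces* pangenome
#' grouped by TM7x response (10 resistant / 3 nonpermissive / 10 permissive
#' genomes), one table section per associated group set. These counts are
#' inputs: feeding each row's counts to [enrichment_score()] reproduces the
#' published enrichment scores, which is the package's primary numerical
#' check.
#'
#' @return Tibble with columns `section`, `pfam_function`, `slug`, and
#'   per-group `n_present_*` / `n_total_*` counts.
#' @export
#' @examples
#' obs <- enriched_function_observations()
#' with(obs[obs$slug == "mur_ligase", ],
#'      enrichment_score(
#'        c(n_present_resistant, n_present_nonpermissive,
#'          n_present_permissive),
#'        c(n_total_resistant, n_total_nonpermissive, n_total_permissive)))
enriched_function_observations <- function() {
  path <- system.file("extdata", "enriched_function_observations.tsv",
                      package = "panphen", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    section = "c", pfam_function = "c", slug = "c", .default = "i"),
    progress = FALSE)
}

#' Score every row of an observation-fractions table
#'
#' Applies [enrichment_score()] to the per-group counts of each row of a
#' table shaped like [enriched_function_observations()].
#'
#' @param obs Tibble with `n_present_<group>` and `n_total_<group>` columns.
#' @return The input with an appended `score` column.
#' @export
score_observations <- function(obs = enriched_function_observations()) {
  np <- as.matrix(obs[grep("^n_present_", names(obs))])
  nt <- as.matrix(obs[sub("n_present_", "n_total_", colnames(np))])
  obs$score <- vapply(seq_len(nrow(obs)),
                      function(i) enrichment_score(np[i, ], nt[i, ]),
                      numeric(1))
  obs
}
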