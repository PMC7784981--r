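#' Phenotype groups
#'
#' The three host-response groups used throughout the package. Susceptible
#' hosts (those that carry the epibiont) split into permissive strains, whose
#' density crashes after infection and then recovers, and nonpermissive
#' strains, which host the parasite with no growth-crash; resistant strains
#' never establish it.
#'
#' @export
phenotype_levels <- c("resistant", "permissive", "nonpermissive")

#' Build or read a phenotype map
#'
#' A phenotype map assigns each genome (or strain) to exactly one of the
#' groups `resistant`, `permissive`, or `nonpermissive`.
#'
#' @param df Data frame with columns `genome_name` and `group`.
#' @return A tibble of class `phenotype_map` with columns `genome_name`,
#'   `group`.
#' @export
#' @examples
#' phenotype_map(data.frame(
#'   genome_name = c("a", "b", "c"),
#'   group = c("resistant", "permissive", "nonpermissive")))
phenotype_map <- function(df) {
  df <- as_tibble(df)
  stopifnot(all(c("genome_name", "group") %in% names(df)))
  bad <- setdiff(unique(df$group), phenotype_levels)
  if (length(bad) > 0) {
    abort(paste0("Unknown phenotype group(s): ", paste(bad, collapse = ", "),
                 ". Expected one of: ",
                 paste(phenotype_levels, collapse = ", ")),
          class = "panphen_format_error")
  }
  if (anyDuplicated(df$genome_name)) {
    dup <- unique(df$genome_name[duplicated(df$genome_name)])
    abort(paste0("Genome(s) assigned more than one group: ",
                 paste(head(dup, 5), collapse = ", ")),
          class = "panphen_format_error")
  }
  out <- dplyr::arrange(df[c("genome_name", "group")], .data$genome_name)
  class(out) <- c("phenotype_map", class(out))
  out
}

#' @rdname phenotype_map
#' @param path Path to a tab-separated file with columns `genome_name`,
#'   `group`.
#' @export
read_phenotype_map <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "panphen_format_error")
  }
  phenotype_map(readr::read_tsv(path, col_types = "cc", progress = FALSE))
}

#' @rdname phenotype_map
#' @param ph A `phenotype_map`.
#' @export
susceptible_genomes <- function(ph) {
  sort(ph$genome_name[ph$group %in% c("permissive", "nonpermissive")])
}

# Check that every matrix genome carries a label; optionally drop unlabeled
# genomes with a warning instead of failing. Silent label mismatch is the
# likeliest user error, so the default is a hard error.
validate_phenotypes <- function(m, ph, allow_unlabeled = FALSE) {
  stopifnot(inherits(ph, "phenotype_map"))
  missing <- setdiff(m$genomes, ph$genome_name)
  if (length(missing) > 0 && !allow_unlabeled) {
    abort(paste0("Genomes without a phenotype label: ",
                 paste(head(missing, 5), collapse = ", "),
                 ". Set `allow_unlabeled = TRUE` to drop them."),
          class = "panphen_lookup_error")
  }
  if (length(missing) > 0) {
    warn(paste0("Dropping ", length(missing), " unlabeled genome(s)."))
  }
  dplyr::filter(ph, .data$genome_name %in% m$genomes)
}
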