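#' Per-function presence profiles across phenotype groups
#'
#' A genome "has" a function iff at least one gene cluster annotated with
#' that function is present (count >= 1) in that genome. Profiles are keyed
#' by accession by default; keying by annotation text merges clusters whose
#' accessions differ but whose descriptions agree.
#'
#' @param m A [gene_cluster_matrix()].
#' @param ph A [phenotype_map()] labeling every matrix genome (see
#'   `allow_unlabeled`).
#' @param annotation_source `"accession"` or `"annotation"`: which field keys
#'   a function.
#' @param allow_unlabeled Drop unlabeled genomes with a warning instead of
#'   failing.
#' @return Tibble with one row per (function, group): columns `accession`,
#'   `annotation`, `group`, `n_present`, `n_total`.
#' @export
function_presence <- function(m, ph,
                              annotation_source = c("accession", "annotation"),
                              allow_unlabeled = FALSE) {
  annotation_source <- match.arg(annotation_source)
  ph <- validate_phenotypes(m, ph, allow_unlabeled)
  genomes <- intersect(m$genomes, ph$genome_name)
  fns <- m$functions
  if (nrow(fns) == 0) {
    warn("No functional annotations present; empty enrichment universe.")
    return(tibble(accession = character(), annotation = character(),
                  group = character(), n_present = integer(),
                  n_total = integer()))
  }
  key <- if (annotation_source == "accession") fns$accession else fns$annotation
  fns <- fns[!is.na(key) & key != "", ]
  key <- key[!is.na(key) & key != ""]
  keys <- sort(unique(key))

  # function x genome presence via a sparse function-by-cluster indicator
  pres <- m$counts[genomes, , drop = FALSE] >= 1L        # genomes x clusters
  ind <- Matrix::sparseMatrix(
    i = match(key, keys),
    j = match(fns$gene_cluster_id, m$clusters),
    x = 1,
    dims = c(length(keys), length(m$clusters)))
  fg <- (ind %*% Matrix::t(Matrix::Matrix(pres * 1))) > 0  # functions x genomes

  grp <- ph$group[match(genomes, ph$genome_name)]
  out <- purrr::map_dfr(sort(unique(grp)), function(g) {
    sel <- grp == g
    tibble(accession = if (annotation_source == "accession") keys else
             first_label(fns, key, keys, "accession"),
           annotation = if (annotation_source == "annotation") keys else
             first_label(fns, key, keys, "annotation"),
           group = g,
           n_present = as.integer(Matrix::rowSums(fg[, sel, drop = FALSE])),
           n_total = sum(sel))
  })
  dplyr::arrange(out, .data$accession, .data$group)
}

# representative label for the non-key field of each function key
first_label <- function(fns, key, keys, field) {
  idx <- match(keys, key)
  fns[[field]][idx]
}

#' Enrichment score for a function across phenotype groups
#'
#' The Rao score statistic of association between group membership and
#' function presence, computed as the Pearson chi-square statistic on the
#' (present/absent) x groups contingency table. For `G` groups the null
#' reference distribution is chi-square with `G - 1` degrees of freedom.
#' A function present in all or in no genomes scores 0. No continuity
#' correction and no minimum-expected-count filtering are applied, so the
#' statistic is defined for groups as small as one genome.
#'
#' The score is bounded by the total number of genomes and attains that bound
#' exactly when presence coincides with a group-subset boundary (e.g. a
#' function found in all resistant and no susceptible genomes of a 23-genome
#' pangenome scores 23).
#'
#' @param n_present Integer vector, genomes per group carrying the function.
#' @param n_total Integer vector, genomes per group (all >= 1).
#' @return Non-negative scalar score.
#' @export
#' @examples
#' enrichment_score(c(10, 0, 0), c(10, 3, 10))  # 23: perfect association
#' enrichment_score(c(2, 1, 10), c(10, 3, 10))  # 13.78
enrichment_score <- function(n_present, n_total) {
  if (length(n_present) != length(n_total) || length(n_total) < 2) {
    abort("Need presence and totals for >= 2 groups.",
          class = "panphen_argument_error")
  }
  if (any(n_total < 1)) {
    abort("Every group must contain at least one genome.",
          class = "panphen_argument_error")
  }
  if (any(n_present < 0) || any(n_present > n_total)) {
    abort("`n_present` must lie in [0, n_total] per group.",
          class = "panphen_argument_error")
  }
  npres <- sum(n_present)
  n <- sum(n_total)
  if (npres == 0 || npres == n) return(0)
  p0 <- npres / n
  e1 <- n_total * p0
  e0 <- n_total * (1 - p0)
  sum((n_present - e1)^2 / e1 + ((n_total - n_present) - e0)^2 / e0)
}

#' Upper-tail p-value for an enrichment score
#'
#' Survival function of the chi-square distribution with `n_groups - 1`
#' degrees of freedom evaluated at the score.
#'
#' @param score Non-negative score statistic.
#' @param n_groups Number of phenotype groups (>= 2).
#' @return p-value in `[0, 1]`. Vectorised over `score`.
#' @export
enrichment_pvalue <- function(score, n_groups) {
  if (n_groups < 2) {
    abort("`n_groups` must be >= 2.", class = "panphen_argument_error")
  }
  if (any(score < 0)) {
    abort("`score` must be >= 0.", class = "panphen_argument_error")
  }
  pchisq(score, df = n_groups - 1, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `q(i) = min over j >= i of p(j) * m / j`, clipped to 1, returned in the
#' input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("All p-values must lie in [0, 1].", class = "panphen_argument_error")
  }
  p.adjust(p_values, method = "BH")
}

#' Groups associated with a function
#'
#' Majority rule: the associated group set contains every group in which at
#' least `cutoff` (default one half) of the genomes carry the function. This
#' reproduces combined headings such as "nonpermissive + resistant" for
#' functions common to both groups; the boundary is inclusive, so a function
#' in exactly half of a group's genomes counts as associated.
#'
#' @param fractions Named numeric vector of per-group presence fractions in
#'   `[0, 1]`.
#' @param cutoff Inclusive presence-fraction threshold.
#' @return Character vector of group names (possibly empty).
#' @export
#' @examples
#' associated_groups(c(resistant = 1, nonpermissive = 0, permissive = 0))
#' associated_groups(c(resistant = 0.5, nonpermissive = 1, permissive = 0))
associated_groups <- function(fractions, cutoff = 0.5) {
  stopifnot(all(fractions >= 0), all(fractions <= 1))
  names(fractions)[fractions >= cutoff]
}

#' Functional enrichment across phenotype groups
#'
#' Scores every annotated function for differential presence across the
#' phenotype groups, attaches chi-square p-values and Benjamini-Hochberg
#' q-values (computed over the full tested-function universe), and assigns
#' associated group sets. Records are ranked by descending score with ties
#' broken lexicographically by accession.
#'
#' @inheritParams function_presence
#' @param cutoff Associated-group presence-fraction cutoff, see
#'   [associated_groups()].
#' @param top_n Optional truncation of the ranked records.
#' @return An object of class `panphen_enrichment`; use [tidy()] for the
#'   per-function records and [glance()] for a one-row summary.
#' @export
run_enrichment <- function(m, ph,
                           annotation_source = c("accession", "annotation"),
                           cutoff = 0.5, top_n = NULL,
                           allow_unlabeled = FALSE) {
  annotation_source <- match.arg(annotation_source)
  prof <- function_presence(m, ph, annotation_source, allow_unlabeled)
  groups <- sort(unique(prof$group))
  wide <- tidyr::pivot_wider(
    prof, names_from = "group",
    values_from = c("n_present", "n_total"))
  if (nrow(wide) == 0) {
    rec <- tibble(accession = character(), annotation = character(),
                  score = numeric(), p_value = numeric(), q_value = numeric(),
                  associated_groups = character())
    return(new_panphen_enrichment(rec, groups, 0L, annotation_source, cutoff))
  }
  np <- as.matrix(wide[paste0("n_present_", groups)])
  nt <- as.matrix(wide[paste0("n_total_", groups)])
  score <- vapply(seq_len(nrow(np)),
                  function(i) enrichment_score(np[i, ], nt[i, ]), numeric(1))
  p <- enrichment_pvalue(score, length(groups))
  q <- bh_fdr(p)
  frac <- np / nt
  colnames(frac) <- groups
  assoc <- vapply(seq_len(nrow(frac)), function(i) {
    paste(associated_groups(frac[i, ], cutoff), collapse = ",")
  }, character(1))
  rec <- tibble(accession = wide$accession, annotation = wide$annotation,
                score = score, p_value = p, q_value = q,
                associated_groups = assoc)
  for (g in groups) {
    rec[[paste0("n_present_", g)]] <- np[, paste0("n_present_", g)]
    rec[[paste0("n_total_", g)]] <- nt[, paste0("n_total_", g)]
  }
  rec <- dplyr::arrange(rec, dplyr::desc(.data$score), .data$accession)
  if (!is.null(top_n)) rec <- head(rec, top_n)
  new_panphen_enrichment(rec, groups, sum(nt[1, ]), annotation_source, cutoff)
}

new_panphen_enrichment <- function(records, groups, n_genomes,
                                   annotation_source, cutoff) {
  structure(
    list(records = records, groups = groups, n_genomes = n_genomes,
         annotation_source = annotation_source, cutoff = cutoff),
    class = "panphen_enrichment")
}

#' @export
print.panphen_enrichment <- function(x, ...) {
  cat("<panphen_enrichment> ", nrow(x$records), " functions, ",
      x$n_genomes, " genomes, groups: ",
      paste(x$groups, collapse = ", "), "\n", sep = "")
  print(head(x$records, 5))
  invisible(x)
}

#' @rdname run_enrichment
#' @param x A `panphen_enrichment` object.
#' @param ... Unused.
#' @method tidy panphen_enrichment
#' @export
tidy.panphen_enrichment <- function(x, ...) x$records

#' @rdname run_enrichment
#' @method glance panphen_enrichment
#' @export
glance.panphen_enrichment <- function(x, ...) {
  tibble(n_functions = nrow(x$records),
         n_genomes = x$n_genomes,
         n_groups = length(x$groups),
         n_significant = sum(x$records$q_value < 0.05),
         max_score = if (nrow(x$records)) max(x$records$score) else NA_real_)
}
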