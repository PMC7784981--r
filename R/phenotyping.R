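#' Read a serial-passage table
#'
#' Comma-separated table with columns `strain`, `dose`, `passage`, `density`,
#' `parasite_score` and optional `total_cfu`, `irregular_cfu`. Host-alone
#' control series are rows with `dose == 0`.
#'
#' @param path Path to the CSV file.
#' @return Tibble of passage records.
#' @export
read_passage_series <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "panphen_format_error")
  }
  df <- suppressWarnings(
    readr::read_csv(path, col_types = readr::cols(
      strain = "c", dose = "d", passage = "i", density = "d",
      parasite_score = "d", .default = "d"), progress = FALSE))
  need <- c("strain", "dose", "passage", "density", "parasite_score")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("Missing required column(s): ", paste(miss, collapse = ", ")),
          class = "panphen_format_error")
  }
  if (any(df$parasite_score < 0 | df$parasite_score > 1, na.rm = TRUE)) {
    abort("`parasite_score` must lie in [0, 1].",
          class = "panphen_format_error")
  }
  df
}

#' Join host-alone controls onto infected passage series
#'
#' Rows with `dose == 0` are the per-strain host-alone controls; this
#' attaches their density as a `control_density` column on the infected rows
#' (matching on strain and passage) and drops the control rows.
#'
#' @param df Passage tibble as read by [read_passage_series()].
#' @return Infected-rows tibble with an added `control_density` column.
#' @export
attach_controls <- function(df) {
  ctrl <- dplyr::select(
    dplyr::filter(df, .data$dose == 0),
    "strain", "passage", control_density = "density")
  inf <- dplyr::filter(df, .data$dose > 0)
  out <- dplyr::left_join(inf, ctrl, by = c("strain", "passage"))
  if (any(is.na(out$control_density))) {
    abort("Control series does not cover every infected passage.",
          class = "panphen_data_error")
  }
  out
}

check_series <- function(series) {
  need <- c("passage", "density", "parasite_score", "control_density")
  miss <- setdiff(need, names(series))
  if (length(miss) > 0) {
    abort(paste0("Series lacks column(s): ", paste(miss, collapse = ", "),
                 "; did you call attach_controls()?"),
          class = "panphen_argument_error")
  }
  series <- dplyr::arrange(series, .data$passage)
  if (any(diff(series$passage) <= 0)) {
    abort("Passage indices must be strictly increasing.",
          class = "panphen_format_error")
  }
  if (any(series$control_density <= 0)) {
    abort("Zero or negative control density at a compared passage.",
          class = "panphen_data_error")
  }
  series
}

#' Locate the growth-crash in a passage series
#'
#' The crash point is the first passage at which the infected culture's
#' density falls below `drop_fraction` of the host-alone control; the crash
#' duration is the number of consecutive passages (starting there) that stay
#' below `recovery_fraction` of control. Ratios to the matched control remove
#' strain- and medium-specific growth-rate differences, so calls are
#' invariant to rescaling both series by the same constant.
#'
#' @param series Tibble for a single strain x dose with columns `passage`,
#'   `density`, `parasite_score`, `control_density` (see
#'   [attach_controls()]), at least 3 passages.
#' @param drop_fraction Density/control ratio below which a passage counts as
#'   crashed (default 0.5).
#' @param recovery_fraction Ratio that must be regained for the crash to end
#'   (default 0.8).
#' @return Tibble with one row: `crash_point`, `crash_duration` (both `NA`
#'   if no passage qualifies).
#' @export
#' @examples
#' s <- tibble::tibble(passage = 0:4,
#'                     density = c(1, 0.9, 0.3, 0.4, 0.95),
#'                     control_density = 1, parasite_score = 0.5)
#' detect_crash(s)  # crash_point 2, duration 2
detect_crash <- function(series, drop_fraction = 0.5,
                         recovery_fraction = 0.8) {
  stopifnot(drop_fraction > 0, drop_fraction < 1,
            recovery_fraction > 0, recovery_fraction < 1,
            recovery_fraction >= drop_fraction)
  series <- check_series(series)
  if (nrow(series) < 3) {
    abort("Need at least 3 passages to call a crash.",
          class = "panphen_argument_error")
  }
  ratio <- series$density / series$control_density
  hit <- which(ratio < drop_fraction)
  if (length(hit) == 0) {
    return(tibble(crash_point = NA_integer_, crash_duration = NA_integer_))
  }
  i <- hit[1]
  low <- ratio[i:length(ratio)] < recovery_fraction
  dur <- if (all(low)) length(low) else which(!low)[1] - 1L
  tibble(crash_point = series$passage[i], crash_duration = as.integer(dur))
}

#' Classify a host strain from its passage series
#'
#' A strain is called `resistant` when the parasite never establishes: its
#' parasite score stays below `establish_score` at every passage from
#' `establish_passages` onward. Otherwise it is `permissive` when
#' [detect_crash()] finds a growth-crash, else `nonpermissive`. The call
#' never uses density for the resistant decision, only the parasite score.
#'
#' @inheritParams detect_crash
#' @param establish_score Parasite score below which the epibiont counts as
#'   absent (default 0.1).
#' @param establish_passages Passage from which establishment is judged
#'   (default 5; series must reach it).
#' @return Tibble with one row: `call`, `crash_point`, `crash_duration`
#'   (crash fields populated only for permissive calls).
#' @export
classify_host <- function(series, establish_score = 0.1,
                          establish_passages = 5L,
                          drop_fraction = 0.5, recovery_fraction = 0.8) {
  series <- check_series(series)
  if (max(series$passage) < establish_passages) {
    abort(paste0("Series must span at least ", establish_passages,
                 " passages."),
          class = "panphen_argument_error")
  }
  late <- series$parasite_score[series$passage >= establish_passages]
  if (all(late < establish_score)) {
    return(tibble(call = "resistant", crash_point = NA_integer_,
                  crash_duration = NA_integer_))
  }
  crash <- detect_crash(series, drop_fraction, recovery_fraction)
  if (!is.na(crash$crash_point)) {
    tibble(call = "permissive", crash_point = crash$crash_point,
           crash_duration = crash$crash_duration)
  } else {
    tibble(call = "nonpermissive", crash_point = NA_integer_,
           crash_duration = NA_integer_)
  }
}

#' Classify every strain x dose series in a passage table
#'
#' @param df Passage tibble including `dose == 0` control rows (see
#'   [read_passage_series()]).
#' @inheritParams classify_host
#' @return Tibble with one row per (strain, dose): `strain`, `dose`, `call`,
#'   `crash_point`, `crash_duration`.
#' @export
classify_hosts <- function(df, establish_score = 0.1,
                           establish_passages = 5L,
                           drop_fraction = 0.5, recovery_fraction = 0.8) {
  withctl <- attach_controls(df)
  out <- dplyr::group_modify(
    dplyr::group_by(withctl, .data$strain, .data$dose),
    function(g, key) classify_host(g, establish_score, establish_passages,
                                   drop_fraction, recovery_fraction))
  dplyr::ungroup(out)
}

#' Dose-response monotonicity of crash points
#'
#' Higher parasite doses should crash the host culture no later. Treating a
#' missing crash point as "+infinity" (never crashed), reports whether
#' `crash_point` is non-increasing in dose, and lists every violating pair.
#' Duplicate doses with conflicting crash points are reported among the
#' violations but are not fatal.
#'
#' @param calls Tibble with columns `dose` and `crash_point` (NA = no crash).
#' @return List with elements `monotone` (logical) and `violations` (tibble
#'   of dose/crash pairs that break monotonicity).
#' @export
#' @examples
#' dose_response(tibble::tibble(dose = c(1, 10, 100),
#'                              crash_point = c(6, 4, 1)))
dose_response <- function(calls) {
  stopifnot(all(c("dose", "crash_point") %in% names(calls)))
  if (length(unique(calls$dose)) < 2) {
    abort("Need at least 2 distinct doses.", class = "panphen_argument_error")
  }
  cp <- ifelse(is.na(calls$crash_point), Inf, calls$crash_point)
  ord <- order(calls$dose)
  viol <- list()
  for (a in seq_along(ord)) {
    for (b in seq_along(ord)) {
      if (b <= a) next
      i <- ord[a]; j <- ord[b]
      bad <- if (calls$dose[i] == calls$dose[j]) cp[i] != cp[j] else
        cp[j] > cp[i]
      if (bad) {
        viol[[length(viol) + 1]] <- tibble(
          dose_low = calls$dose[i], crash_low = calls$crash_point[i],
          dose_high = calls$dose[j], crash_high = calls$crash_point[j])
      }
    }
  }
  violations <- if (length(viol)) dplyr::bind_rows(viol) else
    tibble(dose_low = numeric(), crash_low = integer(),
           dose_high = numeric(), crash_high = integer())
  list(monotone = nrow(violations) == 0, violations = violations)
}
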