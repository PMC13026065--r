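# Reading and writing cohort tables. The on-disk layout is two plain CSVs:
# a long panel (one row per subject-wave) and a baseline table (one row per
# subject). Factor covariates are written as text and restored to their
# canonical levels on read, so a write-then-read round trip reproduces the
# tables exactly.

baseline_factor_levels <- function() {
  list(
    gender = c("female", "male"),
    marital = c("married", "other"),
    residence = c("rural", "urban"),
    education = c("primary_or_below", "middle_school", "high_school_or_above"),
    iadl = c("none", "some", "severe"),
    adl = c("none", "some", "severe")
  )
}

#' Read a long-format behavior panel
#'
#' Reads a CSV with one row per subject-wave. The schema requires `id`,
#' `time` and either a `score` column or the 21 indicator columns of
#' [indicator_spec()]; a missing requirement raises an error naming the
#' absent columns. Unknown extra columns are preserved with a warning.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_panel <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("id", "time")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop_config("panel is missing column(s): %s",
                                paste(miss, collapse = ", "))
  ind <- indicator_spec()$indicator
  if (!"score" %in% names(d) && length(setdiff(ind, names(d)))) {
    stop_config("panel needs either a 'score' column or indicator column(s): %s",
                paste(setdiff(ind, names(d)), collapse = ", "))
  }
  known <- c("id", "wave", "time", "score", ind)
  extra <- setdiff(names(d), known)
  if (length(extra)) {
    rlang::warn(sprintf("unknown panel column(s) preserved untouched: %s",
                        paste(extra, collapse = ", ")))
  }
  num_cols <- intersect(c("time", "score", ind), names(d))
  bad <- num_cols[!vapply(d[num_cols], is.numeric, logical(1))]
  if (length(bad)) stop_config("non-numeric value(s) in column(s): %s",
                               paste(bad, collapse = ", "))
  d
}

#' Read a baseline covariate table
#'
#' Reads a CSV with one row per subject and restores the canonical factor
#' levels of the categorical covariates (reference level first).
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_baseline <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!"id" %in% names(d)) stop_config("baseline is missing column(s): id")
  for (v in names(baseline_factor_levels())) {
    if (v %in% names(d)) {
      lv <- baseline_factor_levels()[[v]]
      bad <- setdiff(unique(d[[v]]), lv)
      if (length(bad)) stop_config("column '%s' has unknown level(s): %s", v,
                                   paste(bad, collapse = ", "))
      d[[v]] <- factor(d[[v]], levels = lv)
    }
  }
  d
}

#' Write a synthetic cohort to disk
#'
#' Writes `baseline.csv` and `panel.csv` under `dir`.
#'
#' @param cohort A `phb_cohort` (see [simulate_cohort()]).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phb_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(baseline = file.path(dir, "baseline.csv"),
             panel = file.path(dir, "panel.csv"))
  readr::write_csv(cohort$baseline, paths["baseline"])
  readr::write_csv(cohort$panel, paths["panel"])
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding `baseline.csv` and `panel.csv`.
#' @return A `phb_cohort` object (without a generating config).
#' @export
read_cohort <- function(dir) {
  baseline <- read_baseline(file.path(dir, "baseline.csv"))
  panel <- read_panel(file.path(dir, "panel.csv"))
  structure(list(baseline = baseline, panel = panel, config = NULL),
            class = "phb_cohort")
}
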