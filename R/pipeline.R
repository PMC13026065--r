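# End-to-end orchestration: score -> trajectories -> determinants ->
# Shapley -> LCA -> mediation, from either a synthetic-cohort config or an
# existing cohort, with every stage seeded and a manifest that makes the
# run reproducible.

#' Run the full trajectory analysis pipeline
#'
#' Executes the analysis stages in sequence on a synthetic or supplied
#' cohort: (1) `score` — entropy-weight scoring of the indicator columns
#' when present (otherwise the panel's `score` column is used as-is);
#' (2) `gbtm` — candidate trajectory models are scanned and the recommended
#' solution assigns each subject a trajectory class (skip this stage by
#' supplying a `trajectory_class` column in the baseline); (3)
#' `determinants` — univariate screens and the multivariable logistic
#' model; (4) `shapley` — per-class contribution decomposition of the
#' determinants; (5) `lca` — latent comorbidity classes on the condition
#' flags, mapped to named patterns (optionally with a bootstrap LRT);
#' (6) `mediation` — path analysis overall and within each pattern.
#' Any stage failure keeps the completed stages and records the failure
#' point in the manifest.
#'
#' @param input A [cohort_config()] (the cohort is simulated) or a
#'   `phb_cohort`.
#' @param stages Character subset of
#'   `c("score", "gbtm", "determinants", "shapley", "lca", "mediation")`.
#' @param gbtm_candidates Candidate list for [scan_models()]; the default
#'   scans 1-3 quadratic classes.
#' @param gbtm_n_starts EM restarts per trajectory candidate.
#' @param lca_k Number of latent comorbidity classes.
#' @param lca_blrt_boot Bootstrap replicates for the class-count LRT; 0
#'   (default) skips the test.
#' @param pattern_rules Pattern naming rules for [map_patterns()].
#' @param mediation_boot Bootstrap replicates for mediation CIs; 0 skips
#'   interval estimation.
#' @param seed Integer seed for every stochastic stage.
#' @return An object of class `phb_run`: a list of stage results
#'   (`weights`, `gbtm_scan`, `gbtm_fit`, `trajectories`, `group_tests`,
#'   `logistic_fit`, `shapley`, `lca_fit`, `patterns`, `paths`,
#'   `subgroup_effects`) plus a `manifest`.
#' @export
#' @examples
#' run <- run_pipeline(cohort_config(n_subjects = 200, seed = 11),
#'                     gbtm_candidates = list(list(k = 2, orders = c(1, 2))),
#'                     gbtm_n_starts = 2, seed = 11)
#' names(run)
run_pipeline <- function(input = cohort_config(),
                         stages = c("score", "gbtm", "determinants",
                                    "shapley", "lca", "mediation"),
                         gbtm_candidates = NULL,
                         gbtm_n_starts = 5L,
                         lca_k = 2L,
                         lca_blrt_boot = 0L,
                         pattern_rules = NULL,
                         mediation_boot = 0L,
                         seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (inherits(input, "cohort_config")) {
    cohort <- simulate_cohort(input)
    config <- input
  } else if (inherits(input, "phb_cohort")) {
    cohort <- input
    config <- cohort$config
  } else {
    stop_config("input must be a cohort_config or a phb_cohort")
  }
  seeds <- derive_seeds(seed, 4L)
  out <- list(cohort = cohort)
  manifest <- list(
    package = "phbtraj",
    version = as.character(utils::packageVersion("phbtraj")),
    seed = as.integer(seed),
    stage_seeds = list(gbtm = seeds[1L], lca = seeds[2L], blrt = seeds[3L],
                       mediation = seeds[4L]),
    stages = stages,
    config_hash = rlang::hash(config),
    failed_stage = NULL
  )
  baseline <- cohort$baseline
  panel <- cohort$panel

  run_stage <- function(name, expr) {
    if (!name %in% stages || !is.null(manifest$failed_stage)) return(invisible())
    tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- list(stage = name, message = conditionMessage(e))
      rlang::warn(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  run_stage("score", {
    if (all(indicator_spec()$indicator %in% names(panel))) {
      scored <- score_behaviors(panel)
      panel <- scored
      out$weights <- attr(scored, "weights")
    }
  })

  run_stage("gbtm", {
    cands <- gbtm_candidates %||%
      list(list(k = 1, orders = 2), list(k = 2, orders = 2),
           list(k = 3, orders = 2))
    scan <- scan_models(panel, candidates = cands,
                        n_starts = gbtm_n_starts, seed = seeds[1L])
    fit <- attr(scan, "fits")[[which(scan$recommended)]]
    attr(scan, "fits") <- NULL
    out$gbtm_scan <- scan
    out$gbtm_fit <- fit
    out$trajectories <- assign_trajectories(fit)
    baseline <- left_join(baseline, out$trajectories[c("id", "trajectory_class")],
                           by = "id")
  })
  if (!"trajectory_class" %in% names(baseline)) {
    if (any(c("determinants", "shapley", "mediation") %in% stages) &&
        is.null(manifest$failed_stage)) {
      stop_config(paste("downstream stages need a trajectory_class column;",
                        "run the gbtm stage or supply labels in the baseline"))
    }
  }

  run_stage("determinants", {
    out$group_tests <- compare_groups(baseline, "trajectory_class")
    preds <- out$group_tests$variable[out$group_tests$significant]
    if (!length(preds)) preds <- c("age", "education", "retirement",
                                   "family_size", "cesd")
    out$logistic_fit <- fit_logistic(baseline, "trajectory_class",
                                      predictors = preds)
  })

  run_stage("shapley", {
    players <- intersect(c("age", "family_size", "education", "retirement",
                           "cesd"), names(baseline))
    out$shapley <- contribution_report(baseline, "trajectory_class", players)
  })

  run_stage("lca", {
    flags <- baseline[, intersect(chronic_conditions, names(baseline))]
    fit <- fit_lca(flags, k = lca_k, seed = seeds[2L])
    out$lca_fit <- fit
    rules <- pattern_rules
    pat <- if (is.null(rules)) assign_patterns(fit, ids = baseline$id) else
      assign_patterns(fit, ids = baseline$id, rules = rules)
    out$patterns <- pat
    baseline <- left_join(baseline, pat[c("id", "pattern")], by = "id")
    if (lca_blrt_boot > 0) {
      out$blrt <- blrt(flags, k = lca_k, n_boot = lca_blrt_boot,
                        seed = seeds[3L])
    }
  })

  run_stage("mediation", {
    paths <- fit_paths(baseline)
    if (mediation_boot > 0) {
      paths <- bootstrap_ci(paths, n_boot = mediation_boot, seed = seeds[4L])
    }
    out$paths <- paths
    if ("pattern" %in% names(baseline) &&
        length(unique(baseline$pattern)) > 1L) {
      sub <- subgroup_paths(baseline)
      out$subgroup_effects <- attr(sub, "effects")
      out$subgroup_fits <- sub
    }
  })

  out$baseline <- baseline
  out$panel <- panel
  out$manifest <- manifest
  structure(out, class = "phb_run")
}

#' @export
print.phb_run <- function(x, ...) {
  done <- setdiff(names(x), c("cohort", "baseline", "panel", "manifest"))
  cat(sprintf("<phb_run> seed %d, stages completed: %s\n", x$manifest$seed,
              paste(done, collapse = ", ")))
  if (!is.null(x$manifest$failed_stage)) {
    cat(sprintf("  FAILED at '%s': %s\n", x$manifest$failed_stage$stage,
                x$manifest$failed_stage$message))
  }
  invisible(x)
}

#' Write a pipeline report bundle
#'
#' Writes every tabular stage result as CSV plus a JSON manifest
#' (`manifest.json` with package version, seeds, stage list and config
#' hash) under `dir`.
#'
#' @param run A `phb_run`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_tables <- function(run, dir) {
  stopifnot(inherits(run, "phb_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(obj, name) {
    if (is.null(obj)) return()
    p <- file.path(dir, paste0(name, ".csv"))
    readr::write_csv(obj, p)
    written <<- c(written, p)
  }
  emit(run$weights, "weights")
  emit(run$gbtm_scan, "trajectory_selection")
  if (!is.null(run$gbtm_fit)) emit(tidy(run$gbtm_fit), "trajectory_coefficients")
  emit(run$trajectories, "trajectory_assignment")
  emit(run$group_tests, "group_tests")
  if (!is.null(run$logistic_fit)) emit(tidy(run$logistic_fit), "determinants")
  emit(run$shapley, "shapley_contributions")
  if (!is.null(run$lca_fit)) emit(tidy(run$lca_fit), "comorbidity_classes")
  emit(run$patterns, "comorbidity_patterns")
  if (!is.null(run$paths)) emit(tidy(run$paths), "mediation_effects")
  emit(run$subgroup_effects, "mediation_subgroups")
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(run$manifest, mp, auto_unbox = TRUE, null = "null")
  invisible(c(written, mp))
}
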