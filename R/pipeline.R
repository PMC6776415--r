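#' Pipeline run configuration
#'
#' Bundles the end-to-end parameters. Defaults follow the analysis protocol
#' the package implements: 40 threshold levels, 10000 permutations, 100
#' rewired nulls, clusters of at least 3 consecutive thresholds.
#'
#' @param cohort A [cohort_spec()] describing the simulated cohort (or `NULL`
#'   when `connectomes` are supplied directly to [run_pipeline()]).
#' @param metrics Global metrics to curve (see [metric_curves()]).
#' @param strategy Edge-weighting tag used to pick the covariate preset.
#' @param n_levels Threshold levels.
#' @param n_perm Permutations for the permutation ANCOVA and MTPC.
#' @param n_null Rewired nulls for small-worldness metrics.
#' @param cluster_min Minimum MTPC cluster extent.
#' @param covariates Covariate columns; default from [covariate_preset()].
#' @param seed Integer master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(),
                       metrics = c("degree", "strength"),
                       strategy = "synthetic",
                       n_levels = 40L, n_perm = 10000L, n_null = 100L,
                       cluster_min = 3L,
                       covariates = covariate_preset(strategy),
                       seed = 1L) {
  if (n_levels < 2L) abort("`n_levels` must be >= 2.")
  if (cluster_min < 1L) abort("`cluster_min` must be >= 1.")
  structure(
    list(cohort = cohort, metrics = metrics, strategy = strategy,
         n_levels = as.integer(n_levels), n_perm = as.integer(n_perm),
         n_null = as.integer(n_null), cluster_min = as.integer(cluster_min),
         covariates = covariates, seed = as.integer(seed)),
    class = "run_config"
  )
}

run_config_defaults <- function() {
  list(n_levels = 40L, n_perm = 10000L, n_null = 100L, cluster_min = 3L)
}

#' Read a pipeline configuration from a YAML file
#'
#' The config file is a flat key/value document. Recognised keys: the
#' [run_config()] fields (`metrics`, `strategy`, `n_levels`, `n_perm`,
#' `n_null`, `cluster_min`, `covariates`, `seed`) and, under `cohort:`, any
#' [cohort_spec()] field. Unknown keys raise an error so typos do not pass
#' silently.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' not found.", path))
  raw <- yaml::read_yaml(path)
  cohort_args <- raw$cohort %||% list()
  raw$cohort <- NULL
  known_cfg <- setdiff(names(formals(run_config)), "cohort")
  bad <- setdiff(names(raw), known_cfg)
  if (length(bad)) {
    abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  bad_cohort <- setdiff(names(cohort_args), names(formals(cohort_spec)))
  if (length(bad_cohort)) {
    abort(sprintf("unknown cohort key(s): %s",
                  paste(bad_cohort, collapse = ", ")))
  }
  raw$cohort <- do.call(cohort_spec, cohort_args)
  do.call(run_config, raw)
}

#' Run the simulate -> curves -> statistics pipeline
#'
#' Simulates (or accepts) a two-group cohort of connectomes, builds the
#' density/weight threshold schedules, computes metric curves and their AUC
#' summaries, and runs the group statistics: permutation ANCOVA on each
#' metric's AUC (Bonferroni-adjusted over metrics) and point-by-point MTPC
#' along each curve. All tabular results (and a reproducibility manifest) are
#' written under `out_dir` when given.
#'
#' @param config A [run_config()].
#' @param connectomes Optional list of [connectome()]s / weight matrices to
#'   analyse instead of simulating.
#' @param covariate_table Covariate tibble matching `connectomes` (required
#'   with `connectomes`).
#' @param out_dir Optional output directory.
#' @return A list of class `pipeline_result`: `schedules`, `curves`, `auc`,
#'   `ancova` (tibble over metrics), `mtpc` (list over metrics),
#'   `mtpc_summary` tibble, `covariates`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), connectomes = NULL,
                         covariate_table = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage, start) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), start, units = "secs"))
  }

  st <- Sys.time()
  if (is.null(connectomes)) {
    sim <- simulate_cohort(config$cohort)
    connectomes <- sim$connectomes
    covariate_table <- sim$covariates
  } else if (is.null(covariate_table)) {
    abort("`covariate_table` is required when `connectomes` are supplied.")
  }
  tick("cohort", st)

  st <- Sys.time()
  schedules <- make_schedules(connectomes, n_levels = config$n_levels)
  curves <- cohort_curves(connectomes, schedules, metrics = config$metrics,
                          ids = covariate_table$id, n_null = config$n_null,
                          seed = config$seed)
  auc <- auc_total(curves)
  tick("curves", st)

  st <- Sys.time()
  auc_wide <- auc |>
    dplyr::left_join(covariate_table, by = c(subject = "id"))
  m <- length(config$metrics)
  ancova_rows <- purrr::map(config$metrics, function(met) {
    d <- dplyr::filter(auc_wide, .data$metric == met)
    res <- ancova_auc(d, auc = "auc_total", group = "group",
                      covariates = config$covariates, mode = "permutation",
                      n_perm = config$n_perm, seed = config$seed)
    glance(res) |>
      dplyr::mutate(metric = met, .before = 1)
  })
  ancova_tbl <- dplyr::bind_rows(ancova_rows) |>
    dplyr::mutate(p.bonferroni = bonferroni_adjust(.data$p.value, m))

  mtpc_list <- purrr::map(config$metrics, function(met) {
    cm <- curve_matrix(curves, met)
    cm$values <- cm$values[covariate_table$id, , drop = FALSE]
    mtpc(cm, group = covariate_table$group,
         covariates = covariate_table[, config$covariates, drop = FALSE],
         n_perm = config$n_perm, cluster_min = config$cluster_min,
         seed = config$seed)
  })
  names(mtpc_list) <- config$metrics
  mtpc_tbl <- purrr::imap(mtpc_list, function(r, met) {
    glance(r) |> dplyr::mutate(metric = met, .before = 1)
  }) |> dplyr::bind_rows()
  tick("stats", st)

  manifest <- list(
    package_version = as.character(utils::packageVersion("tractnet")),
    seed = config$seed,
    n_subjects = nrow(covariate_table),
    config_hash = rlang::hash(config[setdiff(names(config), "cohort")]),
    cohort_hash = rlang::hash(lapply(connectomes, function(x) {
      if (inherits(x, "connectome")) x$weights else x
    })),
    parameters = list(
      n_levels = config$n_levels, n_perm = config$n_perm,
      n_null = config$n_null, cluster_min = config$cluster_min,
      covariates = config$covariates, strategy = config$strategy
    ),
    non_default_parameters = {
      defs <- run_config_defaults()
      names(defs)[vapply(names(defs), function(k) {
        !identical(as.integer(config[[k]]), as.integer(defs[[k]]))
      }, logical(1))]
    },
    timings_sec = timings,
    total_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  result <- structure(
    list(schedules = schedules, curves = curves, auc = auc,
         ancova = ancova_tbl, mtpc = mtpc_list, mtpc_summary = mtpc_tbl,
         covariates = covariate_table, manifest = manifest),
    class = "pipeline_result"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(curves, file.path(out_dir, "metric_curves.csv"))
    readr::write_csv(auc, file.path(out_dir, "auc_total.csv"))
    readr::write_csv(ancova_tbl, file.path(out_dir, "ancova_auc.csv"))
    readr::write_csv(mtpc_tbl, file.path(out_dir, "mtpc_summary.csv"))
    write_cohort_csv(covariate_table, file.path(out_dir, "cohort.csv"))
    jsonlite::write_json(
      list(density = schedules$density, weight = schedules$weight,
           d_max = schedules$d_max, rule = schedules$rule),
      file.path(out_dir, "schedules.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", nrow(x$covariates), " subjects, metrics: ",
      paste(unique(x$auc$metric), collapse = ", "), "\n", sep = "")
  print(x$ancova)
  print(x$mtpc_summary)
  invisible(x)
}
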