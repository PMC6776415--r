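#' Maximum density at which a cohort can be density-matched
#'
#' Density matching thresholds every subject to the same edge count, which is
#' only possible up to the sparsest subject's native density. Returns the
#' minimum over subjects of (edges present) / (possible node pairs).
#'
#' @param cohort List of [connectome()] objects or weight matrices.
#' @return A single density in (0, 1].
#' @export
upper_density <- function(cohort) {
  if (length(cohort) == 0L) abort("empty cohort.")
  dens <- vapply(cohort, function(x) {
    w <- if (inherits(x, "connectome")) x$weights else x
    edge_density_of(w)
  }, numeric(1))
  min(dens)
}

#' Build the density and weight threshold schedules
#'
#' Density levels are `n_levels` evenly spaced values spanning (0, d_max\]
#' where d_max comes from [upper_density()]. Weight thresholds are read off
#' the "average subject" (element-wise mean weight matrix): at each density
#' level the average network is density-thresholded and the weight threshold
#' is the smallest retained weight (`rule = "cutoff"`) or the mean of the
#' retained weights (`rule = "mean_retained"`).
#'
#' @param cohort List of [connectome()] objects or weight matrices.
#' @param n_levels Number of levels (default 40).
#' @param rule How the per-density weight threshold is defined.
#' @return An object of class `threshold_schedules`: list with `density`
#'   (ascending levels), `weight` (levels aligned to `density`), `d_max`,
#'   `rule`, and `average_subject`.
#' @export
make_schedules <- function(cohort, n_levels = 40L,
                           rule = c("cutoff", "mean_retained")) {
  rule <- match.arg(rule)
  d_max <- upper_density(cohort)
  wmats <- lapply(cohort, function(x) {
    if (inherits(x, "connectome")) x$weights else x
  })
  avg <- Reduce(`+`, wmats) / length(wmats)
  density_levels <- d_max * seq_len(n_levels) / n_levels
  weight_levels <- vapply(density_levels, function(d) {
    kept <- density_threshold_values(avg, d)
    if (length(kept) == 0L) return(max(avg))
    if (rule == "cutoff") min(kept) else mean(kept)
  }, numeric(1))
  structure(
    list(density = density_levels, weight = weight_levels, d_max = d_max,
         n_levels = as.integer(n_levels), rule = rule,
         average_subject = avg),
    class = "threshold_schedules"
  )
}

#' @export
print.threshold_schedules <- function(x, ...) {
  cat(sprintf("<threshold_schedules> %d levels, density (%.4f, %.4f], weight [%.3g, %.3g] (%s rule)\n",
              x$n_levels, x$density[1], x$d_max,
              min(x$weight), max(x$weight), x$rule))
  invisible(x)
}

# weights retained when w is thresholded to density level d
density_threshold_values <- function(w, d) {
  n <- nrow(w)
  n_keep <- round(d * n * (n - 1) / 2)
  if (n_keep == 0L) return(numeric(0))
  pairs <- upper_pairs(n)
  vals <- w[pairs]
  ord <- order(-vals, pairs[, 1L], pairs[, 2L])
  vals[ord][seq_len(min(n_keep, sum(vals > 0)))]
}

#' Threshold a weighted network
#'
#' Density thresholding retains the top `round(level * n(n-1)/2)` edges by
#' weight, ties broken by fixed lexicographic node-pair order (never more
#' edges than the network has). Weight thresholding retains edges with
#' `w >= level`. The result is re-normalised for weighted metrics.
#'
#' @param w Weight matrix or [connectome()].
#' @param level Threshold level.
#' @param kind `"density"` or `"weight"`.
#' @return A `tn_graph` (see [normalise_graph()]).
#' @export
threshold_network <- function(w, level, kind = c("density", "weight")) {
  kind <- match.arg(kind)
  if (inherits(w, "connectome")) w <- w$weights
  stop_if_not_weight_matrix(w)
  n <- nrow(w)
  keep <- matrix(FALSE, n, n)
  if (kind == "density") {
    if (level > 1) abort("density level must be <= 1.")
    n_keep <- round(level * n * (n - 1) / 2)
    pairs <- upper_pairs(n)
    vals <- w[pairs]
    ord <- order(-vals, pairs[, 1L], pairs[, 2L])
    sel <- ord[seq_len(min(n_keep, sum(vals > 0)))]
    keep[pairs[sel, , drop = FALSE]] <- TRUE
  } else {
    keep[upper.tri(w) & w >= level] <- TRUE
  }
  keep <- keep | t(keep)
  wt <- ifelse(keep, w, 0)
  normalise_graph(wt)
}

curve_metric_names <- c("degree", "strength", "global_efficiency",
                        "global_efficiency_w", "local_efficiency",
                        "local_efficiency_w", "betweenness", "betweenness_w",
                        "small_worldness", "small_worldness_w")

# global value of one named metric on a thresholded graph
eval_global_metric <- function(g, metric, n_null = 100, seed = 1L) {
  switch(metric,
    degree = mean(degree_strength(g)$degree),
    strength = mean(degree_strength(g)$strength),
    global_efficiency = mean(efficiency_pathlength(g)$efficiency),
    global_efficiency_w = mean(efficiency_pathlength(g)$efficiency_w),
    local_efficiency = mean(local_efficiency(g)$local_efficiency),
    local_efficiency_w = mean(local_efficiency(g)$local_efficiency_w),
    betweenness = mean(betweenness_centrality(g)$betweenness),
    betweenness_w = mean(betweenness_centrality(g)$betweenness_w),
    small_worldness = small_worldness(g, n_null = n_null, seed = seed)$S,
    small_worldness_w = small_worldness(g, n_null = n_null, seed = seed,
                                        weighted = TRUE)$S,
    abort(sprintf("unknown metric '%s'.", metric))
  )
}

#' Metric curves across the threshold schedules
#'
#' Evaluates each requested global metric on the thresholded network at every
#' schedule level. Unweighted degree — itself an index of edge density — is
#' evaluated along the weight-threshold schedule; every other metric along
#' the density schedule (where all subjects share identical edge counts).
#' A metric failure at one level yields `NA` there with a warning; the AUC
#' integrates the remaining finite panels.
#'
#' @param w Weight matrix or [connectome()] for one subject.
#' @param schedules A [make_schedules()] result.
#' @param metrics Character vector of metric names (see Details); default is
#'   all Table-style global metrics except the small-worldness pair, whose
#'   rewired nulls make them far costlier per level.
#' @param subject Optional subject id carried into the output.
#' @param n_null,seed Null count and seed used only by the small-worldness
#'   metrics.
#' @return Tibble of class `metric_curves`: columns `subject`, `metric`,
#'   `level_index`, `threshold`, `schedule`, `value`.
#' @export
metric_curves <- function(w, schedules,
                          metrics = c("degree", "strength",
                                      "global_efficiency",
                                      "global_efficiency_w",
                                      "local_efficiency",
                                      "local_efficiency_w",
                                      "betweenness", "betweenness_w"),
                          subject = NA_character_, n_null = 100, seed = 1L) {
  stopifnot(inherits(schedules, "threshold_schedules"))
  metrics <- match.arg(metrics, curve_metric_names, several.ok = TRUE)
  if (inherits(w, "connectome")) w <- w$weights
  # degree and strength depend only on the retained edge-weight multiset, so
  # they are evaluated from one sorted pass instead of building each
  # thresholded network (identical values; checked by the test suite)
  n <- nrow(w)
  n_pairs <- n * (n - 1) / 2
  v_desc <- sort(w[upper.tri(w)], decreasing = TRUE)
  n_pos <- sum(v_desc > 0)
  cum_w <- cumsum(v_desc)
  vmax <- if (n_pos > 0) v_desc[1L] else 1
  fast_value <- function(m, level, kind) {
    k <- if (kind == "density") {
      min(round(level * n_pairs), n_pos)
    } else {
      sum(v_desc >= level & v_desc > 0)
    }
    if (m == "degree") {
      2 * k / n
    } else {
      if (k == 0L) 0 else 2 * (cum_w[k] / vmax) / n
    }
  }
  rows <- purrr::map(metrics, function(m) {
    kind <- if (m == "degree") "weight" else "density"
    levels <- if (m == "degree") schedules$weight else schedules$density
    vals <- vapply(seq_along(levels), function(li) {
      if (m %in% c("degree", "strength")) {
        return(fast_value(m, levels[li], kind))
      }
      g <- threshold_network(w, levels[li], kind = kind)
      val <- tryCatch(eval_global_metric(g, m, n_null = n_null, seed = seed),
                      error = function(e) {
                        warn(sprintf("metric '%s' failed at level %d: %s",
                                     m, li, conditionMessage(e)))
                        NA_real_
                      })
      val
    }, numeric(1))
    tibble::tibble(subject = subject, metric = m,
                   level_index = seq_along(levels),
                   threshold = levels, schedule = kind, value = vals)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("metric_curves", class(out))
  out
}

#' Total area under metric curves
#'
#' Trapezoidal integral of each metric curve over its own threshold axis —
#' the threshold-free per-subject summary used for group comparison. The
#' degree curve runs along descending-ordered weight thresholds; its AUC is
#' taken over the ascending threshold axis like the rest.
#'
#' @param curves A [metric_curves()] tibble (may hold several subjects).
#' @return Tibble with `subject`, `metric`, `auc_total`.
#' @export
auc_total <- function(curves) {
  curves |>
    dplyr::group_by(.data$subject, .data$metric) |>
    dplyr::arrange(.data$threshold, .by_group = TRUE) |>
    dplyr::summarise(auc_total = trapezoid(.data$threshold, .data$value),
                     .groups = "drop")
}

#' Cohort metric curves
#'
#' Convenience wrapper running [metric_curves()] for every subject of a
#' cohort against shared schedules.
#'
#' @param cohort List of [connectome()] objects or weight matrices.
#' @param schedules A [make_schedules()] result (built from the same cohort
#'   if omitted).
#' @param ids Optional subject ids (defaults to names or sub001...).
#' @inheritParams metric_curves
#' @return A `metric_curves` tibble covering all subjects.
#' @export
cohort_curves <- function(cohort, schedules = NULL,
                          metrics = c("degree", "strength",
                                      "global_efficiency",
                                      "global_efficiency_w",
                                      "local_efficiency",
                                      "local_efficiency_w",
                                      "betweenness", "betweenness_w"),
                          ids = NULL, n_null = 100, seed = 1L) {
  if (is.null(schedules)) schedules <- make_schedules(cohort)
  if (is.null(ids)) {
    ids <- names(cohort) %||% sprintf("sub%03d", seq_along(cohort))
  }
  out <- purrr::map2(cohort, ids, function(w, id) {
    metric_curves(w, schedules, metrics = metrics, subject = id,
                  n_null = n_null, seed = seed)
  }) |> dplyr::bind_rows()
  class(out) <- c("metric_curves", class(out))
  out
}

#' Curve matrix for one metric
#'
#' Reshapes a cohort's curves for one metric into the subjects-by-thresholds
#' matrix the point-by-point statistics consume.
#'
#' @param curves A [metric_curves()] tibble.
#' @param metric Metric name to extract.
#' @return List with `values` (matrix, rownames = subject ids) and
#'   `thresholds`.
#' @export
curve_matrix <- function(curves, metric) {
  sub <- dplyr::filter(curves, .data$metric == !!metric)
  if (nrow(sub) == 0L) abort(sprintf("no curves for metric '%s'.", metric))
  wide <- sub |>
    dplyr::select("subject", "level_index", "value") |>
    tidyr::pivot_wider(names_from = "level_index", values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$subject
  thresholds <- sub |>
    dplyr::distinct(.data$level_index, .data$threshold) |>
    dplyr::arrange(.data$level_index)
  list(values = m, thresholds = thresholds$threshold)
}
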