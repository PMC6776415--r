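# group statistics: AUC ANCOVAs (parametric + Freedman-Lane permutation),
# multi-threshold permutation correction, partial Spearman correlations

build_design <- function(group, covariates) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) abort("`group` must have exactly two levels.")
  n <- length(group)
  z <- NULL
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    z <- as.matrix(as.data.frame(covariates))
    if (anyNA(z)) abort("covariates must be complete (listwise).")
    storage.mode(z) <- "double"
  }
  x0 <- cbind(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")), z)
  x1 <- cbind(x0, group = as.numeric(group) - 1)
  if (qr(x1)$rank < ncol(x1)) {
    cn <- colnames(x1)
    r <- qr(x1)
    bad <- cn[setdiff(seq_along(cn), r$pivot[seq_len(r$rank)])]
    abort(sprintf("singular design; collinear column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  list(x0 = x0, x1 = x1, group = group)
}

# F and t statistics of the group term for a matrix response, via the
# orthonormal bases of the reduced and full design
fl_stats <- function(y, q0, q1, df2) {
  y <- as.matrix(y)
  tot <- colSums(y^2)
  rss0 <- tot - colSums(crossprod(q0, y)^2)
  rss1 <- tot - colSums(crossprod(q1, y)^2)
  f <- pmax(rss0 - rss1, 0) / (rss1 / df2)
  f[rss1 <= .Machine$double.eps * tot] <- 0
  f
}

# signed t of the group coefficient for a matrix response; xtx_inv may be
# precomputed once per design and reused across permutations
group_t <- function(y, x1, df2, xtx_inv = chol2inv(chol(crossprod(x1)))) {
  y <- as.matrix(y)
  beta <- xtx_inv %*% crossprod(x1, y)
  res <- y - x1 %*% beta
  sigma2 <- colSums(res^2) / df2
  gi <- ncol(x1)
  se <- sqrt(pmax(sigma2 * xtx_inv[gi, gi], .Machine$double.xmin))
  as.numeric(beta[gi, ] / se)
}

normality_ok <- function(res) {
  if (length(res) >= 3 && length(res) <= 5000 && sd(res) > 0) {
    shapiro.test(res)$p.value > 0.05
  } else {
    TRUE
  }
}

#' Group ANCOVA on per-subject AUC values
#'
#' Tests the group effect on a threshold-free curve summary, adjusting for
#' covariates. Parametric mode fits `auc ~ covariates + group` and reports
#' the group F test, applying a log10 transform when the raw-scale residuals
#' fail a normality screen but the transformed ones pass. Permutation mode
#' uses the identical F statistic with a Freedman–Lane null: residuals of the
#' reduced (covariates-only) model are permuted, re-added to the reduced
#' fit, and the F statistic recomputed; p = (b + 1)/(m + 1).
#'
#' @param data Data frame with one row per subject.
#' @param auc Name of the AUC column.
#' @param group Name of the two-level group column.
#' @param covariates Character vector of covariate column names (complete
#'   cases required; listwise deletion is applied first).
#' @param mode `"parametric"`, `"permutation"`, or `"auto"` (parametric when
#'   raw or log10 residuals pass the normality screen, else permutation).
#' @param n_perm Number of permutations (default 10000).
#' @param exact Enumerate all n! residual permutations instead of sampling
#'   (permutation mode, n <= 9 only); p is then the exact fraction of
#'   permutations with F* >= F.
#' @param seed Integer seed for the permutation draw.
#' @return An object of class `auc_ancova` with `F`, `df1`, `df2`, `p`,
#'   `mode`, `transform`, `n_perm`, `n`.
#' @export
ancova_auc <- function(data, auc = "auc_total", group = "group",
                       covariates = c("age", "sex"),
                       mode = c("permutation", "parametric", "auto"),
                       n_perm = 10000L, exact = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  cols <- c(auc, group, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  data <- data[complete.cases(data[, cols, drop = FALSE]), , drop = FALSE]
  y <- as.numeric(data[[auc]])
  des <- build_design(data[[group]],
                      if (length(covariates)) data[, covariates, drop = FALSE])
  if (min(table(des$group)) < 2L) abort("need >= 2 subjects per group.")
  n <- length(y)
  df1 <- 1L
  df2 <- n - ncol(des$x1)
  transform <- "none"

  if (mode %in% c("parametric", "auto")) {
    fit_raw <- lm.fit(des$x1, y)
    raw_ok <- normality_ok(fit_raw$residuals)
    log_ok <- FALSE
    ylog <- NULL
    if (!raw_ok && all(y > 0)) {
      ylog <- log10(y)
      log_ok <- normality_ok(lm.fit(des$x1, ylog)$residuals)
    }
    if (raw_ok || log_ok || mode == "parametric") {
      yy <- if (!raw_ok && log_ok) {
        transform <- "log10"
        ylog
      } else {
        y
      }
      q0 <- qr.Q(qr(des$x0))
      q1 <- qr.Q(qr(des$x1))
      f <- fl_stats(yy, q0, q1, df2)
      p <- pf(f, df1, df2, lower.tail = FALSE)
      return(new_auc_ancova(f, df1, df2, p, "parametric", transform, NA_integer_, n))
    }
    mode <- "permutation"
  }

  q0 <- qr.Q(qr(des$x0))
  q1 <- qr.Q(qr(des$x1))
  f_obs <- fl_stats(y, q0, q1, df2)
  fit0 <- q0 %*% crossprod(q0, y)
  res0 <- y - fit0
  if (exact) {
    if (n > 9L) abort("exact enumeration supported only for n <= 9.")
    perm_idx <- all_permutations(n)
    n_perm <- ncol(perm_idx)
  } else {
    set.seed(seed)
    perm_idx <- replicate(n_perm, sample.int(n))
  }
  y_star <- matrix(fit0, n, n_perm) + matrix(res0[perm_idx], n, n_perm)
  f_null <- fl_stats(y_star, q0, q1, df2)
  tie_tol <- 1e-8 * max(1, f_obs)   # float noise guard for equal statistics
  p <- if (exact) {
    mean(f_null >= f_obs - tie_tol)
  } else {
    (sum(f_null >= f_obs - tie_tol) + 1) / (n_perm + 1)
  }
  new_auc_ancova(f_obs, df1, df2, p, "permutation", "none", n_perm, n)
}

new_auc_ancova <- function(f, df1, df2, p, mode, transform, n_perm, n) {
  structure(
    list(F = unname(f), df1 = df1, df2 = df2, p = unname(p), mode = mode,
         transform = transform, n_perm = n_perm, n = n),
    class = "auc_ancova"
  )
}

#' @export
print.auc_ancova <- function(x, ...) {
  cat(sprintf("<auc_ancova> F(%d, %d) = %.3f, p = %.4g [%s%s]\n",
              x$df1, x$df2, x$F, x$p, x$mode,
              if (x$transform != "none") paste0(", ", x$transform) else ""))
  invisible(x)
}

#' @export
tidy.auc_ancova <- function(x, ...) {
  tibble::tibble(term = "group", statistic = x$F, df1 = x$df1, df2 = x$df2,
                 p.value = x$p)
}

#' @export
glance.auc_ancova <- function(x, ...) {
  tibble::tibble(statistic = x$F, df1 = x$df1, df2 = x$df2, p.value = x$p,
                 mode = x$mode, transform = x$transform,
                 n_perm = x$n_perm, n = x$n)
}

find_clusters <- function(exceed, cluster_min) {
  r <- rle(exceed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= cluster_min
  cbind(start = starts[keep], end = ends[keep])
}

cluster_areas <- function(abs_t, thresholds, crit, cluster_min,
                          area = c("above_critical", "total")) {
  area <- match.arg(area)
  cl <- find_clusters(abs_t > crit, cluster_min)
  if (nrow(cl) == 0L) return(numeric(0))
  apply(cl, 1L, function(se) {
    idx <- se[1]:se[2]
    if (length(idx) == 1L) return(0)   # degenerate single-level cluster
    yv <- if (area == "above_critical") abs_t[idx] - crit else abs_t[idx]
    xv <- thresholds[idx]
    if (xv[1] > xv[length(xv)]) {     # descending axis (weight schedule)
      xv <- rev(xv)
      yv <- rev(yv)
    }
    trapezoid(xv, yv)
  })
}

#' Multi-threshold permutation correction (MTPC)
#'
#' Point-by-point group inference along a metric curve with family-wise
#' error control across thresholds. At each threshold a covariate-adjusted
#' group t statistic is computed; the null distribution of the maximum |t|
#' over thresholds (Freedman–Lane permutation) yields the two-tailed
#' FWE-adjusted critical value (95th percentile) and `p_fwe` for the observed
#' peak. Runs of at least `cluster_min` consecutive supra-critical thresholds
#' form clusters whose trapezoidal area of |t| above the critical value
#' (`auc_mtpc`) must additionally exceed the mean analogous null-cluster area
#' (`auc_crit`) for the result to be declared significant.
#'
#' @param y Subjects-by-thresholds matrix of metric values (or the list from
#'   [curve_matrix()]).
#' @param group Two-level group vector.
#' @param covariates Data frame / matrix of covariates, or `NULL`.
#' @param thresholds Threshold axis (defaults to 1..T).
#' @param n_perm Number of permutations (default 10000; < 100 warns).
#' @param cluster_min Minimum consecutive supra-critical thresholds (default 3).
#' @param alpha FWE level for the critical threshold (default 0.05).
#' @param cluster_area `"above_critical"` (default) integrates the excess
#'   |t| - t_crit; `"total"` integrates |t| itself over the cluster.
#' @param seed Integer seed.
#' @return An object of class `mtpc_result`.
#' @export
mtpc <- function(y, group, covariates = NULL, thresholds = NULL,
                 n_perm = 10000L, cluster_min = 3L, alpha = 0.05,
                 cluster_area = c("above_critical", "total"), seed = 1L) {
  cluster_area <- match.arg(cluster_area)
  if (is.list(y) && !is.data.frame(y) && !is.matrix(y)) {
    thresholds <- thresholds %||% y$thresholds
    y <- y$values
  }
  y <- as.matrix(y)
  n <- nrow(y)
  nt <- ncol(y)
  thresholds <- thresholds %||% seq_len(nt)
  if (anyNA(y)) abort("curve matrix contains missing values.")
  if (n_perm < 100L) warn("fewer than 100 permutations; p_fwe is coarse.")
  des <- build_design(group, covariates)
  df2 <- n - ncol(des$x1)
  if (df2 < 1L) abort("degenerate design: no residual degrees of freedom.")

  xtx_inv <- chol2inv(chol(crossprod(des$x1)))
  t_obs <- group_t(y, des$x1, df2, xtx_inv)
  q0 <- qr.Q(qr(des$x0))
  fit0 <- q0 %*% crossprod(q0, y)
  res0 <- y - fit0

  set.seed(seed)
  max_null <- numeric(n_perm)
  null_areas_sum <- 0
  null_areas_n <- 0L
  t_null <- matrix(NA_real_, n_perm, nt)
  for (b in seq_len(n_perm)) {
    yp <- fit0 + res0[sample.int(n), , drop = FALSE]
    tb <- group_t(yp, des$x1, df2, xtx_inv)
    t_null[b, ] <- tb
    max_null[b] <- max(abs(tb))
  }
  t_crit <- unname(quantile(max_null, 1 - alpha, type = 7))
  t_max_idx <- which.max(abs(t_obs))
  t_max <- t_obs[t_max_idx]
  p_fwe <- (sum(max_null >= abs(t_max) - 1e-8 * max(1, abs(t_max))) + 1) /
    (n_perm + 1)

  for (b in seq_len(n_perm)) {
    ar <- cluster_areas(abs(t_null[b, ]), thresholds, t_crit, cluster_min,
                        cluster_area)
    if (length(ar)) {
      null_areas_sum <- null_areas_sum + sum(ar)
      null_areas_n <- null_areas_n + length(ar)
    }
  }
  auc_crit <- if (null_areas_n > 0L) null_areas_sum / null_areas_n else 0

  cl <- find_clusters(abs(t_obs) > t_crit, cluster_min)
  cl_area <- if (nrow(cl)) {
    cluster_areas(abs(t_obs), thresholds, t_crit, cluster_min, cluster_area)
  } else {
    numeric(0)
  }
  clusters <- tibble::tibble(
    start = as.integer(cl[, 1L] %||% integer(0)),
    end = as.integer(cl[, 2L] %||% integer(0)),
    auc_mtpc = cl_area
  )
  significant <- any(clusters$auc_mtpc > auc_crit)

  structure(
    list(t = t_obs, thresholds = thresholds, t_max = t_max,
         tau = thresholds[t_max_idx], df = df2, p_fwe = p_fwe,
         t_crit = t_crit, clusters = clusters, auc_crit = auc_crit,
         significant = significant, n_perm = n_perm,
         cluster_min = cluster_min, alpha = alpha,
         cluster_area = cluster_area, seed = seed),
    class = "mtpc_result"
  )
}

#' @export
print.mtpc_result <- function(x, ...) {
  cat(sprintf("<mtpc_result> t_max(%d) = %.3f at tau = %.4g, p_FWE = %.4g, t_crit = %.3f\n",
              x$df, x$t_max, x$tau, x$p_fwe, x$t_crit))
  cat(sprintf("  %d cluster(s), AUC_crit = %.3f, significant: %s\n",
              nrow(x$clusters), x$auc_crit, if (x$significant) "yes" else "no"))
  invisible(x)
}

#' @export
tidy.mtpc_result <- function(x, ...) {
  tibble::tibble(level_index = seq_along(x$t), threshold = x$thresholds,
                 statistic = x$t, supra_critical = abs(x$t) > x$t_crit)
}

#' @export
glance.mtpc_result <- function(x, ...) {
  tibble::tibble(t_max = x$t_max, tau = x$tau, df = x$df, p_fwe = x$p_fwe,
                 t_crit = x$t_crit, n_clusters = nrow(x$clusters),
                 auc_mtpc = if (nrow(x$clusters)) max(x$clusters$auc_mtpc) else NA_real_,
                 auc_crit = x$auc_crit, significant = x$significant,
                 n_perm = x$n_perm)
}

#' Partial Spearman correlation
#'
#' Rank-based partial correlation: x, y and the covariates are
#' rank-transformed (pairwise-complete rows only), both rank vectors are
#' adjusted for the covariate ranks by linear regression, and the residuals
#' are correlated. Degrees of freedom are n - 2 - (number of covariates).
#'
#' @param data Data frame.
#' @param x,y Column names of the two measures.
#' @param covariates Character vector of covariate column names.
#' @param m_bonferroni Multiplicity for the adjusted p (default 1).
#' @return One-row tibble: `x`, `y`, `rho`, `df`, `n`, `p.value`,
#'   `p.bonferroni`.
#' @export
partial_spearman <- function(data, x, y, covariates = character(),
                             m_bonferroni = 1L) {
  cols <- c(x, y, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  d <- data[complete.cases(data[, cols, drop = FALSE]), cols, drop = FALSE]
  n <- nrow(d)
  k <- length(covariates)
  if (n < 5L) abort("need >= 5 complete pairs after pairwise deletion.")
  ranks <- vapply(d, rank, numeric(n))
  if (any(apply(ranks[, c(x, y), drop = FALSE], 2, sd) == 0)) {
    abort("constant input: ranks have zero variance.")
  }
  rx <- ranks[, x]
  ry <- ranks[, y]
  if (k > 0) {
    z <- cbind(1, ranks[, covariates, drop = FALSE])
    rx <- lm.fit(z, rx)$residuals
    ry <- lm.fit(z, ry)$residuals
  }
  rho <- cor(rx, ry)
  df <- n - 2L - k
  tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  tibble::tibble(x = x, y = y, rho = rho, df = df, n = n, p.value = p,
                 p.bonferroni = bonferroni_adjust(p, m_bonferroni))
}

#' Group ANCOVA table over several metrics
#'
#' Runs [ancova_auc()] for each metric column of a subject-level table and
#' assembles the results in the familiar group-comparison layout (F, df1,
#' df2, p, Bonferroni-adjusted p over the metrics tested). Useful for
#' recomputing a published group-comparison table from deposited
#' subject-level data.
#'
#' @param data Data frame: one row per subject, containing `group`, the
#'   covariates and one column per metric AUC.
#' @param metrics Character vector of metric column names.
#' @inheritParams ancova_auc
#' @return Tibble with one row per metric.
#' @export
ancova_table <- function(data, metrics, group = "group",
                         covariates = c("age", "sex"),
                         mode = c("auto", "parametric", "permutation"),
                         n_perm = 10000L, seed = 1L) {
  mode <- match.arg(mode)
  rows <- purrr::map(metrics, function(met) {
    res <- ancova_auc(data, auc = met, group = group,
                      covariates = covariates, mode = mode,
                      n_perm = n_perm, seed = seed)
    glance(res) |> dplyr::mutate(metric = met, .before = 1)
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(p.bonferroni = bonferroni_adjust(.data$p.value,
                                                   length(metrics)))
}

#' Demographic comparison table (convenience report)
#'
#' Quick group comparison of cohort characteristics: Welch t-tests for
#' continuous columns, chi-squared for binary ones. Intended for describing
#' a cohort, not for inference about the network analysis.
#'
#' @param data Cohort data frame with a two-level `group` column.
#' @param vars Columns to compare (defaults to all numeric columns).
#' @param group Group column name.
#' @return Tibble with per-variable group means, test statistic and p-value.
#' @export
demographics_table <- function(data, vars = NULL, group = "group") {
  g <- as.factor(data[[group]])
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  rows <- purrr::map(vars, function(v) {
    x <- data[[v]]
    ok <- !is.na(x)
    means <- tapply(x[ok], g[ok], mean)
    if (length(unique(stats::na.omit(x))) <= 2) {
      tb <- table(g[ok], x[ok])
      tst <- suppressWarnings(stats::chisq.test(tb))
      tibble::tibble(variable = v, mean_1 = means[1], mean_2 = means[2],
                     test = "chi-squared", statistic = unname(tst$statistic),
                     p.value = tst$p.value)
    } else {
      tst <- stats::t.test(x[ok] ~ g[ok])
      tibble::tibble(variable = v, mean_1 = means[1], mean_2 = means[2],
                     test = "welch-t", statistic = unname(tst$statistic),
                     p.value = tst$p.value)
    }
  })
  out <- dplyr::bind_rows(rows)
  names(out)[2:3] <- paste0("mean_", levels(g))
  out
}

#' Bonferroni adjustment
#'
#' @param p Vector of p-values.
#' @param m Number of comparisons (>= 1).
#' @return `pmin(1, p * m)`.
#' @export
bonferroni_adjust <- function(p, m) {
  if (m < 1) abort("`m` must be >= 1.")
  pmin(1, p * m)
}
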