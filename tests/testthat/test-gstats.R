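sim_auc_data <- function(n = 30, effect = 0, seed = 1) {
  set.seed(seed)
  grp <- factor(rep(c("control", "patient"), each = n / 2))
  age <- runif(n, 50, 85)
  sex <- rbinom(n, 1, 0.5)
  auc <- 10 + 0.02 * age + 0.5 * sex + effect * (grp == "patient") + rnorm(n)
  tibble::tibble(auc_total = auc, group = grp, age = age, sex = sex)
}

test_that("identical AUC values in both groups give F = 0 and p = 1", {
  d <- sim_auc_data(20, seed = 2)
  d$auc_total <- 5
  a_par <- ancova_auc(d, mode = "parametric", covariates = c("age", "sex"))
  expect_equal(a_par$F, 0)
  expect_equal(a_par$p, 1)
  a_perm <- ancova_auc(d, mode = "permutation", n_perm = 200,
                       covariates = c("age", "sex"))
  expect_equal(a_perm$F, 0)
  expect_equal(a_perm$p, 1)
})

test_that("parametric and permutation modes share the identical F statistic", {
  d <- sim_auc_data(24, effect = 1, seed = 3)
  a_par <- ancova_auc(d, mode = "parametric", covariates = c("age", "sex"))
  a_perm <- ancova_auc(d, mode = "permutation", n_perm = 99,
                       covariates = c("age", "sex"))
  expect_equal(a_par$F, a_perm$F, tolerance = 1e-12)
  # and the F matches R's own ANCOVA on the same design
  fit <- lm(auc_total ~ age + sex + group, data = d)
  f_ref <- anova(fit)["group", "F value"]
  expect_equal(a_par$F, f_ref, tolerance = 1e-10)
  expect_equal(a_par$df2, fit$df.residual)
})

test_that("exhaustive permutation p equals the brute-force fraction over label splits", {
  d <- sim_auc_data(8, effect = 2, seed = 4)[, c("auc_total", "group")]
  a <- ancova_auc(d, covariates = character(), mode = "permutation",
                  exact = TRUE)
  # brute force: every assignment of 4 subjects to 'patient'; each split
  # corresponds to 4!4! orderings, so the split fractions weight equally
  y <- d$auc_total
  splits <- utils::combn(8, 4)
  f_split <- apply(splits, 2, function(idx) {
    g <- factor(ifelse(seq_len(8) %in% idx, "p", "c"))
    anova(lm(y ~ g))["g", "F value"]
  })
  p_brute <- mean(f_split >= a$F - 1e-12)
  expect_equal(a$p, p_brute, tolerance = 1e-12)
})

test_that("permutation ANCOVA holds its nominal size under the null", {
  n_rep <- 1000
  rej <- 0L
  for (r in seq_len(n_rep)) {
    d <- sim_auc_data(24, effect = 0, seed = 5000 + r)
    a <- ancova_auc(d, covariates = c("age", "sex"), mode = "permutation",
                    n_perm = 199, seed = r)
    rej <- rej + (a$p <= 0.05)
  }
  lo <- qbinom(0.025, n_rep, 0.05)
  hi <- qbinom(0.975, n_rep, 0.05)
  expect_gte(rej, lo)
  expect_lte(rej, hi)
})

test_that("permutation p-values are invariant to affine covariate rescaling", {
  d <- sim_auc_data(26, effect = 0.8, seed = 6)
  a1 <- ancova_auc(d, covariates = c("age", "sex"), mode = "permutation",
                   n_perm = 500, seed = 9)
  d2 <- d
  d2$age <- d$age * 12 - 300
  a2 <- ancova_auc(d2, covariates = c("age", "sex"), mode = "permutation",
                   n_perm = 500, seed = 9)
  expect_equal(a1$p, a2$p, tolerance = 1e-12)
  expect_equal(a1$F, a2$F, tolerance = 1e-9)
})

test_that("with no covariates the permutation ANCOVA matches a permutation t-test", {
  d <- sim_auc_data(20, effect = 1, seed = 7)[, c("auc_total", "group")]
  a <- ancova_auc(d, covariates = character(), mode = "permutation",
                  n_perm = 400, seed = 13)
  # seed-matched two-sample permutation t-test via the same residual shuffles
  y <- d$auc_total
  n <- length(y)
  tstat <- function(yy) {
    g <- d$group == "patient"
    abs(t.test(yy[g], yy[!g], var.equal = TRUE)$statistic)
  }
  fit0 <- mean(y)
  res0 <- y - fit0
  set.seed(13)
  t_null <- replicate(400, tstat(fit0 + res0[sample.int(n)]))
  p_t <- (sum(t_null >= tstat(y) - 1e-12) + 1) / 401
  expect_equal(a$p, p_t, tolerance = 1e-12)
})

test_that("the parametric path screens residual normality and can log-transform", {
  set.seed(8)
  n <- 40
  grp <- factor(rep(c("control", "patient"), each = n / 2))
  age <- runif(n, 50, 85)
  d <- tibble::tibble(
    auc_total = exp(rnorm(n, sd = 1.2)) * exp(0.02 * age),
    group = grp, age = age, sex = rbinom(n, 1, 0.5))
  a <- ancova_auc(d, covariates = c("age", "sex"), mode = "auto",
                  n_perm = 199)
  # heavy lognormal data: either the log10 transform rescued parametric
  # testing or the permutation fallback engaged
  expect_true((a$mode == "parametric" && a$transform == "log10") ||
                a$mode == "permutation")
  expect_error(
    ancova_auc(dplyr::mutate(d, dup = age), mode = "parametric",
               covariates = c("age", "dup")),
    "collinear")
})

test_that("MTPC applies the cluster-extent and cluster-mass conjunction", {
  set.seed(10)
  n <- 24
  nt <- 20
  grp <- factor(rep(c("a", "b"), each = n / 2))
  covs <- tibble::tibble(age = runif(n, 50, 80))
  y <- matrix(rnorm(n * nt, sd = 0.5), n, nt)
  null_res <- mtpc(y, grp, covs, n_perm = 300, seed = 1)
  expect_false(null_res$significant)
  expect_true(null_res$p_fwe > 0.05 || nrow(null_res$clusters) == 0)

  # effect confined to two adjacent thresholds: excluded by cluster_min = 3
  y2 <- y
  y2[grp == "b", 9:10] <- y2[grp == "b", 9:10] + 3
  res2 <- mtpc(y2, grp, covs, n_perm = 300, cluster_min = 3, seed = 1)
  expect_equal(nrow(res2$clusters), 0)
  expect_false(res2$significant)
  expect_lt(res2$p_fwe, 0.05)   # the peak itself is clearly supra-critical
  res2b <- mtpc(y2, grp, covs, n_perm = 300, cluster_min = 1, seed = 1)
  expect_gte(nrow(res2b$clusters), 1)
  expect_true(res2b$significant)

  # broad effect across many thresholds: detected under the full rule
  y3 <- y
  y3[grp == "b", 5:15] <- y3[grp == "b", 5:15] + 2
  res3 <- mtpc(y3, grp, covs, n_perm = 300, seed = 1)
  expect_true(res3$significant)
  expect_gte(max(res3$clusters$end - res3$clusters$start) + 1, 3)
  expect_true(all(res3$clusters$auc_mtpc >= 0))
  glance_row <- glance(res3)
  expect_true(glance_row$significant)
  expect_equal(nrow(tidy(res3)), nt)
})

test_that("partial Spearman correlations remove monotone confounds", {
  # perfect monotone association
  d <- tibble::tibble(x = 1:20, y = (1:20)^3)
  r <- partial_spearman(d, "x", "y")
  expect_equal(r$rho, 1, tolerance = 1e-12)

  # x and y both driven by a shared covariate: partial rho collapses
  set.seed(12)
  n <- 200
  z <- rnorm(n)
  d2 <- tibble::tibble(x = 2 * z + rnorm(n, sd = 0.4),
                       y = -3 * z + rnorm(n, sd = 0.4), z = z)
  raw <- partial_spearman(d2, "x", "y")
  adj <- partial_spearman(d2, "x", "y", covariates = "z")
  expect_lt(abs(adj$rho), 0.15)
  expect_gt(abs(raw$rho), 0.5)
  expect_equal(adj$df, n - 3)

  # equals an explicit rank-regression oracle on a small sample
  set.seed(13)
  d3 <- tibble::tibble(x = rnorm(10), y = rnorm(10), c1 = rnorm(10))
  mine <- partial_spearman(d3, "x", "y", covariates = "c1")
  rx <- rank(d3$x); ry <- rank(d3$y); rc <- rank(d3$c1)
  ex <- residuals(lm(rx ~ rc))
  ey <- residuals(lm(ry ~ rc))
  expect_equal(mine$rho, cor(ex, ey), tolerance = 1e-12)

  expect_error(partial_spearman(tibble::tibble(x = rep(1, 10), y = 1:10),
                                "x", "y"), "constant")
  expect_error(partial_spearman(tibble::tibble(x = 1:4, y = 4:1), "x", "y"),
               ">= 5")
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.01, 5), 0.05)
  expect_equal(bonferroni_adjust(0.4, 5), 1.0)
  expect_equal(bonferroni_adjust(c(0.2, 0.7), 1), c(0.2, 0.7))
  expect_error(bonferroni_adjust(0.1, 0), ">= 1")
})

test_that("ancova_table assembles per-metric rows with family-wise adjustment", {
  set.seed(14)
  d <- sim_auc_data(30, effect = 1.5, seed = 14)
  d$m1 <- d$auc_total
  d$m2 <- rnorm(30)
  tab <- ancova_table(d, metrics = c("m1", "m2"),
                      covariates = c("age", "sex"), mode = "parametric")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$p.bonferroni, pmin(1, tab$p.value * 2))
})
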