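make_test_cohort <- function(n_sub = 6, n_nodes = 30, seed = 17, ...) {
  sim <- simulate_cohort(cohort_spec(n_controls = ceiling(n_sub / 2),
                                     n_patients = floor(n_sub / 2),
                                     n_nodes = n_nodes, seed = seed, ...))
  sim$connectomes
}

test_that("upper density is the sparsest subject's native density", {
  w1 <- matrix(0, 5, 5)
  w1[1, 2] <- w1[2, 1] <- 1; w1[3, 4] <- w1[4, 3] <- 1; w1[1, 5] <- w1[5, 1] <- 1
  w2 <- w1; w2[2, 3] <- w2[3, 2] <- 1; w2[4, 5] <- w2[5, 4] <- 0.5; w2[1, 3] <- w2[3, 1] <- 2
  expect_equal(upper_density(list(w1, w2)), 0.3)
  expect_equal(upper_density(list(w2, w2)), 0.6)
  expect_error(upper_density(list()), "empty")

  cohort <- make_test_cohort()
  brute <- min(vapply(cohort, function(c) {
    w <- c$weights
    sum(w[upper.tri(w)] > 0) / (nrow(w) * (nrow(w) - 1) / 2)
  }, numeric(1)))
  expect_equal(upper_density(cohort), brute)
})

test_that("density levels are evenly spaced and weight levels are read off the average subject", {
  cohort <- make_test_cohort()
  sch <- make_schedules(cohort, n_levels = 40)
  dmax <- upper_density(cohort)
  expect_equal(sch$density, dmax * (1:40) / 40)
  expect_equal(diff(sch$density), rep(dmax / 40, 39))
  # weight thresholds never increase with density
  expect_true(all(diff(sch$weight) <= 1e-12))

  # three-edge worked example: keeping two edges puts the cut at 0.5
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.9
  w[1, 3] <- w[3, 1] <- 0.5
  w[2, 3] <- w[3, 2] <- 0.1
  sch3 <- make_schedules(list(w), n_levels = 3)
  expect_equal(sch3$weight[2], 0.5)   # density 2/3 keeps two edges
  # mean-retained variant averages the kept weights instead
  sch3b <- make_schedules(list(w), n_levels = 3, rule = "mean_retained")
  expect_equal(sch3b$weight[2], 0.7)
})

test_that("thresholding keeps the strongest edges with deterministic tie-breaks", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.9
  w[1, 3] <- w[3, 1] <- 0.5
  w[2, 3] <- w[3, 2] <- 0.1
  g <- threshold_network(w, 2 / 3, "density")
  expect_equal(sum(g$adj) / 2, 2)
  expect_true(g$adj[1, 2] == 1 && g$adj[1, 3] == 1 && g$adj[2, 3] == 0)

  # weight threshold at the (normalised) maximum keeps only maximal edges
  gw <- threshold_network(w / 0.9, 1.0, "weight")
  expect_equal(sum(gw$adj) / 2, 1)
  expect_error(threshold_network(w, 1.5, "density"), "<= 1")

  # ties broken by lexicographic node pair order, reproducibly
  wt <- matrix(0, 4, 4)
  wt[1, 2] <- wt[2, 1] <- 1; wt[1, 3] <- wt[3, 1] <- 1; wt[1, 4] <- wt[4, 1] <- 1
  gt1 <- threshold_network(wt, 2 / 6, "density")
  expect_equal(gt1$adj[1, 2], 1)
  expect_equal(gt1$adj[1, 3], 1)
  expect_equal(gt1$adj[1, 4], 0)

  # surviving edge count never decreases with density
  set.seed(2)
  wr <- random_weight_matrix(12, 0.6)
  counts <- vapply(seq(0.05, 0.95, by = 0.05), function(d) {
    sum(threshold_network(wr, d, "density")$adj) / 2
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("all subjects share edge counts at each density level; full density is native", {
  cohort <- make_test_cohort(n_sub = 5)
  sch <- make_schedules(cohort, n_levels = 10)
  for (li in seq_len(10)) {
    counts <- vapply(cohort, function(c) {
      sum(threshold_network(c$weights, sch$density[li], "density")$adj) / 2
    }, numeric(1))
    expect_equal(length(unique(counts)), 1L)
  }
  # native density of the sparsest subject: its network survives intact
  dens <- vapply(cohort, function(c) {
    w <- c$weights
    sum(w[upper.tri(w)] > 0) / (nrow(w) * (nrow(w) - 1) / 2)
  }, numeric(1))
  sparsest <- which.min(dens)
  g_full <- threshold_network(cohort[[sparsest]]$weights, sch$d_max, "density")
  expect_equal(g_full$adj, (cohort[[sparsest]]$weights > 0) * 1)
})

test_that("trapezoidal AUC is exact for constants and linear curves and matches a Riemann oracle", {
  sch_x <- seq(0.01, 0.4, length.out = 40)
  const <- tibble::tibble(subject = "s1", metric = "m",
                          level_index = 1:40, threshold = sch_x,
                          schedule = "density", value = 3.3)
  auc_c <- auc_total(const)$auc_total
  expect_equal(auc_c, 3.3 * (max(sch_x) - min(sch_x)), tolerance = 1e-12)

  lin <- const
  lin$value <- 2 * sch_x + 1
  auc_l <- auc_total(lin)$auc_total
  expect_equal(auc_l, (max(sch_x)^2 - min(sch_x)^2) + (max(sch_x) - min(sch_x)),
               tolerance = 1e-12)

  set.seed(8)
  rnd <- const
  rnd$value <- runif(40)
  auc_r <- auc_total(rnd)$auc_total
  # fine-grid Riemann sum over the piecewise-linear interpolant
  xs <- sch_x
  ys <- rnd$value
  grid <- seq(min(xs), max(xs), length.out = 400001)
  riemann <- mean(approx(xs, ys, xout = grid)$y) * (max(xs) - min(xs))
  expect_equal(auc_r, riemann, tolerance = 1e-6)
  expect_equal(auc_r, pracma::trapz(xs, ys), tolerance = 1e-12)
})

test_that("metric curves follow their schedules and degree decreases with weight threshold", {
  cohort <- make_test_cohort(n_sub = 4)
  sch <- make_schedules(cohort, n_levels = 15)
  cur <- metric_curves(cohort[[1]], sch,
                       metrics = c("degree", "strength", "global_efficiency"),
                       subject = "s1")
  expect_setequal(unique(cur$schedule[cur$metric == "degree"]), "weight")
  expect_setequal(unique(cur$schedule[cur$metric != "degree"]), "density")
  deg <- cur[cur$metric == "degree", ]
  # thresholds descend along the weight schedule, so degree rises with index:
  # as a function of the threshold value it is non-increasing
  ord <- order(deg$threshold)
  expect_true(all(diff(deg$value[ord]) <= 1e-12))
})

test_that("the closed-form degree/strength curves equal the thresholded-network route", {
  cohort <- make_test_cohort(n_sub = 3, n_nodes = 25)
  sch <- make_schedules(cohort, n_levels = 12)
  w <- cohort[[2]]$weights
  fast <- metric_curves(w, sch, metrics = c("degree", "strength"))
  slow_strength <- vapply(sch$density, function(d) {
    mean(degree_strength(threshold_network(w, d, "density"))$strength)
  }, numeric(1))
  slow_degree <- vapply(sch$weight, function(tau) {
    mean(degree_strength(threshold_network(w, tau, "weight"))$degree)
  }, numeric(1))
  expect_equal(fast$value[fast$metric == "strength"], slow_strength,
               tolerance = 1e-12)
  expect_equal(fast$value[fast$metric == "degree"], slow_degree,
               tolerance = 1e-12)
})

test_that("curve matrices reshape cohort curves for the group statistics", {
  cohort <- make_test_cohort(n_sub = 4)
  sch <- make_schedules(cohort, n_levels = 8)
  cur <- cohort_curves(cohort, sch, metrics = c("strength"))
  cm <- curve_matrix(cur, "strength")
  expect_equal(dim(cm$values), c(4, 8))
  expect_equal(cm$thresholds, sch$density)
  expect_error(curve_matrix(cur, "betweenness"), "no curves")
})
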