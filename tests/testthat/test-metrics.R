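test_that("weight normalisation divides by the maximum and tolerates empty graphs", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 2
  w[2, 3] <- w[3, 2] <- 4
  g <- normalise_graph(w)
  expect_equal(g$w[1, 2], 0.5)
  expect_equal(g$w[2, 3], 1.0)

  w_eq <- complete_graph(4) * 3
  expect_true(all(normalise_graph(w_eq)$w[upper.tri(w_eq)] == 1))

  empty <- matrix(0, 4, 4)
  g0 <- normalise_graph(empty)
  expect_true(all(g0$w == 0))

  neg <- w
  neg[1, 3] <- neg[3, 1] <- -1
  expect_error(normalise_graph(neg), "negative")
})

test_that("closed forms hold on complete, star and path graphs", {
  k4 <- complete_graph(4)
  ds <- degree_strength(k4)
  expect_equal(ds$degree, rep(3, 4))
  expect_equal(clustering_coef(k4)$clustering, rep(1, 4))
  ep <- efficiency_pathlength(k4)
  expect_equal(ep$efficiency, rep(1, 4))
  expect_equal(ep$path_length, rep(1, 4))
  expect_equal(local_efficiency(k4)$local_efficiency, rep(1, 4))

  st <- star_graph(5)
  ds <- degree_strength(st)
  expect_equal(ds$degree, c(5, rep(1, 5)))
  expect_equal(local_efficiency(st)$local_efficiency, rep(0, 6))
  bc <- betweenness_centrality(st)
  expect_equal(bc$betweenness, c(1, rep(0, 5)))

  p3 <- path_graph(3)
  expect_equal(clustering_coef(p3)$clustering, rep(0, 3))
  ep <- efficiency_pathlength(p3)
  expect_equal(ep$efficiency, c(0.75, 1, 0.75))
  expect_equal(mean(ep$efficiency), 5 / 6)
  expect_equal(betweenness_centrality(p3)$betweenness, c(0, 1, 0))
})

test_that("every metric matches its brute-force oracle on random graphs", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    w <- random_weight_matrix(n, p = runif(1, 0.3, 0.8),
                              binary = rep %% 5 == 0)
    g <- normalise_graph(w)

    o_ds <- oracle_degree_strength(w)
    ds <- degree_strength(g)
    expect_equal(ds$degree, o_ds$degree, tolerance = 1e-12)
    expect_equal(ds$strength, o_ds$strength, tolerance = 1e-12)

    o_cl <- oracle_clustering(w)
    cl <- clustering_coef(g)
    expect_equal(cl$clustering, o_cl$unweighted, tolerance = 1e-12)
    expect_equal(cl$clustering_w, o_cl$weighted, tolerance = 1e-12)

    o_ep <- oracle_efficiency_pathlength(w)
    ep <- efficiency_pathlength(g)
    expect_equal(ep$efficiency, o_ep$unweighted$eff, tolerance = 1e-12)
    expect_equal(ep$path_length, o_ep$unweighted$pl, tolerance = 1e-12)
    expect_equal(ep$efficiency_w, o_ep$weighted$eff, tolerance = 1e-12)
    expect_equal(ep$path_length_w, o_ep$weighted$pl, tolerance = 1e-12)

    o_le <- oracle_local_efficiency(w)
    le <- local_efficiency(g)
    expect_equal(le$local_efficiency, o_le$unweighted, tolerance = 1e-12)
    expect_equal(le$local_efficiency_w, o_le$weighted, tolerance = 1e-12)

    o_b <- oracle_betweenness(w)
    bc <- betweenness_centrality(g)
    expect_equal(bc$betweenness, o_b$unweighted, tolerance = 1e-10)
    expect_equal(bc$betweenness_w, o_b$weighted, tolerance = 1e-10)
  }
})

test_that("weighted metrics reduce to unweighted ones on binary networks", {
  set.seed(7)
  for (rep in 1:10) {
    w <- random_weight_matrix(sample(5:8, 1), p = 0.5, binary = TRUE)
    g <- normalise_graph(w)
    ds <- degree_strength(g)
    expect_equal(ds$strength, ds$degree, tolerance = 1e-12)
    cl <- clustering_coef(g)
    expect_equal(cl$clustering_w, cl$clustering, tolerance = 1e-12)
    ep <- efficiency_pathlength(g)
    expect_equal(ep$efficiency_w, ep$efficiency, tolerance = 1e-12)
    expect_equal(ep$path_length_w, ep$path_length, tolerance = 1e-12)
    le <- local_efficiency(g)
    expect_equal(le$local_efficiency_w, le$local_efficiency, tolerance = 1e-12)
    bc <- betweenness_centrality(g)
    expect_equal(bc$betweenness_w, bc$betweenness, tolerance = 1e-12)
  }
})

test_that("metrics are equivariant under node relabeling", {
  set.seed(11)
  w <- random_weight_matrix(7, p = 0.6)
  perm <- sample(7)
  wp <- w[perm, perm]
  nm <- nodal_metrics(w)
  nmp <- nodal_metrics(wp)
  for (col in setdiff(names(nm), "node")) {
    expect_equal(nmp[[col]], nm[[col]][perm], tolerance = 1e-10,
                 label = col)
  }
})

test_that("adding an edge never decreases global efficiency", {
  set.seed(13)
  for (rep in 1:10) {
    w <- random_weight_matrix(7, p = 0.4, binary = TRUE)
    miss <- which(upper.tri(w) & w == 0, arr.ind = TRUE)
    if (nrow(miss) == 0) next
    pick <- miss[sample(nrow(miss), 1), ]
    w2 <- w
    w2[pick[1], pick[2]] <- w2[pick[2], pick[1]] <- 1
    e1 <- mean(efficiency_pathlength(w)$efficiency)
    e2 <- mean(efficiency_pathlength(w2)$efficiency)
    expect_gte(e2, e1 - 1e-12)
  }
})

test_that("degree-preserving rewiring keeps degrees and the weight multiset", {
  set.seed(5)
  w <- random_weight_matrix(12, p = 0.4)
  wr <- rewire_preserving_degree(w, n_attempts = 500)
  expect_equal(rowSums(wr > 0), rowSums(w > 0))
  expect_equal(sort(wr[upper.tri(wr) & wr > 0]),
               sort(w[upper.tri(w) & w > 0]), tolerance = 1e-12)
  expect_true(isSymmetric(wr))
  # and actually changes the topology for a sparse-ish graph
  expect_gt(sum((wr > 0) != (w > 0)), 0)
})

test_that("complete graphs are invariant under rewiring so S = 1 exactly", {
  sw <- small_worldness(complete_graph(8), n_null = 10, seed = 3)
  expect_equal(sw$S, 1)
  expect_equal(sw$C_rand, sw$C)
  expect_equal(sw$L_rand, sw$L)
})

test_that("small-worldness separates lattice-like from random topology", {
  set.seed(21)
  gws <- igraph::sample_smallworld(1, 90, 5, 0.05)
  wws <- as.matrix(igraph::as_adjacency_matrix(gws))
  s_ws <- small_worldness(wws * 1, n_null = 30, seed = 1)$S
  expect_gt(s_ws, 1.5)

  ger <- igraph::sample_gnp(90, 0.15)
  wer <- as.matrix(igraph::as_adjacency_matrix(ger))
  s_er <- small_worldness(wer * 1, n_null = 30, seed = 2)$S
  expect_gt(s_er, 0.8)
  expect_lt(s_er, 1.2)

  expect_error(small_worldness(path_graph(4)), "4 edges")
})
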