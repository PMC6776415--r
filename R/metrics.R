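#' Normalise a weight matrix into a graph
#'
#' Divides all weights by the maximum weight so that normalised weights lie in
#' \[0, 1\] (the maximum edge has weight 1). An empty network normalises to all
#' zeros without error.
#'
#' @param w Symmetric non-negative weight matrix (zero diagonal).
#' @return An object of class `tn_graph`: list with `n`, binary adjacency
#'   `adj`, and normalised weights `w`.
#' @export
normalise_graph <- function(w) {
  if (inherits(w, "tn_graph")) return(w)
  if (inherits(w, "connectome")) w <- w$weights
  stop_if_not_weight_matrix(w)
  w <- unname(w)
  diag(w) <- 0
  mx <- max(w)
  wn <- if (mx > 0) w / mx else w
  structure(
    list(n = nrow(w), adj = (w > 0) * 1, w = wn),
    class = "tn_graph"
  )
}

#' @export
print.tn_graph <- function(x, ...) {
  cat("<tn_graph> ", x$n, " nodes, ", sum(x$adj) / 2, " edges\n", sep = "")
  invisible(x)
}

as_igraph <- function(adj_or_w, weighted = FALSE) {
  if (weighted) {
    igraph::graph_from_adjacency_matrix(adj_or_w, mode = "undirected",
                                        weighted = TRUE, diag = FALSE)
  } else {
    igraph::graph_from_adjacency_matrix(adj_or_w, mode = "undirected",
                                        diag = FALSE)
  }
}

# weighted shortest-path distance matrix on connection lengths len_ij
# (Inf where disconnected); len is a matrix with 0 meaning "no edge"
shortest_lengths <- function(len) {
  g <- as_igraph(len, weighted = TRUE)
  d <- igraph::distances(g, weights = igraph::E(g)$weight)
  unname(d)
}

#' Degree and strength
#'
#' Degree is the number of edges at each node; strength (weighted degree) is
#' the sum of normalised edge weights at each node.
#'
#' @param g A `tn_graph` (or anything [normalise_graph()] accepts).
#' @return Tibble with `node`, `degree`, `strength`.
#' @export
degree_strength <- function(g) {
  g <- normalise_graph(g)
  tibble::tibble(node = seq_len(g$n),
                 degree = rowSums(g$adj),
                 strength = rowSums(g$w))
}

#' Clustering coefficients
#'
#' Unweighted clustering is the triangle fraction
#' \eqn{C_i = 2t_i/(k_i(k_i-1))}. The weighted form replaces each triangle by
#' the geometric mean of its normalised weights,
#' \eqn{t_i^w = \frac12\sum_{j,h}(\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3}}
#' (cube-root convention), so that binary networks reduce exactly to the
#' unweighted value. Nodes with degree < 2 score 0.
#'
#' @inheritParams degree_strength
#' @return Tibble with `node`, `clustering`, `clustering_w`.
#' @export
clustering_coef <- function(g) {
  g <- normalise_graph(g)
  a <- g$adj
  k <- rowSums(a)
  denom <- k * (k - 1)
  t_bin <- diag(a %*% a %*% a) / 2
  w3 <- g$w^(1 / 3)
  t_w <- diag(w3 %*% w3 %*% w3) / 2
  cu <- ifelse(denom > 0, 2 * t_bin / denom, 0)
  cw <- ifelse(denom > 0, 2 * t_w / denom, 0)
  tibble::tibble(node = seq_len(g$n), clustering = cu, clustering_w = cw)
}

#' Nodal efficiency and characteristic path length
#'
#' Unweighted distances are hop counts; weighted distances are sums of
#' inverse normalised weights along the shortest route. Nodal efficiency is
#' the mean inverse distance to all other nodes (disconnected pairs
#' contribute 0); nodal path length averages only the finite distances and is
#' `NA` for an isolated node.
#'
#' @inheritParams degree_strength
#' @return Tibble with `node`, `efficiency`, `path_length`, `efficiency_w`,
#'   `path_length_w`.
#' @export
efficiency_pathlength <- function(g) {
  g <- normalise_graph(g)
  n <- g$n
  du <- shortest_lengths(g$adj)
  lenw <- ifelse(g$w > 0, 1 / g$w, 0)
  dw <- shortest_lengths(lenw)
  summarise_d <- function(d) {
    diag(d) <- NA
    inv <- 1 / d
    inv[!is.finite(inv)] <- 0
    diag(inv) <- NA
    eff <- rowMeans(inv, na.rm = TRUE)
    dfin <- d
    dfin[!is.finite(dfin)] <- NA
    pl <- rowMeans(dfin, na.rm = TRUE)
    pl[!is.finite(pl)] <- NA
    list(eff = eff, pl = pl)
  }
  u <- summarise_d(du)
  w <- summarise_d(dw)
  tibble::tibble(node = seq_len(n),
                 efficiency = u$eff, path_length = u$pl,
                 efficiency_w = w$eff, path_length_w = w$pl)
}

#' Local efficiency
#'
#' Efficiency of each node's neighbourhood subgraph: how well the neighbours
#' of i communicate when i is removed. The weighted form follows the
#' cube-root convention: neighbour-subgraph distances are computed on
#' cube-rooted connection lengths and each pair contributes
#' \eqn{(\hat w_{ij}\hat w_{ih})^{1/3} / d_{jh}^{(1/3)}(N_i)}, which reduces
#' exactly to the unweighted form on binary networks. Nodes with degree < 2
#' score 0.
#'
#' @inheritParams degree_strength
#' @return Tibble with `node`, `local_efficiency`, `local_efficiency_w`.
#' @export
local_efficiency <- function(g) {
  g <- normalise_graph(g)
  n <- g$n
  k <- rowSums(g$adj)
  eu <- numeric(n)
  ew <- numeric(n)
  lenw3 <- ifelse(g$w > 0, (1 / g$w)^(1 / 3), 0)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    nb <- which(g$adj[i, ] > 0)
    sub_a <- g$adj[nb, nb, drop = FALSE]
    sub_l3 <- lenw3[nb, nb, drop = FALSE]
    du <- shortest_lengths(sub_a)
    dw3 <- shortest_lengths(sub_l3)
    m <- length(nb)
    off <- !diag(m)
    inv_u <- 1 / du
    inv_u[!is.finite(inv_u)] <- 0
    eu[i] <- sum(inv_u[off]) / (k[i] * (k[i] - 1))
    sw <- g$w[i, nb]^(1 / 3)
    inv_w <- 1 / dw3
    inv_w[!is.finite(inv_w)] <- 0
    ew[i] <- sum((outer(sw, sw) * inv_w)[off]) / (k[i] * (k[i] - 1))
  }
  tibble::tibble(node = seq_len(n),
                 local_efficiency = eu, local_efficiency_w = ew)
}

#' Betweenness centrality
#'
#' Fraction of shortest paths between other node pairs that pass through each
#' node, normalised by \eqn{(n-1)(n-2)} so the centre of a star scores 1.
#' The weighted form routes shortest paths on inverse-weight connection
#' lengths. `strict_print_norm = TRUE` uses an \eqn{(n-1)^2} normaliser
#' instead.
#'
#' @inheritParams degree_strength
#' @param strict_print_norm Use the \eqn{(n-1)^2} normaliser.
#' @return Tibble with `node`, `betweenness`, `betweenness_w`.
#' @export
betweenness_centrality <- function(g, strict_print_norm = FALSE) {
  g <- normalise_graph(g)
  n <- g$n
  norm <- if (strict_print_norm) (n - 1)^2 else (n - 1) * (n - 2)
  gu <- as_igraph(g$adj)
  bu <- igraph::betweenness(gu, directed = FALSE)
  lenw <- ifelse(g$w > 0, 1 / g$w, 0)
  gw <- as_igraph(lenw, weighted = TRUE)
  bw <- igraph::betweenness(gw, directed = FALSE, weights = igraph::E(gw)$weight)
  tibble::tibble(node = seq_len(n),
                 betweenness = 2 * unname(bu) / norm,
                 betweenness_w = 2 * unname(bw) / norm)
}

# global (node-averaged) C and L used by small-worldness; computes only the
# requested variant since this sits inside the rewired-null loop
global_cl <- function(g, weighted = FALSE) {
  a <- g$adj
  k <- rowSums(a)
  denom <- k * (k - 1)
  if (weighted) {
    w3 <- g$w^(1 / 3)
    tri <- diag(w3 %*% w3 %*% w3) / 2
    d <- shortest_lengths(ifelse(g$w > 0, 1 / g$w, 0))
  } else {
    tri <- diag(a %*% a %*% a) / 2
    d <- shortest_lengths(a)
  }
  cc <- mean(ifelse(denom > 0, 2 * tri / denom, 0))
  diag(d) <- NA
  d[!is.finite(d)] <- NA
  pl_i <- rowMeans(d, na.rm = TRUE)
  c(C = cc, L = mean(pl_i, na.rm = TRUE))
}

#' Small-worldness against rewired nulls
#'
#' \eqn{S = (C/C_{rand})/(L/L_{rand})} with `C`, `L` the node-averaged
#' clustering coefficient and characteristic path length, and the null values
#' averaged over `n_null` degree-preserving Maslov–Sneppen rewirings
#' (10 x edges swap attempts each; weights travel with the swapped edges for
#' the weighted variant). Values well above 1 indicate small-world topology:
#' lattice-like clustering with near-random path length.
#'
#' @inheritParams degree_strength
#' @param n_null Number of rewired null networks.
#' @param seed Integer seed for the rewiring.
#' @param weighted Compute the weighted variant.
#' @return A list of class `small_world_result` with `S`, `C`, `L`, `C_rand`,
#'   `L_rand`, `n_null`, `weighted`, `seed`.
#' @export
small_worldness <- function(g, n_null = 100, seed = 1L, weighted = FALSE) {
  g <- normalise_graph(g)
  n_edges <- sum(g$adj) / 2
  if (n_edges < 4) abort("rewiring needs at least 4 edges.")
  obs <- global_cl(g, weighted = weighted)
  set.seed(seed)
  crand <- numeric(n_null)
  lrand <- numeric(n_null)
  for (b in seq_len(n_null)) {
    wr <- rewire_preserving_degree(g$w, n_attempts = 10L * n_edges)
    null_cl <- global_cl(normalise_graph(wr), weighted = weighted)
    crand[b] <- null_cl["C"]
    lrand[b] <- null_cl["L"]
  }
  c_rand <- mean(crand)
  l_rand <- mean(lrand)
  s <- (obs["C"] / c_rand) / (obs["L"] / l_rand)
  structure(
    list(S = unname(s), C = unname(obs["C"]), L = unname(obs["L"]),
         C_rand = c_rand, L_rand = l_rand, n_null = n_null,
         weighted = weighted, seed = seed),
    class = "small_world_result"
  )
}

#' @export
print.small_world_result <- function(x, ...) {
  cat(sprintf("<small_world_result> S = %.3f (C = %.3f, L = %.3f, C_rand = %.3f, L_rand = %.3f, %d nulls%s)\n",
              x$S, x$C, x$L, x$C_rand, x$L_rand, x$n_null,
              if (x$weighted) ", weighted" else ""))
  invisible(x)
}

#' Degree-preserving rewiring with weights carried
#'
#' Maslov–Sneppen double-edge swaps on a weight matrix: repeatedly picks two
#' edges (a,b), (c,d) and rewires them to (a,d), (c,b) when this creates no
#' self-loop or duplicate edge, each edge keeping its weight. Preserves every
#' node's degree exactly. Uses R's RNG, so `set.seed()` makes it
#' reproducible.
#'
#' @param w Symmetric non-negative weight matrix.
#' @param n_attempts Number of swap attempts (default 10 x edges).
#' @return A rewired weight matrix.
#' @export
rewire_preserving_degree <- function(w, n_attempts = NULL) {
  stop_if_not_weight_matrix(w)
  pairs <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (is.null(n_attempts)) n_attempts <- 10L * nrow(pairs)
  rewire_double_swap(unname(w), pairs[, 1L], pairs[, 2L],
                     as.integer(n_attempts))
}

#' Full nodal metric table
#'
#' Convenience wrapper joining all nodal metrics into one tibble.
#'
#' @inheritParams degree_strength
#' @return Tibble with one row per node and all nodal metrics.
#' @export
nodal_metrics <- function(g) {
  g <- normalise_graph(g)
  degree_strength(g) |>
    dplyr::left_join(clustering_coef(g), by = "node") |>
    dplyr::left_join(efficiency_pathlength(g), by = "node") |>
    dplyr::left_join(local_efficiency(g), by = "node") |>
    dplyr::left_join(betweenness_centrality(g), by = "node")
}

#' Global metric summary
#'
#' Node-averaged global metrics as a one-row tibble.
#'
#' @inheritParams degree_strength
#' @return One-row tibble of node-averaged metrics.
#' @export
global_metrics <- function(g) {
  nm <- nodal_metrics(g)
  nm |>
    dplyr::summarise(dplyr::across(-"node", ~ mean(.x, na.rm = TRUE)))
}
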