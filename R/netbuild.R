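#' Construct a connectome object
#'
#' Container for a per-subject structural network: streamline counts per node
#' pair, per-edge streamline length lists, node volumes and (once a weighting
#' strategy has been applied) the weight matrix. Synthetic cohorts carry only
#' a weight matrix; count-based invariants are enforced whenever counts are
#' present.
#'
#' @param n_nodes Number of nodes.
#' @param counts Integer streamline-count matrix (symmetric, zero diagonal),
#'   or `NULL` for synthetic networks.
#' @param lengths List of numeric length vectors keyed `"i-j"` (i < j), mm.
#' @param volumes Node volumes in mm^3, or `NULL`.
#' @param weights Weight matrix, or `NULL` before weighting.
#' @param strategy `"length_adjusted"`, `"volume_adjusted"`, or `"synthetic"`.
#'
#' @return An object of class `connectome`.
#' @export
connectome <- function(n_nodes, counts = NULL, lengths = NULL, volumes = NULL,
                       weights = NULL, strategy = "synthetic") {
  if (!is.null(counts)) {
    if (!is_symmetric(counts) || any(diag(counts) != 0)) {
      abort("`counts` must be symmetric with zero diagonal.")
    }
    if (any(counts < 0) || any(counts != round(counts))) {
      abort("`counts` must be non-negative integers.")
    }
  }
  if (!is.null(weights)) {
    stop_if_not_weight_matrix(weights, "weights")
    if (any(diag(weights) != 0)) abort("`weights` must have zero diagonal.")
    if (!is.null(counts) && any((weights > 0) != (counts > 0))) {
      abort("weights must be positive exactly where counts are positive.")
    }
  }
  if (!is.null(volumes) && any(volumes <= 0)) {
    abort("node volumes must be positive.")
  }
  structure(
    list(n_nodes = as.integer(n_nodes), counts = counts, lengths = lengths,
         volumes = volumes, weights = weights, strategy = strategy),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  ne <- if (!is.null(x$weights)) sum(x$weights[upper.tri(x$weights)] > 0)
        else if (!is.null(x$counts)) sum(x$counts[upper.tri(x$counts)] > 0)
        else NA_integer_
  cat("<connectome> ", x$n_nodes, " nodes, ", ne, " edges, strategy: ",
      x$strategy, "\n", sep = "")
  invisible(x)
}

pair_key <- function(i, j) paste0(min(i, j), "-", max(i, j))

#' Assign streamlines to node pairs
#'
#' A streamline contributes to edge (i, j) exactly when its first endpoint
#' lies in region i and its last endpoint in region j with i != j, by
#' nearest-voxel label lookup. Endpoints in background (label 0) or both in
#' the same region contribute nothing; each streamline counts at most once.
#'
#' @param tracks A [streamline_set()].
#' @param parc A [make_parcellation()] / `parcellation` object sharing the
#'   streamlines' world coordinate frame.
#' @return A [connectome()] holding counts, per-edge length lists and node
#'   volumes (no weights yet).
#' @export
assign_edges <- function(tracks, parc) {
  stopifnot(inherits(tracks, "streamline_set"), inherits(parc, "parcellation"))
  n <- length(parc$volumes)
  gs <- dim(parc$labels)
  vs <- parc$voxel_size
  label_at <- function(p) {
    v <- p / vs
    if (any(v < -0.5) || any(v > gs - 0.5)) return(0L)
    v <- pmin(pmax(round(v), 0), gs - 1L)
    parc$labels[v[1] + 1L, v[2] + 1L, v[3] + 1L]
  }
  counts <- matrix(0L, n, n)
  lengths <- list()
  for (m in seq_along(tracks$streamlines)) {
    pts <- tracks$streamlines[[m]]
    i <- label_at(pts[1L, ])
    j <- label_at(pts[nrow(pts), ])
    if (i == 0L || j == 0L || i == j) next
    counts[i, j] <- counts[i, j] + 1L
    counts[j, i] <- counts[i, j]
    key <- pair_key(i, j)
    lengths[[key]] <- c(lengths[[key]], tracks$lengths[[m]])
  }
  connectome(n, counts = counts, lengths = lengths, volumes = parc$volumes,
             strategy = "unweighted")
}

#' Streamline-length-adjusted edge weighting
#'
#' Weights each edge by half the sum of reciprocal streamline lengths,
#' \eqn{w_{ij} = \frac{1}{2}\sum_{m=1}^{N_{ij}} 1/l_m}. Longer streamlines
#' contain more seed points under dense seeding and are therefore
#' over-counted; the reciprocal-length sum removes that distal bias.
#'
#' @param conn A [connectome()] with counts and length lists.
#' @return The connectome with `weights` set and strategy
#'   `"length_adjusted"`.
#' @export
weight_length_adjusted <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  if (is.null(conn$counts)) abort("connectome has no streamline counts.")
  n <- conn$n_nodes
  w <- matrix(0, n, n)
  pairs <- upper_pairs(n)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    nij <- conn$counts[i, j]
    if (nij == 0L) next
    ls <- conn$lengths[[pair_key(i, j)]]
    if (length(ls) != nij) abort("length list inconsistent with counts.")
    if (any(ls <= 0)) abort("streamline lengths must be positive.")
    w[i, j] <- w[j, i] <- 0.5 * sum(1 / ls)
  }
  conn$weights <- w
  conn$strategy <- "length_adjusted"
  conn
}

#' End-node-volume-adjusted edge weighting
#'
#' Weights each edge by the streamline count normalised by the summed
#' end-node volumes, \eqn{w_{ij} = 2N_{ij}/(V_i + V_j)}. Larger regions
#' collect more seeds and hence more streamlines; dividing by end-node volume
#' corrects this and, with it, gross differences in head size.
#'
#' @param conn A [connectome()] with counts and node volumes.
#' @return The connectome with `weights` set and strategy
#'   `"volume_adjusted"`.
#' @export
weight_volume_adjusted <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  if (is.null(conn$counts)) abort("connectome has no streamline counts.")
  if (is.null(conn$volumes)) abort("connectome has no node volumes.")
  v <- conn$volumes
  if (any(v <= 0)) abort("node volumes must be positive.")
  vsum <- outer(v, v, `+`)
  w <- 2 * conn$counts / vsum
  diag(w) <- 0
  conn$weights <- unname(w)
  conn$strategy <- "volume_adjusted"
  conn
}

#' Binary adjacency of a connectome or weight matrix
#'
#' @param x A [connectome()] or a numeric weight matrix.
#' @return Integer 0/1 matrix marking present edges.
#' @export
adjacency_of <- function(x) {
  w <- if (inherits(x, "connectome")) {
    if (!is.null(x$weights)) x$weights else x$counts
  } else x
  a <- (w > 0) * 1L
  diag(a) <- 0L
  a
}
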