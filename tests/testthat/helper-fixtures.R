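# small named graphs used across tests

complete_graph <- function(n) {
  w <- matrix(1, n, n)
  diag(w) <- 0
  w
}

star_graph <- function(n_leaves) {
  n <- n_leaves + 1
  w <- matrix(0, n, n)
  w[1, 2:n] <- w[2:n, 1] <- 1
  w
}

path_graph <- function(n) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) w[i, i + 1] <- w[i + 1, i] <- 1
  w
}

# hand-built straight streamline along x from x0 to x1 at (y, z)
straight_streamline <- function(x0, x1, y = 0, z = 0, step = 0.5) {
  xs <- seq(x0, x1, by = if (x1 >= x0) step else -step)
  cbind(xs, rep(y, length(xs)), rep(z, length(xs)))
}

# a connectome assembled directly from counts and length lists
manual_connectome <- function(n, edges) {
  # edges: list of list(i, j, lengths)
  counts <- matrix(0L, n, n)
  lens <- list()
  vols <- setNames(rep(1, n), seq_len(n))
  for (e in edges) {
    counts[e$i, e$j] <- counts[e$j, e$i] <- length(e$lengths)
    lens[[paste0(min(e$i, e$j), "-", max(e$i, e$j))]] <- e$lengths
  }
  connectome(n, counts = counts, lengths = lens, volumes = vols,
             strategy = "unweighted")
}
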