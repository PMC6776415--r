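# internal helpers shared across modules

# symmetric check with tolerance; matrices here are small (<= a few hundred nodes)
is_symmetric <- function(m, tol = 1e-9) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}

stop_if_not_weight_matrix <- function(w, arg = "w") {
  if (!is.matrix(w) || !is.numeric(w)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg))
  }
  if (nrow(w) != ncol(w)) {
    abort(sprintf("`%s` must be square.", arg))
  }
  if (anyNA(w) || any(!is.finite(w))) {
    abort(sprintf("`%s` contains non-finite values.", arg))
  }
  if (any(w < 0)) {
    abort(sprintf("`%s` contains negative weights.", arg))
  }
  if (!is_symmetric(w, tol = 1e-8)) {
    abort(sprintf("`%s` must be symmetric.", arg))
  }
  invisible(w)
}

# trapezoidal integral of y over x (x strictly increasing); NA values drop the
# corresponding panels so a single failed level does not void the whole curve
trapezoid <- function(x, y) {
  keep <- is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 2L) {
    return(NA_real_)
  }
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

# upper-triangle index pairs in fixed lexicographic (i, j > i) order,
# used everywhere an edge ordering must be reproducible
upper_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

# all n! permutations of 1..n as columns (insert n at every position; small n)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  blocks <- lapply(seq_len(n), function(pos) {
    rbind(sub[seq_len(pos - 1L), , drop = FALSE],
          matrix(n, 1L, ncol(sub)),
          sub[seq_len(n - pos) + (pos - 1L), , drop = FALSE])
  })
  do.call(cbind, blocks)
}

edge_density_of <- function(w) {
  n <- nrow(w)
  sum(w[upper.tri(w)] > 0) / (n * (n - 1) / 2)
}
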