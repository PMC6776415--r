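#' Tracking parameters
#'
#' Stepping and termination rules for deterministic streamline tractography.
#' Defaults follow common practice for whole-brain deterministic tracking:
#' super-resolution seeding on a 0.5 mm grid, 0.5 mm steps, termination when
#' fractional anisotropy falls below 0.2 or the principal-direction change
#' between consecutive steps exceeds 40 degrees.
#'
#' @param seed_grid_spacing Seed grid spacing in mm.
#' @param step_size Integration step in mm.
#' @param fa_threshold Minimum FA for seeding and continuation.
#' @param angle_threshold Maximum direction change per step, degrees (0, 90].
#' @param max_length Loop guard: maximum streamline length in mm.
#'
#' @return An object of class `tracking_params`.
#' @export
tracking_params <- function(seed_grid_spacing = 0.5, step_size = 0.5,
                            fa_threshold = 0.2, angle_threshold = 40,
                            max_length = 250) {
  vals <- c(seed_grid_spacing, step_size, fa_threshold, angle_threshold,
            max_length)
  if (any(vals <= 0)) abort("all tracking parameters must be positive.")
  if (angle_threshold > 90) abort("`angle_threshold` must be in (0, 90].")
  structure(
    list(seed_grid_spacing = seed_grid_spacing, step_size = step_size,
         fa_threshold = fa_threshold, angle_threshold = angle_threshold,
         max_length = max_length),
    class = "tracking_params"
  )
}

fa_from_eigenvalues <- function(lam) {
  ss <- sum(lam^2)
  if (ss <= 0) return(0)
  fa <- sqrt(3 / 2 * sum((lam - mean(lam))^2) / ss)
  min(max(fa, 0), 1)
}

#' Eigen-decompose a tensor field
#'
#' Computes fractional anisotropy and the principal eigenvector at every
#' masked voxel. FA is the standard normalised eigenvalue dispersion
#' \eqn{\sqrt{3/2}\,\sqrt{\sum_i(\lambda_i-\bar\lambda)^2}/\sqrt{\sum_i \lambda_i^2}}.
#'
#' @param field A [tensor_field()].
#' @return List with `fa` (3-D array, 0 outside the mask) and `pev`
#'   (4-D array, unit principal eigenvectors).
#' @export
tensor_eigen <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  gs <- field$grid_shape
  fa <- array(0, gs)
  pev <- array(0, c(gs, 3L))
  for (k in seq_len(gs[3])) for (j in seq_len(gs[2])) for (i in seq_len(gs[1])) {
    if (!field$mask[i, j, k]) next
    m <- components_to_tensor(field$tensors[i, j, k, ])
    e <- eigen(m, symmetric = TRUE)
    fa[i, j, k] <- fa_from_eigenvalues(e$values)
    pev[i, j, k, ] <- e$vectors[, 1L]
  }
  list(fa = fa, pev = pev)
}

# trilinear interpolation of the 6 tensor components at world point p (mm);
# returns NULL outside the grid or when the nearest voxel is unmasked
interp_tensor <- function(field, p) {
  v <- p / field$voxel_size            # continuous 0-based voxel coordinate
  gs <- field$grid_shape
  if (any(v < -0.5) || any(v > gs - 0.5)) return(NULL)
  nearest <- pmin(pmax(round(v), 0), gs - 1L)
  if (!field$mask[nearest[1] + 1L, nearest[2] + 1L, nearest[3] + 1L]) {
    return(NULL)
  }
  v0 <- pmin(pmax(floor(v), 0), gs - 2L)
  fr <- pmin(pmax(v - v0, 0), 1)
  comp <- numeric(6L)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    wgt <- (if (dx) fr[1] else 1 - fr[1]) *
      (if (dy) fr[2] else 1 - fr[2]) *
      (if (dz) fr[3] else 1 - fr[3])
    if (wgt == 0) next
    comp <- comp + wgt *
      field$tensors[v0[1] + dx + 1L, v0[2] + dy + 1L, v0[3] + dz + 1L, ]
  }
  comp
}

# FA and principal direction at an arbitrary world point
point_fa_dir <- function(field, p) {
  comp <- interp_tensor(field, p)
  if (is.null(comp)) return(NULL)
  e <- eigen(components_to_tensor(comp), symmetric = TRUE)
  list(fa = fa_from_eigenvalues(e$values), dir = e$vectors[, 1L])
}

# one-directional Euler walk; returns matrix of points beyond the seed
walk_direction <- function(field, seed, dir0, params, budget) {
  pts <- matrix(numeric(0), ncol = 3)
  p <- seed
  d <- dir0
  len <- 0
  cos_th <- cos(params$angle_threshold * pi / 180)
  repeat {
    if (len + params$step_size > budget) break
    pn <- p + params$step_size * d
    ev <- point_fa_dir(field, pn)
    if (is.null(ev) || ev$fa < params$fa_threshold) break
    dn <- ev$dir
    if (sum(dn * d) < 0) dn <- -dn       # eigenvector sign continuity
    pts <- rbind(pts, pn)
    len <- len + params$step_size
    if (sum(dn * d) < cos_th) break      # curvature rule trips for next step
    p <- pn
    d <- dn
  }
  pts
}

#' Trace a single streamline
#'
#' Bidirectional deterministic tracking from a seed point: Euler integration
#' along the trilinearly interpolated tensor field's principal eigenvector,
#' with the eigenvector sign chosen to continue the previous direction.
#' Terminates on low FA, on a direction change exceeding the angle threshold,
#' on leaving the mask, or at the length guard. Returns `NULL` when the seed
#' itself fails the FA rule or no step can be taken.
#'
#' @param field A [tensor_field()].
#' @param seed Numeric length-3 world coordinate (mm).
#' @param params A [tracking_params()].
#' @return A matrix of ordered points (rows, mm) with attribute `length_mm`,
#'   or `NULL`.
#' @export
trace_streamline <- function(field, seed, params = tracking_params()) {
  stopifnot(inherits(field, "tensor_field"))
  seed <- as.numeric(seed)
  v <- seed / field$voxel_size
  if (any(v < -0.5) || any(v > field$grid_shape - 0.5)) {
    abort("seed lies outside the volume.")
  }
  ev <- point_fa_dir(field, seed)
  if (is.null(ev) || ev$fa < params$fa_threshold) return(NULL)
  half_budget <- params$max_length / 2
  fwd <- walk_direction(field, seed, ev$dir, params, half_budget)
  bwd <- walk_direction(field, seed, -ev$dir, params, half_budget)
  if (nrow(bwd)) bwd <- bwd[rev(seq_len(nrow(bwd))), , drop = FALSE]
  pts <- rbind(bwd, matrix(seed, 1), fwd)
  if (nrow(pts) < 2L) return(NULL)
  dimnames(pts) <- NULL
  attr(pts, "length_mm") <- sum(sqrt(rowSums(diff(pts)^2)))
  pts
}

#' Whole-volume deterministic tractography
#'
#' Seeds a regular grid of spacing `seed_grid_spacing` across the masked
#' volume (sub-voxel "super-resolution" seeding) and attempts one trace per
#' seed. The procedure is fully deterministic: no random numbers are drawn.
#'
#' @param field A [tensor_field()].
#' @param params A [tracking_params()].
#' @return An object of class `streamline_set`: list with `streamlines`
#'   (list of point matrices), `lengths` (mm), `n_seeds`, and `params`.
#' @export
track_whole_volume <- function(field, params = tracking_params()) {
  stopifnot(inherits(field, "tensor_field"))
  if (!any(field$mask)) abort("mask is empty.")
  gs <- field$grid_shape
  vs <- field$voxel_size
  sp <- params$seed_grid_spacing
  axes <- lapply(1:3, function(a) {
    lo <- -vs[a] / 2
    hi <- (gs[a] - 0.5) * vs[a]
    n <- max(1L, floor((hi - lo) / sp))
    lo + (seq_len(n) - 0.5) * sp
  })
  seeds <- as.matrix(expand.grid(x = axes[[1]], y = axes[[2]], z = axes[[3]]))
  streamlines <- list()
  n_seeds <- 0L
  for (s in seq_len(nrow(seeds))) {
    seed <- seeds[s, ]
    nearest <- pmin(pmax(round(seed / vs), 0), gs - 1L)
    if (!field$mask[nearest[1] + 1L, nearest[2] + 1L, nearest[3] + 1L]) next
    n_seeds <- n_seeds + 1L
    sl <- trace_streamline(field, seed, params)
    if (!is.null(sl)) streamlines[[length(streamlines) + 1L]] <- sl
  }
  streamline_set(streamlines, params = params, n_seeds = n_seeds)
}

#' Construct a streamline set
#'
#' @param streamlines List of point matrices (rows = ordered mm coordinates).
#' @param params Optional [tracking_params()] provenance.
#' @param n_seeds Number of seed attempts that produced the set.
#' @return An object of class `streamline_set`.
#' @export
streamline_set <- function(streamlines, params = NULL, n_seeds = NA_integer_) {
  lens <- vapply(streamlines, function(p) {
    if (nrow(p) < 2L) abort("each streamline needs at least 2 points.")
    sum(sqrt(rowSums(diff(p)^2)))
  }, numeric(1))
  structure(
    list(streamlines = streamlines, lengths = lens,
         params = params, n_seeds = n_seeds),
    class = "streamline_set"
  )
}

#' @export
print.streamline_set <- function(x, ...) {
  cat("<streamline_set> ", length(x$streamlines), " streamlines",
      if (length(x$lengths)) sprintf(", mean length %.1f mm", mean(x$lengths)),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.streamline_set <- function(x) length(x$streamlines)
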