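#' Specify a diffusion-tensor phantom
#'
#' A phantom is a small voxel grid of synthetic diffusion tensors used to
#' exercise the tractography stage without acquired imaging data. Four
#' geometries are available: a straight fibre bundle along x, a curved bundle
#' whose principal direction rotates in the x-y plane, two orthogonal crossing
#' bundles, and a fully isotropic volume.
#'
#' @param grid_shape Integer vector of length 3, voxels per axis (all >= 4).
#' @param voxel_size Voxel edge length in mm (> 0).
#' @param geometry One of `"straight_bundle"`, `"curved_bundle"`, `"crossing"`,
#'   `"isotropic"`.
#' @param bundle_fa Fractional anisotropy inside the bundle, in \[0, 1\].
#' @param background_fa Fractional anisotropy of background voxels, in \[0, 1\].
#'   Background tensors have this FA with a per-voxel random principal axis
#'   (exactly isotropic when 0).
#' @param curvature_per_step Curved geometry only: degrees of
#'   tangent rotation seen by a 1 mm chord step taken from the bundle's
#'   reference circle. The curved bundle is an annulus of tangential tensors
#'   around the grid centre with reference radius
#'   `1 / tan(curvature_per_step * pi / 180)` mm.
#' @param mean_diffusivity Mean diffusivity of every tensor, mm^2/s.
#' @param seed Integer seed controlling the random background orientations.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(12L, 8L, 8L),
                         voxel_size = 1,
                         geometry = c("straight_bundle", "curved_bundle",
                                      "crossing", "isotropic"),
                         bundle_fa = 0.8,
                         background_fa = 0,
                         curvature_per_step = 0,
                         mean_diffusivity = 7e-4,
                         seed = 1L) {
  geometry <- match.arg(geometry)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L)) {
    abort("`grid_shape` must be 3 integers, all >= 4.")
  }
  if (voxel_size <= 0) abort("`voxel_size` must be positive.")
  for (fa in c(bundle_fa, background_fa)) {
    if (fa < 0 || fa > 1) abort("FA values must lie in [0, 1].")
  }
  if (curvature_per_step < 0) abort("`curvature_per_step` must be >= 0.")
  structure(
    list(grid_shape = grid_shape, voxel_size = voxel_size, geometry = geometry,
         bundle_fa = bundle_fa, background_fa = background_fa,
         curvature_per_step = curvature_per_step,
         mean_diffusivity = mean_diffusivity, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Construct a tensor field object
#'
#' @param tensors 4-D array `c(grid_shape, 6)` of unique tensor components in
#'   lower-triangular order (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz), mm^2/s.
#' @param voxel_size Voxel edge length in mm (scalar or length 3).
#' @param mask Logical 3-D array of in-brain voxels; defaults to all `TRUE`.
#' @param affine 4x4 voxel-index (0-based, voxel centres) to world-mm
#'   transform; defaults to scaling by `voxel_size`.
#'
#' @return An object of class `tensor_field`.
#' @export
tensor_field <- function(tensors, voxel_size, mask = NULL, affine = NULL) {
  dm <- dim(tensors)
  if (length(dm) != 4L || dm[4L] != 6L) {
    abort("`tensors` must be a 4-D array with 6 components per voxel.")
  }
  if (anyNA(tensors) || any(!is.finite(tensors))) {
    abort("`tensors` contains non-finite entries.")
  }
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) abort("`voxel_size` must be positive.")
  grid_shape <- dm[1:3]
  if (is.null(mask)) mask <- array(TRUE, grid_shape)
  if (!identical(dim(mask), grid_shape)) abort("`mask` shape mismatch.")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  structure(
    list(grid_shape = grid_shape, voxel_size = voxel_size,
         affine = affine, tensors = tensors, mask = mask),
    class = "tensor_field"
  )
}

#' @export
print.tensor_field <- function(x, ...) {
  cat("<tensor_field> ", paste(x$grid_shape, collapse = " x "),
      " voxels @ ", paste(signif(x$voxel_size, 3), collapse = "x"),
      " mm, ", sum(x$mask), " masked voxels\n", sep = "")
  invisible(x)
}

# axially symmetric tensor with principal axis `v` (unit), given FA and MD.
# eigenvalues (a, b, b): solve the FA expression for the ratio b/a.
axial_tensor <- function(v, fa, md) {
  if (fa == 0) {
    return(diag(3) * md)
  }
  fa_of_ratio <- function(r) {
    lam <- c(1, r, r)
    lb <- mean(lam)
    sqrt(3 / 2 * sum((lam - lb)^2) / sum(lam^2))
  }
  r <- stats::uniroot(function(r) fa_of_ratio(r) - fa,
                      lower = 0, upper = 1, tol = 1e-14)$root
  lam <- c(1, r, r)
  lam <- lam * (3 * md / sum(lam))        # fix mean diffusivity
  v <- v / sqrt(sum(v^2))
  # complete an orthonormal frame around v
  u <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- u - sum(u * v) * v
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(v[2] * e2[3] - v[3] * e2[2],
          v[3] * e2[1] - v[1] * e2[3],
          v[1] * e2[2] - v[2] * e2[1])
  vmat <- cbind(v, e2, e3)
  vmat %*% diag(lam) %*% t(vmat)
}

tensor_to_components <- function(m) {
  c(m[1, 1], m[1, 2], m[2, 2], m[1, 3], m[2, 3], m[3, 3])
}

components_to_tensor <- function(comp) {
  matrix(c(comp[1], comp[2], comp[4],
           comp[2], comp[3], comp[5],
           comp[4], comp[5], comp[6]), 3, 3)
}

#' Generate a tensor-field phantom
#'
#' Builds the voxel grid of diffusion tensors described by a [phantom_spec()].
#' Bundle voxels receive an axially symmetric tensor with the requested FA and
#' principal direction; background voxels receive tensors with
#' `background_fa` and random orientation. The crossing geometry composes two
#' orthogonal bundles by averaging their tensors in the overlap, which lowers
#' the FA there — the classic crossing-fibre ambiguity.
#'
#' @param spec A [phantom_spec()].
#' @return A [tensor_field()] whose mask covers the whole grid.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  vs <- spec$voxel_size
  md <- spec$mean_diffusivity
  set.seed(spec$seed)

  tensors <- array(0, c(gs, 6L))
  # background: FA = background_fa, random axis per voxel
  nvox <- prod(gs)
  bg_axes <- matrix(rnorm(3 * nvox), ncol = 3)
  bg_axes <- bg_axes / sqrt(rowSums(bg_axes^2))
  vox <- 0L
  for (k in seq_len(gs[3])) for (j in seq_len(gs[2])) for (i in seq_len(gs[1])) {
    vox <- vox + 1L
    tensors[i, j, k, ] <- tensor_to_components(
      axial_tensor(bg_axes[vox, ], spec$background_fa, md))
  }

  in_band <- function(idx, extent) {
    # central half of the axis, at least 2 voxels wide
    half <- max(1L, floor(extent / 4))
    lo <- floor(extent / 2) - half + 1L
    hi <- floor(extent / 2) + half
    idx >= lo & idx <= hi
  }

  if (spec$geometry %in% c("straight_bundle", "crossing")) {
    for (k in seq_len(gs[3])) for (j in seq_len(gs[2])) for (i in seq_len(gs[1])) {
      in_x_bundle <- in_band(j, gs[2]) && in_band(k, gs[3])   # bundle along x
      in_y_bundle <- in_band(i, gs[1]) && in_band(k, gs[3])   # bundle along y
      t_x <- if (in_x_bundle) axial_tensor(c(1, 0, 0), spec$bundle_fa, md)
      t_y <- if (in_y_bundle && spec$geometry == "crossing") {
        axial_tensor(c(0, 1, 0), spec$bundle_fa, md)
      }
      if (!is.null(t_x) && !is.null(t_y)) {
        tensors[i, j, k, ] <- tensor_to_components((t_x + t_y) / 2)
      } else if (!is.null(t_x)) {
        tensors[i, j, k, ] <- tensor_to_components(t_x)
      } else if (!is.null(t_y)) {
        tensors[i, j, k, ] <- tensor_to_components(t_y)
      }
    }
  } else if (spec$geometry == "curved_bundle") {
    # annular bundle tangential around the grid centre in the x-y plane:
    # a 1 mm chord step from the reference circle turns the tangent by
    # curvature_per_step degrees (r = 1 / tan(angle))
    if (spec$curvature_per_step <= 0 || spec$curvature_per_step >= 90) {
      abort("curved_bundle requires `curvature_per_step` in (0, 90).")
    }
    r_ref <- 1 / tan(spec$curvature_per_step * pi / 180)
    half_width <- max(vs, 1)
    centre <- (gs[1:2] - 1) / 2 * vs
    for (k in seq_len(gs[3])) for (j in seq_len(gs[2])) for (i in seq_len(gs[1])) {
      dx <- (i - 1) * vs - centre[1]
      dy <- (j - 1) * vs - centre[2]
      r <- sqrt(dx^2 + dy^2)
      if (r > 1e-9 && abs(r - r_ref) <= half_width) {
        dirv <- c(-dy, dx, 0) / r
        tensors[i, j, k, ] <- tensor_to_components(
          axial_tensor(dirv, spec$bundle_fa, md))
      }
    }
  }

  tensor_field(tensors, voxel_size = vs)
}

#' Voxel mask of the phantom's bundle
#'
#' Logical array marking the voxels carrying the (x-axis) bundle of a phantom
#' generated by [make_phantom()]. Used by tests and seeding audits.
#'
#' @param spec A [phantom_spec()].
#' @return Logical 3-D array.
#' @export
phantom_bundle_mask <- function(spec) {
  gs <- spec$grid_shape
  in_band <- function(idx, extent) {
    half <- max(1L, floor(extent / 4))
    lo <- floor(extent / 2) - half + 1L
    hi <- floor(extent / 2) + half
    idx >= lo & idx <= hi
  }
  m <- array(FALSE, gs)
  if (spec$geometry == "isotropic") return(m)
  if (spec$geometry == "curved_bundle") {
    vs <- spec$voxel_size
    r_ref <- 1 / tan(spec$curvature_per_step * pi / 180)
    half_width <- max(vs, 1)
    centre <- (gs[1:2] - 1) / 2 * vs
    for (k in seq_len(gs[3])) for (j in seq_len(gs[2])) for (i in seq_len(gs[1])) {
      r <- sqrt(((i - 1) * vs - centre[1])^2 + ((j - 1) * vs - centre[2])^2)
      m[i, j, k] <- r > 1e-9 && abs(r - r_ref) <= half_width
    }
    return(m)
  }
  for (k in seq_len(gs[3])) for (j in seq_len(gs[2])) for (i in seq_len(gs[1])) {
    m[i, j, k] <- in_band(j, gs[2]) && in_band(k, gs[3])
  }
  m
}

#' Generate a toy parcellation
#'
#' Splits a voxel grid into `n_regions` contiguous-ish regions by k-means on
#' voxel-centre coordinates (seeded, so deterministic). Stands in for an
#' anatomical grey-matter parcellation: every label 1..n_regions occupies at
#' least one voxel, and region volumes are voxel counts times voxel volume.
#'
#' @param grid_shape Integer vector of length 3.
#' @param n_regions Number of regions (>= 2, <= number of voxels).
#' @param voxel_size Voxel edge length in mm.
#' @param seed Integer seed.
#'
#' @return An object of class `parcellation`: list with `labels` (integer 3-D
#'   array, 0 = background), `affine`, `voxel_size`, and `volumes` (mm^3, named
#'   by label).
#' @export
make_parcellation <- function(grid_shape, n_regions, voxel_size = 1, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  nvox <- prod(grid_shape)
  if (n_regions < 2L) abort("`n_regions` must be >= 2.")
  if (n_regions > nvox) abort("`n_regions` exceeds the number of voxels.")
  set.seed(seed)
  centres <- expand.grid(i = seq_len(grid_shape[1]),
                         j = seq_len(grid_shape[2]),
                         k = seq_len(grid_shape[3]))
  xyz <- as.matrix(centres) - 1
  km <- suppressWarnings(
    stats::kmeans(xyz, centers = n_regions, iter.max = 50, nstart = 1))
  lab <- km$cluster
  # guarantee every label present (kmeans can in principle empty a cluster)
  missing_labs <- setdiff(seq_len(n_regions), unique(lab))
  if (length(missing_labs)) {
    free <- sample(seq_len(nvox), length(missing_labs))
    lab[free] <- missing_labs
  }
  labels <- array(as.integer(lab), grid_shape)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  vols <- as.numeric(table(factor(lab, levels = seq_len(n_regions)))) *
    prod(voxel_size)
  structure(
    list(labels = labels, voxel_size = voxel_size,
         affine = diag(c(voxel_size, 1)),
         volumes = setNames(vols, seq_len(n_regions))),
    class = "parcellation"
  )
}

#' Split a grid into two equal-volume regions by a plane
#'
#' Convenience parcellation for worked examples: voxels with x-index in the
#' lower half get label 1, the rest label 2.
#'
#' @inheritParams make_parcellation
#' @return A `parcellation` with two labels.
#' @export
make_halves_parcellation <- function(grid_shape, voxel_size = 1) {
  grid_shape <- as.integer(grid_shape)
  labels <- array(2L, grid_shape)
  labels[seq_len(grid_shape[1] %/% 2), , ] <- 1L
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  vols <- as.numeric(table(factor(labels, levels = 1:2))) * prod(voxel_size)
  structure(
    list(labels = labels, voxel_size = voxel_size,
         affine = diag(c(voxel_size, 1)),
         volumes = setNames(vols, 1:2)),
    class = "parcellation"
  )
}

#' @export
print.parcellation <- function(x, ...) {
  cat("<parcellation> ", length(x$volumes), " regions on ",
      paste(dim(x$labels), collapse = " x "), " grid\n", sep = "")
  invisible(x)
}
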