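#' Regular voxel grid specification
#'
#' A `grid_spec` describes an axis-aligned 3-D voxel lattice: the number of
#' voxels per axis, the voxel size in millimetres, and the world coordinate
#' (mm) of the *center* of voxel index `(0, 0, 0)`. Voxel indices are 0-based
#' and world coordinates are voxel-center based, so the world/voxel mapping is
#' the elementwise affine `world = origin + index * voxel_size`. The world
#' axes follow the usual neuroimaging RAS convention: x left-to-right,
#' y posterior-to-anterior, z inferior-to-superior. Rotated (oblique) grids
#' are not supported.
#'
#' @param shape Integer vector of length 3, voxels per axis (each >= 1).
#' @param voxel_size_mm Numeric vector of length 3, voxel edge lengths in mm
#'   (each > 0).
#' @param origin_mm Numeric vector of length 3, world coordinate (mm) of the
#'   center of voxel `(0, 0, 0)`.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(c(48, 48, 48), c(0.5, 0.5, 0.5), c(-12, -12, -34))
#' voxel_volume_mm3(g)
#' @export
grid_spec <- function(shape, voxel_size_mm = c(0.5, 0.5, 0.5), origin_mm = c(0, 0, 0)) {
  shape <- as.integer(shape)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  origin_mm <- as.numeric(origin_mm)
  stopifnot(length(shape) == 3L, length(voxel_size_mm) == 3L, length(origin_mm) == 3L)
  if (any(shape < 1L)) stop("grid shape entries must all be >= 1", call. = FALSE)
  if (any(!is.finite(voxel_size_mm)) || any(voxel_size_mm <= 0)) {
    stop("voxel sizes must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(origin_mm))) stop("grid origin must be finite", call. = FALSE)
  structure(
    list(shape = shape, voxel_size_mm = voxel_size_mm, origin_mm = origin_mm),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d x %d voxels, %.3g x %.3g x %.3g mm, origin (%.3g, %.3g, %.3g) mm\n",
    x$shape[1], x$shape[2], x$shape[3],
    x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3],
    x$origin_mm[1], x$origin_mm[2], x$origin_mm[3]
  ))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("%dx%dx%d @ %.3g mm", x$shape[1], x$shape[2], x$shape[3], x$voxel_size_mm[1])
}

#' Volume of one voxel in cubic millimetres
#'
#' @param grid A [grid_spec()].
#' @return Scalar voxel volume in mm^3.
#' @export
voxel_volume_mm3 <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  prod(grid$voxel_size_mm)
}

#' Are two grids identical?
#'
#' Two volumes or masks are grid-compatible iff their `grid_spec`s are
#' identical (same shape, voxel size and origin). All voxelwise operations in
#' the package require compatibility; nothing resamples.
#'
#' @param a,b [grid_spec()] objects.
#' @param tol Numeric tolerance on voxel size and origin, mm.
#' @return Logical scalar.
#' @export
grids_compatible <- function(a, b, tol = 1e-6) {
  stopifnot(inherits(a, "grid_spec"), inherits(b, "grid_spec"))
  identical(a$shape, b$shape) &&
    all(abs(a$voxel_size_mm - b$voxel_size_mm) <= tol) &&
    all(abs(a$origin_mm - b$origin_mm) <= tol)
}

stop_if_incompatible <- function(a, b, what = "inputs") {
  if (!grids_compatible(a, b)) {
    stop(sprintf("%s are on different grids; voxelwise operations require identical grids", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Convert between voxel indices and world coordinates
#'
#' `voxel_to_world()` maps 0-based voxel indices to world mm (voxel centers);
#' `world_to_voxel()` is the exact inverse (returns fractional indices; round
#' to land on lattice points). Both accept an `n x 3` matrix or a length-3
#' vector.
#'
#' @param idx 0-based voxel indices (vector of 3 or n x 3 matrix).
#' @param xyz World coordinates in mm (vector of 3 or n x 3 matrix).
#' @param grid A [grid_spec()].
#' @return A matrix (or vector) of the same shape as the input.
#' @export
voxel_to_world <- function(idx, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  was_vec <- is.null(dim(idx))
  idx <- rbind_mat3(idx)
  out <- sweep(sweep(idx, 2, grid$voxel_size_mm, "*"), 2, grid$origin_mm, "+")
  if (was_vec) drop(out) else out
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(xyz, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  was_vec <- is.null(dim(xyz))
  xyz <- rbind_mat3(xyz)
  out <- sweep(sweep(xyz, 2, grid$origin_mm, "-"), 2, grid$voxel_size_mm, "/")
  if (was_vec) drop(out) else out
}

rbind_mat3 <- function(x) {
  if (is.null(dim(x))) {
    stopifnot(length(x) == 3L)
    matrix(as.numeric(x), nrow = 1L)
  } else {
    stopifnot(ncol(x) == 3L)
    `dim<-`(as.numeric(x), dim(x))
  }
}

# world z coordinates of all axial slices of the grid, in voxel-index order
grid_z_coords <- function(grid) {
  grid$origin_mm[3] + grid$voxel_size_mm[3] * (seq_len(grid$shape[3]) - 1)
}

#' Axial slice numbering convention
#'
#' Atlas work on the 0.5 mm MNI/ICBM152 grid reports axial positions both as
#' world z (mm) and as template slice numbers. The anchor used throughout this
#' package is the template convention in which slice 112 sits at z = -16 mm
#' with 0.5 mm spacing and slice numbers decrease toward caudal, so
#' `z = -16 + 0.5 * (slice - 112)`. Slice numbering drifts across templates,
#' so the anchor is configurable.
#'
#' @param anchor_slice Slice number at the anchor (default 112).
#' @param anchor_z_mm World z of the anchor slice (default -16 mm).
#' @param spacing_mm Slice spacing in mm (default 0.5).
#' @return An object of class `slice_convention`.
#' @export
slice_convention <- function(anchor_slice = 112L, anchor_z_mm = -16, spacing_mm = 0.5) {
  stopifnot(is.finite(spacing_mm), spacing_mm > 0)
  structure(
    list(anchor_slice = as.integer(anchor_slice),
         anchor_z_mm = as.numeric(anchor_z_mm),
         spacing_mm = as.numeric(spacing_mm)),
    class = "slice_convention"
  )
}

#' Convert slice numbers to world z (mm) and back
#'
#' `slice_to_z()` maps a template axial slice number to world z in mm;
#' `z_to_slice()` is its exact inverse. With the default convention,
#' slice 112 maps to -16 mm and slice 86 to -29 mm. If a `grid` is supplied
#' the result is checked to lie on that grid (range error otherwise).
#'
#' @param slice Integer slice number(s).
#' @param z World z coordinate(s), mm.
#' @param convention A [slice_convention()].
#' @param grid Optional [grid_spec()]; when given, out-of-grid slices error.
#' @return Numeric z in mm (`slice_to_z`) or integer slice (`z_to_slice`).
#' @examples
#' slice_to_z(112) # -16
#' slice_to_z(86)  # -29
#' z_to_slice(-22.5)
#' @export
slice_to_z <- function(slice, convention = slice_convention(), grid = NULL) {
  stopifnot(inherits(convention, "slice_convention"))
  z <- convention$anchor_z_mm + convention$spacing_mm * (slice - convention$anchor_slice)
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "grid_spec"))
    zc <- grid_z_coords(grid)
    bad <- z < min(zc) - 1e-9 | z > max(zc) + 1e-9
    if (any(bad)) {
      stop(sprintf("slice %s is outside the grid (z range %.3g..%.3g mm)",
                   paste(slice[bad], collapse = ", "), min(zc), max(zc)), call. = FALSE)
    }
  }
  z
}

#' @rdname slice_to_z
#' @export
z_to_slice <- function(z, convention = slice_convention()) {
  stopifnot(inherits(convention, "slice_convention"))
  s <- convention$anchor_slice + (z - convention$anchor_z_mm) / convention$spacing_mm
  s_int <- as.integer(round(s))
  if (any(abs(s - s_int) > 1e-6)) {
    stop("z does not fall on a slice under this convention", call. = FALSE)
  }
  s_int
}

# 0-based voxel z index of a template slice on a grid; errors when the slice
# plane does not coincide with a voxel-center plane of the grid.
slice_to_k <- function(slice, grid, convention = slice_convention()) {
  z <- slice_to_z(slice, convention)
  k <- (z - grid$origin_mm[3]) / grid$voxel_size_mm[3]
  k_int <- as.integer(round(k))
  if (any(abs(k - k_int) > 1e-6)) {
    stop("slice plane does not coincide with a voxel-center plane of this grid", call. = FALSE)
  }
  if (any(k_int < 0L | k_int >= grid$shape[3])) {
    stop("slice is outside the grid", call. = FALSE)
  }
  k_int
}
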