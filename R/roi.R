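#' Searching-area specification
#'
#' The LC searching area is a stack of circular in-plane ROIs (discs), one per
#' axial slice, spanning the rostrocaudal extent of the nucleus. The default
#' follows the matched-volume design used for unbiased signal extraction:
#' a 2.5 mm diameter disc per hemisphere over slices 86 (z = -29 mm, the
#' recess of the 4th ventricle) to 112 (z = -16 mm, the SCP decussation),
#' i.e. 27 slices covering 13.5 mm.
#'
#' @param centers Tibble/data frame with columns `slice`, `hemisphere`
#'   (`"left"`/`"right"`), `x`, `y` (disc center, mm) giving the per-slice
#'   center path. Must cover every slice in `caudal_slice:rostral_slice` for
#'   each hemisphere present.
#' @param diameter_mm Disc diameter in mm (default 2.5).
#' @param rostral_slice,caudal_slice Slab limits (defaults 112 and 86).
#' @param convention A [slice_convention()].
#' @return An object of class `search_spec`.
#' @export
search_spec <- function(centers, diameter_mm = 2.5,
                        rostral_slice = 112L, caudal_slice = 86L,
                        convention = slice_convention()) {
  stopifnot(is.data.frame(centers),
            all(c("slice", "hemisphere", "x", "y") %in% names(centers)))
  rostral_slice <- as.integer(rostral_slice)
  caudal_slice <- as.integer(caudal_slice)
  if (!(rostral_slice > caudal_slice)) {
    stop("rostral_slice must exceed caudal_slice", call. = FALSE)
  }
  if (!is.finite(diameter_mm) || diameter_mm <= 0) {
    stop("diameter_mm must be > 0", call. = FALSE)
  }
  slab <- caudal_slice:rostral_slice
  for (h in unique(centers$hemisphere)) {
    have <- sort(unique(centers$slice[centers$hemisphere == h]))
    if (!all(slab %in% have)) {
      stop(sprintf("center path for hemisphere '%s' does not cover every slab slice", h),
           call. = FALSE)
    }
  }
  structure(list(centers = tibble::as_tibble(centers),
                 diameter_mm = diameter_mm,
                 rostral_slice = rostral_slice, caudal_slice = caudal_slice,
                 convention = convention),
            class = "search_spec")
}

#' @export
print.search_spec <- function(x, ...) {
  n_sl <- x$rostral_slice - x$caudal_slice + 1L
  cat(sprintf("<search_spec> %.3g mm discs, slices %d..%d (%d slices, %.3g mm), hemispheres: %s\n",
              x$diameter_mm, x$caudal_slice, x$rostral_slice, n_sl,
              n_sl * x$convention$spacing_mm,
              paste(sort(unique(x$centers$hemisphere)), collapse = ", ")))
  invisible(x)
}

#' Rostrocaudal extent of a searching-area slab in mm
#' @param spec A [search_spec()].
#' @return Extent in mm (number of slices times slice spacing).
#' @export
slab_extent_mm <- function(spec) {
  stopifnot(inherits(spec, "search_spec"))
  (spec$rostral_slice - spec$caudal_slice + 1L) * spec$convention$spacing_mm
}

#' Rasterise a circular in-plane ROI onto one axial slice
#'
#' Membership is by voxel center: a voxel belongs to the disc iff its center
#' lies within Euclidean distance `diameter_mm / 2` of the disc center
#' (closed disc, ties included). On a 0.5 mm grid a 2.5 mm disc centered on a
#' voxel center covers 21 voxels.
#'
#' @param center_xy Numeric length-2, disc center (x, y) in mm.
#' @param diameter_mm Disc diameter in mm.
#' @param grid A [grid_spec()].
#' @param slice Template slice number of the target axial plane.
#' @param convention A [slice_convention()].
#' @return A [roi_mask()]; errors if the disc misses the grid entirely.
#' @export
rasterize_disc <- function(center_xy, diameter_mm, grid, slice,
                           convention = slice_convention()) {
  stopifnot(inherits(grid, "grid_spec"), length(center_xy) == 2L)
  if (!is.finite(diameter_mm) || diameter_mm <= 0) {
    stop("diameter_mm must be > 0", call. = FALSE)
  }
  k <- slice_to_k(slice, grid, convention)
  xs <- grid$origin_mm[1] + grid$voxel_size_mm[1] * (seq_len(grid$shape[1]) - 1)
  ys <- grid$origin_mm[2] + grid$voxel_size_mm[2] * (seq_len(grid$shape[2]) - 1)
  r <- diameter_mm / 2
  inx <- which(abs(xs - center_xy[1]) <= r)
  iny <- which(abs(ys - center_xy[2]) <= r)
  m <- array(FALSE, dim = grid$shape)
  if (length(inx) && length(iny)) {
    d2 <- outer((xs[inx] - center_xy[1])^2, (ys[iny] - center_xy[2])^2, "+")
    m[inx, iny, k + 1L] <- d2 <= r^2 + 1e-12
  }
  if (!any(m)) {
    stop("disc covers no voxel centers on the grid (empty mask)", call. = FALSE)
  }
  roi_mask(m, grid)
}

#' Build a searching area from a per-slice disc path
#'
#' The searching area per hemisphere is the union of per-slice discs over the
#' slab; its volume is the sum of per-slice voxel counts times the voxel
#' volume. At the defaults (2.5 mm discs, 27 slices, 0.5 mm grid, centers on
#' voxel centers) each hemisphere counts 567 voxels = 70.875 mm^3, the
#' matched-volume counterpart of the 72 mm^3 reference cube.
#'
#' @param spec A [search_spec()].
#' @param grid A [grid_spec()].
#' @return A named list of [roi_mask()], one per hemisphere in the spec.
#' @export
build_searching_area <- function(spec, grid) {
  stopifnot(inherits(spec, "search_spec"), inherits(grid, "grid_spec"))
  slab <- spec$caudal_slice:spec$rostral_slice
  hemis <- sort(unique(spec$centers$hemisphere))
  out <- lapply(hemis, function(h) {
    m <- array(FALSE, dim = grid$shape)
    ctr <- spec$centers[spec$centers$hemisphere == h, ]
    for (s in slab) {
      row <- ctr[ctr$slice == s, ][1, ]
      disc <- rasterize_disc(c(row$x, row$y), spec$diameter_mm, grid, s,
                             spec$convention)
      m <- m | disc$mask
    }
    roi_mask(m, grid)
  })
  names(out) <- hemis
  out
}

#' Reference-region specification
#'
#' Candidate reference regions supply the noise baseline for thresholding and
#' CNR. Cubic candidates (pontine tegmentum: central, dorsal, left, right)
#' default to 4 x 4 x 4.5 mm^3 (576 voxels = 72 mm^3 at 0.5 mm); `lc_shaped`
#' candidates clone the searching-area geometry (same shape and size)
#' translated to the root of the superior cerebellar peduncle, so searching
#' area and lc_shaped reference volumes are equal by construction.
#'
#' @param name Candidate name (`central_pt`, `dorsal_pt`, `left_pt`,
#'   `right_pt`, `left_scp`, `right_scp`, or any label).
#' @param shape `"cube"` or `"lc_shaped"`.
#' @param center_mm For cubes: numeric length-3 box center (mm). For
#'   `lc_shaped`: numeric length-2 (x, y) target center; the source path is
#'   rigidly translated in-plane so its mean center lands there.
#' @param dims_mm Cube edge lengths in mm (default `c(4, 4, 4.5)`).
#' @param source_spec For `lc_shaped`: the [search_spec()] to clone, plus the
#'   hemisphere of the path to copy.
#' @param hemisphere For `lc_shaped`: which path of `source_spec` to clone.
#' @return An object of class `reference_spec`.
#' @export
reference_spec <- function(name, shape = c("cube", "lc_shaped"),
                           center_mm, dims_mm = c(4, 4, 4.5),
                           source_spec = NULL, hemisphere = NULL) {
  shape <- match.arg(shape)
  if (shape == "cube") {
    stopifnot(length(center_mm) == 3L, length(dims_mm) == 3L, all(dims_mm > 0))
  } else {
    stopifnot(length(center_mm) == 2L, inherits(source_spec, "search_spec"),
              hemisphere %in% source_spec$centers$hemisphere)
  }
  structure(list(name = name, shape = shape, center_mm = as.numeric(center_mm),
                 dims_mm = as.numeric(dims_mm), source_spec = source_spec,
                 hemisphere = hemisphere),
            class = "reference_spec")
}

#' Rasterise a reference ROI
#'
#' Cubes use a half-open membership rule: a voxel belongs iff its center lies
#' in `[c - d/2, c + d/2)` on every axis, which makes a 4 x 4 x 4.5 mm box
#' centered on a voxel center cover exactly 8 x 8 x 9 = 576 voxels at 0.5 mm.
#' `lc_shaped` ROIs rebuild the searching-area disc stack at the translated
#' center path.
#'
#' @param spec A [reference_spec()].
#' @param grid A [grid_spec()].
#' @return A [roi_mask()].
#' @export
build_reference_roi <- function(spec, grid) {
  stopifnot(inherits(spec, "reference_spec"), inherits(grid, "grid_spec"))
  if (spec$shape == "cube") {
    lo <- spec$center_mm - spec$dims_mm / 2
    hi <- spec$center_mm + spec$dims_mm / 2
    ax <- lapply(1:3, function(a) {
      cs <- grid$origin_mm[a] + grid$voxel_size_mm[a] * (seq_len(grid$shape[a]) - 1)
      which(cs >= lo[a] - 1e-9 & cs < hi[a] - 1e-9)
    })
    if (any(lengths(ax) == 0L)) {
      stop("reference cube covers no voxel centers on the grid", call. = FALSE)
    }
    # geometry error if the box sticks out of the grid
    for (a in 1:3) {
      cs <- grid$origin_mm[a] + grid$voxel_size_mm[a] * c(0, grid$shape[a] - 1)
      if (lo[a] < cs[1] - grid$voxel_size_mm[a] / 2 ||
          hi[a] > cs[2] + grid$voxel_size_mm[a] / 2) {
        stop("reference cube exceeds the grid", call. = FALSE)
      }
    }
    m <- array(FALSE, dim = grid$shape)
    m[ax[[1]], ax[[2]], ax[[3]]] <- TRUE
    return(roi_mask(m, grid))
  }
  src <- spec$source_spec
  ctr <- src$centers[src$centers$hemisphere == spec$hemisphere, ]
  shift <- spec$center_mm - c(mean(ctr$x), mean(ctr$y))
  moved <- dplyr::mutate(ctr, x = .data$x + shift[1], y = .data$y + shift[2])
  clone <- search_spec(moved, diameter_mm = src$diameter_mm,
                       rostral_slice = src$rostral_slice,
                       caudal_slice = src$caudal_slice,
                       convention = src$convention)
  build_searching_area(clone, grid)[[spec$hemisphere]]
}

#' Dice similarity coefficient between two masks
#'
#' `DSC = 2 |A intersect B| / (|A| + |B|)`: 1 for identical non-empty masks,
#' 0 for disjoint ones. Used to score mask agreement, e.g. recovered
#' segmentations against ground truth.
#'
#' @param a,b Grid-compatible [roi_mask()] objects, not both empty.
#' @return DSC in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "roi_mask"), inherits(b, "roi_mask"))
  stop_if_incompatible(a$grid, b$grid, "masks")
  na <- mask_count(a); nb <- mask_count(b)
  if (na + nb == 0L) stop("DSC is undefined for two empty masks", call. = FALSE)
  2 * sum(a$mask & b$mask) / (na + nb)
}

# ---- exact disc/voxel overlap (partial volume) -----------------------------

# Area of { u^2 + v^2 <= r^2 } intersected with [x1,x2] x [y1,y2], circle at
# the origin. Piecewise-exact 1-D integration of the clipped chord length:
# len(x) = max(0, min(y2, h) - max(y1, -h)), h = sqrt(r^2 - x^2), split at the
# x where h crosses |y1| and |y2| so each piece has a closed antiderivative.
circ_rect_area <- function(x1, x2, y1, y2, r) {
  a0 <- max(x1, -r); b0 <- min(x2, r)
  if (a0 >= b0) return(0)
  Hf <- function(x) (x * sqrt(pmax(r^2 - x^2, 0)) + r^2 * asin(pmin(pmax(x / r, -1), 1))) / 2
  brk <- c(a0, b0)
  for (yy in c(y1, y2)) {
    if (abs(yy) < r) {
      xc <- sqrt(r^2 - yy^2)
      brk <- c(brk, -xc, xc)
    }
  }
  brk <- sort(unique(pmin(pmax(brk, a0), b0)))
  total <- 0
  for (i in seq_len(length(brk) - 1L)) {
    a <- brk[i]; b <- brk[i + 1L]
    if (b - a <= 1e-12) next
    xm <- (a + b) / 2
    hm <- sqrt(max(r^2 - xm^2, 0))
    up <- min(y2, hm); lo <- max(y1, -hm)
    if (up <= lo) next
    upper <- if (y2 < hm) y2 * (b - a) else Hf(b) - Hf(a)
    lower <- if (y1 > -hm) y1 * (b - a) else -(Hf(b) - Hf(a))
    total <- total + (upper - lower)
  }
  total
}

# Fraction of each voxel's in-plane footprint covered by a disc of radius
# r_mm at center_xy; returns only voxels with fraction > 0 on the slice with
# 0-based z index k. Used by the phantom's partial-volume blending.
disc_voxel_fractions <- function(center_xy, r_mm, grid, k) {
  xs <- grid$origin_mm[1] + grid$voxel_size_mm[1] * (seq_len(grid$shape[1]) - 1)
  ys <- grid$origin_mm[2] + grid$voxel_size_mm[2] * (seq_len(grid$shape[2]) - 1)
  hx <- grid$voxel_size_mm[1] / 2; hy <- grid$voxel_size_mm[2] / 2
  inx <- which(xs >= center_xy[1] - r_mm - hx & xs <= center_xy[1] + r_mm + hx)
  iny <- which(ys >= center_xy[2] - r_mm - hy & ys <= center_xy[2] + r_mm + hy)
  if (!length(inx) || !length(iny)) {
    return(data.frame(i = integer(), j = integer(), k = integer(), frac = double()))
  }
  vox_area <- (2 * hx) * (2 * hy)
  res <- vector("list", length(inx) * length(iny))
  n <- 0L
  for (ii in inx) {
    dx1 <- xs[ii] - hx - center_xy[1]; dx2 <- xs[ii] + hx - center_xy[1]
    for (jj in iny) {
      dy1 <- ys[jj] - hy - center_xy[2]; dy2 <- ys[jj] + hy - center_xy[2]
      ar <- circ_rect_area(dx1, dx2, dy1, dy2, r_mm)
      if (ar > 0) {
        n <- n + 1L
        res[[n]] <- c(ii - 1L, jj - 1L, k, ar / vox_area)
      }
    }
  }
  if (n == 0L) {
    return(data.frame(i = integer(), j = integer(), k = integer(), frac = double()))
  }
  m <- do.call(rbind, res[seq_len(n)])
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
             k = as.integer(m[, 3]), frac = pmin(m[, 4], 1))
}
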