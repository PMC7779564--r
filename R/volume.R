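#' 3-D image volume on a regular grid
#'
#' An `image_volume` pairs a 3-D numeric array with a [grid_spec()] and a
#' modality tag (`"mt_on"`, `"mt_off"`, `"mtr"`, `"cnr"`, or `"other"`).
#' Values must be finite except for voxels flagged missing with `NA`.
#'
#' @param values 3-D numeric array matching `grid$shape`.
#' @param grid A [grid_spec()].
#' @param modality Modality tag.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, grid,
                         modality = c("other", "mt_on", "mt_off", "mtr", "cnr")) {
  modality <- match.arg(modality)
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.array(values)
  if (!identical(dim(values), NULL) && length(dim(values)) != 3L) {
    stop("values must be a 3-D array", call. = FALSE)
  }
  if (!identical(as.integer(dim(values)), grid$shape)) {
    stop("values dimensions do not match grid shape", call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (any(is.infinite(values))) {
    stop("image values must be finite (use NA for missing voxels)", call. = FALSE)
  }
  structure(list(values = values, grid = grid, modality = modality),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("<image_volume> %s, %s, values %.4g..%.4g (%d NA)\n",
              x$modality, format(x$grid), rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

#' Binary region-of-interest mask on a regular grid
#'
#' A `roi_mask` is a set of voxels on a grid, stored as a logical array.
#' It represents searching areas, reference regions, segmentations, pons
#' masks and thresholded atlas templates.
#'
#' @param mask Logical (or 0/1 numeric) 3-D array matching `grid$shape`.
#' @param grid A [grid_spec()].
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L) stop("mask must be a 3-D array", call. = FALSE)
  if (!identical(as.integer(dim(mask)), grid$shape)) {
    stop("mask dimensions do not match grid shape", call. = FALSE)
  }
  if (is.numeric(mask)) {
    if (any(is.na(mask)) || any(!mask %in% c(0, 1))) {
      stop("numeric mask must contain only 0 and 1", call. = FALSE)
    }
    mask <- mask > 0
  }
  stopifnot(is.logical(mask))
  mask[is.na(mask)] <- FALSE
  structure(list(mask = mask, grid = grid), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d voxels (%.4g mm^3), %s\n",
              mask_count(x), mask_volume_mm3(x), format(x$grid)))
  invisible(x)
}

#' Number of voxels in a mask
#' @param mask A [roi_mask()].
#' @return Integer voxel count.
#' @export
mask_count <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  sum(mask$mask)
}

#' Mask volume in cubic millimetres
#'
#' Volume is voxel count times voxel volume; an empty mask has volume 0.
#' At 0.5 mm isotropic resolution (voxel volume 0.125 mm^3) a 705-voxel mask
#' measures 88.125 mm^3 and a 284-voxel mask 35.5 mm^3.
#'
#' @param mask A [roi_mask()].
#' @return Volume in mm^3.
#' @export
mask_volume_mm3 <- function(mask) {
  mask_count(mask) * voxel_volume_mm3(mask$grid)
}

#' Set operations on masks
#'
#' Voxelwise union, intersection and difference of grid-compatible masks.
#'
#' @param a,b [roi_mask()] objects on the same grid.
#' @return A [roi_mask()].
#' @export
mask_union <- function(a, b) {
  stopifnot(inherits(a, "roi_mask"), inherits(b, "roi_mask"))
  stop_if_incompatible(a$grid, b$grid, "masks")
  roi_mask(a$mask | b$mask, a$grid)
}

#' @rdname mask_union
#' @export
mask_intersect <- function(a, b) {
  stopifnot(inherits(a, "roi_mask"), inherits(b, "roi_mask"))
  stop_if_incompatible(a$grid, b$grid, "masks")
  roi_mask(a$mask & b$mask, a$grid)
}

#' @rdname mask_union
#' @export
mask_difference <- function(a, b) {
  stopifnot(inherits(a, "roi_mask"), inherits(b, "roi_mask"))
  stop_if_incompatible(a$grid, b$grid, "masks")
  roi_mask(a$mask & !b$mask, a$grid)
}

#' Tabulate mask voxels with world coordinates
#'
#' @param mask A [roi_mask()].
#' @param convention A [slice_convention()] used to label slices.
#' @return A tibble with 0-based voxel indices `i, j, k`, world `x, y, z`
#'   (mm), template `slice` number and `hemisphere` (`"left"` for x < 0,
#'   `"right"` for x > 0, `NA` on the midline).
#' @export
mask_voxel_table <- function(mask, convention = slice_convention()) {
  stopifnot(inherits(mask, "roi_mask"))
  idx <- which(mask$mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(tibble::tibble(i = integer(), j = integer(), k = integer(),
                          x = double(), y = double(), z = double(),
                          slice = integer(), hemisphere = character()))
  }
  idx0 <- idx - 1L
  xyz <- voxel_to_world(idx0, mask$grid)
  slice <- convention$anchor_slice +
    as.integer(round((xyz[, 3] - convention$anchor_z_mm) / convention$spacing_mm))
  hemi <- dplyr::case_when(xyz[, 1] < 0 ~ "left", xyz[, 1] > 0 ~ "right",
                           TRUE ~ NA_character_)
  tibble::tibble(i = idx0[, 1], j = idx0[, 2], k = idx0[, 3],
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 slice = slice, hemisphere = hemi)
}

#' Restrict a mask to one hemisphere
#'
#' Hemisphere assignment is by world x: x < 0 is left, x > 0 right; voxels
#' exactly on the midline (x = 0) belong to neither, which keeps the
#' assignment deterministic.
#'
#' @param mask A [roi_mask()].
#' @param side `"left"` or `"right"`.
#' @return A [roi_mask()].
#' @export
mask_hemisphere <- function(mask, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(mask, "roi_mask"))
  g <- mask$grid
  xs <- g$origin_mm[1] + g$voxel_size_mm[1] * (seq_len(g$shape[1]) - 1)
  keep <- if (side == "left") xs < 0 else xs > 0
  m <- mask$mask
  m[!keep, , ] <- FALSE
  roi_mask(m, g)
}

# ---- NIfTI I/O -------------------------------------------------------------

nifti_to_grid <- function(img, tol = 1e-3) {
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  scale <- abs(diag(rot))
  off <- abs(rot - diag(diag(rot)))
  if (any(off > tol * max(scale))) {
    stop("unsupported geometry: NIfTI affine is not axis-aligned (rotation/obliquity present)",
         call. = FALSE)
  }
  if (any(diag(rot) < 0)) {
    stop("unsupported geometry: NIfTI affine flips an axis; expected RAS-aligned data",
         call. = FALSE)
  }
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3-D NIfTI volume", call. = FALSE)
  grid_spec(d, diag(rot), aff[1:3, 4])
}

grid_to_affine <- function(grid) {
  aff <- diag(c(grid$voxel_size_mm, 1))
  aff[1:3, 4] <- grid$origin_mm
  aff
}

#' Read and write NIfTI-1 volumes
#'
#' `read_volume()` loads a `.nii`/`.nii.gz` file whose affine is axis-aligned
#' (off-diagonal terms above a relative tolerance of 1e-3 raise an
#' unsupported-geometry error) into an [image_volume()]; voxel sizes are
#' taken in mm from the header. `write_volume()` writes one back
#' (probability/scalar maps as float32). `read_mask()`/`write_mask()` do the
#' same for binary masks, stored as uint8 0/1.
#'
#' @param path Path to a NIfTI-1 file.
#' @param modality Modality tag for the returned volume.
#' @param vol An [image_volume()].
#' @param mask A [roi_mask()].
#' @return `read_volume()` an [image_volume()]; `read_mask()` a [roi_mask()];
#'   the writers return `path` invisibly.
#' @export
read_volume <- function(path, modality = c("other", "mt_on", "mt_off", "mtr", "cnr")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("cannot read '%s' as NIfTI: %s",
                                                   path, conditionMessage(e)), call. = FALSE))
  vals <- as.array(img)
  attributes(vals) <- list(dim = dim(img))
  image_volume(vals, nifti_to_grid(img), modality = modality)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$grid$voxel_size_mm
  img <- RNifti::`sform<-`(img, structure(grid_to_affine(vol$grid), code = 2L))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  vals <- v$values
  if (any(!vals %in% c(0, 1))) stop("mask file contains values other than 0/1", call. = FALSE)
  roi_mask(vals > 0, v$grid)
}

#' @rdname read_volume
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$mask), dim = mask$grid$shape))
  RNifti::pixdim(img) <- mask$grid$voxel_size_mm
  img <- RNifti::`sform<-`(img, structure(grid_to_affine(mask$grid), code = 2L))
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
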