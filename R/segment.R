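#' Threshold-based LC segmentation within the searching area
#'
#' A voxel inside the searching area is classified as LC iff its MT-on
#' intensity is strictly greater than the threshold (`Mean_REF + k SD_REF`);
#' ties at the threshold are excluded. Per-slice, per-hemisphere voxel
#' counts and peak records (the segmented voxel of maximal CNR per slice and
#' hemisphere) are populated; slices with no suprathreshold voxel yield
#' explicit missing peak records, never imputed values. Peak ties are broken
#' deterministically by the lowest linear voxel index in (x, then y) scan
#' order.
#'
#' @param mt_on_avg Repeat-averaged MT-on [image_volume()].
#' @param searching Named list of [roi_mask()]s, `left` and `right`.
#' @param threshold Intensity threshold from [segmentation_threshold()].
#' @param cnr A CNR [image_volume()] from [cnr_map()], same grid.
#' @param subject_id Label carried into the result tables.
#' @param convention A [slice_convention()].
#' @return A `segmentation_result`: `mask_left`, `mask_right`, `mask`
#'   (union), `threshold`, `counts` (tibble: subject_id, slice, hemisphere,
#'   count) and `peaks` (tibble: subject_id, slice, hemisphere, i, j, k,
#'   x, y, z, cnr — `NA` rows for empty slices).
#' @export
segment_lc <- function(mt_on_avg, searching, threshold, cnr,
                       subject_id = "subject", convention = slice_convention()) {
  stopifnot(inherits(mt_on_avg, "image_volume"), is.list(searching),
            all(c("left", "right") %in% names(searching)),
            inherits(cnr, "image_volume"), is.finite(threshold))
  for (h in c("left", "right")) {
    stopifnot(inherits(searching[[h]], "roi_mask"))
    stop_if_incompatible(mt_on_avg$grid, searching[[h]]$grid, "volume and searching area")
    if (mask_count(searching[[h]]) == 0L) {
      stop(sprintf("empty %s searching area", h), call. = FALSE)
    }
  }
  stop_if_incompatible(mt_on_avg$grid, cnr$grid, "MT-on and CNR volumes")

  g <- mt_on_avg$grid
  masks <- list(); counts <- list(); peaks <- list()
  for (h in c("left", "right")) {
    sel <- searching[[h]]$mask & !is.na(mt_on_avg$values) & mt_on_avg$values > threshold
    masks[[h]] <- roi_mask(sel, g)
    search_tbl <- mask_voxel_table(searching[[h]], convention)
    slices <- sort(unique(search_tbl$slice))
    seg_tbl <- mask_voxel_table(masks[[h]], convention)
    seg_tbl$cnr <- cnr$values[cbind(seg_tbl$i + 1L, seg_tbl$j + 1L, seg_tbl$k + 1L)]
    for (s in slices) {
      on_slice <- seg_tbl[seg_tbl$slice == s, ]
      counts[[length(counts) + 1L]] <- tibble::tibble(
        subject_id = subject_id, slice = s, hemisphere = h, count = nrow(on_slice))
      if (nrow(on_slice) == 0L) {
        peaks[[length(peaks) + 1L]] <- tibble::tibble(
          subject_id = subject_id, slice = s, hemisphere = h,
          i = NA_integer_, j = NA_integer_, k = NA_integer_,
          x = NA_real_, y = NA_real_, z = NA_real_, cnr = NA_real_)
      } else {
        best <- max(on_slice$cnr)
        cand <- on_slice[on_slice$cnr == best, ]
        cand <- cand[order(cand$i, cand$j), ][1, ]
        peaks[[length(peaks) + 1L]] <- tibble::tibble(
          subject_id = subject_id, slice = s, hemisphere = h,
          i = cand$i, j = cand$j, k = cand$k,
          x = cand$x, y = cand$y, z = cand$z, cnr = cand$cnr)
      }
    }
  }
  structure(list(subject_id = subject_id,
                 mask_left = masks$left, mask_right = masks$right,
                 mask = mask_union(masks$left, masks$right),
                 threshold = threshold,
                 counts = dplyr::bind_rows(counts),
                 peaks = dplyr::bind_rows(peaks)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %s: %d voxels (L %d / R %d) above T = %.4g\n",
              x$subject_id, mask_count(x$mask), mask_count(x$mask_left),
              mask_count(x$mask_right), x$threshold))
  invisible(x)
}

#' Long-format slice profile of a segmentation
#'
#' One row per slice and hemisphere with the voxel count and the peak
#' record, ready for slice-wise plotting of counts and peak CNR along the
#' rostrocaudal axis.
#'
#' @param result A `segmentation_result` from [segment_lc()].
#' @return Tibble: subject_id, slice, hemisphere, count, peak_x, peak_y,
#'   peak_z, peak_cnr.
#' @export
slice_profiles <- function(result) {
  stopifnot(inherits(result, "segmentation_result"))
  dplyr::left_join(
    result$counts,
    result$peaks |>
      dplyr::select("subject_id", "slice", "hemisphere",
                    peak_x = "x", peak_y = "y", peak_z = "z", peak_cnr = "cnr"),
    by = c("subject_id", "slice", "hemisphere")
  )
}

#' Build a probabilistic atlas from individual binary masks
#'
#' Adds and averages the individual masks: the atlas value at a voxel is the
#' fraction of subjects whose mask contains it, so every nonzero probability
#' is an integer multiple of `1/n`. Per-slice mean, median and maximum
#' probabilities are profiled over the voxels with nonzero probability (per
#' hemisphere); the median uses lower interpolation on the discrete `k/n`
#' grid.
#'
#' @param masks List of grid-compatible [roi_mask()]s, one per subject.
#' @param convention A [slice_convention()].
#' @return A `prob_atlas`: `prob` (an [image_volume()] in \[0, 1\]),
#'   `n_subjects`, and `profile` (tibble: slice, hemisphere, n_voxels,
#'   mean_p, median_p, max_p).
#' @export
build_prob_atlas <- function(masks, convention = slice_convention()) {
  stopifnot(is.list(masks), length(masks) >= 1L,
            all(vapply(masks, inherits, logical(1), "roi_mask")))
  g <- masks[[1]]$grid
  for (m in masks[-1]) stop_if_incompatible(g, m$grid, "masks")
  n <- length(masks)
  acc <- Reduce(`+`, lapply(masks, function(m) m$mask * 1L))
  prob <- image_volume(acc / n, g, modality = "other")
  nz <- roi_mask(acc > 0L, g)
  tbl <- mask_voxel_table(nz, convention)
  tbl$p <- prob$values[cbind(tbl$i + 1L, tbl$j + 1L, tbl$k + 1L)]
  profile <- tbl |>
    dplyr::filter(!is.na(.data$hemisphere)) |>
    dplyr::group_by(.data$slice, .data$hemisphere) |>
    dplyr::summarise(n_voxels = dplyr::n(),
                     mean_p = mean(.data$p),
                     median_p = stats::quantile(.data$p, 0.5, type = 1),
                     max_p = max(.data$p), .groups = "drop")
  structure(list(prob = prob, n_subjects = n, profile = profile,
                 convention = convention),
            class = "prob_atlas")
}

#' @export
print.prob_atlas <- function(x, ...) {
  cat(sprintf("<prob_atlas> n = %d subjects, %d nonzero voxels, max probability %.4g%%\n",
              x$n_subjects, sum(x$prob$values > 0), 100 * max(x$prob$values)))
  invisible(x)
}

#' Threshold a probabilistic atlas into a binary template
#'
#' Keeps voxels with probability greater than or equal to `p`; `p` may be a
#' fraction (0.05) or a percentage (5), normalised internally. Thresholding
#' is monotone: raising `p` can only shrink the template; `p = 0` returns the
#' union of all contributing masks. The inclusive rule means that with
#' n = 53 the 5% template keeps voxels segmented in at least 3 subjects.
#'
#' @param atlas A `prob_atlas`.
#' @param p Probability threshold, fraction or percent.
#' @return A [roi_mask()]; its voxel count and mm^3 are printed by
#'   [print.roi_mask()] and available via [mask_count()] /
#'   [mask_volume_mm3()].
#' @export
threshold_atlas <- function(atlas, p) {
  stopifnot(inherits(atlas, "prob_atlas"), is.finite(p), p >= 0)
  if (p > 1) p <- p / 100   # percent spelling; above-maximum p gives an empty mask
  if (p == 0) {
    return(roi_mask(atlas$prob$values > 0, atlas$prob$grid))
  }
  roi_mask(atlas$prob$values >= p - 1e-12, atlas$prob$grid)
}

#' Mean CNR within a fixed atlas template
#'
#' Averages a subject's CNR map over the voxels of a fixed atlas-derived
#' mask. Because the mask is identical for every subject, this estimate is
#' not inflated by between-subject differences in segmented volume — the
#' volumetric-bias control that motivates atlas-based contrast extraction.
#'
#' @param cnr A CNR [image_volume()].
#' @param atlas_mask A non-empty [roi_mask()] on the same grid.
#' @return Mean CNR (scalar).
#' @export
atlas_cnr <- function(cnr, atlas_mask) {
  stopifnot(inherits(cnr, "image_volume"), inherits(atlas_mask, "roi_mask"))
  stop_if_incompatible(cnr$grid, atlas_mask$grid, "CNR map and atlas mask")
  if (mask_count(atlas_mask) == 0L) stop("atlas mask is empty", call. = FALSE)
  mean(cnr$values[atlas_mask$mask], na.rm = TRUE)
}
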