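#' Reference-region statistics
#'
#' Mean, sample SD (denominator n - 1), and SNR = mean / SD of the voxel
#' intensities inside an ROI. These are the `Mean_REF` / `SD_REF` that feed
#' the segmentation threshold and the CNR map. A region with zero variance
#' cannot estimate noise and raises a degenerate-region error.
#'
#' @param volume An [image_volume()].
#' @param roi A non-empty grid-compatible [roi_mask()] with at least 2 voxels.
#' @param name Label stored with the result.
#' @return A `reference_stats` object (also a one-row tibble via
#'   [tidy.reference_stats()]): fields `name`, `mean_ref`, `sd_ref`, `snr`,
#'   `n_voxels`.
#' @export
region_stats <- function(volume, roi, name = "reference") {
  stopifnot(inherits(volume, "image_volume"), inherits(roi, "roi_mask"))
  stop_if_incompatible(volume$grid, roi$grid, "volume and ROI")
  vals <- volume$values[roi$mask]
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2L) stop("ROI must contain at least 2 non-missing voxels", call. = FALSE)
  m <- mean(vals)
  s <- stats::sd(vals)
  if (s == 0) {
    stop("degenerate region: zero variance, cannot estimate noise", call. = FALSE)
  }
  structure(list(name = name, mean_ref = m, sd_ref = s, snr = m / s,
                 n_voxels = length(vals)),
            class = "reference_stats")
}

#' @export
print.reference_stats <- function(x, ...) {
  cat(sprintf("<reference_stats> %s: mean %.4g, SD %.4g, SNR %.4g (n = %d)\n",
              x$name, x$mean_ref, x$sd_ref, x$snr, x$n_voxels))
  invisible(x)
}

#' @rdname region_stats
#' @param x A `reference_stats` object.
#' @param ... Unused.
#' @method tidy reference_stats
#' @export
tidy.reference_stats <- function(x, ...) {
  tibble::tibble(name = x$name, mean_ref = x$mean_ref, sd_ref = x$sd_ref,
                 snr = x$snr, n_voxels = x$n_voxels)
}

#' Magnetisation transfer ratio map
#'
#' Voxelwise `MTR(%) = (MToff - MTon) / MToff x 100` from a grid-compatible
#' MT-off / MT-on pair. Voxels whose MT-off intensity is at or below
#' `eps` (default `1e-6` times the MT-off maximum) are flagged missing (`NA`)
#' rather than returned infinite; if every voxel is flagged the result would
#' be empty and an error is raised.
#'
#' @param mt_off,mt_on Grid-compatible [image_volume()]s.
#' @param eps Denominator floor; `NULL` for the default.
#' @return An [image_volume()] with modality `"mtr"`, values in percent.
#' @export
mtr_map <- function(mt_off, mt_on, eps = NULL) {
  stopifnot(inherits(mt_off, "image_volume"), inherits(mt_on, "image_volume"))
  stop_if_incompatible(mt_off$grid, mt_on$grid, "MT-off and MT-on volumes")
  if (is.null(eps)) eps <- 1e-6 * max(abs(mt_off$values), na.rm = TRUE)
  off <- mt_off$values
  bad <- is.na(off) | abs(off) <= eps
  vals <- (off - mt_on$values) / off * 100
  vals[bad] <- NA_real_
  if (all(is.na(vals))) stop("MTR map is empty: all MT-off voxels at or below eps", call. = FALSE)
  image_volume(vals, mt_off$grid, modality = "mtr")
}

#' Segmentation threshold from reference statistics
#'
#' `T = Mean_REF + k_sd x SD_REF`. The default `k_sd = 5` is the stringent
#' choice appropriate to high-SNR 7T data; `k_sd = 4` selects the more
#' liberal variant used in earlier 3T pipelines.
#'
#' @param stats A `reference_stats` object from [region_stats()].
#' @param k_sd Number of SDs above the reference mean (default 5; must be
#'   >= 0).
#' @return Threshold intensity (scalar).
#' @export
segmentation_threshold <- function(stats, k_sd = 5) {
  stopifnot(inherits(stats, "reference_stats"), is.finite(k_sd), k_sd >= 0)
  stats$mean_ref + k_sd * stats$sd_ref
}

#' Contrast-to-noise ratio map
#'
#' Voxelwise `CNR = (V - Mean_REF) / SD_REF` on an MT-on image. Noise is
#' estimated by the reference SD rather than the reference mean, so a voxel
#' exactly at the k-SD segmentation threshold has CNR exactly k.
#'
#' @param mt_on An [image_volume()] (typically the repeat-averaged MT-on).
#' @param stats A `reference_stats` object for the same subject.
#' @return An [image_volume()] with modality `"cnr"`; attribute
#'   `reference` records the reference ROI name.
#' @export
cnr_map <- function(mt_on, stats) {
  stopifnot(inherits(mt_on, "image_volume"), inherits(stats, "reference_stats"),
            stats$sd_ref > 0)
  out <- image_volume((mt_on$values - stats$mean_ref) / stats$sd_ref,
                      mt_on$grid, modality = "cnr")
  attr(out, "reference") <- stats$name
  out
}

#' Per-subject signal summaries for ROI candidates
#'
#' For each subject and each candidate ROI, extracts the mean signal and SNR
#' from the repeat-averaged MT-on image and the mean MTR from the subject's
#' MTR map (computed from a single MT-on repeat paired with the MT-off scan,
#' keeping the MTR and CNR pipelines distinct). This is the long table that
#' [evaluate_references()] consumes.
#'
#' @param subjects List of subject records as returned by
#'   [generate_subject()] (elements `mt_on_repeats`, `mt_off`, `truth`), or
#'   any list with those elements.
#' @param roi_masks Named list of [roi_mask()]s (candidates, plus optionally
#'   the left/right LC searching areas named `left_lc` / `right_lc`).
#' @return Tibble: `subject_id`, `roi`, `mean_signal`, `snr`, `mtr`,
#'   `n_voxels`.
#' @export
collect_roi_stats <- function(subjects, roi_masks) {
  stopifnot(is.list(subjects), is.list(roi_masks), length(roi_masks) > 0,
            !is.null(names(roi_masks)))
  purrr::map_dfr(subjects, function(s) {
    avg <- average_repeats(s$mt_on_repeats)
    mtr_vol <- mtr_map(s$mt_off, s$mt_on_repeats[[1]])
    purrr::map_dfr(names(roi_masks), function(nm) {
      roi_m <- roi_masks[[nm]]
      st <- region_stats(avg, roi_m, name = nm)
      mtr_mean <- mean(mtr_vol$values[roi_m$mask], na.rm = TRUE)
      tibble::tibble(subject_id = s$truth$subject_id, roi = nm,
                     mean_signal = st$mean_ref, snr = st$snr,
                     mtr = mtr_mean,
                     n_voxels = st$n_voxels)
    })
  })
}

#' Evaluate and rank candidate reference regions
#'
#' Implements the reference-selection protocol: candidate regions should show
#' low internal noise (high SNR) and a strong MT effect (high MTR), and
#' bilateral (left/right paired) candidates are only usable if their signal
#' is not lateralised. The function
#' 1. summarises each ROI across the cohort (mean signal, SNR, MTR),
#' 2. runs two-sided paired t-tests of left vs right signal for every
#'    left/right pair present (PT, SCP, and the LC searching areas),
#' 3. gates out bilateral candidates whose asymmetry test is significant at
#'    `alpha` — unless the LC itself is asymmetric, in which case ipsilateral
#'    referencing is flagged as admissible — and
#' 4. ranks the surviving candidates by mean SNR, breaking ties by mean MTR
#'    and then by candidate order, and selects the top one.
#'
#' No multiplicity correction is applied across the (few) asymmetry tests,
#' matching common practice for this design; see the vignette for the
#' limitation.
#'
#' @param stats_tbl Long tibble from [collect_roi_stats()].
#' @param alpha Two-sided significance level for the asymmetry gate.
#' @param lc_rois Character pair naming the left/right LC searching-area rows
#'   in `stats_tbl` (used for the LC asymmetry test only, never as
#'   reference candidates).
#' @return A `reference_evaluation` object: `summary` (per-ROI cohort means),
#'   `asymmetry` (paired t table), `selected` (chosen ROI name),
#'   `ipsilateral_admissible` (logical), and `decision` (human-readable
#'   justification).
#' @export
evaluate_references <- function(stats_tbl, alpha = 0.05,
                                lc_rois = c("left_lc", "right_lc")) {
  stopifnot(is.data.frame(stats_tbl),
            all(c("subject_id", "roi", "mean_signal", "snr", "mtr") %in% names(stats_tbl)))
  if (dplyr::n_distinct(stats_tbl$subject_id) < 2) {
    stop("need at least 2 subjects for asymmetry tests", call. = FALSE)
  }
  rois <- unique(stats_tbl$roi)
  pairs <- list()
  for (base in unique(sub("^(left|right)_", "", grep("^(left|right)_", rois, value = TRUE)))) {
    l <- paste0("left_", base); r <- paste0("right_", base)
    if (l %in% rois && r %in% rois) pairs[[base]] <- c(l, r)
  }
  empty_asym <- tibble::tibble(pair = character(), t = double(), df = double(),
                               p_value = double(), mean_right_minus_left = double(),
                               asymmetric = logical())
  asym <- purrr::map_dfr(names(pairs), function(base) {
    wide <- stats_tbl |>
      dplyr::filter(.data$roi %in% pairs[[base]]) |>
      dplyr::select("subject_id", "roi", "mean_signal") |>
      tidyr::pivot_wider(names_from = "roi", values_from = "mean_signal")
    lcol <- wide[[pairs[[base]][1]]]; rcol <- wide[[pairs[[base]][2]]]
    if (anyNA(lcol) || anyNA(rcol)) {
      stop(sprintf("missing paired ROI values for '%s'", base), call. = FALSE)
    }
    tt <- stats::t.test(rcol, lcol, paired = TRUE)
    tibble::tibble(pair = base, t = unname(tt$statistic), df = unname(tt$parameter),
                   p_value = tt$p.value, mean_right_minus_left = unname(tt$estimate),
                   asymmetric = tt$p.value < alpha)
  })
  if (nrow(asym) == 0L) asym <- empty_asym
  smry <- stats_tbl |>
    dplyr::group_by(.data$roi) |>
    dplyr::summarise(mean_signal = mean(.data$mean_signal), snr = mean(.data$snr),
                     mtr = mean(.data$mtr), .groups = "drop")
  lc_base <- unique(sub("^(left|right)_", "", lc_rois))
  lc_asym <- isTRUE(asym$asymmetric[asym$pair %in% lc_base][1])

  gate_one <- function(pair_name) {
    if (is.na(pair_name) || !pair_name %in% asym$pair) return(FALSE)
    asym$asymmetric[match(pair_name, asym$pair)] && !lc_asym
  }
  candidates <- smry |>
    dplyr::filter(!.data$roi %in% lc_rois) |>
    dplyr::mutate(
      pair = dplyr::if_else(grepl("^(left|right)_", .data$roi),
                            sub("^(left|right)_", "", .data$roi), NA_character_),
      gated = vapply(.data$pair, gate_one, logical(1))
    ) |>
    dplyr::mutate(order = match(.data$roi, setdiff(rois, lc_rois))) |>
    dplyr::arrange(.data$gated, dplyr::desc(.data$snr), dplyr::desc(.data$mtr),
                   .data$order)
  eligible <- candidates[!candidates$gated, ]
  if (nrow(eligible) == 0L) stop("no reference candidate passes the asymmetry gate",
                                 call. = FALSE)
  sel <- eligible$roi[1]
  decision <- sprintf(
    paste0("selected '%s' (cohort mean SNR %.2f, MTR %.2f%%); %d bilateral ",
           "candidate pair(s) %s by the asymmetry gate at alpha = %.2g; LC %s ",
           "lateralised, so ipsilateral referencing is %sadmissible"),
    sel, eligible$snr[1], eligible$mtr[1],
    sum(asym$asymmetric[asym$pair != lc_base]),
    if (any(asym$asymmetric[asym$pair != lc_base])) "excluded" else "not excluded",
    alpha, if (lc_asym) "is" else "is not", if (lc_asym) "" else "not ")
  structure(list(summary = smry, asymmetry = asym, selected = sel,
                 ipsilateral_admissible = lc_asym, candidates = candidates,
                 decision = decision),
            class = "reference_evaluation")
}

#' @export
print.reference_evaluation <- function(x, ...) {
  cat("<reference_evaluation>\n")
  cat(" ", x$decision, "\n")
  print(x$asymmetry)
  invisible(x)
}
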