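#' Plot slice-wise probability profiles of an atlas
#'
#' Mean, median and maximum probability per axial slice and hemisphere,
#' the standard summary of a probabilistic nucleus atlas along the
#' rostrocaudal axis.
#'
#' @param object A `prob_atlas` from [build_prob_atlas()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot prob_atlas
#' @export
autoplot.prob_atlas <- function(object, ...) {
  d <- object$profile |>
    tidyr::pivot_longer(c("mean_p", "median_p", "max_p"),
                        names_to = "statistic", values_to = "probability") |>
    dplyr::mutate(statistic = factor(.data$statistic,
                                     levels = c("mean_p", "median_p", "max_p"),
                                     labels = c("mean", "median", "max")))
  ggplot2::ggplot(d, ggplot2::aes(.data$slice, .data$probability,
                                  colour = .data$hemisphere)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~statistic, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "axial slice (caudal → rostral)",
                  y = "voxel probability",
                  title = sprintf("Probabilistic atlas profiles (n = %d)",
                                  object$n_subjects)) +
    ggplot2::theme_minimal()
}

#' Plot slice-wise segmented voxel counts
#'
#' Faded per-subject lines with the group mean and median overlaid, per
#' hemisphere — the rostrocaudal volumetric profile of the segmentation.
#'
#' @param counts Tibble with columns `subject_id`, `slice`, `hemisphere`,
#'   `count` (e.g. `recovery_report$slice_counts`).
#' @return A ggplot.
#' @export
plot_slice_counts <- function(counts) {
  stopifnot(all(c("subject_id", "slice", "hemisphere", "count") %in% names(counts)))
  grp <- counts |>
    dplyr::group_by(.data$slice, .data$hemisphere) |>
    dplyr::summarise(mean = mean(.data$count),
                     median = stats::median(.data$count), .groups = "drop") |>
    tidyr::pivot_longer(c("mean", "median"), names_to = "summary",
                        values_to = "count")
  ggplot2::ggplot(counts, ggplot2::aes(.data$slice, .data$count)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id), alpha = 0.15) +
    ggplot2::geom_line(data = grp,
                       ggplot2::aes(linetype = .data$summary, colour = .data$hemisphere),
                       linewidth = 0.9) +
    ggplot2::facet_wrap(~hemisphere) +
    ggplot2::labs(x = "axial slice (caudal → rostral)",
                  y = "segmented voxels per slice") +
    ggplot2::theme_minimal()
}

#' Plot slice-wise spatial variability of peak locations
#'
#' Group SD of the peak x and y coordinate per slice and hemisphere; in both
#' the in-vivo data this emulates and the default phantom, variability is
#' highest caudally.
#'
#' @param sd_profile Tibble from [spatial_sd_profile()].
#' @return A ggplot.
#' @export
plot_spatial_sd <- function(sd_profile) {
  stopifnot(all(c("slice", "hemisphere", "sd_x", "sd_y") %in% names(sd_profile)))
  d <- sd_profile |>
    tidyr::pivot_longer(c("sd_x", "sd_y"), names_to = "axis", values_to = "sd_mm") |>
    dplyr::mutate(axis = sub("sd_", "", .data$axis))
  ggplot2::ggplot(d, ggplot2::aes(.data$slice, .data$sd_mm, colour = .data$hemisphere)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~axis, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "axial slice (caudal → rostral)",
                  y = "group SD of peak coordinate (mm)") +
    ggplot2::theme_minimal()
}

#' Plot age against a contrast measure with the fitted regression line
#'
#' @param table Cohort tibble with `age` and the response column.
#' @param response Response column name.
#' @return A ggplot.
#' @export
plot_age_effect <- function(table, response) {
  stopifnot("age" %in% names(table), response %in% names(table))
  ggplot2::ggplot(table, ggplot2::aes(.data$age, .data[[response]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "steelblue") +
    ggplot2::labs(x = "age (years)", y = response) +
    ggplot2::theme_minimal()
}
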