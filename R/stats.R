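#' Slice-wise spatial variability of peak locations
#'
#' Group sample SD of the peak-voxel x and y world coordinates per axial
#' slice and hemisphere. Slices with fewer than 2 non-missing peaks get `NA`
#' (missing peaks are dropped pairwise, never imputed). In vivo this profile
#' shows the highest spatial variability in the caudal part of the nucleus;
#' the phantom reproduces that when its jitter gradient is so configured.
#'
#' @param peaks Peak table (e.g. from [segment_lc()]/[slice_profiles()]) with
#'   columns `slice`, `hemisphere`, `x`, `y` (one row per subject, slice and
#'   hemisphere; `NA` coordinates allowed).
#' @return Tibble: slice, hemisphere, n, sd_x, sd_y (mm).
#' @export
spatial_sd_profile <- function(peaks) {
  stopifnot(is.data.frame(peaks),
            all(c("slice", "hemisphere", "x", "y") %in% names(peaks)))
  sd2 <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) NA_real_ else stats::sd(v)
  }
  peaks |>
    dplyr::group_by(.data$slice, .data$hemisphere) |>
    dplyr::summarise(n = sum(!is.na(.data$x)),
                     sd_x = sd2(.data$x), sd_y = sd2(.data$y),
                     .groups = "drop")
}

#' Linear regression of a contrast measure on age
#'
#' Ordinary least squares of a cohort-table column on age, the standard test
#' for age-related change in LC contrast. Reports the model F statistic with
#' its df pair, p-value, R-squared, and slope/intercept with standard
#' errors. `min_age` restricts the fit to an older subgroup (e.g.
#' `min_age = 60` fits only subjects above 60).
#'
#' @param table Cohort tibble with an `age` column.
#' @param response Name of the response column (string).
#' @param min_age Optional lower age bound (exclusive).
#' @return An `age_regression` object; use [tidy.age_regression()] /
#'   [glance.age_regression()] for tibble views.
#' @export
age_regression <- function(table, response, min_age = NULL) {
  stopifnot(is.data.frame(table), "age" %in% names(table),
            response %in% names(table))
  d <- table[, c("age", response)]
  names(d) <- c("age", ".y")
  if (!is.null(min_age)) d <- d[d$age > min_age, ]
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 3L) stop("need at least 3 complete rows for an age regression", call. = FALSE)
  if (stats::sd(d$.y) == 0) {
    stop("degenerate fit: response is constant", call. = FALSE)
  }
  fit <- stats::lm(.y ~ age, data = d)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  structure(list(
    response = response, n = nrow(d), min_age = min_age, fit = fit,
    f_statistic = unname(fstat["value"]),
    df = c(unname(fstat["numdf"]), unname(fstat["dendf"])),
    p_value = unname(stats::pf(fstat["value"], fstat["numdf"], fstat["dendf"],
                               lower.tail = FALSE)),
    r_squared = sm$r.squared,
    slope = unname(stats::coef(fit)["age"]),
    slope_se = sm$coefficients["age", "Std. Error"],
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    intercept_se = sm$coefficients["(Intercept)", "Std. Error"]
  ), class = "age_regression")
}

#' @export
print.age_regression <- function(x, ...) {
  cat(sprintf("<age_regression> %s ~ age (n = %d%s): F(%d,%d) = %.3f, p = %.3g, R^2 = %.3f\n",
              x$response, x$n,
              if (is.null(x$min_age)) "" else sprintf(", age > %g", x$min_age),
              x$df[1], x$df[2], x$f_statistic, x$p_value, x$r_squared))
  invisible(x)
}

#' Tidy and glance methods for age regressions
#'
#' `tidy()` returns the coefficient table (term, estimate, std.error);
#' `glance()` returns a one-row model summary (F, df pair, p, R-squared, n).
#'
#' @param x An `age_regression` object.
#' @param ... Unused.
#' @method tidy age_regression
#' @export
tidy.age_regression <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "age"),
                 estimate = c(x$intercept, x$slope),
                 std.error = c(x$intercept_se, x$slope_se))
}

#' @rdname tidy.age_regression
#' @method glance age_regression
#' @export
glance.age_regression <- function(x, ...) {
  tibble::tibble(response = x$response, n = x$n,
                 min_age = if (is.null(x$min_age)) NA_real_ else x$min_age,
                 f_statistic = x$f_statistic, df1 = x$df[1], df2 = x$df[2],
                 p_value = x$p_value, r_squared = x$r_squared,
                 slope = x$slope, slope_se = x$slope_se)
}

#' Sex difference in a contrast measure
#'
#' Independent-samples two-sided t-test with pooled variance (df = n - 2)
#' comparing a cohort-table column between male and female subjects.
#'
#' @param table Cohort tibble with a `sex` column (`"male"`/`"female"`).
#' @param response Name of the response column.
#' @return One-row tibble: response, t, df, p_value, mean_male, mean_female.
#' @export
sex_difference <- function(table, response) {
  stopifnot(is.data.frame(table), "sex" %in% names(table),
            response %in% names(table))
  y <- table[[response]]; sex <- table$sex
  keep <- !is.na(y) & sex %in% c("male", "female")
  y <- y[keep]; sex <- sex[keep]
  if (sum(sex == "male") < 2L || sum(sex == "female") < 2L) {
    stop("both sex groups need at least 2 subjects", call. = FALSE)
  }
  tt <- stats::t.test(y[sex == "male"], y[sex == "female"], var.equal = TRUE)
  tibble::tibble(response = response, t = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 mean_male = mean(y[sex == "male"]),
                 mean_female = mean(y[sex == "female"]))
}

#' Type-I error calibration of the age regression under the null
#'
#' Simulates cohorts in which the contrast measure is independent of age —
#' ages uniform over the phantom's range, responses Gaussian with the
#' phantom's CNR-scale moments — runs [age_regression()] on each, and
#' reports the fraction rejected at `alpha`. With a correctly calibrated
#' test this fraction is close to `alpha`.
#'
#' @param n_reps Number of simulated cohorts (default 500).
#' @param n_subjects Cohort size per replicate (default 53).
#' @param age_range Inclusive integer age range (default 52-84).
#' @param cnr_mean,cnr_sd Moments of the null response distribution.
#' @param alpha Nominal level (default 0.05).
#' @param seed RNG seed.
#' @return One-row tibble: n_reps, n_subjects, alpha, rejections,
#'   rejection_rate.
#' @export
calibrate_age_regression_null <- function(n_reps = 500L, n_subjects = 53L,
                                          age_range = c(52L, 84L),
                                          cnr_mean = 10, cnr_sd = 1.5,
                                          alpha = 0.05, seed = 1L) {
  set.seed(seed)
  rej <- vapply(seq_len(n_reps), function(r) {
    tbl <- tibble::tibble(
      age = sample(seq(age_range[1], age_range[2]), n_subjects, replace = TRUE),
      cnr = stats::rnorm(n_subjects, cnr_mean, cnr_sd))
    age_regression(tbl, "cnr")$p_value < alpha
  }, logical(1))
  tibble::tibble(n_reps = n_reps, n_subjects = n_subjects, alpha = alpha,
                 rejections = sum(rej), rejection_rate = mean(rej))
}
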