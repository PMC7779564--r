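#' Run the full phantom recovery experiment
#'
#' End-to-end harness: generates the phantom cohort, averages repeats,
#' evaluates candidate reference regions (asymmetry gate + SNR/MTR ranking),
#' computes per-subject thresholds and CNR maps against the selected
#' reference, segments the nucleus within the searching areas, builds the
#' probabilistic atlas, thresholds it (5% and 25% by default), extracts CNR
#' both from per-slice peak voxels and within the fixed atlas templates, and
#' runs the cohort statistics (spatial SD profile, age regressions, sex
#' tests). Per-subject recovery is scored against the generator's ground
#' truth (Dice, volume error).
#'
#' All randomness flows from `config$seed`; identical config gives a
#' byte-identical written report.
#'
#' @param config A [phantom_config()].
#' @param k_sd Threshold stringency in reference SDs (default 5).
#' @param atlas_thresholds Atlas probability thresholds, percent
#'   (default `c(5, 25)`).
#' @param ablate_caudal_mm Per-subject caudal ablation lengths in mm
#'   (recycled across subjects; default 0 = intact cohort).
#' @param verbose Log per-stage progress to stderr.
#' @return A `recovery_report` list: `seed`, `n_subjects`, `reference`
#'   (the `reference_evaluation`), `subjects` (per-subject tibble with Dice,
#'   volumes, CNR measures), `slice_counts`, `peaks`, `spatial_sd`,
#'   `atlas` (the `prob_atlas`), `atlas_summary` (per-threshold voxel counts
#'   and mm^3), `regressions` (glance rows for all responses), `sex_tests`,
#'   and `checks` (named logical invariant results).
#' @export
run_recovery_experiment <- function(config = phantom_config(), k_sd = 5,
                                    atlas_thresholds = c(5, 25),
                                    ablate_caudal_mm = 0, verbose = FALSE) {
  stopifnot(inherits(config, "phantom_config"))
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  say("[generate] %d subjects x %d repeats", config$n_subjects, config$n_repeats)
  cohort <- stage("generate_cohort",
                  generate_cohort(config, ablate_caudal_mm = ablate_caudal_mm))
  abl <- rep_len(ablate_caudal_mm, config$n_subjects)

  say("[rois] searching areas + reference candidates")
  grid <- config$grid
  sspec <- phantom_search_spec(config)
  searching <- stage("build_searching_area", build_searching_area(sspec, grid))
  ref_specs <- phantom_reference_specs(config)
  ref_masks <- stage("build_reference_roi",
                     lapply(ref_specs, build_reference_roi, grid = grid))
  roi_masks <- c(ref_masks, list(left_lc = searching$left, right_lc = searching$right))

  say("[reference] cohort ROI statistics + selection")
  stats_tbl <- stage("collect_roi_stats", collect_roi_stats(cohort$subjects, roi_masks))
  ref_eval <- stage("evaluate_references", evaluate_references(stats_tbl))
  ref_roi <- ref_masks[[ref_eval$selected]]

  say("[segment] threshold k = %g SD, reference '%s'", k_sd, ref_eval$selected)
  per_subj <- vector("list", config$n_subjects)
  segs <- vector("list", config$n_subjects)
  cnrs <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    s <- cohort$subjects[[i]]
    avg <- average_repeats(s$mt_on_repeats)
    st <- region_stats(avg, ref_roi, name = ref_eval$selected)
    thr <- segmentation_threshold(st, k_sd = k_sd)
    cnr <- cnr_map(avg, st)
    seg <- segment_lc(avg, searching, thr, cnr, subject_id = s$truth$subject_id,
                      convention = config$convention)
    segs[[i]] <- seg; cnrs[[i]] <- cnr
    truth <- s$truth
    peak_l <- mean(seg$peaks$cnr[seg$peaks$hemisphere == "left"], na.rm = TRUE)
    peak_r <- mean(seg$peaks$cnr[seg$peaks$hemisphere == "right"], na.rm = TRUE)
    per_subj[[i]] <- tibble::tibble(
      subject_id = truth$subject_id, age = truth$age, sex = truth$sex,
      ablate_caudal_mm = abl[i],
      threshold = thr,
      dice = dice(seg$mask, truth$mask),
      truth_mm3 = mask_volume_mm3(truth$mask),
      segmented_mm3 = mask_volume_mm3(seg$mask),
      n_left = mask_count(seg$mask_left), n_right = mask_count(seg$mask_right),
      peak_cnr_left = peak_l, peak_cnr_right = peak_r,
      peak_cnr = mean(c(peak_l, peak_r), na.rm = TRUE))
  }

  say("[atlas] build + threshold at %s%%", paste(atlas_thresholds, collapse = "/"))
  atlas <- stage("build_prob_atlas",
                 build_prob_atlas(lapply(segs, `[[`, "mask"), config$convention))
  thr_masks <- lapply(atlas_thresholds, function(p) threshold_atlas(atlas, p))
  names(thr_masks) <- sprintf("p%g", atlas_thresholds)
  atlas_summary <- purrr::map_dfr(seq_along(atlas_thresholds), function(j) {
    tibble::tibble(threshold_pct = atlas_thresholds[j],
                   n_voxels = mask_count(thr_masks[[j]]),
                   volume_mm3 = mask_volume_mm3(thr_masks[[j]]))
  })

  say("[cnr] atlas-based extraction")
  subj_tbl <- dplyr::bind_rows(per_subj)
  for (j in seq_along(atlas_thresholds)) {
    pm <- thr_masks[[j]]
    lm_ <- mask_hemisphere(pm, "left"); rm_ <- mask_hemisphere(pm, "right")
    lab <- sprintf("cnr_prob%g", atlas_thresholds[j])
    vl <- vapply(cnrs, function(cn) atlas_cnr(cn, lm_), numeric(1))
    vr <- vapply(cnrs, function(cn) atlas_cnr(cn, rm_), numeric(1))
    subj_tbl[[paste0(lab, "_left")]] <- vl
    subj_tbl[[paste0(lab, "_right")]] <- vr
    subj_tbl[[lab]] <- (vl + vr) / 2
  }

  say("[stats] spatial SD, age regressions, sex tests")
  peaks <- dplyr::bind_rows(lapply(segs, `[[`, "peaks"))
  counts <- dplyr::bind_rows(lapply(segs, `[[`, "counts"))
  sd_prof <- spatial_sd_profile(peaks)

  responses <- c("peak_cnr", "peak_cnr_left", "peak_cnr_right",
                 sprintf("cnr_prob%g", atlas_thresholds),
                 sprintf("cnr_prob%g_left", atlas_thresholds),
                 sprintf("cnr_prob%g_right", atlas_thresholds))
  regressions <- dplyr::bind_rows(
    purrr::map_dfr(responses, function(rp) glance(age_regression(subj_tbl, rp))),
    purrr::map_dfr(responses, function(rp) {
      if (sum(subj_tbl$age > 60) >= 3) glance(age_regression(subj_tbl, rp, min_age = 60))
      else NULL
    })
  )
  sex_tests <- if (min(table(factor(subj_tbl$sex, c("male", "female")))) >= 2) {
    purrr::map_dfr(c("peak_cnr", sprintf("cnr_prob%g", atlas_thresholds)),
                   function(rp) sex_difference(subj_tbl, rp))
  } else {
    tibble::tibble(response = character(), t = double(), df = double(),
                   p_value = double(), mean_male = double(), mean_female = double())
  }

  say("[checks] invariants")
  probs <- atlas$prob$values[atlas$prob$values > 0]
  slab_z <- phantom_slab_z(config)
  zm <- mean(range(slab_z))
  caudal_z <- slab_z[slab_z < min(slab_z) + diff(range(slab_z)) / 3]
  central_z <- slab_z[abs(slab_z - zm) <= diff(range(slab_z)) / 6]
  sdz <- dplyr::left_join(sd_prof,
                          tibble::tibble(slice = config$z_caudal_slice:config$z_rostral_slice,
                                         z = slab_z), by = "slice")
  mean_sd <- function(zs) mean(c(sdz$sd_x[sdz$z %in% zs], sdz$sd_y[sdz$z %in% zs]),
                               na.rm = TRUE)
  nested <- if (length(thr_masks) >= 2) {
    ord <- order(atlas_thresholds)
    all(vapply(seq_len(length(ord) - 1L), function(j) {
      hi <- thr_masks[[ord[j + 1L]]]; lo <- thr_masks[[ord[j]]]
      !any(hi$mask & !lo$mask)
    }, logical(1)))
  } else TRUE
  checks <- c(
    atlas_probs_multiples_of_1_over_n =
      all(abs(probs * atlas$n_subjects - round(probs * atlas$n_subjects)) < 1e-9),
    atlas_mass_conserved =
      abs(sum(atlas$prob$values) * atlas$n_subjects -
            sum(vapply(segs, function(s) mask_count(s$mask), numeric(1)))) < 1e-6,
    atlas_thresholds_nested = nested,
    mean_dice_ge_0.7 = mean(subj_tbl$dice) >= 0.7,
    volume_error_le_25pct =
      abs(sum(subj_tbl$segmented_mm3) / sum(subj_tbl$truth_mm3) - 1) <= 0.25,
    caudal_sd_exceeds_central = mean_sd(caudal_z) > mean_sd(central_z),
    counts_match_masks =
      all(vapply(seq_along(segs), function(i) {
        sum(segs[[i]]$counts$count) == mask_count(segs[[i]]$mask_left) +
          mask_count(segs[[i]]$mask_right)
      }, logical(1)))
  )
  say("[done] %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))

  structure(list(
    schema_version = "1.0", seed = config$seed, n_subjects = config$n_subjects,
    n_repeats = config$n_repeats, k_sd = k_sd,
    reference = ref_eval, roi_stats = stats_tbl,
    subjects = subj_tbl, slice_counts = counts, peaks = peaks,
    spatial_sd = sd_prof, atlas = atlas, atlas_masks = thr_masks,
    atlas_summary = atlas_summary,
    regressions = regressions, sex_tests = sex_tests, checks = checks
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> n = %d, seed = %d, reference '%s'\n",
              x$n_subjects, x$seed, x$reference$selected))
  cat(sprintf("  mean Dice %.3f, volume ratio %.3f, atlas max p %.2f%%\n",
              mean(x$subjects$dice),
              sum(x$subjects$segmented_mm3) / sum(x$subjects$truth_mm3),
              100 * max(x$atlas$prob$values)))
  ok <- x$checks
  cat(sprintf("  checks: %d/%d passed%s\n", sum(ok), length(ok),
              if (all(ok)) "" else paste0(" (failed: ",
                                          paste(names(ok)[!ok], collapse = ", "), ")")))
  invisible(x)
}

#' Write a recovery report to disk
#'
#' Emits a versioned JSON summary plus TSV tables (per-subject measures,
#' slice counts, peaks, spatial SD, regressions, ROI statistics) and the
#' atlas as float32 NIfTI with uint8 thresholded templates. Output is
#' byte-deterministic for a fixed config and seed.
#'
#' @param report A `recovery_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "recovery_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(d, name) utils::write.table(
    d, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(report$subjects, "subjects.tsv")
  tsv(report$slice_counts, "slice_counts.tsv")
  tsv(report$peaks, "peaks.tsv")
  tsv(report$spatial_sd, "spatial_sd.tsv")
  tsv(report$regressions, "regressions.tsv")
  tsv(report$roi_stats, "roi_stats.tsv")
  write_volume(report$atlas$prob, file.path(dir, "atlas_prob.nii.gz"))
  for (nm in names(report$atlas_masks)) {
    write_mask(report$atlas_masks[[nm]], file.path(dir, sprintf("atlas_%s.nii.gz", nm)))
  }
  js <- list(
    schema_version = report$schema_version, seed = report$seed,
    n_subjects = report$n_subjects, n_repeats = report$n_repeats,
    k_sd = report$k_sd,
    reference = list(selected = report$reference$selected,
                     decision = report$reference$decision,
                     asymmetry = report$reference$asymmetry,
                     bayes_factors = NULL, cca = NULL),
    recovery = list(mean_dice = mean(report$subjects$dice),
                    volume_ratio = sum(report$subjects$segmented_mm3) /
                      sum(report$subjects$truth_mm3)),
    atlas = list(max_probability_pct = 100 * max(report$atlas$prob$values),
                 summary = report$atlas_summary),
    sex_tests = report$sex_tests,
    checks = as.list(report$checks)
  )
  jsonlite::write_json(js, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(dir)
}
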