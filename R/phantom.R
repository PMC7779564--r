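#' Phantom cohort configuration
#'
#' Describes the synthetic MT study the package tests itself against: a
#' pons-sized field at 0.5 mm isotropic resolution containing two rod-shaped
#' low-MTR nuclei (the LC analogue), a bright 4th-ventricle midline stripe
#' between them, superior-cerebellar-peduncle (SCP) tissue lateral to them,
#' and a pontine background. MT contrast follows the magnetisation-transfer
#' signal model: the noiseless MT-off image is the tissue baseline and the
#' noiseless MT-on image is `MT-off x (1 - MTR(tissue))`, so tissues with low
#' MTR (the LC, the ventricle) stay relatively bright once the saturation
#' pulses are on.
#'
#' The nucleus is built as a per-slice disc along a rostrocaudal centerline
#' with
#' * a radius profile peaking centrally (~1.25 mm) and tapering to ~0.6 mm at
#'   both ends,
#' * a multiplicative contrast (amplitude) profile rising from the rostral
#'   end to the center and falling toward the caudal end (ends at 0.6 of the
#'   central contrast), and
#' * per-slice spatial jitter whose SD grows toward the caudal end
#'   (0.25 mm central, 0.6 mm caudal), reproducing the caudally increasing
#'   between-subject spatial variability seen in vivo.
#'
#' Partial volume at the tube boundary is the exact in-plane disc/voxel
#' overlap fraction, which makes sub-voxel jitter meaningful at 0.5 mm. Each
#' MT-on repeat (default 3, emulating repeat-and-average acquisition) adds
#' independent Gaussian noise; `noise_sd` defaults to 27.5 so the
#' single-repeat pontine SNR is about 20.
#'
#' @param n_subjects Cohort size (default 53).
#' @param grid A [grid_spec()] (default 48^3 voxels, 0.5 mm isotropic, origin
#'   chosen so template slices 86..112 lie inside with margin and the world
#'   midline x = 0 falls on a voxel-center column).
#' @param tissue_mtr Named MTR fractions in \[0, 1): `pons`, `scp`, `lc`,
#'   `ventricle`, `background`. `lc` must be below `pons`; that inequality is
#'   what makes the nucleus hyperintense on MT-on.
#' @param mt_off_intensity Named positive baselines for the same tissues.
#' @param lc_x_mm,lc_y_mm Mean centerline position: the tubes run at
#'   x = -`lc_x_mm` (left) and +`lc_x_mm` (right), y = `lc_y_mm`.
#' @param z_caudal_slice,z_rostral_slice Slab limits (defaults 86 and 112).
#' @param lc_radius_mm Central and end radii `c(central, end)` in mm.
#' @param lc_amplitude Central and end contrast multipliers `c(central, end)`.
#' @param jitter_sd_mm Central and caudal-end jitter SD `c(central, caudal)`
#'   in mm; constant at the central value from center to rostral end.
#' @param noise_sd Additive Gaussian noise SD per repeat.
#' @param n_repeats MT-on repeats per subject (default 3).
#' @param seed Top-level seed; per-subject streams are derived from it.
#' @param age_range Inclusive integer age range sampled uniformly.
#' @param male_fraction Probability a subject is male.
#' @param right_intensity_factor Multiplies all intensities at x > 0;
#'   1 means a symmetric cohort, 1.05 injects a +5% right-hemisphere bias.
#' @param convention A [slice_convention()].
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(n_subjects = 53L,
                           grid = grid_spec(c(48L, 48L, 48L), c(0.5, 0.5, 0.5),
                                            c(-12, -12, -34)),
                           tissue_mtr = c(pons = 0.45, scp = 0.55, lc = 0.25,
                                          ventricle = 0.02, background = 0.05),
                           mt_off_intensity = c(pons = 1000, scp = 1000, lc = 1000,
                                                ventricle = 600, background = 100),
                           lc_x_mm = 4, lc_y_mm = 2,
                           z_caudal_slice = 86L, z_rostral_slice = 112L,
                           lc_radius_mm = c(central = 1.25, end = 0.6),
                           lc_amplitude = c(central = 1, end = 0.6),
                           jitter_sd_mm = c(central = 0.25, caudal = 0.6),
                           noise_sd = 27.5,
                           n_repeats = 3L,
                           seed = 1L,
                           age_range = c(52L, 84L),
                           male_fraction = 29 / 53,
                           right_intensity_factor = 1,
                           convention = slice_convention()) {
  stopifnot(inherits(grid, "grid_spec"))
  tis <- c("pons", "scp", "lc", "ventricle", "background")
  stopifnot(all(tis %in% names(tissue_mtr)), all(tis %in% names(mt_off_intensity)))
  if (any(tissue_mtr < 0) || any(tissue_mtr >= 1)) {
    stop("tissue MTR fractions must lie in [0, 1)", call. = FALSE)
  }
  if (tissue_mtr[["lc"]] >= tissue_mtr[["pons"]]) {
    stop("LC MTR must be below pons MTR (the nucleus must be MT-on hyperintense)",
         call. = FALSE)
  }
  stopifnot(all(mt_off_intensity > 0), all(lc_radius_mm > 0), all(lc_amplitude > 0),
            noise_sd >= 0, n_repeats >= 1L, n_subjects >= 1L,
            z_rostral_slice > z_caudal_slice,
            age_range[1] <= age_range[2])
  structure(list(
    n_subjects = as.integer(n_subjects), grid = grid,
    tissue_mtr = tissue_mtr, mt_off_intensity = mt_off_intensity,
    lc_x_mm = lc_x_mm, lc_y_mm = lc_y_mm,
    z_caudal_slice = as.integer(z_caudal_slice),
    z_rostral_slice = as.integer(z_rostral_slice),
    lc_radius_mm = lc_radius_mm, lc_amplitude = lc_amplitude,
    jitter_sd_mm = jitter_sd_mm,
    noise_sd = noise_sd, n_repeats = as.integer(n_repeats),
    seed = as.integer(seed), age_range = as.integer(age_range),
    male_fraction = male_fraction,
    right_intensity_factor = right_intensity_factor,
    convention = convention
  ), class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("<phantom_config> %d subjects x %d MT-on repeats, %s, noise SD %.3g, seed %d\n",
              x$n_subjects, x$n_repeats, format(x$grid), x$noise_sd, x$seed))
  invisible(x)
}

# z positions (mm) of the slab slices, caudal..rostral
phantom_slab_z <- function(config) {
  slice_to_z(config$z_caudal_slice:config$z_rostral_slice, config$convention)
}

# tent profile: end value at both slab extremes, central value at the middle
tent_profile <- function(z, z_lo, z_hi, central, ends) {
  zm <- (z_lo + z_hi) / 2
  t <- 1 - abs(z - zm) / (zm - z_lo)
  ends + (central - ends) * pmax(pmin(t, 1), 0)
}

# jitter SD: caudal value at the caudal end, declining linearly to the
# central value at mid-slab, flat from there to the rostral end
jitter_profile <- function(z, z_lo, z_hi, central, caudal) {
  zm <- (z_lo + z_hi) / 2
  ifelse(z >= zm, central,
         central + (caudal - central) * (zm - z) / (zm - z_lo))
}

lc_radius_at <- function(config, z) {
  zz <- phantom_slab_z(config)
  tent_profile(z, min(zz), max(zz), config$lc_radius_mm[["central"]],
               config$lc_radius_mm[["end"]])
}

lc_amplitude_at <- function(config, z) {
  zz <- phantom_slab_z(config)
  tent_profile(z, min(zz), max(zz), config$lc_amplitude[["central"]],
               config$lc_amplitude[["end"]])
}

jitter_sd_at <- function(config, z) {
  zz <- phantom_slab_z(config)
  jitter_profile(z, min(zz), max(zz), config$jitter_sd_mm[["central"]],
                 config$jitter_sd_mm[["caudal"]])
}

# deterministic per-subject seed stream derived from the top-level seed
subject_seed <- function(seed, subject_index) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(subject_index) * 7919) %%
               2147483647)
}

# fixed anatomy: tissue label array plus the pons mask
phantom_tissue <- function(config) {
  g <- config$grid
  xs <- g$origin_mm[1] + g$voxel_size_mm[1] * (seq_len(g$shape[1]) - 1)
  ys <- g$origin_mm[2] + g$voxel_size_mm[2] * (seq_len(g$shape[2]) - 1)
  X <- array(rep(xs, times = g$shape[2] * g$shape[3]), dim = g$shape)
  Y <- array(rep(rep(ys, each = g$shape[1]), times = g$shape[3]), dim = g$shape)
  lab <- array("background", dim = g$shape)
  pons <- X^2 + Y^2 <= 10.5^2
  lab[pons] <- "pons"
  scp <- ((X - 7.5)^2 + (Y + 3)^2 <= 1.5^2) | ((X + 7.5)^2 + (Y + 3)^2 <= 1.5^2)
  lab[scp] <- "scp"
  vent <- abs(X) <= 1.25 & Y >= 3.25 & Y <= 7.75
  lab[vent] <- "ventricle"
  list(label = lab, pons_mask = roi_mask(pons & !vent, g))
}

# cached per-config anatomy (keyed by grid, cheap to recompute but hot)
.phantom_cache <- new.env(parent = emptyenv())
phantom_tissue_cached <- function(config) {
  key <- paste(c(config$grid$shape, config$grid$voxel_size_mm, config$grid$origin_mm),
               collapse = "_")
  if (is.null(.phantom_cache[[key]])) .phantom_cache[[key]] <- phantom_tissue(config)
  .phantom_cache[[key]]
}

#' Generate one phantom subject
#'
#' Deterministic given `(config$seed, subject_index)`. The noiseless MT-off
#' volume is the tissue baseline map; the noiseless MT-on volume is
#' `MT-off x (1 - MTR)`. LC voxels blend the pontine MTR toward the LC MTR by
#' the exact in-plane disc-overlap (partial-volume) fraction, scaled by the
#' slice amplitude profile; the ground-truth mask keeps voxels whose LC
#' partial-volume fraction is at least 0.5. Each MT-on repeat adds
#' independent Gaussian noise of `noise_sd`; the single MT-off scan also
#' carries one noise realisation.
#'
#' @param config A [phantom_config()].
#' @param subject_index Positive integer.
#' @param ablate_caudal_mm Length (mm) of the caudal end of the nucleus to
#'   erase (zero contrast), simulating focal neuronal loss; default 0.
#' @return A list with elements `mt_on_repeats` (list of [image_volume()]),
#'   `mt_off` ([image_volume()]), and `truth` (a `subject_truth` list:
#'   `subject_id`, `age`, `sex`, per-hemisphere and combined truth masks,
#'   `pons_mask`, and a `centers` tibble with the realised per-slice center,
#'   jitter, amplitude and radius).
#' @export
generate_subject <- function(config, subject_index, ablate_caudal_mm = 0) {
  stopifnot(inherits(config, "phantom_config"), subject_index >= 1)
  g <- config$grid
  set.seed(subject_seed(config$seed, subject_index))
  age <- sample(seq(config$age_range[1], config$age_range[2]), 1L)
  sex <- if (stats::runif(1) < config$male_fraction) "male" else "female"

  anat <- phantom_tissue_cached(config)
  mtr <- array(config$tissue_mtr[anat$label], dim = g$shape)
  base <- array(config$mt_off_intensity[anat$label], dim = g$shape)

  slab <- config$z_caudal_slice:config$z_rostral_slice
  zz <- slice_to_z(slab, config$convention)
  ks <- slice_to_k(slab, g, config$convention)
  pv <- list(left = array(0, dim = g$shape), right = array(0, dim = g$shape))
  rows <- list()
  xr <- g$origin_mm[1] + c(0, g$voxel_size_mm[1] * (g$shape[1] - 1))
  yr <- g$origin_mm[2] + c(0, g$voxel_size_mm[2] * (g$shape[2] - 1))
  pons_mtr <- config$tissue_mtr[["pons"]]
  lc_mtr <- config$tissue_mtr[["lc"]]
  base_pons <- config$mt_off_intensity[["pons"]]
  base_lc <- config$mt_off_intensity[["lc"]]
  for (si in seq_along(slab)) {
    z <- zz[si]
    r <- lc_radius_at(config, z)
    a <- lc_amplitude_at(config, z)
    jsd <- jitter_sd_at(config, z)
    ablated <- (z - zz[1]) < ablate_caudal_mm
    for (side in c("left", "right")) {
      cx0 <- if (side == "left") -config$lc_x_mm else config$lc_x_mm
      jit <- stats::rnorm(2, 0, jsd)
      cx <- cx0 + jit[1]; cy <- config$lc_y_mm + jit[2]
      if (cx - r < xr[1] || cx + r > xr[2] || cy - r < yr[1] || cy + r > yr[2]) {
        stop(sprintf("subject %d: jittered LC tube exits the grid at slice %d",
                     subject_index, slab[si]), call. = FALSE)
      }
      if (!ablated) {
        fr <- disc_voxel_fractions(c(cx, cy), r, g, ks[si])
        if (nrow(fr)) {
          lin <- 1L + fr$i + g$shape[1] * (fr$j + g$shape[2] * fr$k)
          mtr[lin] <- mtr[lin] - fr$frac * a * (pons_mtr - lc_mtr)
          base[lin] <- base[lin] + fr$frac * (base_lc - base_pons)
          pick <- fr$frac >= 0.5
          pv[[side]][lin[pick]] <- pmax(pv[[side]][lin[pick]], fr$frac[pick])
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        slice = slab[si], z = z, hemisphere = side,
        x = cx, y = cy, jitter_x = jit[1], jitter_y = jit[2],
        amplitude = if (ablated) 0 else a, radius_mm = r,
        ablated = ablated)
    }
  }
  centers <- tibble::as_tibble(do.call(rbind, rows))

  mt_on_clean <- base * (1 - mtr)
  mt_off_clean <- base
  if (config$right_intensity_factor != 1) {
    xs <- g$origin_mm[1] + g$voxel_size_mm[1] * (seq_len(g$shape[1]) - 1)
    fac <- ifelse(xs > 0, config$right_intensity_factor, 1)
    mt_on_clean <- sweep(mt_on_clean, 1, fac, "*")
    mt_off_clean <- sweep(mt_off_clean, 1, fac, "*")
  }
  nz <- prod(g$shape)
  mt_on_repeats <- lapply(seq_len(config$n_repeats), function(r) {
    image_volume(mt_on_clean + if (config$noise_sd > 0)
      array(stats::rnorm(nz, 0, config$noise_sd), dim = g$shape) else 0,
      g, modality = "mt_on")
  })
  mt_off <- image_volume(mt_off_clean + if (config$noise_sd > 0)
    array(stats::rnorm(nz, 0, config$noise_sd), dim = g$shape) else 0,
    g, modality = "mt_off")

  truth <- structure(list(
    subject_id = sprintf("sub%03d", subject_index),
    age = age, sex = sex,
    mask_left = roi_mask(pv$left >= 0.5, g),
    mask_right = roi_mask(pv$right >= 0.5, g),
    mask = roi_mask(pv$left >= 0.5 | pv$right >= 0.5, g),
    pons_mask = anat$pons_mask,
    centers = centers
  ), class = "subject_truth")
  list(mt_on_repeats = mt_on_repeats, mt_off = mt_off, truth = truth)
}

#' @export
print.subject_truth <- function(x, ...) {
  cat(sprintf("<subject_truth> %s, age %d, %s; truth %d voxels (L %d / R %d)\n",
              x$subject_id, x$age, x$sex, mask_count(x$mask),
              mask_count(x$mask_left), mask_count(x$mask_right)))
  invisible(x)
}

#' Generate a phantom cohort
#'
#' Generates `n_subjects` phantom subjects (each with `n_repeats` MT-on
#' scans and one MT-off scan, so the default 53-subject, 3-repeat cohort
#' comprises 159 MT-on volumes) and the cohort table. With `dir` set, all
#' volumes are written as NIfTI and the cohort table as TSV.
#'
#' @param config A [phantom_config()].
#' @param dir Optional output directory; created if missing. When `NULL`
#'   (default) the cohort stays in memory.
#' @param ablate_caudal_mm Per-subject ablation lengths (recycled), passed to
#'   [generate_subject()].
#' @return A list with `subjects` (list of [generate_subject()] results),
#'   `cohort` (tibble: subject_id, age, sex, seed), and `files` (tibble of
#'   written paths, empty when `dir` is `NULL`).
#' @export
generate_cohort <- function(config, dir = NULL, ablate_caudal_mm = 0) {
  stopifnot(inherits(config, "phantom_config"))
  abl <- rep_len(ablate_caudal_mm, config$n_subjects)
  subjects <- lapply(seq_len(config$n_subjects), function(i) {
    generate_subject(config, i, ablate_caudal_mm = abl[i])
  })
  cohort <- purrr::map_dfr(subjects, function(s) {
    tibble::tibble(subject_id = s$truth$subject_id, age = s$truth$age,
                   sex = s$truth$sex)
  })
  cohort$seed <- subject_seed(config$seed, seq_len(config$n_subjects))
  files <- tibble::tibble(subject_id = character(), kind = character(),
                          path = character())
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    if (!dir.exists(dir)) stop(sprintf("cannot create output directory '%s'", dir),
                               call. = FALSE)
    rows <- list()
    for (s in subjects) {
      id <- s$truth$subject_id
      for (r in seq_along(s$mt_on_repeats)) {
        p <- file.path(dir, sprintf("%s_mton_rep%d.nii.gz", id, r))
        write_volume(s$mt_on_repeats[[r]], p)
        rows[[length(rows) + 1L]] <- tibble::tibble(subject_id = id,
                                                    kind = sprintf("mt_on_rep%d", r), path = p)
      }
      p <- file.path(dir, sprintf("%s_mtoff.nii.gz", id))
      write_volume(s$mt_off, p)
      rows[[length(rows) + 1L]] <- tibble::tibble(subject_id = id, kind = "mt_off",
                                                  path = p)
      p <- file.path(dir, sprintf("%s_truth.nii.gz", id))
      write_mask(s$truth$mask, p)
      rows[[length(rows) + 1L]] <- tibble::tibble(subject_id = id, kind = "truth_mask",
                                                  path = p)
    }
    files <- dplyr::bind_rows(rows)
    utils::write.table(cohort, file.path(dir, "cohort.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(subjects = subjects, cohort = cohort, files = files)
}

#' Average repeated acquisitions
#'
#' Voxelwise arithmetic mean of aligned, grid-compatible repeats — the
#' off-line repeat averaging used to improve SNR before segmentation (for
#' independent Gaussian noise, averaging m repeats raises region SNR by about
#' `sqrt(m)`).
#'
#' @param repeats Non-empty list of grid-compatible [image_volume()]s.
#' @return An [image_volume()] with the modality of the first repeat.
#' @export
average_repeats <- function(repeats) {
  stopifnot(is.list(repeats), length(repeats) >= 1L)
  stopifnot(all(vapply(repeats, inherits, logical(1), "image_volume")))
  g <- repeats[[1]]$grid
  for (r in repeats[-1]) stop_if_incompatible(g, r$grid, "repeats")
  vals <- Reduce(`+`, lapply(repeats, `[[`, "values")) / length(repeats)
  image_volume(vals, g, modality = repeats[[1]]$modality)
}

#' Default searching-area specification for a phantom configuration
#'
#' Builds the per-slice disc center path at the phantom's mean (unjittered)
#' centerline for both hemispheres — the idealisation of drawing the
#' searching areas on a group template. Pass `offset_mm` to study mis-centred
#' paths.
#'
#' @param config A [phantom_config()].
#' @param diameter_mm Disc diameter (default 2.5 mm).
#' @param offset_mm Length-2 (x, y) shift applied to both paths, mm.
#' @return A [search_spec()].
#' @export
phantom_search_spec <- function(config, diameter_mm = 2.5, offset_mm = c(0, 0)) {
  stopifnot(inherits(config, "phantom_config"))
  slab <- config$z_caudal_slice:config$z_rostral_slice
  centers <- dplyr::bind_rows(
    tibble::tibble(slice = slab, hemisphere = "left",
                   x = -config$lc_x_mm + offset_mm[1], y = config$lc_y_mm + offset_mm[2]),
    tibble::tibble(slice = slab, hemisphere = "right",
                   x = config$lc_x_mm + offset_mm[1], y = config$lc_y_mm + offset_mm[2])
  )
  search_spec(centers, diameter_mm = diameter_mm,
              rostral_slice = config$z_rostral_slice,
              caudal_slice = config$z_caudal_slice,
              convention = config$convention)
}

#' Default reference-region candidates for a phantom configuration
#'
#' Six candidates mirroring the standard pontine layout: central, dorsal,
#' left and right pontine tegmentum (PT) as 4 x 4 x 4.5 mm cubes at
#' mid-pons, and left/right SCP as LC-shaped clones of the searching-area
#' geometry centred at the SCP roots.
#'
#' @param config A [phantom_config()].
#' @return Named list of [reference_spec()]s.
#' @export
phantom_reference_specs <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  zc <- mean(range(phantom_slab_z(config)))
  src <- phantom_search_spec(config)
  list(
    central_pt = reference_spec("central_pt", "cube", c(0, -4, zc)),
    dorsal_pt = reference_spec("dorsal_pt", "cube", c(0, 1, zc)),
    left_pt = reference_spec("left_pt", "cube", c(-4, -5.5, zc)),
    right_pt = reference_spec("right_pt", "cube", c(4, -5.5, zc)),
    left_scp = reference_spec("left_scp", "lc_shaped", c(-7.5, -3),
                              source_spec = src, hemisphere = "left"),
    right_scp = reference_spec("right_scp", "lc_shaped", c(7.5, -3),
                               source_spec = src, hemisphere = "right")
  )
}
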