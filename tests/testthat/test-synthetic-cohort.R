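test_that("noiseless phantom obeys the MT signal model exactly", {
  cfg <- phantom_config(noise_sd = 0, n_repeats = 1L)
  s <- generate_subject(cfg, 1)
  # pure pons voxel away from all structures: baseline 1000, MTR 0.45
  pons_idx <- c(7, 25, 25) # x = -9, y = 0, mid-grid
  expect_equal(s$mt_off$values[pons_idx[1], pons_idx[2], pons_idx[3]], 1000)
  expect_equal(s$mt_on_repeats[[1]]$values[pons_idx[1], pons_idx[2], pons_idx[3]], 550)
  # a full-volume LC voxel reaches the LC MTR at central amplitude 1
  core <- mask_voxel_table(s$truth$mask)
  mtr <- mtr_map(s$mt_off, s$mt_on_repeats[[1]])
  central <- core[abs(core$z + 22.5) < 0.3, ]
  vals <- mtr$values[cbind(central$i + 1, central$j + 1, central$k + 1)]
  expect_true(any(abs(vals - 25) < 1e-9))   # pure-LC voxels hit 25.0% exactly
  on_vals <- s$mt_on_repeats[[1]]$values[cbind(central$i + 1, central$j + 1, central$k + 1)]
  expect_true(any(abs(on_vals - 750) < 1e-9))
  # MTR never undershoots the configured LC MTR nor exceeds the pons MTR inside the tube
  expect_true(all(vals <= 45 + 1e-9 & vals >= 25 - 1e-9))
})

test_that("generation is deterministic in (seed, subject) and subjects are reproducible", {
  cfg <- phantom_config(n_subjects = 2L)
  a <- generate_subject(cfg, 2)
  b <- generate_subject(cfg, 2)
  expect_identical(a$mt_on_repeats[[1]]$values, b$mt_on_repeats[[1]]$values)
  expect_identical(a$mt_off$values, b$mt_off$values)
  expect_identical(a$truth$centers, b$truth$centers)
  expect_identical(a$truth$mask$mask, b$truth$mask$mask)
  # different subjects differ
  c2 <- generate_subject(cfg, 1)
  expect_false(identical(a$mt_on_repeats[[1]]$values, c2$mt_on_repeats[[1]]$values))
})

test_that("truth masks sit inside the pons and the configured slab", {
  cfg <- phantom_config()
  s <- generate_subject(cfg, 3)
  expect_identical(mask_count(mask_difference(s$truth$mask, s$truth$pons_mask)), 0L)
  tbl <- mask_voxel_table(s$truth$mask)
  expect_true(all(tbl$slice >= cfg$z_caudal_slice & tbl$slice <= cfg$z_rostral_slice))
  # hemispheres split cleanly at the midline
  expect_identical(mask_count(mask_intersect(s$truth$mask_left, s$truth$mask_right)), 0L)
})

test_that("cohort generation writes the expected files and respects the age range", {
  cfg <- phantom_config(n_subjects = 3L, n_repeats = 3L, seed = 5L)
  dir <- withr::local_tempdir()
  co <- generate_cohort(cfg, dir = dir)
  expect_equal(sum(co$files$kind %in% sprintf("mt_on_rep%d", 1:3)),
               cfg$n_subjects * cfg$n_repeats)
  expect_equal(sum(co$files$kind == "mt_off"), cfg$n_subjects)
  expect_true(all(file.exists(co$files$path)))
  expect_true(file.exists(file.path(dir, "cohort.tsv")))
  expect_true(all(co$cohort$age >= 52 & co$cohort$age <= 84))
  expect_identical(nrow(co$cohort), 3L)
  # minimal cohort
  co1 <- generate_cohort(phantom_config(n_subjects = 1L, n_repeats = 1L))
  expect_length(co1$subjects[[1]]$mt_on_repeats, 1L)
})

test_that("repeat averaging is the voxelwise mean with geometry checking", {
  g <- tiny_grid()
  a <- constant_volume(100, g)
  b <- constant_volume(200, g)
  expect_equal(average_repeats(list(a, b))$values, array(150, g$shape))
  expect_equal(average_repeats(list(a, a, a))$values, a$values)
  g2 <- grid_spec(g$shape, g$voxel_size_mm, g$origin_mm + 1)
  expect_error(average_repeats(list(a, constant_volume(1, g2))), "different grids")
})

test_that("per-slice jitter realisations match the configured SD gradient", {
  cfg <- phantom_config(noise_sd = 0, n_repeats = 1L, seed = 31L)
  n <- 250
  centers <- purrr::map_dfr(seq_len(n), function(i) generate_subject(cfg, i)$truth$centers)
  realised <- centers |>
    dplyr::group_by(.data$slice) |>
    dplyr::summarise(sd = stats::sd(c(.data$jitter_x, .data$jitter_y)), .groups = "drop")
  cfg_sd <- vapply(slice_to_z(realised$slice),
                   function(z) coeruleus:::jitter_sd_at(cfg, z), numeric(1))
  expect_true(all(abs(realised$sd / cfg_sd - 1) < 0.12))
  # caudal jitter configured (and realised) above central jitter
  expect_gt(realised$sd[realised$slice == 86], realised$sd[realised$slice == 112])
})

test_that("truth masks are left/right symmetric in expectation", {
  cfg <- phantom_config(noise_sd = 0, n_repeats = 1L, seed = 13L)
  counts <- purrr::map_dfr(1:40, function(i) {
    t <- generate_subject(cfg, i)$truth
    tibble::tibble(left = mask_count(t$mask_left), right = mask_count(t$mask_right))
  })
  # mean signed left-right difference is small relative to the mask size
  expect_lt(abs(mean(counts$left - counts$right)), 0.05 * mean(counts$left))
})
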