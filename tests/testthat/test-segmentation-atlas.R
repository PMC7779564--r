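make_search_pair <- function(g) {
  # two 3-voxel bars on slice 100 (k = 2 on the tiny grid, z = -21)
  left <- mask_from_indices(cbind(2:4, 8, 3), g)
  right <- mask_from_indices(cbind(12:14, 8, 3), g)
  list(left = left, right = right)
}

test_that("segmentation keeps strictly suprathreshold searching-area voxels", {
  g <- tiny_grid()
  searching <- make_search_pair(g)
  v <- constant_volume(100, g, "mt_on")
  v$values[2:4, 8, 3] <- c(121, 130, 125)
  v$values[12:14, 8, 3] <- c(119, 120, 100)   # at or below T = 120: excluded
  ref <- constant_volume(0, g)
  ref$values[1:3, 1, 1] <- c(96, 100, 104)
  st <- region_stats(ref, mask_from_indices(cbind(1:3, 1, 1), g))
  thr <- segmentation_threshold(st)            # 120
  cnr <- cnr_map(v, st)
  seg <- segment_lc(v, searching, thr, cnr, subject_id = "s1")

  expect_identical(mask_count(seg$mask_left), 3L)
  expect_identical(mask_count(seg$mask_right), 0L)  # ties at T excluded
  # peak record: the 130 voxel, CNR (130-100)/4 = 7.5
  pk <- seg$peaks[seg$peaks$hemisphere == "left" & !is.na(seg$peaks$cnr), ]
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$cnr, 7.5)
  expect_identical(pk$i, 2L)                   # 0-based index of the 130 voxel
  rk <- seg$peaks[seg$peaks$hemisphere == "right", ]
  expect_true(all(is.na(rk$cnr)))              # missing, never imputed
  # counts conservation
  expect_identical(sum(seg$counts$count),
                   mask_count(seg$mask_left) + mask_count(seg$mask_right))
  prof <- slice_profiles(seg)
  expect_identical(sum(prof$count), 3L)
  expect_true(all(c("peak_x", "peak_cnr") %in% names(prof)))

  # wholly sub-threshold cohort: empty masks, all peaks missing
  v0 <- constant_volume(100, g, "mt_on")
  seg0 <- segment_lc(v0, searching, thr, cnr_map(v0, st))
  expect_identical(mask_count(seg0$mask), 0L)
  expect_true(all(is.na(seg0$peaks$cnr)))
  expect_true(all(seg0$counts$count == 0L))
})

test_that("segmentation recovers the phantom nucleus (Dice and volume)", {
  rep20 <- recovery_report_20()
  expect_gte(mean(rep20$subjects$dice), 0.7)
  expect_lte(abs(sum(rep20$subjects$segmented_mm3) / sum(rep20$subjects$truth_mm3) - 1),
             0.25)
  # every segmented voxel lies inside the searching area and above threshold
  expect_true(all(rep20$subjects$segmented_mm3 <= 2 * 70.875 + 1e-9))
})

test_that("slice-wise count profile peaks in the central third of the slab", {
  rep20 <- recovery_report_20()
  grp <- rep20$slice_counts |>
    dplyr::group_by(.data$slice) |>
    dplyr::summarise(mean_count = mean(.data$count), .groups = "drop")
  slab <- range(grp$slice)
  third <- diff(slab) / 3
  central <- grp$mean_count[grp$slice > slab[1] + third & grp$slice < slab[2] - third]
  caudal_end <- grp$mean_count[grp$slice <= slab[1] + 2]
  rostral_end <- grp$mean_count[grp$slice >= slab[2] - 2]
  expect_gt(max(central), max(caudal_end))
  expect_gt(max(central), max(rostral_end))
})

test_that("peak locations track the jittered centerline on central slices", {
  rep20 <- recovery_report_20()
  cfg <- phantom_config(n_subjects = 20L, seed = 7L)
  truth_centers <- purrr::map_dfr(seq_len(20), function(i) {
    generate_subject(cfg, i)$truth$centers |>
      dplyr::mutate(subject_id = sprintf("sub%03d", i))
  })
  j <- dplyr::inner_join(
    rep20$peaks, truth_centers,
    by = c("subject_id", "slice", "hemisphere"), suffix = c("_peak", "_true"))
  slab <- range(j$slice)
  third <- diff(slab) / 3
  central <- j[j$slice > slab[1] + third & j$slice < slab[2] - third & !is.na(j$x_peak), ]
  # hit = peak voxel lies in the 3x3 in-plane neighbourhood of the voxel
  # containing the true jittered center (a flat-top tube makes all core
  # voxels equal in expectation, so sub-voxel agreement is not defined)
  vx <- 0.5
  hit <- abs(round(central$x_peak / vx) - round(central$x_true / vx)) <= 1 &
    abs(round(central$y_peak / vx) - round(central$y_true / vx)) <= 1
  expect_gte(mean(hit), 0.8)
})

test_that("probabilistic atlas is the voxelwise mask average with exact bookkeeping", {
  g <- tiny_grid()
  # one subject: atlas equals the mask at probability 1
  m1 <- mask_from_indices(cbind(2:4, 2, 1), g)
  a1 <- build_prob_atlas(list(m1))
  expect_equal(a1$prob$values[2:4, 2, 1], rep(1, 3))
  expect_identical(sum(a1$prob$values > 0), 3L)

  # 53 masks, modal voxel shared by 46 -> max probability 86.79%
  masks <- lapply(1:53, function(i) {
    idx <- rbind(if (i <= 46) c(8, 8, 2), c(1 + (i %% 10), 12, 3))
    mask_from_indices(idx, g)
  })
  at <- build_prob_atlas(masks)
  expect_identical(at$n_subjects, 53L)
  expect_equal(round(100 * max(at$prob$values), 2), 86.79)
  # conservation: total probability mass times n equals the summed mask sizes
  expect_equal(sum(at$prob$values) * 53, sum(vapply(masks, mask_count, integer(1))))
  # every nonzero probability is a multiple of 1/53
  nz <- at$prob$values[at$prob$values > 0]
  expect_true(all(abs(nz * 53 - round(nz * 53)) < 1e-9))
  expect_error(build_prob_atlas(list()), "length")
})

test_that("atlas thresholding is inclusive, monotone and percent-aware", {
  rep20 <- recovery_report_20()
  at <- rep20$atlas
  union_mask <- threshold_atlas(at, 0)
  expect_identical(mask_count(union_mask), sum(at$prob$values > 0))
  # fraction and percent spellings agree
  expect_identical(threshold_atlas(at, 0.05)$mask, threshold_atlas(at, 5)$mask)
  # monotone nesting across a sweep
  prev <- union_mask
  for (p in c(5, 10, 25, 50, 75)) {
    cur <- threshold_atlas(at, p)
    expect_identical(mask_count(mask_difference(cur, prev)), 0L)
    prev <- cur
  }
  expect_identical(mask_count(threshold_atlas(at, 100 * max(at$prob$values) + 1)), 0L)
  # inclusive >= : with n = 20 a 5% threshold keeps voxels seen in >= 1 subject
  expect_identical(threshold_atlas(at, 5)$mask, threshold_atlas(at, 0)$mask)
})

test_that("atlas-based CNR is volumetrically unbiased and core-weighted", {
  g <- tiny_grid()
  cn <- constant_volume(5, g, "cnr")
  m <- mask_from_indices(cbind(1:4, 1, 1), g)
  expect_equal(atlas_cnr(cn, m), 5)
  expect_error(atlas_cnr(cn, roi_mask(array(FALSE, g$shape), g)), "empty")

  # stringent (25%) template concentrates on the brighter core
  rep20 <- recovery_report_20()
  expect_gt(mean(rep20$subjects$cnr_prob25), mean(rep20$subjects$cnr_prob5))
})

test_that("caudal ablation depresses atlas CNR more than segmentation-restricted CNR", {
  cfg <- phantom_config(seed = 23L)
  intact <- generate_subject(cfg, 1)
  ablated <- generate_subject(cfg, 1, ablate_caudal_mm = 6.75)  # caudal half gone
  g <- cfg$grid
  ref_roi <- build_reference_roi(phantom_reference_specs(cfg)$central_pt, g)
  searching <- build_searching_area(phantom_search_spec(cfg), g)
  atlas_mask <- intact$truth$mask   # fixed spatial prior, identical for both
  res <- lapply(list(intact = intact, ablated = ablated), function(s) {
    avg <- average_repeats(s$mt_on_repeats)
    st <- region_stats(avg, ref_roi)
    cn <- cnr_map(avg, st)
    seg <- segment_lc(avg, searching, segmentation_threshold(st), cn)
    list(atlas_cnr = atlas_cnr(cn, atlas_mask),
         seg_cnr = mean(cn$values[seg$mask$mask]))
  })
  atlas_drop <- res$intact$atlas_cnr - res$ablated$atlas_cnr
  seg_drop <- abs(res$intact$seg_cnr - res$ablated$seg_cnr)
  expect_gt(atlas_drop, 0)
  expect_gt(atlas_drop, 2 * seg_drop)
})
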