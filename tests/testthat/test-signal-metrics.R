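test_that("region statistics use the sample SD and reject degenerate regions", {
  g <- tiny_grid()
  v <- constant_volume(0, g)
  v$values[1:3] <- c(90, 100, 110)
  roi <- mask_from_indices(cbind(1:3, 1, 1), g)
  st <- region_stats(v, roi)
  expect_equal(st$mean_ref, 100)
  expect_equal(st$sd_ref, 10)
  expect_equal(st$snr, 10)
  expect_identical(st$n_voxels, 3L)
  flat <- constant_volume(550, g)
  expect_error(region_stats(flat, roi), "degenerate region")
  # SNR is invariant under global intensity scaling
  v2 <- image_volume(v$values * 3.7, g)
  expect_equal(region_stats(v2, roi)$snr, st$snr)
})

test_that("region SNR matches the closed-form noise model on a large region", {
  g <- grid_spec(c(30, 30, 30), c(0.5, 0.5, 0.5), c(0, 0, 0))
  set.seed(21)
  sigma <- 27.5
  v <- image_volume(array(550 + rnorm(27000, 0, sigma), dim = g$shape), g)
  roi <- roi_mask(array(TRUE, g$shape), g)
  st <- region_stats(v, roi)
  expect_equal(st$snr, 550 / sigma, tolerance = 0.05)
})

test_that("MTR map applies the percentage formula and flags zero denominators", {
  g <- tiny_grid()
  off <- constant_volume(200, g, "mt_off")
  on <- constant_volume(150, g, "mt_on")
  expect_equal(mtr_map(off, on)$values[1, 1, 1], 25)
  expect_equal(mtr_map(off, off)$values[5, 5, 2], 0)
  # zero MT-off voxels become missing, not infinite
  off2 <- off; off2$values[1, 1, 1] <- 0
  m <- mtr_map(off2, on)
  expect_true(is.na(m$values[1, 1, 1]))
  expect_false(any(is.infinite(m$values)))
  zero <- constant_volume(0, g, "mt_off")
  expect_error(mtr_map(zero, on), "empty")
  # generator round trip: noiseless pair recovers configured tissue MTRs
  cfg <- phantom_config(noise_sd = 0, n_repeats = 1L)
  s <- generate_subject(cfg, 1)
  mm <- mtr_map(s$mt_off, s$mt_on_repeats[[1]])
  expect_equal(mm$values[7, 25, 25], 45, tolerance = 1e-12)  # pons
  vent <- mm$values[25, 40, 25]                               # midline stripe
  expect_equal(vent, 2, tolerance = 1e-12)
})

test_that("segmentation threshold is Mean_REF + k SD_REF with selectable stringency", {
  g <- tiny_grid()
  v <- constant_volume(0, g)
  v$values[1:3] <- c(96, 100, 104)
  st <- region_stats(v, mask_from_indices(cbind(1:3, 1, 1), g))
  expect_equal(st$mean_ref, 100)
  expect_equal(st$sd_ref, 4)
  expect_equal(segmentation_threshold(st), 120)         # default 5 SD
  expect_equal(segmentation_threshold(st, k_sd = 4), 116)
  expect_equal(segmentation_threshold(st, k_sd = 0), 100)
})

test_that("CNR is standardised contrast: threshold voxels score exactly k", {
  g <- tiny_grid()
  v <- constant_volume(0, g)
  v$values[1:3] <- c(96, 100, 104)
  st <- region_stats(v, mask_from_indices(cbind(1:3, 1, 1), g))
  probe <- constant_volume(120, g)
  expect_equal(cnr_map(probe, st)$values[2, 2, 2], 5)
  probe$values[] <- st$mean_ref
  expect_equal(cnr_map(probe, st)$values[1, 1, 1], 0)
  # algebraic identity for random stats: cnr(threshold(k)) == k
  set.seed(8)
  for (r in 1:20) {
    v2 <- constant_volume(0, g)
    v2$values[1:50] <- rnorm(50, runif(1, 10, 1000), runif(1, 1, 50))
    st2 <- region_stats(v2, mask_from_indices(cbind(rep(1:10, 5), rep(1:5, each = 10), 1), g))
    k <- runif(1, 0, 8)
    probe2 <- constant_volume(segmentation_threshold(st2, k), g)
    expect_equal(cnr_map(probe2, st2)$values[1, 1, 1], k, tolerance = 1e-9)
  }
  # CNR invariant under joint affine intensity transforms
  a <- 2.3; b <- 17
  vt <- image_volume(a * v$values + b, g)
  stt <- region_stats(vt, mask_from_indices(cbind(1:3, 1, 1), g))
  pt <- constant_volume(a * 120 + b, g)
  expect_equal(cnr_map(pt, stt)$values[1, 1, 1], 5, tolerance = 1e-9)
})

test_that("noiseless phantom CNR approaches the generator's closed form", {
  # small noise so reference SD stays estimable; CNR -> contrast / sd
  cfg <- phantom_config(noise_sd = 0.5, n_repeats = 1L, seed = 3L)
  s <- generate_subject(cfg, 1)
  pons_ref <- build_reference_roi(phantom_reference_specs(cfg)$central_pt, cfg$grid)
  st <- region_stats(s$mt_on_repeats[[1]], pons_ref)
  cn <- cnr_map(s$mt_on_repeats[[1]], st)
  core <- mask_voxel_table(s$truth$mask)
  central <- core[abs(core$z + 22.5) < 0.3, ]
  top <- max(cn$values[cbind(central$i + 1, central$j + 1, central$k + 1)])
  # closed form: (b(1-MTR_lc) - b(1-MTR_pons)) / sd = 200 / sd
  expect_equal(top, (750 - 550) / st$sd_ref, tolerance = 0.05)
})

test_that("reference evaluation ranks by SNR then MTR and gates asymmetric pairs", {
  # synthesised cohort table: higher-MTR candidate outranks at equal SNR
  tbl <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:8),
                            roi = c("cand_a", "cand_b"))
  set.seed(1)
  tbl$mean_signal <- 500 + rnorm(nrow(tbl))
  tbl$snr <- 20
  tbl$mtr <- ifelse(tbl$roi == "cand_a", 45, 55)
  tbl$n_voxels <- 100L
  ev <- evaluate_references(tbl, lc_rois = character())
  expect_identical(ev$selected, "cand_b")
  expect_error(evaluate_references(tbl[tbl$subject_id == "s01", ], lc_rois = character()),
               "at least 2 subjects")
})

test_that("a symmetric phantom cohort shows no lateralised signal, a biased one does", {
  rep20 <- recovery_report_20()
  asym <- rep20$reference$asymmetry
  expect_false(asym$asymmetric[asym$pair == "lc"])
  expect_false(asym$asymmetric[asym$pair == "pt"])
  expect_false(asym$asymmetric[asym$pair == "scp"])
  expect_true(rep20$reference$selected %in%
                c("central_pt", "dorsal_pt", "left_pt", "right_pt"))

  # +5% right-hemisphere intensity: right > left detected in PT and SCP
  cfgb <- phantom_config(n_subjects = 8L, seed = 17L, right_intensity_factor = 1.05)
  cob <- generate_cohort(cfgb)
  g <- cfgb$grid
  sa <- build_searching_area(phantom_search_spec(cfgb), g)
  masks <- c(lapply(phantom_reference_specs(cfgb), build_reference_roi, grid = g),
             list(left_lc = sa$left, right_lc = sa$right))
  evb <- evaluate_references(collect_roi_stats(cob$subjects, masks))
  ab <- evb$asymmetry
  expect_true(ab$asymmetric[ab$pair == "pt"])
  expect_gt(ab$mean_right_minus_left[ab$pair == "pt"], 0)
  expect_lt(ab$p_value[ab$pair == "pt"], 0.05)
})
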