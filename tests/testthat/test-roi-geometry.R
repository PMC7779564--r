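test_that("disc rasterisation matches a brute-force voxel-center scan", {
  g <- grid_spec(c(40, 40, 6), c(0.5, 0.5, 0.5), c(-10, -10, -22))
  # worked example: 2.5 mm disc centered on a voxel center covers 21 voxels
  d <- rasterize_disc(c(-4, 2), 2.5, g, 100)
  expect_identical(mask_count(d), 21L)
  expect_identical(mask_count(d), brute_disc_count(c(-4, 2), 2.5, g, 0))
  # sub-voxel disc keeps only the center voxel
  expect_identical(mask_count(rasterize_disc(c(-4, 2), 0.5, g, 100)), 1L)
  # off-center placement changes the count; the oracle stays authoritative
  d_off <- rasterize_disc(c(-4.25, 2.25), 2.5, g, 100)
  expect_identical(mask_count(d_off), brute_disc_count(c(-4.25, 2.25), 2.5, g, 0))
  # randomised property sweep
  set.seed(99)
  for (r in 1:20) {
    ctr <- runif(2, -6, 6)
    dia <- runif(1, 0.4, 4)
    got <- tryCatch(mask_count(rasterize_disc(ctr, dia, g, 101)),
                    error = function(e) 0L)
    expect_identical(got, brute_disc_count(ctr, dia, g, 0))
  }
  expect_error(rasterize_disc(c(100, 100), 1, g, 100), "empty mask")
  expect_error(rasterize_disc(c(0, 0), -1, g, 100), "diameter")
})

test_that("searching area reproduces the matched-volume bookkeeping", {
  cfg <- phantom_config()
  spec <- phantom_search_spec(cfg)
  sa <- build_searching_area(spec, cfg$grid)
  for (h in c("left", "right")) {
    expect_identical(mask_count(sa[[h]]), 567L)
    expect_equal(mask_volume_mm3(sa[[h]]), 70.875)
    expect_equal(round(mask_volume_mm3(sa[[h]]), 2), 70.88)
  }
  expect_identical(spec$rostral_slice - spec$caudal_slice + 1L, 27L)
  expect_equal(slab_extent_mm(spec), 13.5)
  # volume equals the sum of per-slice disc counts by construction
  tbl <- mask_voxel_table(sa$left)
  expect_identical(nrow(tbl), 567L)
  expect_identical(length(unique(tbl$slice)), 27L)
})

test_that("a minimal slab is exactly the union of its per-slice discs", {
  g <- grid_spec(c(40, 40, 6), c(0.5, 0.5, 0.5), c(-10, -10, -22.5))
  ctr <- tibble::tibble(slice = 99:100, hemisphere = "left", x = -4, y = 2)
  spec <- search_spec(ctr, rostral_slice = 100, caudal_slice = 99)
  sa <- build_searching_area(spec, g)
  one <- rasterize_disc(c(-4, 2), 2.5, g, 99)
  two <- rasterize_disc(c(-4, 2), 2.5, g, 100)
  expect_identical(sa$left$mask, mask_union(one, two)$mask)
})

test_that("reference ROIs hit their stated volumes and the clone invariant", {
  cfg <- phantom_config()
  g <- cfg$grid
  refs <- phantom_reference_specs(cfg)
  cube <- build_reference_roi(refs$central_pt, g)
  expect_identical(mask_count(cube), 576L)
  expect_equal(mask_volume_mm3(cube), 72)
  # 1 mm cube
  small <- reference_spec("tiny", "cube", c(0, 0, -22.5), dims_mm = c(1, 1, 1))
  expect_identical(mask_count(build_reference_roi(small, g)), 8L)
  # lc_shaped clone matches the searching-area volume exactly
  sa <- build_searching_area(phantom_search_spec(cfg), g)
  for (nm in c("left_scp", "right_scp")) {
    cl <- build_reference_roi(refs[[nm]], g)
    expect_identical(mask_count(cl), mask_count(sa$left))
  }
  # cube and disc-stack volumes agree within one voxel volume per slice
  expect_lte(abs(mask_volume_mm3(cube) - mask_volume_mm3(sa$left)),
             27 * voxel_volume_mm3(g))
  # a cube falling off the grid is a geometry error
  expect_error(build_reference_roi(reference_spec("edge", "cube", c(11.9, 0, -22.5)), g),
               "exceeds the grid")
})

test_that("Dice similarity has its defining values and properties", {
  g <- tiny_grid()
  a <- mask_from_indices(cbind(1:4, 1, 1), g)
  b <- mask_from_indices(cbind(3:6, 1, 1), g)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 0.5)                    # |a|=|b|=4, overlap 2
  disj <- mask_from_indices(cbind(10:13, 2, 2), g)
  expect_equal(dice(a, disj), 0)
  expect_equal(dice(a, b), dice(b, a))
  # removing intersection voxels can only lower the DSC
  b_shrunk <- mask_from_indices(cbind(4:6, 1, 1), g)
  expect_lte(dice(a, b_shrunk), dice(a, b))
  empty <- roi_mask(array(FALSE, g$shape), g)
  expect_error(dice(empty, empty), "undefined")
})

test_that("disc/voxel partial-volume fractions integrate to the disc area", {
  g <- grid_spec(c(40, 40, 4), c(0.5, 0.5, 0.5), c(-10, -10, 0))
  set.seed(4)
  for (r in 1:10) {
    ctr <- runif(2, -3, 3); rad <- runif(1, 0.3, 2)
    fr <- coeruleus:::disc_voxel_fractions(ctr, rad, g, 1L)
    expect_equal(sum(fr$frac) * 0.25, pi * rad^2, tolerance = 1e-8)
    expect_true(all(fr$frac > 0 & fr$frac <= 1))
  }
})
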