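# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

# 20-subject default-parameter cohort pushed through the full pipeline;
# used by the recovery, atlas and cohort-statistics tests
recovery_report_20 <- function() {
  if (is.null(.fixtures$rep20)) {
    .fixtures$rep20 <- run_recovery_experiment(phantom_config(n_subjects = 20L, seed = 7L))
  }
  .fixtures$rep20
}

# small quiet grid for hand-constructed segmentation examples: slices 100..103
tiny_grid <- function() grid_spec(c(16L, 16L, 4L), c(0.5, 0.5, 0.5), c(-4, -4, -22))

# mask from explicit 1-based voxel index rows
mask_from_indices <- function(idx, grid) {
  m <- array(FALSE, dim = grid$shape)
  m[idx] <- TRUE
  roi_mask(m, grid)
}

# brute-force disc oracle: scan every voxel center on the slice
brute_disc_count <- function(center_xy, diameter_mm, grid, k0) {
  xs <- grid$origin_mm[1] + grid$voxel_size_mm[1] * (seq_len(grid$shape[1]) - 1)
  ys <- grid$origin_mm[2] + grid$voxel_size_mm[2] * (seq_len(grid$shape[2]) - 1)
  d2 <- outer((xs - center_xy[1])^2, (ys - center_xy[2])^2, "+")
  sum(d2 <= (diameter_mm / 2)^2 + 1e-12)
}

constant_volume <- function(value, grid, modality = "mt_on") {
  image_volume(array(value, dim = grid$shape), grid, modality = modality)
}
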