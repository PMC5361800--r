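test_that("noise masking flags exactly the signal-free voxels", {
  p <- pulsatile_phantom()
  nm <- mask_noise(p$ph$magnitude)
  air <- !(p$ph$truth_mask | p$ph$tissue_mask)
  expect_identical(unname(which(nm)), which(air))
  # uniform magnitude: nothing flagged
  uni <- array(100, c(8, 8, 8, 5))
  expect_equal(sum(mask_noise(uni)), 0)
  # all-zero magnitude is an error
  expect_error(mask_noise(array(0, c(4, 4, 4, 5))), "no signal")
})

test_that("static tissue detection selects the slab and excludes flow", {
  p <- pulsatile_phantom()
  st <- detect_static_tissue(p$ph$field, p$ph$magnitude)
  # noiseless: entire slab selected, no lumen voxel selected
  expect_true(all(st$mask[p$ph$tissue_mask]))
  expect_false(any(st$mask & p$ph$truth_mask))
  # with velocity noise below the threshold most of the slab survives;
  # oracle: temporal SD of 8 samples ~ chi distribution around sigma
  pn <- pulsatile_phantom(noise_sd = 0.02, seed = 8)
  inj <- inject_artifacts(pn$ph, pn$spec)
  stn <- detect_static_tissue(inj$field, inj$magnitude, sd_threshold = 0.06)
  expect_gt(mean(stn$mask[pn$ph$tissue_mask]), 0.99)
  # impossible threshold errors with advice
  expect_error(detect_static_tissue(inj$field, inj$magnitude,
                                    sd_threshold = 1e-9), "sd_threshold")
})

test_that("eddy-current fits recover injected coefficients", {
  ec <- rbind(c(0.05, 0.001, 0, 0),
              c(-0.02, 0, 5e-4, 0),
              c(0.01, 0, 0, -8e-4))
  p <- pulsatile_phantom(eddy_coeffs = ec)
  inj <- inject_artifacts(p$ph, p$spec)
  st <- detect_static_tissue(inj$field, inj$magnitude)
  ce <- correct_eddy(inj$field, st)
  expect_lt(max(abs(ce$fit$coefficients - ec)), 1e-9)
  # static voxels are flat after correction
  vbar <- apply(ce$field$values[, , , , 1], 1:3, mean)
  expect_lt(max(abs(vbar[st$mask])), 1e-9)
  # correcting twice is a no-op
  ce2 <- correct_eddy(ce$field, st)
  expect_lt(max(abs(ce2$fit$coefficients)), 1e-9)
  # zero injection: corrected field identical up to numerics
  p0 <- pulsatile_phantom()
  st0 <- detect_static_tissue(p0$ph$field, p0$ph$magnitude)
  ce0 <- correct_eddy(p0$ph$field, st0)
  expect_lt(max(abs(ce0$field$values - p0$ph$field$values)), 1e-12)
})

test_that("noisy eddy offsets are recovered at the standard-error scale", {
  ec <- rbind(c(0.05, 0.001, 0, 0), c(0, 0, 0, 0), c(0, 0, 0, 0))
  errs <- vapply(1:10, function(s) {
    p <- pulsatile_phantom(noise_sd = 0.02, eddy_coeffs = ec, seed = 100 + s)
    inj <- inject_artifacts(p$ph, p$spec)
    st <- detect_static_tissue(inj$field, inj$magnitude, sd_threshold = 0.08)
    ce <- correct_eddy(inj$field, st)
    abs(ce$fit$coefficients[1, 1] - 0.05)
  }, numeric(1))
  p <- pulsatile_phantom(noise_sd = 0.02, eddy_coeffs = ec, seed = 101)
  inj <- inject_artifacts(p$ph, p$spec)
  st <- detect_static_tissue(inj$field, inj$magnitude, sd_threshold = 0.08)
  se <- 0.02 / sqrt(8) / sqrt(st$n_voxels)   # temporal mean over 8 frames
  expect_true(all(errs < 5 * se))
})

test_that("rank-deficient static support is rejected for order >= 1", {
  p <- pulsatile_phantom()
  st <- detect_static_tissue(p$ph$field, p$ph$magnitude)
  flat <- st
  plane <- array(FALSE, dim(st$mask))
  plane[, , 5] <- st$mask[, , 5]   # coplanar voxels: z constant
  flat$mask <- plane
  expect_error(correct_eddy(p$ph$field, flat, order = 1L), "rank")
  expect_silent(correct_eddy(p$ph$field, flat, order = 0L))
})

test_that("velocity unwrapping restores an aliased poiseuille core exactly", {
  p <- poiseuille_phantom(vox_per_diam = 16, R = 10, v_max = 1.8, venc = 1.5,
                          length_mm = 24)
  wrapped <- p$ph$field
  wrapped$values <- aorta4d:::wrap_velocity(p$ph$field$values, 1.5)
  n_wrapped <- sum(wrapped$values != p$ph$field$values)
  expect_gt(n_wrapped, 0)
  uw <- unwrap_velocity(wrapped)
  expect_equal(uw$n_corrected, n_wrapped)
  expect_lt(max(abs(uw$field$values - p$ph$field$values)), 1e-12)
  # idempotent; untouched when nothing is wrapped
  expect_equal(unwrap_velocity(uw$field)$n_corrected, 0)
  clean <- poiseuille_phantom(vox_per_diam = 10)$ph$field
  uc <- unwrap_velocity(clean)
  expect_equal(uc$n_corrected, 0)
  expect_identical(uc$field$values, clean$values)
})

test_that("a single aliased voxel is shifted by 2*venc", {
  spec <- phantom_spec(grid_shape = c(16L, 16L, 12L), voxel_size = 1,
                       tube_radius = 5, v_max = 0, n_frames = 5L, seed = 1)
  f <- make_phantom(spec)$field
  f$values[, , , , 3] <- 1.3
  f$values[8, 8, 6, 2, 3] <- aorta4d:::wrap_velocity(1.8, 1.5)  # -1.2
  uw <- unwrap_velocity(f, venc = 1.5)
  expect_equal(uw$field$values[8, 8, 6, 2, 3], 1.8)
  expect_equal(uw$n_corrected, 1L)
})

test_that("full preprocessing recovers the clean field from all artifacts", {
  ec <- rbind(c(0.04, 8e-4, 0, 0), c(-0.02, 0, 6e-4, 0), c(0.01, 0, 0, -5e-4))
  p <- pulsatile_phantom(eddy_coeffs = ec)
  inj <- inject_artifacts(p$ph, p$spec)
  pp <- preprocess_field(inj$field, inj$magnitude)
  expect_lt(max(abs(pp$field$values - p$ph$field$values)), 1e-9)
  # with noise the residual is bounded by a few noise SDs
  pn <- pulsatile_phantom(noise_sd = 0.01, eddy_coeffs = ec, seed = 12)
  injn <- inject_artifacts(pn$ph, pn$spec)
  ppn <- preprocess_field(injn$field, injn$magnitude)
  expect_lt(max(abs(ppn$field$values - pn$ph$field$values)), 5 * 0.01)
})
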