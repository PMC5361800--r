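test_that("poiseuille WSS is recovered within tolerance and scales linearly", {
  p <- poiseuille_phantom(vox_per_diam = 16, R = 10, length_mm = 32)
  mesh <- extract_surface(p$ph$truth_mask, p$spec$voxel_size)
  w <- compute_wss_frame(p$ph$field, mesh, 1)
  # evaluate on the tube wall away from the artificial open-mouth caps
  ctr <- p$spec$grid_shape[1] * p$spec$voxel_size[1] / 2
  rr <- sqrt((mesh$vertices[, 1] - ctr)^2 + (mesh$vertices[, 2] - ctr)^2)
  zmax <- p$spec$grid_shape[3] * p$spec$voxel_size[3]
  interior <- mesh$vertices[, 3] > 0.15 * zmax &
    mesh$vertices[, 3] < 0.85 * zmax & rr > 5
  ok <- interior & stats::complete.cases(w)
  m <- mean(vnorm_rows(w[ok, , drop = FALSE]))
  expect_lt(abs(m / 0.64 - 1), 0.10)
  # linear in velocity: doubling v doubles each WSS vector
  f2 <- p$ph$field; f2$values <- 2 * f2$values
  w2 <- compute_wss_frame(f2, mesh, 1)
  expect_equal(w2[ok, ], 2 * w[ok, ], tolerance = 1e-9)
  # linear in viscosity
  w3 <- compute_wss_frame(p$ph$field, mesh, 1, wss_config(mu = 6.4e-3))
  expect_equal(w3[ok, ], 2 * w[ok, ], tolerance = 1e-9)
})

test_that("WSS vectors are tangential to the wall", {
  p <- poiseuille_phantom(vox_per_diam = 12, R = 9, length_mm = 24)
  mesh <- extract_surface(p$ph$truth_mask, p$spec$voxel_size)
  w <- compute_wss_frame(p$ph$field, mesh, 1)
  ok <- stats::complete.cases(w)
  wn <- abs(rowSums(w[ok, ] * mesh$normals[ok, ]))
  expect_lt(max(wn / pmax(vnorm_rows(w[ok, ]), 1e-12)), 1e-6)
})

test_that("the no-slip-pinned quadratic fit remains available", {
  p <- poiseuille_phantom(vox_per_diam = 16, R = 10, length_mm = 24)
  mesh <- extract_surface(p$ph$truth_mask, p$spec$voxel_size)
  w <- compute_wss_frame(p$ph$field, mesh, 1,
                         wss_config(fit = "quadratic_no_slip",
                                    n_sample_points = 3L))
  ok <- stats::complete.cases(w)
  m <- mean(vnorm_rows(w[ok, , drop = FALSE]))
  expect_gt(m, 0.3)   # right order of magnitude, larger bias expected
  expect_lt(m, 1.0)
  expect_error(wss_config(fit = "quadratic_free_root", n_sample_points = 3L),
               "n_sample_points")
})

test_that("systolic averaging uses a clamped five-frame window", {
  mats <- lapply(1:16, function(f) matrix(f, 4, 3))
  sa <- systolic_average(mats, peak = 2L)
  expect_equal(sa$window, 1:5)                       # clamp at the start
  expect_equal(systolic_average(mats, peak = 15L)$window, 12:16)
  expect_equal(systolic_average(mats, peak = 8L)$window, 6:10)
  # time-constant WSS: average equals the constant magnitude
  cst <- lapply(1:6, function(f) cbind(3, 4, 0))
  expect_equal(unname(systolic_average(cst, peak = 3L)$wss_sys), 5)
  expect_error(systolic_average(mats[1:4], peak = 1L), "5 frames")
})

test_that("womersley systolic WSS matches the analytic five-frame oracle", {
  w <- womersley_phantom()
  mesh <- extract_surface(w$ph$truth_mask, w$spec$voxel_size)
  ctr <- 22
  rr <- sqrt((mesh$vertices[, 1] - ctr)^2 + (mesh$vertices[, 2] - ctr)^2)
  side <- mesh$vertices[, 3] > 4 & mesh$vertices[, 3] < 20 & rr > 5
  peak <- find_peak_systole(w$ph$field, w$ph$truth_mask)
  wm <- compute_wss(w$ph$field, mesh)
  sa <- systolic_average(wm, peak)
  oracle <- mean(w$ph$truth_wss[sa$window])
  expect_lt(abs(mean(sa$wss_sys[side]) / oracle - 1), 0.15)
  # each frame's mean WSS within 15% of the analytic profile derivative
  perfr <- vapply(wm$frames, function(m) {
    ok <- side & stats::complete.cases(m)
    mean(vnorm_rows(m[ok, , drop = FALSE]))
  }, numeric(1))
  expect_true(all(abs(perfr / w$ph$truth_wss - 1) < 0.15))
})

test_that("segmental means are area-weighted with missing empty segments", {
  u <- ubend_phantom()
  mesh <- extract_surface(u$ph$truth_mask, u$spec$voxel_size)
  cl <- extract_centerline(u$ph$truth_mask, u$spec$voxel_size)
  part <- partition_segments(mesh, cl)
  # uniform field: every segment mean equals the constant
  wss_sys <- rep(0.64, nrow(mesh$vertices))
  sm <- segmental_mean_wss(wss_sys, part, mesh)
  expect_equal(as.numeric(sm), rep(0.64, 10))
  # NA vertices are excluded, not zero-filled
  wss_sys[part$labels == 3][1:5] <- NA
  sm2 <- segmental_mean_wss(wss_sys, part, mesh)
  expect_equal(unname(sm2[3]), 0.64)
  # an emptied segment reports NA
  wss_sys[part$labels == 7] <- NA
  expect_true(is.na(segmental_mean_wss(wss_sys, part, mesh)[7]))
})

test_that("velocity MIP erodes one voxel and finds regional maxima", {
  # 5^3 cube erodes to the central 3^3
  cube <- array(FALSE, c(11L, 11L, 11L)); cube[4:8, 4:8, 4:8] <- TRUE
  er <- aorta4d:::erode6(cube)
  expect_equal(sum(er), 27)
  expect_true(all(which(er, arr.ind = TRUE) >= 5 & which(er, arr.ind = TRUE) <= 7))
  # uniform speed: MIP constant on the footprint
  spec <- phantom_spec(grid_shape = c(20L, 20L, 16L), voxel_size = 1,
                       tube_radius = 6, v_profile = "plug", v_max = 1,
                       n_frames = 5L, seed = 2)
  ph <- make_phantom(spec)
  mip <- velocity_mip(ph$field, ph$truth_mask, peak = 1L)
  vals <- mip$mip[mip$mip > 0]
  expect_equal(unique(round(vals, 10)), 1)
  # poiseuille: regional peak equals v_max (axis voxels survive erosion)
  p <- poiseuille_phantom(vox_per_diam = 12, R = 9, length_mm = 24)
  cl <- extract_centerline(p$ph$truth_mask, p$spec$voxel_size)
  zones <- aorta4d:::voxel_zones(p$ph$truth_mask, p$spec$voxel_size, cl)
  mp <- velocity_mip(p$ph$field, p$ph$truth_mask, peak = 1L, zones = zones)
  expect_lt(abs(max(mp$regional, na.rm = TRUE) / 1 - 1), 0.02)
  # erosion emptying the mask is an error
  thin <- array(FALSE, c(8L, 8L, 8L)); thin[4, , ] <- TRUE
  expect_error(velocity_mip(ph$field, thin, peak = 1L), "erosion")
})
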