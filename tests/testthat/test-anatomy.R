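test_that("PC-MRA follows sqrt(mean(mag^2 |v|^2))", {
  p <- plug_phantom()
  pc <- compute_pcmra(p$ph$field, p$ph$magnitude)
  expect_true(all(pc >= 0))
  # static tissue: velocity zero -> PC-MRA exactly zero
  expect_equal(max(pc[p$ph$tissue_mask]), 0)
  # constant |v| = 1 with magnitude 100 gives 100 everywhere
  f <- p$ph$field
  f$values[] <- 0
  f$values[, , , , 3] <- 1
  mag <- array(100, dim(p$ph$magnitude))
  expect_equal(range(compute_pcmra(f, mag)), c(100, 100), tolerance = 1e-12)
  # frame mismatch errors
  expect_error(compute_pcmra(f, mag[, , , 1:3]), "mismatch")
})

test_that("PC-MRA of a poiseuille tube peaks on the axis and falls radially", {
  p <- poiseuille_phantom(vox_per_diam = 12, R = 9, length_mm = 24)
  pc <- compute_pcmra(p$ph$field, p$ph$magnitude)
  geo <- aorta4d:::phantom_geometry(p$spec)
  mid <- dim(pc)[3] %/% 2
  sl <- pc[, , mid]
  d <- geo$d[, , mid]
  ord <- order(d)
  # monotone trend: correlation between radius and PC-MRA strongly negative
  inl <- d < 9
  expect_lt(cor(d[inl], sl[inl]), -0.95)
  # axis value within magnitude-noise of the slice maximum
  expect_gt(sl[which.min(d)], 0.97 * max(sl))
})

test_that("lumen segmentation reaches the truth mask on a blunt-flow phantom", {
  p <- plug_phantom()
  pc <- compute_pcmra(p$ph$field, p$ph$magnitude)
  m <- segment_lumen(pc)
  expect_gte(dice_overlap(m, p$ph$truth_mask), 0.95)
  # threshold monotonicity: higher threshold yields a subset
  m_lo <- segment_lumen(pc, threshold = 0.2)
  m_hi <- segment_lumen(pc, threshold = 0.6)
  expect_true(all(!m_hi | m_lo))
  # zero flow -> empty segmentation error
  p0 <- plug_phantom(v_max = 0)
  expect_error(segment_lumen(compute_pcmra(p0$ph$field, p0$ph$magnitude)),
               "empty|constant")
})

test_that("only the largest of two disjoint components is kept", {
  pc <- array(0, c(30, 12, 12))
  pc[2:13, 4:9, 4:9] <- 1     # 432 voxels
  pc[18:23, 4:9, 4:9] <- 1    # 216 voxels
  m <- segment_lumen(pc, threshold = 0.5, closing = FALSE)
  expect_true(all(which(m) <= 13 * 30 * 144))
  expect_equal(sum(m), 432)
})

test_that("peak systole is the argmax frame with early tie-break", {
  spec <- phantom_spec(grid_shape = c(16L, 16L, 12L), voxel_size = 1,
                       tube_radius = 5, v_max = 0, n_frames = 5L, seed = 1)
  f <- make_phantom(spec)$field
  mask <- make_phantom(spec)$truth_mask
  for (sp in list(c(0.1, 0.6, 0.4, 0.2, 0.1), rep(0.3, 5))) {
    for (fr in 1:5) f$values[, , , fr, 3] <- sp[fr]
    expect_equal(find_peak_systole(f, mask), which.max(sp))
  }
  # invariant to uniform velocity rescaling
  for (fr in 1:5) f$values[, , , fr, 3] <- c(0.1, 0.6, 0.4, 0.2, 0.1)[fr]
  p1 <- find_peak_systole(f, mask)
  f$values <- f$values * 3.7
  expect_equal(find_peak_systole(f, mask), p1)
  # womersley phantom: matches the truth waveform argmax
  w <- womersley_phantom()
  expect_equal(find_peak_systole(w$ph$field, w$ph$truth_mask),
               which.max(w$ph$truth_waveform))
})

test_that("extracted surfaces are closed, oriented and metrically accurate", {
  # digitised sphere, radius 10 mm at 1 mm voxels
  gs <- c(26L, 26L, 26L)
  co <- aorta4d:::voxel_coords(gs, c(1, 1, 1))
  sph <- sqrt((co$x - 13)^2 + (co$y - 13)^2 + (co$z - 13)^2) <= 10
  m <- extract_surface(sph, c(1, 1, 1))
  expect_lt(abs(m$area / (4 * pi * 100) - 1), 0.05)
  expect_equal(mesh_euler_characteristic(m), 2)
  expect_equal(sum(m$vertex_area), m$area)
  # outward unit normals
  expect_equal(max(abs(vapply(seq_len(nrow(m$normals)), function(i)
    sum(m$normals[i, ]^2), numeric(1)) - 1), na.rm = TRUE), 0,
    tolerance = 1e-6)
  radial <- sweep(m$vertices, 2, 13)
  dots <- rowSums(m$normals * radial) / sqrt(rowSums(radial^2))
  expect_gt(min(dots), 0.8)
  # 5^3 voxel cube: closed surface with Euler characteristic 2
  cube <- array(FALSE, c(11L, 11L, 11L)); cube[4:8, 4:8, 4:8] <- TRUE
  expect_equal(mesh_euler_characteristic(extract_surface(cube, c(1, 1, 1))), 2)
  # tube: vertices within half a voxel of the true cylinder
  p <- poiseuille_phantom(vox_per_diam = 16, R = 8, length_mm = 24)
  mt <- extract_surface(p$ph$truth_mask, p$spec$voxel_size)
  ctr <- p$spec$grid_shape[1] * p$spec$voxel_size[1] / 2
  rr <- sqrt((mt$vertices[, 1] - ctr)^2 + (mt$vertices[, 2] - ctr)^2)
  side <- mt$vertices[, 3] > 3 & mt$vertices[, 3] < 21 & rr > 4
  expect_lt(mean(abs(rr[side] - 8)), 0.5 * p$spec$voxel_size[1])
})

test_that("centerlines recover axis, length and bend curvature", {
  p <- poiseuille_phantom(vox_per_diam = 16, R = 8, length_mm = 40)
  cl <- extract_centerline(p$ph$truth_mask, p$spec$voxel_size)
  ctr <- p$spec$grid_shape[1] * p$spec$voxel_size[1] / 2
  interior <- cl$s > 0.15 * cl$length & cl$s < 0.85 * cl$length
  expect_lt(max(abs(cl$points[interior, 1] - ctr)), 0.25)
  expect_lt(stats::median(vnorm_rows(cl$curvature[interior, , drop = FALSE])),
            0.005)
  expect_lt(abs(cl$length / 40 - 1), 0.05)
  expect_true(all(diff(cl$s) > 0))
  expect_equal(max(abs(rowSums(cl$tangent^2) - 1)), 0, tolerance = 1e-6)
  # u-bend: curvature at the apex ~ 1/bend_radius, straight limbs flat
  u <- ubend_phantom()
  clu <- extract_centerline(u$ph$truth_mask, u$spec$voxel_size)
  km <- vnorm_rows(clu$curvature)
  mid <- clu$s > 0.4 * clu$length & clu$s < 0.6 * clu$length
  expect_lt(abs(mean(km[mid]) / (1 / 25) - 1), 0.2)
  limb <- clu$s > 0.05 * clu$length & clu$s < 0.25 * clu$length
  expect_lt(mean(km[limb]), 0.005)
  expect_lt(abs(clu$length / u$ph$geometry$total_length - 1), 0.05)
})

test_that("the 10-segment partition is disjoint, exhaustive and anatomic", {
  u <- ubend_phantom()
  mesh <- extract_surface(u$ph$truth_mask, u$spec$voxel_size)
  cl <- extract_centerline(u$ph$truth_mask, u$spec$voxel_size)
  part <- partition_segments(mesh, cl)
  expect_true(all(part$labels %in% 0:10))
  expect_true(all(1:10 %in% part$labels))
  # exhaustive between the ends: every vertex with zone > 0 has a label
  expect_true(all((part$zone > 0) == (part$labels > 0)))
  # equal default landmarks -> five zones of equal arc length
  expect_equal(part$landmarks, c(0.2, 0.4, 0.6, 0.8))
  # concave (inner) apex vertices carry the inner-arch label
  apex_z <- max(u$ph$geometry$centerline_points[, 3])
  bc <- c(u$spec$grid_shape[1] * u$spec$voxel_size[1] / 2,
          u$spec$grid_shape[2] * u$spec$voxel_size[2] / 2, apex_z - 25)
  vv <- mesh$vertices
  near_apex <- abs(vv[, 1] - bc[1]) < 6 & vv[, 3] > bc[3] + 10
  radbc <- sqrt((vv[, 1] - bc[1])^2 + (vv[, 3] - bc[3])^2)
  expect_true(all(part$labels[near_apex & radbc < 21] == 5))
  expect_true(all(part$labels[near_apex & radbc > 29] == 6))
  # straight limbs follow the arch convention: bend-facing side is inner
  leftlimb <- vv[, 1] < 50 & vv[, 3] < 40 & part$zone %in% 1:2
  expect_gt(mean(part$inner[leftlimb & vv[, 1] > 38.5 & vv[, 1] < 47]), 0.95)
  expect_lt(mean(part$inner[leftlimb & vv[, 1] < 36]), 0.05)
  # landmark validation
  expect_error(partition_segments(mesh, cl, landmarks = c(0.4, 0.2, 0.6, 0.8)),
               "landmarks")
})
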