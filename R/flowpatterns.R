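#' Local normalized helicity
#'
#' LNH is the cosine of the angle between velocity and vorticity,
#' `(v . curl v) / (|v| |curl v|)`, a signed, dimensionless index of helical
#' motion: +1/-1 for perfectly right/left-handed corkscrew flow, ~0 where
#' velocity and vorticity are orthogonal (e.g. ideal parabolic tube flow).
#' The curl is evaluated by central differences.
#'
#' @param field a (preprocessed) `velocity_field`.
#' @param mask logical 3D lumen mask; LNH is reported inside only.
#' @param frame 1-based frame index.
#' @param eps magnitudes below this (m/s resp. 1/s) give NA (undefined).
#' @return 3D array of LNH in `[-1, 1]`, NA outside the mask or where
#'   undefined.
#' @export
local_normalized_helicity <- function(field, mask, frame, eps = 1e-6) {
  vs <- field$voxel_size
  vx <- field$values[, , , frame, 1]
  vy <- field$values[, , , frame, 2]
  vz <- field$values[, , , frame, 3]
  gx <- gradient3(vx, vs); gy <- gradient3(vy, vs); gz <- gradient3(vz, vs)
  # curl in 1/s: velocity m/s, spacing mm -> factor 1000
  cx <- (gz$y - gy$z) * 1000
  cy <- (gx$z - gz$x) * 1000
  cz <- (gy$x - gx$y) * 1000
  vmag <- sqrt(vx^2 + vy^2 + vz^2)
  cmag <- sqrt(cx^2 + cy^2 + cz^2)
  lnh <- (vx * cx + vy * cy + vz * cz) / (vmag * cmag)
  lnh[vmag < eps | cmag < eps * 1000 | !mask] <- NA_real_
  lnh
}

# velocity (m/s == mm/ms) at world points and time t_ms, linear in space
# (trilinear) and time; the cardiac cycle is treated as periodic
sample_velocity_xt <- function(field, pts, t_ms) {
  nt <- field$n_frames
  period <- nt * field$frame_duration
  tm <- t_ms %% period
  fi <- tm / field$frame_duration        # 0-based continuous frame index
  f0 <- floor(fi)
  w1 <- fi - f0
  f0 <- (f0 %% nt) + 1L
  f1 <- (f0 %% nt) + 1L
  out <- matrix(NA_real_, nrow(pts), 3L)
  for (comp in 1:3) {
    a <- interp_trilinear(field$values[, , , f0, comp], pts, field$voxel_size)
    b <- if (w1 > 0) {
      interp_trilinear(field$values[, , , f1, comp], pts, field$voxel_size)
    } else a
    out[, comp] <- (1 - w1) * a + w1 * b
  }
  out
}

# parallel-transported orthonormal frame (e1, e2) perpendicular to the
# centerline tangent, for winding-angle bookkeeping
transport_frame <- function(centerline) {
  tg <- centerline$tangent
  n <- nrow(tg)
  e1 <- matrix(0, n, 3)
  ref <- c(1, 0, 0)
  if (abs(sum(ref * tg[1, ])) > 0.9) ref <- c(0, 1, 0)
  e1[1, ] <- ref - sum(ref * tg[1, ]) * tg[1, ]
  e1[1, ] <- e1[1, ] / sqrt(sum(e1[1, ]^2))
  for (i in 2:n) {
    v <- e1[i - 1, ] - sum(e1[i - 1, ] * tg[i, ]) * tg[i, ]
    nv <- sqrt(sum(v^2))
    e1[i, ] <- if (nv > 1e-9) v / nv else e1[i - 1, ]
  }
  e2 <- cross3(tg, e1)
  list(e1 = e1, e2 = e2)
}

#' Advect tracers and measure their winding about the centerline
#'
#' Massless tracers are integrated through the time-resolved velocity field
#' with a 4th-order Runge-Kutta scheme (time step at most one tenth of the
#' frame duration; velocities interpolated linearly in space and time, the
#' cycle treated as periodic). At every step each tracer's angular position
#' about the nearest centerline point is tracked in a parallel-transported
#' normal frame; the winding is the accumulated (signed) angle. Tracers
#' leaving the field domain keep their partial winding and are flagged.
#'
#' @param field a `velocity_field`.
#' @param seeds n x 3 matrix of seed positions (mm).
#' @param centerline a `centerline`.
#' @param t_span integration window in ms (default one cardiac cycle).
#' @param dt time step, ms (default `frame_duration / 10`).
#' @param off_floor winding increments are only accumulated while the tracer
#'   is at least this far (mm) from the centerline - the angular position of
#'   a tracer on the axis is undefined; defaults to one voxel.
#' @return list: `winding` (signed accumulated angle per tracer, degrees),
#'   `max_winding` (maximum absolute winding, degrees), `exited` (logical).
#' @export
tracer_winding <- function(field, seeds, centerline, t_span = NULL,
                           dt = NULL, off_floor = NULL) {
  if (is.null(dt)) dt <- field$frame_duration / 10
  dt <- min(dt, field$frame_duration / 10)
  if (is.null(t_span)) t_span <- c(0, field$n_frames * field$frame_duration)
  if (is.null(off_floor)) off_floor <- max(field$voxel_size)
  seeds <- as.matrix(seeds)
  n <- nrow(seeds)
  pos <- seeds
  active <- rep(TRUE, n)
  exited <- rep(FALSE, n)
  fr <- transport_frame(centerline)
  ncl <- nrow(centerline$points)
  n_edge <- max(2L, round(0.05 * ncl))
  # angular increment of the step p_old -> p_new, with BOTH endpoints
  # referenced to the same centerline point and transported frame: purely
  # axial motion then contributes exactly zero even where the discrete
  # centerline wobbles, and the increments sum to the true winding
  step_angle <- function(p_old, p_new) {
    ni <- nearest_centerline_point(p_new, centerline)
    cp <- centerline$points[ni, , drop = FALSE]
    e1 <- fr$e1[ni, , drop = FALSE]; e2 <- fr$e2[ni, , drop = FALSE]
    on_ <- p_new - cp; oo <- p_old - cp
    tn <- atan2(rowSums(on_ * e2), rowSums(on_ * e1))
    to <- atan2(rowSums(oo * e2), rowSums(oo * e1))
    rn <- sqrt(rowSums(on_ * e1)^2 + rowSums(on_ * e2)^2)
    ro <- sqrt(rowSums(oo * e1)^2 + rowSums(oo * e2)^2)
    dth <- ((tn - to + pi) %% (2 * pi)) - pi
    # gate: well-defined angular position, interior centerline station
    dth[rn <= off_floor | ro <= off_floor |
        ni <= n_edge | ni > ncl - n_edge] <- 0
    dth
  }
  winding <- numeric(n)
  times <- seq(t_span[1], t_span[2], by = dt)
  for (ti in times[-length(times)]) {
    if (!any(active)) break
    idx <- which(active)
    p <- pos[idx, , drop = FALSE]
    k1 <- sample_velocity_xt(field, p, ti)
    k2 <- sample_velocity_xt(field, p + dt / 2 * k1, ti + dt / 2)
    k3 <- sample_velocity_xt(field, p + dt / 2 * k2, ti + dt / 2)
    k4 <- sample_velocity_xt(field, p + dt * k3, ti + dt)
    step <- dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    bad <- !stats::complete.cases(step)
    pnew <- p + step
    pos[idx, ] <- pnew
    ok <- which(!bad)
    if (length(ok) > 0L) {
      dth <- step_angle(p[ok, , drop = FALSE], pnew[ok, , drop = FALSE])
      winding[idx[ok]] <- winding[idx[ok]] + dth
    }
    if (any(bad)) {
      exited[idx[bad]] <- TRUE
      active[idx[bad]] <- FALSE
    }
  }
  deg <- winding * 180 / pi
  list(winding = deg, max_winding = max(abs(deg)), exited = exited)
}

# tracer seeds on a disk perpendicular to the centerline at arc fraction f
seed_disk <- function(centerline, radius, n = 200L, at_fraction = 0.05,
                      seed = 7L) {
  set.seed(seed)
  i <- which.min(abs(centerline$s - at_fraction * centerline$length))
  fr <- transport_frame(centerline)
  # annulus: avoid the axis, where the angular position is degenerate
  r <- radius * sqrt(stats::runif(n, 0.3, 1))
  a <- stats::runif(n, 0, 2 * pi)
  sweep(r * cos(a) %o% fr$e1[i, ] + r * sin(a) %o% fr$e2[i, ], 2,
        centerline$points[i, ], "+")
}

# fraction of each cross-section (centerline station) with negative axial
# velocity; stations are arc-length bins of the lumen voxels
reversed_fraction_profile <- function(field, mask, centerline, frame,
                                      bin_mm = NULL) {
  vs <- field$voxel_size
  if (is.null(bin_mm)) bin_mm <- 2 * max(vs)
  co <- voxel_coords(dim(mask), vs)
  idx <- which(mask)
  pts <- cbind(co$x[idx], co$y[idx], co$z[idx])
  ni <- nearest_centerline_point(pts, centerline)
  ax <- centerline$tangent[ni, , drop = FALSE]
  vax <- field$values[, , , frame, 1][idx] * ax[, 1] +
         field$values[, , , frame, 2][idx] * ax[, 2] +
         field$values[, , , frame, 3][idx] * ax[, 3]
  bin <- floor(centerline$s[ni] / bin_mm)
  agg <- tapply(vax < 0, bin, mean)
  s_mid <- (as.numeric(names(agg)) + 0.5) * bin_mm
  data.frame(s = s_mid, reversed_fraction = as.numeric(agg))
}

#' Grade a rotation angle on the 3-point helix/vortex scale
#'
#' none = 0 (rotation below `floor_deg`), moderate = 1 (rotation below one
#' full turn), pronounced = 2 (rotation of 360 degrees or more).
#'
#' @param winding_deg winding angle in degrees (absolute value is used).
#' @param floor_deg lower bound for grade 1 (default 90).
#' @return integer grade 0, 1 or 2.
#' @export
grade_rotation <- function(winding_deg, floor_deg = 90) {
  w <- abs(winding_deg)
  ifelse(w >= 360, 2L, ifelse(w >= floor_deg, 1L, 0L))
}

#' Combine helix and vortex gradings for a region
#'
#' The helix grade is computed from the maximal tracer winding in the
#' region; the vortex grade is computed the same way from tracers seeded in
#' reversed-flow areas, and is 0 when no cross-section has more than
#' `reversed_threshold` of its area flowing backward. The combined score is
#' their sum (range 0-4), a semiquantitative severity index.
#'
#' @param helix_winding maximal helix tracer winding, degrees.
#' @param vortex_winding maximal winding of tracers seeded in reversed-flow
#'   areas, degrees (NA when there is none).
#' @param reversed_fraction maximal fraction of a cross-section with
#'   negative axial velocity.
#' @param region region label ("AAo", "arch", "DAo").
#' @param reversed_threshold cross-sectional area fraction above which a
#'   reversed-flow region counts as recirculation (default 0.05).
#' @param floor_deg lower winding bound for grade 1, degrees.
#' @return object of class `flow_grade`: list with the grades, the combined
#'   score and the inputs.
#' @export
grade_flow <- function(helix_winding, vortex_winding = NA_real_,
                       reversed_fraction = 0, region = "DAo",
                       reversed_threshold = 0.05, floor_deg = 90) {
  helix <- grade_rotation(helix_winding, floor_deg)
  vortex <- 0L
  if (!is.na(reversed_fraction) && reversed_fraction > reversed_threshold &&
      !is.na(vortex_winding)) {
    vortex <- grade_rotation(vortex_winding, floor_deg)
  }
  structure(list(region = region, helix_grade = helix, vortex_grade = vortex,
                 combined = helix + vortex,
                 max_winding = max(abs(c(helix_winding, vortex_winding)),
                                   na.rm = TRUE),
                 reversed_fraction = reversed_fraction),
            class = "flow_grade")
}

#' Automatic helix/vortex grading of a vessel region
#'
#' Quantitative surrogate for visual flow-pattern reading: tracers are
#' seeded on a disk at the region entry and advected through the
#' time-resolved field; their maximal winding about the centerline yields
#' the helix grade. Cross-sections whose reversed-flow fraction exceeds the
#' threshold additionally seed vortex tracers at reversed-flow voxels.
#'
#' @param field a `velocity_field`.
#' @param mask lumen mask.
#' @param centerline a `centerline`.
#' @param peak peak systolic frame (used for the reversed-flow profile).
#' @param region region label for the report.
#' @param s_range arc-length fraction window to analyse (default whole
#'   vessel); seeds are placed at its proximal edge.
#' @param n_tracers number of tracers (default 200).
#' @param seed RNG seed for seed placement.
#' @param reversed_threshold see [grade_flow()].
#' @return a `flow_grade`.
#' @export
assess_flow_patterns <- function(field, mask, centerline, peak = 1L,
                                 region = "DAo", s_range = c(0.02, 0.98),
                                 n_tracers = 200L, seed = 7L,
                                 reversed_threshold = 0.05) {
  vs <- field$voxel_size
  # lumen radius estimate from volume and length
  vol <- sum(mask) * prod(vs)
  r_est <- sqrt(vol / (pi * centerline$length))
  seeds <- seed_disk(centerline, 0.8 * r_est, n = n_tracers,
                     at_fraction = s_range[1] + 0.02, seed = seed)
  tw <- tracer_winding(field, seeds, centerline)
  rf <- reversed_fraction_profile(field, mask, centerline, peak)
  infr <- rf$s / centerline$length >= s_range[1] &
    rf$s / centerline$length <= s_range[2]
  rf_max <- if (any(infr)) max(rf$reversed_fraction[infr]) else 0
  vortex_w <- NA_real_
  if (rf_max > reversed_threshold) {
    # seed tracers at reversed-flow voxels inside the analysis window
    co <- voxel_coords(dim(mask), vs)
    idx <- which(mask)
    pts <- cbind(co$x[idx], co$y[idx], co$z[idx])
    ni <- nearest_centerline_point(pts, centerline)
    ax <- centerline$tangent[ni, , drop = FALSE]
    vax <- field$values[, , , peak, 1][idx] * ax[, 1] +
           field$values[, , , peak, 2][idx] * ax[, 2] +
           field$values[, , , peak, 3][idx] * ax[, 3]
    fsel <- centerline$s[ni] / centerline$length
    rev_idx <- which(vax < 0 & fsel >= s_range[1] & fsel <= s_range[2])
    if (length(rev_idx) > 0L) {
      set.seed(seed + 1L)
      take <- rev_idx[sample.int(length(rev_idx),
                                 min(n_tracers, length(rev_idx)))]
      tv <- tracer_winding(field, pts[take, , drop = FALSE], centerline)
      vortex_w <- max(abs(tv$winding))
    }
  }
  grade_flow(tw$max_winding, vortex_w, rf_max, region,
             reversed_threshold = reversed_threshold)
}
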