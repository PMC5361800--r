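#' Flag noise voxels from the magnitude images
#'
#' Voxels whose time-averaged magnitude falls below a fraction of the robust
#' maximum (99th percentile) contain no signal; their velocities are phase
#' noise and are excluded from all downstream statistics.
#'
#' @param magnitude 4D magnitude array (x, y, z, t), non-negative.
#' @param threshold_frac fraction of the 99th-percentile magnitude below
#'   which a voxel is considered noise (default 0.1).
#' @return logical 3D array, `TRUE` at noise voxels, with attributes
#'   `threshold` (absolute magnitude cut) and `threshold_frac`.
#' @export
mask_noise <- function(magnitude, threshold_frac = 0.1) {
  stopifnot(length(dim(magnitude)) == 4L)
  mbar <- apply(magnitude, 1:3, mean)
  if (all(mbar == 0)) stop("no signal: magnitude image is identically zero")
  robust_max <- stats::quantile(mbar, 0.99, names = FALSE)
  thr <- threshold_frac * robust_max
  out <- mbar < thr
  attr(out, "threshold") <- thr
  attr(out, "threshold_frac") <- threshold_frac
  out
}

#' Detect static tissue for eddy-current fitting
#'
#' Static tissue is the fitting support for the eddy-current phase-offset
#' correction: voxels with strong magnitude signal whose velocity is constant
#' over the cardiac cycle. A voxel is selected when it is not a noise voxel
#' and the temporal standard deviation of each velocity component is below
#' `sd_threshold`. Pulsatile lumen voxels are thereby excluded; note that
#' truly steady flow would violate this assumption (a documented limitation,
#' irrelevant for pulsatile acquisitions).
#'
#' @param field a `velocity_field` (>= 5 frames).
#' @param magnitude 4D magnitude array.
#' @param sd_threshold maximal per-component temporal SD, m/s (default 0.05).
#' @param threshold_frac magnitude noise threshold passed to [mask_noise()].
#' @return object of class `static_tissue_mask`: list with `mask` (3D
#'   logical), `sd_threshold`, `threshold_frac`, `n_voxels`.
#' @export
detect_static_tissue <- function(field, magnitude, sd_threshold = 0.05,
                                 threshold_frac = 0.1) {
  stopifnot(inherits(field, "velocity_field"), field$n_frames >= 5L)
  noise <- mask_noise(magnitude, threshold_frac)
  ok <- !noise
  for (comp in 1:3) {
    sds <- apply(field$values[, , , , comp, drop = FALSE], 1:3, stats::sd)
    ok <- ok & (sds < sd_threshold)
  }
  if (!any(ok)) {
    stop("no static tissue found: raise sd_threshold (currently ",
         sd_threshold, " m/s) or lower the magnitude threshold")
  }
  structure(list(mask = ok, sd_threshold = sd_threshold,
                 threshold_frac = threshold_frac, n_voxels = sum(ok)),
            class = "static_tissue_mask")
}

eddy_design_matrix <- function(coords_mm, order) {
  x <- coords_mm[, 1]; y <- coords_mm[, 2]; z <- coords_mm[, 3]
  switch(as.character(order),
    "0" = matrix(1, length(x), 1L),
    "1" = cbind(1, x, y, z),
    "2" = cbind(1, x, y, z, x^2, y^2, z^2, x * y, x * z, y * z),
    stop("eddy-current polynomial order must be 0, 1 or 2"))
}

#' Correct eddy-current induced velocity offsets
#'
#' Fits, per velocity component, a low-order spatial polynomial to the
#' temporal-mean velocity over static-tissue voxels (ordinary least squares)
#' and subtracts the fitted surface from every voxel and frame. The offset is
#' modelled as time-invariant, matching the forward model used by
#' [inject_artifacts()].
#'
#' @param field a `velocity_field`.
#' @param static a `static_tissue_mask` from [detect_static_tissue()].
#' @param order polynomial order, 0, 1 (default) or 2.
#' @return list with `field` (corrected) and `fit`, an `eddy_fit` object
#'   holding the per-component coefficient matrix, residual RMS (m/s) and
#'   the number of static voxels used.
#' @export
correct_eddy <- function(field, static, order = 1L) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(static, "static_tissue_mask"))
  mask <- static$mask
  if (!any(mask)) stop("static tissue mask is empty")
  gs <- field$grid_shape
  co <- voxel_coords(gs, field$voxel_size)
  idx <- which(mask)
  pts <- cbind(co$x[idx], co$y[idx], co$z[idx])
  X <- eddy_design_matrix(pts, order)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("eddy-current fit is rank-deficient: static voxels do not span a ",
         "full-rank order-", order, " design (e.g. coplanar voxels)")
  }
  all_pts <- cbind(as.vector(co$x), as.vector(co$y), as.vector(co$z))
  X_all <- eddy_design_matrix(all_pts, order)
  coefs <- matrix(0, nrow = 3, ncol = ncol(X))
  rms <- numeric(3)
  for (comp in 1:3) {
    vbar <- apply(field$values[, , , , comp, drop = FALSE], 1:3, mean)
    beta <- qr.coef(qrX, vbar[idx])
    coefs[comp, ] <- beta
    rms[comp] <- sqrt(mean((vbar[idx] - X %*% beta)^2))
    surf <- array(X_all %*% beta, gs)
    for (f in seq_len(field$n_frames)) {
      field$values[, , , f, comp] <- field$values[, , , f, comp] - surf
    }
  }
  fit <- structure(list(coefficients = coefs, order = order,
                        residual_rms = rms, n_static_voxels = length(idx)),
                   class = "eddy_fit")
  list(field = field, fit = fit)
}

# median over the 6-neighbourhood of each voxel in a 3D array; missing
# neighbours at the domain border are replaced by the centre value
neighbour_median6 <- function(v) {
  nb <- neighbours6(v, NA)
  for (i in 1:6) {
    miss <- is.na(nb[[i]])
    nb[[i]][miss] <- v[miss]
  }
  median6(nb[[1]], nb[[2]], nb[[3]], nb[[4]], nb[[5]], nb[[6]])
}

# one volume (single frame/component): region-growing unwrap from a seed
# region of unambiguous voxels (|v| <= seed_frac * venc). The wave front is
# compared against the median of its already-validated neighbours and shifted
# by the multiple of 2*venc minimising the difference. Handles contiguous
# wrapped cores that defeat a plain neighbourhood-median sweep.
unwrap_grow3 <- function(v, ve, seed_frac = 0.5) {
  visited <- abs(v) <= seed_frac * ve
  if (!any(visited)) visited[which.min(abs(v))] <- TRUE
  changed <- array(FALSE, dim(v))
  repeat {
    nbv <- vector("list", 6L)
    vis_masked <- v
    vis_masked[!visited] <- NA
    has_nb <- array(FALSE, dim(v))
    for (i in 1:6) {
      ax <- c(1L, 1L, 2L, 2L, 3L, 3L)[i]
      by <- c(1L, -1L, 1L, -1L, 1L, -1L)[i]
      nbv[[i]] <- ax_shift(vis_masked, ax, by, NA)
      has_nb <- has_nb | !is.na(nbv[[i]])
    }
    frontier <- which(!visited & has_nb)
    if (length(frontier) == 0L) break
    m <- vapply(nbv, function(a) a[frontier], numeric(length(frontier)))
    if (length(frontier) == 1L) m <- matrix(m, nrow = 1L)
    ref <- apply(m, 1L, stats::median, na.rm = TRUE)
    k <- round((ref - v[frontier]) / (2 * ve))
    mod <- k != 0L
    if (any(mod)) {
      v[frontier[mod]] <- v[frontier[mod]] + 2 * ve * k[mod]
      changed[frontier[mod]] <- TRUE
    }
    visited[frontier] <- TRUE
  }
  list(v = v, changed = changed)
}

#' Anti-alias (unwrap) phase-wrapped velocities
#'
#' Phase-contrast velocities beyond the venc alias by multiples of 2 venc.
#' The correction works component-wise. Each frame is first swept spatially:
#' any voxel whose value differs from the median of its 6-neighbourhood by
#' more than venc is shifted by the multiple of 2 venc that minimises the
#' difference, iterating to a fixed point; an analogous comparison against
#' the temporal neighbours follows. Because a large contiguous wrapped core
#' can be self-consistent under a plain median sweep, frames containing
#' near-venc values are additionally unwrapped by region growing from a seed
#' region of unambiguous low-velocity voxels, each front voxel being compared
#' to the median of its already-validated neighbours. The combined operation
#' is idempotent and never alters voxels that agree with their neighbours.
#'
#' @param field a `velocity_field` with `|values| <= venc`.
#' @param venc velocity-encoding limit per component (defaults to the
#'   field's own metadata), m/s.
#' @param max_iter maximal number of sweeps before giving up.
#' @return list with `field` (unwrapped) and `n_corrected`, the number of
#'   voxel-frame-component values changed.
#' @export
unwrap_velocity <- function(field, venc = field$venc, max_iter = 30L) {
  stopifnot(inherits(field, "velocity_field"))
  if (length(venc) == 1L) venc <- rep(venc, 3L)
  n_corrected <- 0L
  nt <- field$n_frames
  median_sweeps <- function(comp, ve, changed_idx) {
    for (iter in seq_len(max_iter)) {
      any_change <- FALSE
      for (f in seq_len(nt)) {
        v <- field$values[, , , f, comp]
        med <- neighbour_median6(v)
        k <- round((med - v) / (2 * ve))
        need <- abs(v - med) > ve & k != 0
        if (any(need)) {
          v[need] <- v[need] + 2 * ve * k[need]
          field$values[, , , f, comp] <<- v
          changed_idx[, , , f][need] <- TRUE
          any_change <- TRUE
        }
      }
      # temporal pass: median of the two temporal neighbours
      if (nt >= 3L) {
        vals <- field$values[, , , , comp]
        prv <- vals[, , , c(1L, seq_len(nt - 1L)), drop = FALSE]
        nxt <- vals[, , , c(seq_len(nt)[-1L], nt), drop = FALSE]
        med_t <- (prv + nxt) / 2
        k <- round((med_t - vals) / (2 * ve))
        need <- abs(vals - med_t) > ve & k != 0
        if (any(need)) {
          vals[need] <- vals[need] + 2 * ve * k[need]
          field$values[, , , , comp] <<- vals
          changed_idx[need] <- TRUE
          any_change <- TRUE
        }
      }
      if (!any_change) return(changed_idx)
      if (iter == max_iter) {
        stop("velocity unwrapping did not converge: ",
             sum(changed_idx), " voxels still being updated after ",
             max_iter, " sweeps")
      }
    }
    changed_idx
  }
  for (comp in 1:3) {
    ve <- venc[comp]
    changed_idx <- array(FALSE, c(field$grid_shape, nt))
    changed_idx <- median_sweeps(comp, ve, changed_idx)
    # region-growing pass only when wrapping is plausible
    if (any(abs(field$values[, , , , comp]) > 0.9 * ve)) {
      for (f in seq_len(nt)) {
        gr <- unwrap_grow3(field$values[, , , f, comp], ve)
        field$values[, , , f, comp] <- gr$v
        changed_idx[, , , f] <- changed_idx[, , , f] | gr$changed
      }
      changed_idx <- median_sweeps(comp, ve, changed_idx)
    }
    n_corrected <- n_corrected + sum(changed_idx)
  }
  list(field = field, n_corrected = n_corrected)
}

#' Full phase-contrast preprocessing
#'
#' Convenience wrapper chaining the three corrections in the standard order:
#' noise masking, velocity anti-aliasing, eddy-current offset correction.
#'
#' @param field a `velocity_field`.
#' @param magnitude 4D magnitude array.
#' @param eddy_order polynomial order for [correct_eddy()].
#' @param sd_threshold static-tissue temporal-SD threshold, m/s.
#' @param threshold_frac magnitude noise threshold fraction.
#' @return list with `field` (fully corrected), `noise_mask`, `static`,
#'   `eddy_fit`, `n_unwrapped`.
#' @export
preprocess_field <- function(field, magnitude, eddy_order = 1L,
                             sd_threshold = 0.05, threshold_frac = 0.1) {
  noise <- mask_noise(magnitude, threshold_frac)
  uw <- unwrap_velocity(field)
  static <- detect_static_tissue(uw$field, magnitude, sd_threshold,
                                 threshold_frac)
  ce <- correct_eddy(uw$field, static, eddy_order)
  list(field = ce$field, noise_mask = noise, static = static,
       eddy_fit = ce$fit, n_unwrapped = uw$n_corrected)
}
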