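#' Wall shear stress configuration
#'
#' @param mu dynamic viscosity in Pa s (default 3.2e-3, a standard
#'   whole-blood assumption).
#' @param n_sample_points number of velocity samples along the inward
#'   normal, including the wall point (>= 3; default 3).
#' @param sample_spacing distance between samples in mm; defaults to the
#'   smallest voxel dimension at call time when `NULL`.
#' @param fit wall model. `"quadratic_free_root"` (default) fits an
#'   unconstrained quadratic through the interior samples, estimates the
#'   no-slip point as the near-wall root of the fitted speed profile (a
#'   sub-voxel wall re-localisation that absorbs the placement error of a
#'   voxelised surface) and evaluates the shear rate there; requires
#'   `n_sample_points >= 4`. `"quadratic_no_slip"` fits `v(n) = a n + b n^2`
#'   through the no-slip origin pinned at the mesh vertex and evaluates the
#'   shear rate `a` at the wall.
#' @return object of class `wss_config`.
#' @export
wss_config <- function(mu = 3.2e-3, n_sample_points = 4L,
                       sample_spacing = NULL,
                       fit = c("quadratic_free_root", "quadratic_no_slip")) {
  fit <- match.arg(fit)
  stopifnot(mu > 0, n_sample_points >= 3L)
  if (fit == "quadratic_free_root" && n_sample_points < 4L) {
    stop("fit 'quadratic_free_root' needs n_sample_points >= 4")
  }
  structure(list(mu = mu, n_sample_points = as.integer(n_sample_points),
                 sample_spacing = sample_spacing, fit = fit),
            class = "wss_config")
}

#' Vertex-wise wall shear stress for one time frame
#'
#' For each mesh vertex, the velocity is sampled by trilinear interpolation
#' at inward-normal distances 0, h, 2h, ... (h = `sample_spacing`). The wall
#' sample is replaced by the no-slip condition v(0) = 0 and a quadratic
#' `v(n) = a n + b n^2` is least-squares fitted through the interior samples;
#' the wall shear rate is `a` (per component). The WSS vector is the dynamic
#' viscosity times the shear-rate vector with its wall-normal component
#' projected out, so it is tangential by construction. Vertices whose sample
#' points leave the field domain are flagged (`NA` rows) and excluded from
#' regional means.
#'
#' @param field a preprocessed `velocity_field`.
#' @param mesh a `surface_mesh` with outward unit normals.
#' @param frame 1-based frame index.
#' @param cfg a [wss_config()].
#' @return n x 3 matrix of WSS vectors in N/m^2; flagged vertices are NA.
#' @export
compute_wss_frame <- function(field, mesh, frame, cfg = wss_config()) {
  stopifnot(inherits(field, "velocity_field"), inherits(mesh, "surface_mesh"))
  h <- cfg$sample_spacing
  if (is.null(h)) h <- min(field$voxel_size)
  depths <- h * seq_len(cfg$n_sample_points - 1L)   # interior samples only
  nv <- nrow(mesh$vertices)
  Vs <- array(NA_real_, c(nv, length(depths), 3L))
  for (di in seq_along(depths)) {
    pts <- mesh$vertices - depths[di] * mesh$normals
    for (comp in 1:3) {
      Vs[, di, comp] <- interp_trilinear(field$values[, , , frame, comp],
                                         pts, field$voxel_size)
    }
  }
  a <- matrix(NA_real_, nv, 3L)
  if (cfg$fit == "quadratic_no_slip") {
    # least-squares fit of v = a d + b d^2 through the origin; the normal
    # matrix is shared by all vertices since the depths are fixed
    M <- rbind(c(sum(depths^2), sum(depths^3)),
               c(sum(depths^3), sum(depths^4)))
    Minv <- solve(M)
    for (comp in 1:3) {
      rhs1 <- as.vector(Vs[, , comp] %*% depths)
      rhs2 <- as.vector(Vs[, , comp] %*% (depths^2))
      a[, comp] <- Minv[1, 1] * rhs1 + Minv[1, 2] * rhs2
    }
  } else {
    # unconstrained quadratic v = c0 + c1 d + c2 d^2 through the interior
    # samples; pseudo-inverse shared across vertices
    D <- cbind(1, depths, depths^2)
    Pinv <- solve(crossprod(D), t(D))       # 3 x n_depths
    cc <- array(NA_real_, c(nv, 3L, 3L))    # vertex x coef x component
    for (comp in 1:3) {
      cc[, , comp] <- Vs[, , comp] %*% t(Pinv)
    }
    # no-slip point: near-wall root of the fitted speed profile
    spd <- sqrt(Vs[, , 1]^2 + Vs[, , 2]^2 + Vs[, , 3]^2)
    cs <- spd %*% t(Pinv)
    disc <- cs[, 2]^2 - 4 * cs[, 3] * cs[, 1]
    n0 <- numeric(nv)
    real_root <- !is.na(disc) & disc >= 0 & abs(cs[, 3]) > 1e-12
    sq <- sqrt(pmax(disc[real_root], 0))
    r1 <- (-cs[real_root, 2] + sq) / (2 * cs[real_root, 3])
    r2 <- (-cs[real_root, 2] - sq) / (2 * cs[real_root, 3])
    rr <- ifelse(abs(r1) <= abs(r2), r1, r2)
    # trust the re-localised wall only within one sample spacing
    rr[abs(rr) > depths[1]] <- 0
    n0[real_root] <- rr
    # linear fallback where the quadratic never vanishes
    lin <- !is.na(disc) & !real_root & abs(cs[, 2]) > 1e-12
    n0l <- -cs[lin, 1] / cs[lin, 2]
    n0l[abs(n0l) > depths[1]] <- 0
    n0[lin] <- n0l
    for (comp in 1:3) {
      a[, comp] <- cc[, 2, comp] + 2 * cc[, 3, comp] * n0
    }
  }
  # shear rate in 1/s: velocities are m/s, depths mm
  shear <- a * 1000
  # project out the normal component -> tangential WSS vector
  sn <- rowSums(shear * mesh$normals)
  wss <- cfg$mu * (shear - sn * mesh$normals)
  wss
}

#' Wall shear stress for several frames
#'
#' @param field a `velocity_field`.
#' @param mesh a `surface_mesh`.
#' @param cfg a [wss_config()].
#' @param frames frame indices (default all).
#' @return object of class `wss_map`: `frames` (list of n x 3 WSS matrices),
#'   `frame_index`, `flagged` (vertices with out-of-domain samples in any
#'   frame).
#' @export
compute_wss <- function(field, mesh, cfg = wss_config(), frames = NULL) {
  if (is.null(frames)) frames <- seq_len(field$n_frames)
  out <- lapply(frames, function(f) compute_wss_frame(field, mesh, f, cfg))
  flagged <- Reduce(`|`, lapply(out, function(m) !stats::complete.cases(m)))
  structure(list(frames = out, frame_index = frames, flagged = flagged),
            class = "wss_map")
}

#' Systolic time-averaged WSS magnitude
#'
#' Averages the per-vertex WSS magnitude over the five cardiac time frames
#' centred on peak systole. At the boundaries of the cardiac cycle the
#' window is clamped into the valid frame range (always five frames, never
#' shrunk).
#'
#' @param wss a `wss_map` whose `frames` cover the full cycle, or a plain
#'   list of n x 3 WSS matrices.
#' @param peak 1-based peak systolic frame index.
#' @return list: `wss_sys` (per-vertex mean systolic WSS magnitude, N/m^2),
#'   `window` (the frame indices averaged), `peak`.
#' @export
systolic_average <- function(wss, peak) {
  frames <- if (inherits(wss, "wss_map")) wss$frames else wss
  nf <- length(frames)
  if (nf < 5L) stop("systolic averaging needs at least 5 frames")
  start <- min(max(peak - 2L, 1L), nf - 4L)
  window <- start:(start + 4L)
  nv <- nrow(frames[[1]])
  mags <- vapply(window, function(f) vnorm_rows(frames[[f]]), numeric(nv))
  if (nv == 1L) mags <- matrix(mags, nrow = 1L)
  list(wss_sys = rowMeans(mags), window = window, peak = peak)
}

#' Area-weighted segmental mean WSS
#'
#' Averages the systolic WSS magnitude over the vertices of each of the 10
#' segments, weighting by per-vertex surface area. Flagged vertices (NA) are
#' excluded; an empty segment yields NA (missing), never zero.
#'
#' @param wss_sys per-vertex systolic WSS magnitudes.
#' @param partition a `segment_partition`.
#' @param mesh the `surface_mesh` (for vertex areas).
#' @return named numeric of length 10 (segment labels "1".."10"), with
#'   attribute `n_vertices` giving the per-segment vertex counts.
#' @export
segmental_mean_wss <- function(wss_sys, partition, mesh) {
  stopifnot(inherits(partition, "segment_partition"))
  out <- rep(NA_real_, 10L)
  nvx <- integer(10L)
  for (seg in 1:10) {
    sel <- partition$labels == seg & !is.na(wss_sys)
    nvx[seg] <- sum(sel)
    if (nvx[seg] > 0L) {
      w <- mesh$vertex_area[sel]
      out[seg] <- sum(wss_sys[sel] * w) / sum(w)
    }
  }
  names(out) <- as.character(1:10)
  attr(out, "n_vertices") <- nvx
  out
}

#' Peak systolic velocity maximum intensity projection
#'
#' Erodes the lumen mask by one voxel (6-connected structuring element) to
#' suppress wall-adjacent partial-volume voxels, takes the per-voxel maximum
#' speed over the five systolic frames, and projects the maximum along the
#' chosen axis. Regional peak systolic velocities are reported for the
#' ascending aorta (longitudinal zones 1-2), arch (zone 3) and descending
#' aorta (zones 4-5) when a zone map is supplied.
#'
#' @param field a `velocity_field`.
#' @param mask logical 3D lumen mask.
#' @param peak peak systolic frame (window of 5 frames centred here,
#'   clamped as in [systolic_average()]).
#' @param axis projection axis 1, 2 or 3 (default 2, a parasagittal view
#'   for a vessel lying in the x-z plane).
#' @param zones optional integer 3D array of longitudinal zones from
#'   `voxel_zones()`.
#' @return list: `mip` (2D array), `regional` (named speeds, m/s, for AAo,
#'   arch, DAo; NA without `zones`), `eroded_mask`, `window`.
#' @export
velocity_mip <- function(field, mask, peak, axis = 2L, zones = NULL) {
  er <- erode6(mask)
  if (!any(er)) stop("mask erosion removed all voxels")
  nf <- field$n_frames
  start <- min(max(peak - 2L, 1L), max(nf - 4L, 1L))
  window <- start:min(start + 4L, nf)
  vmax <- array(0, field$grid_shape)
  for (f in window) {
    sp <- sqrt(field$values[, , , f, 1]^2 + field$values[, , , f, 2]^2 +
               field$values[, , , f, 3]^2)
    vmax <- pmax(vmax, sp)
  }
  vmax[!er] <- 0
  mip <- apply(vmax, setdiff(1:3, axis), max)
  regional <- c(AAo = NA_real_, arch = NA_real_, DAo = NA_real_)
  if (!is.null(zones)) {
    zsel <- list(AAo = c(1L, 2L), arch = 3L, DAo = c(4L, 5L))
    for (nm in names(zsel)) {
      sel <- er & array(zones %in% zsel[[nm]], dim(zones))
      if (any(sel)) regional[nm] <- max(vmax[sel])
    }
  }
  list(mip = mip, regional = regional, eroded_mask = er, window = window)
}
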