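#' Specify a synthetic 4D flow phantom
#'
#' Defines a pulsatile tube-flow phantom (straight tube or arch-like U-bend)
#' on a regular voxel grid, together with the acquisition-style corruptions
#' to inject: Gaussian velocity noise, first-order eddy-current velocity
#' offsets, and phase wrapping at the velocity-encoding limit (venc).
#' The phantom carries analytic ground truth (lumen mask, wall shear stress,
#' flow waveform), so every downstream stage of the pipeline can be checked
#' against a closed-form oracle.
#'
#' Velocity units are m/s throughout; lengths are mm; frame times are ms.
#' Axial velocity profiles:
#' * `"poiseuille"`: steady parabolic profile `v_max * (1 - r^2/R^2)`.
#' * `"plug"`: steady uniform profile `v_max` inside the lumen (blunt flow).
#' * `"womersley"`: pulsatile profile driven by `harmonics`, a complex vector
#'   whose first element is the steady centreline amplitude (Poiseuille
#'   component) and whose k-th later element is the complex amplitude of the
#'   k-th temporal harmonic of the classical oscillatory tube-flow solution
#'   (Bessel-function radial profile).
#'
#' @param geometry `"straight_tube"` or `"u_bend_tube"` (an arch-shaped bend
#'   in the x-z plane connecting two vertical limbs).
#' @param tube_radius lumen radius R in mm; must be at least three times the
#'   largest voxel dimension.
#' @param bend_radius bend (centerline) radius in mm, U-bend only.
#' @param grid_shape integer voxel counts (x, y, z).
#' @param voxel_size voxel edge lengths in mm (length 1 or 3).
#' @param n_frames number of cardiac time frames (>= 5).
#' @param frame_duration temporal resolution in ms.
#' @param venc velocity-encoding limit in m/s (length 1 or 3, per axis).
#' @param v_profile `"poiseuille"`, `"plug"` or `"womersley"`.
#' @param v_max peak (centreline) speed in m/s for steady profiles.
#' @param harmonics complex amplitudes for `"womersley"`; see Details.
#' @param swirl_rate solid-body swirl angular rate about the local tube axis,
#'   rad/s (0 disables).
#' @param reversed_flow_patch optional `list(s_range = c(f0, f1), r_min = f)`:
#'   axial velocity is negated for arc-length fractions in `s_range` at radii
#'   `>= r_min * R`, creating a recirculation-like patch.
#' @param noise_sd Gaussian velocity noise SD in m/s (injected artifact).
#' @param eddy_coeffs 3 x 4 matrix of eddy-current offsets per velocity
#'   component: columns are offset (m/s) and spatial gradients (m/s per mm)
#'   along x, y, z; `NULL` for none.
#' @param seed integer RNG seed; equal seeds give bit-identical phantoms.
#' @param mu dynamic viscosity in Pa s used for ground-truth WSS.
#' @param rho fluid density in kg/m^3 (sets the Womersley number).
#' @param tissue_thickness static-tissue slab thickness around the lumen, in
#'   multiples of the largest voxel dimension (>= 5 so the eddy-current
#'   correction has a fitting support).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry = c("straight_tube", "u_bend_tube"),
                         tube_radius = 10,
                         bend_radius = 50,
                         grid_shape = c(40L, 40L, 40L),
                         voxel_size = c(1, 1, 1),
                         n_frames = 8L,
                         frame_duration = 40,
                         venc = 1.5,
                         v_profile = c("poiseuille", "plug", "womersley"),
                         v_max = 1.0,
                         harmonics = NULL,
                         swirl_rate = 0,
                         reversed_flow_patch = NULL,
                         noise_sd = 0,
                         eddy_coeffs = NULL,
                         seed = 1L,
                         mu = 3.2e-3,
                         rho = 1060,
                         tissue_thickness = 5) {
  geometry <- match.arg(geometry)
  v_profile <- match.arg(v_profile)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(venc) == 1L) venc <- rep(venc, 3L)
  stopifnot(length(grid_shape) == 3L, length(voxel_size) == 3L,
            length(venc) == 3L)
  if (tube_radius < 3 * max(voxel_size)) {
    stop("tube_radius is under-resolved: need tube_radius >= 3 * max(voxel_size) (",
         tube_radius, " < ", 3 * max(voxel_size), " mm)")
  }
  if (n_frames < 5L) stop("n_frames must be >= 5")
  if (any(venc <= 0)) stop("venc must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(eddy_coeffs)) {
    eddy_coeffs <- as.matrix(eddy_coeffs)
    stopifnot(nrow(eddy_coeffs) == 3L, ncol(eddy_coeffs) == 4L)
  }
  if (v_profile == "womersley" && is.null(harmonics)) {
    stop("v_profile 'womersley' requires 'harmonics'")
  }
  structure(list(
    geometry = geometry, tube_radius = tube_radius, bend_radius = bend_radius,
    grid_shape = as.integer(grid_shape), voxel_size = as.numeric(voxel_size),
    n_frames = as.integer(n_frames), frame_duration = frame_duration,
    venc = venc, v_profile = v_profile, v_max = v_max,
    harmonics = harmonics, swirl_rate = swirl_rate,
    reversed_flow_patch = reversed_flow_patch,
    noise_sd = noise_sd, eddy_coeffs = eddy_coeffs, seed = as.integer(seed),
    mu = mu, rho = rho, tissue_thickness = tissue_thickness
  ), class = "phantom_spec")
}

#' Read a phantom specification from a JSON file
#'
#' Accepts the arguments of [phantom_spec()] as JSON fields; `harmonics`
#' may be a list of `[re, im]` pairs; `eddy_coeffs` a 3 x 4 matrix (list of
#' rows).
#'
#' @param path JSON file path.
#' @return a [phantom_spec()].
#' @export
phantom_spec_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$harmonics)) {
    h <- x$harmonics
    if (is.matrix(h)) {
      x$harmonics <- complex(real = h[, 1], imaginary = h[, 2])
    } else if (is.list(h)) {
      x$harmonics <- vapply(h, function(p)
        complex(real = p[[1]], imaginary = if (length(p) > 1) p[[2]] else 0),
        complex(1))
    } else {
      x$harmonics <- as.complex(h)
    }
  }
  if (!is.null(x$eddy_coeffs)) x$eddy_coeffs <- matrix(unlist(x$eddy_coeffs),
                                                       nrow = 3, byrow = TRUE)
  if (!is.null(x$reversed_flow_patch)) {
    x$reversed_flow_patch <- as.list(x$reversed_flow_patch)
  }
  do.call(phantom_spec, x)
}

# Bessel function J0 of complex argument by power series (adequate for the
# moderate Womersley numbers of desk-scale phantoms, |z| <~ 25)
bessel_j0_complex <- function(z) {
  term <- rep(1 + 0i, length(z))
  total <- term
  zz <- -(z * z) / 4
  for (k in 1:220) {
    term <- term * zz / (k * k)
    total <- total + term
    if (max(Mod(term)) < 1e-17 * max(Mod(total))) break
  }
  total
}

# axial velocity profile as a function u(r_mm, t_ms); r may be a vector
axial_profile_fun <- function(spec) {
  R <- spec$tube_radius
  switch(spec$v_profile,
    poiseuille = function(r, t) spec$v_max * pmax(0, 1 - (r / R)^2),
    plug = function(r, t) ifelse(r <= R, spec$v_max, 0),
    womersley = {
      h <- spec$harmonics
      period_s <- spec$n_frames * spec$frame_duration / 1000
      nu <- spec$mu / spec$rho                 # kinematic viscosity, m^2/s
      R_m <- R / 1000
      n_osc <- length(h) - 1L
      phis <- vector("list", n_osc)
      omegas <- numeric(n_osc)
      betas <- complex(n_osc)
      if (n_osc > 0) {
        for (k in seq_len(n_osc)) {
          omegas[k] <- 2 * pi * k / period_s
          alpha <- R_m * sqrt(omegas[k] / nu)  # Womersley number
          betas[k] <- complex(modulus = alpha, argument = 3 * pi / 4)
        }
      }
      function(r, t) {
        inside <- r <= R
        u <- as.complex(h[1]) * pmax(0, 1 - (r / R)^2)
        u <- Re(u)
        if (n_osc > 0) {
          t_s <- t / 1000
          for (k in seq_len(n_osc)) {
            prof <- 1 - bessel_j0_complex(betas[k] * r / R) /
              bessel_j0_complex(betas[k])
            u <- u + Re(h[k + 1L] * prof * exp(1i * omegas[k] * t_s))
          }
        }
        u * inside
      }
    })
}

# ground-truth WSS magnitude (N/m^2) at the wall for each frame time, by
# numeric one-sided differentiation of the analytic profile at 1e-4 * R
phantom_truth_wss <- function(spec, times_ms) {
  if (spec$v_profile == "plug") return(rep(NA_real_, length(times_ms)))
  if (spec$v_profile == "poiseuille") {
    # analytic: 2 mu v_max / R
    return(rep(2 * spec$mu * spec$v_max / (spec$tube_radius / 1000),
               length(times_ms)))
  }
  prof <- axial_profile_fun(spec)
  R <- spec$tube_radius
  h <- 1e-4 * R
  vapply(times_ms, function(t) {
    dudr <- (prof(R - h, t) - prof(R, t)) / h   # (m/s) per mm
    spec$mu * abs(dudr) * 1000                  # Pa
  }, numeric(1))
}

# geometry of the tube: per-voxel distance to centerline, arc length,
# tangent and radial unit vectors; plus a dense analytic centerline polyline
phantom_geometry <- function(spec) {
  gs <- spec$grid_shape; vs <- spec$voxel_size
  co <- voxel_coords(gs, vs)
  X <- co$x; Y <- co$y; Z <- co$z
  cx <- gs[1] * vs[1] / 2; cy <- gs[2] * vs[2] / 2
  if (spec$geometry == "straight_tube") {
    d <- sqrt((X - cx)^2 + (Y - cy)^2)
    s <- Z
    tx <- array(0, gs); ty <- array(0, gs); tz <- array(1, gs)
    rx <- (X - cx) / pmax(d, 1e-12); ry <- (Y - cy) / pmax(d, 1e-12)
    rz <- array(0, gs)
    total_length <- gs[3] * vs[3]
    ns <- max(64L, 2L * gs[3])
    s_cl <- seq(0, total_length, length.out = ns)
    cl <- cbind(cx, cy, s_cl)
  } else {
    Rb <- spec$bend_radius
    margin <- spec$tube_radius + spec$tissue_thickness * max(vs) + max(vs)
    z1 <- gs[3] * vs[3] - margin - Rb
    if (z1 <= 2 * max(vs)) {
      stop("grid too small along z for the requested bend_radius")
    }
    xl <- cx - Rb; xr <- cx + Rb
    if (xl - margin < 0 || xr + margin > gs[1] * vs[1]) {
      stop("grid too small along x for the requested bend_radius")
    }
    L1 <- z1
    # piece 1: left (proximal, ascending) limb
    zc1 <- pmin(pmax(Z, 0), z1)
    d1 <- sqrt((X - xl)^2 + (Y - cy)^2 + (Z - zc1)^2)
    # piece 2: semicircular arch, angle phi in [0, pi] from the right limb
    phi <- atan2(Z - z1, X - cx)
    phi <- pmin(pmax(phi, 0), pi)
    px <- cx + Rb * cos(phi); pz <- z1 + Rb * sin(phi)
    d2 <- sqrt((X - px)^2 + (Y - cy)^2 + (Z - pz)^2)
    # piece 3: right (distal, descending) limb
    zc3 <- pmin(pmax(Z, 0), z1)
    d3 <- sqrt((X - xr)^2 + (Y - cy)^2 + (Z - zc3)^2)
    d <- pmin(d1, d2, d3)
    use2 <- d2 <= d1 & d2 <= d3
    use1 <- !use2 & d1 <= d3
    use3 <- !use2 & !use1
    s <- array(0, gs); tx <- array(0, gs); ty <- array(0, gs); tz <- array(0, gs)
    cpx <- array(0, gs); cpy <- array(cy, gs); cpz <- array(0, gs)
    s[use1] <- zc1[use1];                    tz[use1] <- 1
    cpx[use1] <- xl;                         cpz[use1] <- zc1[use1]
    s[use2] <- L1 + Rb * (pi - phi[use2])
    tx[use2] <- sin(phi[use2]);              tz[use2] <- -cos(phi[use2])
    cpx[use2] <- px[use2];                   cpz[use2] <- pz[use2]
    s[use3] <- L1 + pi * Rb + (z1 - zc3[use3]); tz[use3] <- -1
    cpx[use3] <- xr;                         cpz[use3] <- zc3[use3]
    rx <- (X - cpx) / pmax(d, 1e-12)
    ry <- (Y - cpy) / pmax(d, 1e-12)
    rz <- (Z - cpz) / pmax(d, 1e-12)
    total_length <- 2 * L1 + pi * Rb
    ds <- min(vs)
    s_cl <- seq(0, total_length, by = ds)
    cl <- t(vapply(s_cl, function(sv) {
      if (sv <= L1) c(xl, cy, sv)
      else if (sv <= L1 + pi * Rb) {
        ph <- pi - (sv - L1) / Rb
        c(cx + Rb * cos(ph), cy, z1 + Rb * sin(ph))
      } else c(xr, cy, z1 - (sv - L1 - pi * Rb))
    }, numeric(3)))
  }
  list(d = d, s = s, tangent = list(x = tx, y = ty, z = tz),
       radial = list(x = rx, y = ry, z = rz),
       total_length = total_length,
       centerline_points = cl, centerline_s = if (spec$geometry == "straight_tube") s_cl else s_cl)
}

#' Generate a clean synthetic 4D flow dataset
#'
#' Builds the velocity field, magnitude images and ground truth for a
#' [phantom_spec()]. The returned dataset is artifact-free; use
#' [inject_artifacts()] to add noise, eddy-current offsets and venc wrapping.
#' Generation is deterministic given the spec's seed (the seed controls the
#' magnitude-image noise; velocities are analytic).
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_dataset` with elements `field` (a
#'   `velocity_field`), `magnitude` (4D array), `truth_mask` (3D logical),
#'   `truth_wss` (per-frame wall shear stress magnitude, N/m^2; uniform over
#'   the wall for the supported profiles), `truth_waveform` (mean lumen speed
#'   per frame, m/s), `truth_params` (the spec plus injected-artifact record)
#'   and `geometry` (analytic centerline and arc-length data).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  gs <- spec$grid_shape; nt <- spec$n_frames
  geo <- phantom_geometry(spec)
  R <- spec$tube_radius
  lumen <- geo$d <= R
  tt_mm <- spec$tissue_thickness * max(spec$voxel_size)
  tissue <- geo$d > R & geo$d <= R + tt_mm
  prof <- axial_profile_fun(spec)
  times <- (seq_len(nt) - 1L) * spec$frame_duration
  vel <- array(0, c(gs, nt, 3L))
  # swirl: solid-body azimuthal speed about the local tube axis
  if (spec$swirl_rate != 0) {
    et_x <- geo$tangent$y * geo$radial$z - geo$tangent$z * geo$radial$y
    et_y <- geo$tangent$z * geo$radial$x - geo$tangent$x * geo$radial$z
    et_z <- geo$tangent$x * geo$radial$y - geo$tangent$y * geo$radial$x
    v_theta <- spec$swirl_rate * (geo$d / 1000) * lumen   # m/s
  }
  rev_mask <- NULL
  if (!is.null(spec$reversed_flow_patch)) {
    p <- spec$reversed_flow_patch
    r_min <- if (is.null(p$r_min)) 0 else p$r_min
    f <- geo$s / geo$total_length
    rev_mask <- lumen & f >= p$s_range[1] & f <= p$s_range[2] &
      geo$d >= r_min * R
  }
  waveform <- numeric(nt)
  for (f in seq_len(nt)) {
    ax <- array(0, gs)
    ax[lumen] <- prof(geo$d[lumen], times[f])
    if (!is.null(rev_mask)) ax[rev_mask] <- -ax[rev_mask]
    vx <- ax * geo$tangent$x
    vy <- ax * geo$tangent$y
    vz <- ax * geo$tangent$z
    if (spec$swirl_rate != 0) {
      vx <- vx + v_theta * et_x
      vy <- vy + v_theta * et_y
      vz <- vz + v_theta * et_z
    }
    vel[, , , f, 1] <- vx; vel[, , , f, 2] <- vy; vel[, , , f, 3] <- vz
    waveform[f] <- mean(sqrt(vx[lumen]^2 + vy[lumen]^2 + vz[lumen]^2))
  }
  mag <- array(0, c(gs, nt))
  base <- array(5, gs)
  base[lumen | tissue] <- 100
  for (f in seq_len(nt)) {
    mag[, , , f] <- pmax(0, base + array(stats::rnorm(prod(gs), sd = 1), gs))
  }
  field <- structure(list(
    values = vel, voxel_size = spec$voxel_size,
    frame_duration = spec$frame_duration, venc = spec$venc,
    grid_shape = gs, n_frames = nt
  ), class = "velocity_field")
  structure(list(
    field = field, magnitude = mag,
    truth_mask = lumen, tissue_mask = tissue,
    truth_wss = phantom_truth_wss(spec, times),
    truth_waveform = waveform,
    truth_params = list(spec = spec, artifacts_injected = FALSE),
    geometry = list(centerline_points = geo$centerline_points,
                    centerline_s = geo$centerline_s,
                    total_length = geo$total_length,
                    tube_radius = R, d = geo$d, s = geo$s)
  ), class = "phantom_dataset")
}

# phase wrap into [-venc, venc); values already in range pass through
# untouched so an artifact-free injection is bit-identical
wrap_velocity <- function(v, venc) {
  out <- v
  wrapped <- v >= venc | v < -venc
  out[wrapped] <- ((v[wrapped] + venc) %% (2 * venc)) - venc
  out
}

#' Inject acquisition artifacts into a phantom dataset
#'
#' Applies, per velocity component, the forward corruption model
#' `stored = wrap(v_true + eddy(x, y, z) + noise)`, where `eddy` is a
#' first-order spatial polynomial (identical across frames), `noise` is iid
#' Gaussian with SD `noise_sd`, and `wrap(v) = ((v + venc) mod 2 venc) - venc`
#' aliases velocities beyond the velocity-encoding limit. With zero noise and
#' zero eddy coefficients, wrap-free voxels are returned bit-identical.
#'
#' @param data a `phantom_dataset` from [make_phantom()].
#' @param spec the [phantom_spec()]; its `noise_sd` and `eddy_coeffs` define
#'   the injected artifacts and its `seed` (offset by one) the noise draw.
#' @return the dataset with corrupted `field` and the injected parameters
#'   recorded in `truth_params`.
#' @export
inject_artifacts <- function(data, spec) {
  stopifnot(inherits(data, "phantom_dataset"))
  set.seed(spec$seed + 1L)
  vel <- data$field$values
  gs <- spec$grid_shape; nt <- spec$n_frames
  co <- voxel_coords(gs, spec$voxel_size)
  for (comp in 1:3) {
    eddy <- array(0, gs)
    if (!is.null(spec$eddy_coeffs)) {
      b <- spec$eddy_coeffs[comp, ]
      eddy <- b[1] + b[2] * co$x + b[3] * co$y + b[4] * co$z
    }
    for (f in seq_len(nt)) {
      v <- vel[, , , f, comp] + eddy
      if (spec$noise_sd > 0) {
        v <- v + array(stats::rnorm(prod(gs), sd = spec$noise_sd), gs)
      }
      vel[, , , f, comp] <- wrap_velocity(v, spec$venc[comp])
    }
  }
  data$field$values <- vel
  data$truth_params <- list(spec = spec, artifacts_injected = TRUE,
                            eddy_coeffs = spec$eddy_coeffs,
                            noise_sd = spec$noise_sd)
  data
}
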