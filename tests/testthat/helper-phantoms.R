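# Shared small phantoms for the test suite. Sizes are kept small so each
# file runs in seconds; the acceptance tests use the full study geometries.

poiseuille_phantom <- function(vox_per_diam = 16, R = 10, v_max = 1,
                               n_frames = 5L, seed = 1L, venc = 1.5,
                               length_mm = 40, ...) {
  vs <- 2 * R / vox_per_diam
  nxy <- ceiling((2 * R + 14 * vs) / vs / 2) * 2
  nz <- max(12L, round(length_mm / vs))
  spec <- phantom_spec(grid_shape = c(nxy, nxy, nz), voxel_size = vs,
                       tube_radius = R, v_max = v_max, n_frames = n_frames,
                       venc = venc, seed = seed, ...)
  list(spec = spec, ph = make_phantom(spec))
}

plug_phantom <- function(R = 9, v_max = 1, n_frames = 5L, seed = 7L, ...) {
  spec <- phantom_spec(grid_shape = c(40L, 40L, 28L), voxel_size = 1,
                       tube_radius = R, v_profile = "plug", v_max = v_max,
                       n_frames = n_frames, seed = seed, ...)
  list(spec = spec, ph = make_phantom(spec))
}

# dynamically scaled pulsatile phantom (Womersley number ~ 3) so the
# oscillatory boundary layer is resolved on a 1 mm grid
womersley_phantom <- function(harmonics = c(0.6 + 0i, 0.25 - 0.1i),
                              n_frames = 16L, frame_duration = 1250,
                              seed = 4L, ...) {
  spec <- phantom_spec(grid_shape = c(44L, 44L, 24L), voxel_size = 1,
                       tube_radius = 10, v_profile = "womersley",
                       harmonics = harmonics, n_frames = n_frames,
                       frame_duration = frame_duration, seed = seed, ...)
  list(spec = spec, ph = make_phantom(spec))
}

# moderately pulsatile phantom at acquisition-like timing, for preprocessing
# tests (static-tissue detection needs pulsatile lumen flow)
pulsatile_phantom <- function(seed = 5L, noise_sd = 0, eddy_coeffs = NULL,
                              grid = c(32L, 32L, 24L), R = 8) {
  spec <- phantom_spec(grid_shape = grid, voxel_size = 1, tube_radius = R,
                       v_profile = "womersley",
                       harmonics = c(0.5 + 0i, 0.4 + 0i), n_frames = 8L,
                       frame_duration = 40, noise_sd = noise_sd,
                       eddy_coeffs = eddy_coeffs, seed = seed)
  list(spec = spec, ph = make_phantom(spec))
}

swirl_phantom <- function(omega, w = 0.3, seed = 11L, ...) {
  spec <- phantom_spec(grid_shape = c(32L, 32L, 40L), voxel_size = 1,
                       tube_radius = 8, v_profile = "plug", v_max = w,
                       swirl_rate = omega, n_frames = 5L,
                       frame_duration = 40, seed = seed, ...)
  list(spec = spec, ph = make_phantom(spec))
}

ubend_phantom <- function(seed = 9L, ...) {
  spec <- phantom_spec(geometry = "u_bend_tube",
                       grid_shape = c(100L, 30L, 76L), voxel_size = 1.25,
                       tube_radius = 8, bend_radius = 25,
                       v_profile = "plug", v_max = 0.8, n_frames = 5L,
                       seed = seed, ...)
  list(spec = spec, ph = make_phantom(spec))
}

dice_overlap <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
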