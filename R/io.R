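# File I/O: NIfTI volumes for velocity/magnitude/masks, an ASCII PLY mesh
# with per-vertex scalars, and JSON sidecars for metadata. Layout follows a
# common 4D-flow convention: one 4D magnitude file plus three 4D velocity
# component files (vx, vy, vz), with venc, frame duration and axis mapping
# declared in a JSON sidecar.

#' Write a phantom dataset to a directory
#'
#' Writes `mag.nii.gz`, `vx.nii.gz`, `vy.nii.gz`, `vz.nii.gz` (4D),
#' `truth_mask.nii.gz` (3D) and `meta.json` (venc, frame duration, voxel
#' size, axis mapping, truth parameters).
#'
#' @param data a `phantom_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_flow_dataset <- function(data, dir) {
  stopifnot(inherits(data, "phantom_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- data$field$voxel_size
  wr <- function(arr, name) {
    img <- RNifti::asNifti(arr, pixdim = c(vs, data$field$frame_duration)[
      seq_len(length(dim(arr)))])
    RNifti::writeNifti(img, file.path(dir, name))
  }
  wr(data$magnitude, "mag.nii.gz")
  for (comp in 1:3) {
    wr(data$field$values[, , , , comp], paste0("v", c("x", "y", "z")[comp],
                                               ".nii.gz"))
  }
  wr(array(as.integer(data$truth_mask), dim(data$truth_mask)),
     "truth_mask.nii.gz")
  spec <- data$truth_params$spec
  meta <- list(
    venc = data$field$venc, frame_duration_ms = data$field$frame_duration,
    voxel_size_mm = vs, grid_shape = data$field$grid_shape,
    n_frames = data$field$n_frames,
    component_axes = c("x", "y", "z"), component_sign = c(1, 1, 1),
    truth_wss = data$truth_wss, truth_waveform = data$truth_waveform,
    geometry = spec$geometry, tube_radius = spec$tube_radius,
    seed = spec$seed, noise_sd = spec$noise_sd,
    eddy_coeffs = spec$eddy_coeffs
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Read a 4D-flow dataset directory
#'
#' Reads the layout written by [write_flow_dataset()] back into a
#' `velocity_field` plus magnitude (and truth mask if present).
#'
#' @param dir dataset directory.
#' @return list with `field`, `magnitude`, `truth_mask` (or NULL), `meta`.
#' @export
read_flow_dataset <- function(dir) {
  need <- c("mag.nii.gz", "vx.nii.gz", "vy.nii.gz", "vz.nii.gz", "meta.json")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) {
      stop("missing input file: ", file.path(dir, f))
    }
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  mag <- array(as.numeric(RNifti::readNifti(file.path(dir, "mag.nii.gz"))),
               dim = c(meta$grid_shape, meta$n_frames))
  vals <- array(0, c(meta$grid_shape, meta$n_frames, 3L))
  for (comp in 1:3) {
    vals[, , , , comp] <- as.numeric(
      RNifti::readNifti(file.path(dir, paste0("v", c("x", "y", "z")[comp],
                                              ".nii.gz"))))
  }
  field <- structure(list(
    values = vals, voxel_size = as.numeric(meta$voxel_size_mm),
    frame_duration = meta$frame_duration_ms,
    venc = as.numeric(meta$venc),
    grid_shape = as.integer(meta$grid_shape),
    n_frames = as.integer(meta$n_frames)
  ), class = "velocity_field")
  tm_path <- file.path(dir, "truth_mask.nii.gz")
  truth_mask <- if (file.exists(tm_path)) {
    array(as.numeric(RNifti::readNifti(tm_path)) > 0.5, meta$grid_shape)
  } else NULL
  list(field = field, magnitude = mag, truth_mask = truth_mask, meta = meta)
}

#' Write a surface mesh as ASCII PLY
#'
#' Stores vertices, outward normals, optional per-vertex scalar
#' (`wss_sys`) and segment labels, and the triangle list.
#'
#' @param mesh a `surface_mesh`.
#' @param path output file path.
#' @param wss_sys optional per-vertex scalar (N/m^2).
#' @param labels optional per-vertex integer segment labels.
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path, wss_sys = NULL, labels = NULL) {
  nv <- nrow(mesh$vertices)
  nt <- nrow(mesh$triangles)
  props <- c("property float x", "property float y", "property float z",
             "property float nx", "property float ny", "property float nz")
  cols <- cbind(mesh$vertices, mesh$normals)
  if (!is.null(wss_sys)) {
    props <- c(props, "property float wss_sys")
    cols <- cbind(cols, wss_sys)
  }
  if (!is.null(labels)) {
    props <- c(props, "property int segment")
    cols <- cbind(cols, labels)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nv), props,
               paste("element face", nt),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(cols, digits = 7, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(cbind(3L, mesh$triangles - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a centerline as CSV
#'
#' Columns: x, y, z (mm), arclen (mm), curvature magnitude (1/mm).
#'
#' @param centerline a `centerline`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_centerline_csv <- function(centerline, path) {
  df <- data.frame(x = centerline$points[, 1], y = centerline$points[, 2],
                   z = centerline$points[, 3], arclen = centerline$s,
                   curvature = vnorm_rows(centerline$curvature))
  utils::write.csv(format(df, digits = 8, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
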