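# Ten-segment regional partition of the aortic surface. Five consecutive
# longitudinal zones (proximal/distal ascending aorta, arch, proximal/distal
# descending aorta) are delimited by arc-length landmarks along the
# centerline; each zone except the arch is split into an inner (concave,
# toward the centre of curvature) and an outer half, giving the labels
#  1 proximal inner AAo   2 proximal outer AAo
#  3 distal inner AAo     4 distal outer AAo
#  5 inner arch           6 outer arch
#  7 proximal inner DAo   8 proximal outer DAo
#  9 distal inner DAo    10 distal outer DAo

# nearest centerline sample for each query point (n x 3); returns indices
nearest_centerline_point <- function(points, centerline) {
  cp <- centerline$points
  n <- nrow(points)
  out <- integer(n)
  # block-wise distance computation to bound memory
  blk <- 20000L
  for (start in seq(1L, n, by = blk)) {
    sel <- start:min(n, start + blk - 1L)
    d2 <- outer(rowSums(points[sel, , drop = FALSE]^2), rowSums(cp^2), "+") -
      2 * points[sel, , drop = FALSE] %*% t(cp)
    out[sel] <- max.col(-d2, ties.method = "first")
  }
  out
}

# global reference for inner/outer in near-straight regions: the centre of
# curvature at the arch apex (maximal curvature in the middle of the vessel)
arch_curvature_center <- function(centerline) {
  n <- nrow(centerline$points)
  mid <- which(centerline$s >= 0.3 * centerline$length &
               centerline$s <= 0.7 * centerline$length)
  if (length(mid) == 0L) mid <- seq_len(n)
  km <- vnorm_rows(centerline$curvature[mid, , drop = FALSE])
  apex <- mid[which.max(km)]
  kv <- centerline$curvature[apex, ]
  k2 <- sum(kv^2)
  if (k2 < 1e-12) return(NULL)   # essentially straight vessel
  centerline$points[apex, ] + kv / k2
}

#' Partition a vessel surface into the 10 aortic segments
#'
#' Maps every mesh vertex to its nearest centerline point; the arc-length
#' fraction between the configured proximal and distal ends assigns one of
#' five longitudinal zones (landmarks are arc-length fractions), and the
#' inner/outer dichotomy follows the sign of the dot product between the
#' vertex offset (perpendicular to the tangent) and the local curvature
#' vector - offsets toward the centre of curvature are "inner". Where the
#' local curvature is too small to be directional (near-straight segments),
#' the direction toward the arch's centre of curvature is used instead.
#' Vertices outside the configured ends stay unassigned (label 0), which
#' keeps the artificial end caps of an open tube out of the regional means.
#'
#' @param mesh a `surface_mesh`.
#' @param centerline a `centerline`.
#' @param landmarks four increasing arc-length fractions delimiting the five
#'   longitudinal zones (default `c(0.2, 0.4, 0.6, 0.8)`, i.e. equal zones).
#' @param ends arc-length fractions of the proximal and distal analysis
#'   boundaries (default `c(0.02, 0.98)`).
#' @param curvature_frac local-curvature magnitudes below this fraction of
#'   the arch apex curvature fall back to the global arch reference
#'   (default 0.2).
#' @return object of class `segment_partition`: `labels` (integer per
#'   vertex, 0 = unassigned), `zone` (longitudinal zone 1..5, 0 =
#'   unassigned), `inner` (logical), `landmarks`, `ends`.
#' @export
partition_segments <- function(mesh, centerline,
                               landmarks = c(0.2, 0.4, 0.6, 0.8),
                               ends = c(0.02, 0.98),
                               curvature_frac = 0.2) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(centerline, "centerline"))
  if (length(landmarks) != 4L || any(diff(landmarks) <= 0) ||
      landmarks[1] <= 0 || landmarks[4] >= 1) {
    stop("landmarks must be four increasing fractions strictly inside (0,1)")
  }
  ni <- nearest_centerline_point(mesh$vertices, centerline)
  s <- centerline$s[ni]
  f <- (s - ends[1] * centerline$length) /
    ((ends[2] - ends[1]) * centerline$length)
  zone <- findInterval(f, c(landmarks, 1)) + 1L
  zone[f < 0 | f > 1] <- 0L
  # inner/outer classification
  off <- mesh$vertices - centerline$points[ni, , drop = FALSE]
  tg <- centerline$tangent[ni, , drop = FALSE]
  off_p <- off - rowSums(off * tg) * tg
  kv <- centerline$curvature[ni, , drop = FALSE]
  km <- vnorm_rows(kv)
  mid <- which(centerline$s >= 0.3 * centerline$length &
               centerline$s <= 0.7 * centerline$length)
  k_ref <- max(vnorm_rows(centerline$curvature[mid, , drop = FALSE]))
  ctr <- arch_curvature_center(centerline)
  use_local <- km >= curvature_frac * k_ref & k_ref > 1e-9
  inner <- logical(nrow(mesh$vertices))
  inner[use_local] <- rowSums(off_p[use_local, , drop = FALSE] *
                              kv[use_local, , drop = FALSE]) > 0
  if (any(!use_local)) {
    if (is.null(ctr)) {
      # straight vessel: no anatomic inner side; use a fixed reference axis
      ref <- c(1, 0, 0)
      dirs <- matrix(ref, sum(!use_local), 3, byrow = TRUE)
    } else {
      dirs <- sweep(-centerline$points[ni[!use_local], , drop = FALSE], 2,
                    ctr, "+")   # ctr - point
    }
    inner[!use_local] <- rowSums(off_p[!use_local, , drop = FALSE] * dirs) > 0
  }
  base <- c(1L, 3L, 5L, 7L, 9L)
  labels <- integer(nrow(mesh$vertices))
  assigned <- zone > 0L
  labels[assigned] <- base[zone[assigned]] + ifelse(inner[assigned], 0L, 1L)
  # the arch is not split: 5 = inner arch, 6 = outer arch (already encoded)
  structure(list(labels = labels, zone = zone, inner = inner,
                 landmarks = landmarks, ends = ends),
            class = "segment_partition")
}

# longitudinal zone (1..5, 0 = outside ends) for every voxel of a mask,
# by nearest centerline point; used for regional peak-velocity analysis
voxel_zones <- function(mask, voxel_size, centerline,
                        landmarks = c(0.2, 0.4, 0.6, 0.8),
                        ends = c(0.02, 0.98)) {
  gs <- dim(mask)
  co <- voxel_coords(gs, voxel_size)
  idx <- which(mask)
  pts <- cbind(co$x[idx], co$y[idx], co$z[idx])
  ni <- nearest_centerline_point(pts, centerline)
  f <- (centerline$s[ni] - ends[1] * centerline$length) /
    ((ends[2] - ends[1]) * centerline$length)
  zone <- findInterval(f, c(landmarks, 1)) + 1L
  zone[f < 0 | f > 1] <- 0L
  out <- array(0L, gs)
  out[idx] <- zone
  out
}
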