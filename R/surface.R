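# Surface extraction: marching tetrahedra on a smoothed binary occupancy
# field. The mask is zero-padded (so surfaces touching the grid border are
# capped and closed), smoothed with a separable (1,2,1)/4 kernel, and
# contoured at the 0.5 level; each grid cell is split into six tetrahedra
# sharing the main diagonal. Vertex positions come from linear interpolation
# along cell edges, giving sub-voxel wall placement; outward normals come
# from the (negated) field gradient.

# cube corner offsets, ids 1..8 (classic 0..7 ordering)
mt_corner_offsets <- rbind(
  c(0L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 1L, 0L),
  c(0L, 0L, 1L), c(1L, 0L, 1L), c(1L, 1L, 1L), c(0L, 1L, 1L))

# six tetrahedra sharing the 1-7 diagonal (1-based corner ids)
mt_tets <- rbind(
  c(1L, 2L, 3L, 7L), c(1L, 3L, 4L, 7L), c(1L, 4L, 8L, 7L),
  c(1L, 8L, 5L, 7L), c(1L, 5L, 6L, 7L), c(1L, 6L, 2L, 7L))

# case table for one tetrahedron: for each of the 16 inside/outside masks,
# triangles given as (cornerU, cornerV) pairs (local slots 1..4) per vertex
mt_case_table <- local({
  tab <- vector("list", 16L)
  for (m in 0:15) {
    inside <- which(bitwAnd(m, c(1L, 2L, 4L, 8L)) != 0L)
    outside <- setdiff(1:4, inside)
    tris <- NULL
    if (length(inside) == 1L || length(inside) == 3L) {
      v <- if (length(inside) == 1L) inside else outside
      o <- setdiff(1:4, v)
      tris <- matrix(c(v, o[1], v, o[2], v, o[3]), nrow = 1L)
    } else if (length(inside) == 2L) {
      a <- inside[1]; b <- inside[2]; o1 <- outside[1]; o2 <- outside[2]
      # quad corners in cyclic order: (a,o1), (a,o2), (b,o2), (b,o1)
      tris <- rbind(c(a, o1, a, o2, b, o2),
                    c(a, o1, b, o2, b, o1))
    }
    tab[[m + 1L]] <- tris
  }
  tab
})

#' Extract the wall surface of a lumen mask
#'
#' Builds a closed, oriented triangle mesh of the mask boundary by marching
#' tetrahedra on the zero-padded, binomially smoothed occupancy field at the
#' 0.5 level. Outward unit normals are taken from the negated field gradient
#' (the field is high inside); per-vertex areas are one third of the incident
#' triangle areas.
#'
#' @param mask logical 3D array.
#' @param voxel_size voxel edge lengths, mm (length 1 or 3).
#' @param smooth_passes passes of the separable (1,2,1)/4 kernel applied to
#'   the occupancy field before contouring (default 1).
#' @return object of class `surface_mesh`: `vertices` (n x 3, mm),
#'   `triangles` (m x 3 indices, outward-oriented), `normals` (n x 3 outward
#'   unit vectors), `vertex_area` (mm^2), `area` (total mm^2).
#' @export
extract_surface <- function(mask, voxel_size = c(1, 1, 1), smooth_passes = 1L) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(dim(mask)) == 3L, any(mask))
  d0 <- dim(mask)
  dp <- d0 + 2L
  fld <- array(0, dp)
  fld[2:(d0[1] + 1L), 2:(d0[2] + 1L), 2:(d0[3] + 1L)] <- as.numeric(mask)
  fld <- smooth121(fld, passes = smooth_passes)
  level <- 0.5 - 1e-7   # tie-break: corners exactly at 0.5 count as inside
  # world coordinate of padded voxel index i is (i - 1.5) * voxel_size
  nx <- dp[1]; ny <- dp[2]; nz <- dp[3]
  inside <- fld > level
  # active cells: base corner (i,j,k), i < nx etc., where corner states differ
  cs <- inside[1:(nx - 1), 1:(ny - 1), 1:(nz - 1)]
  n_in <- array(0L, dim(cs))
  for (c_id in 1:8) {
    off <- mt_corner_offsets[c_id, ]
    n_in <- n_in + inside[(1 + off[1]):(nx - 1 + off[1]),
                          (1 + off[2]):(ny - 1 + off[2]),
                          (1 + off[3]):(nz - 1 + off[3])]
  }
  act <- which(n_in > 0L & n_in < 8L)
  if (length(act) == 0L) stop("no surface found at the 0.5 level")
  dc <- dim(cs)
  ai <- ((act - 1L) %% dc[1]) + 1L
  aj <- (((act - 1L) %/% dc[1]) %% dc[2]) + 1L
  ak <- ((act - 1L) %/% (dc[1] * dc[2])) + 1L
  # global (padded) linear index of each cube corner for the active cells
  corner_lin <- function(c_id) {
    off <- mt_corner_offsets[c_id, ]
    (ai + off[1]) + (aj + off[2] - 1L) * nx + (ak + off[3] - 1L) * nx * ny
  }
  glin <- vapply(1:8, corner_lin, integer(length(act)))
  if (length(act) == 1L) glin <- matrix(glin, nrow = 1L)
  fvals <- matrix(fld[glin], nrow = length(act))
  ins <- fvals > level
  ekeys <- character(0)
  e_a <- integer(0); e_b <- integer(0)   # corner linear ids per edge
  tri_edge <- integer(0)                 # per triangle-vertex: edge row id
  # accumulate edges and triangles over tets and cases
  edge_env <- new.env(parent = emptyenv())
  all_u <- list(); all_v <- list(); nblk <- 0L
  for (t_id in 1:6) {
    slots <- mt_tets[t_id, ]
    m4 <- 1L * ins[, slots[1]] + 2L * ins[, slots[2]] +
      4L * ins[, slots[3]] + 8L * ins[, slots[4]]
    for (cv in 1:14) {
      tris <- mt_case_table[[cv + 1L]]
      if (is.null(tris)) next
      sel <- which(m4 == cv)
      if (length(sel) == 0L) next
      for (r in seq_len(nrow(tris))) {
        nblk <- nblk + 1L
        uu <- matrix(0L, length(sel), 3L)
        vv <- matrix(0L, length(sel), 3L)
        for (vtx in 1:3) {
          su <- slots[tris[r, 2L * vtx - 1L]]
          sv <- slots[tris[r, 2L * vtx]]
          uu[, vtx] <- glin[sel, su]
          vv[, vtx] <- glin[sel, sv]
        }
        all_u[[nblk]] <- uu
        all_v[[nblk]] <- vv
      }
    }
  }
  U <- do.call(rbind, all_u)   # n_tri x 3 corner ids (inside end)
  V <- do.call(rbind, all_v)
  lo <- pmin(U, V); hi <- pmax(U, V)
  key <- as.vector(lo) + as.vector(hi) * (as.double(nx) * ny * nz + 1)
  uk <- unique(key)
  vid <- match(key, uk)
  tri <- matrix(vid, ncol = 3L)
  # interpolated vertex position for each unique edge
  first <- match(uk, key)
  ua <- as.vector(U)[first]; vb <- as.vector(V)[first]
  fa <- fld[ua]; fb <- fld[vb]
  tt <- (level - fa) / (fb - fa)
  to_xyz <- function(lin) {
    i <- ((lin - 1L) %% nx) + 1L
    j <- (((lin - 1L) %/% nx) %% ny) + 1L
    k <- ((lin - 1L) %/% (nx * ny)) + 1L
    cbind((i - 1.5) * voxel_size[1], (j - 1.5) * voxel_size[2],
          (k - 1.5) * voxel_size[3])
  }
  pa <- to_xyz(ua); pb <- to_xyz(vb)
  verts <- pa + tt * (pb - pa)
  # drop degenerate triangles (repeated vertex ids)
  degen <- tri[, 1] == tri[, 2] | tri[, 2] == tri[, 3] | tri[, 1] == tri[, 3]
  tri <- tri[!degen, , drop = FALSE]
  # orient triangles outward using the field gradient (high inside)
  grad <- gradient3(fld, voxel_size)
  centroids <- (verts[tri[, 1], ] + verts[tri[, 2], ] + verts[tri[, 3], ]) / 3
  gx <- interp_trilinear(grad$x, centroids, voxel_size)
  gy <- interp_trilinear(grad$y, centroids, voxel_size)
  gz <- interp_trilinear(grad$z, centroids, voxel_size)
  tn <- cross3(verts[tri[, 2], , drop = FALSE] - verts[tri[, 1], , drop = FALSE],
               verts[tri[, 3], , drop = FALSE] - verts[tri[, 1], , drop = FALSE])
  flip <- (tn[, 1] * gx + tn[, 2] * gy + tn[, 3] * gz) > 0
  flip[is.na(flip)] <- FALSE
  tmp <- tri[flip, 2]; tri[flip, 2] <- tri[flip, 3]; tri[flip, 3] <- tmp
  # vertex normals: negated unit gradient at the vertex positions
  vgx <- interp_trilinear(grad$x, verts, voxel_size)
  vgy <- interp_trilinear(grad$y, verts, voxel_size)
  vgz <- interp_trilinear(grad$z, verts, voxel_size)
  nrm <- -cbind(vgx, vgy, vgz)
  nn <- vnorm_rows(nrm)
  bad <- !is.finite(nn) | nn < 1e-12
  if (any(bad)) {
    # fall back to area-weighted triangle normals for rare flat-gradient spots
    acc <- matrix(0, nrow(verts), 3L)
    tn2 <- cross3(verts[tri[, 2], , drop = FALSE] - verts[tri[, 1], , drop = FALSE],
                  verts[tri[, 3], , drop = FALSE] - verts[tri[, 1], , drop = FALSE])
    for (cc in 1:3) {
      for (corner in 1:3) {
        acc[, cc] <- acc[, cc] +
          as.vector(tapply(tn2[, cc], tri[, corner], sum)[
            match(seq_len(nrow(verts)), sort(unique(tri[, corner])))])
      }
    }
    acc[is.na(acc)] <- 0
    nrm[bad, ] <- acc[bad, ]
    nn <- vnorm_rows(nrm)
    nn[nn < 1e-12] <- 1
  }
  nrm <- nrm / nn
  # areas
  tn <- cross3(verts[tri[, 2], , drop = FALSE] - verts[tri[, 1], , drop = FALSE],
               verts[tri[, 3], , drop = FALSE] - verts[tri[, 1], , drop = FALSE])
  tri_area <- 0.5 * vnorm_rows(tn)
  va <- numeric(nrow(verts))
  for (corner in 1:3) {
    s <- tapply(tri_area / 3, tri[, corner], sum)
    va[as.integer(names(s))] <- va[as.integer(names(s))] + as.vector(s)
  }
  # manifold check: every undirected edge must border exactly two triangles
  eu <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  ek <- pmin(eu[, 1], eu[, 2]) + pmax(eu[, 1], eu[, 2]) * (nrow(verts) + 1)
  cnt <- table(ek)
  if (any(cnt != 2L)) {
    stop("extracted surface is not a closed manifold (",
         sum(cnt != 2L), " problem edges)")
  }
  structure(list(vertices = verts, triangles = tri, normals = nrm,
                 vertex_area = va, area = sum(tri_area)),
            class = "surface_mesh")
}

#' Euler characteristic of a surface mesh
#'
#' `V - E + F`; equals 2 for a closed surface of genus zero.
#'
#' @param mesh a `surface_mesh`.
#' @return integer.
#' @export
mesh_euler_characteristic <- function(mesh) {
  tri <- mesh$triangles
  eu <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  ek <- pmin(eu[, 1], eu[, 2]) + pmax(eu[, 1], eu[, 2]) *
    (nrow(mesh$vertices) + 1)
  nrow(mesh$vertices) - length(unique(ek)) + nrow(tri)
}
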