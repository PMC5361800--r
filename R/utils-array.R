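# Internal voxel-grid helpers: axis shifts, separable smoothing, 6-connected
# morphology, connected components, trilinear sampling and finite-difference
# gradients. All grids are axis-aligned; voxel centre of 1-based index
# (i, j, k) sits at world coordinate ((i, j, k) - 0.5) * voxel_size in mm.

ax_shift <- function(a, axis, by, fill = 0) {
  d <- dim(a)
  if (by == 0L) return(a)
  out <- array(fill, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  idx <- lapply(d, seq_len)
  src <- idx
  dst <- idx
  if (by > 0) {
    dst[[axis]] <- (by + 1L):n
    src[[axis]] <- 1L:(n - by)
  } else {
    dst[[axis]] <- 1L:(n + by)
    src[[axis]] <- (1L - by):n
  }
  val <- do.call(`[`, c(list(a), src, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), dst, list(val)))
}

# (1, 2, 1)/4 binomial smoothing applied separably along the first three axes
smooth121 <- function(a, passes = 1L) {
  for (p in seq_len(passes)) {
    for (ax in 1:3) {
      a <- (ax_shift(a, ax, 1L, 0) + 2 * a + ax_shift(a, ax, -1L, 0)) / 4
    }
  }
  a
}

neighbours6 <- function(a, fill) {
  list(
    ax_shift(a, 1L,  1L, fill), ax_shift(a, 1L, -1L, fill),
    ax_shift(a, 2L,  1L, fill), ax_shift(a, 2L, -1L, fill),
    ax_shift(a, 3L,  1L, fill), ax_shift(a, 3L, -1L, fill)
  )
}

erode6 <- function(mask) {
  nb <- neighbours6(mask, FALSE)
  mask & nb[[1]] & nb[[2]] & nb[[3]] & nb[[4]] & nb[[5]] & nb[[6]]
}

dilate6 <- function(mask) {
  nb <- neighbours6(mask, FALSE)
  mask | nb[[1]] | nb[[2]] | nb[[3]] | nb[[4]] | nb[[5]] | nb[[6]]
}

close6 <- function(mask) erode6(dilate6(mask))

# integer erosion depth: 1 at boundary voxels, increasing inwards
erosion_depth <- function(mask) {
  depth <- array(0L, dim(mask))
  cur <- mask
  it <- 0L
  while (any(cur)) {
    it <- it + 1L
    depth[cur] <- it
    cur <- erode6(cur)
    if (it > max(dim(mask))) stop("erosion_depth failed to terminate")
  }
  depth
}

flood_fill6 <- function(mask, seed_index) {
  comp <- array(FALSE, dim(mask))
  comp[seed_index] <- TRUE
  repeat {
    grown <- dilate6(comp) & mask
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  comp
}

# keep only the largest 6-connected component of a logical array
largest_component6 <- function(mask) {
  best <- NULL
  best_n <- 0L
  remaining <- mask
  while (any(remaining)) {
    seed <- which(remaining)[1L]
    comp <- flood_fill6(remaining, seed)
    n <- sum(comp)
    if (n > best_n) {
      best <- comp
      best_n <- n
    }
    remaining <- remaining & !comp
  }
  if (is.null(best)) array(FALSE, dim(mask)) else best
}

n_components6 <- function(mask) {
  n <- 0L
  remaining <- mask
  while (any(remaining)) {
    comp <- flood_fill6(remaining, which(remaining)[1L])
    remaining <- remaining & !comp
    n <- n + 1L
  }
  n
}

# Otsu's bimodal threshold on a numeric vector
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) <= 0) stop("otsu_threshold: constant input")
  h <- hist(x, breaks = seq(r[1], r[2], length.out = nbins + 1L), plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, length(p))
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  mids[which.max(sigma_b)]
}

# world coordinates (mm) of every voxel centre, as three arrays
voxel_coords <- function(grid_shape, voxel_size) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  xs <- (seq_len(nx) - 0.5) * voxel_size[1]
  ys <- (seq_len(ny) - 0.5) * voxel_size[2]
  zs <- (seq_len(nz) - 0.5) * voxel_size[3]
  list(
    x = array(rep(xs, times = ny * nz), dim = grid_shape),
    y = array(rep(rep(ys, each = nx), times = nz), dim = grid_shape),
    z = array(rep(zs, each = nx * ny), dim = grid_shape)
  )
}

# trilinear interpolation of a 3D volume at world points (n x 3, mm).
# Points whose 8-voxel support leaves the grid return NA.
interp_trilinear <- function(vol, pts, voxel_size) {
  d <- dim(vol)
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  u <- sweep(pts, 2, voxel_size, "/") + 0.5  # continuous 1-based voxel index
  i0 <- floor(u)
  f <- u - i0
  ok <- is.finite(i0[, 1]) & is.finite(i0[, 2]) & is.finite(i0[, 3]) &
        i0[, 1] >= 1 & i0[, 1] < d[1] &
        i0[, 2] >= 1 & i0[, 2] < d[2] &
        i0[, 3] >= 1 & i0[, 3] < d[3]
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  i <- i0[ok, 1]; j <- i0[ok, 2]; k <- i0[ok, 3]
  fx <- f[ok, 1]; fy <- f[ok, 2]; fz <- f[ok, 3]
  lin <- function(ii, jj, kk) vol[ii + (jj - 1L) * d[1] + (kk - 1L) * d[1] * d[2]]
  v000 <- lin(i,     j,     k)
  v100 <- lin(i + 1, j,     k)
  v010 <- lin(i,     j + 1, k)
  v110 <- lin(i + 1, j + 1, k)
  v001 <- lin(i,     j,     k + 1)
  v101 <- lin(i + 1, j,     k + 1)
  v011 <- lin(i,     j + 1, k + 1)
  v111 <- lin(i + 1, j + 1, k + 1)
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[ok] <- c0 * (1 - fz) + c1 * fz
  out
}

# central-difference gradient of a 3D volume (per mm); one-sided at borders
gradient3 <- function(vol, voxel_size) {
  g <- vector("list", 3L)
  for (ax in 1:3) {
    fwd <- ax_shift(vol, ax, -1L, NA)   # value at index + 1
    bwd <- ax_shift(vol, ax,  1L, NA)   # value at index - 1
    den <- array(2 * voxel_size[ax], dim(vol))
    miss_f <- is.na(fwd); miss_b <- is.na(bwd)
    fwd[miss_f] <- vol[miss_f]
    bwd[miss_b] <- vol[miss_b]
    den[miss_f | miss_b] <- voxel_size[ax]
    g[[ax]] <- (fwd - bwd) / den
  }
  names(g) <- c("x", "y", "z")
  g
}

# vectorised median of six aligned arrays via a sorting network
median6 <- function(a1, a2, a3, a4, a5, a6) {
  v <- list(a1, a2, a3, a4, a5, a6)
  cmp <- function(i, j) {
    lo <- pmin(v[[i]], v[[j]])
    hi <- pmax(v[[i]], v[[j]])
    v[[i]] <<- lo
    v[[j]] <<- hi
  }
  # insertion-sort network for 6 elements
  pairs <- list(c(1,2), c(2,3), c(1,2), c(3,4), c(2,3), c(1,2),
                c(4,5), c(3,4), c(2,3), c(1,2),
                c(5,6), c(4,5), c(3,4), c(2,3), c(1,2))
  for (p in pairs) cmp(p[1], p[2])
  (v[[3]] + v[[4]]) / 2
}

vnorm_rows <- function(m) sqrt(rowSums(m * m))

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
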