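# internal geometry helpers ---------------------------------------------

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_affine4 <- function(m) {
  is.matrix(m) && all(dim(m) == c(4L, 4L)) && all(is.finite(m)) &&
    isTRUE(all.equal(m[4, ], c(0, 0, 0, 1), tolerance = 1e-8)) &&
    abs(det(m[1:3, 1:3])) > 1e-12
}

# world coordinates of every voxel (0-based indices), n x 3, voxel-fastest-x
grid_world <- function(shape, affine) {
  i <- seq_len(shape[1]) - 1
  j <- seq_len(shape[2]) - 1
  k <- seq_len(shape[3]) - 1
  vox <- cbind(
    rep(i, times = shape[2] * shape[3]),
    rep(rep(j, each = shape[1]), times = shape[3]),
    rep(k, each = shape[1] * shape[2])
  )
  apply_affine_points(affine, vox)
}

# apply a 4x4 affine to an n x 3 point matrix
apply_affine_points <- function(m, pts) {
  sweep(pts %*% t(m[1:3, 1:3, drop = FALSE]), 2, m[1:3, 4], `+`)
}

world_to_voxel <- function(affine, pts) {
  apply_affine_points(solve(affine), pts)
}

# finite-difference Jacobian (world frame) of a dense world map W (n x 3)
# sampled on a voxel grid; returns n x 9 column-major 3x3 Jacobians
world_map_jacobian <- function(W, shape, affine) {
  n <- prod(shape)
  arr <- array(W, c(shape, 3L))
  G <- matrix(0, n, 9)  # dW/dvoxel, columns (d/di, d/dj, d/dk) x 3 comps
  for (comp in 1:3) {
    a <- arr[, , , comp]
    for (ax in 1:3) {
      d <- shape[ax]
      hi <- pmin(seq_len(d) + 1L, d)
      lo <- pmax(seq_len(d) - 1L, 1L)
      denom <- hi - lo
      if (ax == 1) {
        diff <- (a[hi, , , drop = FALSE] - a[lo, , , drop = FALSE]) /
          array(denom, dim(a))
      } else if (ax == 2) {
        diff <- (a[, hi, , drop = FALSE] - a[, lo, , drop = FALSE]) /
          aperm(array(denom, dim(a)[c(2, 1, 3)]), c(2, 1, 3))
      } else {
        diff <- (a[, , hi, drop = FALSE] - a[, , lo, drop = FALSE]) /
          aperm(array(denom, dim(a)[c(3, 1, 2)]), c(2, 3, 1))
      }
      G[, comp + 3L * (ax - 1L)] <- as.vector(diff)
    }
  }
  # chain rule: dW/dx_world = (dW/dvox) %*% inv(linear(affine))
  Li <- solve(affine[1:3, 1:3])
  out <- matrix(0, n, 9)
  for (a in 1:3) for (b in 1:3) {
    col <- a + 3L * (b - 1L)
    acc <- 0
    for (s in 1:3) acc <- acc + G[, a + 3L * (s - 1L)] * Li[s, b]
    out[, col] <- acc
  }
  out
}

# translation / rotation / scale / shear builders (4x4, world frame)
t4 <- function(t) { m <- diag(4); m[1:3, 4] <- t; m }

rot3 <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx); cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

lin4 <- function(L) { m <- diag(4); m[1:3, 1:3] <- L; m }

# polar rotation factor of an invertible 3x3 matrix
polar_rotation <- function(L) {
  s <- svd(L)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u; u[, 3] <- -u[, 3]
    R <- u %*% t(s$v)
  }
  R
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# binary dilation of a voxel mask (6-neighbourhood, `iters` passes)
dilate_mask <- function(m, shape, iters = 2L) {
  arr <- array(m, shape)
  for (i in seq_len(iters)) {
    out <- arr
    out[-1, , ] <- out[-1, , ] | arr[-shape[1], , ]
    out[-shape[1], , ] <- out[-shape[1], , ] | arr[-1, , ]
    out[, -1, ] <- out[, -1, ] | arr[, -shape[2], ]
    out[, -shape[2], ] <- out[, -shape[2], ] | arr[, -1, ]
    out[, , -1] <- out[, , -1] | arr[, , -shape[3]]
    out[, , -shape[3]] <- out[, , -shape[3]] | arr[, , -1]
    arr <- out
  }
  as.vector(arr)
}
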