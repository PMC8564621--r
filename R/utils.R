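## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a fixed RNG seed, restoring the caller's RNG state
#' @noRd
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

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Shift a matrix by (dy, dx), padding with `fill`
#' @noRd
shift2d <- function(m, dy, dx, fill = 0) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  ys <- max(1, 1 + dy):min(ny, ny + dy)
  xs <- max(1, 1 + dx):min(nx, nx + dx)
  if (length(ys) && length(xs))
    out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

#' Shift a 3D array by (dy, dx, dz), padding with `fill`
#' @noRd
shift3d <- function(a, dy, dx, dz, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  ys <- max(1, 1 + dy):min(d[1], d[1] + dy)
  xs <- max(1, 1 + dx):min(d[2], d[2] + dx)
  zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
  if (length(ys) && length(xs) && length(zs))
    out[ys, xs, zs] <- a[ys - dy, xs - dx, zs - dz]
  out
}

#' Binary dilation of a 3D logical array (6- or 26-neighbourhood)
#' @noRd
dilate3d <- function(mask, connectivity = 6) {
  out <- mask
  offs <- if (connectivity == 6) {
    list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  } else {
    o <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
    o <- o[!(o$dy == 0 & o$dx == 0 & o$dz == 0), ]
    lapply(seq_len(nrow(o)), function(i) as.numeric(o[i, ]))
  }
  for (v in offs) out <- out | shift3d(mask, v[1], v[2], v[3], fill = FALSE)
  out
}

#' Repeated 3D dilation
#' @noRd
dilate3d_n <- function(mask, n, connectivity = 6) {
  for (i in seq_len(n)) mask <- dilate3d(mask, connectivity)
  mask
}

dilate2d <- function(mask, connectivity = 8) {
  out <- mask
  o <- expand.grid(dy = -1:1, dx = -1:1)
  o <- o[!(o$dy == 0 & o$dx == 0), ]
  if (connectivity == 4) o <- o[abs(o$dy) + abs(o$dx) == 1, ]
  for (i in seq_len(nrow(o)))
    out <- out | shift2d(mask, o$dy[i], o$dx[i], fill = FALSE)
  out
}

#' Smooth Gaussian random field on a 2D grid via Fourier-domain filtering
#' (periodic boundary, which avoids edge ringing); zero mean, unit-ish scale.
#' @noRd
gaussian_field2d <- function(ny, nx, smoothness) {
  noise <- matrix(rnorm(ny * nx), ny, nx)
  fy <- c(0:floor(ny / 2), -(ceiling(ny / 2) - 1):-1) / ny
  fx <- c(0:floor(nx / 2), -(ceiling(nx / 2) - 1):-1) / nx
  f2 <- outer(fy^2, fx^2, `+`)
  filt <- exp(-2 * (pi * smoothness)^2 * f2)
  sm <- Re(fft(fft(noise) * filt, inverse = TRUE)) / (ny * nx)
  s <- sd(sm)
  if (s > 0) sm / s else sm
}

#' Bilinear sampling of a matrix at 0-based point coordinates; out-of-bounds -> fill
#' @noRd
sample_bilinear <- function(img, x, y, fill = 0) {
  ny <- nrow(img); nx <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  tx <- x - x0; ty <- y - y0
  gv <- function(ix, iy) {
    ok <- ix >= 0 & ix <= nx - 1 & iy >= 0 & iy <= ny - 1
    v <- rep(fill, length(ix))
    v[ok] <- img[cbind(iy[ok] + 1, ix[ok] + 1)]
    v
  }
  v00 <- gv(x0, y0); v10 <- gv(x0 + 1, y0)
  v01 <- gv(x0, y0 + 1); v11 <- gv(x0 + 1, y0 + 1)
  (1 - ty) * ((1 - tx) * v00 + tx * v10) + ty * ((1 - tx) * v01 + tx * v11)
}

#' Nearest-neighbour sampling of a matrix at 0-based coordinates
#' @noRd
sample_nearest <- function(img, x, y, fill = 0) {
  ix <- round(x); iy <- round(y)
  ny <- nrow(img); nx <- ncol(img)
  ok <- ix >= 0 & ix <= nx - 1 & iy >= 0 & iy <= ny - 1
  v <- rep(fill, length(ix))
  v[ok] <- img[cbind(iy[ok] + 1, ix[ok] + 1)]
  v
}

#' Trilinear sampling of a 3D array at 0-based (x, y, z); out-of-bounds -> fill
#' @noRd
sample_trilinear <- function(vol, x, y, z, fill = 0) {
  d <- dim(vol)
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  tx <- x - x0; ty <- y - y0; tz <- z - z0
  gv <- function(ix, iy, iz) {
    ok <- ix >= 0 & ix <= d[2] - 1 & iy >= 0 & iy <= d[1] - 1 & iz >= 0 & iz <= d[3] - 1
    v <- rep(fill, length(ix))
    v[ok] <- vol[cbind(iy[ok] + 1, ix[ok] + 1, iz[ok] + 1)]
    v
  }
  v000 <- gv(x0, y0, z0);     v100 <- gv(x0 + 1, y0, z0)
  v010 <- gv(x0, y0 + 1, z0); v110 <- gv(x0 + 1, y0 + 1, z0)
  v001 <- gv(x0, y0, z0 + 1); v101 <- gv(x0 + 1, y0, z0 + 1)
  v011 <- gv(x0, y0 + 1, z0 + 1); v111 <- gv(x0 + 1, y0 + 1, z0 + 1)
  c00 <- (1 - tx) * v000 + tx * v100
  c10 <- (1 - tx) * v010 + tx * v110
  c01 <- (1 - tx) * v001 + tx * v101
  c11 <- (1 - tx) * v011 + tx * v111
  (1 - tz) * ((1 - ty) * c00 + ty * c10) + tz * ((1 - ty) * c01 + ty * c11)
}

## Keys cubic-convolution kernel (a = -0.5), the classical "bicubic" kernel.
keys_weights <- function(t) {
  ## weights for samples at offsets -1, 0, 1, 2 given fractional position t
  a <- -0.5
  w <- function(x) {
    ax <- abs(x)
    ifelse(ax <= 1, (a + 2) * ax^3 - (a + 3) * ax^2 + 1,
           ifelse(ax < 2, a * ax^3 - 5 * a * ax^2 + 8 * a * ax - 4 * a, 0))
  }
  cbind(w(t + 1), w(t), w(t - 1), w(t - 2))
}

#' Tricubic (Keys) sampling of a 3D array at 0-based (x, y, z)
#' @noRd
sample_tricubic <- function(vol, x, y, z, fill = 0) {
  d <- dim(vol)
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  wx <- keys_weights(x - x0); wy <- keys_weights(y - y0); wz <- keys_weights(z - z0)
  out <- numeric(length(x))
  gv <- function(ix, iy, iz) {
    ok <- ix >= 0 & ix <= d[2] - 1 & iy >= 0 & iy <= d[1] - 1 & iz >= 0 & iz <= d[3] - 1
    v <- rep(fill, length(ix))
    v[ok] <- vol[cbind(iy[ok] + 1, ix[ok] + 1, iz[ok] + 1)]
    v
  }
  for (kz in 0:3) for (ky in 0:3) for (kx in 0:3) {
    w <- wx[, kx + 1] * wy[, ky + 1] * wz[, kz + 1]
    nz <- which(w != 0)
    if (length(nz))
      out[nz] <- out[nz] + w[nz] * gv(x0[nz] + kx - 1, y0[nz] + ky - 1, z0[nz] + kz - 1)
  }
  out
}

#' Bicubic (Keys) sampling of a matrix at 0-based (x, y)
#' @noRd
sample_bicubic <- function(img, x, y, fill = 0) {
  ny <- nrow(img); nx <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  wx <- keys_weights(x - x0); wy <- keys_weights(y - y0)
  out <- numeric(length(x))
  gv <- function(ix, iy) {
    ok <- ix >= 0 & ix <= nx - 1 & iy >= 0 & iy <= ny - 1
    v <- rep(fill, length(ix))
    v[ok] <- img[cbind(iy[ok] + 1, ix[ok] + 1)]
    v
  }
  for (ky in 0:3) for (kx in 0:3) {
    w <- wx[, kx + 1] * wy[, ky + 1]
    nz <- which(w != 0)
    if (length(nz))
      out[nz] <- out[nz] + w[nz] * gv(x0[nz] + kx - 1, y0[nz] + ky - 1)
  }
  out
}
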