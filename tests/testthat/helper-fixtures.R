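## Shared fixtures: everything is generated in code at test time.

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

## filled disk as a logical matrix (0-based centre coordinates (x, y))
disk_mask <- function(r, centre = c(32, 32), n = 64) {
  gx <- matrix(rep(0:(n - 1), each = n), n, n)
  gy <- matrix(rep(0:(n - 1), n), n, n)
  (gx - centre[1])^2 + (gy - centre[2])^2 <= r^2
}

## filled ball as a logical 3D array (1-based centre)
ball_mask <- function(r, centre, dims) {
  co <- as.matrix(expand.grid(y = seq_len(dims[1]), x = seq_len(dims[2]),
                              z = seq_len(dims[3])))
  d2 <- (co[, 1] - centre[1])^2 + (co[, 2] - centre[2])^2 + (co[, 3] - centre[3])^2
  array(d2 <= r^2, dims)
}

## straight axis-aligned tube phantom: lumen radius r_vox, wall w_vox (voxels)
tube_phantom <- function(dims = c(48, 48, 96), r_vox = 8, w_vox = 4, vs = 8.5) {
  make_lung_phantom(phantom_params(
    shape = dims, voxel_size = vs, n_airways = 0, n_bubbles = 0,
    airspace_fraction = 0,
    vessels = list(list(p0 = c(dims[2] / 2, dims[1] / 2, 0),
                        p1 = c(dims[2] / 2, dims[1] / 2, dims[3] - 1),
                        radius = r_vox * vs)),
    wall_thickness = w_vox * vs, rng_seed = 1))
}

## two lumen-grey chambers joined by a 3-voxel-wide channel, in parenchyma
neck_phantom <- function() {
  d <- c(40, 40, 80)
  g <- array(17000, d)
  ch <- ball_mask(12, c(20, 20, 20), d) | ball_mask(12, c(20, 20, 60), d)
  g[ch] <- 21000
  g[19:21, 19:21, 20:60] <- 21000   # 3 x 3 neck along z
  ct_volume(g, 8.5)
}

## independent 26-connected component counter (plain R flood fill)
flood_count <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  nlab <- 0L
  idx <- which(mask)
  for (i in idx) {
    if (lab[i] > 0) next
    nlab <- nlab + 1L
    queue <- i
    lab[i] <- nlab
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      z <- (cur - 1) %/% (d[1] * d[2])
      rem <- (cur - 1) %% (d[1] * d[2])
      x <- rem %/% d[1]; y <- rem %% d[1]
      for (k in seq_len(nrow(offs))) {
        yy <- y + offs[k, 1]; xx <- x + offs[k, 2]; zz <- z + offs[k, 3]
        if (yy < 0 || yy >= d[1] || xx < 0 || xx >= d[2] || zz < 0 || zz >= d[3])
          next
        j <- yy + 1 + d[1] * (xx + d[2] * zz)
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- nlab
          queue <- c(queue, j)
        }
      }
    }
  }
  nlab
}

## phantom parameters with structure sizes scaled to fit small volumes
small_params <- function(shape, seed, ...) {
  phantom_params(shape = shape,
                 vessel_radius_range = c(25, 60), wall_thickness = 20,
                 airway_radius_range = c(50, 90),
                 airspace_radius_range = c(40, 80),
                 bubble_radius_range = c(30, 50),
                 rng_seed = seed, ...)
}

## textured test image: a phantom CT plane (deterministic)
textured_plane <- function(n = 128, seed = 7, z = 18) {
  ph <- make_lung_phantom(small_params(c(n, n, max(z + 1, 24)), seed,
                                       n_bubbles = 0))
  ph$volume$voxels[, , z + 1]
}
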