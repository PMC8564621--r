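test_that("16-bit conversion maps the percentile window linearly", {
  set.seed(1)
  v <- array(rnorm(16^3), c(16, 16, 16))
  ## full window: extremes map to 0 and 65535
  out <- convert_to_uint16(v, window = c(0, 100))
  expect_equal(out$voxels[which.min(v)], 0)
  expect_equal(out$voxels[which.max(v)], 65535)
  ## constant volume: all zero, with a warning
  expect_warning(cz <- convert_to_uint16(array(3.7, c(4, 4, 4))), "constant")
  expect_true(all(cz$voxels == 0))
  ## brute-force per-voxel oracle for a clipped window
  out2 <- convert_to_uint16(v, window = c(1, 99))
  qs <- quantile(v, c(0.01, 0.99), names = FALSE)
  oracle <- round(pmin(pmax((v - qs[1]) / (qs[2] - qs[1]), 0), 1) * 65535)
  expect_equal(as.numeric(out2$voxels), as.numeric(oracle))
  expect_error(convert_to_uint16(array(c(1, NA), c(2, 1, 1))), "finite")
  expect_error(convert_to_uint16(v, window = c(99, 1)), "low < high")
})

test_that("reslicing to an existing xy plane re-indexes z only", {
  set.seed(2)
  vol <- ct_volume(array(sample(0:65535, 10 * 12 * 8, TRUE), c(10, 12, 8)), 5)
  pl <- section_plane(c(0, 0, 3), c(1, 0, 3), c(0, 1, 3))
  out <- reslice_to_plane(vol, pl, interpolation_order = 0,
                          out_shape = c(10, 12, 5))
  for (k in 0:4)
    expect_equal(out$voxels[, , k + 1], vol$voxels[, , k + 4])
})

test_that("reslicing across a 90-degree rotation equals an axis swap", {
  set.seed(3)
  vol <- ct_volume(array(sample(0:65535, 12^3, TRUE), c(12, 12, 12)), 5)
  ## plane with normal +y: the new z axis walks along +y, the in-plane x
  ## axis stays x, and the in-plane y axis runs along -z (right-handed frame)
  pl <- section_plane(c(0, 0, 11), c(1, 0, 11), c(0, 0, 1))
  out <- reslice_to_plane(vol, pl, interpolation_order = 0,
                          out_shape = c(12, 12, 12))
  for (k in 1:12)
    expect_equal(out$voxels[, , k], t(vol$voxels[k, , 12:1]),
                 info = paste("slice", k))
})

test_that("oblique order-1 reslice matches an independent trilinear oracle", {
  set.seed(4)
  vol <- ct_volume(array(runif(10^3, 0, 65535), c(10, 10, 10)), 5)
  pl <- section_plane(c(0, 0, 2), c(9, 0, 4), c(0, 9, 3))
  out <- reslice_to_plane(vol, pl, interpolation_order = 1,
                          out_shape = c(6, 6, 3))
  ## rebuild the sampling grid exactly as documented and interpolate by hand
  nrm <- pl$normal; if (nrm[3] < 0) nrm <- -nrm
  ex <- c(1, 0, 0) - sum(c(1, 0, 0) * nrm) * nrm; ex <- ex / sqrt(sum(ex^2))
  ey <- c(nrm[2] * ex[3] - nrm[3] * ex[2], nrm[3] * ex[1] - nrm[1] * ex[3],
          nrm[1] * ex[2] - nrm[2] * ex[1])
  trilin <- function(p) {
    x <- p[1]; y <- p[2]; z <- p[3]
    x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
    acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      xi <- x0 + dx; yi <- y0 + dy; zi <- z0 + dz
      w <- (1 - abs(x - xi)) * (1 - abs(y - yi)) * (1 - abs(z - zi))
      v <- if (xi < 0 || xi > 9 || yi < 0 || yi > 9 || zi < 0 || zi > 9) 0
           else vol$voxels[yi + 1, xi + 1, zi + 1]
      acc <- acc + w * v
    }
    acc
  }
  for (k in 0:2) for (gy in c(0, 3, 5)) for (gx in c(0, 2, 5)) {
    p <- pl$p1 + gx * ex + gy * ey + k * nrm
    expect_equal(out$voxels[gy + 1, gx + 1, k + 1], trilin(p),
                 tolerance = 1e-9)
  }
})

test_that("constant volumes stay constant through order-0/1 reslicing", {
  vol <- ct_volume(array(1234, c(8, 8, 8)), 5)
  pl <- section_plane(c(1, 1, 1), c(6, 2, 3), c(2, 6, 4))
  for (ord in c(0, 1)) {
    out <- reslice_to_plane(vol, pl, ord, out_shape = c(4, 4, 2))
    inside <- out$voxels[out$voxels > 0]
    expect_true(all(inside == 1234))
  }
  expect_error(section_plane(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)), "collinear")
})

test_that("bubble masking zeroes bubbles and rims and nothing far away", {
  p <- phantom_params(shape = c(96, 96, 96), n_bubbles = 3, rng_seed = 9)
  ph <- make_lung_phantom(p)
  res <- mask_air_bubbles(ph$volume)
  gtb <- ph$ground_truth$bubble$mask | ph$ground_truth$rim$mask
  expect_gt(sum(gtb), 0)
  ## >= 95% of bubble+rim voxels are masked
  expect_gte(sum(res$bubble_mask$mask & gtb) / sum(gtb), 0.95)
  ## nothing masked farther than rim_thickness + 2 voxels from a bubble
  far <- ph$ground_truth$bubble$mask
  for (i in seq_len(p$rim_thickness + 2)) far <- xrh:::dilate3d(far, 26)
  expect_equal(sum(res$bubble_mask$mask & !far), 0)
  ## multiplication contract and idempotence
  expect_true(all(res$masked$voxels[res$bubble_mask$mask] == 0))
  unchanged <- !res$bubble_mask$mask
  expect_equal(res$masked$voxels[unchanged], ph$volume$voxels[unchanged])
  again <- mask_air_bubbles(res$masked)
  expect_identical(again$masked$voxels, res$masked$voxels)
})

test_that("bubble-free volumes pass through bubble masking unchanged", {
  ph <- make_lung_phantom(phantom_params(shape = c(48, 48, 48), n_bubbles = 0,
                                         rng_seed = 2))
  res <- mask_air_bubbles(ph$volume)
  expect_equal(sum(res$bubble_mask$mask), 0)
  expect_identical(res$masked$voxels, ph$volume$voxels)
})
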