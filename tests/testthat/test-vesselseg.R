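test_that("speed image applies the two-sided threshold windows", {
  g <- array(c(21000, 30000, 12000, 19000, 24000, 18000), c(1, 1, 6))
  vol <- ct_volume(g, 8.5)
  sp <- make_speed_image(vol)
  expect_equal(sp[1, 1, 1], 1)    # lumen grey -> +1
  expect_equal(sp[1, 1, 2], -1)   # wall grey -> -1
  expect_equal(sp[1, 1, 3], -1)   # paraffin -> -1
  expect_equal(sp[1, 1, 4], 1)    # window edges inclusive
  expect_equal(sp[1, 1, 5], 1)
  ## sign map matches a brute-force per-voxel window test on a phantom
  ph <- make_lung_phantom(small_params(c(32, 32, 32), 6, n_bubbles = 0))
  sp2 <- make_speed_image(ph$volume, ramp = 500)
  inwin <- ph$volume$voxels >= 19000 & ph$volume$voxels <= 24000
  expect_identical(sp2 > 0, inwin)
  ## contiguity invariant of the windows
  expect_error(speed_params(c(19000, 24000), c(25000, 65535)), "contiguous")
  expect_error(speed_params(c(24000, 19000)), "increasing")
})

test_that("active contour fills a uniform-lumen sphere (Dice >= 0.95)", {
  d <- c(32, 32, 32)
  g <- array(17000, d)
  sph <- ball_mask(10, c(16, 16, 16), d)
  g[sph] <- 21000
  sp <- make_speed_image(ct_volume(g, 8.5))
  lab <- active_contour_grow(sp, matrix(c(15, 15, 15), 1),
                             contour_params(0.2), 8.5)
  expect_gte(dice_coef(lab$mask, sph), 0.95)
  ## seeds are contained in the final label
  expect_true(lab$mask[16, 16, 16])
})

test_that("the wall acts as a barrier: no growth outside the lumen", {
  ph <- tube_phantom()
  sp <- make_speed_image(ph$volume)
  lab <- active_contour_grow(sp, matrix(c(24, 24, 48), 1),
                             contour_params(0.2), 8.5)
  gt <- ph$ground_truth$vessel_lumen$mask
  dil <- xrh:::dilate3d(gt, 26)
  expect_equal(sum(lab$mask & !dil), 0)
  expect_gte(dice_coef(lab$mask, gt), 0.95)
})

test_that("smoothing force 0.4 blocks a 3-voxel neck that leaks at 0", {
  vol <- neck_phantom()
  sp <- make_speed_image(vol)
  seed <- matrix(c(19, 19, 19), 1)
  grow <- function(f) active_contour_grow(sp, seed,
                                          contour_params(f, max_iterations = 200),
                                          8.5)$mask
  m0 <- grow(0); m2 <- grow(0.2); m4 <- grow(0.4)
  chamber2 <- function(m) sum(m[, , 50:80])
  expect_gt(chamber2(m0), 0)            # leak without smoothing
  expect_equal(chamber2(m4), 0)         # blocked at the lung setting
  expect_lte(sum(m4), sum(m2))          # stronger smoothing, smaller volume
})

test_that("growth is monotone without smoothing and rejects bad seeds", {
  d <- c(24, 24, 24)
  g <- array(21000, d)
  vol <- ct_volume(g, 8.5)
  sp <- make_speed_image(vol)
  prev <- 0
  for (it in c(2, 5, 9, 14)) {
    lab <- active_contour_grow(sp, matrix(c(12, 12, 12), 1),
                               contour_params(0, max_iterations = it), 8.5)
    expect_gte(sum(lab$mask), prev)
    prev <- sum(lab$mask)
  }
  ## seed in the wall window is rejected; all seeds invalid is a failure
  g2 <- array(30000, d); g2[12, 12, 12] <- 21000
  sp2 <- make_speed_image(ct_volume(g2, 8.5))
  expect_warning(
    lab2 <- active_contour_grow(sp2, rbind(c(11, 11, 11), c(2, 2, 2)),
                                contour_params(0.2), 8.5),
    "rejected")
  expect_warning(expect_error(
    active_contour_grow(sp2, matrix(c(2, 2, 2), 1), contour_params(0.2), 8.5),
    "no valid seeds"))
})

test_that("sub-volume processing matches whole-volume segmentation", {
  ph <- make_lung_phantom(phantom_params(
    shape = c(64, 64, 64), n_vessels = 2, vessel_radius_range = c(40, 80),
    n_airways = 1, airway_radius_range = c(100, 150), n_bubbles = 0,
    rng_seed = 5))
  lum <- ph$ground_truth$vessel_lumen$mask
  w <- which(lum, arr.ind = TRUE)
  set.seed(2)
  pick <- w[sample(nrow(w), 10), ]
  seeds <- cbind(pick[, 2] - 1, pick[, 1] - 1, pick[, 3] - 1)
  whole <- segment_vessels(ph$volume, seeds, subvolume_shape = 64,
                           contour = contour_params(0.4))
  sub <- segment_vessels(ph$volume, seeds, subvolume_shape = 40, overlap = 16,
                         contour = contour_params(0.4))
  expect_gte(dice_coef(whole$mask, sub$mask), 0.98)
})

test_that("a tube crossing sub-volumes is followed into unseeded tiles", {
  ph <- tube_phantom()
  seg <- segment_vessels(ph$volume, matrix(c(24, 24, 10), 1),
                         subvolume_shape = c(48, 48, 48), overlap = 16)
  lab <- xrh:::.cc_label_3d(seg$mask, dim(seg$mask), 26L)
  expect_equal(attr(lab, "n_components"), 1L)
  expect_gte(dice_coef(seg$mask, ph$ground_truth$vessel_lumen$mask), 0.95)
  ## no seeds: empty label
  empty <- suppressWarnings(
    segment_vessels(ph$volume, matrix(numeric(0), 0, 3),
                    subvolume_shape = c(48, 48, 48)))
  expect_equal(sum(empty$mask), 0)
})

test_that("network volume follows the closed form", {
  m <- array(FALSE, c(100, 100, 100))
  m[seq_len(1e6)] <- TRUE
  expect_identical(network_volume(m, 10), 1.0)
  expect_equal(network_volume(array(FALSE, c(4, 4, 4)), 10), 0)
  ## phantom cylinder within 3% of pi r^2 L
  vs <- 8.5
  ph <- tube_phantom(dims = c(96, 96, 100), r_vox = 20, w_vox = 4, vs = vs)
  vol_mm3 <- network_volume(ph$ground_truth$vessel_lumen)
  analytic <- pi * (20 * vs)^2 * (100 * vs) * 1e-9
  expect_lt(abs(vol_mm3 - analytic) / analytic, 0.03)
})
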