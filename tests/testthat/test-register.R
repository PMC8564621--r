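test_that("file pairing matches on keys, sorts, and reports the unmatched", {
  d <- withr::local_tempdir()
  file.create(file.path(d, c("sec_005.tif", "ct_005.tif", "ct_006.tif")))
  res <- pair_images(d)
  expect_equal(nrow(res$pairs), 1)
  expect_equal(res$pairs$key, "005")
  expect_equal(res$unmatched, "ct_006.tif")
  ## empty directory
  d2 <- withr::local_tempdir()
  res2 <- pair_images(d2)
  expect_equal(nrow(res2$pairs), 0)
  ## 22 synthetic pairs come back in ascending key order
  d3 <- withr::local_tempdir()
  keys <- sprintf("%03d", sample(seq(2, 86, by = 4)))
  file.create(file.path(d3, c(paste0("sec_", keys, ".tif"),
                              paste0("ct_", keys, ".tif"))))
  res3 <- pair_images(d3)
  expect_equal(nrow(res3$pairs), 22)
  expect_equal(res3$pairs$key, keys[order(as.numeric(keys))])
  ## duplicate keys on one side are rejected with a listing
  d4 <- withr::local_tempdir()
  file.create(file.path(d4, c("sec_001.tif", "sec_001.tiff", "ct_001.tif")))
  expect_error(pair_images(d4), "duplicate")
})

test_that("TPS with lambda = 0 interpolates exactly and satisfies side conditions", {
  set.seed(10)
  for (rep in 1:25) {
    n <- sample(4:50, 1)
    mv <- matrix(runif(2 * n, 0, 200), ncol = 2)
    fx <- mv + matrix(rnorm(2 * n, 0, 8), ncol = 2)
    lm <- landmark_set(mv, fx, min_spacing = 0)
    tps <- fit_tps(lm)
    expect_lt(max(abs(tps_apply(tps, mv) - fx)), 1e-6)
    side <- c(colSums(tps$weights),
              colSums(tps$weights * mv[, 1]), colSums(tps$weights * mv[, 2]))
    expect_lt(max(abs(side)), 1e-8)
  }
  ## identity landmarks give the identity transform on a test grid
  mv <- matrix(runif(20, 0, 50), ncol = 2)
  tid <- fit_tps(landmark_set(mv, mv, min_spacing = 0))
  grid <- as.matrix(expand.grid(seq(0, 50, 5), seq(0, 50, 5)))
  expect_lt(max(abs(tps_apply(tid, grid) - grid)), 1e-6)
  ## degenerate (collinear) landmarks are rejected
  col <- cbind(1:5, 2 * (1:5))
  expect_error(fit_tps(landmark_set(col, col + 1, min_spacing = 0)),
               "collinear")
})

test_that("TPS fitted to affine-consistent landmarks reproduces the affine", {
  set.seed(11)
  mv <- matrix(runif(16, 0, 100), ncol = 2)
  A <- matrix(c(1.05, 0.15, -0.2, 0.92), 2)
  b <- c(7, -4)
  fx <- t(A %*% t(mv)) + matrix(b, nrow(mv), 2, byrow = TRUE)
  tps <- fit_tps(landmark_set(mv, fx, min_spacing = 0))
  expect_lt(max(abs(tps$weights)), 1e-8)
  pts <- matrix(runif(200, -20, 120), ncol = 2)
  truth <- t(A %*% t(pts)) + matrix(b, 100, 2, byrow = TRUE)
  expect_lt(max(abs(tps_apply(tps, pts) - truth)), 1e-6)
})

test_that("warping follows BigWarp backward semantics", {
  img <- textured_plane(64, seed = 12, z = 4)
  ## identity transform: output equals input
  mv <- as.matrix(expand.grid(c(5, 30, 58), c(5, 30, 58)))
  lm <- landmark_set(mv, mv, min_spacing = 0)
  expect_equal(warp_image(img, lm, interpolation_order = 1), img,
               tolerance = 1e-9)
  ## pure integer translation equals an integer-shift oracle at order 0
  sh <- c(4, -3)  # (dx, dy): moving point p maps to fixed p + sh
  lm2 <- landmark_set(mv, sweep(mv, 2, sh, `+`), min_spacing = 0)
  out <- warp_image(img, lm2, interpolation_order = 0)
  oracle <- xrh:::shift2d(img, sh[2], sh[1], fill = 0)
  expect_equal(out, oracle)
  ## landmark CSV round trip (BigWarp-style interchange)
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmarks_csv(lm2, path)
  back <- read_landmarks_csv(path, min_spacing = 0)
  expect_equal(back$moving_pts, lm2$moving_pts)
  expect_equal(back$fixed_pts, lm2$fixed_pts)
})

test_that("feature matching recovers known transforms and flags failure", {
  img <- textured_plane(128, seed = 7, z = 18)
  nimg <- normalize_for_matching(img)
  ## identical images: all displacements ~0
  lm <- hierarchical_match(nimg, nimg, normalized = TRUE)
  disp <- lm$fixed_pts - lm$moving_pts
  expect_lt(max(abs(disp)), 0.5)
  expect_gte(nrow(lm$moving_pts), 4)
  ## pure translation: median displacement recovered within 1 px
  sh <- c(15, -7)
  moved <- xrh:::shift2d(img, -sh[2], -sh[1], fill = median(img))
  lm2 <- hierarchical_match(normalize_for_matching(moved), nimg)
  disp2 <- lm2$fixed_pts - lm2$moving_pts
  expect_lt(abs(median(disp2[, 1]) - sh[1]), 1)
  expect_lt(abs(median(disp2[, 2]) - sh[2]), 1)
  ## constant (textureless) images: failure signal, no crash
  flat <- matrix(0.5, 64, 64)
  expect_error(hierarchical_match(flat, flat, normalized = TRUE),
               class = "xrh_match_failure")
})

test_that("match displacements are scale-equivariant on upsampled pairs", {
  img <- textured_plane(96, seed = 15, z = 10)
  sh <- c(5, -4)
  moved <- xrh:::shift2d(img, -sh[2], -sh[1], fill = median(img))
  lm1 <- hierarchical_match(normalize_for_matching(moved),
                            normalize_for_matching(img))
  up <- function(m) as.matrix(EBImage::resize(EBImage::Image(m / 65535),
                                              w = 192, h = 192)) * 65535
  lm2 <- hierarchical_match(normalize_for_matching(up(moved)),
                            normalize_for_matching(up(img)))
  d1 <- apply(lm1$fixed_pts - lm1$moving_pts, 2, median)
  d2 <- apply(lm2$fixed_pts - lm2$moving_pts, 2, median)
  expect_lt(max(abs(d2 - 2 * d1)), 1)
})

test_that("register_pair aligns both channels and reports diagnostics", {
  p <- small_params(c(128, 128, 24), 7)
  ph <- make_lung_phantom(p)
  z <- 10
  ct <- ph$volume$voxels[, , z + 1]
  ## identity deformation: warped AF equals the input within interpolation tol
  ident <- make_deformation(c(128, 128), 0, 32, 1)
  sec <- extract_section(ph, z, ident, p, noise_sd = 0)
  res <- register_pair(sec, ct)
  expect_lt(mean(abs(res$warped_af - sec$af)), 0.01 * diff(range(sec$af)))
  expect_equal(length(res$diagnostics$residuals), res$diagnostics$n_landmarks)
  expect_lt(max(res$diagnostics$residuals), 1e-6)   # lambda = 0 interpolates
  ## smooth deformation: landmark correspondences recover the true field
  def <- make_deformation(c(128, 128), 20, 32, 42)
  sec2 <- extract_section(ph, z, def, p)
  res2 <- register_pair(sec2, ct)
  lm <- res2$landmarks
  dxm <- xrh:::sample_bilinear(def$dx, lm$moving_pts[, 1], lm$moving_pts[, 2])
  dym <- xrh:::sample_bilinear(def$dy, lm$moving_pts[, 1], lm$moving_pts[, 2])
  err <- sqrt((lm$fixed_pts[, 1] - (lm$moving_pts[, 1] + dxm))^2 +
              (lm$fixed_pts[, 2] - (lm$moving_pts[, 2] + dym))^2)
  expect_lt(mean(err), 3)
  ## the IF channel moves with the identical transform: its structures land
  ## on the undeformed epithelium positions
  ep <- ph$ground_truth$epithelium$mask[, , z + 1]
  ifm <- res2$warped_if > 25000
  near <- ep
  for (i in 1:3) near <- xrh:::dilate2d(near)
  expect_gt(sum(ifm & near) / max(sum(ifm), 1), 0.9)
})
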