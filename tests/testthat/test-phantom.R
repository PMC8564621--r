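test_that("single straight tube matches the analytic cylinder volume", {
  vs <- 8.5
  p <- phantom_params(shape = c(64, 64, 64), voxel_size = vs,
                      n_airways = 0, n_bubbles = 0, airspace_fraction = 0,
                      vessels = list(list(p0 = c(32, 32, 0), p1 = c(32, 32, 63),
                                          radius = 8 * vs)),
                      wall_thickness = 3 * vs, rng_seed = 1)
  ph <- make_lung_phantom(p)
  cnt <- sum(ph$ground_truth$vessel_lumen$mask | ph$ground_truth$vessel_wall$mask)
  expect_lt(abs(cnt - pi * 11^2 * 64) / (pi * 11^2 * 64), 0.05)
  ## lumen alone is the inner cylinder
  expect_lt(abs(sum(ph$ground_truth$vessel_lumen$mask) - pi * 64 * 64) /
              (pi * 64 * 64), 0.05)
})

test_that("empty structure counts give empty ground-truth labels", {
  p <- phantom_params(shape = c(24, 24, 24), n_vessels = 0, n_airways = 0,
                      n_bubbles = 0, airspace_fraction = 0, rng_seed = 2)
  ph <- make_lung_phantom(p)
  for (role in c("airspace", "airway_lumen", "epithelium", "vessel_lumen",
                 "vessel_wall", "bubble", "rim"))
    expect_equal(sum(ph$ground_truth[[role]]$mask), 0, info = role)
  expect_true(all(ph$ground_truth$tissue$mask))
})

test_that("identical parameters and seed give bit-identical phantoms", {
  p <- small_params(c(48, 48, 48), 9)
  a <- make_lung_phantom(p)
  b <- make_lung_phantom(p)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(lapply(a$ground_truth, `[[`, "mask"),
                   lapply(b$ground_truth, `[[`, "mask"))
})

test_that("ground-truth labels are mutually exclusive and never cover bubbles", {
  p <- phantom_params(shape = c(96, 96, 96), rng_seed = 5)
  ph <- make_lung_phantom(p)
  total <- Reduce(`+`, lapply(ph$ground_truth, function(g) g$mask * 1L))
  expect_true(all(total == 1L))   # every voxel has exactly one role
  bub <- ph$ground_truth$bubble$mask
  others <- Reduce(`|`, lapply(ph$ground_truth[names(ph$ground_truth) != "bubble"],
                               `[[`, "mask"))
  expect_equal(sum(bub & others), 0)
})

test_that("printed threshold window selects exactly the lumen label", {
  ph <- make_lung_phantom(phantom_params(shape = c(64, 64, 64), rng_seed = 3,
                                         bubble_radius_range = c(60, 100)))
  sel <- ph$volume$voxels >= 19000 & ph$volume$voxels <= 24000
  gt <- ph$ground_truth$vessel_lumen$mask
  expect_equal(sum(sel & gt) / sum(sel | gt), 1)   # Jaccard = 1
})

test_that("structures larger than the volume are rejected with a diagnostic", {
  expect_error(
    make_lung_phantom(phantom_params(shape = c(24, 24, 24), voxel_size = 8.5,
                                     vessel_radius_range = c(80, 101),
                                     n_airways = 0, n_bubbles = 0,
                                     airspace_fraction = 0)),
    "too small")
  expect_error(phantom_params(shape = c(8, 8, 8), voxel_size = 1,
                              vessel_radius_range = c(1, 20)),
               "smaller than the volume extent")
})

test_that("deformation field honours the amplitude and smoothness contracts", {
  ## amplitude 0 is the identity field
  z <- make_deformation(c(32, 32), 0, 16, 1)
  expect_true(all(z$dx == 0) && all(z$dy == 0))
  ## maximum magnitude is rescaled to the amplitude exactly
  f <- make_deformation(c(64, 64), 20, 16, 2)
  expect_equal(max(sqrt(f$dx^2 + f$dy^2)), 20, tolerance = 1e-9)
  expect_true(all(is.finite(f$dx)) && all(is.finite(f$dy)))
  ## larger correlation length means a smoother field (same seed)
  s32 <- make_deformation(c(64, 64), 20, 32, 3)
  s4 <- make_deformation(c(64, 64), 20, 4, 3)
  grad_mag <- function(d) mean(abs(diff(d$dx))) + mean(abs(diff(d$dy)))
  expect_lt(grad_mag(s32), grad_mag(s4))
  expect_error(make_deformation(c(32, 32), -1, 16), "amplitude")
  expect_error(make_deformation(c(32, 32), 5, 0), "smoothness")
})

test_that("extracted sections respect the deformation and channel contracts", {
  p <- small_params(c(64, 64, 16), 4)
  ph <- make_lung_phantom(p)
  ident <- make_deformation(c(64, 64), 0, 16, 1)
  ## identity deformation: AF channel equals the monotone remap of the plane
  sec <- extract_section(ph, 5, ident, p, noise_sd = 0)
  expect_equal(sec$af, xrh:::af_remap(ph$volume$voxels[, , 6]))
  ## IF channel is nonzero only at (deformed) epithelium pixels, +-1 px
  def <- make_deformation(c(64, 64), 6, 32, 8)
  sec2 <- extract_section(ph, 5, def, p, noise_sd = 0)
  ep <- ph$ground_truth$epithelium$mask[, , 6]
  ep_def <- apply_deformation(ep * 1, def) > 0
  band <- xrh:::dilate2d(ep_def) | ep_def
  expect_equal(sum(sec2$if_ch > 0 & !band), 0)
  ## warping back with the inverse field recovers the undeformed channel
  und <- xrh:::af_remap(ph$volume$voxels[, , 6])
  rec <- apply_deformation(sec2$af, invert_deformation(def))
  interior <- 9:56
  err <- mean(abs(rec[interior, interior] - und[interior, interior]))
  expect_lt(err, 0.02 * diff(range(und)))
  expect_error(extract_section(ph, 99, ident, p), "out of range")
})

test_that("section-to-slice assignment follows the microtome thickness", {
  expect_equal(section_to_slice(0, 8.5), 0L)
  expect_equal(section_to_slice(c(19, 95), 8.5), c(9L, 45L))
  expect_equal(section_to_slice(10, 4), 10L)  # 4 um voxels: 1 slice/section
})
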