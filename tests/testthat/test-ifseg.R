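test_that("IF thresholding recovers the stained label and removes speckle", {
  p <- small_params(c(64, 64, 16), 4)
  ph <- make_lung_phantom(p)
  def <- make_deformation(c(64, 64), 6, 32, 8)
  sec <- extract_section(ph, 5, def, p, noise_sd = 0)
  m <- threshold_if(sec$if_ch, 25000, min_area = 1)
  ep_def <- apply_deformation(ph$ground_truth$epithelium$mask[, , 6] * 1, def) > 0.5
  band <- xrh:::dilate2d(ep_def) | ep_def
  expect_equal(sum(m & !band), 0)
  shrunk <- ep_def & !xrh:::dilate2d(!ep_def)
  expect_true(all(m[shrunk]))
  ## threshold above the maximum: empty; at 0: full
  expect_equal(sum(threshold_if(sec$if_ch, max(sec$if_ch) + 1)), 0)
  expect_true(all(threshold_if(sec$if_ch, 0, min_area = 1)))
  ## small-object removal
  sp <- matrix(0, 32, 32)
  sp[5, 5] <- 1; sp[20:25, 20:25] <- 1
  out <- threshold_if(sp, 0.5, min_area = 10)
  expect_false(out[5, 5])
  expect_true(all(out[20:25, 20:25]))
})

test_that("sparse stacks validate indices and record gaps", {
  masks <- lapply(1:6, function(i) disk_mask(6, n = 32))
  stk <- assemble_sparse(masks, c(32, 32, 30), indices = c(0, 5, 10, 15, 20, 25))
  expect_length(stk$entries, 6)
  expect_equal(max(diff(as.integer(names(stk$entries)))), 5)
  expect_true(stk$interpolatable)
  single <- assemble_sparse(masks[1], c(32, 32, 30), indices = 3)
  expect_false(single$interpolatable)
  expect_error(contour_interpolate(single), "at least 2")
  expect_error(assemble_sparse(masks[1:2], c(32, 32, 30), indices = c(1, 30)),
               "z-range")
  expect_error(assemble_sparse(masks[1:2], c(32, 32, 30), indices = c(1, 1)),
               "duplicate")
})

test_that("identical disks interpolate to the identical disk on every slice", {
  d10 <- disk_mask(10)
  stk <- assemble_sparse(list(d10, d10), c(64, 64, 5), indices = c(0, 4))
  out <- contour_interpolate(stk)
  for (z in 1:3) expect_identical(out$mask[, , z + 1], d10)
  ## labelled slices verbatim; outside the outermost entries empty
  stk2 <- assemble_sparse(list(d10, disk_mask(5)), c(64, 64, 10),
                          indices = c(2, 7))
  out2 <- contour_interpolate(stk2)
  expect_identical(out2$mask[, , 3], d10)
  expect_identical(out2$mask[, , 8], disk_mask(5))
  expect_equal(sum(out2$mask[, , c(1, 2, 9, 10)]), 0)
})

test_that("concentric disks follow the linear-radius distance-field oracle", {
  stk <- assemble_sparse(list(disk_mask(12), disk_mask(4)), c(64, 64, 9),
                         indices = c(0, 8))
  out <- contour_interpolate(stk)
  for (z in 1:7) {
    r_eff <- sqrt(sum(out$mask[, , z + 1]) / pi)
    r_lin <- 12 + (4 - 12) * z / 8
    expect_lt(abs(r_eff - r_lin), 1)
  }
})

test_that("unpaired components taper monotonically and vanish by the midpoint", {
  stk <- assemble_sparse(list(disk_mask(10), matrix(FALSE, 64, 64)),
                         c(64, 64, 7), indices = c(0, 6))
  out <- contour_interpolate(stk)
  counts <- apply(out$mask, 3, sum)
  expect_true(all(diff(counts) <= 0))        # monotone shrink
  expect_equal(sum(counts[4:7]), 0)          # empty from z = 3 on
  expect_gt(counts[2], 0)
  ## translated disks morph along the connecting translation
  stk2 <- assemble_sparse(list(disk_mask(8, centre = c(20, 32)),
                               disk_mask(8, centre = c(44, 32))),
                          c(64, 64, 5), indices = c(0, 4))
  out2 <- contour_interpolate(stk2)
  mid <- out2$mask[, , 3]
  cen <- xrh:::mask_centroid(mid)
  expect_lt(abs(cen[1] - 32), 1.5)
  expect_lt(abs(sqrt(sum(mid) / pi) - 8), 1.5)
})

test_that("tissue masking removes airspace labels, never adds, idempotent", {
  set.seed(30)
  for (i in 1:50) {
    d <- c(16, 16, 8)
    vol <- ct_volume(array(sample(c(11000, 17000, 21000, 30000), prod(d), TRUE),
                           d), 8.5)
    lab <- label_volume(array(runif(prod(d)) > 0.7, d), 8.5)
    out <- mask_by_tissue(lab, vol, 13500)
    ## counting oracle: removed voxels = labelled voxels below the threshold
    removed <- sum(lab$mask) - sum(out$mask)
    expect_identical(removed, sum(lab$mask & vol$voxels < 13500))
    expect_equal(sum(out$mask & vol$voxels < 13500), 0)
    expect_true(all(!out$mask | lab$mask))   # output subset of input
    again <- mask_by_tissue(out, vol, 13500)
    expect_identical(again$mask, out$mask)
  }
  ## degenerate cases
  d <- c(8, 8, 4)
  air <- ct_volume(array(11000, d), 8.5)
  lab <- label_volume(array(TRUE, d), 8.5)
  expect_equal(sum(mask_by_tissue(lab, air, 13500)$mask), 0)
  tis <- ct_volume(array(17000, d), 8.5)
  expect_identical(mask_by_tissue(lab, tis, 13500)$mask, lab$mask)
  expect_error(mask_by_tissue(lab, ct_volume(array(1, c(4, 4, 4)), 8.5), 1),
               "match")
})

test_that("label statistics agree with an independent flood-fill counter", {
  ## closed form: two 100-voxel blobs at 10 um
  m <- array(FALSE, c(20, 20, 10))
  m[1:4, 1:5, 1:5] <- TRUE          # 100 voxels
  m[10:13, 10:14, 6:10] <- TRUE     # 100 voxels, disjoint
  st <- label_volume_stats(label_volume(m, 10))
  expect_equal(st$volume_mm3, 2e-4)
  expect_equal(st$n_components, 2L)
  expect_equal(label_volume_stats(label_volume(array(FALSE, c(4, 4, 4)), 10)),
               list(volume_mm3 = 0, n_components = 0L))
  ## phantom epithelium vs the plain-R flood fill oracle
  ph <- make_lung_phantom(small_params(c(32, 32, 32), 6, n_bubbles = 0))
  ep <- ph$ground_truth$epithelium
  st2 <- label_volume_stats(ep)
  expect_equal(st2$n_components, flood_count(ep$mask))
  expect_equal(st2$volume_mm3, sum(ep$mask) * 8.5^3 * 1e-9)
})

test_that("interpolated epithelium does not cross into vessel labels", {
  p <- small_params(c(64, 64, 32), 13)
  ph <- make_lung_phantom(p)
  idx <- c(0, 8, 16, 24)
  masks <- lapply(idx, function(z) ph$ground_truth$epithelium$mask[, , z + 1])
  stk <- assemble_sparse(masks, dim(ph$volume$voxels), indices = idx)
  dense <- contour_interpolate(stk, 8.5)
  dense <- mask_by_tissue(dense, ph$volume, 13500)
  vessels <- ph$ground_truth$vessel_lumen$mask | ph$ground_truth$vessel_wall$mask
  expect_equal(sum(dense$mask & vessels), 0)
})
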