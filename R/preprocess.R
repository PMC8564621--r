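#' Convert a 32-bit reconstruction to 16-bit with percentile windowing
#'
#' Linearly maps the grey-value window \[P_low, P_high\] (percentiles of the
#' input) onto \[0, 65535\], clipping values outside the window — the standard
#' conditioning step applied to floating-point CT reconstructions before any
#' further processing.
#'
#' @param volume32 3D numeric array (finite values).
#' @param window percentile pair `(low, high)`, `low < high`.
#' @param voxel_size voxel size (um) for the returned volume.
#' @param provenance provenance string for the returned volume.
#' @return A [ct_volume()] with values in \[0, 65535\].
#' @export
convert_to_uint16 <- function(volume32, window = c(0.01, 99.99),
                              voxel_size = 1, provenance = "converted") {
  if (!all(is.finite(volume32))) stop("volume must be finite")
  if (window[1] >= window[2]) stop("window must satisfy low < high")
  qs <- quantile(volume32, probs = window / 100, names = FALSE, type = 7)
  if (qs[2] <= qs[1]) {
    warning("constant volume (or degenerate window): mapping everything to 0")
    return(ct_volume(array(0, dim(volume32)), voxel_size, provenance))
  }
  v <- (volume32 - qs[1]) / (qs[2] - qs[1])
  ct_volume(round(clamp(v, 0, 1) * 65535), voxel_size, provenance)
}

#' Section plane defined by three points
#'
#' @param p1,p2,p3 non-collinear points in 0-based (x, y, z) voxel
#'   coordinates, defining the histology sectioning plane (3-point
#'   alignment).
#' @return An object of class `section_plane`.
#' @export
section_plane <- function(p1, p2, p3) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  n <- pracma_cross(p2 - p1, p3 - p1)
  if (sqrt(sum(n^2)) < 1e-9)
    stop("plane points are collinear (triangle area is zero)")
  structure(list(p1 = p1, p2 = p2, p3 = p3, normal = n / sqrt(sum(n^2))),
            class = "section_plane")
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Reslice a volume so its z-axis is normal to a section plane
#'
#' Rotates and reslices the dataset so that slice 0 of the output contains
#' the given plane, using bicubic interpolation by default (orders 0, 1 and 3
#' are available).  In-plane orientation is resolved by projecting the
#' original x-axis onto the plane.  Samples falling outside the input volume
#' are 0.
#'
#' @param volume a [ct_volume()].
#' @param plane a [section_plane()]; must intersect the volume.
#' @param interpolation_order 0, 1 or 3 (default 3, cubic).
#' @param out_shape optional c(ny, nx, nz) of the output grid; by default the
#'   input shape is kept.
#' @return A resliced [ct_volume()].
#' @export
reslice_to_plane <- function(volume, plane, interpolation_order = 3,
                             out_shape = dim(volume$voxels)) {
  stopifnot(inherits(volume, "ct_volume"), inherits(plane, "section_plane"))
  d <- dim(volume$voxels)
  nrm <- plane$normal
  if (nrm[3] < 0) nrm <- -nrm   # keep new z pointing into +z half-space
  ## in-plane axes: original x projected onto the plane, then the cross
  ex <- c(1, 0, 0) - sum(c(1, 0, 0) * nrm) * nrm
  if (sqrt(sum(ex^2)) < 1e-9) ex <- c(0, 1, 0) - sum(c(0, 1, 0) * nrm) * nrm
  ex <- ex / sqrt(sum(ex^2))
  ey <- pracma_cross(nrm, ex)
  origin <- plane$p1
  ny <- out_shape[1]; nx <- out_shape[2]; nz <- out_shape[3]
  ## plane must intersect the voxel grid: check signed distance of corners
  corners <- as.matrix(expand.grid(x = c(0, d[2] - 1), y = c(0, d[1] - 1),
                                   z = c(0, d[3] - 1)))
  sd <- as.numeric((corners - matrix(origin, 8, 3, byrow = TRUE)) %*% nrm)
  if (all(sd > 0) || all(sd < 0))
    stop("plane does not intersect the volume")
  out <- array(0, c(ny, nx, nz))
  gx <- rep(0:(nx - 1), each = ny)
  gy <- rep(0:(ny - 1), nx)
  sampler <- switch(as.character(interpolation_order),
                    "0" = function(X, Y, Z) {
                      ix <- round(X); iy <- round(Y); iz <- round(Z)
                      ok <- ix >= 0 & ix <= d[2] - 1 & iy >= 0 & iy <= d[1] - 1 &
                            iz >= 0 & iz <= d[3] - 1
                      v <- numeric(length(X))
                      v[ok] <- volume$voxels[cbind(iy[ok] + 1, ix[ok] + 1, iz[ok] + 1)]
                      v
                    },
                    "1" = function(X, Y, Z) sample_trilinear(volume$voxels, X, Y, Z),
                    "3" = function(X, Y, Z) sample_tricubic(volume$voxels, X, Y, Z),
                    stop("interpolation_order must be 0, 1 or 3"))
  for (k in 0:(nz - 1)) {
    X <- origin[1] + gx * ex[1] + gy * ey[1] + k * nrm[1]
    Y <- origin[2] + gx * ex[2] + gy * ey[2] + k * nrm[2]
    Z <- origin[3] + gx * ex[3] + gy * ey[3] + k * nrm[3]
    out[, , k + 1] <- matrix(sampler(X, Y, Z), ny, nx)
  }
  ct_volume(clamp(out, 0, 65535), volume$voxel_size,
            provenance = paste0(volume$provenance, " [resliced]"))
}

#' Detect and zero air-bubble artefacts and their bright rims
#'
#' Air bubbles trapped in the paraffin show as near-black voids outlined by
#' bright phase-contrast-like rims.  The detector is rule-based: candidate
#' voids are connected components of voxels darker than `void_threshold`
#' that do not touch the volume border (an enclosedness/hole test), and each
#' component's rim is its morphological dilation intersected with voxels
#' brighter than `rim_threshold` (or darker than the void threshold, which
#' re-attaches stray dark fragments split off by discretization).  Detection
#' is iterated on the masked volume to a fixed point, so the whole operation
#' is idempotent; the returned masked volume has grey value exactly 0
#' wherever the bubble mask is set and is unchanged elsewhere.
#'
#' @param volume a [ct_volume()].
#' @param void_threshold grey value below which a voxel is a void candidate;
#'   must sit below the airspace/paraffin grey level.
#' @param rim_threshold grey value above which a voxel can belong to an
#'   edge-enhancement rim (the vessel-wall window's lower bound by default).
#' @param rim_dilation how far (voxels) from a void to search for rim voxels.
#' @param min_voxels ignore void components smaller than this (noise guard).
#' @return A list with `bubble_mask` (a [label_volume()]) and `masked` (a
#'   [ct_volume()]).
#' @export
mask_air_bubbles <- function(volume, void_threshold = 8000,
                             rim_threshold = 24000, rim_dilation = 3,
                             min_voxels = 8) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$voxels)
  detect <- function(v) {
    cand <- v < void_threshold
    mask <- array(FALSE, d)
    if (!any(cand)) return(mask)
    labels <- .cc_label_3d(cand, d, 26L)
    nlab <- attr(labels, "n_components")
    labels <- array(labels, d)
    if (nlab == 0) return(mask)
    ## border-touching labels are open to the outside, not enclosed bubbles
    border_labels <- unique(c(labels[1, , ], labels[d[1], , ],
                              labels[, 1, ], labels[, d[2], ],
                              labels[, , 1], labels[, , d[3]]))
    border_labels <- border_labels[border_labels > 0]
    counts <- tabulate(labels[labels > 0], nbins = nlab)
    keep <- setdiff(which(counts >= min_voxels), border_labels)
    if (!length(keep)) return(mask)
    interior <- array(labels %in% keep, d)
    near <- dilate3d_n(interior, rim_dilation, connectivity = 26)
    ## the rim, plus stray dark voxels split off a kept void by
    ## discretization (their own components fall under min_voxels)
    interior | (near & (v > rim_threshold | v < void_threshold))
  }
  ## iterate to the fixed point: zeroing a rim can connect stray fragments,
  ## so detection is repeated on the masked volume until nothing changes,
  ## making the operation idempotent by construction
  mask <- array(FALSE, d)
  masked <- volume$voxels
  for (it in 1:5) {
    new_mask <- detect(masked)
    grew <- new_mask & !mask
    if (!any(grew)) break
    mask <- mask | new_mask
    masked[mask] <- 0
  }
  list(bubble_mask = label_volume(mask, volume$voxel_size),
       masked = ct_volume(masked, volume$voxel_size,
                          provenance = paste0(volume$provenance, " [debubbled]")))
}
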