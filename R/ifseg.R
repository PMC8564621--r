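#' Threshold a warped immunofluorescence image into a binary mask
#'
#' Applies the absolute intensity threshold that separates positive staining
#' from background, then removes speckle objects smaller than `min_area`
#' pixels.
#'
#' @param warped_if numeric matrix (warped IF channel).
#' @param threshold absolute intensity; pixels `>= threshold` are positive.
#' @param min_area minimum connected-object area kept, in pixels.
#' @return logical matrix.
#' @export
threshold_if <- function(warped_if, threshold, min_area = 10) {
  mask <- warped_if >= threshold
  if (min_area > 1 && any(mask)) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    counts <- tabulate(as.integer(lab[lab > 0]))
    small <- which(counts < min_area)
    if (length(small)) mask[as.matrix(lab) %in% small] <- FALSE
  }
  mask
}

#' Assemble sparse 2D masks into a labelled-slice stack
#'
#' Records which CT slices carry a registered IF segmentation mask; gaps
#' between consecutive labelled slices (sections were stained up to 40 um
#' apart, about 5 CT slices at 8.5 um) are later filled by
#' [contour_interpolate()].
#'
#' @param masks named list of logical matrices; names are 0-based slice
#'   indices (or a bare list with `indices` supplied).
#' @param volume_shape c(ny, nx, nz) of the target volume.
#' @param indices optional integer vector of 0-based slice indices.
#' @return object of class `sparse_label_stack` with `entries` (masks keyed
#'   by slice index, ascending), `volume_shape` and `interpolatable`.
#' @export
assemble_sparse <- function(masks, volume_shape, indices = NULL) {
  idx <- as.integer(indices %||% names(masks))
  if (length(idx) != length(masks) || anyNA(idx))
    stop("every mask needs a slice index")
  if (anyDuplicated(idx)) stop("duplicate slice indices")
  if (any(idx < 0 | idx > volume_shape[3] - 1))
    stop("slice index out of the volume z-range")
  for (m in masks)
    if (!identical(dim(m), as.integer(volume_shape[1:2])))
      stop("mask shape does not match the slice shape")
  o <- order(idx)
  structure(list(entries = setNames(masks[o], idx[o]),
                 volume_shape = as.integer(volume_shape),
                 interpolatable = length(idx) >= 2),
            class = "sparse_label_stack")
}

## signed Euclidean distance of a binary 2D mask (positive inside)
signed_distance2d <- function(mask) {
  if (!any(mask)) return(matrix(-1e6, nrow(mask), ncol(mask)))
  if (all(mask)) return(matrix(1e6, nrow(mask), ncol(mask)))
  dpos <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
  dneg <- as.matrix(EBImage::distmap(EBImage::Image((!mask) * 1)))
  dpos - dneg
}

## centroid (x, y) of a mask, 0-based
mask_centroid <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  c(mean(w[, 2]) - 1, mean(w[, 1]) - 1)
}

## sample a shifted signed-distance field: sd(x - t), bilinear
sample_sd_shifted <- function(sd, tx, ty) {
  ny <- nrow(sd); nx <- ncol(sd)
  gx <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  gy <- matrix(rep(0:(ny - 1), nx), ny, nx)
  matrix(sample_bilinear(sd, gx - tx, gy - ty, fill = -1e6), ny, nx)
}

## pair components of two slices: overlap after aligning bounding-box
## centroids; returns groups as list of list(a = labels in A, b = labels in B)
pair_components <- function(labA, labB) {
  nA <- max(labA); nB <- max(labB)
  edges <- NULL
  for (i in seq_len(nA)) {
    wa <- which(labA == i, arr.ind = TRUE)
    ca <- c(mean(range(wa[, 2])), mean(range(wa[, 1])))
    ma <- labA == i
    for (j in seq_len(nB)) {
      wb <- which(labB == j, arr.ind = TRUE)
      cb <- c(mean(range(wb[, 2])), mean(range(wb[, 1])))
      sh <- round(cb - ca)   # (x, y) shift aligning the bounding boxes
      shifted <- shift2d(ma, sh[2], sh[1], fill = FALSE)
      if (any(shifted & (labB == j))) edges <- rbind(edges, c(i, j))
    }
  }
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  ## connected components of the bipartite overlap graph
  groups <- list()
  usedA <- logical(nA); usedB <- logical(nB)
  for (i in seq_len(nA)) {
    if (usedA[i]) next
    qa <- i; qb <- integer(0)
    repeat {
      nb <- union(qb, edges[edges[, 1] %in% qa, 2])
      na <- union(qa, edges[edges[, 2] %in% nb, 1])
      if (setequal(na, qa) && setequal(nb, qb)) break
      qa <- na; qb <- nb
    }
    usedA[qa] <- TRUE; usedB[qb] <- TRUE
    groups[[length(groups) + 1]] <- list(a = qa, b = qb)
  }
  for (j in seq_len(nB)) if (!usedB[j])
    groups[[length(groups) + 1]] <- list(a = integer(0), b = j)
  groups
}

## intermediate mask between maskA (fraction 0) and maskB (fraction 1)
interp_gap_slice <- function(maskA, maskB, f) {
  ny <- nrow(maskA); nx <- ncol(maskA)
  out <- matrix(FALSE, ny, nx)
  emptyA <- !any(maskA); emptyB <- !any(maskB)
  if (emptyA && emptyB) return(out)
  taper <- function(mask, ff) {
    ## unpaired component: monotone shrink, extinct from the midpoint on
    if (ff >= 0.5) return(matrix(FALSE, nrow(mask), ncol(mask)))
    sd <- signed_distance2d(mask)
    sd >= 2 * ff * max(sd)
  }
  if (emptyB) return(taper(maskA, f))
  if (emptyA) return(taper(maskB, 1 - f))
  labA <- as.matrix(EBImage::bwlabel(EBImage::Image(maskA * 1)))
  labB <- as.matrix(EBImage::bwlabel(EBImage::Image(maskB * 1)))
  for (g in pair_components(labA, labB)) {
    ma <- array(labA %in% g$a, dim(labA))
    mb <- array(labB %in% g$b, dim(labB))
    if (!any(ma)) { out <- out | taper(mb, 1 - f); next }
    if (!any(mb)) { out <- out | taper(ma, f); next }
    t <- mask_centroid(mb) - mask_centroid(ma)
    sda <- sample_sd_shifted(signed_distance2d(ma), f * t[1], f * t[2])
    sdb <- sample_sd_shifted(signed_distance2d(mb), -(1 - f) * t[1], -(1 - f) * t[2])
    out <- out | ((1 - f) * sda + f * sdb >= 0)
  }
  out
}

#' Morphological contour interpolation of a sparse label stack
#'
#' Fills every gap between consecutive labelled slices by signed-distance
#' -field morphing: corresponding connected components (paired by overlap
#' after aligning their bounding boxes) are interpolated along their
#' connecting translation; components with no partner taper monotonically and
#' are extinct from the gap midpoint onward.  Labelled slices are reproduced
#' verbatim and slices outside the first/last entry stay empty.
#'
#' @param stack a [assemble_sparse()] stack with at least 2 entries.
#' @param voxel_size voxel size (um) for the result.
#' @return A [label_volume()] over the full volume shape.
#' @export
contour_interpolate <- function(stack, voxel_size = 1) {
  stopifnot(inherits(stack, "sparse_label_stack"))
  if (!stack$interpolatable)
    stop("need at least 2 labelled slices to interpolate")
  d <- stack$volume_shape
  out <- array(FALSE, d)
  idx <- as.integer(names(stack$entries))
  for (k in seq_along(idx))
    out[, , idx[k] + 1] <- stack$entries[[k]]
  for (k in seq_len(length(idx) - 1)) {
    z1 <- idx[k]; z2 <- idx[k + 1]
    if (z2 - z1 < 2) next
    A <- stack$entries[[k]]; B <- stack$entries[[k + 1]]
    for (z in (z1 + 1):(z2 - 1)) {
      f <- (z - z1) / (z2 - z1)
      out[, , z + 1] <- interp_gap_slice(A, B, f)
    }
  }
  label_volume(out, voxel_size)
}

#' Constrain a label volume to tissue voxels of the CT volume
#'
#' Binarizes the CT volume at `tissue_threshold` (tissue = 1, airspace and
#' paraffin = 0) and multiplies the label volume by it, removing segmented
#' voxels that interpolation placed in airspaces or lumina.  The operation
#' never adds voxels and is idempotent.
#'
#' @param dense a [label_volume()].
#' @param volume a [ct_volume()] on the same grid.
#' @param tissue_threshold grey value at/above which a voxel is tissue.
#' @return A [label_volume()].
#' @export
mask_by_tissue <- function(dense, volume, tissue_threshold) {
  if (!identical(dim(dense$mask), dim(volume$voxels)))
    stop("label and volume shapes must match")
  label_volume(dense$mask & (volume$voxels >= tissue_threshold),
               dense$voxel_size)
}

#' Volume and 26-connected component count of a label volume
#'
#' @param label a [label_volume()].
#' @param voxel_size voxel size (um); defaults to the label's.
#' @return list with `volume_mm3` and `n_components`.
#' @export
label_volume_stats <- function(label, voxel_size = NULL) {
  voxel_size <- voxel_size %||% label$voxel_size
  n_comp <- if (any(label$mask)) {
    attr(.cc_label_3d(label$mask, dim(label$mask), 26L), "n_components")
  } else 0L
  list(volume_mm3 = network_volume(label$mask, voxel_size),
       n_components = as.integer(n_comp))
}
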