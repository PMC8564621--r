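#' Paired landmark set
#'
#' Equal-length lists of moving-image and fixed-image (x, y) point
#' coordinates (0-based pixels) that drive the thin-plate-spline warp.
#'
#' @param moving_pts,fixed_pts two-column matrices of (x, y) coordinates.
#' @param scale_level optional integer vector recording the pyramid level each
#'   pair was found at (provenance only).
#' @param min_spacing minimum allowed distance between two moving points, in
#'   pixels; closer duplicates are an error because exact-interpolation TPS
#'   cannot separate them.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(moving_pts, fixed_pts, scale_level = NULL,
                         min_spacing = 8) {
  moving_pts <- matrix(as.numeric(moving_pts), ncol = 2)
  fixed_pts <- matrix(as.numeric(fixed_pts), ncol = 2)
  if (nrow(moving_pts) != nrow(fixed_pts))
    stop("moving and fixed point lists must have equal length")
  if (nrow(moving_pts) && !all(is.finite(moving_pts)) || !all(is.finite(fixed_pts)))
    stop("landmark coordinates must be finite")
  if (nrow(moving_pts) > 1) {
    d <- as.matrix(stats::dist(moving_pts))
    diag(d) <- Inf
    if (min(d) < min_spacing * 0.999)
      stop(sprintf("two moving landmarks are closer than min_spacing = %g px",
                   min_spacing))
  }
  structure(list(moving_pts = moving_pts, fixed_pts = fixed_pts,
                 scale_level = scale_level %||% rep(1L, nrow(moving_pts)),
                 min_spacing = min_spacing),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d pairs\n", nrow(x$moving_pts)))
  invisible(x)
}

#' Write/read landmark pairs as CSV (x_moving, y_moving, x_fixed, y_fixed)
#'
#' The CSV layout is interchangeable with manually placed BigWarp-style
#' landmark exports, so manual landmarks can be substituted for automated ones.
#' @param landmarks a [landmark_set()].
#' @param path CSV path.
#' @export
write_landmarks_csv <- function(landmarks, path) {
  df <- data.frame(x_moving = landmarks$moving_pts[, 1],
                   y_moving = landmarks$moving_pts[, 2],
                   x_fixed = landmarks$fixed_pts[, 1],
                   y_fixed = landmarks$fixed_pts[, 2])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @param min_spacing passed to [landmark_set()].
#' @export
read_landmarks_csv <- function(path, min_spacing = 8) {
  df <- read.csv(path)
  landmark_set(cbind(df$x_moving, df$y_moving), cbind(df$x_fixed, df$y_fixed),
               min_spacing = min_spacing)
}

## TPS radial basis: U(r) = r^2 log r, with U(0) = 0.
tps_kernel <- function(r) {
  out <- r * r * log(r)
  out[r == 0] <- 0
  out
}

#' Fit a thin-plate-spline transform to landmark pairs
#'
#' Solves the classical TPS linear system with kernel `U(r) = r^2 log(r)`.
#' With `lambda = 0` (the default, matching BigWarp's behaviour) the transform
#' interpolates exactly: every moving point is mapped onto its fixed partner.
#'
#' @param landmarks a [landmark_set()] with at least 3 non-collinear pairs.
#' @param lambda regularization weight (>= 0); 0 gives exact interpolation.
#' @param invert if `TRUE`, fit the reverse-direction transform (fixed ->
#'   moving) on the same pairs, as needed for backward image warping.
#' @return An object of class `tps_transform` with elements `control_pts`
#'   (source landmark locations), `affine` (6 coefficients), `weights`
#'   (n x 2 bending weights) and `lambda`.
#' @export
fit_tps <- function(landmarks, lambda = 0, invert = FALSE) {
  src <- if (invert) landmarks$fixed_pts else landmarks$moving_pts
  dst <- if (invert) landmarks$moving_pts else landmarks$fixed_pts
  n <- nrow(src)
  if (n < 3) stop("need at least 3 landmark pairs to fit a TPS")
  ## collinearity test: area spanned by the source points
  sv <- svd(sweep(src, 2, colMeans(src)))$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("landmarks are collinear (or duplicated); TPS system is singular")
  K <- tps_kernel(as.matrix(stats::dist(src)))
  if (lambda > 0) K <- K + diag(lambda, n)
  P <- cbind(1, src)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(dst, matrix(0, 3, 2))
  sol <- solve(L, rhs)
  structure(list(control_pts = src,
                 weights = sol[seq_len(n), , drop = FALSE],
                 affine = sol[n + 1:3, , drop = FALSE],
                 lambda = lambda,
                 inverted = invert),
            class = "tps_transform")
}

#' Apply a TPS transform to points
#'
#' @param tps a `tps_transform` from [fit_tps()].
#' @param pts two-column matrix of (x, y) coordinates.
#' @return Transformed coordinates, same shape.
#' @export
tps_apply <- function(tps, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  P <- cbind(1, pts)
  lin <- P %*% tps$affine
  ## pairwise distances points x control points
  d2 <- outer(pts[, 1], tps$control_pts[, 1], `-`)^2 +
        outer(pts[, 2], tps$control_pts[, 2], `-`)^2
  U <- tps_kernel(sqrt(d2))
  lin + U %*% tps$weights
}

#' @export
print.tps_transform <- function(x, ...) {
  cat(sprintf("<tps_transform> %d control points, lambda = %g%s\n",
              nrow(x$control_pts), x$lambda,
              if (x$inverted) " (reverse direction)" else ""))
  invisible(x)
}

#' Warp a 2D image with a fitted TPS
#'
#' Backward warping: every output pixel on the fixed grid is sampled at its
#' inverse-mapped location in the moving image.  The inverse map is obtained
#' by fitting the reverse-direction TPS on the same landmark pairs (BigWarp
#' semantics).  Out-of-bounds samples are 0.
#'
#' @param image numeric matrix (moving image).
#' @param landmarks the [landmark_set()] defining the transform, or a
#'   reverse-direction `tps_transform` (from `fit_tps(..., invert = TRUE)`).
#' @param out_shape c(ny, nx) of the output; defaults to `dim(image)`.
#' @param interpolation_order 0 (nearest), 1 (bilinear) or 3 (bicubic).
#' @return Warped image matrix of shape `out_shape`.
#' @export
warp_image <- function(image, landmarks, out_shape = dim(image),
                       interpolation_order = 1) {
  inv <- if (inherits(landmarks, "tps_transform")) {
    if (!landmarks$inverted)
      stop("supply a reverse-direction tps_transform or a landmark_set")
    landmarks
  } else fit_tps(landmarks, invert = TRUE)
  ny <- out_shape[1]; nx <- out_shape[2]
  grid <- cbind(rep(0:(nx - 1), each = ny), rep(0:(ny - 1), nx))
  src <- tps_apply(inv, grid)
  vals <- switch(as.character(interpolation_order),
    "0" = sample_nearest(image, src[, 1], src[, 2]),
    "1" = sample_bilinear(image, src[, 1], src[, 2]),
    "3" = sample_bicubic(image, src[, 1], src[, 2]),
    stop("interpolation_order must be 0, 1 or 3"))
  matrix(vals, ny, nx)
}
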