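## Multi-scale feature correspondence between an autofluorescence section and
## its micro-CT plane.  Keypoints are difference-of-Gaussian extrema detected
## on the contrast-normalized fixed image; each keypoint's neighbourhood is
## then located in the moving image by normalized cross-correlation over a
## bounded displacement search, with subpixel refinement, a distinctness
## (ratio) test, and a robust global-affine consensus filter before any
## thin-plate-spline fitting.

#' Contrast-normalize an image for multimodal feature matching
#'
#' Percentile windowing to \[0, 1\] followed by adaptive histogram
#' equalization, so that a monotone grey-value remapping between modalities
#' (CT grey vs tissue autofluorescence) does not defeat correlation matching.
#'
#' @param img numeric matrix.
#' @param invert flip polarity first (for modalities where tissue/air
#'   contrast is reversed).
#' @return matrix with values in \[0, 1\].
#' @export
normalize_for_matching <- function(img, invert = FALSE) {
  if (invert) img <- -img
  qs <- quantile(img, c(0.01, 0.99), names = FALSE)
  if (qs[2] <= qs[1]) return(matrix(0, nrow(img), ncol(img)))
  v <- clamp((img - qs[1]) / (qs[2] - qs[1]), 0, 1)
  nt <- max(2L, min(8L, floor(min(dim(v)) / 32)))
  out <- tryCatch(
    as.matrix(EBImage::clahe(EBImage::Image(v), nx = nt, ny = nt, bins = 256)),
    error = function(e) v)
  out
}

## local maxima of a response map (8-neighbour non-max suppression)
local_maxima <- function(resp, threshold) {
  mx <- resp
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    mx <- pmax(mx, shift2d(resp, dy, dx, fill = -Inf))
  }
  which(resp >= mx & resp > threshold, arr.ind = TRUE)
}

#' Detect blob-like keypoints via difference-of-Gaussian extrema
#'
#' @param img normalized image matrix.
#' @param sigma base Gaussian scale in pixels.
#' @param margin exclusion border in pixels.
#' @param threshold_rel response threshold relative to the maximum response.
#' @param n_max keep at most this many strongest keypoints.
#' @return matrix with columns `x`, `y` (0-based) and `strength`.
#' @export
detect_keypoints <- function(img, sigma = 1.6, margin = 16,
                             threshold_rel = 0.05, n_max = 400) {
  if (sd(img) == 0) return(matrix(numeric(0), 0, 3,
                                  dimnames = list(NULL, c("x", "y", "strength"))))
  g1 <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma))
  g2 <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma * 1.6))
  resp <- abs(g1 - g2)
  pk <- local_maxima(resp, threshold_rel * max(resp))
  if (!nrow(pk)) return(matrix(numeric(0), 0, 3,
                               dimnames = list(NULL, c("x", "y", "strength"))))
  x <- pk[, 2] - 1; y <- pk[, 1] - 1
  keep <- x >= margin & x < ncol(img) - margin & y >= margin & y < nrow(img) - margin
  x <- x[keep]; y <- y[keep]
  s <- resp[cbind(y + 1, x + 1)]
  o <- order(-s)
  o <- head(o, n_max)
  cbind(x = x[o], y = y[o], strength = s[o])
}

## FFT cross-correlation of `kernel` over `img` ("valid" region), returning
## a matrix of raw correlation sums indexed by kernel top-left offset.
xcorr2 <- function(img, kernel) {
  ni <- dim(img); nk <- dim(kernel)
  nf <- ni + nk - 1
  pad <- function(m, d) { out <- matrix(0, d[1], d[2]); out[seq_len(nrow(m)), seq_len(ncol(m))] <- m; out }
  F1 <- fft(pad(img, nf))
  F2 <- fft(pad(kernel[rev(seq_len(nk[1])), rev(seq_len(nk[2])), drop = FALSE], nf))
  full <- Re(fft(F1 * F2, inverse = TRUE)) / prod(nf)
  full[nk[1]:ni[1], nk[2]:ni[2], drop = FALSE]
}

## NCC of a patch against all positions inside a search window.
ncc_map <- function(window, patch) {
  n <- length(patch)
  pz <- patch - mean(patch)
  psd <- sqrt(sum(pz^2))
  if (psd == 0) return(NULL)
  ones <- matrix(1, nrow(patch), ncol(patch))
  num <- xcorr2(window, pz)
  s1 <- xcorr2(window, ones)
  s2 <- xcorr2(window^2, ones)
  varw <- pmax(s2 - s1^2 / n, 0)
  den <- sqrt(varw) * psd
  out <- num / den
  out[den < 1e-9] <- 0
  out
}

## quadratic subpixel refinement of a peak at (iy, ix) in map m
subpixel_peak <- function(m, iy, ix) {
  dy <- dx <- 0
  if (iy > 1 && iy < nrow(m)) {
    a <- m[iy - 1, ix]; b <- m[iy, ix]; c <- m[iy + 1, ix]
    den <- a - 2 * b + c
    if (den < 0) dy <- clamp(0.5 * (a - c) / den, -0.5, 0.5)
  }
  if (ix > 1 && ix < ncol(m)) {
    a <- m[iy, ix - 1]; b <- m[iy, ix]; c <- m[iy, ix + 1]
    den <- a - 2 * b + c
    if (den < 0) dx <- clamp(0.5 * (a - c) / den, -0.5, 0.5)
  }
  c(dy, dx)
}

## reflective padding of a matrix by p pixels on every side
pad_reflect <- function(m, p) {
  ny <- nrow(m); nx <- ncol(m)
  p <- min(p, ny - 1, nx - 1)
  ridx <- c(rev(seq_len(p) + 1), seq_len(ny), ny - seq_len(p))
  cidx <- c(rev(seq_len(p) + 1), seq_len(nx), nx - seq_len(p))
  m[ridx, cidx, drop = FALSE]
}

## Match keypoints of `fixed` into `moving` by windowed NCC.  Both images are
## reflect-padded so keypoints may sit anywhere in the true image area.
## Returns data.frame(mx, my, fx, fy, score) in unpadded coordinates.
match_level <- function(moving, fixed, patch_radius, search_radius,
                        ratio, min_corr, n_max) {
  true_ny <- nrow(fixed); true_nx <- ncol(fixed)
  marg <- patch_radius + search_radius + 1
  pad <- min(marg, true_ny - 1, true_nx - 1)
  moving <- pad_reflect(moving, pad)
  fixed <- pad_reflect(fixed, pad)
  kp <- detect_keypoints(fixed, margin = marg, n_max = 4 * n_max)
  if (nrow(kp)) {
    ## keep keypoints inside the true (unpadded) image area
    keep <- kp[, "x"] >= pad & kp[, "x"] < pad + true_nx &
            kp[, "y"] >= pad & kp[, "y"] < pad + true_ny
    kp <- head(kp[keep, , drop = FALSE], n_max)
  }
  if (!nrow(kp)) return(NULL)
  res <- vector("list", nrow(kp))
  for (i in seq_len(nrow(kp))) {
    x <- kp[i, "x"]; y <- kp[i, "y"]
    P <- fixed[(y - patch_radius):(y + patch_radius) + 1,
               (x - patch_radius):(x + patch_radius) + 1]
    W <- moving[(y - patch_radius - search_radius):(y + patch_radius + search_radius) + 1,
                (x - patch_radius - search_radius):(x + patch_radius + search_radius) + 1]
    if (sd(P) == 0 || sd(W) == 0) next
    m <- ncc_map(W, P)
    if (is.null(m)) next
    pk <- which(m == max(m), arr.ind = TRUE)[1, ]
    best <- m[pk[1], pk[2]]
    if (best < min_corr) next
    ## distinctness: best peak must beat the best peak found elsewhere
    m2 <- m
    m2[max(1, pk[1] - 3):min(nrow(m), pk[1] + 3),
       max(1, pk[2] - 3):min(ncol(m), pk[2] + 3)] <- -Inf
    second <- max(m2)
    if (is.finite(second) && second > 0 && (1 - best) > ratio * (1 - second)) next
    sp <- subpixel_peak(m, pk[1], pk[2])
    dy <- (pk[1] - 1 + sp[1]) - search_radius
    dx <- (pk[2] - 1 + sp[2]) - search_radius
    res[[i]] <- c(mx = x + dx, my = y + dy, fx = x, fy = y, score = best)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(NULL)
  out <- as.data.frame(do.call(rbind, res))
  ## back to unpadded coordinates; drop matches landing in the padding
  out$mx <- out$mx - pad; out$my <- out$my - pad
  out$fx <- out$fx - pad; out$fy <- out$fy - pad
  out[out$mx >= 0 & out$mx < true_nx & out$my >= 0 & out$my < true_ny, ,
      drop = FALSE]
}

## Local displacement-consistency filter: the sectioning deformation is
## smooth, so a correct match's displacement must agree with the median
## displacement of its nearest neighbours.
local_consistency <- function(mx, my, fx, fy, k = 6, tol = 6) {
  n <- length(mx)
  if (n < 10) return(rep(TRUE, n))
  ux <- fx - mx; uy <- fy - my
  keep <- logical(n)
  for (i in seq_len(n)) {
    d2 <- (mx - mx[i])^2 + (my - my[i])^2
    nb <- order(d2)[2:min(k + 1, n)]
    keep[i] <- sqrt((ux[i] - median(ux[nb]))^2 +
                    (uy[i] - median(uy[nb]))^2) <= tol
  }
  keep
}

## Robust affine consensus (RANSAC on 3-point samples + least-squares refit).
affine_consensus <- function(mx, my, fx, fy, tol = 15, iterations = 600) {
  n <- length(mx)
  if (n < 4) return(rep(TRUE, n))
  A <- cbind(1, mx, my)
  best_inl <- NULL
  ## internally seeded so the consensus is a pure function of its inputs
  with_seed(20211103L, for (it in seq_len(iterations)) {
    s <- sample.int(n, 3)
    M <- A[s, , drop = FALSE]
    if (abs(det(M)) < 1e-6) next
    cf <- tryCatch(solve(M, cbind(fx[s], fy[s])), error = function(e) NULL)
    if (is.null(cf)) next
    pred <- A %*% cf
    r <- sqrt((pred[, 1] - fx)^2 + (pred[, 2] - fy)^2)
    inl <- r <= tol
    if (is.null(best_inl) || sum(inl) > sum(best_inl)) best_inl <- inl
  })
  if (is.null(best_inl) || sum(best_inl) < 3) return(rep(TRUE, n))
  ## refit on inliers and re-evaluate
  cf <- stats::lsfit(A[best_inl, 2:3, drop = FALSE],
                     cbind(fx[best_inl], fy[best_inl]))$coefficients
  pred <- A %*% rbind(cf[1, ], cf[2, ], cf[3, ])
  r <- sqrt((pred[, 1] - fx)^2 + (pred[, 2] - fy)^2)
  r <= tol
}

#' Hierarchical feature correspondence between two images
#'
#' Runs keypoint detection and correlation matching independently at each of
#' `levels` image resolutions (full, 1/2, 1/4 ... ), giving a hierarchy of
#' feature sizes; coarse-level matches are rescaled to full resolution, the
#' union is filtered by a distinctness (ratio) test and a robustly fitted
#' global affine consensus, and deduplicated so no two moving points are
#' closer than `min_spacing`.
#'
#' @param moving,fixed numeric matrices of the same scene (moving = deformed
#'   section autofluorescence, fixed = CT plane); both must be non-constant.
#' @param levels number of pyramid levels (default 3).
#' @param patch_radius descriptor patch radius in pixels (per level).
#' @param search_radius maximum displacement searched at full resolution, in
#'   pixels; coarser levels cover proportionally larger ranges.
#' @param ratio distinctness (Lowe-style) ratio threshold on correlation
#'   distances.
#' @param min_corr minimum acceptable peak correlation.
#' @param min_spacing deduplication radius in full-resolution pixels.
#' @param affine_tol inlier tolerance (px) of the robust affine consensus.
#' @param max_landmarks keep at most this many strongest matches.
#' @param normalized set `TRUE` if both images are already contrast
#'   normalized to \[0, 1\].
#' @return A [landmark_set()]; moving/fixed points in full-resolution pixels.
#' @export
hierarchical_match <- function(moving, fixed, levels = 3,
                               patch_radius = 10, search_radius = 30,
                               ratio = 0.85, min_corr = 0.5,
                               min_spacing = 8, affine_tol = 15,
                               max_landmarks = 200, normalized = FALSE) {
  if (sd(moving) == 0 || sd(fixed) == 0)
    stop(structure(class = c("xrh_match_failure", "error", "condition"),
                   list(message = "constant (textureless) image: no features to match",
                        call = sys.call())))
  if (!normalized) {
    moving <- normalize_for_matching(moving)
    fixed <- normalize_for_matching(fixed)
  }
  all <- list()
  for (lev in seq_len(levels)) {
    s <- 2^(-(lev - 1))
    if (s < 1) {
      mv <- as.matrix(EBImage::resize(EBImage::Image(moving),
                                      w = max(8, round(ncol(moving) * s)),
                                      h = max(8, round(nrow(moving) * s))))
      fx <- as.matrix(EBImage::resize(EBImage::Image(fixed),
                                      w = max(8, round(ncol(fixed) * s)),
                                      h = max(8, round(nrow(fixed) * s))))
    } else {
      mv <- moving; fx <- fixed
    }
    sr <- max(4, ceiling(search_radius * s) + 2)
    m <- match_level(mv, fx, patch_radius, sr, ratio, min_corr,
                     n_max = ceiling(400 * s))
    if (is.null(m)) next
    ## map level coordinates back to full resolution (pixel-centre aligned)
    f <- 1 / s
    m$mx <- (m$mx + 0.5) * f - 0.5; m$my <- (m$my + 0.5) * f - 0.5
    m$fx <- (m$fx + 0.5) * f - 0.5; m$fy <- (m$fy + 0.5) * f - 0.5
    m$level <- lev
    all[[lev]] <- m
  }
  m <- do.call(rbind, all)
  if (is.null(m) || nrow(m) < 4)
    stop(structure(class = c("xrh_match_failure", "error", "condition"),
                   list(message = sprintf(
                     "fewer than 4 feature matches survived (%d)",
                     if (is.null(m)) 0L else nrow(m)), call = sys.call())))
  inl <- affine_consensus(m$mx, m$my, m$fx, m$fy, tol = affine_tol)
  m <- m[inl, , drop = FALSE]
  if (nrow(m) < 4)
    stop(structure(class = c("xrh_match_failure", "error", "condition"),
                   list(message = "fewer than 4 matches after affine consensus",
                        call = sys.call())))
  ## the residual deformation is smooth: drop matches whose displacement
  ## disagrees with their neighbourhood (outliers would be interpolated
  ## verbatim by an exact TPS)
  m <- m[local_consistency(m$mx, m$my, m$fx, m$fy), , drop = FALSE]
  if (nrow(m) < 4)
    stop(structure(class = c("xrh_match_failure", "error", "condition"),
                   list(message = "fewer than 4 matches after consistency filtering",
                        call = sys.call())))
  ## dedup: keep the strongest match within each min_spacing neighbourhood
  m <- m[order(-m$score), , drop = FALSE]
  keep <- logical(nrow(m))
  kx <- ky <- numeric(0)
  for (i in seq_len(nrow(m))) {
    if (length(kx) && min((kx - m$mx[i])^2 + (ky - m$my[i])^2) < min_spacing^2)
      next
    keep[i] <- TRUE
    kx <- c(kx, m$mx[i]); ky <- c(ky, m$my[i])
    if (sum(keep) >= max_landmarks) break
  }
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 4)
    stop(structure(class = c("xrh_match_failure", "error", "condition"),
                   list(message = "fewer than 4 matches after deduplication",
                        call = sys.call())))
  landmark_set(cbind(m$mx, m$my), cbind(m$fx, m$fy),
               scale_level = m$level, min_spacing = min_spacing)
}
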