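#' Binarize an image into the 255/1 tissue/airspace encoding
#'
#' Tissue pixels are encoded 255 and airspace pixels 1 — the 8-bit encoding
#' whose pixelwise product distinguishes tissue-tissue, air-air and
#' mismatched overlap in a single pass.
#'
#' @param image numeric matrix.
#' @param method `"otsu"` (default; requires a non-constant image) or
#'   `"fixed"`.
#' @param threshold threshold for `method = "fixed"` (pixels `>= threshold`
#'   are tissue).
#' @return integer matrix containing only values 1 and 255.
#' @export
binarize_tissue <- function(image, method = c("otsu", "fixed"),
                            threshold = NULL) {
  method <- match.arg(method)
  if (method == "otsu") {
    rng <- range(image)
    if (rng[1] == rng[2])
      stop("constant image: automatic (Otsu) thresholding is undefined")
    v <- (image - rng[1]) / (rng[2] - rng[1])
    th <- EBImage::otsu(EBImage::Image(v), range = c(0, 1))
    tissue <- v > th
  } else {
    if (is.null(threshold)) stop("method = 'fixed' needs a threshold")
    tissue <- image >= threshold
  }
  matrix(ifelse(tissue, 255L, 1L), nrow(image), ncol(image))
}

#' Registration accuracy report from two 255/1 masks
#'
#' Computes the per-pixel product of the two masks in double precision (so
#' 255 x 255 = 65025 cannot clip): 65025 means tissue over tissue (accurate),
#' 1 means airspace over airspace (accurate) and 255 means tissue over
#' airspace in either direction (inaccurate).
#'
#' @param mask_a,mask_b matrices containing only values 1 and 255, same shape.
#' @param valid optional logical matrix: pixels to evaluate (e.g. excluding
#'   padding introduced by warping); default all.
#' @return list with `report` (class `registration_report`: percentages
#'   `pct_tissue_tissue`, `pct_air_air`, `pct_mismatch` summing to 100, and
#'   `n_pixels`) and `category_image` (integer matrix: 2 = tissue-tissue,
#'   1 = air-air, 3 = mismatch, 0 = not evaluated).
#' @export
overlap_report <- function(mask_a, mask_b, valid = NULL) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("masks must have the same shape")
  if (!all(mask_a %in% c(1, 255)) || !all(mask_b %in% c(1, 255)))
    stop("masks must contain only the values 1 and 255")
  valid <- valid %||% matrix(TRUE, nrow(mask_a), ncol(mask_a))
  prod <- as.numeric(mask_a) * as.numeric(mask_b)
  cat_img <- matrix(0L, nrow(mask_a), ncol(mask_a))
  cat_img[valid & prod == 65025] <- 2L
  cat_img[valid & prod == 1] <- 1L
  cat_img[valid & prod == 255] <- 3L
  n <- sum(valid)
  if (n == 0) stop("no pixels to evaluate")
  report <- structure(list(
    pct_tissue_tissue = 100 * sum(cat_img == 2L) / n,
    pct_air_air = 100 * sum(cat_img == 1L) / n,
    pct_mismatch = 100 * sum(cat_img == 3L) / n,
    n_pixels = n), class = "registration_report")
  list(report = report, category_image = cat_img)
}

#' @export
print.registration_report <- function(x, ...) {
  cat(sprintf(paste0("<registration_report> accurate %.2f%% ",
                     "(tissue-tissue %.2f%%, air-air %.2f%%), ",
                     "inaccurate %.2f%% of %d px\n"),
              x$pct_tissue_tissue + x$pct_air_air, x$pct_tissue_tissue,
              x$pct_air_air, x$pct_mismatch, x$n_pixels))
  invisible(x)
}

#' Accurate-overlap percentage of a report
#' @param report a `registration_report`.
#' @export
accurate_pct <- function(report) report$pct_tissue_tissue + report$pct_air_air

#' Colour overlay of registration accuracy over a CT slice
#'
#' Inaccurate (tissue-air) overlap is rendered red, accurate overlap cyan
#' (airspace-airspace) or blue (tissue-tissue), blended over the CT slice.
#'
#' @param ct_slice numeric matrix (grey background).
#' @param category_image category matrix from [overlap_report()].
#' @param alpha blend weight of the category colour.
#' @return numeric array `ny x nx x 3` with values in \[0, 1\].
#' @export
overlay_figure <- function(ct_slice, category_image, alpha = 0.5) {
  if (!identical(dim(ct_slice), dim(category_image)))
    stop("shapes must match")
  g <- ct_slice / max(ct_slice, 1)
  cols <- rbind(c(0, 0, 0),      # 0: not evaluated -> plain grey
                c(0, 1, 1),      # 1: air-air -> cyan
                c(0, 0, 1),      # 2: tissue-tissue -> blue
                c(1, 0, 0))      # 3: mismatch -> red
  out <- array(0, c(dim(g), 3))
  w <- ifelse(category_image == 0L, 0, alpha)
  for (ch in 1:3) {
    col <- matrix(cols[category_image + 1L, ch], nrow(g), ncol(g))
    out[, , ch] <- (1 - w) * g + w * col
  }
  out
}

#' Write an accuracy bar chart (accurate vs inaccurate) as PNG
#'
#' @param reports list of `registration_report`s (one per image pair).
#' @param path output PNG path.
#' @export
write_accuracy_barchart <- function(reports, path) {
  acc <- vapply(reports, accurate_pct, numeric(1))
  inacc <- vapply(reports, function(r) r$pct_mismatch, numeric(1))
  grDevices::png(path, width = 640, height = 480)
  on.exit(grDevices::dev.off())
  stats <- c(mean(acc), mean(inacc))
  err <- c(sd(acc), sd(inacc))
  bp <- graphics::barplot(stats, names.arg = c("accurate", "inaccurate"),
                          col = c("blue", "red"), ylim = c(0, 100),
                          ylab = "% of evaluated pixels")
  if (length(acc) > 1)
    graphics::arrows(bp, stats - err, bp, stats + err, angle = 90, code = 3,
                     length = 0.1)
  invisible(path)
}
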