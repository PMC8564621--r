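#' Pair section and CT-slice image files by nomenclature
#'
#' Files are matched on the key captured by one regex group (typically the
#' slice number embedded in the file name), ensuring matched images are
#' opened together for registration.  Pairs are returned sorted by key;
#' unmatched files on either side are reported in the result.
#'
#' @param directory directory to scan.
#' @param section_pattern,ct_pattern regular expressions with exactly one
#'   capture group each, selecting section and CT-slice files and capturing
#'   the shared key.
#' @return A list with `pairs` (data.frame `key`, `section`, `ct`) and
#'   `unmatched` (character vector of unpaired file names).
#' @export
pair_images <- function(directory,
                        section_pattern = "^sec_([0-9]+)\\.tiff?$",
                        ct_pattern = "^ct_([0-9]+)\\.tiff?$") {
  grab <- function(pattern) {
    files <- list.files(directory)
    hit <- grepl(pattern, files)
    keys <- sub(pattern, "\\1", files[hit])
    if (anyDuplicated(keys))
      stop("duplicate keys on one side: ",
           paste(files[hit][keys %in% keys[duplicated(keys)]], collapse = ", "))
    list(files = files[hit], keys = keys)
  }
  sec <- grab(section_pattern)
  ct <- grab(ct_pattern)
  common <- intersect(sec$keys, ct$keys)
  common <- common[order(as.numeric(common))]
  pairs <- data.frame(
    key = common,
    section = file.path(directory, sec$files[match(common, sec$keys)]),
    ct = file.path(directory, ct$files[match(common, ct$keys)]),
    stringsAsFactors = FALSE)
  unmatched <- c(sec$files[!sec$keys %in% common], ct$files[!ct$keys %in% common])
  list(pairs = pairs, unmatched = unmatched)
}

#' Apply a similarity (rotation + scale) pre-alignment to an image
#'
#' Reproduces, deterministically, the manual "rotate and downscale" step that
#' brings a microscopy section onto the CT pixel grid: the known pixel sizes
#' give the scale and the mounting orientation gives the rotation.  Backward
#' mapping with bicubic interpolation about the image centre.
#'
#' @param img numeric matrix.
#' @param rotation_deg rotation angle, degrees, counter-clockwise.
#' @param scale output-to-input scale factor (e.g. microscopy at 0.645 um/px
#'   downscaled to CT at 8.5 um/px uses `scale = 8.5 / 0.645`).
#' @param out_shape output c(ny, nx); defaults to `round(dim(img) / scale)`.
#' @export
apply_similarity <- function(img, rotation_deg = 0, scale = 1,
                             out_shape = NULL) {
  out_shape <- out_shape %||% pmax(8, round(dim(img) / scale))
  ny <- out_shape[1]; nx <- out_shape[2]
  th <- rotation_deg * pi / 180
  cin <- (dim(img) - 1) / 2    # (y, x) centre of input
  cout <- (c(ny, nx) - 1) / 2
  gx <- rep(0:(nx - 1), each = ny) - cout[2]
  gy <- rep(0:(ny - 1), nx) - cout[1]
  ## backward map: output pixel -> input location (rotate by -theta, scale up)
  sx <- scale * (cos(th) * gx + sin(th) * gy) + cin[2]
  sy <- scale * (-sin(th) * gx + cos(th) * gy) + cin[1]
  matrix(sample_bicubic(img, sx, sy), ny, nx)
}

#' Register one fluorescence section to its CT plane and warp both channels
#'
#' The automated warping workflow for one image pair: contrast normalization,
#' hierarchical feature correspondence ([hierarchical_match()]),
#' thin-plate-spline fit ([fit_tps()]), then backward warping of the
#' autofluorescence channel and — with the identical transform — the
#' immunofluorescence channel, keeping the two channels pixel-aligned.
#'
#' @param section a [section_image()], already on (or pre-alignable to) the
#'   CT pixel grid.
#' @param ct_slice numeric matrix: the corresponding CT plane (fixed image).
#' @param config named list of options: `prealign` (list `rotation_deg`,
#'   `scale`), `levels`, `patch_radius`, `search_radius`, `ratio`,
#'   `min_corr`, `min_spacing`, `affine_tol`, `max_landmarks`, `lambda`,
#'   `interpolation_order`, `invert_moving`.  Missing entries take the
#'   defaults of the underlying functions.
#' @return list with `warped_af`, `warped_if` (matrices on the CT grid),
#'   `landmarks` (a [landmark_set()]) and `diagnostics` (landmark count,
#'   per-landmark TPS residuals, match levels).
#' @export
register_pair <- function(section, ct_slice, config = list()) {
  cfg <- utils::modifyList(list(
    prealign = list(rotation_deg = 0, scale = 1),
    levels = 3, patch_radius = 10, search_radius = 30,
    ratio = 0.85, min_corr = 0.5, min_spacing = 8, affine_tol = 15,
    max_landmarks = 200, lambda = 0, interpolation_order = 1,
    invert_moving = FALSE), config)
  af <- section$af; ifc <- section$if_ch
  if (cfg$prealign$rotation_deg != 0 || cfg$prealign$scale != 1) {
    af <- apply_similarity(af, cfg$prealign$rotation_deg, cfg$prealign$scale)
    ifc <- apply_similarity(ifc, cfg$prealign$rotation_deg, cfg$prealign$scale)
  }
  lm <- tryCatch(
    hierarchical_match(normalize_for_matching(af, invert = cfg$invert_moving),
                       normalize_for_matching(ct_slice),
                       levels = cfg$levels, patch_radius = cfg$patch_radius,
                       search_radius = cfg$search_radius, ratio = cfg$ratio,
                       min_corr = cfg$min_corr, min_spacing = cfg$min_spacing,
                       affine_tol = cfg$affine_tol,
                       max_landmarks = cfg$max_landmarks, normalized = TRUE),
    xrh_match_failure = function(e) {
      stop(structure(class = c("xrh_match_failure", "error", "condition"),
                     list(message = sprintf("pair (section %d / CT slice %d): %s",
                                            section$section_index,
                                            section$ct_slice,
                                            conditionMessage(e)),
                          call = sys.call())))
    })
  tps <- fit_tps(lm, lambda = cfg$lambda)
  inv <- fit_tps(lm, lambda = cfg$lambda, invert = TRUE)
  resid <- sqrt(rowSums((tps_apply(tps, lm$moving_pts) - lm$fixed_pts)^2))
  out_shape <- dim(ct_slice)
  list(warped_af = warp_image(af, inv, out_shape, cfg$interpolation_order),
       warped_if = warp_image(ifc, inv, out_shape, cfg$interpolation_order),
       landmarks = lm,
       tps = tps,
       diagnostics = list(n_landmarks = nrow(lm$moving_pts),
                          residuals = resid,
                          levels = lm$scale_level))
}
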