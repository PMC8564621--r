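#' 3D grayscale micro-CT volume
#'
#' A `ct_volume` is the fixed 3D reference for the whole workflow: a numeric
#' array of 16-bit grey values indexed `[y, x, z]` with an isotropic physical
#' voxel size in micrometres.
#'
#' @param voxels numeric array with three dimensions; values in \[0, 65535\].
#' @param voxel_size isotropic voxel edge length in micrometres (> 0).
#' @param provenance free-text description of where the volume came from.
#' @return An object of class `ct_volume` (a list with elements `voxels`,
#'   `voxel_size`, `provenance`).
#' @export
ct_volume <- function(voxels, voxel_size, provenance = "") {
  if (length(dim(voxels)) != 3L) stop("`voxels` must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (micrometres)")
  if (length(voxels) == 0L) stop("volume grid is empty")
  rng <- range(voxels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 65535)
    stop("grey values must be finite and within [0, 65535]")
  structure(list(voxels = voxels, voxel_size = voxel_size,
                 provenance = provenance),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels @ %.3g um%s\n",
              d[1], d[2], d[3], x$voxel_size,
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""))
  invisible(x)
}

#' 3D binary label volume
#'
#' A `label_volume` is a binary segmentation mask sharing a [ct_volume()]'s
#' grid (vessels, epithelium, tissue, bubbles, ...).
#'
#' @param mask logical (or 0/1) array with three dimensions.
#' @param voxel_size isotropic voxel size in micrometres.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(mask, voxel_size) {
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3D array")
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1))) stop("`mask` must be binary")
    mask <- array(as.logical(mask), dim(mask))
  }
  if (!is.numeric(voxel_size) || voxel_size <= 0)
    stop("`voxel_size` must be positive")
  structure(list(mask = mask, voxel_size = voxel_size), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<label_volume> %d x %d x %d, %d voxels labelled @ %.3g um\n",
              d[1], d[2], d[3], sum(x$mask), x$voxel_size))
  invisible(x)
}

#' 2D multi-channel fluorescence section image
#'
#' Ties a two-channel wide-field fluorescence image (autofluorescence +
#' immunofluorescence) to a physical section index and its assigned CT slice.
#'
#' @param af numeric matrix, autofluorescence channel (registration channel).
#' @param if_ch numeric matrix, immunofluorescence channel, same shape.
#' @param section_index integer physical section number (0-based).
#' @param ct_slice integer index of the CT slice this section maps to (0-based).
#' @return An object of class `section_image`.
#' @export
section_image <- function(af, if_ch, section_index, ct_slice) {
  if (!identical(dim(af), dim(if_ch)))
    stop("channels must share one shape")
  structure(list(af = af, if_ch = if_ch,
                 section_index = as.integer(section_index),
                 ct_slice = as.integer(ct_slice)),
            class = "section_image")
}

#' Assign a physical section to a CT slice index
#'
#' Serial sections are cut at a fixed microtome thickness (4 um here), so
#' section `i` sits at depth `i * thickness` and maps to the nearest CT slice.
#'
#' @param section_index 0-based physical section number(s).
#' @param voxel_size CT voxel size in micrometres.
#' @param section_thickness microtome section thickness in micrometres.
#' @return 0-based CT slice indices.
#' @export
section_to_slice <- function(section_index, voxel_size, section_thickness = 4) {
  as.integer(round(section_index * section_thickness / voxel_size))
}

## ---------------------------------------------------------------------------
## I/O: multi-page TIFF stacks and NIfTI.  16-bit TIFFs are stored by the
## `tiff` package as values in [0, 1]; we map grey value g <-> g / 65535.

#' Write a volume as a 16-bit multi-page TIFF stack
#' @param vol a [ct_volume()] or [label_volume()].
#' @param path output file path.
#' @export
write_volume_tiff <- function(vol, path) {
  a <- if (inherits(vol, "label_volume")) vol$mask * 65535 else vol$voxels
  pages <- lapply(seq_len(dim(a)[3]), function(k) a[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a 16-bit multi-page TIFF stack as a volume
#' @param path TIFF file path.
#' @param voxel_size voxel size in micrometres to attach.
#' @return A [ct_volume()].
#' @export
read_volume_tiff <- function(path, voxel_size) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  a <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    if (length(dim(p)) == 3L) p <- p[, , 1]
    a[, , k] <- p
  }
  ct_volume(round(a * 65535), voxel_size, provenance = path)
}

#' Write a volume to NIfTI (voxel size recorded in the header, in mm)
#' @inheritParams write_volume_tiff
#' @export
write_volume_nifti <- function(vol, path) {
  a <- if (inherits(vol, "label_volume")) vol$mask * 1 else vol$voxels
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- rep(vol$voxel_size / 1000, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#' @param path NIfTI file path.
#' @param voxel_size optional override in micrometres; by default taken from
#'   the header (pixdim, mm).
#' @export
read_volume_nifti <- function(path, voxel_size = NULL) {
  img <- RNifti::readNifti(path)
  vs <- voxel_size %||% (RNifti::pixdim(img)[1] * 1000)
  ct_volume(array(as.numeric(img), dim(img)), vs, provenance = path)
}

#' Write a two-channel section image as a 2-page TIFF
#' @param section a [section_image()].
#' @param path output path.
#' @export
write_section_tiff <- function(section, path) {
  tiff::writeTIFF(list(section$af / 65535, section$if_ch / 65535), path,
                  bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a two-channel section TIFF written by [write_section_tiff()]
#' @param path TIFF path.
#' @param section_index,ct_slice indices to attach (see [section_image()]).
#' @export
read_section_tiff <- function(path, section_index = 0L, ct_slice = 0L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  section_image(round(pages[[1]] * 65535), round(pages[[2]] * 65535),
                section_index, ct_slice)
}
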