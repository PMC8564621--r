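#' Parameters for the synthetic lung phantom
#'
#' The phantom emulates the appearance of unstained FFPE lung tissue in a
#' laboratory micro-CT scan: a paraffin/airspace background, parenchymal
#' tissue, thin-walled airways lined by epithelium, blood vessels with a
#' bright collagen-rich wall around a darker lumen, and wax air-bubble
#' artefacts outlined by bright edge-enhancement rims.  Default grey levels
#' are chosen so the standard lumen threshold window (19000-24000) and wall
#' window (24001-65535) apply unchanged.
#'
#' All lengths are in micrometres unless stated otherwise.
#'
#' @param shape voxels per axis as c(ny, nx, nz).
#' @param voxel_size isotropic voxel size (um).
#' @param n_vessels,vessel_radius_range,wall_thickness blood vessel count,
#'   lumen radius range (um) and wall thickness (um).
#' @param n_airways,airway_radius_range,epithelium_thickness airway count,
#'   inner radius range (um) and epithelial lining thickness (um).
#' @param airspace_fraction target fraction of the volume occupied by
#'   wax-filled alveolar airspaces (0-1).
#' @param airspace_radius_range semi-axis range of the ellipsoidal airspaces (um).
#' @param n_bubbles,bubble_radius_range air-bubble count and radius range (um).
#' @param rim_thickness bubble edge-enhancement rim thickness, in voxels.
#' @param intensity_levels named grey values (uint16) for roles `paraffin`,
#'   `airspace`, `parenchyma`, `vessel_wall`, `lumen`, `epithelium`, `bubble`,
#'   `rim`.
#' @param rng_seed integer seed; identical parameters and seed give a
#'   bit-identical phantom.
#' @param vessels optional explicit vessel list overriding random routing;
#'   each element is `list(p0 = c(x,y,z), p1 = c(x,y,z), radius = <um>)` in
#'   0-based voxel coordinates.
#' @return A validated list of class `phantom_params`.
#' @export
phantom_params <- function(shape = c(128, 128, 128),
                           voxel_size = 8.5,
                           n_vessels = 3,
                           vessel_radius_range = c(30, 120),
                           wall_thickness = 25,
                           n_airways = 2,
                           airway_radius_range = c(120, 250),
                           epithelium_thickness = 17,
                           airspace_fraction = 0.35,
                           airspace_radius_range = c(60, 200),
                           n_bubbles = 3,
                           bubble_radius_range = c(60, 170),
                           rim_thickness = 2,
                           intensity_levels = c(paraffin = 12000,
                                                airspace = 11000,
                                                parenchyma = 17000,
                                                vessel_wall = 30000,
                                                lumen = 21000,
                                                epithelium = 14500,
                                                bubble = 3000,
                                                rim = 40000),
                           rng_seed = 1L,
                           vessels = NULL) {
  p <- list(shape = as.integer(shape), voxel_size = voxel_size,
            n_vessels = n_vessels, vessel_radius_range = vessel_radius_range,
            wall_thickness = wall_thickness, n_airways = n_airways,
            airway_radius_range = airway_radius_range,
            epithelium_thickness = epithelium_thickness,
            airspace_fraction = airspace_fraction,
            airspace_radius_range = airspace_radius_range,
            n_bubbles = n_bubbles, bubble_radius_range = bubble_radius_range,
            rim_thickness = rim_thickness,
            intensity_levels = intensity_levels, rng_seed = as.integer(rng_seed),
            vessels = vessels)
  extent_um <- min(p$shape) * p$voxel_size
  lens <- c(if (p$n_vessels > 0 || !is.null(p$vessels))
              c(p$vessel_radius_range, p$wall_thickness),
            if (p$n_airways > 0) c(p$airway_radius_range, p$epithelium_thickness),
            if (p$airspace_fraction > 0) p$airspace_radius_range,
            if (p$n_bubbles > 0) p$bubble_radius_range)
  if (any(lens <= 0) || any(lens >= extent_um))
    stop("all radii/thicknesses must be > 0 and smaller than the volume extent")
  need <- c("paraffin", "airspace", "parenchyma", "vessel_wall", "lumen",
            "epithelium", "bubble", "rim")
  if (!all(need %in% names(p$intensity_levels)))
    stop("intensity_levels must name: ", paste(need, collapse = ", "))
  il <- p$intensity_levels
  if (any(il < 0 | il > 65535)) stop("intensity_levels must be within [0, 65535]")
  if (il["vessel_wall"] <= 24000)
    stop("vessel wall grey level must exceed 24000 (upper threshold window)")
  if (il["lumen"] < 19000 || il["lumen"] > 24000)
    stop("lumen grey level must lie within 19000-24000 (lower threshold window)")
  if (p$airspace_fraction < 0 || p$airspace_fraction > 1)
    stop("airspace_fraction must be in [0, 1]")
  class(p) <- "phantom_params"
  p
}

## internal role codes for the paint buffer
.roles <- c(parenchyma = 1L, airspace = 2L, airway_lumen = 3L, epithelium = 4L,
            vessel_lumen = 5L, vessel_wall = 6L, bubble = 7L, rim = 8L)

## 0-based voxel-centre coordinate vectors for a box (R index ranges)
box_coords <- function(yr, xr, zr) {
  list(y = yr - 1, x = xr - 1, z = zr - 1)
}

## Paint a capped cylinder (segment p0-p1, 0-based (x,y,z), radii in voxels)
## into `role` via a distance test.  Returns updated role array.
paint_tube <- function(role, p0, p1, r_outer, classify) {
  d <- dim(role)
  seg <- p1 - p0
  len <- sqrt(sum(seg^2))
  if (len == 0) return(role)
  nseg <- max(1L, ceiling(len / 24))
  ts <- seq(0, 1, length.out = nseg + 1)
  ## distance-to-segment accumulated over sub-segments, each in a local box
  for (i in seq_len(nseg)) {
    a <- p0 + ts[i] * seg
    b <- p0 + ts[i + 1] * seg
    lo <- floor(pmin(a, b) - r_outer - 1)
    hi <- ceiling(pmax(a, b) + r_outer + 1)
    xr <- max(1, lo[1] + 1):min(d[2], hi[1] + 1)
    yr <- max(1, lo[2] + 1):min(d[1], hi[2] + 1)
    zr <- max(1, lo[3] + 1):min(d[3], hi[3] + 1)
    if (!length(xr) || !length(yr) || !length(zr)) next
    cx <- xr - 1; cy <- yr - 1; cz <- zr - 1
    ## coordinates of every voxel centre in the box
    Y <- array(rep(cy, times = length(xr) * length(zr)),
               c(length(yr), length(xr), length(zr)))
    X <- array(rep(rep(cx, each = length(yr)), times = length(zr)),
               c(length(yr), length(xr), length(zr)))
    Z <- array(rep(cz, each = length(yr) * length(xr)),
               c(length(yr), length(xr), length(zr)))
    ab <- b - a
    ab2 <- sum(ab^2)
    t <- ((X - a[1]) * ab[1] + (Y - a[2]) * ab[2] + (Z - a[3]) * ab[3]) / ab2
    t <- clamp(t, 0, 1)
    dist <- sqrt((X - (a[1] + t * ab[1]))^2 +
                 (Y - (a[2] + t * ab[2]))^2 +
                 (Z - (a[3] + t * ab[3]))^2)
    sub <- role[yr, xr, zr]
    sub <- classify(sub, dist)
    role[yr, xr, zr] <- sub
  }
  role
}

## minimum distance between 3D segments p1-p2 and q1-q2
segseg_dist <- function(p1, p2, q1, q2) {
  u <- p2 - p1; v <- q2 - q1; w <- p1 - q1
  a <- sum(u * u); b <- sum(u * v); c <- sum(v * v)
  d0 <- sum(u * w); e <- sum(v * w)
  den <- a * c - b * b
  s <- if (den > 1e-12) clamp((b * e - c * d0) / den, 0, 1) else 0
  t <- if (c > 1e-12) clamp((b * s + e) / c, 0, 1) else 0
  s <- if (a > 1e-12) clamp((b * t - d0) / a, 0, 1) else 0
  t <- if (c > 1e-12) clamp((b * s + e) / c, 0, 1) else 0
  sqrt(sum((p1 + s * u - q1 - t * v)^2))
}

## Random chord through the volume: entry and exit points on different faces.
random_chord <- function(shape) {
  d <- c(shape[2], shape[1], shape[3]) # (x, y, z) extents
  faces <- sample(0:5, 2)
  while (faces[2] == faces[1]) faces[2] <- sample(0:5, 1)
  pt_on_face <- function(f) {
    p <- runif(3) * (d - 1)
    ax <- f %/% 2 + 1
    p[ax] <- if (f %% 2 == 0) 0 else d[ax] - 1
    p
  }
  list(p0 = pt_on_face(faces[1]), p1 = pt_on_face(faces[2]))
}

#' Generate a synthetic lung-like micro-CT volume with ground truth
#'
#' Builds the phantom described in [phantom_params()]: parenchyma background,
#' ellipsoidal wax-filled airspaces, airway tubes with an epithelial lining,
#' randomly routed blood-vessel tubes (dark lumen, bright wall), and air
#' bubbles with bright edge-enhancement rims.  Every structural role gets an
#' exact binary ground-truth label on the same grid.
#'
#' @param params a [phantom_params()] object.
#' @return A list with `volume` (a [ct_volume()]) and `ground_truth`, a named
#'   list of [label_volume()]s for roles `tissue` (parenchyma), `airspace`,
#'   `airway_lumen`, `epithelium`, `vessel_lumen`, `vessel_wall`, `bubble`
#'   and `rim`.
#' @export
make_lung_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  d <- params$shape
  vs <- params$voxel_size
  if (params$n_vessels > 0 || !is.null(params$vessels)) {
    rmax <- if (is.null(params$vessels)) max(params$vessel_radius_range)
            else max(vapply(params$vessels, `[[`, numeric(1), "radius"))
    ## a tube's diameter must fit across the volume (it may run along the
    ## smallest axis, so the middle extent is the binding one)
    if (sort(d)[2] * vs <= 2 * (rmax + params$wall_thickness))
      stop("volume too small to fit the requested vessels")
  }
  role <- array(.roles[["parenchyma"]], d)

  with_seed(params$rng_seed, {
    ## 1. alveolar airspaces: axis-aligned ellipsoids painted into parenchyma
    target <- params$airspace_fraction * prod(d)
    n_air <- 0
    tries <- 0
    rr <- params$airspace_radius_range / vs
    while (n_air < target && tries < 8000) {
      tries <- tries + 1
      ctr <- runif(3) * (c(d[1], d[2], d[3]) - 1) # (y, x, z)
      ax <- runif(3, rr[1], rr[2])                # semi-axes in voxels
      yr <- max(1, floor(ctr[1] - ax[1]) + 1):min(d[1], ceiling(ctr[1] + ax[1]) + 1)
      xr <- max(1, floor(ctr[2] - ax[2]) + 1):min(d[2], ceiling(ctr[2] + ax[2]) + 1)
      zr <- max(1, floor(ctr[3] - ax[3]) + 1):min(d[3], ceiling(ctr[3] + ax[3]) + 1)
      e <- outer(((yr - 1) - ctr[1])^2 / ax[1]^2,
                 ((xr - 1) - ctr[2])^2 / ax[2]^2, `+`)
      e <- outer(e, ((zr - 1) - ctr[3])^2 / ax[3]^2, `+`)
      sub <- role[yr, xr, zr]
      inside <- e <= 1 & sub == .roles[["parenchyma"]]
      n_air <- n_air + sum(inside)
      sub[inside] <- .roles[["airspace"]]
      role[yr, xr, zr] <- array(sub, dim(e))
    }

    ## 2. airways: tubes with a wax-filled lumen lined by epithelium.
    ## Airways are routed to cross the full z extent (the sectioned depth is
    ## a thin slab near z = 0, and stained sections must intersect airway
    ## epithelium for the immunofluorescence to carry signal).
    ep <- params$epithelium_thickness / vs
    airway_axes <- list()
    for (i in seq_len(params$n_airways)) {
      ch <- list(p0 = c(runif(2, 0.15, 0.85) * c(d[2] - 1, d[1] - 1), 0),
                 p1 = c(runif(2, 0.15, 0.85) * c(d[2] - 1, d[1] - 1), d[3] - 1))
      r_in <- runif(1, params$airway_radius_range[1], params$airway_radius_range[2]) / vs
      airway_axes[[length(airway_axes) + 1]] <- list(p0 = ch$p0, p1 = ch$p1,
                                                     r = r_in)
      ## lumen always paints; the lining never overwrites lumen already
      ## painted by a neighbouring sub-segment of the same tube
      role <- paint_tube(role, ch$p0, ch$p1, r_in, function(sub, dist) {
        sub[dist < r_in - ep] <- .roles[["airway_lumen"]]
        sub[dist >= r_in - ep & dist < r_in &
            sub != .roles[["airway_lumen"]]] <- .roles[["epithelium"]]
        sub
      })
    }

    ## 3. blood vessels: dark lumen, bright thick wall.  Vessels travel in
    ## bronchovascular bundles alongside -- not through -- airways, so
    ## random routes that would interpenetrate an airway are resampled.
    wall <- params$wall_thickness / vs
    vdefs <- params$vessels
    if (is.null(vdefs)) {
      vdefs <- lapply(seq_len(params$n_vessels), function(i) {
        radius <- runif(1, params$vessel_radius_range[1],
                        params$vessel_radius_range[2])
        rv <- radius / vs
        for (try in 1:60) {
          ch <- random_chord(d)
          clear <- all(vapply(airway_axes, function(aw)
            segseg_dist(ch$p0, ch$p1, aw$p0, aw$p1) > aw$r + rv + wall,
            logical(1)))
          if (clear) break
        }
        c(ch, list(radius = radius))
      })
    } else {
      vdefs <- lapply(vdefs, function(v)
        list(p0 = as.numeric(v$p0), p1 = as.numeric(v$p1), radius = v$radius))
    }
    for (v in vdefs) {
      r <- v$radius / vs
      role <- paint_tube(role, v$p0, v$p1, r + wall, function(sub, dist) {
        sub[dist < r] <- .roles[["vessel_lumen"]]
        sub[dist >= r & dist < r + wall &
            sub != .roles[["vessel_lumen"]]] <- .roles[["vessel_wall"]]
        sub
      })
    }

    ## 4. air bubbles with bright rims; placed away from vessel walls since
    ## bubbles arise in wax during embedding, not inside vessels
    rimv <- params$rim_thickness
    for (i in seq_len(params$n_bubbles)) {
      r <- runif(1, params$bubble_radius_range[1], params$bubble_radius_range[2]) / vs
      placed <- FALSE
      for (try in 1:200) {
        ctr <- r + rimv + 1 + runif(3) * (c(d[1], d[2], d[3]) - 2 * (r + rimv + 1) - 1)
        marg <- r + rimv + 6
        yr <- max(1, floor(ctr[1] - marg) + 1):min(d[1], ceiling(ctr[1] + marg) + 1)
        xr <- max(1, floor(ctr[2] - marg) + 1):min(d[2], ceiling(ctr[2] + marg) + 1)
        zr <- max(1, floor(ctr[3] - marg) + 1):min(d[3], ceiling(ctr[3] + marg) + 1)
        sub <- role[yr, xr, zr]
        if (any(sub == .roles[["vessel_wall"]])) next
        e <- sqrt(outer(outer(((yr - 1) - ctr[1])^2, ((xr - 1) - ctr[2])^2, `+`),
                        ((zr - 1) - ctr[3])^2, `+`))
        sub[e <= r] <- .roles[["bubble"]]
        sub[e > r & e <= r + rimv] <- .roles[["rim"]]
        role[yr, xr, zr] <- array(sub, dim(e))
        placed <- TRUE
        break
      }
      if (!placed) warning("could not place bubble ", i, " away from vessels")
    }
  })

  il <- params$intensity_levels
  grey <- c(il[["parenchyma"]], il[["airspace"]], il[["airspace"]],
            il[["epithelium"]], il[["lumen"]], il[["vessel_wall"]],
            il[["bubble"]], il[["rim"]])
  vol <- array(grey[role], d)

  gt_role <- function(code) label_volume(role == code, vs)
  gt <- list(tissue = gt_role(.roles[["parenchyma"]]),
             airspace = gt_role(.roles[["airspace"]]),
             airway_lumen = gt_role(.roles[["airway_lumen"]]),
             epithelium = gt_role(.roles[["epithelium"]]),
             vessel_lumen = gt_role(.roles[["vessel_lumen"]]),
             vessel_wall = gt_role(.roles[["vessel_wall"]]),
             bubble = gt_role(.roles[["bubble"]]),
             rim = gt_role(.roles[["rim"]]))
  list(volume = ct_volume(vol, vs, provenance = "synthetic lung phantom"),
       ground_truth = gt)
}

#' Smooth random in-plane deformation field
#'
#' Emulates the smooth stretching/compression that microtome sectioning
#' imposes on FFPE sections: band-limited Gaussian noise, low-pass filtered
#' at the requested correlation length and rescaled so the maximum
#' displacement magnitude equals `amplitude` exactly (when `amplitude > 0`).
#'
#' @param shape c(ny, nx) of the section grid.
#' @param amplitude maximum displacement magnitude in pixels (>= 0).
#' @param smoothness correlation length in pixels (> 0).
#' @param rng_seed integer seed.
#' @return An object of class `deformation_field` with per-pixel `dx`, `dy`
#'   matrices plus the generating `amplitude` and `smoothness`.
#' @export
make_deformation <- function(shape, amplitude, smoothness, rng_seed = 1L) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (smoothness <= 0) stop("smoothness must be > 0")
  ny <- shape[1]; nx <- shape[2]
  if (amplitude == 0) {
    dx <- dy <- matrix(0, ny, nx)
  } else {
    with_seed(rng_seed, {
      dx <- gaussian_field2d(ny, nx, smoothness)
      dy <- gaussian_field2d(ny, nx, smoothness)
    })
    mag <- sqrt(dx^2 + dy^2)
    s <- amplitude / max(mag)
    dx <- dx * s; dy <- dy * s
  }
  structure(list(dx = dx, dy = dy, amplitude = amplitude,
                 smoothness = smoothness),
            class = "deformation_field")
}

#' Numerically invert a deformation field
#'
#' Given the backward-warp field `d` used by [extract_section()]
#' (`section(p) = plane(p + d(p))`), returns the field `dinv` with
#' `dinv(q) = -d(p)` at `q = p + d(p)`, found by fixed-point iteration.
#' Warping the section with `dinv` recovers the undeformed plane.
#'
#' @param deform a [make_deformation()] field.
#' @param iterations fixed-point iterations (the field is smooth, so few are
#'   needed).
#' @return A `deformation_field` holding the inverse displacements.
#' @export
invert_deformation <- function(deform, iterations = 20) {
  ny <- nrow(deform$dx); nx <- ncol(deform$dx)
  gx <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  gy <- matrix(rep(0:(ny - 1), nx), ny, nx)
  ix <- matrix(0, ny, nx); iy <- matrix(0, ny, nx)
  for (it in seq_len(iterations)) {
    sx <- clamp(gx + ix, 0, nx - 1)
    sy <- clamp(gy + iy, 0, ny - 1)
    ix <- -matrix(sample_bilinear(deform$dx, sx, sy), ny, nx)
    iy <- -matrix(sample_bilinear(deform$dy, sx, sy), ny, nx)
  }
  structure(list(dx = ix, dy = iy, amplitude = max(sqrt(ix^2 + iy^2)),
                 smoothness = deform$smoothness),
            class = "deformation_field")
}

#' Apply a deformation field to a 2D image (backward warping)
#'
#' `out(p) = image(p + d(p))`, bilinear interpolation, out-of-bounds = `fill`.
#' @param image numeric matrix.
#' @param deform a `deformation_field` matching the image shape.
#' @param fill value for out-of-bounds samples.
#' @export
apply_deformation <- function(image, deform, fill = 0) {
  ny <- nrow(image); nx <- ncol(image)
  if (!identical(dim(deform$dx), dim(image)))
    stop("deformation grid does not match the image shape")
  gx <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  gy <- matrix(rep(0:(ny - 1), nx), ny, nx)
  matrix(sample_bilinear(image, gx + deform$dx, gy + deform$dy, fill = fill),
         ny, nx)
}

## Monotone grey-value remapping used to simulate tissue autofluorescence:
## wax/airspace dark, parenchyma mid-bright, collagen-rich walls brightest.
af_remap <- function(grey) {
  q <- clamp((grey - 9000) / (41000 - 9000), 0, 1)
  58000 * q^0.6
}

#' Extract an elastically deformed 2D "section" from a phantom
#'
#' Simulates cutting a physical section at CT slice `z`: the autofluorescence
#' channel is a monotone grey-value remapping of the micro-CT plane (tissue
#' bright, airspaces dark) with mild multiplicative noise, and the
#' immunofluorescence channel renders the epithelium ground-truth label at
#' high intensity over a zero background.  Both channels receive the same
#' in-plane deformation (backward warping, bilinear).
#'
#' @param phantom result of [make_lung_phantom()].
#' @param z 0-based slice index.
#' @param deform a [make_deformation()] field matching the slice shape.
#' @param params the generating [phantom_params()] (for seeds/levels).
#' @param section_index physical section number to record.
#' @param stain_level IF intensity for stained epithelium.
#' @param noise_sd multiplicative noise s.d. on the autofluorescence channel.
#' @return A [section_image()] whose `ct_slice` is `z`.
#' @export
extract_section <- function(phantom, z, deform, params, section_index = 0L,
                            stain_level = 50000, noise_sd = 0.02) {
  d <- dim(phantom$volume$voxels)
  if (z < 0 || z > d[3] - 1) stop("slice index z out of range")
  plane <- phantom$volume$voxels[, , z + 1]
  if (!identical(dim(deform$dx), dim(plane)))
    stop("deformation grid does not match the slice shape")
  af <- af_remap(plane)
  if (noise_sd > 0) {
    noise <- with_seed(params$rng_seed + 7919L * (z + 1L),
                       matrix(rnorm(length(af), 1, noise_sd), nrow(af)))
    af <- clamp(af * noise, 0, 65535)
  }
  ifimg <- phantom$ground_truth$epithelium$mask[, , z + 1] * stain_level
  section_image(apply_deformation(af, deform),
                apply_deformation(ifimg, deform),
                section_index = section_index, ct_slice = z)
}
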