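---
title: "Methods: co-registration and segmentation of micro-CT / immunofluorescence lung data"
author: "xrh package"
output: rmarkdown::html_document
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

A paraffin-embedded tissue block is imaged twice: once whole, by laboratory
micro-CT at an isotropic voxel size of 6.0–8.5 µm, and once destructively,
as serial 4 µm microtome sections imaged by wide-field fluorescence
microscopy in two channels — tissue autofluorescence (structure) and
immunofluorescence (IF, a specific marker such as cytokeratin 18 in airway
epithelium). Sectioning deforms the tissue smoothly (stretch/compression)
and occasionally destructively (tears, lost fragments), so a section no
longer matches its geometric plane in the volume and rigid overlay fails.

`xrh` models the recoverable part of that deformation as a smooth 2D
displacement field and estimates it per section by landmark correspondence
plus thin-plate-spline (TPS) interpolation. Everything downstream — overlap
scoring, vessel segmentation, IF label interpolation — consumes either the
CT volume or images warped onto its grid.

## Thin-plate-spline warping

Given paired landmarks $(m_i, f_i)$ the transform is
$T(p) = A\,[1, p]^\top + \sum_i w_i\, U(\lVert p - m_i \rVert)$ with kernel
$U(r) = r^2 \log r$, $U(0)=0$, subject to the side conditions
$\sum_i w_i = 0$ and $\sum_i w_i\, m_i = 0$. With regularization
$\lambda = 0$ (the default, matching interactive landmark-warping tools) the
transform interpolates the landmarks exactly; the package verifies
$\le 10^{-6}$ px on random sets of 4–50 pairs and $\le 10^{-8}$ on the side
conditions, and that affine-consistent landmarks drive the bending weights
to zero. Image warping is backward: the inverse map is obtained by fitting
the reverse-direction TPS on the same pairs, so the moving image is sampled
at inverse-mapped output pixels (out-of-bounds = 0). Exact interpolation
has one important consequence that shapes the matching stage: **any wrong
landmark is reproduced verbatim in the warp**, so outlier rejection must
happen before fitting.

## Hierarchical feature correspondence

Correspondences are found automatically between the contrast-normalized
autofluorescence section (moving) and its CT plane (fixed):

* both images are percentile-windowed and adaptive-histogram-equalized, so
  that the monotone grey-value relation between modalities does not defeat
  correlation matching (an optional polarity inversion flag covers
  contrast-reversed modalities);
* at each of 3 pyramid levels (full, 1/2, 1/4 resolution) keypoints are
  detected as difference-of-Gaussian extrema on the fixed image and located
  in the moving image by normalized cross-correlation (NCC) over a bounded
  displacement search, with quadratic subpixel refinement. The pyramid
  realizes a hierarchy of feature sizes: coarse levels see large structures
  and large displacements, the full level refines small ones. Images are
  reflect-padded so keypoints may sit anywhere in the true image area;
* matches pass a distinctness (ratio) test against the second-best
  correlation peak, then a robust global-affine consensus (RANSAC, inlier
  tolerance 15 px), then a local displacement-consistency filter (each
  match's displacement must agree within 6 px with the median of its 6
  nearest neighbours — justified exactly by the smooth-deformation model
  and by the exact-interpolation hazard above);
* surviving matches are deduplicated to a minimum spacing of 8 px, keeping
  the strongest, capped at 200 landmarks.

The descriptor is a normalized intensity patch rather than a gradient
orientation histogram: the pre-alignment step (a deterministic
similarity transform from the known pixel sizes, e.g. 0.645 µm/px
microscopy onto 6–8.5 µm/px CT, plus mounting rotation) removes gross
rotation and scale, after which NCC patches are the simpler, directly
calibrated choice. Fewer than 4 surviving matches raises a typed failure
(`xrh_match_failure`) naming the pair, so a batch run can skip or fall back.

On synthetic deformed sections (20 px amplitude, 32 px correlation length,
256² pixels) this recovers the hidden deformation with a mean landmark
residual of ~1.7 px and lifts the accurate-overlap score from ~79%
(rigid) to ~97%.

## Overlap accuracy metric

Both images are binarized to the 255 (tissue) / 1 (airspace) encoding —
Otsu by default for fluorescence, a fixed threshold for CT — and multiplied
per pixel **in double precision**: an 8-bit product would saturate at 255
and destroy the classification, so the product is interpreted as
65025 = tissue–tissue (accurate), 1 = air–air (accurate), 255 = mismatch
(inaccurate). A validity mask (the warp of an all-ones image) excludes
padding introduced by warping from the evaluated pixel count; how border
padding is treated is otherwise a free choice, and excluding it avoids
rewarding or punishing empty corners. The metric is symmetric and provably
identical to direct boolean counting (property-tested on random masks).

## Seeded active-contour vessel segmentation

The speed image is +1 inside the lumen grey window (default 19000–24000),
−1 elsewhere (the wall window 24001–65535 and everything darker), with a
linear ramp of 500 grey levels at each window edge. Evolution is a discrete
narrow-band scheme on the binary front:

* **balloon step** — the front advances one voxel (6-connected) into
  strictly positive speed; it can never cross the barrier, so walls are
  respected exactly (tested: zero voxels outside the dilated true lumen);
* **curvature step** — one morphological opening per iteration by a ball of
  radius `round(smoothing_force / 0.2)` voxels. Opening is anti-extensive
  (never adds voxels, hence cannot breach the barrier), preserves flat
  fronts and any blob that contains the ball, and removes protrusions or
  channels narrower than the ball. This is the discrete meaning given here
  to "resistance for entering narrow objects": at the generic default 0.2
  the ball has radius 1; at the lung setting 0.4, radius 2, which blocks a
  3-voxel-wide neck that a smoothing-free front leaks through.

A literal convex combination of a bounded region term and a bounded
curvature term cannot produce this behaviour (for a 3-voxel neck the
curvature magnitude needed exceeds the weight ratio), and curvature
realized as sup-inf/inf-sup operator pairs collapses the radius-2 seed
balls before they can grow; the opening-based term was chosen because it
has neither failure mode and keeps both printed parameter values (0.2,
0.4) meaningful. Seeds outside the lumen window are rejected individually
with a diagnostic; all-invalid is an error. Convergence is declared when
the net changed-voxel fraction per iteration falls below `convergence_tol`
(default 10⁻⁶) — "net" so that a blocked neck (balloon adds, opening
removes) counts as converged.

Whole volumes are processed in overlapping sub-volumes (default 64³ with a
16-voxel margin) to bound memory; voxels segmented inside a tile re-seed
neighbouring tiles until the labelling is stable, so structures crossing
tile boundaries are followed (sub-volume vs whole-volume Dice ≥ 0.98 on
phantoms). Network volume is `count × voxel_size³ × 10⁻⁹` mm³.

## IF segmentation and contour interpolation

Warped IF images are thresholded at an absolute intensity — the threshold
is a required input because it depends on staining and exposure; the
phantom default sits midway between background and stain level — with
small-object removal below 10 px. Masks are inserted at their CT slice
(sections are cut at 4 µm, so section *i* maps to slice
`round(i·4/voxel_size)`; stained sections may be up to 40 µm ≈ 5 slices
apart). Gaps are filled by signed-distance-field morphing: 2D connected
components of the two bounding slices are paired by overlap after aligning
their bounding-box centroids; each paired group is interpolated along its
connecting translation as
$\{(1-f)\,\mathrm{sd}_A(x - f t) + f\,\mathrm{sd}_B(x + (1-f)t) \ge 0\}$;
unpaired components shrink monotonically (threshold on their own distance
field) and are extinct from the gap midpoint onward. On analytic shapes
this coincides with the expected behaviour exactly: identical disks are
reproduced bit-for-bit on every intermediate slice, concentric disks follow
the linear radius to < 1 px. Labelled slices are kept verbatim; slices
outside the outermost entries stay empty (no extrapolation). Finally the
dense label is multiplied by the binarized CT tissue mask, which removes
interpolation excursions into airspaces or lumina; the operation is
idempotent and can only remove voxels.

## Air-bubble masking

Wax air bubbles image as near-black voids outlined by bright
edge-enhancement rims. The detector is rule-based: void candidates are
26-connected components darker than `void_threshold` (default 8000) that do
not touch the volume border (enclosedness test) and have at least
`min_voxels = 8` voxels; each kept void's rim is its 3-voxel dilation
intersected with voxels brighter than 24000 or darker than the void
threshold (the latter re-attaches stray dark fragments split off by
discretization). Detection is iterated on the masked volume to a fixed
point (≤ 5 passes) because zeroing a rim can connect fragments that the
first pass missed; the fixed-point form makes masking idempotent by
construction. Masked voxels are set exactly to 0 and all others unchanged.

# The synthetic phantom: what it emulates, and what it does not

`make_lung_phantom()` builds a lung-like 16-bit volume: parenchyma
(grey 17000) with ellipsoidal wax-filled airspaces (11000), airway tubes
crossing the full z extent with a wax lumen and a 17 µm epithelial lining
(14500), randomly routed vessel tubes (lumen 21000, 25 µm bright wall
30000), and spherical bubbles (3000) with 2-voxel rims (40000). The grey
levels are chosen so the standard printed windows apply unchanged:
thresholding 19000–24000 selects exactly the vessel-lumen label
(Jaccard = 1). Three realism constraints are built in: airways must cross
the sectioned depth so sections carry IF signal; vessels are re-routed so
they never interpenetrate airways (vessels travel alongside airways in
bronchovascular bundles, and interpenetration would make the observed
epithelium/vessel disjointness unattainable by construction); bubbles are
seeded only in wall-free neighbourhoods, since they arise in wax. Every
role has an exact binary ground-truth label; identical parameters and seed
give bit-identical output.

Sectioning is simulated as a band-limited Gaussian random displacement
field (Fourier-domain low-pass at the requested correlation length,
rescaled so the maximum displacement equals the amplitude exactly), applied
by backward bilinear warping to an autofluorescence channel (a monotone
grey remap of the CT plane with 2% multiplicative noise) and to the IF
channel (the epithelium label rendered at 50000 over a zero background).
The packaged study conditions are 20 px amplitude and 32 px smoothness —
large enough that rigid overlay visibly fails, smooth enough to be
TPS-recoverable, which is the regime the method addresses.

What the phantom deliberately does **not** model: X-ray physics and
reconstruction artefacts (beam hardening, noise spectra, rings), partial
volume effects at structure boundaries (grey levels are piecewise
constant), tears and lost tissue (the deformation is smooth and
invertible), out-of-plane deformation (the warp is 2D, as is the method's),
real staining variability, and anatomically branched airway/vessel trees
(tubes are independent chords). Passing tests therefore demonstrate that
the algorithms are correct and self-consistent under smooth deformations
and clean two-phase contrast — not that registration accuracy on real FFPE
tissue will reach the same numbers; on real data, accuracy is bounded by
tears, out-of-plane motion and texture quality, and the overlap metric is
the intended monitor for that.

# Numerical choices and degenerate inputs

* Coordinates: matrices/arrays are indexed `[y, x(, z)]`; user-facing point
  coordinates are 0-based `(x, y, z)` at voxel centres.
* Reslicing resolves the in-plane rotation (undetermined by three points)
  by projecting the original x-axis onto the plane; interpolation orders 0,
  1, 3 with order 3 as Keys cubic convolution (a = −0.5); out-of-volume
  samples are 0; degenerate (collinear) planes are rejected.
* 16-bit conversion windows at the (0.01, 99.99) percentiles by default;
  a constant volume maps to all zeros with a warning.
* The RANSAC affine consensus is internally seeded, making every matching
  call a pure function of its inputs; all generator functions take explicit
  seeds, and the pipeline's manifest checksums are bit-reproducible.
* Deduplication ties are broken by match strength (higher correlation
  wins); landmark sets reject moving points closer than the minimum
  spacing, since exact TPS cannot separate near-duplicates.
* Empty gaps (both bounding slices empty) stay empty; a single labelled
  slice is a valid stack flagged non-interpolatable.

# Problem sizes

The test-suite and acceptance experiments use: 24³–96³ phantoms for
structure-level properties, 128³ with six sections for the end-to-end
pipeline (about 15 s per run), and 256³ with six 256² sections for the
registration-recovery experiment — sizes chosen so the full suite and the
acceptance script each complete in a few minutes on one CPU while keeping
every structure several voxels across, the same scale separation as the
real data (vessels ≥ 25 µm at 8.5 µm voxels).

# Known limitations

* The warp is strictly 2D per section; out-of-plane sectioning distortion
  is not recovered (and not modelled by the phantom).
* Landmark quality depends on texture: nearly texture-free sections fail
  with a match-failure signal rather than degrading silently.
* The active-contour curvature force is quantized (ball radii 0, 1, 2, …),
  so smoothing forces between multiples of 0.2 round to the nearest radius.
* Airway lumina cannot be segmented by the vessel pipeline: their walls sit
  near the paraffin grey level, outside the barrier window — the same
  contrast limitation the correlative workflow exists to work around.
* The bubble detector assumes bubbles are strictly darker than airspaces
  and enclosed by tissue or wax; voids open to the volume border are
  (correctly) ignored.
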