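# xrh — immunofluorescence-guided 3D segmentation of micro-CT lung tissue

Laboratory micro-CT of unstained formalin-fixed paraffin-embedded (FFPE)
tissue blocks ("3D X-ray histology") images soft tissue at voxel sizes below
10 µm, but it cannot by itself identify cell types or immunoreactivity.
Those come from 2D fluorescence microscopy of the very sections microtomed
from the same block — and sectioning stretches, compresses and tears the
tissue, so the 2D images no longer match their plane in the 3D volume.

`xrh` is an R toolkit for closing that gap. For researchers working with
correlative micro-CT + immunofluorescence (IF) data it provides the full
workflow:

1. **Preprocessing** — 16-bit conversion with percentile windowing, 3-point
   reslicing of the volume to the histology sectioning plane, and rule-based
   detection/zeroing of wax air-bubble artefacts and their bright
   edge-enhancement rims (`convert_to_uint16()`, `reslice_to_plane()`,
   `mask_air_bubbles()`).
2. **Automated 2D→3D registration** — multi-scale feature correspondence
   between a section's tissue autofluorescence and its CT plane, followed by
   landmark-based thin-plate-spline (TPS) warping with kernel
   `U(r) = r² log r` and exact interpolation at `λ = 0`
   (`hierarchical_match()`, `fit_tps()`, `warp_image()`, `register_pair()`).
3. **Registration quality control** — the tissue/airspace overlap metric:
   both images are binarized with tissue = 255 and airspace = 1; the
   pixelwise product (computed in a width that cannot clip) classifies
   65025 → tissue-over-tissue (accurate), 1 → air-over-air (accurate),
   255 → tissue-over-air (inaccurate) (`binarize_tissue()`,
   `overlap_report()`, `overlay_figure()`).
4. **Seeded vessel segmentation** — an active-contour front grown from
   manually placed lumen seeds under a two-sided threshold speed image
   (lumen window 19000–24000, wall window 24001–65535) with a curvature
   "smoothing force" that resists entry into narrow openings
   (`make_speed_image()`, `active_contour_grow()`, `segment_vessels()`).
5. **IF label interpolation** — absolute-threshold IF masks inserted at
   their CT slice positions, morphological contour interpolation across the
   unstained gaps, and constraint by a binarized CT tissue mask
   (`threshold_if()`, `assemble_sparse()`, `contour_interpolate()`,
   `mask_by_tissue()`).
6. **Orchestration** — a YAML-configured pipeline with a checksummed JSON
   manifest and full determinism (`validate_config()`, `run_workflow()`),
   plus a synthetic lung phantom with exact ground-truth labels and
   simulated sectioning deformations so everything above is testable with no
   external data (`make_lung_phantom()`, `make_deformation()`,
   `extract_section()`, `xrh_make_demo()`).

## Worked example

Generate a 128³ demo dataset (phantom volume, six deformed two-channel
sections, vessel seed points and a ready-made config) and run the whole
pipeline:

```r
library(xrh)
cfg <- xrh_make_demo("demo", seed = 4)   # writes demo/volume.tif, sec_*.tif, ...
manifest <- run_workflow(cfg)
```

The run log reports each stage; on this dataset it prints:

```
loaded volume 128x128x128
bubble masking done
pair 000: 34 landmarks, accurate 87.8%
pair 009: 57 landmarks, accurate 94.9%
pair 018: 57 landmarks, accurate 95.8%
pair 027: 70 landmarks, accurate 96.1%
pair 036: 60 landmarks, accurate 92.3%
pair 045: 66 landmarks, accurate 94.2%
IF interpolation done
vessel segmentation done
```

and the manifest summarises:

```
preprocess ok | 33202 bubble voxels masked
register   ok | 6 pairs registered, 0 failed
regqc      ok | mean accurate 93.4%
ifseg      ok | 0.004803 mm3 in 14 components
vesselseg  ok | 0.05922 mm3
```

Reading this: the bubble detector zeroed the three simulated wax bubbles and
their bright rims; all six deformed sections were re-registered to their CT
planes with on average ~93% of pixels showing tissue-over-tissue or
air-over-air overlap (in the 256-cube recovery experiment run by
`scripts/acceptance.R`, the rigid, unwarped overlay scores ~79% against ~97%
after warping); the interpolated cytokeratin-positive epithelium network
measures 0.0048 mm³ and the segmented vessel network 0.059 mm³ at 8.5 µm
voxels — and it contains zero voxels overlapping the vessel segmentation.
`demo/out/` holds the warped channels, landmark CSVs, colour overlay PNGs
(red = inaccurate, cyan = air–air, blue = tissue–tissue), the accuracy
bar chart, both label volumes and `manifest.json` with MD5 checksums;
re-running with the same seed reproduces every checksum bit for bit.

The same steps are available individually; e.g. registering one pair:

```r
res <- register_pair(section, ct_slice)         # landmarks + TPS + warp
res$diagnostics$n_landmarks                     # ~50-200 on a full section
rep <- overlap_report(binarize_tissue(res$warped_af),
                      binarize_tissue(ct_slice, "fixed", 13500))
accurate_pct(rep$report)
```

A thin command-line wrapper is installed at `inst/scripts/xrh`
(`xrh phantom --dir DIR`, `xrh run config.yaml`).

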