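# nucleoshape

Quantification of nuclear shape and nuclear envelope (NE) abnormalities in
2D fluorescence micrographs.

A cell type's nucleus has a characteristic, usually near-round shape.
Deviations — lobulation, elongation, micronuclei, NE blebs, NE
invaginations — mark cancers, laminopathies and premature-aging syndromes,
and scoring them by eye is slow and observer-biased. `nucleoshape` is for
cell biologists and image-analysis groups who want those readouts as
numbers: it segments nuclei from a DNA stain (with border and mitotic QC),
computes the standard 2D shape descriptors per nucleus, and runs three
automated detectors for NE abnormalities, all validated against a built-in
synthetic micrograph generator that plants objects with known ground truth.

## The quantities it computes

Per nucleus (area *A*, perimeter *P* from a sub-pixel, de-biased contour):

| descriptor | definition | circle |
|---|---|---|
| form factor (circularity) | 4πA/P² | 1 |
| eccentricity | √(1 − λ₂/λ₁) of the moment-equivalent ellipse | 0 |
| axis ratio | √(λ₁/λ₂) (length-to-width) | 1 |
| solidity | A / area of convex hull | 1 |
| mean negative curvature | mean signed curvature over concave arcs | 0 |
| EFD harmonics needed | harmonics for a 95%-fidelity reconstruction | 1 |
| EFD coefficient ratio | Σₙ≥₂ Eₙ / E₁, harmonic-ellipse energies | ~0 |
| radial asymmetry | pixels outside the largest inscribed circle | ~0 |
| point asymmetry | pixels without a centroid-reflected partner | ~0 |

Detectors:

* **Micronuclei** — small extranuclear chromatin bodies, classified by
  comparative size within the cell: equivalent diameter at most 1/3 of the
  parent nucleus'. Reports per-object records and the micronuclear
  frequency (% of nuclei with ≥ 1 micronucleus).
* **NE invaginations** — intranuclear lamin B separated from the NE rim by
  shrinking the nucleus mask; reports object counts and intranuclear area
  per nucleus.
* **NE blebs** — two routes: chromatin minus the filled lamin-B object
  (blebs lack lamin B), or a maximal morphological cleanup that cuts blebs
  off a single NE/nucleoplasm stain, with micronucleus-like residuals
  rejected. Reports per-bleb area, relative area, optional channel
  enrichment (e.g. lamin A/C at bleb sites), and bleb frequency.

## Worked example

Simulate a 50-nucleus field at SNR 5 with planted micronuclei (20% of
nuclei) and invaginations (0–3 per nucleus), then analyse it:

```r
library(nucleoshape)

spec <- scene_spec(width = 1500, height = 1320, n_nuclei = 50,
                   micronucleus_prob = 0.2, invag_count_range = c(0, 3))
sc <- render_scene(spec, seed = 42)

mn <- detect_micronuclei(sc$channels$dna)
mn$frequency
#> [1] 22

inv <- detect_invaginations(sc$channels$dna, sc$channels$laminB)
mean(inv$results$intranuclear_object_count)
#> [1] 1.433333

res <- run_pipeline(list(scene = sc$channels),
                    which = c("shape", "micronuclei"))
res
#> <nuc_run>
#>   images: 1   nuclei retained: 50
#>   mean form factor 0.975  eccentricity 0.504  solidity 0.996
#>   micronucleus frequency: 22.0%
#>   config 4cab88ef0a261b24727d11f6682bde4b
```

The measured 22% micronuclear frequency is the realised planted rate for
this seed (11 of 50 nuclei drew a micronucleus), and the mean invagination
count matches the planted 0–3 draw; the shape means are what near-round,
mildly lobulated synthetic nuclei should give (form factor and solidity
close to 1, mid-range eccentricity from the 1–1.4 aspect ratios).
`render_scene()` also returns the ground-truth table and per-object pixel
masks, and `score_detections()` matches detections against them by IoU.

On real images, use `read_image()` per channel (TIFF/PNG, raw intensities)
or point `run_pipeline()` at a directory of `<image>_<role>.tif` files.
All thresholds and size parameters live in `nuc_config()` and serialise to
YAML via `write_config()`. A thin command-line front end is installed at
`inst/cli/nucleoshape.R` (subcommands `run`, `simulate`, `score`).

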