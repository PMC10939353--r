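# pictdist

Fluorophore-to-fluorophore distance measurement from two-colour PICT
microscopy, in R.

PICT (Protein interactions from Imaging Complexes after Translocation)
recruits a tagged protein complex to anchor platforms on the yeast plasma
membrane and images anchor (RFP) and prey (GFP) as pairs of
diffraction-limited spots. Each spot is ~300 nm wide, but its centroid
localizes to a few nanometres, and the distribution of anchor-to-prey
centroid distances across many cells determines the true label separation
with a precision of a few nanometres. `pictdist` is for microscopists and
structural biologists who have such two-channel datasets (or want to
prototype the analysis on simulated ones) and need the full computational
chain in one place:

1. **Registration** — affine correction of chromatic aberration calibrated
   on multicolour bead fields, validated on held-out beads via the target
   registration error (TRE); proceed only when TRE < 1 nm.
2. **Preprocessing** — rolling-ball background subtraction (default radius
   70 px) followed by median-filter subtraction (default window 11 px,
   twice the diffraction limit).
3. **Detection and linking** — Crocker–Grier-style sub-pixel centroiding,
   mutual-nearest-neighbour pair linking (2–3 px cap), chromatic
   correction of the anchor coordinates.
4. **Selection** — a quality cascade: spot isolation (10 px), proximity to
   the segmented cell contour (13 px), feature-density filtering on
   (second momentum, eccentricity) retaining the densest 50%, and a 2D
   Gaussian goodness-of-fit threshold (R² ≥ 0.35).
5. **Estimation** — maximum likelihood under the Rician distance law

   p(d | μ, σ) = (d/σ²) · exp(−(μ² + d²)/(2σ²)) · I₀(dμ/σ²),

   where μ is the true separation and σ the localization scale, with
   bootstrap outlier rejection over a grid of upper-tail trim fractions
   and bootstrap standard errors.

A synthetic-scene generator (bead calibration grids with a known affine
distortion; yeast-like cell images with membrane-anchored spot pairs at a
known separation) provides ground truth for every stage, so the entire
workflow is testable without any external data.

## Worked example

Simulate a complete study — bead calibration with a planted chromatic
distortion plus cell fields with a true separation of 20 nm and 7 nm
per-channel localization jitter — and run the whole workflow:

```r
library(pictdist)

cfg <- run_config(seed = 101, out_dir = "run_example", mode = "inter")
run <- run_workflow(cfg)
#> [16:51:47] registration: simulating 20 bead FOVs
#> [16:51:53] registration: TRE 0.555 nm on 279 beads
#> [16:51:58] detect: 162 linked pairs across 9 FOVs
#> [16:52:01] estimate: mu 20.31 nm (sigma 10.20), 81/81 pairs

print(run$fit)
#> Rician fluorophore separation fit
#>   mu    = 20.306 nm  (bootstrap SE 1.500)
#>   sigma = 10.202 nm  (bootstrap SE 1.110)
#>   n = 81 of 81 pairs used (trim 0.0%), logLik -295.31
```

Reading the output: the registration map corrected the planted distortion
down to a held-out TRE of 0.56 nm (comfortably under the 1 nm gate); 162
anchor–prey pairs were linked across 9 fields and 81 survived the
selection cascade (the density filter alone retains 50% by design); the
Rician MLE recovers μ = 20.3 ± 1.5 nm against the simulated truth of
20 nm, with σ ≈ 10.2 nm matching the planted √2 · 7 ≈ 9.9 nm jitter plus
detection error. The outlier-rejection step kept all 81 distances (trim
0%), as it should on clean data. `plot(run$fit)` draws the distance
histogram with the fitted density and μ; `summary(run$fit)` adds the
trim-candidate score table.

Individual stages are exported for piecemeal use — e.g.
`register_beads()`, `preprocess_image()`, `detect_spots()`,
`link_pairs()`, `isolation_filter()` … `estimate_distance()` — and
`dataset_qc()` checks anchor brightness/shape consistency across
datasets. A thin command-line front end mirroring the stages lives at
`inst/cli/f2f.R` (`simulate`, `register`, `preprocess`, `run`).

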