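---
title: "Measuring fluorophore-to-fluorophore distances from PICT images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring fluorophore-to-fluorophore distances from PICT images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

PICT (Protein interactions from Imaging Complexes after Translocation)
recruits a tagged protein complex to engineered anchor platforms on the
yeast plasma membrane and images the anchor (RFP) and a prey subunit (GFP)
as two diffraction-limited spots. Although each spot is hundreds of
nanometres wide, its centroid can be localized to a few nanometres, and
the *distribution* of anchor-to-prey centroid distances over many cells
pins down the true label separation far below the diffraction limit.

`pictdist` implements the full computational chain from raw two-channel
TIFFs to that separation: channel registration, background subtraction,
spot detection and linking, a quality cascade over the linked pairs, and
maximum-likelihood estimation of the separation under the Rician distance
law with bootstrap outlier rejection. A synthetic-scene generator with
known ground truth stands in for microscope data everywhere the package
needs to test itself.

## The distance model

If the true separation of the two labels is $\mu$ and each measured 2D
displacement carries isotropic Gaussian localization error of per-axis
scale $\sigma$, the measured distance $d$ follows the Rice distribution

$$
p(d \mid \mu, \sigma) \;=\; \frac{d}{\sigma^2}
\exp\!\left(-\frac{\mu^2 + d^2}{2\sigma^2}\right)
I_0\!\left(\frac{d\mu}{\sigma^2}\right),
$$

with $I_0$ the modified Bessel function of order zero. At $\mu = 0$ this
is the Rayleigh distribution; for $\mu \gg \sigma$ it approaches
$\mathcal N(\mu, \sigma^2)$. The distribution is right-skewed, which is
why the mean of the measured distances overestimates $\mu$ and a proper
MLE is required. A frequently reprinted variant of this density carries an
extra $1/2\pi$ factor; that form does not integrate to one, and since the
package asserts normalization in its tests and reports log-likelihoods, we
use the normalized density (MLE locations are identical either way).

Two numerical points deserve mention:

* **Bessel stability.** `besselI(x, 0, expon.scaled = TRUE)` underflows to
  zero for $x \gtrsim 5\times10^5$, which a run with $\mu \approx 1000$,
  $\sigma \approx 1$ hits easily. `rice_logpdf()` therefore switches to a
  four-term uniform asymptotic series above $x = 500$ (relative error
  below $10^{-9}$ at the crossover), keeping the log-density finite for
  arbitrary arguments.
* **Multi-start optimization.** The Rice likelihood can hold a local
  maximum on the $\mu = 0$ (Rayleigh) boundary next to an interior
  optimum. `fit_rice()` runs a bounded quasi-Newton search (analytic
  gradient, parameters $(\mu, \log\sigma)$, $\mu \ge 0$) from a
  moment-based start — $\sigma_0$ from the Rayleigh-corrected variance,
  $\mu_0$ from $E[d^2] = \mu^2 + 2\sigma^2$ — plus two further starts, and
  keeps the best converged solution. A $\hat\mu$ on the boundary is
  reported as 0 with a flag, not an error. Note that at true $\mu = 0$ the
  Fisher information for $\mu$ degenerates and $\hat\mu$ converges only at
  the $n^{-1/4}$ rate; tests assert $\hat\mu \ll \hat\sigma$ rather than a
  fixed small number.

## Outlier rejection

Mislinked spots and off-equatorial cells put spurious mass in the upper
tail of the distance distribution, where the skewed Rice MLE is most
sensitive. `bootstrap_outlier_rejection()` considers upper-tail trim
fractions $q \in \{0, 0.025, \dots, 0.30\}$. For each candidate it refits
the model on the kept subset (bootstrap-resampled, `n_boot` times) and
scores the candidate by the per-point log-likelihood **of the full
sample** under a two-component model: kept points follow the refit Rice
density with weight $1-q$, rejected points a uniform background on
$[0, \max d]$ with weight $q$. The candidate with the highest
bootstrap-averaged score wins; ties go to the smaller trim.

Scoring the *full* sample is the load-bearing choice. Any score computed
only on the kept subset — including censored or truncated likelihoods —
improves monotonically as the tail is trimmed (trimming reduces entropy),
so it over-trims cleanly Rician data; we verified this directly before
settling on the mixture score. Under the mixture score, discarding genuine
tail mass costs more (those points are billed at the flat outlier rate)
than covering it with the Rice fit, so clean samples select $q = 0$, while
far outliers are cheaper to park in the background component than to
absorb by inflating $\hat\sigma$. With simulated Rice(20, 10) samples the
selected trim is 0 in every seed we tried, and with 5% contamination
planted at ten times the typical distance the selected trim is exactly 5%
with all planted points rejected.

Bootstrap refits on the selected subset also provide the standard errors
reported for $\hat\mu$ and $\hat\sigma$.

## Registration and its error budget

Chromatic aberration shifts the two channels against each other by up to a
few pixels across the field of view. The registration module fits an
affine map (least squares on homogeneous coordinates) from channel-1 to
channel-2 bead centroids, pooled over a grid of bead fields, and validates
it on a held-out half of the fields (alternating split at the field level,
so fit and validation beads are independent; the fit half receives the
extra field when the count is odd). The validation report gives per-axis
mean absolute deviations and, as the scalar gate, the mean Euclidean
residual (TRE). Distance measurements should proceed only when the TRE is
below 1 nm; `run_workflow()` warns at the gate by default and can enforce
it as a hard stop.

Sub-nanometre TRE puts a hard budget on bead localization (a pixel is
64.5 nm). Three implementation details serve that budget:

* bead centroids are refined by an isotropic 2D-Gaussian least-squares
  fit, whose accuracy on bright beads is photon-limited
  ($\sim \sigma_{\mathrm{PSF}}/\sqrt{N}$, about 0.2 nm at the default
  bead brightness);
* beads with a neighbour within 1.5 detection windows are discarded —
  a neighbouring PSF tail inside the fitting window biases the position
  by $\ge 0.01$ px, an order of magnitude above the budget;
* unresolved bead aggregates merge into a single elongated blob invisible
  to the neighbour rule, so blobs with eccentricity above 0.2 are dropped
  too (isolated genuine beads stay below 0.17 in our scenes).

## Preprocessing and spot detection

Background is removed in the two standard subtractive stages, each clipped
at zero: a rolling-ball estimate (ball structuring element of radius 70 px
by default, "slightly larger than a cell"; computed on a block-minimum
shrunken image and enlarged back, the classic large-radius strategy) for
the smooth extracellular background, then subtraction of the
median-filtered image (square window, default 11 px = twice the
diffraction limit, large enough to erase spots but preserve the cell
contour) for the cytoplasmic signal. The median stage genuinely shrinks
spot cores — an 11 px window cannot fully erase a PSF with
$\sigma \approx 2.3$ px — so the stage is idempotent on spot-free scenes
and position-preserving (not intensity-preserving) on spots; tests check
exactly that.

Spots are localized by Crocker–Grier-style iterative intensity-weighted
centroiding over a circular window (default diameter 11 px). Two
refinements matter at our accuracy scale: the window is re-centred at
*fractional* positions (bilinear resampling), which removes the
half-pixel truncation bias an integer-stepped window leaves behind; and
centroid weights are soft-thresholded at 10% of the window peak, which
stops one-sided residual background (the cytoplasm remnant at a cell
edge) from dragging the centroid. Mass, second momentum (intensity-
weighted mean squared radius) and eccentricity (from the intensity
covariance eigenvalues) come from the same window. Cross-channel linking
is mutual nearest neighbour with a user cap (2 px intra-assembly, 3 px
inter-assembly recommended); ties prefer the brighter channel-2 spot, and
greedy matching is deliberately not offered as a default.

## The selection cascade

Four filters run in fixed order; each appends a `pass_*` flag and a pair
failing stage $k$ is not evaluated at stage $k+1$:

1. **Isolation** — any other detected spot within 10 px (twice the
   diffraction limit minus one) of either member fails the pair.
2. **Cell contour** — both members must lie within 13 px (twice the
   diffraction limit plus two) of a cell boundary pixel (Euclidean
   distance transform; spots slightly outside the cell are fine, the
   anchor straddles the membrane). Segmentation is a pluggable contract:
   any label image of matching shape is accepted (e.g. from a
   neural-network tool); the bundled fallback erases spots with a median
   filter, smooths, thresholds with Otsu, fills holes and labels
   components. In the workflow the fallback runs on the cytoplasmic
   (prey) channel — the anchor channel's membrane rim would dilate the
   contour. On disk-shaped synthetic cells the fallback reaches IoU
   $\ge 0.9$ against truth; bright spots straddling the boundary pull
   that down to $\approx 0.88$, which is precisely the regime where an
   external segmentation backend is worth plugging in.
3. **Feature density** — per channel, a Gaussian-kernel density estimate
   (Scott's-rule bandwidth on standardized features) over the pairs'
   (second momentum, eccentricity); each pair is scored by the lower of
   its two channels' density percentile ranks, and the densest
   `round(n * cutoff)` pairs pass. With the default cutoff 0.5 the densest
   50% of the population is retained, so the retained fraction equals the
   cutoff by construction. Below 20 active pairs the estimate is
   meaningless and the filter skips with a warning (pass-by-default,
   flagged `NA`).
4. **Gaussian goodness of fit** — an isotropic 2D Gaussian plus offset is
   fitted over each member's window; a pair needs
   $R^2 = 1 - SS_{res}/SS_{tot} \ge 0.35$ in both channels. Out-of-focus
   or double-lobed artefacts fail; a non-converged fit scores $-\infty$.
   We fit the joint 2D model rather than the two 1D marginals; for an
   isotropic model with symmetric windows the two are nearly equivalent,
   and the joint fit reuses the bead-refinement code path.

## What the synthetic scenes emulate — and what they do not

`make_bead_dataset()` renders two-channel bead grids: channel-2 positions
uniform with a 4$\sigma_{\mathrm{PSF}}$ minimum spacing (aggregates
negligible by construction), channel-1 positions given by a configurable
affine distortion plus isotropic localization noise, pixel-integrated
Gaussian PSFs, Poisson shot noise and Gaussian read noise. Defaults:
$5\times10^5$ photons per bead (calibration beads are far brighter than
single fluorescent proteins), background 100 counts, read noise 2.

`make_pict_fov()` renders yeast-like cells as disks (radius 25 px
$\approx 1.6\,\mu$m) with elevated cytoplasm (+25 counts over a
100-count background), a Gaussian membrane rim (+30 counts peak, 3 px
radial width, anchor channel only), and anchor/prey pairs on the disk
boundary. The prey truth position is the anchor truth position plus a
displacement of length `true_sep_nm` in a uniform direction; each
channel's rendered position carries independent per-axis jitter of
`loc_noise_nm`, so measured distances follow
Rice(`true_sep_nm`, $\sqrt2\,$`loc_noise_nm`) — this documents exactly
which $\sigma$ the estimator should recover (detection error adds a few
nm in quadrature on top). Spots default to 15000 photons (anchor
platforms carry dozens of protein copies; peak SNR $\approx 30$). These
brightness and background levels are the generator's study conditions:
absolute photon counts vary from setup to setup and are free parameters
here, fixed once at construction time such that the scenes are consistent
with the fixture contracts (sub-0.1 px centroid integrity through
preprocessing, segmentable cells) and left alone thereafter.

The scenes do **not** emulate bud/mother morphology, spectral
bleed-through, focus drift, uneven illumination, or clustered cells.
Passing tests therefore demonstrate the correctness of the computational
chain under the stated imaging model, not robustness to every real-data
pathology — that is what the workflow's guard rails (TRE gate, anchor QC,
pluggable segmentation) are for.

## Anchor QC across datasets

Anchor platforms assemble from a roughly fixed protein copy number, so
across healthy datasets the mean anchor brightness and mean second
momentum move together. `dataset_qc()` fits a robust linear trend
(`MASS::rlm`) across datasets in that plane and flags datasets whose
standardized residual exceeds 3 robust SDs. The rule is deliberately
simple: the decision threshold is configurable, the raw scatter is
returned for inspection, one dataset yields means only, and two yield a
trend with a low-n warning and no flags.

## Problem sizes and reproducibility

Every stochastic stage takes an explicit seed and restores the caller's
RNG state; a serialized `run_config()` plus its seed fully determines a
run, and cached stage outputs never change results relative to a cold
run. The default study conditions used by the package's own validation
are: a 100-field bead grid (25–75 beads per field) for registration,
with a 0.3% scaling + 1.5 px translation distortion and 0.2 nm
localization noise; and, per end-to-end replicate, 9 fields of 9 cells
with 2 pairs each (~160 truth pairs, of which ~70 survive the cascade,
the density filter alone retaining 50% by design) at a true separation
of 20 nm and 7 nm per-channel jitter, repeated over 20 seeds. These
sizes keep a full validation run in the minutes range on a single core
while leaving the estimator's sampling error (~1.5 nm at n≈70) well
inside the 2–5 nm precision envelope the workflow targets.

## Known limitations

* The affine registration model cannot represent nonlinear (polynomial or
  spline) distortion fields; with strong field curvature the TRE gate will
  simply refuse the dataset.
* The threshold segmentation backend assumes cytoplasmic fluorescence
  distinguishes cells from background; dark cells need an external mask.
* The bootstrap rejection scheme follows the published description's
  intent (maximize the likelihood of the distribution without outliers)
  but the original's exact supplementary procedure is not reproduced
  verbatim; the scheme here is specified completely above and validated
  by its planted-outlier behaviour.
* Distances are 2D (equatorial-plane); no axial (z) information is used
  or modelled.
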