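---
title: "Multi-directional OCT: phantom models and processing chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-directional OCT: phantom models and processing chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdoct)
```

# The imaging scenario

Multi-directional OCT probes one retinal location simultaneously with
three sample beams whose pupil entry positions form an equilateral
triangle. After the eye's optics focus the three parallel beams onto a
mutual spot, each beam's chief ray reaches the retina inclined by
`atan(R / L)` against the optical axis, where `R = side / sqrt(3)` is
the triangle's circumradius and `L` the axial eye length. For the
default geometry (2.5 mm side, 24 mm eye) this is 3.4 degrees, and the
smallest pupil that passes all three 0.8 mm beams unvignetted is
`2 R + d = 3.69` mm. Two readings of "beam inclination" exist — against
the axis, or pairwise between beams (larger by a factor of about
`sqrt(3)` at these angles). This package adopts the axis reading as the
primary quantity, because it is what determines each channel's
illumination direction relative to the anatomical axis, and exposes
the pairwise angle separately via `pairwise_beam_angle()`.

Tissue whose scatterers are oriented — photoreceptor outer segments,
RNFL axon bundles, Henle fibers — returns more light into the beam
aligned with its preferred axis. With three directions acquired at
once, per-channel intensity differences encode that orientation.

# Phantom: what is modelled

`phantom_truth()` + `render_multichannel()` generate the synthetic
study conditions for the whole chain. The scene is a 280-pixel-deep,
laterally periodic retina at 3.5 µm axial pitch (so the protocol's
20-pixel window spans ~70 µm and its 15-pixel window ~53 µm). Twelve
layers run ILM → RNFL → inner-retina lump → HFL → ONL → ELM → IS/OS →
outer-segment gap → COST → pre-RPE gap → RPE → choroid; the two
low-reflectivity gap bands place IS/OS and COST inside the
`[RPE-29, RPE-10]` evaluation window, as they are in real scans. All
interfaces share a smooth two-cycle undulation (±4 px) so nothing is
accidentally axis-aligned; raster volumes additionally get a Gaussian
foveal pit. The RNFL is 58 px thick — an optic-nerve-head-region
thickness — so the 100×50-pixel metric ROIs fit inside it, and 59 rows
of vitreous above the ILM hold the background ROIs.

## Directional reflectance models

The angular forms are phenomenological: the simplest periodic
functions with the observed periodicities, not biophysical models.
With `phi` the angle between scan azimuth and a channel's pupil entry
azimuth:

* **Photoreceptor bands (IS/OS, COST)** —
  `g = exp(kappa (cos phi - 1))`, a von Mises-type single lobe per
  revolution, peak 1 when the beam is aligned. Default `kappa = 1.5`
  gives a ~20:1 peak-to-trough ratio, strong enough that each channel
  owns one clear sector of a circumpapillary scan.
* **RNFL** — `g = (1 - m) + m cos^2 phi`: cylindrical scatterers are
  symmetric under 180-degree rotation, so the gain is
  180-degree-periodic with two lobes. Default `m = 0.6` keeps the
  trough at 40 % of the peak, matching the "faint" colour oscillation
  this layer shows relative to the photoreceptor bands.
* **HFL** — `g = max(0, cos phi)^p` (`p = 2` default): the obliquely
  running Henle fibers are visible only when illuminated from the side
  they lean toward, hence a strictly one-sided gain.

For circumpapillary scans `phi` comes from the scan azimuth; for
linear/raster scans it is the polar angle of each position about the
scan centre, which is what radially arranged foveal photoreceptor and
Henle fibers produce.

Azimuthal means of the gains have closed forms used as oracles in the
tests: 1 (isotropic), `exp(-kappa) I0(kappa)` (von Mises), `1 - m/2`
(bilobed), and `Gamma((p+1)/2) / (2 sqrt(pi) Gamma(p/2 + 1))` for the
clipped cosine (`1/4` at `p = 2`).

## Noise model

Each pixel's expected intensity is multiplied by unit-mean exponential
speckle — fully developed speckle, independent across channels by
default. An optional mixing parameter `rho` replaces each channel's
speckle field by `(1 - rho) E_c + rho E_shared`; this preserves the
unit mean and interpolates monotonically between independent and
common speckle, but intermediate `rho` does not keep exact exponential
marginals — it is a study knob, not a physical claim. Zero-mean
Gaussian background noise (default sd 0.05 in linear units) is added
everywhere after the axial channel offset is applied, so the vitreous
contains noise only. Vessels are azimuth intervals whose columns are
attenuated by a factor 0.2 below the vessel row; no flow is modelled.

Raw spectral fringes (`render_spectra()`) are synthesized on a grid
uniform in wavelength (hence non-uniform in wavenumber) as a Gaussian
envelope times `1 + sum_r 2 sqrt(R_r) cos(2 k z_r + a2 (k-k0)^2 +
a3 (k-k0)^3)`, with reflectivities taken from the expected-intensity
column. Only quadratic + cubic dispersion is synthesized, and only
single-reference terms (no autocorrelation), which is exactly what the
four-step reconstruction addresses.

# Processing chain conventions

**Reconstruction.** Mean spectrum subtraction works per frame (it
therefore needs lateral structure; a perfectly uniform frame is its
own DC term and cancels). Resampling to uniform k uses a natural cubic
spline by default (linear optional); apodization is Hann; the analytic
signal is built by zeroing negative FFT frequencies; dispersion
compensation is the pure phase `exp(-i[a2 (k-k0)^2 + a3 (k-k0)^3])`;
the A-scan is the magnitude of the positive-frequency FFT half. These
sub-choices are standard SD-OCT practice and all sit in
`recon_config()`.

**Registration.** The dominant inter-channel error is an axial offset
from sample-arm length mismatch. `estimate_rigid()` does exhaustive
FFT cross-correlation over translations (default ±100 px axial, ±20 px
lateral) with three-point quadratic sub-pixel refinement, repeated
over a coarse angle grid (default ±2°, step 1°) with quadratic
refinement of the score-vs-angle curve. Out-of-field pixels are filled
with 0 (background) so windows near edges read as empty rather than
biased. Interpolation is bilinear; single-pixel-scale content at
Nyquist (thin bands, raw speckle) is necessarily attenuated by any
linear interpolator, which matters for round-trip comparisons but not
for the correlation peak the estimator uses.

**Segmentation.** Boundary finding is an exact dynamic-programming
shortest path: one row per column, hard jump limit (default 2 px)
between neighbours, pixel costs summed, ties broken toward the
smaller row index. The ILM cost is one minus the normalized
dark-to-bright vertical gradient of the log-scaled, σ=2-blurred image,
plus a small anterior bias (0.15 across the full depth) so the topmost
strong edge wins; the RPE cost is one minus normalized brightness,
restricted below the ILM, with a small posterior bias (0.05) so the
bright RPE band beats the thick RNFL at its directional peak. Inputs
without retinal structure are rejected by a row-mean contrast test
(default threshold: 12 noise units) rather than a gradient-maximum
test, whose extreme-value statistics are fragile. Columns whose
RPE-band intensity falls below 35 % of the B-scan median are flagged
as vessel shadows and the boundary is linearly interpolated across
them. The segmented "RPE row" of a band of finite thickness is its
bright centre; the phantom exposes that centre as the RPE anchor its
truth tables and tests use.

**Windows and profiles.** The IS/OS–COST window is anchored on the
segmented RPE with its posterior edge 10 px anterior of it (rows
`[RPE-29, RPE-10]`), excluding the directionally invariant RPE signal
itself; the RNFL window starts 3 px posterior of the ILM (rows
`[ILM+3, ILM+17]`), excluding the specular vitreoretinal reflection.
The stated shift always positions the window's anchor-near edge; this
reading is unit-tested as exact row arithmetic. Window means are
averaged over 10 consecutive B-scans, normalized by the B-scan-median
mean of a 10-px band centred on the RPE (per-B-scan normalization;
per-A-scan is available as an option), rescaled to max 1 for display,
and smoothed by locally weighted regression — degree 1 (`lowess`) or
degree 2 (`loess`) — with default span 0.05, applied on the circularly
wrap-padded profile for circumpapillary scans. Peaks are circular
local maxima with prominence at least 0.1 of the profile range.

**Colour fusion.** Channels 1–3 are tinted cyan, magenta and yellow.
The colour average divides by three, so equal display-scaled channel
intensities give an achromatic grey at 2/3 of the common value; the
colour MIP takes the componentwise maximum, so equal channels
reproduce the common value in every RGB component. Display scaling is
10·log10 with a floor at the 0.1th percentile of positive values,
clipped to the [1st, 99.5th] percentiles — the mapping itself is a
display choice and never feeds quantification, which always works on
linear intensity.

**Metrics.** SNR uses linear data; CNR and ENL use log data defined as
dB above the image noise floor (10·log10 of intensity referenced to
the 0.1th-percentile floor). The reference matters: CNR is invariant
to a log offset but ENL is not, and an unreferenced log scale puts the
signal mean near zero where ENL is meaningless. Five ROI pairs are
used, each 100 columns × 50 rows — signal inside the RNFL band,
background in the vitreous — and metrics are averaged over pairs (five
paired background ROIs, not one shared one).

# Problem sizes and reproducibility

The standard simulation experiments run at 1024 A-scans per
circumpapillary B-scan with 10 B-scans averaged for profiles and 10
phantom seeds for the averaging experiment; full instrument sizes
(6144 A-scans, 250-B-scan rasters) are parameters. Every random stage
is driven by a single integer seed, and a fixed seed reproduces
rendered stacks bit-identically.

# What the phantom does and does not establish

The phantom reproduces the *geometry* of the directional signatures
(one lobe per channel ~120° apart, two RNFL lobes ~180° apart,
one-sided HFL visibility), the speckle statistics relevant to
compounding, vessel shadowing, and the inter-channel depth offsets the
registration removes. Passing tests therefore demonstrate that the
chain recovers known directional structure under realistic noise.
They do not validate: absolute reflectivity or sensitivity scales
(phantom units are arbitrary), the biophysical origin of the
photoreceptor sectors (pointing versus coupling is deliberately left
open in the phenomenological gain), eye motion between B-scans,
sensitivity roll-off, wave-optical effects (defocus, aberrations,
lateral PSF), pathology, or the fine hyporeflective network structure
seen inside HFL in vivo. Table-1-style absolute metric values from
instrument data are likewise out of reach; only the *direction and
approximate magnitude* of the averaging improvements (SNR +10·log10(3)
dB from independent background noise; CNR and ENL strictly improved)
are meaningful phantom claims.

# Known limitations

* The rigid registration searches a coarse angle grid; rotations are
  fine-alignment only (|θ| ≤ 5°) and sub-degree accuracy relies on the
  quadratic refinement being locally valid.
* `segment_rpe`'s posterior bias assumes the RPE is the brightest
  band below the ILM; gross pathology violating that assumption will
  misroute the path.
* The DP boundary search is per-B-scan (2D); no 3D smoothness is
  enforced across a volume.
* En-face projections assume the slab stays inside the volume for
  every A-scan; strongly tilted volumes need flattening first.
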