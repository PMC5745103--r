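# mdoct

Simulation and analysis tools for **multi-directional spectral-domain
OCT** of the retina: imaging with three sample beams that enter the
pupil at the corners of an equilateral triangle and probe the same
retinal spot simultaneously from three directions. Because strongly
anisotropic structures — the photoreceptor IS/OS and COST bands
(optical Stiles–Crawford-type apodization), the cylindrically
scattering nerve fiber layer (RNFL), and Henle's fiber layer (HFL) —
reflect differently into each beam, the three co-registered channels
carry directional contrast that a single-beam system cannot see, and
averaging them compounds three independent speckle realizations.

The package is aimed at people building or validating processing
chains for such instruments. It provides every stage as a plain R
function, plus a forward simulator so the whole chain can be tested
without instrument data:

* **phantom** — renders three-channel retinal B-scans/volumes with
  known layer boundaries, azimuth-dependent layer reflectance,
  fully developed speckle (unit-mean exponential), Gaussian background
  noise, vessel shadows and per-channel depth offsets; optionally raw
  spectral fringes. Directional models: single-lobe von Mises
  `exp(kappa (cos(phi - phi_c) - 1))` for the photoreceptor bands,
  bilobed `(1 - m) + m cos^2(phi - phi_c)` for the RNFL, clipped cosine
  `max(0, cos(phi - phi_c))^p` for HFL.
* **recon** — standard SD-OCT reconstruction: mean spectrum
  subtraction, lambda-to-k resampling, numerical dispersion
  compensation (`exp(-i[a2 (k-k0)^2 + a3 (k-k0)^3])`), FFT.
* **register** — rigid-body inter-channel registration (FFT
  cross-correlation with sub-pixel refinement; depth offsets dominate),
  ILM flattening, and three-volume fusion with surface re-warping.
* **segment** — ILM/RPE boundary segmentation as an exact
  dynamic-programming shortest path through a gradient/brightness cost
  image with a hard column-to-column jump limit; vessel-shadow columns
  are flagged and bridged.
* **direction** — the core quantification: layer-anchored evaluation
  windows (IS/OS–COST: 20 px ending 10 px anterior of the RPE; RNFL:
  15 px starting 3 px posterior of the ILM), per-A-scan window means,
  RPE normalization, circular lowess/loess smoothing, circular peak
  and sector detection, cyan/magenta/yellow additive colour fusion,
  intensity MIP/average compensation and en-face colour MIPs.
* **metrics** — speckle-reduction metrics over paired ROIs:
  `SNR = 10 log10(mu_s,lin^2 / sigma_b,lin^2)`,
  `CNR = (mu_s,log - mu_b,log) / sqrt(sigma_s,log^2 + sigma_b,log^2)`,
  `ENL = mu_s,log^2 / sigma_s,log^2`.

## Worked example

```r
library(mdoct)

g <- beam_geometry()            # 2.5 mm triangle side, 0.8 mm beams, 24 mm eye
min_pupil_aperture(g)           # 3.686751  -> the ~3.7 mm minimum pupil
chief_ray_inclination(g)        # 3.44166   -> the ~3.5 deg beam inclination

## full chain on a simulated circumpapillary scan
ex <- experiment_photoreceptor_sectors(seed = 1, ascans = 1024, n_bscans = 10)
ex$separations
##      1-2      2-3      3-1
## 119.8828 116.0156 124.1016
ex$n_sectors
## [1] 3
```

The three IS/OS–COST intensity lobes sit ~120 degrees apart — one per
pupil entry position — and dominant-channel labelling of the
colour-averaged image yields exactly three colour sectors. The same
phantom run through `experiment_rnfl_lobes()` gives two lobes per
channel ~180 degrees apart, and `experiment_snr_averaging()` shows the
three-channel intensity average gaining ~5 dB of SNR over the mean
single channel (10 log10(3) = 4.77 dB from the independent background
noise, plus a small contribution from the directional signal means).

A thin command-line wrapper is installed at `inst/cli/mdoct`
(subcommands `simulate`, `reconstruct`, `register`, `segment`,
`analyze`, `fuse`, `metrics`, `report`), e.g.

```sh
Rscript inst/cli/mdoct simulate --pattern cp --ascans 1024 --seed 7 --out sim
Rscript inst/cli/mdoct analyze --in sim --out analysis --n-bscans 1
```

## Documentation

The methods vignette (`vignettes/multidirectional-oct.Rmd`) describes
the phantom's directional reflectance models and their parameters, the
processing-chain conventions, the numerical choices in each stage, and
what the simulation does and does not establish about real data.
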