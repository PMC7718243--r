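# qmtcest

Quantitative analysis of continuous-wave saturation-transfer MRI for
tumour characterization, with a digital-phantom validation framework.

Saturation-transfer MRI probes tissue microstructure and metabolism
without contrast agents: magnetization transfer (MT) from semisolid
macromolecules (membranes, collagen) reports on cellular density and
connective tissue, while chemical exchange saturation transfer (CEST)
from amide (3.5 ppm) and guanidinium (2.0 ppm) protons — and the
relayed NOE of aliphatic protons (−3.3 ppm) — reports on mobile
protein/metabolite content.  This package implements the full
quantitative pipeline used to compare such effects between tumour and
necrotic regions of prostate-cancer xenografts, for MRI physicists and
preclinical imaging groups:

* **Two-pool MT fitting.** The steady-state two-pool model with a
  super-Lorentzian semisolid lineshape,

  Z = [R₁F·R₁MT + R₁F·R_rf,MT + R₁F·R_MT + R₁MT·R_MT·M₀MT] /
  [(R₁F + R_rf,F + R_MT·M₀MT)(R₁MT + R_rf,MT + R_MT) − R_MT²·M₀MT],

  with R_rf,F = ω₁²T₂F/(1+(ΔωT₂F)²), R_rf,MT = πω₁²g(Δ), fitted to
  Z-spectra at B₁ = 0.1, 3, 6 µT.  The coupled product R_MT·M₀,MT (the
  "MT effect", Hz) is the headline parameter, alongside T₂,F and T₂,MT.
* **Relaxometry.** T₁ from inversion recovery (polarity-restored
  magnitude fitting) and T₂ from the WASSR spectrum via the
  steady-state direct-saturation signal
  Z = R₁(R₂²+Δω²)/(R₁(R₂²+Δω²)+ω₁²R₂).
* **CEST/rNOE isolation.** Extrapolated semisolid MT reference (EMR):
  MTR_REX = 1/Z_lab − 1/Z_EMR and AREX = MTR_REX/T₁, per voxel at
  ±3.5/2.0/−3.3 ppm and B₁ = 0.5/2 µT.
* **Preprocessing.** Drift correction from interleaved 667-ppm
  references, per-voxel B₀ mapping (Lorentzian decomposition of WASSR
  and low-B₁ spectra), spectrum re-centring, 3×3 mask erosion,
  B₀-outlier exclusion, map normalization.
* **Segmentation.** FastICA (3 components) + mutual-information
  sorting + 5-class full-covariance Gaussian mixture +
  rule-based anatomical labelling.
* **Statistics.** ROI Z-spectra, pooled t-tests with the figure star
  codes, calliper tumour volume, report tables.
* **Synthetic data.** `phantom_spec()` / `make_phantom()` /
  `simulate_study()` build 64×64 digital tumour phantoms (muscle rim,
  connective ring, tumour, necrotic core, blood/edema specks) and
  forward-simulate complete acquisitions — Z-spectrum stacks at five B₁
  levels with interleaved references, WASSR, inversion recovery —
  with drift, noise and B₀ inhomogeneity, retaining per-voxel ground
  truth for recovery scoring.  NIfTI/CSV/YAML I/O via
  `write_study()`/`read_study()`.

## Worked example

Recover the published 22Rv1 tumour-region MT parameters from noiseless
simulated spectra:

```r
library(qmtcest)
b <- mt_recovery_benchmark("22Rv1", "tumour")
b$fit$params
#> Two-pool MT parameters: T2,F = 47 ms, R_MT = 20 Hz, M0,MT = 0.09,
#>   T2,MT = 7.8 us, MT effect R_MT*M0,MT = 1.8 Hz
```

The fitted MT effect (1.8 Hz), T₂,F (47 ms) and T₂,MT (7.8 µs) equal
the generating group means; the residual norm is ~1e-15, i.e. the
four-parameter fit inverts the forward model exactly at these values.

Simulate and preprocess a phantom study:

```r
g  <- make_phantom(phantom_spec(seed = 1))
table(factor(REGION_LABELS[g$label], levels = REGION_LABELS))
#>        background            muscle muscle_connective            tumour
#>              1720               984               308               877
#>          necrosis       blood_edema
#>               140                67

st <- simulate_study(g, protocol(b1_levels = c(0.1, 2),
                                 offsets = default_offsets(c(0.1, 2)),
                                 noise_sd = 0.005), seed = 1)
pp <- preprocess_study(st)
pp$report$n_valid
#> [1] 2160          # of 2376 masked voxels, after erosion + B0 exclusion
pp$report$drift_slope_mean
#> [1] 0.000199      # recovers the generated 2e-04 drift per index
```

WASSR T₂ mapping at the published necrotic-region values:

```r
off <- seq(-1, 1, 0.1)
z   <- eq1_signal(off, b1_ut = 0.1, t1_ms = 2000, t2_ms = 44)
fit_t2_wassr(z, off, t1_ms = 2000)$t2_ms
#> [1] 44            # ms
```

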