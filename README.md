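# phycomon

In-line fluorescence monitoring of cyanobacterial cultures in a (virtual)
photobioreactor.

Cyanobacteria — the dominant contributors to harmful algal blooms — carry
the blue pigment phycocyanin (absorption 620–630 nm, in-vivo emission near
657 nm). Its fluorescence distinguishes the target organism from everything
else that scatters light, which plain optical density (OD) cannot do. This
package implements the complete measurement chain of a six-LED excitation /
compact-spectrometer fluorescence module mounted on a small stirred
photobioreactor, against a fully simulated instrument backend:

* **spectral core** — a `spectrum` type with saturation masking, trapezoidal
  band integration, exposure normalization and parabolic peak refinement;
* **dual-exposure protocol** — each round pauses interfering jobs, gates the
  photoperiod lights, drives each LED one at a time and takes a short
  (0.1 s, excitation peak) and a long (5 s, fluorescence) capture;
* **scattering correction** — the fluorescence band of the long capture is
  normalized against the scattered LED peak of the short capture, both per
  second of exposure:

  `index = (∫ fluor band / t_long) / (∫ LED band / t_short)`

  cancelling the density-dependent scattering common to both;
* **virtual reactor** — an optical forward model (Gaussian LED lines and
  emission bands, density-linear scattering, shot + read noise, detector
  saturation) and culture dynamics for healthy growth, photoinhibition and
  contamination scenarios;
* **analytics** — Theil–Sen trend classification of the joint OD/fluorescence
  series (healthy growth / degradation / contamination), nearest-LED
  excitation selection, and limit-of-detection estimation
  (3.3 σ_blank / slope) with a Monte-Carlo cross-check.

## Worked example

Simulate 24 hours of a photoinhibited culture (irradiance 300 µmol photons
m⁻² s⁻¹ against a 150 threshold), measuring the phycocyanin channel hourly,
then classify the trend:

```r
library(phycomon)

cfg <- run_config(scenario = "photoinhibition", seed = 7, duration_h = 24)
run <- simulate_run(cfg)
run
#> <phycomon_run> 24 rounds | 24 index values | 17280 OD readings | 0 failures

classify_trend(run_series(run))
#> <trend_verdict> degradation (OD falling, fluorescence falling; confidence 0.96; onset 3.0 h)
```

Both normalized traces fall — pigment is being destroyed and cells are
dying — so the verdict is `degradation`, with the sign pattern persistent
from hour 3. A contaminated run instead shows OD rising while fluorescence
collapses and is labelled `contamination`.

Estimate the limit of detection from a simulated calibration series
(0–50 cells/µL, twenty blanks):

```r
set.seed(1)
cal <- generate_calibration_series(c(0, 5, 10, 20, 30, 40, 50), n_blanks = 20)
estimate_lod(cal)
#> <lod_estimate> LoD 2.49 cells/uL (k = 3.3, blank SD 0.000283, slope 0.000376, R^2 0.971)
```

i.e. with the default noise model, a phycocyanin signal 3.3 blank standard
deviations above baseline corresponds to about 2.5 cells/µL.

A thin CLI over the same functions is installed at
`inst/scripts/phycomon`:

```sh
Rscript inst/scripts/phycomon simulate --scenario contamination --hours 12 --seed 7 --out rundir/
Rscript inst/scripts/phycomon analyze trend --run rundir/
#> <trend_verdict> contamination (OD rising, fluorescence falling; confidence 0.97; onset 4.0 h)
Rscript inst/scripts/phycomon select-led --excitation-nm 620
#> led615 (peak 615 nm, 334 mW)
```

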