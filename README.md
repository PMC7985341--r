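# epiwarp

Quantifying susceptibility-induced geometric distortions in gradient-echo
EPI (GE-EPI) and their correction by the two standard routes — dual-echo
gradient-echo (GRE) field mapping and reversed phase-encoding
(blip-up/blip-down, "TOPUP-style") displacement estimation — on fully
synthetic data with known ground truth.

## The problem

GE-EPI samples k-space slowly along the phase-encoding (PE) axis, so local
deviations ΔB₀ of the static field (strongest near air/tissue interfaces
such as the sinuses) accumulate into spatial shifts: tissue appears
displaced, compressed or stretched along PE. The per-voxel displacement is

```
VSM = s_y · ΔB₀ / (BW_PE × R),    BW_PE = 1 / (echospacing × n_y)
```

with `s_y` the PE voxel size (mm), `BW_PE` the PE bandwidth (Hz/pixel),
`n_y` the echoes per excitation and `R` the in-plane acceleration factor.
With `s_y = 2.5 mm`, `echospacing = 0.57 ms`, `n_y = 78`, `R = 2`, a
−76 Hz offset shifts tissue by −4.2 mm; +282 Hz by +15.7 mm.

The package provides, as S4 classes and functions:

* **Distortion physics** — `db0ToVsm()`, `applyDistortion()` (mass-conserving
  1-D forward warp), `unwarpVolume()` / `correctSeries()` (Jacobian-restoring
  inverse).
* **Synthetic data** — `makePhantom()`, `makeField()`, `synthDualEcho()`,
  `synthEpiRun()`, `makePhantomRun()`: a multi-tissue head phantom, a smooth
  ΔB₀ field with focal sinus offsets (−170…+280 Hz), dual-echo GRE images
  with Rician noise, and AP/PA EPI runs with block-design BOLD activations
  and resting-network fluctuations.
* **GRE chain** — `rescalePhase()`, `unwrapPhase()` (quality-guided region
  growing), `phaseToField()`, `smoothField()`, `correctGRE()`.
* **Reversed-PE chain** — `estimateFieldTopup()` (regularized Gauss–Newton on
  a coarse-to-fine spline field, midway assumption), `correctPair()`.
* **Assessment** — `nmse()`, `crossCorrelation()`, `diceCoef()`,
  `assignRSNs()` (randomized mutually exclusive template matching),
  `bbrCost()` (boundary-based registration cost), `vsmRoiRange()`.
* **Functional analyses** — `preprocessSeries()`, `doubleGammaHrf()`,
  `fitGlm()`, `clusterThreshold()`, `groupMap()`, `extractComponents()`
  (spatial FastICA).
* **Orchestration** — `RunConfig()`, `fullRun()`, `reportTables()`.

## Worked example

```r
library(epiwarp)

geom <- EPIGeometry()                    # 2.5 mm, 0.57 ms, 78 echoes, R = 2
field <- FieldOffsetMap(array(-76, c(1, 1, 1)))
mapValues(db0ToVsm(field, geom))         # -4.223... mm, prints as -4.2

report <- fullRun(RunConfig(seed = 0L))  # ~2 min on one CPU
report
#> AssessmentReport (seed 0 )
#>   PA/AP nMSE: uncorrected=0.0877, topup=0.0010, gre=0.0013
#>   BBR cost:   uncorrected=0.4418, topup=0.4358, gre=0.4358
#>   RSN Dice:   uncorrected=0.933, topup=0.949, gre=0.949
#>   max Z:      uncorrected=27.94, topup=28.16, gre=28.09
```

Reading the report: the AP/PA normalized mean squared error collapses by two
orders of magnitude after either correction (the reversed-PE estimate, which
minimizes exactly this difference, edges out the field map); the
boundary-based registration cost drops when the corrected volume is compared
against the white-matter surface of the undistorted truth; overlap of the
recovered networks and of the task activation with their ground-truth masks
improves after correction. `reportTables(report, "out/")` writes each table
as CSV.

## Acceptance script

`scripts/acceptance.R` recomputes the six reference voxel-shift values by
running the package's field-to-shift conversion on the published acquisition
constants and ΔB₀ extrema, and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
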