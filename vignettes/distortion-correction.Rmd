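---
title: "Simulating and correcting EPI susceptibility distortions"
author: "epiwarp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and correcting EPI susceptibility distortions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Gradient-echo EPI accumulates off-resonance phase between successive
phase-encoding (PE) lines, so a local static-field offset ΔB₀(x) (Hz)
displaces signal along PE by

$$\mathrm{VSM}(x) = \frac{s_y \,\Delta B_0(x)}{BW_{PE} \times R},
\qquad BW_{PE} = \frac{1}{\mathrm{echospacing} \times n_y},$$

in mm, where $s_y$ is the PE voxel size, $n_y$ the echoes per excitation
and $R$ the in-plane acceleration. Using the nominal echo spacing together
with $R$ is algebraically identical to using the effective (spacing$/R$)
value with $R = 1$; `db0ToVsm()` accepts either convention and the package
asserts their equivalence in its tests. An AP acquisition shifts signal by
$+\mathrm{VSM}/s_y$ voxels, a PA acquisition by the negative — this sign
flip is what both correction approaches exploit.

`applyDistortion()` implements the forward model as a monotone 1-D warp per
PE line. With `conserveMass = TRUE` (the default, and the physically
sensible choice for spin density) every voxel cell's signal is redistributed
over the image of that cell under the warp, so compressed regions brighten
and each line's total signal is conserved to machine precision. The
spec-level alternative — pointwise interpolation through the inverse map
weighted by a finite-difference Jacobian — cannot conserve the discrete line
sums to better than O(h²), which is why the conservative (cell-edge)
resampler was chosen for the mass-conserving branch; the non-conserving
branch (`conserveMass = FALSE`) uses exactly the root-interpolated inverse
map. `unwarpVolume()` is the pull-back inverse: values are read at
$y + d(y)$ by linear interpolation and multiplied by the local Jacobian
$1 + \partial d/\partial y$ (central differences, floored at 0.05 to avoid
division blow-ups at near-singular warps). Out-of-grid samples read as zero
background. Warps with $|\partial d/\partial y| \ge 1$ voxel/voxel are not
invertible and are rejected with a count of violating locations.

Whether unwarping should modulate intensities by the Jacobian is left open
by the methods this package emulates; both behaviours are exposed through
`conserveMass` and the round-trip tests exercise both.

## The synthetic world

`PhantomSpec()` describes everything the generators need. Defaults are
fixed once and define the package's "stated world":

* **Grid** 48 × 64 × 32 voxels at 2.5 mm isotropic (PE along the second
  axis). This matches the voxel size of a typical accelerated 3T fMRI
  protocol while keeping every stage in seconds-to-minutes on one CPU.
* **Tissues** — nested ellipsoids: GM 1000, WM 700, ventricular CSF 1300,
  background 0 (arbitrary units). The GM > WM ordering gives the
  white-matter surface the contrast polarity that boundary-based
  registration scores.
* **Field** — a low-order polynomial background (≤ 10 Hz) plus two Gaussian
  blobs: +280 Hz (σ = 14 mm) in the inferior frontal region and −170 Hz
  (σ = 12 mm) near the temporal lobe, emulating the focal offsets near the
  air-filled sinuses. These amplitudes reproduce the reported −170…+280 Hz
  scale of measured ΔB₀ extrema and imply shifts up to ~16 mm (6.4 voxels),
  while the blob widths keep the warp invertible
  (max $|\partial d/\partial y| \approx 0.7$).
* **Dual-echo GRE** — TE₁/TE₂ = 4.92/7.38 ms (ΔTE = 2.46 ms). Each echo is
  simulated as a complex signal $S e^{i 2\pi \Delta B_0 TE}$ plus complex
  Gaussian noise, so magnitudes are exactly Rician and the phase difference
  wraps naturally into (−π, π].
* **EPI runs** — TR 1 s; a 28 s block structure (18 s stimulation + 10 s
  rest), scaled to 6 blocks (168 volumes) so a full experiment stays within
  minutes; 2% BOLD amplitude (a typical block-design effect size); three
  bilateral network masks with < 0.1 Hz fluctuations at 1% amplitude;
  acquisition noise 2% of mean brain intensity (SNR 50), added after the
  distortion, as in acquisition. Ten PA calibration volumes are generated
  and the pipeline uses the last one, mirroring the acquisition protocol it
  emulates.

What a green test does *not* establish: the phantom has no motion, no
physiological noise, no through-plane dropout, no k-space/GRAPPA
reconstruction effects, and its GRE field map is perfectly aligned with the
EPI grid — on real data the field-map route additionally suffers
registration error. Absolute metric values (e.g. nMSE levels) therefore sit
far from human-data values; only their orderings and recovery errors are
meaningful, and those are what the tests assert.

## The GRE chain

`correctGRE()` composes: phase rescale → quality-guided unwrapping →
division by ΔTE (rad/s) → division by 2π (Hz) → masked Gaussian smoothing →
VSM → unwarp. Numerical choices:

* **Unwrapping** is region growing in decreasing quality order (quality =
  the first-echo magnitude when available, otherwise inverse local
  phase-gradient variance), seeded at the highest-quality voxel. The output
  is congruent with the input modulo 2π at every voxel — asserted at 1e-9 —
  and anchored at the seed. Disconnected mask components unwrap
  independently with a warning, since their relative 2π offsets are
  indeterminate.
* **Despiking**: isolated unwrap failures at low-SNR voxels appear as
  half-cycle (1/(2ΔTE) ≈ 203 Hz) outliers; voxels deviating from their
  local 3³ in-mask median by more than that are replaced by the median
  before smoothing, the same defensive step field-map pipelines apply.
* **Masking**: the first-echo magnitude is thresholded at 0.75 × its Otsu
  level and reduced to its largest connected component (noise speckles off
  the head would otherwise seed bogus unwrap components).
* **Smoothing** defaults to FWHM 4 mm with mask-renormalized weights (the
  pipeline's spatial smoothing scale; the emulated tool's kernel is not
  published). `fwhm = 0` disables it, which the noise-free recovery test
  uses.
* **Extrapolation**: outside the mask the field is extended by iterative
  nearest-neighbour averaging and then clamped into the Lipschitz envelope
  of the in-mask values along PE (slope ≤ 0.8 voxel/voxel). In-mask values
  are never touched; the extension only prevents the unwarp from becoming
  non-invertible at the brain edge.

On the noise-free phantom the chain recovers ΔB₀ to machine precision
(RMSE ≈ 1e-14 Hz); at SNR 50 the VSM error is ≈ 0.06 mm RMSE.

## The reversed-PE chain

`estimateFieldTopup()` estimates the shift field from one AP and one PA
image under the midway assumption, minimizing

$$\sum_x \left[U(AP, +v) - U(PA, -v)\right]^2 + \lambda\,\mathrm{bending}(v)$$

where $U$ is the Jacobian-modulated unwarp. Design:

* The field is parameterized by coefficients on a coarse knot grid with a
  trilinear (tensor hat) basis, shifts along PE only. The basis is
  interpolating, which makes coarse-to-fine prolongation trivial (sample the
  field at the finer knots).
* Gauss–Newton with backtracking line search; candidate steps that would
  break warp invertibility are rejected inside the line search. The exact
  data-term derivative includes the Jacobian-modulation term
  $A(y+d)\,\partial_y B$ — on piecewise-constant anatomy this term dominates
  in flat regions and omitting it (the common "gradient-only" shortcut)
  produces ascent directions.
* The objective is non-increasing over accepted iterations (asserted on the
  trace); non-convergence at `maxIter` returns the best iterate with a
  warning.
* λ defaults to $0.1 \cdot f_{data}(0) / \sum_k L_{kk}$ with $L$ the
  second-difference bending penalty. The literal "bending of a unit field"
  normalization is degenerate (a constant field has zero bending), so the
  trace of $L$ stands in as the scale; the value is exposed in
  `TopupParams`.
* Pyramid: 8/4/2 mm Gaussian pre-smoothing with 15 mm knots is the
  estimator's standalone default. The bundled pipeline (`RunConfig()`) uses
  an extended schedule — 8/4/2/0 mm smoothing with 15/10/7.5/5 mm knots —
  because 15 mm knots cannot resolve focal field features of σ ≈ 12 mm; the
  finer final level is what lets the reversed-PE route reach the AP/PA
  agreement it is designed to minimize (VSM RMSE ≈ 0.08 mm at 2% noise).
  The emulated tool's own shipped configuration is likewise multi-level and
  is not reproduced verbatim here.

## Assessment metrics

* **nMSE** uses the symmetric normalization
  $2\sum(A-B)^2 / \sum(A^2+B^2)$ (so a comparison against a zero image
  yields 2). The source text does not print its exact normalization;
  absolute nMSE values depend on this choice, orderings do not.
* **Cross-correlation** is Pearson over the masked voxels (the alternative,
  an uncentred inner product, is not used); a brain mask is applied by
  default.
* **RSN assignment**: components are matched to templates by Dice after
  thresholding IC z-maps at 3.0; templates are assigned greedily in
  randomized order, mutually exclusively, and the order with the highest
  mean Dice wins. All T! orders are enumerated when T! ≤ 10000, otherwise
  that many are sampled under a seed; ties break toward the lowest component
  index for reproducibility.
* **BBR cost** samples intensities 2 mm either side of the white-matter
  surface along its normals and soft-clips the percent contrast through
  $(1+\tanh(-sQ/100))/2$ (slope 0.5 by default — the sampling geometry is
  specified by the emulated method, the clipping shape follows the
  boundary-registration literature). 0.5 means no contrast; lower is
  better.
* **GLM**: OLS with an HRF-convolved boxcar (double-gamma, peak ≈ 5 s,
  1:6 undershoot, unit peak), exact t→Z transform capped at |Z| = 40.
  Cluster inference is a fixed extent threshold (default 10 voxels) instead
  of random-field cluster p-values — a documented divergence from the
  emulated pipeline. Prewhitening is omitted because the generator draws
  white noise, making OLS exact. The group stage is a one-sample t over
  subject effect maps (a stand-in for mixed-effects modelling); voxels with
  zero between-subject variance are flagged NA.
* **Spatial ICA** uses a fixed component count K (the eigenspectrum-based
  automatic order estimation of the emulated tool is out of scope) with
  FastICA (tanh contrast, symmetric decorrelation) implemented in-package,
  as no ICA implementation is available in the environment; maps are
  z-scored with skewness-positive sign.

## Degenerate inputs and tie-breaks

Empty masks, zero-width phase ranges, both-zero images (nMSE), zero-variance
images (correlation), rank-deficient designs, non-invertible warps and
fewer components than templates all raise errors; two empty masks give
Dice 0 with a warning. `assignRSNs` ties break toward the lowest component
index; `which.max` does the same inside the greedy step.

## Limitations

The estimator family is 1-D by construction: through-plane dephasing and
signal dropout are not modelled or corrected (neither approach corrects
them on real data either). The phantom's piecewise-constant anatomy makes
round-trip warp errors concentrate at tissue edges, so round-trip accuracy
contracts are stated on band-limited volumes. Reported absolute metric
levels are not comparable to human-study values; the package's claims are
orderings, calibrations, and ground-truth recovery errors.
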