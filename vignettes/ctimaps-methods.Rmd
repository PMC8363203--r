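---
title: "Conductivity tensor imaging without MR-EPT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conductivity tensor imaging without MR-EPT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Electrical conductivity of brain tissue at its physiological frequency
range (around 10 Hz) is anisotropic — higher along white-matter fibre
bundles — and cannot be measured directly by MRI. MR electrical
properties tomography (MR-EPT) recovers conductivity at the Larmor
frequency (about 128 MHz at 3T) from the trans-receive phase via the
Helmholtz equation, but the Laplace operator involved is noise-sensitive
and breaks down at tissue boundaries. `ctimaps` implements an
alternative route that avoids MR-EPT entirely:

1. **High-frequency conductivity from water content.** Two spin-echo
   images at repetition times TR1 = 700 ms and TR2 = 3000 ms give a
   ratio image $I_r$. Water volume fraction follows the calibrated
   exponential $W = w_1 e^{-w_2 I_r}$ ($w_1 = 1.525$, $w_2 = 1.443$),
   and high-frequency conductivity follows
   $\sigma_{HF} = c_1 + c_2 e^{c_3 W}$
   ($c_1 = 0.286$ S/m, $c_2 = 1.526\times10^{-5}$ S/m, $c_3 = 11.852$),
   defined for $0.6 \le W \le 1$. Both are pixelwise operations, so the
   spatial resolution of $\sigma_{HF}$ matches the spin-echo data.
2. **Microstructure from multi-shell diffusion.** The direction-averaged
   signal at shells $b = 50, 150, 1000, 1800, 4500$ s/mm$^2$ is fitted
   by a three-compartment model with intracellular fraction $v_{ic}$,
   free-water fraction $v_{iso}$ and extracellular mean diffusivity
   $d_e^*$:
   $$\frac{S_b}{S_0} = (1 - v_{iso})\left[v_{ic}\,e^{-b\,v_{ic} d_{ic}}
   + (1 - v_{ic})\,e^{-b\,(1 - v_{ic}) d_e^*}\right]
   + v_{iso}\,e^{-b\,d_{iso}},$$
   with $d_{ic} = 1.7\times10^{-3}$ and $d_{iso} = 3\times10^{-3}$
   mm$^2$/s fixed a priori. Derived quantities are
   $\chi_e = (1-v_{iso})(1-v_{ic}) + v_{iso}$,
   $d_e = [(1-v_{iso})(1-v_{ic})^2 d_e^* + v_{iso} d_{iso}]/\chi_e$ and
   $d_i = v_{ic} d_{ic}$.
3. **Tensor assembly.** The water diffusion tensor $D$ is fitted at
   $b = 1000$ s/mm$^2$ only; the extracellular tensor is the rescaling
   $D_e = \eta D$ with $\eta = 3 d_e / \mathrm{tr}(D)$ (so
   $\mathrm{tr}(D_e) = 3 d_e$ exactly), and the low-frequency
   conductivity tensor is
   $$C_{LF} = \frac{\chi_e \sigma_{HF}}
   {\chi_e d_e + (1 - \chi_e) d_i \beta}\, D_e,$$
   with $\beta = 0.41$ the ratio of intra- to extracellular ion
   concentrations. The isotropic-equivalent map $\sigma_{LF}^{iso}$ is
   the geometric mean of the eigenvalues of $C_{LF}$ — the conductivity
   of the isotropic ellipsoid of equal volume.

The exponents of the compartment model contain the volume fractions
(e.g. $e^{-b\,v_{ic} d_{ic}}$), which differs from canonical NODDI; the
model is implemented exactly as stated above. Consequences of that
choice for identifiability are discussed below.

## Fitting: leave-one-out MIP, labelling, imputation

With one direction average per shell there are only five data points
for three parameters, and the fit is fragile. Three stabilisations are
applied, in order:

* **Leave-one-out MIP.** With $n = 16$ directions per shell, the fit is
  run $n$ times, run $j$ averaging the $n-1$ directions excluding $j$
  (the same exclusion index at every shell, since directions are matched
  across shells in the protocol). The final map is the voxelwise
  maximum over the $\binom{16}{15} = 16$ runs, counteracting the
  systematic underestimation of individual fits. Per-run maps are kept
  for diagnostics.
* **Cutoff labelling.** Voxels of $v_{ic}$ or $v_{iso}$ below 0.15 are
  assumed outside the physiological range and marked invalid. For
  $v_{ic}$ the CSF (segmented by thresholding $\sigma_{HF}$ at 2 S/m)
  is exempt, because $v_{ic} = 0$ is correct there. $d_e^*$ receives no
  cutoff — the procedure describes the cutoff for the volume-fraction
  maps only — and is imputed only where the fit is degenerate.
* **Delaunay imputation.** Invalid voxels are re-filled slice-by-slice
  (axial planes by default, configurable) by Delaunay triangulation of
  the valid voxels with linear interpolation (via the `interp`
  package); voxels outside the convex hull, or slices with fewer than
  three valid voxels, fall back to the nearest valid neighbour. Linear
  interpolation on a triangulation reproduces planar fields exactly,
  which the tests exploit.

### The optimiser

The stated minimisation is a bounded Nelder–Mead
($v_{ic}, v_{iso} \in [0, 1]$, $d_e^* \ge 0$, initial point
$(0, 0.5, 0)$). We map the box to $\mathbb{R}^3$ with logit/softplus
transforms — avoiding projection artifacts at the bounds — and run
Nelder–Mead (objective tolerance $10^{-10}$, at most 2000 iterations
per descent, incumbent restarts). Because the exact boundary maps to
$-\infty$ under the transform, boundary initial values are inset by
$10^{-3}$ before transforming.

Two facts about the objective shaped the implementation:

* **Twin basins.** Whenever $v_{ic} d_{ic} \approx (1 - v_{ic}) d_e^*$,
  the intra- and extracellular exponentials are nearly
  indistinguishable, and the sum of two similar exponentials is itself
  well approximated by a single exponential at an intermediate rate.
  The objective then has a second, shallow minimum near $v_{ic} = 0$
  separated from the true one by objective differences of order
  $10^{-13}$. A descent from one fixed start lands in either basin
  unpredictably. The fit therefore adds a coarse grid scan over the
  box, a descent from the best grid cell, a Levenberg–Marquardt polish
  with the analytic Jacobian (Nelder–Mead simplexes collapse
  prematurely inside the flat valley), and a sweep of curvature-aware
  descents along the $v_{ic}$ axis. On noise-free signals this recovers
  interior parameters to near machine precision, which the brute-force
  grid-search oracle in the test suite confirms independently.
* **The free-water ridge.** When the data follow
  $S_b/S_0 = e^{-b d_{iso}}$ exactly (pure CSF), every point of the
  ridge $v_{ic} = 0$, $d_e^* = d_{iso}$, $v_{iso}$ arbitrary fits
  perfectly: $v_{iso}$ is unidentifiable. The derived quantities are
  invariant along the ridge ($\chi_e = 1$, $d_e = d_{iso}$,
  $d_i = 0$), so downstream maps are unaffected; tests assert the
  derived quantities, not the raw ridge coordinate.

## The synthetic phantom

The phantom emulates the acquisition end-to-end with no data download:
concentric shells (CSF rim, GM ribbon, WM core) plus a central CSF
ventricle block on a 32³ grid at 1 mm isotropic spacing by default.
Per-tissue ground truth uses literature-typical 3T values (defaults,
not claims):

| tissue | $W$ | $T_1$ (s) | $v_{ic}$ | $v_{iso}$ | $d_e^*$ (mm²/s) |
|---|---|---|---|---|---|
| GM  | 0.846 | 1.30 | 0.4 | 0.2 | 1.2e-3 |
| WM  | 0.727 | 0.83 | 0.6 | 0.2 | 0.8e-3 |
| CSF | 0.990 | 4.0  | 0.0 | 1.0 | 3.0e-3 |

The spin-echo pair is simulated either by saturation recovery
$S(TR) = PD\,(1 - e^{-TR/T_1})$ (identical TE assumed, cancelling in
the ratio) or in a *calibrated* mode that inverts the water transfer
function so $W$ round-trips exactly — the mode used by the exactness
tests. DWI is simulated in a *spherical* mode emitting the
direction-independent compartment signal (so the direction average
equals the model to machine precision) or in a *tensor* mode emitting
$S = S_0 e^{-b\,g^T D g}$ from per-tissue tensors, used to exercise the
tensor-fit path; tensor-mode mean diffusivities are set to the
$b = 1000$ apparent diffusivity of the spherical model so the two modes
agree at the tensor shell. No jointly consistent orientation-dispersion
model linking the compartment model to an anisotropic tensor is
attempted (none is defined for this model); WM anisotropy in tensor
mode is a separate construction from a principal orientation and a
fractional eccentricity with the trace preserved.

Noise: Gaussian for spin-echo magnitudes, Rician
($|S + \epsilon_1 + i\epsilon_2|$) for DWI, both seeded and
reproducible. The default noisy condition is $\sigma = 2.5$ at a proton
density of 100, i.e. SNR $\approx 40$ at $b = 0$. Slice gaps are not
simulated: the reconstruction is pixelwise per slice, so achieved
resolution is independent of gap, and phantoms use gapless grids.

What the phantom does *not* emulate: realistic anatomy, partial-volume
mixing at boundaries, susceptibility distortion, multiband/SENSE
artifacts, B1+ transmit inhomogeneity (a known limitation of the water
route, deliberately not corrected), or spatially correlated noise.
Passing phantom tests therefore demonstrates correctness of the
computational chain, not in vivo accuracy.

## Evaluation statistics

Per-tissue distributions of $\sigma_{LF}^{iso}$ are summarised by mean,
population standard deviation (switchable; population is used in the
mean±std tables) and CV = std/mean in %. GM/WM separability uses the
coefficient of joint variation
$CJV = (std_{GM} + std_{WM}) / (mean_{GM} - mean_{WM})$, reported in %
with the GM-minus-WM orientation fixed by contract. CSF is segmented by
$\sigma_{HF} \ge 2$ S/m; GM/WM masks are user inputs (on real data they
come from an anatomical segmenter, which is out of scope) or phantom
ground truth.

The spatial-resolution surrogate is a power spectral density along one
axis: per in-mask line, the longest contiguous in-mask segment of at
least 16 voxels is taken, segments are truncated to the shortest
qualifying length so frequency bins align, raw periodograms (no
windowing — the simplest faithful reading) are averaged across lines,
converted to dB, and the DC bin is removed; zero power is floored at
−120 dB. Band-limited references are produced by linear down- then
up-sampling of the in-plane axes to a coarser spacing; supra-Nyquist
bins of a 2 mm reference must fall below the native profile, which the
acceptance tests verify on a textured phantom.

## Numerical choices and degenerate inputs

* Undefined voxels (outside masks, outside the $W$ validity range,
  degenerate fits, zero denominators in the tensor relation) are `NA`
  and propagate; every stage tolerates them and counts them in
  metadata, since these are the method's known failure surfaces.
* Out-of-range $W$ (< 0.6 or > 1) is masked, not clamped: the
  conductivity transfer function is exponential and extrapolation
  amplifies water-map errors (its derivative grows like
  $e^{c_3 W}$).
* The tensor fit is a one-pass reweighted log-linear least squares
  (weights = squared predicted signals); exact parity with any external
  iterative estimator is not claimed. Non-positive signals are floored
  at $10^{-10}$ and counted.
* The eigendecomposition of symmetric tensors (the "SVD" of the
  procedure) clamps negative eigenvalues to zero with a per-voxel
  count, rather than taking absolute values — conservative, and it
  makes the isotropic-equivalent of any non-PSD voxel zero.
* Shells are identified by clustering b-values within ±25 s/mm²;
  $S_0$ is the mean of all $b = 0$ volumes.
* Gradient vectors are interpreted in the image coordinate frame
  (FSL dialect).
* Voxels with identical signal vectors share one fit (a pure
  memoisation; piecewise-constant phantoms collapse to a handful of
  unique problems).

## Problem sizes

The reference phantom is 32³ (≈ 12.5k tissue voxels); the leave-one-out
MIP then solves 16 × 12.5k ≈ 200k three-parameter fits, about a
millisecond each in the compiled core, and the noise-free pipeline
completes in seconds thanks to deduplication. The brute-force
grid-search oracle used by the tests evaluates 201³ parameter
combinations per instance and is intentionally kept to 20 instances.

## Known limitations

* The compartment model as printed is weakly identifiable near
  $v_{ic} d_{ic} = (1 - v_{ic}) d_e^*$ — which includes typical
  grey-matter parameters. Noise-free data are recovered exactly, but
  under measurement noise the global minimiser can collapse $v_{ic}$
  toward zero there; the cutoff-and-impute repair then reconstructs
  those voxels from their neighbourhood. This mirrors the instability
  the MIP/labelling procedure was designed against, and it bounds what
  per-voxel accuracy can be expected from noisy data at these
  parameters.
* Direction-averaging magnitude data does not remove the Rician floor:
  at $b = 4500$ s/mm² and SNR 40 the per-volume SNR of brain tissue is
  near 1, and the averaged signal acquires a substantial positive bias
  that propagates into $d_e^*$. Upstream denoising (part of the
  acquisition-side preprocessing, out of scope here) mitigates this on
  real data.
* The water route assumes consistent receiver gain between the two
  spin-echo scans (a >10× median discrepancy triggers a warning) and no
  B1+ correction is applied.
* CSF conductivity inherits the amplified error of the exponential
  transfer function at high $W$; real-data CSF statistics are wide for
  that reason.
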