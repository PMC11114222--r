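---
title: "Guided super-resolution of FLIM images: model and methods"
author: "flimfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guided super-resolution of FLIM images: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Fluorescence lifetime imaging (FLIM) measures, per pixel, the
characteristic decay time of fluorescence emission — an intensity-independent
reporter of the fluorophore's molecular environment.  Time-resolved
detectors (SPAD arrays, scanned TCSPC) trade spatial resolution for timing:
a typical wide-field SPAD has a low pixel count and a low fill factor, so
the lifetime image samples the field of view sparsely, while an ordinary
camera records intensity at high resolution with near-100% fill factor.

`flimfuse` fuses the two single-sample measurements.  Writing
$\tau_{LR} = A\,\tau_{HR}$ for the decimation (point-sampling) operator $A$
with integer factor $\lambda \in \{2,4,8,16\}$, it recovers the
high-resolution lifetime map as

$$
\tau_{HR}^{*} = \arg\min_{\hat\tau \ge 0}\;
\lVert A\hat\tau - \tau_{LR}\rVert_2^2
+ \gamma\lVert (\hat\tau - \hat\tau_{LP})\cdot m_{LP}\rVert_2^2
+ \beta\lVert (\hat\tau - \hat\tau_{GP})\cdot m_{GP}\rVert_2^2
+ \alpha\lVert D\hat\tau\rVert_1
$$

where $\hat\tau_{LP}$ and $\hat\tau_{GP}$ are two statistically informed
high-resolution priors built *from the sample itself* (no external training
data), $m_{LP}, m_{GP}$ are their validity masks, and $D$ is the
anisotropic (horizontal + vertical forward-difference) total-variation
operator.  Because both priors are derived from the same field of view, the
method cannot hallucinate out-of-distribution structure the way externally
trained super-resolution networks can; when neither prior carries signal,
the TV term reduces the method to edge-preserving interpolation.

## Why intensity carries lifetime information — and why not perfectly

For a single fluorophore the quantum yield is $Q = k_r \tau$: brightness
and lifetime are linked through the radiative rate.  Across a field of
view, however, measured intensity is quantum yield *times absorbance*
(concentration × absorptivity × thickness), and absorbance is unknown and
spatially varying.  Intensity is therefore an informative but confounded
proxy for lifetime — which is exactly why the priors are *statistical*, and
why the synthetic phantom (below) deliberately includes a smooth random
absorbance field so that intensity is *not* a global function of lifetime.

## The local prior

In each $w \times w$ window of low-resolution samples (default $w = 5$),
the (intensity, lifetime) pairs — intensity read off the high-resolution
image at the sampled positions — are fitted with a one-dimensional map
$f$, and $f$ is evaluated at the high-resolution intensity pixels of the
window's central $\lambda \times \lambda$ block:
$\hat\tau_{\lambda i + x, \lambda j + y} = f_{i,j}(I_{\lambda i + x, \lambda j + y})$.
Sliding the window with unit stride tiles the grid exactly once.

Choices the window fit has to make, and what we chose:

* **Function family.** Linear interpolation is the default
  (`localPriorConfig(kind = ...)` also offers nearest-neighbor, natural
  cubic splines, and an RBF kernel-ridge regressor for model-comparison
  work).  Linear interpolation with a 5×5 window is the shipped default.
* **Duplicate intensities** are averaged before fitting — a function must
  be single-valued.  Nearest-neighbor ties resolve toward the lower
  intensity.
* **Extrapolation is clamped** to the nearest sampled lifetime.  Unbounded
  linear extrapolation amplifies noise at extreme intensities; clamping
  bounds every prediction by the window's observed lifetime range, and the
  solver's TV term damps the residual block artifacts.
* **Borders:** windows are shifted (not shrunk) to stay inside the sample
  grid, so border blocks still see $w^2$ samples.
* **Degenerate windows** (all intensities equal) fall back to the constant
  map at the mean lifetime; a block is marked invalid only when its window
  contains no valid samples at all.

## The global prior

Morphologically similar structures often share lifetimes across a field of
view (vesicles vs. membranes, globules vs. cell walls).  The global prior
learns this mapping with a small convolutional regressor trained from
scratch on the sample being upsampled:

* **Inputs** are $13 \times 13$ intensity patches in two channels: one
  min–max normalized per patch (shape/texture), one divided by the global
  image maximum (absolute brightness).  Labels are the central pixel's
  measured lifetime, one labeled patch per valid low-resolution sample
  whose patch fits inside the image.
* **Augmentation.** Every patch is replaced by its 8 dihedral images
  (exactly 8×).  For $\lambda \ge 8$ the sampled grid is small, so the 8
  one-pixel-shifted neighbor patches are added with the same ("blind")
  label first — 9 positions × 8 symmetries = 72× on interior samples.
* **Architecture.** Three valid-mode 3×3 convolutions (channels
  2→16→32→64, ReLU) followed by three fully connected layers (128→32→1,
  linear output).  Only the layer count is prescribed by the method; the
  widths here are the minimal configuration that maps 13×13×2 to a scalar
  and are fixed for reproducibility.  The output bias is initialized at the
  mean training label so early epochs fit structure rather than scale.
* **Training.** Adam (learning rate $10^{-3}$), batch 100, mean absolute
  error, 150 epochs; a 90/10 train/validation split *grouped by source
  sample* so augmented copies of one patch never straddle the split.  The
  network is trained three times from different initializations and the
  prior with the *median* final validation MAE is kept — an outlier-robust
  compromise between best and worst restarts ("median quality" is not
  further specified by the method; final validation MAE is our
  operationalization).
* **Borders.** No 13×13 patch fits within 6 pixels of the image edge, so
  the prior's border is marked invalid and exerts no pull in the solver.
* The whole network, including Adam and backpropagation, is implemented in
  vectorized R (im2col + BLAS products, sparse scatter matrices for the
  gradients); analytic gradients are verified against finite differences in
  the test suite, and training is bit-deterministic given the seed in
  single-threaded mode.

A `"desk"` preset (`globalPriorConfig("desk")`: 20 epochs, 1 restart,
training set capped at 12,000 instances by a seeded subsample) is provided
for continuous testing on a single CPU; the `"full"` preset is the
published recipe.

## The solver

With the splitting $D\hat\tau = z$, the augmented Lagrangian is minimized
by ADMM (20 outer iterations by default):

1. **Primal update in $\hat\tau$:** 90 iterations of monotone FISTA on the
   smooth part, with projection onto $\hat\tau \ge 0$ and step size $1/L$,
   where $L$ is a power-iteration estimate (30 iterations, deterministic
   start, 2% safety margin) of the composite quadratic operator's largest
   eigenvalue.  The monotone variant never accepts an objective increase
   (falling back to a plain projected-gradient step and restarting the
   momentum), which gives the non-increasing inner objective the tests
   assert.
2. **$z$-update:** the closed-form soft threshold
   $z = \mathrm{soft}(D\hat\tau + y/\rho,\ \alpha/\rho)$.
3. **Dual update:** $y \leftarrow y + \rho(D\hat\tau - z)$.

Weights: $\gamma = 0.1$ always; $\beta = 0.02$ for $\lambda \in \{2,4\}$
and $0.5$ for $\lambda \in \{8,16\}$ (resolved automatically from the
sampling factor unless overridden).  Two knobs the method leaves open:

* $\alpha$ (TV weight) defaults to 1% of the dynamic range of the measured
  $\tau_{LR}$ — it scales the penalty to the data's units rather than
  fixing an absolute number.
* $\rho$ (penalty parameter) defaults to 1 with no adaptive rescaling, so
  runs are deterministic.

Initialization is the bilinear upsampling of $\tau_{LR}$ (a cheap warm
start), $z = D\hat\tau_0$, $y = 0$.  The boundary condition for $D$ is
Neumann (zero trailing difference), which makes the implemented adjoint
exact — the test suite checks $\langle Dx, y\rangle = \langle x, D^T
y\rangle$ to $10^{-12}$, and likewise for $A$.  The formal constraint is
stated on $A\hat\tau - z$ in one place in the source material but on
$D\hat\tau - z$ everywhere the updates are derived; the gradient-domain
splitting is the consistent reading and is what we implement.

## The synthetic phantom

The generator emulates the statistical structure the method relies on,
with photon-level physics:

* **Scene:** piecewise-constant lifetime maps from placed disk "vesicles"
  and curvilinear "membrane" ridges on a background (later classes
  overwrite earlier ones), so class-conditional recovery can be scored
  against an exact ground truth.
* **Intensity:** expectation $\propto$ absorbance × $k_r$ × $\tau$,
  rescaled to a target photon budget and Poisson-sampled.  The default
  absorbance is a smooth random field (correlation length ≥ 8 px), the
  confounder that keeps intensity from being a global function of
  lifetime.
* **Datacube:** per sampled pixel, a mono-exponential arrival-time
  histogram whose expected total equals the decimated expected intensity
  (tying the two measurements together), optionally convolved with a
  Gaussian IRF, Poisson-sampled per bin.
* **Acquisition defaults:** 128 bins of 160 ps (a ≈20 ns window, about 5
  lifetimes for the slowest 4 ns class) and a few thousand photons per
  pixel.  These mirror line-averaged confocal practice: with a window much
  shorter than ~4–5 lifetimes the background and lifetime become nearly
  degenerate and any least-squares estimator acquires a visible downward
  bias; the nonlinear fit needs both an adequate window and an adequate
  photon budget to reach percent-level accuracy.
* The `lp_exact` fixture switches to a noiseless affine
  intensity–lifetime link so local-prior recovery can be asserted exactly;
  `two_class_8x` (160×160, $\lambda = 8$, 2 ns blobs on a 4 ns
  ridge/background matrix, 5000 photons/pixel) is the end-to-end recovery
  fixture.

What the phantom does *not* model — optical PSF blur, detector crosstalk,
afterpulsing, multi-exponential decay mixtures, autofluorescence — bounds
what passing tests show: they validate the estimator, priors and solver
under the stated forward model, not performance on any particular
microscope's data.

## Lifetime estimation

Per-pixel lifetimes come from bounded nonlinear least squares on the model
$a\,e^{-t/\tau} + b$, convolved with the measured IRF when one is
supplied; without an IRF the fit starts at the histogram peak.  $\tau$ is
bounded to (0.01, 100) ns.  Because $a$ and $b$ enter linearly, the fit is
organized around variable projection: a log-spaced $\tau$ scan (plus a
log-linear tail estimate) with the non-negative $(a, b)$ solved
analytically per candidate initializes a Levenberg–Marquardt refinement,
and a final golden-section polish of the $\tau$ profile guards against the
box-constrained joint search stalling on the $b = 0$ boundary — the test
suite checks the result is never beaten by a dense $(\tau, a, b)$ grid
scan.  The method family ("least-squares deconvolution") does not
pin down the parameterization; mono-exponential-plus-background is the
minimal choice, and it is exactly the class the phantom generates.  Pixels
with fewer than 50 total photons (configurable) are not fitted — below
that, fit variance dominates — and pixels whose fit lands on a $\tau$ bound
are marked invalid rather than propagated.

## Numerical and scale choices

* Problem sizes in the shipped tests: phantoms up to 160×160 at
  $\lambda = 8$, solver oracles at ≤ 12×12, 200-replicate Poisson fitting
  studies, and the desk-preset regressor; these sizes exercise every code
  path at full iteration counts (20 ADMM × 90 FISTA) while keeping the
  default suite practical on one CPU.
* SSIM uses the standard 11×11 Gaussian window ($\sigma = 1.5$,
  $K_1 = 0.01$, $K_2 = 0.03$), valid mode; PSNR caps at 140 dB for
  identical images.  The perceptual LPIPS metric requires externally
  pretrained network weights and is deliberately not implemented; the
  evaluation harness reports PSNR/SSIM.
* TIFF I/O stores values divided by a per-file scale recorded in a JSON
  sidecar (the underlying writer clamps to [0, 1]); readers restore
  physical units.
* Registration uses the four-point direct linear transform and
  inverse-mapped bilinear warping with an explicit validity mask, so
  unmapped regions can be excluded from the priors downstream.

## Known limitations

* Mono-exponential fitting only; phasor, center-of-mass and
  multi-exponential estimators are out of scope.
* The decimation model is pure point sampling — no fill-factor footprint,
  no sub-pixel offsets beyond the integer `SamplingSpec` offset.
* The global prior assigns morphologically similar structures similar
  lifetimes; genuine outliers (same shape, different lifetime) are pulled
  toward the class mean, and only the local prior and data fidelity can
  retain them.
* On fields of view without repeated morphology or local
  intensity–lifetime correlation, the method degrades gracefully to
  TV-regularized interpolation — by construction, not failure.
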