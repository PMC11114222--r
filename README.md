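# flimfuse

Guided super-resolution of fluorescence lifetime images by
intensity–lifetime fusion.

## The problem

Fluorescence lifetime imaging microscopy (FLIM) reports, per pixel, the
characteristic decay time τ of fluorescence emission — a
concentration-independent probe of molecular environment, binding and
metabolism.  Time-resolved detectors pay for their timing resolution with
spatial resolution: wide-field SPAD arrays have low pixel counts and low
fill factors, and scanned TCSPC needs long line averages, so the lifetime
image samples the field of view sparsely while an ordinary camera captures
intensity at full resolution in parallel.

`flimfuse` is for microscopists and image-analysis developers who have that
pair of measurements — a low-resolution lifetime map τ_LR (or the raw
photon-arrival datacube behind it) and a co-registered high-resolution
intensity image I — and want a high-resolution lifetime map without
external training data.

## The method

With the decimation (point-sampling) operator A and integer upsampling
factor λ ∈ {2, 4, 8, 16}, the forward model is τ_LR = A τ_HR.  The
reconstruction solves

    τ*_HR = argmin_{τ̂ ≥ 0}  ‖A τ̂ − τ_LR‖₂²
            + γ ‖(τ̂ − τ̂_LP)·m_LP‖₂²  + β ‖(τ̂ − τ̂_GP)·m_GP‖₂²
            + α ‖D τ̂‖₁

by ADMM with monotone-FISTA primal updates (20 × 90 iterations), where D is
the anisotropic total-variation operator and the two priors are built from
the sample itself:

* **Local prior (LP):** in every 5×5 window of lifetime samples, a 1-D
  intensity→lifetime map (linear interpolation by default) is fitted and
  evaluated at the window's central block of intensity pixels.
* **Global prior (GP):** a small convolutional regressor (3 conv + 3 fully
  connected layers) is trained from scratch on 13×13 two-channel intensity
  patches labeled with their central lifetime sample, augmented 8× by
  dihedral symmetry (72× with neighbor labeling at λ ≥ 8), and evaluated at
  every unsampled pixel.  Three restarts; the median-validation-quality
  prior is kept.

Weights: γ = 0.1; β = 0.02 (λ ≤ 4) or 0.5 (λ ≥ 8); α defaults to 1% of the
dynamic range of τ_LR.  Lifetimes are estimated from photon histograms by
bounded mono-exponential least squares (optionally IRF-convolved).  A
physics-grounded phantom generator (piecewise lifetime scenes, a
confounding absorbance field, Poisson photon noise) makes everything
testable without microscope data.  See the methods vignette
(`vignettes/flimfuse-methods.Rmd`) for the full account.

## Worked example

Generate a synthetic two-class scene (2 ns "vesicle" blobs on a 4 ns
"membrane"/background matrix, 8× undersampled lifetime, Poisson photon
noise, smooth absorbance confounder), fit the datacube, and fuse:

```r
library(flimfuse)

fx  <- makeFixture("two_class_8x", seed = 7)   # 160x160 truth, 20x20 samples
fit <- fitImage(fx$cube)                       # per-pixel decay fits
res <- runPipeline(tauLR = fit$lifetime,
                   intensityHR = fx$intensityHR,
                   spec  = fx$sampling,
                   gpConfig = globalPriorConfig("desk", seed = 7),
                   tauGT = fx$tauGT)

blob <- fx$classIndex == 3
mean(tauMap(res$tauHR)[blob])    # 2.24  (truth 2 ns)
mean(tauMap(res$tauHR)[!blob])   # 3.92  (truth 4 ns)
res$metrics
#>         method      psnr      ssim
#> 1        fused 20.627177 0.8368475
#> 2     bilinear 17.879986 0.6758914
#> 3  local_prior 16.254197 0.4109503
#> 4 global_prior  2.320547 0.6513232
```

The fused reconstruction recovers both class lifetimes to within ~0.25 ns
and beats bilinear interpolation by ~3 dB PSNR and ~0.16 SSIM on the same
ground truth.  (The `global_prior` row is scored on the full frame
including its 6-pixel invalid border, which depresses its PSNR; inside the
solver that border is masked out.)  The `"desk"` global-prior preset
(20 epochs, 1 restart) is sized for a single CPU; `"full"` is the
published-scale recipe (150 epochs, 3 restarts, median selection).

A thin command-line wrapper over the same functions is installed at
`inst/scripts/flimfuse.R` (`simulate`, `fit`, `prior-local`,
`prior-global`, `reconstruct`, `baseline`, `evaluate`, `register`, `run`).

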