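# rldamp

Compressive-sensing image reconstruction by **residual-learning
denoising-based approximate message passing (RL-DAMP)**, for grayscale
images measured through an undersampled Fourier (k-space) operator — the
standard acquisition model of compressed-sensing MRI.  The package is
aimed at researchers studying nonlocal regularisation for CS recovery:
it ships the full solver, the two ablation baselines needed to isolate
the contribution of residual learning, variable-density mask generation,
PSNR/SSIM evaluation and synthetic test images, so every experiment runs
self-contained.

## The method

Measurements follow `y = A x + w`, where `A` selects `m` rows of the
unitary 2-D DFT of the `n`-pixel image `x` (sampling ratio `m/n`) and
`w` is optional white Gaussian noise.  Reconstruction runs the D-AMP
iteration from `x⁽⁰⁾ = 0`, `z⁽⁰⁾ = y`:

    z⁽ᵗ⁾ = y − A x⁽ᵗ⁾ + z⁽ᵗ⁻¹⁾ · div D(h⁽ᵗ⁻¹⁾)/m      (Onsager correction)
    h⁽ᵗ⁾ = x⁽ᵗ⁾ + Re(A* z⁽ᵗ⁾),   σ̂² = ‖z⁽ᵗ⁾‖²/m
    x⁽ᵗ⁺¹⁾ = D(h⁽ᵗ⁾, σ̂)

The divergence in the Onsager term is estimated by Monte-Carlo probing
with Rademacher vectors.  The denoiser `D` is the package's
contribution: for every exemplar patch (6×6, one every 5 pixels) the 36
most similar patches are found by block matching and stacked into a
group matrix `H`; a guide estimate `B` of the same group is formed from
a pilot denoising of `h`; the **residual** `R = H − B` is SVD'd and its
singular values `s_j` are soft-shrunk by `σ²τ_j`, with adaptive weights

    τ_j = (α + 1) / (β + |s_j|),        α = 0, β = 0.01,

the posterior mean of a Gamma–Laplacian (Laplacian-scale-mixture)
hierarchy — one expectation–maximisation sweep per call.  Shrunken
groups `B + U diag(ŝ) Vᵀ` are aggregated by overlap averaging.  Because
only the residual is shrunk, fine textures survive where plain low-rank
shrinkage over-smooths; the `lr-amp` baseline (guide forced to zero) and
the classic `wavelet-amp` soft-thresholding baseline quantify exactly
that difference.

## Worked example

```r
library(rldamp)

phantom <- make_phantom(128)                    # Shepp-Logan, 0-255 scale
rec <- damp(phantom, ratio = 0.2, method = "rl-damp", iters = 20, seed = 11)
summary(rec)
#> Method: rl-damp   sampling ratio: 0.200   iterations: 20
#> Final effective noise sd: 9.584
#> PSNR: 40.64 dB (iteration 1: 20.37 dB)   SSIM: 0.9867

lr <- damp(phantom, ratio = 0.2, method = "lr-amp",      iters = 20, seed = 11)
wv <- damp(phantom, ratio = 0.2, method = "wavelet-amp", iters = 20, seed = 11)
round(c(rl = tail(rec$psnr_trace, 1), lr = tail(lr$psnr_trace, 1),
        wavelet = tail(wv$psnr_trace, 1)), 2)
#>      rl      lr wavelet
#>   40.64   35.85   32.69
```

From 20% of the Fourier coefficients, residual learning recovers the
phantom ~4.8 dB above the low-rank ablation and ~8 dB above wavelet
AMP; `plot(rec)` draws the PSNR-per-iteration trace and
`plot(rec, "image")` the reconstruction.  `fitted()` and `residuals()`
return the image estimate and the k-space misfit.

A shell front end with `mask`, `fixtures`, `measure`, `reconstruct`,
`evaluate` and `grid` subcommands is installed at
`system.file("cli", "rldamp", package = "rldamp")`.

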