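---
title: "Residual-learning D-AMP: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual-learning D-AMP: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rldamp)
```

This vignette is the package's account of its method: the measurement
model and solver, the adaptive shrinkage at its core, every tunable
parameter with its default and rationale, the numerical decisions made
where the design was genuinely open, what the synthetic fixtures do and
do not emulate, and known limitations.

## Measurement model

A grayscale image `x` (floating point, 0–255 scale, `n` pixels) is
observed through `y = A x + w`.  `A` selects `m` rows of the *unitary*
2-D DFT, so its rows are orthonormal: `A A* = I` and `A* A` is an
orthogonal projection.  Unit-norm rows matter — AMP's state evolution
and its noise estimator both assume them.  Which rows are selected is
decided by a variable-density mask (`generate_vd_mask()`): a fully
sampled square centred on DC holding `center_fraction = 0.3` of the
budget, the remainder drawn without replacement with probability
`(1 + r/r0)^(-decay)` (`decay = 3`, `r0 = side/16`).  The law mimics
the standard CS-MRI acquisition: dense at low spatial frequencies,
sparse at high ones.  Only the qualitative shape of such masks is ever
published, so the exact law is a package choice; all four parameters
are exposed and a 20-ratio cardinality grid plus a radial-monotonicity
Monte-Carlo test pin the implementation.  Measurement noise of standard
deviation `σ` (quoted on the intensity scale) is split `σ²/2` per
complex component, so the image-domain equivalent noise has standard
deviation exactly `σ`.

## The D-AMP iteration

From `x⁽⁰⁾ = 0`, `z⁽⁰⁾ = y`, each of `T` iterations updates the
residual with the Onsager correction `z⁽ᵗ⁻¹⁾ · div D/m`, forms the
intermediate image `h = x + Re(A* z)`, estimates the effective noise,
and applies the denoiser.  Design points:

* **Divergence by Monte-Carlo probing.** The nonlocal denoiser has no
  analytic derivative, so `div D` is estimated as
  `⟨b, (D(h + εb) − D(h))/ε⟩` with i.i.d. Rademacher probes,
  `ε = max(‖h‖∞, 1)·10⁻³`, one probe per iteration (20 in oracle
  tests).  Rademacher rather than Gaussian probes make the estimate
  exact for every probe on linear maps, which is also what the unit
  tests assert.  `D(h)` is reused from the previous iteration, so the
  correction costs one extra denoiser call.
* **Noise units.** The maximum-likelihood estimate `σ̂² = ‖z‖²/m` is
  recorded per iteration, but it lives in measurement units.  The
  per-pixel variance of the real part of `A* z` under the unitary
  partial DFT is exactly `‖z‖²/(2n)`, and that is what the denoiser
  threshold receives.  This is a unit conversion, not a calibration:
  with `σ̂²` passed raw, thresholds are inflated by `2n/m`, the
  shrinkage is simultaneously far too weak relative to the singular
  value scale (below) and the iteration diverges.
* **Complex intermediates.** Test images are real; the imaginary part
  of `A* z` is retained only inside the residual recursion.  The
  denoiser consumes `Re(h)` — the standard treatment of real images
  under Fourier sampling.
* **Stopping.** A fixed budget `T` (default 50; the experiments here
  use 20, where the phantom runs have converged), no early exit by
  default; an optional relative-change tolerance is available.

At full sampling the iteration recovers the image to high precision
within a few iterations, but *not* in one: at `t = 1` the residual
equals `y`, so `σ̂²` is the mean signal power and the first denoising
pass smooths an already-exact `h`.  The noise estimate then contracts
geometrically.  The tests assert this convergent behaviour.

## The residual-learning denoiser

For every exemplar (6×6 patches, stride 5 — every pixel is covered; the
grid always includes the last valid corner), block matching over a
31-pixel window collects the `N = 36` nearest patches by Euclidean
distance, ties broken by scan order.  Patch size and `N` are chosen so
the group matrix is square (36×36), which makes its SVD basis a square
orthogonal dictionary.  Matching runs on the *guide* image — the less
noisy surface — and the same coordinates cut the noisy group `H` and
the guide group `B`.

The residual `R = H − B` is SVD'd; weights
`τ_j = (α+1)/(β+|s_j|)` (Gamma–Laplacian conjugacy, `α = 0`,
`β = 0.01`, one EM sweep per call, `inner_em_iters` exposes more); the
spectrum is shrunk by `max(s − σ_g² τ, 0)` and the group is rebuilt as
`B + U diag(ŝ) Vᵀ`.  Overlap-averaged aggregation returns the image.
Two scale decisions deserve emphasis:

* **Spectral gain.** The shrinkage acts on singular values.  The
  largest singular value of an `M×N` pure-noise matrix with per-entry
  sd `σ` concentrates at `(√M + √N)σ`, not `σ`, so the group-level
  variance is `(spectral_gain · σ_pixel)²` with
  `spectral_gain = √M + √N = 12` by default.  Because `τ` falls like
  `1/s`, this choice zeroes exactly the spectrum below the noise bulk
  edge and leaves large (signal) singular values almost untouched —
  the adaptive-weight analogue of the optimal hard spectral cut.
  Without the gain the denoiser barely contracts; its divergence then
  exceeds `m` and the Onsager recursion explodes.
* **The guide.** The reference guide in the literature is BM3D.  No R
  implementation exists in this stack, and the spirit of the guide is
  "a good nonlocal pilot estimate", so the default guide is the
  package's own weighted-SVT denoiser run at `guide_gain =
  1.25 × spectral_gain` — deliberately slightly oversmoothed, exactly
  as two-stage collaborative filtering uses a harder first stage.  The
  residual pass then restores the detail the pilot lost; that division
  of labour is where residual learning pays.  A translation-invariant
  Haar soft-threshold guide (`"wavelet"`) is registered as well — it
  is excellent on piecewise-smooth images but leaves repeated textures
  entirely in the residual, which defeats the shrinkage and
  destabilises AMP, which is why it is not the default.  External
  denoisers (e.g. a BM3D binding) can be registered by name.

The ablation denoiser (`lr-amp`) is the identical pipeline with the
guide forced to zero — plain adaptive-weight SVT of the groups — and
the `wavelet-amp` baseline is a single-phase Haar soft threshold at
`1.75 σ_pixel` (the classic 1.5–2σ rule; single-phase because the
textbook AMP iteration thresholds in one orthogonal basis).  On
one-shot Gaussian denoising the residual pass re-admits a little noise
and trails the plain low-rank pass by a few percent MSE; inside the
AMP loop the ordering reverses decisively (about +1.6 dB on texture
and +5 dB on the phantom at ratio 0.2), because the near-unbiasedness
of residual shrinkage is what the iteration compounds.  This is the
package's central reproducible claim, asserted in the acceptance
tests.

## Numerical choices

* Shrunken singular values are clamped at zero; spectra stay sorted
  because `s − σ²/(β+s)` is increasing in `s`.
* `σ² = 0` short-circuits every denoiser to the identity.
* Block-matching ties are broken by (distance, row-major scan order)
  with a stable sort, making every run bit-reproducible; the C++ fast
  path is asserted equal to the plain-R reference implementation.
* Border handling clamps the exemplar grid so the last row/column of
  patches touches the image edge; no padding, no invented pixels;
  aggregation divides by exact coverage counts and refuses zero
  coverage.
* All randomness (masks, noise, probes, fixtures) flows through
  `(seed, parameters)` and restores the caller's RNG state.

## Fixtures: what they emulate and what they do not

`make_phantom()` (Shepp-Logan, piecewise-constant ellipses) stands in
for MR-like images; `make_selfsimilar_image()` (a seeded 6×6 tile,
tiled with per-tile intensity jitter, default jitter 5 grey levels in
the experiments) for repeated natural textures; both live on the 0–255
scale.  `make_wavelet_sparse_image()` (5% of Haar coefficients nonzero
in the sparse-recovery experiments) is the classic exactly-sparse CS
test input.  The experiment sizes reported by `scripts/acceptance.R` —
128×128 images, ratio 0.2 operating point, `T = 20` — are the
package's standard benchmark configuration.  What the fixtures do not
emulate: the broadband, scale-mixed statistics of photographic images,
anatomical variability, partial-volume effects, or complex-valued MR
phase.  Passing tests demonstrate correctness of the machinery and the
claimed orderings on these synthetic families, not clinical image
quality; published benchmark images (Boat, Barbara, Chest, Brain) are
copyrighted and deliberately not shipped, though the CLI accepts any
user-supplied PNG/PGM.

## Known limitations

* Single-coil, real-valued images only; no parallel-imaging operators.
* The Haar-based guide and baseline favour axis-aligned structure;
  smoother wavelets would lift the wavelet baseline slightly.
* The texture fixture at ratio 0.2 is genuinely hard (broadband
  spectrum); absolute PSNRs there are low for every method and only
  the ordering is meaningful.
* `Gamma(α, β)` with `α = 0` is an improper prior; it is used only
  through the proper posterior `Gamma(α+1, β+|s|)`.
* Runtime is dominated by per-group SVDs (`O(G·M³)` per denoiser
  call); the hot paths are in C++ but large images at `T = 50` are
  minutes, not seconds, on one core.
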