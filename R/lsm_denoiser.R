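# The residual-learning group denoiser: guide estimation, Laplacian-
# scale-mixture (LSM) weights with an EM expectation step, weighted
# singular-value shrinkage of patch-group residuals, and the image-level
# denoisers plugged into the AMP iteration.

# ---- guide denoiser plug-in registry --------------------------------------

.guide_registry <- new.env(parent = emptyenv())

#' Register a guide denoiser plug-in
#'
#' Guide denoisers estimate a clean image from a noisy one and are looked
#' up by name in [guide_estimate()].  A plug-in is a
#' `function(noisy, sigma, ...)` returning a matrix of the same shape.
#' The package registers `"lowrank"` (the nonlocal weighted-SVT denoiser
#' run as an oversmoothing pilot, the default) and `"wavelet"`
#' (translation-invariant Haar soft thresholding, [wavelet_denoise()]);
#' external denoisers such as a BM3D binding can be registered under
#' their own names.
#'
#' @param name plug-in name.
#' @param fn `function(noisy, sigma)`.
#' @export
register_guide_denoiser <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .guide_registry)
  invisible(name)
}

#' Estimate a guide (pre-denoised) image
#'
#' The guide is the reference that the residual-learning denoiser shrinks
#' *towards*: patch groups of the noisy image are centred on the matching
#' groups of the guide and only the residual's singular values are
#' thresholded.
#'
#' @param noisy real matrix.
#' @param sigma noise standard deviation (intensity units), `>= 0`.
#' @param denoiser_id plug-in name (default `"lowrank"`).
#' @param ... forwarded to the plug-in (e.g. `config` for the built-ins).
#' @return guide image, same shape as `noisy`.
#' @export
guide_estimate <- function(noisy, sigma, denoiser_id = "lowrank", ...) {
  if (sigma < 0) stop("`sigma` must be nonnegative")
  if (!exists(denoiser_id, envir = .guide_registry, inherits = FALSE))
    stop(sprintf("unknown guide denoiser '%s'; see register_guide_denoiser()",
                 denoiser_id))
  fn <- get(denoiser_id, envir = .guide_registry)
  fn(noisy, sigma, ...)
}

# ---- LSM weights and shrinkage --------------------------------------------

#' LSM hyperparameters
#'
#' Gamma hyperprior over the Laplacian inverse-scale of each residual
#' singular value: `gamma_{ij} ~ Gamma(alpha, beta)` (shape/rate).  The
#' defaults `alpha = 0`, `beta = 0.01` make the prior nearly
#' non-informative so the weights adapt to the data.
#'
#' @param alpha shape offset, `>= 0` (dimensionless).
#' @param beta rate, `> 0` (singular-value units).
#' @return list of class `"lsm_hyper"`.
#' @export
lsm_hyper <- function(alpha = 0, beta = 0.01) {
  if (alpha < 0) stop("`alpha` must be >= 0")
  if (beta <= 0) stop("`beta` must be > 0")
  structure(list(alpha = alpha, beta = beta), class = "lsm_hyper")
}

#' Posterior expectation of the LSM scale parameters (E-step)
#'
#' The Gamma hyperprior is conjugate to the Laplacian, so the posterior of
#' the inverse scale given a singular value `s` is
#' `Gamma(alpha + 1, beta + |s|)` and its mean is the adaptive weight
#' `tau = (alpha + 1) / (beta + |s|)`: large singular values (signal) get
#' small weights, small ones (noise) get large weights.
#'
#' @param s_prev vector of singular values (`>= 0`).
#' @param hyper an [lsm_hyper()] object.
#' @return weight vector `tau`, same length as `s_prev`.
#' @export
gamma_posterior_expectation <- function(s_prev, hyper = lsm_hyper()) {
  if (!inherits(hyper, "lsm_hyper")) hyper <- do.call(lsm_hyper, as.list(hyper))
  if (any(s_prev < 0)) stop("singular values must be nonnegative")
  (hyper$alpha + 1) / (hyper$beta + abs(s_prev))
}

#' Weighted soft shrinkage of a singular-value vector (M-step)
#'
#' Solves, elementwise, `argmin_u (u - s)^2 / (2 sigma2) + tau * u`
#' subject to `u >= 0`, whose closed form is `max(s - sigma2 * tau, 0)`.
#'
#' @param s_raw singular values (`>= 0`).
#' @param tau positive weights, same length.
#' @param sigma2 noise variance (intensity^2 units).
#' @return shrunken singular values.
#' @export
shrink_spectrum <- function(s_raw, tau, sigma2) {
  if (length(s_raw) != length(tau)) stop_dim("`s_raw` and `tau` lengths differ")
  if (sigma2 < 0) stop("`sigma2` must be nonnegative")
  pmax(s_raw - sigma2 * tau, 0)
}

#' Residual-learning denoising of one patch group
#'
#' Computes the residual `R = H - B` between the noisy group and the guide
#' group, takes its SVD `R = U diag(s) V'`, forms the LSM weights from the
#' spectrum (one EM expectation step per call, optionally iterated), soft
#' shrinks the singular values by `sigma2 * tau`, and returns
#' `B + U diag(s_hat) V'`.  With a constant weight `tau = lambda / sigma2`
#' this reduces to singular-value thresholding of the residual at
#' `lambda`, i.e. the nuclear-norm proximal operator.
#'
#' @param H noisy `M x N` group matrix.
#' @param B guide group matrix, same shape (or the zero matrix for the
#'   plain low-rank ablation).
#' @param sigma2 noise variance.
#' @param hyper an [lsm_hyper()] object.
#' @param inner_iters number of EM reweighting sweeps (default 1).
#' @param tau_fixed optional fixed weight vector overriding the E-step
#'   (recycled to the spectrum length).
#' @return denoised `M x N` matrix.
#' @export
denoise_group <- function(H, B, sigma2, hyper = lsm_hyper(),
                          inner_iters = 1L, tau_fixed = NULL) {
  if (!identical(dim(H), dim(B))) stop_dim("`H` and `B` must have equal shape")
  if (!all(is.finite(H)) || !all(is.finite(B)))
    stop("non-finite entries in group matrices")
  if (sigma2 <= 0 && is.null(tau_fixed)) {
    if (sigma2 < 0) stop("`sigma2` must be positive")
    return(H)  # zero noise: nothing to shrink
  }
  R <- H - B
  sv <- svd(R)
  s <- sv$d
  for (it in seq_len(max(1L, inner_iters))) {
    tau <- if (is.null(tau_fixed)) gamma_posterior_expectation(s, hyper)
           else rep_len(tau_fixed, length(s))
    s <- shrink_spectrum(sv$d, tau, sigma2)
  }
  B + sv$u %*% (s * t(sv$v))
}

# ---- image-level denoisers ------------------------------------------------

#' Configuration of the nonlocal denoisers
#'
#' Bundles the patch-group and LSM parameters.  Defaults give square
#' `36 x 36` group matrices: `6 x 6` patches, 36 similar patches per
#' exemplar, exemplars every 5 pixels, a 31-pixel search window, Gamma
#' hyperparameters `alpha = 0`, `beta = 0.01`, one EM sweep per call, and
#' the `"wavelet"` guide.
#'
#' @param patch_size patch side (pixels).
#' @param num_similar patches per group.
#' @param stride exemplar spacing (pixels).
#' @param window block-matching search window side (pixels).
#' @param alpha,beta LSM Gamma hyperparameters.
#' @param inner_em_iters EM reweighting sweeps per denoiser call.
#' @param guide guide denoiser plug-in name.
#' @param guide_spins cycle-spinning shifts used by the wavelet guide.
#' @param lambda_factor threshold multiplier of the wavelet guide/baseline
#'   (in units of the per-pixel noise sd; the classic 1.5-2 sigma rule).
#' @param spectral_gain maps the per-pixel noise sd onto the singular-value
#'   scale of a patch-group residual: the largest singular value of an
#'   `M x N` pure-noise matrix concentrates at `(sqrt(M) + sqrt(N)) *
#'   sigma`, so the group shrinkage uses `(spectral_gain * sigma)^2` as
#'   its variance.  `NULL` (default) computes `sqrt(M) + sqrt(N)` from
#'   the patch parameters (12 for 6x6 patches, 36 members).
#' @param guide_gain spectral gain of the `"lowrank"` guide pass; `NULL`
#'   (default) uses `1.25 * spectral_gain`.  The guide is deliberately a
#'   little oversmoothed (a higher-confidence pilot, as in two-stage
#'   collaborative filtering); the residual pass then restores the detail
#'   it lost.
#' @return list of class `"lsm_config"`.
#' @export
lsm_config <- function(patch_size = 6L, num_similar = 36L, stride = 5L,
                       window = 31L, alpha = 0, beta = 0.01,
                       inner_em_iters = 1L, guide = "lowrank",
                       guide_spins = 4L, lambda_factor = 1.75,
                       spectral_gain = NULL, guide_gain = NULL) {
  if (is.null(spectral_gain))
    spectral_gain <- sqrt(patch_size^2) + sqrt(num_similar)
  if (is.null(guide_gain)) guide_gain <- 1.25 * spectral_gain
  cfg <- list(patch_size = as.integer(patch_size),
              num_similar = as.integer(num_similar),
              stride = as.integer(stride), window = as.integer(window),
              alpha = alpha, beta = beta,
              inner_em_iters = as.integer(inner_em_iters),
              guide = guide, guide_spins = as.integer(guide_spins),
              lambda_factor = lambda_factor,
              spectral_gain = spectral_gain, guide_gain = guide_gain)
  stopifnot(cfg$patch_size >= 1, cfg$num_similar >= 1, cfg$stride >= 1,
            cfg$window >= cfg$patch_size)
  lsm_hyper(cfg$alpha, cfg$beta)  # validates
  structure(cfg, class = "lsm_config")
}

# shared driver: match on `match_img`, cut H from noisy and B from guide
# (or zero), denoise every group, aggregate.  Fast path in C++.
# `sigma2` is the per-pixel noise variance; the group shrinkage operates
# on singular values, whose noise scale is spectral_gain * sigma.
nonlocal_denoise_pass <- function(noisy, guide, match_img, sigma2, config,
                                  use_guide) {
  ex <- select_exemplars(dim(noisy), config$patch_size, config$stride)
  coords <- cpp_block_match_all(match_img, ex, config$patch_size,
                                config$window, config$num_similar)
  sigma2_group <- config$spectral_gain^2 * sigma2
  cpp_lsm_denoise_pass(noisy, guide, coords, config$num_similar,
                       config$patch_size, sigma2_group, config$alpha,
                       config$beta, config$inner_em_iters, use_guide)
}

#' Residual-learning nonlocal image denoiser
#'
#' The denoising operator D(.) plugged into the AMP iteration: estimate a
#' guide with [guide_estimate()], block-match similar patches on the
#' guide, cut each group from both the noisy image (`H`) and the guide
#' (`B`) at the same coordinates, shrink the residual spectra with
#' [denoise_group()], and aggregate all patches by overlap averaging.
#'
#' @param noisy real matrix.
#' @param sigma2 noise variance (intensity^2 units).
#' @param config an [lsm_config()].
#' @return denoised image, same shape.
#' @export
lsm_image_denoiser <- function(noisy, sigma2, config = lsm_config()) {
  if (sigma2 < 0) stop("`sigma2` must be nonnegative")
  if (sigma2 == 0) return(noisy)
  guide <- guide_estimate(noisy, sqrt(sigma2), config$guide, config = config)
  nonlocal_denoise_pass(noisy, guide, guide, sigma2, config, TRUE)
}

#' Low-rank (non-residual) nonlocal denoiser — ablation
#'
#' Identical pipeline to [lsm_image_denoiser()] but with the guide forced
#' to zero: the weighted singular-value shrinkage acts on the patch groups
#' themselves, not on their residual against a guide.  Block matching runs
#' on the noisy image (there is no guide to match on).
#'
#' @inheritParams lsm_image_denoiser
#' @return denoised image.
#' @export
lr_amp_denoiser <- function(noisy, sigma2, config = lsm_config()) {
  if (sigma2 < 0) stop("`sigma2` must be nonnegative")
  if (sigma2 == 0) return(noisy)
  zero <- matrix(0, nrow(noisy), ncol(noisy))
  nonlocal_denoise_pass(noisy, zero, noisy, sigma2, config, FALSE)
}
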