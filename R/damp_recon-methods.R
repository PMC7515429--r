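# S3 methods for the reconstruction object returned by run_damp()/damp().

#' @export
print.damp_recon <- function(x, ...) {
  cat(sprintf("D-AMP reconstruction (%s), %d iterations, %d x %d image\n",
              x$denoiser, x$iterations, nrow(x$image), ncol(x$image)))
  cat(sprintf("  final effective noise sd: %.4g\n", sqrt(utils::tail(x$sigma2_trace, 1))))
  if (length(x$psnr_trace))
    cat(sprintf("  final PSNR %.2f dB, SSIM %.4f\n",
                utils::tail(x$psnr_trace, 1), utils::tail(x$ssim_trace, 1)))
  invisible(x)
}

#' Summarise a D-AMP reconstruction
#'
#' @param object a `"damp_recon"` object.
#' @param ... unused.
#' @return a list of class `"summary.damp_recon"` with the method,
#'   sampling ratio, iteration count, trace extrema and final metrics.
#' @export
summary.damp_recon <- function(object, ...) {
  out <- list(denoiser = object$denoiser,
              iterations = object$iterations,
              ratio = object$operator$m / object$operator$n,
              sigma_final = sqrt(utils::tail(object$sigma2_trace, 1)),
              psnr_final = if (length(object$psnr_trace)) utils::tail(object$psnr_trace, 1) else NA_real_,
              ssim_final = if (length(object$ssim_trace)) utils::tail(object$ssim_trace, 1) else NA_real_,
              psnr_first = if (length(object$psnr_trace)) object$psnr_trace[1] else NA_real_)
  class(out) <- "summary.damp_recon"
  out
}

#' @export
print.summary.damp_recon <- function(x, ...) {
  cat(sprintf("Method: %s   sampling ratio: %.3f   iterations: %d\n",
              x$denoiser, x$ratio, x$iterations))
  cat(sprintf("Final effective noise sd: %.4g\n", x$sigma_final))
  if (is.finite(x$psnr_final) || is.finite(x$psnr_first))
    cat(sprintf("PSNR: %.2f dB (iteration 1: %.2f dB)   SSIM: %.4f\n",
                x$psnr_final, x$psnr_first, x$ssim_final))
  invisible(x)
}

#' Extract the reconstructed image
#'
#' @param object a `"damp_recon"` object.
#' @param ... unused.
#' @return the final image estimate clipped to [0, 255].
#' @export
fitted.damp_recon <- function(object, ...) object$image

#' Measurement-domain residuals of a reconstruction
#'
#' @param object a `"damp_recon"` object.
#' @param ... unused.
#' @return complex vector `y - A x_hat`.
#' @export
residuals.damp_recon <- function(object, ...) {
  object$y - cs_forward(object$operator, object$estimate)
}

#' Plot a reconstruction's convergence trace
#'
#' PSNR versus iteration when ground truth was supplied, otherwise the
#' effective noise sd trace; optionally the reconstructed image itself.
#'
#' @param x a `"damp_recon"` object.
#' @param which `"trace"` or `"image"`.
#' @param ... forwarded to the base plotting call.
#' @export
plot.damp_recon <- function(x, which = c("trace", "image"), ...) {
  which <- match.arg(which)
  if (which == "image") {
    img <- t(x$image[nrow(x$image):1, , drop = FALSE])
    graphics::image(img, col = gray(seq(0, 1, length.out = 256)),
                    axes = FALSE, asp = ncol(x$image) / nrow(x$image), ...)
    return(invisible(x))
  }
  if (length(x$psnr_trace)) {
    graphics::plot(seq_along(x$psnr_trace), x$psnr_trace, type = "b",
                   xlab = "iteration", ylab = "PSNR (dB)",
                   main = sprintf("D-AMP convergence (%s)", x$denoiser), ...)
  } else {
    graphics::plot(seq_along(x$sigma2_trace), sqrt(x$sigma2_trace), type = "b",
                   xlab = "iteration", ylab = "effective noise sd",
                   main = sprintf("D-AMP noise contraction (%s)", x$denoiser), ...)
  }
  invisible(x)
}
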