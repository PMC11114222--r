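# PSNR and SSIM image-quality metrics plus the method-comparison harness.

.PSNR_CAP <- 140   # dB sentinel reported when the images are identical

#' Peak signal-to-noise ratio
#'
#' \code{10 log10(dataRange^2 / MSE)} in dB.  Identical images (zero MSE)
#' return the documented cap of 140 dB rather than infinity.
#'
#' @param ref,test numeric matrices of identical shape.
#' @param dataRange positive dynamic range of the reference.
#' @return PSNR in dB.
#' @export
psnr <- function(ref, test, dataRange) {
  stopifnot(identical(dim(ref), dim(test)), dataRange > 0)
  mse <- mean((ref - test)^2)
  if (mse == 0) return(.PSNR_CAP)
  min(10 * log10(dataRange^2 / mse), .PSNR_CAP)
}

.gaussKernel1d <- function(size = 11L, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# valid-mode separable filtering with a 1-D kernel (rows then cols)
.filterValid <- function(x, k) {
  n <- length(k)
  M <- nrow(x); N <- ncol(x)
  out <- matrix(0, M - n + 1L, N)
  for (i in seq_len(n))
    out <- out + k[i] * x[i:(M - n + i), , drop = FALSE]
  out2 <- matrix(0, nrow(out), N - n + 1L)
  for (i in seq_len(n))
    out2 <- out2 + k[i] * out[, i:(N - n + i), drop = FALSE]
  out2
}

#' Structural similarity index
#'
#' Mean local SSIM with the standard 11 x 11 Gaussian window
#' (sigma = 1.5) and stabilization constants K1 = 0.01, K2 = 0.03, computed
#' in valid mode (windows fully inside the image).
#'
#' @param ref,test numeric matrices (min dimension >= 11).
#' @param dataRange positive dynamic range.
#' @param windowSize odd Gaussian window size (default 11).
#' @param sigma Gaussian window standard deviation (default 1.5).
#' @param map return the per-window SSIM map instead of its mean.
#' @return scalar mean SSIM in [-1, 1] (or the SSIM map).
#' @export
ssim <- function(ref, test, dataRange, windowSize = 11L, sigma = 1.5,
                 map = FALSE) {
  stopifnot(identical(dim(ref), dim(test)), dataRange > 0)
  if (min(dim(ref)) < windowSize)
    stop("images smaller than the SSIM window")
  k <- .gaussKernel1d(windowSize, sigma)
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  mu1 <- .filterValid(ref, k);  mu2 <- .filterValid(test, k)
  s11 <- .filterValid(ref * ref, k) - mu1^2
  s22 <- .filterValid(test * test, k) - mu2^2
  s12 <- .filterValid(ref * test, k) - mu1 * mu2
  sm <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
        ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  if (map) sm else mean(sm)
}

#' Compare reconstruction methods against a ground truth
#'
#' Computes PSNR over the masked pixels and SSIM averaged over windows
#' whose center lies in the mask, one row per method.  The data range
#' defaults to the ground-truth max - min over the mask.
#'
#' @param tauGT ground-truth lifetime matrix (or \code{LifetimeImage}).
#' @param estimates named list of estimate matrices (or
#'   \code{LifetimeImage}s).
#' @param mask logical matrix of pixels to evaluate (default: all).
#' @param dataRange optional override of the dynamic range.
#' @return data.frame with columns \code{method}, \code{psnr}, \code{ssim}.
#' @export
evaluateMethods <- function(tauGT, estimates, mask = NULL, dataRange = NULL) {
  gt <- if (is(tauGT, "LifetimeImage")) tauGT@tau else as.matrix(tauGT)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(gt), ncol(gt))
  if (!any(mask)) stop("empty evaluation mask")
  if (is.null(dataRange)) {
    dataRange <- max(gt[mask]) - min(gt[mask])
    if (dataRange <= 0) dataRange <- max(gt[mask]) + 1e-12
  }
  h <- 5L   # center offset of the 11 x 11 SSIM window
  res <- lapply(names(estimates), function(nm) {
    est <- estimates[[nm]]
    est <- if (is(est, "LifetimeImage") || is(est, "PriorImage")) tauMap(est)
           else as.matrix(est)
    stopifnot(identical(dim(est), dim(gt)))
    p <- 10 * log10(dataRange^2 / max(mean((gt[mask] - est[mask])^2), 0))
    if (!is.finite(p)) p <- .PSNR_CAP
    smap <- ssim(gt, est, dataRange, map = TRUE)
    ctr <- mask[(h + 1L):(nrow(gt) - h), (h + 1L):(ncol(gt) - h), drop = FALSE]
    data.frame(method = nm, psnr = min(p, .PSNR_CAP),
               ssim = mean(smap[ctr]), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
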