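# Decimation forward model A and its adjoint.
#
# A point-samples the high-resolution grid at a regular lambda-spaced lattice;
# its adjoint embeds a low-resolution image back into a zero field at the
# sampled positions.  Both are pure index operations, so A A^T = I and the
# adjoint identity <A x, y> = <x, A^T y> holds exactly.

# 1-based row/col indices of the sampled high-res positions
.sampleIndices <- function(spec, outDim) {
  lambda <- spec@factor
  list(rows = seq.int(spec@offset[1] + 1L, outDim[1], by = lambda),
       cols = seq.int(spec@offset[2] + 1L, outDim[2], by = lambda))
}

.checkDivisible <- function(d, spec) {
  lambda <- spec@factor
  if (d[1] %% lambda != 0L || d[2] %% lambda != 0L)
    stop(sprintf(
      "image dimensions (%d x %d) are not divisible by the sampling factor %d",
      d[1], d[2], lambda))
}

.decimateMatrix <- function(x, spec) {
  .checkDivisible(dim(x), spec)
  idx <- .sampleIndices(spec, dim(x))
  x[idx$rows, idx$cols, drop = FALSE]
}

#' Decimate a high-resolution lifetime image (forward operator A)
#'
#' Point-samples the high-resolution grid: output pixel \code{(i, j)}
#' (0-based) equals input pixel \code{(factor*i + offset[1],
#' factor*j + offset[2])}.
#'
#' @param tauHR a \code{LifetimeImage} (or plain matrix) of size
#'   \code{M x N}, divisible by the sampling factor.
#' @param spec a \code{SamplingSpec}.
#' @return A \code{LifetimeImage} (or matrix, matching the input) of size
#'   \code{M/factor x N/factor}.
#' @examples
#' x <- matrix(0:15, 4, 4, byrow = TRUE)
#' decimate(x, samplingSpec(2))
#' @export
decimate <- function(tauHR, spec) {
  stopifnot(is(spec, "SamplingSpec"))
  if (is(tauHR, "LifetimeImage")) {
    lifetimeImage(.decimateMatrix(tauHR@tau, spec),
                  .decimateMatrix(tauHR@valid, spec),
                  pixelPitch = tauHR@pixelPitch * spec@factor)
  } else {
    .decimateMatrix(as.matrix(tauHR), spec)
  }
}

#' Embed a low-resolution image at the sampled positions (adjoint A^T)
#'
#' Returns a high-resolution field that is zero everywhere except at the
#' sampled lattice positions, where it carries the low-resolution values.
#' Satisfies \code{<A x, y> == <x, A^T y>} for all x, y.
#'
#' @param tauLR a \code{LifetimeImage} or matrix of size \code{m x n}.
#' @param spec a \code{SamplingSpec}.
#' @param outShape integer length-2 high-resolution shape \code{c(M, N)}
#'   with \code{M == factor * m}, \code{N == factor * n}.
#' @return numeric matrix \code{M x N}.
#' @export
embedAdjoint <- function(tauLR, spec, outShape) {
  stopifnot(is(spec, "SamplingSpec"))
  x <- if (is(tauLR, "LifetimeImage")) tauLR@tau else as.matrix(tauLR)
  outShape <- as.integer(outShape)
  if (!identical(dim(x) * spec@factor, outShape))
    stop(sprintf(
      "out shape (%d x %d) incompatible with %d x %d input at factor %d",
      outShape[1], outShape[2], nrow(x), ncol(x), spec@factor))
  out <- matrix(0, outShape[1], outShape[2])
  idx <- .sampleIndices(spec, outShape)
  out[idx$rows, idx$cols] <- x
  out
}

#' Bilinear upsampling baseline aligned to the sampling lattice
#'
#' Separable linear interpolation of the low-resolution lifetime samples
#' onto the high-resolution grid, using the same sample-position convention
#' as \code{\link{decimate}} so that sampled positions are reproduced
#' exactly; pixels beyond the outermost samples are clamped to the edge
#' value.  Invalid samples are dropped per axis before interpolation.
#'
#' @param tauLR a \code{LifetimeImage} or matrix.
#' @param spec a \code{SamplingSpec} (or a bare integer factor).
#' @return A \code{LifetimeImage} of size \code{factor*m x factor*n}.
#' @export
bilinearBaseline <- function(tauLR, spec) {
  if (is.numeric(spec)) spec <- samplingSpec(spec)
  x <- if (is(tauLR, "LifetimeImage")) tauLR@tau else as.matrix(tauLR)
  v <- if (is(tauLR, "LifetimeImage")) tauLR@valid else
    matrix(TRUE, nrow(x), ncol(x))
  x[!v] <- NA_real_
  M <- nrow(x) * spec@factor; N <- ncol(x) * spec@factor
  idx <- .sampleIndices(spec, c(M, N))
  interp1 <- function(pos, val, xout) {
    ok <- !is.na(val)
    if (!any(ok)) return(rep(NA_real_, length(xout)))
    if (sum(ok) == 1L) return(rep(val[ok], length(xout)))
    stats::approx(pos[ok], val[ok], xout = xout, rule = 2)$y
  }
  # rows first, then columns
  tmp <- apply(x, 2, interp1, pos = idx$rows, xout = seq_len(M))
  out <- t(apply(tmp, 1, interp1, pos = idx$cols, xout = seq_len(N)))
  valid <- is.finite(out)
  out[!valid] <- 0
  lifetimeImage(out, valid)
}
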