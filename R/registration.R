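# Four-point perspective co-registration of the intensity camera frame onto
# the lifetime sensor frame.  Coordinates are (row, col).

.collinear3 <- function(p, tol = 1e-9) {
  # any 3 of the 4 points collinear?
  combs <- utils::combn(4L, 3L)
  for (k in seq_len(ncol(combs))) {
    a <- p[combs[1, k], ]; b <- p[combs[2, k], ]; c <- p[combs[3, k], ]
    cross <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    scale <- max(abs(c(a, b, c)), 1)
    if (abs(cross) <= tol * scale^2) return(TRUE)
  }
  FALSE
}

#' Perspective transform from four point correspondences
#'
#' Direct linear transform: the eight unknowns of the homography (with
#' \code{H[3,3] = 1}) are solved from the 8 linear equations given by four
#' (row, col) correspondences \code{src[k] -> dst[k]}.
#'
#' @param src,dst numeric 4 x 2 matrices of (row, col) points; no three of
#'   either set may be collinear.
#' @return A \code{\link{Homography-class}} object.
#' @examples
#' s <- rbind(c(0, 0), c(0, 10), c(10, 0), c(10, 10))
#' homographyFromPoints(s, s + 5)   # translation
#' @export
homographyFromPoints <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(identical(dim(src), c(4L, 2L)), identical(dim(dst), c(4L, 2L)))
  if (.collinear3(src) || .collinear3(dst))
    stop("singular geometry: three of the four points are collinear")
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (k in 1:4) {
    r <- src[k, 1]; c <- src[k, 2]
    rp <- dst[k, 1]; cp <- dst[k, 2]
    A[2 * k - 1, ] <- c(r, c, 1, 0, 0, 0, -r * rp, -c * rp)
    A[2 * k, ]     <- c(0, 0, 0, r, c, 1, -r * cp, -c * cp)
    b[2 * k - 1] <- rp
    b[2 * k] <- cp
  }
  h <- tryCatch(solve(A, b),
                error = function(e) stop("singular geometry: DLT system is rank deficient"))
  H <- matrix(c(h, 1), 3, 3, byrow = TRUE)
  new("Homography", matrix = H / H[3, 3])
}

#' Apply a homography to (row, col) points
#' @param H a \code{Homography}.
#' @param pts n x 2 matrix of (row, col) points.
#' @return n x 2 matrix of mapped points.
#' @export
applyHomography <- function(H, pts) {
  pts <- as.matrix(pts)
  hp <- cbind(pts, 1) %*% t(H@matrix)
  hp[, 1:2, drop = FALSE] / hp[, 3]
}

#' Warp an image by a perspective transform
#'
#' Inverse-mapped bilinear resampling: each output pixel is looked up at
#' \code{H^-1 (output coordinate)} in the source image.  Output pixels that
#' map outside the source are set to 0 and flagged invalid in the
#' \code{"valid"} attribute of the result.
#'
#' @param image numeric matrix (or \code{IntensityImage}).
#' @param H a \code{Homography} mapping source to destination coordinates.
#' @param outShape integer length-2 output shape (default: input shape).
#' @return numeric matrix with a logical \code{"valid"} attribute.
#' @export
warpPerspective <- function(image, H, outShape = NULL) {
  x <- if (is(image, "IntensityImage")) image@values else as.matrix(image)
  if (is.null(outShape)) outShape <- dim(x)
  M <- outShape[1]; N <- outShape[2]
  Hi <- solve(H@matrix)
  grid <- cbind(rep(seq_len(M), times = N), rep(seq_len(N), each = M), 1)
  sp <- grid %*% t(Hi)
  sr <- sp[, 1] / sp[, 3]
  sc <- sp[, 2] / sp[, 3]
  eps <- 1e-9                               # forgive inverse-map round-off
  ok <- sr >= 1 - eps & sr <= nrow(x) + eps & sc >= 1 - eps & sc <= ncol(x) + eps
  sr <- pmin(pmax(sr, 1), nrow(x)); sc <- pmin(pmax(sc, 1), ncol(x))
  r0 <- pmin(floor(sr), nrow(x) - 1); c0 <- pmin(floor(sc), ncol(x) - 1)
  fr <- sr - r0;   fc <- sc - c0
  val <- numeric(M * N)
  if (any(ok)) {
    ro <- r0[ok]; co <- c0[ok]
    val[ok] <-
      x[cbind(ro, co)] * (1 - fr[ok]) * (1 - fc[ok]) +
      x[cbind(ro + 1, co)] * fr[ok] * (1 - fc[ok]) +
      x[cbind(ro, co + 1)] * (1 - fr[ok]) * fc[ok] +
      x[cbind(ro + 1, co + 1)] * fr[ok] * fc[ok]
  }
  out <- matrix(val, M, N)
  attr(out, "valid") <- matrix(ok, M, N)
  out
}
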