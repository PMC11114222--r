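# Local prior: sliding-window intensity-to-lifetime maps.
#
# In each w x w window of low-resolution samples, the (intensity, lifetime)
# pairs are fitted with a 1-D function which is then evaluated at the
# high-resolution intensity pixels of the window's central lambda x lambda
# block.  Sliding the window with unit stride tiles the high-resolution
# grid exactly once.

#' Fit a scalar intensity-to-lifetime window function
#'
#' Pairs with duplicate intensities are averaged first (a function must be
#' single-valued); outside the sampled intensity range the map is clamped
#' to the nearest sampled lifetime, so interpolating kinds never produce
#' lifetimes beyond the window's sampled range.  If all intensities are
#' identical the constant map at the mean lifetime is returned (degenerate
#' fallback, flagged via \code{attr(f, "degenerate")}).
#'
#' @param intensity numeric vector of sample intensities.
#' @param lifetime numeric vector of sample lifetimes (ns), same length.
#' @param kind one of \code{"linear_interp"}, \code{"nearest"},
#'   \code{"cubic_spline"}, \code{"rbf_gp"}.  For \code{"rbf_gp"} a kernel
#'   ridge regressor with a squared-exponential kernel is used
#'   (length-scale = half the intensity range, nugget 1e-6 x var).
#' @return a vectorized function \code{f(intensity) -> lifetime}.
#' @examples
#' f <- fitWindowFunction(c(1, 3), c(2, 4))
#' f(2)    # 3, midpoint of the line
#' f(10)   # 4, clamped extrapolation
#' @export
fitWindowFunction <- function(intensity, lifetime,
                              kind = c("linear_interp", "nearest",
                                       "cubic_spline", "rbf_gp")) {
  kind <- match.arg(kind)
  stopifnot(length(intensity) == length(lifetime), length(intensity) >= 1L)
  # average duplicates
  ux <- sort(unique(intensity))
  uy <- vapply(ux, function(v) mean(lifetime[intensity == v]), numeric(1))
  if (length(ux) < 2L) {
    f <- local({ m <- mean(lifetime); function(x) rep(m, length(x)) })
    attr(f, "degenerate") <- TRUE
    return(f)
  }
  lo <- ux[1]; hi <- ux[length(ux)]
  f <- switch(kind,
    linear_interp = local({
      af <- stats::approxfun(ux, uy, rule = 2)
      function(x) af(x)
    }),
    nearest = local({
      x0 <- ux; y0 <- uy
      function(x) {
        # nearest sampled intensity; ties resolved toward lower intensity
        i <- vapply(x, function(q) {
          d <- abs(x0 - q)
          which(d <= min(d))[1]
        }, integer(1))
        y0[i]
      }
    }),
    cubic_spline = local({
      sf <- stats::splinefun(ux, uy, method = "natural")
      function(x) sf(pmin(pmax(x, lo), hi))
    }),
    rbf_gp = local({
      ell <- max((hi - lo) / 2, 1e-12)
      nug <- 1e-6 * max(stats::var(uy), 1e-12)
      K <- exp(-outer(ux, ux, "-")^2 / (2 * ell^2))
      mu <- mean(uy)
      w <- solve(K + diag(nug, length(ux)), uy - mu)
      function(x) {
        xq <- pmin(pmax(x, lo), hi)
        mu + as.vector(exp(-outer(xq, ux, "-")^2 / (2 * ell^2)) %*% w)
      }
    }))
  attr(f, "degenerate") <- FALSE
  f
}

#' Build the high-resolution local-prior image
#'
#' For each low-resolution sample \code{(i, j)}, a \code{window x window}
#' neighborhood of (intensity, lifetime) pairs -- intensities read off the
#' high-resolution image at the sampled positions -- is fitted with
#' \code{\link{fitWindowFunction}} and evaluated at the high-resolution
#' intensity pixels of the \code{lambda x lambda} block anchored at that
#' sample, so every high-resolution pixel receives exactly one prediction.
#' Windows are clamped (shifted) at the borders so border blocks still see
#' a full window of samples.  A block is invalid only when its window
#' contains no valid samples at all.
#'
#' @param tauLR low-resolution \code{LifetimeImage}.
#' @param intensityHR high-resolution \code{IntensityImage}.
#' @param spec a \code{SamplingSpec}.
#' @param cfg a \code{LocalPriorConfig}.
#' @return A \code{PriorImage} at the intensity image's resolution.
#' @export
buildLocalPrior <- function(tauLR, intensityHR, spec,
                            cfg = localPriorConfig()) {
  stopifnot(is(tauLR, "LifetimeImage"), is(intensityHR, "IntensityImage"),
            is(spec, "SamplingSpec"), is(cfg, "LocalPriorConfig"))
  I <- intensityHR@values
  lambda <- spec@factor
  m <- nrow(tauLR@tau); n <- ncol(tauLR@tau)
  if (!identical(dim(I), c(m * lambda, n * lambda)))
    stop("intensity image shape inconsistent with tauLR and sampling factor")
  idx <- .sampleIndices(spec, dim(I))
  Is <- I[idx$rows, idx$cols, drop = FALSE]   # intensity at sampled positions

  w <- cfg@window; h <- (w - 1L) %/% 2L
  wlo <- function(c0, len) min(max(1L, c0 - h), max(1L, len - w + 1L))
  out <- matrix(0, nrow(I), ncol(I))
  valid <- matrix(FALSE, nrow(I), ncol(I))
  for (i in seq_len(m)) {
    ri <- wlo(i, m); rows <- ri:min(m, ri + w - 1L)
    bi <- ((i - 1L) * lambda + 1L):(i * lambda)
    for (j in seq_len(n)) {
      cj <- wlo(j, n); cols <- cj:min(n, cj + w - 1L)
      bj <- ((j - 1L) * lambda + 1L):(j * lambda)
      vw <- tauLR@valid[rows, cols]
      if (!any(vw)) next                       # no usable samples: invalid block
      f <- fitWindowFunction(Is[rows, cols][vw], tauLR@tau[rows, cols][vw],
                             kind = cfg@kind)
      out[bi, bj] <- f(I[bi, bj])
      valid[bi, bj] <- TRUE
    }
  }
  priorImage(out, valid)
}
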