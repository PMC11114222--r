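# Per-pixel lifetime estimation from TCSPC photon-count histograms.
#
# Model: h_k = a * exp(-t_k / tau) + b, optionally convolved with a measured
# IRF, fitted by bounded nonlinear least squares (Levenberg-Marquardt via
# minpack.lm).  Initial values come from a log-linear regression on the
# background-subtracted tail, which is exact in the noiseless case.

.TAU_MIN <- 0.01
.TAU_MAX <- 100

# discrete linear convolution of decay with irf, truncated to length t
.irfConvolve <- function(decay, irf) {
  t <- length(decay)
  full <- stats::convolve(irf, rev(decay), type = "open")
  full[seq_len(t)]
}

.decayModel <- function(par, tk, irf) {
  d <- par[["a"]] * exp(-tk / par[["tau"]])
  if (length(irf)) d <- .irfConvolve(d, irf)
  d + par[["b"]]
}

# log-linear slope estimate on the background-subtracted decay
.logLinearTau <- function(h, tk) {
  nb <- max(3L, length(h) %/% 20L)
  b0 <- min(mean(utils::tail(h, nb)), min(h) + 1e-12)
  hs <- h - b0
  use <- which(hs > 0.05 * max(hs))
  if (length(use) >= 2L) {
    sl <- stats::lm.fit(cbind(1, tk[use]), log(hs[use]))$coefficients[2]
    if (is.finite(sl) && sl < 0) return(-1 / sl)
  }
  NA_real_
}

# constrained (a, b >= 0) least squares for a fixed decay shape e
.ampBackLS <- function(e, h) {
  X <- cbind(e, 1)
  cf <- tryCatch(as.vector(solve(crossprod(X), crossprod(X, h))),
                 error = function(.) c(-1, -1))
  if (any(cf < 0)) {
    a1 <- max(sum(e * h) / sum(e * e), 0)    # b pinned at 0
    b1 <- max(mean(h), 0)                    # a pinned at 0
    cf <- if (sum((a1 * e - h)^2) <= sum((b1 - h)^2)) c(a1, 0) else c(0, b1)
  }
  list(a = cf[1], b = cf[2], rss = sum((cf[1] * e + cf[2] - h)^2))
}

# variable-projection initialization: scan candidate lifetimes (log-spaced
# grid plus the log-linear estimate), solving amplitude and background
# analytically for each; immune to the boundary stalls a joint nonlinear
# search can hit
.initDecay <- function(h, tk, irf) {
  taus <- exp(seq(log(0.02), log(80), length.out = 60L))
  tll <- .logLinearTau(h, tk)
  if (is.finite(tll)) taus <- c(taus, min(max(tll, .TAU_MIN), .TAU_MAX))
  best <- NULL
  for (tau in taus) {
    e <- exp(-tk / tau)
    if (length(irf)) e <- .irfConvolve(e, irf)
    ls <- .ampBackLS(e, h)
    if (is.null(best) || ls$rss < best["rss"])
      best <- c(tau = tau, a = ls$a, b = ls$b, rss = ls$rss)
  }
  best
}

#' Fit a mono-exponential decay to a photon-arrival histogram
#'
#' Least-squares fit of \code{a * exp(-t/tau) + b} (convolved with the IRF
#' when one is supplied) to a TCSPC histogram.  Without an IRF the fit
#' starts at the peak bin and pre-peak bins are excluded; with an IRF all
#' bins participate.  The lifetime is bounded to (0.01, 100) ns; a fit
#' pinned at a bound or with vanishing decay amplitude is flagged
#' \code{atBound} (e.g. a constant histogram, which degenerates to a
#' background-only fit with no decay signal).
#'
#' @param histogram non-negative numeric vector of photon counts per bin
#'   (at least 4 bins, at least one positive count).
#' @param binWidth time-bin width in ns.
#' @param irf optional instrument response function (normalized to sum 1).
#' @return list with \code{tau} (ns), \code{amplitude}, \code{background}
#'   (photons/bin), \code{residualNorm} and logical \code{atBound}.
#' @examples
#' h <- 100 * exp(-(0:74) * 0.16 / 2)
#' fitMonoexponential(h, 0.16)$tau
#' @export
fitMonoexponential <- function(histogram, binWidth, irf = NULL) {
  if (anyNA(histogram) || any(!is.finite(histogram)))
    stop("histogram contains non-finite entries")
  if (length(histogram) < 4L) stop("need at least 4 time bins")
  if (sum(histogram) <= 0) stop("empty signal: histogram has no photons")
  if (binWidth <= 0) stop("binWidth must be positive")
  irf <- if (is.null(irf)) numeric() else as.numeric(irf)

  h <- as.numeric(histogram)
  if (!length(irf)) {           # start at the peak; drop pre-peak bins
    kp <- which.max(h)
    h <- h[kp:length(h)]
    if (length(h) < 4L) stop("fewer than 4 bins after the histogram peak")
  }
  tk <- (seq_along(h) - 1) * binWidth
  p0 <- .initDecay(h, tk, irf)
  fit <- minpack.lm::nls.lm(
    par = p0[c("tau", "a", "b")],
    lower = c(.TAU_MIN, 0, 0), upper = c(.TAU_MAX, Inf, Inf),
    fn = function(p) .decayModel(p, tk, irf) - h,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- stats::coef(fit)
  rss <- sum(fit$fvec^2)
  if (rss > p0[["rss"]]) {                  # keep the scan if LM stalled
    p <- p0[c("tau", "a", "b")]
    rss <- p0[["rss"]]
  }
  # 1-D variable-projection polish: the joint search can stall on the
  # amplitude/background bounds, but the profile in tau cannot
  profRss <- function(tau) {
    e <- exp(-tk / tau)
    if (length(irf)) e <- .irfConvolve(e, irf)
    .ampBackLS(e, h)$rss
  }
  br <- c(max(p[["tau"]] * 0.7, .TAU_MIN), min(p[["tau"]] * 1.4, .TAU_MAX))
  opt <- stats::optimize(profRss, interval = br, tol = 1e-10)
  if (opt$objective < rss) {
    e <- exp(-tk / opt$minimum)
    if (length(irf)) e <- .irfConvolve(e, irf)
    ls <- .ampBackLS(e, h)
    p <- c(tau = opt$minimum, a = ls$a, b = ls$b)
    rss <- ls$rss
  }
  list(tau = unname(p[["tau"]]),
       amplitude = unname(p[["a"]]),
       background = unname(p[["b"]]),
       residualNorm = sqrt(rss),
       atBound = p[["tau"]] <= .TAU_MIN * (1 + 1e-9) ||
                 p[["tau"]] >= .TAU_MAX * (1 - 1e-9) ||
                 p[["a"]] <= 1e-6 * max(p[["b"]], 1e-12))
}

#' Fit every pixel of a datacube
#'
#' Runs \code{\link{fitMonoexponential}} on each pixel's histogram and
#' integrates the cube along time for the low-resolution intensity image.
#' Pixels whose total photon count falls below \code{minCounts}, whose fit
#' errors out, or whose lifetime lands on a bound are marked invalid.
#'
#' @param cube a \code{FLIMDataCube}.
#' @param minCounts total-photon threshold below which a pixel is not
#'   fitted (default 50; below this, fit variance dominates the estimate).
#' @return list with \code{lifetime} (a \code{LifetimeImage}) and
#'   \code{intensity} (an \code{IntensityImage}; per-pixel sum over time,
#'   conserving total counts exactly).
#' @export
fitImage <- function(cube, minCounts = 50) {
  stopifnot(is(cube, "FLIMDataCube"))
  d <- dim(cube@counts)
  tau <- matrix(0, d[1], d[2])
  valid <- matrix(FALSE, d[1], d[2])
  intensity <- apply(cube@counts, c(1, 2), sum)
  irf <- if (length(cube@irf)) cube@irf else NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (intensity[i, j] < minCounts) next
    res <- tryCatch(
      fitMonoexponential(cube@counts[i, j, ], cube@binWidth, irf),
      error = function(e) NULL)
    if (!is.null(res) && !res$atBound) {
      tau[i, j] <- res$tau
      valid[i, j] <- TRUE
    }
  }
  list(lifetime = lifetimeImage(tau, valid),
       intensity = intensityImage(intensity))
}
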