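# Physics-grounded synthetic FLIM phantom generator.
#
# Scenes are piecewise lifetime maps built from blob ("vesicle") and ridge
# ("membrane") morphologies on a background.  Expected fluorescence
# intensity follows the quantum-yield relation: intensity is proportional
# to absorbance x k_r x tau, with the absorbance field acting as the
# confounder that prevents intensity from being a global function of
# lifetime.  Datacubes hold mono-exponential decays, optionally convolved
# with a Gaussian IRF, with Poisson photon noise per time bin; each
# low-resolution pixel's expected photon total equals its decimated
# expected intensity, tying the two measurements together.

#' Phantom scene specification
#'
#' @param shape integer length-2 high-resolution shape \code{c(M, N)}.
#' @param classes list of class definitions, each a list with
#'   \code{morphology} ("blob", "ridge" or "background"), \code{tau} (ns),
#'   \code{density} (objects per 10,000 pixels; ignored for background),
#'   optional \code{size} (blob radius / ridge half-width, px, default 6)
#'   and optional \code{kr} (relative radiative rate, default 1).
#' @param absorbance list with \code{kind} ("constant", "smooth_field" or
#'   "correlated") and \code{amplitude} (relative modulation depth).
#' @param photonsPerPixel expected mean photon count per high-res pixel.
#' @param bins number of time bins (>= 16).
#' @param binWidth time-bin width (ns).
#' @param irfWidth optional Gaussian IRF standard deviation (ns); NA = none.
#' @param localLinearity when TRUE the scene is built so lifetime is an
#'   affine function of the (noiseless) intensity, for local-prior
#'   exact-recovery checks; classes are ignored in that mode.
#' @param seed RNG seed; every generator operation is deterministic in it.
#' @return object of class \code{"PhantomSpec"} (a validated list).
#' @export
phantomSpec <- function(shape,
                        classes = list(
                          list(morphology = "background", tau = 4.0),
                          list(morphology = "ridge", tau = 4.0,
                               density = 1.2, size = 3),
                          list(morphology = "blob", tau = 2.0,
                               density = 2.5, size = 9)),
                        absorbance = list(kind = "smooth_field", amplitude = 0.3),
                        photonsPerPixel = 3000, bins = 128L, binWidth = 0.16,
                        irfWidth = NA_real_, localLinearity = FALSE,
                        seed = 1L) {
  spec <- list(shape = as.integer(shape), classes = classes,
               absorbance = absorbance,
               photonsPerPixel = photonsPerPixel, bins = as.integer(bins),
               binWidth = binWidth, irfWidth = irfWidth,
               localLinearity = isTRUE(localLinearity), seed = as.integer(seed))
  stopifnot(length(spec$shape) == 2L, all(spec$shape >= 8L),
            spec$photonsPerPixel > 0, spec$bins >= 16L, spec$binWidth > 0)
  for (cl in classes) {
    stopifnot(cl$morphology %in% c("blob", "ridge", "background"),
              cl$tau > 0)
  }
  stopifnot(absorbance$kind %in% c("constant", "smooth_field", "correlated"))
  class(spec) <- "PhantomSpec"
  spec
}

# separable Gaussian blur with renormalized (Neumann-like) boundaries
.gaussBlur <- function(x, sigma) {
  band <- function(n) {
    B <- exp(-outer(seq_len(n), seq_len(n), "-")^2 / (2 * sigma^2))
    B / rowSums(B)
  }
  band(nrow(x)) %*% x %*% t(band(ncol(x)))
}

.smoothField <- function(M, N, corrLen = 8) {
  .gaussBlur(matrix(stats::rnorm(M * N), M, N), corrLen)
}

#' Generate a phantom scene
#'
#' Places the spec's classes in order (later classes overwrite earlier
#' ones) to build a piecewise lifetime map, and draws the absorbance field.
#' With \code{localLinearity = TRUE} the lifetime is instead an affine map
#' of a smooth synthetic intensity field (absorbance constant 1).
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return list with \code{tau} (a \code{LifetimeImage}), \code{absorbance}
#'   (matrix), \code{classIndex} (integer matrix, index into
#'   \code{spec$classes}; 0 in localLinearity mode), \code{kr} (matrix of
#'   radiative-rate factors).
#' @export
generateScene <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  set.seed(spec$seed)
  M <- spec$shape[1]; N <- spec$shape[2]
  R <- matrix(rep(seq_len(M), times = N), M, N)
  C <- matrix(rep(seq_len(N), each = M), M, N)

  if (spec$localLinearity) {
    f <- .smoothField(M, N, corrLen = max(8, round(min(M, N) / 10)))
    f <- (f - min(f)) / (max(f) - min(f))        # synthetic intensity shape
    tau <- 2 + 2 * f                              # affine intensity-lifetime link
    return(list(tau = lifetimeImage(tau), absorbance = matrix(1, M, N),
                classIndex = matrix(0L, M, N), kr = matrix(1, M, N),
                shapeField = f))
  }

  tau <- matrix(NA_real_, M, N)
  classIndex <- matrix(0L, M, N)
  kr <- matrix(1, M, N)
  for (ci in seq_along(spec$classes)) {
    cl <- spec$classes[[ci]]
    krv <- if (is.null(cl$kr)) 1 else cl$kr
    sz <- if (is.null(cl$size)) 6 else cl$size
    mask <- switch(cl$morphology,
      background = matrix(TRUE, M, N),
      blob = {
        nObj <- max(1L, stats::rpois(1, cl$density * M * N / 1e4))
        mk <- matrix(FALSE, M, N)
        for (k in seq_len(nObj)) {
          r0 <- stats::runif(1, 1, M); c0 <- stats::runif(1, 1, N)
          rad <- sz * stats::runif(1, 0.7, 1.3)
          mk <- mk | ((R - r0)^2 + (C - c0)^2 <= rad^2)
        }
        mk
      },
      ridge = {
        nObj <- max(1L, stats::rpois(1, cl$density * M * N / 1e4))
        mk <- matrix(FALSE, M, N)
        for (k in seq_len(nObj)) {
          th <- stats::runif(1, 0, pi)
          u <- cos(th) * R + sin(th) * C
          v <- -sin(th) * R + cos(th) * C
          amp <- stats::runif(1, 0.02, 0.08) * min(M, N)
          per <- stats::runif(1, 0.5, 1.5) * min(M, N)
          off <- stats::runif(1, min(v), max(v))
          mk <- mk | (abs(v - off - amp * sin(2 * pi * u / per)) <= sz)
        }
        mk
      })
    tau[mask] <- cl$tau
    classIndex[mask] <- ci
    kr[mask] <- krv
  }
  if (anyNA(tau))
    stop("scene has uncovered pixels; include a background class first")

  absorb <- switch(spec$absorbance$kind,
    constant = matrix(1, M, N),
    smooth_field = {
      f <- .smoothField(M, N)
      pmax(1 + spec$absorbance$amplitude * f / stats::sd(f), 0.1)
    },
    correlated = {
      f <- .smoothField(M, N)
      s <- (tau - mean(tau)) / max(stats::sd(tau), 1e-12)
      pmax(1 + spec$absorbance$amplitude *
             (0.7 * s + 0.3 * f / stats::sd(f)), 0.1)
    })
  list(tau = lifetimeImage(tau), absorbance = absorb,
       classIndex = classIndex, kr = kr)
}

#' Render the high-resolution intensity image
#'
#' Expected intensity is proportional to absorbance x k_r x lifetime
#' (quantum yield Q = k_r tau), rescaled so its mean equals
#' \code{photonsPerPixel}, then Poisson-sampled per pixel (skipped in
#' localLinearity mode, where the noiseless expectation is returned so the
#' affine intensity-lifetime link is exact).
#'
#' @param scene output of \code{\link{generateScene}}.
#' @param spec the \code{\link{phantomSpec}}.
#' @return list with \code{intensity} (an \code{IntensityImage}) and
#'   \code{expected} (the noiseless expectation matrix).
#' @export
renderIntensity <- function(scene, spec) {
  expected <- scene$absorbance * scene$kr * tauMap(scene$tau)
  expected <- expected * spec$photonsPerPixel / mean(expected)
  set.seed(spec$seed + 1L)
  values <- if (spec$localLinearity) expected else {
    matrix(stats::rpois(length(expected), expected), nrow(expected))
  }
  list(intensity = intensityImage(values), expected = expected)
}

.gaussianIRF <- function(bins, binWidth, irfWidth) {
  sB <- irfWidth / binWidth
  mu <- max(4 * sB, 1)
  k <- exp(-((seq_len(bins) - 1) - mu)^2 / (2 * sB^2))
  k / sum(k)
}

#' Render the low-resolution time-resolved datacube
#'
#' For each sampled position, a mono-exponential arrival-time histogram
#' with expected total photon count equal to the decimated expected
#' intensity, convolved with a Gaussian IRF when \code{irfWidth} is set
#' (renormalized so expected totals are conserved exactly), then
#' Poisson-sampled per bin.
#'
#' @param scene output of \code{\link{generateScene}}.
#' @param intensityExpected noiseless expected-intensity matrix (from
#'   \code{\link{renderIntensity}}).
#' @param spec the \code{\link{phantomSpec}}.
#' @param sampling a \code{SamplingSpec}.
#' @return A \code{FLIMDataCube}.
#' @export
renderDatacube <- function(scene, intensityExpected, spec, sampling) {
  tauL <- .decimateMatrix(tauMap(scene$tau), sampling)
  NL <- .decimateMatrix(intensityExpected, sampling)
  m <- nrow(tauL); n <- ncol(tauL)
  tk <- (seq_len(spec$bins) - 1) * spec$binWidth
  W <- exp(-outer(tk, 1 / as.vector(tauL)))          # bins x (m*n)
  irf <- numeric()
  if (!is.na(spec$irfWidth) && spec$irfWidth > 0) {
    irf <- .gaussianIRF(spec$bins, spec$binWidth, spec$irfWidth)
    Cm <- matrix(0, spec$bins, spec$bins)            # causal convolution matrix
    for (j in seq_len(spec$bins))
      Cm[j:spec$bins, j] <- irf[seq_len(spec$bins - j + 1L)]
    W <- Cm %*% W
  }
  W <- sweep(W, 2, colSums(W), "/")
  E <- sweep(W, 2, as.vector(NL), "*")
  set.seed(spec$seed + 2L)
  counts <- array(0, dim = c(m, n, spec$bins))
  draws <- matrix(stats::rpois(length(E), E), nrow(E))  # bins x (m*n)
  for (b in seq_len(spec$bins))
    counts[, , b] <- matrix(draws[b, ], m, n)
  flimDataCube(counts, spec$binWidth, irf)
}

#' Build a named deterministic test phantom
#'
#' Bundles a full co-registered set of objects for a named scenario:
#' \describe{
#'   \item{flat}{constant 2.5 ns scene, factor 4, 64 x 64.}
#'   \item{lp_exact}{lifetime affine in the (noiseless) intensity, factor 4,
#'     96 x 96 -- the local prior should recover the truth wherever the
#'     pixel intensity lies within its window's sampled range.}
#'   \item{step_edge}{two-level (2 ns / 4 ns) vertical step, factor 4,
#'     64 x 64, constant absorbance.}
#'   \item{two_class_8x}{blob ("vesicle", 2 ns) and ridge/background
#'     ("membrane", 4 ns) classes at factor 8, 160 x 160, with a smooth
#'     confounding absorbance field.}
#' }
#'
#' @param name fixture name.
#' @param seed RNG seed.
#' @return list with \code{cube} (\code{FLIMDataCube}), \code{tauLR}
#'   (exact decimation of the ground truth), \code{intensityHR},
#'   \code{tauGT} (\code{LifetimeImage}), \code{classIndex}, \code{spec}
#'   (the \code{PhantomSpec}) and \code{sampling} (\code{SamplingSpec}).
#' @export
makeFixture <- function(name = c("flat", "lp_exact", "step_edge",
                                 "two_class_8x"), seed = 1L) {
  name <- match.arg(name)
  seed <- as.integer(seed)
  bundle <- switch(name,
    flat = {
      spec <- phantomSpec(c(64, 64),
        classes = list(list(morphology = "background", tau = 2.5)),
        absorbance = list(kind = "constant", amplitude = 0),
        photonsPerPixel = 1000, seed = seed)
      list(spec = spec, sampling = samplingSpec(4))
    },
    lp_exact = {
      spec <- phantomSpec(c(96, 96), localLinearity = TRUE,
        photonsPerPixel = 1000, seed = seed)
      list(spec = spec, sampling = samplingSpec(4))
    },
    step_edge = {
      spec <- phantomSpec(c(64, 64),
        classes = list(list(morphology = "background", tau = 2.0)),
        absorbance = list(kind = "constant", amplitude = 0),
        photonsPerPixel = 1000, seed = seed)
      list(spec = spec, sampling = samplingSpec(4), step = TRUE)
    },
    two_class_8x = {
      spec <- phantomSpec(c(160, 160),
        classes = list(
          list(morphology = "background", tau = 4.0),
          list(morphology = "ridge", tau = 4.0, density = 1.0, size = 3),
          list(morphology = "blob", tau = 2.0, density = 2.2, size = 10)),
        absorbance = list(kind = "smooth_field", amplitude = 0.3),
        photonsPerPixel = 5000, seed = seed)
      list(spec = spec, sampling = samplingSpec(8))
    })
  spec <- bundle$spec
  scene <- generateScene(spec)
  if (isTRUE(bundle$step)) {    # overwrite with the two-level step
    tau <- tauMap(scene$tau)
    tau[, (ncol(tau) %/% 2 + 1):ncol(tau)] <- 4.0
    scene$tau <- lifetimeImage(tau)
    scene$classIndex <- (tau > 3) + 1L
  }
  ri <- renderIntensity(scene, spec)
  cube <- renderDatacube(scene, ri$expected, spec, bundle$sampling)
  list(cube = cube,
       tauLR = decimate(scene$tau, bundle$sampling),
       intensityHR = ri$intensity,
       tauGT = scene$tau,
       classIndex = scene$classIndex,
       spec = spec,
       sampling = bundle$sampling)
}
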