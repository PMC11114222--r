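#' @import methods
NULL

#' Regular decimation geometry linking the lifetime and intensity grids
#'
#' A \code{SamplingSpec} describes how the low-resolution lifetime grid is
#' point-sampled from the high-resolution intensity grid: low-resolution
#' sample \code{(i, j)} (0-based) sits at high-resolution pixel
#' \code{(factor * i + offset[1], factor * j + offset[2])}.  This is the
#' sparse-sampling operator A of the forward model \code{tau_LR = A tau_HR},
#' which models the large dead space between the active areas of a SPAD
#' array (or the coarse scan pitch of a scanning system) relative to a
#' ~100% fill-factor intensity camera.
#'
#' @slot factor integer upsampling factor (lambda), one of 1, 2, 4, 8, 16.
#' @slot offset integer length-2 (row, col) sub-block offset, each in
#'   \code{[0, factor)}; default \code{c(0, 0)} places samples at the
#'   top-left pixel of each \code{factor x factor} block.
#' @export
setClass("SamplingSpec",
  representation(factor = "integer", offset = "integer"),
  prototype(factor = 1L, offset = c(0L, 0L)))

setValidity("SamplingSpec", function(object) {
  msgs <- character()
  if (length(object@factor) != 1L || is.na(object@factor) || object@factor < 1L)
    msgs <- c(msgs, "factor must be a single integer >= 1")
  else if (!object@factor %in% c(1L, 2L, 4L, 8L, 16L))
    msgs <- c(msgs, "factor must be one of 1, 2, 4, 8, 16")
  if (length(object@offset) != 2L || anyNA(object@offset))
    msgs <- c(msgs, "offset must be two integers")
  else if (length(object@factor) == 1L && !is.na(object@factor) &&
           (any(object@offset < 0L) || any(object@offset >= object@factor)))
    msgs <- c(msgs, "offset entries must lie in [0, factor)")
  if (length(msgs)) msgs else TRUE
})

#' @rdname SamplingSpec-class
#' @param factor integer upsampling factor.
#' @param offset integer length-2 (row, col) offset within each block.
#' @return A \code{SamplingSpec} object.
#' @examples
#' samplingSpec(8)
#' @export
samplingSpec <- function(factor, offset = c(0L, 0L)) {
  new("SamplingSpec", factor = as.integer(factor), offset = as.integer(offset))
}

#' Per-pixel fluorescence lifetime map
#'
#' Holds a matrix of fluorescence lifetimes (ns) together with a validity
#' mask marking pixels where the lifetime estimate is trustworthy (e.g. the
#' decay fit converged with enough photons).  Used both for the measured
#' low-resolution image tau_LR and for high-resolution estimates.
#'
#' @slot tau numeric matrix of lifetimes in ns.
#' @slot valid logical matrix, same shape as \code{tau}.
#' @slot pixelPitch optional pixel pitch in micrometres (NA if unknown).
#' @export
setClass("LifetimeImage",
  representation(tau = "matrix", valid = "matrix", pixelPitch = "numeric"),
  prototype(pixelPitch = NA_real_))

setValidity("LifetimeImage", function(object) {
  msgs <- character()
  if (!identical(dim(object@tau), dim(object@valid)))
    msgs <- c(msgs, "tau and valid must have identical dimensions")
  if (!is.logical(object@valid))
    msgs <- c(msgs, "valid must be a logical matrix")
  tv <- object@tau[object@valid]
  if (length(tv) && (anyNA(tv) || any(tv < 0)))
    msgs <- c(msgs, "tau must be finite and >= 0 wherever valid")
  if (length(msgs)) msgs else TRUE
})

#' @rdname LifetimeImage-class
#' @param tau numeric matrix of lifetimes (ns).
#' @param valid logical matrix; default marks all finite non-negative pixels.
#' @param pixelPitch optional pixel pitch (um).
#' @return A \code{LifetimeImage}.
#' @export
lifetimeImage <- function(tau, valid = NULL, pixelPitch = NA_real_) {
  tau <- as.matrix(tau)
  if (is.null(valid)) valid <- is.finite(tau) & tau >= 0
  storage.mode(valid) <- "logical"
  new("LifetimeImage", tau = tau, valid = valid, pixelPitch = as.numeric(pixelPitch))
}

#' High-resolution fluorescence intensity image
#'
#' @slot values non-negative numeric matrix (photon counts or camera units).
#' @export
setClass("IntensityImage", representation(values = "matrix"))

setValidity("IntensityImage", function(object) {
  if (anyNA(object@values) || any(object@values < 0))
    "values must be finite and >= 0" else TRUE
})

#' @rdname IntensityImage-class
#' @param values non-negative numeric matrix.
#' @return An \code{IntensityImage}.
#' @export
intensityImage <- function(values) {
  new("IntensityImage", values = as.matrix(values))
}

#' Time-resolved photon-count datacube
#'
#' Photon arrival-time histograms on the low-resolution grid: one TCSPC
#' histogram of \code{t} time bins per pixel, with the bin width in ns and
#' an optional measured instrument response function (IRF, normalized to
#' sum 1) describing the temporal blur of the system.
#'
#' @slot counts non-negative array \code{[m, n, t]} of photon counts.
#' @slot binWidth positive time-bin width (ns).
#' @slot irf numeric vector of length \code{t} summing to 1, or length 0
#'   when no IRF is available.
#' @export
setClass("FLIMDataCube",
  representation(counts = "array", binWidth = "numeric", irf = "numeric"),
  prototype(irf = numeric()))

setValidity("FLIMDataCube", function(object) {
  msgs <- character()
  d <- dim(object@counts)
  if (length(d) != 3L) msgs <- c(msgs, "counts must be a 3-d [m, n, t] array")
  else if (d[3] < 4L) msgs <- c(msgs, "need at least 4 time bins")
  if (anyNA(object@counts) || any(object@counts < 0))
    msgs <- c(msgs, "counts must be finite and >= 0")
  if (length(object@binWidth) != 1L || !is.finite(object@binWidth) ||
      object@binWidth <= 0)
    msgs <- c(msgs, "binWidth must be a single positive number")
  if (length(object@irf)) {
    if (length(d) == 3L && length(object@irf) != d[3])
      msgs <- c(msgs, "irf must have one entry per time bin")
    if (any(object@irf < 0) || abs(sum(object@irf) - 1) >= 1e-9)
      msgs <- c(msgs, "irf must be non-negative and sum to 1 (within 1e-9)")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname FLIMDataCube-class
#' @param counts array \code{[m, n, t]} of photon counts.
#' @param binWidth time-bin width in ns.
#' @param irf optional IRF vector (normalized to sum 1).
#' @return A \code{FLIMDataCube}.
#' @export
flimDataCube <- function(counts, binWidth, irf = numeric()) {
  new("FLIMDataCube", counts = counts, binWidth = as.numeric(binWidth),
      irf = as.numeric(irf))
}

#' High-resolution lifetime prior with validity mask
#'
#' The local and global priors are high-resolution lifetime estimates with
#' per-pixel validity: invalid pixels contribute nothing to the inverse
#' retrieval (their fidelity terms are masked out).
#'
#' @slot tau numeric matrix of prior lifetimes (ns).
#' @slot valid logical matrix.
#' @export
setClass("PriorImage", representation(tau = "matrix", valid = "matrix"))

setValidity("PriorImage", function(object) {
  if (!identical(dim(object@tau), dim(object@valid)))
    "tau and valid must have identical dimensions"
  else if (!is.logical(object@valid)) "valid must be logical"
  else TRUE
})

#' @rdname PriorImage-class
#' @param tau numeric matrix (ns).
#' @param valid logical matrix.
#' @return A \code{PriorImage}.
#' @export
priorImage <- function(tau, valid = NULL) {
  tau <- as.matrix(tau)
  if (is.null(valid)) valid <- is.finite(tau)
  storage.mode(valid) <- "logical"
  new("PriorImage", tau = tau, valid = valid)
}

#' 3x3 planar perspective transform
#'
#' Homogeneous mapping between the intensity-camera frame and the lifetime
#' sensor frame, normalized so the bottom-right element is 1.  Coordinates
#' are (row, col).
#'
#' @slot matrix 3x3 numeric matrix with \code{matrix[3,3] == 1}.
#' @export
setClass("Homography", representation(matrix = "matrix"))

setValidity("Homography", function(object) {
  H <- object@matrix
  if (!identical(dim(H), c(3L, 3L))) return("matrix must be 3x3")
  if (abs(H[3, 3] - 1) > 1e-9) return("matrix must be normalized to H[3,3] = 1")
  if (abs(det(H)) <= 1e-12) return("matrix must be invertible")
  TRUE
})

#' Local-prior settings
#'
#' @slot window odd window size in low-resolution samples (3..9; default 5).
#' @slot kind interpolation family fitted in each window: one of
#'   \code{"linear_interp"} (default), \code{"nearest"}, \code{"cubic_spline"},
#'   \code{"rbf_gp"}.
#' @export
setClass("LocalPriorConfig",
  representation(window = "integer", kind = "character"),
  prototype(window = 5L, kind = "linear_interp"))

setValidity("LocalPriorConfig", function(object) {
  msgs <- character()
  w <- object@window
  if (length(w) != 1L || is.na(w) || w %% 2L == 0L || w < 3L || w > 9L)
    msgs <- c(msgs, "window must be an odd integer in [3, 9]")
  if (!object@kind %in% c("linear_interp", "nearest", "cubic_spline", "rbf_gp"))
    msgs <- c(msgs, "unknown function kind")
  if (length(msgs)) msgs else TRUE
})

#' @rdname LocalPriorConfig-class
#' @param window odd window size (low-res samples).
#' @param kind window function family.
#' @return A \code{LocalPriorConfig}.
#' @export
localPriorConfig <- function(window = 5L, kind = "linear_interp") {
  new("LocalPriorConfig", window = as.integer(window), kind = kind)
}

#' Global-prior (patch regressor) settings
#'
#' Training hyper-parameters of the per-sample convolutional regressor that
#' maps 13 x 13 two-channel intensity patches to the central-pixel lifetime.
#' The \code{"full"} preset matches the published training recipe (batch
#' 100, 150 epochs, mean absolute error, Adam, 3 restarts with median-quality
#' selection); the \code{"desk"} preset (20 epochs, 1 restart, capped
#' training set) is sized for test suites on a single CPU.
#'
#' @slot patch odd patch size in pixels (default 13).
#' @slot epochs training epochs (default 150).
#' @slot batch mini-batch size (default 100).
#' @slot learningRate Adam step size (default 1e-3).
#' @slot loss loss name; only \code{"mae"} is supported.
#' @slot symmetryAugment augment with the 8 dihedral images of each patch.
#' @slot neighborAugment \code{NA} = auto (enabled for factor >= 8), else
#'   logical: add the 8 one-pixel-shifted neighbor patches with the same label.
#' @slot restarts independent trainings; the median-validation-MAE prior is kept.
#' @slot maxTrain cap on training instances after augmentation (Inf = no cap).
#' @slot seed RNG seed for initialization, shuffling and the split.
#' @export
setClass("GlobalPriorConfig",
  representation(patch = "integer", epochs = "integer", batch = "integer",
    learningRate = "numeric", loss = "character", symmetryAugment = "logical",
    neighborAugment = "logical", restarts = "integer", maxTrain = "numeric",
    seed = "integer"),
  prototype(patch = 13L, epochs = 150L, batch = 100L, learningRate = 1e-3,
    loss = "mae", symmetryAugment = TRUE, neighborAugment = NA,
    restarts = 3L, maxTrain = Inf, seed = 1L))

setValidity("GlobalPriorConfig", function(object) {
  msgs <- character()
  if (object@patch %% 2L == 0L || object@patch < 3L)
    msgs <- c(msgs, "patch must be odd and >= 3")
  if (object@restarts < 1L) msgs <- c(msgs, "restarts must be >= 1")
  if (object@epochs < 1L || object@batch < 1L)
    msgs <- c(msgs, "epochs and batch must be >= 1")
  if (object@learningRate <= 0) msgs <- c(msgs, "learningRate must be > 0")
  if (!identical(object@loss, "mae")) msgs <- c(msgs, "loss must be 'mae'")
  if (length(msgs)) msgs else TRUE
})

#' @rdname GlobalPriorConfig-class
#' @param preset \code{"full"} (published recipe) or \code{"desk"}
#'   (20 epochs, 1 restart, training set capped at 12000 instances).
#' @param ... slot overrides, e.g. \code{epochs = 50}.
#' @return A \code{GlobalPriorConfig}.
#' @export
globalPriorConfig <- function(preset = c("full", "desk"), ...) {
  preset <- match.arg(preset)
  args <- list(...)
  if (preset == "desk") {
    if (is.null(args$epochs)) args$epochs <- 20L
    if (is.null(args$restarts)) args$restarts <- 1L
    if (is.null(args$maxTrain)) args$maxTrain <- 12000
  }
  for (nm in c("patch", "epochs", "batch", "restarts", "seed"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("GlobalPriorConfig"), args))
}

#' ADMM inverse-retrieval settings
#'
#' Weights and iteration counts of the prior-augmented, anisotropic-TV
#' regularized reconstruction.  \code{gamma} weighs the local-prior fidelity
#' term, \code{beta} the global-prior term, \code{alpha} the TV penalty and
#' \code{rho} the ADMM penalty parameter.  \code{NA} values are resolved at
#' run time: \code{beta} from the upsampling factor (0.02 for 2x/4x, 0.5
#' for 8x/16x) and \code{alpha} as 1% of the dynamic range of the measured
#' low-resolution lifetime image.
#'
#' @slot gamma local-prior weight (default 0.1).
#' @slot beta global-prior weight (default NA = auto from factor).
#' @slot alpha TV weight (default NA = 0.01 x dynamic range of tau_LR).
#' @slot rho ADMM penalty parameter (default 1).
#' @slot admmIters outer ADMM iterations (default 20).
#' @slot fistaIters inner FISTA iterations per primal update (default 90).
#' @export
setClass("ADMMConfig",
  representation(gamma = "numeric", beta = "numeric", alpha = "numeric",
    rho = "numeric", admmIters = "integer", fistaIters = "integer"),
  prototype(gamma = 0.1, beta = NA_real_, alpha = NA_real_, rho = 1,
    admmIters = 20L, fistaIters = 90L))

setValidity("ADMMConfig", function(object) {
  msgs <- character()
  for (nm in c("gamma", "beta", "alpha", "rho")) {
    v <- slot(object, nm)
    if (!is.na(v) && v < 0) msgs <- c(msgs, paste(nm, "must be >= 0"))
  }
  if (object@admmIters < 1L || object@fistaIters < 1L)
    msgs <- c(msgs, "iteration counts must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' @rdname ADMMConfig-class
#' @param gamma,beta,alpha,rho,admmIters,fistaIters see slots.
#' @return An \code{ADMMConfig}.
#' @export
admmConfig <- function(gamma = 0.1, beta = NA_real_, alpha = NA_real_,
                       rho = 1, admmIters = 20L, fistaIters = 90L) {
  new("ADMMConfig", gamma = gamma, beta = beta, alpha = alpha, rho = rho,
      admmIters = as.integer(admmIters), fistaIters = as.integer(fistaIters))
}

#' Resolve the global-prior weight from the upsampling factor
#'
#' Returns 0.02 for factors 2 and 4 and 0.5 for 8 and 16 when \code{beta}
#' is NA, else \code{beta} unchanged.
#' @param beta possibly-NA beta.
#' @param factor upsampling factor.
#' @return numeric beta.
#' @export
resolveBeta <- function(beta, factor) {
  if (!is.na(beta)) return(beta)
  if (factor >= 8) 0.5 else 0.02
}
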