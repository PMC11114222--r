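# End-to-end orchestration: fit (optional) -> local prior -> global prior
# -> ADMM inverse retrieval -> metrics vs the bilinear baseline.

#' Run the full guided super-resolution pipeline
#'
#' Executes the stages in order: per-pixel lifetime fitting when a datacube
#' is supplied (otherwise the given low-resolution lifetime image is used),
#' local-prior construction, global-prior training, ADMM inverse retrieval,
#' and evaluation against the bilinear baseline (and the ground truth when
#' provided).  All randomness (global-prior initialization, shuffling,
#' split) is controlled by \code{gpConfig@seed}, so a rerun with the same
#' inputs and configuration is bit-identical in single-threaded mode.
#'
#' @param tauLR low-resolution \code{LifetimeImage}; may be NULL when
#'   \code{cube} is given.
#' @param intensityHR high-resolution \code{IntensityImage}.
#' @param spec a \code{SamplingSpec}.
#' @param cube optional \code{FLIMDataCube}; fitted with
#'   \code{\link{fitImage}} to obtain \code{tauLR}.
#' @param lpConfig a \code{LocalPriorConfig}.
#' @param gpConfig a \code{GlobalPriorConfig}.
#' @param irConfig an \code{ADMMConfig}.
#' @param tauGT optional ground-truth \code{LifetimeImage} for metrics.
#' @param minCounts photon threshold for \code{\link{fitImage}}.
#' @param outDir optional directory; when set, all intermediates are
#'   written as TIFF/JSON plus a \code{manifest.json} with configuration,
#'   package version and md5 hashes of the outputs.
#' @return list with \code{tauHR}, \code{lp}, \code{gp}, \code{baseline},
#'   \code{tauLR}, \code{diagnostics} (ADMM traces plus global-prior
#'   training histories) and \code{metrics} (data.frame, when ground truth
#'   was given).
#' @export
runPipeline <- function(tauLR = NULL, intensityHR, spec, cube = NULL,
                        lpConfig = localPriorConfig(),
                        gpConfig = globalPriorConfig(),
                        irConfig = admmConfig(),
                        tauGT = NULL, minCounts = 50, outDir = NULL) {
  if (is.null(tauLR)) {
    if (is.null(cube)) stop("need either tauLR or a datacube")
    tauLR <- fitImage(cube, minCounts = minCounts)$lifetime
  }
  lp <- buildLocalPrior(tauLR, intensityHR, spec, lpConfig)
  gpRes <- buildGlobalPrior(tauLR, intensityHR, spec, gpConfig)
  gp <- gpRes$prior
  rec <- admmReconstruct(tauLR, lp, gp, spec, irConfig)
  base <- bilinearBaseline(tauLR, spec)
  metrics <- NULL
  if (!is.null(tauGT)) {
    metrics <- evaluateMethods(tauGT,
      list(fused = rec$tauHR, bilinear = base, local_prior = lp,
           global_prior = gp),
      mask = validMask(tauGT))
  }
  out <- list(tauHR = rec$tauHR, lp = lp, gp = gp, baseline = base,
              tauLR = tauLR,
              diagnostics = c(rec$diagnostics,
                              list(gpValMAE = gpRes$valMAE,
                                   gpHistories = gpRes$histories)),
              metrics = metrics)
  if (!is.null(outDir)) .writeRunDir(out, spec, lpConfig, gpConfig,
                                     irConfig, outDir)
  out
}

.writeRunDir <- function(out, spec, lpConfig, gpConfig, irConfig, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    writeLifetimeTiff(out$tauHR, file.path(outDir, "tau_hr.tif")),
    writeLifetimeTiff(out$tauLR, file.path(outDir, "tau_lr.tif")),
    writeLifetimeTiff(priorAsLifetime(out$lp), file.path(outDir, "lp.tif")),
    writeLifetimeTiff(priorAsLifetime(out$gp), file.path(outDir, "gp.tif")),
    writeLifetimeTiff(out$baseline, file.path(outDir, "bilinear.tif")))
  utils::write.csv(
    data.frame(iter = seq_along(out$diagnostics$cost),
               cost = out$diagnostics$cost,
               primal_residual = out$diagnostics$primalResidual),
    file.path(outDir, "diagnostics.csv"), row.names = FALSE)
  if (!is.null(out$metrics))
    utils::write.csv(out$metrics, file.path(outDir, "metrics.csv"),
                     row.names = FALSE)
  manifest <- list(
    package = "flimfuse",
    version = as.character(utils::packageVersion("flimfuse")),
    factor = upsamplingFactor(spec), offset = sampleOffset(spec),
    local_prior = list(window = lpConfig@window, kind = lpConfig@kind),
    global_prior = list(patch = gpConfig@patch, epochs = gpConfig@epochs,
                        batch = gpConfig@batch, restarts = gpConfig@restarts,
                        seed = gpConfig@seed),
    admm = list(gamma = irConfig@gamma, beta = out$diagnostics$beta,
                alpha = out$diagnostics$alpha, rho = irConfig@rho,
                admm_iters = irConfig@admmIters,
                fista_iters = irConfig@fistaIters),
    hashes = as.list(tools::md5sum(paths)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

#' Serialize pipeline configuration to JSON
#'
#' Writes the sampling factor/offset and the three stage configurations so
#' a run can be reproduced from the file alone (together with its inputs
#' and seed).  \code{\link{readPipelineConfig}} restores equivalent
#' configuration objects.
#'
#' @param spec a \code{SamplingSpec}.
#' @param lpConfig a \code{LocalPriorConfig}.
#' @param gpConfig a \code{GlobalPriorConfig}.
#' @param irConfig an \code{ADMMConfig}.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writePipelineConfig <- function(spec, lpConfig, gpConfig, irConfig, path) {
  slots2list <- function(obj)
    stats::setNames(lapply(slotNames(obj), function(s) slot(obj, s)),
                    slotNames(obj))
  cfg <- list(sampling = list(factor = spec@factor, offset = spec@offset),
              local_prior = slots2list(lpConfig),
              global_prior = slots2list(gpConfig),
              admm = slots2list(irConfig))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Restore pipeline configuration from JSON
#' @param path JSON file written by \code{\link{writePipelineConfig}}.
#' @return list with \code{spec}, \code{lpConfig}, \code{gpConfig},
#'   \code{irConfig}.
#' @export
readPipelineConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  gp <- cfg$global_prior
  list(
    spec = samplingSpec(cfg$sampling$factor, cfg$sampling$offset),
    lpConfig = localPriorConfig(cfg$local_prior$window, cfg$local_prior$kind),
    gpConfig = new("GlobalPriorConfig",
      patch = as.integer(gp$patch), epochs = as.integer(gp$epochs),
      batch = as.integer(gp$batch), learningRate = num(gp$learningRate),
      loss = gp$loss, symmetryAugment = as.logical(gp$symmetryAugment),
      neighborAugment = as.logical(
        if (is.null(gp$neighborAugment)) NA else gp$neighborAugment),
      restarts = as.integer(gp$restarts),
      maxTrain = if (is.null(gp$maxTrain)) Inf else num(gp$maxTrain),
      seed = as.integer(gp$seed)),
    irConfig = admmConfig(num(cfg$admm$gamma), num(cfg$admm$beta),
                          num(cfg$admm$alpha), num(cfg$admm$rho),
                          as.integer(cfg$admm$admmIters),
                          as.integer(cfg$admm$fistaIters)))
}

#' Convert a prior to a lifetime image (clamping invalid pixels to 0)
#' @param prior a \code{PriorImage}.
#' @return A \code{LifetimeImage} with the same validity mask.
#' @export
priorAsLifetime <- function(prior) {
  tau <- tauMap(prior)
  tau[!validMask(prior)] <- 0
  lifetimeImage(pmax(tau, 0), validMask(prior))
}
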