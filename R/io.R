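# TIFF + JSON-sidecar I/O.
#
# TIFF pages are stored as value/scale with the linear scale recorded in a
# JSON sidecar ("<path>.json"), so physical units (ns, photons) survive the
# [0, 1] sample range of the TIFF writer.  A missing sidecar means scale 1.

.sidecarPath <- function(path) paste0(path, ".json")

.writeScaled <- function(pages, path, meta = list()) {
  mx <- max(vapply(pages, max, numeric(1)), 0)
  scale <- if (mx > 0) mx else 1
  tiff::writeTIFF(lapply(pages, function(p) p / scale), path,
                  bits.per.sample = 32L)
  meta$scale <- scale
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.readScaled <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- if (file.exists(.sidecarPath(path)))
    jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  else list(scale = 1)
  list(pages = lapply(pages, function(p) p * meta$scale), meta = meta)
}

#' Write a lifetime image as TIFF (ns) with JSON sidecar
#' @param img a \code{LifetimeImage} or \code{PriorImage}.
#' @param path output TIFF path; the validity mask and value scale go into
#'   \code{<path>.json}.
#' @return the path, invisibly.
#' @export
writeLifetimeTiff <- function(img, path) {
  .writeScaled(list(tauMap(img)), path,
               list(units = "ns", valid = validMask(img)))
}

#' Read a lifetime image written by \code{\link{writeLifetimeTiff}}
#' @param path TIFF path.
#' @return A \code{LifetimeImage}.
#' @export
readLifetimeTiff <- function(path) {
  r <- .readScaled(path)
  tau <- r$pages[[1]]
  valid <- if (!is.null(r$meta$valid))
    matrix(as.logical(r$meta$valid), nrow(tau), ncol(tau))
  else NULL
  lifetimeImage(tau, valid)
}

#' Write an intensity image as TIFF with JSON sidecar
#' @param img an \code{IntensityImage}.
#' @param path output TIFF path.
#' @return the path, invisibly.
#' @export
writeIntensityTiff <- function(img, path) {
  .writeScaled(list(intensityValues(img)), path, list(units = "counts"))
}

#' Read an intensity image
#' @param path TIFF path.
#' @return An \code{IntensityImage}.
#' @export
readIntensityTiff <- function(path) {
  intensityImage(.readScaled(path)$pages[[1]])
}

#' Write a datacube as multi-page TIFF plus JSON sidecar
#'
#' One page per time bin; the sidecar holds \code{bin_width_ns}, the value
#' scale and the IRF when present.
#'
#' @param cube a \code{FLIMDataCube}.
#' @param path output TIFF path.
#' @return the path, invisibly.
#' @export
writeDataCubeTiff <- function(cube, path) {
  d <- dim(cube@counts)
  pages <- lapply(seq_len(d[3]), function(b) cube@counts[, , b])
  meta <- list(units = "photons", bin_width_ns = cube@binWidth)
  if (length(cube@irf)) meta$irf <- cube@irf
  .writeScaled(pages, path, meta)
}

#' Read a datacube written by \code{\link{writeDataCubeTiff}}
#' @param path TIFF path (with its \code{.json} sidecar alongside).
#' @return A \code{FLIMDataCube}.
#' @export
readDataCubeTiff <- function(path) {
  r <- .readScaled(path)
  d <- dim(r$pages[[1]])
  counts <- array(0, c(d[1], d[2], length(r$pages)))
  for (b in seq_along(r$pages)) counts[, , b] <- round(r$pages[[b]])
  flimDataCube(counts, r$meta$bin_width_ns,
               if (is.null(r$meta$irf)) numeric() else r$meta$irf)
}

#' Write a phantom fixture bundle to a directory
#'
#' Writes \code{cube.tif}, \code{tau_lr.tif}, \code{int_hr.tif},
#' \code{tau_gt.tif} (each with its JSON sidecar) and \code{spec.json}.
#'
#' @param bundle a fixture from \code{\link{makeFixture}}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeFixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeDataCubeTiff(bundle$cube, file.path(dir, "cube.tif"))
  writeLifetimeTiff(bundle$tauLR, file.path(dir, "tau_lr.tif"))
  writeIntensityTiff(bundle$intensityHR, file.path(dir, "int_hr.tif"))
  writeLifetimeTiff(bundle$tauGT, file.path(dir, "tau_gt.tif"))
  sp <- bundle$spec; class(sp) <- NULL
  sp$sampling_factor <- upsamplingFactor(bundle$sampling)
  sp$sampling_offset <- sampleOffset(bundle$sampling)
  jsonlite::write_json(sp, file.path(dir, "spec.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
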