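# Global prior: a per-sample convolutional regressor from two-channel
# intensity patches to the central-pixel lifetime.  All training data come
# from the field of view being upsampled: every valid low-resolution sample
# whose p x p intensity neighborhood fits inside the image contributes one
# labeled patch, augmented by the 8 dihedral symmetries and (for high
# upsampling factors) the 8 one-pixel-shifted neighbor patches carrying the
# same label.

#' Labeled intensity patches for global-prior training
#'
#' @slot patches numeric matrix \code{K x (2 p^2)}; each row is one
#'   two-channel patch (channel 0: per-patch min-max normalized; channel 1:
#'   divided by the global intensity maximum), each channel stored
#'   column-major.
#' @slot labels numeric vector of central-pixel lifetimes (ns).
#' @slot centers integer \code{K x 2} high-resolution (row, col) centers.
#' @slot groups integer vector: id of the originating low-resolution sample
#'   (augmented copies keep their source's id, so train/validation splits
#'   can be grouped by sample center).
#' @slot p odd patch size.
#' @export
setClass("PatchSet",
  representation(patches = "matrix", labels = "numeric", centers = "matrix",
    groups = "integer", p = "integer"))

setValidity("PatchSet", function(object) {
  msgs <- character()
  K <- nrow(object@patches)
  if (ncol(object@patches) != 2L * object@p^2)
    msgs <- c(msgs, "patch matrix width must be 2 * p^2")
  if (length(object@labels) != K || nrow(object@centers) != K ||
      length(object@groups) != K)
    msgs <- c(msgs, "labels, centers and groups must match the patch count")
  if (K && any(object@labels <= 0)) msgs <- c(msgs, "labels must be > 0")
  if (K && (min(object@patches) < -1e-9 || max(object@patches) > 1 + 1e-9))
    msgs <- c(msgs, "normalized channels must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "PatchSet", function(object) {
  cat(sprintf("PatchSet: %d patches (%d x %d x 2), %d source samples\n",
      nrow(object@patches), object@p, object@p, length(unique(object@groups))))
})

#' Two-channel patch normalization
#'
#' Channel 0 is the per-patch min-max normalization
#' \code{(raw - min) / (max - min)} (all zeros for a flat patch), focusing
#' on shape and texture; channel 1 is \code{raw / globalMax}, keeping
#' absolute intensity information.
#'
#' @param raw numeric \code{p x p} matrix of intensities.
#' @param globalMax maximum of the full intensity image (> 0).
#' @return numeric array \code{p x p x 2}.
#' @export
normalizePatch <- function(raw, globalMax) {
  if (!is.finite(globalMax) || globalMax <= 0)
    stop("globalMax must be a positive number")
  raw <- as.matrix(raw)
  rng <- max(raw) - min(raw)
  ch0 <- if (rng > 0) (raw - min(raw)) / rng else raw * 0
  array(c(ch0, raw / globalMax), dim = c(nrow(raw), ncol(raw), 2L))
}

# Build the K x (2 p^2) normalized patch matrix for a rectangular grid of
# centers (rows x cols, all at >= (p-1)/2 pixels from every edge).
.patchMatrix <- function(I, rows, cols, p, globalMax) {
  h <- (p - 1L) %/% 2L
  K <- length(rows) * length(cols)
  raw <- matrix(0, K, p * p)
  for (pc in seq_len(p)) for (pr in seq_len(p)) {
    raw[, pr + p * (pc - 1L)] <-
      as.vector(I[rows + (pr - 1L - h), cols + (pc - 1L - h)])
  }
  rmin <- raw[, 1]; rmax <- raw[, 1]
  for (k in 2:ncol(raw)) {
    rmin <- pmin(rmin, raw[, k]); rmax <- pmax(rmax, raw[, k])
  }
  rng <- rmax - rmin
  rng[rng == 0] <- Inf                      # flat patch -> channel 0 all zeros
  cbind((raw - rmin) / rng, raw / globalMax)
}

#' Extract labeled training patches at the sampled positions
#'
#' One patch per valid low-resolution sample whose \code{p x p}
#' neighborhood lies fully inside the intensity image; the label is that
#' sample's lifetime.
#'
#' @param intensityHR high-resolution \code{IntensityImage}.
#' @param tauLR low-resolution \code{LifetimeImage}.
#' @param spec a \code{SamplingSpec}.
#' @param p odd patch size (default 13).
#' @return A \code{\link{PatchSet}}.
#' @export
extractPatches <- function(intensityHR, tauLR, spec, p = 13L) {
  stopifnot(is(intensityHR, "IntensityImage"), is(tauLR, "LifetimeImage"),
            is(spec, "SamplingSpec"))
  p <- as.integer(p)
  if (p %% 2L == 0L) stop("patch size must be odd")
  I <- intensityHR@values
  if (nrow(I) <= p || ncol(I) <= p) stop("image smaller than the patch size")
  h <- (p - 1L) %/% 2L
  idx <- .sampleIndices(spec, dim(I))
  ri <- which(idx$rows >= h + 1L & idx$rows <= nrow(I) - h)
  ci <- which(idx$cols >= h + 1L & idx$cols <= ncol(I) - h)
  if (!length(ri) || !length(ci))
    stop("empty training set: no sample admits a full patch")
  rows <- idx$rows[ri]; cols <- idx$cols[ci]
  gmax <- max(I)
  patches <- .patchMatrix(I, rows, cols, p, gmax)
  centers <- cbind(rep(rows, times = length(cols)),
                   rep(cols, each = length(rows)))
  labels <- as.vector(tauLR@tau[ri, ci])
  ok <- as.vector(tauLR@valid[ri, ci])
  if (!any(ok)) stop("empty training set: no valid sample admits a full patch")
  new("PatchSet", patches = patches[ok, , drop = FALSE], labels = labels[ok],
      centers = centers[ok, , drop = FALSE],
      groups = seq_len(sum(ok)), p = p)
}

# dihedral-group permutations of the 2 p^2 patch layout
.dihedralPerms <- function(p) {
  base <- matrix(seq_len(p * p), p, p)
  ops <- list(
    function(m) m,
    function(m) t(m)[, seq(p, 1)],          # rotate 90
    function(m) m[seq(p, 1), seq(p, 1)],    # rotate 180
    function(m) t(m)[seq(p, 1), ],          # rotate 270
    function(m) m[seq(p, 1), ],             # mirror (flip rows)
    function(m) t(m)[, seq(p, 1)][seq(p, 1), ],
    function(m) m[seq(p, 1), seq(p, 1)][seq(p, 1), ],
    function(m) t(m)[seq(p, 1), ][seq(p, 1), ])
  lapply(ops, function(f) { v <- as.vector(f(base)); c(v, v + p * p) })
}

#' Eightfold dihedral augmentation of a patch set
#'
#' Replaces each patch by its 8 dihedral-group images (4 rotations times
#' mirroring), copying labels, centers and group ids, so the training set
#' grows exactly eightfold.  Degenerate (symmetric) patches yield duplicate
#' rows, which are retained by design.
#'
#' @param ps a \code{\link{PatchSet}}.
#' @return A \code{\link{PatchSet}} with \code{8 K} patches.
#' @export
augmentSymmetry <- function(ps) {
  stopifnot(is(ps, "PatchSet"), nrow(ps@patches) > 0L)
  perms <- .dihedralPerms(ps@p)
  patches <- do.call(rbind, lapply(perms, function(pm) ps@patches[, pm, drop = FALSE]))
  new("PatchSet", patches = patches, labels = rep(ps@labels, times = 8L),
      centers = ps@centers[rep(seq_len(nrow(ps@centers)), times = 8L), , drop = FALSE],
      groups = rep(ps@groups, times = 8L), p = ps@p)
}

#' Neighbor-patch augmentation with blind labels
#'
#' For each sampled patch, the 8 patches whose centers are the immediate
#' (one-pixel) neighbors of the sample center are added with the sample's
#' own lifetime label (assuming lifetime varies slowly within one intensity
#' pixel).  Neighbors whose patch would leave the image are skipped.  On
#' interior samples the factor is 9x before symmetry augmentation, 72x
#' after.
#'
#' @param ps a \code{\link{PatchSet}} of original (unaugmented) sampled patches.
#' @param intensityHR the \code{IntensityImage} the patches came from.
#' @return A \code{\link{PatchSet}} containing the originals plus neighbors.
#' @export
augmentNeighbors <- function(ps, intensityHR) {
  stopifnot(is(ps, "PatchSet"))
  I <- intensityHR@values
  p <- ps@p; h <- (p - 1L) %/% 2L
  gmax <- max(I)
  out <- list(ps@patches)
  labels <- list(ps@labels); centers <- list(ps@centers); groups <- list(ps@groups)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (o in seq_len(nrow(offs))) {
    r2 <- ps@centers[, 1] + offs$dr[o]
    c2 <- ps@centers[, 2] + offs$dc[o]
    ok <- r2 >= h + 1L & r2 <= nrow(I) - h & c2 >= h + 1L & c2 <= ncol(I) - h
    if (!any(ok)) next
    w <- which(ok)
    pm <- matrix(0, length(w), 2L * p * p)
    for (k in seq_along(w)) {
      raw <- I[(r2[w[k]] - h):(r2[w[k]] + h), (c2[w[k]] - h):(c2[w[k]] + h)]
      pm[k, ] <- as.vector(normalizePatch(raw, gmax))
    }
    out[[length(out) + 1L]] <- pm
    labels[[length(labels) + 1L]] <- ps@labels[w]
    centers[[length(centers) + 1L]] <- cbind(r2[w], c2[w])
    groups[[length(groups) + 1L]] <- ps@groups[w]
  }
  new("PatchSet", patches = do.call(rbind, out),
      labels = unlist(labels), centers = do.call(rbind, centers),
      groups = unlist(groups), p = p)
}

#' Train the patch-to-lifetime regressor once
#'
#' Splits the patch set 90/10 into training and validation by source-sample
#' group (augmented copies of one sample never straddle the split), then
#' trains the 3-conv + 3-FC network with Adam on mean absolute error.
#' When \code{cfg@maxTrain} caps the training set, a seeded uniform
#' subsample of training instances is used; the validation set is never
#' subsampled.
#'
#' @param ps an augmented \code{\link{PatchSet}}.
#' @param cfg a \code{GlobalPriorConfig}.
#' @param seedOffset added to \code{cfg@seed} (used for restarts).
#' @return A patch-regressor model list with elements \code{params},
#'   \code{arch}, \code{history} (per-epoch train/val MAE) and
#'   \code{valMAE} (final validation MAE).
#' @export
trainPatchRegressor <- function(ps, cfg = globalPriorConfig(), seedOffset = 0L) {
  stopifnot(is(ps, "PatchSet"), is(cfg, "GlobalPriorConfig"))
  if (!nrow(ps@patches)) stop("empty patch set")
  set.seed(cfg@seed + seedOffset)
  gids <- unique(ps@groups)
  nval <- max(1L, round(0.1 * length(gids)))
  if (nval >= length(gids)) stop("validation split empty: too few sample groups")
  valG <- sample(gids, nval)
  isVal <- ps@groups %in% valG
  tri <- which(!isVal); vai <- which(isVal)
  if (length(tri) > cfg@maxTrain)
    tri <- sort(sample(tri, cfg@maxTrain))
  net <- .nnTrain(ps@patches[tri, , drop = FALSE], ps@labels[tri],
                  ps@patches[vai, , drop = FALSE], ps@labels[vai],
                  ps@p, cfg@epochs, cfg@batch, cfg@learningRate)
  net$valMAE <- net$history$val[nrow(net$history)]
  net
}

#' Predict the global-prior image
#'
#' Evaluates the trained regressor at every high-resolution pixel whose
#' \code{p x p} patch fits inside the image; the \code{(p-1)/2}-pixel
#' border (6 pixels for the default 13 x 13 patch) is marked invalid.
#'
#' @param model a model from \code{\link{trainPatchRegressor}}.
#' @param intensityHR the \code{IntensityImage}.
#' @param p odd patch size (must match the model).
#' @return A \code{\link{PriorImage}}.
#' @export
predictGlobalPrior <- function(model, intensityHR, p = 13L) {
  I <- intensityHR@values
  p <- as.integer(p); h <- (p - 1L) %/% 2L
  rows <- (h + 1L):(nrow(I) - h)
  cols <- (h + 1L):(ncol(I) - h)
  X <- .patchMatrix(I, rows, cols, p, max(I))
  pred <- .nnPredict(model, X)
  tau <- matrix(0, nrow(I), ncol(I))
  tau[rows, cols] <- matrix(pred, length(rows), length(cols))
  valid <- matrix(FALSE, nrow(I), ncol(I))
  valid[rows, cols] <- TRUE
  priorImage(pmax(tau, 0), valid)
}

#' Select the median-quality prior across restarts
#'
#' Quality is the final validation MAE; with \code{k} restarts the prior of
#' rank \code{floor((k + 1) / 2)} (the lower median) is returned, ties
#' resolved toward the earlier restart.  With fewer than 3 priors the best
#' available one is returned with a warning.
#'
#' @param priors list of \code{\link{PriorImage}} objects.
#' @param valMAE numeric vector of final validation MAEs, same length.
#' @return The selected \code{\link{PriorImage}}.
#' @export
selectMedianPrior <- function(priors, valMAE) {
  stopifnot(length(priors) == length(valMAE), length(priors) >= 1L)
  if (length(priors) < 3L) {
    warning("fewer than 3 restarts; returning the best available prior")
    return(priors[[which.min(valMAE)]])
  }
  ord <- order(valMAE)
  medVal <- valMAE[ord[(length(priors) + 1L) %/% 2L]]
  priors[[which(valMAE == medVal)[1]]]      # ties: earliest restart wins
}

#' Build the global-prior image end to end
#'
#' Extracts sampled patches, applies symmetry augmentation and (when
#' enabled, by default for upsampling factors >= 8) neighbor augmentation,
#' trains \code{cfg@restarts} regressors from different initializations and
#' returns the prior of median validation quality.
#'
#' @param tauLR low-resolution \code{LifetimeImage}.
#' @param intensityHR high-resolution \code{IntensityImage}.
#' @param spec a \code{SamplingSpec}.
#' @param cfg a \code{GlobalPriorConfig}.
#' @return list with \code{prior} (a \code{\link{PriorImage}}),
#'   \code{valMAE} (per restart), \code{histories} (per restart) and
#'   \code{nPatches} (augmented training-set size).
#' @export
buildGlobalPrior <- function(tauLR, intensityHR, spec,
                             cfg = globalPriorConfig()) {
  ps <- extractPatches(intensityHR, tauLR, spec, cfg@patch)
  neigh <- cfg@neighborAugment
  if (is.na(neigh)) neigh <- spec@factor >= 8L
  if (neigh) ps <- augmentNeighbors(ps, intensityHR)
  if (cfg@symmetryAugment) ps <- augmentSymmetry(ps)
  priors <- vector("list", cfg@restarts)
  valMAE <- numeric(cfg@restarts)
  histories <- vector("list", cfg@restarts)
  for (r in seq_len(cfg@restarts)) {
    net <- trainPatchRegressor(ps, cfg, seedOffset = r - 1L)
    priors[[r]] <- predictGlobalPrior(net, intensityHR, cfg@patch)
    valMAE[r] <- net$valMAE
    histories[[r]] <- net$history
  }
  prior <- if (cfg@restarts >= 3L) selectMedianPrior(priors, valMAE)
           else priors[[which.min(valMAE)]]
  list(prior = prior, valMAE = valMAE, histories = histories,
       nPatches = nrow(ps@patches))
}
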