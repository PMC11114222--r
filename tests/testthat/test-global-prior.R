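# Patch extraction, augmentation and the patch-to-lifetime regressor.

miniPatchSet <- function(seed = 1, M = 48L, lambda = 8L, p = 13L) {
  set.seed(seed)
  I <- intensityImage(matrix(runif(M * M, 0, 100), M, M))
  tl <- lifetimeImage(matrix(runif((M %/% lambda)^2, 2, 4),
                             M %/% lambda, M %/% lambda))
  list(ps = extractPatches(I, tl, samplingSpec(lambda), p), I = I, tl = tl)
}

test_that("patch extraction respects the edge margin geometry", {
  mp <- miniPatchSet()
  # brute-force enumeration: sample centers at >= 6 px from every edge
  centers <- expand.grid(r = seq(1, 48, by = 8), c = seq(1, 48, by = 8))
  keep <- centers$r >= 7 & centers$r <= 42 & centers$c >= 7 & centers$c <= 42
  expect_equal(nrow(mp$ps@patches), sum(keep))
  expect_true(all(mp$ps@centers[, 1] >= 7 & mp$ps@centers[, 1] <= 42))
  # larger grid, factor 8, 13x13 patches: count equals the exhaustive scan
  set.seed(2)
  I2 <- intensityImage(matrix(runif(192 * 256), 192, 256))
  tl2 <- lifetimeImage(matrix(runif(24 * 32, 2, 4), 24, 32))
  ps2 <- extractPatches(I2, tl2, samplingSpec(8), 13L)
  rs <- seq(1, 192, by = 8); cs <- seq(1, 256, by = 8)
  expect_equal(nrow(ps2@patches),
               sum(rs >= 7 & rs <= 186) * sum(cs >= 7 & cs <= 250))
})

test_that("patch normalization produces the two documented channels", {
  raw <- matrix(seq(2, 10, length.out = 25), 5, 5)
  arr <- normalizePatch(raw, 20)
  expect_equal(arr[, , 1][raw == 6][1], 0.5)          # per-patch affine map
  expect_equal(range(arr[, , 1]), c(0, 1))
  expect_equal(arr[, , 2], raw / 20)
  expect_true(all(normalizePatch(matrix(5, 5, 5), 10)[, , 1] == 0))  # flat
  expect_equal(max(normalizePatch(matrix(c(rep(1, 24), 10), 5, 5), 10)[, , 2]), 1)
  expect_error(normalizePatch(raw, 0), "positive")
  # constant image: all extracted patches identical after normalization
  Ic <- intensityImage(matrix(7, 48, 48))
  tlc <- lifetimeImage(matrix(3, 6, 6))
  psc <- extractPatches(Ic, tlc, samplingSpec(8), 13L)
  expect_true(all(apply(psc@patches, 2, function(cl) length(unique(cl))) == 1))
})

test_that("dihedral augmentation is exactly eightfold with distinct images", {
  mp <- miniPatchSet()
  aug <- augmentSymmetry(mp$ps)
  expect_identical(nrow(aug@patches), 8L * nrow(mp$ps@patches))
  expect_identical(aug@labels, rep(mp$ps@labels, times = 8))
  # a generic (asymmetric) patch has 8 pairwise distinct images
  k <- nrow(mp$ps@patches)
  imgs <- aug@patches[seq(1, 8 * k, by = k), , drop = FALSE]
  expect_equal(nrow(unique(imgs)), 8)
  # a constant patch yields 8 identical copies, all retained
  Ic <- intensityImage(matrix(1, 32, 32))
  psc <- extractPatches(Ic, lifetimeImage(matrix(2, 4, 4)),
                        samplingSpec(8), 13L)
  augc <- augmentSymmetry(psc)
  expect_identical(nrow(augc@patches), 8L * nrow(psc@patches))
  expect_equal(nrow(unique(augc@patches[augc@groups == 1, , drop = FALSE])), 1)
})

test_that("neighbor labeling gives 9 positions interior, fewer at margins", {
  mp <- miniPatchSet()
  aug <- augmentNeighbors(mp$ps, mp$I)
  # exhaustive bounds-check oracle for the expected count
  want <- 0L
  for (k in seq_len(nrow(mp$ps@centers))) {
    r <- mp$ps@centers[k, 1]; c <- mp$ps@centers[k, 2]
    for (dr in -1:1) for (dc in -1:1)
      if (r + dr >= 7 && r + dr <= 42 && c + dc >= 7 && c + dc <= 42)
        want <- want + 1L
  }
  expect_identical(nrow(aug@patches), want)
  # strictly interior samples get all 9 positions, hence 72x with symmetry
  interior <- mp$ps@centers[, 1] >= 8 & mp$ps@centers[, 1] <= 41 &
              mp$ps@centers[, 2] >= 8 & mp$ps@centers[, 2] <= 41
  g <- mp$ps@groups[interior][1]
  expect_identical(sum(aug@groups == g), 9L)
  full <- augmentSymmetry(aug)
  expect_identical(sum(full@groups == g), 72L)
})

test_that("regressor training learns constants and beats a constant baseline", {
  mp <- miniPatchSet(seed = 5, M = 96L)
  # constant labels: predictions converge to the constant
  psc <- mp$ps
  psc@labels <- rep(3, length(psc@labels))
  cfg <- globalPriorConfig("desk", epochs = 12L, seed = 2L, restarts = 1L)
  net <- trainPatchRegressor(augmentSymmetry(psc), cfg)
  pred <- flimfuse:::.nnPredict(net, psc@patches)
  expect_lt(max(abs(pred - 3)), 0.05 * 3)
  # labels a smooth function of patch mean intensity: beat the best constant
  ps <- mp$ps
  mu <- rowMeans(ps@patches[, 170:338])     # global-intensity channel
  ps@labels <- 2 + 2 * sin(pi * mu / max(mu))
  net2 <- trainPatchRegressor(augmentSymmetry(ps), cfg)
  constMAE <- mean(abs(ps@labels - median(ps@labels)))  # best constant for MAE
  expect_lt(net2$valMAE, constMAE)
})

test_that("training curves are deterministic under a fixed seed", {
  mp <- miniPatchSet(seed = 9)
  cfg <- globalPriorConfig("desk", epochs = 3L, seed = 4L)
  n1 <- trainPatchRegressor(augmentSymmetry(mp$ps), cfg)
  n2 <- trainPatchRegressor(augmentSymmetry(mp$ps), cfg)
  expect_identical(n1$history, n2$history)
  expect_identical(n1$params, n2$params)
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  net <- flimfuse:::.nnInit(13L, 2L, labelMean = 3)
  X <- matrix(runif(4 * 338), 4, 338); y <- runif(4, 2, 4)
  lg <- flimfuse:::.nnLossGrad(net, X, y)
  for (nm in c("W1", "b1", "W2", "W3", "b3", "W4", "W5", "W6", "b6")) {
    for (rep in 1:3) {
      i <- sample(length(net$params[[nm]]), 1)
      eps <- 1e-6
      up <- net; up$params[[nm]][i] <- up$params[[nm]][i] + eps
      dn <- net; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
      num <- (flimfuse:::.nnLossGrad(up, X, y)$loss -
              flimfuse:::.nnLossGrad(dn, X, y)$loss) / (2 * eps)
      expect_lt(abs(num - lg$grads[[nm]][i]) / max(abs(num), 1e-8), 1e-4)
    }
  }
})

test_that("prediction covers the interior with the exact invalid border", {
  mp <- miniPatchSet(seed = 3)
  cfg <- globalPriorConfig("desk", epochs = 2L, seed = 1L)
  net <- trainPatchRegressor(augmentSymmetry(mp$ps), cfg)
  prior <- predictGlobalPrior(net, mp$I, 13L)
  v <- validMask(prior)
  expect_false(any(v[1:6, ])); expect_false(any(v[, 1:6]))
  expect_false(any(v[43:48, ])); expect_false(any(v[, 43:48]))
  expect_true(all(v[7:42, 7:42]))
})

test_that("median-quality selection follows the validation MAE ranking", {
  mk <- function(x) priorImage(matrix(x, 4, 4))
  priors <- list(mk(1), mk(2), mk(3))
  expect_equal(tauMap(selectMedianPrior(priors, c(0.10, 0.50, 0.30)))[1], 3)
  # identical scores: first restart wins deterministically
  expect_equal(tauMap(selectMedianPrior(priors, c(0.2, 0.2, 0.2)))[1], 1)
  # five restarts: third-ranked, against an explicit sort oracle
  p5 <- lapply(1:5, mk)
  scores <- c(0.4, 0.1, 0.9, 0.3, 0.2)
  want <- which(scores == sort(scores)[3])
  expect_equal(tauMap(selectMedianPrior(p5, scores))[1], want)
  expect_warning(selectMedianPrior(p5[1:2], c(0.5, 0.1)), "fewer than 3")
})
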