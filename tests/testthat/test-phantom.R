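# Synthetic FLIM phantom generator.

test_that("scenes are piecewise with exactly the specified class lifetimes", {
  sp1 <- phantomSpec(c(32, 32),
                     classes = list(list(morphology = "background", tau = 3)),
                     absorbance = list(kind = "constant", amplitude = 0))
  sc1 <- generateScene(sp1)
  expect_true(all(tauMap(sc1$tau) == 3))
  sp2 <- phantomSpec(c(96, 96), seed = 4L)
  sc2 <- generateScene(sp2)
  expect_setequal(unique(as.vector(tauMap(sc2$tau))), c(2, 4))
  # determinism: identical scenes from identical seeds
  sc2b <- generateScene(sp2)
  expect_identical(tauMap(sc2$tau), tauMap(sc2b$tau))
  expect_identical(sc2$absorbance, sc2b$absorbance)
})

test_that("expected intensity follows absorbance x k_r x lifetime", {
  sp <- phantomSpec(c(128, 128), seed = 6L)
  sc <- generateScene(sp)
  ri <- renderIntensity(sc, sp)
  # proportionality at constant absorbance
  spc <- phantomSpec(c(64, 64),
                     classes = list(list(morphology = "background", tau = 2.5)),
                     absorbance = list(kind = "constant", amplitude = 0),
                     seed = 2L)
  scc <- generateScene(spc)
  ric <- renderIntensity(scc, spc)
  expect_true(all(ric$expected == ric$expected[1, 1]))
  # the expectation is proportional to absorbance x k_r x tau ...
  ratio <- ri$expected / (sc$absorbance * sc$kr * tauMap(sc$tau))
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-12)
  # ... so doubling absorbance at a doubled photon budget doubles it
  # (the budget normalization otherwise absorbs a global rescaling)
  sc2 <- sc; sc2$absorbance <- sc$absorbance * 2
  sp2 <- sp; sp2$photonsPerPixel <- 2 * sp$photonsPerPixel
  ri2 <- renderIntensity(sc2, sp2)
  expect_equal(ri2$expected, 2 * ri$expected, tolerance = 1e-12)
  # Poisson means agree with the expectation within 3 standard errors
  n <- length(ri$expected)
  se <- sqrt(sum(ri$expected)) / n
  expect_gte(n, 1e4)
  expect_lt(abs(mean(intensityValues(ri$intensity)) - mean(ri$expected)),
            3 * se)
  # mean matches the photon budget within 2%
  expect_lt(abs(mean(intensityValues(ri$intensity)) - sp$photonsPerPixel) /
              sp$photonsPerPixel, 0.02)
})

test_that("datacube decays have the right slope and conserve photons", {
  sp <- phantomSpec(c(64, 64),
                    classes = list(list(morphology = "background", tau = 2.5)),
                    absorbance = list(kind = "constant", amplitude = 0),
                    photonsPerPixel = 2e5, seed = 8L)
  sc <- generateScene(sp)
  ri <- renderIntensity(sc, sp)
  samp <- samplingSpec(8)
  cube <- renderDatacube(sc, ri$expected, sp, samp)
  # log-linear regression oracle on a huge-budget pixel
  h <- photonCounts(cube)[1, 1, ]
  use <- h > 50
  slope <- coef(lm(log(h[use]) ~ seq_along(h)[use]))[2]
  expect_lt(abs(-sp$binWidth / slope - 2.5) / 2.5, 0.01)
  # photon totals track the decimated expected intensity
  totals <- apply(photonCounts(cube), c(1, 2), sum)
  dec <- decimate(ri$expected, samp)
  expect_lt(max(abs(totals - dec) / dec), 0.05)
  expect_identical(photonCounts(renderDatacube(sc, ri$expected, sp, samp)),
                   photonCounts(cube))   # seed determinism
})

test_that("an IRF-convolved cube still fits back to the true lifetime", {
  sp <- phantomSpec(c(32, 32),
                    classes = list(list(morphology = "background", tau = 3)),
                    absorbance = list(kind = "constant", amplitude = 0),
                    photonsPerPixel = 5e4, irfWidth = 0.3, seed = 9L)
  sc <- generateScene(sp)
  ri <- renderIntensity(sc, sp)
  cube <- renderDatacube(sc, ri$expected, sp, samplingSpec(8))
  expect_equal(sum(instrumentResponse(cube)), 1, tolerance = 1e-12)
  fit <- fitImage(cube)
  expect_lt(abs(mean(tauMap(fit$lifetime)[validMask(fit$lifetime)]) - 3) / 3,
            0.02)
})

test_that("fixtures are deterministic bundles with consistent geometry", {
  fx <- makeFixture("two_class_8x", seed = 7)
  expect_identical(dim(fx$intensityHR), c(160L, 160L))
  expect_identical(dim(fx$tauLR), c(20L, 20L))
  expect_identical(dim(fx$cube)[1:2], c(20L, 20L))
  expect_identical(tauMap(fx$tauLR), decimate(tauMap(fx$tauGT), fx$sampling))
  fx2 <- makeFixture("two_class_8x", seed = 7)
  expect_identical(photonCounts(fx$cube), photonCounts(fx2$cube))
  expect_identical(intensityValues(fx$intensityHR),
                   intensityValues(fx2$intensityHR))
  # lp_exact really is affine in intensity
  lx <- makeFixture("lp_exact", seed = 5)
  I <- intensityValues(lx$intensityHR)
  fitl <- lm(as.vector(tauMap(lx$tauGT)) ~ as.vector(I))
  r2 <- suppressWarnings(summary(fitl)$r.squared)  # "essentially perfect fit"
  expect_gt(r2, 1 - 1e-12)
})
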