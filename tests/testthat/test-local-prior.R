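# Sliding-window local prior.

test_that("window functions interpolate, clamp and average duplicates", {
  f <- fitWindowFunction(c(1, 3), c(2, 4))
  expect_equal(f(2), 3)                      # midpoint of the line
  expect_equal(f(0), 2)                      # clamped extrapolation
  expect_equal(f(10), 4)
  fd <- fitWindowFunction(c(1, 1, 2), c(2, 3, 5))
  expect_equal(fd(1), 2.5)                   # duplicates averaged
  expect_equal(fd(1.5), 3.75)
  # degenerate window: constant map at the mean lifetime
  fc <- fitWindowFunction(c(2, 2, 2), c(1, 2, 3))
  expect_true(attr(fc, "degenerate"))
  expect_equal(fc(c(0, 5)), c(2, 2))
})

test_that("all window-function kinds reproduce their knots", {
  x <- c(1, 2, 4, 7); y <- c(2, 2.5, 4, 3)
  for (kind in c("linear_interp", "nearest", "cubic_spline", "rbf_gp")) {
    f <- fitWindowFunction(x, y, kind)
    expect_equal(f(x), y, tolerance = 1e-4, label = kind)
  }
  # nearest: ties resolved toward the lower intensity
  fn <- fitWindowFunction(c(1, 3), c(10, 20), "nearest")
  expect_equal(fn(2), 10)
})

test_that("window fits are invariant to pair order and range-bounded", {
  set.seed(14)
  for (kind in c("linear_interp", "nearest")) {
    x <- runif(9, 0, 10); y <- runif(9, 1, 5)
    ord <- sample(9)
    f1 <- fitWindowFunction(x, y, kind)
    f2 <- fitWindowFunction(x[ord], y[ord], kind)
    q <- seq(-2, 12, length.out = 50)
    expect_equal(f1(q), f2(q))
    expect_true(all(f1(q) >= min(y) - 1e-12 & f1(q) <= max(y) + 1e-12))
  }
})

test_that("an affine intensity-lifetime relation is recovered exactly", {
  # tau = 0.5 I + 1 globally; every block's intensities lie within the
  # window's sampled range away from the image border
  set.seed(15)
  sp <- samplingSpec(2)
  I <- matrix(runif(24 * 24, 10, 20), 24, 24)
  tauHR <- 0.5 * I + 1
  tauLR <- decimate(lifetimeImage(tauHR), sp)
  prior <- buildLocalPrior(tauLR, intensityImage(I), sp, localPriorConfig())
  inRange <- abs(tauMap(prior) - tauHR) < 1e-9
  expect_gt(mean(inRange), 0.95)
  # constant lifetime input gives a constant prior regardless of intensity
  cpr <- buildLocalPrior(lifetimeImage(matrix(2.5, 12, 12)),
                         intensityImage(I), sp)
  expect_true(all(tauMap(cpr) == 2.5))
  expect_true(all(validMask(cpr)))
})

test_that("per-block predictions match a brute-force window oracle", {
  set.seed(16)
  m <- 5; lambda <- 2L
  sp <- samplingSpec(lambda)
  I <- matrix(runif(m * lambda * m * lambda, 0, 100), m * lambda)
  tl <- matrix(runif(m * m, 1, 5), m, m)
  prior <- buildLocalPrior(lifetimeImage(tl), intensityImage(I), sp,
                           localPriorConfig(window = 3))
  Is <- I[seq(1, m * lambda, by = lambda), seq(1, m * lambda, by = lambda)]
  for (i in seq_len(m)) for (j in seq_len(m)) {
    # clamped 3x3 sample window centered on (i, j)
    r0 <- min(max(1, i - 1), m - 2); c0 <- min(max(1, j - 1), m - 2)
    xs <- as.vector(Is[r0:(r0 + 2), c0:(c0 + 2)])
    ys <- as.vector(tl[r0:(r0 + 2), c0:(c0 + 2)])
    ux <- sort(unique(xs))
    uy <- vapply(ux, function(v) mean(ys[xs == v]), numeric(1))
    block <- I[(lambda * (i - 1) + 1):(lambda * i),
               (lambda * (j - 1) + 1):(lambda * j)]
    want <- matrix(approx(ux, uy, xout = pmin(pmax(block, min(ux)), max(ux)),
                          rule = 2)$y, lambda, lambda)
    expect_equal(tauMap(prior)[(lambda * (i - 1) + 1):(lambda * i),
                               (lambda * (j - 1) + 1):(lambda * j)],
                 want, tolerance = 1e-12)
  }
})

test_that("predicted blocks tile the grid and invalid windows are masked", {
  set.seed(17)
  sp <- samplingSpec(4)
  tl <- matrix(runif(36, 2, 4), 6, 6)
  valid <- matrix(TRUE, 6, 6)
  valid[1:6, 1:3] <- FALSE                  # left half has no usable samples
  I <- intensityImage(matrix(runif(576, 0, 10), 24, 24))
  prior <- buildLocalPrior(lifetimeImage(tl, valid), I, sp,
                           localPriorConfig(window = 3))
  # windows covering only invalid samples yield invalid blocks
  expect_false(any(validMask(prior)[, 1:4]))
  # every remaining pixel received exactly one prediction
  expect_true(all(validMask(prior)[, 13:24]))
})
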