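# Gradient operator, soft threshold, FISTA and the ADMM solver.

test_that("gradD computes forward differences with Neumann boundary", {
  expect_true(all(unlist(gradD(matrix(5, 6, 6))) == 0))
  ramp <- matrix(rep(2 * (1:6), times = 4), 6, 4)   # row-ramp, slope 2
  g <- gradD(ramp)
  expect_true(all(g$dr[1:5, ] == 2))
  expect_true(all(g$dr[6, ] == 0))
  expect_true(all(g$dc == 0))
})

test_that("divAdjoint is the exact adjoint of gradD", {
  set.seed(31)
  for (rep in 1:100) {
    x <- matrix(rnorm(36), 6, 6)
    y <- list(dr = matrix(rnorm(36), 6, 6), dc = matrix(rnorm(36), 6, 6))
    y$dr[6, ] <- 0; y$dc[, 6] <- 0          # range of D
    lhs <- sum(gradD(x)$dr * y$dr) + sum(gradD(x)$dc * y$dc)
    expect_lt(abs(lhs - sum(x * divAdjoint(y))), 1e-12)
  }
  # and D matches its dense-matrix form
  dm <- denseGradMatrices(5, 7)
  x <- matrix(rnorm(35), 5, 7)
  g <- gradD(x)
  expect_equal(as.vector(g$dr), as.vector(dm$Dr %*% as.vector(x)))
  expect_equal(as.vector(g$dc), as.vector(dm$Dc %*% as.vector(x)))
})

test_that("softThreshold matches its definition and a grid-search oracle", {
  expect_equal(softThreshold(3, 1), 2)
  expect_equal(softThreshold(-0.5, 1), 0)
  expect_equal(softThreshold(-3, 1), -2)
  x <- rnorm(20)
  expect_equal(softThreshold(x, 0), x)
  expect_error(softThreshold(x, -1), ">= 0")
  # z-update: argmin_z alpha|z| + y (g - z) + rho/2 (g - z)^2
  set.seed(32)
  for (rep in 1:20) {
    alpha <- runif(1, 0, 2); rho <- runif(1, 0.5, 2)
    g <- runif(1, -3, 3); y <- runif(1, -2, 2)
    zGrid <- seq(-6, 6, by = 1e-4)
    obj <- alpha * abs(zGrid) + y * (g - zGrid) + rho / 2 * (g - zGrid)^2
    zStar <- zGrid[which.min(obj)]
    expect_equal(softThreshold(g + y / rho, alpha / rho), zStar,
                 tolerance = 1e-3)
  }
})

test_that("evaluateCost matches an independent term-by-term summation", {
  set.seed(33)
  sp <- samplingSpec(2)
  tl <- lifetimeImage(matrix(runif(16, 2, 4), 4, 4))
  lp <- priorImage(matrix(runif(64, 2, 4), 8, 8),
                   matrix(runif(64) > 0.3, 8, 8))
  gp <- priorImage(matrix(runif(64, 2, 4), 8, 8),
                   matrix(runif(64) > 0.3, 8, 8))
  x <- matrix(runif(64, 1, 5), 8, 8)
  cfg <- admmConfig(gamma = 0.1, beta = 0.02, alpha = 0.05)
  expect_equal(evaluateCost(x, tl, lp, gp, sp, cfg),
               directCost(x, tl, lp, gp, sp, 0.1, 0.02, 0.05),
               tolerance = 1e-12)
  # embedding of tau_LR with matching priors leaves only the TV term
  xe <- embedAdjoint(tl, sp, c(8, 8))
  pe <- priorImage(xe)
  g <- gradD(xe)
  expect_equal(evaluateCost(xe, tl, pe, pe, sp, cfg),
               0.05 * (sum(abs(g$dr)) + sum(abs(g$dc))))
  # all-constant problem has zero cost
  cc <- matrix(3, 8, 8)
  expect_equal(evaluateCost(cc, lifetimeImage(matrix(3, 4, 4)),
                            priorImage(cc), priorImage(cc), sp, cfg), 0)
})

test_that("FISTA solves the quadratic subproblem to the dense optimum", {
  set.seed(34)
  M <- 8; sp <- samplingSpec(2)
  tl <- lifetimeImage(matrix(runif(16, 2, 4), 4, 4))
  lp <- priorImage(matrix(runif(64, 2, 4), M, M))
  gp <- priorImage(matrix(runif(64, 2, 4), M, M))
  gamma <- 0.1; beta <- 0.02; rho <- 1
  z0 <- gradD(matrix(runif(64, 2, 4), M, M))
  y0 <- list(dr = matrix(0, M, M), dc = matrix(0, M, M))
  A <- denseDecimationMatrix(M, M, sp)
  dm <- denseGradMatrices(M, M)
  H <- 2 * crossprod(A) + 2 * (gamma + beta) * diag(M * M) +
    rho * (crossprod(dm$Dr) + crossprod(dm$Dc))
  b <- 2 * crossprod(A, as.vector(tauMap(tl))) +
    2 * gamma * as.vector(tauMap(lp)) + 2 * beta * as.vector(tauMap(gp)) +
    rho * (crossprod(dm$Dr, as.vector(z0$dr)) +
           crossprod(dm$Dc, as.vector(z0$dc)))
  xStar <- solve(H, b)                      # interior optimum (all positive)
  expect_true(all(xStar > 0))
  cfg <- admmConfig(gamma = gamma, beta = beta, alpha = 0, rho = rho,
                    fistaIters = 400L)
  xf <- fistaPrimalUpdate(matrix(3, M, M), z0, y0, tl, lp, gp, sp, cfg)
  expect_lt(max(abs(as.vector(xf) - xStar)) / max(abs(xStar)), 1e-4)
  # stationary start: a constant problem stays constant
  cl <- lifetimeImage(matrix(2, 4, 4))
  cc <- matrix(2, M, M)
  cfg0 <- admmConfig(gamma = 0, beta = 0, alpha = 0, rho = 1e-9,
                     fistaIters = 50L)
  zc <- gradD(cc)
  out <- fistaPrimalUpdate(cc, zc, y0, cl, NULL, NULL, sp, cfg0)
  expect_equal(out, cc, tolerance = 1e-9)
})

test_that("ADMM minimizes: monotone cost, shrinking residual, tau >= 0", {
  pb <- makeStepProblem()
  rec <- admmReconstruct(pb$fx$tauLR, pb$lp, NULL, pb$fx$sampling, admmConfig())
  d <- rec$diagnostics
  n <- length(d$cost)
  expect_true(all(diff(d$cost[3:n]) <= 1e-6 * abs(d$cost[3:(n - 1)])))
  expect_gt(d$primalResidual[1] / d$primalResidual[n], 10)
  expect_gte(min(tauMap(rec$tauHR)), 0)
  # the step edge survives within one pixel: no value crosses the midline
  # further than one column from the true edge
  est <- tauMap(rec$tauHR)
  expect_true(all(est[, 1:31] < 3))
  expect_true(all(est[, 34:64] > 3))
})

test_that("constant problems are reproduced and fidelity is exact", {
  sp <- samplingSpec(4)
  cl <- lifetimeImage(matrix(2.7, 4, 4))
  cp <- priorImage(matrix(2.7, 16, 16))
  rec <- admmReconstruct(cl, cp, cp, sp, admmConfig())
  expect_equal(tauMap(rec$tauHR), matrix(2.7, 16, 16), tolerance = 1e-9)
  expect_lt(tail(rec$diagnostics$cost, 1), 1e-12)
  # gamma = beta = alpha = 0: sampled positions reproduce tau_LR
  set.seed(36)
  tl <- lifetimeImage(matrix(runif(16, 2, 4), 4, 4))
  r0 <- admmReconstruct(tl, NULL, NULL, sp,
                        admmConfig(gamma = 0, beta = 0, alpha = 0))
  expect_lt(max(abs(decimate(tauMap(r0$tauHR), sp) - tauMap(tl))), 1e-6)
})

test_that("TV-only inpainting matches a long-run convex-solver oracle", {
  set.seed(37)
  sp <- samplingSpec(4)
  tl <- lifetimeImage(matrix(runif(9, 2, 4), 3, 3))
  lp <- priorImage(matrix(runif(144, 2, 4), 12, 12))
  gp <- priorImage(matrix(runif(144, 2, 4), 12, 12))
  cfg <- admmConfig(gamma = 0.1, beta = 0.5, alpha = 0.02)
  rec <- admmReconstruct(tl, lp, gp, sp, cfg)
  cAdmm <- tail(rec$diagnostics$cost, 1)
  cOracle <- subgradientOracle(tl, lp, gp, sp, cfg, iters = 20000)
  expect_lt(cAdmm, cOracle * 1.01)
})
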