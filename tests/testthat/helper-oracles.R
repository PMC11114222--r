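# Shared independent oracles and small fixtures for the test suite.

# Dense-matrix representations of the decimation and gradient operators,
# built column by column from the identity (independent of the operator
# implementations' internals beyond calling them on basis vectors would
# not be independent -- so these build the matrices from first principles).
denseDecimationMatrix <- function(M, N, spec) {
  lambda <- upsamplingFactor(spec); off <- sampleOffset(spec)
  m <- M %/% lambda; n <- N %/% lambda
  A <- matrix(0, m * n, M * N)
  for (j in seq_len(n)) for (i in seq_len(m)) {
    hr <- lambda * (i - 1) + off[1] + 1
    hc <- lambda * (j - 1) + off[2] + 1
    A[i + m * (j - 1), hr + M * (hc - 1)] <- 1
  }
  A
}

denseGradMatrices <- function(M, N) {
  n <- M * N
  Dr <- matrix(0, n, n); Dc <- matrix(0, n, n)
  for (cc in seq_len(N)) for (r in seq_len(M)) {
    k <- r + M * (cc - 1)
    if (r < M) { Dr[k, k] <- -1; Dr[k, k + 1] <- 1 }
    if (cc < N) { Dc[k, k] <- -1; Dc[k, k + M] <- 1 }
  }
  list(Dr = Dr, Dc = Dc)
}

# Grid-search least-squares mono-exponential fit: for each tau on a dense
# grid, amplitude and background follow from a 2x2 linear solve; the
# returned tau minimizes the residual sum of squares.  Independent of the
# package's Levenberg-Marquardt path.
gridSearchDecayFit <- function(h, binWidth, tauGrid = seq(0.5, 8, by = 0.005)) {
  kp <- which.max(h)
  h <- h[kp:length(h)]
  tk <- (seq_along(h) - 1) * binWidth
  best <- c(tau = NA_real_, rss = Inf)
  for (tau in tauGrid) {
    e <- exp(-tk / tau)
    X <- cbind(e, 1)
    cf <- tryCatch(solve(crossprod(X), crossprod(X, h)), error = function(.) NULL)
    if (is.null(cf)) next
    if (any(cf < 0)) {
      # constrained optimum sits on a boundary: refit each single-term model
      a1 <- max(sum(e * h) / sum(e * e), 0)            # b = 0
      b1 <- max(mean(h), 0)                            # a = 0
      cf <- if (sum((a1 * e - h)^2) <= sum((b1 - h)^2))
        c(a1, 0) else c(0, b1)
    }
    rss <- sum((X %*% cf - h)^2)
    if (rss < best["rss"]) best <- c(tau = tau, rss = rss)
  }
  best
}

# Full nonsmooth reconstruction cost, recomputed term by term without
# evaluateCost (summation oracle).
directCost <- function(x, tauLR, lp, gp, spec, gamma, beta, alpha) {
  lam <- upsamplingFactor(spec); off <- sampleOffset(spec)
  tl <- tauMap(tauLR); vl <- validMask(tauLR)
  s <- 0
  for (j in seq_len(ncol(tl))) for (i in seq_len(nrow(tl))) {
    if (!vl[i, j]) next
    s <- s + (x[lam * (i - 1) + off[1] + 1, lam * (j - 1) + off[2] + 1] - tl[i, j])^2
  }
  pterm <- function(pr, w) {
    if (is.null(pr)) return(0)
    w * sum(((x - tauMap(pr)) * (validMask(pr) * 1))^2)
  }
  tv <- 0
  for (j in seq_len(ncol(x))) for (i in seq_len(nrow(x) - 1))
    tv <- tv + abs(x[i + 1, j] - x[i, j])
  for (j in seq_len(ncol(x) - 1)) for (i in seq_len(nrow(x)))
    tv <- tv + abs(x[i, j + 1] - x[i, j])
  s + pterm(lp, gamma) + pterm(gp, beta) + alpha * tv
}

# Long-run projected subgradient descent on the nonsmooth cost; generic
# convex-solver oracle for small instances.
subgradientOracle <- function(tauLR, lp, gp, spec, cfg, iters = 30000,
                              step0 = 0.05) {
  M <- nrow(tauMap(tauLR)) * upsamplingFactor(spec)
  N <- ncol(tauMap(tauLR)) * upsamplingFactor(spec)
  gamma <- cfg@gamma
  beta <- resolveBeta(cfg@beta, upsamplingFactor(spec))
  tl <- tauMap(tauLR)
  alpha <- if (is.na(cfg@alpha)) 0.01 * (max(tl) - min(tl)) else cfg@alpha
  cost <- function(x) evaluateCost(x, tauLR, lp, gp, spec, cfg)
  x <- matrix(mean(tl), M, N)
  best <- cost(x)
  for (it in seq_len(iters)) {
    r <- decimate(x, spec) - tl
    g <- gradD(x)
    sg <- 2 * embedAdjoint(r, spec, c(M, N)) +
      2 * gamma * (validMask(lp) * 1) * (x - tauMap(lp)) +
      2 * beta * (validMask(gp) * 1) * (x - tauMap(gp)) +
      alpha * divAdjoint(list(dr = sign(g$dr), dc = sign(g$dc)))
    x <- pmax(x - (step0 / sqrt(it)) * sg, 0)
    cc <- cost(x)
    if (cc < best) best <- cc
  }
  best
}

# Small ridge-free phantom pair used by several solver tests
makeStepProblem <- function(seed = 3) {
  fx <- makeFixture("step_edge", seed = seed)
  lp <- buildLocalPrior(fx$tauLR, fx$intensityHR, fx$sampling)
  list(fx = fx, lp = lp)
}
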