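# Prior-augmented, anisotropic-TV regularized inverse retrieval.
#
# Cost:  ||A tau - tau_LR||_2^2 + gamma ||(tau - tau_LP) . m_LP||_2^2
#        + beta ||(tau - tau_GP) . m_GP||_2^2 + alpha ||D tau||_1,
#        subject to tau >= 0,
# split as D tau - z = 0 and solved by ADMM: the tau update is an
# accelerated projected-gradient (monotone FISTA) minimization of the
# smooth part, the z update is the elementwise soft threshold, and the dual
# update is a gradient ascent step on the scaled multiplier.

#' Forward-difference image gradient (operator D)
#'
#' Anisotropic finite differences along rows (channel 1) and columns
#' (channel 2) with Neumann boundary (zero trailing difference), so
#' \code{\link{divAdjoint}} is the exact adjoint.
#'
#' @param x numeric matrix.
#' @return list with matrices \code{dr} and \code{dc}.
#' @export
gradD <- function(x) {
  M <- nrow(x); N <- ncol(x)
  dr <- rbind(x[-1, , drop = FALSE] - x[-M, , drop = FALSE], rep(0, N))
  dc <- cbind(x[, -1, drop = FALSE] - x[, -N, drop = FALSE], rep(0, M))
  list(dr = dr, dc = dc)
}

#' Adjoint of the forward-difference gradient (D^T)
#'
#' @param g list with matrices \code{dr}, \code{dc} as from
#'   \code{\link{gradD}} (the trailing row/column entries are ignored, as D
#'   never produces them).
#' @return numeric matrix such that \code{<gradD(x), g> == <x, divAdjoint(g)>}.
#' @export
divAdjoint <- function(g) {
  dr <- g$dr; dc <- g$dc
  M <- nrow(dr); N <- ncol(dr)
  out <- matrix(0, M, N)
  # row differences: contributes -dr[i,] at i, +dr[i-1,] at i (i < M rows used)
  out[1, ] <- -dr[1, ]
  if (M > 2) out[2:(M - 1), ] <- dr[1:(M - 2), , drop = FALSE] -
                                  dr[2:(M - 1), , drop = FALSE]
  out[M, ] <- out[M, ] + dr[M - 1, ]
  out[, 1] <- out[, 1] - dc[, 1]
  if (N > 2) out[, 2:(N - 1)] <- out[, 2:(N - 1)] +
    dc[, 1:(N - 2), drop = FALSE] - dc[, 2:(N - 1), drop = FALSE]
  out[, N] <- out[, N] + dc[, N - 1]
  out
}

#' Elementwise soft-threshold operator
#'
#' \code{sign(v) * max(|v| - t, 0)}: the closed-form solution of the
#' l1-penalized quadratic z-update.
#'
#' @param v numeric array.
#' @param t threshold, \code{t >= 0}.
#' @return array like \code{v}.
#' @export
softThreshold <- function(v, t) {
  if (t < 0) stop("threshold must be >= 0")
  sign(v) * pmax(abs(v) - t, 0)
}

# resolve masks/arrays once; shared by the solver and the cost
.admmProblem <- function(tauLR, lp, gp, spec, cfg) {
  stopifnot(is(tauLR, "LifetimeImage"), is(spec, "SamplingSpec"),
            is(cfg, "ADMMConfig"))
  mLow <- tauLR@valid * 1
  yLow <- tauLR@tau * mLow
  M <- nrow(yLow) * spec@factor; N <- ncol(yLow) * spec@factor
  asPrior <- function(pr) {
    if (is.null(pr)) return(list(tau = matrix(0, M, N), m = matrix(0, M, N)))
    stopifnot(is(pr, "PriorImage"))
    if (!identical(dim(pr@tau), c(M, N))) stop("prior shape mismatch")
    list(tau = pr@tau, m = pr@valid * 1)
  }
  tv <- tauLR@tau[tauLR@valid]
  dynRange <- if (length(tv)) max(tv) - min(tv) else 0
  list(yLow = yLow, mLow = mLow, M = M, N = N,
       lp = asPrior(lp), gp = asPrior(gp),
       gamma = cfg@gamma,
       beta = resolveBeta(cfg@beta, spec@factor),
       alpha = if (is.na(cfg@alpha)) 0.01 * dynRange else cfg@alpha,
       rho = cfg@rho, spec = spec)
}

#' Evaluate the reconstruction cost
#'
#' The full objective: decimation data fidelity, masked local- and
#' global-prior fidelities, and the anisotropic-TV l1 penalty.
#'
#' @param tauHat numeric matrix (candidate high-resolution lifetimes).
#' @param tauLR low-resolution \code{LifetimeImage}.
#' @param lp,gp \code{PriorImage} objects (or NULL to drop the term).
#' @param spec a \code{SamplingSpec}.
#' @param cfg an \code{ADMMConfig}.
#' @return scalar cost.
#' @export
evaluateCost <- function(tauHat, tauLR, lp, gp, spec, cfg = admmConfig()) {
  pb <- .admmProblem(tauLR, lp, gp, spec, cfg)
  .costEq(tauHat, pb)
}

.costEq <- function(x, pb) {
  r <- (.decimateMatrix(x, pb$spec) - pb$yLow) * pb$mLow
  g <- gradD(x)
  sum(r^2) +
    pb$gamma * sum((pb$lp$m * (x - pb$lp$tau))^2) +
    pb$beta  * sum((pb$gp$m * (x - pb$gp$tau))^2) +
    pb$alpha * (sum(abs(g$dr)) + sum(abs(g$dc)))
}

# gradient of the smooth augmented-Lagrangian part in tau
.smoothGrad <- function(x, z, y, pb) {
  r <- (.decimateMatrix(x, pb$spec) - pb$yLow) * pb$mLow
  g <- gradD(x)
  gr <- list(dr = y$dr + pb$rho * (g$dr - z$dr),
             dc = y$dc + pb$rho * (g$dc - z$dc))
  2 * embedAdjoint(r, pb$spec, c(pb$M, pb$N)) +
    2 * pb$gamma * pb$lp$m * (x - pb$lp$tau) +
    2 * pb$beta * pb$gp$m * (x - pb$gp$tau) +
    divAdjoint(gr)
}

.smoothObj <- function(x, z, y, pb) {
  r <- (.decimateMatrix(x, pb$spec) - pb$yLow) * pb$mLow
  g <- gradD(x)
  sum(r^2) +
    pb$gamma * sum((pb$lp$m * (x - pb$lp$tau))^2) +
    pb$beta * sum((pb$gp$m * (x - pb$gp$tau))^2) +
    sum(y$dr * (g$dr - z$dr)) + sum(y$dc * (g$dc - z$dc)) +
    pb$rho / 2 * (sum((g$dr - z$dr)^2) + sum((g$dc - z$dc)^2))
}

# largest eigenvalue of the quadratic-form Hessian operator, by power
# iteration (deterministic start)
.powerIterL <- function(pb, iters = 30L) {
  v <- matrix(sin(seq_len(pb$M * pb$N)), pb$M, pb$N)
  v <- v / sqrt(sum(v^2))
  Hop <- function(v) {
    g <- gradD(v)
    2 * embedAdjoint(.decimateMatrix(v, pb$spec) * pb$mLow, pb$spec,
                     c(pb$M, pb$N)) +
      2 * pb$gamma * pb$lp$m * v + 2 * pb$beta * pb$gp$m * v +
      pb$rho * divAdjoint(g)
  }
  lam <- 1
  for (k in seq_len(iters)) {
    w <- Hop(v)
    lam <- sqrt(sum(w^2))
    if (lam == 0) return(1)
    v <- w / lam
  }
  lam
}

# Monotone FISTA with non-negativity projection for the tau update
.fistaUpdate <- function(x0, z, y, pb, iters, L) {
  step <- 1 / L
  x <- x0; xPrev <- x0; tAcc <- 1
  fBest <- .smoothObj(x0, z, y, pb)
  for (k in seq_len(iters)) {
    tNext <- (1 + sqrt(1 + 4 * tAcc^2)) / 2
    v <- x + ((tAcc - 1) / tNext) * (x - xPrev)
    cand <- pmax(v - step * .smoothGrad(v, z, y, pb), 0)
    fCand <- .smoothObj(cand, z, y, pb)
    if (!is.finite(fCand))
      stop(sprintf("FISTA diverged at inner iteration %d", k))
    xPrev <- x
    if (fCand <= fBest) {                  # monotone acceptance
      x <- cand; fBest <- fCand
    } else {
      cand2 <- pmax(x - step * .smoothGrad(x, z, y, pb), 0)
      f2 <- .smoothObj(cand2, z, y, pb)
      if (f2 <= fBest) { x <- cand2; fBest <- f2 }
      tNext <- 1                           # restart momentum
    }
    tAcc <- tNext
  }
  x
}

#' One accelerated primal update of the high-resolution lifetime
#'
#' Runs the configured number of monotone-FISTA iterations (projection onto
#' the non-negative orthant; step size from a power-iteration estimate of
#' the Lipschitz constant) on the smooth part of the augmented Lagrangian,
#' holding the splitting variable \code{z} and dual \code{y} fixed.
#'
#' @param tauHat current iterate (matrix \code{M x N}).
#' @param z,y lists with matrices \code{dr}, \code{dc}.
#' @param tauLR low-resolution \code{LifetimeImage}.
#' @param lp,gp \code{PriorImage} priors (or NULL).
#' @param spec a \code{SamplingSpec}.
#' @param cfg an \code{ADMMConfig}.
#' @return updated matrix \code{M x N} (non-negative).
#' @export
fistaPrimalUpdate <- function(tauHat, z, y, tauLR, lp, gp, spec,
                              cfg = admmConfig()) {
  pb <- .admmProblem(tauLR, lp, gp, spec, cfg)
  L <- 1.02 * .powerIterL(pb)
  .fistaUpdate(tauHat, z, y, pb, cfg@fistaIters, L)
}

#' Reconstruct the high-resolution lifetime image by ADMM
#'
#' Initializes at the bilinear upsampling of the measured low-resolution
#' lifetimes and alternates: (i) a monotone-FISTA primal update of the
#' lifetime image, (ii) the closed-form soft-threshold update
#' \code{z = soft(D tau + y/rho, alpha/rho)} of the gradient-domain
#' splitting variable, and (iii) the dual ascent
#' \code{y = y + rho (D tau - z)}.  Invalid prior pixels exert no pull
#' (their fidelity terms are masked), and invalid low-resolution samples
#' are excluded from the data-fidelity term.
#'
#' @param tauLR low-resolution \code{LifetimeImage}.
#' @param lp local-prior \code{PriorImage} (or NULL to drop the term).
#' @param gp global-prior \code{PriorImage} (or NULL).
#' @param spec a \code{SamplingSpec}.
#' @param cfg an \code{ADMMConfig}.
#' @return list with \code{tauHR} (a \code{LifetimeImage}, all valid) and
#'   \code{diagnostics}: per-outer-iteration \code{cost} (the full
#'   objective), \code{primalResidual} (\code{||D tau - z||_2}), plus the
#'   resolved \code{alpha}, \code{beta} and step bound \code{L}.
#' @export
admmReconstruct <- function(tauLR, lp, gp, spec, cfg = admmConfig()) {
  pb <- .admmProblem(tauLR, lp, gp, spec, cfg)
  L <- 1.02 * .powerIterL(pb)
  x <- pmax(tauMap(bilinearBaseline(tauLR, spec)), 0)
  z <- gradD(x)
  y <- list(dr = z$dr * 0, dc = z$dc * 0)
  cost <- numeric(cfg@admmIters)
  pres <- numeric(cfg@admmIters)
  for (it in seq_len(cfg@admmIters)) {
    x <- .fistaUpdate(x, z, y, pb, cfg@fistaIters, L)
    g <- gradD(x)
    thr <- if (pb$rho > 0) pb$alpha / pb$rho else 0
    z <- list(dr = softThreshold(g$dr + y$dr / pb$rho, thr),
              dc = softThreshold(g$dc + y$dc / pb$rho, thr))
    y <- list(dr = y$dr + pb$rho * (g$dr - z$dr),
              dc = y$dc + pb$rho * (g$dc - z$dc))
    cost[it] <- .costEq(x, pb)
    pres[it] <- sqrt(sum((g$dr - z$dr)^2) + sum((g$dc - z$dc)^2))
  }
  list(tauHR = lifetimeImage(x),
       diagnostics = list(cost = cost, primalResidual = pres,
                          alpha = pb$alpha, beta = pb$beta,
                          gamma = pb$gamma, rho = pb$rho, L = L))
}
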