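# Minimal convolutional patch regressor: 3 valid-mode 3x3 conv layers
# (channels 2 -> 16 -> 32 -> 64, ReLU) followed by 3 fully connected layers
# (128 -> 32 -> 1, linear output), trained with Adam on mean absolute error.
#
# Implemented directly on BLAS matrix products via im2col.  Activations for
# a batch of B patches are stored as a B x (s^2 * c) matrix with element
# layout pos + s^2*(ch-1), pos column-major within a channel.  All routines
# are deterministic given the R RNG state and a single-threaded BLAS.

.CONV_CHANNELS <- c(16L, 32L, 64L)
.FC_WIDTHS <- c(128L, 32L, 1L)

# im2col index matrix for a valid 3x3 convolution on an s x s, cin-channel
# input: idx[q, k] is the input column holding kernel element k at output
# position q (k ordered dr-fastest, then dc, then channel).
.im2colIndex <- function(s, cin) {
  so <- s - 2L
  q <- seq_len(so * so)
  or <- (q - 1L) %% so + 1L
  oc <- (q - 1L) %/% so + 1L
  idx <- matrix(0L, so * so, 9L * cin)
  for (ch in seq_len(cin)) for (dc in 0:2) for (dr in 0:2) {
    k <- dr + 1L + 3L * dc + 9L * (ch - 1L)
    idx[, k] <- (or + dr) + s * (oc + dc - 1L) + s * s * (ch - 1L)
  }
  idx
}

# sparse gather matrix: Xcol columns (k-major, position fastest) from the
# flat activation layout; its transpose scatter-adds gradients back
.im2colScatter <- function(idx, s, cin) {
  Matrix::sparseMatrix(i = seq_len(length(idx)), j = as.vector(idx), x = 1,
                       dims = c(length(idx), s * s * cin))
}

# He-scaled Gaussian init; uses the current RNG state
.nnInit <- function(p, cin = 2L, labelMean = 0) {
  sizes <- c(p, p - 2L, p - 4L, p - 6L)
  if (sizes[4] < 1L) stop("patch too small for three 3x3 conv layers")
  chans <- c(cin, .CONV_CHANNELS)
  idx <- lapply(1:3, function(l) .im2colIndex(sizes[l], chans[l]))
  net <- list(params = list(), arch = list(
    p = p, cin = cin, sizes = sizes, chans = chans, idx = idx,
    scat = lapply(1:3, function(l) .im2colScatter(idx[[l]], sizes[l], chans[l])),
    flat = sizes[4]^2 * chans[4], fc = .FC_WIDTHS))
  for (l in 1:3) {
    fanIn <- 9L * chans[l]
    net$params[[paste0("W", l)]] <-
      matrix(stats::rnorm(fanIn * chans[l + 1], 0, sqrt(2 / fanIn)),
             fanIn, chans[l + 1])
    net$params[[paste0("b", l)]] <- numeric(chans[l + 1])
  }
  fcIn <- c(net$arch$flat, .FC_WIDTHS[1], .FC_WIDTHS[2])
  for (l in 1:3) {
    fanIn <- fcIn[l]
    net$params[[paste0("W", l + 3L)]] <-
      matrix(stats::rnorm(fanIn * .FC_WIDTHS[l], 0, sqrt(2 / fanIn)),
             fanIn, .FC_WIDTHS[l])
    net$params[[paste0("b", l + 3L)]] <- numeric(.FC_WIDTHS[l])
  }
  # start the output at the mean label so early epochs fit structure, not scale
  net$params$b6 <- labelMean
  net
}

.convForward <- function(A, W, b, idx, B) {
  P <- nrow(idx)
  Xcol <- A[, as.vector(idx), drop = FALSE]
  dim(Xcol) <- c(B * P, ncol(idx))
  Z <- Xcol %*% W
  Z <- Z + rep(b, each = nrow(Z))
  A1 <- Z * (Z > 0)
  dim(A1) <- c(B, P * ncol(W))
  list(A = A1, Xcol = Xcol, mask = Z > 0)
}

.nnForward <- function(net, X, keepCache = FALSE) {
  arch <- net$arch; pr <- net$params
  B <- nrow(X)
  cache <- list(A0 = X)
  A <- X
  for (l in 1:3) {
    cv <- .convForward(A, pr[[paste0("W", l)]], pr[[paste0("b", l)]],
                       arch$idx[[l]], B)
    A <- cv$A
    if (keepCache) {
      cache[[paste0("Xcol", l)]] <- cv$Xcol
      cache[[paste0("mask", l)]] <- cv$mask
    }
  }
  A3 <- A                                  # B x flat
  Z4 <- A3 %*% pr$W4; Z4 <- Z4 + rep(pr$b4, each = B)
  A4 <- Z4 * (Z4 > 0)
  Z5 <- A4 %*% pr$W5; Z5 <- Z5 + rep(pr$b5, each = B)
  A5 <- Z5 * (Z5 > 0)
  pred <- as.vector(A5 %*% pr$W6 + pr$b6)
  if (keepCache) {
    cache$A3 <- A3; cache$A4 <- A4; cache$A5 <- A5
    cache$m4 <- Z4 > 0; cache$m5 <- Z5 > 0
  }
  list(pred = pred, cache = cache)
}

.convBackward <- function(dA, W, idx, scat, Xcol, mask, B) {
  P <- nrow(idx); cout <- ncol(W)
  dZ <- dA
  dim(dZ) <- c(B * P, cout)
  dZ <- dZ * mask
  grads <- list(dW = crossprod(Xcol, dZ), db = colSums(dZ))
  dXcol <- tcrossprod(dZ, W)               # (B*P) x 9cin
  dim(dXcol) <- c(B, P * ncol(idx))        # columns k-major, position fastest
  grads$dA <- as.matrix(dXcol %*% scat)    # scatter-add back to the input layout
  grads
}

# forward + backward for one batch; returns MAE loss and parameter gradients
.nnLossGrad <- function(net, X, y) {
  arch <- net$arch; pr <- net$params
  B <- nrow(X)
  fw <- .nnForward(net, X, keepCache = TRUE)
  ca <- fw$cache
  r <- fw$pred - y
  loss <- mean(abs(r))
  dpred <- matrix(sign(r) / B, ncol = 1)
  g <- list()
  g$W6 <- crossprod(ca$A5, dpred); g$b6 <- sum(dpred)
  dA5 <- tcrossprod(dpred, pr$W6) * ca$m5
  g$W5 <- crossprod(ca$A4, dA5); g$b5 <- colSums(dA5)
  dA4 <- tcrossprod(dA5, pr$W5) * ca$m4
  g$W4 <- crossprod(ca$A3, dA4); g$b4 <- colSums(dA4)
  dA <- tcrossprod(dA4, pr$W4)             # B x flat
  for (l in 3:1) {
    cb <- .convBackward(dA, pr[[paste0("W", l)]], arch$idx[[l]],
                        arch$scat[[l]],
                        ca[[paste0("Xcol", l)]], ca[[paste0("mask", l)]], B)
    g[[paste0("W", l)]] <- cb$dW
    g[[paste0("b", l)]] <- cb$db
    dA <- cb$dA
  }
  list(loss = loss, grads = g)
}

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t; c2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    gnm <- paste0("", nm)
    g <- grads[[gnm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(params = params, state = st)
}

# Train the regressor.  X: K x (p^2*2) normalized patches, y: labels (ns),
# valX/valY: held-out instances for the per-epoch validation MAE.
.nnTrain <- function(Xtr, ytr, Xval, yval, p, epochs, batch, lr) {
  net <- .nnInit(p, 2L, labelMean = mean(ytr))
  st <- .adamInit(net$params)
  K <- nrow(Xtr)
  hist <- data.frame(epoch = seq_len(epochs), train = NA_real_, val = NA_real_)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(K)
    losses <- numeric(0)
    for (b0 in seq(1L, K, by = batch)) {
      ix <- ord[b0:min(K, b0 + batch - 1L)]
      lg <- .nnLossGrad(net, Xtr[ix, , drop = FALSE], ytr[ix])
      if (!is.finite(lg$loss))
        stop(sprintf("training diverged (non-finite loss at epoch %d)", ep))
      up <- .adamStep(net$params, lg$grads, st, lr)
      net$params <- up$params; st <- up$state
      losses <- c(losses, lg$loss)
    }
    hist$train[ep] <- mean(losses)
    hist$val[ep] <- mean(abs(.nnPredict(net, Xval) - yval))
  }
  net$history <- hist
  net
}

# batched forward pass, prediction only
.nnPredict <- function(net, X, chunk = 2048L) {
  n <- nrow(X)
  out <- numeric(n)
  for (b0 in seq(1L, n, by = chunk)) {
    ix <- b0:min(n, b0 + chunk - 1L)
    out[ix] <- .nnForward(net, X[ix, , drop = FALSE])$pred
  }
  out
}
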