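# Internal neural-network primitives: batch normalization, sigmoid, max
# pooling, fully connected layers, softmax/cross-entropy and Adam.  The 1-D
# convolution forward/gradient kernels live in src/conv1d.cpp.  Activations
# flow as (n*P) x C matrices with row index (i-1)*P + p for sample i,
# position p.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.relu <- function(x) pmax(x, 0)

# --- batch normalization ----------------------------------------------------

.bn_forward <- function(Z, gamma, beta, rm, rv, mode,
                        momentum = 0.1, eps = 1e-5) {
  if (mode == "identity") {
    return(list(out = Z, cache = NULL, rm = rm, rv = rv))
  }
  if (mode == "train") {
    mu <- colMeans(Z)
    v <- colMeans(Z^2) - mu^2          # biased variance, per channel
    v <- pmax(v, 0)
    rm <- (1 - momentum) * rm + momentum * mu
    rv <- (1 - momentum) * rv + momentum * v
  } else {                              # eval
    mu <- rm
    v <- rv
  }
  istd <- 1 / sqrt(v + eps)
  zhat <- sweep(sweep(Z, 2, mu, "-"), 2, istd, "*")
  out <- sweep(sweep(zhat, 2, gamma, "*"), 2, beta, "+")
  cache <- if (mode == "train") list(zhat = zhat, istd = istd, gamma = gamma)
           else NULL
  list(out = out, cache = cache, rm = rm, rv = rv)
}

.bn_backward <- function(dOut, cache) {
  zhat <- cache$zhat
  dGamma <- colSums(dOut * zhat)
  dBeta <- colSums(dOut)
  dZhat <- sweep(dOut, 2, cache$gamma, "*")
  # standard batch-norm backward over the (batch x position) axis
  mean1 <- colMeans(dZhat)
  mean2 <- colMeans(dZhat * zhat)
  dZ <- sweep(sweep(dZhat, 2, mean1, "-") - sweep(zhat, 2, mean2, "*"),
              2, cache$istd, "*")
  list(dZ = dZ, dGamma = dGamma, dBeta = dBeta)
}

# --- max pooling ------------------------------------------------------------

# A: (n*P) x C activations; returns out and idx, both n x (C * nW) with
# column block c holding windows of channel c.  Global pooling is the single
# window width = stride = P.
.pool_max <- function(A, n, P, width, stride) {
  C <- ncol(A)
  nW <- (P - width) %/% stride + 1L
  if (nW < 1) stop("pooling window wider than the feature map")
  out <- matrix(0, n, C * nW)
  idx <- matrix(0L, n, C * nW)
  rowBase <- (seq_len(n) - 1L) * P
  for (c in seq_len(C)) {
    M <- matrix(A[, c], n, P, byrow = TRUE)
    for (w in seq_len(nW)) {
      cols <- ((w - 1L) * stride + 1L):((w - 1L) * stride + width)
      sub <- M[, cols, drop = FALSE]
      am <- max.col(sub, ties.method = "first")
      j <- (c - 1L) * nW + w
      out[, j] <- sub[cbind(seq_len(n), am)]
      idx[, j] <- rowBase + cols[am]
    }
  }
  list(out = out, idx = idx, nW = nW)
}

.pool_backward <- function(dOut, idx, n, P, C, nW) {
  dA <- matrix(0, n * P, C)
  for (j in seq_len(ncol(dOut))) {
    c <- (j - 1L) %/% nW + 1L
    rows <- idx[, j]
    dA[cbind(rows, c)] <- dA[cbind(rows, c)] + dOut[, j]
  }
  dA
}

# --- one operation group ----------------------------------------------------

.init_group <- function(Fsize, d, C) {
  sd <- sqrt(1 / (Fsize * d))
  list(W = matrix(stats::rnorm(Fsize * d * C, sd = sd), Fsize * d, C),
       b = numeric(C),
       gamma = rep(1, C), beta = numeric(C),
       rm = numeric(C), rv = rep(1, C))
}

.group_forward <- function(X, dims, gp, Fsize, mode, pool) {
  P <- dims[2] - Fsize + 1L
  Z <- .conv1d_forward_cpp(X, dims, gp$W, gp$b)
  bn <- .bn_forward(Z, gp$gamma, gp$beta, gp$rm, gp$rv, mode)
  A <- .sigmoid(bn$out)
  width <- if (pool$mode == "global") P else min(pool$width, P)
  stride <- if (pool$mode == "global") P else min(pool$stride, P)
  pl <- .pool_max(A, dims[1], P, width, stride)
  list(out = pl$out,
       cache = list(A = A, idx = pl$idx, nW = pl$nW, P = P,
                    bn = bn$cache, Fsize = Fsize),
       rm = bn$rm, rv = bn$rv)
}

.group_backward <- function(dOut, cache, X, dims) {
  n <- dims[1]
  C <- ncol(cache$A)
  dA <- .pool_backward(dOut, cache$idx, n, cache$P, C, cache$nW)
  dPre <- dA * cache$A * (1 - cache$A)        # sigmoid'
  if (is.null(cache$bn)) {
    dZ <- dPre
    dGamma <- NULL; dBeta <- NULL
  } else {
    bb <- .bn_backward(dPre, cache$bn)
    dZ <- bb$dZ; dGamma <- bb$dGamma; dBeta <- bb$dBeta
  }
  cg <- .conv1d_grad_cpp(X, dims, dZ, cache$Fsize)
  list(dW = cg$dW, db = cg$db, dGamma = dGamma, dBeta = dBeta)
}

# --- fully connected / softmax ----------------------------------------------

.init_fc <- function(nin, nout) {
  list(W = matrix(stats::rnorm(nin * nout, sd = sqrt(1 / nin)), nin, nout),
       b = numeric(nout))
}

.softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# --- Adam -------------------------------------------------------------------

.adam_new <- function(param) list(m = param * 0, v = param * 0)

.adam_upd <- function(param, grad, st, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), st = st)
}
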