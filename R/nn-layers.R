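## Minimal CNN primitives on (H, W, N, C) arrays, written against R's
## column-major layout so that reshaping to (H*W*N) x C matrices is
## copy-free and 3x3 convolutions become nine BLAS matrix products.
## Weights for a 3x3 convolution are stored as a (9, Cin, Cout) array,
## one (Cin x Cout) matrix per kernel offset.

# Forward 3x3 convolution; returns the output and the cached im2col
# patch matrix for the backward pass (compiled, see src/conv3x3.cpp).
convForward <- function(x, W, b) {
  .conv3x3Forward(x, dim(x), W, b, dim(W)[3])
}

# Backward from the cached im2col matrix. dx is computed gather-style
# with the offset-flipped, transposed kernel, so no scatter
# accumulation is needed.
convBackward <- function(X9, dims, W, dy) {
  .conv3x3Backward(X9, dims, W, dy, dim(W)[3])
}

## Batch normalization over (H, W, N) per channel; biased batch variance
## is used both for normalization and for the running statistics
## (compiled, see src/bnorm.cpp).
bnForward <- function(x, gamma, beta, rm, rv, training,
                      momentum = 0.1, eps = 1e-5) {
  d <- dim(x); P <- prod(d[1:3]); C <- d[4]
  r <- .bnForwardC(x, P, C, gamma, beta, rm, rv, training, momentum, eps)
  list(y = r$y, cache = list(xhat = r$xhat, ivs = r$ivs, P = P, C = C),
       rm = r$rm, rv = r$rv)
}

bnBackward <- function(cache, gamma, dy) {
  r <- .bnBackwardC(dy, cache$xhat, cache$ivs, cache$P, cache$C, gamma)
  list(dx = r$dx, dgamma = r$dgamma, dbeta = r$dbeta)
}

reluForward <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

reluBackward <- function(mask, dy) dy * mask

## 2x2 max pooling (stride 2); the gradient is routed to the (first)
## argmax of each window. Compiled, see src/pool.cpp.
maxPoolForward <- function(x) {
  r <- .maxPool2C(x, dim(x))
  list(y = r$y, arg = r$arg, dims = dim(x))
}

maxPoolBackward <- function(cache, dy) {
  .maxPool2BackwardC(dy, cache$arg, cache$dims)
}

upsample2 <- function(x) .upsample2C(x, dim(x))

## Adjoint of nearest-neighbour 2x upsampling: sum over 2x2 blocks.
poolSum <- function(x) .poolSumC(x, dim(x))

concatC <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

splitC <- function(d, C1) {
  list(a = d[, , , seq_len(C1), drop = FALSE],
       b = d[, , , -seq_len(C1), drop = FALSE])
}

## He-normal initialization for one conv layer (+ optional BN).
initConvLayer <- function(Cin, Cout, batchNorm = TRUE) {
  W <- array(stats::rnorm(9 * Cin * Cout, 0, sqrt(2 / (9 * Cin))),
             c(9, Cin, Cout))
  layer <- list(W = W, b = numeric(Cout))
  if (batchNorm) {
    layer$gamma <- rep(1, Cout)
    layer$beta <- numeric(Cout)
  }
  layer
}

## ------------------------------------------------------------------
## Adam optimizer over a nested list of parameter arrays
## ------------------------------------------------------------------

adamInit <- function(params) {
  zero <- function(p) if (is.list(p)) lapply(p, zero) else p * 0
  list(m = zero(params), v = zero(params), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      out
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
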