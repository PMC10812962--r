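## U-Net construction, forward and backward passes.
##
## Architecture (depth d, base channels c): d encoder convolutions with
## channels c, 2c, ..., each conv -> BN -> ReLU -> 2x2 max pool; one
## bottleneck conv at c*2^d; d decoder stages (2x nearest upsample,
## concatenate the matching encoder skip, conv -> BN -> ReLU); a final
## linear 3x3 conv to one channel. 2d + 2 convolutional layers total.

#' Build an untrained U-Net synthesis model
#'
#' Parameters are He-initialized from the given seed, so two builds with
#' the same spec and seed have identical initial parameters. The
#' forward pass maps an (H, W) slice batch to same-shape output; H and W
#' must be divisible by `2^depth`.
#'
#' @param spec A [SynthModelSpec-class].
#' @param seed Integer seed for initialization.
#' @return An untrained [UNetModel-class].
#' @export
buildModel <- function(spec = synthModelSpec(), seed = 20260104) {
  stopifnot(is(spec, "SynthModelSpec"))
  validObject(spec)
  d <- spec@depth; c0 <- spec@baseChannels; bn <- spec@batchNorm
  withr::with_seed(as.integer(seed), {
    params <- list(enc = list(), dec = list())
    cin <- 1L
    for (l in seq_len(d)) {
      cout <- c0 * 2^(l - 1)
      params$enc[[l]] <- initConvLayer(cin, cout, bn)
      cin <- cout
    }
    params$bottleneck <- initConvLayer(cin, c0 * 2^d, bn)
    cin <- c0 * 2^d
    for (l in rev(seq_len(d))) {
      skipC <- c0 * 2^(l - 1)
      cout <- skipC
      params$dec[[l]] <- initConvLayer(cin + skipC, cout, bn)
      cin <- cout
    }
    params$out <- initConvLayer(cin, 1L, batchNorm = FALSE)
    stats <- list(enc = list(), dec = list())
    for (l in seq_len(d)) {
      stats$enc[[l]] <- list(rm = numeric(c0 * 2^(l - 1)),
                             rv = rep(1, c0 * 2^(l - 1)))
      stats$dec[[l]] <- list(rm = numeric(c0 * 2^(l - 1)),
                             rv = rep(1, c0 * 2^(l - 1)))
    }
    stats$bottleneck <- list(rm = numeric(c0 * 2^d), rv = rep(1, c0 * 2^d))
    new("UNetModel", spec = spec, params = params, stats = stats,
        trained = FALSE, config = NULL)
  })
}

## One conv -> (BN) -> ReLU block. Returns output, cache, updated stats.
blockForward <- function(x, layer, st, training, bn) {
  cv <- convForward(x, layer$W, layer$b)
  z <- cv$y
  cache <- list(X9 = cv$X9, dims = dim(x))
  if (bn) {
    r <- bnForward(z, layer$gamma, layer$beta, st$rm, st$rv, training)
    z <- r$y
    cache$bn <- r$cache
    st <- list(rm = r$rm, rv = r$rv)
  }
  r <- reluForward(z)
  cache$relu <- r$mask
  list(y = r$y, cache = cache, st = st)
}

blockBackward <- function(dy, layer, cache, bn) {
  dy <- reluBackward(cache$relu, dy)
  g <- list()
  if (bn) {
    r <- bnBackward(cache$bn, layer$gamma, dy)
    dy <- r$dx
    g$gamma <- r$dgamma
    g$beta <- r$dbeta
  }
  r <- convBackward(cache$X9, cache$dims, layer$W, dy)
  g$W <- r$dW
  g$b <- r$db
  list(dx = r$dx, grads = g)
}

## Forward pass over a batch. x: (H, W, N, 1). Returns prediction,
## caches for backprop and updated BN running stats.
unetForward <- function(model, x, training = FALSE) {
  spec <- model@spec
  d <- spec@depth; bn <- spec@batchNorm
  dims <- dim(x)
  if (dims[1] %% 2^d != 0 || dims[2] %% 2^d != 0)
    stop(sprintf("input size %dx%d not divisible by 2^depth = %d",
                 dims[1], dims[2], 2^d))
  p <- model@params; st <- model@stats
  caches <- list(enc = vector("list", d), dec = vector("list", d))
  skips <- vector("list", d)
  h <- x
  for (l in seq_len(d)) {
    r <- blockForward(h, p$enc[[l]], st$enc[[l]], training, bn)
    caches$enc[[l]] <- r$cache
    st$enc[[l]] <- if (bn) r$st else st$enc[[l]]
    skips[[l]] <- r$y
    pool <- maxPoolForward(r$y)
    caches$pool[[l]] <- pool
    h <- pool$y
  }
  r <- blockForward(h, p$bottleneck, st$bottleneck, training, bn)
  caches$bottleneck <- r$cache
  st$bottleneck <- if (bn) r$st else st$bottleneck
  h <- r$y
  for (l in rev(seq_len(d))) {
    h <- upsample2(h)
    caches$upC[[l]] <- dim(h)[4]
    h <- concatC(h, skips[[l]])
    r <- blockForward(h, p$dec[[l]], st$dec[[l]], training, bn)
    caches$dec[[l]] <- r$cache
    st$dec[[l]] <- if (bn) r$st else st$dec[[l]]
    h <- r$y
  }
  cv <- convForward(h, p$out$W, p$out$b)
  caches$outX9 <- cv$X9
  caches$outDims <- dim(h)
  list(pred = cv$y, caches = caches, stats = st)
}

## Backward pass; dpred has the prediction's shape. Returns gradient
## list mirroring model@params.
unetBackward <- function(model, caches, dpred) {
  spec <- model@spec
  d <- spec@depth; bn <- spec@batchNorm
  p <- model@params
  grads <- list(enc = vector("list", d), dec = vector("list", d))
  r <- convBackward(caches$outX9, caches$outDims, p$out$W, dpred)
  grads$out <- list(W = r$dW, b = r$db)
  dh <- r$dx
  dskips <- vector("list", d)
  for (l in seq_len(d)) {
    r <- blockBackward(dh, p$dec[[l]], caches$dec[[l]], bn)
    grads$dec[[l]] <- r$grads
    sp <- splitC(r$dx, caches$upC[[l]])
    dskips[[l]] <- sp$b
    dh <- poolSum(sp$a)
  }
  r <- blockBackward(dh, p$bottleneck, caches$bottleneck, bn)
  grads$bottleneck <- r$grads
  dh <- r$dx
  for (l in rev(seq_len(d))) { # undo encoder stages d, d-1, ..., 1
    dpool <- maxPoolBackward(caches$pool[[l]], dh)
    dskip <- dpool + dskips[[l]]
    r <- blockBackward(dskip, p$enc[[l]], caches$enc[[l]], bn)
    grads$enc[[l]] <- r$grads
    dh <- r$dx
  }
  grads
}
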