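# Shared small fixtures, built in code at test time.

tinyPhantomSpec <- function(..., seed = 424242) {
  phantomSpec(matrixSize = c(2, 32, 32), nSubjects = 2, seed = seed, ...)
}

tinyTruth <- function(id = "S001", ...) {
  generatePhantom(tinyPhantomSpec(...), id)
}

# Direct (windowless loops) SSIM recomputation used as the in-suite
# oracle for ssimVolume: same Gaussian window definition, written
# independently of the package's separable-filter implementation.
naiveSsimSlice <- function(x, y, dataRange, sigma = 1.5, radius = 5) {
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  k1 <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  K <- outer(k1, k1)
  K <- K / sum(K)
  n1 <- nrow(x); n2 <- ncol(x)
  pad <- function(z) {
    idx1 <- c(radius:1, 1:n1, n1:(n1 - radius + 1))
    idx2 <- c(radius:1, 1:n2, n2:(n2 - radius + 1))
    z[idx1, idx2]
  }
  xp <- pad(x); yp <- pad(y)
  vals <- c()
  for (i in (radius + 1):(n1 - radius)) {
    for (j in (radius + 1):(n2 - radius)) {
      wx <- xp[i:(i + 2 * radius), j:(j + 2 * radius)]
      wy <- yp[i:(i + 2 * radius), j:(j + 2 * radius)]
      mx <- sum(K * wx); my <- sum(K * wy)
      vx <- sum(K * wx^2) - mx^2
      vy <- sum(K * wy^2) - my^2
      cxy <- sum(K * wx * wy) - mx * my
      vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                  ((mx^2 + my^2 + C1) * (vx + vy + C2)))
    }
  }
  mean(vals)
}
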