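# Independent brute-force oracles used by the unit and acceptance tests.

# All-pairs STDP sum as an explicit double loop over the printed piecewise
# exponential (independent of the vectorized implementation path).
bruteForcePairSum <- function(pre, post, p) {
  total <- 0
  for (a in seq_along(pre)) for (b in seq_along(post)) {
    dt <- post[b] - pre[a]
    total <- total + if (dt > 0) p@aPlus * exp(-dt / p@tauPlus)
                     else if (dt < 0) -p@aMinus * exp(dt / p@tauMinus)
                     else 0
  }
  total
}

# Naive quadruple-loop valid 4x4 convolution, 2x2/stride-2 floor pooling and
# per-channel rescale to [0, 255] - the pipeline the fast path must match.
bruteForcePreprocess <- function(image, kernel, pooling = "max") {
  conv <- matrix(0, 25, 25)
  for (r in 1:25) for (c in 1:25) {
    acc <- 0
    for (a in 0:3) for (b in 0:3) acc <- acc + kernel[a + 1, b + 1] * image[r + a, c + b]
    conv[r, c] <- acc
  }
  pooled <- matrix(0, 12, 12)
  for (r in 1:12) for (c in 1:12) {
    win <- conv[(2 * r - 1):(2 * r), (2 * c - 1):(2 * c)]
    pooled[r, c] <- if (pooling == "max") max(win) else mean(win)
  }
  rng <- range(pooled)
  if (diff(rng) > 1e-12) (pooled - rng[1]) / diff(rng) * 255 else pmin(pmax(pooled, 0), 255)
}

# Two orthogonal 4-pixel patterns: the separable toy classification task.
toyPatterns <- function() {
  A <- matrix(0, 2, 2); A[1, ] <- 255
  B <- matrix(0, 2, 2); B[2, ] <- 255
  list(images = array(c(A, B), dim = c(2, 2, 2)), labels = c(0L, 1L))
}
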