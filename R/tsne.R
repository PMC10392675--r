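#' @include utils.R
NULL

# Exact t-SNE (quadratic in n). Perplexity calibration by per-point
# binary search on the Gaussian bandwidth; symmetrized affinities;
# early exaggeration; momentum gradient descent. Adequate for the
# latent-space sizes this package projects (a few thousand points).

tsneAffinities <- function(X, perplexity, tol = 1e-5, maxIter = 50L) {
  n <- nrow(X)
  D2 <- as.matrix(dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betaMin <- -Inf; betaMax <- Inf
    di <- D2[i, -i]
    for (it in seq_len(maxIter)) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) p <- rep(1 / length(p), length(p)) else p <- p / sp
      H <- -sum(p[p > 0] * log(p[p > 0]))
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) {  # entropy too high -> narrower kernel
        betaMin <- beta
        beta <- if (is.finite(betaMax)) (beta + betaMax) / 2 else beta * 2
      } else {
        betaMax <- beta
        beta <- if (is.finite(betaMin)) (beta + betaMin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.eps)
}

tsneEmbed <- function(X, perplexity = 30, dims = 2L, maxIter = 500L,
                      eta = 200, seed = 1L, exaggeration = 12,
                      exaggerateIter = 100L, verbose = FALSE) {
  n <- nrow(X)
  if (n - 1 < 3 * perplexity)
    stop("too few points (", n, ") for perplexity ", perplexity,
         " (need n > 3 * perplexity + 1)")
  P <- tsneAffinities(X, perplexity)
  Y <- withSeed(seed, matrix(rnorm(n * dims, sd = 1e-4), n, dims))
  inc <- Y * 0
  momentum <- 0.5
  Pex <- P * exaggeration
  for (it in seq_len(maxIter)) {
    Pit <- if (it <= exaggerateIter) Pex else P
    D2 <- as.matrix(dist(Y))^2
    Qnum <- 1 / (1 + D2)
    diag(Qnum) <- 0
    Q <- pmax(Qnum / sum(Qnum), .Machine$double.eps)
    W <- (Pit - Q) * Qnum
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    if (it == round(exaggerateIter * 2.5)) momentum <- 0.8
    inc <- momentum * inc - eta * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
    if (verbose && it %% 100 == 0) {
      kl <- sum(Pit * log(Pit / Q))
      message("t-SNE iteration ", it, ", KL = ", signif(kl, 4))
    }
  }
  Y
}
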