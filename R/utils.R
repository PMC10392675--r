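#' @importFrom stats rnorm runif approx sd dist ks.test
#' @importFrom utils head read.table write.table write.csv read.csv
NULL

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG stream.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483646L) + 1L)
  expr
}

# Deterministic derived seed, kept inside 32-bit integer range.
deriveSeed <- function(master, ...) {
  parts <- c(master, ...)
  s <- 0
  for (p in parts) s <- (s * 69069 + as.numeric(p) + 1) %% 2147483647
  as.integer(s)
}

sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -30), 30)))

reluFwd <- function(x) {
  x[x < 0] <- 0
  x
}

bceLoss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Glorot-uniform initialization (the package's default weight scheme).
glorotInit <- function(dims, fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

wrapDihedral <- function(x) ((x + 180) %% 360) - 180

# Fold values into [-band, band] by reflection (triangle wave).
reflectIntoBand <- function(x, band) {
  z <- (x + band) %% (4 * band)
  ifelse(z > 2 * band, 4 * band - z, z) - band
}
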