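# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

# Small dataset for API and shape tests (signal present but the scale is
# too small for the fixed training regime to exploit well).
tinyTS <- function() memo("tinyTS", function() {
  cfg <- generatorConfig(n_ligands = 4, n_per_class = 10, n_frames = 200,
                         master_seed = 42)
  ts <- splitByLigand(generateDataset(cfg), 1:3, 4L)
  suppressMessages(applyNormalizer(ts, fitNormalizer(ts)))
})

# The study-scale fixture: 12 ligands x 2 x 50 trajectories of 1,000
# frames, ligand-held-out split 9/3, classifier trained with the
# standard regime. Shared by the capacity and interpretation tests.
bigFixture <- function() memo("bigFixture", function() {
  cfg <- generatorConfig(n_ligands = 12, n_per_class = 50,
                         n_frames = 1000, master_seed = 11)
  ts <- splitByLigand(generateDataset(cfg), 1:9, 10:12)
  ts <- suppressMessages(applyNormalizer(ts, fitNormalizer(ts)))
  model <- trainClassifier(buildCNN1D(seed = 5), ts, seed = 5)
  list(ts = ts, model = model)
})

numGrad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

randomRotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3))) * sample(c(-1, 1), 1)
}
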