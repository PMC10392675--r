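test_that("class labels follow the per-ligand preferred enantiomer", {
  cfg <- generatorConfig(n_ligands = 2, n_per_class = 2, n_frames = 60,
                         master_seed = 1)
  ts <- generateDataset(cfg)
  # scramble and reassign
  ts@info$class_label <- NA_character_
  ts@info$ligand_id <- rep(c(1L, 35L), each = 4)
  ts@info$enantiomer <- rep(c("S", "R"), 4)
  pref <- c(`1` = "S", `35` = "R")
  out <- assignClassLabels(ts, pref)
  lab <- classLabels(out)
  ids <- ligandIds(out); en <- out@info$enantiomer
  expect_true(all(lab[ids == 1 & en == "S"] == "reactive"))
  expect_true(all(lab[ids == 1 & en == "R"] == "non-reactive"))
  # (R)-preferred ligand: an S trajectory is non-reactive
  expect_true(all(lab[ids == 35 & en == "S"] == "non-reactive"))
  expect_true(all(lab[ids == 35 & en == "R"] == "reactive"))
  # unknown ligand
  expect_error(assignClassLabels(out, c(`1` = "S")), "labeling error")
  # empty input passes through
  empty <- ts[integer(0)]
  expect_identical(nTrajectories(assignClassLabels(empty, pref)), 0L)
})

test_that("ligand-held-out split is leak-free and validated", {
  ts <- tinyTS()
  expect_identical(sort(unique(ligandIds(ts)[trainIndices(ts)])), 1:3)
  expect_identical(sort(unique(ligandIds(ts)[validationIndices(ts)])), 4L)
  expect_length(intersect(trainIndices(ts), validationIndices(ts)), 0L)
  expect_error(splitByLigand(ts, 1:3, 3:4), "overlap")
  expect_error(splitByLigand(ts, 1:2, 4), "not assigned")
  # single-ligand dataset entirely in train -> empty validation warning
  one <- ts[which(ligandIds(ts) == 1L)]
  expect_warning(s1 <- splitByLigand(one, 1L, 2L), "empty validation")
  expect_length(validationIndices(s1), 0L)
})

test_that("signal and matrix-image encodings are consistent transpositions", {
  cfg <- generatorConfig(n_ligands = 1, n_per_class = 1, master_seed = 4)
  ts <- generateDataset(cfg)        # one trajectory at canonical size
  sig <- toSignalBatch(ts)
  img <- toMatrixImageBatch(ts)
  expect_identical(dim(sig), c(2L, 1000L, 15L))
  expect_identical(dim(img), c(2L, 15L, 1000L, 1L))
  for (i in 1:2)
    expect_identical(sig[i, , ], t(img[i, , , 1]))
  # round trip through the other encoding is lossless
  back <- aperm(img[, , , 1, drop = TRUE], c(1, 3, 2))
  expect_identical(back, sig)
})

test_that("trajectory rendering draws bands with blank separators", {
  T <- 137
  m <- matrix(0.5, T, 15)
  img <- renderTrajectoryImage(m, size = 320L)
  expect_identical(dim(img), c(320L, 320L))
  slot <- 320L %/% 15L
  bandH <- slot - 4L
  gapRows <- setdiff(seq_len(320L),
                     unlist(lapply(0:14, function(d) d * slot + seq_len(bandH))))
  # separator and padding rows never contain trace pixels
  expect_true(all(img[gapRows, ] == 1))
  # constant channel -> one straight horizontal trace row per band
  for (d in c(1, 8, 15)) {
    r0 <- (d - 1L) * slot
    band <- img[r0 + seq_len(bandH), ]
    expect_identical(sum(band == 0), 320L)
    expect_length(unique(which(band == 0, arr.ind = TRUE)[, "row"]), 1L)
  }
  # determinism
  expect_identical(img, renderTrajectoryImage(m, size = 320L))
  expect_error(renderTrajectoryImage(matrix(0, 5, 200), size = 320L),
               "too many channels")
})

test_that("rendered foreground matches an independent rasterization oracle", {
  set.seed(6)
  T <- 50
  m <- matrix(runif(T * 3), T, 3)
  size <- 60L; gap <- 4L
  img <- renderTrajectoryImage(m, size = size, gap = gap)
  slot <- size %/% 3L; bandH <- slot - gap
  # oracle: resample each channel at column centres, map to a row in its
  # band, connect consecutive columns with vertical fills
  oracle <- matrix(1, size, size)
  for (d in 1:3) {
    tPos <- (seq_len(size) - 1) / (size - 1) * (T - 1) + 1
    y <- approx(seq_len(T), pmin(pmax(m[, d], 0), 1), xout = tPos)$y
    rows <- (d - 1L) * slot + 1L + round((1 - y) * (bandH - 1L))
    oracle[rows[1], 1] <- 0
    for (cc in 2:size)
      oracle[min(rows[cc - 1], rows[cc]):max(rows[cc - 1], rows[cc]), cc] <- 0
  }
  expect_identical(sum(img == 0), sum(oracle == 0))
  expect_identical(img, oracle)
})

test_that("forecast windows respect boundaries, stride and targets", {
  ts <- tinyTS()                    # 200 frames
  w <- makeForecastWindows(ts, query_channel = 4L, window = 50L,
                           stride = 19L)
  nPer <- length(seq.int(1L, 150L, by = 19L))
  expect_identical(dim(forecastInputs(w)),
                   c(50L, 15L, nPer * nTrajectories(ts)))
  # every target equals the source value one step after its window
  pr <- w@provenance
  X <- tensors(ts)
  for (m in sample(length(forecastTargets(w)), 40)) {
    expect_identical(forecastTargets(w)[m],
                     X[pr$start[m] + 50L, 4L, pr$trajectory[m]])
    expect_identical(forecastInputs(w)[, , m],
                     X[pr$start[m] + 0:49, , pr$trajectory[m]])
  }
  expect_true(all(pr$start + 50L <= nFrames(ts)))
  # canonical arithmetic: 1,000 frames, stride 19 -> 50 windows/trajectory
  cfg1 <- generatorConfig(n_ligands = 1, n_per_class = 1, master_seed = 4)
  w1 <- makeForecastWindows(generateDataset(cfg1))
  expect_identical(dim(forecastInputs(w1))[3], 2L * 50L)
  # stride = T -> one window per trajectory
  wT <- makeForecastWindows(ts, stride = nFrames(ts))
  expect_identical(dim(forecastInputs(wT))[3], nTrajectories(ts))
  expect_error(makeForecastWindows(ts, stride = 0), "stride")
})

test_that("lagged windows thin frames before windowing", {
  ts <- tinyTS()
  w1 <- makeLaggedWindows(ts, lag = 1L)
  w0 <- makeForecastWindows(ts)
  expect_identical(forecastInputs(w1), forecastInputs(w0))
  expect_identical(forecastTargets(w1), forecastTargets(w0))
  # lag 3 on 200 frames -> effective 67-frame series, windows of 50
  w3 <- makeLaggedWindows(ts, lag = 3L)
  expect_identical(w3@lag, 3L)
  keep <- seq.int(1L, 200L, by = 3L)
  X <- tensors(ts)
  pr <- w3@provenance
  for (m in seq_len(min(10, length(forecastTargets(w3))))) {
    src <- X[keep, , pr$trajectory[m]]
    expect_identical(forecastTargets(w3)[m], src[pr$start[m] + 50L, 4L])
  }
  expect_error(makeLaggedWindows(ts, lag = 5L), "insufficient")
})
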