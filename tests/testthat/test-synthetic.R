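test_that("ligand profiles are deterministic, distinct and canonical", {
  cfg <- generatorConfig()
  profs <- makeLigandProfiles(cfg)
  expect_length(profs, 49L)
  # canonical (R)-preferred ligands
  pref <- vapply(profs, `[[`, "", "preferred_enantiomer")
  expect_identical(which(pref == "R"), c(32L, 33L, 35L, 36L, 45L))
  # determinism and seed sensitivity
  profs2 <- makeLigandProfiles(cfg)
  expect_identical(profs, profs2)
  profs3 <- makeLigandProfiles(generatorConfig(master_seed = 2L))
  expect_true(any(profs[[1]]$channel_baselines !=
                    profs3[[1]]$channel_baselines))
  # baselines differ across ligands
  expect_true(any(profs[[1]]$channel_baselines !=
                    profs[[2]]$channel_baselines))
  # spreads strictly positive
  for (p in profs[1:3]) expect_true(all(p$channel_spreads > 0))
})

test_that("configuration errors are caught", {
  expect_error(generatorConfig(n_ligands = 0), "counts")
  expect_error(generatorConfig(n_frames = 50), "51")
  expect_error(generatorConfig(slow_channel = 16), "slow_channel")
  expect_error(generatorConfig(coupled_channels = 3L), "slow channel")
  cfg <- generatorConfig(n_ligands = 1, n_frames = 60)
  p <- makeLigandProfiles(cfg)[[1]]
  expect_error(generateTrajectory(p, "maybe", 1L, cfg), "labeling error")
})

test_that("single trajectories have the documented shape and ranges", {
  cfg <- generatorConfig(n_ligands = 1, master_seed = 3)
  p <- makeLigandProfiles(cfg)[[1]]
  x <- generateTrajectory(p, "reactive", 1L, cfg)
  expect_identical(dim(x), c(1000L, 15L))
  kinds <- trajsel:::channelKinds(15L)
  for (d in which(kinds == "distance")) expect_true(all(x[, d] > 0))
  for (d in which(kinds == "angle"))
    expect_true(all(x[, d] >= 0 & x[, d] <= 180))
  for (d in which(kinds == "dihedral"))
    expect_true(all(x[, d] >= -180 & x[, d] < 180))
})

test_that("slow channel stays inside the drift band around -90", {
  cfg <- generatorConfig(n_ligands = 2, n_per_class = 3, n_frames = 500,
                         master_seed = 7)
  p <- makeLigandProfiles(cfg)[[1]]
  for (label in c("reactive", "non-reactive")) {
    x <- generateTrajectory(p, label, 2L, cfg)
    slow <- x[, cfg$slow_channel]
    expect_equal(slow[1], -90)
    expect_lte(max(abs(slow - slow[1])), cfg$drift_band)
  }
})

test_that("zero-noise classes share per-channel time-averaged means", {
  cfg <- generatorConfig(n_ligands = 1, n_frames = 400, noise_sd = 0,
                         master_seed = 5)
  p <- makeLigandProfiles(cfg)[[1]]
  xr <- generateTrajectory(p, "reactive", 1L, cfg)
  xn <- generateTrajectory(p, "non-reactive", 1L, cfg)
  # integer cycle counts + zero noise: column means collapse to the
  # baselines for both classes
  expect_equal(colMeans(xr), colMeans(xn), tolerance = 1e-10)
})

test_that("dataset counts, balance and determinism hold", {
  cfg <- generatorConfig(n_ligands = 2, n_per_class = 3, n_frames = 60,
                         master_seed = 9)
  ts <- generateDataset(cfg)
  expect_s4_class(ts, "TrajectorySet")
  expect_identical(nTrajectories(ts), 12L)
  expect_identical(as.integer(table(classLabels(ts))), c(6L, 6L))
  # balanced per ligand
  tab <- table(ligandIds(ts), classLabels(ts))
  expect_true(all(tab == 3L))
  # bit-identical regeneration from the master seed
  ts2 <- generateDataset(cfg)
  expect_identical(tensors(ts), tensors(ts2))
})

test_that("class marginals are indistinguishable at generator defaults", {
  cfg <- generatorConfig(n_ligands = 6, n_per_class = 20, n_frames = 500,
                         master_seed = 13)
  ks <- classMarginalKS(generateDataset(cfg))
  expect_length(ks, 15L)
  expect_lt(max(ks), cfg$ks_threshold)
})

test_that("null dataset permutes labels but preserves counts", {
  cfg <- generatorConfig(n_ligands = 3, n_per_class = 4, n_frames = 60,
                         master_seed = 21)
  ts <- generateDataset(cfg)
  tsN <- generateNullDataset(cfg)
  expect_identical(tensors(ts), tensors(tsN))   # same data, labels moved
  for (lg in 1:3) {
    sel <- ligandIds(tsN) == lg
    expect_identical(as.integer(table(classLabels(tsN)[sel])), c(4L, 4L))
  }
  expect_false(all(classLabels(ts) == classLabels(tsN)))
  # reproducible permutation
  expect_identical(classLabels(generateNullDataset(cfg)),
                   classLabels(tsN))
})

test_that("frame shuffling destroys the temporal class signal", {
  cfg <- generatorConfig(n_ligands = 6, n_per_class = 20, n_frames = 400,
                         master_seed = 2)
  ts <- shuffleFrames(generateDataset(cfg), seed = 3)
  ts <- splitByLigand(ts, 1:4, 5:6)
  ts <- suppressMessages(applyNormalizer(ts, fitNormalizer(ts)))
  fit <- trainClassifier(buildCNN1D(seed = 2), ts, seed = 2)
  acc <- accuracy(evaluateModel(fit, ts, "validation"))
  expect_gte(acc, 0.4)
  expect_lte(acc, 0.6)
})

test_that("static coupling survives frame shuffling", {
  cfg <- generatorConfig(n_ligands = 6, n_per_class = 20, n_frames = 400,
                         coupling_mode = "static", master_seed = 2)
  ts <- generateDataset(cfg)
  expect_lt(max(classMarginalKS(ts)), cfg$ks_threshold)
  ts <- shuffleFrames(ts, seed = 3)
  # the phase-locked signal lives in instantaneous cross-channel
  # correlation; per-trajectory standardization removes the per-ligand
  # level offsets that otherwise dominate, and a longer budget than the
  # default regime is allowed here because the property under test is
  # the data's, not the optimizer's
  X <- tensors(ts)
  for (i in seq_len(dim(X)[3])) X[, , i] <- scale(X[, , i]) / 6 + 0.5
  ts@tensors <- X
  ts <- splitByLigand(ts, 1:4, 5:6)
  fit <- trainClassifier(buildCNN1D(seed = 2), ts, seed = 2,
                         epochs = 20, lr = 1e-3)
  acc <- accuracy(evaluateModel(fit, ts, "validation"))
  expect_gt(acc, 0.65)
})
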