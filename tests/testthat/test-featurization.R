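test_that("distances match hand values and a brute-force oracle", {
  co <- rbind(c(0, 0, 0), c(3, 4, 0))
  expect_equal(computeDistance(co, c(0, 1)), 5)
  expect_equal(computeDistance(rbind(c(1, 2, 3), c(1, 2, 3)), c(0, 1)), 0)
  set.seed(1)
  for (i in 1:20) {
    co <- matrix(rnorm(6), 2, 3)
    oracle <- sqrt(sum((co[1, ] - co[2, ])^2))
    expect_equal(computeDistance(co, c(0, 1)), oracle, tolerance = 1e-12)
  }
  expect_error(computeDistance(co, c(0, 5)), "out of range")
})

test_that("angles match hand values and the arccos oracle", {
  expect_equal(computeAngle(rbind(c(-1, 0, 0), c(0, 0, 0), c(2, 0, 0)),
                            c(0, 1, 2)), 180)
  expect_equal(computeAngle(rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)),
                            c(0, 1, 2)), 90)
  set.seed(2)
  for (i in 1:20) {
    co <- matrix(rnorm(9), 3, 3)
    u <- co[1, ] - co[2, ]; v <- co[3, ] - co[2, ]
    oracle <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    expect_equal(computeAngle(co, c(0, 1, 2)), oracle, tolerance = 1e-9)
  }
  expect_error(computeAngle(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
                            c(0, 1, 2)), "degenerate")
})

test_that("dihedrals follow the sign convention and the atan2 oracle", {
  # planar cis: both end atoms on the same side
  cis <- rbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
  expect_equal(computeDihedral(cis, 0:3), 0)
  # planar trans maps to -180 (half-open interval)
  trans <- rbind(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
  expect_equal(computeDihedral(trans, 0:3), -180)
  set.seed(3)
  for (i in 1:20) {
    co <- matrix(rnorm(12), 4, 3)
    # independent oracle: Newman-projection construction - project the
    # outer bonds onto the plane perpendicular to the central bond and
    # take the signed angle between the projections
    b2 <- co[3, ] - co[2, ]
    b2 <- b2 / sqrt(sum(b2^2))
    proj <- function(v) v - sum(v * b2) * b2
    u <- proj(co[1, ] - co[2, ])
    w <- proj(co[4, ] - co[3, ])
    cr <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
    oracle <- atan2(sum(cr * b2), sum(u * w)) * 180 / pi
    expect_equal(computeDihedral(co, 0:3), -oracle, tolerance = 1e-9)
  }
})

test_that("descriptors are invariant to rigid motion; dihedrals flip under reflection", {
  set.seed(4)
  defs <- DescriptorSet(c("a", "b", "c"),
                        c("distance", "angle", "dihedral"),
                        list(c(0L, 1L), c(0L, 1L, 2L), c(0L, 1L, 2L, 3L)))
  for (i in 1:5) {
    co <- matrix(rnorm(18), 6, 3)
    R <- randomRotation()
    R <- R * det(R)            # proper rotation
    shift <- rnorm(3)
    co2 <- sweep(co %*% t(R), 2, shift, "+")
    for (k in seq_along(defs@name)) {
      f1 <- trajsel:::featurizeColumn(array(co, c(6, 3, 1)), defs@kind[k],
                                      defs@atoms[[k]])
      f2 <- trajsel:::featurizeColumn(array(co2, c(6, 3, 1)), defs@kind[k],
                                      defs@atoms[[k]])
      expect_equal(f1, f2, tolerance = 1e-9)
    }
    # reflection: distances/angles unchanged, dihedral sign flips
    co3 <- co; co3[, 1] <- -co3[, 1]
    d1 <- trajsel:::featurizeColumn(array(co, c(6, 3, 1)), "dihedral", 0:3)
    d2 <- trajsel:::featurizeColumn(array(co3, c(6, 3, 1)), "dihedral", 0:3)
    expect_equal(abs(d1), abs(d2), tolerance = 1e-9)
    if (abs(abs(d1) - 180) > 1e-6 && abs(d1) > 1e-6)
      expect_equal(d1, -d2, tolerance = 1e-9)
  }
})

test_that("featurizeTrajectory matches the per-frame scalar path", {
  set.seed(5)
  T <- 25; natoms <- 8
  frames <- array(rnorm(natoms * 3 * T), c(natoms, 3, T))
  defs <- DescriptorSet(c("d1", "d2", "d3"),
                        c("distance", "angle", "dihedral"),
                        list(c(0L, 4L), c(1L, 2L, 3L), c(4L, 5L, 6L, 7L)))
  ts <- featurizeTrajectory(frames, defs)
  expect_identical(dim(tensors(ts)), c(25L, 3L, 1L))
  for (t in seq_len(T)) {
    co <- frames[, , t]
    expect_equal(tensors(ts)[t, 1, 1], computeDistance(co, c(0, 4)),
                 tolerance = 1e-12)
    expect_equal(tensors(ts)[t, 2, 1], computeAngle(co, c(1, 2, 3)),
                 tolerance = 1e-12)
    expect_equal(tensors(ts)[t, 3, 1], computeDihedral(co, c(4, 5, 6, 7)),
                 tolerance = 1e-12)
  }
  # single frame
  ts1 <- featurizeTrajectory(frames[, , 1, drop = FALSE], defs)
  expect_identical(dim(tensors(ts1)), c(1L, 3L, 1L))
  # out-of-range atoms
  bad <- DescriptorSet("x", "distance", list(c(0L, 20L)))
  expect_error(featurizeTrajectory(frames, bad), "exceeds topology")
})

test_that("multi-model PDB round trip through featurization", {
  co <- array(round(rnorm(4 * 3 * 3, sd = 3), 3), c(4, 3, 3))
  lines <- character(0)
  for (f in 1:3) {
    lines <- c(lines, sprintf("MODEL     %4d", f))
    for (a in 1:4)
      lines <- c(lines, sprintf(
        "ATOM  %5d  C%d  LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
        a, a, co[a, 1, f], co[a, 2, f], co[a, 3, f]))
    lines <- c(lines, "ENDMDL")
  }
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), pdb)
  got <- readMultiModelPDB(pdb)
  expect_identical(dim(got), c(4L, 3L, 3L))
  expect_equal(got[, , 2], co[, , 2], tolerance = 1e-9)
  defs <- DescriptorSet("d1", "distance", list(c(0L, 3L)))
  ts <- featurizeTrajectory(got, defs)
  expect_identical(dim(tensors(ts)), c(3L, 1L, 1L))
})

test_that("descriptor definition files round-trip and validate", {
  defs <- defaultDescriptorSet()
  expect_length(defs, 15L)
  f <- tempfile()
  writeDescriptorDefinitions(defs, f)
  back <- readDescriptorDefinitions(f)
  expect_identical(back@name, defs@name)
  expect_identical(back@kind, defs@kind)
  expect_identical(back@atoms, defs@atoms)
  expect_identical(back@units, defs@units)
  # validity: tuple length, duplicate atoms
  expect_error(DescriptorSet("x", "angle", list(c(0L, 1L))), "tuple")
  expect_error(DescriptorSet("x", "distance", list(c(1L, 1L))), "distinct")
})

test_that("min-max normalizer fits on train only, inverts, clips", {
  ts <- tinyTS()
  norm <- fitNormalizer(ts)
  # worked value: channel with train range [2, 4], value 3 -> 0.5
  norm2 <- list(method = "minmax", offset = 2, scale = 2, names = "x")
  expect_equal(as.numeric(applyNormalizer(matrix(3), norm2)), 0.5)
  # round trip on in-range values
  x <- tensors(tinyTS())[, , 1:5]
  normed <- suppressMessages(applyNormalizer(x, fitNormalizer(tinyTS(),
                                             indices = 1:5)))
  back <- invertNormalizer(normed, fitNormalizer(tinyTS(), indices = 1:5))
  expect_equal(back, x, tolerance = 1e-12)
  # train-only fitting: extending the fit set must change the extrema
  cfgW <- generatorConfig(n_ligands = 3, n_per_class = 2, n_frames = 100,
                          master_seed = 77)
  tsW <- generateDataset(cfgW)
  nTr <- fitNormalizer(tsW, indices = 1:4)
  nAll <- fitNormalizer(tsW, indices = seq_len(nTrajectories(tsW)))
  expect_false(isTRUE(all.equal(nTr$offset, nAll$offset)) &&
                 isTRUE(all.equal(nTr$scale, nAll$scale)))
  # values outside the train range are clipped and reported
  expect_message(out <- applyNormalizer(matrix(c(-1, 5), 2, 1), norm2),
                 "clipped")
  expect_equal(as.numeric(out), c(0, 1))
  # constant channel
  cts <- tsW
  cts@tensors[, 2, ] <- 7
  expect_warning(nc <- fitNormalizer(cts), "constant")
  expect_equal(nc$scale[2], 1)
})
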