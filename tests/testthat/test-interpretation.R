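test_that("1D CAM has the documented geometry, alignment and equivariance", {
  fx <- bigFixture()
  x <- tensors(fx$ts)[, , validationIndices(fx$ts)[1]]
  sal <- computeCAM1D(fx$model, x)
  act <- saliency(sal, upsampled = FALSE)
  up <- saliency(sal)
  expect_identical(dim(act), c(16L, 192L))
  expect_identical(dim(up), c(16L, 1000L))
  expect_true(all(act >= 0))
  # nearest-neighbour upsampling by the pooling factor with edge padding:
  # 192 x 5 = 960 interior columns, 20 on each edge
  expect_identical(up[, 21:980], act[, rep(1:192, each = 5)])
  expect_true(all(up[, 1:20] == up[, 21]))
  expect_true(all(up[, 981:1000] == up[, 980]))
  # raw mode returns the rectified feature maps themselves
  raw <- computeCAM1D(fx$model, x, mode = "cam_raw")
  w <- drop(modelParameters(fx$model)$Wd)
  expect_equal(saliency(sal, upsampled = FALSE),
               pmax(w * saliency(raw, upsampled = FALSE), 0),
               tolerance = 1e-12)
  # permuting conv filters and dense weights permutes saliency rows
  perm <- c(3:16, 1:2)
  mp <- fx$model
  mp@params$W2 <- mp@params$W2[, , perm]
  mp@params$b2 <- mp@params$b2[perm]
  mp@params$Wd <- mp@params$Wd[perm, , drop = FALSE]
  sal2 <- computeCAM1D(mp, x)
  expect_equal(saliency(sal2, upsampled = FALSE),
               saliency(sal, upsampled = FALSE)[perm, ],
               tolerance = 1e-12)
  # all-zero feature maps produce all-zero saliency
  mz <- fx$model
  mz@params$W2[] <- 0; mz@params$b2[] <- 0
  expect_true(all(saliency(computeCAM1D(mz, x)) == 0))
  # architectures without feature maps before the output unit refuse
  expect_error(computeCAM1D(buildCNN2D(seed = 1), x), "unsupported")
})

test_that("saliency time indices map to the correct input footprint", {
  set.seed(13)
  # brute force: perturb one input frame and record which outputs move
  params <- trajsel:::initCNN1D(2L, filters = 3L, kernel = 7L, pool = 5L)
  T <- 80L
  X <- array(rnorm(T * 2), c(T, 2, 1))
  base <- trajsel:::cnn1dForward(params, X)$featureMap
  for (t in c(1L, 4L, 8L)) {   # map indices of the second conv layer
    fp <- trajsel:::cam1dReceptiveField(t)
    touched <- logical(T)
    for (fr in seq_len(T)) {
      Xp <- X; Xp[fr, , 1] <- Xp[fr, , 1] + 10
      moved <- trajsel:::cnn1dForward(params, Xp)$featureMap[t, , 1] !=
        base[t, , 1]
      touched[fr] <- any(moved)
    }
    expect_true(all(which(touched) >= fp[1] & which(touched) <= fp[2]))
    # footprint endpoints genuinely influence the output
    expect_true(touched[fp[1]] || touched[fp[1] + 1L])
    expect_true(touched[fp[2]] || touched[fp[2] - 1L])
  }
})

test_that("max-activation records locate class-separating descriptor values", {
  fx <- bigFixture()
  mx <- extractMaxActivationValues(fx$model, fx$ts, filter_id = 4L,
                                   indices = "validation")
  nval <- length(validationIndices(fx$ts))
  expect_identical(nrow(mx), nval)
  expect_true(all(mx$argmax_time >= 1 & mx$argmax_time <= nFrames(fx$ts)))
  # ties break to the earliest index: constant saliency model
  mz <- fx$model
  mz@params$W2[] <- 0; mz@params$b2[] <- 1
  mx0 <- extractMaxActivationValues(mz, fx$ts,
                                    indices = validationIndices(fx$ts)[1:3])
  expect_true(all(mx0$argmax_time == 1L))
  # activations spread over the whole trajectory, not one quarter
  qs <- table(cut(mx$argmax_time, breaks = c(0, 250, 500, 750, 1000)))
  expect_lt(max(qs) / nval, 0.75)
  # the coupled query channel separates classes at max activation,
  # an uncoupled channel does not
  ksD4 <- suppressWarnings(
    ks.test(mx$d4[mx$class == "reactive"],
            mx$d4[mx$class == "non-reactive"]))
  expect_lt(ksD4$p.value, 0.01)
  ksD1 <- suppressWarnings(
    ks.test(mx$d1[mx$class == "reactive"],
            mx$d1[mx$class == "non-reactive"]))
  expect_gt(ksD1$p.value, 0.01)
  expect_error(extractMaxActivationValues(fx$model, fx$ts, filter_id = 99L),
               "filter id")
})

test_that("Grad-CAM is rectified, upsampled, and reduces to weighted maps", {
  set.seed(14)
  m <- buildCNN2DCAM(input_size = 46L, seed = 3)
  img <- matrix(runif(46 * 46), 46, 46)
  sal <- computeGradCAM2D(m, img)
  expect_true(all(saliency(sal) >= 0))
  expect_identical(dim(saliency(sal)), c(46L, 46L))
  expect_identical(sal@mode, "gradcam")
  # closed form: with the dense path opened up (all-positive hidden
  # pre-activations), channel weights are exactly the spatially averaged
  # gradients; verify the map against a direct computation
  fwd <- trajsel:::camForward(m@params, array(img, c(46, 46, 1, 1)))
  sign <- if (fwd$prob >= 0.5) 1 else -1
  dZd1 <- sign * t(m@params$Wd2) * (fwd$Zd1 > 0)
  dFlat <- m@params$Wd1 %*% t(dZd1)
  dFm <- array(dFlat, fwd$cache$d4)
  wts <- apply(dFm[, , , 1, drop = FALSE], 3, mean)
  manual <- matrix(0, 1, 1)
  for (f in seq_len(16)) manual <- manual + wts[f] * fwd$featureMap[, , f, 1]
  manual <- pmax(manual, 0)
  expect_equal(saliency(sal, upsampled = FALSE), manual, tolerance = 1e-12)
  expect_error(computeGradCAM2D(buildCNN1D(seed = 1), img), "unsupported")
})

test_that("Grad-CAM of a pixel detector highlights trace bands over gaps", {
  # a hand-built dark-pixel detector: filter 1 of every conv layer
  # averages its receptive field of the trace mask; the dense head reads
  # it out. The saliency of such a model must concentrate on the bands
  # that contain trajectory traces, not the blank separators.
  m <- buildCNN2DCAM(input_size = 94L, render_gap = 8L, seed = 4)
  for (l in 1:4) {
    K <- m@params[[paste0("K", l)]] * 0
    if (l == 1) K[, , 1, 1] <- -1 / 9 else K[, , 1, 1] <- 1 / 9
    m@params[[paste0("K", l)]] <- K
    b <- m@params[[paste0("b", l)]] * 0
    if (l == 1) b[1] <- 1          # background 1 -> response 0
    m@params[[paste0("b", l)]] <- b
  }
  m@params$Wd1[] <- 0
  m@params$Wd1[, 1] <- 1 / nrow(m@params$Wd1)
  m@params$bd1[] <- 0
  m@params$Wd2[] <- 0; m@params$Wd2[1, 1] <- 1; m@params$bd2 <- 0
  set.seed(15)
  tensor <- matrix(runif(120 * 5), 120, 5)
  img <- renderTrajectoryImage(tensor, size = 94L, gap = 8L)
  up <- saliency(computeGradCAM2D(m, img, target = "reactive"))
  slot <- 94L %/% 5L; bandH <- slot - 8L
  bandRows <- unlist(lapply(0:4, function(d) d * slot + seq_len(bandH)))
  gapRows <- setdiff(seq_len(94L), bandRows)
  expect_gt(mean(up[bandRows, ]), mean(up[gapRows, ]))
})

test_that("t-SNE projects duplicated points together and separates classes", {
  set.seed(16)
  # duplicated rows stay (near) coincident
  X <- matrix(rnorm(40 * 5), 40, 5)
  X <- rbind(X, X[1:5, ])
  Y <- trajsel:::tsneEmbed(X, perplexity = 8, maxIter = 600, seed = 2)
  for (i in 1:5) {
    dup <- sqrt(sum((Y[40 + i, ] - Y[i, ]) ^ 2))
    others <- sqrt(rowSums(sweep(Y[-c(i, 40 + i), ], 2, Y[i, ]) ^ 2))
    expect_lt(dup, median(others) / 2)
  }
  expect_error(trajsel:::tsneEmbed(X[1:10, ], perplexity = 30), "too few")
})

test_that("latent projection of the trained classifier separates classes", {
  skip_if_not_installed("cluster")
  fx <- bigFixture()
  proj <- projectLatentSpace(fx$model, fx$ts, "validation",
                             perplexity = 30, max_iter = 400, seed = 1)
  expect_identical(nrow(proj), length(validationIndices(fx$ts)))
  expect_identical(colnames(proj),
                   c("tsne1", "tsne2", "class", "ligand_id", "trajectory"))
  sil <- cluster::silhouette(as.integer(factor(proj$class)),
                             dist(cbind(proj$tsne1, proj$tsne2)))
  expect_gt(mean(sil[, 3]), 0)
})

test_that("the ablation protocol has the 15 + All layout and finds planted signal", {
  # the heavier planted-signal recovery runs in the acceptance suite;
  # here the protocol shape is exercised at a miniature scale
  cfg <- generatorConfig(n_ligands = 2, n_per_class = 6, n_frames = 100,
                         n_channels = 4L, slow_channel = 3L,
                         coupled_channels = 4L, master_seed = 19)
  ts <- splitByLigand(generateDataset(cfg), 1L, 2L)
  ts <- suppressMessages(applyNormalizer(ts, fitNormalizer(ts)))
  ab <- ablationStudy(ts, replicas = 2L, epochs = 2L, seed = 1)
  tb <- ablationTable(ab)
  expect_identical(nrow(tb), 5L)               # All + one row per channel
  expect_identical(tb$name[1], "All")
  expect_identical(tb$channel[-1], 1:4)
  expect_true(all(tb$mean_accuracy >= 0 & tb$mean_accuracy <= 1))
  expect_true(all(tb$sd_accuracy >= 0))
  expect_identical(ab@replicas, 2L)
  expect_error(ablationStudy(ts, channels = 9L), "out of range")
})
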