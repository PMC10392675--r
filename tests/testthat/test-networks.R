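# The layer stacks are implemented from first principles; every backward
# pass is checked against central finite differences on small shapes.

test_that("1D-CNN analytic gradients match finite differences", {
  set.seed(42)
  X <- array(rnorm(30 * 3 * 2), c(30, 3, 2))
  y <- c(1, 0)
  params <- trajsel:::initCNN1D(3L, filters = 4L, kernel = 3L, pool = 2L)
  lossOf <- function(p) trajsel:::bceLoss(trajsel:::cnn1dForward(p, X)$prob, y)
  fwd <- trajsel:::cnn1dForward(params, X)
  grads <- trajsel:::cnn1dBackward(params, fwd, (fwd$prob - y) / 2)
  for (nm in c("W1", "b1", "W2", "b2", "Wd", "bd")) {
    f <- function(v) { p <- params; p[[nm]][] <- v; lossOf(p) }
    ng <- numGrad(f, as.numeric(params[[nm]]))
    expect_equal(as.numeric(grads[[nm]]), ng, tolerance = 1e-6)
  }
})

test_that("2D-CNN analytic gradients match finite differences", {
  set.seed(7)
  X <- array(rnorm(4 * 40 * 2), c(4, 40, 1, 2))
  y <- c(0, 1)
  params <- trajsel:::initCNN2D(4L, 40L, dropout = 0)
  lossOf <- function(p)
    trajsel:::bceLoss(trajsel:::cnn2dForward(p, X, train = FALSE)$prob, y)
  fwd <- trajsel:::cnn2dForward(params, X, train = FALSE)
  grads <- trajsel:::cnn2dBackward(params, fwd, (fwd$prob - y) / 2)
  for (nm in c("K1", "b1", "K2", "b2", "Wd", "bd")) {
    f <- function(v) { p <- params; p[[nm]][] <- v; lossOf(p) }
    ng <- numGrad(f, as.numeric(params[[nm]]))
    expect_equal(as.numeric(grads[[nm]]), ng, tolerance = 1e-6)
  }
})

test_that("saliency-model and LSTM gradients match finite differences", {
  set.seed(8)
  # four conv/pool blocks close at a 46-pixel input (final map 1x1x16)
  params <- trajsel:::initCNN2DCAM(46L)
  X <- array(rnorm(46 * 46), c(46, 46, 1, 1)); y <- 1
  lossOf <- function(p)
    trajsel:::bceLoss(trajsel:::camForward(p, X)$prob, y)
  fwd <- trajsel:::camForward(params, X)
  grads <- trajsel:::camBackward(params, fwd, fwd$prob - y)
  for (nm in c("K2", "b3", "K4", "Wd1", "Wd2", "bd2")) {
    v <- as.numeric(params[[nm]])
    pick <- if (length(v) > 120) sample(length(v), 120) else seq_along(v)
    f <- function(vv) { p <- params
      w <- as.numeric(p[[nm]]); w[pick] <- vv; p[[nm]][] <- w; lossOf(p) }
    ng <- numGrad(f, v[pick])
    expect_equal(as.numeric(grads[[nm]])[pick], ng, tolerance = 1e-5)
  }
  # stacked LSTM forecaster
  Xw <- array(rnorm(6 * 3 * 2), c(6, 3, 2)); yw <- rnorm(2)
  lp <- trajsel:::initLSTMForecaster(3L, 5L, 4L)
  lossOf <- function(p)
    mean((trajsel:::lstmForecasterForward(p, Xw)$pred - yw)^2)
  fwd <- trajsel:::lstmForecasterForward(lp, Xw)
  grads <- trajsel:::lstmForecasterBackward(lp, Xw, fwd,
                                            2 * (fwd$pred - yw) / 2)
  flat <- trajsel:::flattenLSTMParams(lp)
  for (nm in names(flat)) {
    f <- function(v) { fl <- flat; fl[[nm]][] <- v
      lossOf(trajsel:::unflattenLSTMParams(fl)) }
    ng <- numGrad(f, as.numeric(flat[[nm]]))
    expect_equal(as.numeric(grads[[nm]]), ng, tolerance = 1e-6)
  }
})

test_that("1D-CNN shape arithmetic: 1000 -> 994 -> 198 -> 192 -> 16", {
  m <- buildCNN1D(seed = 1)
  X <- array(rnorm(1000 * 15), c(1000, 15, 1))
  fwd <- trajsel:::cnn1dForward(m@params, X)
  expect_identical(dim(fwd$cache$Z1)[1:2], c(994L, 16L))
  expect_identical(dim(fwd$cache$P1$out)[1:2], c(198L, 16L))
  expect_identical(dim(fwd$cache$Z2)[1:2], c(192L, 16L))
  expect_identical(dim(fwd$emb), c(1L, 16L))
  expect_true(fwd$prob > 0 && fwd$prob < 1)
})

test_that("2D-CNN shape arithmetic: 996 -> 332 -> 328 -> 109, flatten 6540", {
  m <- buildCNN2D(seed = 1)
  X <- array(rnorm(15 * 1000), c(15, 1000, 1, 1))
  fwd <- trajsel:::cnn2dForward(m@params, X, train = FALSE)
  expect_identical(dim(fwd$cache$Z1)[1:3], c(15L, 996L, 8L))
  expect_identical(dim(fwd$cache$P1$out)[1:3], c(15L, 332L, 8L))
  expect_identical(dim(fwd$cache$Z2)[1:3], c(15L, 328L, 4L))
  expect_identical(dim(fwd$cache$P2$out)[1:3], c(15L, 109L, 4L))
  expect_identical(nrow(fwd$flat), 6540L)
  expect_true(fwd$prob > 0 && fwd$prob < 1)
})

test_that("saliency 2D-CNN spatial sizes: 318 ... 18, flatten 5184", {
  expect_identical(trajsel:::camSpatialSizes(320L),
                   c(318L, 159L, 157L, 78L, 76L, 38L, 36L, 18L))
  m <- buildCNN2DCAM(seed = 1)
  X <- array(runif(320 * 320), c(320, 320, 1, 1))
  fwd <- trajsel:::camForward(m@params, X)
  expect_identical(dim(fwd$featureMap)[1:3], c(18L, 18L, 16L))
  expect_identical(nrow(fwd$flat), 5184L)
  expect_true(fwd$prob > 0 && fwd$prob < 1)
})

test_that("height-1 kernels give channel-permutation equivariance", {
  set.seed(9)
  m <- buildCNN2D(n_channels = 6L, n_frames = 60L, seed = 2)
  X <- array(rnorm(6 * 60), c(6, 60, 1, 1))
  perm <- sample(6)
  Xp <- X[perm, , , , drop = FALSE]
  f1 <- trajsel:::cnn2dForward(m@params, X, train = FALSE)
  f2 <- trajsel:::cnn2dForward(m@params, Xp, train = FALSE)
  # rows of every pre-flatten feature map permute with the input
  expect_equal(f2$cache$P2$out[, , , 1], f1$cache$P2$out[perm, , , 1],
               tolerance = 1e-12)
})

test_that("training is reproducible under a fixed seed", {
  ts <- tinyTS()
  f1 <- trainClassifier(buildCNN1D(seed = 3), ts, epochs = 2, seed = 3)
  f2 <- trainClassifier(buildCNN1D(seed = 3), ts, epochs = 2, seed = 3)
  expect_identical(trainingHistory(f1), trainingHistory(f2))
  expect_identical(modelParameters(f1), modelParameters(f2))
  f3 <- trainClassifier(buildCNN1D(seed = 4), ts, epochs = 2, seed = 4)
  expect_false(identical(modelParameters(f1), modelParameters(f3)))
})

test_that("non-finite losses abort with diagnostics", {
  ts <- tinyTS()
  m <- buildCNN1D(seed = 1)
  m@params$Wd[] <- NaN
  expect_error(trainClassifier(m, ts, epochs = 1, seed = 1),
               "non-finite loss")
})
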