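#' @include AllClasses.R nn-core.R nn-lstm.R dataset.R
NULL

newModel <- function(arch, spec, params, normalizer = NULL) {
  new("TrainedModel", arch = arch, spec = spec, params = params,
      history = data.frame(), normalizer = normalizer, threshold = 0.5)
}

#' Build the 1D-CNN trajectory classifier
#'
#' Layer stack: Conv1D (16 filters, kernel 7) - MaxPooling1D (5) -
#' Conv1D (16 filters, kernel 7) - GlobalMaxPooling1D - Dense (1,
#' sigmoid); hidden activations ReLU, valid padding throughout, so a
#' 1,000-frame input passes through lengths 994, 198, 192 and a
#' 16-vector embedding. Default training regime: binary cross-entropy,
#' RMSprop with learning rate 1e-4, 10 epochs, minibatches of 8.
#'
#' @param n_channels input channels (default 15).
#' @param filters,kernel,pool architecture sizes (defaults 16, 7, 5).
#' @param epochs,batch_size,lr training regime defaults.
#' @param seed weight-initialization seed.
#' @return an untrained [TrainedModel] (arch \code{"cnn1d"}).
#' @export
buildCNN1D <- function(n_channels = 15L, filters = 16L, kernel = 7L,
                       pool = 5L, epochs = 10L, batch_size = 8L,
                       lr = 1e-4, seed = 1L) {
  params <- withSeed(seed, initCNN1D(n_channels, filters, kernel, pool))
  newModel("cnn1d",
           list(n_channels = n_channels, filters = filters, kernel = kernel,
                pool = pool, epochs = epochs, batch_size = batch_size,
                optimizer = "rmsprop", lr = lr, loss = "bce", seed = seed),
           params)
}

#' Build the 2D-CNN trajectory classifier
#'
#' Input shape channels x frames x 1. Stack: Conv2D (8 filters, 1x5) -
#' MaxPooling2D (1x3) - Dropout (0.3) - Conv2D (4 filters, 1x5) -
#' MaxPooling2D (1x3) - Flatten - Dense (1, sigmoid). The height-1
#' kernels never mix descriptor channels; with 15 x 1000 inputs the
#' widths along time are 996, 332, 328, 109 and the flatten length is
#' 15 x 109 x 4 = 6,540. Default regime: binary cross-entropy, RMSprop
#' 1e-4, 20 epochs, minibatches of 16.
#'
#' @param n_channels,n_frames input image size (defaults 15, 1000).
#' @param dropout dropout rate after the first pooling (default 0.3).
#' @param epochs,batch_size,lr training regime defaults.
#' @param seed weight-initialization seed.
#' @return an untrained [TrainedModel] (arch \code{"cnn2d"}).
#' @export
buildCNN2D <- function(n_channels = 15L, n_frames = 1000L, dropout = 0.3,
                       epochs = 20L, batch_size = 16L, lr = 1e-4,
                       seed = 1L) {
  params <- withSeed(seed, initCNN2D(n_channels, n_frames, dropout))
  newModel("cnn2d",
           list(n_channels = n_channels, n_frames = n_frames,
                dropout = dropout, epochs = epochs, batch_size = batch_size,
                optimizer = "rmsprop", lr = lr, loss = "bce", seed = seed),
           params)
}

#' Build the overparameterised 2D-CNN used for saliency imaging
#'
#' Input: rendered trajectory images (size x size x 1, default 320).
#' Stack: Conv2D 3x3 with 128/64/32/16 filters, each followed by 2x2
#' max pooling, then Flatten - Dense (256, ReLU) - Dense (1, sigmoid).
#' At 320 the spatial sizes run 318, 159, 157, 78, 76, 38, 36, 18; the
#' final feature map is 18 x 18 x 16 (flatten length 5,184). Default
#' regime: binary cross-entropy, RMSprop 1e-4, 20 epochs, minibatch 1.
#'
#' @param input_size image side length (default 320).
#' @param render_gap blank separator rows used when rendering input
#'   images (see [renderTrajectoryImage()]).
#' @param epochs,batch_size,lr training regime defaults.
#' @param seed weight-initialization seed.
#' @return an untrained [TrainedModel] (arch \code{"cnn2d_cam"}).
#' @export
buildCNN2DCAM <- function(input_size = 320L, render_gap = 4L,
                          epochs = 20L, batch_size = 1L,
                          lr = 1e-4, seed = 1L) {
  params <- withSeed(seed, initCNN2DCAM(input_size))
  newModel("cnn2d_cam",
           list(input_size = input_size, render_gap = render_gap,
                epochs = epochs,
                batch_size = batch_size, optimizer = "rmsprop", lr = lr,
                loss = "bce", seed = seed),
           params)
}

#' Build the LSTM next-step forecaster
#'
#' Stack: LSTM (16 units, tanh) - LSTM (8 units, tanh) - Dense (1,
#' linear). Consumes windows of 50 steps x 15 descriptors and predicts
#' the query descriptor at the next step; the second recurrent layer's
#' final state is the 8-dimensional embedding used downstream. Default
#' regime: mean squared error, Adam with learning rate 0.01, 5 epochs,
#' batch 128.
#'
#' @param n_channels input channels (default 15).
#' @param units1,units2 recurrent layer sizes (defaults 16, 8).
#' @param epochs,batch_size,lr training regime defaults.
#' @param seed weight-initialization seed.
#' @return an untrained [TrainedModel] (arch \code{"lstm_forecaster"}).
#' @export
buildLSTMForecaster <- function(n_channels = 15L, units1 = 16L,
                                units2 = 8L, epochs = 5L,
                                batch_size = 128L, lr = 0.01, seed = 1L) {
  params <- withSeed(seed, initLSTMForecaster(n_channels, units1, units2))
  newModel("lstm_forecaster",
           list(n_channels = n_channels, units1 = units1, units2 = units2,
                epochs = epochs, batch_size = batch_size,
                optimizer = "adam", lr = lr, loss = "mse", seed = seed),
           params)
}

#' Build the forecasting reference models
#'
#' Four comparators sharing the [ForecastWindowSet] interface:
#' \code{baseline} predicts the last observed query value (no
#' parameters); \code{linear} is an affine map on the flattened window;
#' \code{dense} adds one ReLU hidden layer (64 units); and
#' \code{cnn1d_forecaster} is the smallest temporal-convolution
#' regressor (Conv1D 16 filters kernel 7 - GlobalMaxPool - Dense 1).
#'
#' @param n_channels,window input window shape (defaults 15, 50).
#' @param seed weight-initialization seed.
#' @return named list of untrained [TrainedModel] objects.
#' @export
buildForecastBaselines <- function(n_channels = 15L, window = 50L,
                                   seed = 1L) {
  flat <- n_channels * window
  common <- list(n_channels = n_channels, window = window, epochs = 5L,
                 batch_size = 128L, optimizer = "adam", lr = 0.01,
                 loss = "mse", seed = seed)
  withSeed(seed, list(
    baseline = newModel("baseline", common, list()),
    linear = newModel("linear", common,
                      list(W = glorotInit(c(flat, 1), flat, 1), b = 0)),
    dense = newModel("dense", common,
                     list(W1 = glorotInit(c(flat, 64), flat, 64),
                          b1 = numeric(64),
                          W2 = glorotInit(c(64, 1), 64, 1), b2 = 0)),
    cnn1d_forecaster = newModel("cnn1d_forecaster", common,
                                list(W1 = glorotInit(c(7, n_channels, 16),
                                                     7 * n_channels, 16),
                                     b1 = numeric(16),
                                     Wd = glorotInit(c(16, 1), 16, 1),
                                     bd = 0))))
}

# --------------------------------------------------------------- training --

classifierBatchGrad <- function(model, X, y, train = TRUE) {
  if (model@arch == "cnn1d") {
    fwd <- cnn1dForward(model@params, X)
    dLogit <- (fwd$prob - y) / length(y)
    list(fwd = fwd, grads = cnn1dBackward(model@params, fwd, dLogit))
  } else if (model@arch == "cnn2d") {
    fwd <- cnn2dForward(model@params, X, train = train)
    dLogit <- (fwd$prob - y) / length(y)
    list(fwd = fwd, grads = cnn2dBackward(model@params, fwd, dLogit))
  } else if (model@arch == "cnn2d_cam") {
    fwd <- camForward(model@params, X)
    dLogit <- (fwd$prob - y) / length(y)
    list(fwd = fwd, grads = camBackward(model@params, fwd, dLogit))
  } else stop("unsupported classifier architecture: ", model@arch)
}

classifierInput <- function(model, ts, idx) {
  if (model@arch == "cnn1d") {
    ts@tensors[, , idx, drop = FALSE]
  } else if (model@arch == "cnn2d") {
    x <- aperm(ts@tensors[, , idx, drop = FALSE], c(2, 1, 3))
    array(x, c(dim(x)[1], dim(x)[2], 1L, dim(x)[3]))
  } else if (model@arch == "cnn2d_cam") {
    size <- model@spec$input_size
    gap <- if (is.null(model@spec$render_gap)) 4L else model@spec$render_gap
    out <- array(NA_real_, c(size, size, 1L, length(idx)))
    for (j in seq_along(idx))
      out[, , 1L, j] <- renderTrajectoryImage(ts@tensors[, , idx[j]],
                                              size = size, gap = gap)
    out
  } else stop("unsupported classifier architecture: ", model@arch)
}

binaryTargets <- function(labels) {
  if (anyNA(labels)) stop("labeling error: missing class labels")
  as.numeric(labels == "reactive")
}

#' Train a binary trajectory classifier
#'
#' Runs the model's training regime (optimizer, learning rate, epochs,
#' batch size from the builder, overridable here) on the training split
#' of a normalized [TrajectorySet]. Shuffling and weight randomness are
#' fully seeded; the validation split is never touched during fitting.
#' Aborts with diagnostics if the loss turns non-finite.
#'
#' @param model an untrained classifier from [buildCNN1D()],
#'   [buildCNN2D()] or [buildCNN2DCAM()].
#' @param ts a normalized [TrajectorySet] with a split assigned (or
#'   \code{indices} given explicitly).
#' @param epochs,batch_size,lr,seed optional overrides of the model's
#'   regime.
#' @param indices training trajectories (default: the training split).
#' @param channels optional channel subset (used by the ablation
#'   protocol); the model must have been built for that width.
#' @param verbose print per-epoch progress.
#' @return the fitted [TrainedModel] with per-epoch history.
#' @export
trainClassifier <- function(model, ts, epochs = NULL, batch_size = NULL,
                            lr = NULL, seed = NULL, indices = NULL,
                            channels = NULL, verbose = FALSE) {
  spec <- model@spec
  if (!is.null(epochs)) spec$epochs <- epochs
  if (!is.null(batch_size)) spec$batch_size <- batch_size
  if (!is.null(lr)) spec$lr <- lr
  if (!is.null(seed)) spec$seed <- seed
  idx <- resolveIndices(ts, if (is.null(indices)) "train" else indices)
  if (!is.null(channels)) {
    ts@tensors <- ts@tensors[, channels, , drop = FALSE]
    ts@descriptors <- DescriptorSet(descriptorNames(ts)[channels],
                                    ts@descriptors@kind[channels],
                                    ts@descriptors@atoms[channels],
                                    ts@descriptors@units[channels])
  }
  y <- binaryTargets(classLabels(ts)[idx])
  opt <- makeOptimizer(spec$optimizer, spec$lr)
  params <- model@params
  hist <- data.frame()
  withSeed(deriveSeed(spec$seed, 101L), {
    for (ep in seq_len(spec$epochs)) {
      ord <- sample(length(idx))
      lossSum <- 0; correct <- 0
      for (b in split(ord, ceiling(seq_along(ord) / spec$batch_size))) {
        model@params <- params
        X <- classifierInput(model, ts, idx[b])
        bg <- classifierBatchGrad(model, X, y[b], train = TRUE)
        loss <- bceLoss(bg$fwd$prob, y[b])
        if (!is.finite(loss))
          stop("training aborted: non-finite loss at epoch ", ep,
               " (lr ", spec$lr, ", batch ", spec$batch_size, ")")
        lossSum <- lossSum + loss * length(b)
        correct <- correct +
          sum((bg$fwd$prob >= model@threshold) == (y[b] == 1))
        keep <- intersect(names(bg$grads), names(params))
        params <- optimizerStep(opt, params, bg$grads[keep])
      }
      hist <- rbind(hist, data.frame(epoch = ep,
                                     loss = lossSum / length(idx),
                                     accuracy = correct / length(idx)))
      if (verbose)
        message(sprintf("epoch %d/%d  loss %.4f  acc %.4f", ep,
                        spec$epochs, lossSum / length(idx),
                        correct / length(idx)))
    }
  })
  model@params <- params
  model@spec <- spec
  model@history <- hist
  model@normalizer <- ts@normalizer
  model
}

#' Classifier scores for a set of trajectories
#'
#' @param model a trained classifier.
#' @param ts a [TrajectorySet] normalized like the training data.
#' @param indices trajectories to score (default all; accepts
#'   \code{"train"}/\code{"validation"}).
#' @param batch_size scoring batch size.
#' @return numeric vector of sigmoid scores in (0, 1).
#' @export
predictClassifier <- function(model, ts, indices = NULL, batch_size = 64L) {
  idx <- resolveIndices(ts, indices)
  out <- numeric(length(idx))
  for (b in split(seq_along(idx), ceiling(seq_along(idx) / batch_size))) {
    X <- classifierInput(model, ts, idx[b])
    out[b] <- switch(model@arch,
      cnn1d = cnn1dForward(model@params, X)$prob,
      cnn2d = cnn2dForward(model@params, X, train = FALSE)$prob,
      cnn2d_cam = camForward(model@params, X)$prob,
      stop("unsupported classifier architecture: ", model@arch))
  }
  out
}

#' Penultimate-layer embeddings of the 1D-CNN
#'
#' The 16-dimensional post-GlobalMaxPool vector per trajectory.
#'
#' @inheritParams predictClassifier
#' @return matrix, trajectories x filters.
#' @export
cnn1dEmbeddings <- function(model, ts, indices = NULL, batch_size = 64L) {
  stopifnot(model@arch == "cnn1d")
  idx <- resolveIndices(ts, indices)
  out <- NULL
  for (b in split(seq_along(idx), ceiling(seq_along(idx) / batch_size))) {
    X <- classifierInput(model, ts, idx[b])
    emb <- cnn1dForward(model@params, X)$emb
    out <- rbind(out, emb)
  }
  out
}

# ------------------------------------------------------------- forecasting --

forecasterPredictBatch <- function(model, X) {
  switch(model@arch,
    baseline = {
      q <- attr(X, "queryChannel")
      X[dim(X)[1], q, ]
    },
    linear = {
      flat <- matrix(X, prod(dim(X)[1:2]), dim(X)[3])
      drop(t(flat) %*% model@params$W) + model@params$b
    },
    dense = {
      flat <- matrix(X, prod(dim(X)[1:2]), dim(X)[3])
      h <- reluFwd(t(flat) %*% model@params$W1 +
                     matrix(model@params$b1, ncol(flat), 64, byrow = TRUE))
      drop(h %*% model@params$W2) + model@params$b2
    },
    cnn1d_forecaster = cnn1dRegForward(model@params, X)$pred,
    lstm_forecaster = lstmForecasterForward(model@params, X)$pred,
    stop("unsupported forecaster architecture: ", model@arch))
}

forecasterBatchGrad <- function(model, X, y) {
  if (model@arch == "lstm_forecaster") {
    fwd <- lstmForecasterForward(model@params, X)
    dPred <- 2 * (fwd$pred - y) / length(y)
    list(pred = fwd$pred,
         grads = lstmForecasterBackward(model@params, X, fwd, dPred),
         nested = TRUE)
  } else if (model@arch == "cnn1d_forecaster") {
    fwd <- cnn1dRegForward(model@params, X)
    dPred <- 2 * (fwd$pred - y) / length(y)
    list(pred = fwd$pred,
         grads = cnn1dRegBackward(model@params, fwd, dPred))
  } else if (model@arch == "linear") {
    flat <- matrix(X, prod(dim(X)[1:2]), dim(X)[3])
    pred <- drop(t(flat) %*% model@params$W) + model@params$b
    dPred <- 2 * (pred - y) / length(y)
    list(pred = pred,
         grads = list(W = flat %*% matrix(dPred, ncol = 1),
                      b = sum(dPred)))
  } else if (model@arch == "dense") {
    flat <- matrix(X, prod(dim(X)[1:2]), dim(X)[3])
    Z1 <- t(flat) %*% model@params$W1 +
      matrix(model@params$b1, ncol(flat), 64, byrow = TRUE)
    A1 <- reluFwd(Z1)
    pred <- drop(A1 %*% model@params$W2) + model@params$b2
    dPred <- 2 * (pred - y) / length(y)
    dA1 <- matrix(dPred, ncol = 1) %*% t(model@params$W2)
    dZ1 <- dA1 * (Z1 > 0)
    list(pred = pred,
         grads = list(W1 = flat %*% dZ1, b1 = colSums(dZ1),
                      W2 = t(A1) %*% matrix(dPred, ncol = 1),
                      b2 = sum(dPred)))
  } else stop("unsupported forecaster architecture: ", model@arch)
}

#' Train a next-step forecaster
#'
#' Minimizes mean squared error over a [ForecastWindowSet] with the
#' model's regime (default Adam, learning rate 0.01, 5 epochs, batch
#' 128). The \code{baseline} model has no parameters and returns
#' immediately with its evaluation history.
#'
#' @param model from [buildLSTMForecaster()] or
#'   [buildForecastBaselines()].
#' @param windows a [ForecastWindowSet].
#' @param epochs,batch_size,lr,seed optional regime overrides.
#' @param verbose print per-epoch progress.
#' @return the fitted [TrainedModel].
#' @export
trainForecaster <- function(model, windows, epochs = NULL,
                            batch_size = NULL, lr = NULL, seed = NULL,
                            verbose = FALSE) {
  spec <- model@spec
  if (!is.null(epochs)) spec$epochs <- epochs
  if (!is.null(batch_size)) spec$batch_size <- batch_size
  if (!is.null(lr)) spec$lr <- lr
  if (!is.null(seed)) spec$seed <- seed
  X <- windows@inputs
  y <- windows@targets
  if (model@arch == "baseline") {
    attr(X, "queryChannel") <- windows@queryChannel
    mse <- mean((forecasterPredictBatch(model, X) - y)^2)
    model@history <- data.frame(epoch = 1L, loss = mse)
    model@spec <- spec
    return(model)
  }
  opt <- makeOptimizer(spec$optimizer, spec$lr)
  nested <- model@arch == "lstm_forecaster"
  params <- if (nested) flattenLSTMParams(model@params) else model@params
  hist <- data.frame()
  withSeed(deriveSeed(spec$seed, 103L), {
    for (ep in seq_len(spec$epochs)) {
      ord <- sample(length(y))
      lossSum <- 0
      for (b in split(ord, ceiling(seq_along(ord) / spec$batch_size))) {
        model@params <- if (nested) unflattenLSTMParams(params) else params
        bg <- forecasterBatchGrad(model, X[, , b, drop = FALSE], y[b])
        loss <- mean((bg$pred - y[b])^2)
        if (!is.finite(loss))
          stop("training aborted: non-finite loss at epoch ", ep)
        lossSum <- lossSum + loss * length(b)
        keep <- intersect(names(bg$grads), names(params))
        params <- optimizerStep(opt, params, bg$grads[keep])
      }
      hist <- rbind(hist, data.frame(epoch = ep, loss = lossSum / length(y)))
      if (verbose)
        message(sprintf("epoch %d/%d  mse %.5f", ep, spec$epochs,
                        lossSum / length(y)))
    }
  })
  model@params <- if (nested) unflattenLSTMParams(params) else params
  model@spec <- spec
  model@history <- hist
  model
}

#' Forecast MSE of a trained model on a window set
#'
#' @param model a trained forecaster.
#' @param windows a [ForecastWindowSet].
#' @param batch_size scoring batch size.
#' @return mean squared error (numeric scalar).
#' @export
forecastMSE <- function(model, windows, batch_size = 256L) {
  X <- windows@inputs
  y <- windows@targets
  preds <- numeric(length(y))
  for (b in split(seq_along(y), ceiling(seq_along(y) / batch_size))) {
    Xb <- X[, , b, drop = FALSE]
    attr(Xb, "queryChannel") <- windows@queryChannel
    preds[b] <- forecasterPredictBatch(model, Xb)
  }
  mean((preds - y)^2)
}

#' Per-window embeddings from a trained LSTM forecaster
#'
#' Final-step hidden state of the second recurrent layer (8-d).
#'
#' @param model a trained \code{lstm_forecaster}.
#' @param windows a [ForecastWindowSet].
#' @param batch_size scoring batch size.
#' @return matrix, windows x units2.
#' @export
lstmEmbeddings <- function(model, windows, batch_size = 256L) {
  stopifnot(model@arch == "lstm_forecaster")
  X <- windows@inputs
  M <- dim(X)[3]
  out <- matrix(NA_real_, M, nrow(model@params$Wd))
  for (b in split(seq_len(M), ceiling(seq_len(M) / batch_size)))
    out[b, ] <- lstmForecasterForward(model@params,
                                      X[, , b, drop = FALSE])$emb
  out
}

#' Aggregate per-window embeddings to one vector per trajectory
#'
#' Mean of the 8-d window embeddings over each source trajectory.
#'
#' @param embeddings matrix from [lstmEmbeddings()].
#' @param windows the [ForecastWindowSet] the embeddings came from.
#' @return list with \code{embeddings} (trajectories x units) and
#'   \code{trajectory} (source trajectory index per row).
#' @export
aggregateEmbeddings <- function(embeddings, windows) {
  traj <- windows@provenance$trajectory
  ids <- sort(unique(traj))
  agg <- t(vapply(ids, function(i)
    colMeans(embeddings[traj == i, , drop = FALSE]),
    numeric(ncol(embeddings))))
  list(embeddings = agg, trajectory = ids)
}

#' Binary classification from forecaster embeddings
#'
#' A single dense sigmoid head trained with binary cross-entropy on
#' fixed embedding vectors (one per example). Reports loss and accuracy
#' on the held-out set when one is supplied, else on the training set.
#'
#' @param embeddings numeric matrix, examples x dims.
#' @param labels class labels ("reactive"/"non-reactive") or 0/1.
#' @param val_embeddings,val_labels optional held-out set.
#' @param epochs,batch_size,lr,seed training regime of the head
#'   (defaults: 50 epochs, batch 32, Adam 0.01).
#' @return list with \code{model} ([TrainedModel],
#'   \code{embedding_classifier}) and \code{report} ([EvalReport]).
#' @export
classifyFromEmbeddings <- function(embeddings, labels,
                                   val_embeddings = NULL, val_labels = NULL,
                                   epochs = 50L, batch_size = 32L,
                                   lr = 0.01, seed = 1L) {
  y <- if (is.numeric(labels)) labels else binaryTargets(labels)
  if (nrow(embeddings) != length(y))
    stop("label/embedding count mismatch: ", nrow(embeddings), " vs ",
         length(y))
  dims <- ncol(embeddings)
  spec <- list(dims = dims, epochs = epochs, batch_size = batch_size,
               optimizer = "adam", lr = lr, loss = "bce", seed = seed)
  params <- withSeed(seed, list(W = glorotInit(c(dims, 1), dims, 1), b = 0))
  opt <- makeOptimizer("adam", lr)
  hist <- data.frame()
  withSeed(deriveSeed(seed, 107L), {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(y))
      lossSum <- 0; correct <- 0
      for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
        Xb <- embeddings[b, , drop = FALSE]
        p <- sigmoid(drop(Xb %*% params$W) + params$b)
        lossSum <- lossSum + bceLoss(p, y[b]) * length(b)
        correct <- correct + sum((p >= 0.5) == (y[b] == 1))
        dLogit <- (p - y[b]) / length(b)
        grads <- list(W = t(Xb) %*% matrix(dLogit, ncol = 1),
                      b = sum(dLogit))
        params <- optimizerStep(opt, params, grads)
      }
      hist <- rbind(hist, data.frame(epoch = ep, loss = lossSum / length(y),
                                     accuracy = correct / length(y)))
    }
  })
  model <- newModel("embedding_classifier", spec, params)
  model@history <- hist
  evX <- if (is.null(val_embeddings)) embeddings else val_embeddings
  evY <- if (is.null(val_labels)) y else {
    if (is.numeric(val_labels)) val_labels else binaryTargets(val_labels)
  }
  scores <- sigmoid(drop(evX %*% params$W) + params$b)
  report <- scoreReport(scores, evY, ligand = rep(NA_integer_, length(evY)))
  list(model = model, report = report)
}

# --------------------------------------------------------------- evaluation --

# Rank-based AUC (Mann-Whitney with tie correction); identical to the
# trapezoidal area over all thresholds.
aucFromScores <- function(scores, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

scoreReport <- function(scores, y, ligand, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  conf <- matrix(0L, 2, 2,
                 dimnames = list(truth = c("non-reactive", "reactive"),
                                 predicted = c("non-reactive", "reactive")))
  for (t in 0:1) for (p in 0:1)
    conf[t + 1, p + 1] <- sum(y == t & pred == p)
  wrong <- pred != y
  pl <- data.frame(ligand_id = integer(0), class = character(0),
                   n = integer(0), misclassified = integer(0))
  if (!all(is.na(ligand))) {
    for (lg in sort(unique(ligand)))
      for (t in 0:1) {
        sel <- ligand == lg & y == t
        pl <- rbind(pl, data.frame(
          ligand_id = lg,
          class = if (t == 1) "reactive" else "non-reactive",
          n = sum(sel), misclassified = sum(wrong & sel)))
      }
  }
  new("EvalReport",
      accuracy = mean(!wrong),
      auc = aucFromScores(scores, y),
      confusion = conf, perLigand = pl,
      n = length(y), loss = bceLoss(scores, y))
}

#' Evaluate a trained classifier on a split
#'
#' Accuracy at the model threshold, rank/trapezoidal ROC-AUC, the
#' confusion table, mean binary cross-entropy, and per-ligand
#' misclassification counts split by true class.
#'
#' @param model a trained classifier.
#' @param ts a [TrajectorySet] normalized like the training data.
#' @param split \code{"validation"} (default), \code{"train"},
#'   \code{"all"} or explicit indices.
#' @return an [EvalReport].
#' @export
evaluateModel <- function(model, ts, split = "validation") {
  idx <- resolveIndices(ts, split)
  if (!length(idx)) stop("empty evaluation split")
  scores <- predictClassifier(model, ts, idx)
  y <- binaryTargets(classLabels(ts)[idx])
  scoreReport(scores, y, ligandIds(ts)[idx], model@threshold)
}
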