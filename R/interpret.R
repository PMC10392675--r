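#' @include AllClasses.R models.R tsne.R
NULL

#' Single-channel ablation importance study
#'
#' Trains, from scratch, one 1D-CNN per descriptor channel on the
#' single-channel slice of the training split (plus an all-channel
#' reference), repeats over independently seeded replicas, and reports
#' per-channel validation accuracy (mean and standard deviation over 5
#' replicas by default). With 15 channels this is the 75-model protocol
#' plus 5 reference models; the first row of the table is the "All"
#' reference.
#'
#' @param ts a normalized, split [TrajectorySet].
#' @param replicas independently seeded training replicas (default 5).
#' @param channels channels to ablate (default all).
#' @param epochs,batch_size,lr overrides of the 1D-CNN regime (the
#'   defaults are the classifier's own regime; smaller values are
#'   useful for reduced-size studies).
#' @param seed base seed; replica r uses seed + r.
#' @param verbose print progress per trained model.
#' @return an [AblationResult].
#' @export
ablationStudy <- function(ts, replicas = 5L, channels = NULL,
                          epochs = NULL, batch_size = NULL, lr = NULL,
                          seed = 1L, verbose = FALSE) {
  D <- nChannels(ts)
  if (is.null(channels)) channels <- seq_len(D)
  if (any(channels < 1 | channels > D))
    stop("channel index out of range")
  accOne <- function(chs, sd.) {
    model <- buildCNN1D(n_channels = length(chs), seed = sd.)
    fit <- trainClassifier(model, ts, epochs = epochs,
                           batch_size = batch_size, lr = lr, seed = sd.,
                           channels = chs)
    tsSub <- ts
    tsSub@tensors <- ts@tensors[, chs, , drop = FALSE]
    tsSub@descriptors <- DescriptorSet(
      descriptorNames(ts)[chs], ts@descriptors@kind[chs],
      ts@descriptors@atoms[chs], ts@descriptors@units[chs])
    accuracy(evaluateModel(fit, tsSub, "validation"))
  }
  rows <- list()
  refAcc <- vapply(seq_len(replicas), function(r) {
    if (verbose) message("reference replica ", r)
    accOne(seq_len(D), deriveSeed(seed, 0L, r))
  }, numeric(1))
  rows[[1]] <- data.frame(channel = NA_integer_, name = "All",
                          mean_accuracy = mean(refAcc),
                          sd_accuracy = sd(refAcc))
  for (d in channels) {
    acc <- vapply(seq_len(replicas), function(r) {
      if (verbose) message("channel ", d, " replica ", r)
      accOne(d, deriveSeed(seed, d, r))
    }, numeric(1))
    rows[[length(rows) + 1]] <- data.frame(
      channel = d, name = descriptorNames(ts)[d],
      mean_accuracy = mean(acc), sd_accuracy = sd(acc))
  }
  new("AblationResult", table = do.call(rbind, rows),
      replicas = as.integer(replicas))
}

#' Class activation map of the 1D-CNN
#'
#' The 1D-CNN ends in GlobalMaxPool directly followed by the single
#' sigmoid unit, so classic CAM applies: each final-conv feature map
#' (length 192 at defaults, 16 filters) is scaled by that filter's
#' dense-layer weight, rectified, and carried back to the input time
#' axis by nearest-neighbour repetition with the pooling factor (5),
#' with edge frames beyond the upsampled span taking the nearest
#' saliency value. \code{mode = "cam_raw"} skips the weight scaling
#' and returns the rectified feature maps themselves.
#'
#' @param model a trained \code{cnn1d} [TrainedModel].
#' @param tensor one trajectory: frames x channels matrix (normalized
#'   like the training data).
#' @param mode \code{"cam_weighted"} (default) or \code{"cam_raw"}.
#' @return a [SaliencyMap]; activations are filters x map-time, the
#'   upsampled matrix filters x frames.
#' @export
computeCAM1D <- function(model, tensor, mode = c("cam_weighted", "cam_raw")) {
  mode <- match.arg(mode)
  if (model@arch != "cnn1d")
    stop("unsupported architecture for CAM: ", model@arch,
         " (the feature maps must directly precede the output unit)")
  stopifnot(is.matrix(tensor))
  T <- nrow(tensor)
  X <- array(tensor, c(T, ncol(tensor), 1L))
  fwd <- cnn1dForward(model@params, X)
  fm <- t(fwd$featureMap[, , 1])                  # filters x map-time
  act <- if (mode == "cam_weighted") {
    pmax(drop(model@params$Wd) * fm, 0)
  } else fm                                        # already post-ReLU
  pool <- model@params$pool
  up <- act[, rep(seq_len(ncol(act)), each = pool), drop = FALSE]
  if (ncol(up) < T) {
    lead <- (T - ncol(up)) %/% 2
    trail <- T - ncol(up) - lead
    up <- cbind(up[, rep(1L, lead), drop = FALSE], up,
                up[, rep(ncol(up), trail), drop = FALSE])
  } else if (ncol(up) > T) {
    up <- up[, seq_len(T), drop = FALSE]
  }
  new("SaliencyMap", activations = act, upsampled = up,
      factor = as.numeric(pool), mode = mode,
      meta = list(layer = "conv2", n_filters = nrow(act),
                  alignment = "nearest-neighbour x pool, edge-padded"))
}

bilinearUpsample <- function(m, outH, outW) {
  inH <- nrow(m); inW <- ncol(m)
  ry <- if (outH == 1) rep(1, outH) else (seq_len(outH) - 1) / (outH - 1) * (inH - 1) + 1
  rx <- if (outW == 1) rep(1, outW) else (seq_len(outW) - 1) / (outW - 1) * (inW - 1) + 1
  y0 <- pmin(floor(ry), inH - 1); x0 <- pmin(floor(rx), inW - 1)
  fy <- ry - y0; fx <- rx - x0
  if (inH == 1) { y0 <- rep(1, outH); fy <- rep(0, outH) }
  if (inW == 1) { x0 <- rep(1, outW); fx <- rep(0, outW) }
  a <- m[y0, x0, drop = FALSE]; b <- m[pmin(y0 + 1, inH), x0, drop = FALSE]
  cc <- m[y0, pmin(x0 + 1, inW), drop = FALSE]
  d <- m[pmin(y0 + 1, inH), pmin(x0 + 1, inW), drop = FALSE]
  Fy <- matrix(fy, outH, outW); Fx <- matrix(fx, outH, outW, byrow = TRUE)
  a * (1 - Fy) * (1 - Fx) + b * Fy * (1 - Fx) + cc * (1 - Fy) * Fx +
    d * Fy * Fx
}

#' Grad-CAM of the image-based 2D-CNN
#'
#' The saliency-imaging architecture flattens into a hidden dense layer,
#' so classic CAM is structurally impossible; gradient-weighted CAM is
#' used instead (recorded in the result's metadata). Channel weights
#' are the spatially averaged gradients of the class logit with respect
#' to the final conv feature maps (18 x 18 x 16 at the default input
#' size); the weighted sum is rectified and bilinearly upsampled to the
#' input image.
#'
#' @param model a trained \code{cnn2d_cam} [TrainedModel].
#' @param image input image matrix (size x size) as produced by
#'   [renderTrajectoryImage()].
#' @param target class whose score is explained: the predicted class
#'   (default; the non-reactive score is the negated logit of the
#'   single sigmoid unit), or explicitly \code{"reactive"} /
#'   \code{"non-reactive"}.
#' @return a [SaliencyMap] (activations: final-map resolution;
#'   upsampled: input resolution).
#' @export
computeGradCAM2D <- function(model, image,
                             target = c("predicted", "reactive",
                                        "non-reactive")) {
  target <- match.arg(target)
  if (model@arch != "cnn2d_cam")
    stop("unsupported architecture for Grad-CAM: ", model@arch)
  stopifnot(is.matrix(image))
  size <- nrow(image)
  X <- array(image, c(size, ncol(image), 1L, 1L))
  fwd <- camForward(model@params, X)
  sign <- switch(target,
    predicted = if (fwd$prob >= model@threshold) 1 else -1,
    reactive = 1,
    `non-reactive` = -1)
  # gradient of the class score w.r.t. the final conv feature maps:
  # backprop through the two dense layers and the flatten only
  dAd1 <- sign * t(model@params$Wd2)              # 1 x 256
  dZd1 <- dAd1 * (fwd$Zd1 > 0)
  dFlat <- model@params$Wd1 %*% t(dZd1)           # features x 1
  d4 <- fwd$cache$d4
  dFm <- array(dFlat, d4)                         # H x W x F x 1
  fm <- fwd$featureMap
  weights <- apply(dFm[, , , 1, drop = FALSE], 3, mean)
  cam <- matrix(0, d4[1], d4[2])
  for (f in seq_len(d4[3]))
    cam <- cam + weights[f] * fm[, , f, 1]
  cam <- pmax(cam, 0)
  up <- bilinearUpsample(cam, size, ncol(image))
  new("SaliencyMap", activations = cam, upsampled = up,
      factor = size / d4[1], mode = "gradcam",
      meta = list(layer = "conv4",
                  note = paste("classic CAM not applicable (hidden dense",
                               "layer after flatten); Grad-CAM used")))
}

#' Descriptor values at each trajectory's maximum CAM activation
#'
#' For every trajectory: locate the time of maximum saliency of one
#' chosen filter of the 1D-CNN class activation map (earliest index on
#' ties), record every descriptor's value at that time and the class
#' label. The per-descriptor, per-class value distributions are the
#' violin-plot data relating descriptor preferences to the classifier's
#' decisions.
#'
#' @param model a trained \code{cnn1d} [TrainedModel].
#' @param ts a normalized [TrajectorySet].
#' @param filter_id filter whose saliency is scanned (default 4).
#' @param indices trajectories to process (default all).
#' @param mode CAM mode passed to [computeCAM1D()].
#' @return data.frame: trajectory, argmax_time, class, then one column
#'   per descriptor with its value at the argmax time.
#' @export
extractMaxActivationValues <- function(model, ts, filter_id = 4L,
                                       indices = NULL,
                                       mode = "cam_weighted") {
  idx <- resolveIndices(ts, indices)
  nf <- nrow(model@params$Wd)
  if (filter_id < 1 || filter_id > nf)
    stop("filter id out of range (model has ", nf, " filters)")
  rows <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    sal <- computeCAM1D(model, ts@tensors[, , i], mode = mode)
    trace <- saliency(sal)[filter_id, ]
    tmax <- which.max(trace)                     # earliest tie wins
    vals <- as.list(ts@tensors[tmax, , i])
    names(vals) <- descriptorNames(ts)
    rows[[j]] <- cbind(data.frame(trajectory = i, argmax_time = tmax,
                                  class = classLabels(ts)[i]),
                       as.data.frame(vals))
  }
  do.call(rbind, rows)
}

#' Project 1D-CNN latent space to 2-d by t-SNE
#'
#' Embeds the 16-dimensional penultimate-layer (post-GlobalMaxPool)
#' representations of a split with exact t-SNE (perplexity 30 by
#' default, seeded).
#'
#' @param model a trained \code{cnn1d} [TrainedModel].
#' @param ts a normalized [TrajectorySet].
#' @param split \code{"validation"} (default), \code{"train"},
#'   \code{"all"} or indices.
#' @param perplexity t-SNE perplexity (default 30).
#' @param max_iter gradient-descent iterations.
#' @param seed embedding initialization seed.
#' @return data.frame: tsne1, tsne2, class, ligand_id, trajectory.
#' @export
projectLatentSpace <- function(model, ts, split = "validation",
                               perplexity = 30, max_iter = 500L,
                               seed = 1L) {
  idx <- resolveIndices(ts, split)
  emb <- cnn1dEmbeddings(model, ts, idx)
  Y <- tsneEmbed(emb, perplexity = perplexity, maxIter = max_iter,
                 seed = seed)
  data.frame(tsne1 = Y[, 1], tsne2 = Y[, 2],
             class = classLabels(ts)[idx],
             ligand_id = ligandIds(ts)[idx],
             trajectory = idx)
}

# Receptive-field bookkeeping: input frame range feeding map index t
# (1-based) of the final conv layer of the 1D-CNN stack.
cam1dReceptiveField <- function(t, kernel = 7L, pool = 5L) {
  p1 <- c(t, t + kernel - 1L)                # second conv footprint
  a1 <- c((p1[1] - 1L) * pool + 1L, p1[2] * pool)  # through the pool
  c(a1[1], a1[2] + kernel - 1L)              # first conv footprint
}
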