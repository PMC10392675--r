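#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @aliases tensors,TrajectorySet-method
setMethod("tensors", "TrajectorySet", function(x, ...) x@tensors)

#' @rdname accessors
setMethod("trajectoryInfo", "TrajectorySet", function(x, ...) x@info)

#' @rdname accessors
setMethod("descriptors", "TrajectorySet", function(x, ...) x@descriptors)

#' @rdname accessors
setMethod("descriptorNames", "TrajectorySet", function(x, ...)
  x@descriptors@name)

#' @rdname accessors
setMethod("descriptorNames", "DescriptorSet", function(x, ...) x@name)

#' @rdname accessors
setMethod("nTrajectories", "TrajectorySet", function(x) dim(x@tensors)[3])

#' @rdname accessors
setMethod("nFrames", "TrajectorySet", function(x) dim(x@tensors)[1])

#' @rdname accessors
setMethod("nChannels", "TrajectorySet", function(x) dim(x@tensors)[2])

#' @rdname accessors
setMethod("classLabels", "TrajectorySet", function(x) x@info$class_label)

#' @rdname accessors
setMethod("ligandIds", "TrajectorySet", function(x) x@info$ligand_id)

#' @rdname accessors
setMethod("trainIndices", "TrajectorySet", function(x) x@split$train)

#' @rdname accessors
setMethod("validationIndices", "TrajectorySet", function(x)
  x@split$validation)

#' @rdname accessors
setMethod("normalizer", "TrajectorySet", function(x) x@normalizer)

#' @rdname accessors
setMethod("normalizer", "TrainedModel", function(x) x@normalizer)

#' @rdname accessors
setMethod("architecture", "TrainedModel", function(x) x@arch)

#' @rdname accessors
setMethod("trainingHistory", "TrainedModel", function(x) x@history)

#' @rdname accessors
setMethod("modelParameters", "TrainedModel", function(x) x@params)

#' @rdname accessors
setMethod("accuracy", "EvalReport", function(x) x@accuracy)

#' @rdname accessors
setMethod("rocAUC", "EvalReport", function(x) x@auc)

#' @rdname accessors
setMethod("perLigandErrors", "EvalReport", function(x) x@perLigand)

#' @rdname accessors
setMethod("saliency", "SaliencyMap", function(x, upsampled = TRUE, ...)
  if (upsampled) x@upsampled else x@activations)

#' @rdname accessors
setMethod("ablationTable", "AblationResult", function(x) x@table)

#' @rdname accessors
setMethod("forecastTargets", "ForecastWindowSet", function(x) x@targets)

#' @rdname accessors
setMethod("forecastInputs", "ForecastWindowSet", function(x) x@inputs)

#' @rdname accessors
setMethod("length", "DescriptorSet", function(x) length(x@name))

#' Subset a TrajectorySet by trajectory
#'
#' Drops any existing split/normalizer bookkeeping that indexing would
#' invalidate (indices refer to the original ordering).
#'
#' @param x a TrajectorySet
#' @param i trajectory indices
#' @param j,...,drop ignored
#' @return a TrajectorySet with the selected trajectories.
#' @export
setMethod("[", "TrajectorySet", function(x, i, j, ..., drop = FALSE) {
  i <- seq_len(nTrajectories(x))[i]
  new("TrajectorySet",
      tensors = x@tensors[, , i, drop = FALSE],
      info = x@info[i, , drop = FALSE],
      descriptors = x@descriptors, dt = x@dt,
      split = list(train = integer(0), validation = integer(0)),
      normalizer = x@normalizer,
      metadata = x@metadata)
})

setMethod("show", "DescriptorSet", function(object) {
  cat("DescriptorSet with", length(object@name), "descriptors\n")
  tab <- table(factor(object@kind, c("distance", "angle", "dihedral")))
  cat("  ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  if (length(object@name))
    cat("  names:", paste(object@name, collapse = " "), "\n")
})

setMethod("show", "TrajectorySet", function(object) {
  d <- dim(object@tensors)
  cat("TrajectorySet:", d[3], "trajectories x", d[1], "frames x",
      d[2], "channels\n")
  cl <- table(object@info$class_label)
  if (length(cl))
    cat("  classes:", paste(names(cl), cl, sep = "=", collapse = ", "), "\n")
  cat("  ligands:", length(unique(object@info$ligand_id)),
      "| dt:", object@dt, "ps/frame\n")
  if (length(object@split$train) || length(object@split$validation))
    cat("  split: train", length(object@split$train), "/ validation",
        length(object@split$validation), "\n")
  cat("  normalized:", !is.null(object@normalizer), "\n")
})

setMethod("show", "ForecastWindowSet", function(object) {
  d <- dim(object@inputs)
  cat("ForecastWindowSet:", d[3], "windows of", d[1], "steps x",
      d[2], "channels; query channel", object@queryChannel,
      "; lag", object@lag, "\n")
})

setMethod("show", "TrainedModel", function(object) {
  cat("TrainedModel <", object@arch, ">\n", sep = "")
  if (nrow(object@history)) {
    last <- object@history[nrow(object@history), ]
    cat("  epochs:", nrow(object@history), "| final loss:",
        signif(last$loss, 4))
    if (!is.null(last$accuracy) && !is.na(last$accuracy))
      cat(" | final accuracy:", signif(last$accuracy, 4))
    cat("\n")
  }
  np <- sum(vapply(object@params, length, numeric(1)))
  cat("  parameters:", np, "\n")
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport on", object@n, "trajectories\n")
  cat("  accuracy:", signif(object@accuracy, 4),
      "| ROC-AUC:", signif(object@auc, 4),
      "| loss:", signif(object@loss, 4), "\n")
  print(object@confusion)
})

setMethod("show", "SaliencyMap", function(object) {
  cat("SaliencyMap <", object@mode, ">: ",
      nrow(object@activations), " x ", ncol(object@activations),
      " (upsampled ", nrow(object@upsampled), " x ",
      ncol(object@upsampled), ", factor ", object@factor, ")\n", sep = "")
})

setMethod("show", "AblationResult", function(object) {
  cat("AblationResult:", nrow(object@table) - 1L, "single-channel models,",
      object@replicas, "replicas each\n")
  print(head(object@table[order(-object@table$mean_accuracy), ], 6))
})
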