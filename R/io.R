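#' @include AllClasses.R
#' @importFrom jsonlite write_json read_json
NULL

#' Write / read a TrajectorySet container
#'
#' A hierarchical on-disk container: a directory with
#' \code{manifest.json} (shape, dt, seeds, units, split),
#' \code{info.csv} (per-trajectory metadata), \code{descriptors.tsv}
#' (the definitions) and the tensor stack in \code{tensors.parquet}
#' (via the \pkg{arrow} package) or \code{tensors.csv} as a fallback.
#' The round trip preserves names, units and values exactly.
#'
#' @param ts a [TrajectorySet].
#' @param path container directory (created if needed).
#' @param format \code{"parquet"} (default when arrow is installed) or
#'   \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
writeTrajectorySet <- function(ts, path,
                               format = c("auto", "parquet", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (requireNamespace("arrow", quietly = TRUE)) "parquet"
              else "csv"
  if (format == "parquet" && !requireNamespace("arrow", quietly = TRUE))
    stop("the 'arrow' package is required for parquet containers")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(ts@tensors)
  manifest <- list(container = "trajsel-dataset", version = 1L,
                   n_frames = d[1], n_channels = d[2],
                   n_trajectories = d[3], dt = ts@dt,
                   units = ts@descriptors@units,
                   tensor_format = format,
                   split = ts@split, normalizer = ts@normalizer,
                   metadata = ts@metadata)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write.csv(as.data.frame(ts@info), file.path(path, "info.csv"),
            row.names = FALSE)
  writeDescriptorDefinitions(ts@descriptors,
                             file.path(path, "descriptors.tsv"))
  long <- data.frame(trajectory = rep(seq_len(d[3]), each = d[1]),
                     frame = rep(seq_len(d[1]), d[3]))
  flat <- matrix(aperm(ts@tensors, c(1, 3, 2)), d[1] * d[3], d[2])
  colnames(flat) <- ts@descriptors@name
  long <- cbind(long, as.data.frame(flat))
  if (format == "parquet")
    arrow::write_parquet(long, file.path(path, "tensors.parquet"))
  else
    write.csv(long, file.path(path, "tensors.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrajectorySet
#' @export
readTrajectorySet <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$container, "trajsel-dataset"))
    stop(path, " is not a trajsel dataset container")
  info <- read.csv(file.path(path, "info.csv"), stringsAsFactors = FALSE)
  defs <- readDescriptorDefinitions(file.path(path, "descriptors.tsv"))
  long <- if (identical(manifest$tensor_format, "parquet")) {
    as.data.frame(arrow::read_parquet(file.path(path, "tensors.parquet")))
  } else {
    read.csv(file.path(path, "tensors.csv"), check.names = FALSE)
  }
  T <- manifest$n_frames; D <- manifest$n_channels
  N <- manifest$n_trajectories
  flat <- as.matrix(long[, defs@name, drop = FALSE])
  tens <- aperm(array(flat, c(T, N, D)), c(1, 3, 2))
  split <- manifest$split
  split <- list(train = as.integer(unlist(split$train)),
                validation = as.integer(unlist(split$validation)))
  norm <- manifest$normalizer
  if (!is.null(norm)) {
    norm$offset <- as.numeric(unlist(norm$offset))
    norm$scale <- as.numeric(unlist(norm$scale))
    norm$names <- as.character(unlist(norm$names))
  }
  new("TrajectorySet", tensors = tens,
      info = S4Vectors::DataFrame(ligand_id = as.integer(info$ligand_id),
                                  enantiomer = as.character(info$enantiomer),
                                  class_label = as.character(info$class_label),
                                  replicate = as.integer(info$replicate)),
      descriptors = defs, dt = manifest$dt,
      split = split, normalizer = norm,
      metadata = if (is.null(manifest$metadata)) list()
                 else manifest$metadata)
}

#' Export one trajectory as CSV (frames x channels)
#'
#' Header row carries the descriptor names.
#'
#' @param ts a [TrajectorySet].
#' @param i trajectory index.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
exportTrajectoryCSV <- function(ts, i, file) {
  m <- ts@tensors[, , i]
  colnames(m) <- descriptorNames(ts)
  write.csv(as.data.frame(m), file, row.names = FALSE)
  invisible(file)
}

#' Write an evaluation report as columnar text and JSON
#'
#' @param report an [EvalReport].
#' @param prefix path prefix; writes \code{<prefix>.json} and
#'   \code{<prefix>_per_ligand.csv}.
#' @return the JSON path, invisibly.
#' @export
writeEvalReport <- function(report, prefix) {
  out <- list(accuracy = report@accuracy, roc_auc = report@auc,
              loss = report@loss, n = report@n,
              confusion = report@confusion)
  jsonlite::write_json(out, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor")
  write.csv(report@perLigand, paste0(prefix, "_per_ligand.csv"),
            row.names = FALSE)
  invisible(paste0(prefix, ".json"))
}

#' Save / load a trained model archive
#'
#' One JSON file holding the architecture spec, the learned parameter
#' arrays, the training history, the normalizer reference and the seed,
#' so a saved model reproduces its evaluations exactly.
#'
#' @param model a [TrainedModel].
#' @param file archive path (JSON).
#' @return \code{file} invisibly (write) or the [TrainedModel] (load).
#' @export
saveTrainedModel <- function(model, file) {
  ser <- list(arch = model@arch, spec = model@spec,
              threshold = model@threshold,
              history = model@history,
              normalizer = model@normalizer,
              params = serializeParams(model@params))
  jsonlite::write_json(ser, file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(file)
}

serializeParams <- function(p) {
  lapply(p, function(x) {
    if (is.list(x)) serializeParams(x)
    else list(dim = if (is.null(dim(x))) length(x) else dim(x),
              data = as.numeric(x))
  })
}

deserializeParams <- function(p) {
  lapply(p, function(x) {
    if (!is.null(x$dim) && !is.null(x$data)) {
      d <- as.integer(unlist(x$dim))
      v <- as.numeric(unlist(x$data))
      if (length(d) > 1) array(v, d) else v
    } else deserializeParams(x)
  })
}

#' @rdname saveTrainedModel
#' @export
loadTrainedModel <- function(file) {
  ser <- jsonlite::read_json(file, simplifyVector = TRUE)
  params <- deserializeParams(ser$params)
  # scalar hyper-entries stored alongside arrays
  for (nm in c("pool", "dropout", "inputSize"))
    if (!is.null(params[[nm]])) params[[nm]] <- params[[nm]][1]
  norm <- ser$normalizer
  if (!is.null(norm)) {
    norm$offset <- as.numeric(unlist(norm$offset))
    norm$scale <- as.numeric(unlist(norm$scale))
  }
  m <- new("TrainedModel", arch = ser$arch,
           spec = lapply(ser$spec, function(s) if (is.list(s)) unlist(s) else s),
           params = params,
           history = as.data.frame(ser$history),
           normalizer = norm, threshold = as.numeric(ser$threshold))
  m
}
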