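#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' DescriptorSet: geometric descriptor definitions
#'
#' An ordered collection of geometric observables measured on every
#' trajectory frame. Each descriptor is a distance (2 atoms, Angstrom),
#' an angle (3 atoms, degrees) or a dihedral (4 atoms, degrees), defined
#' by 0-based atom indices into the topology.
#'
#' @slot name character, descriptor labels (d1, d2, ...).
#' @slot kind character, one of \code{"distance"}, \code{"angle"},
#'   \code{"dihedral"}.
#' @slot atoms list of integer vectors, 0-based atom indices; length 2, 3
#'   or 4 matching \code{kind}.
#' @slot units character, \code{"angstrom"} or \code{"degrees"}.
#'
#' @seealso [defaultDescriptorSet()], [readDescriptorDefinitions()]
#' @exportClass DescriptorSet
setClass("DescriptorSet",
  representation(name = "character", kind = "character",
                 atoms = "list", units = "character"))

setValidity("DescriptorSet", function(object) {
  n <- length(object@name)
  if (length(object@kind) != n || length(object@atoms) != n ||
      length(object@units) != n)
    return("name, kind, atoms and units must have equal length")
  if (anyDuplicated(object@name))
    return("descriptor names must be unique")
  ok.kind <- object@kind %in% c("distance", "angle", "dihedral")
  if (!all(ok.kind))
    return("kind must be distance, angle or dihedral")
  want <- c(distance = 2L, angle = 3L, dihedral = 4L)[object@kind]
  len <- vapply(object@atoms, length, integer(1))
  if (n > 0 && any(len != want))
    return("atom tuple length must be 2/3/4 for distance/angle/dihedral")
  dup <- vapply(object@atoms, function(a) anyDuplicated(a) > 0, logical(1))
  if (any(dup))
    return("atom indices must be distinct within a descriptor")
  neg <- vapply(object@atoms, function(a) any(a < 0), logical(1))
  if (any(neg))
    return("atom indices must be non-negative (0-based)")
  want.u <- ifelse(object@kind == "distance", "angstrom", "degrees")
  if (n > 0 && !all(object@units == want.u))
    return("distance descriptors carry angstrom, angle/dihedral degrees")
  TRUE
})

#' TrajectorySet: labelled descriptor time series
#'
#' The central container: a stack of per-trajectory descriptor tensors
#' (frames x channels) together with per-trajectory metadata (ligand id,
#' enantiomer, class label), the descriptor definitions, an optional
#' ligand-held-out train/validation split and an optional fitted
#' normalizer.
#'
#' @slot tensors numeric array, frames x channels x trajectories.
#' @slot info a [S4Vectors::DataFrame] with one row per trajectory and
#'   columns \code{ligand_id}, \code{enantiomer}, \code{class_label},
#'   \code{replicate}.
#' @slot descriptors a [DescriptorSet] describing the channel axis.
#' @slot dt numeric, simulated time per frame in picoseconds.
#' @slot split list with integer index vectors \code{train} and
#'   \code{validation} (possibly empty when no split has been assigned).
#' @slot normalizer fitted per-channel normalization (list) or NULL.
#' @slot metadata free-form list (seeds, generator config, provenance).
#'
#' @seealso [generateDataset()], [splitByLigand()], [fitNormalizer()]
#' @exportClass TrajectorySet
setClass("TrajectorySet",
  representation(tensors = "array", info = "DataFrame",
                 descriptors = "DescriptorSet", dt = "numeric",
                 split = "list", normalizer = "listOrNULL",
                 metadata = "list"))

setValidity("TrajectorySet", function(object) {
  d <- dim(object@tensors)
  if (length(d) != 3)
    return("tensors must be a 3-d array (frames x channels x trajectories)")
  if (nrow(object@info) != d[3])
    return("info must have one row per trajectory")
  need <- c("ligand_id", "enantiomer", "class_label", "replicate")
  if (!all(need %in% colnames(object@info)))
    return(paste("info must contain columns:", paste(need, collapse = ", ")))
  if (length(object@descriptors@name) != d[2])
    return("descriptor count must match the channel dimension")
  if (anyNA(object@tensors))
    return("tensors must not contain missing values")
  bad <- object@info$class_label[!is.na(object@info$class_label)]
  if (length(bad) && !all(bad %in% c("reactive", "non-reactive")))
    return("class_label must be 'reactive' or 'non-reactive'")
  if (!all(names(object@split) %in% c("train", "validation")))
    return("split may only contain 'train' and 'validation'")
  idx <- unlist(object@split, use.names = FALSE)
  if (length(idx) && (any(idx < 1) || any(idx > d[3])))
    return("split indices out of range")
  if (length(intersect(object@split$train, object@split$validation)))
    return("train and validation indices overlap")
  TRUE
})

#' ForecastWindowSet: sliding windows for next-step forecasting
#'
#' Fixed-length multichannel windows cut from trajectory tensors, each
#' paired with the value of the query descriptor one step after the
#' window. Windows never cross trajectory boundaries.
#'
#' @slot inputs numeric array, window x channels x windows.
#' @slot targets numeric, query-descriptor value at window end + 1.
#' @slot provenance DataFrame with columns \code{trajectory} (index into
#'   the source TrajectorySet) and \code{start} (1-based start frame).
#' @slot queryChannel integer, channel forecast by the targets.
#' @slot lag integer, frame thinning factor applied before windowing.
#'
#' @seealso [makeForecastWindows()], [makeLaggedWindows()]
#' @exportClass ForecastWindowSet
setClass("ForecastWindowSet",
  representation(inputs = "array", targets = "numeric",
                 provenance = "DataFrame", queryChannel = "integer",
                 lag = "integer"))

setValidity("ForecastWindowSet", function(object) {
  d <- dim(object@inputs)
  if (length(d) != 3) return("inputs must be window x channels x windows")
  if (length(object@targets) != d[3])
    return("one target per window required")
  if (nrow(object@provenance) != d[3])
    return("one provenance row per window required")
  if (object@queryChannel < 1 || object@queryChannel > d[2])
    return("queryChannel out of range")
  TRUE
})

#' TrainedModel: a fitted network with its training record
#'
#' @slot arch character architecture id (\code{cnn1d}, \code{cnn2d},
#'   \code{cnn2d_cam}, \code{lstm_forecaster}, \code{baseline},
#'   \code{linear}, \code{dense}, \code{cnn1d_forecaster},
#'   \code{embedding_classifier}).
#' @slot spec list, the architecture/training configuration (layer sizes,
#'   optimizer, learning rate, epochs, batch size, seed).
#' @slot params list of learned weight arrays.
#' @slot history data.frame with one row per epoch (loss, and accuracy
#'   for classifiers).
#' @slot normalizer the normalization parameters the model expects its
#'   inputs to have been through (or NULL).
#' @slot threshold numeric classification threshold on the sigmoid
#'   output (0.5 by default; ignored for regressors).
#'
#' @exportClass TrainedModel
setClass("TrainedModel",
  representation(arch = "character", spec = "list", params = "list",
                 history = "data.frame", normalizer = "listOrNULL",
                 threshold = "numeric"))

setValidity("TrainedModel", function(object) {
  known <- c("cnn1d", "cnn2d", "cnn2d_cam", "lstm_forecaster", "baseline",
             "linear", "dense", "cnn1d_forecaster", "embedding_classifier")
  if (!object@arch %in% known)
    return(paste("unknown architecture id:", object@arch))
  if (length(object@threshold) != 1 || object@threshold <= 0 ||
      object@threshold >= 1)
    return("threshold must be a single value in (0, 1)")
  TRUE
})

#' EvalReport: classifier evaluation summary
#'
#' @slot accuracy numeric, fraction of correct calls at the model
#'   threshold.
#' @slot auc numeric, area under the ROC curve (trapezoidal).
#' @slot confusion 2x2 integer matrix (truth rows x prediction columns).
#' @slot perLigand data.frame of misclassification counts per ligand and
#'   true class.
#' @slot n integer, number of evaluated trajectories.
#' @slot loss numeric, mean binary cross-entropy of the scores.
#'
#' @exportClass EvalReport
setClass("EvalReport",
  representation(accuracy = "numeric", auc = "numeric",
                 confusion = "matrix", perLigand = "data.frame",
                 n = "integer", loss = "numeric"))

setValidity("EvalReport", function(object) {
  if (object@accuracy < 0 || object@accuracy > 1)
    return("accuracy must lie in [0, 1]")
  if (!is.na(object@auc) && (object@auc < 0 || object@auc > 1))
    return("auc must lie in [0, 1]")
  if (sum(object@confusion) != object@n)
    return("confusion counts must sum to n")
  TRUE
})

#' SaliencyMap: class-activation scores aligned to the input
#'
#' @slot activations numeric matrix: filters x time (1D CAM) or
#'   height x width (2D Grad-CAM), non-negative.
#' @slot upsampled numeric matrix, activations carried back to input
#'   resolution (filters x frames, or image height x width).
#' @slot factor numeric, upsampling factor from map to input axis.
#' @slot mode character, \code{"cam_weighted"}, \code{"cam_raw"} or
#'   \code{"gradcam"}.
#' @slot meta list (source layer, filter ids, alignment rule, any
#'   method-substitution notes).
#'
#' @exportClass SaliencyMap
setClass("SaliencyMap",
  representation(activations = "matrix", upsampled = "matrix",
                 factor = "numeric", mode = "character", meta = "list"))

setValidity("SaliencyMap", function(object) {
  if (any(object@activations < -1e-12))
    return("activations must be non-negative")
  if (!object@mode %in% c("cam_weighted", "cam_raw", "gradcam"))
    return("mode must be cam_weighted, cam_raw or gradcam")
  TRUE
})

#' AblationResult: single-channel retraining importance study
#'
#' @slot table data.frame with one row per channel: \code{channel},
#'   \code{name}, \code{mean_accuracy}, \code{sd_accuracy}; plus an
#'   initial \code{"All"} reference row using every channel.
#' @slot replicas integer, number of independently seeded replicas.
#'
#' @exportClass AblationResult
setClass("AblationResult",
  representation(table = "data.frame", replicas = "integer"))

setValidity("AblationResult", function(object) {
  tb <- object@table
  need <- c("channel", "name", "mean_accuracy", "sd_accuracy")
  if (!all(need %in% colnames(tb)))
    return(paste("table must contain:", paste(need, collapse = ", ")))
  if (any(tb$mean_accuracy < 0 | tb$mean_accuracy > 1))
    return("mean accuracies must lie in [0, 1]")
  if (any(tb$sd_accuracy < 0)) return("sd must be non-negative")
  if (object@replicas < 2 && any(tb$sd_accuracy > 0))
    return("sd requires at least 2 replicas")
  TRUE
})
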