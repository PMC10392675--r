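#' @include AllClasses.R utils.R
NULL

#' Assign reactive / non-reactive class labels
#'
#' A trajectory is labelled \code{"reactive"} exactly when its
#' enantiomer tag equals its ligand's preferred enantiomer (typically
#' (S) for this enzyme, with per-ligand exceptions), and
#' \code{"non-reactive"} otherwise.
#'
#' @param ts a [TrajectorySet] whose \code{info} has \code{ligand_id}
#'   and \code{enantiomer}.
#' @param preferred_map named character vector: ligand id ->
#'   preferred enantiomer ("S" or "R").
#' @return the [TrajectorySet] with \code{class_label} filled in.
#' @examples
#' # ligand 1 prefers S: an S trajectory is reactive
#' @export
assignClassLabels <- function(ts, preferred_map) {
  if (nTrajectories(ts) == 0) return(ts)
  ids <- as.character(ligandIds(ts))
  unknown <- setdiff(unique(ids), names(preferred_map))
  if (length(unknown))
    stop("labeling error: no preferred enantiomer for ligand(s) ",
         paste(unknown, collapse = ", "))
  pref <- unname(preferred_map[ids])
  ts@info$class_label <- ifelse(ts@info$enantiomer == pref,
                                "reactive", "non-reactive")
  validObject(ts)
  ts
}

#' Ligand-held-out train/validation split
#'
#' Assigns every trajectory of a ligand entirely to one split, so the
#' validation set measures generalization to unseen ligands. With the
#' canonical defaults (ligands 1-38 train, 39-49 validation, 100 per
#' class) the validation set has 2,200 trajectories and the training
#' set 7,600.
#'
#' @param ts a [TrajectorySet].
#' @param train_ligands,val_ligands disjoint ligand id sets covering
#'   every ligand present.
#' @return the [TrajectorySet] with its \code{split} slot assigned.
#' @export
splitByLigand <- function(ts, train_ligands, val_ligands) {
  if (length(intersect(train_ligands, val_ligands)))
    stop("configuration error: train and validation ligand sets overlap")
  present <- unique(ligandIds(ts))
  missing <- setdiff(present, c(train_ligands, val_ligands))
  if (length(missing))
    stop("configuration error: ligand(s) not assigned to any split: ",
         paste(missing, collapse = ", "))
  tr <- which(ligandIds(ts) %in% train_ligands)
  va <- which(ligandIds(ts) %in% val_ligands)
  if (!length(va))
    warning("empty validation split")
  if (!length(tr))
    warning("empty training split")
  ts@split <- list(train = tr, validation = va)
  validObject(ts)
  ts
}

resolveIndices <- function(ts, indices) {
  if (is.null(indices)) return(seq_len(nTrajectories(ts)))
  if (is.character(indices)) {
    indices <- match.arg(indices, c("train", "validation", "all"))
    if (indices == "all") return(seq_len(nTrajectories(ts)))
    idx <- ts@split[[indices]]
    if (!length(idx)) stop("requested split '", indices, "' is empty")
    return(idx)
  }
  indices
}

#' Network input encodings
#'
#' \code{toSignalBatch} stacks trajectories as a
#' \code{n x frames x channels} array (the 1D-CNN's multichannel-signal
#' view). \code{toMatrixImageBatch} stacks them as
#' \code{n x channels x frames x 1} (the 2D-CNN's one-colour-channel
#' image view). The two encodings are transpositions of the same
#' normalized tensor: \code{signal[i, t, d] == matrix[i, d, t, 1]}.
#'
#' @param ts a [TrajectorySet].
#' @param indices trajectory indices, or \code{"train"} /
#'   \code{"validation"} / \code{"all"} (default all).
#' @return numeric array in the stated axis order.
#' @export
toSignalBatch <- function(ts, indices = NULL) {
  idx <- resolveIndices(ts, indices)
  aperm(ts@tensors[, , idx, drop = FALSE], c(3, 1, 2))
}

#' @rdname toSignalBatch
#' @export
toMatrixImageBatch <- function(ts, indices = NULL) {
  idx <- resolveIndices(ts, indices)
  x <- aperm(ts@tensors[, , idx, drop = FALSE], c(3, 2, 1))
  array(x, c(dim(x), 1L))
}

#' Render a trajectory as a grayscale trace image
#'
#' Draws each normalized channel as a polyline trace inside its own
#' horizontal band, separated by blank rows, on a light background
#' (background 1, trace 0). Band layout: each channel owns a slot of
#' \code{floor(size / D)} rows of which the last \code{gap} rows stay
#' blank; remainder rows pad the bottom. Values are linearly resampled
#' to \code{size} columns and vertically connected column-to-column
#' (no anti-aliasing), so the rendering is deterministic.
#'
#' @param tensor frames x channels matrix of normalized values in
#'   [0, 1] (values are clipped defensively).
#' @param size image side length in pixels (default 320).
#' @param gap blank separator rows between bands (default 4).
#' @return size x size numeric matrix in [0, 1]; rows are image rows
#'   (top to bottom), channel 1 in the top band.
#' @export
renderTrajectoryImage <- function(tensor, size = 320L, gap = 4L) {
  stopifnot(is.matrix(tensor))
  T <- nrow(tensor); D <- ncol(tensor)
  slot <- size %/% D
  bandH <- slot - gap
  if (bandH < 2)
    stop("too many channels (", D, ") for a ", size, "-pixel band layout")
  img <- matrix(1, size, size)
  v <- pmin(pmax(tensor, 0), 1)
  cols <- seq_len(size)
  tPos <- if (T == 1) rep(1, size) else (cols - 1) / (size - 1) * (T - 1) + 1
  for (d in seq_len(D)) {
    y <- approx(seq_len(T), v[, d], xout = tPos, rule = 2)$y
    r0 <- (d - 1L) * slot + 1L
    rows <- r0 + round((1 - y) * (bandH - 1L))
    img[rows[1], 1] <- 0
    for (cc in 2:size) {
      rr <- seq(rows[cc - 1], rows[cc])
      img[rr, cc] <- 0
    }
  }
  img
}

#' Sliding forecast windows
#'
#' Cuts 50-step (by default) multichannel windows from every
#' trajectory, each paired with the query descriptor's value at the
#' next step. Windows never cross trajectory boundaries. The default
#' stride of 19 yields 50 windows per default-length trajectory, i.e.
#' 490,000 (~500,000) windows for the full 9,800-trajectory dataset.
#'
#' @param ts a [TrajectorySet] (normalized values recommended).
#' @param query_channel channel to forecast (default 4, the
#'   Ha-Nz-CE-angle analogue).
#' @param window window length (default 50).
#' @param stride start-to-start step between windows (default 19).
#' @param indices trajectory subset (default all; also accepts
#'   \code{"train"} / \code{"validation"}).
#' @return a [ForecastWindowSet].
#' @export
makeForecastWindows <- function(ts, query_channel = 4L, window = 50L,
                                stride = 19L, indices = NULL) {
  if (stride < 1) stop("stride must be >= 1")
  idx <- resolveIndices(ts, indices)
  T <- nFrames(ts); D <- nChannels(ts)
  if (T < window + 1)
    stop("trajectories too short for window length ", window)
  starts <- seq.int(1L, T - window, by = stride)
  M <- length(starts) * length(idx)
  inputs <- array(NA_real_, c(window, D, M))
  targets <- numeric(M)
  traj <- integer(M); st <- integer(M)
  m <- 0L
  for (i in idx) {
    x <- ts@tensors[, , i]
    for (s in starts) {
      m <- m + 1L
      inputs[, , m] <- x[s:(s + window - 1L), ]
      targets[m] <- x[s + window, query_channel]
      traj[m] <- i; st[m] <- s
    }
  }
  new("ForecastWindowSet", inputs = inputs, targets = targets,
      provenance = S4Vectors::DataFrame(trajectory = traj, start = st),
      queryChannel = as.integer(query_channel), lag = 1L)
}

#' Time-lagged forecast windows
#'
#' Thins every trajectory to every k-th frame before windowing, so a
#' window spans k-times longer simulated time at the same length.
#' \code{lag = 1} is identical to [makeForecastWindows()].
#'
#' @param ts a [TrajectorySet].
#' @param lag frame thinning factor k (>= 1).
#' @inheritParams makeForecastWindows
#' @return a [ForecastWindowSet] with the \code{lag} recorded.
#' @export
makeLaggedWindows <- function(ts, lag, query_channel = 4L, window = 50L,
                              stride = 19L, indices = NULL) {
  if (lag < 1) stop("lag must be >= 1")
  lag <- as.integer(lag)
  keep <- seq.int(1L, nFrames(ts), by = lag)
  if (length(keep) < window + 1)
    stop("insufficient frames after lagging: ", length(keep),
         " < ", window + 1)
  ts@tensors <- ts@tensors[keep, , , drop = FALSE]
  out <- makeForecastWindows(ts, query_channel = query_channel,
                             window = window, stride = stride,
                             indices = indices)
  out@lag <- lag
  out
}
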