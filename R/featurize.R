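#' @include AllClasses.R utils.R
NULL

#' DescriptorSet constructor
#'
#' @param name descriptor labels.
#' @param kind \code{"distance"}, \code{"angle"} or \code{"dihedral"}.
#' @param atoms list of 0-based atom index vectors (length 2/3/4).
#' @param units optional; inferred from kind when missing.
#' @return a [DescriptorSet].
#' @export
DescriptorSet <- function(name, kind, atoms, units = NULL) {
  if (is.null(units))
    units <- ifelse(kind == "distance", "angstrom", "degrees")
  new("DescriptorSet", name = as.character(name), kind = as.character(kind),
      atoms = lapply(atoms, as.integer), units = as.character(units))
}

#' The default 15-descriptor layout
#'
#' Canonical channel layout used throughout the package: distances on
#' channels 1, 2, 11-15 (Angstrom), angles on 4-8 (degrees), dihedrals
#' on 3, 9, 10 (degrees). Channels with a documented chemical identity:
#' d1 (Halpha-Nz distance), d3 (chi1 dihedral of the ligand), d4
#' (Halpha-Nz-CE angle), d5/d6 (Halpha-Nz-Hz angles), d11
#' (water-to-Lys-NH2 distance), d12 (water-to-Thr-OH distance), d15
#' (Nz-Calpha distance). The remaining channels (d2, d7-d10, d13, d14)
#' are configurable stand-ins that keep the kind/unit layout; replace
#' their atom tuples for a real topology via [DescriptorSet()] or
#' [readDescriptorDefinitions()]. The default atom indices address a
#' small synthetic topology and are placeholders, not chemistry.
#'
#' @param n_channels number of descriptors (canonical: 15).
#' @param slow_channel dihedral channel index used when
#'   \code{n_channels != 15}.
#' @return a [DescriptorSet].
#' @export
defaultDescriptorSet <- function(n_channels = 15L, slow_channel = 3L) {
  if (n_channels == 15L) {
    kind <- rep("distance", 15L)
    kind[4:8] <- "angle"
    kind[c(3L, 9L, 10L)] <- "dihedral"
  } else {
    kind <- rep(c("distance", "angle", "dihedral"), length.out = n_channels)
    kind[slow_channel] <- "dihedral"
  }
  need <- c(distance = 2L, angle = 3L, dihedral = 4L)[kind]
  atoms <- lapply(seq_len(n_channels), function(d)
    as.integer((d - 1L) + seq_len(need[d]) - 1L))
  DescriptorSet(paste0("d", seq_len(n_channels)), kind, atoms)
}

#' Euclidean distance between two atoms of one frame
#'
#' @param coords numeric matrix, atoms x 3.
#' @param pair two 0-based atom indices.
#' @return distance in the coordinate units (Angstrom), non-negative.
#' @examples
#' computeDistance(rbind(c(0, 0, 0), c(3, 4, 0)), c(0, 1))  # 5
#' @export
computeDistance <- function(coords, pair) {
  idx <- checkAtomIndices(coords, pair, 2L)
  sqrt(sum((coords[idx[1], ] - coords[idx[2], ])^2))
}

#' Angle spanned by three atoms of one frame
#'
#' @param coords numeric matrix, atoms x 3.
#' @param triple three 0-based atom indices (vertex in the middle).
#' @return angle in degrees, in [0, 180].
#' @export
computeAngle <- function(coords, triple) {
  idx <- checkAtomIndices(coords, triple, 3L)
  u <- coords[idx[1], ] - coords[idx[2], ]
  v <- coords[idx[3], ] - coords[idx[2], ]
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("degenerate geometry: coincident points in angle computation")
  acos(pmin(pmax(sum(u * v) / (nu * nv), -1), 1)) * 180 / pi
}

#' Dihedral (torsion) angle of four atoms of one frame
#'
#' Signed torsion following the IUPAC convention, computed with the
#' atan2 construction; returned in [-180, 180) (a planar trans
#' arrangement maps to -180).
#'
#' @param coords numeric matrix, atoms x 3.
#' @param quad four 0-based atom indices along the bonded chain.
#' @return dihedral in degrees, in [-180, 180).
#' @export
computeDihedral <- function(coords, quad) {
  idx <- checkAtomIndices(coords, quad, 4L)
  p <- coords[idx, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 == 0 || sum(n1^2) == 0 || sum(n2^2) == 0)
    stop("degenerate geometry: collinear points in dihedral computation")
  m <- cross3(n1, b2 / nb2)
  ang <- atan2(sum(m * n2), sum(n1 * n2)) * 180 / pi
  if (ang >= 180) ang <- ang - 360
  if (ang == 180) ang <- -180
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

checkAtomIndices <- function(coords, atoms, n) {
  if (length(atoms) != n)
    stop("featurization error: expected ", n, " atom indices")
  idx <- as.integer(atoms) + 1L  # 0-based externally, 1-based internally
  if (any(idx < 1) || any(idx > nrow(coords)))
    stop("featurization error: atom index out of range")
  idx
}

# Vectorized whole-trajectory path: coords is atoms x 3 x frames.
featurizeColumn <- function(coords, kind, atoms) {
  idx <- as.integer(atoms) + 1L
  T <- dim(coords)[3]
  P <- lapply(idx, function(a) t(coords[a, , ]))  # each T x 3 (frames x xyz)
  if (T == 1) P <- lapply(idx, function(a) matrix(coords[a, , 1], 1, 3))
  if (kind == "distance") {
    sqrt(rowSums((P[[1]] - P[[2]])^2))
  } else if (kind == "angle") {
    u <- P[[1]] - P[[2]]; v <- P[[3]] - P[[2]]
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    if (any(nu == 0 | nv == 0))
      stop("degenerate geometry at frame ",
           which(nu == 0 | nv == 0)[1])
    acos(pmin(pmax(rowSums(u * v) / (nu * nv), -1), 1)) * 180 / pi
  } else {
    b1 <- P[[2]] - P[[1]]; b2 <- P[[3]] - P[[2]]; b3 <- P[[4]] - P[[3]]
    n1 <- rowCross(b1, b2); n2 <- rowCross(b2, b3)
    nb2 <- sqrt(rowSums(b2^2))
    if (any(nb2 == 0 | rowSums(n1^2) == 0 | rowSums(n2^2) == 0))
      stop("degenerate geometry at frame ",
           which(nb2 == 0 | rowSums(n1^2) == 0 | rowSums(n2^2) == 0)[1])
    m <- rowCross(n1, b2 / nb2)
    ang <- atan2(rowSums(m * n2), rowSums(n1 * n2)) * 180 / pi
    ang[ang >= 180] <- ang[ang >= 180] - 360
    ang
  }
}

rowCross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Featurize a coordinate trajectory into descriptor time series
#'
#' Applies every descriptor definition to every frame, producing a
#' frames x descriptors matrix in definition order.
#'
#' @param frames either a list of atoms x 3 coordinate matrices or an
#'   atoms x 3 x frames array (e.g. from [readMultiModelPDB()]).
#' @param defs a [DescriptorSet].
#' @param ligand_id,enantiomer,class_label,dt metadata attached to the
#'   resulting set.
#' @return a [TrajectorySet] with a single trajectory.
#' @export
featurizeTrajectory <- function(frames, defs, ligand_id = NA_integer_,
                                enantiomer = NA_character_,
                                class_label = NA_character_, dt = 20 / 1000) {
  if (is.list(frames)) {
    stopifnot(length(frames) >= 1)
    coords <- array(unlist(frames), c(nrow(frames[[1]]), 3, length(frames)))
  } else {
    stopifnot(length(dim(frames)) == 3, dim(frames)[2] == 3)
    coords <- frames
  }
  natoms <- dim(coords)[1]
  maxIdx <- max(unlist(defs@atoms)) + 1L
  if (maxIdx > natoms)
    stop("featurization error: descriptor atom index ", maxIdx - 1L,
         " exceeds topology size ", natoms)
  T <- dim(coords)[3]
  vals <- matrix(NA_real_, T, length(defs@name))
  for (d in seq_along(defs@name))
    vals[, d] <- featurizeColumn(coords, defs@kind[d], defs@atoms[[d]])
  new("TrajectorySet",
      tensors = array(vals, c(T, ncol(vals), 1L)),
      info = buildInfoFrame(ligand_id, enantiomer, class_label, 1L),
      descriptors = defs, dt = dt,
      split = list(train = integer(0), validation = integer(0)),
      normalizer = NULL, metadata = list(source = "featurized"))
}

#' Read a multi-model PDB trajectory
#'
#' Parses MODEL/ENDMDL blocks of ATOM/HETATM records into an
#' atoms x 3 x frames coordinate array. A file without MODEL records is
#' read as a single frame. This is the built-in frame source; binary
#' trajectory formats (XTC/DCD/TRR) can be plugged in by supplying any
#' reader that returns the same array layout to
#' [featurizeTrajectory()].
#'
#' @param file path to a PDB file.
#' @return array atoms x 3 x frames, with attribute \code{"atom_names"}.
#' @export
readMultiModelPDB <- function(file) {
  lines <- readLines(file)
  isAtom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  isModel <- startsWith(lines, "MODEL")
  modelOf <- cumsum(isModel)
  if (!any(isModel)) modelOf <- rep(1L, length(lines))
  at <- which(isAtom)
  if (!length(at)) stop("no ATOM/HETATM records in ", file)
  frames <- split(at, modelOf[at])
  natoms <- length(frames[[1]])
  if (!all(vapply(frames, length, integer(1)) == natoms))
    stop("frames differ in atom count; cannot build a trajectory")
  coords <- array(NA_real_, c(natoms, 3, length(frames)))
  for (f in seq_along(frames)) {
    ln <- lines[frames[[f]]]
    coords[, 1, f] <- as.numeric(substr(ln, 31, 38))
    coords[, 2, f] <- as.numeric(substr(ln, 39, 46))
    coords[, 3, f] <- as.numeric(substr(ln, 47, 54))
  }
  if (anyNA(coords)) stop("malformed coordinate fields in ", file)
  attr(coords, "atom_names") <- trimws(substr(lines[frames[[1]]], 13, 16))
  coords
}

#' Read descriptor definitions from columnar text
#'
#' Whitespace-separated columns: name, kind, comma-separated 0-based
#' atom indices, units. Lines starting with '#' are ignored.
#'
#' @param file path to the definitions file.
#' @return a [DescriptorSet].
#' @export
readDescriptorDefinitions <- function(file) {
  tb <- read.table(file, header = FALSE, comment.char = "#",
                   col.names = c("name", "kind", "atoms", "units"),
                   stringsAsFactors = FALSE)
  DescriptorSet(tb$name, tb$kind,
                lapply(strsplit(tb$atoms, ","), as.integer), tb$units)
}

#' Write descriptor definitions to columnar text
#' @param defs a [DescriptorSet].
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeDescriptorDefinitions <- function(defs, file) {
  tb <- data.frame(name = defs@name, kind = defs@kind,
                   atoms = vapply(defs@atoms, paste, "", collapse = ","),
                   units = defs@units)
  write.table(tb, file, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Fit a per-channel normalizer on the training split
#'
#' Default method is min-max to [0, 1] using the training extrema of
#' each channel. A constant channel gets scale 1 with a warning.
#' Fitting never reads rows outside \code{indices}.
#'
#' @param ts a [TrajectorySet].
#' @param indices trajectories to fit on; defaults to the training
#'   split when one is assigned, else all trajectories.
#' @param method only \code{"minmax"} is currently defined.
#' @return normalizer: list(method, offset, scale, names).
#' @export
fitNormalizer <- function(ts, indices = NULL, method = "minmax") {
  method <- match.arg(method, "minmax")
  if (is.null(indices)) {
    indices <- if (length(trainIndices(ts))) trainIndices(ts)
               else seq_len(nTrajectories(ts))
  }
  x <- ts@tensors[, , indices, drop = FALSE]
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  scale <- hi - lo
  if (any(scale == 0)) {
    warning("constant channel(s): ",
            paste(descriptorNames(ts)[scale == 0], collapse = ", "),
            "; scale set to 1")
    scale[scale == 0] <- 1
  }
  list(method = method, offset = lo, scale = scale,
       names = descriptorNames(ts))
}

#' Apply (or invert) a fitted normalizer
#'
#' Values outside the training range are clipped to [0, 1]; the number
#' of clipped values is reported via a message. Applying then inverting
#' recovers unclipped inputs to numerical precision.
#'
#' @param x a [TrajectorySet], a frames x channels matrix or a
#'   frames x channels x n array.
#' @param norm a normalizer from [fitNormalizer()].
#' @param clip clip transformed values into [0, 1] (default TRUE).
#' @return object of the same shape, normalized; for a TrajectorySet
#'   the normalizer is recorded in the returned object.
#' @export
applyNormalizer <- function(x, norm, clip = TRUE) {
  if (is(x, "TrajectorySet")) {
    x@tensors <- applyNormalizer(x@tensors, norm, clip)
    x@normalizer <- norm
    return(x)
  }
  d <- if (is.matrix(x)) 2L else length(dim(x))
  stopifnot(dim(x)[2] == length(norm$offset))
  out <- sweep(x, 2, norm$offset, "-")
  out <- sweep(out, 2, norm$scale, "/")
  if (clip) {
    nclip <- sum(out < 0 | out > 1)
    if (nclip > 0)
      message(nclip, " value(s) outside the training range were clipped")
    out[out < 0] <- 0
    out[out > 1] <- 1
  }
  out
}

#' @rdname applyNormalizer
#' @export
invertNormalizer <- function(x, norm) {
  if (is(x, "TrajectorySet")) {
    x@tensors <- invertNormalizer(x@tensors, norm)
    x@normalizer <- NULL
    return(x)
  }
  out <- sweep(x, 2, norm$scale, "*")
  sweep(out, 2, norm$offset, "+")
}
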