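#' @include AllClasses.R utils.R
NULL

#' Generator configuration for synthetic descriptor trajectories
#'
#' Defines the statistical emulator of the MD descriptor dataset: 49
#' ligands, two enantiomer classes with 100 trajectories each, 1,000
#' frames (20 ps) of 15 geometric descriptors per trajectory. The two
#' classes share identical per-channel marginal distributions by
#' construction; class information is carried only in temporal motifs
#' (default, \code{coupling_mode = "temporal"}: the coupled channels
#' oscillate fast in reactive and slow in non-reactive trajectories at
#' equal amplitude) or in static cross-channel combinations
#' (\code{coupling_mode = "static"}: the coupled channels share one
#' frequency and the reactive class locks them to a common phase, so
#' classes differ in instantaneous cross-channel correlation, which
#' frame shuffling cannot destroy).
#'
#' @param n_ligands number of ligands (default 49).
#' @param n_per_class trajectories per class per ligand (default 100).
#' @param n_frames frames per trajectory (default 1000); at least 51 so
#'   that forecasting windows of 50 steps plus a target fit.
#' @param n_channels descriptor channels (default 15).
#' @param dt simulated time per frame in ps (default 20/1000).
#' @param slow_channel index of the slow chi1-like dihedral channel
#'   (default 3); modelled as a reflected random walk in a narrow band
#'   around -90 degrees (the catalytic orientation) for both classes.
#' @param drift_band half-width (degrees) of the slow channel's band.
#' @param coupled_channels channels carrying the class signal
#'   (default c(4, 5, 6, 11): the Ha-Nz-CE angle analogue, its two
#'   sibling angles and the water-Lys distance analogue).
#' @param coupling_mode \code{"temporal"} or \code{"static"}.
#' @param reactive_cycles,nonreactive_cycles integer oscillation counts
#'   per trajectory for the coupled channels in temporal mode; equal
#'   amplitude, so per-channel marginals match across classes.
#' @param hard_ligand_frac fraction of ligands with attenuated coupling
#'   (intrinsically harder to classify).
#' @param noise_sd per-frame Gaussian noise, as a fraction of each
#'   channel's oscillation amplitude.
#' @param ks_threshold declared bound on the per-channel two-sample
#'   Kolmogorov-Smirnov statistic between class marginals.
#' @param master_seed integer master seed; the full dataset is a
#'   deterministic function of it.
#' @return a \code{trajselGeneratorConfig} list.
#' @examples
#' cfg <- generatorConfig(n_ligands = 2, n_per_class = 3, n_frames = 100)
#' ts <- generateDataset(cfg)
#' ts
#' @export
generatorConfig <- function(n_ligands = 49L, n_per_class = 100L,
                            n_frames = 1000L, n_channels = 15L,
                            dt = 20 / 1000, slow_channel = 3L,
                            drift_band = 15, coupled_channels = c(4L, 5L, 6L, 11L),
                            coupling_mode = c("temporal", "static"),
                            reactive_cycles = 40L, nonreactive_cycles = 10L,
                            hard_ligand_frac = 0.1,
                            noise_sd = 0.1, ks_threshold = 0.05,
                            master_seed = 1L) {
  coupling_mode <- match.arg(coupling_mode)
  cfg <- list(n_ligands = as.integer(n_ligands),
              n_per_class = as.integer(n_per_class),
              n_frames = as.integer(n_frames),
              n_channels = as.integer(n_channels),
              dt = dt, slow_channel = as.integer(slow_channel),
              drift_band = drift_band,
              coupled_channels = as.integer(coupled_channels),
              coupling_mode = coupling_mode,
              reactive_cycles = as.integer(reactive_cycles),
              nonreactive_cycles = as.integer(nonreactive_cycles),
              hard_ligand_frac = hard_ligand_frac,
              noise_sd = noise_sd, ks_threshold = ks_threshold,
              master_seed = as.integer(master_seed))
  if (cfg$n_ligands < 1 || cfg$n_per_class < 1)
    stop("configuration error: counts must be positive")
  if (cfg$n_frames < 51L)
    stop("configuration error: n_frames must be >= 51 (window of 50 + target)")
  if (cfg$n_channels < 1)
    stop("configuration error: n_channels must be positive")
  if (cfg$slow_channel < 1 || cfg$slow_channel > cfg$n_channels)
    stop("configuration error: slow_channel out of range")
  if (any(cfg$coupled_channels < 1 | cfg$coupled_channels > cfg$n_channels))
    stop("configuration error: coupled_channels out of range")
  if (cfg$slow_channel %in% cfg$coupled_channels)
    stop("configuration error: the slow channel cannot carry the coupling")
  if (cfg$noise_sd < 0) stop("configuration error: noise_sd must be >= 0")
  class(cfg) <- "trajselGeneratorConfig"
  cfg
}

# Channel kind layout. For the canonical 15 channels: distances
# 1,2,11-15 (Angstrom); angles 4-8 (degrees); dihedrals 3,9,10
# (degrees). Other widths cycle through the kinds, forcing the slow
# channel to dihedral.
channelKinds <- function(n_channels, slow_channel = 3L) {
  if (n_channels == 15L) {
    k <- rep("distance", 15L)
    k[4:8] <- "angle"
    k[c(3L, 9L, 10L)] <- "dihedral"
  } else {
    k <- rep(c("distance", "angle", "dihedral"), length.out = n_channels)
    k[slow_channel] <- "dihedral"
  }
  k
}

#' Ligand profiles: per-ligand generator parameters
#'
#' Draws, deterministically from the master seed, the per-ligand
#' channel baselines, oscillation amplitudes, base frequencies, the
#' class-specific motif frequencies of the coupled channels and the
#' preferred enantiomer. Baselines differ across ligands so that a
#' ligand-held-out split is a genuine generalization test. In the
#' canonical 49-ligand layout, ligands 32, 33, 35, 36 and 45 prefer the
#' (R)-enantiomer; all others prefer (S).
#'
#' @param config a [generatorConfig()].
#' @return list of ligand profiles (one per ligand).
#' @examples
#' profs <- makeLigandProfiles(generatorConfig(n_ligands = 3))
#' profs[[1]]$preferred_enantiomer
#' @export
makeLigandProfiles <- function(config) {
  stopifnot(inherits(config, "trajselGeneratorConfig"))
  D <- config$n_channels
  kinds <- channelKinds(D, config$slow_channel)
  rPreferred <- c(32L, 33L, 35L, 36L, 45L)
  withSeed(deriveSeed(config$master_seed, 11L), {
    nHard <- floor(config$hard_ligand_frac * config$n_ligands)
    hardSet <- if (nHard > 0)
      sample(seq_len(config$n_ligands), nHard) else integer(0)
    lapply(seq_len(config$n_ligands), function(lig) {
      baselines <- numeric(D)
      spreads <- numeric(D)
      for (d in seq_len(D)) {
        if (d == config$slow_channel) {
          baselines[d] <- -90
          spreads[d] <- config$drift_band
        } else if (kinds[d] == "distance") {
          baselines[d] <- runif(1, 3.2, 4.8)
          spreads[d] <- runif(1, 0.5, 0.9)
        } else if (kinds[d] == "angle") {
          baselines[d] <- runif(1, 105, 130)
          spreads[d] <- runif(1, 12, 20)
        } else {
          baselines[d] <- runif(1, -105, -75)
          spreads[d] <- runif(1, 15, 25)
        }
      }
      # base (class-shared) integer cycle counts per channel
      cycles <- sample(3:10, D, replace = TRUE)
      hard <- lig %in% hardSet
      nc <- length(config$coupled_channels)
      jit <- sample(-1:1, nc, replace = TRUE)
      rc <- config$reactive_cycles + jit
      nr <- config$nonreactive_cycles + jit
      if (hard) {  # pull the class frequencies toward each other
        mid <- (rc + nr) / 2
        rc <- as.integer(round(mid + (rc - mid) * 0.4))
        nr <- as.integer(round(mid + (nr - mid) * 0.4))
      }
      list(ligand_id = lig,
           preferred_enantiomer = if (lig %in% rPreferred) "R" else "S",
           channel_baselines = baselines,
           channel_spreads = spreads,
           channel_kinds = kinds,
           channel_cycles = cycles,
           pattern_params = list(reactive_cycles = rc,
                                 nonreactive_cycles = nr,
                                 coupled_channels = config$coupled_channels,
                                 hard = hard),
           seed = deriveSeed(config$master_seed, 13L, lig))
    })
  })
}

#' Generate one synthetic descriptor trajectory
#'
#' Produces an n_frames x n_channels matrix for one ligand, class and
#' replicate. Non-slow channels are sinusoid-plus-noise with a uniform
#' random phase per channel; the coupled channels oscillate with the
#' class-specific cycle count (temporal mode) or receive a shared
#' per-frame latent with a class-dependent sign pattern (static mode).
#' The slow channel is a reflected random walk confined to
#' \code{drift_band} degrees around -90. Integer cycle counts and equal
#' amplitudes make the stationary per-channel marginals of the two
#' classes identical by construction. Angle channels are clipped to
#' [0, 180], dihedrals wrapped to [-180, 180), distances kept strictly
#' positive.
#'
#' @param profile a ligand profile from [makeLigandProfiles()].
#' @param class_label \code{"reactive"} or \code{"non-reactive"}.
#' @param replicate replicate index (determines the RNG stream).
#' @param config the [generatorConfig()] used to build the profiles.
#' @return numeric matrix, n_frames x n_channels.
#' @examples
#' cfg <- generatorConfig(n_ligands = 1, n_frames = 200)
#' p <- makeLigandProfiles(cfg)[[1]]
#' x <- generateTrajectory(p, "reactive", 1L, cfg)
#' dim(x)
#' @export
generateTrajectory <- function(profile, class_label, replicate, config) {
  if (!class_label %in% c("reactive", "non-reactive"))
    stop("labeling error: unknown class tag '", class_label, "'")
  T <- config$n_frames
  D <- config$n_channels
  reactive <- class_label == "reactive"
  seed <- deriveSeed(profile$seed, if (reactive) 1L else 2L, replicate)
  withSeed(seed, {
    out <- matrix(0, T, D)
    tt <- (seq_len(T) - 1) / T
    coupled <- profile$pattern_params$coupled_channels
    # static mode: the coupled channels share one frequency; the
    # reactive class locks them to a common random phase (instantaneous
    # cross-channel correlation, which frame shuffling cannot destroy),
    # the non-reactive class draws independent phases. Equal amplitude
    # and frequency keep the per-channel marginals identical.
    sharedPhase <- runif(1, 0, 2 * pi)
    sharedCycles <- profile$channel_cycles[coupled[1]]
    for (d in seq_len(D)) {
      base <- profile$channel_baselines[d]
      amp <- profile$channel_spreads[d]
      if (d == config$slow_channel) {
        stepSd <- config$drift_band * config$noise_sd * 2
        walk <- c(0, cumsum(rnorm(T - 1, 0, stepSd)))
        out[, d] <- base + reflectIntoBand(walk, config$drift_band)
        next
      }
      ci <- match(d, coupled)
      cyc <- if (is.na(ci)) profile$channel_cycles[d]
        else if (config$coupling_mode == "temporal") {
          if (reactive) profile$pattern_params$reactive_cycles[ci]
          else profile$pattern_params$nonreactive_cycles[ci]
        } else sharedCycles
      phase <- runif(1, 0, 2 * pi)
      if (!is.na(ci) && config$coupling_mode == "static" && reactive)
        phase <- sharedPhase
      x <- base + amp * sin(2 * pi * cyc * tt + phase) +
        rnorm(T, 0, config$noise_sd * amp)
      kind <- profile$channel_kinds[d]
      out[, d] <- switch(kind,
        distance = pmax(x, 0.01),
        angle = pmin(pmax(x, 0), 180),
        dihedral = wrapDihedral(x))
    }
    out
  })
}

buildInfoFrame <- function(ligand, enantiomer, class, replicate) {
  S4Vectors::DataFrame(ligand_id = as.integer(ligand),
                       enantiomer = enantiomer,
                       class_label = class,
                       replicate = as.integer(replicate))
}

otherEnantiomer <- function(e) ifelse(e == "S", "R", "S")

#' Generate the full labelled synthetic dataset
#'
#' Runs [generateTrajectory()] for every ligand, class and replicate of
#' the configuration: n_ligands x 2 classes x n_per_class trajectories,
#' exactly balanced per ligand (defaults: 49 x 2 x 100 = 9,800). The
#' enantiomer tag of each trajectory follows from the ligand's preferred
#' enantiomer and the class (reactive trajectories carry the preferred
#' enantiomer).
#'
#' @param config a [generatorConfig()].
#' @return a [TrajectorySet].
#' @examples
#' ts <- generateDataset(generatorConfig(n_ligands = 2, n_per_class = 3,
#'                                       n_frames = 100))
#' nTrajectories(ts)  # 12
#' @export
generateDataset <- function(config) {
  profiles <- makeLigandProfiles(config)
  T <- config$n_frames
  D <- config$n_channels
  N <- config$n_ligands * 2L * config$n_per_class
  tens <- array(NA_real_, c(T, D, N))
  lig <- integer(N); enant <- character(N)
  cls <- character(N); repl <- integer(N)
  i <- 0L
  for (p in profiles) {
    for (label in c("reactive", "non-reactive")) {
      e <- if (label == "reactive") p$preferred_enantiomer
           else otherEnantiomer(p$preferred_enantiomer)
      for (r in seq_len(config$n_per_class)) {
        i <- i + 1L
        tens[, , i] <- generateTrajectory(p, label, r, config)
        lig[i] <- p$ligand_id; enant[i] <- e
        cls[i] <- label; repl[i] <- r
      }
    }
  }
  new("TrajectorySet", tensors = tens,
      info = buildInfoFrame(lig, enant, cls, repl),
      descriptors = defaultDescriptorSet(D, config$slow_channel),
      dt = config$dt,
      split = list(train = integer(0), validation = integer(0)),
      normalizer = NULL,
      metadata = list(generator = unclass(config),
                      master_seed = config$master_seed))
}

#' Generate a class-uninformative (null) dataset
#'
#' Identical to [generateDataset()] but the class labels are randomly
#' permuted within each ligand afterwards, destroying all class signal
#' while preserving the label counts. Serves as the chance-level control
#' (a classifier's expected validation accuracy is 0.5).
#'
#' @param config a [generatorConfig()].
#' @param permute_seed seed of the label permutation (derived from the
#'   master seed by default).
#' @return a [TrajectorySet] with permuted \code{class_label}.
#' @export
generateNullDataset <- function(config,
                                permute_seed = deriveSeed(config$master_seed, 99L)) {
  ts <- generateDataset(config)
  info <- ts@info
  withSeed(permute_seed, {
    for (lg in unique(info$ligand_id)) {
      idx <- which(info$ligand_id == lg)
      info$class_label[idx] <- info$class_label[idx][sample(length(idx))]
    }
  })
  ts@info <- info
  ts@metadata$null_permuted <- TRUE
  ts@metadata$permute_seed <- permute_seed
  ts
}

#' Shuffle frame order within each trajectory
#'
#' Destroys temporal structure while leaving every per-frame marginal
#' (and any purely static cross-channel combination) untouched. Used to
#' verify where the class signal lives: with temporal coupling,
#' shuffling drives a classifier to chance; with static coupling it does
#' not.
#'
#' @param ts a [TrajectorySet].
#' @param seed permutation seed.
#' @return a [TrajectorySet] with independently permuted frames per
#'   trajectory.
#' @export
shuffleFrames <- function(ts, seed = 1L) {
  tens <- ts@tensors
  withSeed(seed, {
    for (i in seq_len(dim(tens)[3]))
      tens[, , i] <- tens[sample(nrow(tens)), , i]
  })
  ts@tensors <- tens
  ts@metadata$frames_shuffled <- TRUE
  ts
}

#' Per-channel class-marginal agreement (two-sample KS statistic)
#'
#' Pools every frame of every trajectory per class and computes, per
#' channel, the two-sample Kolmogorov-Smirnov statistic between the two
#' class distributions. At generator defaults every channel's statistic
#' stays below the configured \code{ks_threshold}: the classes are
#' marginally indistinguishable.
#'
#' @param ts a [TrajectorySet].
#' @return numeric vector of KS statistics, one per channel.
#' @export
classMarginalKS <- function(ts) {
  cls <- classLabels(ts)
  a <- which(cls == "reactive")
  b <- which(cls == "non-reactive")
  if (!length(a) || !length(b))
    stop("both classes must be present")
  vapply(seq_len(nChannels(ts)), function(d) {
    x <- as.vector(ts@tensors[, d, a])
    y <- as.vector(ts@tensors[, d, b])
    as.numeric(suppressWarnings(ks.test(x, y))$statistic)
  }, numeric(1))
}
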