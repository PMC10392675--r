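#' @include synthetic.R dataset.R models.R interpret.R io.R
NULL

#' Pipeline run configuration
#'
#' Flat, fully serializable configuration for [runPipeline()]. Any
#' entry of the generator configuration may be overridden through
#' \code{...}.
#'
#' @param out_dir output directory of the run.
#' @param master_seed seed driving every stage.
#' @param n_ligands,n_per_class,n_frames generator sizes.
#' @param train_frac fraction of ligands assigned to training (ligands
#'   are split by index order, lowest ids to training, as in the
#'   canonical 1-38 / 39-49 assignment).
#' @param architectures classifier architectures to train
#'   (\code{"cnn1d"} and/or \code{"cnn2d"}).
#' @param epochs optional epoch override for every trained model.
#' @param ablation run the single-channel ablation study.
#' @param ablation_replicas replicas for the ablation study.
#' @param cam emit CAM saliency artifacts.
#' @param tsne emit the t-SNE latent projection.
#' @param tsne_perplexity perplexity (reduced automatically when the
#'   validation split is small).
#' @param verbose log stage progress to stderr.
#' @param ... generator overrides passed to [generatorConfig()].
#' @return a \code{trajselRunConfig} list.
#' @export
pipelineConfig <- function(out_dir, master_seed = 1L, n_ligands = 4L,
                           n_per_class = 20L, n_frames = 400L,
                           train_frac = 0.75,
                           architectures = "cnn1d", epochs = NULL,
                           ablation = FALSE, ablation_replicas = 2L,
                           cam = TRUE, tsne = TRUE, tsne_perplexity = 30,
                           verbose = FALSE, ...) {
  cfg <- list(out_dir = out_dir, master_seed = as.integer(master_seed),
              n_ligands = as.integer(n_ligands),
              n_per_class = as.integer(n_per_class),
              n_frames = as.integer(n_frames),
              train_frac = train_frac,
              architectures = architectures, epochs = epochs,
              ablation = ablation,
              ablation_replicas = as.integer(ablation_replicas),
              cam = cam, tsne = tsne, tsne_perplexity = tsne_perplexity,
              verbose = verbose, generator = list(...))
  class(cfg) <- "trajselRunConfig"
  cfg
}

#' Reduced-size demo configuration
#'
#' Exercises every pipeline stage in well under a minute: 2 ligands,
#' 10 trajectories per class, 200 frames, 2 training epochs.
#'
#' @param out_dir output directory.
#' @param master_seed seed.
#' @return a \code{trajselRunConfig}.
#' @export
demoConfig <- function(out_dir, master_seed = 1L) {
  pipelineConfig(out_dir, master_seed = master_seed, n_ligands = 2L,
                 n_per_class = 10L, n_frames = 200L, train_frac = 0.5,
                 epochs = 2L, ablation = FALSE, cam = TRUE, tsne = FALSE)
}

pipelineLog <- function(cfg, ...) {
  msg <- paste0(...)
  if (isTRUE(cfg$verbose)) message("[trajsel] ", msg)
  msg
}

#' Run the end-to-end pipeline
#'
#' Stages: synthetic dataset generation, ligand-held-out split and
#' normalization, classifier training and evaluation, optional ablation
#' study, CAM saliency, max-activation table and t-SNE projection. All
#' artifacts land in the configured output directory together with a
#' manifest logging every seed, stage and artifact checksum; a rerun
#' with the same configuration reproduces identical data artifacts.
#'
#' @param config a [pipelineConfig()] or [demoConfig()].
#' @return invisibly, a list with the run directory, the manifest, the
#'   dataset and the trained models.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "trajselRunConfig"))
  outDir <- config$out_dir
  parent <- dirname(normalizePath(outDir, mustWork = FALSE))
  if (!dir.exists(parent) || file.access(parent, 2) != 0)
    stop("output path not writable: ", outDir)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  stage <- function(name, expr) {
    log <<- c(log, pipelineLog(config, "stage: ", name))
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  gen <- do.call(generatorConfig,
                 c(list(n_ligands = config$n_ligands,
                        n_per_class = config$n_per_class,
                        n_frames = config$n_frames,
                        master_seed = config$master_seed),
                   config$generator))
  ts <- stage("synth", generateDataset(gen))
  nTrain <- max(1L, min(config$n_ligands - 1L,
                        round(config$train_frac * config$n_ligands)))
  ts <- stage("dataset", {
    ts <- splitByLigand(ts, seq_len(nTrain),
                        seq.int(nTrain + 1L, config$n_ligands))
    norm <- fitNormalizer(ts)
    applyNormalizer(ts, norm)
  })
  stage("write-dataset", writeTrajectorySet(ts, file.path(outDir, "dataset")))

  models <- list()
  reports <- list()
  for (arch in config$architectures) {
    models[[arch]] <- stage(paste0("train-", arch), {
      model <- switch(arch,
        cnn1d = buildCNN1D(n_channels = nChannels(ts),
                           seed = deriveSeed(config$master_seed, 201L)),
        cnn2d = buildCNN2D(n_channels = nChannels(ts),
                           n_frames = nFrames(ts),
                           seed = deriveSeed(config$master_seed, 202L)),
        stop("unsupported pipeline architecture: ", arch))
      trainClassifier(model, ts, epochs = config$epochs,
                      verbose = config$verbose)
    })
    reports[[arch]] <- stage(paste0("eval-", arch), {
      rep <- evaluateModel(models[[arch]], ts, "validation")
      writeEvalReport(rep, file.path(outDir, paste0("eval_", arch)))
      rep
    })
    if (arch == "cnn1d")
      stage("save-model",
            saveTrainedModel(models[[arch]],
                             file.path(outDir, "model_cnn1d.json")))
  }

  if (isTRUE(config$ablation))
    stage("ablation", {
      ab <- ablationStudy(ts, replicas = config$ablation_replicas,
                          epochs = config$epochs,
                          seed = deriveSeed(config$master_seed, 203L))
      write.csv(ablationTable(ab), file.path(outDir, "ablation.csv"),
                row.names = FALSE)
    })

  if (isTRUE(config$cam) && "cnn1d" %in% names(models))
    stage("cam", {
      sal <- computeCAM1D(models$cnn1d,
                          ts@tensors[, , validationIndices(ts)[1]])
      write.csv(saliency(sal), file.path(outDir, "cam_filters_x_time.csv"),
                row.names = FALSE)
      maxact <- extractMaxActivationValues(models$cnn1d, ts,
                                           indices = "validation")
      write.csv(maxact, file.path(outDir, "max_activation_values.csv"),
                row.names = FALSE)
    })

  if (isTRUE(config$tsne) && "cnn1d" %in% names(models))
    stage("tsne", {
      nval <- length(validationIndices(ts))
      perp <- min(config$tsne_perplexity, floor((nval - 2) / 3))
      proj <- projectLatentSpace(models$cnn1d, ts, "validation",
                                 perplexity = perp,
                                 seed = deriveSeed(config$master_seed, 204L))
      write.csv(proj, file.path(outDir, "tsne_latent.csv"),
                row.names = FALSE)
    })

  cfgFile <- file.path(outDir, "run_config.json")
  cfgSer <- unclass(config)
  cfgSer$out_dir <- NULL   # location-independent, so reruns hash equal
  jsonlite::write_json(cfgSer, cfgFile, auto_unbox = TRUE,
                       digits = NA, null = "null")
  artifacts <- setdiff(list.files(outDir, recursive = TRUE),
                       "manifest.json")
  manifest <- list(
    package = "trajsel",
    master_seed = config$master_seed,
    config_hash = unname(tools::md5sum(cfgFile)),
    stages = log,
    artifacts = as.list(tools::md5sum(file.path(outDir, artifacts))))
  names(manifest$artifacts) <- artifacts
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = outDir, manifest = manifest, dataset = ts,
                 models = models, reports = reports))
}
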