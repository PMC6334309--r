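#' Default run configuration
#'
#' The unified configuration for the end-to-end pipeline
#' (phantom -> VOI -> augmentation -> WGAN -> pretrain -> fine-tune ->
#' evaluation). Two presets are provided:
#' \describe{
#'   \item{\code{"paper"}}{echoes the full-scale hyperparameters: WGAN for
#'     1000 epochs at learning rate 0.00005 (RMSprop), fine-tuning for 30
#'     epochs at 0.0001 (SGD), dropout 0.5, a 27/33 benign/malignant
#'     cohort, full augmentation (256 views per nodule) and full channel
#'     widths. GPU-scale; not meant for test runs.}
#'   \item{\code{"tiny"}}{a CPU-scale configuration (small cohort, reduced
#'     angle grid, 1/8 channel widths, short schedules) that exercises
#'     every stage in minutes.}
#' }
#'
#' @param preset \code{"tiny"} or \code{"paper"}.
#' @return nested configuration list of class \code{"runConfig"}.
#' @export
defaultRunConfig <- function(preset = c("tiny", "paper")) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    cfg <- list(
      preset = "paper",
      master_seed = 0L,
      out_dir = "nodulegan-run",
      cohort = list(n_benign = 27L, n_malignant = 33L),
      phantom = list(volume_shape = c(64L, 64L, 64L), noise_sigma = 20,
                     diameter_range = c(8, 16)),
      voi = list(resolution_mm = 1),
      augment = list(angle_min = -40, angle_max = 40, angle_step = 5,
                     tilt_axes = c("x", "y"), include_axial = FALSE,
                     out_size = 64L),
      wgan = list(latent_dim = 100L, lr = 0.00005, epochs = 1000L,
                  clip_value = 0.01, n_critic = 5L, batch_size = 64L,
                  widths = "paper"),
      pretrain = list(epochs = 10L, lr = 0.001, momentum = 0.9,
                      batch_size = 32L, preset = "paper"),
      finetune = list(epochs = 30L, lr = 0.0001, momentum = 0.9,
                      batch_size = 32L),
      evaluation = list(k = 3L, n_gen_per_class = 20000L,
                        aggregate = "mean", test_views = "augmented",
                        strategies = c("scratch", "wgan")))
  } else {
    cfg <- list(
      preset = "tiny",
      master_seed = 0L,
      out_dir = "nodulegan-run",
      cohort = list(n_benign = 10L, n_malignant = 10L),
      phantom = list(volume_shape = c(48L, 48L, 48L), noise_sigma = 20,
                     diameter_range = c(8, 12)),
      voi = list(resolution_mm = 1),
      augment = list(angle_min = -40, angle_max = 40, angle_step = 40,
                     tilt_axes = c("x", "y"), include_axial = FALSE,
                     out_size = 32L),
      wgan = list(latent_dim = 100L, lr = 5e-4, epochs = 6L,
                  clip_value = 0.01, n_critic = 2L, batch_size = 16L,
                  widths = "tiny"),
      pretrain = list(epochs = 8L, lr = 0.02, momentum = 0.9,
                      batch_size = 16L, preset = "tiny"),
      finetune = list(epochs = 12L, lr = 0.02, momentum = 0.9,
                      batch_size = 16L),
      evaluation = list(k = 3L, n_gen_per_class = 64L,
                        aggregate = "mean", test_views = "augmented",
                        strategies = c("scratch", "wgan")))
  }
  structure(cfg, class = "runConfig")
}

mergeConfig <- function(base, override, path = "") {
  for (nm in names(override)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base))
      stop("unknown configuration key: ", here)
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(override[[nm]]))
        stop("configuration key ", here, " must be a mapping")
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]], here)
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

validateRunConfig <- function(cfg) {
  chk <- function(ok, key, msg) if (!ok) stop("invalid configuration: ", key, " ", msg)
  chk(cfg$preset %in% c("tiny", "paper"), "preset", "must be 'tiny' or 'paper'")
  chk(cfg$cohort$n_benign >= 0, "cohort.n_benign", "must be >= 0")
  chk(cfg$cohort$n_malignant >= 0, "cohort.n_malignant", "must be >= 0")
  chk(cfg$voi$resolution_mm > 0, "voi.resolution_mm", "must be > 0")
  chk(cfg$wgan$lr > 0, "wgan.lr", "must be > 0")
  chk(cfg$wgan$epochs >= 0, "wgan.epochs", "must be >= 0")
  chk(cfg$wgan$clip_value > 0, "wgan.clip_value", "must be > 0")
  chk(cfg$wgan$n_critic >= 1, "wgan.n_critic", "must be >= 1")
  chk(cfg$wgan$latent_dim >= 1, "wgan.latent_dim", "must be >= 1")
  chk(cfg$pretrain$lr > 0, "pretrain.lr", "must be > 0")
  chk(cfg$pretrain$epochs >= 1, "pretrain.epochs", "must be >= 1")
  chk(cfg$finetune$lr > 0, "finetune.lr", "must be > 0")
  chk(cfg$finetune$epochs >= 0, "finetune.epochs", "must be >= 0")
  chk(cfg$evaluation$k >= 1, "evaluation.k", "must be >= 1")
  chk(all(cfg$evaluation$strategies %in% c("scratch", "wgan")),
      "evaluation.strategies", "must be a subset of scratch, wgan")
  # the stage-config invariants are re-checked by their own constructors
  invisible(cfg)
}

#' Load a run configuration from YAML
#'
#' Missing keys take the preset's defaults; unknown keys are rejected with
#' the offending YAML path (typo safety); invariant violations name the
#' key. An empty file yields the preset defaults unchanged. The fully
#' merged configuration is what [runPipeline()] echoes into its manifest,
#' so no default is silent.
#'
#' @param path YAML file path.
#' @param preset base preset to merge into.
#' @return a validated \code{"runConfig"}.
#' @export
loadRunConfig <- function(path, preset = NULL) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (is.null(preset)) preset <- if (!is.null(raw$preset)) raw$preset else "tiny"
  cfg <- mergeConfig(defaultRunConfig(preset), raw)
  validateRunConfig(cfg)
  structure(cfg, class = "runConfig")
}

#' @rdname loadRunConfig
#' @param config a \code{"runConfig"} to serialize.
#' @export
dumpRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

configHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # stable text serialization, independent of in-memory attribute order
  writeLines(yaml::as.yaml(x), f)
  unname(tools::md5sum(f))
}

logStage <- function(logPath, stage, hash, elapsed, extra = list()) {
  rec <- c(list(stage = stage, hash = hash,
                elapsed_s = round(elapsed, 2),
                time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), extra)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = logPath, append = TRUE, sep = "")
}

# Run `fun` or reuse the cached result keyed by `hash`.
cachedStage <- function(cacheDir, stage, hash, fun, logPath) {
  file <- file.path(cacheDir, paste0(stage, "-", hash, ".rds"))
  t0 <- proc.time()[3]
  if (file.exists(file)) {
    out <- readRDS(file)
    logStage(logPath, stage, hash, proc.time()[3] - t0, list(cached = TRUE))
    return(out)
  }
  out <- fun()
  saveRDS(out, file)
  logStage(logPath, stage, hash, proc.time()[3] - t0, list(cached = FALSE))
  out
}

#' Run the full pipeline from one configuration
#'
#' Executes phantom generation, VOI extraction, augmentation, per-class
#' WGAN training, classifier pretraining, fine-tuning and case-level
#' evaluation, in that order, via [compareStrategies()]. Each stage's
#' output is cached under \code{out_dir/cache} keyed by a hash of its
#' configuration and its upstream inputs, so a rerun with the same
#' configuration reuses cached stages and changing the master seed
#' invalidates exactly the stages whose inputs change. Structured JSON
#' lines are appended to \code{out_dir/run-log.jsonl}.
#'
#' @param config a \code{"runConfig"} (see [defaultRunConfig()] /
#'   [loadRunConfig()]).
#' @return list of class \code{"runManifest"}: the comparison, file paths,
#'   config echo, and stage hashes.
#' @export
runPipeline <- function(config = defaultRunConfig("tiny")) {
  validateRunConfig(config)
  outDir <- config$out_dir
  cacheDir <- file.path(outDir, "cache")
  dir.create(cacheDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run-log.jsonl")

  ph <- config$phantom
  phCfg <- phantomConfig(volumeShape = ph$volume_shape,
                         noiseSigma = ph$noise_sigma,
                         diameterRange = ph$diameter_range)
  phantomHash <- configHash(list(ph = ph, cohort = config$cohort,
                                 seed = config$master_seed))
  cases <- cachedStage(cacheDir, "phantom", phantomHash, function() {
    generateCohort(config$cohort$n_benign, config$cohort$n_malignant,
                   phCfg, seed = config$master_seed)
  }, logPath)

  au <- config$augment
  augCfg <- augmentConfig(angleMin = au$angle_min, angleMax = au$angle_max,
                          angleStep = au$angle_step, tiltAxes = au$tilt_axes,
                          includeAxial = au$include_axial,
                          outSize = au$out_size)
  wg <- config$wgan
  wganCfg <- wganConfig(latentDim = wg$latent_dim, lr = wg$lr,
                        epochs = wg$epochs, clipValue = wg$clip_value,
                        nCritic = wg$n_critic, batchSize = wg$batch_size,
                        widths = wg$widths)
  pr <- config$pretrain
  preCfg <- pretrainConfig(epochs = pr$epochs, lr = pr$lr,
                           momentum = pr$momentum, batchSize = pr$batch_size,
                           preset = pr$preset)
  ft <- config$finetune
  ftCfg <- finetuneConfig(epochs = ft$epochs, lr = ft$lr,
                          momentum = ft$momentum, batchSize = ft$batch_size)
  ev <- config$evaluation

  evalHash <- configHash(list(upstream = phantomHash, voi = config$voi,
                              augment = au, wgan = wg, pretrain = pr,
                              finetune = ft, evaluation = ev))
  comparison <- cachedStage(cacheDir, "evaluation", evalHash, function() {
    compareStrategies(cases, strategies = ev$strategies, k = ev$k,
                      seed = config$master_seed,
                      voiResolution = config$voi$resolution_mm,
                      augCfg = augCfg, wganCfg = wganCfg, preCfg = preCfg,
                      ftCfg = ftCfg, nGenPerClass = ev$n_gen_per_class,
                      aggregate = ev$aggregate, testViews = ev$test_views)
  }, logPath)

  utils::write.csv(cohortManifest(cases), file.path(outDir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(comparison$table, file.path(outDir, "comparison.csv"),
                   row.names = FALSE)
  metrics <- lapply(seq_len(nrow(comparison$table)), function(i)
    as.list(comparison$table[i, ]))
  names(metrics) <- comparison$table$strategy
  jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  for (strat in names(comparison$roc))
    utils::write.csv(comparison$roc[[strat]]$points,
                     file.path(outDir, paste0("roc_", strat, ".csv")),
                     row.names = FALSE)
  manifest <- list(config = unclass(config),
                   hashes = list(phantom = phantomHash, evaluation = evalHash),
                   files = list(cohort = "cohort.csv",
                                comparison = "comparison.csv",
                                metrics = "metrics.json"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  structure(c(manifest, list(comparison = comparison, cases = cases)),
            class = "runManifest")
}

#' @export
print.runManifest <- function(x, ...) {
  cat("noduleGAN run (", x$config$preset, " preset) -> ", x$config$out_dir,
      "\n", sep = "")
  print(x$comparison$table, row.names = FALSE)
  invisible(x)
}
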