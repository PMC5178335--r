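## End-to-end orchestration: synthetic corpus (or user WAVs plus an
## annotation table) -> segmentation -> MFCC features with per-channel
## mean subtraction -> UBM from a disjoint background syllable pool ->
## per-task leave-one-out classification, balanced accuracy and
## permutation significance -> score-space projection -> report bundle.

#' RunConfig: full experiment configuration
#'
#' @slot spec a [SynthSpec-class] (synthetic mode), or NULL when
#'   `annotationPath` points at user data.
#' @slot annotationPath annotation table for pre-recorded audio ("" in
#'   synthetic mode).
#' @slot segConfig a [SegmenterConfig-class].
#' @slot fparams a [FrameParams-class].
#' @slot cconfig a [CepstralConfig-class].
#' @slot ubmK UBM component count (default 16).
#' @slot mapConfig a [MapConfig-class].
#' @slot tasks named list of [TaskSpec-class].
#' @slot backgroundSize background syllable pool size cap (the study used
#'   3900; capped at the available pool).
#' @slot nPerm permutations per task.
#' @slot seed global seed; every stage derives its own stream from it.
#' @slot outDir output directory.
#' @slot cacheDir feature-cache directory ("" disables caching).
#' @slot runControl run the non-voiced control for the context task.
#' @export
setClass("RunConfig",
  representation(spec = "ANY", annotationPath = "character",
                 segConfig = "SegmenterConfig", fparams = "FrameParams",
                 cconfig = "CepstralConfig", ubmK = "integer",
                 mapConfig = "MapConfig", tasks = "list",
                 backgroundSize = "integer", nPerm = "integer",
                 seed = "integer", outDir = "character",
                 cacheDir = "character", runControl = "logical"))

setValidity("RunConfig", function(object) {
  if (is.null(object@spec) && !nzchar(object@annotationPath))
    return("either a SynthSpec or an annotationPath is required")
  if (!is.null(object@spec) && !is(object@spec, "SynthSpec"))
    return("spec must be a SynthSpec or NULL")
  if (!all(vapply(object@tasks, is, TRUE, "TaskSpec")))
    return("tasks must be TaskSpec objects")
  if (object@ubmK < 1L) return("ubmK must be >= 1")
  TRUE
})

#' Default classification tasks
#'
#' The task set mirrors the study design: emitter and context with at
#' least 15 vocalizations per class, addressee sex with at least 20 and
#' with mating aggression excluded (those calls are addressed exclusively
#' to the male, so including them would conflate addressee with context),
#' and interaction outcome with at least 10 per class.
#'
#' @param matingContext label of the mating-aggression context to exclude
#'   from addressee-axis tasks.
#' @return named list of [TaskSpec-class].
#' @export
defaultTasks <- function(matingContext = "mating_aggr") {
  notMating <- function(a) a$context != matingContext
  list(
    emitter = taskSpec("emitter", minClassSize = 15L, name = "emitter"),
    context = taskSpec("context", minClassSize = 15L, name = "context"),
    addressee_sex = taskSpec("addressee_sex", populationFilter = notMating,
                             minClassSize = 20L, name = "addressee_sex"),
    outcome = taskSpec("outcome", minClassSize = 10L, name = "outcome"))
}

#' Create a run configuration
#'
#' @param spec a [SynthSpec-class] for synthetic mode (default demo
#'   corpus), or NULL with `annotationPath` set for user audio.
#' @param annotationPath annotation table path for user audio.
#' @param segConfig,fparams,cconfig,mapCfg stage configurations.
#' @param ubmK UBM components.
#' @param tasks named list of [TaskSpec-class].
#' @param backgroundSize background syllable pool cap.
#' @param nPerm permutations per task.
#' @param seed global seed.
#' @param outDir,cacheDir output and cache directories.
#' @param runControl run the non-voiced control.
#' @return a validated [RunConfig-class].
#' @export
runConfig <- function(spec = synthSpec(), annotationPath = "",
                      segConfig = segmenterConfig(),
                      fparams = frameParams(), cconfig = cepstralConfig(),
                      ubmK = 16L, mapCfg = mapConfig(),
                      tasks = defaultTasks(), backgroundSize = 3900L,
                      nPerm = 100L, seed = 1L,
                      outDir = tempfile("batvoc_out"), cacheDir = "",
                      runControl = TRUE) {
  new("RunConfig", spec = spec, annotationPath = annotationPath,
      segConfig = segConfig, fparams = fparams, cconfig = cconfig,
      ubmK = as.integer(ubmK), mapConfig = mapCfg, tasks = tasks,
      backgroundSize = as.integer(backgroundSize),
      nPerm = as.integer(nPerm), seed = as.integer(seed), outDir = outDir,
      cacheDir = cacheDir, runControl = runControl)
}

## deterministic config fingerprint (FNV-1a over the deparsed object,
## ignoring paths so cache keys survive directory relocation)
configHash <- function(config) {
  skip <- c("outDir", "cacheDir", "annotationPath")
  txt <- paste(vapply(setdiff(slotNames(config), skip), function(s)
    paste(deparse(slot(config, s)), collapse = ""), ""), collapse = ";")
  h <- 2166136261
  for (b in utf8ToInt(txt)) h <- mulmod32(xor32(h, b), 16777619)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## pooled, channel-mean-subtracted frames of a set of syllables
backgroundFrames <- function(ann, segments, fparams, cconfig) {
  frames <- list(); channels <- integer(0)
  for (i in seq_len(nrow(ann))) {
    segs <- segments[segments$voc_id == ann$voc_id[i], , drop = FALSE]
    if (!nrow(segs)) next
    w <- readWav(ann$wav_path[i])
    audio <- w$samples[, min(ann$channel[i], ncol(w$samples))]
    m <- featurizeVocalization(audio, w$sampleRate, segs, fparams, cconfig)
    if (is.null(m)) next
    frames[[length(frames) + 1L]] <- m
    channels <- c(channels, ann$channel[i])
  }
  if (!length(frames)) stop("background pool yielded no frames")
  for (ch in unique(channels)) {
    idx <- which(channels == ch)
    mu <- colMeans(do.call(rbind, frames[idx]))
    for (i in idx) frames[[i]] <- sweep(frames[[i]], 2L, mu)
  }
  do.call(rbind, frames)
}

#' Run a full experiment
#'
#' Executes every stage from the configuration: corpus generation (or
#' loading), voiced-segment detection, MFCC extraction with per-channel
#' mean subtraction, UBM training on a disjoint background syllable pool,
#' per-task leave-one-out classification with permutation tests, the
#' non-voiced control, and a score-space projection for the first task.
#' Writes per-task confusion matrices (raw and row-normalized), projection
#' coordinates and a JSON report into `outDir`. Results are reproducible
#' from configuration plus seed alone; with a `cacheDir` set, re-runs
#' reuse cached features keyed by the configuration hash.
#'
#' @param config a [RunConfig-class].
#' @return the report, invisibly (a named list; see the written
#'   `report.json`).
#' @export
runExperiment <- function(config) {
  validObject(config)
  hash <- configHash(config)
  if (!dir.exists(config@outDir)) dir.create(config@outDir, recursive = TRUE)
  seed <- config@seed

  ## --- corpus -------------------------------------------------------------
  if (!is.null(config@spec)) {
    spec <- config@spec
    spec@seed <- deriveSeed(seed, "data")
    dataset <- generateDataset(spec,
                               dir = file.path(config@outDir, "audio_main"))
    bgSpec <- spec
    bgSpec@seed <- deriveSeed(seed, "background")
    bgDataset <- generateDataset(bgSpec,
                                 dir = file.path(config@outDir, "audio_bg"))
    bgAnn <- annotations(bgDataset)
  } else {
    ann <- readAnnotations(config@annotationPath)
    bad <- which(is.na(ann$voc_id) | !file.exists(ann$wav_path))
    if (length(bad))
      stop("corrupt annotation row(s): ", paste(bad, collapse = ", "))
    ## background = held-out half of the corpus, never classified
    nbg <- floor(nrow(ann) / 3)
    bgIdx <- withSeed(deriveSeed(seed, "bgsplit"),
                      sample.int(nrow(ann), nbg))
    dataset <- ann[-bgIdx, , drop = FALSE]
    bgAnn <- ann[bgIdx, , drop = FALSE]
  }

  ## --- segmentation + background UBM --------------------------------------
  segments <- segmentDataset(dataset, config@segConfig)
  bgSegments <- segmentDataset(bgAnn, config@segConfig)
  nBg <- min(config@backgroundSize, nrow(bgSegments))
  bgPool <- sampleBackgroundSyllables(bgSegments, nBg,
                                      seed = deriveSeed(seed, "bgsample"))
  bgAnnDf <- if (is(bgAnn, "SynthDataset")) annotations(bgAnn) else bgAnn
  X <- backgroundFrames(bgAnnDf, bgPool, config@fparams, config@cconfig)
  ubm <- fitGmmEM(X, K = config@ubmK, seed = deriveSeed(seed, "ubm"))

  ## --- features (cached) ---------------------------------------------------
  fs <- NULL
  cachePath <- if (nzchar(config@cacheDir))
    file.path(config@cacheDir, hash) else ""
  if (nzchar(cachePath) && file.exists(file.path(cachePath, "manifest.tsv")))
    fs <- readFeatureCache(cachePath)
  if (is.null(fs)) {
    fs <- featurizeDataset(dataset, segments = segments,
                           segConfig = config@segConfig,
                           fparams = config@fparams,
                           cconfig = config@cconfig, cms = TRUE)
    if (nzchar(cachePath)) writeFeatureCache(fs, cachePath)
  }

  ## --- tasks ---------------------------------------------------------------
  results <- list()
  firstLoo <- NULL
  for (nm in names(config@tasks)) {
    res <- tryCatch(
      runTask(fs, config@tasks[[nm]], ubm, config@mapConfig,
              nPerm = config@nPerm, seed = deriveSeed(seed, "task", nm)),
      batvoc_task_abort = function(e)
        list(task = nm, status = "aborted", message = conditionMessage(e),
             report = e$report))
    if (is.null(res$status)) {
      res$status <- "ok"
      cm <- res$confusion
      utils::write.table(cm@counts,
        file.path(config@outDir, paste0("confusion_", nm, ".csv")),
        sep = ",", col.names = NA, quote = FALSE)
      utils::write.table(round(rowNormalized(cm), 6),
        file.path(config@outDir, paste0("confusion_", nm, "_rownorm.csv")),
        sep = ",", col.names = NA, quote = FALSE)
      if (is.null(firstLoo)) firstLoo <- res$loo
    }
    results[[nm]] <- res
  }

  ## --- non-voiced control --------------------------------------------------
  control <- NULL
  if (config@runControl && "context" %in% names(config@tasks)) {
    control <- nonvoicedControl(dataset, segments, config@tasks$context,
                                ubm, config@mapConfig,
                                nPerm = config@nPerm,
                                seed = deriveSeed(seed, "control"),
                                segConfig = config@segConfig,
                                fparams = config@fparams,
                                cconfig = config@cconfig)
  }

  ## --- projection ----------------------------------------------------------
  projection <- NULL
  if (!is.null(firstLoo) && nrow(scoreMatrix(firstLoo)) >
        ncol(scoreMatrix(firstLoo))) {
    projection <- ldaProject(firstLoo)
    writeProjection(projection, file.path(config@outDir, "projection.tsv"))
  }

  ## --- report --------------------------------------------------------------
  taskJson <- lapply(results, function(r) {
    if (!is.null(r$status) && r$status == "aborted")
      return(list(status = "aborted", message = r$message))
    list(status = "ok", classes = r$classes, classSizes = r$classSizes,
         ba = r$ba, chance = r$chance, p = r$permutation@pValue,
         nPerm = r$permutation@nPerm)
  })
  report <- list(configHash = hash, seed = seed,
                 nVocalizations = length(vocFeatures(fs)),
                 ubmComponents = config@ubmK, tasks = taskJson,
                 control = if (is.null(control)) NULL else
                   list(task = control$task, ba = control$ba,
                        chance = control$chance,
                        p = control$permutation@pValue))
  jsonlite::write_json(report, file.path(config@outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$results <- results
  report$control_result <- control
  report$projection <- projection
  report$ubm <- ubm
  invisible(report)
}
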