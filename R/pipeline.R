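# End-to-end pipeline driver and model checkpoint I/O.

paramsFlatten <- function(p) {
  if (is.list(p)) return(unlist(lapply(p, paramsFlatten), use.names = FALSE))
  as.numeric(p)
}

paramsUnflatten <- function(template, vec, pos = 1L) {
  if (is.list(template)) {
    out <- template
    for (k in seq_along(template)) {
      r <- paramsUnflatten(template[[k]], vec, pos)
      out[[k]] <- r$value
      pos <- r$pos
    }
    return(list(value = out, pos = pos))
  }
  n <- length(template)
  v <- vec[pos:(pos + n - 1L)]
  if (!is.null(dim(template))) dim(v) <- dim(template)
  list(value = v, pos = pos + n)
}

#' Save / load a trained ensemble
#'
#' Checkpoints are self-describing JSON archives carrying the variant
#' name, encoder and dense hyperparameters, per-model normalization
#' statistics and flattened weights. Loading refuses a checkpoint whose
#' stored specification does not match the requested variant.
#'
#' @param ensemble a `zindoEnsemble` from [trainEnsemble()].
#' @param path checkpoint file path.
#' @return `saveEnsemble` returns `path` invisibly; `loadEnsemble`
#'   returns the restored `zindoEnsemble`.
#' @export
saveEnsemble <- function(ensemble, path) {
  spec <- ensemble$spec
  payload <- list(
    format = "zindoml-ensemble-1",
    variant = spec@name,
    encoder = spec@encoder,
    dense = spec@dense,
    mordfLen = ensemble$models[[1]]$mordfLen,
    mfpLen = ensemble$models[[1]]$mfpLen,
    models = lapply(ensemble$models, function(m) {
      list(norm = m$norm,
           linear = m$linear,
           params = if (!is.null(m$params)) paramsFlatten(m$params),
           state = if (!is.null(m$state)) paramsFlatten(m$state))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname saveEnsemble
#' @param variant optional variant name that the checkpoint must match.
#' @export
loadEnsemble <- function(path, variant = NULL) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  if (!identical(payload$format, "zindoml-ensemble-1"))
    stop("not a zindoml ensemble checkpoint: ", path)
  if (!is.null(variant) &&
      gsub("\\s", "", variant) != gsub("\\s", "", payload$variant))
    stop("checkpoint variant '", payload$variant,
         "' does not match requested '", variant, "'")
  spec <- parseVariant(payload$variant,
                       dense = do.call(denseBlockSpec, payload$dense),
                       encoder = do.call(encoderSpec,
                                         payload$encoder[c("nodeChannels",
                                                           "hiddenDim",
                                                           "fingerprintDim",
                                                           "atomSteps",
                                                           "molSteps")]))
  models <- lapply(seq_along(payload$models), function(k) {
    stored <- payload$models[[k]]
    m <- assembleVariant(spec, mordfLen = payload$mordfLen,
                         mfpLen = payload$mfpLen, seed = k)
    if (!is.null(stored$params) && length(stored$params))
      m$params <- paramsUnflatten(m$params, as.numeric(stored$params))$value
    if (!is.null(m$state) && !is.null(stored$state) && length(stored$state))
      m$state <- paramsUnflatten(m$state, as.numeric(stored$state))$value
    if (!is.null(stored$norm)) {
      for (nm in names(stored$norm))
        if (!is.null(stored$norm[[nm]]))
          m$norm[[nm]] <- lapply(stored$norm[[nm]], as.numeric)
    }
    if (!is.null(stored$linear) && length(stored$linear))
      m$linear <- lapply(stored$linear, as.numeric)
    m
  })
  structure(list(models = models, histories = NULL, foldSplit = NULL,
                 spec = spec), class = "zindoEnsemble")
}

.defaultRunConfig <- function() {
  list(stages = c("synth", "featurize", "train", "evaluate"),
       outDir = "zindoml-run",
       seed = 1L,
       force = FALSE,
       variant = "Dense(MPNN(DA, EA), E_ZINDO)",
       synth = list(n = 500L, rule = "heteroaromatic", amplitude = 0.4,
                    noiseSd = 0.05, m = 1.08, c = 0.52),
       split = list(testFraction = 0.25),
       encoder = list(hiddenDim = 64L, fingerprintDim = 64L,
                      atomSteps = 2L, molSteps = 2L),
       dense = list(layerSizes = c(64L, 32L), dropout = 0.2,
                    batchNorm = TRUE),
       train = list(k = 2L, lr = 1e-3, batchSize = 32L, maxEpochs = 30L,
                    patience = 10L))
}

#' Run the end-to-end pipeline
#'
#' Executes the requested stages (`synth`, `featurize`, `train`,
#' `evaluate`; or a dataset-reading variant via `config$data`) against
#' one output directory. The configuration is validated (including the
#' variant name) before any compute; every run writes a manifest with
#' the configuration hash and seeds, and a state file listing completed
#' stages so interrupted runs can be resumed. A rerun against an output
#' directory holding a manifest with the same hash is refused unless
#' `force` is set.
#'
#' @param config nested list (see the package vignette) or the path to a
#'   YAML file with the same structure; omitted entries take defaults.
#' @return invisibly, a list with the paths of the written artifacts and
#'   the evaluation report (when the evaluate stage ran).
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.defaultRunConfig(), config)
  # validation first: fail before any compute
  vspec <- parseVariant(cfg$variant,
                        dense = do.call(denseBlockSpec, cfg$dense),
                        encoder = do.call(encoderSpec, cfg$encoder))
  badStages <- setdiff(cfg$stages, c("synth", "featurize", "train",
                                     "evaluate"))
  if (length(badStages)) stop("unknown stage(s): ",
                              paste(badStages, collapse = ", "))
  cfgHash <- objectHash(cfg[setdiff(names(cfg), "force")])
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  manifestPath <- file.path(cfg$outDir, "manifest.json")
  statePath <- file.path(cfg$outDir, "state.json")
  if (file.exists(manifestPath) && !isTRUE(cfg$force)) {
    prev <- jsonlite::read_json(manifestPath)
    if (identical(prev$config_hash, cfgHash))
      stop("output directory already holds a completed run with this ",
           "configuration (hash ", cfgHash, "); use force = TRUE to rerun")
  }
  jsonlite::write_json(list(config_hash = cfgHash, seed = cfg$seed,
                            variant = vspec@name,
                            package_version =
                              as.character(utils::packageVersion("zindoml")),
                            created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                            config = cfg),
                       manifestPath, auto_unbox = TRUE, digits = NA)
  done <- character(0)
  markDone <- function(stage) {
    done <<- c(done, stage)
    jsonlite::write_json(list(completed = done), statePath,
                         auto_unbox = FALSE)
  }
  out <- list(manifest = manifestPath)

  ds <- NULL
  if ("synth" %in% cfg$stages) {
    spec <- syntheticSpec(nMolecules = cfg$synth$n, seed = cfg$seed,
                          m = cfg$synth$m, c = cfg$synth$c,
                          noiseSd = cfg$synth$noiseSd,
                          rule = cfg$synth$rule,
                          amplitude = cfg$synth$amplitude)
    ds <- generateDataset(spec)
    writeDataset(ds, file.path(cfg$outDir, "dataset"))
    out$dataset <- file.path(cfg$outDir, "dataset")
    markDone("synth")
  } else if (!is.null(cfg$data)) {
    ds <- readDataset(cfg$data$molecules, cfg$data$electronic,
                      cfg$data$targets)
  }
  if (is.null(ds)) stop("no dataset: enable the synth stage or set config$data")

  feats <- NULL
  if (any(c("featurize", "train", "evaluate") %in% cfg$stages)) {
    feats <- featurizeDataset(ds, withMordf = vspec@useMoRdf,
                              withMfp = vspec@useMfp)
    markDone("featurize")
  }

  ids <- datasetIds(ds)
  nTest <- max(1L, round(length(ids) * cfg$split$testFraction))
  testIds <- withRNG(cfg$seed, sample(ids, nTest))
  trainIds <- setdiff(ids, testIds)

  ensemble <- NULL
  if ("train" %in% cfg$stages) {
    tc <- trainConfig(k = cfg$train$k, lr = cfg$train$lr,
                      batchSize = cfg$train$batchSize,
                      maxEpochs = cfg$train$maxEpochs,
                      patience = cfg$train$patience,
                      baseSeed = cfg$seed)
    ensemble <- trainEnsemble(vspec, feats, trainIds, tc)
    ckpt <- file.path(cfg$outDir, "ensemble.json")
    saveEnsemble(ensemble, ckpt)
    out$checkpoint <- ckpt
    for (f in seq_along(ensemble$histories))
      utils::write.csv(ensemble$histories[[f]],
                       file.path(cfg$outDir,
                                 sprintf("history_fold%02d.csv", f)),
                       row.names = FALSE)
    markDone("train")
  }

  if ("evaluate" %in% cfg$stages) {
    if (is.null(ensemble)) stop("evaluate stage requires a trained ensemble")
    pred <- ensemblePredict(ensemble, feats, testIds)
    truth <- vapply(feats[testIds], `[[`, numeric(1), "eHigh")
    report <- regressionMetrics(pred$e_pred, truth)
    predPath <- file.path(cfg$outDir, "predictions.csv")
    utils::write.csv(cbind(pred, e_true = unname(truth)), predPath,
                     row.names = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(cfg$outDir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
    out$predictions <- predPath
    out$evaluation <- report
    markDone("evaluate")
  }
  invisible(out)
}
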