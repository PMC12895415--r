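# Model variants: the "component(descriptor)" naming scheme, the linear
# baseline, and assembly of encoder/dense models over any combination of
# the neural fingerprint, the ZINDO energy (with its residual
# connection), the MO-RDF and the Morgan fingerprint.

#' Ordinary least-squares baseline between low- and high-level energies
#'
#' Fits `eHigh = m * eLow + c` by OLS and reports the Pearson
#' correlation of the fit inputs. This is the reference the learned
#' corrections are compared against.
#'
#' @param eLow,eHigh numeric vectors (eV).
#' @return list with `m`, `c`, `r`.
#' @export
linearFit <- function(eLow, eHigh) {
  if (length(eLow) != length(eHigh) || length(eLow) < 2L)
    stop("linearFit needs two equal-length vectors with n >= 2")
  if (stats::sd(eLow) == 0) stop("linearFit: eLow has zero variance")
  fit <- stats::lm.fit(cbind(1, eLow), eHigh)
  list(m = unname(fit$coefficients[2L]), c = unname(fit$coefficients[1L]),
       r = stats::cor(eLow, eHigh))
}

#' @rdname linearFit
#' @param baseline output of [linearFit()] (or any list with `m`, `c`).
#' @export
linearPredict <- function(baseline, eLow) baseline$m * eLow + baseline$c

#' Residual (delta-learning) prediction head
#'
#' The network output is interpreted as the learned correction
#' `deltaPred`; the final prediction adds back the low-level energy:
#' `ePred = mlOut + eLow`. With a zero network the prediction reduces
#' exactly to the low-level input.
#'
#' @param mlOut network output (eV-scale correction).
#' @param eLow low-level S1 energy (eV).
#' @return predicted high-level energy (eV).
#' @export
residualPredict <- function(mlOut, eLow) {
  if (!all(is.finite(mlOut)) || !all(is.finite(eLow)))
    stop("residualPredict: inputs must be finite")
  mlOut + eLow
}

#' Parse a model-variant name
#'
#' Accepts the canonical `"component(descriptor)"` strings:
#' `"Linear(E_ZINDO)"`, `"MPNN(DA)"`, `"MPNN(DA, EA)"` and
#' `"Dense(...)"` with arguments drawn from `MPNN(DA)`, `MPNN(DA, EA)`,
#' `E_ZINDO`, `MO-RDF`, `MFP`. Names round-trip through
#' [variantName()].
#'
#' @param name variant name string.
#' @param dense a [denseBlockSpec()] for the final embedding block.
#' @param encoder an [encoderSpec()]; its `nodeChannels` is forced to
#'   match the DA/EA mode.
#' @return a [VariantSpec-class].
#' @export
parseVariant <- function(name, dense = denseBlockSpec(),
                         encoder = encoderSpec()) {
  raw <- gsub("\\s+", "", name)
  mk <- function(useEncoder = FALSE, ea = FALSE, useEZindo = FALSE,
                 useMoRdf = FALSE, useMfp = FALSE, linearOnly = FALSE) {
    encoder$nodeChannels <- if (ea) 45L else 41L
    sp <- new("VariantSpec", name = "", useEncoder = useEncoder, ea = ea,
              useEZindo = useEZindo, useMoRdf = useMoRdf, useMfp = useMfp,
              linearOnly = linearOnly, dense = unclass(dense),
              encoder = unclass(encoder))
    sp@name <- variantName(sp)
    validObject(sp)
    sp
  }
  if (raw == "Linear(E_ZINDO)")
    return(mk(useEZindo = TRUE, linearOnly = TRUE))
  if (raw == "MPNN(DA)") return(mk(useEncoder = TRUE))
  if (raw == "MPNN(DA,EA)") return(mk(useEncoder = TRUE, ea = TRUE))
  m <- regmatches(raw, regexec("^Dense\\((.*)\\)$", raw))[[1]]
  if (length(m) == 2L) {
    args <- m[2L]
    useEncoder <- ea <- FALSE
    if (startsWith(args, "MPNN(DA,EA)")) {
      useEncoder <- ea <- TRUE
      args <- sub("^MPNN\\(DA,EA\\),?", "", args)
    } else if (startsWith(args, "MPNN(DA)")) {
      useEncoder <- TRUE
      args <- sub("^MPNN\\(DA\\),?", "", args)
    }
    parts <- setdiff(strsplit(args, ",", fixed = TRUE)[[1]], "")
    known <- c("E_ZINDO", "MO-RDF", "MFP")
    if (length(setdiff(parts, known)))
      stop("unknown variant component(s): ",
           paste(setdiff(parts, known), collapse = ", "))
    return(mk(useEncoder = useEncoder, ea = ea,
              useEZindo = "E_ZINDO" %in% parts,
              useMoRdf = "MO-RDF" %in% parts,
              useMfp = "MFP" %in% parts))
  }
  stop("cannot parse variant name: ", name)
}

#' @rdname parseVariant
#' @param spec a [VariantSpec-class].
#' @export
variantName <- function(spec) {
  if (spec@linearOnly) return("Linear(E_ZINDO)")
  mp <- if (spec@useEncoder)
    paste0("MPNN(DA", if (spec@ea) ", EA" else "", ")") else NULL
  extra <- c(if (spec@useEZindo) "E_ZINDO",
             if (spec@useMoRdf) "MO-RDF",
             if (spec@useMfp) "MFP")
  if (spec@useEncoder && !length(extra)) return(mp)
  paste0("Dense(", paste(c(mp, extra), collapse = ", "), ")")
}

setMethod("show", "VariantSpec", function(object) {
  cat("VariantSpec:", object@name, "\n")
})

# Width of the concatenated dense input of a variant.
variantInputWidth <- function(spec, mordfLen = 726L, mfpLen = 2048L) {
  (if (spec@useEncoder) spec@encoder$fingerprintDim else 0L) +
    (if (spec@useEZindo) 1L else 0L) +
    (if (spec@useMoRdf) mordfLen else 0L) +
    (if (spec@useMfp) mfpLen else 0L)
}

#' Assemble a model from a variant specification
#'
#' Instantiates the parameters of the requested variant: the
#' message-passing encoder branch (when enabled), the final dense
#' embedding block over the concatenation of the enabled inputs (neural
#' fingerprint, z-scored ZINDO energy, MO-RDF, Morgan fingerprint) and a
#' scalar output head. When the ZINDO energy is enabled it is also
#' routed around the network through the residual connection, so the
#' network learns the correction only. For `"Linear(E_ZINDO)"` the model
#' is the closed-form baseline and carries no network parameters.
#'
#' @param spec a [VariantSpec-class] or a variant name string.
#' @param mordfLen MO-RDF vector length (default 726).
#' @param mfpLen Morgan fingerprint length (default 2048).
#' @param seed initialization seed.
#' @return a `zindoModel` list (spec, params, state, normalization
#'   placeholders).
#' @export
assembleVariant <- function(spec, mordfLen = 726L, mfpLen = 2048L,
                            seed = 1L) {
  if (is.character(spec)) spec <- parseVariant(spec)
  validObject(spec)
  model <- list(spec = spec, mordfLen = as.integer(mordfLen),
                mfpLen = as.integer(mfpLen),
                linear = NULL, params = NULL, state = NULL,
                norm = list(ea = NULL, ezindo = NULL, mordf = NULL))
  if (spec@linearOnly) {
    class(model) <- "zindoModel"
    return(model)
  }
  withRNG(seed, {
    params <- list()
    if (spec@useEncoder)
      params$enc <- encoderInit(structure(spec@encoder,
                                          class = "EncoderSpec"))
    inW <- variantInputWidth(spec, mordfLen, mfpLen)
    useDense <- .variantHasDense(spec)
    state <- NULL
    if (useDense) {
      db <- denseBlockInit(inW, spec@dense)
      params$dense <- db$params
      state <- db$state
      params$head <- .linInit(utils::tail(spec@dense$layerSizes, 1L), 1L)
    } else {
      params$head <- .linInit(inW, 1L)
    }
    model$params <- params
    model$state <- state
    class(model) <- "zindoModel"
    model
  })
}

# Stand-alone MPNN variants map the fingerprint straight through the
# scalar head; everything else goes through the dense block.
.variantHasDense <- function(spec)
  !(spec@useEncoder && !spec@useEZindo && !spec@useMoRdf && !spec@useMfp)

# --- batched forward/backward ----------------------------------------
# batch: list(graph (or NULL), eLow, mordf, mfp, y)
modelForward <- function(model, batch, train = FALSE) {
  spec <- model$spec
  if (spec@linearOnly) {
    if (is.null(model$linear)) stop("linear baseline not fitted")
    return(list(pred = linearPredict(model$linear, batch$eLow)))
  }
  parts <- list()
  caches <- list()
  if (spec@useEncoder) {
    ef <- encoderForward(model$params$enc,
                         structure(spec@encoder, class = "EncoderSpec"),
                         batch$graph)
    parts$fp <- ef$out
    caches$enc <- ef$cache
  }
  if (spec@useEZindo)
    parts$ez <- matrix(.zapply(batch$eLow, model$norm$ezindo), ncol = 1L)
  if (spec@useMoRdf)
    parts$mordf <- .zapplyMat(batch$mordf, model$norm$mordf)
  if (spec@useMfp) parts$mfp <- batch$mfp
  X <- do.call(cbind, unname(parts))
  caches$widths <- vapply(parts, ncol, integer(1))
  if (.variantHasDense(spec)) {
    df <- denseBlockForward(model$params$dense, model$state, X, spec@dense,
                            train = train)
    caches$dense <- df$caches
    caches$state <- df$state
    hf <- .linFwd(model$params$head, df$out)
  } else {
    hf <- .linFwd(model$params$head, X)
  }
  caches$head <- hf
  mlOut <- as.vector(hf$out)
  pred <- if (spec@useEZindo) residualPredict(mlOut, batch$eLow) else mlOut
  list(pred = pred, mlOut = mlOut, caches = caches)
}

modelBackward <- function(model, batch, fw, dPred) {
  spec <- model$spec
  grads <- paramsZero(model$params)
  dHead <- matrix(dPred, ncol = 1L)
  hb <- .linBwd(model$params$head, fw$caches$head, dHead)
  grads$head$W <- hb$grads$W
  grads$head$b <- hb$grads$db
  dX <- hb$dX
  if (.variantHasDense(spec)) {
    db <- denseBlockBackward(model$params$dense, fw$caches$dense, dX,
                             spec@dense)
    grads$dense <- db$grads
    dX <- db$dX
  }
  if (spec@useEncoder) {
    wfp <- fw$caches$widths[["fp"]]
    eb <- encoderBackward(model$params$enc,
                          structure(spec@encoder, class = "EncoderSpec"),
                          batch$graph, fw$caches$enc,
                          dX[, seq_len(wfp), drop = FALSE])
    grads$enc <- eb$grads
  }
  grads
}

.zapply <- function(x, st) if (is.null(st)) x else (x - st$mean) / st$sd
.zapplyMat <- function(x, st) if (is.null(st)) x else applyColStats(x, st)

#' Precompute per-molecule model inputs
#'
#' Builds, once per molecule, the node features (DA part and raw EA
#' columns kept separate so EA standardization can be fitted per
#' training fold), directed edges, the MO-RDF vector, and optionally the
#' Morgan fingerprint.
#'
#' @param dataset a [ZindoDataset-class].
#' @param grid a [MoRdfGrid-class] for the MO-RDF branch.
#' @param withMordf,withMfp compute the respective descriptor.
#' @return named list of per-molecule feature lists (class
#'   `zindoFeatures`).
#' @export
featurizeDataset <- function(dataset, grid = mordfGrid(),
                             withMordf = TRUE, withMfp = FALSE) {
  ids <- datasetIds(dataset)
  tgt <- targetRecords(dataset)
  out <- lapply(ids, function(id) {
    mol <- dataset@molecules[[id]]
    el <- dataset@electronic[[id]]
    if (is.null(el)) stop("no electronic record for ", id)
    f <- list(id = id,
              node = buildNodeFeatures(mol, mode = "DA"),
              ea = cbind(el$mulliken, el$potential, el$n_elec, el$n_hole),
              edges = .directedEdges(mol),
              eLow = el$e_s1_low,
              fLow = el$f_low)
    if (withMordf) f$mordf <- moRdf(mol, el$w_homo, grid)
    if (withMfp) f$mfp <- morganFingerprint(mol)
    k <- match(id, tgt$molecule_id)
    f$eHigh <- if (!is.na(k)) tgt$e_s1_high[k] else NA_real_
    f$fHigh <- if (!is.na(k)) tgt$f_high[k] else NA_real_
    f
  })
  names(out) <- ids
  class(out) <- "zindoFeatures"
  out
}

# Assemble a training batch for `model` from precomputed features.
makeBatch <- function(feats, ids, model, target = c("energy", "oscillator")) {
  target <- match.arg(target)
  spec <- model$spec
  sel <- feats[ids]
  batch <- list(
    eLow = vapply(sel, function(f)
      if (target == "energy") f$eLow else f$fLow, numeric(1)),
    y = vapply(sel, function(f)
      if (target == "energy") f$eHigh else f$fHigh, numeric(1)))
  if (!spec@linearOnly && spec@useEncoder) {
    eaStats <- model$norm$ea
    nodes <- lapply(sel, function(f) {
      if (spec@ea) {
        ea <- if (is.null(eaStats)) f$ea else applyColStats(f$ea, eaStats)
        cbind(f$node, ea)
      } else f$node
    })
    batch$graph <- .assembleGraph(Map(function(n, f)
      list(node = n, edges = f$edges), nodes, sel))
  }
  if (!spec@linearOnly && spec@useMoRdf)
    batch$mordf <- do.call(rbind, lapply(sel, `[[`, "mordf"))
  if (!spec@linearOnly && spec@useMfp)
    batch$mfp <- do.call(rbind, lapply(sel, `[[`, "mfp"))
  batch
}

# Fit the normalization statistics of a model on the training portion.
fitModelNorm <- function(model, feats, trainIds,
                         target = c("energy", "oscillator")) {
  target <- match.arg(target)
  spec <- model$spec
  sel <- feats[trainIds]
  if (!spec@linearOnly && spec@useEncoder && spec@ea)
    model$norm$ea <- colStats(do.call(rbind, lapply(sel, `[[`, "ea")))
  if (!spec@linearOnly && spec@useEZindo) {
    e <- vapply(sel, function(f)
      if (target == "energy") f$eLow else f$fLow, numeric(1))
    model$norm$ezindo <- list(mean = mean(e), sd = max(stats::sd(e), 1e-8))
  }
  if (!spec@linearOnly && spec@useMoRdf)
    model$norm$mordf <- colStats(do.call(rbind, lapply(sel, `[[`, "mordf")))
  model
}

#' Predict with a fitted model
#'
#' Deterministic evaluation-mode forward pass over precomputed features.
#'
#' @param model a `zindoModel`.
#' @param feats a `zindoFeatures` list from [featurizeDataset()].
#' @param ids molecule ids to predict (default all).
#' @param target `"energy"` or `"oscillator"`.
#' @return named numeric vector of predictions.
#' @export
modelPredict <- function(model, feats, ids = names(feats),
                         target = "energy") {
  preds <- numeric(0)
  # bounded batches keep memory flat for wide inputs
  chunk <- split(ids, ceiling(seq_along(ids) / 256L))
  for (ch in chunk) {
    batch <- makeBatch(feats, ch, model, target = target)
    fw <- modelForward(model, batch, train = FALSE)
    preds <- c(preds, stats::setNames(fw$pred, ch))
  }
  preds
}
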