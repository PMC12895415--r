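# k-fold cross-validation training and ensemble prediction.

#' Training configuration constructor
#'
#' Defaults follow the published recipe: Adam, learning rate 1e-4,
#' batch size 32, up to 500 epochs with a triangular cyclical
#' learning-rate schedule (bounds lr/10 to lr, period 20 epochs) and
#' early stopping on validation MAE (patience 50).
#'
#' @param k folds (default 10).
#' @param lr base learning rate.
#' @param batchSize minibatch size.
#' @param maxEpochs epoch cap.
#' @param cyclicalLr enable the cyclical schedule.
#' @param cyclePeriod schedule period in epochs.
#' @param earlyStopping enable early stopping.
#' @param patience early-stopping patience in epochs.
#' @param baseSeed base seed; fold f trains under baseSeed + f.
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(k = 10L, lr = 1e-4, batchSize = 32L,
                        maxEpochs = 500L, cyclicalLr = TRUE,
                        cyclePeriod = 20L, earlyStopping = TRUE,
                        patience = 50L, baseSeed = 1L) {
  new("TrainConfig", k = as.numeric(k), lr = lr,
      batchSize = as.numeric(batchSize), maxEpochs = as.numeric(maxEpochs),
      cyclicalLr = isTRUE(cyclicalLr), cyclePeriod = as.numeric(cyclePeriod),
      earlyStopping = isTRUE(earlyStopping), patience = as.numeric(patience),
      baseSeed = as.numeric(baseSeed))
}

#' Shuffled k-fold partition
#'
#' Deterministically (per seed) shuffles the ids and partitions them
#' into k folds whose sizes differ by at most one.
#'
#' @param ids id vector.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return list with `foldAssignments` (named integer vector in 1..k)
#'   and `folds` (list of id vectors).
#' @export
kfoldSplit <- function(ids, k, seed = 1L) {
  n <- length(ids)
  if (k > n) stop("k = ", k, " exceeds the ", n, " available ids")
  withRNG(seed, {
    perm <- sample(ids)
    assign <- rep(seq_len(k), length.out = n)
    folds <- unname(split(perm, assign))
    fa <- stats::setNames(assign[match(ids, perm)], ids)
    list(foldAssignments = fa, folds = folds)
  })
}

#' Train one fold model
#'
#' Minimizes the mean squared error of the (residual) prediction with
#' Adam over minibatches, under the cyclical learning-rate schedule,
#' stopping early when the validation MAE has not improved for
#' `patience` epochs and returning the best-validation checkpoint. For
#' the linear baseline the fit is closed form.
#'
#' @param model an assembled `zindoModel` (see [assembleVariant()]).
#' @param feats precomputed features ([featurizeDataset()]).
#' @param trainIds,valIds id partitions (validation ids are never used
#'   in gradient updates).
#' @param config a [TrainConfig-class]; the fold seed should already be
#'   folded into `baseSeed`.
#' @param target `"energy"` or `"oscillator"`.
#' @return list with the trained `model` and a `history` data.frame
#'   (epoch, train_loss, val_mae, lr).
#' @export
trainFold <- function(model, feats, trainIds, valIds, config = trainConfig(),
                      target = "energy") {
  validObject(config)
  if (!length(trainIds) || !length(valIds))
    stop("trainFold: empty train or validation set")
  if (length(intersect(trainIds, valIds)))
    stop("trainFold: train and validation ids overlap")
  spec <- model$spec
  y <- vapply(feats[trainIds], function(f)
    if (target == "energy") f$eHigh else f$fHigh, numeric(1))
  eLow <- vapply(feats[trainIds], function(f)
    if (target == "energy") f$eLow else f$fLow, numeric(1))
  if (spec@linearOnly) {
    model$linear <- linearFit(eLow, y)
    valB <- makeBatch(feats, valIds, model, target)
    valMae <- mean(abs(modelForward(model, valB)$pred - valB$y))
    return(list(model = model,
                history = data.frame(epoch = 1L, train_loss = NA_real_,
                                     val_mae = valMae, lr = NA_real_)))
  }
  model <- fitModelNorm(model, feats, trainIds, target)
  withRNG(config@baseSeed, {
    opt <- adamInit(model$params)
    best <- list(mae = Inf, params = model$params, state = model$state)
    history <- NULL
    sinceBest <- 0L
    for (epoch in seq_len(config@maxEpochs)) {
      lrE <- cyclicalLr(epoch, config@lr, config@cyclePeriod,
                        config@cyclicalLr)
      ord <- sample(trainIds)
      nb <- ceiling(length(ord) / config@batchSize)
      lossSum <- 0
      for (b in seq_len(nb)) {
        ids <- ord[((b - 1L) * config@batchSize + 1L):
                     min(b * config@batchSize, length(ord))]
        batch <- makeBatch(feats, ids, model, target)
        fw <- modelForward(model, batch, train = TRUE)
        if (!is.null(fw$caches$state)) model$state <- fw$caches$state
        resid <- fw$pred - batch$y
        loss <- mean(resid^2)
        if (!is.finite(loss))
          stop("training diverged (non-finite loss) at epoch ", epoch)
        lossSum <- lossSum + loss * length(ids)
        grads <- modelBackward(model, batch, fw,
                               dPred = 2 * resid / length(ids))
        st <- adamStep(model$params, grads, opt, lrE)
        model$params <- st$params
        opt <- st$opt
      }
      valB <- makeBatch(feats, valIds, model, target)
      valMae <- mean(abs(modelForward(model, valB, train = FALSE)$pred -
                           valB$y))
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = lossSum / length(ord),
                                  val_mae = valMae, lr = lrE))
      if (valMae < best$mae - 1e-12) {
        best <- list(mae = valMae, params = model$params,
                     state = model$state)
        sinceBest <- 0L
      } else sinceBest <- sinceBest + 1L
      if (config@earlyStopping && sinceBest >= config@patience) break
    }
    model$params <- best$params
    model$state <- best$state
    list(model = model, history = history)
  })
}

#' Train a k-fold ensemble
#'
#' Splits the training ids into k folds, trains one model per fold
#' (validating on the held-out fold, seeding fold f with
#' `baseSeed + f`), and returns the fitted ensemble.
#'
#' @param variant a [VariantSpec-class] or variant name.
#' @param feats precomputed features.
#' @param trainIds training ids.
#' @param config a [TrainConfig-class].
#' @param target `"energy"` or `"oscillator"`.
#' @param mordfLen,mfpLen descriptor widths (for parameter shapes).
#' @return list of class `zindoEnsemble`: `models`, `histories`,
#'   `foldSplit`, `spec`.
#' @export
trainEnsemble <- function(variant, feats, trainIds, config = trainConfig(),
                          target = "energy", mordfLen = 726L,
                          mfpLen = 2048L) {
  if (is.character(variant)) variant <- parseVariant(variant)
  ks <- kfoldSplit(trainIds, config@k, seed = config@baseSeed)
  models <- vector("list", length(ks$folds))
  histories <- vector("list", length(ks$folds))
  for (f in seq_along(ks$folds)) {
    valIds <- ks$folds[[f]]
    trIds <- setdiff(trainIds, valIds)
    foldCfg <- config
    foldCfg@baseSeed <- config@baseSeed + f
    model <- assembleVariant(variant, mordfLen = mordfLen, mfpLen = mfpLen,
                             seed = config@baseSeed + f)
    res <- trainFold(model, feats, trIds, valIds, foldCfg, target)
    models[[f]] <- res$model
    histories[[f]] <- res$history
  }
  structure(list(models = models, histories = histories, foldSplit = ks,
                 spec = variant), class = "zindoEnsemble")
}

#' Average fold-model predictions
#'
#' Applies every ensemble member to the molecules and averages the
#' predictions, retaining the per-fold values.
#'
#' @param ensemble a `zindoEnsemble` (or plain list of `zindoModel`s).
#' @param feats precomputed features.
#' @param ids ids to predict (default all).
#' @param target `"energy"` or `"oscillator"`.
#' @return data.frame with `molecule_id`, `e_pred`, `delta_pred` and a
#'   `per_fold` matrix attribute (folds in columns).
#' @export
ensemblePredict <- function(ensemble, feats, ids = names(feats),
                            target = "energy") {
  models <- if (inherits(ensemble, "zindoEnsemble")) ensemble$models
            else ensemble
  specs <- vapply(models, function(m) m$spec@name, character(1))
  if (length(unique(specs)) != 1L)
    stop("ensemble members disagree on the variant: ",
         paste(unique(specs), collapse = " vs "))
  perFold <- vapply(models, function(m)
    modelPredict(m, feats, ids, target), numeric(length(ids)))
  perFold <- matrix(perFold, nrow = length(ids),
                    dimnames = list(ids, NULL))
  ePred <- rowMeans(perFold)
  eLow <- vapply(feats[ids], function(f)
    if (target == "energy") f$eLow else f$fLow, numeric(1))
  out <- data.frame(molecule_id = ids, e_pred = unname(ePred),
                    delta_pred = unname(ePred - eLow))
  attr(out, "per_fold") <- perFold
  out
}
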