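test_that("k-fold split partitions ids into near-equal shuffled folds", {
  ids <- sprintf("m%03d", 1:100)
  ks <- kfoldSplit(ids, 10, seed = 5)
  expect_identical(sort(unlist(ks$folds)), sort(ids))
  expect_true(all(lengths(ks$folds) == 10L))
  # fold sizes for n = 7602, k = 10: two folds of 761, eight of 760
  big <- kfoldSplit(as.character(1:7602), 10, seed = 5)
  expect_identical(sort(as.integer(table(lengths(big$folds)))), c(2L, 8L))
  expect_identical(sort(unname(lengths(big$folds))),
                   sort(c(761L, 761L, rep(760L, 8))))
  # deterministic per seed
  expect_identical(kfoldSplit(ids, 10, seed = 5), ks)
  expect_false(identical(kfoldSplit(ids, 10, seed = 6)$folds, ks$folds))
  expect_error(kfoldSplit(ids[1:5], 10), "exceeds")
  # every id gets exactly one fold
  expect_identical(sort(names(ks$foldAssignments)), sort(ids))
  expect_true(all(ks$foldAssignments %in% 1:10))
})

test_that("training a zero-deviation dataset converges to the residual identity", {
  ds <- generateDataset(syntheticSpec(nMolecules = 280, seed = 51,
                                      m = 1, c = 0, rule = "none",
                                      noiseSd = 0))
  feats <- featurizeDataset(ds, withMordf = FALSE)
  ids <- names(feats)
  sp <- parseVariant("Dense(MPNN(DA, EA), E_ZINDO)",
                     dense = denseBlockSpec(c(16L, 8L), dropout = 0),
                     encoder = encoderSpec(nodeChannels = 45L,
                                           hiddenDim = 16L,
                                           fingerprintDim = 16L))
  model <- assembleVariant(sp, seed = 6)
  res <- trainFold(model, feats, ids[1:240], ids[241:280],
                   trainConfig(k = 2, lr = 3e-3, batchSize = 32,
                               maxEpochs = 50, patience = 50,
                               baseSeed = 6))
  expect_lt(min(res$history$val_mae), 0.01)
  expect_lte(nrow(res$history), 50L)
})

test_that("early stopping halts after the patience window", {
  ds <- generateDataset(syntheticSpec(nMolecules = 60, seed = 52))
  feats <- featurizeDataset(ds, withMordf = FALSE)
  ids <- names(feats)
  sp <- parseVariant("Dense(MPNN(DA, EA), E_ZINDO)",
                     dense = denseBlockSpec(c(8L, 4L), dropout = 0,
                                            batchNorm = FALSE),
                     encoder = tinyEncoderSpec(45L))
  model <- assembleVariant(sp, seed = 7)
  # a vanishing learning rate freezes the model (no batch statistics or
  # dropout either): the validation MAE cannot improve after the first
  # epoch, so training stops at patience + 1 epochs, not at the cap
  res <- trainFold(model, feats, ids[1:45], ids[46:60],
                   trainConfig(k = 2, lr = 1e-15, maxEpochs = 40,
                               patience = 3, baseSeed = 7))
  expect_identical(nrow(res$history), 4L)
})

test_that("fixed seeds reproduce training histories exactly", {
  ds <- generateDataset(syntheticSpec(nMolecules = 60, seed = 53))
  feats <- featurizeDataset(ds, withMordf = FALSE)
  ids <- names(feats)
  sp <- parseVariant("Dense(MPNN(DA, EA), E_ZINDO)",
                     dense = tinyDenseSpec(),
                     encoder = tinyEncoderSpec(45L))
  cfg <- trainConfig(k = 2, lr = 1e-3, maxEpochs = 4, patience = 10,
                     baseSeed = 11)
  r1 <- trainFold(assembleVariant(sp, seed = 11), feats, ids[1:45],
                  ids[46:60], cfg)
  r2 <- trainFold(assembleVariant(sp, seed = 11), feats, ids[1:45],
                  ids[46:60], cfg)
  expect_identical(r1$history, r2$history)
})

test_that("train/validation overlap is rejected", {
  ds <- generateDataset(syntheticSpec(nMolecules = 20, seed = 54))
  feats <- featurizeDataset(ds, withMordf = FALSE)
  ids <- names(feats)
  model <- assembleVariant(parseVariant("Dense(MPNN(DA, EA), E_ZINDO)",
                                        dense = tinyDenseSpec(),
                                        encoder = tinyEncoderSpec(45L)),
                           seed = 1)
  expect_error(trainFold(model, feats, ids[1:10], ids[10:15],
                         trainConfig(k = 2)),
               "overlap")
})

test_that("ensemble prediction is the exact fold mean", {
  ds <- generateDataset(syntheticSpec(nMolecules = 15, seed = 55))
  feats <- featurizeDataset(ds, withMordf = FALSE)
  mkLinear <- function(m, c) {
    mod <- assembleVariant("Linear(E_ZINDO)")
    mod$linear <- list(m = m, c = c, r = 1)
    mod
  }
  # two constant models: 3.0 and 4.0 eV -> mean 3.5
  ens <- list(mkLinear(0, 3), mkLinear(0, 4))
  pred <- ensemblePredict(ens, feats)
  expect_true(all(pred$e_pred == 3.5))
  # single model equals its own prediction
  one <- ensemblePredict(list(mkLinear(1.08, 0.52)), feats)
  eLow <- vapply(feats, `[[`, numeric(1), "eLow")
  expect_equal(one$e_pred, unname(1.08 * eLow + 0.52))
  # ten models against the loop-and-average oracle
  set.seed(56)
  coefs <- replicate(10, c(runif(1, 0.9, 1.2), runif(1, 0, 1)))
  ens10 <- lapply(seq_len(10), function(k)
    mkLinear(coefs[1, k], coefs[2, k]))
  p10 <- ensemblePredict(ens10, feats)
  oracle <- sapply(seq_along(eLow), function(i)
    mean(sapply(seq_len(10), function(k)
      coefs[1, k] * eLow[i] + coefs[2, k])))
  expect_lt(max(abs(p10$e_pred - oracle)), 1e-12)
  # per-fold values are retained and average exactly to the prediction
  pf <- attr(p10, "per_fold")
  expect_identical(ncol(pf), 10L)
  expect_lt(max(abs(rowMeans(pf) - p10$e_pred)), 1e-12)
  # members with different variants are refused
  bad <- list(mkLinear(1, 0),
              assembleVariant(parseVariant("Dense(E_ZINDO, MO-RDF)",
                                           dense = tinyDenseSpec())))
  expect_error(ensemblePredict(bad, feats), "disagree")
})
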