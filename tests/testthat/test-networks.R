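test_that("linear baseline recovers exact and noisy lines", {
  e <- seq(1.5, 5.5, length.out = 40)
  fit <- linearFit(e, 1.08 * e + 0.52)
  expect_lt(abs(fit$m - 1.08), 1e-10)
  expect_lt(abs(fit$c - 0.52), 1e-10)
  expect_lt(abs(fit$r - 1), 1e-10)

  two <- linearFit(c(1, 3), c(2, 8))
  expect_equal(two$m, 3)
  expect_equal(two$c, -1)

  set.seed(30)
  x <- runif(200, 1.5, 5.5)
  y <- 1.08 * x + 0.52 + rnorm(200, sd = 0.1)
  fit2 <- linearFit(x, y)
  # normal-equations oracle
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_lt(abs(fit2$c - beta[1]), 1e-12)
  expect_lt(abs(fit2$m - beta[2]), 1e-12)
  expect_error(linearFit(rep(2, 10), runif(10)), "variance")
})

test_that("linear prediction is m*e + c elementwise", {
  b <- list(m = 1.08, c = 0.52)
  expect_equal(linearPredict(b, 3.0), 3.76)
  expect_equal(linearPredict(list(m = 1, c = 0), 2.7), 2.7)
  e <- seq(1, 5, by = 0.5)
  oracle <- vapply(e, function(x) 1.08 * x + 0.52, numeric(1))
  expect_equal(linearPredict(b, e), oracle)
})

test_that("dense block honours shape, determinism and the null map", {
  set.seed(31)
  X <- matrix(rnorm(5 * 10), 5, 10)
  spec <- denseBlockSpec(c(512L, 256L, 32L))
  r1 <- denseBlock(X, spec, seed = 3)
  expect_identical(dim(r1$out), c(5L, 32L))
  r2 <- denseBlock(X, spec, params = r1$params, state = r1$state, seed = 99)
  expect_identical(r1$out, r2$out)   # eval mode is deterministic
  # zeroed affine weights with no normalization: softplus(0) block output
  spec0 <- denseBlockSpec(c(4L, 2L), dropout = 0, batchNorm = FALSE,
                          activation = "lrelu")
  r3 <- denseBlock(X, spec0, seed = 5)
  zeroP <- lapply(r3$params, function(p) list(W = p$W * 0, b = p$b * 0))
  r4 <- denseBlock(X, spec0, params = zeroP, seed = 5)
  expect_true(all(r4$out == 0))
  expect_error(denseBlock(matrix(0, 2, 3), spec0, params = r3$params),
               "width")
})

test_that("residual head adds the low-level energy exactly", {
  expect_identical(residualPredict(0, 2.8), 2.8)
  expect_identical(residualPredict(0.7, 3.0), 3.7)
  set.seed(32)
  ml <- rnorm(20); el <- runif(20, 1.5, 5.5)
  oracle <- vapply(seq_len(20), function(k) ml[k] + el[k], numeric(1))
  expect_identical(residualPredict(ml, el), oracle)
})

test_that("encoder output is fixed-length, finite and permutation-invariant", {
  fx <- toyFixtures()
  m <- molecules(fx)$pyridine
  sp <- tinyEncoderSpec()
  emb <- encoderForwardMolecules(list(m), spec = sp, seed = 8)
  expect_identical(dim(emb), c(1L, 6L))
  expect_true(all(is.finite(emb)))
  set.seed(33)
  ns <- asNamespace("zindoml")
  params <- ns$withRNG(8, ns$encoderInit(sp))
  for (k in 1:3) {
    perm <- sample(nAtoms(m))
    mp <- permuteMolecule(m, order(perm))
    embP <- encoderForwardMolecules(list(mp), params = params, spec = sp)
    embR <- encoderForwardMolecules(list(m), params = params, spec = sp)
    expect_lt(max(abs(embP - embR)), 1e-8)
  }
  # single-atom molecule: no message edges, still finite
  single <- Molecule("he", "C", matrix(0, 1, 3))
  embS <- encoderForwardMolecules(list(single), spec = sp, seed = 8)
  expect_true(all(is.finite(embS)))
  # channel mismatch is refused
  expect_error(encoderForwardMolecules(list(m), spec = tinyEncoderSpec(45L),
                                       seed = 8),
               "electronic record|channels")
})

test_that("variant names parse, round-trip and gate the right branches", {
  rows <- c("Linear(E_ZINDO)", "Dense(E_ZINDO, MO-RDF)",
            "Dense(E_ZINDO, MO-RDF, MFP)", "MPNN(DA)", "MPNN(DA, EA)",
            "Dense(MPNN(DA), E_ZINDO)", "Dense(MPNN(DA, EA), E_ZINDO)",
            "Dense(MPNN(DA, EA), E_ZINDO, MO-RDF)",
            "Dense(MPNN(DA, EA), E_ZINDO, MFP)",
            "Dense(MPNN(DA, EA), E_ZINDO, MO-RDF, MFP)")
  for (nm in rows) {
    sp <- parseVariant(nm)
    expect_identical(variantName(sp), nm)
    expect_identical(variantName(parseVariant(variantName(sp))), nm)
  }
  expect_true(parseVariant("Linear(E_ZINDO)")@linearOnly)
  mp <- parseVariant("MPNN(DA)")
  expect_true(mp@useEncoder && !mp@useEZindo && !mp@ea)
  expect_identical(mp@encoder$nodeChannels, 41L)
  expect_identical(parseVariant("MPNN(DA, EA)")@encoder$nodeChannels, 45L)
  expect_error(parseVariant("Dense(MPNN(DA), BOGUS)"), "unknown")
  expect_error(parseVariant("Quantum(E_ZINDO)"), "cannot parse")
})

test_that("dense input width is the sum of the enabled branches", {
  sp <- parseVariant("Dense(MPNN(DA, EA), E_ZINDO, MO-RDF)",
                     encoder = tinyEncoderSpec())
  model <- assembleVariant(sp, seed = 2)
  expect_identical(nrow(model$params$dense[[1]]$W),
                   sp@encoder$fingerprintDim + 1L + 726L)
  sp2 <- parseVariant("Dense(E_ZINDO, MO-RDF, MFP)")
  m2 <- assembleVariant(sp2, seed = 2)
  expect_identical(nrow(m2$params$dense[[1]]$W), 1L + 726L + 2048L)
})

test_that("zeroed head reduces every residual variant to the ZINDO identity", {
  ds <- generateDataset(syntheticSpec(nMolecules = 6, seed = 41))
  feats <- featurizeDataset(ds, withMordf = TRUE)
  ns <- asNamespace("zindoml")
  for (nm in c("Dense(MPNN(DA, EA), E_ZINDO)",
               "Dense(E_ZINDO, MO-RDF)",
               "Dense(MPNN(DA), E_ZINDO, MO-RDF)")) {
    sp <- parseVariant(nm, dense = tinyDenseSpec(),
                       encoder = tinyEncoderSpec())
    model <- assembleVariant(sp, seed = 3)
    model <- ns$fitModelNorm(model, feats, names(feats))
    model$params$head$W <- model$params$head$W * 0
    model$params$head$b <- model$params$head$b * 0
    batch <- ns$makeBatch(feats, names(feats), model)
    fw <- ns$modelForward(model, batch, train = FALSE)
    expect_identical(fw$pred, batch$eLow)
  }
})

test_that("model forward is deterministic in eval mode and feeds every branch", {
  ds <- generateDataset(syntheticSpec(nMolecules = 4, seed = 42))
  feats <- featurizeDataset(ds, withMordf = TRUE)
  ns <- asNamespace("zindoml")
  sp <- parseVariant("Dense(MPNN(DA, EA), E_ZINDO, MO-RDF)",
                     dense = denseBlockSpec(c(8L, 4L), dropout = 0),
                     encoder = tinyEncoderSpec())
  model <- assembleVariant(sp, seed = 4)
  model <- ns$fitModelNorm(model, feats, names(feats))
  batch <- ns$makeBatch(feats, names(feats)[1:2], model)
  f1 <- ns$modelForward(model, batch)
  f2 <- ns$modelForward(model, batch)
  expect_identical(f1$pred, f2$pred)
  # gradient reaches every enabled branch and matches finite differences
  grads <- ns$modelBackward(model, batch, f1,
                            dPred = 2 * (f1$pred - batch$y) / 2)
  expect_gt(sum(abs(ns$paramsFlatten(grads$enc))), 0)
  expect_gt(sum(abs(ns$paramsFlatten(grads$dense))), 0)
  expect_gt(sum(abs(ns$paramsFlatten(grads$head))), 0)
  lossOf <- function(m) {
    fw <- ns$modelForward(m, batch)
    mean((fw$pred - batch$y)^2)
  }
  flat <- ns$paramsFlatten(model$params)
  gflat <- ns$paramsFlatten(grads)
  set.seed(43)
  for (k in sample(length(flat), 25)) {
    eps <- 1e-5
    mp <- model
    v <- flat; v[k] <- flat[k] + eps
    mp$params <- ns$paramsUnflatten(model$params, v)$value
    up <- lossOf(mp)
    v[k] <- flat[k] - eps
    mp$params <- ns$paramsUnflatten(model$params, v)$value
    dn <- lossOf(mp)
    num <- (up - dn) / (2 * eps)
    expect_lt(abs(num - gflat[k]), 1e-4 * max(1, abs(num)))
  }
})

test_that("assembling Linear(E_ZINDO) yields the closed-form baseline path", {
  model <- assembleVariant("Linear(E_ZINDO)")
  expect_null(model$params)
  ds <- generateDataset(syntheticSpec(nMolecules = 30, seed = 44,
                                      rule = "none", noiseSd = 0))
  feats <- featurizeDataset(ds, withMordf = FALSE)
  res <- trainFold(model, feats, names(feats)[1:20], names(feats)[21:30],
                   trainConfig(k = 2))
  expect_lt(abs(res$model$linear$m - 1.08), 1e-8)
  expect_lt(abs(res$model$linear$c - 0.52), 1e-8)
})
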