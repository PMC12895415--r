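# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards. All randomized operations
# in the package route through this so library calls never perturb user
# RNG streams and are reproducible per seed.
withRNG <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Sum rows of `x` (vector or matrix) grouped by integer segment ids,
# returning an nseg-row result with zero rows for empty segments.
segSum <- function(x, seg, nseg) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  out <- matrix(0, nseg, ncol(x))
  if (nrow(x)) {
    s <- rowsum(x, seg)
    out[as.integer(rownames(s)), ] <- s
  }
  out
}

# Per-segment max of a vector (for numerically stable softmax).
segMax <- function(x, seg, nseg) {
  out <- rep(-Inf, nseg)
  if (length(x)) {
    sp <- split(x, seg)
    out[as.integer(names(sp))] <- vapply(sp, max, numeric(1))
  }
  out
}

# Softmax of scores `e` within segments. Returns the weights; segments
# absent from `seg` contribute nothing.
segSoftmax <- function(e, seg, nseg) {
  m <- segMax(e, seg, nseg)
  ex <- exp(e - m[seg])
  tot <- segSum(ex, seg, nseg)[, 1L]
  ex / tot[seg]
}

# Backward pass of segSoftmax: given d(alpha), return d(e).
segSoftmaxGrad <- function(alpha, dalpha, seg, nseg) {
  s <- segSum(alpha * dalpha, seg, nseg)[, 1L]
  alpha * (dalpha - s[seg])
}

# Column-standardization statistics with a variance floor so constant
# channels pass through unscaled.
colStats <- function(x, sdFloor = 1e-8) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv < sdFloor] <- 1
  list(mean = mu, sd = sdv)
}

applyColStats <- function(x, stats) {
  x <- as.matrix(x)
  sweep(sweep(x, 2L, stats$mean, "-"), 2L, stats$sd, "/")
}

# Stable softplus and its derivative (the logistic function).
softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
softplusGrad <- function(x) 1 / (1 + exp(-pmin(pmax(x, -30), 30)))

leakyRelu <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)
leakyReluGrad <- function(x, slope = 0.01) ifelse(x > 0, 1, slope)

sigmoid <- function(x) 1 / (1 + exp(-pmin(pmax(x, -30), 30)))

# Short deterministic hash of an R object (used in run manifests).
objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
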