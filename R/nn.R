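# Minimal neural-network primitives (dense blocks with batch
# normalization and dropout, GRU cells, Adam, cyclical learning rate)
# with hand-written forward/backward passes on base R matrices. Written
# in the package because the modeling stack is the method itself; the
# backward passes are verified against finite differences in the test
# suite.

.glorot <- function(nin, nout) {
  l <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -l, l), nin, nout)
}

.linInit <- function(nin, nout)
  list(W = .glorot(nin, nout), b = rep(0, nout))

.linFwd <- function(p, X) {
  list(out = sweep(X %*% p$W, 2L, p$b, "+"), X = X)
}

.linBwd <- function(p, cache, dY) {
  list(dX = dY %*% t(p$W),
       grads = list(W = crossprod(cache$X, dY), db = colSums(dY)))
}

# --- batch normalization ---------------------------------------------
.bnInit <- function(dim)
  list(gamma = rep(1, dim), beta = rep(0, dim))

.bnStateInit <- function(dim)
  list(mean = rep(0, dim), var = rep(1, dim))

.bnFwd <- function(p, state, X, train, momentum = 0.1, eps = 1e-5) {
  if (train) {
    mu <- colMeans(X)
    v <- colMeans(sweep(X, 2L, mu, "-")^2)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(X, 2L, mu, "-"), 2L, inv, "*")
  out <- sweep(sweep(xhat, 2L, p$gamma, "*"), 2L, p$beta, "+")
  list(out = out, state = state,
       cache = list(xhat = xhat, inv = inv, train = train))
}

.bnBwd <- function(p, cache, dY) {
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, p$gamma, "*")
  if (cache$train) {
    n <- nrow(xhat)
    dX <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(xhat), byrow = TRUE) -
                  xhat * matrix(colMeans(dxhat * xhat), n, ncol(xhat),
                                byrow = TRUE),
                2L, cache$inv, "*")
  } else {
    dX <- sweep(dxhat, 2L, cache$inv, "*")
  }
  list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
}

# --- dense block ------------------------------------------------------
#' Dense block specification
#'
#' Layer sizes, dropout fraction, batch-normalization switch and
#' activation of a dense embedding block. The published configuration is
#' three layers of 512, 256 and 32 neurons with 20 percent dropout and
#' batch normalization.
#'
#' @param layerSizes integer vector of layer widths.
#' @param dropout dropout fraction in [0, 1).
#' @param batchNorm apply batch normalization after each affine map.
#' @param activation `"softplus"` (smooth rectifier) or `"lrelu"`.
#' @return a list of class `DenseBlockSpec`.
#' @export
denseBlockSpec <- function(layerSizes = c(512L, 256L, 32L), dropout = 0.2,
                           batchNorm = TRUE, activation = "softplus") {
  if (any(layerSizes <= 0)) stop("layer sizes must be positive")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(layerSizes = as.integer(layerSizes), dropout = dropout,
                 batchNorm = isTRUE(batchNorm), activation = activation),
            class = "DenseBlockSpec")
}

.act <- function(x, kind) switch(kind, softplus = softplus(x),
                                 lrelu = leakyRelu(x),
                                 stop("unknown activation ", kind))
.actGrad <- function(x, kind) switch(kind, softplus = softplusGrad(x),
                                     lrelu = leakyReluGrad(x))

denseBlockInit <- function(inDim, spec) {
  sizes <- c(inDim, spec$layerSizes)
  layers <- lapply(seq_along(spec$layerSizes), function(k) {
    p <- .linInit(sizes[k], sizes[k + 1L])
    if (spec$batchNorm) p <- c(p, .bnInit(sizes[k + 1L]))
    p
  })
  state <- if (spec$batchNorm)
    lapply(spec$layerSizes, .bnStateInit) else NULL
  list(params = layers, state = state)
}

denseBlockForward <- function(params, state, X, spec, train = FALSE) {
  caches <- vector("list", length(params))
  for (k in seq_along(params)) {
    p <- params[[k]]
    lf <- .linFwd(p, X)
    A <- lf$out
    bnCache <- NULL
    if (spec$batchNorm) {
      bf <- .bnFwd(p, state[[k]], A, train)
      A <- bf$out
      state[[k]] <- bf$state
      bnCache <- bf$cache
    }
    H <- .act(A, spec$activation)
    mask <- NULL
    if (train && spec$dropout > 0) {
      keep <- 1 - spec$dropout
      mask <- matrix(stats::rbinom(length(H), 1L, keep) / keep,
                     nrow(H), ncol(H))
      H <- H * mask
    }
    caches[[k]] <- list(lin = lf, bn = bnCache, preact = A, mask = mask)
    X <- H
  }
  list(out = X, caches = caches, state = state)
}

denseBlockBackward <- function(params, caches, dOut, spec) {
  grads <- vector("list", length(params))
  dX <- dOut
  for (k in rev(seq_along(params))) {
    cc <- caches[[k]]
    if (!is.null(cc$mask)) dX <- dX * cc$mask
    dA <- dX * .actGrad(cc$preact, spec$activation)
    bnG <- NULL
    if (spec$batchNorm) {
      bb <- .bnBwd(params[[k]], cc$bn, dA)
      dA <- bb$dX
      bnG <- bb$grads
    }
    lb <- .linBwd(params[[k]], cc$lin, dA)
    # field order must mirror the parameter list (W, b, gamma, beta)
    g <- list(W = lb$grads$W, b = lb$grads$db)
    if (spec$batchNorm) g <- c(g, list(gamma = bnG$gamma, beta = bnG$beta))
    grads[[k]] <- g
    dX <- lb$dX
  }
  list(dX = dX, grads = grads)
}

#' Run a dense block forward
#'
#' Standalone forward pass of a dense embedding block (affine, optional
#' batch normalization, smooth-rectifier activation, dropout), mainly
#' for inspection and testing; model training drives the same internals.
#' Evaluation mode is deterministic.
#'
#' @param X input matrix (rows = samples).
#' @param spec a [denseBlockSpec()].
#' @param params,state optional initialized parameters/state (fresh
#'   Glorot initialization under `seed` otherwise).
#' @param train training mode (enables dropout and batch statistics).
#' @param seed seed for initialization (and dropout when training).
#' @return list with `out` (embedding matrix), `params`, `state`.
#' @export
denseBlock <- function(X, spec = denseBlockSpec(), params = NULL,
                       state = NULL, train = FALSE, seed = 1L) {
  X <- as.matrix(X)
  withRNG(seed, {
    if (is.null(params)) {
      ini <- denseBlockInit(ncol(X), spec)
      params <- ini$params
      state <- ini$state
    }
    if (ncol(cbind(params[[1L]]$W))[1] && nrow(params[[1L]]$W) != ncol(X))
      stop("input width ", ncol(X), " does not match block (expects ",
           nrow(params[[1L]]$W), ")")
    fw <- denseBlockForward(params, state, X, spec, train = train)
    list(out = fw$out, params = params, state = fw$state)
  })
}

# --- GRU cell ---------------------------------------------------------
gruInit <- function(inDim, hDim) {
  list(Wz = .glorot(inDim, hDim), Uz = .glorot(hDim, hDim), bz = rep(0, hDim),
       Wr = .glorot(inDim, hDim), Ur = .glorot(hDim, hDim), br = rep(0, hDim),
       Wh = .glorot(inDim, hDim), Uh = .glorot(hDim, hDim), bh = rep(0, hDim))
}

gruForward <- function(p, C, H) {
  Z <- sigmoid(sweep(C %*% p$Wz + H %*% p$Uz, 2L, p$bz, "+"))
  R <- sigmoid(sweep(C %*% p$Wr + H %*% p$Ur, 2L, p$br, "+"))
  Ht <- tanh(sweep(C %*% p$Wh + (R * H) %*% p$Uh, 2L, p$bh, "+"))
  Hn <- (1 - Z) * H + Z * Ht
  list(out = Hn, cache = list(C = C, H = H, Z = Z, R = R, Ht = Ht))
}

gruBackward <- function(p, cache, dHn) {
  C <- cache$C; H <- cache$H; Z <- cache$Z; R <- cache$R; Ht <- cache$Ht
  dZ <- dHn * (Ht - H)
  dHt <- dHn * Z
  dH <- dHn * (1 - Z)
  dAh <- dHt * (1 - Ht^2)
  dC <- dAh %*% t(p$Wh)
  dRH <- dAh %*% t(p$Uh)
  dR <- dRH * H
  dH <- dH + dRH * R
  dAr <- dR * R * (1 - R)
  dC <- dC + dAr %*% t(p$Wr)
  dH <- dH + dAr %*% t(p$Ur)
  dAz <- dZ * Z * (1 - Z)
  dC <- dC + dAz %*% t(p$Wz)
  dH <- dH + dAz %*% t(p$Uz)
  grads <- list(Wz = crossprod(C, dAz), Uz = crossprod(H, dAz),
                bz = colSums(dAz),
                Wr = crossprod(C, dAr), Ur = crossprod(H, dAr),
                br = colSums(dAr),
                Wh = crossprod(C, dAh), Uh = crossprod(R * H, dAh),
                bh = colSums(dAh))
  list(dC = dC, dH = dH, grads = grads)
}

# --- parameter-tree utilities ----------------------------------------
paramsMap <- function(f, a) {
  if (is.list(a)) return(lapply(a, function(x) paramsMap(f, x)))
  f(a)
}

paramsMap2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (k in seq_along(a)) out[[k]] <- paramsMap2(f, a[[k]], b[[k]])
    return(out)
  }
  f(a, b)
}

paramsZero <- function(a) paramsMap(function(x) x * 0, a)

# --- Adam -------------------------------------------------------------
adamInit <- function(params)
  list(m = paramsZero(params), v = paramsZero(params), t = 0L)

adamStep <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- paramsMap2(function(m, g) beta1 * m + (1 - beta1) * g,
                      opt$m, grads)
  opt$v <- paramsMap2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      opt$v, grads)
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  step <- paramsMap2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                     opt$m, opt$v)
  params <- paramsMap2(`-`, params, step)
  list(params = params, opt = opt)
}

# Triangular cyclical learning rate between lr/10 and lr.
cyclicalLr <- function(epoch, lr, period = 20L, enabled = TRUE) {
  if (!enabled) return(lr)
  lo <- lr / 10
  phase <- ((epoch - 1L) %% period) / period      # 0 .. <1
  tri <- 1 - abs(2 * phase - 1)                   # 0 -> 1 -> 0
  lo + (lr - lo) * tri
}
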