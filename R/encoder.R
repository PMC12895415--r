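# Attention-based message-passing encoder ("neural fingerprint"). Atom
# states are refreshed by graph-attention message passing with GRU
# updates; a molecule-level super node then attends over its atoms for
# the readout, and a final linear layer emits the fingerprint. The
# construction is permutation-invariant: messages are aggregated by
# softmax-weighted sums within segments.

#' Encoder hyperparameters
#'
#' @param nodeChannels node feature width (41 for DA, 45 for DA+EA).
#' @param hiddenDim hidden state width.
#' @param fingerprintDim output fingerprint width.
#' @param atomSteps number of atom-level message-passing steps.
#' @param molSteps number of molecule-level readout steps.
#' @return list of class `EncoderSpec`.
#' @export
encoderSpec <- function(nodeChannels = 41L, hiddenDim = 200L,
                        fingerprintDim = 256L, atomSteps = 2L,
                        molSteps = 2L) {
  structure(list(nodeChannels = as.integer(nodeChannels),
                 hiddenDim = as.integer(hiddenDim),
                 fingerprintDim = as.integer(fingerprintDim),
                 atomSteps = as.integer(atomSteps),
                 molSteps = as.integer(molSteps)),
            class = "EncoderSpec")
}

encoderInit <- function(spec) {
  H <- spec$hiddenDim
  stepInit <- function() {
    list(a = matrix(stats::runif(2 * H, -sqrt(6 / (2 * H + 1)),
                                 sqrt(6 / (2 * H + 1))), 2 * H, 1),
         ba = 0,
         Wm = .glorot(H, H),
         gru = gruInit(H, H))
  }
  list(init = .linInit(spec$nodeChannels, H),
       atom = lapply(seq_len(spec$atomSteps), function(i) stepInit()),
       mol = lapply(seq_len(spec$molSteps), function(i) stepInit()),
       out = .linInit(H, spec$fingerprintDim))
}

# graph: list(X [N x F], edges [E x 2, directed, cols src,dst],
#             molIndex [N], nMol)
encoderForward <- function(params, spec, graph) {
  if (ncol(graph$X) != spec$nodeChannels)
    stop("node features have ", ncol(graph$X), " channels; encoder expects ",
         spec$nodeChannels)
  N <- nrow(graph$X)
  lin0 <- .linFwd(params$init, graph$X)
  H <- leakyRelu(lin0$out)
  cache <- list(lin0 = lin0, pre0 = lin0$out, atom = list(), mol = list())
  E <- nrow(graph$edges)
  for (t in seq_along(params$atom)) {
    p <- params$atom[[t]]
    if (E > 0) {
      src <- graph$edges[, 1L]; dst <- graph$edges[, 2L]
      hcat <- cbind(H[dst, , drop = FALSE], H[src, , drop = FALSE])
      pre <- as.vector(hcat %*% p$a) + p$ba
      e <- leakyRelu(pre)
      alpha <- segSoftmax(e, dst, N)
      M <- H[src, , drop = FALSE] %*% p$Wm
      C <- segSum(alpha * M, dst, N)
    } else {
      hcat <- pre <- alpha <- M <- NULL
      C <- matrix(0, N, spec$hiddenDim)
    }
    gf <- gruForward(p$gru, C, H)
    cache$atom[[t]] <- list(H = H, hcat = hcat, pre = pre, alpha = alpha,
                            M = M, gru = gf$cache)
    H <- gf$out
  }
  S <- segSum(H, graph$molIndex, graph$nMol)
  cache$Hfinal <- H
  for (t in seq_along(params$mol)) {
    p <- params$mol[[t]]
    scat <- cbind(S[graph$molIndex, , drop = FALSE], H)
    pre <- as.vector(scat %*% p$a) + p$ba
    e <- leakyRelu(pre)
    alpha <- segSoftmax(e, graph$molIndex, graph$nMol)
    M <- H %*% p$Wm
    C <- segSum(alpha * M, graph$molIndex, graph$nMol)
    gf <- gruForward(p$gru, C, S)
    cache$mol[[t]] <- list(S = S, scat = scat, pre = pre, alpha = alpha,
                           M = M, gru = gf$cache)
    S <- gf$out
  }
  linO <- .linFwd(params$out, S)
  cache$linO <- linO
  list(out = linO$out, cache = cache)
}

encoderBackward <- function(params, spec, graph, cache, dOut) {
  N <- nrow(graph$X)
  grads <- paramsZero(params)
  lb <- .linBwd(params$out, cache$linO, dOut)
  grads$out$W <- lb$grads$W
  grads$out$b <- lb$grads$db
  dS <- lb$dX
  dH <- matrix(0, N, spec$hiddenDim)
  for (t in rev(seq_along(params$mol))) {
    p <- params$mol[[t]]
    cc <- cache$mol[[t]]
    gb <- gruBackward(p$gru, cc$gru, dS)
    grads$mol[[t]]$gru <- gb$grads
    dC <- gb$dC
    dS <- gb$dH
    dCn <- dC[graph$molIndex, , drop = FALSE]
    dM <- cc$alpha * dCn
    dalpha <- rowSums(dCn * cc$M)
    de <- segSoftmaxGrad(cc$alpha, dalpha, graph$molIndex, graph$nMol)
    dpre <- de * leakyReluGrad(cc$pre)
    dscat <- dpre %*% t(p$a)
    grads$mol[[t]]$a <- crossprod(cc$scat, dpre)
    grads$mol[[t]]$ba <- sum(dpre)
    grads$mol[[t]]$Wm <- crossprod(cache$Hfinal, dM)
    Hd <- spec$hiddenDim
    dS <- dS + segSum(dscat[, 1:Hd, drop = FALSE], graph$molIndex,
                      graph$nMol)
    dH <- dH + dscat[, Hd + 1:Hd, drop = FALSE] + dM %*% t(p$Wm)
  }
  dH <- dH + dS[graph$molIndex, , drop = FALSE]   # S0 = sum of H
  E <- nrow(graph$edges)
  for (t in rev(seq_along(params$atom))) {
    p <- params$atom[[t]]
    cc <- cache$atom[[t]]
    gb <- gruBackward(p$gru, cc$gru, dH)
    grads$atom[[t]]$gru <- gb$grads
    dC <- gb$dC
    dH <- gb$dH
    if (E > 0) {
      src <- graph$edges[, 1L]; dst <- graph$edges[, 2L]
      dCe <- dC[dst, , drop = FALSE]
      dM <- cc$alpha * dCe
      dalpha <- rowSums(dCe * cc$M)
      de <- segSoftmaxGrad(cc$alpha, dalpha, dst, N)
      dpre <- de * leakyReluGrad(cc$pre)
      dhcat <- dpre %*% t(p$a)
      grads$atom[[t]]$a <- crossprod(cc$hcat, dpre)
      grads$atom[[t]]$ba <- sum(dpre)
      grads$atom[[t]]$Wm <- crossprod(cc$H[src, , drop = FALSE], dM)
      Hd <- spec$hiddenDim
      dH <- dH + segSum(dhcat[, 1:Hd, drop = FALSE], dst, N) +
        segSum(dhcat[, Hd + 1:Hd, drop = FALSE] + dM %*% t(p$Wm), src, N)
    } else {
      grads$atom[[t]]$a <- matrix(0, 2 * spec$hiddenDim, 1)
      grads$atom[[t]]$ba <- 0
      grads$atom[[t]]$Wm <- matrix(0, spec$hiddenDim, spec$hiddenDim)
    }
  }
  dpre0 <- dH * leakyReluGrad(cache$pre0)
  lb0 <- .linBwd(params$init, cache$lin0, dpre0)
  grads$init$W <- lb0$grads$W
  grads$init$b <- lb0$grads$db
  list(dX = lb0$dX, grads = grads)
}

#' Neural fingerprint of molecules
#'
#' Runs the message-passing encoder over one or more molecules and
#' returns the fixed-length embedding per molecule. Mainly a
#' convenience/testing surface; model training shares the internals.
#'
#' @param mols list of [Molecule-class] objects.
#' @param params encoder parameters (fresh seeded initialization if
#'   `NULL`).
#' @param spec an [encoderSpec()].
#' @param elecs optional list of electronic records (needed when
#'   `spec$nodeChannels == 45`).
#' @param eaStats EA standardization statistics.
#' @param seed seed for fresh initialization.
#' @return matrix, one fingerprint row per molecule.
#' @export
encoderForwardMolecules <- function(mols, params = NULL,
                                    spec = encoderSpec(), elecs = NULL,
                                    eaStats = NULL, seed = 1L) {
  mode <- if (spec$nodeChannels == 45L) "DA+EA" else "DA"
  feats <- lapply(seq_along(mols), function(k)
    list(node = buildNodeFeatures(mols[[k]],
                                  elec = if (!is.null(elecs)) elecs[[k]],
                                  mode = mode, eaStats = eaStats),
         edges = .directedEdges(mols[[k]])))
  graph <- .assembleGraph(feats)
  if (is.null(params)) params <- withRNG(seed, encoderInit(spec))
  encoderForward(params, spec, graph)$out
}

# Directed edge list (both directions) of a molecule.
.directedEdges <- function(mol) {
  if (!nrow(mol@bonds)) return(matrix(0L, 0, 2))
  b <- mol@bonds[, 1:2, drop = FALSE]
  rbind(cbind(b[, 1L], b[, 2L]), cbind(b[, 2L], b[, 1L]))
}

# Stack per-molecule node/edge tensors into one batched graph.
.assembleGraph <- function(feats) {
  sizes <- vapply(feats, function(f) nrow(f$node), integer(1))
  offs <- cumsum(c(0L, sizes[-length(sizes)]))
  X <- do.call(rbind, lapply(feats, `[[`, "node"))
  edges <- do.call(rbind, lapply(seq_along(feats), function(k) {
    e <- feats[[k]]$edges
    if (nrow(e)) e + offs[k] else e
  }))
  molIndex <- rep(seq_along(feats), sizes)
  list(X = X, edges = edges, molIndex = molIndex, nMol = length(feats))
}
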