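# Independent brute-force oracles and small random fixtures used across
# the suite. Oracles are deliberately naive (double loops, explicit
# enumeration) and share no code with the implementation paths they
# check.

oraclePotential <- function(Z, coords) {
  n <- length(Z)
  phi <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      phi[i] <- phi[i] + Z[j] / r
    }
  }
  phi
}

oraclePopulations <- function(coeffs, basisToAtom, nAtoms) {
  p <- numeric(nAtoms)
  for (k in seq_along(coeffs))
    p[basisToAtom[k]] <- p[basisToAtom[k]] + coeffs[k]^2
  p / sum(coeffs^2)
}

oracleMoRdf <- function(coords, w, grid) {
  r <- gridPoints(grid)
  f <- numeric(length(r))
  n <- nrow(coords)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i <= j) next
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      x <- r - d
      f <- f + w[i] * w[j] *
        exp(-x^2 / (2 * grid@sigma^2)) / (grid@sigma * sqrt(2 * pi))
    }
  }
  f
}

# Random well-separated geometry (minimum pairwise distance enforced).
randomGeometry <- function(n, spread = 4, minDist = 0.8) {
  repeat {
    coords <- matrix(stats::runif(3 * n, -spread, spread), n, 3)
    if (n < 2 || min(stats::dist(coords)) > minDist) return(coords)
  }
}

randomRotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3, 3))) *
    sample(c(-1, 1), 1)
}

# Apply an atom permutation to a Molecule, returning a new object.
permuteMolecule <- function(mol, perm) {
  inv <- order(perm)
  bonds <- mol@bonds
  if (nrow(bonds)) {
    bonds[, 1L] <- inv[bonds[, 1L]]
    bonds[, 2L] <- inv[bonds[, 2L]]
  }
  Molecule(id = mol@id, elements = mol@elements[perm],
           coords = mol@coords[perm, , drop = FALSE], bonds = bonds,
           smiles = mol@smiles, aromaticAtom = mol@aromaticAtom[perm],
           aromaticBond = mol@aromaticBond,
           formalCharge = mol@formalCharge[perm], nH = mol@nH[perm])
}

# Small shared variant/config used by network-level tests.
tinyEncoderSpec <- function(channels = 41L)
  encoderSpec(nodeChannels = channels, hiddenDim = 8L, fingerprintDim = 6L,
              atomSteps = 2L, molSteps = 2L)

tinyDenseSpec <- function() denseBlockSpec(c(8L, 4L), dropout = 0.2)
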