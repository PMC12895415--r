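#' MO-RDF sampling grid constructor
#'
#' Defaults reproduce the published descriptor: 0.5 to 15 Angstrom at
#' 0.02 Angstrom intervals with a 0.05 Angstrom Gaussian width, both
#' endpoints included, giving a 726-point feature vector.
#'
#' @param rMin,rMax grid range (Angstrom).
#' @param step grid spacing (Angstrom).
#' @param sigma Gaussian smoothing width (Angstrom).
#' @return a [MoRdfGrid-class].
#' @export
mordfGrid <- function(rMin = 0.5, rMax = 15.0, step = 0.02, sigma = 0.05) {
  new("MoRdfGrid", rMin = rMin, rMax = rMax, step = step, sigma = sigma)
}

#' @rdname mordfGrid
#' @param grid a [MoRdfGrid-class].
#' @export
nPoints <- function(grid) as.integer(round((grid@rMax - grid@rMin) / grid@step) + 1)

#' @rdname mordfGrid
#' @export
gridPoints <- function(grid) grid@rMin + grid@step * (seq_len(nPoints(grid)) - 1)

setMethod("show", "MoRdfGrid", function(object) {
  cat(sprintf("MoRdfGrid: %.2f..%.2f Angstrom, step %.3f, sigma %.3f (%d points)\n",
              object@rMin, object@rMax, object@step, object@sigma,
              nPoints(object)))
})

#' Atomic potentials from nuclear charges and geometry
#'
#' For every atom i, the summed Coulomb-like contribution of all other
#' atoms, `phi_i = sum_{j != i} Z_j / r_ij` (units e/Angstrom). All atoms
#' present in the geometry participate in the sum, hydrogens included.
#'
#' @param Z per-atom nuclear charges (e), or a [Molecule-class] (then
#'   `coords` is taken from it).
#' @param coords N x 3 positions (Angstrom).
#' @return numeric vector of per-atom potentials.
#' @export
atomicPotential <- function(Z, coords) {
  if (is(Z, "Molecule")) {
    coords <- Z@coords
    Z <- Z@Z
  }
  coords <- as.matrix(coords)
  n <- length(Z)
  if (n == 0L) stop("atomicPotential: empty molecule")
  if (nrow(coords) != n) stop("atomicPotential: Z/coords length mismatch")
  if (n == 1L) return(0)
  D <- as.matrix(stats::dist(coords))
  off <- D[upper.tri(D)]
  if (any(off < 1e-6)) {
    idx <- which(D < 1e-6 & upper.tri(D), arr.ind = TRUE)[1L, ]
    stop(sprintf("coincident atoms %d and %d (r = %.2e Angstrom)",
                 idx[1L], idx[2L], D[idx[1L], idx[2L]]))
  }
  IR <- 1 / D
  diag(IR) <- 0
  as.vector(IR %*% Z)
}

#' Per-atom populations of an orbital
#'
#' Mulliken-style populations in an orthogonalized (INDO-type) basis:
#' squared coefficients summed per atom and normalized to unit total,
#' `p_i = sum_{mu in atom i} c_mu^2 / sum_mu c_mu^2`.
#'
#' @param coeffs orbital coefficients per basis function.
#' @param basisToAtom integer map from basis function to atom index.
#' @param nAtoms number of atoms (defaults to `max(basisToAtom)`).
#' @return numeric vector of per-atom populations summing to 1.
#' @export
orbitalPopulations <- function(coeffs, basisToAtom, nAtoms = max(basisToAtom)) {
  if (length(coeffs) != length(basisToAtom))
    stop("coeffs and basisToAtom must have equal length")
  if (any(basisToAtom < 1 | basisToAtom > nAtoms))
    stop("basisToAtom entries must index valid atoms")
  tot <- sum(coeffs^2)
  if (tot <= 0) stop("all-zero orbital coefficient vector")
  p <- segSum(coeffs^2, basisToAtom, nAtoms)[, 1L]
  p / tot
}

#' NTO particle and hole densities
#'
#' Per-atom populations of the natural transition orbital pair that
#' describes the S0 -> S1 excitation. By default only the dominant pair
#' is used; pass coefficient lists plus singular values to combine
#' several pairs weighted by their squared singular values.
#'
#' @param holeCoeffs,particleCoeffs coefficient vectors of the dominant
#'   NTO pair, or lists of vectors for the multi-pair mode.
#' @param basisToAtom basis-function-to-atom map.
#' @param nAtoms number of atoms.
#' @param singularValues NTO singular values (multi-pair mode only).
#' @return list with components `n_hole` and `n_elec`, each summing to 1.
#' @export
particleHoleDensities <- function(holeCoeffs, particleCoeffs, basisToAtom,
                                  nAtoms = max(basisToAtom),
                                  singularValues = NULL) {
  one <- function(cc) orbitalPopulations(cc, basisToAtom, nAtoms)
  if (is.list(holeCoeffs)) {
    if (is.null(singularValues) ||
        length(singularValues) != length(holeCoeffs))
      stop("multi-pair mode needs one singular value per NTO pair")
    wts <- singularValues^2 / sum(singularValues^2)
    nh <- Reduce(`+`, Map(function(cc, w) w * one(cc), holeCoeffs, wts))
    ne <- Reduce(`+`, Map(function(cc, w) w * one(cc), particleCoeffs, wts))
    return(list(n_hole = nh, n_elec = ne))
  }
  list(n_hole = one(holeCoeffs), n_elec = one(particleCoeffs))
}

#' Molecular-orbital-weighted radial distribution function
#'
#' Orientation-invariant electronic descriptor: every unordered atom
#' pair (i > j) contributes a normalized Gaussian centred at its
#' distance, weighted by the product of the per-atom orbital populations,
#' `f(r) = sum_{i>j} w_i w_j g(r - |r_i - r_j|)` with
#' `g(x) = exp(-x^2 / (2 sigma^2)) / (sigma sqrt(2 pi))`.
#'
#' @param coords N x 3 positions (Angstrom), or a [Molecule-class].
#' @param w per-atom weights (typically HOMO populations, sum 1).
#' @param grid a [MoRdfGrid-class]; default [mordfGrid()].
#' @return numeric vector of length `nPoints(grid)`.
#' @export
moRdf <- function(coords, w, grid = mordfGrid()) {
  if (is(coords, "Molecule")) coords <- coords@coords
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(w) != n) stop("moRdf: weights/coords length mismatch")
  validObject(grid)
  r <- gridPoints(grid)
  if (n < 2L) return(rep(0, length(r)))
  if (any(w < 0))
    warning("moRdf: negative weights supplied; populations should be >= 0")
  D <- as.matrix(stats::dist(coords))
  iu <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[upper.tri(D)]
  wp <- w[iu[, 1L]] * w[iu[, 2L]]
  # P x K Gaussian evaluation, collapsed over pairs
  X <- outer(d, r, function(dd, rr) rr - dd)
  G <- stats::dnorm(X, mean = 0, sd = grid@sigma)
  as.vector(crossprod(G, wp))
}

#' Morgan (circular) fingerprint
#'
#' 2048-bit hashed circular-substructure fingerprint of radius 2 bonds.
#' Computed with OpenBabel's ECFP4 implementation (radius 2) and folded
#' from its native 4096 bits down to the 2048-bit contract width by OR.
#' Deterministic for a fixed structure and invariant under atom
#' reordering.
#'
#' @param mol a [Molecule-class] or a SMILES string.
#' @param nBits fingerprint width (default 2048).
#' @return integer 0/1 vector of length `nBits`.
#' @export
morganFingerprint <- function(mol, nBits = 2048L) {
  if (is.character(mol)) {
    fmt <- "SMILES"; input <- mol
  } else if (nzchar(mol@smiles)) {
    fmt <- "SMILES"; input <- mol@smiles
  } else {
    fmt <- "SDF"
    input <- paste(ChemmineR::sdf2str(moleculeToSDF(mol)), collapse = "\n")
  }
  fps <- ChemmineOB::forEachMol(fmt, input, function(m)
    ChemmineOB::fingerprint_OB(list(m), "ECFP4"))
  if (!length(fps)) stop("unparseable structure for fingerprinting")
  bits <- as.integer(fps[[1L]])
  if (length(bits) < nBits)
    stop("fingerprint backend returned fewer than ", nBits, " bits")
  folds <- split(bits, (seq_along(bits) - 1L) %% nBits)
  out <- as.integer(vapply(folds, function(b) any(b > 0), logical(1)))
  names(out) <- NULL
  out[seq_len(nBits)]
}

# Fixed one-hot vocabulary of the default-atom featurization. 41
# channels: element (13), heavy degree (7), formal charge (5),
# hybridization (4), aromaticity (1), ring membership (1), implicit H
# count (6), radical electrons (1), chirality (3).
.NF_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl",
                  "Br", "I", "other")
.NF_WIDTH_DA <- 41L

.oneHot <- function(value, levels) {
  v <- numeric(length(levels))
  k <- match(value, levels)
  if (is.na(k)) k <- length(levels)
  v[k] <- 1
  v
}

.atomHybridization <- function(mol) {
  n <- nAtoms(mol)
  hyb <- rep("sp3", n)
  if (nrow(mol@bonds)) {
    for (b in seq_len(nrow(mol@bonds))) {
      o <- mol@bonds[b, 3L]
      for (a in mol@bonds[b, 1:2]) {
        if (o == 3) hyb[a] <- "sp"
        else if (o == 2 && hyb[a] != "sp") hyb[a] <- "sp2"
      }
    }
  }
  hyb[mol@aromaticAtom] <- "sp2"
  hyb[mol@elements == "H"] <- "other"
  hyb
}

#' Node feature matrix for the message-passing encoder
#'
#' Builds the default-atom (DA) featurization: 41 one-hot/flag channels
#' per atom covering element, heavy-atom degree, formal charge,
#' hybridization, aromaticity, ring membership, implicit hydrogen count,
#' radical electrons and chirality. In `"DA+EA"` mode the four electronic
#' atom (EA) descriptors (Mulliken charge, atomic potential, NTO
#' particle and hole density, in that order) are appended, z-scored with
#' the supplied training-set statistics, for 45 channels total.
#'
#' @param mol a [Molecule-class].
#' @param elec electronic record (required for `"DA+EA"`).
#' @param mode `"DA"` or `"DA+EA"`.
#' @param eaStats list with `mean` and `sd` of length 4 (training-set
#'   statistics for the EA columns); identity scaling if `NULL`.
#' @return numeric matrix, one row per atom; 41 or 45 columns.
#' @export
buildNodeFeatures <- function(mol, elec = NULL, mode = c("DA", "DA+EA"),
                              eaStats = NULL) {
  mode <- match.arg(mode)
  n <- nAtoms(mol)
  deg <- .heavyDegree(mol)
  inRing <- .ringAtoms(mol)
  hyb <- .atomHybridization(mol)
  rows <- lapply(seq_len(n), function(a) {
    c(.oneHot(mol@elements[a], .NF_ELEMENTS),
      .oneHot(as.character(min(deg[a], 6L)), as.character(0:6)),
      .oneHot(as.character(max(-2, min(2, mol@formalCharge[a]))),
              as.character(-2:2)),
      .oneHot(hyb[a], c("sp", "sp2", "sp3", "other")),
      as.numeric(mol@aromaticAtom[a]),
      as.numeric(inRing[a]),
      .oneHot(as.character(min(mol@nH[a], 5L)), as.character(0:5)),
      0,           # radical electrons (closed-shell inputs)
      .oneHot("none", c("none", "R", "S")))
  })
  X <- do.call(rbind, rows)
  stopifnot(ncol(X) == .NF_WIDTH_DA)
  if (mode == "DA+EA") {
    if (is.null(elec) || is.null(elec$mulliken) || is.null(elec$potential) ||
        is.null(elec$n_elec) || is.null(elec$n_hole))
      stop("DA+EA featurization requires a populated electronic record ",
           "(mulliken, potential, n_elec, n_hole); refusing to zero-fill")
    EA <- cbind(elec$mulliken, elec$potential, elec$n_elec, elec$n_hole)
    if (nrow(EA) != n) stop("electronic arrays do not match atom count")
    if (!is.null(eaStats)) EA <- applyColStats(EA, eaStats)
    X <- cbind(X, EA)
  }
  dimnames(X) <- NULL
  X
}

#' Edge feature matrix for the message-passing encoder
#'
#' One row per bond: bond-type one-hot (single, double, triple,
#' aromatic), conjugation flag (both endpoints sp2/sp or aromatic), ring
#' membership and a stereo one-hot (none, any, Z, E; `none` for inputs
#' without stereo annotation). Width 10; symmetric in the bond direction
#' by construction.
#'
#' @param mol a [Molecule-class].
#' @return numeric matrix with `nrow(bonds)` rows and 10 columns.
#' @export
buildEdgeFeatures <- function(mol) {
  nb <- nrow(mol@bonds)
  ringBond <- .ringBonds(mol)
  hyb <- .atomHybridization(mol)
  rows <- lapply(seq_len(nb), function(b) {
    i <- mol@bonds[b, 1L]; j <- mol@bonds[b, 2L]
    type <- if (mol@aromaticBond[b]) "aromatic"
            else c("single", "double", "triple")[mol@bonds[b, 3L]]
    pi_i <- mol@aromaticAtom[i] || hyb[i] %in% c("sp", "sp2")
    pi_j <- mol@aromaticAtom[j] || hyb[j] %in% c("sp", "sp2")
    c(.oneHot(type, c("single", "double", "triple", "aromatic")),
      as.numeric(pi_i && pi_j),
      as.numeric(ringBond[b]),
      .oneHot("none", c("none", "any", "Z", "E")))
  })
  out <- if (nb) do.call(rbind, rows) else matrix(0, 0, 10)
  dimnames(out) <- NULL
  out
}
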