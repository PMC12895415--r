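# Synthetic molecules-with-electronic-structure generator. Emulates the
# statistical shape of a ZINDO -> TDDFT delta-learning dataset: a linear
# low-to-high map (slope m, intercept c) plus a structure-dependent
# deviation and Gaussian noise, with per-atom electronic fields whose
# spatial structure is correlated with the deviation's trigger so the
# electronic descriptors are genuinely informative.

# --- fragment library ------------------------------------------------
# Each scaffold: element vector, bond matrix (i, j, order), aromatic
# flags, explicit implicit-H counts, SMILES tokens (one per atom, ring
# closure digits as %1/%2 placeholders), and attachable positions.
.mkRing6 <- function(elements, nH, tokens) {
  bonds <- cbind(i = 1:6, j = c(2:6, 1), order = 1)
  list(elements = elements, bonds = bonds, arom = rep(TRUE, 6),
       aromBond = rep(TRUE, 6), nH = nH, tokens = tokens,
       attach = which(elements == "C"))
}

.mkRing5 <- function(elements, nH, tokens) {
  bonds <- cbind(i = 1:5, j = c(2:5, 1), order = 1)
  list(elements = elements, bonds = bonds, arom = rep(TRUE, 5),
       aromBond = rep(TRUE, 5), nH = nH, tokens = tokens,
       attach = which(elements == "C"))
}

# Linearly fused aromatic ring systems (naphthalene-type). Ring k+1 is
# fused on the bond opposite the previous fusion bond, giving acenes.
.mkAcene <- function(nRings) {
  elements <- rep("C", 6)
  bonds <- cbind(i = 1:6, j = c(2:6, 1), order = 1)
  fuse <- c(1L, 2L)
  for (k in seq_len(nRings - 1L)) {
    n0 <- length(elements)
    newIdx <- n0 + 1:4
    elements <- c(elements, rep("C", 4))
    bonds <- rbind(bonds,
                   cbind(i = c(fuse[1L], newIdx[1:3]),
                         j = c(newIdx[1:3], newIdx[4L]), order = 1),
                   cbind(i = newIdx[4L], j = fuse[2L], order = 1))
    fuse <- c(newIdx[2L], newIdx[3L])
  }
  n <- length(elements)
  deg <- tabulate(c(bonds[, 1L], bonds[, 2L]), nbins = n)
  tokens <- if (nRings == 2L)
    c("c%1", "c", "c", "c%2", "c", "c", "c", "c", "c%2", "c%1")[1:n]
  else NULL
  list(elements = elements, bonds = bonds, arom = rep(TRUE, n),
       aromBond = rep(TRUE, nrow(bonds)), nH = ifelse(deg >= 3L, 0, 1),
       tokens = tokens, attach = which(deg == 2L))
}

.scaffoldLibrary <- function() {
  list(
    benzene = .mkRing6(rep("C", 6), rep(1, 6),
                       c("c%1", "c", "c", "c", "c", "c%1")),
    pyridine = .mkRing6(c("N", rep("C", 5)), c(0, rep(1, 5)),
                        c("n%1", "c", "c", "c", "c", "c%1")),
    pyrimidine = .mkRing6(c("N", "C", "N", "C", "C", "C"),
                          c(0, 1, 0, 1, 1, 1),
                          c("n%1", "c", "n", "c", "c", "c%1")),
    furan = .mkRing5(c("O", rep("C", 4)), c(0, rep(1, 4)),
                     c("o%1", "c", "c", "c", "c%1")),
    thiophene = .mkRing5(c("S", rep("C", 4)), c(0, rep(1, 4)),
                         c("s%1", "c", "c", "c", "c%1")),
    pyrrole = .mkRing5(c("N", rep("C", 4)), c(1, rep(1, 4)),
                       c("[nH]%1", "c", "c", "c", "c%1")),
    naphthalene = .mkAcene(2L)
  )
}

# Terminal substituents: saturated caps only, so they never extend the
# conjugated core.
.capLibrary <- function() {
  list(
    fluoro = list(elements = "F", bonds = NULL, nH = 0, smiles = "F"),
    methyl = list(elements = "C", bonds = NULL, nH = 3, smiles = "C"),
    hydroxy = list(elements = "O", bonds = NULL, nH = 1, smiles = "O"),
    amino = list(elements = "N", bonds = NULL, nH = 2, smiles = "N"),
    methoxy = list(elements = c("O", "C"),
                   bonds = cbind(i = 1, j = 2, order = 1),
                   nH = c(0, 3), smiles = "OC")
  )
}

# Assemble a random molecule from the grammar under the current RNG
# stream. Returns the graph pieces plus an equivalent SMILES string.
.sampleMoleculeGraph <- function() {
  scaffolds <- .scaffoldLibrary()
  caps <- .capLibrary()
  sc1 <- scaffolds[[sample(length(scaffolds), 1L)]]
  twoRings <- stats::runif(1) < 0.45
  linker <- if (twoRings) sample(c("direct", "vinyl"), 1L) else "none"
  sc2 <- if (twoRings) scaffolds[[sample(length(scaffolds) - 1L, 1L)]] else NULL

  elements <- sc1$elements
  bonds <- sc1$bonds
  arom <- sc1$arom
  aromBond <- sc1$aromBond
  nH <- sc1$nH
  subs1 <- rep("", length(sc1$elements))   # smiles decoration per atom
  subs2 <- NULL

  attachPool <- sc1$attach
  linkPos <- NA_integer_
  if (twoRings) {
    linkPos <- sample(attachPool, 1L)
    attachPool <- setdiff(attachPool, linkPos)
    off <- length(elements)
    if (linker == "vinyl") {
      elements <- c(elements, "C", "C")
      bonds <- rbind(bonds,
                     cbind(i = linkPos, j = off + 1L, order = 1),
                     cbind(i = off + 1L, j = off + 2L, order = 2))
      arom <- c(arom, FALSE, FALSE)
      aromBond <- c(aromBond, FALSE, FALSE)
      nH <- c(nH, 1, 1)
      joinFrom <- off + 2L
      off <- off + 2L
    } else joinFrom <- linkPos
    idx2 <- off + seq_along(sc2$elements)
    elements <- c(elements, sc2$elements)
    b2 <- sc2$bonds
    b2[, 1:2] <- b2[, 1:2] + off
    bonds <- rbind(bonds, b2, cbind(i = joinFrom, j = off + 1L, order = 1))
    arom <- c(arom, sc2$arom)
    aromBond <- c(aromBond, sc2$aromBond, FALSE)
    nH <- c(nH, sc2$nH)
    nH[linkPos] <- max(0, nH[linkPos] - 1)
    nH[off + 1L] <- max(0, nH[off + 1L] - 1)
    subs2 <- rep("", length(sc2$elements))
    attachPool <- c(attachPool, off + setdiff(sc2$attach, 1L))
  }

  nCaps <- sample(0:3, 1L)
  capNames <- character(0)
  if (nCaps > 0 && length(attachPool)) {
    pos <- sample(attachPool, min(nCaps, length(attachPool)))
    for (p in pos) {
      cap <- caps[[sample(length(caps), 1L)]]
      capNames <- c(capNames, cap$smiles)
      off <- length(elements)
      elements <- c(elements, cap$elements)
      arom <- c(arom, rep(FALSE, length(cap$elements)))
      nH <- c(nH, cap$nH)
      bonds <- rbind(bonds, cbind(i = p, j = off + 1L, order = 1))
      aromBond <- c(aromBond, FALSE)
      if (!is.null(cap$bonds)) {
        cb <- cap$bonds
        cb[, 1:2] <- cb[, 1:2] + off
        bonds <- rbind(bonds, cb)
        aromBond <- c(aromBond, rep(FALSE, nrow(cb)))
      }
      nH[p] <- max(0, nH[p] - 1)
      if (p <= length(subs1)) subs1[p] <- paste0(subs1[p], "(", cap$smiles, ")")
      else subs2[p - length(subs1) -
                   (if (linker == "vinyl") 2L else 0L)] <-
        paste0("(", cap$smiles, ")")
    }
  }

  smiles <- .assembleSmiles(sc1, subs1, linker, sc2, subs2, linkPos)
  list(elements = elements, bonds = bonds, arom = arom,
       aromBond = aromBond, nH = nH, smiles = smiles)
}

.tokensWithDigits <- function(tokens, d1, d2) {
  tk <- gsub("%1", d1, tokens, fixed = TRUE)
  gsub("%2", d2, tk, fixed = TRUE)
}

.assembleSmiles <- function(sc1, subs1, linker, sc2, subs2, linkPos) {
  if (is.null(sc1$tokens)) return("")
  tk1 <- .tokensWithDigits(sc1$tokens, "1", "2")
  if (!is.null(sc2)) {
    if (is.null(sc2$tokens)) return("")
    tk2 <- .tokensWithDigits(sc2$tokens, "3", "4")
    # substituents of scaffold 2 attach to atoms 2..n (atom 1 is the join)
    tail2 <- paste0(tk2, ifelse(seq_along(tk2) == 1L, "", subs2))
    lk <- if (linker == "vinyl") "C=C" else ""
    subs1[linkPos] <- paste0(subs1[linkPos],
                             "(", lk, paste(tail2, collapse = ""), ")")
  }
  paste(paste0(tk1, subs1), collapse = "")
}

#' Registered structural deviation rules
#'
#' Named graph-dependent deviation functions delta(molecule) available
#' to the generator: `none`, `heteroaromatic` (amplitude times an
#' indicator of an aromatic nitrogen), `heteroatom_count` (0.08 eV per
#' non-carbon heavy atom, capped at 5), `conjugation_length`
#' (0.04 eV per conjugated-core heavy atom) and `ring_fusion`
#' (amplitude for molecules with a fused ring system).
#'
#' @param rule rule name.
#' @param amplitude deviation amplitude in eV (used by the indicator
#'   rules; default 0.4).
#' @return function mapping a [Molecule-class] to a deviation in eV.
#' @export
deviationRule <- function(rule = c("heteroaromatic", "none",
                                   "heteroatom_count", "conjugation_length",
                                   "ring_fusion"),
                          amplitude = 0.4) {
  rule <- match.arg(rule)
  switch(rule,
    none = function(mol) 0,
    heteroaromatic = function(mol)
      amplitude * any(mol@elements == "N" & mol@aromaticAtom),
    heteroatom_count = function(mol)
      0.08 * min(sum(!mol@elements %in% c("C", "H")), 5L),
    conjugation_length = function(mol)
      0.04 * extractConjugatedCore(mol)$core_hac,
    ring_fusion = function(mol) {
      rings <- moleculeRings(mol)
      if (length(rings) < 2L) return(0)
      counts <- tabulate(unlist(rings), nbins = nAtoms(mol))
      amplitude * any(counts >= 2L)
    })
}

#' Synthetic dataset specification
#'
#' Defaults encode the emulated study conditions: low-level S1 energies
#' uniform on 1.5 to 5.5 eV, the published linear low-to-high map
#' (slope 1.08, intercept 0.52 eV), a structure-dependent deviation of
#' 0.4 eV triggered by heteroaromatic nitrogen, and 0.05 eV Gaussian
#' noise, which keeps essentially all residuals inside the 0 to 1.5 eV
#' band characteristic of the real ZINDO-to-TDDFT errors.
#'
#' @param nMolecules number of molecules.
#' @param seed RNG seed.
#' @param m,c slope and intercept (eV) of the low-to-high linear map.
#' @param noiseSd Gaussian noise standard deviation (eV).
#' @param rule deviation rule name (see [deviationRule()]).
#' @param amplitude deviation amplitude (eV).
#' @return list of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(nMolecules = 100L, seed = 1L, m = 1.08,
                          c = 0.52, noiseSd = 0.05,
                          rule = "heteroaromatic", amplitude = 0.4) {
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  structure(list(nMolecules = as.integer(nMolecules),
                 seed = as.integer(seed), m = m, c = c,
                 noiseSd = noiseSd, rule = rule, amplitude = amplitude),
            class = "SyntheticSpec")
}

# Per-atom electronic fields correlated with the deviation trigger.
.syntheticElectronic <- function(mol, eLow, fLow) {
  n <- nAtoms(mol)
  arom <- mol@aromaticAtom
  hetN <- mol@elements == "N" & arom
  wRaw <- stats::runif(n, 0.2, 1) * (0.15 + arom)
  holeRaw <- stats::runif(n, 0.2, 1) * (0.15 + arom)
  elecRaw <- stats::runif(n, 0.2, 1) * (0.15 + arom + 2.5 * hetN)
  base <- c(C = 0, N = -0.2, O = -0.3, S = -0.05, F = -0.25, H = 0.1)
  mu <- base[mol@elements]
  mu[is.na(mu)] <- 0
  mu <- mu + stats::rnorm(n, sd = 0.03)
  mu <- mu - mean(mu)
  electronicRecord(
    molecule_id = mol@id, e_s1_low = eLow, f_low = fLow,
    mulliken = unname(mu),
    potential = atomicPotential(mol),
    n_elec = elecRaw / sum(elecRaw),
    n_hole = holeRaw / sum(holeRaw),
    w_homo = wRaw / sum(wRaw))
}

#' Generate a synthetic delta-learning dataset
#'
#' Samples molecules from a combinatorial grammar over C/N/O/S/F
#' scaffolds (aromatic rings, conjugated linkers, saturated terminal
#' caps), embeds deterministic 3-D coordinates, and emits low-level
#' electronic records plus high-level targets following
#' `eHigh = m * eLow + c + delta(molecule) + N(0, noiseSd)`. Per-atom
#' HOMO populations, particle/hole densities and Mulliken charges are
#' generated with their mass correlated to the deviation trigger;
#' atomic potentials are computed exactly from the embedded geometry.
#' Fully reproducible per seed.
#'
#' @param spec a [syntheticSpec()].
#' @return a [ZindoDataset-class] with attributes `delta` (true
#'   per-molecule deviations, eV) and `spec`.
#' @export
generateDataset <- function(spec = syntheticSpec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  delta <- deviationRule(spec$rule, spec$amplitude)
  withRNG(spec$seed, {
    mols <- vector("list", spec$nMolecules)
    elec <- vector("list", spec$nMolecules)
    dvec <- numeric(spec$nMolecules)
    eHigh <- numeric(spec$nMolecules)
    fHigh <- numeric(spec$nMolecules)
    ids <- sprintf("synth%05d", seq_len(spec$nMolecules))
    for (i in seq_len(spec$nMolecules)) {
      gr <- .sampleMoleculeGraph()
      mol <- Molecule(id = ids[i], elements = gr$elements,
                      coords = matrix(0, length(gr$elements), 3) +
                        cbind(seq_along(gr$elements), 0, 0),
                      bonds = gr$bonds, smiles = gr$smiles,
                      aromaticAtom = gr$arom, aromaticBond = gr$aromBond,
                      nH = gr$nH)
      mol <- embedCoords3D(mol, seed = (spec$seed * 131L + i) %% 2147483647L)
      eLow <- stats::runif(1, 1.5, 5.5)
      trig <- delta(mol)
      fLow <- 0.4 * stats::rexp(1, rate = 4) +
        (trig > 0) * 0.55 * stats::runif(1, 0.6, 1.4)
      mols[[i]] <- mol
      elec[[i]] <- .syntheticElectronic(mol, eLow, fLow)
      dvec[i] <- trig
      eHigh[i] <- spec$m * eLow + spec$c + trig +
        stats::rnorm(1, sd = spec$noiseSd)
      fHigh[i] <- max(0, 0.85 * fLow + 0.03 + stats::rnorm(1, sd = 0.05))
    }
    targets <- data.frame(molecule_id = ids, e_s1_high = eHigh,
                          f_high = fHigh)
    ds <- zindoDataset(mols, elec, targets)
    attr(ds, "delta") <- stats::setNames(dvec, ids)
    attr(ds, "spec") <- spec
    ds
  })
}

# --- fixed fixture set ------------------------------------------------

.fixtureMol <- function(id, smiles, elements, bonds, arom = NULL,
                        aromBond = NULL, nH = NULL, seed = 42L,
                        coords = NULL) {
  n <- length(elements)
  mol <- Molecule(id = id, elements = elements,
                  coords = if (is.null(coords))
                    cbind(seq_len(n), 0, 0) else coords,
                  bonds = bonds, smiles = smiles,
                  aromaticAtom = if (is.null(arom)) rep(FALSE, n) else arom,
                  aromaticBond = if (is.null(aromBond))
                    rep(FALSE, nrow(bonds)) else aromBond,
                  nH = nH)
  if (is.null(coords)) mol <- embedCoords3D(mol, seed = seed)
  mol
}

.ringBondsMat <- function(n) cbind(i = 1:n, j = c(2:n, 1), order = 1)

#' Fixed fixture molecules covering curation and descriptor edge cases
#'
#' A deterministic set of hand-constructed molecules: benzene (with
#' explicit hydrogens), methane (explicit hydrogens, literal tetrahedral
#' geometry), ethane, cyclohexane, pyridine, nitrosobenzene,
#' nitrobenzene, chlorobenzene, naphthalene, 1-methylnaphthalene,
#' anthracene, biphenyl (with a para-ethyl variant) and a 26-heavy-atom
#' chain. Each carries fixed coordinates and simple deterministic
#' electronic fields.
#'
#' @return a [ZindoDataset-class] of the fixtures.
#' @export
toyFixtures <- function() {
  mols <- list()

  hex <- .ringBondsMat(6)
  aromHex <- rep(TRUE, 6)

  # benzene with explicit hydrogens: 12 atoms
  ang <- 2 * pi * (0:5) / 6
  cC <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  cH <- cbind(2.48 * cos(ang), 2.48 * sin(ang), 0)
  mols$benzene <- .fixtureMol(
    "benzene", "c1ccccc1", c(rep("C", 6), rep("H", 6)),
    rbind(hex, cbind(i = 1:6, j = 7:12, order = 1)),
    arom = c(aromHex, rep(FALSE, 6)),
    aromBond = c(rep(TRUE, 6), rep(FALSE, 6)),
    nH = rep(0, 12), coords = rbind(cC, cH))

  # methane, literal tetrahedral geometry (explicit H)
  t <- 1.09 / sqrt(3)
  mols$methane <- .fixtureMol(
    "methane", "C", c("C", "H", "H", "H", "H"),
    cbind(i = 1, j = 2:5, order = 1), nH = rep(0, 5),
    coords = rbind(c(0, 0, 0), c(t, t, t), c(t, -t, -t),
                   c(-t, t, -t), c(-t, -t, t)))

  mols$ethane <- .fixtureMol(
    "ethane", "CC", c("C", "C"), cbind(i = 1, j = 2, order = 1),
    nH = c(3, 3), coords = rbind(c(0, 0, 0), c(1.54, 0, 0)))

  mols$cyclohexane <- .fixtureMol(
    "cyclohexane", "C1CCCCC1", rep("C", 6), hex, nH = rep(2, 6),
    seed = 101L)

  mols$pyridine <- .fixtureMol(
    "pyridine", "c1ccncc1", c("N", rep("C", 5)), hex,
    arom = aromHex, aromBond = rep(TRUE, 6), nH = c(0, rep(1, 5)),
    seed = 102L)

  mols$nitrosobenzene <- .fixtureMol(
    "nitrosobenzene", "O=Nc1ccccc1", c(rep("C", 6), "N", "O"),
    rbind(hex, cbind(i = c(1, 7), j = c(7, 8), order = c(1, 2))),
    arom = c(aromHex, FALSE, FALSE),
    aromBond = c(rep(TRUE, 6), FALSE, FALSE),
    nH = c(0, rep(1, 5), 0, 0), seed = 103L)

  mols$nitrobenzene <- .fixtureMol(
    "nitrobenzene", "O=[N+]([O-])c1ccccc1", c(rep("C", 6), "N", "O", "O"),
    rbind(hex, cbind(i = c(1, 7, 7), j = c(7, 8, 9), order = c(1, 2, 1))),
    arom = c(aromHex, FALSE, FALSE, FALSE),
    aromBond = c(rep(TRUE, 6), FALSE, FALSE, FALSE),
    nH = c(0, rep(1, 5), 0, 0, 0), seed = 104L)

  mols$chlorobenzene <- .fixtureMol(
    "chlorobenzene", "Clc1ccccc1", c(rep("C", 6), "Cl"),
    rbind(hex, cbind(i = 1, j = 7, order = 1)),
    arom = c(aromHex, FALSE), aromBond = c(rep(TRUE, 6), FALSE),
    nH = c(0, rep(1, 5), 0), seed = 105L)

  naph <- .mkAcene(2L)
  mols$naphthalene <- .fixtureMol(
    "naphthalene", "c1ccc2ccccc2c1", naph$elements, naph$bonds,
    arom = naph$arom, aromBond = naph$aromBond, nH = naph$nH, seed = 106L)

  mols$methylnaphthalene <- .fixtureMol(
    "methylnaphthalene", "Cc1cccc2ccccc12", c(naph$elements, "C"),
    rbind(naph$bonds, cbind(i = 3, j = 11, order = 1)),
    arom = c(naph$arom, FALSE), aromBond = c(naph$aromBond, FALSE),
    nH = c(replace(naph$nH, 3, 0), 3), seed = 107L)

  anth <- .mkAcene(3L)
  mols$anthracene <- .fixtureMol(
    "anthracene", "c1ccc2cc3ccccc3cc2c1", anth$elements, anth$bonds,
    arom = anth$arom, aromBond = anth$aromBond, nH = anth$nH, seed = 108L)

  mols$biphenyl <- .fixtureMol(
    "biphenyl", "c1ccc(-c2ccccc2)cc1", rep("C", 12),
    rbind(hex, cbind(i = 7:12, j = c(8:12, 7), order = 1),
          cbind(i = 1, j = 7, order = 1)),
    arom = rep(TRUE, 12), aromBond = c(rep(TRUE, 12), FALSE),
    nH = c(0, rep(1, 5), 0, rep(1, 5)), seed = 109L)

  mols$ethylbiphenyl <- .fixtureMol(
    "ethylbiphenyl", "CCc1ccc(-c2ccccc2)cc1", c(rep("C", 12), "C", "C"),
    rbind(hex, cbind(i = 7:12, j = c(8:12, 7), order = 1),
          cbind(i = 1, j = 7, order = 1),
          cbind(i = c(4, 13), j = c(13, 14), order = 1)),
    arom = c(rep(TRUE, 12), FALSE, FALSE),
    aromBond = c(rep(TRUE, 12), FALSE, FALSE, FALSE),
    nH = c(0, 1, 1, 0, 1, 1, 0, rep(1, 5), 2, 3), seed = 110L)

  mols$chain26 <- .fixtureMol(
    "chain26", paste(rep("C", 26), collapse = ""), rep("C", 26),
    cbind(i = 1:25, j = 2:26, order = 1),
    nH = c(3, rep(2, 24), 3), seed = 111L)

  # deterministic electronic fields
  eLowTable <- seq(2.0, by = 0.18, length.out = length(mols))
  elec <- vector("list", length(mols))
  for (k in seq_along(mols)) {
    m <- mols[[k]]
    n <- nAtoms(m)
    w <- if (any(m@aromaticAtom)) as.numeric(m@aromaticAtom) else rep(1, n)
    nh <- rev(seq_len(n))
    elec[[k]] <- electronicRecord(
      molecule_id = m@id, e_s1_low = eLowTable[k],
      f_low = 0.1 + 0.05 * k,
      mulliken = round(seq(-0.1, 0.1, length.out = n), 6),
      potential = atomicPotential(m),
      n_elec = w / sum(w), n_hole = nh / sum(nh), w_homo = w / sum(w))
  }
  targets <- data.frame(
    molecule_id = vapply(mols, function(m) m@id, character(1)),
    e_s1_high = 1.08 * eLowTable + 0.52,
    f_high = 0.1 + 0.04 * seq_along(mols))
  zindoDataset(mols, elec, targets)
}
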