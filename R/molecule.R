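# Element bookkeeping used across the package. Nuclear charges in
# elementary charge units; default valences drive implicit-H counting.
.ELEMENT_Z <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14,
                P = 15, S = 16, Cl = 17, Br = 35, I = 53)
.ELEMENT_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                      P = 3, S = 2, Cl = 1, Br = 1, I = 1)

.elementZ <- function(elements) {
  z <- .ELEMENT_Z[elements]
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(elements[is.na(z)]), collapse = ", "))
  }
  unname(z)
}

#' Construct a Molecule
#'
#' Builds a validated [Molecule-class] object. Nuclear charges are
#' derived from the element symbols; implicit hydrogen counts default to
#' standard valence minus the bond-order sum (aromatic bonds counted as
#' 1.5), floored at zero.
#'
#' @param id molecule identifier.
#' @param elements character vector of element symbols.
#' @param coords N x 3 numeric matrix, Angstrom.
#' @param bonds E x 3 matrix (i, j, order); zero-row matrix for atoms
#'   without bonds.
#' @param smiles optional SMILES string.
#' @param aromaticAtom,aromaticBond logical aromaticity flags; default
#'   all FALSE.
#' @param formalCharge per-atom formal charges; default 0.
#' @param nH per-atom implicit hydrogen counts; default derived from
#'   valence.
#' @return a [Molecule-class] object.
#' @export
Molecule <- function(id, elements, coords, bonds = matrix(0, 0, 3),
                     smiles = "", aromaticAtom = NULL, aromaticBond = NULL,
                     formalCharge = NULL, nH = NULL) {
  n <- length(elements)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  bonds <- as.matrix(bonds)
  if (nrow(bonds) && ncol(bonds) != 3L)
    stop("bonds must have columns (i, j, order)")
  storage.mode(bonds) <- "double"
  colnames(coords) <- c("x", "y", "z")
  if (nrow(bonds)) colnames(bonds) <- c("i", "j", "order")
  if (is.null(aromaticAtom)) aromaticAtom <- rep(FALSE, n)
  if (is.null(aromaticBond)) aromaticBond <- rep(FALSE, nrow(bonds))
  if (is.null(formalCharge)) formalCharge <- rep(0, n)
  if (is.null(nH)) nH <- .inferNH(elements, bonds, aromaticBond, formalCharge)
  new("Molecule", id = as.character(id), smiles = as.character(smiles),
      elements = elements, Z = .elementZ(elements), coords = coords,
      bonds = bonds, aromaticAtom = as.logical(aromaticAtom),
      aromaticBond = as.logical(aromaticBond),
      formalCharge = as.numeric(formalCharge), nH = as.numeric(nH))
}

# Implicit-H counts from default valences; aromatic bonds count 1.5.
.inferNH <- function(elements, bonds, aromaticBond, formalCharge) {
  n <- length(elements)
  order_sum <- rep(0, n)
  if (nrow(bonds)) {
    eff <- ifelse(aromaticBond, 1.5, bonds[, 3L])
    for (b in seq_len(nrow(bonds))) {
      order_sum[bonds[b, 1L]] <- order_sum[bonds[b, 1L]] + eff[b]
      order_sum[bonds[b, 2L]] <- order_sum[bonds[b, 2L]] + eff[b]
    }
  }
  val <- .ELEMENT_VALENCE[elements]
  val[is.na(val)] <- 0
  nH <- pmax(0, round(val + formalCharge - order_sum))
  nH[elements == "H"] <- 0
  nH
}

#' @describeIn Molecule number of atoms (including explicit hydrogens).
#' @param object,x a [Molecule-class].
#' @export
nAtoms <- function(x) length(x@elements)

#' Heavy-atom count
#'
#' Number of non-hydrogen atoms of a molecule.
#' @param x a [Molecule-class].
#' @return integer heavy-atom count.
#' @export
hac <- function(x) sum(x@elements != "H")

#' @rdname Molecule-class
#' @export
setMethod("show", "Molecule", function(object) {
  cat("Molecule '", object@id, "': ", nAtoms(object), " atoms (",
      hac(object), " heavy), ", nrow(object@bonds), " bonds",
      if (nzchar(object@smiles)) paste0(", SMILES ", object@smiles) else "",
      "\n", sep = "")
})

# igraph view of the bond graph (heavy + explicit H atoms).
.molGraph <- function(mol) {
  g <- igraph::make_empty_graph(n = nAtoms(mol), directed = FALSE)
  if (nrow(mol@bonds))
    g <- igraph::add_edges(g, t(mol@bonds[, 1:2, drop = FALSE]))
  g
}

# Heavy-atom degree (explicit hydrogens excluded from the count).
.heavyDegree <- function(mol) {
  deg <- rep(0L, nAtoms(mol))
  if (nrow(mol@bonds)) {
    heavy <- mol@elements != "H"
    for (b in seq_len(nrow(mol@bonds))) {
      i <- mol@bonds[b, 1L]; j <- mol@bonds[b, 2L]
      if (heavy[j]) deg[i] <- deg[i] + 1L
      if (heavy[i]) deg[j] <- deg[j] + 1L
    }
  }
  deg
}

# Atoms lying on at least one cycle: vertices of biconnected components
# with >= 3 vertices.
.ringAtoms <- function(mol) {
  n <- nAtoms(mol)
  inRing <- rep(FALSE, n)
  if (nrow(mol@bonds) == 0) return(inRing)
  g <- .molGraph(mol)
  bc <- igraph::biconnected_components(g)
  for (comp in bc$components) {
    v <- as.integer(comp)
    if (length(v) >= 3L) inRing[v] <- TRUE
  }
  inRing
}

# Bonds lying on a cycle (non-bridge edges).
.ringBonds <- function(mol) {
  nb <- nrow(mol@bonds)
  if (nb == 0) return(logical(0))
  g <- .molGraph(mol)
  bridges <- igraph::bridges(g)
  res <- rep(TRUE, nb)
  res[as.integer(bridges)] <- FALSE
  res
}

# Smallest-set-of-smallest-rings. For each non-bridge edge, the shortest
# cycle through it is found by BFS in the graph with that edge removed;
# cycles are then greedily selected shortest-first subject to GF(2)
# independence in edge space. Exact for the molecule sizes handled here.
.sssr <- function(mol) {
  nb <- nrow(mol@bonds)
  if (nb == 0) return(list())
  g <- .molGraph(mol)
  ringEdge <- .ringBonds(mol)
  nRings <- nb - nAtoms(mol) + igraph::count_components(g)
  if (nRings <= 0) return(list())
  cycles <- list()
  for (e in which(ringEdge)) {
    i <- mol@bonds[e, 1L]; j <- mol@bonds[e, 2L]
    g2 <- igraph::delete_edges(g, e)
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = i, to = j))
    p <- as.integer(sp$vpath[[1]])
    if (length(p) >= 2L) cycles[[length(cycles) + 1L]] <- p
  }
  if (!length(cycles)) return(list())
  cycles <- cycles[order(lengths(cycles))]
  # GF(2) independence over edge incidence vectors
  edgeKey <- function(i, j) paste(pmin(i, j), pmax(i, j))
  allKeys <- edgeKey(mol@bonds[, 1L], mol@bonds[, 2L])
  basis <- NULL
  out <- list()
  for (cyc in cycles) {
    v <- rep(0L, nb)
    m <- length(cyc)
    ks <- edgeKey(cyc, cyc[c(2:m, 1L)])
    v[match(ks, allKeys)] <- 1L
    red <- v
    if (!is.null(basis)) {
      for (r in seq_len(nrow(basis))) {
        piv <- which(basis[r, ] == 1L)[1L]
        if (red[piv] == 1L) red <- (red + basis[r, ]) %% 2L
      }
    }
    if (any(red == 1L)) {
      basis <- rbind(basis, red)
      out[[length(out) + 1L]] <- sort(cyc)
      if (length(out) == nRings) break
    }
  }
  out
}

#' Ring systems of a molecule
#'
#' Returns the smallest set of smallest rings as a list of atom-index
#' vectors, with attributes `aromatic` (all atoms of the ring flagged
#' aromatic) and `carbocycle` (all ring atoms carbon).
#'
#' @param mol a [Molecule-class].
#' @return list of integer vectors (one per ring).
#' @export
moleculeRings <- function(mol) {
  rings <- .sssr(mol)
  attr(rings, "aromatic") <-
    vapply(rings, function(r) all(mol@aromaticAtom[r]), logical(1))
  attr(rings, "carbocycle") <-
    vapply(rings, function(r) all(mol@elements[r] == "C"), logical(1))
  rings
}

#' Parse a SMILES string into a Molecule
#'
#' Uses ChemmineR/OpenBabel for structure generation and ring/aromaticity
#' perception. The returned coordinates are the generated 2-D layout
#' (z = 0); call [embedCoords3D()] for a deterministic 3-D embedding.
#'
#' @param smiles SMILES string.
#' @param id molecule identifier (default the SMILES itself).
#' @return a [Molecule-class].
#' @export
moleculeFromSmiles <- function(smiles, id = smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, id)))
  sdfToMolecule(sdf[[1]], id = id, smiles = smiles)
}

#' Convert a ChemmineR SDF object to a Molecule
#'
#' @param sdf a `ChemmineR::SDF` object.
#' @param id molecule identifier.
#' @param smiles optional SMILES to record.
#' @return a [Molecule-class].
#' @export
sdfToMolecule <- function(sdf, id, smiles = "") {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- gsub("_.*$", "", rownames(ab))
  nc <- min(3L, ncol(ab))
  coords <- cbind(ab[, seq_len(nc), drop = FALSE],
                  matrix(0, nrow(ab), 3L - nc))
  aromType4 <- logical(0)
  bonds <- if (!is.null(bb) && nrow(bb)) {
    ord <- as.numeric(bb[, 3])
    aromType4 <- ord == 4          # V2000 aromatic bond type
    ord[aromType4] <- 1
    cbind(i = as.numeric(bb[, 1]), j = as.numeric(bb[, 2]), order = ord)
  } else matrix(0, 0, 3)
  mol <- Molecule(id = id, elements = elements, coords = coords,
                  bonds = bonds, smiles = smiles)
  if (any(aromType4)) {
    aromAtom <- rep(FALSE, nAtoms(mol))
    aromAtom[c(bonds[aromType4, 1L], bonds[aromType4, 2L])] <- TRUE
    return(initialize(mol, aromaticAtom = aromAtom, aromaticBond = aromType4,
                      nH = .inferNH(elements, bonds, aromType4,
                                    mol@formalCharge)))
  }
  .perceiveAromaticity(mol, sdf)
}

# Aromaticity flags from ChemmineR ring perception on the parsed SDF.
.perceiveAromaticity <- function(mol, sdf) {
  res <- try(suppressWarnings(
    ChemmineR::rings(sdf, type = "all", arom = TRUE, inner.warning = FALSE)),
    silent = TRUE)
  if (inherits(res, "try-error") || !length(res$RINGS)) return(mol)
  aromAtom <- rep(FALSE, nAtoms(mol))
  for (k in seq_along(res$RINGS)) {
    if (isTRUE(res$AROMATIC[[k]])) {
      idx <- as.integer(gsub("^.*_", "", res$RINGS[[k]]))
      aromAtom[idx] <- TRUE
    }
  }
  aromBond <- rep(FALSE, nrow(mol@bonds))
  if (nrow(mol@bonds)) {
    ringBond <- .ringBonds(mol)
    aromBond <- ringBond & aromAtom[mol@bonds[, 1L]] & aromAtom[mol@bonds[, 2L]]
  }
  initialize(mol, aromaticAtom = aromAtom, aromaticBond = aromBond)
}

#' Deterministic 3-D embedding of a molecular graph
#'
#' Generates reproducible 3-D coordinates with a seeded force-directed
#' layout scaled so the mean bonded distance is 1.45 Angstrom. Geometry
#' fidelity is not the goal: the embedding gives well-separated,
#' orientation-arbitrary positions for distance-based descriptors, and is
#' byte-identical for a fixed seed.
#'
#' @param mol a [Molecule-class].
#' @param seed integer seed.
#' @return the molecule with replaced coordinates.
#' @export
embedCoords3D <- function(mol, seed = 1L) {
  n <- nAtoms(mol)
  coords <- withRNG(seed, {
    if (n == 1L) {
      matrix(0, 1, 3)
    } else {
      g <- .molGraph(mol)
      xy <- igraph::layout_with_fr(g, dim = 3, niter = 300)
      xy <- xy + matrix(stats::rnorm(3 * n, sd = 0.02), n, 3)
      if (nrow(mol@bonds)) {
        d <- sqrt(rowSums((xy[mol@bonds[, 1L], , drop = FALSE] -
                           xy[mol@bonds[, 2L], , drop = FALSE])^2))
        xy <- xy * (1.45 / mean(d))
      }
      xy
    }
  })
  colnames(coords) <- c("x", "y", "z")
  initialize(mol, coords = coords)
}

#' Canonical, atom-order-independent serialization of a molecular graph
#'
#' Iterative neighborhood-refinement labels (element, aromaticity and
#' formal charge seeds, refined over bond orders) are serialized into a
#' canonical string that is invariant under atom renumbering. Used as the
#' clustering key for conjugated cores.
#'
#' @param elements,bonds,aromaticAtom,formalCharge graph description as
#'   in [Molecule()].
#' @return single canonical string ("" for an empty graph).
#' @export
canonicalGraphKey <- function(elements, bonds, aromaticAtom = NULL,
                              formalCharge = NULL) {
  n <- length(elements)
  if (n == 0L) return("")
  if (is.null(aromaticAtom)) aromaticAtom <- rep(FALSE, n)
  if (is.null(formalCharge)) formalCharge <- rep(0, n)
  lab <- paste0(elements, ifelse(aromaticAtom, "a", "-"), formalCharge)
  lab <- match(lab, sort(unique(lab)))
  nb <- vector("list", n)
  bo <- character(0)
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1L]; j <- bonds[b, 2L]
      nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
    }
    bo <- bonds[, 3L]
    bkey <- function(b) paste0("o", bo[b])
  }
  edgeLab <- function(atom) {
    if (nrow(bonds) == 0) return(character(0))
    sel <- which(bonds[, 1L] == atom | bonds[, 2L] == atom)
    other <- ifelse(bonds[sel, 1L] == atom, bonds[sel, 2L], bonds[sel, 1L])
    sort(paste0(bkey(sel), ":", lab[other]))
  }
  for (iter in seq_len(n)) {
    sig <- vapply(seq_len(n), function(a)
      paste0(lab[a], "|", paste(edgeLab(a), collapse = ",")), character(1))
    newLab <- match(sig, sort(unique(sig)))
    if (identical(newLab, lab)) break
    lab <- newLab
  }
  atomPart <- sort(paste0(elements, ifelse(aromaticAtom, "a", "-"),
                          formalCharge, "#", lab))
  bondPart <- character(0)
  if (nrow(bonds)) {
    a <- pmin(lab[bonds[, 1L]], lab[bonds[, 2L]])
    b <- pmax(lab[bonds[, 1L]], lab[bonds[, 2L]])
    bondPart <- sort(paste0(a, "~", b, "~", bo))
  }
  paste(paste(atomPart, collapse = ";"), paste(bondPart, collapse = ";"),
        sep = "//")
}
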