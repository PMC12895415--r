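# Dataset-curation operators: conjugated-core extraction and clustering,
# candidate filters, core-analogue test sampling, the external-set ring
# filter and the parity split.

#' Extract the conjugated core of a molecule
#'
#' The core is the maximal connected subgraph of pi-conjugated atoms:
#' atoms in aromatic systems plus atoms on conjugated double/triple-bond
#' paths attached to them, with saturated (sp3) substituents excluded.
#' The result is reported as an atom-order-independent canonical key
#' plus the core heavy-atom count, so molecules differing only by
#' saturated terminal groups (e.g. naphthalene and 1-methylnaphthalene)
#' share a key.
#'
#' @param mol a [Molecule-class].
#' @return list with `core_key` (canonical string, `""` when the
#'   molecule has no conjugated atoms), `core_hac` (heavy-atom count of
#'   the core) and `core_atoms` (atom indices).
#' @export
extractConjugatedCore <- function(mol) {
  n <- nAtoms(mol)
  heavy <- mol@elements != "H"
  cand <- mol@aromaticAtom
  if (nrow(mol@bonds)) {
    multi <- mol@bonds[, 3L] >= 2
    for (b in which(multi)) {
      cand[mol@bonds[b, 1L]] <- TRUE
      cand[mol@bonds[b, 2L]] <- TRUE
    }
  }
  cand <- cand & heavy
  if (!any(cand))
    return(list(core_key = "", core_hac = 0L, core_atoms = integer(0)))
  # connected components within the candidate-induced subgraph
  keepBond <- nrow(mol@bonds) > 0 &
    cand[mol@bonds[, 1L]] & cand[mol@bonds[, 2L]]
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (any(keepBond))
    g <- igraph::add_edges(g, t(mol@bonds[keepBond, 1:2, drop = FALSE]))
  comp <- igraph::components(g)
  compSize <- tabulate(comp$membership[cand], nbins = comp$no)
  core <- which(cand & comp$membership == which.max(compSize))
  sel <- which(keepBond & mol@bonds[, 1L] %in% core &
                 mol@bonds[, 2L] %in% core)
  bonds <- mol@bonds[sel, , drop = FALSE]
  # normalize Kekule alternation: aromatic bonds keyed as order 1.5 so
  # the canonical key is independent of the Kekule structure chosen
  if (nrow(bonds)) bonds[, 3L] <- ifelse(mol@aromaticBond[sel], 1.5,
                                         bonds[, 3L])
  remap <- match(seq_len(n), core)
  if (nrow(bonds)) {
    bonds[, 1L] <- remap[bonds[, 1L]]
    bonds[, 2L] <- remap[bonds[, 2L]]
  }
  key <- canonicalGraphKey(mol@elements[core], bonds,
                           mol@aromaticAtom[core], mol@formalCharge[core])
  list(core_key = key, core_hac = length(core), core_atoms = core)
}

#' Cluster molecules by unique conjugated core
#'
#' Groups molecules sharing a conjugated-core key and discards clusters
#' whose core has fewer than `minCoreHac` heavy atoms (limited
#' conjugation). Singleton clusters (one member) are reported
#' separately.
#'
#' @param mols list of [Molecule-class] objects (or a
#'   [ZindoDataset-class]).
#' @param minCoreHac minimum core heavy-atom count to retain (strict
#'   `< minCoreHac` discard).
#' @return list with `clusters` (list of `core_key`, `core_hac`,
#'   `member_ids`), `discarded` (ids whose core was too small),
#'   `singletons` (core keys with exactly one member).
#' @export
clusterUniqueCores <- function(mols, minCoreHac = 6L) {
  if (is(mols, "ZindoDataset")) mols <- mols@molecules
  ids <- unname(vapply(mols, function(m) m@id, character(1)))
  cores <- lapply(mols, extractConjugatedCore)
  keys <- vapply(cores, `[[`, character(1), "core_key")
  hacs <- vapply(cores, function(x) as.integer(x$core_hac), integer(1))
  keep <- hacs >= minCoreHac
  discarded <- ids[!keep]
  clusters <- list()
  for (k in unique(keys[keep])) {
    sel <- keep & keys == k
    clusters[[length(clusters) + 1L]] <-
      list(core_key = k, core_hac = hacs[sel][1L], member_ids = ids[sel])
  }
  singletons <- vapply(clusters, function(cl)
    length(cl$member_ids) == 1L, logical(1))
  list(clusters = clusters, discarded = discarded,
       singletons = vapply(clusters[singletons], `[[`, character(1),
                           "core_key"))
}

# Nitroso pattern on the bond graph: an N with exactly one double bond
# to O, no second O neighbor (which would make it nitro/nitrate/N-oxide)
# and at most one further heavy substituent.
.hasNitroso <- function(mol) {
  if (!nrow(mol@bonds)) return(FALSE)
  for (a in which(mol@elements == "N")) {
    sel <- which(mol@bonds[, 1L] == a | mol@bonds[, 2L] == a)
    nbr <- ifelse(mol@bonds[sel, 1L] == a, mol@bonds[sel, 2L],
                  mol@bonds[sel, 1L])
    ord <- mol@bonds[sel, 3L]
    oNbr <- mol@elements[nbr] == "O"
    if (sum(oNbr) != 1L) next
    if (ord[oNbr] != 2) next
    if (mol@aromaticAtom[a]) next
    return(TRUE)
  }
  FALSE
}

#' Filter training candidates
#'
#' Keeps molecules with (i) all heavy atoms in {C, N, O, S, F}, (ii) a
#' heavy-atom count between 10 and 25 inclusive, and (iii) no nitroso
#' (-N=O) group (nitroso compounds cluster around one S1 energy and
#' artificially inflate accuracy). Removal reasons are recorded per
#' molecule.
#'
#' @param mols list of [Molecule-class] objects (or a
#'   [ZindoDataset-class]).
#' @param hacRange inclusive heavy-atom-count bounds.
#' @param allowedElements permitted heavy elements.
#' @return list with `kept` (ids) and `removed` (data.frame of id,
#'   reason).
#' @export
filterTrainingCandidates <- function(mols, hacRange = c(10L, 25L),
                                     allowedElements = c("C", "N", "O",
                                                         "S", "F")) {
  if (is(mols, "ZindoDataset")) mols <- mols@molecules
  kept <- character(0)
  removed <- data.frame(molecule_id = character(), reason = character())
  for (m in mols) {
    heavyEl <- unique(m@elements[m@elements != "H"])
    reason <- NULL
    if (!all(heavyEl %in% allowedElements)) reason <- "element"
    else if (hac(m) < hacRange[1L] || hac(m) > hacRange[2L]) reason <- "hac"
    else if (.hasNitroso(m)) reason <- "nitroso"
    if (is.null(reason)) kept <- c(kept, m@id)
    else removed <- rbind(removed,
                          data.frame(molecule_id = m@id, reason = reason))
  }
  list(kept = kept, removed = removed)
}

#' Sample core-analogue test molecules
#'
#' For every training molecule, draws up to `maxPerCore` non-training
#' members of its conjugated-core cluster uniformly without replacement,
#' so each test molecule shares a core with exactly one training
#' molecule. Deterministic for a fixed seed.
#'
#' @param clusters output of [clusterUniqueCores()] (or its `clusters`
#'   element).
#' @param trainIds training molecule ids.
#' @param maxPerCore analogue cap per training molecule.
#' @param seed RNG seed.
#' @return character vector of sampled test ids.
#' @export
sampleCoreAnalogues <- function(clusters, trainIds, maxPerCore = 3L,
                                seed = 1L) {
  if (!is.null(clusters$clusters)) clusters <- clusters$clusters
  byId <- list()
  for (cl in clusters) for (id in cl$member_ids) byId[[id]] <- cl
  withRNG(seed, {
    testIds <- character(0)
    for (tid in trainIds) {
      cl <- byId[[tid]]
      if (is.null(cl)) next
      pool <- setdiff(cl$member_ids, c(trainIds, testIds))
      if (!length(pool)) next
      take <- min(maxPerCore, length(pool))
      testIds <- c(testIds, sample(pool, take))
    }
    testIds
  })
}

#' Ring-based external-set filter
#'
#' Keeps molecules with exactly 1 or 2 rings (smallest set of smallest
#' rings) none of which is an all-carbon nonaromatic (alicyclic) ring;
#' ring-free molecules are removed. Optionally restricts to an exact
#' heavy-atom count.
#'
#' @param mols list of [Molecule-class] objects (or a
#'   [ZindoDataset-class]).
#' @param exactHac require this exact heavy-atom count (`NULL` to skip).
#' @return list with `kept` and `removed` (data.frame of id, reason).
#' @export
qcdgeFilter <- function(mols, exactHac = NULL) {
  if (is(mols, "ZindoDataset")) mols <- mols@molecules
  kept <- character(0)
  removed <- data.frame(molecule_id = character(), reason = character())
  for (m in mols) {
    rings <- moleculeRings(m)
    reason <- NULL
    if (!is.null(exactHac) && hac(m) != exactHac) reason <- "hac"
    else if (length(rings) < 1L || length(rings) > 2L) reason <- "ring_count"
    else if (any(attr(rings, "carbocycle") & !attr(rings, "aromatic")))
      reason <- "alicyclic"
    if (is.null(reason)) kept <- c(kept, m@id)
    else removed <- rbind(removed,
                          data.frame(molecule_id = m@id, reason = reason))
  }
  list(kept = kept, removed = removed)
}

#' Parity train/test split over sorted ids
#'
#' Ids are sorted ascending (numerically when possible); odd positions
#' form the training set and even positions the testing set, so set
#' sizes differ by at most one.
#'
#' @param ids molecule ids (unique).
#' @return list with `train` and `test` id vectors.
#' @export
paritySplit <- function(ids) {
  if (anyDuplicated(ids)) stop("paritySplit: duplicate ids")
  num <- suppressWarnings(as.numeric(ids))
  ord <- if (!anyNA(num)) order(num) else order(ids)
  sorted <- ids[ord]
  pos <- seq_along(sorted)
  list(train = sorted[pos %% 2L == 1L], test = sorted[pos %% 2L == 0L])
}
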