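#' Residual between high- and low-level excitation energies
#'
#' The delta-learning target: `deltaE = eHigh - eLow` (eV), the residual
#' a correction model learns on top of the low-level (ZINDO) energy.
#'
#' @param eHigh,eLow numeric vectors of S1 energies in eV (recycled to a
#'   common length).
#' @return numeric vector of residuals in eV.
#' @export
residualDelta <- function(eHigh, eLow) {
  if (!all(is.finite(eHigh)) || !all(is.finite(eLow)))
    stop("residualDelta: inputs must be finite")
  eHigh - eLow
}

#' Construct a per-molecule electronic record
#'
#' Bundles the low-level (ZINDO) outputs for one molecule: the S1
#' energy, oscillator strength and the per-atom electronic descriptors.
#' HOMO populations are normalized to sum to 1 (so the MO-RDF magnitude
#' is comparable across molecules); particle and hole densities are
#' expected normalized already, as population analyses produce them.
#'
#' @param molecule_id molecule identifier.
#' @param e_s1_low low-level S1 energy, eV.
#' @param f_low low-level oscillator strength (dimensionless, >= 0);
#'   `NA` when unavailable (flagged, never defaulted to 0).
#' @param mulliken per-atom Mulliken charges (e).
#' @param potential per-atom atomic potentials (e/Angstrom).
#' @param n_elec,n_hole per-atom NTO particle/hole densities.
#' @param w_homo per-atom HOMO populations.
#' @param normalizeW normalize `w_homo` to unit sum (default TRUE).
#' @return a named list (the electronic record).
#' @export
electronicRecord <- function(molecule_id, e_s1_low, f_low = NA_real_,
                             mulliken = NULL, potential = NULL,
                             n_elec = NULL, n_hole = NULL, w_homo = NULL,
                             normalizeW = TRUE) {
  if (!is.finite(e_s1_low)) stop("e_s1_low must be finite")
  if (!is.na(f_low) && f_low < 0) stop("f_low must be >= 0")
  if (!is.null(w_homo) && normalizeW) {
    s <- sum(w_homo)
    if (s <= 0) stop("w_homo must have positive sum")
    w_homo <- w_homo / s
  }
  list(molecule_id = as.character(molecule_id),
       e_s1_low = as.numeric(e_s1_low), f_low = as.numeric(f_low),
       mulliken = mulliken, potential = potential,
       n_elec = n_elec, n_hole = n_hole, w_homo = w_homo)
}

#' Assemble a ZindoDataset from components
#'
#' @param molecules list of [Molecule-class] objects.
#' @param electronic list of electronic records ([electronicRecord()]).
#' @param targets data.frame with `molecule_id`, `e_s1_high` and
#'   optionally `f_high`; zero-row default for prediction-only datasets.
#' @return a validated [ZindoDataset-class].
#' @export
zindoDataset <- function(molecules, electronic = list(),
                         targets = data.frame(molecule_id = character(),
                                              e_s1_high = numeric(),
                                              f_high = numeric())) {
  names(molecules) <- vapply(molecules, function(m) m@id, character(1))
  if (length(electronic))
    names(electronic) <- vapply(electronic, `[[`, character(1), "molecule_id")
  if (nrow(targets) && !"f_high" %in% names(targets))
    targets$f_high <- NA_real_
  new("ZindoDataset", molecules = molecules, electronic = electronic,
      targets = targets)
}

#' @rdname zindoDataset
#' @param x a [ZindoDataset-class].
#' @export
datasetIds <- function(x) names(x@molecules)

#' @rdname zindoDataset
#' @export
molecules <- function(x) x@molecules

#' @rdname zindoDataset
#' @export
electronicRecords <- function(x) x@electronic

#' @rdname zindoDataset
#' @export
targetRecords <- function(x) x@targets

setMethod("show", "ZindoDataset", function(object) {
  cat("ZindoDataset: ", length(object@molecules), " molecules, ",
      length(object@electronic), " electronic records, ",
      nrow(object@targets), " targets\n", sep = "")
})

#' Subset a dataset by molecule ids
#'
#' @param x a [ZindoDataset-class].
#' @param i character vector of molecule ids.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "ZindoDataset", function(x, i, j, ..., drop = FALSE) {
  i <- as.character(i)
  missing_ids <- setdiff(i, datasetIds(x))
  if (length(missing_ids))
    stop("unknown molecule ids: ", paste(utils::head(missing_ids, 3), collapse = ", "))
  zindoDataset(x@molecules[i],
               x@electronic[intersect(i, names(x@electronic))],
               x@targets[x@targets$molecule_id %in% i, , drop = FALSE])
})

.SCHEMA_VERSION <- "1.0"

#' Write a dataset to the on-disk JSON schema
#'
#' Emits three JSON files under `dir`: `molecules.json` (full-precision
#' geometry, bonds and annotations), `electronic.json` and
#' `targets.json`, each carrying a `schema_version` field. All floats are
#' written at full precision so a read/write round trip is lossless to
#' 1e-12.
#'
#' @param dataset a [ZindoDataset-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  molPath <- file.path(dir, "molecules.json")
  elPath <- file.path(dir, "electronic.json")
  tgPath <- file.path(dir, "targets.json")
  mols <- lapply(dataset@molecules, function(m) {
    list(id = m@id, smiles = m@smiles, elements = m@elements,
         coords = unname(apply(m@coords, 1L, as.numeric, simplify = FALSE)),
         bonds = if (nrow(m@bonds))
           unname(apply(m@bonds, 1L, as.numeric, simplify = FALSE)) else list(),
         aromatic_atom = m@aromaticAtom, aromatic_bond = m@aromaticBond,
         formal_charge = m@formalCharge, n_h = m@nH)
  })
  jsonlite::write_json(list(schema_version = .SCHEMA_VERSION,
                            molecules = unname(mols)),
                       molPath, auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(list(schema_version = .SCHEMA_VERSION,
                            records = unname(dataset@electronic)),
                       elPath, auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(list(schema_version = .SCHEMA_VERSION,
                            records = dataset@targets),
                       tgPath, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(molPath, elPath, tgPath))
}

.readMoleculesJson <- function(path) {
  obj <- jsonlite::read_json(path)
  lapply(obj$molecules, function(m) {
    coords <- do.call(rbind, lapply(m$coords, unlist))
    bonds <- if (length(m$bonds)) do.call(rbind, lapply(m$bonds, unlist))
             else matrix(0, 0, 3)
    Molecule(id = m$id, elements = unlist(m$elements), coords = coords,
             bonds = bonds, smiles = if (is.null(m$smiles)) "" else m$smiles,
             aromaticAtom = unlist(m$aromatic_atom),
             aromaticBond = if (length(m$aromatic_bond))
               unlist(m$aromatic_bond) else logical(0),
             formalCharge = unlist(m$formal_charge), nH = unlist(m$n_h))
  })
}

# Multi-record XYZ reader (trivial whitespace format; ids from the
# comment line or the companion CSV).
.readXyz <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) stop("malformed XYZ at line ", i)
    comment <- trimws(lines[i + 1L])
    rows <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(rows), "\\s+")
    elements <- vapply(parts, `[[`, character(1), 1L)
    coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    out[[length(out) + 1L]] <- list(elements = elements, coords = coords,
                                    comment = comment)
    i <- i + 2L + n
  }
  out
}

.readMoleculeTable <- function(moleculeFile, tableFile = NULL) {
  ext <- tolower(tools::file_ext(moleculeFile))
  if (ext == "json") return(.readMoleculesJson(moleculeFile))
  tab <- NULL
  if (!is.null(tableFile)) {
    tab <- utils::read.csv(tableFile, stringsAsFactors = FALSE)
    if (!all(c("id", "smiles") %in% names(tab)))
      stop("molecule table must have columns id,smiles")
  }
  if (ext == "sdf") {
    sdfs <- ChemmineR::read.SDFset(moleculeFile)
    mols <- lapply(seq_along(sdfs), function(k) {
      id <- if (!is.null(tab)) tab$id[k] else paste0("mol", k)
      smiles <- if (!is.null(tab)) tab$smiles[k] else ""
      sdfToMolecule(sdfs[[k]], id = id, smiles = smiles)
    })
  } else if (ext == "xyz") {
    recs <- .readXyz(moleculeFile)
    mols <- lapply(seq_along(recs), function(k) {
      r <- recs[[k]]
      id <- if (!is.null(tab)) tab$id[k]
            else if (nzchar(r$comment)) r$comment else paste0("mol", k)
      smiles <- if (!is.null(tab)) tab$smiles[k] else ""
      Molecule(id = id, elements = r$elements, coords = r$coords,
               smiles = smiles)
    })
  } else stop("unsupported molecule file format: .", ext)
  mols
}

.readRecordsJson <- function(path, kind) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$schema_version))
    stop(kind, " file lacks schema_version: ", path)
  obj$records
}

#' Read and join a dataset from disk
#'
#' Loads molecules (native JSON schema, or SDF/XYZ plus an `id,smiles`
#' CSV table), the electronic-record JSON and optionally the target
#' JSON, joins them by molecule id and validates per-atom array lengths.
#' Records with missing required fields are dropped and reported in the
#' `dropReport` attribute, never silently imputed; structural contract
#' violations (per-atom array length mismatch, unknown elements) are
#' hard errors naming the record.
#'
#' @param moleculeFile path to `molecules.json`, an SDF or an XYZ file.
#' @param electronicFile path to the electronic-record JSON.
#' @param targetFile path to the target JSON, or `NULL` for
#'   prediction-only datasets.
#' @param moleculeTable optional CSV path with `id,smiles` rows matching
#'   the SDF/XYZ record order.
#' @return a [ZindoDataset-class] with attribute `dropReport`
#'   (data.frame of dropped ids and reasons).
#' @export
readDataset <- function(moleculeFile, electronicFile, targetFile = NULL,
                        moleculeTable = NULL) {
  mols <- .readMoleculeTable(moleculeFile, moleculeTable)
  names(mols) <- vapply(mols, function(m) m@id, character(1))
  recs <- .readRecordsJson(electronicFile, "electronic")
  electronic <- list()
  for (r in recs) {
    id <- r$molecule_id
    mol <- mols[[id]]
    if (is.null(mol)) next
    for (fld in c("mulliken", "potential", "n_elec", "n_hole", "w_homo")) {
      v <- r[[fld]]
      if (!is.null(v) && length(unlist(v)) != nAtoms(mol))
        stop("electronic record '", id, "': per-atom field '", fld,
             "' has length ", length(unlist(v)), " but the molecule has ",
             nAtoms(mol), " atoms")
    }
    electronic[[id]] <- electronicRecord(
      molecule_id = id, e_s1_low = r$e_s1_low,
      f_low = if (is.null(r$f_low)) NA_real_ else r$f_low,
      mulliken = if (!is.null(r$mulliken)) unlist(r$mulliken),
      potential = if (!is.null(r$potential)) unlist(r$potential),
      n_elec = if (!is.null(r$n_elec)) unlist(r$n_elec),
      n_hole = if (!is.null(r$n_hole)) unlist(r$n_hole),
      w_homo = if (!is.null(r$w_homo)) unlist(r$w_homo),
      normalizeW = FALSE)
  }
  targets <- data.frame(molecule_id = character(), e_s1_high = numeric(),
                        f_high = numeric())
  if (!is.null(targetFile)) {
    trecs <- .readRecordsJson(targetFile, "target")
    targets <- do.call(rbind, lapply(trecs, function(r)
      data.frame(molecule_id = r$molecule_id, e_s1_high = r$e_s1_high,
                 f_high = if (is.null(r$f_high)) NA_real_ else r$f_high)))
    if (is.null(targets))
      targets <- data.frame(molecule_id = character(),
                            e_s1_high = numeric(), f_high = numeric())
  }
  drop <- data.frame(molecule_id = character(), reason = character())
  keep <- names(mols)
  noElec <- setdiff(keep, names(electronic))
  if (length(noElec)) {
    drop <- rbind(drop, data.frame(molecule_id = noElec,
                                   reason = "missing_electronic"))
    keep <- setdiff(keep, noElec)
  }
  if (!is.null(targetFile)) {
    noTgt <- setdiff(keep, targets$molecule_id)
    if (length(noTgt)) {
      drop <- rbind(drop, data.frame(molecule_id = noTgt,
                                     reason = "missing_target"))
      keep <- setdiff(keep, noTgt)
    }
    targets <- targets[targets$molecule_id %in% keep, , drop = FALSE]
  }
  ds <- zindoDataset(mols[keep], electronic[keep], targets)
  attr(ds, "dropReport") <- drop
  ds
}

#' Export molecules to SDF (V2000)
#'
#' Writes the heavy-atom/explicit-H structures of a dataset or molecule
#' list to a multi-record SDF via ChemmineR. Coordinates are truncated to
#' the fixed-width V2000 precision; use the JSON schema for lossless
#' round trips.
#'
#' @param molecules list of [Molecule-class] objects (or a
#'   [ZindoDataset-class]).
#' @param path output SDF path.
#' @return invisibly, `path`.
#' @export
writeMoleculesSdf <- function(molecules, path) {
  if (is(molecules, "ZindoDataset")) molecules <- molecules@molecules
  sdfs <- lapply(molecules, moleculeToSDF)
  sdfset <- methods::new("SDFset", SDF = sdfs,
                         ID = vapply(molecules, function(m) m@id, character(1)))
  ChemmineR::write.SDF(sdfset, file = path)
  invisible(path)
}

#' Convert a Molecule to a ChemmineR SDF object
#'
#' @param mol a [Molecule-class].
#' @return a `ChemmineR::SDF`.
#' @export
moleculeToSDF <- function(mol) {
  n <- nAtoms(mol)
  ab <- cbind(round(mol@coords, 4),   # fixed-width V2000 precision
              matrix(0, n, 13,
                     dimnames = list(NULL, paste0("C", 4:16))))
  colnames(ab)[1:3] <- c("C1", "C2", "C3")
  rownames(ab) <- paste(mol@elements, seq_len(n), sep = "_")
  nb <- nrow(mol@bonds)
  bb <- if (nb) {
    # aromatic bonds exported as V2000 type 4 so downstream perception
    # (e.g. OpenBabel fingerprints) sees the aromatic system
    ord <- ifelse(mol@aromaticBond, 4, mol@bonds[, 3])
    m <- cbind(mol@bonds[, 1:2, drop = FALSE],
               matrix(ord, nb, 1),
               matrix(0, nb, 4))
    colnames(m) <- paste0("C", 1:7)
    rownames(m) <- as.character(seq_len(nb))
    m
  } else matrix(0, 0, 7, dimnames = list(NULL, paste0("C", 1:7)))
  header <- c(Molecule_Name = mol@id, Source = "zindoml", Comment = "",
              Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                    n, nb))
  methods::new("SDF", header = header, atomblock = ab, bondblock = bb,
               datablock = character(0))
}
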