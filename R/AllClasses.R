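#' @import methods
NULL

#' Molecule with explicit geometry and bond graph
#'
#' Central container for one molecule: per-atom element symbols, nuclear
#' charges, Cartesian coordinates (Angstrom), the bond list and the
#' chemically annotated flags (aromaticity, formal charge, implicit
#' hydrogen counts) that the featurizers and curation operators consume.
#' Hydrogens may be explicit (rows of their own) or implicit (counted in
#' `nH`); all per-atom descriptor arrays are indexed over the atoms that
#' are actually present.
#'
#' @slot id single molecule identifier.
#' @slot smiles SMILES string (may be empty for programmatically built
#'   structures).
#' @slot elements character vector of element symbols, one per atom.
#' @slot Z numeric nuclear charges (elementary charge units).
#' @slot coords numeric N x 3 matrix of Cartesian positions in Angstrom.
#' @slot bonds integer/numeric E x 3 matrix with columns `i`, `j`,
#'   `order` (1, 2 or 3; aromatic bonds carry their Kekule order).
#' @slot aromaticAtom logical per-atom aromaticity flags.
#' @slot aromaticBond logical per-bond aromaticity flags.
#' @slot formalCharge numeric per-atom formal charges.
#' @slot nH numeric per-atom implicit hydrogen counts.
#'
#' @export
setClass("Molecule",
  representation(
    id = "character",
    smiles = "character",
    elements = "character",
    Z = "numeric",
    coords = "matrix",
    bonds = "matrix",
    aromaticAtom = "logical",
    aromaticBond = "logical",
    formalCharge = "numeric",
    nH = "numeric"
  )
)

setValidity("Molecule", function(object) {
  n <- length(object@elements)
  msg <- character()
  if (length(object@id) != 1L) msg <- c(msg, "id must be a single string")
  if (length(object@Z) != n) msg <- c(msg, "Z length != atom count")
  if (nrow(object@coords) != n || ncol(object@coords) != 3L)
    msg <- c(msg, "coords must be an N x 3 matrix")
  if (length(object@aromaticAtom) != n)
    msg <- c(msg, "aromaticAtom length != atom count")
  if (length(object@formalCharge) != n)
    msg <- c(msg, "formalCharge length != atom count")
  if (length(object@nH) != n) msg <- c(msg, "nH length != atom count")
  if (nrow(object@bonds) > 0) {
    if (ncol(object@bonds) != 3L) msg <- c(msg, "bonds must have 3 columns")
    idx <- c(object@bonds[, 1L], object@bonds[, 2L])
    if (any(idx < 1 | idx > n)) msg <- c(msg, "bond endpoint out of range")
    if (length(object@aromaticBond) != nrow(object@bonds))
      msg <- c(msg, "aromaticBond length != bond count")
  }
  if (n > 1L) {
    d <- stats::dist(object@coords)
    if (any(d <= 0)) msg <- c(msg, "coincident atoms (zero pairwise distance)")
  }
  if (length(msg)) msg else TRUE
})

#' Joined molecular/electronic/target dataset
#'
#' Holds one [Molecule] per id together with the low-level electronic
#' record (ZINDO S1 energy, oscillator strength, per-atom Mulliken
#' charges, atomic potentials, particle/hole densities and HOMO
#' populations) and, optionally, the high-level target record (TDDFT S1
#' energy and oscillator strength).
#'
#' @slot molecules named list of [Molecule] objects.
#' @slot electronic named list of electronic records (see
#'   [electronicRecord()]).
#' @slot targets data.frame with columns `molecule_id`, `e_s1_high`,
#'   `f_high` (may have zero rows for prediction-only datasets).
#'
#' @export
setClass("ZindoDataset",
  representation(
    molecules = "list",
    electronic = "list",
    targets = "data.frame"
  )
)

setValidity("ZindoDataset", function(object) {
  msg <- character()
  ids <- names(object@molecules)
  if (length(ids) && any(ids == "")) msg <- c(msg, "molecules must be named by id")
  if (length(object@electronic)) {
    bad <- setdiff(names(object@electronic), ids)
    if (length(bad))
      msg <- c(msg, paste0("electronic records for unknown ids: ",
                           paste(utils::head(bad, 3), collapse = ", ")))
    for (id in names(object@electronic)) {
      rec <- object@electronic[[id]]
      mol <- object@molecules[[id]]
      if (is.null(mol)) next
      na <- length(mol@elements)
      for (fld in c("mulliken", "potential", "n_elec", "n_hole", "w_homo")) {
        v <- rec[[fld]]
        if (!is.null(v) && length(v) != na) {
          msg <- c(msg, paste0("electronic field '", fld, "' of '", id,
                               "' has length ", length(v),
                               " but molecule has ", na, " atoms"))
          break
        }
      }
      for (fld in c("n_elec", "n_hole", "w_homo")) {
        v <- rec[[fld]]
        if (is.null(v)) next
        if (any(v < -1e-9)) {
          msg <- c(msg, paste0("negative ", fld, " entries in '", id, "'"))
        } else if (abs(sum(v) - 1) > 1e-6) {
          msg <- c(msg, paste0(fld, " of '", id, "' does not sum to 1"))
        }
      }
    }
  }
  if (nrow(object@targets)) {
    need <- c("molecule_id", "e_s1_high")
    if (!all(need %in% names(object@targets)))
      msg <- c(msg, "targets must have molecule_id and e_s1_high columns")
  }
  if (length(msg)) msg else TRUE
})

#' Sampling grid for the MO-weighted radial distribution function
#'
#' The descriptor is evaluated on an inclusive regular grid from `rMin`
#' to `rMax` in steps of `step`, smoothing each pair distance with a
#' normalized Gaussian of width `sigma`. The defaults (0.5 to 15 Angstrom
#' in 0.02 Angstrom steps, sigma 0.05 Angstrom) give a 726-point vector.
#'
#' @slot rMin,rMax grid range in Angstrom (both ends included).
#' @slot step grid spacing in Angstrom.
#' @slot sigma Gaussian smoothing width in Angstrom.
#'
#' @export
setClass("MoRdfGrid",
  representation(rMin = "numeric", rMax = "numeric",
                 step = "numeric", sigma = "numeric")
)

setValidity("MoRdfGrid", function(object) {
  msg <- character()
  if (object@step <= 0) msg <- c(msg, "step must be > 0")
  if (object@sigma <= 0) msg <- c(msg, "sigma must be > 0")
  if (object@rMax <= object@rMin) msg <- c(msg, "rMax must exceed rMin")
  if (length(msg)) msg else TRUE
})

#' Model variant specification
#'
#' Describes which descriptor branches compose a named model variant,
#' using the "component(descriptor)" naming convention, e.g.
#' `"Dense(MPNN(DA, EA), E_ZINDO, MO-RDF)"` or `"Linear(E_ZINDO)"`.
#'
#' @slot name canonical variant name (round-trips through
#'   [parseVariant()] / [variantName()]).
#' @slot useEncoder use the message-passing encoder branch.
#' @slot ea augment node features with the four electronic atom terms.
#' @slot useEZindo include the ZINDO S1 energy (dense input plus the
#'   residual connection).
#' @slot useMoRdf include the MO-RDF descriptor branch.
#' @slot useMfp include the Morgan fingerprint branch.
#' @slot linearOnly plain linear baseline (no network).
#' @slot dense list describing the final dense block (layer sizes,
#'   dropout, batch normalization, activation).
#' @slot encoder list of encoder hyperparameters (hiddenDim,
#'   fingerprintDim, atomSteps, molSteps).
#'
#' @export
setClass("VariantSpec",
  representation(
    name = "character",
    useEncoder = "logical",
    ea = "logical",
    useEZindo = "logical",
    useMoRdf = "logical",
    useMfp = "logical",
    linearOnly = "logical",
    dense = "list",
    encoder = "list"
  )
)

setValidity("VariantSpec", function(object) {
  msg <- character()
  if (!object@linearOnly &&
      !(object@useEncoder || object@useEZindo || object@useMoRdf || object@useMfp))
    msg <- c(msg, "at least one input source must be enabled")
  if (object@ea && !object@useEncoder)
    msg <- c(msg, "EA descriptors require the encoder branch")
  d <- object@dense
  if (!object@linearOnly) {
    if (any(d$layerSizes <= 0)) msg <- c(msg, "dense layer sizes must be positive")
    if (d$dropout < 0 || d$dropout >= 1) msg <- c(msg, "dropout must be in [0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' Training configuration
#'
#' Hyperparameters of per-fold training: k-fold count, Adam learning
#' rate, batch size, epoch cap, triangular cyclical learning-rate
#' schedule and early stopping on validation MAE.
#'
#' @slot k number of cross-validation folds.
#' @slot lr base learning rate.
#' @slot batchSize minibatch size.
#' @slot maxEpochs epoch cap per fold.
#' @slot cyclicalLr use the triangular cyclical schedule between lr/10
#'   and lr.
#' @slot cyclePeriod cycle length in epochs.
#' @slot earlyStopping stop when validation MAE has not improved for
#'   `patience` epochs.
#' @slot patience early-stopping patience in epochs.
#' @slot baseSeed base RNG seed; fold f uses baseSeed + f.
#'
#' @export
setClass("TrainConfig",
  representation(
    k = "numeric", lr = "numeric", batchSize = "numeric",
    maxEpochs = "numeric", cyclicalLr = "logical", cyclePeriod = "numeric",
    earlyStopping = "logical", patience = "numeric", baseSeed = "numeric"
  )
)

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@k < 2) msg <- c(msg, "k must be >= 2")
  if (object@lr <= 0) msg <- c(msg, "lr must be > 0")
  if (object@batchSize < 1) msg <- c(msg, "batchSize must be >= 1")
  if (object@maxEpochs < 1) msg <- c(msg, "maxEpochs must be >= 1")
  if (length(msg)) msg else TRUE
})
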