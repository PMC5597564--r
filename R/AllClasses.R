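## S4 containers for the docking engine.  Coordinates are Angstrom throughout,
## right-handed axes, 0-based atom serials on file mapped to 1-based row
## indices in memory (R convention).

#' LigandTopology: a ligand template with its rotatable-bond tree
#'
#' Immutable description of a ligand: reference (input) conformation, bond
#' list, and the torsion tree rooted at the PDBQT ROOT block.  Each torsion is
#' a rotatable bond `axis = c(a, b)` together with the set of atoms distal to
#' the bond (`moved`), which are the only atoms displaced when that torsion
#' gene changes.
#'
#' @slot atoms data.frame with one row per atom: `name`, `element`, `type`
#'   (AutoDock atom type code), `charge` (partial charge, e), `resName`,
#'   `resSeq`.
#' @slot refCoords numeric matrix (n x 3), the template conformation (A).
#' @slot bonds integer matrix (m x 2) of 1-based atom index pairs.
#' @slot torsions list of `list(axis = c(a, b), moved = <int>, parent = k)`
#'   in depth-first PDBQT record order; `parent` is the index of the enclosing
#'   branch (0 for branches hanging off the ROOT block).
#' @slot torsdof integer, torsional degrees of freedom as declared by TORSDOF
#'   (defaults to the number of branches).
#' @slot rootAtoms integer vector, atoms of the rigid ROOT block.
#' @exportClass LigandTopology
setClass("LigandTopology",
  representation(
    atoms     = "data.frame",
    refCoords = "matrix",
    bonds     = "matrix",
    torsions  = "list",
    torsdof   = "integer",
    rootAtoms = "integer"
  )
)

setValidity("LigandTopology", function(object) {
  n <- nrow(object@refCoords)
  msg <- character()
  if (n < 1L) msg <- c(msg, "ligand must contain at least one atom")
  if (!all(is.finite(object@refCoords))) msg <- c(msg, "non-finite coordinates")
  if (ncol(object@refCoords) != 3L) msg <- c(msg, "refCoords must be n x 3")
  if (nrow(object@atoms) != n) msg <- c(msg, "atoms table and refCoords disagree")
  if (length(object@rootAtoms) < 1L || any(object@rootAtoms < 1L | object@rootAtoms > n))
    msg <- c(msg, "invalid ROOT atom indices")
  if (length(object@bonds) && (any(object@bonds < 1L | object@bonds > n)))
    msg <- c(msg, "bond indices out of range")
  for (k in seq_along(object@torsions)) {
    tor <- object@torsions[[k]]
    if (!all(c("axis", "moved") %in% names(tor))) {
      msg <- c(msg, sprintf("torsion %d lacks axis/moved", k)); next
    }
    if (any(tor$axis %in% tor$moved))
      msg <- c(msg, sprintf("torsion %d moves one of its own axis atoms", k))
    if (any(tor$moved %in% object@rootAtoms))
      msg <- c(msg, sprintf("torsion %d moves a ROOT atom", k))
    p <- tor$parent
    if (!is.null(p) && p > 0L) {
      par <- object@torsions[[p]]
      if (!all(tor$moved %in% par$moved))
        msg <- c(msg, sprintf("torsion %d not nested inside its parent", k))
    }
  }
  if (length(msg)) msg else TRUE
})

#' ReceptorModel: a rigid receptor and its search box
#'
#' @slot atoms data.frame as in [LigandTopology-class].
#' @slot coords numeric matrix (n x 3), A.
#' @slot boxCenter numeric length-3, center of the search box (A).
#' @slot boxHalf numeric length-3, positive half-extents of the box (A).
#' @exportClass ReceptorModel
setClass("ReceptorModel",
  representation(
    atoms     = "data.frame",
    coords    = "matrix",
    boxCenter = "numeric",
    boxHalf   = "numeric"
  )
)

setValidity("ReceptorModel", function(object) {
  msg <- character()
  if (nrow(object@coords) != nrow(object@atoms))
    msg <- c(msg, "atoms table and coords disagree")
  if (nrow(object@coords) && !all(is.finite(object@coords)))
    msg <- c(msg, "non-finite coordinates")
  if (length(object@boxCenter) != 3L || length(object@boxHalf) != 3L)
    msg <- c(msg, "box center/half-extent must be length 3")
  if (any(!is.finite(object@boxHalf)) || any(object@boxHalf <= 0))
    msg <- c(msg, "box half-extents must be positive")
  if (length(msg)) msg else TRUE
})

#' EnergyModel: parameters of the semi-empirical pairwise scoring function
#'
#' Holds the per-atom-type table (12-6 well depth/radius, hydrogen-bond 12-10
#' parameters, solvation volume and parameter) plus the global term weights,
#' the sigmoidal distance-dependent dielectric constants, the nonbonded
#' cutoff, and the short-range clash clamp.
#'
#' @slot typeTable data.frame with columns `type`, `Rii` (A), `epsii`
#'   (kcal/mol), `vol` (A^3), `solpar`, `hb` ("", "D" donor, "A" acceptor),
#'   `hbRij` (A), `hbEps` (kcal/mol).
#' @slot weights named numeric: `vdw`, `hbond`, `elec`, `desolv`, `tor`.
#' @slot cutoff nonbonded cutoff (A); pairs beyond it contribute exactly 0.
#' @slot clashDist distances below this (A) are clamped; a linear penalty of
#'   `clashSlope` per A of overlap is added, so energies stay finite.
#' @slot clashSlope linear clash penalty slope (kcal/mol per A).
#' @slot dielectric named numeric constants of the Mehler-Solmajer sigmoidal
#'   dielectric: `eps0`, `A`, `lambda`, `k`.
#' @slot qsolpar charge-dependent addition to the atomic solvation parameter.
#' @slot sigma Gaussian desolvation range (A).
#' @slot elecScale Coulomb conversion factor (kcal A / mol e^2).
#' @exportClass EnergyModel
setClass("EnergyModel",
  representation(
    typeTable  = "data.frame",
    weights    = "numeric",
    cutoff     = "numeric",
    clashDist  = "numeric",
    clashSlope = "numeric",
    dielectric = "numeric",
    qsolpar    = "numeric",
    sigma      = "numeric",
    elecScale  = "numeric"
  )
)

setValidity("EnergyModel", function(object) {
  msg <- character()
  need <- c("type", "Rii", "epsii", "vol", "solpar", "hb", "hbRij", "hbEps")
  if (!all(need %in% names(object@typeTable)))
    msg <- c(msg, "typeTable lacks required columns")
  if (!all(c("vdw", "hbond", "elec", "desolv", "tor") %in% names(object@weights)))
    msg <- c(msg, "weights must name vdw, hbond, elec, desolv, tor")
  if (!all(is.finite(object@weights))) msg <- c(msg, "non-finite weights")
  if (length(object@cutoff) != 1L || object@cutoff <= 0)
    msg <- c(msg, "cutoff must be a positive scalar")
  if (any(object@typeTable$Rii <= 0) || any(object@typeTable$epsii < 0))
    msg <- c(msg, "Rii must be positive and epsii non-negative")
  if (length(msg)) msg else TRUE
})

#' DockingRun: the result of one seeded search run
#'
#' @slot algorithm label, e.g. "cepga" or "ga".
#' @slot seed integer RNG seed of the run.
#' @slot bestGenome best genome ever evaluated.
#' @slot bestEnergy its energy (scoring units).
#' @slot finalRmsd heavy-atom RMSD (A) of the best pose against the reference
#'   coordinates, or NA when the context carries no reference.
#' @slot evaluations total objective evaluations consumed.
#' @slot generations generations completed.
#' @slot trace data.frame (`neval`, `energy`): best-so-far improvements;
#'   `energy` strictly decreasing, `neval` strictly increasing.
#' @exportClass DockingRun
setClass("DockingRun",
  representation(
    algorithm   = "character",
    seed        = "integer",
    bestGenome  = "numeric",
    bestEnergy  = "numeric",
    finalRmsd   = "numeric",
    evaluations = "integer",
    generations = "integer",
    trace       = "data.frame"
  )
)

setValidity("DockingRun", function(object) {
  msg <- character()
  tr <- object@trace
  if (!all(c("neval", "energy") %in% names(tr)))
    msg <- c(msg, "trace must have columns neval, energy")
  if (nrow(tr) > 1L) {
    if (any(diff(tr$energy) >= 0)) msg <- c(msg, "trace energies not strictly decreasing")
    if (any(diff(tr$neval) <= 0)) msg <- c(msg, "trace neval not strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "LigandTopology", function(object) {
  cat(sprintf("LigandTopology: %d atoms (%d heavy), %d bonds, %d torsions (TORSDOF %d)\n",
              nrow(object@atoms), length(heavyAtoms(object)), nrow(object@bonds),
              length(object@torsions), object@torsdof))
  cat(sprintf("  ROOT block: %d atoms\n", length(object@rootAtoms)))
})

setMethod("show", "ReceptorModel", function(object) {
  cat(sprintf("ReceptorModel: %d atoms\n", nrow(object@coords)))
  cat(sprintf("  search box center (%.2f, %.2f, %.2f) A, half-extent (%.2f, %.2f, %.2f) A\n",
              object@boxCenter[1], object@boxCenter[2], object@boxCenter[3],
              object@boxHalf[1], object@boxHalf[2], object@boxHalf[3]))
})

setMethod("show", "EnergyModel", function(object) {
  w <- object@weights
  cat(sprintf("EnergyModel: %d atom types; weights vdw=%.4f hbond=%.4f elec=%.4f desolv=%.4f tor=%.4f\n",
              nrow(object@typeTable), w["vdw"], w["hbond"], w["elec"], w["desolv"], w["tor"]))
  cat(sprintf("  cutoff %.1f A, clash clamp below %.2f A\n", object@cutoff, object@clashDist))
})

setMethod("show", "DockingRun", function(object) {
  cat(sprintf("DockingRun [%s, seed %d]: best energy %.4f after %d evaluations (%d generations)\n",
              object@algorithm, object@seed, object@bestEnergy,
              object@evaluations, object@generations))
  if (is.finite(object@finalRmsd))
    cat(sprintf("  RMSD vs reference: %.3f A (%s)\n", object@finalRmsd,
                if (isValidPose(object@finalRmsd)) "valid, < 2.0 A" else "invalid, >= 2.0 A"))
})

## ---- generics & accessors -------------------------------------------------

#' Number of rotatable bonds of a ligand
#' @param x a [LigandTopology-class]
#' @return integer
#' @export
setGeneric("nTorsions", function(x) standardGeneric("nTorsions"))

#' @rdname nTorsions
#' @export
setMethod("nTorsions", "LigandTopology", function(x) length(x@torsions))

#' Number of atoms
#' @param x a [LigandTopology-class] or [ReceptorModel-class]
#' @return integer
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "LigandTopology", function(x) nrow(x@refCoords))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "ReceptorModel", function(x) nrow(x@coords))

#' Atom table of a molecule
#' @param x a [LigandTopology-class] or [ReceptorModel-class]
#' @return data.frame
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' @rdname atomData
#' @export
setMethod("atomData", "LigandTopology", function(x) x@atoms)

#' @rdname atomData
#' @export
setMethod("atomData", "ReceptorModel", function(x) x@atoms)

#' Reference coordinates (template conformation / receptor coordinates)
#' @param x a [LigandTopology-class] or [ReceptorModel-class]
#' @return numeric matrix (n x 3), A
#' @export
setGeneric("refCoords", function(x) standardGeneric("refCoords"))

#' @rdname refCoords
#' @export
setMethod("refCoords", "LigandTopology", function(x) x@refCoords)

#' @rdname refCoords
#' @export
setMethod("refCoords", "ReceptorModel", function(x) x@coords)

#' Search box of a receptor
#' @param x a [ReceptorModel-class]
#' @return list with `center` and `half` (A)
#' @export
setGeneric("searchBox", function(x) standardGeneric("searchBox"))

#' @rdname searchBox
#' @export
setMethod("searchBox", "ReceptorModel", function(x)
  list(center = x@boxCenter, half = x@boxHalf))

#' Best energy / best genome / trace of a run
#' @param x a [DockingRun-class]
#' @return scalar, numeric vector, or data.frame respectively
#' @export
setGeneric("bestEnergy", function(x) standardGeneric("bestEnergy"))

#' @rdname bestEnergy
#' @export
setMethod("bestEnergy", "DockingRun", function(x) x@bestEnergy)

#' @rdname bestEnergy
#' @export
setGeneric("bestGenome", function(x) standardGeneric("bestGenome"))

#' @rdname bestEnergy
#' @export
setMethod("bestGenome", "DockingRun", function(x) x@bestGenome)

#' @rdname bestEnergy
#' @export
setGeneric("runTrace", function(x) standardGeneric("runTrace"))

#' @rdname bestEnergy
#' @export
setMethod("runTrace", "DockingRun", function(x) x@trace)

#' @rdname bestEnergy
#' @export
setGeneric("finalRmsd", function(x) standardGeneric("finalRmsd"))

#' @rdname bestEnergy
#' @export
setMethod("finalRmsd", "DockingRun", function(x) x@finalRmsd)

#' Indices of heavy (non-hydrogen) atoms
#' @param x a [LigandTopology-class]
#' @return integer vector of atom indices
#' @export
heavyAtoms <- function(x) which(x@atoms$element != "H")

#' Construct a LigandTopology
#'
#' Low-level constructor; [readLigandPdbqt()] and [makeFixture()] are the
#' usual entry points.
#'
#' @param atoms data.frame (`name`, `element`, `type`, `charge`, optionally
#'   `resName`, `resSeq`).
#' @param coords n x 3 matrix (A).
#' @param bonds m x 2 integer matrix.
#' @param torsions list of `list(axis, moved, parent)`.
#' @param rootAtoms integer vector of ROOT-block atoms.
#' @param torsdof TORSDOF override; defaults to `length(torsions)`.
#' @return a validated [LigandTopology-class]
#' @export
LigandTopology <- function(atoms, coords, bonds = matrix(integer(), 0, 2),
                           torsions = list(), rootAtoms = seq_len(nrow(coords)),
                           torsdof = length(torsions)) {
  atoms <- normalizeAtomTable(atoms)
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  storage.mode(bonds) <- "integer"
  torsions <- lapply(torsions, function(t) {
    t$axis <- as.integer(t$axis); t$moved <- as.integer(t$moved)
    t$parent <- as.integer(if (is.null(t$parent)) 0L else t$parent)
    t
  })
  new("LigandTopology", atoms = atoms, refCoords = coords,
      bonds = matrix(bonds, ncol = 2), torsions = torsions,
      torsdof = as.integer(torsdof), rootAtoms = as.integer(rootAtoms))
}

#' Construct a ReceptorModel
#'
#' @param atoms data.frame as for [LigandTopology()].
#' @param coords n x 3 matrix (A).
#' @param boxCenter,boxHalf search box (A); default box: coordinate bounding
#'   box padded by 4 A.
#' @return a validated [ReceptorModel-class]
#' @export
ReceptorModel <- function(atoms, coords, boxCenter = NULL, boxHalf = NULL) {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  if (is.null(boxCenter) || is.null(boxHalf)) {
    if (!nrow(coords)) stop("an empty receptor needs an explicit search box")
    lo <- apply(coords, 2, min) - 4; hi <- apply(coords, 2, max) + 4
    boxCenter <- (lo + hi) / 2; boxHalf <- (hi - lo) / 2
  }
  new("ReceptorModel", atoms = normalizeAtomTable(atoms), coords = coords,
      boxCenter = as.numeric(boxCenter), boxHalf = as.numeric(boxHalf))
}

normalizeAtomTable <- function(atoms) {
  atoms <- as.data.frame(atoms)
  n <- nrow(atoms)
  if (is.null(atoms$name)) atoms$name <- paste0(atoms$element, seq_len(n))
  if (is.null(atoms$element)) atoms$element <- typeToElement(atoms$type)
  if (is.null(atoms$charge)) atoms$charge <- rep(0, n)
  if (is.null(atoms$resName)) atoms$resName <- rep("LIG", n)
  if (is.null(atoms$resSeq)) atoms$resSeq <- rep(1L, n)
  rownames(atoms) <- NULL
  atoms[c("name", "element", "type", "charge", "resName", "resSeq")]
}
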