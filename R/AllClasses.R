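#' @include filadyn-package.R
NULL

.atomColumns <- c("type", "eleno", "elety", "resid", "chain", "resno",
                  "insert", "x", "y", "z", "o", "b", "elesy")

#' Atomic structure
#'
#' A hierarchical atomic model (chains > residues > atoms) stored as a flat
#' atom table in the column layout used by PDB records: record type
#' (ATOM/HETATM), atom serial, atom name, residue name, chain id, author
#' residue number, insertion code, coordinates in Angstrom, occupancy,
#' B-factor and element symbol. Residue identity is (chain, resno, insert)
#' with author numbering preserved from the input.
#'
#' @slot atoms a \code{data.frame} with columns
#'   \code{type, eleno, elety, resid, chain, resno, insert, x, y, z, o, b, elesy}.
#' @seealso [readStructure()], [extractCA()]
#' @exportClass Structure
setClass("Structure", representation(atoms = "data.frame"))

setValidity("Structure", function(object) {
  a <- object@atoms
  if (!all(.atomColumns %in% names(a)))
    return(paste("atom table must contain columns:",
                 paste(.atomColumns, collapse = ", ")))
  if (nrow(a) == 0) return("empty structure: no atoms")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite atom coordinates")
  TRUE
})

#' Rigid-body transform
#'
#' Proper rotation (3x3, det +1) plus translation (Angstrom). Apply with
#' [applyTransform()]; invert with [invertTransform()].
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation numeric(3), Angstrom.
#' @exportClass RigidTransform
setClass("RigidTransform",
         representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (length(object@translation) != 3) return("translation must be length 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    return("rotation columns not orthonormal")
  if (det(R) < 0) return("rotation is improper (det < 0)")
  TRUE
})

#' Native-contact list
#'
#' Residue-bead pairs within the native-contact cutoff, with their reference
#' (native) distances. Pairs are stored once with \code{i < j}; intra-chain
#' pairs closer in sequence than \code{minSeqSep} are excluded.
#'
#' @slot pairs data.frame with columns \code{i, j, d0} (bead indices, native
#'   distance in Angstrom).
#' @slot cutoff contact cutoff in Angstrom.
#' @slot minSeqSep minimum intra-chain sequence separation.
#' @slot nBeads number of beads the indices refer to.
#' @exportClass ContactList
setClass("ContactList",
         representation(pairs = "data.frame", cutoff = "numeric",
                        minSeqSep = "integer", nBeads = "integer"))

setValidity("ContactList", function(object) {
  p <- object@pairs
  if (!all(c("i", "j", "d0") %in% names(p))) return("pairs needs i, j, d0")
  if (nrow(p) > 0) {
    if (any(p$i >= p$j)) return("pairs must have i < j")
    if (any(p$d0 > object@cutoff + 1e-9)) return("d0 exceeds cutoff")
    if (anyDuplicated(p[, c("i", "j")])) return("duplicate pairs")
  }
  if (object@cutoff <= 0) return("cutoff must be positive")
  TRUE
})

#' Ordered residue selection
#'
#' An ordered set of residues addressed by (chain, residue number), labelled
#' by its role (pocket, interface or custom).
#'
#' @slot ids data.frame with columns \code{chain, resno} (and optionally
#'   \code{resid}, the 3-letter residue name).
#' @slot label one of \code{"pocket"}, \code{"interface"}, \code{"custom"}.
#' @exportClass ResidueSet
setClass("ResidueSet",
         representation(ids = "data.frame", label = "character"))

setValidity("ResidueSet", function(object) {
  ids <- object@ids
  if (!all(c("chain", "resno") %in% names(ids)))
    return("ids needs chain and resno columns")
  if (anyDuplicated(ids[, c("chain", "resno")])) return("duplicate residue ids")
  if (!object@label %in% c("pocket", "interface", "custom"))
    return("label must be pocket, interface or custom")
  TRUE
})

#' Go model for discrete molecular dynamics
#'
#' One bead per residue at the native C-alpha position. Bonded neighbours are
#' held in a hard distance window around the native bond length; native
#' contacts feel a single square well centred on the native distance; all
#' remaining pairs interact through hardcore repulsion. Reduced units: bead
#' mass 1, well depth \code{epsilon} = 1, kB = 1.
#'
#' @slot coords native bead coordinates (N x 3, Angstrom).
#' @slot bonds data.frame \code{i, j, length} of bonded neighbours.
#' @slot contacts a [ContactList-class] of attractive native pairs.
#' @slot beadInfo data.frame \code{chain, resno, resid} per bead.
#' @slot params list: \code{epsilon}, \code{wellLow}, \code{wellHigh}
#'   (well boundaries as fractions of the native distance), \code{hardcore}
#'   (Angstrom), \code{bondLow}, \code{bondHigh} (bond window fractions).
#' @exportClass GoModel
setClass("GoModel",
         representation(coords = "matrix", bonds = "data.frame",
                        contacts = "ContactList", beadInfo = "data.frame",
                        params = "list"))

setValidity("GoModel", function(object) {
  if (ncol(object@coords) != 3) return("coords must be N x 3")
  b <- object@bonds
  cp <- object@contacts@pairs
  if (nrow(b) > 0 && nrow(cp) > 0) {
    key <- function(d) paste(pmin(d$i, d$j), pmax(d$i, d$j))
    if (any(key(b) %in% key(cp)))
      return("bonded pairs must not appear in the contact list")
  }
  if (nrow(cp) > 0 &&
      any(object@params$wellLow * cp$d0 <= 0))
    return("contact inner wall must be positive")
  TRUE
})

#' DMD trajectory
#'
#' Snapshots of an event-driven run: bead coordinates, total and kinetic
#' energy per frame, with the run metadata (seed, temperature, step counts)
#' needed to reproduce it exactly.
#'
#' @slot frames list of N x 3 coordinate matrices.
#' @slot step DMD step index of each frame.
#' @slot energy total energy per frame (reduced units).
#' @slot kinetic kinetic energy per frame.
#' @slot meta list of run metadata (seed, temperature, nSteps,
#'   snapshotEvery, thermostatRate, nEvents).
#' @exportClass Trajectory
setClass("Trajectory",
         representation(frames = "list", step = "numeric", energy = "numeric",
                        kinetic = "numeric", meta = "list"))

setValidity("Trajectory", function(object) {
  if (length(object@frames) != length(object@step))
    return("frame count must match step vector")
  if (!all(vapply(object@frames,
                  function(f) all(is.finite(f)), logical(1))))
    return("non-finite coordinates in trajectory")
  TRUE
})

#' Gaussian-network-model mode spectrum
#'
#' Eigendecomposition of the Kirchhoff (connectivity) matrix. Eigenvalues are
#' ascending; modes with eigenvalue below \code{zeroTol} are rigid-body /
#' disconnection modes and are excluded from analysis indices. The amplitude
#' of non-zero mode k is 1/lambda_k.
#'
#' @slot values all eigenvalues, ascending.
#' @slot vectors matching eigenvectors (one scalar component per node).
#' @slot nZero number of zero modes (one per connected component).
#' @slot zeroTol eigenvalue tolerance used to flag zero modes.
#' @slot cutoff contact cutoff (Angstrom) used to build the network.
#' @exportClass ModeSpectrum
setClass("ModeSpectrum",
         representation(values = "numeric", vectors = "matrix",
                        nZero = "integer", zeroTol = "numeric",
                        cutoff = "numeric"))

#' Per-mode inter-residue dynamic correlation
#'
#' For one normal mode and one residue set: the correlation matrix
#' \eqn{c_{ij} = u_i u_j / \sqrt{u_i u_i \times u_j u_j}} (sign concordance of
#' the mode shape over the set) and its mean C over distinct pairs. C = 1
#' means the set moves fully in phase (no deformation in that mode).
#'
#' @slot mode non-zero mode index (1 = lowest internal mode).
#' @slot lambda the mode eigenvalue.
#' @slot cmat correlation matrix over the set (NA where the component is
#'   numerically zero).
#' @slot correlation mean over distinct pairs.
#' @exportClass ModeCorrelation
setClass("ModeCorrelation",
         representation(mode = "integer", lambda = "numeric",
                        cmat = "matrix", correlation = "numeric"))

#' Screw (helical) parameters of a rigid transform
#'
#' Decomposition of a rigid motion into rotation by \code{twist} degrees about
#' a \code{axis} through \code{point}, plus \code{rise} Angstrom of
#' translation along the axis. \code{repeatsPerTurn = 360 / twist}.
#' Handedness is the sign of the twist about the axis once the rise is forced
#' non-negative (+1 = right-handed).
#'
#' @slot twist degrees in (0, 180].
#' @slot axis unit 3-vector.
#' @slot point a point on the axis.
#' @slot rise Angstrom per repeat along the axis (>= 0).
#' @slot repeatsPerTurn 360 / twist.
#' @slot handedness +1 (right) or -1 (left).
#' @exportClass ScrewParameters
setClass("ScrewParameters",
         representation(twist = "numeric", axis = "numeric", point = "numeric",
                        rise = "numeric", repeatsPerTurn = "numeric",
                        handedness = "numeric"))

setValidity("ScrewParameters", function(object) {
  if (abs(sqrt(sum(object@axis^2)) - 1) > 1e-8) return("axis must be unit")
  if (object@twist <= 0 || object@twist > 180 + 1e-9)
    return("twist must lie in (0, 180]")
  TRUE
})

#' Filament model
#'
#' n copies of an asymmetric unit, copy k being the generating transform
#' applied k times. Materialize all copies with [filamentStructure()].
#'
#' @slot unit the asymmetric unit ([Structure-class]).
#' @slot transform the generating [RigidTransform-class].
#' @slot nUnits number of copies (copy 0 = the unit itself).
#' @exportClass FilamentModel
setClass("FilamentModel",
         representation(unit = "Structure", transform = "RigidTransform",
                        nUnits = "integer"))

#' Buried-interface report
#'
#' PISA-style interface characterization: the buried interface area is half
#' the difference between the summed accessible surface areas of the isolated
#' partners and of the complex, with per-residue buried areas for both
#' partners.
#'
#' @slot area buried interface area (Angstrom^2).
#' @slot perResidue data.frame \code{partner, chain, resno, resid,
#'   areaIsolated, areaComplex, buried}.
#' @slot residuesA,residuesB interface [ResidueSet-class]s (buried area above
#'   the noise floor).
#' @slot params list: probe radius, point count, radii set, noise floor.
#' @exportClass InterfaceReport
setClass("InterfaceReport",
         representation(area = "numeric", perResidue = "data.frame",
                        residuesA = "ResidueSet", residuesB = "ResidueSet",
                        params = "list"))
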