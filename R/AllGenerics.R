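#' @include AllClasses.R
NULL

#' Accessors
#'
#' Small accessor generics for the package's S4 containers, in place of
#' direct slot access.
#'
#' @param x an object.
#' @name accessors
NULL

#' @describeIn accessors atom table of a [Structure-class].
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))
#' @export
setMethod("atomData", "Structure", function(x) x@atoms)

#' @describeIn accessors number of atoms.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @export
setMethod("nAtoms", "Structure", function(x) nrow(x@atoms))

#' @describeIn accessors chain identifiers present in a structure.
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))
#' @export
setMethod("chainIds", "Structure", function(x) unique(x@atoms$chain))

#' @describeIn accessors residue id table of a [ResidueSet-class].
#' @export
setGeneric("residueIds", function(x) standardGeneric("residueIds"))
#' @export
setMethod("residueIds", "ResidueSet", function(x) x@ids)

#' @describeIn accessors pair table of a [ContactList-class].
#' @export
setGeneric("contactPairs", function(x) standardGeneric("contactPairs"))
#' @export
setMethod("contactPairs", "ContactList", function(x) x@pairs)

#' @describeIn accessors rotation matrix of a [RigidTransform-class].
#' @export
setGeneric("rotation", function(x) standardGeneric("rotation"))
#' @export
setMethod("rotation", "RigidTransform", function(x) x@rotation)

#' @describeIn accessors translation vector of a [RigidTransform-class].
#' @export
setGeneric("translation", function(x) standardGeneric("translation"))
#' @export
setMethod("translation", "RigidTransform", function(x) x@translation)

#' @describeIn accessors eigenvalues of a [ModeSpectrum-class] (ascending).
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))
#' @export
setMethod("eigenvalues", "ModeSpectrum", function(x) x@values)

#' @describeIn accessors eigenvectors of a [ModeSpectrum-class].
#' @export
setGeneric("eigenvectors", function(x) standardGeneric("eigenvectors"))
#' @export
setMethod("eigenvectors", "ModeSpectrum", function(x) x@vectors)

#' @describeIn accessors number of zero (rigid/disconnection) modes.
#' @export
setGeneric("nZeroModes", function(x) standardGeneric("nZeroModes"))
#' @export
setMethod("nZeroModes", "ModeSpectrum", function(x) x@nZero)

#' @describeIn accessors coordinate frames of a [Trajectory-class].
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @export
setMethod("frames", "Trajectory", function(x) x@frames)

#' @describeIn accessors buried interface area of an [InterfaceReport-class].
#' @export
setGeneric("interfaceArea", function(x) standardGeneric("interfaceArea"))
#' @export
setMethod("interfaceArea", "InterfaceReport", function(x) x@area)

#' Length of selections and filaments
#' @param x a [ResidueSet-class] (number of residues) or [ContactList-class]
#'   (number of pairs).
#' @export
setMethod("length", "ResidueSet", function(x) nrow(x@ids))
#' @rdname length-ResidueSet-method
#' @export
setMethod("length", "ContactList", function(x) nrow(x@pairs))

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  prot <- a[a$type == "ATOM", ]
  nres <- nrow(unique(prot[, c("chain", "resno", "insert")]))
  cat("Structure:", nrow(a), "atoms,", nres, "residues,",
      length(unique(a$chain)), "chain(s) [",
      paste(unique(a$chain), collapse = " "), "]\n")
  if (any(a$type == "HETATM"))
    cat("  HETATM residues:",
        paste(unique(a$resid[a$type == "HETATM"]), collapse = " "), "\n")
})

setMethod("show", "RigidTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("RigidTransform: rotation %.2f deg, |t| = %.2f A\n",
              ang, sqrt(sum(object@translation^2))))
})

setMethod("show", "ContactList", function(object) {
  cat(sprintf("ContactList: %d pairs over %d beads (cutoff %.2f A, minSeqSep %d)\n",
              nrow(object@pairs), object@nBeads, object@cutoff,
              object@minSeqSep))
})

setMethod("show", "ResidueSet", function(object) {
  cat(sprintf("ResidueSet (%s): %d residues on chain(s) %s\n", object@label,
              nrow(object@ids),
              paste(unique(object@ids$chain), collapse = " ")))
})

setMethod("show", "GoModel", function(object) {
  cat(sprintf("GoModel: %d beads, %d bonds, %d native contacts (eps = %g)\n",
              nrow(object@coords), nrow(object@bonds),
              nrow(object@contacts@pairs), object@params$epsilon))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames, %g DMD steps, T = %g, seed = %s\n",
              length(object@frames), object@meta$nSteps,
              object@meta$temperature, object@meta$seed))
})

setMethod("show", "ModeSpectrum", function(object) {
  nz <- length(object@values) - object@nZero
  cat(sprintf("ModeSpectrum: %d nodes, %d zero mode(s), %d internal modes (cutoff %.2f A)\n",
              length(object@values), object@nZero, nz, object@cutoff))
})

setMethod("show", "ModeCorrelation", function(object) {
  cat(sprintf("ModeCorrelation: mode %d (lambda = %.4g), set of %d, C = %.4f\n",
              object@mode, object@lambda, nrow(object@cmat), object@correlation))
})

setMethod("show", "ScrewParameters", function(object) {
  cat(sprintf(
    "ScrewParameters: twist %.3f deg, rise %.3f A, %.3f repeats/turn, %s-handed\n",
    object@twist, object@rise, object@repeatsPerTurn,
    if (object@handedness >= 0) "right" else "left"))
})

setMethod("show", "FilamentModel", function(object) {
  cat(sprintf("FilamentModel: %d copies of a %d-atom unit\n",
              object@nUnits, nrow(object@unit@atoms)))
})

setMethod("show", "InterfaceReport", function(object) {
  cat(sprintf(
    "InterfaceReport: buried area %.1f A^2; %d + %d interface residues\n",
    object@area, nrow(object@residuesA@ids), nrow(object@residuesB@ids)))
})
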