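#' @include AllClasses.R AllGenerics.R
NULL

#' Read an atomic structure from PDB or mmCIF
#'
#' Parses all ATOM/HETATM records into a [Structure-class]. Parsing is
#' delegated to \pkg{bio3d}; the chain/residue hierarchy and author residue
#' numbering are preserved, and HETATM ligands stay retrievable by residue
#' name. Alternate locations are reduced to the highest-occupancy conformer.
#'
#' @param path file path.
#' @param format \code{"pdb"}, \code{"cif"} or \code{"auto"} (by extension).
#' @return a [Structure-class].
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' writeLines(c(
#'  "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
#'  "END"), f)
#' readStructure(f)
#' @export
readStructure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$|\\.mmcif$", path, ignore.case = TRUE))
      "cif" else "pdb"
  }
  obj <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  a <- obj$atom
  if (is.null(a) || nrow(a) == 0) stop("empty structure: ", path)
  a$insert[is.na(a$insert)] <- ""
  a$chain[is.na(a$chain)] <- " "
  if (!is.null(a$alt)) {
    # keep highest-occupancy altloc per (chain, resno, insert, elety)
    alt <- !is.na(a$alt) & a$alt != "" & a$alt != "A"
    if (any(!is.na(a$alt) & a$alt != "")) {
      key <- paste(a$chain, a$resno, a$insert, a$elety)
      keep <- rep(TRUE, nrow(a))
      for (k in unique(key[duplicated(key)])) {
        idx <- which(key == k)
        occ <- a$o[idx]
        occ[is.na(occ)] <- 1
        keep[idx] <- seq_along(idx) == which.max(occ)
      }
      a <- a[keep, ]
    }
  }
  atoms <- data.frame(type = a$type, eleno = a$eleno, elety = a$elety,
                      resid = a$resid, chain = a$chain, resno = a$resno,
                      insert = a$insert, x = a$x, y = a$y, z = a$z,
                      o = ifelse(is.na(a$o), 1, a$o),
                      b = ifelse(is.na(a$b), 0, a$b),
                      elesy = .guessElement(a),
                      stringsAsFactors = FALSE)
  new("Structure", atoms = atoms)
}

.guessElement <- function(a) {
  e <- a$elesy
  if (is.null(e)) e <- rep(NA_character_, nrow(a))
  miss <- is.na(e) | e == ""
  # fall back on the first alphabetic character of the atom name
  e[miss] <- sub("^[0-9]*([A-Za-z]).*$", "\\1", a$elety[miss])
  toupper(e)
}

#' Construct a Structure from an atom table
#'
#' Lower-level constructor used by the synthetic-fixture generator. Missing
#' bookkeeping columns (serials, occupancy, B-factor) are filled with
#' defaults.
#'
#' @param atoms data.frame with at least \code{chain, resno, x, y, z};
#'   optional \code{type, elety, resid, insert, elesy}.
#' @return a [Structure-class].
#' @export
structureFromAtoms <- function(atoms) {
  n <- nrow(atoms)
  def <- list(type = "ATOM", eleno = seq_len(n), elety = "CA",
              resid = "ALA", insert = "", o = 1, b = 0, elesy = "C")
  for (nm in names(def))
    if (is.null(atoms[[nm]])) atoms[[nm]] <- def[[nm]]
  new("Structure", atoms = atoms[, .atomColumns])
}

#' Write a structure as PDB
#'
#' Fixed-width PDB emission; with a list input each element becomes one MODEL
#' block (multi-model PDB, e.g. for trajectory snapshots or filament copies).
#'
#' @param x a [Structure-class], or a list of them for a multi-model file.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeStructure <- function(x, path) {
  if (is(x, "Structure")) x <- list(x)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(x) > 1
  for (m in seq_along(x)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    a <- x[[m]]@atoms
    nm <- ifelse(nchar(a$elety) < 4, sprintf(" %-3s", a$elety),
                 sprintf("%-4s", a$elety))
    writeLines(sprintf(
      "%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$type, a$eleno %% 100000, nm, "", substr(a$resid, 1, 3),
      substr(a$chain, 1, 1), a$resno %% 10000, substr(a$insert, 1, 1),
      a$x, a$y, a$z, a$o, a$b, a$elesy), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Extract the C-alpha trace
#'
#' One bead per standard amino-acid residue possessing a CA atom, in
#' chain-then-residue-number order. Ligands (HETATM) and waters are excluded;
#' residues lacking a CA atom are skipped with a warning.
#'
#' @param structure a [Structure-class].
#' @param chains optional chain-id subset.
#' @return data.frame \code{chain, resno, resid, x, y, z}, one row per bead.
#' @seealso [caCoords()] for the bare coordinate matrix.
#' @export
extractCA <- function(structure, chains = NULL) {
  a <- atomData(structure)
  if (!is.null(chains)) {
    missing <- setdiff(chains, unique(a$chain))
    if (length(missing))
      stop("requested chain(s) absent: ", paste(missing, collapse = ", "))
    a <- a[a$chain %in% chains, ]
  }
  prot <- a[a$type == "ATOM" & !(a$resid %in% c("HOH", "WAT")), ]
  if (nrow(prot) == 0) stop("no protein atoms in selection")
  key <- paste(prot$chain, prot$resno, prot$insert)
  ca <- prot[prot$elety == "CA", ]
  lost <- setdiff(unique(key), paste(ca$chain, ca$resno, ca$insert))
  if (length(lost))
    warning(length(lost), " residue(s) lack a CA atom and were skipped")
  ca <- ca[order(ca$chain, ca$resno, ca$insert), ]
  data.frame(chain = ca$chain, resno = ca$resno, resid = ca$resid,
             x = ca$x, y = ca$y, z = ca$z, stringsAsFactors = FALSE)
}

#' C-alpha coordinates as a matrix
#' @param structure a [Structure-class] or the data.frame from [extractCA()].
#' @param chains optional chain subset (ignored for a data.frame input).
#' @return N x 3 numeric matrix.
#' @export
caCoords <- function(structure, chains = NULL) {
  ca <- if (is.data.frame(structure)) structure
        else extractCA(structure, chains)
  as.matrix(ca[, c("x", "y", "z")])
}

#' Rigid transform constructor
#' @param rotation 3x3 proper rotation matrix.
#' @param translation numeric(3).
#' @return a [RigidTransform-class].
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' Apply, invert and compose rigid transforms
#'
#' \code{applyTransform} maps coordinates (N x 3) or a whole
#' [Structure-class] through \code{x' = R x + t}. \code{invertTransform}
#' returns the inverse motion; \code{composeTransform(a, b)} returns the
#' transform "apply \code{b}, then \code{a}".
#'
#' @param transform a [RigidTransform-class].
#' @param x coordinates (N x 3 matrix) or a [Structure-class].
#' @return transformed coordinates or structure.
#' @export
applyTransform <- function(transform, x) {
  if (is(x, "Structure")) {
    a <- x@atoms
    xyz <- applyTransform(transform, as.matrix(a[, c("x", "y", "z")]))
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    return(new("Structure", atoms = a))
  }
  sweep(x %*% t(transform@rotation), 2, transform@translation, "+")
}

#' @rdname applyTransform
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  rigidTransform(Rt, -as.numeric(Rt %*% transform@translation))
}

#' @rdname applyTransform
#' @param a,b transforms to compose.
#' @export
composeTransform <- function(a, b) {
  rigidTransform(a@rotation %*% b@rotation,
                 as.numeric(a@rotation %*% b@translation) + a@translation)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal proper rotation + translation mapping \code{mobile} onto
#' \code{reference} in the least-squares sense, via singular value
#' decomposition of the covariance matrix; a reflection solution is corrected
#' by flipping the sign of the smallest singular vector. Returns the
#' transform and the RMSD of the residuals after applying it.
#'
#' @param mobile,reference N x 3 coordinate matrices with matched rows
#'   (N >= 3, not all collinear).
#' @return list with elements \code{transform} ([RigidTransform-class]) and
#'   \code{rmsd} (Angstrom).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("coordinate sets differ in size: ", nrow(mobile), " vs ",
         nrow(reference))
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 points to superpose")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  sv <- svd(crossprod(P, Q))
  if (sv$d[1] < 1e-10 || sv$d[2] < 1e-10)
    stop("degenerate geometry: points coincident or collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cr - as.numeric(R %*% cm)
  moved <- sweep(mobile %*% t(R), 2, t, "+")
  rmsd <- sqrt(mean(rowSums((moved - reference)^2)))
  list(transform = rigidTransform(R, t), rmsd = rmsd)
}

#' RMSD between two matched coordinate sets (no fitting)
#' @param a,b N x 3 matrices.
#' @return root-mean-square deviation in Angstrom.
#' @export
coordRmsd <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))
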