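#' @include structio.R
NULL

#' Native contacts of a C-alpha trace
#'
#' All bead pairs within \code{cutoff} Angstrom in the native structure, the
#' definition used both for the attractive pairs of the Go model and for the
#' springs of the elastic network. Intra-chain pairs with sequence separation
#' below \code{minSeqSep} are excluded (i, i+1 neighbours are bonds, not
#' contacts); inter-chain pairs have no separation constraint. The cutoff is
#' inclusive (\code{<=}), distances Euclidean.
#'
#' @param ca data.frame from [extractCA()] (or any data.frame with
#'   \code{chain, resno, x, y, z}).
#' @param cutoff contact cutoff in Angstrom (default 7.5).
#' @param minSeqSep minimum intra-chain separation in residue numbering
#'   (default 2).
#' @return a [ContactList-class] with native distances stored.
#' @export
nativeContacts <- function(ca, cutoff = 7.5, minSeqSep = 2L) {
  if (cutoff <= 0) stop("cutoff must be positive")
  n <- nrow(ca)
  if (n < 2) stop("need at least 2 beads")
  xyz <- caCoords(ca)
  d <- as.matrix(dist(xyz))
  sameChain <- outer(ca$chain, ca$chain, "==")
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  ok <- d <= cutoff & (!sameChain | sep >= minSeqSep)
  ok[lower.tri(ok, diag = TRUE)] <- FALSE
  idx <- which(ok, arr.ind = TRUE)
  pairs <- data.frame(i = idx[, 1], j = idx[, 2],
                      d0 = d[idx])
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  new("ContactList", pairs = pairs, cutoff = cutoff,
      minSeqSep = as.integer(minSeqSep), nBeads = as.integer(n))
}

.residueSetFromAtoms <- function(a, keep, label) {
  sel <- unique(a[keep, c("chain", "resno", "resid")])
  sel <- sel[order(sel$chain, sel$resno), , drop = FALSE]
  rownames(sel) <- NULL
  new("ResidueSet", ids = sel, label = label)
}

#' Pocket (active-site) residues around bound substrates
#'
#' Every protein residue with at least one atom within \code{expansion}
#' Angstrom of at least one ligand atom — the fixed-radius expansion around
#' the bound substrates that defines the active-site pocket. On atomic
#' structures the distance is measured all-atom; on C-alpha-only models it is
#' the bead-to-ligand distance with the same cutoff.
#'
#' @param structure a [Structure-class].
#' @param ligandAtoms data.frame of ligand atoms with \code{x, y, z}
#'   (e.g. rows of [ligandAtoms()]).
#' @param expansion expansion radius in Angstrom (default 6).
#' @return a [ResidueSet-class] labelled \code{"pocket"}, ordered by
#'   (chain, resno).
#' @export
pocketResidues <- function(structure, ligandAtoms, expansion = 6.0) {
  if (is.null(ligandAtoms) || nrow(ligandAtoms) == 0)
    stop("ligand atom list is empty")
  a <- atomData(structure)
  prot <- a$type == "ATOM" & !(a$resid %in% c("HOH", "WAT"))
  pm <- as.matrix(a[prot, c("x", "y", "z")])
  lm <- as.matrix(ligandAtoms[, c("x", "y", "z")])
  near <- .anyWithin(pm, lm, expansion)
  keep <- which(prot)[near]
  .residueSetFromAtoms(a, keep, "pocket")
}

# rows of a within cutoff of any row of b
.anyWithin <- function(a, b, cutoff) {
  c2 <- cutoff^2
  res <- logical(nrow(a))
  for (k in seq_len(nrow(b))) {
    dx <- a[, 1] - b[k, 1]; dy <- a[, 2] - b[k, 2]; dz <- a[, 3] - b[k, 3]
    res <- res | (dx * dx + dy * dy + dz * dz <= c2)
  }
  res
}

#' Atoms of HETATM ligands, by residue name
#' @param structure a [Structure-class].
#' @param resnames ligand residue names to select (default: all HETATM except
#'   water).
#' @return data.frame of ligand atom records.
#' @export
ligandAtoms <- function(structure, resnames = NULL) {
  a <- atomData(structure)
  het <- a[a$type == "HETATM" & !(a$resid %in% c("HOH", "WAT")), ]
  if (!is.null(resnames)) het <- het[het$resid %in% resnames, ]
  het
}

#' Interface residues between two chain groups
#'
#' Residues of \code{groupA} with at least one atom within \code{cutoff}
#' Angstrom of any atom of \code{groupB} (0.75 nm by default, the junction
#' interface definition). Groups must be disjoint, non-empty chain sets.
#'
#' @param structure a [Structure-class].
#' @param groupA,groupB character vectors of chain ids.
#' @param cutoff distance cutoff in Angstrom (default 7.5).
#' @return a [ResidueSet-class] labelled \code{"interface"} (residues of
#'   \code{groupA}).
#' @export
interfaceResidues <- function(structure, groupA, groupB, cutoff = 7.5) {
  if (length(intersect(groupA, groupB)))
    stop("chain groups overlap: ", paste(intersect(groupA, groupB),
                                         collapse = ", "))
  if (!length(groupA) || !length(groupB)) stop("empty chain group")
  a <- atomData(structure)
  missing <- setdiff(c(groupA, groupB), unique(a$chain))
  if (length(missing))
    stop("chain(s) absent from structure: ", paste(missing, collapse = ", "))
  selA <- a$chain %in% groupA & a$type == "ATOM" &
    !(a$resid %in% c("HOH", "WAT"))
  selB <- a$chain %in% groupB & a$type == "ATOM" &
    !(a$resid %in% c("HOH", "WAT"))
  am <- as.matrix(a[selA, c("x", "y", "z")])
  bm <- as.matrix(a[selB, c("x", "y", "z")])
  near <- .anyWithin(am, bm, cutoff)
  .residueSetFromAtoms(a, which(selA)[near], "interface")
}

#' Junction residue set of a filament unit
#'
#' The interface set used for dynamics at a filament junction: the union of
#' the enzyme residues contacting the cross-linking chains and those
#' contacting the adjacent enzyme oligomer.
#'
#' @param structure a [Structure-class].
#' @param enzymeChains chains of the oligomer whose residues are reported.
#' @param linkerChains chains of the cross-linking molecules.
#' @param adjacentChains chains of the adjacent oligomer (optional).
#' @param cutoff distance cutoff in Angstrom (default 7.5).
#' @return a [ResidueSet-class] labelled \code{"interface"}.
#' @export
junctionResidues <- function(structure, enzymeChains, linkerChains,
                             adjacentChains = NULL, cutoff = 7.5) {
  s1 <- interfaceResidues(structure, enzymeChains, linkerChains, cutoff)
  if (is.null(adjacentChains) || !length(adjacentChains)) return(s1)
  s2 <- interfaceResidues(structure, enzymeChains, adjacentChains, cutoff)
  ids <- unique(rbind(s1@ids, s2@ids))
  ids <- ids[order(ids$chain, ids$resno), , drop = FALSE]
  rownames(ids) <- NULL
  new("ResidueSet", ids = ids, label = "interface")
}

#' Transfer a residue set between structures
#'
#' Maps a selection defined on one structure onto another, either through an
#' explicit residue-number offset/map or through chain pairing by order. Every
#' source residue must resolve on the target.
#'
#' @param set a [ResidueSet-class] on \code{source}.
#' @param source,target [Structure-class] objects.
#' @param chainMap named character vector mapping source chain ids to target
#'   chain ids (default: identity).
#' @param resnoOffset integer added to residue numbers (default 0), or a
#'   function applied to them.
#' @return a [ResidueSet-class] on \code{target}.
#' @export
mapResidueSet <- function(set, source, target, chainMap = NULL,
                          resnoOffset = 0L) {
  ids <- set@ids
  tchain <- if (is.null(chainMap)) ids$chain
            else unname(chainMap[ids$chain])
  tres <- if (is.function(resnoOffset)) resnoOffset(ids$resno)
          else ids$resno + resnoOffset
  ta <- atomData(target)
  tkey <- paste(ta$chain, ta$resno)
  want <- paste(tchain, tres)
  bad <- !(want %in% tkey)
  if (any(bad))
    stop("unmapped residue(s) on target: ",
         paste(utils::head(want[bad], 10), collapse = "; "))
  resid <- ta$resid[match(want, tkey)]
  out <- data.frame(chain = tchain, resno = tres, resid = resid,
                    stringsAsFactors = FALSE)
  new("ResidueSet", ids = out, label = set@label)
}

#' Residue set constructor
#' @param chain,resno vectors defining the residues.
#' @param resid optional residue names.
#' @param label set label (default "custom").
#' @return a [ResidueSet-class].
#' @export
residueSet <- function(chain, resno, resid = NA_character_,
                       label = "custom") {
  new("ResidueSet",
      ids = data.frame(chain = chain, resno = as.integer(resno),
                       resid = resid, stringsAsFactors = FALSE),
      label = label)
}

#' Bead indices of a residue set on a C-alpha trace
#' @param ca data.frame from [extractCA()].
#' @param set a [ResidueSet-class].
#' @return integer vector of row indices into \code{ca}.
#' @export
beadIndices <- function(ca, set) {
  key <- paste(ca$chain, ca$resno)
  idx <- match(paste(set@ids$chain, set@ids$resno), key)
  if (anyNA(idx))
    stop("residue set has members without a CA bead")
  idx
}

#' Write a residue set as TSV
#' @param set a [ResidueSet-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeResidueSet <- function(set, path) {
  out <- cbind(set@ids, label = set@label)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
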