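#' @include selection.R
NULL

# standard protein van der Waals radii (Angstrom)
.vdwRadii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
               MG = 1.73, ZN = 1.39, FE = 1.40, CA = 2.00, "NA" = 2.27,
               K = 2.75, MN = 1.40)

.atomRadii <- function(elements, radii = .vdwRadii) {
  r <- radii[toupper(elements)]
  if (anyNA(r)) {
    bad <- unique(elements[is.na(r)])
    stop("no van der Waals radius for element(s): ",
         paste(bad, collapse = ", "))
  }
  unname(r)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA with a probe sphere rolled over van der Waals spheres.
#' Test points sit on a deterministic golden-spiral lattice, so results are
#' exactly reproducible for a fixed point count.
#'
#' @param x a [Structure-class], an atom data.frame with \code{x, y, z} and
#'   \code{elesy}, or a bare N x 3 coordinate matrix (then \code{radii} must
#'   be given per atom).
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param nPoints test points per atom (default 960).
#' @param radii named per-element radii set (default: C 1.70, N 1.55, O 1.52,
#'   S 1.80 Angstrom and other common elements), or a numeric vector of
#'   per-atom radii when \code{x} is a coordinate matrix.
#' @return numeric vector of per-atom areas (Angstrom^2); total SASA is its
#'   sum.
#' @export
sasa <- function(x, probe = 1.4, nPoints = 960L, radii = .vdwRadii) {
  if (is(x, "Structure")) x <- atomData(x)
  if (is.data.frame(x)) {
    coords <- as.matrix(x[, c("x", "y", "z")])
    r <- .atomRadii(x$elesy, radii)
  } else {
    coords <- as.matrix(x)
    if (length(radii) == 1) radii <- rep(radii, nrow(coords))
    if (length(radii) != nrow(coords))
      stop("per-atom radii must match the coordinate matrix")
    r <- as.numeric(radii)
  }
  .sasa_points(coords, r, probe, as.integer(nPoints))
}

.sasaSubset <- function(a, sel, probe, nPoints, radii) {
  sub <- a[sel, , drop = FALSE]
  areas <- sasa(sub, probe = probe, nPoints = nPoints, radii = radii)
  key <- paste(sub$chain, sub$resno, sub$insert)
  byRes <- tapply(areas, key, sum)
  list(total = sum(areas), byRes = byRes, sub = sub, key = key)
}

#' PISA-style buried interface area
#'
#' The interface area between two chain groups is computed as the difference
#' between the summed accessible surface areas of the isolated groups and of
#' the complex, divided by two:
#' \deqn{A = (SASA(A) + SASA(B) - SASA(A \cup B)) / 2.}
#' Per-residue buried area (isolated minus complexed) is reported for both
#' partners; residues with buried area above the noise floor form the
#' interface residue lists.
#'
#' @param structure a [Structure-class].
#' @param groupA,groupB disjoint chain-id sets.
#' @param probe probe radius (Angstrom, default 1.4).
#' @param nPoints test points per atom (default 960).
#' @param radii per-element radii set.
#' @param includeHet include ligands/waters in the surface (default FALSE).
#' @param noiseFloor per-residue buried-area threshold in Angstrom^2
#'   (default 0.1) below which quadrature noise is ignored.
#' @return an [InterfaceReport-class].
#' @export
buriedInterfaceArea <- function(structure, groupA, groupB, probe = 1.4,
                                nPoints = 960L, radii = .vdwRadii,
                                includeHet = FALSE, noiseFloor = 0.1) {
  if (length(intersect(groupA, groupB)))
    stop("chain groups overlap")
  if (!length(groupA) || !length(groupB)) stop("empty chain group")
  a <- atomData(structure)
  if (!includeHet) a <- a[a$type == "ATOM" & !(a$resid %in% c("HOH", "WAT")), ]
  selA <- a$chain %in% groupA
  selB <- a$chain %in% groupB
  if (!any(selA) || !any(selB)) stop("empty chain group after filtering")
  sA <- .sasaSubset(a, selA, probe, nPoints, radii)
  sB <- .sasaSubset(a, selB, probe, nPoints, radii)
  sAB <- .sasaSubset(a, selA | selB, probe, nPoints, radii)
  area <- (sA$total + sB$total - sAB$total) / 2

  perPartner <- function(s, partner) {
    resKey <- names(s$byRes)
    complexed <- sAB$byRes[resKey]
    info <- s$sub[match(resKey, s$key), c("chain", "resno", "resid")]
    data.frame(partner = partner, info,
               areaIsolated = as.numeric(s$byRes),
               areaComplex = as.numeric(complexed),
               buried = as.numeric(s$byRes) - as.numeric(complexed),
               row.names = NULL)
  }
  pr <- rbind(perPartner(sA, "A"), perPartner(sB, "B"))
  pr <- pr[order(pr$partner, pr$chain, pr$resno), ]
  rownames(pr) <- NULL
  mkSet <- function(partner) {
    sel <- pr$partner == partner & pr$buried > noiseFloor
    new("ResidueSet",
        ids = pr[sel, c("chain", "resno", "resid")],
        label = "interface")
  }
  new("InterfaceReport", area = area, perResidue = pr,
      residuesA = mkSet("A"), residuesB = mkSet("B"),
      params = list(probe = probe, nPoints = nPoints,
                    noiseFloor = noiseFloor, radii = radii))
}

#' Interface residue census
#'
#' Counts the residues of \code{groupA} that bury surface area against
#' \code{groupB}, with the per-residue table — the census used to identify
#' which enzyme residues participate in interface formation.
#'
#' @inheritParams buriedInterfaceArea
#' @param threshold buried-area threshold (Angstrom^2); defaults to the
#'   noise floor (0.1), i.e. "any buried area".
#' @return list: \code{count}, \code{residues} ([ResidueSet-class]),
#'   \code{table} (per-residue buried areas of groupA), \code{report} (the
#'   full [InterfaceReport-class]).
#' @export
interfaceCensus <- function(structure, groupA, groupB, threshold = 0.1,
                            probe = 1.4, nPoints = 960L, radii = .vdwRadii,
                            includeHet = FALSE) {
  rep <- buriedInterfaceArea(structure, groupA, groupB, probe = probe,
                             nPoints = nPoints, radii = radii,
                             includeHet = includeHet,
                             noiseFloor = threshold)
  tab <- rep@perResidue
  tab <- tab[tab$partner == "A" & tab$buried > threshold, ]
  rownames(tab) <- NULL
  list(count = nrow(tab), residues = rep@residuesA, table = tab,
       report = rep)
}

#' Write an interface report
#' @param report an [InterfaceReport-class].
#' @param jsonPath path for the JSON summary (optional).
#' @param tsvPath path for the per-residue TSV (optional).
#' @return invisibly, the summary list.
#' @export
writeInterfaceReport <- function(report, jsonPath = NULL, tsvPath = NULL) {
  summary <- list(area = report@area,
                  nResiduesA = nrow(report@residuesA@ids),
                  nResiduesB = nrow(report@residuesB@ids),
                  probe = report@params$probe,
                  nPoints = report@params$nPoints)
  if (!is.null(jsonPath))
    jsonlite::write_json(summary, jsonPath, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsvPath))
    write.table(report@perResidue, tsvPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(summary)
}
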