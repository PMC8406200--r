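#' @include filament.R godynamics.R gnm.R
NULL

# run code under a local RNG seed without disturbing the caller's stream
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

.unitSphere <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-6) return(v / n)
  }
}

.minCross <- function(a, b) {
  # minimum distance between two point sets
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(min(d2), 0))
}

#' Generate a compact self-avoiding C-alpha chain
#'
#' Sequential random placement with 3.8-Angstrom virtual bonds inside a
#' sphere of radius \code{radiusFactor * n^(1/3)}, keeping all non-bonded
#' beads at least \code{minSep} apart (above the hardcore diameter of the Go
#' model). The confinement collapses the chain so native contacts exist. The
#' result is centred at the origin. Same seed, same chain.
#'
#' @param n number of residues (>= 4).
#' @param seed RNG seed.
#' @param chainId chain identifier (default "A").
#' @param bond virtual bond length (Angstrom, default 3.8).
#' @param minSep minimum non-bonded bead separation (default 4.0).
#' @param radiusFactor confinement radius prefactor (default 3.0).
#' @return a [Structure-class] of CA pseudo-atoms.
#' @export
makeCompactChain <- function(n, seed = 1, chainId = "A", bond = 3.8,
                             minSep = 4.0, radiusFactor = 3.0) {
  if (n < 4) stop("need at least 4 residues")
  R <- radiusFactor * n^(1 / 3)
  xyz <- .withSeed(seed, {
    out <- NULL
    for (restart in 1:200) {
      pts <- matrix(NA_real_, n, 3)
      pts[1, ] <- c(0, 0, 0)
      ok <- TRUE
      for (i in 2:n) {
        placed <- FALSE
        for (try in 1:150) {
          cand <- pts[i - 1, ] + bond * .unitSphere()
          if (sqrt(sum(cand^2)) > R) next
          if (i > 2) {
            d2 <- rowSums(sweep(pts[1:(i - 2), , drop = FALSE], 2, cand)^2)
            if (min(d2) < minSep^2) next
          }
          pts[i, ] <- cand
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) { out <- pts; break }
    }
    if (is.null(out))
      stop("chain generation failed after bounded retries (n too large ",
           "for the confinement radius?)")
    sweep(out, 2, colMeans(out))
  })
  structureFromAtoms(data.frame(chain = chainId, resno = seq_len(n),
                                x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

# place four rigid copies of `coords` (centred) in C4 arrangement around z,
# with the radial offset chosen so the closest inter-chain approach falls in
# [sepLo, sepHi]
.packTetramer <- function(coords, sepLo = 4.4, sepHi = 6.0) {
  place <- function(d) {
    lapply(0:3, function(k) {
      Rk <- rotationMatrix(c(0, 0, 1), 90 * k)
      sweep(coords, 2, c(d, 0, 0), "+") %*% t(Rk)
    })
  }
  minNeighbour <- function(copies) {
    min(.minCross(copies[[1]], copies[[2]]),
        .minCross(copies[[1]], copies[[4]]))
  }
  lo <- 0
  hi <- 4 * max(sqrt(rowSums(coords^2))) + 20
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    m <- minNeighbour(place(mid))
    if (m < sepLo) lo <- mid else if (m > sepHi) hi <- mid else break
  }
  copies <- place(mid)
  if (minNeighbour(copies) < sepLo || minNeighbour(copies) > sepHi)
    stop("tetramer packing failed to converge")
  if (.minCross(copies[[1]], copies[[3]]) < sepLo)
    stop("opposite chains overlap in tetramer packing")
  copies
}

.chainsToStructure <- function(coordList, chainIds, hetRows = NULL) {
  tabs <- lapply(seq_along(coordList), function(k) {
    xyz <- coordList[[k]]
    data.frame(chain = chainIds[k], resno = seq_len(nrow(xyz)),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  })
  a <- do.call(rbind, tabs)
  a$type <- "ATOM"; a$elety <- "CA"; a$resid <- "ALA"; a$elesy <- "C"
  if (!is.null(hetRows)) a <- rbind(a, hetRows)
  structureFromAtoms(a)
}

# pocket site of one chain: a ligand pseudo-atom planted just outside the
# face of the chain pointing along `outward`; anchor beads near that face
# are scanned and the placement whose members move most coherently in the
# low normal modes of the free assembly wins (the planted contrast requires
# intact pockets in the free state), with member connectivity and size as
# tie-breaks
.plantPocket <- function(xyz, outward, expansion = 6.0, minMembers = 6L,
                         coherence = NULL) {
  proj <- as.numeric(xyz %*% outward)
  cand <- order(proj, decreasing = TRUE)[seq_len(min(8L, nrow(xyz)))]
  deg <- rowSums(as.matrix(dist(xyz)) <= 7.5) - 1L
  best <- NULL
  for (b in cand) {
    for (off in seq(3.0, 1.0, by = -0.5)) {
      lig <- xyz[b, ] + off * outward
      members <- which(sqrt(rowSums(sweep(xyz, 2, lig)^2)) <= expansion)
      if (length(members) < 4L) next
      coh <- if (is.null(coherence)) 0 else coherence(members)
      sc <- c(coh, min(deg[members]), length(members))
      if (is.null(best) || sc[1] > best$sc[1] ||
          (sc[1] == best$sc[1] && (sc[2] > best$sc[2] ||
            (sc[2] == best$sc[2] && sc[3] > best$sc[3]))))
        best <- list(ligand = lig, members = members, anchor = b, sc = sc)
    }
  }
  if (is.null(best))
    stop("pocket planting failed: chain surface too sparse")
  best
}

#' Generate a tetramer analog with planted pockets
#'
#' Four copies of one compact chain in a C4 arrangement around the z axis
#' (chains A-D), packed so neighbouring chains form inter-chain native
#' contacts without clashes. Each chain carries one planted ligand
#' pseudo-atom (HETATM, residue name LIG) just outside its radially-outward
#' face; the residues within the pocket expansion radius of the ligand are
#' the planted pocket and are recorded as ground truth. Candidate ligand
#' placements are scored by how coherently their member beads move in the
#' low normal modes of the free assembly, so planted pockets sit on
#' internally rigid faces: the free-state pocket is intact by construction,
#' which is the reference side of the planted filamentation contrast.
#'
#' @param nRes residues per chain (default 40).
#' @param seed RNG seed.
#' @param expansion pocket expansion radius (Angstrom, default 6).
#' @return list: \code{structure} ([Structure-class] with ligands),
#'   \code{pockets} (list of [ResidueSet-class], one per chain),
#'   \code{ligands} (data.frame of ligand pseudo-atoms),
#'   \code{chains} (protein chain ids).
#' @export
makeTetramerAnalog <- function(nRes = 40L, seed = 1, expansion = 6.0) {
  chain <- makeCompactChain(nRes, seed = seed)
  coords <- caCoords(extractCA(chain))
  copies <- .packTetramer(coords)
  ids <- c("A", "B", "C", "D")
  # low modes of the bare assembly, used to plant pockets on rigid faces
  sp <- gnmModes(do.call(rbind, copies), 7.5)
  nz <- nZeroModes(sp)
  nLow <- min(5L, length(eigenvalues(sp)) - nz)
  lowU <- eigenvectors(sp)[, nz + seq_len(nLow), drop = FALSE]
  uMax <- apply(abs(lowU), 2, max)
  pockets <- list(); ligRows <- NULL
  for (k in 1:4) {
    outward <- as.numeric(rotationMatrix(c(0, 0, 1), 90 * (k - 1)) %*%
                            c(1, 0, 0))
    offIdx <- (k - 1) * nRes
    coherence <- function(members) {
      idx <- offIdx + members
      mean(vapply(seq_len(nLow), function(m) {
        u <- lowU[idx, m]
        act <- abs(u) >= 0.05 * uMax[m]
        if (sum(act) < 2) return(1)
        s <- sign(u[act])
        cm <- outer(s, s)
        mean(cm[upper.tri(cm)])
      }, numeric(1)))
    }
    p <- .plantPocket(copies[[k]], outward, expansion,
                      coherence = coherence)
    pockets[[ids[k]]] <- residueSet(ids[k], p$members, "ALA", "pocket")
    ligRows <- rbind(ligRows, data.frame(
      chain = ids[k], resno = 9000L, x = p$ligand[1], y = p$ligand[2],
      z = p$ligand[3], type = "HETATM", elety = "C1", resid = "LIG",
      elesy = "C", stringsAsFactors = FALSE))
  }
  structure <- .chainsToStructure(copies, ids, ligRows)
  list(structure = structure, pockets = pockets, ligands = ligRows,
       chains = ids)
}

# straight linker chain along the pocket-to-pocket axis, displaced
# perpendicularly (on the `side` of the junction) until clash-free while
# still contacting the pocket regions of both tetramers
.placeLinker <- function(c1, c2, side, allBeads, pocketBeads1, pocketBeads2,
                         nBeads = 9L, bond = 3.8, minSep = 4.0,
                         cutoff = 7.5) {
  u <- c2 - c1
  u <- u / sqrt(sum(u^2))
  w <- c(u[2], -u[1], 0)
  if (sqrt(sum(w^2)) < 1e-6) w <- c(1, 0, 0)
  w <- w / sqrt(sum(w^2))
  zp <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
          u[1] * w[2] - u[2] * w[1])
  mid <- (c1 + c2) / 2
  for (nb in unique(c(nBeads, 4L, 3L))) {
    span <- (seq_len(nb) - (nb + 1) / 2) * bond
    along <- outer(span, u)
    for (reach in c(cutoff, cutoff + 1)) {
      for (tilt in c(0, 15, -15, 30, -30, 45, -45, 60, -60, 75, -75, 90)) {
        dir <- cos(tilt * pi / 180) * side * w + sin(tilt * pi / 180) * zp
        for (off in seq(4.0, 30, by = 0.25)) {
          pts <- sweep(along, 2, mid + off * dir, "+")
          if (.minCross(pts, allBeads) < minSep) next
          if (.minCross(pts, pocketBeads1) <= reach &&
              .minCross(pts, pocketBeads2) <= reach)
            return(pts)
        }
      }
    }
  }
  stop("linker placement failed: no clash-free pose contacting both pockets")
}

# pry a pocket open: spread the beads near the ligand radially from their
# centroid by up to `delta` Angstrom, halving delta until no bead sinks
# below minSep of any other bead and no strained pair shortens below 87%
# of its relaxed length
.pryPocket <- function(xyz, ligand, others, expansion, delta,
                       minSep = 3.8) {
  sel <- which(sqrt(rowSums(sweep(xyz, 2, ligand)^2)) <= expansion + 0.5)
  if (length(sel) < 2) stop("pocket prying failed: no beads near ligand")
  ctr <- colMeans(xyz[sel, , drop = FALSE])
  dir <- sweep(xyz[sel, , drop = FALSE], 2, ctr)
  nrm <- sqrt(rowSums(dir^2))
  dir <- dir / pmax(nrm, 1e-6)
  dir[nrm < 1e-6, ] <- 0
  relaxed <- as.matrix(dist(xyz))
  n <- nrow(xyz)
  bonded <- abs(outer(seq_len(n), seq_len(n), "-")) <= 1  # incl. diagonal
  for (halving in 0:4) {
    cand <- xyz
    cand[sel, ] <- cand[sel, ] + delta * dir
    dAll <- as.matrix(dist(cand))
    ratio <- dAll / pmax(relaxed, 1e-9)
    ratio[bonded] <- 1
    nonBonded <- dAll
    nonBonded[bonded] <- Inf
    ok <- min(nonBonded[sel, , drop = FALSE]) >= minSep &&
      min(ratio[sel, ]) >= 0.86 &&
      (length(others) == 0 || .minCross(cand[sel, , drop = FALSE],
                                        others) >= minSep)
    if (ok) return(list(xyz = cand, sel = sel, delta = delta))
    delta <- delta / 2
  }
  stop("pocket prying failed: could not strain pocket without clashes")
}

#' Generate an octamer analog with planted junction and allosteric effect
#'
#' Two tetramer analogs joined head-to-tail by two short linker chains (S and
#' T), emulating two enzyme tetramers bridged by two cross-linker dimers.
#' The second tetramer is the first rotated 180 degrees about z and shifted
#' along x, so the junction-facing chains are A (tetramer 1, chains A-D) and
#' E (tetramer 2, chains E-H). The construction plants the allosteric
#' signature of filamentation in two ways:
#' \itemize{
#' \item entrapment strain: every pocket of the assembled unit is pried
#'   open by \code{pry} Angstrom, while the tetramer-internal square wells
#'   of the accompanying Go contact list (\code{goContacts}) keep the
#'   relaxed free-tetramer reference distances. The assembly is therefore
#'   frustrated exactly at the pockets: junction contacts (referenced to the
#'   assembled geometry) hold the pried state, intra-tetramer contacts pull
#'   back toward the relaxed one, and the pocket geometry fluctuates between
#'   the two, raising pocket d_rms relative to the free tetramer by
#'   construction;
#' \item junction-straddling active sites: the substrate pseudo-atoms of
#'   the junction-facing chains A and E sit in the cleft between the two
#'   tetramers, so their pockets contain residues of both tetramers (and of
#'   the linkers running through the cleft). The soft inter-tetramer modes
#'   of the elastic network then deform those pockets by construction,
#'   lowering the low-mode pocket correlation C_pocket.
#' }
#' This is a synthetic surrogate with the effect true by construction, not a
#' biological model.
#'
#' @inheritParams makeTetramerAnalog
#' @param linkerBeads beads per linker chain (default 5).
#' @param pry radial pocket strain applied to every pocket in the assembled
#'   state (Angstrom, default 0.6; halved automatically while it would
#'   create clashes or compress any pair below 86% of its relaxed length).
#' @param contactCutoff,minSeqSep native-contact definition used for
#'   \code{goContacts} (defaults 7.5 Angstrom, 2).
#' @return list: \code{structure} (the assembled, strained octamer),
#'   \code{pockets} (8 sets, chains A-H), \code{ligands},
#'   \code{tetramer1}/\code{tetramer2}/\code{linkers} (chain-id vectors),
#'   \code{junctionPatches} (planted interface [ResidueSet-class] per
#'   tetramer: residues within 7.5 Angstrom of a linker),
#'   \code{goContacts} (a [ContactList-class] on the C-alpha trace of
#'   \code{structure} whose tetramer-internal reference distances come from
#'   the relaxed free-tetramer geometry), and \code{relaxedCA} (the
#'   unstrained bead coordinates, for reference).
#' @export
makeOctamerAnalog <- function(nRes = 40L, seed = 1, expansion = 6.0,
                              linkerBeads = 5L, pry = 0.6,
                              contactCutoff = 7.5, minSeqSep = 2L) {
  tet <- makeTetramerAnalog(nRes, seed, expansion)
  coords1 <- lapply(tet$chains, function(ch)
    caCoords(extractCA(tet$structure, ch)))
  flip <- rotationMatrix(c(0, 0, 1), 180)
  place2 <- function(D) lapply(coords1, function(m)
    sweep(m %*% t(flip), 2, c(D, 0, 0), "+"))
  all1 <- do.call(rbind, coords1)
  minTT <- function(D) .minCross(all1, do.call(rbind, place2(D)))
  lo <- 0; hi <- 4 * max(abs(all1)) + 40
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    m <- minTT(mid)
    if (m < 5.5) lo <- mid else if (m > 6.8) hi <- mid else break
  }
  D <- mid
  if (minTT(D) < 5.5 || minTT(D) > 6.8)
    stop("octamer junction packing failed to converge")
  coords2 <- place2(D)

  ids1 <- c("A", "B", "C", "D"); ids2 <- c("E", "F", "G", "H")
  lig1 <- tet$ligands
  lig2 <- tet$ligands
  ligXyz <- sweep(as.matrix(tet$ligands[, c("x", "y", "z")]) %*% t(flip),
                  2, c(D, 0, 0), "+")
  lig2$x <- ligXyz[, 1]; lig2$y <- ligXyz[, 2]; lig2$z <- ligXyz[, 3]
  lig2$chain <- ids2[match(lig2$chain, ids1)]
  ligRows <- rbind(lig1, lig2)

  # the junction-facing active sites sit in the junction cleft: the
  # substrate pseudo-atoms of chains A and E move to the midpoint of the
  # closest approach between those chains, so each junction pocket straddles
  # both tetramers and the soft inter-tetramer modes deform it by
  # construction
  dAE <- outer(rowSums(coords1[[1]]^2), rowSums(coords2[[1]]^2), "+") -
    2 * coords1[[1]] %*% t(coords2[[1]])
  hit <- which(dAE == min(dAE), arr.ind = TRUE)[1, ]
  junctionMid <- (coords1[[1]][hit[1], ] + coords2[[1]][hit[2], ]) / 2
  ligRows[ligRows$chain == "A", c("x", "y", "z")] <-
    as.list(junctionMid + c(0, 0.8, 0))
  ligRows[ligRows$chain == "E", c("x", "y", "z")] <-
    as.list(junctionMid - c(0, 0.8, 0))
  ligOfChain <- function(id)
    as.numeric(ligRows[ligRows$chain == id, c("x", "y", "z")])

  # entrapment strain: pry every pocket of the assembled unit open while the
  # relaxed coordinates stay the intra-tetramer Go reference; the junction
  # pockets are pried around the cleft, the others around their own ligands
  relaxed1 <- coords1; relaxed2 <- coords2
  pryApplied <- numeric(0)
  for (side in 1:2) {
    for (k in 1:4) {
      id <- if (side == 1) ids1[k] else ids2[k]
      lg <- ligOfChain(id)
      cur <- if (side == 1) coords1 else coords2
      other <- if (side == 1) coords2 else coords1
      pp <- .pryPocket(cur[[k]], lg,
                       rbind(do.call(rbind, cur[-k]),
                             do.call(rbind, other)), expansion, pry)
      if (side == 1) coords1[[k]] <- pp$xyz else coords2[[k]] <- pp$xyz
      if (!(id %in% c("A", "E")))
        # re-centre the ligand inside the opened pocket so the planted
        # membership survives the strain (junction ligands stay in the cleft)
        ligRows[ligRows$chain == id, c("x", "y", "z")] <-
          as.list(colMeans(pp$xyz[pp$sel, , drop = FALSE]))
      pryApplied[id] <- pp$delta
    }
  }

  pock1 <- coords1[[1]][
    sqrt(rowSums(sweep(coords1[[1]], 2, ligOfChain("A"))^2)) <=
      expansion + 1, , drop = FALSE]
  pock2 <- coords2[[1]][
    sqrt(rowSums(sweep(coords2[[1]], 2, ligOfChain("E"))^2)) <=
      expansion + 1, , drop = FALSE]
  if (nrow(pock1) < 1 || nrow(pock2) < 1)
    stop("junction pockets lost contact with the junction cleft")
  c1 <- colMeans(pock1); c2 <- colMeans(pock2)
  allBeads <- rbind(do.call(rbind, coords1), do.call(rbind, coords2))
  linkS <- .placeLinker(c1, c2, +1, allBeads, pock1, pock2, linkerBeads)
  linkT <- .placeLinker(c1, c2, -1, rbind(allBeads, linkS), pock1, pock2,
                        linkerBeads)

  structure <- .chainsToStructure(c(coords1, coords2, list(linkS, linkT)),
                                  c(ids1, ids2, "S", "T"), ligRows)

  # planted pockets: for each chain's ligand, every residue of the whole
  # assembly (any chain) within the expansion radius — the same rule
  # pocketResidues() applies
  ca0 <- extractCA(structure)
  xyz0 <- caCoords(ca0)
  pockets <- list()
  for (id in c(ids1, ids2)) {
    lg <- ligOfChain(id)
    members <- which(sqrt(rowSums(sweep(xyz0, 2, lg)^2)) <= expansion)
    if (length(members) < 2)
      stop("pocket lost after junction strain (chain ", id, ")")
    pockets[[id]] <- residueSet(ca0$chain[members], ca0$resno[members],
                                "ALA", "pocket")
  }

  # frustrated Go contact list: eligibility and reference distances of
  # tetramer-internal pairs from the relaxed geometry, junction pairs
  # (cross-tetramer or involving a linker) from the assembled geometry
  ca <- extractCA(structure)
  assembled <- caCoords(ca)
  relaxedCA <- rbind(do.call(rbind, relaxed1), do.call(rbind, relaxed2),
                     linkS, linkT)
  tetOf <- ifelse(ca$chain %in% ids1, 1L,
                  ifelse(ca$chain %in% ids2, 2L, 0L))
  dAsm <- as.matrix(dist(assembled))
  dRel <- as.matrix(dist(relaxedCA))
  sameTet <- outer(tetOf, tetOf, "==") & outer(tetOf > 0, tetOf > 0, "&")
  dRef <- ifelse(sameTet, dRel, dAsm)
  # pairs the strain compressed close to the inner wall are re-referenced to
  # the assembled geometry so the initial state is never inside the hardcore
  compressed <- sameTet & dAsm < 0.86 * dRef
  dRef[compressed] <- dAsm[compressed]
  sameChain <- outer(ca$chain, ca$chain, "==")
  sep <- abs(outer(seq_len(nrow(ca)), seq_len(nrow(ca)), "-"))
  ok <- dRef <= contactCutoff & (!sameChain | sep >= minSeqSep)
  ok[lower.tri(ok, diag = TRUE)] <- FALSE
  idx <- which(ok, arr.ind = TRUE)
  goContacts <- new("ContactList",
                    pairs = data.frame(i = idx[, 1], j = idx[, 2],
                                       d0 = dRef[idx]),
                    cutoff = contactCutoff,
                    minSeqSep = as.integer(minSeqSep),
                    nBeads = nrow(ca))

  # planted junction patches: tetramer residues within 7.5 A of a linker
  links <- rbind(linkS, linkT)
  patch <- function(coordList, ids) {
    rows <- NULL
    for (k in seq_along(coordList)) {
      d2 <- outer(rowSums(coordList[[k]]^2), rowSums(links^2), "+") -
        2 * coordList[[k]] %*% t(links)
      hit <- which(apply(d2, 1, min) <= 7.5^2)
      if (length(hit))
        rows <- rbind(rows, data.frame(chain = ids[k], resno = hit))
    }
    residueSet(rows$chain, rows$resno, "ALA", "interface")
  }
  list(structure = structure, pockets = pockets, ligands = ligRows,
       tetramer1 = ids1, tetramer2 = ids2, linkers = c("S", "T"),
       junctionPatches = list(tetramer1 = patch(coords1, ids1),
                              tetramer2 = patch(coords2, ids2)),
       goContacts = goContacts, relaxedCA = relaxedCA,
       pryApplied = pryApplied)
}

#' Generate an elongated unit for filament-geometry fixtures
#'
#' A compact chain stretched along x and rotated into its principal frame,
#' so its long molecular axis is exactly the lab x axis — which makes
#' planted kink angles recoverable to numerical precision.
#'
#' @param n residues (default 40).
#' @param seed RNG seed.
#' @param stretch elongation factor along x (default 3).
#' @return a [Structure-class].
#' @export
makeRodUnit <- function(n = 40L, seed = 1, stretch = 3) {
  chain <- makeCompactChain(n, seed = seed)
  xyz <- caCoords(extractCA(chain))
  xyz[, 1] <- xyz[, 1] * stretch
  xyz <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(stats::cov(xyz), symmetric = TRUE)$vectors
  if (det(ev) < 0) ev[, 3] <- -ev[, 3]
  xyz <- xyz %*% ev  # principal frame: x = largest variance
  structureFromAtoms(data.frame(chain = "A", resno = seq_len(n),
                                x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

#' Generate a helical filament fixture with known screw parameters
#'
#' Places n copies of a unit by the exact screw transform "rotate by
#' \code{twist} about x (and bend by \code{kink} about y), then translate
#' \code{rise} along x". With \code{kink = 0} the generating transform is a
#' pure screw about x with the given twist and rise; with a kink, the angle
#' between the principal axes of consecutive copies of an x-elongated unit
#' equals \code{kink} exactly. Ground truth is returned alongside the model.
#'
#' @param unit a [Structure-class] (use [makeRodUnit()] for kink fixtures).
#' @param twist twist per repeat, degrees in (0, 180].
#' @param rise rise per repeat (Angstrom).
#' @param kink bend per repeat (degrees, default 0).
#' @param n number of copies.
#' @return list: \code{filament} ([FilamentModel-class]), \code{transform},
#'   \code{truth} (twist, rise, kink, n).
#' @export
makeHelicalFixture <- function(unit, twist = 40, rise = 50, kink = 0,
                               n = 9L) {
  if (twist <= 0 || twist > 180) stop("twist must lie in (0, 180]")
  R <- rotationMatrix(c(1, 0, 0), twist) %*% rotationMatrix(c(0, 1, 0), kink)
  tr <- rigidTransform(R, c(rise, 0, 0))
  fil <- replicateFilament(unit, tr, n)
  if (n > 1 && is.finite(cl <- filamentClashReport(fil)) && cl < 2)
    warning(sprintf("filament copies clash (min CA distance %.2f A)", cl))
  list(filament = fil, transform = tr,
       truth = list(twist = twist, rise = rise, kink = kink, n = n))
}
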