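#' @include selection.R
NULL

#' Build a Go model from a C-alpha trace
#'
#' One bead per residue at the native coordinates. Consecutive residues of a
#' chain become bonds (hard windows around the native bond length); native
#' contacts become square wells centred on their native distances; every
#' other pair is hardcore-repulsive. Bonded pairs are removed from the
#' contact list if present.
#'
#' @param ca data.frame from [extractCA()].
#' @param contacts a [ContactList-class] derived from the same coordinates
#'   (default: computed at 7.5 Angstrom, minimum sequence separation 2).
#' @param epsilon square-well depth (reduced units, default 1).
#' @param wellLow,wellHigh well boundaries as fractions of the native
#'   distance (defaults 0.85, 1.15).
#' @param hardcore hardcore diameter for non-native pairs (Angstrom,
#'   default 3.6).
#' @param bondLow,bondHigh bond window as fractions of the native bond
#'   length (defaults 0.98, 1.02).
#' @return a [GoModel-class].
#' @export
buildGoModel <- function(ca, contacts = NULL, epsilon = 1, wellLow = 0.85,
                         wellHigh = 1.15, hardcore = 3.6, bondLow = 0.98,
                         bondHigh = 1.02) {
  xyz <- caCoords(ca)
  n <- nrow(xyz)
  if (is.null(contacts)) contacts <- nativeContacts(ca)
  if (contacts@nBeads != n)
    stop("contact list was derived from a different bead count")
  # bonds: consecutive residues of the same chain
  bi <- which(ca$chain[-n] == ca$chain[-1] &
              diff(ca$resno) == 1L)
  bonds <- data.frame(i = bi, j = bi + 1L)
  bonds$length <- sqrt(rowSums((xyz[bonds$i, , drop = FALSE] -
                                xyz[bonds$j, , drop = FALSE])^2))
  cp <- contacts@pairs
  if (nrow(bonds) > 0 && nrow(cp) > 0) {
    bk <- paste(bonds$i, bonds$j)
    cp <- cp[!(paste(cp$i, cp$j) %in% bk), , drop = FALSE]
  }
  if (nrow(cp) > 0 && any(wellLow * cp$d0 <= 0))
    stop("contact distance below hardcore diameter")
  contacts2 <- new("ContactList", pairs = cp, cutoff = contacts@cutoff,
                   minSeqSep = contacts@minSeqSep, nBeads = contacts@nBeads)
  new("GoModel", coords = xyz, bonds = bonds, contacts = contacts2,
      beadInfo = ca[, c("chain", "resno", "resid")],
      params = list(epsilon = epsilon, wellLow = wellLow,
                    wellHigh = wellHigh, hardcore = hardcore,
                    bondLow = bondLow, bondHigh = bondHigh))
}

#' Classify every bead pair of a Go model
#'
#' Returns the partition of all unordered pairs into bond / contact /
#' repulsive classes (each pair in exactly one class).
#'
#' @param model a [GoModel-class].
#' @return data.frame \code{i, j, class}.
#' @export
pairClasses <- function(model) {
  n <- nrow(model@coords)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cls <- rep("repulsive", nrow(idx))
  key <- paste(idx[, 1], idx[, 2])
  cls[key %in% paste(model@bonds$i, model@bonds$j)] <- "bond"
  cls[key %in% paste(model@contacts@pairs$i, model@contacts@pairs$j)] <-
    "contact"
  data.frame(i = idx[, 1], j = idx[, 2], class = cls)
}

#' Run event-driven discrete molecular dynamics
#'
#' Ballistic motion between events; at each event (hardcore collision,
#' square-well boundary crossing, bond-window wall) the radial relative
#' velocity is updated by exact energy/momentum conservation. An
#' Andersen-style thermostat resamples a random bead's velocity from the
#' Maxwell-Boltzmann distribution at a Poisson rate; with
#' \code{thermostatRate = 0} the run is microcanonical and conserves total
#' energy. One DMD step = one processed event. A fixed seed gives a
#' bit-identical trajectory.
#'
#' @param model a [GoModel-class].
#' @param nSteps number of DMD steps (events) to process.
#' @param temperature reduced temperature (units of epsilon / kB,
#'   default 0.5).
#' @param seed integer RNG seed.
#' @param snapshotEvery record a frame every this many steps (default 1000).
#' @param thermostatRate Andersen collision rate per bead per reduced time
#'   unit (default 1; 0 disables the thermostat).
#' @param initVelocities optional N x 3 matrix of initial velocities
#'   (default: Maxwell-Boltzmann at \code{temperature}, net momentum
#'   removed).
#' @return a [Trajectory-class].
#' @export
runDMD <- function(model, nSteps, temperature = 0.5, seed = 1,
                   snapshotEvery = 1000L, thermostatRate = 1,
                   initVelocities = NULL) {
  if (nSteps <= 0) stop("nSteps must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  p <- model@params
  res <- .dmd_run(model@coords,
                  as.matrix(model@bonds[, c("i", "j")]),
                  model@bonds$length,
                  as.matrix(model@contacts@pairs[, c("i", "j")]),
                  model@contacts@pairs$d0,
                  p$epsilon, p$wellLow, p$wellHigh, p$hardcore,
                  p$bondLow, p$bondHigh,
                  temperature, thermostatRate, nSteps,
                  as.integer(snapshotEvery), as.integer(seed),
                  initVelocities)
  new("Trajectory", frames = res$frames, step = res$step,
      energy = res$energy, kinetic = res$kinetic,
      meta = list(seed = seed, temperature = temperature, nSteps = nSteps,
                  snapshotEvery = snapshotEvery,
                  thermostatRate = thermostatRate, nEvents = res$nEvents,
                  time = res$time, finalVelocities = res$finalVelocities))
}

#' Kinetic temperature of a trajectory
#' @param trajectory a [Trajectory-class].
#' @param burnInFraction fraction of steps discarded before averaging
#'   (default 1/3).
#' @return mean kinetic temperature 2K / (3 N kB) over retained frames.
#' @export
kineticTemperature <- function(trajectory, burnInFraction = 1 / 3) {
  n <- nrow(trajectory@frames[[1]])
  keep <- trajectory@step >= burnInFraction * max(trajectory@step)
  mean(2 * trajectory@kinetic[keep] / (3 * n))
}

#' Pocket-deformation statistic d_rms
#'
#' Root-mean-square deviation of all pairwise distances within a residue set
#' from their native values:
#' \deqn{d_{rms} = \sqrt{ \frac{1}{N} \sum_{i<j} (d_{ij} - d^0_{ij})^2 },
#'       \quad N = n(n-1)/2,}
#' over all \eqn{n(n-1)/2} pairs of the n set members (not only native
#' contacts). It is invariant to rigid motion of the frame and is zero at
#' the native coordinates.
#'
#' @param coords frame coordinates (N x 3 over all beads).
#' @param reference native coordinates (same shape), or a precomputed n x n
#'   native distance matrix over the set.
#' @param setIdx bead indices of the set (n >= 2).
#' @return d_rms in Angstrom.
#' @export
computeDrms <- function(coords, reference, setIdx) {
  n <- length(setIdx)
  if (n < 2) stop("set must contain at least 2 residues")
  d <- dist(coords[setIdx, , drop = FALSE])
  isDistMat <- is.matrix(reference) && nrow(reference) == n &&
    ncol(reference) == n &&
    !(ncol(reference) == 3 && nrow(reference) == nrow(coords)) &&
    isSymmetric(unname(reference)) && all(abs(diag(reference)) < 1e-12)
  d0 <- if (isDistMat) as.dist(reference)
        else dist(reference[setIdx, , drop = FALSE])
  sqrt(mean((as.numeric(d) - as.numeric(d0))^2))
}

#' d_rms distribution over trajectories
#'
#' Evaluates [computeDrms()] on every retained frame (after discarding the
#' burn-in prefix of each run) and pools the values across replicas.
#'
#' @param trajectories a [Trajectory-class] or list of them.
#' @param model the [GoModel-class] providing the native reference.
#' @param setIdx bead indices of the pocket (or other) set.
#' @param burnInFraction fraction of steps discarded (default 1/3,
#'   matching a production protocol that analyzes the last two thirds).
#' @return list: \code{perFrame} (data.frame replica, step, drms),
#'   \code{mean}, \code{sd}, \code{n}.
#' @export
drmsProfile <- function(trajectories, model, setIdx, burnInFraction = 1 / 3) {
  if (is(trajectories, "Trajectory")) trajectories <- list(trajectories)
  if (!length(trajectories)) stop("need at least one trajectory")
  ref <- model@coords
  rows <- lapply(seq_along(trajectories), function(r) {
    tr <- trajectories[[r]]
    total <- tr@meta$nSteps
    if (burnInFraction * total >= max(tr@step))
      stop("burn-in discards the whole trajectory")
    keep <- which(tr@step >= burnInFraction * total)
    vals <- vapply(tr@frames[keep],
                   function(f) computeDrms(f, ref, setIdx), numeric(1))
    data.frame(replica = r, step = tr@step[keep], drms = vals)
  })
  pf <- do.call(rbind, rows)
  list(perFrame = pf, mean = mean(pf$drms), sd = sd(pf$drms), n = nrow(pf))
}

#' Run a replicated DMD experiment
#'
#' Runs \code{replicas} independent trajectories with seeds
#' \code{baseSeed + 0:(replicas-1)} (different initial velocities per
#' replica) and returns them as a list.
#'
#' @inheritParams runDMD
#' @param replicas number of independent runs (default 8).
#' @param baseSeed seed of the first replica.
#' @return list of [Trajectory-class] objects.
#' @export
runReplicas <- function(model, nSteps, replicas = 8L, baseSeed = 1,
                        temperature = 0.5, snapshotEvery = 1000L,
                        thermostatRate = 1) {
  lapply(seq_len(replicas) - 1L, function(k)
    runDMD(model, nSteps, temperature = temperature, seed = baseSeed + k,
           snapshotEvery = snapshotEvery, thermostatRate = thermostatRate))
}

#' Export a trajectory
#'
#' Writes snapshot frames as a multi-model PDB (one MODEL block per frame)
#' or as plain XYZ.
#'
#' @param trajectory a [Trajectory-class].
#' @param model the [GoModel-class] the run used (provides bead identities).
#' @param path output file.
#' @param format \code{"pdb"} or \code{"xyz"}.
#' @return \code{path}, invisibly.
#' @export
writeTrajectory <- function(trajectory, model, path,
                            format = c("pdb", "xyz")) {
  format <- match.arg(format)
  info <- model@beadInfo
  if (format == "pdb") {
    frames <- lapply(frames(trajectory), function(f)
      structureFromAtoms(data.frame(chain = info$chain, resno = info$resno,
                                    resid = info$resid,
                                    x = f[, 1], y = f[, 2], z = f[, 3])))
    writeStructure(frames, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (k in seq_along(frames(trajectory))) {
      f <- frames(trajectory)[[k]]
      writeLines(c(as.character(nrow(f)),
                   sprintf("step %g", trajectory@step[k]),
                   sprintf("CA %.4f %.4f %.4f", f[, 1], f[, 2], f[, 3])),
                 con)
    }
  }
  invisible(path)
}
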