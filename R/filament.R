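#' @include structio.R
NULL

#' Filament propagation transform of an asymmetric unit
#'
#' Least-squares rigid transform mapping one oligomer of the asymmetric unit
#' onto the equivalent adjacent oligomer — the generating step of the
#' filament. C-alpha beads of the two selections are paired chain-by-chain
#' in the given order, residue-by-residue in sequence order.
#'
#' @param unit a [Structure-class] holding both oligomers.
#' @param selT1,selT2 chain-id vectors of the first and second oligomer, in
#'   corresponding order.
#' @return list from [superpose()]: \code{transform}, \code{rmsd}.
#' @export
unitTransform <- function(unit, selT1, selT2) {
  ca1 <- do.call(rbind, lapply(selT1, function(ch) extractCA(unit, ch)))
  ca2 <- do.call(rbind, lapply(selT2, function(ch) extractCA(unit, ch)))
  if (nrow(ca1) != nrow(ca2))
    stop("unequal residue pairing: ", nrow(ca1), " vs ", nrow(ca2),
         " C-alpha beads")
  superpose(caCoords(ca1), caCoords(ca2))
}

#' Screw decomposition of a rigid transform
#'
#' Any proper rigid motion is a rotation by a twist angle about a unique axis
#' plus a rise along that axis. The twist comes from the rotation-matrix
#' trace, the axis from its rotation eigenvector, the rise from the
#' translation component along the axis, and the axis point from the
#' perpendicular component. The axis sign is chosen so the rise is
#' non-negative; the handedness is the sign of the twist about that axis
#' (+1 = right-handed). \code{repeatsPerTurn = 360 / twist}.
#'
#' @param transform a [RigidTransform-class] with twist >= 0.1 degree
#'   (a near-pure translation has no well-defined axis).
#' @return a [ScrewParameters-class].
#' @export
screwDecompose <- function(transform) {
  R <- transform@rotation
  t <- transform@translation
  cosTh <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  theta <- acos(cosTh)
  if (theta * 180 / pi < 0.1)
    stop("twist below 0.1 degree: near-pure translation, axis ill-defined")
  # axis from the antisymmetric part (sign convention: rotation by +theta)
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (sqrt(sum(w^2)) > 1e-8) {
    axis <- w / sqrt(sum(w^2))
  } else {
    # theta ~ 180 degrees: axis from the +1 eigenvector of R
    ev <- eigen(R)
    k <- which.min(abs(ev$values - 1))
    axis <- Re(ev$vectors[, k])
    axis <- axis / sqrt(sum(axis^2))
  }
  signedTwist <- theta
  rise <- sum(t * axis)
  if (rise < 0) {
    axis <- -axis
    rise <- -rise
    signedTwist <- -theta
  }
  tPerp <- t - sum(t * axis) * axis
  # axis point: solve (I - R) p = t_perp in the plane normal to the axis
  M <- diag(3) - R
  sv <- svd(M)
  dInv <- ifelse(sv$d > 1e-9, 1 / sv$d, 0)
  point <- as.numeric(sv$v %*% (dInv * crossprod(sv$u, tPerp)))
  new("ScrewParameters", twist = theta * 180 / pi, axis = axis,
      point = point, rise = rise,
      repeatsPerTurn = 360 / (theta * 180 / pi),
      handedness = sign(signedTwist))
}

#' Recompose a rigid transform from screw parameters
#' @param screw a [ScrewParameters-class].
#' @return the [RigidTransform-class] it describes.
#' @export
screwCompose <- function(screw) {
  a <- screw@axis
  th <- screw@handedness * screw@twist * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  t <- screw@rise * a + as.numeric((diag(3) - R) %*% screw@point)
  rigidTransform(R, t)
}

#' Rotation + screw-axis helper for tests and fixtures
#' @param axis rotation axis (normalized internally).
#' @param angleDeg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotationMatrix <- function(axis, angleDeg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Replicate a unit into a filament
#'
#' Copy k (k = 0..n-1) is the generating transform applied k times to the
#' unit — the iterative replication/alignment construction of a filament
#' from its asymmetric unit.
#'
#' @param unit a [Structure-class].
#' @param transform the generating [RigidTransform-class].
#' @param n number of copies (n = 1 returns the unit alone).
#' @return a [FilamentModel-class].
#' @export
replicateFilament <- function(unit, transform, n) {
  if (n < 1) stop("n must be at least 1")
  new("FilamentModel", unit = unit, transform = transform,
      nUnits = as.integer(n))
}

#' Materialize filament copies
#' @param filament a [FilamentModel-class].
#' @return list of [Structure-class] copies (element k+1 = transform^k
#'   applied to the unit).
#' @export
filamentCopies <- function(filament) {
  out <- vector("list", filament@nUnits)
  cur <- filament@unit
  out[[1]] <- cur
  if (filament@nUnits > 1)
    for (k in 2:filament@nUnits) {
      cur <- applyTransform(filament@transform, cur)
      out[[k]] <- cur
    }
  out
}

#' Materialize a filament as one structure
#'
#' Concatenates all copies into a single [Structure-class]; chains of copy k
#' are suffixed with the copy index via distinct residue-number offsets kept,
#' and atom serials renumbered.
#'
#' @param filament a [FilamentModel-class].
#' @return a [Structure-class].
#' @export
filamentStructure <- function(filament) {
  copies <- filamentCopies(filament)
  tabs <- lapply(seq_along(copies), function(k) {
    a <- copies[[k]]@atoms
    a$chain <- paste0(a$chain, k)
    a
  })
  a <- do.call(rbind, tabs)
  a$eleno <- seq_len(nrow(a))
  new("Structure", atoms = a)
}

#' Minimum inter-copy C-alpha distance (steric-clash report)
#' @param filament a [FilamentModel-class].
#' @return minimum C-alpha distance between any two distinct copies
#'   (Angstrom).
#' @export
filamentClashReport <- function(filament) {
  copies <- filamentCopies(filament)
  if (length(copies) < 2) return(Inf)
  xyz <- lapply(copies, caCoords)
  best <- Inf
  for (i in seq_along(xyz)[-length(xyz)])
    for (j in (i + 1):length(xyz)) {
      d2 <- min(outer(rowSums(xyz[[i]]^2), rowSums(xyz[[j]]^2), "+") -
                  2 * xyz[[i]] %*% t(xyz[[j]]))
      best <- min(best, sqrt(max(d2, 0)))
    }
  best
}

.principalAxes <- function(xyz) {
  e <- eigen(stats::cov(xyz), symmetric = TRUE)
  # eigenvalues descending: [,1] = largest coordinate variance (long axis,
  # smallest inertia moment); [,3] = smallest variance (plane normal)
  e$vectors
}

#' Kink angle between adjacent filament oligomers
#'
#' The angle between the designated molecular axes of the two oligomers of an
#' asymmetric unit, measuring the bend the junction introduces. Axis rules:
#' \code{"inertia"} uses the principal axis with the smallest inertia moment
#' (largest coordinate variance, the long molecular axis); \code{"plane"}
#' uses the normal of the best-fit plane (smallest variance direction).
#' Axes are lines, so the angle lies in [0, 90] degrees.
#'
#' @param unit a [Structure-class] holding both oligomers.
#' @param selT1,selT2 chain-id vectors of the two oligomers.
#' @param axisRule \code{"inertia"} (default) or \code{"plane"}.
#' @return angle in degrees.
#' @export
kinkAngle <- function(unit, selT1, selT2, axisRule = c("inertia", "plane")) {
  axisRule <- match.arg(axisRule)
  ax <- function(chains) {
    xyz <- caCoords(unit, chains)
    e <- eigen(stats::cov(xyz), symmetric = TRUE)
    rel <- e$values / max(e$values)
    col <- if (axisRule == "inertia") 1 else 3
    if (axisRule == "inertia" && rel[1] - rel[2] < 1e-6)
      stop("degenerate (near-spherical) inertia: axis ill-defined")
    e$vectors[, col]
  }
  u <- ax(selT1); v <- ax(selT2)
  acos(min(1, abs(sum(u * v)))) * 180 / pi
}
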