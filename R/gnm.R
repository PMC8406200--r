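#' @include selection.R
NULL

#' Kirchhoff (connectivity) matrix of a Gaussian network model
#'
#' Each residue is one network node; nodes within the contact cutoff are
#' connected by identical elastic springs. Off-diagonal entries are -1 for
#' connected pairs, 0 otherwise; the diagonal holds the node degree, so all
#' row sums are zero.
#'
#' @param coords node coordinates (N x 3) or an [extractCA()] data.frame.
#' @param cutoff spring cutoff in Angstrom (default 7.5, matching the native
#'   contact definition; 10 is another common choice for C-alpha networks).
#' @return symmetric N x N Kirchhoff matrix.
#' @export
buildKirchhoff <- function(coords, cutoff = 7.5) {
  if (cutoff <= 0) stop("cutoff must be positive")
  xyz <- if (is.data.frame(coords)) caCoords(coords) else as.matrix(coords)
  n <- nrow(xyz)
  if (n < 2) stop("need at least 2 nodes")
  adj <- as.matrix(dist(xyz)) <= cutoff
  diag(adj) <- FALSE
  K <- -1 * adj
  diag(K) <- rowSums(adj)
  K
}

#' Normal-mode decomposition of a Kirchhoff matrix
#'
#' Full eigendecomposition with modes sorted by ascending eigenvalue. Modes
#' with eigenvalue below \code{zeroTol} are zero (rigid-body/disconnection)
#' modes — one per connected component of the network — and are excluded
#' from analysis indexing: internal mode 1 is the lowest non-zero mode. The
#' amplitude of mode k is 1/lambda_k.
#'
#' @param kirchhoff symmetric connectivity matrix from [buildKirchhoff()].
#' @param zeroTol eigenvalue threshold flagging zero modes (default 1e-10).
#' @param cutoff cutoff recorded as metadata (optional).
#' @return a [ModeSpectrum-class].
#' @export
modeDecomposition <- function(kirchhoff, zeroTol = 1e-10, cutoff = NA_real_) {
  if (max(abs(kirchhoff - t(kirchhoff))) > 1e-9)
    stop("Kirchhoff matrix must be symmetric")
  e <- eigen(kirchhoff, symmetric = TRUE)
  ord <- rev(seq_along(e$values))  # ascending
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  vals[abs(vals) < zeroTol] <- abs(vals[abs(vals) < zeroTol])
  new("ModeSpectrum", values = vals, vectors = vecs,
      nZero = as.integer(sum(vals < zeroTol)), zeroTol = zeroTol,
      cutoff = cutoff)
}

#' GNM spectrum of a structure in one call
#' @inheritParams buildKirchhoff
#' @inheritParams modeDecomposition
#' @return a [ModeSpectrum-class].
#' @export
gnmModes <- function(coords, cutoff = 7.5, zeroTol = 1e-10) {
  modeDecomposition(buildKirchhoff(coords, cutoff), zeroTol = zeroTol,
                    cutoff = cutoff)
}

#' Mode amplitudes 1/lambda
#' @param spectrum a [ModeSpectrum-class].
#' @param modes internal mode indices (1 = lowest non-zero mode); default all.
#' @return numeric vector of amplitudes.
#' @export
modeAmplitudes <- function(spectrum, modes = NULL) {
  lam <- spectrum@values[-seq_len(spectrum@nZero)]
  if (is.null(modes)) modes <- seq_along(lam)
  if (any(modes > length(lam))) stop("mode index exceeds available modes")
  1 / lam[modes]
}

.modeVector <- function(spectrum, mode) {
  nz <- spectrum@nZero
  total <- length(spectrum@values)
  if (mode < 1 || mode > total - nz)
    stop("mode index exceeds available non-zero modes")
  list(u = spectrum@vectors[, nz + mode], lambda = spectrum@values[nz + mode])
}

#' Inter-residue dynamic correlation of one mode over a residue set
#'
#' For mode shape u, the pair correlation is
#' \eqn{c_{ij} = u_i u_j / \sqrt{u_i u_i \times u_j u_j}}, which for a single
#' Gaussian-network mode reduces to the sign concordance of the two
#' components (+1 in phase, -1 out of phase). Components with magnitude
#' below \code{tol} times the largest component of the mode are treated as
#' zero and excluded from the pair average. The set mean C is taken over
#' distinct pairs i < j; C = 1 means no deformation of the set in this mode.
#'
#' @param spectrum a [ModeSpectrum-class].
#' @param mode internal (non-zero) mode index.
#' @param setIdx node indices of the residue set (length >= 2).
#' @param tol relative zero tolerance for mode components (default 1e-9).
#' @param minParticipation optional participation floor, as a fraction of the
#'   mode's largest component (default 0 = off). Residues whose component
#'   magnitude falls below it are static in this mode: their sign carries no
#'   information about deformation, so they are excluded from the pair
#'   average. A set with fewer than two participating members does not
#'   deform in the mode and gets C = 1.
#' @return a [ModeCorrelation-class].
#' @export
modeCorrelation <- function(spectrum, mode, setIdx, tol = 1e-9,
                            minParticipation = 0) {
  if (length(setIdx) < 2) stop("set must contain at least 2 residues")
  mv <- .modeVector(spectrum, mode)
  u <- mv$u[setIdx]
  umax <- max(abs(mv$u))
  zero <- abs(u) < tol * umax
  if (sum(!zero) < 2)
    stop("undefined correlation: all set components are numerically zero")
  drop <- zero | abs(u) < minParticipation * umax
  s <- sign(u)
  s[drop] <- NA
  cmat <- outer(s, s)
  diag(cmat)[!drop] <- 1
  C <- if (sum(!drop) < 2) 1
       else mean(cmat[upper.tri(cmat)], na.rm = TRUE)
  new("ModeCorrelation", mode = as.integer(mode), lambda = mv$lambda,
      cmat = cmat, correlation = C)
}

#' Per-mode correlation profile of a residue set
#'
#' Frequency (eigenvalue), amplitude (1/lambda) and mean inter-residue
#' dynamic correlation C for internal modes 1..M — the per-mode profile used
#' for both the pocket set (C_pocket) and the junction interface set
#' (C_interface).
#'
#' @param spectrum a [ModeSpectrum-class].
#' @param setIdx node indices of the residue set.
#' @param modes number of internal modes M, or an explicit index vector
#'   (default 20, a typical "top modes" window).
#' @param tol relative zero tolerance passed to [modeCorrelation()].
#' @param minParticipation participation floor passed to [modeCorrelation()].
#' @return data.frame \code{mode, lambda, amplitude, C}.
#' @export
correlationProfile <- function(spectrum, setIdx, modes = 20L, tol = 1e-9,
                               minParticipation = 0) {
  nInternal <- length(spectrum@values) - spectrum@nZero
  idx <- if (length(modes) == 1L) seq_len(modes) else as.integer(modes)
  if (max(idx) > nInternal)
    stop("requested ", max(idx), " modes but only ", nInternal,
         " non-zero modes exist")
  rows <- lapply(idx, function(k) {
    mc <- modeCorrelation(spectrum, k, setIdx, tol, minParticipation)
    data.frame(mode = k, lambda = mc@lambda, amplitude = 1 / mc@lambda,
               C = mc@correlation)
  })
  do.call(rbind, rows)
}

#' Average correlation profile over several residue sets
#'
#' Computes [correlationProfile()] per set (e.g. per pocket) and returns the
#' per-mode mean C across sets alongside the individual profiles — the two
#' ways of summarizing several pockets into one curve.
#'
#' @param spectrum a [ModeSpectrum-class].
#' @param setList list of node-index vectors.
#' @inheritParams correlationProfile
#' @return list: \code{profile} (data.frame mode, lambda, amplitude, C =
#'   mean over sets), \code{perSet} (list of per-set profiles).
#' @export
pooledCorrelationProfile <- function(spectrum, setList, modes = 20L,
                                     tol = 1e-9, minParticipation = 0) {
  per <- lapply(setList, function(s)
    correlationProfile(spectrum, s, modes, tol, minParticipation))
  base <- per[[1]][, c("mode", "lambda", "amplitude")]
  Cm <- rowMeans(vapply(per, function(p) p$C, numeric(nrow(base))))
  list(profile = cbind(base, C = Cm), perSet = per)
}
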