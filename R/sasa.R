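#' Deterministic quadrature points on the unit sphere
#'
#' Golden-spiral construction: identical output for identical \code{n}, with
#' near-uniform coverage (the centroid of the point set is close to the
#' origin).
#'
#' @param n number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
spherePoints <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  theta <- acos(pmin(1, pmax(-1, z)))
  phi <- k * pi * (3 - sqrt(5))
  cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

# Canonical right-handed frame of a point cloud, equivariant under rigid
# motion: columns are covariance eigenvectors (decreasing eigenvalue), each
# sign-fixed by the third central moment along it. Sphere quadrature points
# are expressed in this frame so that numerically computed areas are exactly
# invariant when the chain moves rigidly (and buried area differences stay
# >= 0, because complex and isolated-chain evaluations see identical
# per-atom point sets).
chainFrame <- function(xyz) {
  if (nrow(xyz) < 3L) return(diag(3))
  xc <- sweep(xyz, 2, colMeans(xyz))
  V <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)$vectors
  for (k in 1:3) {
    p <- xc %*% V[, k]
    s <- sum(p^3)
    denom <- sum(abs(p)^3)
    if (denom > 0 && s / denom < -1e-6) V[, k] <- -V[, k]
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  V
}

#' Shrake--Rupley solvent-accessible surface area
#'
#' Numerical SASA: each atom is inflated by the probe radius and covered
#' with \code{nPoints} deterministic quadrature points; a point is exposed
#' when it lies outside every neighboring inflated sphere. Per-atom area is
#' \code{exposed/nPoints * 4*pi*(r+probe)^2}. Neighbor search is restricted
#' to atoms within \code{r_i + r_j + 2*probe}. Quadrature directions are
#' expressed in each chain's canonical frame, making the result invariant
#' under rigid motion of a chain or of the whole complex.
#'
#' @param x a [DimerComplex-class] or an atom data.frame.
#' @param probe probe radius in Angstrom (1.4 = water).
#' @param nPoints quadrature points per atom.
#' @param radii van der Waals radii table (defaults to the shipped one).
#' @return a [SasaResult-class].
#' @examples
#' # a single atom is an exact sphere: 4*pi*(1.87 + 1.4)^2
#' a <- data.frame(serial = 1L, atomName = "CA", element = "C", altLoc = "",
#'                 resName = "ALA", chainId = "A", resSeq = 1L, iCode = "",
#'                 x = 0, y = 0, z = 0, occupancy = 1)
#' totalArea(computeSasa(a))
#' @seealso [deltaAsa()], [solvationDeltaG()]
#' @export
computeSasa <- function(x, probe = 1.4, nPoints = 960L, radii = NULL) {
  at <- if (is.data.frame(x)) x else atoms(x)
  if (nrow(at) < 1L) stop("no atoms")
  if (is.null(radii)) radii <- loadShipped("vdw_radii.tsv")
  r <- atomRadii(at, radii)
  xyz <- coordMatrix(at)
  n <- nrow(at)
  base <- spherePoints(nPoints)
  rp <- r + probe
  # per-chain oriented quadrature directions
  dirs <- vector("list", 0)
  chainOf <- at$chainId
  for (ch in unique(chainOf)) {
    V <- chainFrame(xyz[chainOf == ch, , drop = FALSE])
    dirs[[ch]] <- base %*% t(V)
  }
  d2 <- crossDist2(xyz, xyz)
  lim2 <- outer(rp, rp, "+")^2
  area <- numeric(n)
  const <- 4 * pi
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < lim2[i, ])
    nb <- nb[nb != i]
    ai <- const * rp[i]^2
    if (!length(nb)) { area[i] <- ai; next }
    pts <- dirs[[chainOf[i]]] * rp[i]
    pts <- sweep(pts, 2, xyz[i, ], "+")
    pd2 <- crossDist2(pts, xyz[nb, , drop = FALSE])
    thr <- matrix(rp[nb]^2, nrow(pd2), length(nb), byrow = TRUE)
    exposed <- rowSums(pd2 < thr) == 0L
    area[i] <- ai * sum(exposed) / nPoints
  }
  keys <- residueKeys(at)
  resArea <- rowsum(area, keys, reorder = FALSE)
  new("SasaResult", atomArea = area,
      residueArea = stats::setNames(as.numeric(resArea), rownames(resArea)),
      total = sum(area), probe = probe, nPoints = as.integer(nPoints))
}

#' Per-atom SASA of each chain in isolation
#'
#' Convenience for pipelines scoring many rigid-body poses of one reference:
#' an isolated chain's area does not change under rigid motion (the
#' quadrature frame moves with the chain), so it can be computed once per
#' reference and passed to [deltaAsa()] / [extractFeatures()].
#'
#' @param x a [DimerComplex-class].
#' @inheritParams computeSasa
#' @return list with numeric elements \code{receptor} and \code{ligand}
#'   (per-atom areas, in each chain's atom order).
#' @export
isolatedChainSasa <- function(x, probe = 1.4, nPoints = 960L, radii = NULL) {
  list(receptor = atomArea(computeSasa(atoms(x, "receptor"), probe, nPoints, radii)),
       ligand = atomArea(computeSasa(atoms(x, "ligand"), probe, nPoints, radii)))
}

#' Buried surface area per residue
#'
#' BSA(residue) = ASA(residue, its chain alone) - ASA(residue, complex).
#' Both evaluations use the same radii and the same per-atom quadrature
#' point sets, so BSA is exactly >= 0: forming the complex can only occlude
#' test points.
#'
#' @param x a [DimerComplex-class].
#' @param params parameter bundle from [ifaceParams()] (probe, nPoints,
#'   radii).
#' @param isolated optional precomputed [isolatedChainSasa()] result for
#'   rigid-body poses of the same reference.
#' @return named numeric of per-residue BSA (Angstrom^2) over all residues,
#'   with attribute \code{"atomDelta"} holding per-atom buried area in the
#'   complex's atom order.
#' @seealso [solvationDeltaG()], [extractFeatures()]
#' @export
deltaAsa <- function(x, params = ifaceParams(), isolated = NULL) {
  at <- atoms(x)
  cplx <- computeSasa(at, params$probe, params$nPoints, params$radii)
  if (is.null(isolated))
    isolated <- isolatedChainSasa(x, params$probe, params$nPoints, params$radii)
  alone <- numeric(nrow(at))
  alone[at$chainId == x@receptorChain] <- isolated$receptor
  alone[at$chainId == x@ligandChain] <- isolated$ligand
  dAtom <- alone - atomArea(cplx)
  # guard against a caller passing isolated areas from a non-rigid variant
  dAtom[dAtom < 0 & dAtom > -1e-9] <- 0
  keys <- residueKeys(at)
  dRes <- rowsum(dAtom, keys, reorder = FALSE)
  out <- stats::setNames(as.numeric(dRes), rownames(dRes))
  attr(out, "atomDelta") <- dAtom
  out
}

#' Solvation-model estimate of the interface binding free energy
#'
#' Atomic-solvation-parameter surrogate:
#' \code{dG = -sum_atoms sigma(class(atom)) * dASA(atom)} (kcal/mol), where
#' \code{dASA} is the area the atom buries on complex formation and
#' \code{sigma} is the per-class solvation parameter (positive for carbon,
#' so burying hydrophobic surface is stabilizing). More negative = more
#' stable. This is a transparent stand-in for a full interface
#' thermodynamics calculation: only the sign/ordering behavior (genuine
#' interfaces more stable than broken poses) is claimed, not absolute
#' magnitudes.
#'
#' @inheritParams deltaAsa
#' @param bsa optional precomputed [deltaAsa()] result for this complex.
#' @return dG in kcal/mol (0 when nothing is buried).
#' @export
solvationDeltaG <- function(x, params = ifaceParams(), bsa = NULL,
                            isolated = NULL) {
  if (is.null(bsa)) bsa <- deltaAsa(x, params, isolated)
  dAtom <- attr(bsa, "atomDelta")
  at <- atoms(x)
  cls <- solvationClasses(at, params$charged)
  sigma <- stats::setNames(params$solvation$sigma, params$solvation$class)
  s <- sigma[cls]
  if (anyNA(s)) {
    warning("atoms with unknown solvation class treated as sigma = 0")
    s[is.na(s)] <- 0
  }
  -sum(s * dAtom)
}
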