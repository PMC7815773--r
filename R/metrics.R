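#' Kabsch optimal superposition
#'
#' Finds the proper rotation R and translation t minimizing the RMSD of
#' \code{Q} mapped onto \code{P} (\code{Q[i,] -> R Q[i,] + t}). The SVD
#' determinant correction enforces a proper rotation (no reflection), and
#' degenerate (e.g. collinear) sets still return a minimizing transform.
#'
#' @param P,Q N x 3 coordinate matrices in atom correspondence (N >= 3).
#' @return a [SuperpositionResult-class].
#' @examples
#' P <- matrix(rnorm(15), 5, 3)
#' kabsch(P, P)  # rmsd 0, identity rotation
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q) || ncol(P) != 3L || ncol(Q) != 3L)
    stop("P and Q must be N x 3 with equal N")
  if (nrow(P) < 3L) stop("at least 3 atom pairs required")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Qc, Pc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rmsd <- sqrt(mean(rowSums((Qc %*% t(R) - Pc)^2)))
  new("SuperpositionResult", rotation = R,
      translation = as.numeric(cp - R %*% cq), rmsd = rmsd,
      nAtoms = nrow(P))
}

# TRUE when the two chains carry identical residue sequences (homodimer):
# the chain labeling of a pose is then arbitrary and both assignments are
# evaluated.
chainsInterchangeable <- function(x) {
  seqOf <- function(at) {
    at <- at[order(at$resSeq, at$iCode), ]
    at$resName[!duplicated(residueKeys(at))]
  }
  identical(seqOf(atoms(x, "receptor")), seqOf(atoms(x, "ligand")))
}

# relabel the model's chains to evaluate the swapped assignment; residue
# numbering is kept so keys line up with the other chain of the reference
swapModelChains <- function(model) {
  at <- atoms(model)
  r <- model@receptorChain; l <- model@ligandChain
  ch <- at$chainId
  at$chainId[ch == r] <- l
  at$chainId[ch == l] <- r
  at <- at[order(match(at$chainId, c(r, l))), , drop = FALSE]
  rownames(at) <- NULL
  new("DimerComplex", atoms = at, receptorChain = r, ligandChain = l,
      label = model@label)
}

modelCandidates <- function(reference, model, chainSwap) {
  cands <- list(model)
  doSwap <- switch(chainSwap,
    never = FALSE,
    always = TRUE,
    auto = chainsInterchangeable(reference))
  if (doSwap) cands <- c(cands, list(swapModelChains(model)))
  cands
}

#' Fraction of native contacts (FNAT)
#'
#' The number of reference-complex cross-chain residue contacts conserved in
#' the model, divided by the number of contacts in the reference; 1.0 means
#' the model reproduces the native interface completely. Contacts are
#' matched by residue-key pair, so reference and model must share the
#' author residue numbering; model residues that are missing simply count as
#' unconserved. For homodimers (identical chain sequences) both chain
#' assignments are evaluated and the larger FNAT reported.
#'
#' @param reference the native [DimerComplex-class] (must have at least one
#'   cross-chain contact).
#' @param model the docked pose, same two chains.
#' @param cutoff heavy-atom contact cutoff (A).
#' @param chainSwap \code{"auto"} (swap only for homodimers),
#'   \code{"never"}, or \code{"always"}.
#' @return fraction in [0, 1].
#' @seealso [irmsd()], [scoreDecoy()]
#' @export
fnat <- function(reference, model, cutoff = 5.0,
                 chainSwap = c("auto", "never", "always")) {
  chainSwap <- match.arg(chainSwap)
  refMap <- residueContacts(reference, cutoff)
  refPairs <- paste(contactPairs(refMap)$receptor, contactPairs(refMap)$ligand)
  if (!length(refPairs)) stop("reference complex has no interface")
  best <- 0
  for (cand in modelCandidates(reference, model, chainSwap)) {
    m <- residueContacts(cand, cutoff)
    mp <- paste(contactPairs(m)$receptor, contactPairs(m)$ligand)
    best <- max(best, sum(refPairs %in% mp) / length(refPairs))
  }
  best
}

irmsdOne <- function(reference, model, interfaceCutoff, atomNames) {
  iface <- interfaceResidues(reference, "contact_distance",
                             cutoff = interfaceCutoff)
  keys <- c(iface$receptor, iface$ligand)
  if (!length(keys)) stop("reference complex has an empty interface")
  pick <- function(at) {
    sel <- residueKeys(at) %in% keys & at$atomName %in% atomNames
    at[sel, , drop = FALSE]
  }
  ra <- pick(atoms(reference))
  ma <- pick(atoms(model))
  rid <- paste(residueKeys(ra), ra$atomName)
  mid <- paste(residueKeys(ma), ma$atomName)
  common <- intersect(rid, mid)
  if (length(common) < 3L)
    stop("fewer than 3 matched interface atoms between reference and model")
  dropped <- length(rid) - length(common)
  P <- coordMatrix(ra)[match(common, rid), , drop = FALSE]
  Q <- coordMatrix(ma)[match(common, mid), , drop = FALSE]
  out <- kabsch(P, Q)@rmsd
  attr(out, "nDropped") <- dropped
  out
}

#' Interface RMSD (iRMSD)
#'
#' Backbone RMSD of the interface region after optimal superposition.
#' Interface residues are defined on the reference only (any heavy atom
#' within \code{interfaceCutoff}, default 10 A, of the other chain), so all
#' decoys of one reference are measured against the same residue set. The
#' backbone atoms (default N, CA, C, O) of those residues from both chains
#' are pooled, matched between reference and model by residue key and atom
#' name (unmatched atoms are dropped pairwise), and superposed jointly with
#' [kabsch()]; the minimized RMSD is returned. Homodimer chain-swap
#' ambiguity is resolved as in [fnat()] (minimum over assignments).
#'
#' @inheritParams fnat
#' @param interfaceCutoff reference interface definition cutoff (A).
#' @param atomNames atoms pooled per interface residue; set to \code{"CA"}
#'   for a CA-only variant.
#' @return RMSD in Angstrom (0 for a model identical to, or a rigid motion
#'   of, the reference).
#' @export
irmsd <- function(reference, model, interfaceCutoff = 10.0,
                  atomNames = c("N", "CA", "C", "O"),
                  chainSwap = c("auto", "never", "always")) {
  chainSwap <- match.arg(chainSwap)
  vals <- vapply(modelCandidates(reference, model, chainSwap),
                 function(cand) as.numeric(
                   irmsdOne(reference, cand, interfaceCutoff, atomNames)),
                 numeric(1))
  min(vals)
}

#' Score a decoy pose against its reference
#'
#' Computes both CAPRI-style quality metrics plus the sizes of the native
#' contact set and reference interface.
#'
#' @inheritParams fnat
#' @param params parameter bundle ([ifaceParams()]): contact and interface
#'   cutoffs.
#' @return a [DecoyQuality-class].
#' @export
scoreDecoy <- function(reference, model, params = ifaceParams(),
                       chainSwap = c("auto", "never", "always")) {
  chainSwap <- match.arg(chainSwap)
  refMap <- residueContacts(reference, params$contactCutoff)
  iface <- interfaceResidues(reference, "contact_distance",
                             cutoff = params$interfaceCutoff)
  new("DecoyQuality",
      fnat = fnat(reference, model, params$contactCutoff, chainSwap),
      irmsd = irmsd(reference, model, params$interfaceCutoff,
                    chainSwap = chainSwap),
      nNativeContacts = nrow(contactPairs(refMap)),
      nInterfaceResidues = length(iface$receptor) + length(iface$ligand))
}
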