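#' Cross-chain residue contacts
#'
#' A receptor residue and a ligand residue are in contact when any pair of
#' their heavy atoms lies within \code{cutoff} (default 5 A, the CAPRI
#' convention used for FNAT). The result is a set: each residue pair appears
#' once.
#'
#' @param x a (filtered) [DimerComplex-class].
#' @param cutoff heavy-atom distance cutoff in Angstrom.
#' @return a [ContactMap-class].
#' @seealso [fnat()], [interfaceResidues()]
#' @export
residueContacts <- function(x, cutoff = 5.0) {
  if (cutoff <= 0) stop("cutoff must be positive")
  rec <- atoms(x, "receptor")
  lig <- atoms(x, "ligand")
  pairs <- data.frame(receptor = character(0), ligand = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(rec) && nrow(lig)) {
    d2 <- crossDist2(coordMatrix(rec), coordMatrix(lig))
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hit)) {
      rk <- residueKeys(rec)[hit[, 1]]
      lk <- residueKeys(lig)[hit[, 2]]
      keep <- !duplicated(paste(rk, lk))
      pairs <- data.frame(receptor = rk[keep], ligand = lk[keep],
                          stringsAsFactors = FALSE)
    }
  }
  new("ContactMap", pairs = pairs, cutoff = cutoff)
}

#' Interface residues of a complex
#'
#' Two definitions are supported: \code{"contact_distance"} selects residues
#' with any heavy atom within \code{cutoff} (default 10 A, the convention
#' used to pool interface residues for iRMSD) of the other chain;
#' \code{"delta_asa"} selects residues burying more than \code{threshold}
#' A^2 (default 0.1) of accessible surface on complex formation -- the
#' area-based interface notion used for feature extraction.
#'
#' @param x a [DimerComplex-class].
#' @param mode \code{"contact_distance"} or \code{"delta_asa"}.
#' @param cutoff distance cutoff (A) for \code{contact_distance} mode.
#' @param threshold BSA threshold (A^2) for \code{delta_asa} mode.
#' @param params parameter bundle (SASA settings for \code{delta_asa} mode).
#' @param bsa optional precomputed [deltaAsa()] result.
#' @return list with character vectors \code{receptor} and \code{ligand} of
#'   residue keys.
#' @export
interfaceResidues <- function(x, mode = c("contact_distance", "delta_asa"),
                              cutoff = 10.0, threshold = 0.1,
                              params = ifaceParams(), bsa = NULL) {
  mode <- match.arg(mode)
  if (mode == "contact_distance") {
    if (cutoff <= 0) stop("cutoff must be positive")
    rec <- atoms(x, "receptor")
    lig <- atoms(x, "ligand")
    if (!nrow(rec) || !nrow(lig))
      return(list(receptor = character(0), ligand = character(0)))
    d2 <- crossDist2(coordMatrix(rec), coordMatrix(lig))
    hitRec <- apply(d2 <= cutoff^2, 1, any)
    hitLig <- apply(d2 <= cutoff^2, 2, any)
    list(receptor = unique(residueKeys(rec)[hitRec]),
         ligand = unique(residueKeys(lig)[hitLig]))
  } else {
    if (threshold <= 0) stop("threshold must be positive")
    if (is.null(bsa)) bsa <- deltaAsa(x, params)
    keys <- names(bsa)[bsa > threshold]
    recKeys <- unique(residueKeys(atoms(x, "receptor")))
    list(receptor = intersect(keys, recKeys),
         ligand = setdiff(keys, recKeys))
  }
}

# shared donor/acceptor-style cross-chain pair scan
crossPairScan <- function(x, selA, selB, dMax, kind) {
  rec <- atoms(x, "receptor")
  lig <- atoms(x, "ligand")
  matchTable <- function(at, tab) {
    hit <- paste(at$resName, at$atomName) %in% paste(tab$res, tab$atom)
    if (any(tab$res == "*"))
      hit <- hit | at$atomName %in% tab$atom[tab$res == "*"]
    which(hit)
  }
  rows <- list()
  addPairs <- function(don, donAt, acc, accAt) {
    if (!length(don) || !length(acc)) return()
    d2 <- crossDist2(coordMatrix(donAt[don, , drop = FALSE]),
                     coordMatrix(accAt[acc, , drop = FALSE]))
    hit <- which(d2 <= dMax^2, arr.ind = TRUE)
    if (!nrow(hit)) return()
    dA <- donAt[don[hit[, 1]], ]
    aA <- accAt[acc[hit[, 2]], ]
    pair <- t(apply(cbind(dA$resName, aA$resName), 1, sort))
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind,
      donorAtom = paste0(residueKeys(dA), ":", dA$atomName),
      acceptorAtom = paste0(residueKeys(aA), ":", aA$atomName),
      residuePair = paste(pair[, 1], pair[, 2], sep = "-"),
      distance = sqrt(d2[hit]),
      stringsAsFactors = FALSE)
  }
  # both directions: donor on receptor/acceptor on ligand and vice versa
  addPairs(matchTable(rec, selA), rec, matchTable(lig, selB), lig)
  addPairs(matchTable(lig, selA), lig, matchTable(rec, selB), rec)
  if (!length(rows))
    return(data.frame(kind = character(0), donorAtom = character(0),
                      acceptorAtom = character(0), residuePair = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  # the same physical atom pair can qualify in both directions (e.g. two
  # hydroxyls); keep each unordered atom pair once
  key <- apply(cbind(out$donorAtom, out$acceptorAtom), 1,
               function(p) paste(sort(p), collapse = "|"))
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-chain hydrogen bonds
#'
#' Distance-only criterion (hydrogens are absent from heavy-atom models):
#' a donor heavy atom on one chain within \code{dMax} (default 3.5 A) of an
#' acceptor heavy atom on the other chain. Donor and acceptor atoms come
#' from editable shipped tables (backbone N donors and side-chain N/O of
#' R, K, H, W, N, Q, S, T, Y; backbone O acceptors and side-chain O of
#' D, E, N, Q, S, T, Y plus histidine ring N). Each record carries its
#' unordered residue-type pair (e.g. \code{"ARG-ASP"}).
#'
#' @param x a (filtered) [DimerComplex-class].
#' @param dMax donor--acceptor heavy-atom distance cutoff (A).
#' @param params parameter bundle supplying the donor/acceptor tables.
#' @return data.frame with columns kind, donorAtom, acceptorAtom,
#'   residuePair, distance.
#' @seealso [saltBridges()], [extractFeatures()]
#' @export
hydrogenBonds <- function(x, dMax = 3.5, params = ifaceParams()) {
  crossPairScan(x, params$donors, params$acceptors, dMax, "hydrogen_bond")
}

#' Cross-chain salt bridges
#'
#' Pairs of oppositely charged side-chain heavy atoms (Asp/Glu carboxylate O
#' against Lys NZ, Arg NE/NH1/NH2 or His ND1/NE2) on opposite chains within
#' \code{dMax} (default 4 A).
#'
#' @inheritParams hydrogenBonds
#' @param dMax charged-atom distance cutoff (A).
#' @return data.frame as in [hydrogenBonds()] with kind
#'   \code{"salt_bridge"}.
#' @export
saltBridges <- function(x, dMax = 4.0, params = ifaceParams()) {
  chg <- params$charged
  neg <- chg[chg$sign == "-", ]
  pos <- chg[chg$sign == "+", ]
  out <- crossPairScan(x, neg, pos, dMax, "salt_bridge")
  out
}
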