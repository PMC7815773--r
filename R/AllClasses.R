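#' @import methods
NULL

ATOM_COLUMNS <- c("serial", "atomName", "element", "altLoc", "resName",
                  "chainId", "resSeq", "iCode", "x", "y", "z", "occupancy")

#' The 20 standard amino-acid three-letter codes
#'
#' Alphabetical vector of the residue types over which the interface feature
#' schema is defined.
#'
#' @export
standardResidues <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

checkAtomTable <- function(atoms) {
  msg <- character(0)
  missing <- setdiff(ATOM_COLUMNS, names(atoms))
  if (length(missing))
    msg <- c(msg, paste("atom table lacks columns:", paste(missing, collapse = ", ")))
  if (!length(msg)) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    if (!all(is.finite(xyz)))
      msg <- c(msg, "non-finite coordinates")
    if (any(!nzchar(atoms$atomName)))
      msg <- c(msg, "empty atom names")
  }
  msg
}

#' Two-chain protein complex
#'
#' An S4 container for a protein--protein dimer: one receptor chain and one
#' ligand chain of heavy atoms with Cartesian coordinates in Angstrom, exactly
#' as given in PDB columns 31--54. Residue identity is the author-assigned
#' (chain, residue number, insertion code) triple; no renumbering is ever
#' performed, so reference and decoy poses of the same complex share residue
#' keys and can be compared contact-by-contact.
#'
#' @slot atoms data.frame of atom records (columns \code{serial},
#'   \code{atomName}, \code{element}, \code{altLoc}, \code{resName},
#'   \code{chainId}, \code{resSeq}, \code{iCode}, \code{x}, \code{y},
#'   \code{z}, \code{occupancy}), receptor atoms first, in file order.
#' @slot receptorChain single chain identifier of the receptor.
#' @slot ligandChain single chain identifier of the ligand.
#' @slot label free-text identifier of the complex.
#'
#' @seealso [parsePDB()], [filterAtoms()], [makeToyDimer()]
#' @export
setClass("DimerComplex",
  representation(atoms = "data.frame", receptorChain = "character",
                 ligandChain = "character", label = "character"),
  validity = function(object) {
    msg <- checkAtomTable(object@atoms)
    ch <- unique(object@atoms$chainId)
    if (length(ch) != 2L)
      msg <- c(msg, sprintf("expected exactly 2 chains, found %d", length(ch)))
    if (object@receptorChain == object@ligandChain)
      msg <- c(msg, "receptor and ligand chain identifiers coincide")
    if (!all(c(object@receptorChain, object@ligandChain) %in% ch))
      msg <- c(msg, "declared chains absent from atom table")
    if (length(msg)) msg else TRUE
  })

#' Solvent-accessible surface area result
#'
#' Per-atom and per-residue solvent-accessible surface areas (Angstrom^2)
#' from the Shrake--Rupley engine, plus the quadrature parameters used.
#'
#' @slot atomArea numeric, one area per input atom.
#' @slot residueArea named numeric, residue key -> summed area.
#' @slot total total area (sum over atoms).
#' @slot probe probe radius (Angstrom).
#' @slot nPoints number of quadrature points per atom.
#' @seealso [computeSasa()]
#' @export
setClass("SasaResult",
  representation(atomArea = "numeric", residueArea = "numeric",
                 total = "numeric", probe = "numeric", nPoints = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (any(object@atomArea < 0)) msg <- c(msg, "negative atom areas")
    if (abs(object@total - sum(object@atomArea)) > 1e-6)
      msg <- c(msg, "total does not equal sum of atom areas")
    if (length(msg)) msg else TRUE
  })

#' Cross-chain residue contact map
#'
#' The set of (receptor residue, ligand residue) pairs with any heavy-atom
#' pair within the distance cutoff. Substrate of the FNAT metric.
#'
#' @slot pairs data.frame with character columns \code{receptor} and
#'   \code{ligand} (residue keys), no duplicates.
#' @slot cutoff heavy-atom distance cutoff (Angstrom).
#' @seealso [residueContacts()], [fnat()]
#' @export
setClass("ContactMap",
  representation(pairs = "data.frame", cutoff = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (!all(c("receptor", "ligand") %in% names(object@pairs)))
      msg <- c(msg, "pairs needs receptor/ligand columns")
    else if (anyDuplicated(paste(object@pairs$receptor, object@pairs$ligand)))
      msg <- c(msg, "duplicate contact pairs")
    if (object@cutoff <= 0) msg <- c(msg, "cutoff must be positive")
    if (length(msg)) msg else TRUE
  })

#' CAPRI-style quality of one decoy pose
#'
#' @slot fnat fraction of the reference complex's cross-chain residue
#'   contacts conserved in the pose, in [0, 1].
#' @slot irmsd interface backbone RMSD (Angstrom) after Kabsch superposition
#'   of the pooled reference-defined interface.
#' @slot nNativeContacts number of contacts in the reference.
#' @slot nInterfaceResidues number of reference interface residues.
#' @seealso [scoreDecoy()], [categorize()]
#' @export
setClass("DecoyQuality",
  representation(fnat = "numeric", irmsd = "numeric",
                 nNativeContacts = "integer", nInterfaceResidues = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (object@fnat < 0 || object@fnat > 1) msg <- c(msg, "fnat outside [0,1]")
    if (object@irmsd < 0) msg <- c(msg, "negative irmsd")
    if (length(msg)) msg else TRUE
  })

#' Optimal rigid superposition result
#'
#' Output of [kabsch()]: the proper rotation and translation minimizing the
#' RMSD of one coordinate set onto another, and the minimized RMSD.
#'
#' @slot rotation 3x3 orthonormal matrix, determinant +1.
#' @slot translation length-3 vector.
#' @slot rmsd minimized root-mean-square deviation (Angstrom).
#' @slot nAtoms number of superposed atom pairs.
#' @export
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", nAtoms = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (object@rmsd < 0) msg <- c(msg, "negative rmsd")
    if (max(abs(crossprod(object@rotation) - diag(3))) > 1e-6 ||
        abs(det(object@rotation) - 1) > 1e-6)
      msg <- c(msg, "rotation not a proper rotation")
    if (length(msg)) msg else TRUE
  })

#' Native/non-native categorization scheme
#'
#' Decoys are native-like when FNAT > 0.8 (FNAT metric) or iRMSD < 5 A
#' (iRMSD metric). Non-native-like decoys are drawn from one of four bands:
#' \describe{
#'   \item{FNAT}{high [0, 0.25]; moderate (0.25, 0.5]; weak (0.5, 0.8];
#'     mixed [0, 0.8]}
#'   \item{iRMSD}{high [15, Inf); moderate [10, 15); weak [5, 10);
#'     mixed [5, Inf)}
#' }
#' "high" means highly distinguishable from native. Values outside the native
#' region and the band are excluded.
#'
#' @slot metric "fnat" or "irmsd".
#' @slot band "high", "moderate", "weak" or "mixed".
#' @seealso [categorize()], [assembleExamples()]
#' @export
setClass("CategoryScheme",
  representation(metric = "character", band = "character"),
  validity = function(object) {
    msg <- character(0)
    if (!object@metric %in% c("fnat", "irmsd"))
      msg <- c(msg, "metric must be 'fnat' or 'irmsd'")
    if (!object@band %in% c("high", "moderate", "weak", "mixed"))
      msg <- c(msg, "band must be high/moderate/weak/mixed")
    if (length(msg)) msg else TRUE
  })

#' Labeled interface feature set
#'
#' Feature matrix plus class labels for classifier training; one row per
#' pose, columns following the fixed feature schema.
#'
#' @slot features numeric matrix, rows = poses, columns = schema features.
#' @slot labels factor with levels \code{non_native}, \code{native}.
#' @slot meta data.frame of per-row metadata (id, fnat, irmsd, source, ...).
#' @slot schemaVersion schema version tag.
#' @seealso [assembleExamples()], [crossValidate()]
#' @export
setClass("LabeledSet",
  representation(features = "matrix", labels = "factor", meta = "data.frame",
                 schemaVersion = "character"),
  validity = function(object) {
    msg <- character(0)
    if (nrow(object@features) != length(object@labels))
      msg <- c(msg, "features/labels length mismatch")
    if (!identical(levels(object@labels), c("non_native", "native")))
      msg <- c(msg, "labels must have levels non_native, native")
    if (length(msg)) msg else TRUE
  })

#' Fitted RBF-SVM interface classifier
#'
#' Wraps an RBF-kernel support vector machine fitted on standardized
#' interface features, with a Platt sigmoid mapping decision values to the
#' probability of the native class. Scaling statistics are estimated on the
#' training data only and stored so prediction reproduces them.
#'
#' @slot fit the underlying \code{e1071::svm} object.
#' @slot center,scale per-feature standardization statistics (constant
#'   features get scale 1).
#' @slot platt numeric c(a, b): p(native) = 1 / (1 + exp(a * f + b)).
#' @slot orientation +1/-1 sign making decision values increase with
#'   native-likeness.
#' @slot schemaVersion feature schema version the model expects.
#' @slot cost,gamma SVM hyperparameters.
#' @seealso [trainInterfaceSvm()], [predictProbability()]
#' @export
setClass("SvmModel",
  representation(fit = "ANY", center = "numeric", scale = "numeric",
                 platt = "numeric", orientation = "numeric",
                 schemaVersion = "character", cost = "numeric",
                 gamma = "numeric"),
  validity = function(object) {
    if (any(object@scale <= 0)) "non-positive feature scales" else TRUE
  })

setMethod("show", "DimerComplex", function(object) {
  a <- object@atoms
  nr <- sum(a$chainId == object@receptorChain)
  cat(sprintf("DimerComplex '%s': receptor %s (%d atoms, %d residues), ligand %s (%d atoms, %d residues)\n",
      object@label,
      object@receptorChain, nr,
      length(unique(residueKeys(a[a$chainId == object@receptorChain, ]))),
      object@ligandChain, nrow(a) - nr,
      length(unique(residueKeys(a[a$chainId == object@ligandChain, ])))))
})

setMethod("show", "SasaResult", function(object) {
  cat(sprintf("SasaResult: %d atoms, total %.2f A^2 (probe %.2f A, %d points)\n",
      length(object@atomArea), object@total, object@probe, object@nPoints))
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap: %d cross-chain residue pairs at %.1f A cutoff\n",
      nrow(object@pairs), object@cutoff))
})

setMethod("show", "DecoyQuality", function(object) {
  cat(sprintf("DecoyQuality: fnat %.3f, irmsd %.3f A (%d native contacts, %d interface residues)\n",
      object@fnat, object@irmsd, object@nNativeContacts,
      object@nInterfaceResidues))
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: rmsd %.4f A over %d atoms\n",
      object@rmsd, object@nAtoms))
})

setMethod("show", "CategoryScheme", function(object) {
  cat(sprintf("CategoryScheme: metric %s, band %s\n", object@metric, object@band))
})

setMethod("show", "LabeledSet", function(object) {
  cat(sprintf("LabeledSet: %d poses x %d features (%d native, %d non-native), schema %s\n",
      nrow(object@features), ncol(object@features),
      sum(object@labels == "native"), sum(object@labels == "non_native"),
      object@schemaVersion))
})

setMethod("show", "SvmModel", function(object) {
  cat(sprintf("SvmModel: RBF SVM (C=%.3g, gamma=%.3g), %d features, schema %s\n",
      object@cost, object@gamma, length(object@center), object@schemaVersion))
})
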