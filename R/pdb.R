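bio3dToAtoms <- function(atom) {
  element <- toupper(trimws(atom$elesy))
  noEl <- is.na(element) | !nzchar(element)
  if (any(noEl)) {
    # infer element from the atom name: strip digits, take first letter,
    # honoring the PDB convention that names like "1HB" are hydrogens
    nm <- gsub("[0-9']", "", toupper(atom$elety[noEl]))
    element[noEl] <- substr(nm, 1, 1)
  }
  data.frame(
    serial = as.integer(atom$eleno),
    atomName = trimws(atom$elety),
    element = element,
    altLoc = ifelse(is.na(atom$alt), "", atom$alt),
    resName = trimws(atom$resid),
    chainId = as.character(atom$chain),
    resSeq = as.integer(atom$resno),
    iCode = ifelse(is.na(atom$insert), "", atom$insert),
    x = atom$x, y = atom$y, z = atom$z,
    occupancy = ifelse(is.na(atom$o), 1, atom$o),
    recordType = atom$type,
    stringsAsFactors = FALSE)
}

#' Read a two-chain complex from PDB format
#'
#' Parses a PDB file (plain or gzip-compressed) or a character vector of PDB
#' lines into a [DimerComplex-class]. Only the first MODEL of multi-model
#' files is used (a decoy is a single pose). Atoms are kept in file order;
#' columns follow the fixed-width PDB convention (coordinates from columns
#' 31--54). Parsing is delegated to \code{bio3d::read.pdb}.
#'
#' @param file path to a PDB file (optionally \code{.gz}), or a character
#'   vector of PDB-format lines (anything containing a newline, or of length
#'   > 1, is treated as literal text).
#' @param chainIds optional length-2 character vector selecting the receptor
#'   and ligand chains, in that order. When \code{NULL} the file must contain
#'   exactly two chains.
#' @param label identifier stored on the complex (defaults to the file name).
#' @return a [DimerComplex-class] (unfiltered: hydrogens, HETATM and
#'   alternate locations are retained; see [filterAtoms()]).
#' @examples
#' pdb <- c(
#'  "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
#'  "ATOM      2  CA  GLY B   1       4.000   0.000   0.000  1.00  0.00           C")
#' parsePDB(pdb, label = "toy")
#' @seealso [writePDB()], [filterAtoms()]
#' @export
parsePDB <- function(file, chainIds = NULL, label = NULL) {
  isText <- length(file) > 1L || grepl("\n", file[1]) ||
    (!file.exists(file[1]) && grepl("^(ATOM|HETATM|MODEL|HEADER)", file[1]))
  if (isText) {
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp))
    writeLines(unlist(strsplit(file, "\n")), tmp)
    path <- tmp
    if (is.null(label)) label <- "pdb-text"
  } else {
    if (!file.exists(file)) stop("file not found: ", file)
    path <- file
    if (grepl("\\.gz$", file)) {
      tmp <- tempfile(fileext = ".pdb")
      on.exit(unlink(tmp))
      con <- gzfile(file, "rt")
      writeLines(readLines(con), tmp)
      close(con)
      path <- tmp
    }
    if (is.null(label)) label <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(file))
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- bio3dToAtoms(pdb$atom)
  chainsPresent <- unique(at$chainId[at$recordType == "ATOM"])
  if (is.null(chainIds)) {
    if (length(chainsPresent) < 2L)
      stop("fewer than two chains present and none requested")
    if (length(chainsPresent) > 2L)
      stop("more than two chains present (", paste(chainsPresent, collapse = ","),
           "); specify chainIds")
    chainIds <- chainsPresent
  } else {
    stopifnot(length(chainIds) == 2L)
    missing <- setdiff(chainIds, chainsPresent)
    if (length(missing))
      stop("requested chain(s) not in file: ", paste(missing, collapse = ", "))
  }
  at <- at[at$chainId %in% chainIds, , drop = FALSE]
  # receptor atoms first, each chain in file order
  at <- at[order(match(at$chainId, chainIds)), , drop = FALSE]
  rownames(at) <- NULL
  new("DimerComplex", atoms = at, receptorChain = chainIds[1],
      ligandChain = chainIds[2], label = label)
}

#' Restrict a complex to heavy atoms of standard residues
#'
#' Removes hydrogens/deuteriums, HETATM records (including waters), residues
#' outside the 20 standard amino-acid types (non-standard residues such as
#' MSE are dropped, not remapped: the feature schema is defined over the 20
#' standard types), and alternate locations other than blank or the given
#' set. Idempotent. A residue losing all of its atoms is dropped with a
#' warning, not an error.
#'
#' @param x a [DimerComplex-class].
#' @param keepAltLoc alternate-location codes to keep (besides blank).
#' @return the filtered [DimerComplex-class].
#' @seealso [parsePDB()]
#' @export
filterAtoms <- function(x, keepAltLoc = "A") {
  at <- x@atoms
  before <- unique(residueKeys(at))
  keep <- at$element != "H" & at$element != "D"
  if ("recordType" %in% names(at)) keep <- keep & at$recordType == "ATOM"
  keep <- keep & at$resName %in% standardResidues()
  keep <- keep & (at$altLoc == "" | at$altLoc %in% keepAltLoc)
  at <- at[keep, , drop = FALSE]
  # a kept alt-loc can still leave duplicate (residue, atom) entries
  at <- at[!duplicated(paste(residueKeys(at), at$atomName)), , drop = FALSE]
  at$recordType <- NULL
  lost <- setdiff(before, unique(residueKeys(at)))
  if (length(lost))
    warning(length(lost), " residue(s) dropped entirely by filtering")
  rownames(at) <- NULL
  new("DimerComplex", atoms = at, receptorChain = x@receptorChain,
      ligandChain = x@ligandChain, label = x@label)
}

#' Apply a rigid-body transform to atoms
#'
#' Maps every coordinate to \code{x' = R x + t}. All non-coordinate fields
#' are preserved, and interatomic distances are exactly conserved up to
#' floating point.
#'
#' @param x a [DimerComplex-class] or an atom data.frame.
#' @param rotation 3x3 orthonormal rotation matrix, determinant +1 (checked
#'   to 1e-6).
#' @param translation length-3 translation vector (Angstrom).
#' @param chain for a complex: transform "both" chains, or only the
#'   "receptor"/"ligand" (used to build rigid-body decoy poses).
#' @return object of the same type with transformed coordinates.
#' @export
rigidTransform <- function(x, rotation = diag(3), translation = c(0, 0, 0),
                           chain = c("both", "receptor", "ligand")) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be orthonormal with determinant +1")
  applyRT <- function(at, rows) {
    xyz <- as.matrix(at[rows, c("x", "y", "z")])
    xyz <- sweep(xyz %*% t(rotation), 2, translation, "+")
    at[rows, c("x", "y", "z")] <- xyz
    at
  }
  if (is.data.frame(x)) return(applyRT(x, seq_len(nrow(x))))
  chain <- match.arg(chain)
  at <- x@atoms
  rows <- switch(chain,
    both = seq_len(nrow(at)),
    receptor = which(at$chainId == x@receptorChain),
    ligand = which(at$chainId == x@ligandChain))
  new("DimerComplex", atoms = applyRT(at, rows),
      receptorChain = x@receptorChain, ligandChain = x@ligandChain,
      label = x@label)
}

#' Write a complex in PDB format
#'
#' Fixed-width PDB output via \code{bio3d::write.pdb}; round-trips through
#' [parsePDB()] reproduce all atom fields and coordinates to 3 decimals.
#' Coordinates outside the format's fixed columns (beyond +-9999.999) are an
#' error.
#'
#' @param x a [DimerComplex-class].
#' @param file output path; when \code{NULL} the PDB text is returned as a
#'   character vector of lines.
#' @return \code{file} (invisibly) or the PDB lines.
#' @seealso [parsePDB()]
#' @export
writePDB <- function(x, file = NULL) {
  at <- x@atoms
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  if (any(abs(xyz) > 9999.999))
    stop("coordinates beyond +-9999.999 cannot be represented in PDB format")
  out <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  bio3d::write.pdb(file = out, xyz = xyz, type = rep("ATOM", nrow(at)),
                   resno = at$resSeq, resid = at$resName, eleno = at$serial,
                   elety = at$atomName, chain = at$chainId,
                   insert = ifelse(at$iCode == "", NA, at$iCode),
                   alt = ifelse(at$altLoc == "", NA, at$altLoc),
                   o = at$occupancy, b = rep(0, nrow(at)),
                   elesy = at$element)
  if (is.null(file)) {
    on.exit(unlink(out))
    return(readLines(out))
  }
  invisible(file)
}
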