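.dockifaceCache <- new.env(parent = emptyenv())

readShippedTable <- function(name) {
  path <- system.file("extdata", name, package = "dockiface")
  if (!nzchar(path)) stop("shipped table not found: ", name)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

loadShipped <- function(name) {
  if (is.null(.dockifaceCache[[name]]))
    .dockifaceCache[[name]] <- readShippedTable(name)
  .dockifaceCache[[name]]
}

#' Analysis parameters with documented defaults
#'
#' One bundle for every tunable cutoff and table in the pipeline. Defaults:
#' \itemize{
#'   \item \code{contactCutoff} 5 A -- heavy-atom residue contact distance
#'     (CAPRI convention) used for FNAT;
#'   \item \code{interfaceCutoff} 10 A -- heavy-atom cutoff defining
#'     interface residues on the reference for iRMSD (CAPRI convention);
#'   \item \code{bsaThreshold} 0.1 A^2 -- buried-surface-area threshold
#'     defining the feature-extraction interface;
#'   \item \code{hbondCutoff} 3.5 A -- donor--acceptor heavy-atom distance
#'     (distance-only criterion; hydrogens are absent);
#'   \item \code{saltBridgeCutoff} 4 A -- charged-atom pair distance;
#'   \item \code{probe} 1.4 A water probe, \code{nPoints} 960 quadrature
#'     points for Shrake--Rupley SASA;
#'   \item \code{clashCutoff} 2 A -- minimum allowed cross-chain heavy-atom
#'     distance in generated decoys;
#'   \item \code{svmCost} 10 and \code{svmGamma} NULL (meaning 1/n_features).
#' }
#' The van der Waals radii, solvation parameters, hydrogen-bond donor and
#' acceptor atoms and charged-atom definitions are read from editable
#' plain-text tables shipped under \code{inst/extdata}; pass modified
#' data.frames here to override them.
#'
#' @param ... named overrides of any listed element.
#' @return named list of parameters.
#' @examples
#' p <- ifaceParams(contactCutoff = 4.5)
#' p$contactCutoff
#' @export
ifaceParams <- function(...) {
  p <- list(
    contactCutoff = 5.0,
    interfaceCutoff = 10.0,
    bsaThreshold = 0.1,
    hbondCutoff = 3.5,
    saltBridgeCutoff = 4.0,
    probe = 1.4,
    nPoints = 960L,
    clashCutoff = 2.0,
    svmCost = 10,
    svmGamma = NULL,
    radii = loadShipped("vdw_radii.tsv"),
    solvation = loadShipped("solvation_params.tsv"),
    donors = loadShipped("hbond_donors.tsv"),
    acceptors = loadShipped("hbond_acceptors.tsv"),
    charged = loadShipped("charged_atoms.tsv"))
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  p
}

# Per-atom van der Waals radius lookup. Most specific rule wins:
# (res, atom) > (*, atom) > element > default. All radii must be in
# (0.5, 3) Angstrom.
atomRadii <- function(atoms, radii) {
  stopifnot(all(radii$radius > 0.5 & radii$radius < 3.0))
  at <- radii[radii$kind == "atom", ]
  el <- radii[radii$kind == "element", ]
  def <- radii$radius[radii$kind == "default"][1]
  r <- rep(NA_real_, nrow(atoms))
  key1 <- paste(atoms$resName, atoms$atomName)
  idx <- match(key1, paste(at$res, at$atom))
  r[!is.na(idx)] <- at$radius[idx[!is.na(idx)]]
  idx2 <- match(paste("*", atoms$atomName), paste(at$res, at$atom))
  fill <- is.na(r) & !is.na(idx2)
  r[fill] <- at$radius[idx2[fill]]
  idx3 <- match(atoms$element, el$atom)
  fill <- is.na(r) & !is.na(idx3)
  r[fill] <- el$radius[idx3[fill]]
  if (anyNA(r)) {
    warning(sum(is.na(r)), " atom(s) missing from radii table; using default ",
            def, " A")
    r[is.na(r)] <- def
  }
  r
}

# Solvation class per atom: charged O/N from the charged-atom table,
# otherwise the element symbol (C, N, O, S).
solvationClasses <- function(atoms, charged) {
  cls <- atoms$element
  key <- paste(atoms$resName, atoms$atomName)
  hit <- match(key, paste(charged$res, charged$atom))
  chg <- !is.na(hit)
  cls[chg & cls == "O"] <- "chargedO"
  cls[chg & cls == "N"] <- "chargedN"
  cls
}
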