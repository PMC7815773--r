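#' Construct a categorization scheme
#'
#' @param metric \code{"fnat"} or \code{"irmsd"}.
#' @param band \code{"high"}, \code{"moderate"}, \code{"weak"} or
#'   \code{"mixed"} (how distinguishable the non-native class is from the
#'   native one).
#' @return a [CategoryScheme-class].
#' @export
categoryScheme <- function(metric = c("fnat", "irmsd"),
                           band = c("high", "moderate", "weak", "mixed")) {
  new("CategoryScheme", metric = match.arg(metric), band = match.arg(band))
}

#' Categorize a decoy as native, non-native or excluded
#'
#' Native: FNAT > 0.8 (FNAT schemes) or iRMSD < 5 A (iRMSD schemes).
#' Non-native when the metric falls in the scheme's band:
#' \itemize{
#'   \item FNAT -- high: FNAT <= 0.25; moderate: 0.25 < FNAT <= 0.5;
#'     weak: 0.5 < FNAT <= 0.8; mixed: FNAT <= 0.8.
#'   \item iRMSD -- high: >= 15 A; moderate: 10 <= iRMSD < 15; weak:
#'     5 <= iRMSD < 10; mixed: iRMSD >= 5.
#' }
#' Anything else is excluded. The three narrow bands partition the
#' non-native region, so the boundary values 0.25/0.5/0.8 (FNAT) and
#' 5/10/15 A (iRMSD) each belong to exactly one band under the half-open
#' convention above.
#'
#' @param quality a [DecoyQuality-class] (or a number: the scheme's metric
#'   value).
#' @param scheme a [CategoryScheme-class].
#' @return \code{"native"}, \code{"non_native"}, or \code{"excluded"}.
#' @export
categorize <- function(quality, scheme) {
  val <- if (is(quality, "DecoyQuality")) {
    if (scheme@metric == "fnat") decoyFnat(quality) else decoyIrmsd(quality)
  } else as.numeric(quality)
  if (scheme@metric == "fnat") {
    if (val > 0.8) return("native")
    inBand <- switch(scheme@band,
      high = val <= 0.25,
      moderate = val > 0.25 && val <= 0.5,
      weak = val > 0.5 && val <= 0.8,
      mixed = TRUE)
  } else {
    if (val < 5) return("native")
    inBand <- switch(scheme@band,
      high = val >= 15,
      moderate = val >= 10 && val < 15,
      weak = val >= 5 && val < 10,
      mixed = TRUE)
  }
  if (inBand) "non_native" else "excluded"
}

#' Tabulate a decoy set
#'
#' @param decoys list of decoy records from [generateDecoys()].
#' @param scheme optional [CategoryScheme-class]; adds a class column.
#' @return data.frame with id, fnat, irmsd (and class).
#' @export
decoyManifest <- function(decoys, scheme = NULL) {
  df <- data.frame(
    id = vapply(decoys, function(d) complexLabel(d$complex), character(1)),
    fnat = vapply(decoys, function(d) decoyFnat(d$quality), numeric(1)),
    irmsd = vapply(decoys, function(d) decoyIrmsd(d$quality), numeric(1)),
    stringsAsFactors = FALSE)
  if (!is.null(scheme))
    df$class <- vapply(decoys, function(d) categorize(d$quality, scheme),
                       character(1))
  df
}

#' Assemble a 1:5 labeled example set for one reference
#'
#' Builds the per-complex training unit: 2 native poses (the reference
#' itself plus the single decoy with the best metric among those passing the
#' native cutoff -- highest FNAT or lowest iRMSD) and 10 non-native poses
#' sampled uniformly (seeded) from the decoys falling in the scheme's band.
#' Features are extracted for all 12 poses.
#'
#' @param reference the native [DimerComplex-class].
#' @param decoys list of records \code{list(complex=, quality=)} as returned
#'   by [generateDecoys()] (scored against this reference).
#' @param scheme a [CategoryScheme-class].
#' @param seed integer seed for the non-native sampling.
#' @param nNonNative band decoys sampled per reference (10 gives the 1:5
#'   ratio).
#' @param strict if TRUE (default), error when no decoy passes the native
#'   cutoff or fewer than \code{nNonNative} decoys are in the band; if
#'   FALSE, return what is available with a \code{"shortfall"} attribute on
#'   the result.
#' @param params parameter bundle for feature extraction.
#' @param isolated optional [isolatedChainSasa()] of the reference, reused
#'   for every rigid-body pose.
#' @return a [LabeledSet-class] with 2 native + \code{nNonNative} rows.
#' @export
assembleExamples <- function(reference, decoys, scheme, seed = 1L,
                             nNonNative = 10L, strict = TRUE,
                             params = ifaceParams(), isolated = NULL) {
  classes <- vapply(decoys, function(d) categorize(d$quality, scheme),
                    character(1))
  metric <- vapply(decoys, function(d)
    if (scheme@metric == "fnat") decoyFnat(d$quality) else decoyIrmsd(d$quality),
    numeric(1))
  nativeIdx <- which(classes == "native")
  bandIdx <- which(classes == "non_native")
  shortfall <- character(0)
  if (!length(nativeIdx)) {
    if (strict) stop("no decoy passes the native cutoff (strict mode)")
    shortfall <- c(shortfall, "no_native_decoy")
    bestNative <- integer(0)
  } else {
    bestNative <- nativeIdx[if (scheme@metric == "fnat") which.max(metric[nativeIdx])
                            else which.min(metric[nativeIdx])]
  }
  if (length(bandIdx) < nNonNative) {
    if (strict) stop("only ", length(bandIdx), " decoys in the '",
                     scheme@band, "' band; ", nNonNative, " required")
    shortfall <- c(shortfall, "band_undersampled")
    chosen <- bandIdx
  } else {
    chosen <- withSeed(seed, sort(sample(bandIdx, nNonNative)))
  }
  if (is.null(isolated))
    isolated <- isolatedChainSasa(reference, params$probe, params$nPoints,
                                  params$radii)
  poses <- c(list(list(complex = reference,
                       quality = new("DecoyQuality", fnat = 1, irmsd = 0,
                                     nNativeContacts = 0L,
                                     nInterfaceResidues = 0L),
                       source = "reference")),
             lapply(decoys[bestNative], function(d) c(d, source = "decoy")),
             lapply(decoys[chosen], function(d) c(d, source = "decoy")))
  labels <- c(rep("native", 1 + length(bestNative)),
              rep("non_native", length(chosen)))
  feats <- t(vapply(poses, function(p)
    as.numeric(extractFeatures(p$complex, params, isolated)),
    numeric(length(featureSchema()))))
  colnames(feats) <- as.character(featureSchema())
  meta <- data.frame(
    id = vapply(poses, function(p) complexLabel(p$complex), character(1)),
    fnat = vapply(poses, function(p) decoyFnat(p$quality), numeric(1)),
    irmsd = vapply(poses, function(p) decoyIrmsd(p$quality), numeric(1)),
    source = vapply(poses, function(p) p$source, character(1)),
    reference = complexLabel(reference),
    stringsAsFactors = FALSE)
  out <- new("LabeledSet", features = feats,
             labels = factor(labels, levels = c("non_native", "native")),
             meta = meta, schemaVersion = FEATURE_SCHEMA_VERSION)
  if (length(shortfall)) attr(out, "shortfall") <- shortfall
  out
}

#' Concatenate labeled sets
#'
#' @param ... [LabeledSet-class] objects sharing one schema version.
#' @return a single [LabeledSet-class].
#' @export
combineLabeledSets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is(sets[[1]], "LabeledSet"))
    sets <- sets[[1]]
  stopifnot(length(sets) >= 1L)
  versions <- unique(vapply(sets, function(s) s@schemaVersion, character(1)))
  if (length(versions) != 1L) stop("schema version mismatch")
  new("LabeledSet",
      features = do.call(rbind, lapply(sets, featureMatrix)),
      labels = factor(unlist(lapply(sets, function(s) as.character(setLabels(s)))),
                      levels = c("non_native", "native")),
      meta = do.call(rbind, lapply(sets, setMeta)),
      schemaVersion = versions)
}

# --- synthetic structure generation -----------------------------------------

# compact self-avoiding CA walk: 3.8 A steps, persistence plus a pull toward
# the running centroid, non-adjacent CA pairs kept >= 4 A apart
caWalk <- function(n, maxRestart = 50L) {
  for (attempt in seq_len(maxRestart)) {
    ca <- matrix(NA_real_, n, 3)
    ca[1, ] <- c(0, 0, 0)
    dir <- randomUnitVector()
    ca[2, ] <- ca[1, ] + 3.8 * dir
    ok <- TRUE
    for (i in 3:n) {
      placed <- FALSE
      for (try in 1:60) {
        pull <- unitVector(colMeans(ca[1:(i - 1), , drop = FALSE]) - ca[i - 1, ])
        cand <- unitVector(0.9 * dir + 1.1 * randomUnitVector() + 0.55 * pull)
        pos <- ca[i - 1, ] + 3.8 * cand
        d2 <- rowSums(sweep(ca[1:(i - 2), , drop = FALSE], 2, pos)^2)
        if (all(d2 > 16)) { ca[i, ] <- pos; dir <- cand; placed <- TRUE; break }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(ca)
  }
  stop("could not build a self-avoiding CA trace")
}

# idealized backbone + CB around a CA trace
buildChainAtoms <- function(ca, resNames, chainId, serialStart = 1L) {
  n <- nrow(ca)
  rows <- vector("list", n)
  serial <- serialStart
  for (i in seq_len(n)) {
    ePrev <- if (i > 1) unitVector(ca[i - 1, ] - ca[i, ]) else
      unitVector(ca[i, ] - ca[i + 1, ])
    eNext <- if (i < n) unitVector(ca[i + 1, ] - ca[i, ]) else
      unitVector(ca[i, ] - ca[i - 1, ])
    zax <- unitVector(pracmaCross(ePrev, eNext))
    names <- c("N", "CA", "C", "O", "CB")
    pos <- rbind(
      ca[i, ] + 1.45 * unitVector(ePrev + 0.35 * zax),
      ca[i, ],
      ca[i, ] + 1.52 * unitVector(eNext + 0.35 * zax),
      ca[i, ] + 1.52 * unitVector(eNext + 0.35 * zax) +
        1.23 * unitVector(zax - 0.4 * eNext),
      ca[i, ] + 1.53 * unitVector(-0.6 * (ePrev + eNext) - zax))
    if (resNames[i] == "GLY") { names <- names[1:4]; pos <- pos[1:4, , drop = FALSE] }
    rows[[i]] <- data.frame(
      serial = seq(serial, length.out = length(names)),
      atomName = names,
      element = substr(names, 1, 1),
      altLoc = "", resName = resNames[i], chainId = chainId,
      resSeq = i, iCode = "",
      x = pos[, 1], y = pos[, 2], z = pos[, 3], occupancy = 1,
      stringsAsFactors = FALSE)
    serial <- serial + length(names)
  }
  do.call(rbind, rows)
}

pracmaCross <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  if (sqrt(sum(v^2)) < 1e-8) {
    # near-collinear neighbors: any perpendicular will do, chosen
    # deterministically from the larger component
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- c(a[2] * p[3] - a[3] * p[2],
           a[3] * p[1] - a[1] * p[3],
           a[1] * p[2] - a[2] * p[1])
  }
  v
}

# residue composition enriched for types frequently driving genuine
# interfaces (R, D, E, F, Y, I), remainder uniform
sampleSequence <- function(n) {
  aa <- standardResidues()
  w <- rep(1, 20)
  w[aa %in% c("ARG", "ASP", "GLU", "PHE", "TYR", "ILE")] <- 3
  sample(aa, n, replace = TRUE, prob = w / sum(w))
}

#' Generate a synthetic two-chain complex
#'
#' Builds a seeded toy dimer: two chains of idealized backbone (N, CA, C, O
#' and CB except glycine) on compact self-avoiding CA traces with 3.8 A
#' CA--CA virtual bonds, residue types drawn from a distribution enriched
#' for interface-prone types (R, D, E, F, Y, I). The ligand chain is placed
#' against the receptor (closest heavy-atom approach between 3.0 and 3.8 A)
#' and placements are retried until at least \code{minInterfaceFraction} of
#' all residues are interfacial (any heavy atom within 10 A of the other
#' chain) and the 5 A residue contact map has at least \code{minContacts}
#' pairs. Identical inputs give bit-identical coordinates.
#'
#' @param nRes residues per chain (>= 5).
#' @param seed integer seed.
#' @param minInterfaceFraction required interfacial residue fraction.
#' @param minContacts required number of cross-chain residue contact pairs
#'   at 5 A, so FNAT takes reasonably fine-grained values on decoys of this
#'   reference; defaults to 8 for chains of 10+ residues and scales down for
#'   shorter ones.
#' @param maxTries placement retries before erroring.
#' @return a filtered [DimerComplex-class] (chains A and B).
#' @seealso [generateDecoys()]
#' @export
makeToyDimer <- function(nRes = 30L, seed = 1L, minInterfaceFraction = 0.2,
                         minContacts = max(3L, min(8L, nRes - 2L)),
                         maxTries = 300L) {
  if (nRes < 5L) stop("nRes must be >= 5")
  withSeed(seed, {
    recSeq <- sampleSequence(nRes)
    ligSeq <- sampleSequence(nRes)
    rec <- buildChainAtoms(caWalk(nRes), recSeq, "A")
    lig0 <- buildChainAtoms(caWalk(nRes), ligSeq, "B",
                            serialStart = max(rec$serial) + 1L)
    recXyz <- as.matrix(rec[, c("x", "y", "z")])
    for (try in seq_len(maxTries)) {
      u <- randomUnitVector()
      spin <- rotationAboutAxis(randomUnitVector(), stats::runif(1, 0, 2 * pi))
      lig <- lig0
      xyz <- as.matrix(lig[, c("x", "y", "z")])
      xyz <- sweep(xyz, 2, colMeans(xyz)) %*% t(spin)
      # slide the ligand in along -u until the chains nestle (closest
      # heavy-atom approach ~3.0-3.8 A, just outside van der Waals contact)
      lo <- 0; hi <- 80
      for (bis in 1:40) {
        d <- (lo + hi) / 2
        cand <- sweep(xyz, 2, colMeans(recXyz) + d * u, "+")
        mind <- sqrt(min(crossDist2(recXyz, cand)))
        if (mind < 3.0) lo <- d else hi <- d
        if (mind >= 3.0 && mind <= 3.8) break
      }
      cand <- sweep(xyz, 2, colMeans(recXyz) + (lo + hi) / 2 * u, "+")
      mind <- sqrt(min(crossDist2(recXyz, cand)))
      if (mind < 3.0 || mind > 3.8) next
      lig[, c("x", "y", "z")] <- cand
      dimer <- new("DimerComplex",
                   atoms = rbind(rec, lig), receptorChain = "A",
                   ligandChain = "B",
                   label = sprintf("toy_n%d_s%d", nRes, seed))
      iface <- interfaceResidues(dimer, "contact_distance", cutoff = 10)
      frac <- (length(iface$receptor) + length(iface$ligand)) / (2 * nRes)
      nContacts <- nrow(contactPairs(residueContacts(dimer, 5)))
      if (frac >= minInterfaceFraction && nContacts >= minContacts)
        return(dimer)
    }
    stop("could not place chains with the required interface fraction")
  })
}

# band membership helpers for stratification
bandCounts <- function(fnatVals, irmsdVals) {
  c(fnat_native = sum(fnatVals > 0.8),
    fnat_high = sum(fnatVals <= 0.25),
    fnat_moderate = sum(fnatVals > 0.25 & fnatVals <= 0.5),
    fnat_weak = sum(fnatVals > 0.5 & fnatVals <= 0.8),
    irmsd_native = sum(irmsdVals < 5),
    irmsd_high = sum(irmsdVals >= 15),
    irmsd_moderate = sum(irmsdVals >= 10 & irmsdVals < 15),
    irmsd_weak = sum(irmsdVals >= 5 & irmsdVals < 10))
}

# proposal ranges for the perturbation magnitude [0, 1] that tend to land in
# each band; actual band assignment always uses the measured metrics
BAND_PROPOSALS <- list(
  fnat_native = c(0.00, 0.035), fnat_weak = c(0.02, 0.10),
  fnat_moderate = c(0.05, 0.18), fnat_high = c(0.12, 1.00),
  irmsd_native = c(0.00, 0.12), irmsd_weak = c(0.15, 0.42),
  irmsd_moderate = c(0.38, 0.65), irmsd_high = c(0.55, 1.00))

#' Generate rigid-body decoy poses of a reference complex
#'
#' Emulates a docking decoy set: the ligand chain is rotated about its
#' centroid (0--180 degrees about a random axis) and translated (0--25 A in
#' a random direction), both scaled by a per-pose magnitude. Poses bringing
#' any cross-chain heavy-atom pair closer than \code{maxClashOverlap}
#' (default 2 A) are rejected and redrawn. Every pose is returned with its
#' measured FNAT and iRMSD. In stratified mode, sampling continues until
#' every FNAT band and every iRMSD band (including the native regions) holds
#' at least \code{k} poses, drawing the magnitude from per-band proposal
#' ranges; classification into bands always uses the measured metrics.
#'
#' @param reference a filtered [DimerComplex-class] with a non-empty
#'   interface.
#' @param n number of poses.
#' @param seed integer seed.
#' @param maxClashOverlap minimum allowed cross-chain heavy-atom distance
#'   (A).
#' @param stratify if TRUE, guarantee band coverage.
#' @param k minimum poses per band in stratified mode.
#' @param maxAttempts overall sampling budget before erroring (stratified
#'   mode errors list the still-empty bands).
#' @param params parameter bundle (contact/interface cutoffs for scoring).
#' @return list of records \code{list(complex, quality)}; see
#'   [decoyManifest()].
#' @export
generateDecoys <- function(reference, n = 60L, seed = 1L,
                           maxClashOverlap = 2.0, stratify = FALSE, k = 5L,
                           maxAttempts = 600L * n, params = ifaceParams()) {
  refMap <- residueContacts(reference, params$contactCutoff)
  if (!nrow(contactPairs(refMap))) stop("reference has no interface")
  recXyz <- coordMatrix(atoms(reference, "receptor"))
  ligAtoms <- atoms(reference, "ligand")
  ligXyz <- coordMatrix(ligAtoms)
  ligCenter <- colMeans(ligXyz)
  withSeed(seed, {
    out <- list()
    fnats <- numeric(0); irmsds <- numeric(0)
    attempts <- 0L
    target <- function() {
      if (!stratify) return(if (length(out) >= n) NULL else "any")
      cnt <- bandCounts(fnats, irmsds)
      need <- names(cnt)[cnt < k]
      if (!length(need) && length(out) >= n) return(NULL)
      # cycle deficient bands at random so one hard band cannot starve the
      # others of sampling budget
      if (length(need)) need[sample.int(length(need), 1)] else "any"
    }
    repeat {
      want <- target()
      if (is.null(want)) break
      attempts <- attempts + 1L
      if (attempts > maxAttempts) {
        if (stratify) {
          cnt <- bandCounts(fnats, irmsds)
          stop("stratification unreachable; underfilled bands: ",
               paste(names(cnt)[cnt < k], collapse = ", "))
        }
        stop("decoy sampling budget exhausted")
      }
      u <- if (identical(want, "any")) stats::runif(1)
           else stats::runif(1, BAND_PROPOSALS[[want]][1],
                             BAND_PROPOSALS[[want]][2])
      R <- rotationAboutAxis(randomUnitVector(), u * pi)
      shift <- u * 25 * randomUnitVector()
      xyz <- sweep(sweep(ligXyz, 2, ligCenter) %*% t(R), 2,
                   ligCenter + shift, "+")
      if (min(crossDist2(recXyz, xyz)) < maxClashOverlap^2) next
      la <- ligAtoms
      la[, c("x", "y", "z")] <- xyz
      pose <- new("DimerComplex",
                  atoms = rbind(atoms(reference, "receptor"), la),
                  receptorChain = reference@receptorChain,
                  ligandChain = reference@ligandChain,
                  label = sprintf("%s_decoy%03d", complexLabel(reference),
                                  length(out) + 1L))
      q <- scoreDecoy(reference, pose, params)
      out[[length(out) + 1L]] <- list(complex = pose, quality = q)
      fnats <- c(fnats, decoyFnat(q)); irmsds <- c(irmsds, decoyIrmsd(q))
    }
    out
  })
}
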