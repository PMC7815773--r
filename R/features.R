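FEATURE_SCHEMA_VERSION <- "iface-274/1.0"

#' The fixed interface feature schema
#'
#' Ordered names of the 274 interface descriptors, stable across runs so
#' feature vectors are positionally comparable:
#' \itemize{
#'   \item \code{asa_<TYPE>} (20): accessible surface area (A^2) of interface
#'     residues of each type, measured in the complex;
#'   \item \code{bsa_<TYPE>} (20): buried surface area (A^2) per type;
#'   \item \code{comp_<TYPE>} (20): interface residue-type frequency, pooled
#'     over both chains (sums to 1, or all 0 when there is no interface);
#'   \item \code{hbond_<T1>_<T2>} (210): cross-chain hydrogen-bond count per
#'     unordered residue-type pair;
#'   \item \code{hbond_total}, \code{salt_bridges}: total counts;
#'   \item \code{interface_area}: sum of per-residue BSA / 2 (A^2);
#'   \item \code{delta_g}: solvation-model binding free energy (kcal/mol).
#' }
#'
#' @return character vector of length 274 with attribute \code{"version"}.
#' @export
featureSchema <- function() {
  aa <- standardResidues()
  pairs <- outer(aa, aa, function(a, b) paste(a, b, sep = "_"))
  pairNames <- pairs[upper.tri(pairs, diag = TRUE)]
  # upper.tri of the alphabetical outer grid enumerates each unordered pair
  # once with T1 <= T2
  nm <- c(paste0("asa_", aa), paste0("bsa_", aa), paste0("comp_", aa),
          paste0("hbond_", sort(pairNames)), "hbond_total", "salt_bridges",
          "interface_area", "delta_g")
  attr(nm, "version") <- FEATURE_SCHEMA_VERSION
  nm
}

#' Extract the interface feature vector of a complex
#'
#' Computes the full fixed-schema descriptor of one interface. The
#' interface is defined area-wise: residues burying more than
#' \code{params$bsaThreshold} A^2 on complex formation. A pose with no
#' interface residues (e.g. a pose where the chains have separated) gets an
#' all-zero vector with the \code{"noInterface"} attribute set, so
#' non-binding poses can still be scored.
#'
#' @param x a filtered [DimerComplex-class].
#' @param params parameter bundle ([ifaceParams()]).
#' @param isolated optional [isolatedChainSasa()] result (exact for
#'   rigid-body poses of the same reference; saves two SASA evaluations per
#'   pose).
#' @return named numeric of length 274 with attributes
#'   \code{"schemaVersion"}, \code{"label"}, and \code{"noInterface"}.
#' @seealso [featureSchema()], [assembleExamples()]
#' @export
extractFeatures <- function(x, params = ifaceParams(), isolated = NULL) {
  schema <- featureSchema()
  v <- stats::setNames(numeric(length(schema)), schema)
  at <- atoms(x)
  cplx <- computeSasa(at, params$probe, params$nPoints, params$radii)
  if (is.null(isolated))
    isolated <- isolatedChainSasa(x, params$probe, params$nPoints, params$radii)
  alone <- numeric(nrow(at))
  alone[at$chainId == x@receptorChain] <- isolated$receptor
  alone[at$chainId == x@ligandChain] <- isolated$ligand
  dAtom <- pmax(alone - atomArea(cplx), 0)
  keys <- residueKeys(at)
  bsaRes <- rowsum(dAtom, keys, reorder = FALSE)
  bsa <- stats::setNames(as.numeric(bsaRes), rownames(bsaRes))
  ifaceKeys <- names(bsa)[bsa > params$bsaThreshold]
  noInterface <- length(ifaceKeys) == 0L
  if (!noInterface) {
    resType <- residueNamesByKey(at)
    types <- resType[ifaceKeys]
    asaRes <- residueArea(cplx)[ifaceKeys]
    for (tp in unique(types)) {
      sel <- types == tp
      v[paste0("asa_", tp)] <- sum(asaRes[sel])
      v[paste0("bsa_", tp)] <- sum(bsa[ifaceKeys][sel])
      v[paste0("comp_", tp)] <- sum(sel) / length(ifaceKeys)
    }
    hb <- hydrogenBonds(x, params$hbondCutoff, params)
    if (nrow(hb)) {
      cnt <- table(gsub("-", "_", hb$residuePair))
      v[paste0("hbond_", names(cnt))] <- as.numeric(cnt)
    }
    v["hbond_total"] <- nrow(hb)
    v["salt_bridges"] <- nrow(saltBridges(x, params$saltBridgeCutoff, params))
    v["interface_area"] <- sum(bsa[ifaceKeys]) / 2
    # dG over all buried area (atoms of sub-threshold residues contribute
    # negligibly since their dASA is < 0.1 A^2)
    cls <- solvationClasses(at, params$charged)
    sigma <- stats::setNames(params$solvation$sigma, params$solvation$class)
    v["delta_g"] <- -sum(sigma[cls] * dAtom)
  }
  attr(v, "schemaVersion") <- FEATURE_SCHEMA_VERSION
  attr(v, "label") <- x@label
  attr(v, "noInterface") <- noInterface
  v
}

#' Screen features for native vs non-native differences
#'
#' Two-sided Mann--Whitney (Wilcoxon rank-sum) test per feature between the
#' native and non-native groups; features with p <= alpha form the
#' significant set. Constant features are reported with p = 1. No
#' multiple-testing correction is applied by default (a Benjamini--Hochberg
#' option is available).
#'
#' @param native,nonNative numeric matrices (rows = poses, columns =
#'   schema features), at least 3 rows each.
#' @param alpha significance level (default 0.01).
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return data.frame with columns feature, p, significant.
#' @export
featureSignificance <- function(native, nonNative, alpha = 0.01,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  native <- as.matrix(native); nonNative <- as.matrix(nonNative)
  if (nrow(native) < 3L || nrow(nonNative) < 3L)
    stop("at least 3 samples per group are required")
  if (ncol(native) != ncol(nonNative)) stop("feature count mismatch")
  p <- vapply(seq_len(ncol(native)), function(j) {
    a <- native[, j]; b <- nonNative[, j]
    if (length(unique(c(a, b))) == 1L) return(1)
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1
  padj <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  nm <- colnames(native)
  if (is.null(nm)) nm <- paste0("f", seq_len(ncol(native)))
  data.frame(feature = nm, p = p, significant = padj <= alpha,
             stringsAsFactors = FALSE)
}

#' Write / read labeled feature tables
#'
#' Tab-separated table with a one-line header: metadata columns (id, label,
#' fnat, irmsd, source when available) followed by the schema features. The
#' schema (version + ordered feature names) is stored as JSON alongside
#' (\code{<file>.schema.json}) and checked on read.
#'
#' @param x a [LabeledSet-class].
#' @param file path of the TSV.
#' @return \code{readFeatureTable} returns a [LabeledSet-class];
#'   \code{writeFeatureTable} returns \code{file} invisibly.
#' @export
writeFeatureTable <- function(x, file) {
  meta <- setMeta(x)
  df <- cbind(meta, label = as.character(setLabels(x)),
              as.data.frame(featureMatrix(x)))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(version = x@schemaVersion,
                            features = colnames(featureMatrix(x))),
                       paste0(file, ".schema.json"), auto_unbox = TRUE)
  invisible(file)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  schemaFile <- paste0(file, ".schema.json")
  schema <- if (file.exists(schemaFile)) {
    js <- jsonlite::read_json(schemaFile, simplifyVector = TRUE)
    stats::setNames(js$features, NULL)
  } else featureSchema()
  version <- if (file.exists(schemaFile))
    jsonlite::read_json(schemaFile, simplifyVector = TRUE)$version
  else FEATURE_SCHEMA_VERSION
  missing <- setdiff(schema, names(df))
  if (length(missing))
    stop("feature table lacks schema columns: ", paste(utils::head(missing, 3),
         collapse = ", "))
  feats <- as.matrix(df[, schema, drop = FALSE])
  metaCols <- setdiff(names(df), c(schema, "label"))
  new("LabeledSet", features = feats,
      labels = factor(df$label, levels = c("non_native", "native")),
      meta = df[, metaCols, drop = FALSE], schemaVersion = version)
}
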