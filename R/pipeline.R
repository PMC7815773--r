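#' End-to-end synthetic benchmark of the classification pipeline
#'
#' Runs the whole pipeline on synthetic data for each seed: generate
#' \code{nRefs} toy dimers, build a stratified rigid-body decoy ladder per
#' reference, assemble the 1:5 labeled set (2 native + 10 non-native poses
#' per reference) under each requested band scheme, pool references, and
#' evaluate the RBF-SVM with repeated 80/20 cross-validation. The expected
#' qualitative structure is that the "high" (highly distinguishable) band is
#' classified best and "weak" worst.
#'
#' @param seeds integer vector; one full pipeline run per seed.
#' @param bands band schemes to evaluate.
#' @param metric \code{"fnat"} or \code{"irmsd"} categorization.
#' @param nRefs toy dimer references per seed.
#' @param nRes residues per chain.
#' @param nDecoys decoy ladder size per reference.
#' @param k minimum poses per band in the stratified ladders (>= 10 so
#'   strict 1:5 assembly always succeeds).
#' @param nTrials cross-validation trials.
#' @param cost,gamma SVM hyperparameters.
#' @param params parameter bundle.
#' @param verbose print per-run progress.
#' @return data.frame with one row per (seed, band): meanAccuracy,
#'   sdAccuracy, meanAuc, sdAuc, n (pooled pose count).
#' @export
simulateBenchmark <- function(seeds = 1:5,
                              bands = c("high", "moderate", "weak"),
                              metric = "fnat", nRefs = 6L, nRes = 30L,
                              nDecoys = 90L, k = 10L, nTrials = 100L,
                              cost = 10, gamma = NULL,
                              params = ifaceParams(), verbose = FALSE) {
  rows <- list()
  for (seed in seeds) {
    refs <- lapply(seq_len(nRefs), function(i)
      makeToyDimer(nRes, seed = 1000L * seed + i))
    iso <- lapply(refs, isolatedChainSasa,
                  probe = params$probe, nPoints = params$nPoints,
                  radii = params$radii)
    ladders <- lapply(seq_len(nRefs), function(i)
      generateDecoys(refs[[i]], n = nDecoys, seed = 1000L * seed + 500L + i,
                     stratify = TRUE, k = k, params = params))
    for (band in bands) {
      scheme <- categoryScheme(metric, band)
      sets <- lapply(seq_len(nRefs), function(i)
        assembleExamples(refs[[i]], ladders[[i]], scheme,
                         seed = 1000L * seed + 700L + i, params = params,
                         isolated = iso[[i]]))
      pooled <- combineLabeledSets(sets)
      cv <- crossValidate(pooled, nTrials = nTrials,
                          seed = 1000L * seed + 900L, cost = cost,
                          gamma = gamma)
      if (verbose)
        message(sprintf("seed %d band %-8s acc %.2f%% auc %.3f", seed, band,
                        cv$summary$meanAccuracy, cv$summary$meanAuc))
      rows[[length(rows) + 1L]] <- data.frame(
        seed = seed, band = band,
        meanAccuracy = cv$summary$meanAccuracy,
        sdAccuracy = cv$summary$sdAccuracy,
        meanAuc = cv$summary$meanAuc, sdAuc = cv$summary$sdAuc,
        n = nrow(featureMatrix(pooled)))
    }
  }
  do.call(rbind, rows)
}
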