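test_that("categorization follows the documented band conventions at the boundaries", {
  sch <- function(m, b) categoryScheme(m, b)
  # FNAT: native strictly above 0.8
  expect_identical(categorize(0.9, sch("fnat", "high")), "native")
  expect_identical(categorize(0.81, sch("fnat", "weak")), "native")
  # high band includes 0 and the 0.25 boundary
  expect_identical(categorize(0.0, sch("fnat", "high")), "non_native")
  expect_identical(categorize(0.20, sch("fnat", "high")), "non_native")
  expect_identical(categorize(0.25, sch("fnat", "high")), "non_native")
  expect_identical(categorize(0.25, sch("fnat", "moderate")), "excluded")
  expect_identical(categorize(0.5, sch("fnat", "moderate")), "non_native")
  expect_identical(categorize(0.5, sch("fnat", "weak")), "excluded")
  expect_identical(categorize(0.6, sch("fnat", "moderate")), "excluded")
  expect_identical(categorize(0.8, sch("fnat", "weak")), "non_native")
  expect_identical(categorize(0.8, sch("fnat", "mixed")), "non_native")
  # iRMSD: native strictly below 5 A; bands closed on the left
  expect_identical(categorize(4.2, sch("irmsd", "high")), "native")
  expect_identical(categorize(5, sch("irmsd", "weak")), "non_native")
  expect_identical(categorize(5, sch("irmsd", "moderate")), "excluded")
  expect_identical(categorize(10, sch("irmsd", "moderate")), "non_native")
  expect_identical(categorize(10, sch("irmsd", "weak")), "excluded")
  expect_identical(categorize(15, sch("irmsd", "high")), "non_native")
  expect_identical(categorize(15, sch("irmsd", "moderate")), "excluded")
  expect_identical(categorize(17, sch("irmsd", "mixed")), "non_native")
})

test_that("the three narrow bands partition the non-native region", {
  fn <- seq(0, 1, by = 0.01)
  for (v in fn) {
    lab <- vapply(c("high", "moderate", "weak"), function(b)
      categorize(v, categoryScheme("fnat", b)), character(1))
    if (v > 0.8) expect_true(all(lab == "native"))
    else expect_equal(sum(lab == "non_native"), 1)
    mixed <- categorize(v, categoryScheme("fnat", "mixed"))
    expect_identical(mixed, if (v > 0.8) "native" else "non_native")
  }
  ir <- seq(0, 25, by = 0.25)
  for (v in ir) {
    lab <- vapply(c("high", "moderate", "weak"), function(b)
      categorize(v, categoryScheme("irmsd", b)), character(1))
    if (v < 5) expect_true(all(lab == "native"))
    else expect_equal(sum(lab == "non_native"), 1)
  }
})

test_that("toy dimers are reproducible, interfacial, and contact-rich", {
  a <- makeToyDimer(30, seed = 1)
  b <- makeToyDimer(30, seed = 1)
  expect_identical(atoms(a), atoms(b))
  expect_error(makeToyDimer(4), ">= 5")
  for (s in 1:20) {
    d <- makeToyDimer(30, seed = s)
    iface <- interfaceResidues(d, "contact_distance", cutoff = 10)
    frac <- (length(iface$receptor) + length(iface$ligand)) / 60
    expect_gte(frac, 0.2)
    expect_gte(nrow(contactPairs(residueContacts(d, 5))), 8)
    # idealized backbone geometry: consecutive CA at the virtual bond length
    ca <- atoms(d, "receptor")
    ca <- as.matrix(ca[ca$atomName == "CA", c("x", "y", "z")])
    expect_equal(unname(sqrt(rowSums(diff(ca)^2))), rep(3.8, nrow(ca) - 1),
                 tolerance = 1e-6)
  }
})

test_that("decoy generation is seeded, clash-free and spans the quality range", {
  ref <- makeToyDimer(20, seed = 9)
  d1 <- generateDecoys(ref, n = 12, seed = 5)
  d2 <- generateDecoys(ref, n = 12, seed = 5)
  expect_identical(decoyManifest(d1), decoyManifest(d2))
  expect_length(d1, 12)
  recXyz <- as.matrix(atoms(ref, "receptor")[, c("x", "y", "z")])
  for (d in d1) {
    ligXyz <- as.matrix(atoms(d$complex, "ligand")[, c("x", "y", "z")])
    expect_gte(sqrt(min(dockiface:::crossDist2(recXyz, ligXyz))), 2.0)
  }
  # an unperturbed pose scores perfectly; a 25 A translation destroys it
  expect_equal(fnat(ref, ref), 1.0)
  gone <- rigidTransform(ref, translation = c(25, 0, 0), chain = "ligand")
  expect_equal(fnat(ref, gone), 0.0)
})

test_that("stratified ladders cover every band with at least k poses", {
  ref <- makeToyDimer(30, seed = 1)
  dec <- generateDecoys(ref, n = 60, seed = 7, stratify = TRUE, k = 3)
  mf <- decoyManifest(dec)
  cnt <- dockiface:::bandCounts(mf$fnat, mf$irmsd)
  expect_true(all(cnt >= 3), info = paste(names(cnt), cnt, collapse = "; "))
})

test_that("1:5 assembly returns 2 natives and 10 band non-natives, deterministically", {
  ref <- makeToyDimer(30, seed = 2)
  dec <- generateDecoys(ref, n = 90, seed = 8, stratify = TRUE, k = 10)
  iso <- isolatedChainSasa(ref)
  for (metric in c("fnat", "irmsd")) for (band in c("high", "moderate", "weak", "mixed")) {
    ls <- assembleExamples(ref, dec, categoryScheme(metric, band), seed = 3,
                           isolated = iso)
    expect_equal(as.integer(table(setLabels(ls))[c("native", "non_native")]),
                 c(2L, 10L))
    meta <- setMeta(ls)
    expect_identical(meta$source[1], "reference")
    # every sampled non-native is in the requested band
    sel <- as.character(setLabels(ls)) == "non_native"
    vals <- if (metric == "fnat") meta$fnat[sel] else meta$irmsd[sel]
    expect_true(all(vapply(vals, function(v)
      categorize(v, categoryScheme(metric, band)), character(1)) == "non_native"))
  }
  s1 <- assembleExamples(ref, dec, categoryScheme("fnat", "high"), seed = 3,
                         isolated = iso)
  s2 <- assembleExamples(ref, dec, categoryScheme("fnat", "high"), seed = 3,
                         isolated = iso)
  expect_identical(featureMatrix(s1), featureMatrix(s2))
})

test_that("assembly shortfalls error in strict mode and flag in lenient mode", {
  ref <- makeToyDimer(15, seed = 3)
  fake <- function(f, r) list(
    complex = ref,
    quality = new("DecoyQuality", fnat = f, irmsd = r,
                  nNativeContacts = 5L, nInterfaceResidues = 10L))
  # no decoy passes the native cutoff
  onlyBad <- lapply(seq(0, 0.2, length.out = 12), function(f) fake(f, 20))
  expect_error(assembleExamples(ref, onlyBad, categoryScheme("fnat", "high"),
                                strict = TRUE), "native cutoff")
  len <- assembleExamples(ref, onlyBad, categoryScheme("fnat", "high"),
                          strict = FALSE)
  expect_true("no_native_decoy" %in% attr(len, "shortfall"))
  expect_equal(sum(setLabels(len) == "native"), 1L)  # the reference itself
  # too few in-band decoys
  sparse <- c(lapply(c(0.9, 0.95), function(f) fake(f, 1)),
              lapply(c(0.1, 0.2), function(f) fake(f, 20)))
  expect_error(assembleExamples(ref, sparse, categoryScheme("fnat", "high"),
                                strict = TRUE), "band")
  len2 <- assembleExamples(ref, sparse, categoryScheme("fnat", "high"),
                           strict = FALSE)
  expect_true("band_undersampled" %in% attr(len2, "shortfall"))
  expect_equal(sum(setLabels(len2) == "non_native"), 2L)
})
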