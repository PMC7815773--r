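test_that("residue contacts respect the distance cutoff exactly", {
  far <- rigidTransform(makeToyDimer(8, seed = 3), translation = c(100, 0, 0),
                        chain = "ligand")
  expect_equal(nrow(contactPairs(residueContacts(far))), 0L)

  near <- mkDimer(mkAtoms(list(1, "CA", "ALA", "A", 1, 0, 0, 0),
                          list(2, "CA", "GLY", "B", 7, 4.9, 0, 0)))
  expect_equal(nrow(contactPairs(residueContacts(near, 5))), 1L)
  justOut <- mkDimer(mkAtoms(list(1, "CA", "ALA", "A", 1, 0, 0, 0),
                             list(2, "CA", "GLY", "B", 7, 5.1, 0, 0)))
  expect_equal(nrow(contactPairs(residueContacts(justOut, 5))), 0L)
  expect_error(residueContacts(near, -1), "positive")
})

test_that("residue contacts equal the brute-force all-pairs scan", {
  for (s in c(2, 8)) {
    d <- makeToyDimer(30, seed = s)
    got <- contactPairs(residueContacts(d, 5))
    expect_identical(sort(paste(got$receptor, got$ligand)), bruteContacts(d, 5))
  }
})

test_that("contacts transpose when receptor and ligand roles swap", {
  d <- makeToyDimer(15, seed = 4)
  swapped <- new("DimerComplex", atoms = atoms(d),
                 receptorChain = ligandChain(d), ligandChain = receptorChain(d),
                 label = "swapped")
  a <- contactPairs(residueContacts(d))
  b <- contactPairs(residueContacts(swapped))
  expect_setequal(paste(a$receptor, a$ligand), paste(b$ligand, b$receptor))
})

test_that("interface residues: contact-distance and delta-ASA definitions", {
  far <- rigidTransform(makeToyDimer(8, seed = 3), translation = c(100, 0, 0),
                        chain = "ligand")
  iface <- interfaceResidues(far, "contact_distance")
  expect_length(iface$receptor, 0)
  expect_length(iface$ligand, 0)

  pairAt8 <- mkDimer(mkAtoms(list(1, "CA", "ALA", "A", 1, 0, 0, 0),
                             list(2, "CA", "GLY", "B", 1, 8, 0, 0)))
  iface8 <- interfaceResidues(pairAt8, "contact_distance", cutoff = 10)
  expect_identical(iface8$receptor, "A:1:")
  expect_identical(iface8$ligand, "B:1:")

  d <- makeToyDimer(12, seed = 5)
  bsa <- deltaAsa(d)
  got <- interfaceResidues(d, "delta_asa", bsa = bsa)
  expect_setequal(c(got$receptor, got$ligand), names(bsa)[bsa > 0.1])
})

test_that("hydrogen bonds: donor-acceptor geometry and residue-pair tagging", {
  mk <- function(dist) mkDimer(mkAtoms(
    list(1, "CA", "ASP", "A", 1, -3, 0, 0),
    list(2, "OD1", "ASP", "A", 1, 0, 0, 0),
    list(3, "CA", "ARG", "B", 1, dist + 3, 0, 0),
    list(4, "NH1", "ARG", "B", 1, dist, 0, 0)))
  hb <- hydrogenBonds(mk(2.9))
  expect_equal(nrow(hb), 1L)
  expect_identical(hb$residuePair, "ARG-ASP")
  expect_equal(hb$distance, 2.9, tolerance = 1e-9)
  expect_equal(nrow(hydrogenBonds(mk(4.0))), 0L)
})

test_that("salt bridges pair only oppositely charged atoms", {
  glulys <- mkDimer(mkAtoms(list(1, "OE1", "GLU", "A", 1, 0, 0, 0),
                            list(2, "CA", "GLU", "A", 1, -3, 0, 0),
                            list(3, "NZ", "LYS", "B", 1, 3.5, 0, 0),
                            list(4, "CA", "LYS", "B", 1, 6.5, 0, 0)))
  sb <- saltBridges(glulys)
  expect_equal(nrow(sb), 1L)
  expect_identical(sb$kind, "salt_bridge")
  gluser <- mkDimer(mkAtoms(list(1, "OE1", "GLU", "A", 1, 0, 0, 0),
                            list(2, "CA", "GLU", "A", 1, -3, 0, 0),
                            list(3, "OG", "SER", "B", 1, 3.0, 0, 0),
                            list(4, "CA", "SER", "B", 1, 6.0, 0, 0)))
  expect_equal(nrow(saltBridges(gluser)), 0L)
})

test_that("bond enumerations equal an exhaustive donor x acceptor scan", {
  params <- ifaceParams()
  inTable <- function(at, tab) {
    paste(at$resName, at$atomName) %in% paste(tab$res, tab$atom) |
      at$atomName %in% tab$atom[tab$res == "*"]
  }
  for (s in c(6, 16)) {
    d <- makeToyDimer(25, seed = s)
    rec <- atoms(d, "receptor"); lig <- atoms(d, "ligand")
    pairs <- character(0)
    for (i in seq_len(nrow(rec))) for (j in seq_len(nrow(lig))) {
      dd <- sqrt(sum((c(rec$x[i], rec$y[i], rec$z[i]) -
                      c(lig$x[j], lig$y[j], lig$z[j]))^2))
      ok <- dd <= 3.5 &&
        ((inTable(rec[i, ], params$donors) && inTable(lig[j, ], params$acceptors)) ||
         (inTable(lig[j, ], params$donors) && inTable(rec[i, ], params$acceptors)))
      if (ok) pairs <- c(pairs, paste(sort(c(
        paste0(residueKeys(rec[i, ]), ":", rec$atomName[i]),
        paste0(residueKeys(lig[j, ]), ":", lig$atomName[j]))), collapse = "|"))
    }
    hb <- hydrogenBonds(d)
    got <- apply(cbind(hb$donorAtom, hb$acceptorAtom), 1,
                 function(p) paste(sort(p), collapse = "|"))
    expect_setequal(got, unique(pairs))
  }
})

test_that("hydrogen-bonded residue pairs are contacts at 5 A", {
  found <- 0L
  for (s in c(3, 14)) {
    d <- makeToyDimer(25, seed = s)
    hb <- hydrogenBonds(d)
    found <- found + nrow(hb)
    cm <- contactPairs(residueContacts(d, 5))
    contactSet <- paste(cm$receptor, cm$ligand)
    donRes <- sub(":[^:]+$", "", hb$donorAtom)
    accRes <- sub(":[^:]+$", "", hb$acceptorAtom)
    for (i in seq_len(nrow(hb))) {
      pair <- c(donRes[i], accRes[i])
      rec <- pair[startsWith(pair, "A:")]
      lig <- pair[startsWith(pair, "B:")]
      expect_true(paste(rec, lig) %in% contactSet)
    }
  }
  expect_gt(found, 0)  # the chosen fixtures do contain hydrogen bonds
})

test_that("interface enumerations are invariant under global rigid motion", {
  d <- makeToyDimer(20, seed = 17)
  set.seed(7)
  d2 <- rigidTransform(d, randomRotation(), rnorm(3, sd = 20))
  a <- contactPairs(residueContacts(d)); b <- contactPairs(residueContacts(d2))
  expect_identical(paste(a$receptor, a$ligand), paste(b$receptor, b$ligand))
  expect_identical(hydrogenBonds(d)$residuePair, hydrogenBonds(d2)$residuePair)
  expect_identical(nrow(saltBridges(d)), nrow(saltBridges(d2)))
  i1 <- interfaceResidues(d); i2 <- interfaceResidues(d2)
  expect_identical(i1, i2)
})
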