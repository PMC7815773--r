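# Fixture builders and independent oracles used across the suite.

mkAtoms <- function(...) {
  # rows: list(serial, atomName, resName, chainId, resSeq, x, y, z)
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) data.frame(
    serial = r[[1]], atomName = r[[2]],
    element = substr(gsub("[0-9]", "", r[[2]]), 1, 1),
    altLoc = "", resName = r[[3]], chainId = r[[4]], resSeq = r[[5]],
    iCode = "", x = r[[6]], y = r[[7]], z = r[[8]], occupancy = 1,
    stringsAsFactors = FALSE)))
}

mkDimer <- function(atoms, receptor = "A", ligand = "B", label = "fixture") {
  new("DimerComplex", atoms = atoms, receptorChain = receptor,
      ligandChain = ligand, label = label)
}

# single-atom-per-residue dimer: receptor residues along x at y=0, ligand
# residues at y=gap; residue i of each chain faces residue i of the other
rowDimer <- function(n, gap = 4, spacing = 10, ligY = NULL) {
  rec <- lapply(seq_len(n), function(i)
    list(i, "CA", "GLY", "A", i, (i - 1) * spacing, 0, 0))
  lig <- lapply(seq_len(n), function(i)
    list(n + i, "CA", "GLY", "B", i, (i - 1) * spacing,
         if (is.null(ligY)) gap else ligY[i], 0))
  mkDimer(do.call(mkAtoms, c(rec, lig)))
}

# ---- oracles ----------------------------------------------------------------

# all-pairs residue contact scan, nested loops, no grids
bruteContacts <- function(dimer, cutoff) {
  rec <- atoms(dimer, "receptor"); lig <- atoms(dimer, "ligand")
  rk <- residueKeys(rec); lk <- residueKeys(lig)
  out <- character(0)
  for (i in seq_len(nrow(rec))) for (j in seq_len(nrow(lig))) {
    d <- sqrt(sum((c(rec$x[i], rec$y[i], rec$z[i]) -
                   c(lig$x[j], lig$y[j], lig$z[j]))^2))
    if (d <= cutoff) out <- c(out, paste(rk[i], lk[j]))
  }
  sort(unique(out))
}

# numerical minimization over Euler angles of the superposed RMSD
optimKabschRmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  rot <- function(a) {
    Rz <- matrix(c(cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1]), 0, 0, 0, 1), 3)
    Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0, sin(a[2]), 0, cos(a[2])), 3)
    Rx <- matrix(c(1, 0, 0, 0, cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3])), 3)
    Rz %*% Ry %*% Rx
  }
  f <- function(a) sqrt(mean(rowSums((Qc %*% t(rot(a)) - Pc)^2)))
  best <- Inf
  for (start in list(c(0, 0, 0), c(pi / 2, 1, -1), c(-2, 2, 0.5), c(3, -1, 2))) {
    r <- stats::optim(start, f, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    best <- min(best, r$value)
  }
  best
}

# Horn quaternion closed-form superposition RMSD (independent of the SVD
# route used by the package)
quatRmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(Qc, Pc)
  K <- matrix(0, 4, 4)
  K[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  K[1, 2] <- K[2, 1] <- M[2, 3] - M[3, 2]
  K[1, 3] <- K[3, 1] <- M[3, 1] - M[1, 3]
  K[1, 4] <- K[4, 1] <- M[1, 2] - M[2, 1]
  K[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  K[2, 3] <- K[3, 2] <- M[1, 2] + M[2, 1]
  K[2, 4] <- K[4, 2] <- M[1, 3] + M[3, 1]
  K[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  K[3, 4] <- K[4, 3] <- M[2, 3] + M[3, 2]
  K[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  lambda <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(Pc^2) + sum(Qc^2) - 2 * lambda) / nrow(P)
  sqrt(max(msd, 0))
}

# independently coded iRMSD: brute-force interface selection + quaternion
# superposition of the pooled backbone
oracleIrmsd <- function(reference, model, cutoff = 10,
                        atomNames = c("N", "CA", "C", "O")) {
  ra <- atoms(reference); ma <- atoms(model)
  rec <- ra[ra$chainId == receptorChain(reference), ]
  lig <- ra[ra$chainId == ligandChain(reference), ]
  ifaceKeys <- character(0)
  for (i in seq_len(nrow(rec))) {
    d <- sqrt((rec$x[i] - lig$x)^2 + (rec$y[i] - lig$y)^2 + (rec$z[i] - lig$z)^2)
    if (any(d <= cutoff)) ifaceKeys <- c(ifaceKeys, residueKeys(rec)[i])
    sel <- d <= cutoff
    ifaceKeys <- c(ifaceKeys, residueKeys(lig)[sel])
  }
  ifaceKeys <- unique(ifaceKeys)
  pickId <- function(at) paste(residueKeys(at), at$atomName)
  rsel <- residueKeys(ra) %in% ifaceKeys & ra$atomName %in% atomNames
  msel <- residueKeys(ma) %in% ifaceKeys & ma$atomName %in% atomNames
  rr <- ra[rsel, ]; mm <- ma[msel, ]
  common <- intersect(pickId(rr), pickId(mm))
  P <- as.matrix(rr[match(common, pickId(rr)), c("x", "y", "z")])
  Q <- as.matrix(mm[match(common, pickId(mm)), c("x", "y", "z")])
  quatRmsd(P, Q)
}

# analytic accessible area of two intersecting probe-inflated spheres
twoSphereArea <- function(r1, r2, d, probe) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  x2 <- d - x1
  h1 <- R1 - x1  # cap of sphere 1 buried inside sphere 2
  h2 <- R2 - x2
  (4 * pi * R1^2 - 2 * pi * R1 * h1) + (4 * pi * R2^2 - 2 * pi * R2 * h2)
}

# plain Shrake-Rupley with a fixed global point orientation and no neighbor
# pruning; independent of the package engine
plainSasa <- function(at, radii, probe = 1.4, n = 4000) {
  k <- seq_len(n)
  gz <- 1 - (2 * k - 1) / n
  th <- acos(pmin(1, pmax(-1, gz)))
  ph <- k * pi * (3 - sqrt(5))
  pts0 <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  xyz <- as.matrix(at[, c("x", "y", "z")])
  r <- dockiface:::atomRadii(at, radii)
  area <- numeric(nrow(at))
  for (i in seq_len(nrow(at))) {
    p <- sweep(pts0 * (r[i] + probe), 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n)
    for (j in seq_len(nrow(at))) {
      if (j == i) next
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
            (p[, 3] - xyz[j, 3])^2
      exposed <- exposed & d2 > (r[j] + probe)^2
    }
    area[i] <- 4 * pi * (r[i] + probe)^2 * mean(exposed)
  }
  area
}

randomRotation <- function() {
  ax <- c(stats::rnorm(3)); ax <- ax / sqrt(sum(ax^2))
  dockiface:::rotationAboutAxis(ax, stats::runif(1, 0, 2 * pi))
}
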