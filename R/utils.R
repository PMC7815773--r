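# Internal helpers shared across modules.

#' Residue keys of an atom table
#'
#' Residue identity throughout the package is the author-assigned triple
#' (chain, residue number, insertion code), encoded as the string
#' \code{"chain:resSeq:iCode"}. Keys are never renumbered, so reference and
#' decoy poses of the same complex stay comparable.
#'
#' @param atoms atom data.frame (see [DimerComplex-class]).
#' @return character vector, one key per atom row.
#' @export
residueKeys <- function(atoms) {
  sprintf("%s:%d:%s", atoms$chainId, atoms$resSeq, atoms$iCode)
}

# residue name of the first atom of each key, named by key
residueNamesByKey <- function(atoms) {
  keys <- residueKeys(atoms)
  first <- !duplicated(keys)
  stats::setNames(atoms$resName[first], keys[first])
}

# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

unitVector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(1, 0, 0) else v / n
}

# Rotation matrix for angle (radians) about unit axis (Rodrigues).
rotationAboutAxis <- function(axis, angle) {
  u <- unitVector(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

randomUnitVector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# squared cross-set distances: rows of A (n x 3) vs rows of B (m x 3)
crossDist2 <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  outer(a2, b2, "+") - 2 * tcrossprod(A, B)
}

coordMatrix <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])
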