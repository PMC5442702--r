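# Internal geometry and table helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

# Angle at vertex b of the triple a-b-c, degrees.
.angle3 <- function(a, b, c) {
  u <- .unit(a - b)
  v <- .unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# Optimal rotation (Kabsch, via SVD) mapping centered P onto centered Q.
# P, Q: n x 3 matrices of paired coordinates. Returns the 3x3 rotation R
# such that P %*% R best matches Q in least squares.
.kabschRotation <- function(P, Q) {
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# Place atom D given positions of A, B, C, the bond length |C-D|, the
# angle B-C-D (degrees) and the torsion A-B-C-D (degrees). Standard
# internal-to-Cartesian (NeRF) construction.
.placeAtom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  bc <- .unit(c - b)
  n <- .unit(.cross3(b - a, bc))
  m <- cbind(bc, .cross3(n, bc), n)
  as.numeric(c + m %*% d2)
}

# Cross product without pulling in an extra dependency.
.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Near-uniform points on the unit sphere (golden-spiral / Fibonacci).
# Deterministic for a given n.
.spherePoints <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Bondi van der Waals radii (Angstrom) by element symbol.
.BONDI <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
            P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

.vdwRadius <- function(element) {
  el <- toupper(trimws(element))
  r <- .BONDI[el]
  if (anyNA(r)) {
    bad <- unique(el[is.na(r)])
    stop("no van der Waals radius for element(s): ",
         paste(bad, collapse = ", "))
  }
  unname(r)
}

# Infer the element symbol from a PDB atom name when columns 77-78 are
# blank: first alphabetic character, except obvious two-letter cases.
.elementFromName <- function(name) {
  nm <- toupper(trimws(name))
  el <- substr(gsub("[^A-Z]", "", nm), 1, 1)
  el[nm == "SE"] <- "SE"
  el
}

# 3-letter -> 1-letter amino-acid code; MSE maps to M, unknowns to X.
.AA321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
            MSE = "M")

.aa321 <- function(name3) {
  a <- .AA321[toupper(trimws(name3))]
  a[is.na(a)] <- "X"
  unname(a)
}

.AA123 <- stats::setNames(names(.AA321)[1:20], unname(.AA321)[1:20])

.aa123 <- function(aa1) {
  a <- .AA123[toupper(aa1)]
  a[is.na(a)] <- "UNK"
  unname(a)
}

.AA20 <- sort(unname(.AA321)[1:20])

# Run a block with a private RNG stream derived from `seed`, restoring
# (or clearing) the global .Random.seed afterwards.
.withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  force(code)
}
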