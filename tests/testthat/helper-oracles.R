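# Independent scoring oracles and small fixture builders used across
# the suite. The aligners here share only the scoring *convention*
# with the package (BLOSUM62, gap of length L costs open + L * ext),
# not any code path.

.blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

subScore <- function(a, b) .blosum62[a, b]

# Affine-gap global alignment score by an independent Gotoh dynamic
# program (three-state recursion).
gotohScore <- function(sa, sb, open = 10, ext = 0.5) {
  a <- strsplit(sa, "")[[1]]
  b <- strsplit(sb, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e18
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- subScore(a[i], b[j])
      M[i + 1, j + 1] <- s + max(M[i, j], Ix[i, j], Iy[i, j])
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - (open + ext),
                              Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - (open + ext),
                              Iy[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# True exhaustive enumeration over every gapped alignment (monotone
# edit path), scoring affine gaps directly. Exponential; only for
# very short sequences. Validates the Gotoh oracle.
enumAlignScore <- function(sa, sb, open = 10, ext = 0.5) {
  a <- strsplit(sa, "")[[1]]
  b <- strsplit(sb, "")[[1]]
  best <- -Inf
  rec <- function(i, j, last, acc) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, acc)
      return(invisible())
    }
    if (i <= length(a) && j <= length(b))
      rec(i + 1, j + 1, "m", acc + subScore(a[i], b[j]))
    if (i <= length(a))
      rec(i + 1, j, "x",
          acc - ext - if (last == "x") 0 else open)
    if (j <= length(b))
      rec(i, j + 1, "y",
          acc - ext - if (last == "y") 0 else open)
  }
  rec(1, 1, "m", 0)
  best
}

aaLetters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randAaSeq <- function(n) paste(sample(aaLetters, n, replace = TRUE),
                               collapse = "")

# Build a StructureModel from a compact atom spec.
mkModel <- function(df, chain = "A") {
  df$resname <- df$resname %||% "GLY"
  df$bfactor <- df$bfactor %||% 10
  df$element <- df$element %||% substr(df$name, 1, 1)
  df$serial <- seq_len(nrow(df))
  df$altloc <- df$altloc %||% " "
  df$chain <- chain
  df$icode <- " "
  df$occupancy <- df$occupancy %||% 1
  cols <- c("serial", "name", "altloc", "resname", "chain", "resnum",
            "icode", "x", "y", "z", "occupancy", "bfactor", "element")
  new("StructureModel", atoms = df[order(df$resnum), cols])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Constant-coordinate trajectory from a StructureModel.
staticTrajectory <- function(model, nframes, dt = 1) {
  xyz <- as.matrix(atomTable(model)[, c("x", "y", "z")])
  coords <- array(NA_real_, c(nframes, nrow(xyz), 3))
  for (f in seq_len(nframes)) coords[f, , ] <- xyz
  new("Trajectory", atoms = atomTable(model), coords = coords, dt = dt)
}

# Handcrafted 3-residue PDB text (CA only) with given B-factors.
toyPdbLines <- function(resnums = 1:3, b = c(10, 20, 30),
                        resnames = c("ALA", "GLY", "SER")) {
  sprintf(
    "ATOM  %5d  CA  %3s A%4d      %6.3f   0.000   0.000  1.00 %5.2f           C",
    seq_along(resnums), resnames, resnums, seq_along(resnums) * 3.8, b)
}
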