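#' @include AllClasses.R AllGenerics.R
NULL

.WATER <- c("HOH", "WAT", "DOD", "H2O")

# Vectorized fixed-width parse of PDB ATOM/HETATM lines. `lineno` are
# the 1-based line numbers in the source file, used in error messages.
.parseAtomLines <- function(lines, lineno) {
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(!is.finite(v) & trimws(s) != "")
    if (length(bad) > 0)
      stop("PDB parse error at line ", lineno[bad[1]], ": bad ", what,
           " field '", trimws(s[bad[1]]), "'", call. = FALSE)
    v
  }
  # pad short lines so substr never runs off the end
  lines <- formatC(lines, width = -80)
  x <- num(substr(lines, 31, 38), "x")
  y <- num(substr(lines, 39, 46), "y")
  z <- num(substr(lines, 47, 54), "z")
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    bad <- which(is.na(x) | is.na(y) | is.na(z))[1]
    stop("PDB parse error at line ", lineno[bad],
         ": missing coordinate", call. = FALSE)
  }
  occ <- num(substr(lines, 55, 60), "occupancy")
  occ[is.na(occ)] <- 1
  b <- num(substr(lines, 61, 66), "B-factor")
  b[is.na(b)] <- 0
  serial <- suppressWarnings(as.integer(trimws(substr(lines, 7, 11))))
  serial[is.na(serial)] <- seq_along(lines)[is.na(serial)]
  resnum <- suppressWarnings(as.integer(trimws(substr(lines, 23, 26))))
  if (anyNA(resnum))
    stop("PDB parse error at line ", lineno[which(is.na(resnum))[1]],
         ": bad residue number", call. = FALSE)
  name <- trimws(substr(lines, 13, 16))
  element <- trimws(substr(lines, 77, 78))
  noel <- element == ""
  element[noel] <- .elementFromName(name[noel])
  data.frame(
    record = trimws(substr(lines, 1, 6)),
    serial = serial,
    name = name,
    altloc = substr(lines, 17, 17),
    resname = trimws(substr(lines, 18, 20)),
    chain = substr(lines, 22, 22),
    resnum = resnum,
    icode = substr(lines, 27, 27),
    x = x, y = y, z = z,
    occupancy = occ, bfactor = b,
    element = toupper(element),
    stringsAsFactors = FALSE)
}

# Collapse alternate locations: per (chain, resnum, icode, atom name)
# keep the record with the highest occupancy; ties go to the
# alphabetically first altloc. The kept atom's occupancy is left as is.
.collapseAltloc <- function(a) {
  key <- paste(a$chain, a$resnum, a$icode, a$name, sep = "\r")
  o <- order(key, -a$occupancy, a$altloc)
  a <- a[o, , drop = FALSE]
  a[!duplicated(key[o]), , drop = FALSE]
}

.orderAtoms <- function(a) {
  a <- a[order(a$chain, a$resnum, a$icode, a$serial), , drop = FALSE]
  rownames(a) <- NULL
  a
}

#' Read a PDB-format structure
#'
#' Parses the ATOM (and optionally HETATM) records of a PDB-dialect
#' text file into a \linkS4class{StructureModel}. Waters are always
#' excluded; other hetero groups only when \code{hetero = TRUE}.
#' Alternate locations are collapsed to the highest-occupancy record
#' (ties: alphabetically first altloc). For multi-model files only the
#' first model is read (see \code{\link{readTrajectory}}).
#'
#' @param path path to a PDB file.
#' @param chain optional chain identifier to extract; an error is
#'   raised if the chain is absent.
#' @param hetero logical, keep non-water HETATM records.
#' @return A \linkS4class{StructureModel}.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(c(
#'  "ATOM      1  CA  ALA A   1      11.000  10.000  10.000  1.00 10.00",
#'  "ATOM      2  CA  GLY A   2      14.800  10.000  10.000  1.00 20.00"),
#'  pdb)
#' readStructure(pdb)
#' @export
readStructure <- function(path, chain = NULL, hetero = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  # restrict to the first model when MODEL records are present
  mstart <- which(trimws(rec) == "MODEL")
  if (length(mstart) > 1) lines <- lines[seq_len(mstart[2] - 1)]
  rec <- substr(lines, 1, 6)
  keep <- rec == "ATOM  " | (hetero & rec == "HETATM") | rec == "ATOM"
  idx <- which(keep)
  if (length(idx) == 0)
    stop("PDB parse error: no ATOM records in '", path, "'")
  a <- .parseAtomLines(lines[idx], idx)
  a <- a[!(a$resname %in% .WATER), , drop = FALSE]
  if (!is.null(chain)) {
    if (!chain %in% a$chain)
      stop("chain '", chain, "' not found in '", path, "' (present: ",
           paste(sort(unique(a$chain)), collapse = ","), ")")
    a <- a[a$chain == chain, , drop = FALSE]
  }
  a <- .collapseAltloc(a)
  a$record <- NULL
  new("StructureModel", atoms = .orderAtoms(a), modelId = 1L)
}

#' Write a structure or trajectory as PDB text
#'
#' Coordinates are written with 3 decimals and B-factors with 2, so a
#' read/write round trip preserves them to that precision. Trajectory
#' frames are delimited with MODEL/ENDMDL records.
#'
#' @param x a \linkS4class{StructureModel} or \linkS4class{Trajectory}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeStructure <- function(x, path) {
  if (is(x, "Trajectory")) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    nf <- nFrames(x)
    for (i in seq_len(nf)) {
      writeLines(sprintf("MODEL %8d", i), con)
      writeLines(.formatAtomLines(x@atoms, x@coords[i, , , drop = TRUE]),
                 con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    return(invisible(path))
  }
  stopifnot(is(x, "StructureModel"))
  a <- x@atoms
  writeLines(c(.formatAtomLines(a), "TER", "END"), path)
  invisible(path)
}

.formatAtomLines <- function(a, xyz = NULL) {
  if (is.null(xyz)) xyz <- cbind(a$x, a$y, a$z)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  nm <- ifelse(nchar(a$name) >= 4, sprintf("%-4s", a$name),
               sprintf(" %-3s", a$name))
  sprintf("ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$serial %% 100000, nm, a$altloc, a$resname, a$chain,
          a$resnum, a$icode, xyz[, 1], xyz[, 2], xyz[, 3],
          a$occupancy, a$bfactor, a$element)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Frames are MODEL/ENDMDL blocks in file order; a file without MODEL
#' records yields a single-frame trajectory (static-structure analysis
#' mode). All frames must share the same atoms (count, names, residue
#' numbers); a mismatch raises an error naming the offending frame.
#'
#' @param path path to a (multi-model) PDB file.
#' @param dt time between consecutive frames, ps.
#' @return A \linkS4class{Trajectory}.
#' @export
readTrajectory <- function(path, dt = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(dt > 0)
  lines <- readLines(path, warn = FALSE)
  rec <- trimws(substr(lines, 1, 6))
  mstart <- which(rec == "MODEL")
  isatom <- rec == "ATOM"
  idx <- which(isatom)
  if (length(idx) == 0)
    stop("PDB parse error: no ATOM records in '", path, "'")
  frame <- if (length(mstart) == 0) rep(1L, length(idx))
           else findInterval(idx, mstart)
  if (any(frame == 0))
    stop("PDB parse error: ATOM records before the first MODEL record")
  a <- .parseAtomLines(lines[idx], idx)
  a <- cbind(a, frame = frame)
  a <- a[!(a$resname %in% .WATER), , drop = FALSE]
  nf <- max(a$frame)
  counts <- tabulate(a$frame, nbins = nf)
  if (length(unique(counts)) != 1) {
    bad <- which(counts != counts[1])[1]
    stop("topology mismatch at frame ", bad, ": ", counts[bad],
         " atoms, expected ", counts[1])
  }
  n <- counts[1]
  first <- a[a$frame == 1L, , drop = FALSE]
  sig <- function(d) paste(d$name, d$chain, d$resnum, d$icode, sep = "\r")
  ref_sig <- sig(first)
  coords <- array(NA_real_, dim = c(nf, n, 3))
  for (i in seq_len(nf)) {
    fi <- a[a$frame == i, , drop = FALSE]
    if (!identical(sig(fi), ref_sig))
      stop("topology mismatch at frame ", i,
           ": atom identities differ from frame 1")
    coords[i, , ] <- as.matrix(fi[, c("x", "y", "z")])
  }
  first$record <- NULL
  first$frame <- NULL
  rownames(first) <- NULL
  new("Trajectory", atoms = first, coords = coords, dt = dt)
}

#' Extract a single frame of a trajectory as a structure
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param i frame index (1-based).
#' @return A \linkS4class{StructureModel}.
#' @export
trajectoryFrame <- function(traj, i) {
  stopifnot(is(traj, "Trajectory"), i >= 1, i <= nFrames(traj))
  a <- traj@atoms
  a$x <- traj@coords[i, , 1]
  a$y <- traj@coords[i, , 2]
  a$z <- traj@coords[i, , 3]
  new("StructureModel", atoms = .orderAtoms(a), modelId = as.integer(i))
}

# Per-residue first-occurrence table preserving atom order.
.residueTable <- function(a) {
  key <- paste(a$chain, a$resnum, a$icode, sep = "\r")
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resnum = a$resnum[first],
             icode = a$icode[first], resname = a$resname[first],
             key = key[first], stringsAsFactors = FALSE)
}

#' Extract the C-alpha B-factor profile of a structure
#'
#' One value per residue possessing a CA atom, in residue order;
#' residues without a CA are skipped with a warning giving their count.
#'
#' @param model a \linkS4class{StructureModel}.
#' @return A \linkS4class{BFactorProfile} labelled with author residue
#'   numbers.
#' @export
extractCaProfile <- function(model) {
  stopifnot(is(model, "StructureModel"))
  a <- model@atoms
  if (nrow(a) == 0) stop("empty structure")
  res <- .residueTable(a)
  ca <- a[a$name == "CA" & a$element != "CA", , drop = FALSE]
  ca_key <- paste(ca$chain, ca$resnum, ca$icode, sep = "\r")
  hit <- match(res$key, ca_key)
  skipped <- sum(is.na(hit))
  if (skipped == nrow(res))
    stop("empty profile: structure has no CA atoms")
  if (skipped > 0)
    warning(skipped, " residue(s) without a CA atom skipped")
  keep <- !is.na(hit)
  if (any(ca$bfactor[hit[keep]] < 0))
    stop("negative B-factor in the structure")
  new("BFactorProfile",
      resnums = as.integer(res$resnum[keep]),
      values = ca$bfactor[hit[keep]],
      chain = res$chain[keep][1])
}

#' Extract the one-letter sequence of a structure
#'
#' Residues are reported in author-numbering order; non-standard
#' residues map to 'X' (selenomethionine MSE maps to 'M').
#'
#' @param model a \linkS4class{StructureModel}.
#' @return A list with \code{sequence} (single string) and
#'   \code{resnums} (integer vector of the same length).
#' @export
extractSequence <- function(model) {
  stopifnot(is(model, "StructureModel"))
  a <- model@atoms
  if (nrow(a) == 0) stop("empty structure")
  res <- .residueTable(a)
  list(sequence = paste(.aa321(res$resname), collapse = ""),
       resnums = as.integer(res$resnum))
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  out <- character(0)
  for (i in seq_along(seqs)) {
    body <- gsub("(.{60})", "\\1\n", seqs[[i]])
    out <- c(out, paste0(">", names(seqs)[i]), strsplit(body, "\n")[[1]])
  }
  writeLines(out, path)
  invisible(path)
}
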