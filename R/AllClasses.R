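#' @import methods
NULL

# ---- StructureModel ---------------------------------------------------

#' Single-model protein structure
#'
#' A parsed single-model structure: an atom table in PDB author
#' numbering, ordered by (chain, residue number, insertion code). B
#' isotropic temperature factors are carried per atom in Angstrom^2;
#' coordinates are in Angstrom.
#'
#' @slot atoms data.frame with columns \code{serial}, \code{name},
#'   \code{altloc}, \code{resname}, \code{chain}, \code{resnum},
#'   \code{icode}, \code{x}, \code{y}, \code{z}, \code{occupancy},
#'   \code{bfactor}, \code{element}.
#' @slot modelId integer model number from the source file.
#' @export
setClass("StructureModel",
         representation(atoms = "data.frame", modelId = "integer"),
         prototype(modelId = 1L))

.ATOM_COLS <- c("serial", "name", "altloc", "resname", "chain", "resnum",
                "icode", "x", "y", "z", "occupancy", "bfactor", "element")

setValidity("StructureModel", function(object) {
  a <- object@atoms
  if (!all(.ATOM_COLS %in% names(a)))
    return(paste("atom table must have columns:",
                 paste(.ATOM_COLS, collapse = ", ")))
  if (nrow(a) == 0) return(TRUE)
  if (!all(is.finite(c(a$x, a$y, a$z)))) return("non-finite coordinates")
  if (any(a$bfactor < 0)) return("negative B-factor")
  if (any(a$occupancy < 0 | a$occupancy > 1))
    return("occupancy outside [0, 1]")
  key <- order(a$chain, a$resnum, a$icode)
  if (is.unsorted(key)) return("atoms not ordered by (chain, resnum, icode)")
  TRUE
})

# ---- Trajectory -------------------------------------------------------

#' Multi-frame trajectory with fixed topology
#'
#' Frames share one atom table (the topology, from the first frame);
#' coordinates are stored as an \code{nframes x natoms x 3} array in
#' Angstrom. \code{dt} is the time between consecutive frames in ps.
#'
#' @slot atoms topology atom table (as in \linkS4class{StructureModel}).
#' @slot coords numeric array \code{[frame, atom, xyz]}.
#' @slot dt numeric, ps per frame.
#' @export
setClass("Trajectory",
         representation(atoms = "data.frame", coords = "array",
                        dt = "numeric"),
         prototype(dt = 1))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3 || d[3] != 3)
    return("coords must be an nframes x natoms x 3 array")
  if (d[2] != nrow(object@atoms))
    return("coords atom dimension disagrees with the atom table")
  if (length(object@dt) != 1 || !is.finite(object@dt) || object@dt <= 0)
    return("dt must be a single positive number")
  TRUE
})

# ---- B-factor profiles ------------------------------------------------

#' Per-residue C-alpha B-factor profile
#'
#' Raw isotropic B-factors (Angstrom^2) of the C-alpha atoms of one
#' chain, labelled by author residue numbers.
#'
#' @slot resnums integer author residue numbers.
#' @slot values numeric B-factors, same length.
#' @slot chain chain identifier the profile was extracted from.
#' @export
setClass("BFactorProfile",
         representation(resnums = "integer", values = "numeric",
                        chain = "character"),
         prototype(chain = NA_character_))

setValidity("BFactorProfile", function(object) {
  if (length(object@resnums) != length(object@values))
    return("resnums and values differ in length")
  # non-negativity of raw B is enforced at construction (the
  # NormalizedProfile subclass legitimately stores negative z-scores,
  # and superclass validity runs on a coerced copy)
  TRUE
})

#' Normalized (z-scored) B-factor profile
#'
#' The per-structure z-scores B' = (B - <B>) / sd(B) of a
#' \linkS4class{BFactorProfile}, with the centering mean and the sample
#' standard deviation retained. By construction the stored values have
#' mean 0 and sample standard deviation 1.
#'
#' @slot meanB mean of the raw B-factors, Angstrom^2.
#' @slot sdB sample (n - 1) standard deviation of the raw B-factors.
#' @export
setClass("NormalizedProfile",
         contains = "BFactorProfile",
         representation(meanB = "numeric", sdB = "numeric"))

setValidity("NormalizedProfile", function(object) {
  v <- object@values
  if (length(v) < 3) return("a normalized profile needs >= 3 residues")
  if (abs(mean(v)) > 1e-9) return("normalized values must have mean 0")
  if (abs(stats::sd(v) - 1) > 1e-9)
    return("normalized values must have sample sd 1")
  if (object@sdB <= 0) return("sdB must be positive")
  TRUE
})

# ---- Pairwise alignment ----------------------------------------------

#' Global pairwise sequence alignment
#'
#' Gapped strings of a global alignment plus the per-column index pairs
#' back into the two ungapped inputs (NA where a sequence is gapped).
#'
#' @slot alignedA,alignedB gapped strings of equal length.
#' @slot score alignment score in substitution-matrix units.
#' @slot pairs data.frame with columns \code{idxA}, \code{idxB}
#'   (1-based indices into the ungapped sequences, NA at gaps).
#' @export
setClass("SequenceAlignment",
         representation(alignedA = "character", alignedB = "character",
                        score = "numeric", pairs = "data.frame"))

setValidity("SequenceAlignment", function(object) {
  if (nchar(object@alignedA) != nchar(object@alignedB))
    return("aligned strings differ in length")
  p <- object@pairs
  if (nrow(p) != nchar(object@alignedA))
    return("pairs must cover every alignment column exactly once")
  if (any(is.na(p$idxA) & is.na(p$idxB)))
    return("column with gaps in both sequences")
  TRUE
})

# ---- Paired profile ---------------------------------------------------

#' Aligned pair of normalized B-factor profiles
#'
#' One row per alignment column: residue numbers and normalized
#' B-factors of target (A) and homolog (B) where present, and the
#' difference delta = B'_A - B'_B on match columns only.
#'
#' @slot columns data.frame with columns \code{col}, \code{resnumA},
#'   \code{resnumB}, \code{aaA}, \code{aaB}, \code{bA}, \code{bB},
#'   \code{bpA}, \code{bpB}, \code{delta}.
#' @export
setClass("PairedProfile", representation(columns = "data.frame"))

setValidity("PairedProfile", function(object) {
  d <- object@columns
  need <- c("col", "resnumA", "resnumB", "aaA", "aaB",
            "bA", "bB", "bpA", "bpB", "delta")
  if (!all(need %in% names(d)))
    return(paste("columns must contain:", paste(need, collapse = ", ")))
  match_col <- !is.na(d$resnumA) & !is.na(d$resnumB)
  if (any(!is.na(d$delta) & !match_col))
    return("delta defined on a non-match column")
  if (any(is.na(d$delta) & match_col &
          !is.na(d$bpA) & !is.na(d$bpB)))
    return("delta missing on a match column with both profiles present")
  TRUE
})

# ---- MSA --------------------------------------------------------------

#' Multiple sequence alignment
#'
#' Aligned sequences of equal length over the amino-acid alphabet plus
#' the gap character '-'. Input '.' gap characters and lowercase letters
#' are normalized on reading.
#'
#' @slot ids record identifiers (first token of each FASTA header).
#' @slot seqs uppercase gapped sequences, all the same length.
#' @export
setClass("Msa", representation(ids = "character", seqs = "character"))

setValidity("Msa", function(object) {
  if (length(object@ids) != length(object@seqs))
    return("ids and seqs differ in length")
  if (length(object@seqs) < 1) return("an MSA needs at least one record")
  w <- nchar(object@seqs)
  if (length(unique(w)) != 1)
    return(paste0("unequal sequence lengths (record '",
                  object@ids[which(w != w[1])[1]], "')"))
  TRUE
})
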