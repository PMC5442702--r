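#' @include AllClasses.R AllGenerics.R
NULL

#' Normalize a B-factor profile to zero mean and unit variance
#'
#' Crystallographic B-factors refined by different procedures are not
#' directly comparable between structures, so each profile is reduced
#' to per-structure z-scores B' = (B - <B>) / sd(B), where <B> is the
#' mean and sd(B) the sample (n - 1) standard deviation of the C-alpha
#' B-factors of that structure. The resulting dimensionless profiles
#' can be compared across structures.
#'
#' @param profile a \linkS4class{BFactorProfile} (or numeric vector,
#'   in which case labels 1..n are assumed).
#' @return A \linkS4class{NormalizedProfile}.
#' @examples
#' p <- new("BFactorProfile", resnums = 1:3, values = c(10, 20, 30))
#' bValues(normalizeBFactors(p))   # -1 0 1
#' @export
normalizeBFactors <- function(profile) {
  if (is.numeric(profile))
    profile <- new("BFactorProfile",
                   resnums = seq_along(profile), values = as.numeric(profile))
  stopifnot(is(profile, "BFactorProfile"))
  v <- profile@values
  if (length(v) < 3)
    stop("profile too short: need >= 3 residues, got ", length(v))
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop("degenerate profile: standard deviation is zero")
  m <- mean(v)
  new("NormalizedProfile",
      resnums = profile@resnums,
      values = (v - m) / s,
      chain = profile@chain,
      meanB = m, sdB = s)
}

#' Global pairwise sequence alignment
#'
#' Needleman-Wunsch global alignment of two amino-acid sequences via
#' \code{Biostrings::pairwiseAlignment}, defaulting to BLOSUM62 with
#' affine gap penalties (a gap of length L costs
#' \code{gapOpening + L * gapExtension}).
#'
#' @param seqA,seqB one-letter amino-acid strings (the 20 standard
#'   letters plus 'X').
#' @param gapOpening,gapExtension affine gap penalties (positive).
#' @param matrix name of the substitution matrix (data set in
#'   Biostrings).
#' @return A \linkS4class{SequenceAlignment}.
#' @export
alignPair <- function(seqA, seqB, gapOpening = 10, gapExtension = 0.5,
                      matrix = "BLOSUM62") {
  if (!nzchar(seqA) || !nzchar(seqB))
    stop("cannot align an empty sequence")
  bad <- grepl(paste0("[^", paste(.AA20, collapse = ""), "X]"),
               c(seqA, seqB))
  if (any(bad))
    stop("sequence ", which(bad)[1],
         " contains letters outside the amino-acid alphabet")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqA), Biostrings::AAString(seqB),
    substitutionMatrix = matrix,
    gapOpening = gapOpening, gapExtension = gapExtension,
    type = "global")
  ga <- as.character(Biostrings::alignedPattern(aln))
  gb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(ga, "")[[1]]
  cb <- strsplit(gb, "")[[1]]
  idxA <- ifelse(ca == "-", NA_integer_, cumsum(ca != "-"))
  idxB <- ifelse(cb == "-", NA_integer_, cumsum(cb != "-"))
  new("SequenceAlignment", alignedA = ga, alignedB = gb,
      score = Biostrings::score(aln),
      pairs = data.frame(idxA = idxA, idxB = idxB))
}

#' Pair two normalized profiles along an alignment
#'
#' Builds the per-column table used for cross-structure flexibility
#' comparison: residue numbers, one-letter residues and normalized
#' B-factors of both structures where present, and the difference
#' delta = B'_A - B'_B on match columns (both residues present).
#'
#' @param aln a \linkS4class{SequenceAlignment} of the two sequences
#'   underlying the profiles (A = target, B = homolog).
#' @param npA,npB \linkS4class{NormalizedProfile}s whose lengths equal
#'   the respective ungapped sequence lengths.
#' @return A \linkS4class{PairedProfile}.
#' @export
pairProfiles <- function(aln, npA, npB) {
  stopifnot(is(aln, "SequenceAlignment"),
            is(npA, "NormalizedProfile"), is(npB, "NormalizedProfile"))
  p <- aln@pairs
  nA <- sum(!is.na(p$idxA))
  nB <- sum(!is.na(p$idxB))
  if (length(npA@values) != nA)
    stop("profile A has ", length(npA@values),
         " residues but sequence A has ", nA)
  if (length(npB@values) != nB)
    stop("profile B has ", length(npB@values),
         " residues but sequence B has ", nB)
  ca <- strsplit(aln@alignedA, "")[[1]]
  cb <- strsplit(aln@alignedB, "")[[1]]
  resA <- ifelse(is.na(p$idxA), NA_integer_, npA@resnums[p$idxA])
  resB <- ifelse(is.na(p$idxB), NA_integer_, npB@resnums[p$idxB])
  bpA <- ifelse(is.na(p$idxA), NA_real_, npA@values[p$idxA])
  bpB <- ifelse(is.na(p$idxB), NA_real_, npB@values[p$idxB])
  bA <- ifelse(is.na(p$idxA), NA_real_,
               npA@values[p$idxA] * npA@sdB + npA@meanB)
  bB <- ifelse(is.na(p$idxB), NA_real_,
               npB@values[p$idxB] * npB@sdB + npB@meanB)
  delta <- ifelse(!is.na(resA) & !is.na(resB), bpA - bpB, NA_real_)
  new("PairedProfile", columns = data.frame(
    col = seq_len(nrow(p)),
    resnumA = resA, resnumB = resB,
    aaA = ifelse(ca == "-", NA_character_, ca),
    aaB = ifelse(cb == "-", NA_character_, cb),
    bA = bA, bB = bB, bpA = bpA, bpB = bpB, delta = delta,
    stringsAsFactors = FALSE))
}

#' Call flexible segments of the target from a paired profile
#'
#' Scans the target residues of a \linkS4class{PairedProfile} for
#' maximal runs of consecutive positions whose normalized B-factor
#' exceeds the homolog's by at least \code{deltaMin} (match columns),
#' and optionally for runs where the homolog is gapped (insertions in
#' the target, which have no homolog counterpart to compare against
#' and are flagged as their own kind). Runs shorter than \code{minRun}
#' are dropped.
#'
#' @param pp a \linkS4class{PairedProfile}.
#' @param deltaMin minimum normalized B-factor excess (dimensionless,
#'   > 0) for a match column to count as flexible.
#' @param minRun minimum segment length in residues.
#' @param includeGapOpposite also report runs of target residues that
#'   face gaps in the homolog.
#' @return data.frame with columns \code{start}, \code{end} (target
#'   author numbering, inclusive), \code{length}, \code{meanDelta}
#'   (NA for gap-opposite segments), \code{kind} ("matched" or
#'   "gap-opposite"), sorted by \code{start}.
#' @export
callFlexibleSegments <- function(pp, deltaMin = 0.5, minRun = 3,
                                 includeGapOpposite = TRUE) {
  stopifnot(is(pp, "PairedProfile"), deltaMin > 0, minRun >= 1)
  d <- pp@columns
  d <- d[!is.na(d$resnumA), , drop = FALSE]   # target positions only
  if (nrow(d) == 0) return(.emptySegments())
  state <- character(nrow(d))
  state[] <- "cold"
  state[!is.na(d$delta) & d$delta >= deltaMin] <- "matched"
  if (includeGapOpposite) state[is.na(d$resnumB)] <- "gap-opposite"
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values != "cold" & r$lengths >= minRun
  if (!any(keep)) return(.emptySegments())
  segs <- data.frame(
    start = d$resnumA[starts[keep]],
    end = d$resnumA[ends[keep]],
    length = r$lengths[keep],
    meanDelta = vapply(which(keep), function(i) {
      if (r$values[i] == "gap-opposite") return(NA_real_)
      mean(d$delta[starts[i]:ends[i]])
    }, numeric(1)),
    kind = r$values[keep],
    stringsAsFactors = FALSE)
  segs <- segs[order(segs$start), , drop = FALSE]
  rownames(segs) <- NULL
  segs
}

.emptySegments <- function() {
  data.frame(start = integer(0), end = integer(0), length = integer(0),
             meanDelta = numeric(0), kind = character(0),
             stringsAsFactors = FALSE)
}

#' Full flexibility comparison of a target against a homolog
#'
#' Convenience wrapper running the whole comparison: extract C-alpha
#' profiles and sequences from both structures, normalize, align,
#' pair, and call flexible segments of the target.
#'
#' @param target,homolog \linkS4class{StructureModel}s.
#' @param deltaMin,minRun,includeGapOpposite passed to
#'   \code{\link{callFlexibleSegments}}.
#' @param ... passed to \code{\link{alignPair}}.
#' @return list with elements \code{alignment}, \code{paired}
#'   (a \linkS4class{PairedProfile}), and \code{segments}.
#' @export
compareFlexibility <- function(target, homolog, deltaMin = 0.5,
                               minRun = 3, includeGapOpposite = TRUE,
                               ...) {
  sa <- extractSequence(target)
  sb <- extractSequence(homolog)
  npA <- normalizeBFactors(extractCaProfile(target))
  npB <- normalizeBFactors(extractCaProfile(homolog))
  aln <- alignPair(sa$sequence, sb$sequence, ...)
  pp <- pairProfiles(aln, npA, npB)
  list(alignment = aln, paired = pp,
       segments = callFlexibleSegments(pp, deltaMin, minRun,
                                       includeGapOpposite))
}
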