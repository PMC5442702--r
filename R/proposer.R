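#' @include AllClasses.R AllGenerics.R
NULL

#' Propose rigidifying consensus substitutions in flexible segments
#'
#' Thermophilic family members tend to carry the family consensus at
#' positions where a mesophilic target is flexible. For every position
#' inside a called flexible segment, a substitution to the consensus
#' residue is proposed when (1) the consensus differs from the
#' wild-type residue, (2) the consensus frequency reaches
#' \code{minConsensus}, and (3) the consensus is more frequent in the
#' family than the wild-type residue. With \code{serThrBonus} the
#' frequency floor drops to \code{serThrFloor} when the consensus is
#' Ser or Thr, residues associated with rigidity in thermophiles.
#'
#' @param segments data.frame of flexible segments as returned by
#'   \code{\link{callFlexibleSegments}} (columns \code{start},
#'   \code{end}).
#' @param cols conservation table from
#'   \code{\link{columnFrequencies}}; \code{refPos} must be in the
#'   same numbering as the segments.
#' @param wtSeq wild-type one-letter sequence string.
#' @param wtResnums author residue numbers parallel to \code{wtSeq}
#'   (default \code{1:nchar(wtSeq)}).
#' @param minConsensus minimum consensus frequency (default 0.25).
#' @param serThrBonus logical; apply the Ser/Thr floor (default FALSE).
#' @param serThrFloor frequency floor used for Ser/Thr consensus when
#'   \code{serThrBonus} is on (default 0.20).
#' @return data.frame sorted by position with columns \code{position},
#'   \code{wtAa}, \code{proposedAa}, \code{wtFreq},
#'   \code{consensusFreq}, \code{label} (e.g. "N207S"), and logical
#'   rationale flags \code{inFlexibleSegment}, \code{consensusDiffers},
#'   \code{serThrPreferred}.
#' @examples
#' segs <- data.frame(start = 207, end = 210)
#' cols <- data.frame(refPos = 207:210,
#'                    consensusAa = c("S", "S", "G", "S"),
#'                    consensusFreq = c(.31, .31, .48, .31),
#'                    freq.N = c(.07, 0, 0, 0), freq.G = c(0, .04, .48, 0),
#'                    freq.A = c(0, 0, 0, .11), freq.S = c(.31, .31, 0, .31))
#' proposeMutations(segs, cols, "NGGA", 207:210)$label  # N207S G208S A210S
#' @export
proposeMutations <- function(segments, cols, wtSeq,
                             wtResnums = seq_len(nchar(wtSeq)),
                             minConsensus = 0.25, serThrBonus = FALSE,
                             serThrFloor = 0.20) {
  stopifnot(nchar(wtSeq) == length(wtResnums), minConsensus > 0)
  wt <- strsplit(wtSeq, "")[[1]]
  pos <- unlist(lapply(seq_len(NROW(segments)), function(i)
    segments$start[i]:segments$end[i]))
  pos <- sort(unique(intersect(pos, wtResnums)))
  missing <- setdiff(pos, cols$refPos)
  if (length(missing) > 0)
    stop("conservation table lacks position(s): ",
         paste(missing, collapse = ", "))
  out <- lapply(pos, function(p) {
    ci <- cols[cols$refPos == p, , drop = FALSE][1, ]
    wtAa <- wt[match(p, wtResnums)]
    cons <- ci$consensusAa
    wtFreqCol <- paste0("freq.", wtAa)
    wtFreq <- if (wtFreqCol %in% names(ci)) ci[[wtFreqCol]] else NA_real_
    floorHere <- if (serThrBonus && cons %in% c("S", "T")) serThrFloor
                 else minConsensus
    ok <- cons != wtAa &&
      ci$consensusFreq >= floorHere &&
      (is.na(wtFreq) || ci$consensusFreq > wtFreq)
    if (!ok) return(NULL)
    data.frame(position = p, wtAa = wtAa, proposedAa = cons,
               wtFreq = wtFreq, consensusFreq = ci$consensusFreq,
               label = paste0(wtAa, p, cons),
               inFlexibleSegment = TRUE,
               consensusDiffers = TRUE,
               serThrPreferred = cons %in% c("S", "T"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(position = integer(0), wtAa = character(0),
                      proposedAa = character(0), wtFreq = numeric(0),
                      consensusFreq = numeric(0), label = character(0),
                      inFlexibleSegment = logical(0),
                      consensusDiffers = logical(0),
                      serThrPreferred = logical(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$position), , drop = FALSE]
}

#' Apply point substitutions to a sequence
#'
#' Each proposal's wild-type residue is checked against the sequence
#' at its position before editing; a mismatch raises an error naming
#' the position (this guards against numbering bugs upstream).
#'
#' @param seq wild-type one-letter sequence string.
#' @param proposals data.frame with columns \code{position},
#'   \code{wtAa}, \code{proposedAa} (as from
#'   \code{\link{proposeMutations}}).
#' @param resnums author residue numbers parallel to \code{seq}
#'   (default \code{1:nchar(seq)}).
#' @return The mutant sequence string.
#' @export
applyMutations <- function(seq, proposals,
                           resnums = seq_len(nchar(seq))) {
  stopifnot(nchar(seq) == length(resnums))
  s <- strsplit(seq, "")[[1]]
  for (i in seq_len(NROW(proposals))) {
    p <- proposals$position[i]
    j <- match(p, resnums)
    if (is.na(j)) stop("position ", p, " not in the sequence numbering")
    if (s[j] != proposals$wtAa[i])
      stop("wild-type mismatch at position ", p, ": sequence has '",
           s[j], "', proposal expects '", proposals$wtAa[i], "'")
    s[j] <- proposals$proposedAa[i]
  }
  paste(s, collapse = "")
}

#' Minimal-edit codon substitution for a target amino acid
#'
#' Among all codons encoding \code{targetAa}, returns the one with the
#' smallest Hamming distance to the wild-type codon; ties are broken
#' lexicographically (A < C < G < T). This mirrors mutagenesis primer
#' design, where single-nucleotide codon edits are preferred.
#'
#' @param wtCodon wild-type DNA triplet (A/C/G/T).
#' @param targetAa one-letter amino acid to encode.
#' @param codonTable NCBI genetic-code table id (default "1",
#'   standard).
#' @return list with \code{wtCodon}, \code{newCodon}, \code{edits}
#'   (Hamming distance 0-3) and \code{targetAa}.
#' @examples
#' minimalCodonEdit("AAC", "S")   # AGC, 1 edit
#' @export
minimalCodonEdit <- function(wtCodon, targetAa, codonTable = "1") {
  wtCodon <- toupper(wtCodon)
  targetAa <- toupper(targetAa)
  if (!grepl("^[ACGT]{3}$", wtCodon))
    stop("invalid codon '", wtCodon, "': need a DNA triplet")
  code <- Biostrings::getGeneticCode(as.character(codonTable))
  if (targetAa == "*" || !(targetAa %in% code))
    stop("target amino acid '", targetAa,
         "' is not encodable in table ", codonTable)
  cands <- sort(names(code)[code == targetAa])   # lexicographic, A<C<G<T
  wt <- strsplit(wtCodon, "")[[1]]
  dist <- vapply(strsplit(cands, ""),
                 function(cc) sum(cc != wt), integer(1))
  best <- cands[which.min(dist)]   # first minimum = lexicographic tie-break
  list(wtCodon = wtCodon, newCodon = best, edits = min(dist),
       targetAa = targetAa)
}
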