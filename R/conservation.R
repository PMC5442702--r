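#' @include AllClasses.R AllGenerics.R
NULL

#' Read an aligned FASTA file
#'
#' Parsing is case-insensitive and '.' gap characters are converted to
#' '-'. All records must have the same aligned length; a ragged file
#' raises an error naming the first offending record.
#'
#' @param path path to an aligned FASTA file.
#' @return An \linkS4class{Msa}.
#' @export
readMsa <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) < 1) stop("no records in '", path, "'")
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
  seqs <- toupper(chartr(".", "-", as.character(ss)))
  w <- nchar(seqs)
  if (length(unique(w)) != 1) {
    bad <- which(w != w[1])[1]
    stop("alignment error: record '", ids[bad], "' has length ",
         w[bad], ", expected ", w[1])
  }
  new("Msa", ids = unname(ids), seqs = unname(seqs))
}

#' Per-position residue frequencies mapped to a reference sequence
#'
#' For every non-gap position of the reference record, counts the
#' residues of all records in that alignment column. Gaps are counted
#' in the denominator (frequencies are fractions of all family
#' sequences) but are never reported as the consensus; the consensus
#' is the most frequent amino acid. Reference positions are numbered
#' by reference residue order, optionally shifted by \code{offset} to
#' match author numbering.
#'
#' @param msa an \linkS4class{Msa}.
#' @param refId identifier of the reference record.
#' @param offset integer added to the 1-based reference residue index
#'   to produce \code{refPos} (default 0).
#' @return data.frame with one row per reference position: columns
#'   \code{refPos}, \code{alnCol}, \code{refAa}, \code{consensusAa},
#'   \code{consensusFreq}, \code{infoBits}, and \code{freq.<residue>}
#'   columns for the 20 amino acids plus \code{freq.gap}.
#' @export
columnFrequencies <- function(msa, refId, offset = 0) {
  stopifnot(is(msa, "Msa"))
  k <- match(refId, msa@ids)
  if (is.na(k))
    stop("reference id '", refId, "' not found in the MSA")
  mat <- do.call(rbind, strsplit(msa@seqs, ""))
  refChars <- mat[k, ]
  cols <- which(refChars != "-")
  alphabet <- c(.AA20, "-")
  n <- length(msa@seqs)
  freqs <- t(vapply(cols, function(j) {
    cj <- mat[, j]
    cj[!(cj %in% alphabet)] <- "-"   # unknown letters count as gaps
    tabulate(factor(cj, levels = alphabet), nbins = 21) / n
  }, numeric(21)))
  colnames(freqs) <- alphabet
  aaFreqs <- freqs[, .AA20, drop = FALSE]
  consIdx <- max.col(aaFreqs, ties.method = "first")
  out <- data.frame(
    refPos = seq_along(cols) + offset,
    alnCol = cols,
    refAa = refChars[cols],
    consensusAa = .AA20[consIdx],
    consensusFreq = aaFreqs[cbind(seq_along(cols), consIdx)],
    infoBits = apply(freqs, 1, .infoBits),
    stringsAsFactors = FALSE)
  ff <- as.data.frame(freqs)
  names(ff) <- paste0("freq.", c(.AA20, "gap"))
  cbind(out, ff)
}

.infoBits <- function(f) {
  aa <- f[!(names(f) %in% c("-", "gap"))]
  m <- sum(aa)
  if (m <= 0) return(0)
  g <- aa / m
  g <- g[g > 0]
  max(0, log2(20) + sum(g * log2(g)))
}

#' Information content of a conservation column
#'
#' Shannon information in bits relative to a uniform background over
#' the 20 amino acids: log2(20) minus the entropy of the residue
#' distribution renormalized to its non-gap mass. An all-gap column
#' carries 0 bits. No small-sample correction is applied.
#'
#' @param freqs either a named numeric vector of residue frequencies
#'   (may include a "-" or "gap" entry) or one row of the data.frame
#'   returned by \code{\link{columnFrequencies}}.
#' @return bits, in [0, log2(20)].
#' @examples
#' informationContent(c(S = 0.5, T = 0.5))   # 3.3219
#' @export
informationContent <- function(freqs) {
  if (is.data.frame(freqs)) {
    fc <- grep("^freq\\.", names(freqs), value = TRUE)
    stopifnot(length(fc) > 0, nrow(freqs) == 1)
    v <- as.numeric(freqs[1, fc])
    names(v) <- sub("^freq\\.", "", fc)
    freqs <- v
  }
  stopifnot(is.numeric(freqs), !is.null(names(freqs)))
  if (any(freqs < 0)) stop("negative frequency")
  .infoBits(freqs)
}
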