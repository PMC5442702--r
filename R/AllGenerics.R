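#' @include AllClasses.R
NULL

#' Accessors for structure, trajectory and profile objects
#'
#' \code{atomTable} returns the per-atom data.frame; \code{nFrames} and
#' \code{timeStep} describe a trajectory; \code{residueNumbers} and
#' \code{bValues} return a profile's labels and values; \code{meanB}
#' and \code{sdB} return the centering statistics of a normalized
#' profile; \code{alignmentPairs} and \code{alignmentScore} expose a
#' pairwise alignment; \code{profileColumns} returns the per-column
#' table of a paired profile; \code{msaIds} / \code{msaSeqs} the
#' records of an MSA.
#'
#' @param x the object.
#' @return The slot contents described above.
#' @name accessors
#' @aliases atomTable nFrames timeStep residueNumbers bValues meanB sdB
#'   alignmentPairs alignmentScore profileColumns msaIds msaSeqs
NULL

#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("timeStep", function(x) standardGeneric("timeStep"))
#' @rdname accessors
#' @export
setGeneric("residueNumbers", function(x) standardGeneric("residueNumbers"))
#' @rdname accessors
#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))
#' @rdname accessors
#' @export
setGeneric("meanB", function(x) standardGeneric("meanB"))
#' @rdname accessors
#' @export
setGeneric("sdB", function(x) standardGeneric("sdB"))
#' @rdname accessors
#' @export
setGeneric("alignmentPairs", function(x) standardGeneric("alignmentPairs"))
#' @rdname accessors
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))
#' @rdname accessors
#' @export
setGeneric("profileColumns", function(x) standardGeneric("profileColumns"))
#' @rdname accessors
#' @export
setGeneric("msaIds", function(x) standardGeneric("msaIds"))
#' @rdname accessors
#' @export
setGeneric("msaSeqs", function(x) standardGeneric("msaSeqs"))

#' @rdname accessors
setMethod("atomTable", "StructureModel", function(x) x@atoms)
#' @rdname accessors
setMethod("atomTable", "Trajectory", function(x) x@atoms)
#' @rdname accessors
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[1])
#' @rdname accessors
setMethod("timeStep", "Trajectory", function(x) x@dt)
#' @rdname accessors
setMethod("residueNumbers", "BFactorProfile", function(x) x@resnums)
#' @rdname accessors
setMethod("bValues", "BFactorProfile", function(x) x@values)
#' @rdname accessors
setMethod("meanB", "NormalizedProfile", function(x) x@meanB)
#' @rdname accessors
setMethod("sdB", "NormalizedProfile", function(x) x@sdB)
#' @rdname accessors
setMethod("alignmentPairs", "SequenceAlignment", function(x) x@pairs)
#' @rdname accessors
setMethod("alignmentScore", "SequenceAlignment", function(x) x@score)
#' @rdname accessors
setMethod("profileColumns", "PairedProfile", function(x) x@columns)
#' @rdname accessors
setMethod("msaIds", "Msa", function(x) x@ids)
#' @rdname accessors
setMethod("msaSeqs", "Msa", function(x) x@seqs)

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  nres <- nrow(unique(a[, c("chain", "resnum", "icode")]))
  cat("StructureModel:", nrow(a), "atoms,", nres, "residues, chain(s):",
      paste(unique(a$chain), collapse = ","), "\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", nFrames(object), "frames x", nrow(object@atoms),
      "atoms, dt =", object@dt, "ps\n")
})

setMethod("show", "BFactorProfile", function(object) {
  cat(class(object), "over", length(object@values), "residues",
      sprintf("(%d..%d)\n", min(object@resnums), max(object@resnums)))
})

setMethod("show", "SequenceAlignment", function(object) {
  cat("SequenceAlignment:", nchar(object@alignedA), "columns, score",
      object@score, "\n")
})

setMethod("show", "PairedProfile", function(object) {
  d <- object@columns
  cat("PairedProfile:", nrow(d), "columns,",
      sum(!is.na(d$delta)), "match columns with delta\n")
})

setMethod("show", "Msa", function(object) {
  cat("Msa:", length(object@seqs), "sequences x",
      nchar(object@seqs[1]), "columns\n")
})
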