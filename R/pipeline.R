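#' @include flexibility.R conservation.R proposer.R
NULL

.writeTsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  path
}

#' Run the full mutation-design pipeline
#'
#' Executes flexibility comparison, conservation analysis and mutation
#' proposal in one reproducible run and writes a report bundle:
#' \code{paired_profile.tsv}, \code{segments.tsv},
#' \code{conservation.tsv}, \code{proposals.tsv},
#' \code{mutant.fasta}, a human-readable \code{summary.txt}, and
#' \code{config.json} (the effective configuration, package version
#' and MD5 hashes of the inputs). Outputs contain no timestamps, so a
#' rerun with identical inputs and configuration is byte-identical.
#'
#' @param targetPdb,homologPdb paths to the target and homolog PDB
#'   files.
#' @param msaFasta path to the family MSA (aligned FASTA).
#' @param refId reference record id in the MSA (numbering source for
#'   conservation columns).
#' @param outDir output directory (created if needed).
#' @param chainTarget,chainHomolog optional chain selections.
#' @param deltaMin,minRun,includeGapOpposite segment-calling
#'   parameters (see \code{\link{callFlexibleSegments}}).
#' @param minConsensus,serThrBonus proposal policy (see
#'   \code{\link{proposeMutations}}).
#' @param offset integer added to MSA reference positions to align
#'   them with the structure's author numbering.
#' @return invisibly, a list with \code{segments}, \code{proposals},
#'   \code{mutant} and \code{files}.
#' @export
runDesignPipeline <- function(targetPdb, homologPdb, msaFasta, refId,
                              outDir, chainTarget = NULL,
                              chainHomolog = NULL, deltaMin = 0.5,
                              minRun = 3, includeGapOpposite = TRUE,
                              minConsensus = 0.25, serThrBonus = FALSE,
                              offset = 0) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  config <- list(
    tool = "flexfort",
    version = as.character(utils::packageVersion("flexfort")),
    parameters = list(deltaMin = deltaMin, minRun = minRun,
                      includeGapOpposite = includeGapOpposite,
                      minConsensus = minConsensus,
                      serThrBonus = serThrBonus, offset = offset,
                      chainTarget = chainTarget,
                      chainHomolog = chainHomolog),
    inputs = list(
      targetPdb = unname(tools::md5sum(targetPdb)),
      homologPdb = unname(tools::md5sum(homologPdb)),
      msaFasta = unname(tools::md5sum(msaFasta))))

  target <- stage("read-target",
                  readStructure(targetPdb, chain = chainTarget))
  homolog <- stage("read-homolog",
                   readStructure(homologPdb, chain = chainHomolog))
  cmp <- stage("flexibility-compare",
               compareFlexibility(target, homolog, deltaMin = deltaMin,
                                  minRun = minRun,
                                  includeGapOpposite = includeGapOpposite))
  msa <- stage("read-msa", readMsa(msaFasta))
  cols <- stage("conservation",
                columnFrequencies(msa, refId, offset = offset))
  wt <- extractSequence(target)
  proposals <- stage("propose",
                     proposeMutations(cmp$segments, cols, wt$sequence,
                                      wt$resnums,
                                      minConsensus = minConsensus,
                                      serThrBonus = serThrBonus))
  mutant <- stage("apply",
                  applyMutations(wt$sequence, proposals, wt$resnums))

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    paired_profile = .writeTsv(profileColumns(cmp$paired),
                               file.path(outDir, "paired_profile.tsv")),
    segments = .writeTsv(cmp$segments,
                         file.path(outDir, "segments.tsv")),
    conservation = .writeTsv(cols,
                             file.path(outDir, "conservation.tsv")),
    proposals = .writeTsv(proposals,
                          file.path(outDir, "proposals.tsv")),
    mutant = writeFasta(c(mutant = mutant),
                        file.path(outDir, "mutant.fasta")),
    config = local({
      p <- file.path(outDir, "config.json")
      jsonlite::write_json(config, p, auto_unbox = TRUE, pretty = TRUE,
                           null = "null", digits = NA)
      p
    }))
  summary <- c(
    "flexfort design report",
    sprintf("target: %d residues; homolog: %d residues",
            length(wt$resnums), length(extractSequence(homolog)$resnums)),
    sprintf("alignment score: %.1f", alignmentScore(cmp$alignment)),
    sprintf("flexible segments called: %d", nrow(cmp$segments)),
    if (nrow(cmp$segments) > 0)
      sprintf("  %s %d-%d (%s)", cmp$segments$kind, cmp$segments$start,
              cmp$segments$end, ifelse(is.na(cmp$segments$meanDelta), "-",
                                       sprintf("mean dB' %.2f",
                                               cmp$segments$meanDelta))),
    sprintf("proposals: %s",
            if (nrow(proposals) > 0)
              paste(proposals$label, collapse = ", ") else "(none)"))
  writeLines(summary, file.path(outDir, "summary.txt"))
  files <- c(files, summary = file.path(outDir, "summary.txt"))
  invisible(list(segments = cmp$segments, proposals = proposals,
                 mutant = mutant, files = files))
}
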