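#' MethylationExperiment: positions-by-samples methylation container
#'
#' An S4 class extending \linkS4class{RangedSummarizedExperiment} holding, for
#' a set of retained CpG groups (rows) and samples (columns), two assays:
#' \code{"frequency"} (methylation frequency in [0,1]) and \code{"coverage"}
#' (called reads per sample, after ambiguous-read exclusion). Row ranges carry
#' the 1-based inclusive coordinates of each CpG group plus its
#' \code{n_motifs}; \code{colData} carries the sample sheet (\code{sample_id},
#' \code{group}).
#'
#' Validity requires: both assays present with identical dimensions, all
#' frequencies in [0,1] with no missing cells, non-negative coverages, and a
#' \code{group} column with at least one level.
#'
#' @aliases MethylationExperiment-class
#' @exportClass MethylationExperiment
setClass("MethylationExperiment",
         contains = "RangedSummarizedExperiment")

setValidity("MethylationExperiment", function(object) {
  msgs <- character(0)
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("frequency", "coverage") %in% an))
    msgs <- c(msgs, "assays must include 'frequency' and 'coverage'")
  else {
    fr <- assay(object, "frequency")
    cv <- assay(object, "coverage")
    if (anyNA(fr) || anyNA(cv))
      msgs <- c(msgs, "no missing cells allowed after matrix construction")
    else {
      if (any(fr < 0 | fr > 1))
        msgs <- c(msgs, "frequencies must lie in [0, 1]")
      if (any(cv < 0))
        msgs <- c(msgs, "coverages must be non-negative")
    }
  }
  if (!"group" %in% colnames(colData(object)))
    msgs <- c(msgs, "colData must contain a 'group' column")
  if (!"n_motifs" %in% colnames(mcols(rowRanges(object))))
    msgs <- c(msgs, "rowRanges mcols must contain 'n_motifs'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MethylationExperiment
#'
#' @param frequency numeric matrix, positions x samples, values in [0,1].
#' @param coverage numeric matrix of called reads, same dimensions.
#' @param rowRanges \link[GenomicRanges]{GRanges} of positions (1-based
#'   inclusive) with an \code{n_motifs} metadata column.
#' @param sampleData \code{data.frame} or \link[S4Vectors]{DataFrame} with one
#'   row per sample, containing at least a \code{group} column; row order must
#'   match the matrix columns.
#' @return A \linkS4class{MethylationExperiment}.
#' @examples
#' gr <- GenomicRanges::GRanges("tig1", IRanges::IRanges(c(11, 101), width = 1),
#'                              n_motifs = c(1L, 1L))
#' fr <- matrix(c(0, 1, 0.5, 0.5), 2, 2,
#'              dimnames = list(NULL, c("s1", "s2")))
#' cv <- matrix(10L, 2, 2, dimnames = dimnames(fr))
#' me <- MethylationExperiment(fr, cv, gr,
#'                             data.frame(group = c("a", "b"),
#'                                        row.names = c("s1", "s2")))
#' frequencies(me)
#' @export
MethylationExperiment <- function(frequency, coverage, rowRanges, sampleData) {
  if (is.data.frame(sampleData)) sampleData <- DataFrame(sampleData)
  se <- SummarizedExperiment(
    assays = list(frequency = frequency, coverage = coverage),
    rowRanges = rowRanges,
    colData = sampleData)
  new("MethylationExperiment", se)
}

#' @describeIn MethylationExperiment methylation-frequency assay accessor.
#' @param object,x a \code{MethylationExperiment}.
#' @export
frequencies <- function(x) assay(x, "frequency")

#' @describeIn MethylationExperiment called-read coverage assay accessor.
#' @export
coverages <- function(x) assay(x, "coverage")

#' @describeIn MethylationExperiment per-sample group labels, as a factor
#'   named by sample id.
#' @export
groupLabels <- function(x) {
  g <- factor(colData(x)$group)
  names(g) <- colnames(x)
  g
}

setMethod("show", "MethylationExperiment", function(object) {
  g <- groupLabels(object)
  cat(sprintf("MethylationExperiment: %d positions x %d samples\n",
              nrow(object), ncol(object)))
  cat("groups:",
      paste(sprintf("%s (n=%d)", levels(g), tabulate(g)), collapse = ", "),
      "\n")
  fr <- frequencies(object)
  if (length(fr))
    cat(sprintf("mean frequency: %.4f; coverage range: %d-%d\n",
                mean(fr), min(coverages(object)), max(coverages(object))))
  invisible(NULL)
})
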