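# Re-export the Bioconductor generics users need to work with the
# containers this package returns, so attaching poreMethyl suffices.

#' @importFrom SummarizedExperiment rowRanges
#' @export
SummarizedExperiment::rowRanges

#' @importFrom SummarizedExperiment colData
#' @export
SummarizedExperiment::colData

#' @importFrom SummarizedExperiment assay
#' @export
SummarizedExperiment::assay

#' @importFrom S4Vectors mcols
#' @export
S4Vectors::mcols
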