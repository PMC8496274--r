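#' Count the CpG-depletion ingredients of DNA sequences
#'
#' Counts, per sequence and case-insensitively: C bases, G bases, forward
#' strand CG dinucleotides, and the sequence length. IUPAC ambiguity codes
#' (N etc.) contribute to the length but not to the base or dinucleotide
#' counts. CG cannot overlap itself, so dinucleotide counting at every
#' offset is overlap-free by construction.
#'
#' @param seqs a \link[Biostrings]{DNAStringSet} or character vector of DNA
#'   sequences (non-empty).
#' @return A \code{data.frame} with columns \code{seq_id, length, n_C, n_G,
#'   n_CpG}.
#' @examples
#' countCpGFeatures(c(a = "ACGT", b = "cgCG"))
#' @export
countCpGFeatures <- function(seqs) {
  if (is.character(seqs)) {
    if (any(!nzchar(seqs))) stopData("empty sequence in input")
    ids <- names(seqs)
    if (is.null(ids)) ids <- sprintf("seq_%d", seq_along(seqs))
    seqs <- DNAStringSet(seqs)
    names(seqs) <- ids
  }
  if (any(width(seqs) == 0L)) stopData("empty sequence in input")
  lf <- letterFrequency(seqs, c("C", "G"))
  data.frame(
    seq_id = if (is.null(names(seqs))) sprintf("seq_%d", seq_along(seqs)) else names(seqs),
    length = width(seqs),
    n_C = as.integer(lf[, "C"]),
    n_G = as.integer(lf[, "G"]),
    n_CpG = vcountPattern("CG", seqs),
    stringsAsFactors = FALSE)
}

#' CpG observed/expected ratio
#'
#' The CpG depletion statistic
#' \deqn{\mathrm{CpG\ O/E} = \frac{n_{CpG}}{n_C \times n_G} \times
#'       \frac{l^2}{l-1}}
#' where \eqn{l} is the sequence length. Low values indicate historical
#' germline methylation, because methylated cytosine deaminates to thymine
#' over evolutionary time; invertebrate gene bodies with persistent
#' methylation are therefore CpG-depleted.
#'
#' The statistic is undefined when a sequence has no C, no G, or length < 2;
#' such records get \code{NA} (flagged, never silently dropped).
#'
#' @param n_C,n_G,n_CpG,length count vectors as produced by
#'   \code{\link{countCpGFeatures}}.
#' @return Numeric vector of CpG O/E values (\code{NA} where undefined).
#' @examples
#' cpgOE(1, 1, 1, 4)   # 16/3
#' @export
cpgOE <- function(n_C, n_G, n_CpG, length) {
  out <- rep(NA_real_, max(length(n_C), length(length)))
  ok <- n_C > 0 & n_G > 0 & length >= 2
  out[ok] <- (n_CpG[ok] / (as.numeric(n_C[ok]) * as.numeric(n_G[ok]))) *
    (as.numeric(length[ok])^2 / (as.numeric(length[ok]) - 1))
  out
}

#' Per-sequence CpG O/E table with outlier flags
#'
#' Runs \code{\link{countCpGFeatures}} and \code{\link{cpgOE}} over a set of
#' sequences and flags outliers: a record is an outlier exactly when its CpG
#' O/E is NOT strictly inside \code{(lo, hi)}. Records with an undefined
#' statistic carry \code{cpg_oe = NA} and \code{outlier = NA}.
#'
#' @inheritParams countCpGFeatures
#' @param lo,hi strict outlier bounds; defaults 0.001 and 2.
#' @return \code{data.frame} with columns \code{seq_id, length, n_C, n_G,
#'   n_CpG, cpg_oe, outlier}.
#' @export
cpgOETable <- function(seqs, lo = 0.001, hi = 2) {
  df <- countCpGFeatures(seqs)
  df$cpg_oe <- cpgOE(df$n_C, df$n_G, df$n_CpG, df$length)
  df$outlier <- !(df$cpg_oe > lo & df$cpg_oe < hi)
  df
}

#' Filter CpG O/E outliers
#'
#' Keeps records with \code{lo < cpg_oe < hi}, strict on both sides.
#' Records with an undefined statistic (\code{NA}) are also removed here,
#' but their count is logged separately so the filtering funnel stays
#' auditable.
#'
#' @param records a \code{data.frame} with a \code{cpg_oe} column.
#' @param lo,hi strict bounds (defaults 0.001, 2).
#' @return The kept records.
#' @export
filterOEOutliers <- function(records, lo = 0.001, hi = 2) {
  keep <- !is.na(records$cpg_oe) & records$cpg_oe > lo & records$cpg_oe < hi
  n_undef <- sum(is.na(records$cpg_oe))
  if (n_undef)
    pmMsg("filterOEOutliers: %d record(s) with undefined CpG O/E removed",
          n_undef)
  pmFunnel("filterOEOutliers", nrow(records), sum(keep),
           sprintf("%g < CpG O/E < %g", lo, hi))
  records[keep, , drop = FALSE]
}
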