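#' Summarise methylation per transcript
#'
#' Pools site-level counts within each transcript: the transcript's mean
#' methylation frequency is \eqn{\sum called\_methylated / \sum called\_sites}
#' (coverage-weighted), its called-CpG count is the sum of \code{num_motifs}
#' over covered groups, and its coverage fraction relates that to the total
#' CpGs present in the transcript sequence. Transcripts with a pooled
#' frequency of exactly 0 or exactly 1 are classed
#' \code{fully_unmethylated} / \code{fully_methylated}; everything else is
#' \code{intermediate}.
#'
#' @param sites site table (after read-coverage filtering), typically from
#'   \code{\link{aggregateSites}} + \code{\link{filterMinCalled}}.
#' @param cpgTotals named integer vector of total CpG counts per transcript
#'   (names are transcript ids), e.g. from \code{\link{countCpGFeatures}}
#'   on the same FASTA the reads were mapped to.
#' @param weighted pool counts across sites (default); \code{FALSE} takes
#'   the unweighted mean of site frequencies instead.
#' @return \code{data.frame} with columns \code{seq_id, n_cpgs_total,
#'   n_cpgs_called, coverage_fraction, mean_frequency, methylation_class}.
#' @export
transcriptMethylation <- function(sites, cpgTotals, weighted = TRUE) {
  if (nrow(sites)) {
    absent <- setdiff(unique(sites$chromosome), names(cpgTotals))
    if (length(absent))
      stopData("site contig(s) absent from cpgTotals (FASTA/mapping mismatch): %s",
               paste(head(absent, 5L), collapse = ", "))
  }
  dt <- as.data.table(sites)
  agg <- dt[, .(
    n_cpgs_called = sum(num_motifs),
    mean_frequency = if (weighted)
      sum(called_sites_methylated) / sum(called_sites)
    else mean(methylated_frequency)
  ), by = .(seq_id = chromosome)]
  agg <- as.data.frame(agg)
  agg$n_cpgs_total <- as.integer(cpgTotals[agg$seq_id])
  agg$coverage_fraction <- agg$n_cpgs_called / agg$n_cpgs_total
  agg$methylation_class <- ifelse(
    agg$mean_frequency == 0, "fully_unmethylated",
    ifelse(agg$mean_frequency == 1, "fully_methylated", "intermediate"))
  agg[, c("seq_id", "n_cpgs_total", "n_cpgs_called", "coverage_fraction",
          "mean_frequency", "methylation_class")]
}

#' Filter transcripts on CpG coverage fraction
#'
#' Excludes transcripts with methylation called for fewer than
#' \code{minFraction} of the CpGs in the sequence (strictly fewer: a
#' transcript at exactly the threshold survives).
#'
#' @param records output of \code{\link{transcriptMethylation}}.
#' @param minFraction minimum coverage fraction, default 0.2.
#' @return The kept records.
#' @export
filterTranscriptCoverage <- function(records, minFraction = 0.2) {
  keep <- records$coverage_fraction >= minFraction
  pmFunnel("filterTranscriptCoverage", nrow(records), sum(keep),
           sprintf("coverage fraction >= %g", minFraction))
  records[keep, , drop = FALSE]
}

#' Correlate CpG O/E with transcript methylation
#'
#' Pearson product-moment correlation between per-transcript CpG O/E and
#' nanopore-derived mean methylation frequency, with a two-sided p-value
#' from the t distribution on n - 2 degrees of freedom. In methylated
#' genomes the expected relationship is negative: historically methylated
#' transcripts are CpG-depleted.
#'
#' @param cpg_oe,mean_frequency paired numeric vectors (after outlier and
#'   coverage filtering).
#' @return list with \code{r}, \code{p.value}, \code{n}.
#' @export
correlateOEMethylation <- function(cpg_oe, mean_frequency) {
  ok <- is.finite(cpg_oe) & is.finite(mean_frequency)
  x <- cpg_oe[ok]; y <- mean_frequency[ok]
  if (length(x) < 3L)
    stopData("need at least 3 complete pairs for a correlation")
  if (sd(x) == 0 || sd(y) == 0)
    stopData("undefined correlation: zero variance in %s",
             if (sd(x) == 0) "cpg_oe" else "mean_frequency")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p.value = ct$p.value, n = length(x))
}

#' Compare CpG O/E of fully unmethylated vs fully methylated transcripts
#'
#' Two-sample t-test (Welch by default, pooled optional) of CpG O/E between
#' the two extreme methylation classes. When both classes have zero
#' variance but different means the t statistic is undefined; the result is
#' then flagged as perfect separation instead of returning a number.
#'
#' @param records output of \code{\link{transcriptMethylation}} joined with
#'   a \code{cpg_oe} column.
#' @param pooled use the pooled-variance (classic) t-test instead of Welch.
#' @return list with \code{statistic}, \code{p.value}, \code{group_means}
#'   (named: fully_unmethylated, fully_methylated), \code{group_ns}, and
#'   logical \code{perfect_separation}.
#' @export
compareExtremes <- function(records, pooled = FALSE) {
  un <- records$cpg_oe[records$methylation_class == "fully_unmethylated"]
  me <- records$cpg_oe[records$methylation_class == "fully_methylated"]
  un <- un[is.finite(un)]; me <- me[is.finite(me)]
  if (length(un) == 0L) stopData("no fully_unmethylated transcripts")
  if (length(me) == 0L) stopData("no fully_methylated transcripts")
  gm <- c(fully_unmethylated = mean(un), fully_methylated = mean(me))
  gn <- c(fully_unmethylated = length(un), fully_methylated = length(me))
  if ((length(un) < 2L || var(un) == 0) && (length(me) < 2L || var(me) == 0)) {
    return(list(statistic = NA_real_, p.value = NA_real_, group_means = gm,
                group_ns = gn,
                perfect_separation = gm[1L] != gm[2L]))
  }
  tt <- t.test(un, me, var.equal = pooled)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       group_means = gm, group_ns = gn, perfect_separation = FALSE)
}
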