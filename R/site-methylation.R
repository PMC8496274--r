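#' Classify a per-read log-likelihood ratio
#'
#' A read's call at a CpG group is \code{"methylated"} when its LLR exceeds
#' \code{callThreshold}, \code{"unmethylated"} when it is below
#' \code{-callThreshold}, and \code{"ambiguous"} otherwise; ambiguous reads
#' are excluded from called counts downstream. Non-finite LLRs give
#' \code{NA} (rejected call).
#'
#' @param llr numeric vector of log-likelihood ratios (positive supports
#'   5-methylcytosine).
#' @param callThreshold positive LLR magnitude required to call a read;
#'   default 2.
#' @return Character vector over \code{methylated / unmethylated /
#'   ambiguous}, with \code{NA} for non-finite input.
#' @examples
#' callRead(c(5, -5, 1), callThreshold = 2)
#' @export
callRead <- function(llr, callThreshold = 2) {
  if (!is.numeric(callThreshold) || length(callThreshold) != 1L ||
      !is.finite(callThreshold) || callThreshold <= 0)
    stopUsage("callThreshold must be a single positive number")
  out <- rep(NA_character_, length(llr))
  fin <- is.finite(llr)
  out[fin & llr > callThreshold] <- "methylated"
  out[fin & llr < -callThreshold] <- "unmethylated"
  out[fin & abs(llr) <= callThreshold] <- "ambiguous"
  out
}

#' Aggregate per-read calls into site methylation frequencies
#'
#' Groups per-read calls by CpG group (contig, start, end), applies the LLR
#' call threshold, and summarises each group into called reads, called
#' methylated reads and their ratio (the methylation frequency). Groups with
#' no unambiguous read are dropped (frequency undefined).
#'
#' Counts follow the convention of the upstream frequency-summary helper:
#' \code{called_sites} and \code{called_sites_methylated} are read counts
#' multiplied by the number of CpG motifs in the group.
#'
#' With \code{splitGroups = TRUE} each multi-CpG group is expanded into
#' single-CpG records located at the forward-strand C offsets of each CG in
#' the group context sequence (offsets relative to the first CG, which sits
#' at the group start); each split record carries the group's per-motif read
#' counts.
#'
#' Minus-strand calls are by default collapsed onto the forward-strand C of
#' the palindromic CpG (position minus one); set
#' \code{collapseStrands = FALSE} to keep strands separate.
#'
#' Duplicate (read, group) pairs keep their first occurrence. Groups whose
#' member rows disagree on \code{num_motifs} or \code{sequence} raise an
#' error naming the group.
#'
#' @param calls per-read call \code{data.frame} from
#'   \code{\link{readMethylationCalls}}.
#' @param callThreshold LLR call threshold (default 2), see
#'   \code{\link{callRead}}.
#' @param splitGroups expand multi-CpG groups into per-CpG records
#'   (default \code{FALSE}: groups are the analysis unit, as appropriate
#'   when the caller cannot resolve CpGs within ~6 bases of each other).
#' @param collapseStrands collapse minus-strand calls onto the forward
#'   strand C (default \code{TRUE}).
#' @return Site table \code{data.frame} sorted by (chromosome, start) with
#'   columns \code{chromosome, start, end, num_motifs, called_sites,
#'   called_sites_methylated, methylated_frequency, group_sequence}
#'   (0-based inclusive coordinates).
#' @export
aggregateSites <- function(calls, callThreshold = 2, splitGroups = FALSE,
                           collapseStrands = TRUE) {
  cols <- c("chromosome", "strand", "start", "end", "read_name",
            "log_lik_ratio", "num_motifs", "sequence")
  missing <- setdiff(cols, names(calls))
  if (length(missing))
    stopData("calls are missing column(s): %s", paste(missing, collapse = ", "))
  dt <- as.data.table(calls)[, cols, with = FALSE]
  if (nrow(dt) == 0L) return(.emptySiteTable())
  if (collapseStrands) {
    minus <- dt$strand == "-"
    if (any(minus)) {
      dt[minus, `:=`(start = start - 1L, end = end - 1L, strand = "+")]
    }
  }
  ndup <- sum(duplicated(dt[, .(chromosome, start, end, read_name)]))
  if (ndup > 0L) {
    pmMsg("aggregateSites: collapsed %d duplicate (read, group) pair(s)", ndup)
    dt <- dt[!duplicated(dt[, .(chromosome, start, end, read_name)])]
  }
  consist <- dt[, .(n_nm = data.table::uniqueN(num_motifs),
                    n_sq = data.table::uniqueN(toupper(sequence))),
                by = .(chromosome, start, end)]
  bad <- consist[consist$n_nm > 1L | consist$n_sq > 1L]
  if (nrow(bad))
    stopData("inconsistent num_motifs or sequence within group %s:%d-%d",
             bad$chromosome[1L], bad$start[1L], bad$end[1L])
  dt[, state := callRead(log_lik_ratio, callThreshold)]
  agg <- dt[, .(
    num_motifs = num_motifs[1L],
    group_sequence = sequence[1L],
    n_called = sum(state %in% c("methylated", "unmethylated"), na.rm = TRUE),
    n_meth = sum(state == "methylated", na.rm = TRUE)
  ), by = .(chromosome, start, end)]
  agg <- agg[agg$n_called > 0L]
  setorder(agg, chromosome, start)
  sites <- data.frame(
    chromosome = agg$chromosome,
    start = agg$start,
    end = agg$end,
    num_motifs = agg$num_motifs,
    called_sites = agg$n_called * agg$num_motifs,
    called_sites_methylated = agg$n_meth * agg$num_motifs,
    methylated_frequency = agg$n_meth / agg$n_called,
    group_sequence = agg$group_sequence,
    stringsAsFactors = FALSE)
  if (splitGroups) sites <- .splitGroups(sites)
  sites
}

#' @noRd
.emptySiteTable <- function() {
  data.frame(chromosome = character(0), start = integer(0), end = integer(0),
             num_motifs = integer(0), called_sites = integer(0),
             called_sites_methylated = integer(0),
             methylated_frequency = numeric(0),
             group_sequence = character(0), stringsAsFactors = FALSE)
}

# expand each group into per-CpG records at the CG offsets of its context
# sequence; per-motif read counts (group counts / num_motifs)
#' @noRd
.splitGroups <- function(sites) {
  if (nrow(sites) == 0L) return(sites)
  offs <- gregexpr("CG", toupper(sites$group_sequence), fixed = TRUE)
  reps <- sites$num_motifs
  idx <- rep(seq_len(nrow(sites)), reps)
  pos <- unlist(lapply(seq_len(nrow(sites)), function(i) {
    o <- as.integer(offs[[i]])
    if (length(o) != sites$num_motifs[i])
      stopData("group %s:%d-%d: %d CG in sequence but num_motifs=%d",
               sites$chromosome[i], sites$start[i], sites$end[i],
               length(o), sites$num_motifs[i])
    sites$start[i] + (o - o[1L])
  }))
  out <- data.frame(
    chromosome = sites$chromosome[idx],
    start = pos,
    end = pos,
    num_motifs = 1L,
    called_sites = sites$called_sites[idx] %/% sites$num_motifs[idx],
    called_sites_methylated =
      sites$called_sites_methylated[idx] %/% sites$num_motifs[idx],
    methylated_frequency = sites$methylated_frequency[idx],
    group_sequence = sites$group_sequence[idx],
    stringsAsFactors = FALSE)
  out[order(out$chromosome, out$start), , drop = FALSE]
}

#' Filter sites on called-read coverage
#'
#' Keeps sites supported by at least \code{minCalled} called reads, counting
#' reads (i.e. \code{called_sites / num_motifs}), and logs the filtering
#' funnel. Typical thresholds: 10 reads per CpG motif for transcriptome
#' validation, 3 called sites per group per sample for genome-wide
#' comparison.
#'
#' @param sites a site table from \code{\link{aggregateSites}}.
#' @param minCalled minimum called reads (positive integer).
#' @return The kept site rows.
#' @export
filterMinCalled <- function(sites, minCalled) {
  if (!is.numeric(minCalled) || length(minCalled) != 1L || minCalled < 1)
    stopUsage("minCalled must be a positive integer")
  reads <- sites$called_sites / sites$num_motifs
  keep <- reads >= minCalled
  pmFunnel("filterMinCalled", nrow(sites), sum(keep),
           sprintf("min %d called reads", as.integer(minCalled)))
  sites[keep, , drop = FALSE]
}
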