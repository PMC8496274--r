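#' Read a FASTA file into a DNAStringSet
#'
#' Thin wrapper around \code{\link[Biostrings]{readDNAStringSet}} that first
#' validates the file structure so that malformed records are reported with
#' their line number, and that record ids are unique within the file.
#' Lower-case bases are accepted (the DNA alphabet is case-insensitive
#' downstream); wrapped sequence lines are concatenated.
#'
#' @param path path to a FASTA file.
#' @return A \link[Biostrings]{DNAStringSet}, one element per record, named by
#'   the first whitespace-delimited token of each header.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "AC", "GT"), tf)
#' readFasta(tf)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stopData("FASTA file not found: %s", path)
  lines <- readLines(path)
  hdr <- which(startsWith(lines, ">"))
  if (length(hdr) == 0L)
    stopData("%s: no FASTA header found (line 1)", path)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  bad <- which(!nzchar(ids))
  if (length(bad))
    stopData("%s: empty FASTA header at line %d", path, hdr[bad[1L]])
  if (anyDuplicated(ids)) {
    d <- ids[duplicated(ids)][1L]
    stopData("%s: duplicate FASTA id '%s' (line %d)",
             path, d, hdr[which(ids == d)[2L]])
  }
  # a header immediately followed by another header (or EOF) has no sequence
  nxt <- c(hdr[-1L], length(lines) + 1L)
  empty <- which(nxt == hdr + 1L)
  if (length(empty))
    stopData("%s: record '%s' has no sequence (line %d)",
             path, ids[empty[1L]], hdr[empty[1L]])
  x <- readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (any(width(x) == 0L))
    stopData("%s: empty sequence for record '%s'", path,
             names(x)[which(width(x) == 0L)[1L]])
  x
}

.CALL_COLS <- c("chromosome", "strand", "start", "end", "read_name",
                "log_lik_ratio", "num_motifs", "sequence")

#' Read a per-read methylation call table
#'
#' Parses the tab-separated per-read output dialect of signal-level nanopore
#' methylation callers: one row per read x CpG group, with a log-likelihood
#' ratio (positive values support 5-methylcytosine). Both \code{num_motifs}
#' and \code{num_cpgs} header spellings are accepted for the CpG-count
#' column; extra columns are ignored. Coordinates are 0-based inclusive, as
#' produced by the upstream caller.
#'
#' Rows violating the row invariants (non-finite LLR, \code{start > end},
#' \code{num_motifs} not matching the number of CG dinucleotides in the
#' context sequence, a multi-CpG group with \code{start == end} mismatch) are
#' rejected with a warning listing their row numbers.
#'
#' @param path path to the tab-separated call file (with header row).
#' @return A \code{data.frame} with columns \code{chromosome, strand, start,
#'   end, read_name, log_lik_ratio, num_motifs, sequence}. The integer row
#'   numbers of rejected rows (in file order, excluding the header) are
#'   attached as attribute \code{"rejected"}.
#' @export
readMethylationCalls <- function(path) {
  if (!file.exists(path)) stopData("call file not found: %s", path)
  dt <- fread(path, sep = "\t", header = TRUE, data.table = TRUE,
              showProgress = FALSE)
  if ("num_cpgs" %in% names(dt) && !"num_motifs" %in% names(dt))
    data.table::setnames(dt, "num_cpgs", "num_motifs")
  missing <- setdiff(.CALL_COLS, names(dt))
  if (length(missing))
    stopData("call file %s is missing mandatory column(s): %s",
             path, paste(missing, collapse = ", "))
  dt <- dt[, .CALL_COLS, with = FALSE]
  if (nrow(dt) == 0L) return(as.data.frame(dt))
  dt[, start := suppressWarnings(as.integer(start))]
  dt[, end := suppressWarnings(as.integer(end))]
  dt[, num_motifs := suppressWarnings(as.integer(num_motifs))]
  dt[, log_lik_ratio := suppressWarnings(as.numeric(log_lik_ratio))]
  ncg <- countFixed(toupper(dt$sequence), "CG")
  ok <- !is.na(dt$start) & !is.na(dt$end) & !is.na(dt$num_motifs) &
    is.finite(dt$log_lik_ratio) &
    dt$strand %in% c("+", "-") &
    dt$start <= dt$end &
    dt$num_motifs >= 1L &
    dt$num_motifs == ncg &
    !(dt$num_motifs == 1L & dt$start != dt$end)
  rejected <- which(!ok)
  if (length(rejected))
    warning(sprintf("%s: rejected %d invalid row(s): %s", path,
                    length(rejected),
                    paste(head(rejected, 10L), collapse = ", ")))
  out <- as.data.frame(dt[ok])
  attr(out, "rejected") <- rejected
  out
}

#' Read a sample sheet
#'
#' A sample sheet assigns one per-read call file to each sample and labels
#' samples with their experimental group (e.g. aposymbiotic vs symbiotic).
#' Tab-separated with header columns \code{sample_id}, \code{path},
#' \code{group}. Relative paths are resolved against the sheet's directory.
#'
#' @param path path to the sample sheet TSV.
#' @return A \code{data.frame} with columns \code{sample_id, path, group}.
#' @export
readSampleSheet <- function(path) {
  if (!file.exists(path)) stopData("sample sheet not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "path", "group")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopData("sample sheet %s is missing column(s): %s", path,
             paste(missing, collapse = ", "))
  df <- df[, need]
  validateSampleSheet(df)
  rel <- !grepl("^(/|~)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  df
}

#' @noRd
validateSampleSheet <- function(df) {
  if (anyDuplicated(df$sample_id))
    stopData("duplicate sample_id in sample sheet: %s",
             df$sample_id[duplicated(df$sample_id)][1L])
  if (length(unique(df$group)) < 1L || any(!nzchar(df$group)))
    stopData("every sample sheet entry needs a non-empty group label")
  invisible(df)
}

.SITE_DISK_COLS <- c("chromosome", "start", "end", "num_motifs_in_group",
                     "called_sites", "called_sites_methylated",
                     "methylated_frequency", "group_sequence")

#' Write / read a site methylation frequency table
#'
#' Site tables summarise per-read calls per CpG group: called reads, called
#' methylated reads and their ratio (the methylation frequency), using
#' 0-based inclusive coordinates and the column layout of the upstream
#' frequency-summary helper. Comment lines beginning with \code{#} (used to
#' echo the parameters a table was produced with) are skipped on read.
#'
#' \code{writeSiteTable} requires input sorted by (chromosome, start), the
#' order downstream merging assumes. \code{readSiteTable} verifies that the
#' stored frequency equals \code{called_sites_methylated / called_sites} and
#' errors otherwise, so corrupted or hand-edited tables fail loudly.
#'
#' @param sites a site table \code{data.frame} as returned by
#'   \code{\link{aggregateSites}} (columns \code{chromosome, start, end,
#'   num_motifs, called_sites, called_sites_methylated, methylated_frequency,
#'   group_sequence}).
#' @param path file path.
#' @param params optional named list echoed as \code{# key=value} header
#'   comment lines, making output files self-describing.
#' @return \code{writeSiteTable} returns \code{path} invisibly;
#'   \code{readSiteTable} returns the site table \code{data.frame}.
#' @export
writeSiteTable <- function(sites, path, params = NULL) {
  sites <- as.data.frame(sites)
  o <- order(sites$chromosome, sites$start)
  if (!identical(o, seq_len(nrow(sites))) && nrow(sites) > 1L)
    stopData("site table must be sorted by (chromosome, start) before writing")
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(params))
    writeLines(sprintf("# %s=%s", k, format(params[[k]])), con)
  out <- data.frame(
    chromosome = sites$chromosome,
    start = sites$start,
    end = sites$end,
    num_motifs_in_group = sites$num_motifs,
    called_sites = sites$called_sites,
    called_sites_methylated = sites$called_sites_methylated,
    methylated_frequency = sprintf("%.15g", sites$methylated_frequency),
    group_sequence = sites$group_sequence,
    stringsAsFactors = FALSE)
  writeLines(paste(.SITE_DISK_COLS, collapse = "\t"), con)
  if (nrow(out))
    write.table(out, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeSiteTable
#' @export
readSiteTable <- function(path) {
  if (!file.exists(path)) stopData("site table not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(.SITE_DISK_COLS, names(df))
  if (length(missing))
    stopData("site table %s is missing column(s): %s", path,
             paste(missing, collapse = ", "))
  out <- data.frame(
    chromosome = as.character(df$chromosome),
    start = as.integer(df$start),
    end = as.integer(df$end),
    num_motifs = as.integer(df$num_motifs_in_group),
    called_sites = as.integer(df$called_sites),
    called_sites_methylated = as.integer(df$called_sites_methylated),
    methylated_frequency = as.numeric(df$methylated_frequency),
    group_sequence = as.character(df$group_sequence),
    stringsAsFactors = FALSE)
  if (nrow(out)) {
    expect <- out$called_sites_methylated / out$called_sites
    bad <- which(abs(out$methylated_frequency - expect) > 1e-9)
    if (length(bad))
      stopData("site table %s: methylated_frequency inconsistent with counts at row %d",
               path, bad[1L])
  }
  out
}

#' Export differentially methylated regions as BED6
#'
#' Converts regions (1-based inclusive \link[GenomicRanges]{GRanges}, as
#' produced by \code{\link{mergeRegions}}) to BED's 0-based half-open
#' convention. The score column is the absolute between-group mean-frequency
#' difference scaled to 0-1000 and clipped; the name column is the region
#' name (or \code{DMR_<i>}).
#'
#' @param regions a \code{GRanges} with per-group mean-frequency metadata
#'   columns named \code{mean_<group>}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(regions, path) {
  n <- length(regions)
  if (n == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  mc <- as.data.frame(mcols(regions))
  meancols <- grep("^mean_", names(mc), value = TRUE)
  if (length(meancols) >= 2L) {
    diff <- abs(mc[[meancols[1L]]] - mc[[meancols[2L]]])
  } else {
    diff <- rep(0, n)
  }
  score <- pmax(0L, pmin(1000L, as.integer(round(diff * 1000))))
  nm <- names(regions)
  if (is.null(nm)) nm <- sprintf("DMR_%d", seq_len(n))
  bed <- data.frame(
    chrom = as.character(seqnames(regions)),
    start = start(regions) - 1L,   # to 0-based half-open
    end = end(regions),
    name = nm,
    score = score,
    strand = ".",
    stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
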