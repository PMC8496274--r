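#' Simulate CpG-depleted transcript sequences with known methylation levels
#'
#' Emulates the evolutionary footprint of germline methylation: each
#' transcript draws a true methylation level from a sparse bimodal prior
#' (by default 90\% of transcripts near 0, 10\% near 1, the pattern typical
#' of invertebrate gene bodies), its sequence is built from independent
#' equiprobable bases, and each CG dinucleotide is then replaced by TG
#' independently with probability \code{decayRate} times the transcript's
#' methylation level (methylated cytosine deaminates to thymine). With
#' \code{decayRate = 0} composition stays neutral and expected CpG O/E is
#' close to 1; with a high decay rate, highly methylated transcripts are
#' strongly CpG-depleted, so the negative CpG O/E vs methylation
#' relationship is recoverable downstream.
#'
#' @param n number of transcripts.
#' @param length transcript length in bases.
#' @param decayRate per-CpG replacement probability scale in [0, 1].
#' @param priorHighProb probability that a transcript is drawn from the
#'   high-methylation mode (default 0.1).
#' @param priorShape Beta shape parameter for the two modes: low mode is
#'   Beta(1, priorShape), high mode Beta(priorShape, 1); default 20 keeps
#'   the modes near 0 and 1.
#' @param priorSpikeProb probability that a mode draw collapses to its
#'   exact boundary (0 for the low mode, 1 for the high mode), default 0.5:
#'   invertebrate transcriptomes contain genes that are entirely
#'   unmethylated (or entirely methylated), and the extremes contrast
#'   downstream relies on both exact classes existing.
#' @param seed integer seed (mandatory: no silent nondeterminism).
#' @return list with \code{sequences} (a \link[Biostrings]{DNAStringSet})
#'   and \code{truth} (\code{data.frame} with \code{seq_id, meth_level}).
#' @export
simulateDepletedSequences <- function(n = 200, length = 2000, decayRate = 0.9,
                                      priorHighProb = 0.1, priorShape = 20,
                                      priorSpikeProb = 0.5, seed) {
  if (missing(seed)) stopUsage("seed is mandatory")
  if (decayRate < 0 || decayRate > 1)
    stopUsage("decayRate must lie in [0, 1] (replacement is a probability)")
  with_seed(seed, {
    high <- runif(n) < priorHighProb
    spike <- runif(n) < priorSpikeProb
    levels <- ifelse(high, rbeta(n, priorShape, 1), rbeta(n, 1, priorShape))
    levels[high & spike] <- 1
    levels[!high & spike] <- 0
    seqs <- vapply(seq_len(n), function(i) {
      b <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
      if (decayRate * levels[i] > 0) {
        cg <- which(b[-length] == "C" & b[-1L] == "G")
        if (base::length(cg)) {
          hit <- cg[runif(base::length(cg)) < decayRate * levels[i]]
          b[hit] <- "T"   # CG -> TG; cannot create a new CG
        }
      }
      paste(b, collapse = "")
    }, character(1))
    ids <- sprintf("transcript_%04d", seq_len(n))
    dss <- DNAStringSet(seqs)
    names(dss) <- ids
    list(sequences = dss,
         truth = data.frame(seq_id = ids, meth_level = levels,
                            stringsAsFactors = FALSE))
  })
}

# locate CpG groups in sequences: CpGs whose successive C positions are
# within `groupingDistance` bases share one group (the signal-level caller
# cannot resolve CpGs closer than ~6 bases). Coordinates 0-based.
#' @noRd
.cpgGroups <- function(sequences, groupingDistance = 6L) {
  chr <- as.character(sequences)
  out <- lapply(seq_along(chr), function(i) {
    s <- toupper(chr[[i]])
    m <- gregexpr("CG", s, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) return(NULL)
    pos <- as.integer(m)               # 1-based C positions
    block <- cumsum(c(TRUE, diff(pos) > groupingDistance))
    first <- tapply(pos, block, min)
    last <- tapply(pos, block, max)
    nm <- as.integer(table(block))
    data.frame(
      chromosome = names(sequences)[i],
      start = as.integer(first) - 1L,   # 0-based first C
      end = as.integer(last) - 1L,      # 0-based last C
      num_motifs = nm,
      sequence = substring(s, first, last + 1L),
      stringsAsFactors = FALSE)
  })
  dt <- rbindlist(out)
  as.data.frame(dt)
}

# one sample's per-read rows for a table of groups with a `truth` column
#' @noRd
.readsForGroups <- function(groups, readsPerSite, llrMu, llrSigma,
                            readPrefix = "read") {
  ng <- nrow(groups)
  n <- ng * readsPerSite
  gi <- rep(seq_len(ng), each = readsPerSite)
  meth <- rbinom(n, 1L, groups$truth[gi])
  llr <- rnorm(n, mean = ifelse(meth == 1L, llrMu, -llrMu), sd = llrSigma)
  data.frame(
    chromosome = groups$chromosome[gi],
    strand = "+",
    start = groups$start[gi],
    end = groups$end[gi],
    read_name = sprintf("%s_%07d", readPrefix, seq_len(n)),
    log_lik_ratio = llr,
    num_motifs = groups$num_motifs[gi],
    sequence = groups$sequence[gi],
    stringsAsFactors = FALSE)
}

#' Simulate a per-read methylation call table for a set of sequences
#'
#' Finds CpG groups in the sequences (CpGs within \code{groupingDistance}
#' bases merged into one group sharing coordinates and context), then, per
#' group and read, draws a methylation state from Bernoulli(truth) and an
#' LLR from the bimodal Gaussian mixture N(+llrMu, llrSigma) /
#' N(-llrMu, llrSigma) — the shape of the empirical per-read LLR
#' distribution of signal-level callers. Output rows are valid per-read
#' call-table rows.
#'
#' @param sequences a named \link[Biostrings]{DNAStringSet}.
#' @param truthLevels numeric vector of true methylation levels, one per
#'   sequence (recycled if length 1); a read's state at any group of a
#'   sequence is Bernoulli with this probability.
#' @param readsPerSite reads simulated per group.
#' @param llrMu,llrSigma LLR mixture mode magnitude and spread (defaults 5
#'   and 1: calling at threshold 2 is then near-perfect).
#' @param groupingDistance CpG merge distance in bases, default 6.
#' @param sample sample id used in read names.
#' @param seed integer seed (mandatory).
#' @return A per-read call \code{data.frame} in the layout of
#'   \code{\link{readMethylationCalls}}.
#' @export
simulateReadCalls <- function(sequences, truthLevels, readsPerSite = 15,
                              llrMu = 5, llrSigma = 1, groupingDistance = 6L,
                              sample = "s1", seed) {
  if (missing(seed)) stopUsage("seed is mandatory")
  if (any(truthLevels < 0 | truthLevels > 1))
    stopUsage("truthLevels must lie in [0, 1]")
  truthLevels <- rep_len(truthLevels, length(sequences))
  names(truthLevels) <- names(sequences)
  with_seed(seed, {
    groups <- .cpgGroups(sequences, groupingDistance)
    if (nrow(groups) == 0L)
      return(.readsForGroups(cbind(groups, truth = numeric(0)),
                             readsPerSite, llrMu, llrSigma))
    groups$truth <- truthLevels[groups$chromosome]
    .readsForGroups(groups, readsPerSite, llrMu, llrSigma,
                    readPrefix = sample)
  })
}

#' Simulate a multi-sample two-group methylation experiment
#'
#' Generates the full input set for the differential pipeline with known
#' truth: a grid of single-CpG positions along a contig, a group design
#' (default 4 vs 4 with baselines 0.055 / 0.059, the sparse genome-wide
#' means typical of an invertebrate methylome), optional injected
#' differentially methylated blocks, per-sample jitter, and per-read call
#' tables drawn through the LLR mixture.
#'
#' Per position, each group's true frequency is its baseline unless a
#' \code{dmrSpec} block covers the position; each sample's true frequency
#' adds Gaussian jitter (sd \code{jitterSD}) truncated to [0, 1]; reads are
#' then Bernoulli draws as in \code{\link{simulateReadCalls}}.
#'
#' @param groups \code{data.frame} with columns \code{label, n, baseline}:
#'   one row per group.
#' @param nPositions number of baseline positions.
#' @param spacing distance in bases between consecutive positions.
#' @param contig contig name for the baseline positions.
#' @param jitterSD per-sample truth jitter (sd of the truncated Gaussian).
#' @param readsPerSite reads per position per sample.
#' @param llrMu,llrSigma LLR mixture parameters.
#' @param dmrSpec optional \code{data.frame} with columns \code{contig,
#'   start, end} plus one column per group label giving that group's true
#'   frequency inside the block, and optionally \code{spacing} and
#'   \code{jitter_sd} per block (defaults: the global spacing, jitter 0).
#'   Block positions are appended after the baseline positions; blocks must
#'   not overlap each other or the baseline grid.
#' @param seed integer seed (mandatory).
#' @param dir if non-NULL, call tables, sample sheet and truth table are
#'   also written there as TSV files.
#' @return list with \code{sample_sheet} (\code{sample_id, path, group};
#'   paths NA unless \code{dir} given), \code{calls} (named list of
#'   per-sample call \code{data.frame}s), and \code{truth}
#'   (\code{data.frame} per position: coordinates, per-group true
#'   frequency columns \code{truth_<label>}, and logical \code{in_dmr}).
#' @export
simulateExperiment <- function(groups = data.frame(label = c("apo", "sym"),
                                                   n = c(4L, 4L),
                                                   baseline = c(0.055, 0.059)),
                               nPositions = 5000, spacing = 100L,
                               contig = "tig1", jitterSD = 0.002,
                               readsPerSite = 20, llrMu = 5, llrSigma = 1,
                               dmrSpec = NULL, seed, dir = NULL) {
  if (missing(seed)) stopUsage("seed is mandatory")
  stopifnot(all(c("label", "n", "baseline") %in% names(groups)))
  pos <- .experimentPositions(groups, nPositions, spacing, contig, jitterSD,
                              dmrSpec)
  nlab <- groups$label
  sample_ids <- unlist(lapply(seq_len(nrow(groups)), function(i)
    sprintf("%s_%d", groups$label[i], seq_len(groups$n[i]))))
  sample_group <- rep(groups$label, groups$n)
  with_seed(seed, {
    calls <- list()
    for (k in seq_along(sample_ids)) {
      g <- sample_group[k]
      truth_s <- pos[[paste0("truth_", g)]] +
        rnorm(nrow(pos), 0, pos$jitter_sd)
      truth_s <- pmin(1, pmax(0, truth_s))
      gtab <- data.frame(chromosome = pos$chromosome, start = pos$start,
                         end = pos$end, num_motifs = 1L,
                         sequence = pos$sequence, truth = truth_s,
                         stringsAsFactors = FALSE)
      calls[[sample_ids[k]]] <- .readsForGroups(
        gtab, readsPerSite, llrMu, llrSigma, readPrefix = sample_ids[k])
    }
    sheet <- data.frame(sample_id = sample_ids, path = NA_character_,
                        group = sample_group, stringsAsFactors = FALSE)
    truth <- pos[, c("chromosome", "start", "end",
                     paste0("truth_", nlab), "in_dmr")]
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      for (s in sample_ids) {
        p <- file.path(dir, paste0("calls_", s, ".tsv"))
        write.table(calls[[s]], p, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        sheet$path[sheet$sample_id == s] <- p
      }
      write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      sheet_out <- sheet
      sheet_out$path <- basename(sheet_out$path)
      write.table(sheet_out, file.path(dir, "sample_sheet.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    list(sample_sheet = sheet, calls = calls, truth = truth)
  })
}

# lay out baseline grid + dmr blocks; one CpG per position, context TACGTT
#' @noRd
.experimentPositions <- function(groups, nPositions, spacing, contig,
                                 jitterSD, dmrSpec) {
  base_start <- seq(0L, by = as.integer(spacing),
                    length.out = nPositions) + 2L  # C offset in TACGTT
  pos <- data.frame(chromosome = contig, start = base_start, end = base_start,
                    sequence = "TACGTT", jitter_sd = jitterSD,
                    in_dmr = FALSE, stringsAsFactors = FALSE)
  for (g in groups$label) pos[[paste0("truth_", g)]] <-
    groups$baseline[groups$label == g]
  if (!is.null(dmrSpec) && nrow(dmrSpec)) {
    need <- c("contig", "start", "end", groups$label)
    missing <- setdiff(need, names(dmrSpec))
    if (length(missing))
      stopUsage("dmrSpec is missing column(s): %s",
                paste(missing, collapse = ", "))
    o <- order(dmrSpec$contig, dmrSpec$start)
    dmrSpec <- dmrSpec[o, , drop = FALSE]
    if (nrow(dmrSpec) > 1L) {
      same <- dmrSpec$contig[-1L] == dmrSpec$contig[-nrow(dmrSpec)]
      if (any(same & dmrSpec$start[-1L] <= dmrSpec$end[-nrow(dmrSpec)]))
        stopUsage("overlapping dmrSpec entries")
    }
    blocks <- lapply(seq_len(nrow(dmrSpec)), function(i) {
      sp <- if ("spacing" %in% names(dmrSpec)) dmrSpec$spacing[i]
            else as.integer(spacing)
      js <- if ("jitter_sd" %in% names(dmrSpec)) dmrSpec$jitter_sd[i] else 0
      st <- seq(dmrSpec$start[i], dmrSpec$end[i], by = sp)
      b <- data.frame(chromosome = dmrSpec$contig[i], start = st, end = st,
                      sequence = "TACGTT", jitter_sd = js, in_dmr = TRUE,
                      stringsAsFactors = FALSE)
      for (g in groups$label) b[[paste0("truth_", g)]] <- dmrSpec[[g]][i]
      b
    })
    overlap <- any(vapply(blocks, function(b)
      any(b$chromosome == pos$chromosome[1L] & b$start %in% pos$start),
      logical(1)))
    if (overlap) stopUsage("dmrSpec block overlaps the baseline position grid")
    pos <- rbind(pos, do.call(rbind, blocks))
  }
  pos <- pos[order(pos$chromosome, pos$start), , drop = FALSE]
  rownames(pos) <- NULL
  pos
}

#' Simulate a methylation matrix directly at the frequency level
#'
#' Constructs a \linkS4class{MethylationExperiment} from per-group true
#' frequencies plus continuous per-sample jitter, without the per-read
#' binomial sampling layer: the high-coverage limit of the read-level
#' generator, useful for studying estimator behaviour when frequencies are
#' effectively continuous (at realistic read depths, frequencies are ratios
#' of small integers and exact between-sample ties occur by chance).
#'
#' @param truth numeric matrix, positions x groups, columns named by group
#'   label: the true frequency of each group at each position.
#' @param groupN named integer vector of samples per group (names matching
#'   \code{colnames(truth)}).
#' @param jitterSD per-sample Gaussian jitter sd, scalar or per-position
#'   vector; jittered values are truncated to [0, 1].
#' @param positions optional \code{data.frame} with \code{chromosome, start,
#'   end} (0-based inclusive); default: one position every 100 bases on
#'   contig \code{"tig1"}.
#' @param coverage nominal coverage recorded in the coverage assay
#'   (default 1000).
#' @param seed integer seed (mandatory).
#' @return A \linkS4class{MethylationExperiment}.
#' @export
simulateFrequencyMatrix <- function(truth, groupN, jitterSD, positions = NULL,
                                    coverage = 1000L, seed) {
  if (missing(seed)) stopUsage("seed is mandatory")
  labels <- colnames(truth)
  if (is.null(labels) || is.null(names(groupN)) ||
      !setequal(labels, names(groupN)))
    stopUsage("truth columns and groupN names must carry matching group labels")
  np <- nrow(truth)
  if (is.null(positions)) {
    st <- seq(0L, by = 100L, length.out = np)
    positions <- data.frame(chromosome = "tig1", start = st, end = st)
  }
  jitterSD <- rep_len(jitterSD, np)
  with_seed(seed, {
    cols <- list(); ids <- character(0); glab <- character(0)
    for (g in labels) {
      for (k in seq_len(groupN[[g]])) {
        f <- pmin(1, pmax(0, truth[, g] + rnorm(np, 0, jitterSD)))
        cols[[length(cols) + 1L]] <- f
        ids <- c(ids, sprintf("%s_%d", g, k))
        glab <- c(glab, g)
      }
    }
    fr <- do.call(cbind, cols)
    colnames(fr) <- ids
    cv <- matrix(as.numeric(coverage), np, length(ids),
                 dimnames = list(NULL, ids))
    gr <- GRanges(positions$chromosome,
                  IRanges(positions$start + 1L, positions$end + 1L),
                  n_motifs = 1L)
    MethylationExperiment(fr, cv, gr,
                          DataFrame(sample_id = ids, group = glab,
                                    row.names = ids))
  })
}
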