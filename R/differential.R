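#' Build the positions-by-samples methylation matrix
#'
#' Joins per-sample site tables into a \linkS4class{MethylationExperiment}.
#' Positions are kept only when present with at least \code{minCalled}
#' called reads in EVERY sample (strict intersection join): a single
#' low-coverage sample drops the position. The frequency and coverage
#' assays are filled from each sample's table; 0-based table coordinates
#' become 1-based in the row ranges.
#'
#' @param siteTables named list of site tables (one per sample, names =
#'   sample ids), as from \code{\link{aggregateSites}}.
#' @param sampleSheet \code{data.frame} with columns \code{sample_id} and
#'   \code{group} (a \code{path} column is ignored here).
#' @param minCalled minimum called reads per position per sample; default 3.
#' @return A \linkS4class{MethylationExperiment}. Empty (0-row) when no
#'   position passes in every sample, with a warning.
#' @export
buildMethylationMatrix <- function(siteTables, sampleSheet, minCalled = 3) {
  validateSampleSheet(sampleSheet)
  ids <- sampleSheet$sample_id
  absent <- setdiff(ids, names(siteTables))
  if (length(absent))
    stopData("sample(s) in sheet without a site table: %s",
             paste(absent, collapse = ", "))
  keyed <- lapply(ids, function(s) {
    st <- siteTables[[s]]
    reads <- st$called_sites / st$num_motifs
    st <- st[reads >= minCalled, , drop = FALSE]
    st$key_ <- paste(st$chromosome, st$start, st$end, sep = "\r")
    st
  })
  names(keyed) <- ids
  common <- Reduce(intersect, lapply(keyed, `[[`, "key_"))
  if (length(common) == 0L) {
    warning("no position passes the per-sample coverage threshold in every sample")
  }
  ref <- keyed[[1L]]
  ref <- ref[match(common, ref$key_), , drop = FALSE]
  ord <- order(ref$chromosome, ref$start)
  ref <- ref[ord, , drop = FALSE]
  common <- common[ord]
  freq <- cov <- matrix(NA_real_, nrow = length(common), ncol = length(ids),
                        dimnames = list(NULL, ids))
  for (s in ids) {
    st <- keyed[[s]]
    i <- match(common, st$key_)
    freq[, s] <- st$methylated_frequency[i]
    cov[, s] <- st$called_sites[i] / st$num_motifs[i]
  }
  gr <- GRanges(ref$chromosome,
                IRanges(start = ref$start + 1L, end = ref$end + 1L),
                n_motifs = ref$num_motifs)
  pmFunnel("buildMethylationMatrix",
           max(vapply(siteTables[ids], nrow, integer(1))),
           length(common),
           sprintf("min %d called reads in every one of %d samples",
                   as.integer(minCalled), length(ids)))
  MethylationExperiment(freq, cov, gr,
                        DataFrame(sample_id = ids, group = sampleSheet$group,
                                  row.names = ids))
}

#' Genome-wide per-sample mean methylation and group contrast
#'
#' Computes each sample's mean methylation frequency over all retained
#' positions and, for a two-group design, a two-sample t-test on the
#' per-sample means. With zero variance inside both groups the t statistic
#' is undefined: equal group means give t = 0, p = 1, different means are
#' flagged perfect separation.
#'
#' @param me a \linkS4class{MethylationExperiment}.
#' @param pooled pooled-variance t-test instead of Welch (default FALSE).
#' @return list with \code{sample_means} (named), \code{group_means},
#'   \code{statistic}, \code{p.value}, \code{perfect_separation}.
#' @export
genomewideMeans <- function(me, pooled = FALSE) {
  sm <- colMeans(frequencies(me))
  g <- groupLabels(me)
  gm <- c(tapply(sm, g, mean))
  out <- list(sample_means = sm, group_means = gm,
              statistic = NA_real_, p.value = NA_real_,
              perfect_separation = FALSE)
  if (nlevels(g) != 2L) return(out)
  a <- sm[g == levels(g)[1L]]
  b <- sm[g == levels(g)[2L]]
  if (length(a) < 2L || length(b) < 2L) return(out)
  if (var(a) == 0 && var(b) == 0) {
    if (gm[1L] == gm[2L]) {
      out$statistic <- 0; out$p.value <- 1
    } else {
      out$perfect_separation <- TRUE
    }
    return(out)
  }
  tt <- t.test(a, b, var.equal = pooled)
  out$statistic <- unname(tt$statistic)
  out$p.value <- tt$p.value
  out
}

#' Principal components analysis of sample methylation profiles
#'
#' Samples are observations and positions variables; per-position centering
#' only, no unit-variance scaling (frequencies already share the [0,1]
#' scale). Variance-explained fractions sum to 1 over all components. Signs
#' follow a deterministic convention: within each component the
#' largest-magnitude position loading is made positive, so results do not
#' depend on underlying LAPACK sign choices.
#'
#' @param me a \linkS4class{MethylationExperiment} with >= 3 samples.
#' @return list with \code{scores} (samples x components),
#'   \code{variance_explained}, \code{sdev}.
#' @export
methylationPCA <- function(me) {
  if (ncol(me) < 3L) stopUsage("PCA needs at least 3 samples")
  x <- t(frequencies(me))
  if (all(apply(x, 2L, var) == 0))
    stopData("constant matrix: zero variance at every position")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  for (k in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, variance_explained = ve, sdev = pc$sdev)
}

# vectorized group means/variances for a frequency matrix
#' @noRd
.groupStats <- function(fr, g) {
  lv <- levels(g)
  lapply(lv, function(l) {
    m <- fr[, g == l, drop = FALSE]
    n <- ncol(m)
    mu <- rowMeans(m)
    v <- rowSums((m - mu)^2) / (n - 1L)
    list(mean = mu, var = v, n = n)
  })
}

#' Per-position two-group t-tests with perfect-difference flagging
#'
#' Welch's t-test (or pooled-variance, \code{flavor = "pooled"}) at every
#' retained position, comparing the two sample groups. Positions where both
#' groups have (numerically) zero within-group variance are not testable:
#' with differing means they are "perfect" differences (t and p undefined,
#' \code{perfect = TRUE}); with equal means they get t = 0, p = 1. BH
#' q-values are computed over the testable positions only (perfect
#' positions form their own reporting channel and do not enter the FDR
#' family).
#'
#' @param me a \linkS4class{MethylationExperiment} with exactly 2 groups,
#'   >= 2 samples each.
#' @param flavor \code{"welch"} (default) or \code{"pooled"}.
#' @param alpha FDR level for the significance flags, default 0.05.
#' @param epsilon zero-variance tolerance, default 1e-12 (frequencies are
#'   ratios of small integers, so exact zeros are representable).
#' @return \code{data.frame}, one row per position: \code{chromosome, start,
#'   end} (1-based), per-group means (\code{mean_<group>}),
#'   \code{t_statistic, p_value, q_value, significant, perfect}.
#' @export
perSiteTests <- function(me, flavor = c("welch", "pooled"), alpha = 0.05,
                         epsilon = 1e-12) {
  flavor <- match.arg(flavor)
  g <- groupLabels(me)
  if (nlevels(g) != 2L) stopUsage("perSiteTests needs exactly 2 groups")
  if (any(tabulate(g) < 2L)) stopUsage("need >= 2 samples per group")
  fr <- frequencies(me)
  gs <- .groupStats(fr, g)
  m1 <- gs[[1L]]$mean; v1 <- gs[[1L]]$var; n1 <- gs[[1L]]$n
  m2 <- gs[[2L]]$mean; v2 <- gs[[2L]]$var; n2 <- gs[[2L]]$n
  novar <- v1 < epsilon & v2 < epsilon
  perfect <- novar & abs(m1 - m2) > epsilon
  tied <- novar & !perfect
  tstat <- p <- rep(NA_real_, nrow(fr))
  testable <- !novar
  if (any(testable)) {
    if (flavor == "welch") {
      se2 <- v1[testable] / n1 + v2[testable] / n2
      tt <- (m1[testable] - m2[testable]) / sqrt(se2)
      df <- se2^2 / ((v1[testable] / n1)^2 / (n1 - 1L) +
                     (v2[testable] / n2)^2 / (n2 - 1L))
    } else {
      sp2 <- ((n1 - 1L) * v1[testable] + (n2 - 1L) * v2[testable]) /
        (n1 + n2 - 2L)
      tt <- (m1[testable] - m2[testable]) / sqrt(sp2 * (1 / n1 + 1 / n2))
      df <- rep(n1 + n2 - 2L, sum(testable))
    }
    tstat[testable] <- tt
    p[testable] <- 2 * pt(-abs(tt), df)
  }
  tstat[tied] <- 0
  p[tied] <- 1
  q <- rep(NA_real_, length(p))
  signif <- rep(NA, length(p))
  idx <- which(!perfect)
  if (length(idx)) {
    adj <- bhAdjust(p[idx], alpha = alpha)
    q[idx] <- adj$q_values
    signif[idx] <- adj$significant
  }
  gr <- rowRanges(me)
  out <- data.frame(
    chromosome = as.character(seqnames(gr)),
    start = start(gr), end = end(gr),
    stringsAsFactors = FALSE)
  out[[paste0("mean_", levels(g)[1L])]] <- m1
  out[[paste0("mean_", levels(g)[2L])]] <- m2
  out$t_statistic <- tstat
  out$p_value <- p
  out$q_value <- q
  out$significant <- signif
  out$perfect <- perfect
  pmMsg("perSiteTests (%s): %d positions, %d testable, %d perfect, %d significant at FDR %g",
        flavor, nrow(out), sum(testable | tied), sum(perfect),
        sum(signif, na.rm = TRUE), alpha)
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up BH over a family of finite p-values in (0, 1]:
#' \eqn{q_{(i)} = \min_{j \ge i} m\, p_{(j)} / j}, capped at 1. Positions
#' whose test is undefined (perfect differences) must be excluded from the
#' family before calling this; they are reported through their own channel.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param alpha significance level for the flags, default 0.05.
#' @return list with \code{q_values} and logical \code{significant}
#'   (\code{q <= alpha}).
#' @export
bhAdjust <- function(p_values, alpha = 0.05) {
  if (length(p_values) && (anyNA(p_values) ||
                           any(p_values <= 0 | p_values > 1)))
    stopData("all p-values must be finite and in (0, 1]")
  q <- p.adjust(p_values, method = "BH")
  list(q_values = q, significant = q <= alpha)
}

#' Find perfect between-group differences
#'
#' Flags positions where each group's within-group variance is below
#' \code{epsilon} while the group means differ by more than \code{epsilon}:
#' the configuration in which a t statistic is undefined ("t-tests are not
#' possible; the p-value is hypothetically infinite"). These are the
#' positions differential-region merging operates on.
#'
#' @inheritParams perSiteTests
#' @return Logical vector, one flag per position of \code{me}.
#' @export
findPerfectDifferences <- function(me, epsilon = 1e-12) {
  g <- groupLabels(me)
  if (nlevels(g) != 2L) stopUsage("findPerfectDifferences needs exactly 2 groups")
  fr <- frequencies(me)
  gs <- .groupStats(fr, g)
  gs[[1L]]$var < epsilon & gs[[2L]]$var < epsilon &
    abs(gs[[1L]]$mean - gs[[2L]]$mean) > epsilon
}

#' Merge flagged positions into differentially methylated regions
#'
#' Single-linkage merge of flagged positions on the same contig whose
#' successive gaps (next start minus previous end) are at most
#' \code{maxGap} bases. Each region reports its span, member count, member
#' indices and per-group mean frequency over member positions.
#'
#' @param me a \linkS4class{MethylationExperiment}; its row order must be
#'   sorted by (contig, start).
#' @param flagged logical vector over positions of \code{me} (e.g. from
#'   \code{\link{findPerfectDifferences}}, or \code{q <= alpha} flags).
#' @param maxGap maximum within-region gap in bases, default 2000.
#' @return \link[GenomicRanges]{GRanges} of regions (1-based inclusive)
#'   with metadata columns \code{n_positions}, \code{mean_<group>} per
#'   group, and \code{members} (an IntegerList of row indices into
#'   \code{me}).
#' @export
mergeRegions <- function(me, flagged, maxGap = 2000) {
  gr <- rowRanges(me)
  o <- order(as.character(seqnames(gr)), start(gr))
  if (!identical(o, seq_along(gr)) && length(gr) > 1L)
    stopData("positions must be sorted by (contig, start) before merging")
  idx <- which(flagged)
  if (length(idx) == 0L)
    return(GRanges(n_positions = integer(0), members = IRanges::IntegerList()))
  chrom <- as.character(seqnames(gr))[idx]
  s <- start(gr)[idx]; e <- end(gr)[idx]
  newblock <- c(TRUE, chrom[-1L] != chrom[-length(idx)] |
                        (s[-1L] - e[-length(idx)]) > maxGap)
  block <- cumsum(newblock)
  fr <- frequencies(me)
  g <- groupLabels(me)
  lv <- levels(g)
  reg <- lapply(split(seq_along(idx), block), function(ii) {
    rows <- idx[ii]
    means <- vapply(lv, function(l)
      mean(fr[rows, g == l, drop = FALSE]), numeric(1))
    list(chrom = chrom[ii[1L]], start = min(s[ii]), end = max(e[ii]),
         n = length(rows), means = means, members = rows)
  })
  out <- GRanges(
    unname(vapply(reg, `[[`, character(1), "chrom")),
    IRanges(unname(vapply(reg, `[[`, numeric(1), "start")),
            unname(vapply(reg, `[[`, numeric(1), "end"))),
    n_positions = unname(vapply(reg, `[[`, integer(1), "n")))
  for (i in seq_along(lv))
    mcols(out)[[paste0("mean_", lv[i])]] <-
      unname(vapply(reg, function(r) r$means[i], numeric(1)))
  mcols(out)$members <- IRanges::IntegerList(lapply(reg, `[[`, "members"))
  names(out) <- sprintf("DMR_%d", seq_along(out))
  pmMsg("mergeRegions: %d flagged position(s) -> %d region(s) (max gap %d bp)",
        length(idx), length(out), as.integer(maxGap))
  out
}
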