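# Independent reference implementations used as oracles. Deliberately naive
# (plain loops, no grouping machinery) so they share no code path with the
# package.

bruteCpGCounts <- function(s) {
  s <- toupper(s)
  l <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  n_C <- sum(ch == "C")
  n_G <- sum(ch == "G")
  n_CpG <- 0L
  if (l >= 2) {
    for (i in 1:(l - 1)) {
      if (substr(s, i, i + 1) == "CG") n_CpG <- n_CpG + 1L
    }
  }
  c(n_C = n_C, n_G = n_G, n_CpG = n_CpG, length = l)
}

bruteOE <- function(n_C, n_G, n_CpG, l) {
  if (n_C == 0 || n_G == 0 || l < 2) return(NA_real_)
  (n_CpG / (n_C * n_G)) * (l^2 / (l - 1))
}

bruteBH <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * p[o[j]] / j, numeric(1))
    q[o[i]] <- min(1, min(vals))
  }
  list(q_values = q, significant = q <= alpha)
}

# naive per-read aggregation: one pass with environments keyed by group
naiveAggregate <- function(calls, threshold = 2, split = FALSE) {
  seen <- new.env(); acc <- new.env()
  order_keys <- character(0)
  for (i in seq_len(nrow(calls))) {
    strand <- calls$strand[i]
    start <- calls$start[i]; end <- calls$end[i]
    if (strand == "-") { start <- start - 1L; end <- end - 1L }
    key <- paste(calls$chromosome[i], start, end, sep = "|")
    rkey <- paste(key, calls$read_name[i], sep = "|")
    if (!is.null(seen[[rkey]])) next
    seen[[rkey]] <- TRUE
    if (is.null(acc[[key]])) {
      acc[[key]] <- list(chromosome = calls$chromosome[i], start = start,
                         end = end, nm = calls$num_motifs[i],
                         seq = calls$sequence[i], called = 0L, meth = 0L)
      order_keys <- c(order_keys, key)
    }
    llr <- calls$log_lik_ratio[i]
    if (is.finite(llr)) {
      if (llr > threshold) {
        acc[[key]]$meth <- acc[[key]]$meth + 1L
        acc[[key]]$called <- acc[[key]]$called + 1L
      } else if (llr < -threshold) {
        acc[[key]]$called <- acc[[key]]$called + 1L
      }
    }
  }
  rows <- list()
  for (key in order_keys) {
    a <- acc[[key]]
    if (a$called == 0L) next
    if (!split) {
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = a$chromosome, start = a$start, end = a$end,
        num_motifs = a$nm, called_sites = a$called * a$nm,
        called_sites_methylated = a$meth * a$nm,
        methylated_frequency = a$meth / a$called,
        group_sequence = a$seq, stringsAsFactors = FALSE)
    } else {
      sq <- toupper(a$seq)
      offs <- integer(0)
      for (j in 1:(nchar(sq) - 1L))
        if (substr(sq, j, j + 1L) == "CG") offs <- c(offs, j)
      for (o in offs) {
        pos <- a$start + (o - offs[1L])
        rows[[length(rows) + 1L]] <- data.frame(
          chromosome = a$chromosome, start = pos, end = pos,
          num_motifs = 1L, called_sites = a$called,
          called_sites_methylated = a$meth,
          methylated_frequency = a$meth / a$called,
          group_sequence = a$seq, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(poreMethyl:::.emptySiteTable())
  out <- out[order(out$chromosome, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

permTestP <- function(x, y, B = 2000, seed = 99) {
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  n <- length(x)
  withr::with_seed(seed, {
    hits <- 0L
    for (b in seq_len(B)) {
      i <- sample(length(pool), n)
      if (abs(mean(pool[i]) - mean(pool[-i])) >= obs - 1e-12)
        hits <- hits + 1L
    }
    hits / B
  })
}

# build a valid per-read call table row-by-row from per-group read LLRs
makeCalls <- function(groups) {
  rows <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    nm <- if (is.null(g$num_motifs)) 1L else g$num_motifs
    sq <- if (is.null(g$sequence)) "TACGTT" else g$sequence
    st <- if (is.null(g$strand)) "+" else g$strand
    data.frame(chromosome = g$chromosome, strand = st,
               start = g$start, end = g$end,
               read_name = sprintf("g%d_r%d", i, seq_along(g$llr)),
               log_lik_ratio = g$llr, num_motifs = nm, sequence = sq,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# random valid single-CpG call tables for oracle tests
randomCalls <- function(nrows, ncontigs = 3, npos = 25, seed) {
  withr::with_seed(seed, {
    contig <- sprintf("tig%d", sample(ncontigs, nrows, TRUE))
    # positions drawn per contig from a small grid so groups collide often
    pos <- sample(seq(2, by = 17, length.out = npos), nrows, TRUE)
    multi <- pos %% 2 == 0
    sq <- ifelse(multi, "TACGTTACGA", "TACGTT")  # 2 CGs vs 1 CG
    nm <- ifelse(multi, 2L, 1L)
    end <- ifelse(multi, pos + 5L, pos)
    data.frame(chromosome = contig, strand = "+", start = pos, end = end,
               read_name = sprintf("r%d", sample(5000, nrows, TRUE)),
               log_lik_ratio = round(rnorm(nrows, 0, 4), 3),
               num_motifs = nm, sequence = sq, stringsAsFactors = FALSE)
  })
}

# small ready-made MethylationExperiment from explicit frequency rows
makeME <- function(freqRows, groups = rep(c("apo", "sym"), each = 4),
                   start = NULL, contig = "tig1", coverage = 10) {
  fr <- do.call(rbind, freqRows)
  ids <- sprintf("%s_%d", groups, stats::ave(seq_along(groups),
                                             groups, FUN = seq_along))
  colnames(fr) <- ids
  if (is.null(start)) start <- seq(1, by = 100, length.out = nrow(fr))
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(start, start),
                               n_motifs = 1L)
  cv <- matrix(coverage, nrow(fr), ncol(fr), dimnames = dimnames(fr))
  MethylationExperiment(fr, cv, gr,
                        S4Vectors::DataFrame(sample_id = ids, group = groups,
                                             row.names = ids))
}
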