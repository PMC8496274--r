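test_that("callRead thresholds LLRs symmetrically", {
  expect_equal(callRead(c(5, -5, 1, -2, 2.0001), callThreshold = 2),
               c("methylated", "unmethylated", "ambiguous", "ambiguous",
                 "methylated"))
  expect_true(is.na(callRead(NaN)))
  expect_true(is.na(callRead(Inf)))
  expect_error(callRead(1, callThreshold = 0), "positive")
})

test_that("aggregateSites counts called and methylated reads per group", {
  calls <- makeCalls(list(
    list(chromosome = "tig1", start = 100, end = 100,
         llr = c(rep(5, 6), rep(-5, 4), rep(1, 2)))))
  sites <- suppressMessages(aggregateSites(calls, callThreshold = 2))
  expect_equal(sites$called_sites, 10L)
  expect_equal(sites$called_sites_methylated, 6L)
  expect_equal(sites$methylated_frequency, 0.6)

  # unanimous methylated
  calls <- makeCalls(list(
    list(chromosome = "tig1", start = 7, end = 7, llr = rep(10, 8))))
  sites <- suppressMessages(aggregateSites(calls))
  expect_equal(sites$methylated_frequency, 1)

  # conservation: meth + unmeth + ambiguous = total reads
  calls <- makeCalls(list(
    list(chromosome = "tig1", start = 3, end = 3,
         llr = c(4, -4, 0.5, -0.1, 9, -9, 2.5))))
  st <- callRead(calls$log_lik_ratio, 2)
  expect_equal(sum(st == "methylated") + sum(st == "unmethylated") +
                 sum(st == "ambiguous"), nrow(calls))
})

test_that("multi-CpG groups split into per-CpG records with per-motif counts", {
  # group with 2 motifs: sequence TACGTTACGA has CGs at offsets 3 and 8
  llr <- c(rep(5, 6), rep(-5, 4))
  calls <- makeCalls(list(
    list(chromosome = "tig1", start = 100, end = 105, num_motifs = 2L,
         sequence = "TACGTTACGA", llr = llr)))
  unsplit <- suppressMessages(aggregateSites(calls, splitGroups = FALSE))
  expect_equal(unsplit$called_sites, 20L)          # 10 reads x 2 motifs
  expect_equal(unsplit$called_sites_methylated, 12L)

  split <- suppressMessages(aggregateSites(calls, splitGroups = TRUE))
  expect_equal(nrow(split), 2L)
  expect_equal(split$start, c(100L, 105L))         # offsets 3 and 8 -> +5
  expect_equal(split$end, split$start)
  expect_equal(split$num_motifs, c(1L, 1L))
  expect_equal(split$called_sites, c(10L, 10L))
  expect_equal(split$called_sites_methylated, c(6L, 6L))
})

test_that("minus-strand calls collapse onto the forward-strand C", {
  calls <- makeCalls(list(
    list(chromosome = "tig1", start = 101, end = 101, strand = "-",
         llr = rep(5, 3)),
    list(chromosome = "tig1", start = 100, end = 100, strand = "+",
         llr = rep(5, 3))))
  sites <- suppressMessages(aggregateSites(calls))
  expect_equal(nrow(sites), 1L)                    # palindromic CpG merged
  expect_equal(sites$start, 100L)
  expect_equal(sites$called_sites, 6L)

  sep <- suppressMessages(aggregateSites(calls, collapseStrands = FALSE))
  expect_equal(nrow(sep), 2L)
})

test_that("duplicate (read, group) pairs collapse to the first occurrence", {
  calls <- makeCalls(list(
    list(chromosome = "tig1", start = 10, end = 10, llr = c(5, -5))))
  calls$read_name <- c("r1", "r1")
  sites <- suppressMessages(aggregateSites(calls))
  expect_equal(sites$called_sites, 1L)
  expect_equal(sites$methylated_frequency, 1)      # first row won
})

test_that("groups disagreeing on num_motifs or sequence are an error", {
  calls <- makeCalls(list(
    list(chromosome = "tig1", start = 10, end = 15, num_motifs = 2L,
         sequence = "TACGTTACGA", llr = 5)))
  bad <- calls[c(1, 1), ]
  bad$read_name <- c("r1", "r2")
  bad$sequence[2] <- "TTCGTTACGA"
  expect_error(suppressMessages(aggregateSites(bad)), "inconsistent")
})

test_that("aggregation matches the naive reference on randomized call files", {
  for (seed in c(101, 202, 303)) {
    calls <- randomCalls(2000, seed = seed)
    for (split in c(FALSE, TRUE)) {
      got <- suppressMessages(aggregateSites(calls, splitGroups = split))
      ref <- naiveAggregate(calls, split = split)
      rownames(got) <- rownames(ref) <- NULL
      expect_equal(got, ref, tolerance = 1e-12)
    }
  }
})

test_that("raising the call threshold never increases called reads", {
  calls <- randomCalls(3000, seed = 7)
  lo <- suppressMessages(aggregateSites(calls, callThreshold = 1))
  hi <- suppressMessages(aggregateSites(calls, callThreshold = 3))
  key <- function(x) paste(x$chromosome, x$start, x$end)
  common <- intersect(key(lo), key(hi))
  expect_true(all(hi$called_sites[match(common, key(hi))] <=
                    lo$called_sites[match(common, key(lo))]))
})

test_that("coverage filter boundaries follow the stated rules", {
  sites <- data.frame(
    chromosome = "tig1", start = c(1L, 2L, 3L), end = c(1L, 2L, 3L),
    num_motifs = 1L, called_sites = c(9L, 10L, 3L),
    called_sites_methylated = c(0L, 5L, 3L),
    methylated_frequency = c(0, 0.5, 1), group_sequence = "TACGTT",
    stringsAsFactors = FALSE)
  kept10 <- suppressMessages(filterMinCalled(sites, 10))
  expect_equal(kept10$called_sites, 10L)           # 9 excluded at min 10
  kept3 <- suppressMessages(filterMinCalled(sites, 3))
  expect_equal(nrow(kept3), 3L)                    # 3 kept at min 3
  expect_equal(nrow(suppressMessages(
    filterMinCalled(sites[0, ], 10))), 0L)
  expect_error(filterMinCalled(sites, 0), "positive")

  # the filter counts reads, not motif-multiplied sites
  multi <- sites[2, ]; multi$num_motifs <- 2L; multi$called_sites <- 18L
  expect_equal(nrow(suppressMessages(filterMinCalled(multi, 10))), 0L)
})

test_that("estimated frequencies recover simulated truth at 30 reads", {
  withr::with_seed(5, {
    truth <- runif(500)
  })
  seqs <- Biostrings::DNAStringSet(rep("TTTACGTTT", 500))
  names(seqs) <- sprintf("site_%03d", 1:500)
  calls <- simulateReadCalls(seqs, truth, readsPerSite = 30,
                             llrMu = 5, llrSigma = 1, seed = 6)
  sites <- suppressMessages(aggregateSites(calls, callThreshold = 2))
  est <- sites$methylated_frequency[match(names(seqs), sites$chromosome)]
  expect_gte(cor(est, truth), 0.95)
  rmse <- sqrt(mean((est - truth)^2))
  se_bound <- mean(sqrt(truth * (1 - truth) / 30))
  expect_lte(rmse, 1.2 * se_bound)
})
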