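siteTableAt <- function(positions, called, meth) {
  data.frame(chromosome = "tig1", start = positions, end = positions,
             num_motifs = 1L, called_sites = called,
             called_sites_methylated = meth,
             methylated_frequency = meth / called,
             group_sequence = "TACGTT", stringsAsFactors = FALSE)
}

test_that("matrix construction intersects positions at per-sample coverage", {
  sheet <- data.frame(sample_id = sprintf("s%d", 1:8),
                      group = rep(c("apo", "sym"), each = 4))
  # position 100 well covered everywhere; position 200 at 2 reads in s8
  tabs <- lapply(1:8, function(i) {
    called <- c(5L, if (i == 8) 2L else 5L)
    siteTableAt(c(100L, 200L), called, c(2L, 1L))
  })
  names(tabs) <- sheet$sample_id
  me <- suppressMessages(buildMethylationMatrix(tabs, sheet, minCalled = 3))
  expect_s4_class(me, "MethylationExperiment")
  expect_equal(nrow(me), 1L)
  expect_equal(GenomicRanges::start(rowRanges(me)), 101L)  # 0-based -> 1-based
  expect_equal(dim(frequencies(me)), c(1L, 8L))
  expect_true(all(coverages(me) >= 3))

  # empty intersection warns and yields an empty object
  tabs$s1 <- siteTableAt(300L, 5L, 0L)
  expect_warning(me0 <- suppressMessages(
    buildMethylationMatrix(tabs, sheet, minCalled = 3)), "no position")
  expect_equal(nrow(me0), 0L)

  expect_error(suppressMessages(
    buildMethylationMatrix(tabs[1:7], sheet)), "without a site table")
})

test_that("genome-wide means and group contrast handle degenerate designs", {
  me <- makeME(list(c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)))
  gm <- genomewideMeans(me)
  expect_equal(unname(gm$statistic), 0)
  expect_equal(gm$p.value, 1)

  me <- makeME(list(c(0.1, 0.1, 0.1, 0.1, 0.2, 0.2, 0.2, 0.2)))
  gm <- genomewideMeans(me)
  expect_true(gm$perfect_separation)
  expect_true(is.na(gm$p.value))
  expect_equal(unname(gm$group_means), c(0.1, 0.2))

  # sample means agree with a direct Welch t-test on the means
  withr::with_seed(71, {
    fr <- lapply(1:50, function(i) runif(8))
  })
  me <- makeME(fr)
  gm <- genomewideMeans(me)
  ref <- t.test(gm$sample_means[1:4], gm$sample_means[5:8])
  expect_equal(unname(gm$statistic), unname(ref$statistic), tolerance = 1e-10)
  expect_equal(gm$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("per-site Welch and pooled tests match stats::t.test", {
  withr::with_seed(81, {
    fr <- lapply(1:200, function(i) round(runif(8), 2))
  })
  me <- makeME(fr)
  for (flavor in c("welch", "pooled")) {
    res <- suppressMessages(perSiteTests(me, flavor = flavor))
    for (i in seq_along(fr)) {
      a <- fr[[i]][1:4]; b <- fr[[i]][5:8]
      if (var(a) < 1e-12 && var(b) < 1e-12) next
      ref <- t.test(a, b, var.equal = flavor == "pooled")
      expect_equal(res$t_statistic[i], unname(ref$statistic),
                   tolerance = 1e-10)
      expect_equal(res$p_value[i], ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("zero-variance positions split into perfect and tied classes", {
  me <- makeME(list(
    c(0, 0, 0, 0, 1, 1, 1, 1),          # perfect difference
    c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5),  # tied constants
    c(0, 0, 0, 0.01, 1, 1, 1, 1),       # variance in group 1: testable
    c(0.1, 0.2, 0.1, 0.2, 0.1, 0.2, 0.1, 0.2))) # identical samples
  res <- suppressMessages(perSiteTests(me, flavor = "pooled"))
  expect_equal(res$perfect, c(TRUE, FALSE, FALSE, FALSE))
  expect_true(is.na(res$p_value[1]))
  expect_true(is.na(res$q_value[1]))
  expect_equal(res$t_statistic[2], 0)
  expect_equal(res$p_value[2], 1)
  expect_false(is.na(res$p_value[3]))
  expect_equal(res$p_value[4], 1)

  flags <- findPerfectDifferences(me)
  expect_equal(flags, c(TRUE, FALSE, FALSE, FALSE))

  # perfect positions are excluded from the BH family
  expect_equal(sum(!is.na(res$q_value)), 3L)
})

test_that("BH adjustment implements the step-up rule and rejects bad input", {
  out <- bhAdjust(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(out$q_values, rep(0.04, 4))
  expect_true(all(out$significant))
  expect_equal(bhAdjust(0.03)$q_values, 0.03)
  out1 <- bhAdjust(rep(1, 5))
  expect_equal(out1$q_values, rep(1, 5))
  expect_false(any(out1$significant))
  expect_error(bhAdjust(c(0.5, 0)), "in \\(0, 1\\]")
  expect_error(bhAdjust(c(0.5, 1.2)), "in \\(0, 1\\]")
  expect_error(bhAdjust(c(0.5, NA)), "in \\(0, 1\\]")

  # q >= p always, and equality with brute-force step-up on random vectors
  withr::with_seed(91, {
    for (i in 1:50) {
      p <- runif(sample(1:40, 1))
      got <- bhAdjust(p)
      ref <- bruteBH(p)
      expect_equal(got$q_values, ref$q_values, tolerance = 1e-12)
      expect_identical(got$significant, ref$significant)
      expect_true(all(got$q_values >= p - 1e-15))
    }
  })
})

test_that("PCA centers without scaling, normalizes variance and fixes signs", {
  withr::with_seed(101, {
    fr <- lapply(1:60, function(i) round(runif(8), 2))
  })
  me <- makeME(fr)
  pc <- methylationPCA(me)
  expect_equal(sum(pc$variance_explained), 1, tolerance = 1e-10)

  # scores invariant (up to nothing: sign convention is deterministic)
  # under sample reordering
  perm <- c(3, 1, 4, 2, 7, 5, 8, 6)
  fr2 <- lapply(fr, function(r) r[perm])
  me2 <- makeME(fr2, groups = rep(c("apo", "sym"), each = 4))
  pc2 <- methylationPCA(me2)
  expect_equal(abs(pc2$scores[order(perm), 1:3]), abs(pc$scores[, 1:3]),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(pc2$variance_explained, pc$variance_explained,
               tolerance = 1e-10)

  # identical samples get identical scores
  me3 <- makeME(list(c(0.1, 0.1, 0.3, 0.4, 0.2, 0.2, 0.6, 0.1),
                     c(0.9, 0.9, 0.2, 0.1, 0.4, 0.4, 0.3, 0.8)))
  pc3 <- methylationPCA(me3)
  expect_equal(pc3$scores[1, ], pc3$scores[2, ], tolerance = 1e-10)

  expect_error(methylationPCA(makeME(list(rep(0.5, 8)))), "zero variance")

  # a strong group effect separates groups in sign on the top component
  withr::with_seed(111, {
    fr4 <- lapply(1:100, function(i)
      pmin(1, pmax(0, c(rnorm(4, 0.1, 0.02), rnorm(4, 0.9, 0.02)))))
  })
  pc4 <- methylationPCA(makeME(fr4))
  s1 <- pc4$scores[, 1]
  expect_true(all(sign(s1[1:4]) == sign(s1[1])))
  expect_true(all(sign(s1[5:8]) == -sign(s1[1])))
})

test_that("region merging follows the gap rule and summarises members", {
  me <- makeME(list(c(0, 0, 0, 0, 1, 1, 1, 1),
                    c(0, 0, 0, 0, 1, 1, 1, 1),
                    c(0, 0, 0, 0, 0.8, 0.8, 0.8, 0.8)),
               start = c(101, 601, 12001))
  flags <- rep(TRUE, 3)
  reg <- suppressMessages(mergeRegions(me, flags, maxGap = 1000))
  expect_equal(length(reg), 2L)
  expect_equal(GenomicRanges::start(reg), c(101L, 12001L))
  expect_equal(GenomicRanges::end(reg), c(601L, 12001L))
  expect_equal(mcols(reg)$n_positions, c(2L, 1L))
  expect_equal(mcols(reg)$mean_apo, c(0, 0))
  expect_equal(mcols(reg)$mean_sym, c(1, 0.8))
  expect_equal(as.integer(mcols(reg)$members[[1]]), c(1L, 2L))

  expect_equal(length(suppressMessages(
    mergeRegions(me, rep(FALSE, 3)))), 0L)

  # unsorted positions refused
  me_bad <- makeME(list(c(0, 0, 0, 0, 1, 1, 1, 1),
                        c(0, 0, 0, 0, 1, 1, 1, 1)),
                   start = c(500, 100))
  expect_error(suppressMessages(mergeRegions(me_bad, c(TRUE, TRUE))),
               "sorted")
})

test_that("BH keeps empirical false discovery in check on null-plus-signal data", {
  # frequency-level simulation: 800 null + 30 signal, 5 replicates
  fdp <- vapply(1:5, function(rep) {
    truth <- cbind(apo = rep(0.3, 830), sym = c(rep(0.3, 800), rep(0.7, 30)))
    me <- simulateFrequencyMatrix(truth, c(apo = 4L, sym = 4L),
                                  jitterSD = 0.05, seed = 7000 + rep)
    res <- suppressMessages(perSiteTests(me))
    disc <- which(res$significant)
    if (length(disc) == 0L) return(0)
    sum(disc <= 800) / length(disc)
  }, numeric(1))
  expect_lt(mean(fdp), 0.10)
})

test_that("perfect-difference detection is noise-free at matrix level", {
  truth <- cbind(apo = rep(0.4, 10000), sym = rep(0.4, 10000))
  me <- simulateFrequencyMatrix(truth, c(apo = 4L, sym = 4L),
                                jitterSD = 0.01, seed = 77)
  expect_equal(sum(findPerfectDifferences(me)), 0L)
})
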