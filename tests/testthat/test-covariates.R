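# Hand-built bin table: one chromosome, uniform context composition and
# callability, linear signal; convenient ground truth for decile logic.
toy_bin_info <- function(n_bins = 200, signal = seq_len(n_bins)) {
  data.frame(chrom = "chr1",
             start = (seq_len(n_bins) - 1) * 1000,
             end = seq_len(n_bins) * 1000,
             n_CpG = 100, n_strong = 300, n_weak = 600,
             callable_perpos = 50, callable_years_perpos = 3000,
             signal = signal)
}

test_that("track averaging is positionwise and honours the data policy", {
  rep_df <- data.frame(chrom = "chr1", start = c(0, 100, 200),
                       end = c(100, 200, 300),
                       track1 = c(10, 5, NA), track2 = c(20, 5, NA))
  avg <- average_tracks(rep_df)
  expect_equal(avg$signal, c(15, 5))
  expect_identical(nrow(avg), 2L)   # the all-NA bin is dropped
  rep_df$track2[2] <- NA
  expect_identical(nrow(average_tracks(rep_df, policy = "all")), 1L)
  expect_equal(average_tracks(rep_df, policy = "any")$signal, c(15, 5))
  # identical tracks average to themselves
  same <- data.frame(chrom = "chr1", start = 0, end = 100,
                     track1 = 7, track2 = 7, track3 = 7)
  expect_equal(average_tracks(same)$signal, 7)
  expect_error(average_tracks(same[, 1:3]), "tracks")
})

test_that("decile splitting partitions callability and ranks rates by lateness", {
  bi <- toy_bin_info()
  # uniform weights: each decile holds ~10% of the callable mass
  calls_none <- data.frame(chrom = character(), pos = integer(),
                           context_class = character())
  dr <- replication_decile_rates(calls_none, bi)
  denom_by_decile <- as.numeric(tapply(dr$denominator_years, dr$decile, sum))
  expect_equal(denom_by_decile / sum(dr$denominator_years),
               rep(0.1, 10), tolerance = 0.02)
  expect_true(all(diff(tapply(dr$mean_signal, dr$decile, unique)) > 0))

  # mutations enriched at low signal (late replication): monotone trend
  set.seed(3)
  n <- 4000
  bin_idx <- sample.int(200, n, replace = TRUE,
                        prob = rev(seq_len(200)))
  calls <- data.frame(chrom = "chr1", pos = (bin_idx - 1) * 1000 + 500,
                      context_class = sample(c("CpG", "strong", "weak"), n,
                                             replace = TRUE))
  dr2 <- replication_decile_rates(calls, bi)
  pooled <- tapply(dr2$count, dr2$decile, sum)
  expect_lt(cor(seq_len(10), as.numeric(pooled), method = "spearman"), -0.9)

  # uniform placement with contexts drawn at their genomic shares: every
  # per-decile, per-context CI should cover the pooled rate
  calls_u <- data.frame(chrom = "chr1",
                        pos = sample.int(200 * 1000, n),
                        context_class = sample(c("CpG", "strong", "weak"), n,
                                               replace = TRUE,
                                               prob = c(0.1, 0.3, 0.6)))
  dr3 <- replication_decile_rates(calls_u, bi)
  pooled_rate <- sum(dr3$count) / sum(dr3$denominator_years)
  covered <- mean(dr3$ci_low <= pooled_rate & pooled_rate <= dr3$ci_high)
  expect_gt(covered, 0.85)
  expect_error(replication_decile_rates(calls_u, toy_bin_info(signal = rep(1, 200))),
               "constant")
})

test_that("replication association test recovers a known log-odds slope", {
  bi <- toy_bin_info(signal = seq(30, 70, length.out = 200))
  beta <- -0.05
  set.seed(8)
  lambda <- exp(-6 + beta * bi$signal)
  gen_calls <- function() {
    counts <- rpois(200, lambda * 1000 * 50 / 10)  # per-bin expected load
    idx <- rep(seq_len(200), counts)
    data.frame(chrom = "chr1", pos = (idx - 1) * 1000 + 1,
               context_class = sample(c("CpG", "strong", "weak"),
                                      length(idx), replace = TRUE))
  }
  fit <- replication_association_test(gen_calls(), bi)
  expect_false(fit$separation)
  expect_lt(abs(fit$coefficient - beta), 2 * fit$se)
  expect_lt(fit$p_value, 1e-6)

  # scaling the signal by c scales the slope by 1/c
  calls <- gen_calls()
  f1 <- replication_association_test(calls, bi, signal_digits = 6)
  bi2 <- bi; bi2$signal <- bi$signal * 2
  f2 <- replication_association_test(calls, bi2, signal_digits = 6)
  expect_equal(f2$coefficient, f1$coefficient / 2, tolerance = 1e-6)
})

test_that("replication association p-values are calibrated under the null", {
  bi <- toy_bin_info(signal = seq(30, 70, length.out = 200))
  set.seed(17)
  pvals <- replicate(60, {
    idx <- sample.int(200, 600, replace = TRUE)
    calls <- data.frame(chrom = "chr1", pos = (idx - 1) * 1000 + 1,
                        context_class = sample(c("CpG", "strong", "weak"),
                                               600, replace = TRUE))
    replication_association_test(calls, bi)$p_value
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("CMH odds ratio matches the formula oracle and mantelhaen.test", {
  t1 <- matrix(c(10, 5, 5, 10), 2, byrow = TRUE)
  expect_equal(cmh_or(list(t1, t1, t1))$or, 4)
  # single stratum reduces to the plain 2x2 odds ratio
  t2 <- matrix(c(12, 7, 30, 80), 2, byrow = TRUE)
  expect_equal(cmh_or(list(t2))$or, (12 * 80) / (7 * 30))
  # proportional strata equal the common stratum OR
  expect_equal(cmh_or(list(t2, 3 * t2, 10 * t2))$or,
               cmh_or(list(t2))$or, tolerance = 1e-12)

  set.seed(5)
  for (i in 1:25) {
    tabs <- lapply(1:3, function(j)
      matrix(rpois(4, 40) + 1, 2))
    got <- cmh_or(tabs)
    a <- sapply(tabs, function(t) t[1, 1]); b <- sapply(tabs, function(t) t[1, 2])
    cc <- sapply(tabs, function(t) t[2, 1]); d <- sapply(tabs, function(t) t[2, 2])
    n <- a + b + cc + d
    expect_equal(got$or, sum(a * d / n) / sum(b * cc / n), tolerance = 1e-12)
    arr <- array(unlist(tabs), dim = c(2, 2, 3))
    mh <- mantelhaen.test(arr, correct = FALSE)
    expect_equal(unname(got$or), unname(mh$estimate), tolerance = 1e-10)
    expect_true(got$ci_low <= got$or && got$or <= got$ci_high)
  }
})

test_that("late-early CMH split detects late-replication excess by group", {
  bi <- toy_bin_info(signal = seq(30, 70, length.out = 200))
  set.seed(31)
  late_idx <- c(sample.int(100, 600, replace = TRUE),       # low-signal half
                sample.int(200, 200, replace = TRUE))
  all_idx <- sample.int(200, 800, replace = TRUE)
  calls <- data.frame(
    chrom = "chr1",
    pos = (c(late_idx, all_idx) - 1) * 1000 + 1,
    context_class = sample(c("CpG", "strong", "weak"), 1600, replace = TRUE))
  groups <- rep(c("clustered", "non_clustered"), each = 800)
  res <- clustered_cmh_or(calls, groups, bi)
  or_cl <- res$or[res$group == "clustered"]
  or_nc <- res$or[res$group == "non_clustered"]
  expect_gt(or_cl, 1.5)
  expect_gt(or_cl, or_nc)
  expect_lt(abs(log(or_nc)), 0.35)
})

test_that("crossover overlap permutation test behaves at its extremes", {
  # every call inside its own family's bin, none inside other families'
  fams <- sprintf("F%02d", 1:12)
  bins <- data.frame(family_id = fams, chrom = "chr1",
                     start = seq(0, by = 1e6, length.out = 12),
                     end = seq(1e4, by = 1e6, length.out = 12))
  calls <- data.frame(individual_id = fams, chrom = "chr1",
                      pos = bins$start + 5000)
  res <- crossover_overlap_test(calls, bins, permutations = 500, seed = 2)
  expect_identical(res$observed, 12L)
  expect_equal(res$p_value, 1 / 501)

  # identical bins across families: full exchangeability, p ~ 1
  bins_same <- do.call(rbind, lapply(fams, function(f)
    data.frame(family_id = f, chrom = "chr1", start = 0, end = 1e5)))
  calls2 <- data.frame(individual_id = fams, chrom = "chr1", pos = 5e4)
  res2 <- crossover_overlap_test(calls2, bins_same, permutations = 300,
                                 seed = 3)
  expect_equal(res2$expected, res2$observed)
  expect_equal(res2$p_value, 1)
  expect_error(crossover_overlap_test(calls,
                                      bins[bins$family_id == "F01", ]),
               "at least 2")
})

test_that("the interval convention is half-open zero-based", {
  bins <- data.frame(family_id = c("A", "B"), chrom = "chr1",
                     start = c(100, 5000), end = c(200, 5100))
  # bin [100, 200) in 0-based coordinates covers 1-based positions 101..200
  calls <- data.frame(individual_id = rep("A", 4), chrom = "chr1",
                      pos = c(100, 101, 200, 201))
  res <- crossover_overlap_test(calls, bins, permutations = 10, seed = 1)
  expect_identical(res$observed, 2L)
})

test_that("crossover test has power against a cohort-scale 40% excess", {
  set.seed(41)
  n_fam <- 266
  fams <- sprintf("F%03d", seq_len(n_fam))
  G <- 2e9   # single synthetic chromosome; keeps coordinates in int range
  rejections <- replicate(25, {
    bins <- do.call(rbind, lapply(fams, function(f) {
      n <- rpois(1, 60)
      start <- sort(runif(n, 0, G - 2.2e5))
      data.frame(family_id = f, chrom = "chr1", start = start,
                 end = start + rexp(n, 1 / 2.01e5))
    }))
    # ~60 expected chance overlaps, inflated 40% for own-family placement
    calls <- do.call(rbind, lapply(fams, function(f) {
      n <- rpois(1, 63)
      own <- bins[bins$family_id == f, ]
      p_in <- 0.4 * sum(own$end - own$start) / G
      inside <- runif(n) < p_in
      pos <- numeric(n)
      if (any(inside)) {
        j <- sample.int(nrow(own), sum(inside), replace = TRUE)
        pos[inside] <- floor(runif(sum(inside), own$start[j], own$end[j])) + 1
      }
      pos[!inside] <- sample.int(G, sum(!inside))
      data.frame(individual_id = f, chrom = "chr1", pos = pos)
    }))
    crossover_overlap_test(calls, bins, permutations = 400,
                           seed = sample.int(1e6, 1))$p_value < 0.05
  })
  expect_gte(mean(rejections), 0.8)
})

test_that("permutation p-values are valid under exchangeable truth", {
  set.seed(51)
  n_fam <- 20
  fams <- sprintf("F%02d", seq_len(n_fam))
  pvals <- replicate(150, {
    bins <- do.call(rbind, lapply(fams, function(f) {
      start <- sort(sample.int(1e7, 4))
      data.frame(family_id = f, chrom = "chr1", start = start,
                 end = start + 5e4)
    }))
    calls <- data.frame(individual_id = sample(fams, 200, replace = TRUE),
                        chrom = "chr1", pos = sample.int(1e7, 200))
    crossover_overlap_test(calls, bins, permutations = 150,
                           seed = sample.int(1e6, 1))$p_value
  })
  for (alpha in c(0.05, 0.1, 0.25))
    expect_lte(mean(pvals <= alpha), alpha + 0.06)
})
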