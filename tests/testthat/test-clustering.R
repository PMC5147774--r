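test_that("forward-scan distances follow their definitions", {
  d <- nearest_distances(c(100, 150, 10050), rep("a", 3))
  expect_equal(d$any, c(50, 9900))
  expect_equal(sort(d$same), c(50, 9900))
  expect_length(d$different, 0)

  # interleaved individuals: same-individual distances skip the other one
  d2 <- nearest_distances(c(10, 20, 30, 40), c("a", "b", "a", "b"))
  expect_equal(d2$any, c(10, 10, 10))
  expect_equal(sort(d2$same), c(20, 20))
  expect_equal(d2$different, c(10, 10, 10))

  expect_identical(lengths(nearest_distances(5, "a")),
                   c(any = 0L, same = 0L, different = 0L))
  expect_error(nearest_distances(c(5, 1), c("a", "b")), "sorted")
})

test_that("the independence null reproduces the two-point order-statistic median", {
  g <- generate_genome(cohort_config(genome_length = 1e5, seed = 31))
  counts <- matrix(c(0, 0, 2), 1, dimnames = list(NULL,
                                                  c("CpG", "strong", "weak")))
  null <- simulate_independence_null(counts, g, replicates = 1500, seed = 5)
  # closed form: for two uniform points on [0, G], P(|U1-U2| <= d) =
  # 1 - (1 - d/G)^2, so the median distance is G (1 - 1/sqrt(2))
  G <- sum(g$chrom_lengths)
  expect_length(null$medians$any, 1)
  expect_equal(null$medians$any, G * (1 - 1 / sqrt(2)), tolerance = 0.1)
})

test_that("null draws avoid zero-callability regions and respect class counts", {
  g <- generate_genome(cohort_config(genome_length = 2e4, seed = 32))
  bins <- data.frame(chrom = rep(g$chrom_names, each = 2),
                     start = rep(c(0, 5000), 2),
                     end = rep(c(5000, 10000), 2))
  bins$callability <- c(1, 0, 1, 0)   # second half of each chromosome dead
  pool <- denovotrio:::null_position_pool(g, bins)
  counts <- matrix(c(3, 5, 10), 1,
                   dimnames = list(NULL, c("CpG", "strong", "weak")))
  set.seed(2)
  for (i in 1:20) {
    d <- denovotrio:::draw_null_set(pool, counts)
    expect_length(d$pos, 18)
    local_pos <- ifelse(d$pos > g$chrom_lengths[1],
                        d$pos - g$chrom_lengths[1], d$pos)
    expect_true(all(local_pos <= 5000))
  }
  bins0 <- bins; bins0$callability <- 0
  expect_error(simulate_independence_null(counts, g, bins0, replicates = 2),
               "zero callability")
})

test_that("null distance medians are monotone in rank and cover an MNM-free cohort", {
  cfg <- cohort_config(n_families = 12, genome_length = 2e6, seed = 33,
                       mnm_fraction = 0)
  g <- generate_genome(cfg)
  fam <- generate_families(cfg)
  mut <- generate_mutations(g, fam, cfg)
  snv <- mut[mut$kind == "SNV", ]
  snv$concat_pos <- concat_positions(snv$chrom, snv$pos, g$chrom_lengths)
  snv <- snv[order(snv$concat_pos), ]
  counts <- t(sapply(split(snv$context_class, snv$family_id),
                     function(x) table(factor(x, c("CpG", "strong", "weak")))))
  null <- simulate_independence_null(counts, g, replicates = 60, seed = 6)
  expect_true(all(diff(null$medians$any) >= 0))
  expect_true(all(diff(null$medians$same) >= 0))
  obs <- nearest_distances(snv$concat_pos, snv$family_id)
  ks <- suppressWarnings(ks.test(obs$same, null$medians$same))
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation expectation is degenerate for one individual and calibrated for labels", {
  pe1 <- permutation_expected_fraction(c(100, 5000, 1e6), rep("a", 3),
                                       threshold = 20000, permutations = 50)
  expect_identical(pe1$observed, pe1$expected)
  expect_error(permutation_expected_fraction(1:3, c("a", "b", "c"),
                                             threshold = 0), "threshold")

  # reference cohort counts pass through the observed-fraction computation:
  # 279 pairs < 20kb apart among 17812 SNVs -> 558 clustered mutations
  set.seed(9)
  n_iso <- 17812 - 558
  iso <- sort(sample(seq(1e6, 2.4e9, by = 1e5), n_iso))
  pair_anchor <- seq(2.5e9, by = 3e6, length.out = 279)
  pos <- sort(c(iso, pair_anchor, pair_anchor + 500))
  indiv <- rep("same", length(pos))
  obs <- denovotrio:::fraction_within_threshold(indiv, pos, 20000)
  expect_equal(obs, 558 / 17812)
  expect_equal(round(100 * obs, 1), 3.1)
})

test_that("single-linkage clustering follows the gap rule and recovers truth clusters", {
  m <- records_from_positions(c(100, 600, 30000), rep("a", 3))
  res <- build_clusters(m)
  expect_identical(nrow(res$clusters), 1L)
  expect_identical(res$clusters$n, 2L)
  expect_setequal(res$members$pos, c(100, 600))

  # single linkage spans > 20kb through <= 20kb links
  chain <- records_from_positions(c(0, 15000, 30000), rep("a", 3))
  res2 <- build_clusters(chain)
  expect_identical(res2$clusters$n, 3L)
  expect_gt(res2$clusters$span, 20000)

  # same-chromosome requirement unless strict concatenation is requested
  cross <- data.frame(individual_id = "a", chrom = c("chr1", "chr2"),
                      pos = c(999900, 50), kind = "SNV",
                      concat_pos = c(999900, 1000050))
  expect_identical(nrow(build_clusters(cross)$clusters), 0L)
  expect_identical(nrow(build_clusters(cross, strict_concat = TRUE)$clusters),
                   1L)

  # recovery of generator truth clusters on a sparse cohort
  cfg <- cohort_config(n_families = 20, genome_length = 1e7, seed = 35,
                       mean_snv = 6, mnm_fraction = 0.5, mean_indel = 0.2)
  g <- generate_genome(cfg)
  fam <- generate_families(cfg)
  mut <- generate_mutations(g, fam, cfg)
  mut$individual_id <- mut$family_id
  mut$concat_pos <- concat_positions(mut$chrom, mut$pos, g$chrom_lengths)
  mut <- mut[order(mut$concat_pos), ]
  built <- build_clusters(mut)
  truth_lab <- ifelse(is.na(mut$cluster_id),
                      paste0("s", seq_len(nrow(mut))), mut$cluster_id)
  built_lab <- built$members$cluster_id[
    match(paste(mut$individual_id, mut$concat_pos),
          paste(built$members$individual_id, built$members$concat_pos))]
  built_lab[is.na(built_lab)] <- paste0("b", seq_len(sum(is.na(built_lab))))
  expect_gte(rand_index(truth_lab, built_lab), 0.99)
})

test_that("cluster membership is a partition of the clustered mutations", {
  co <- small_cohort()
  tr <- truth_records(co)
  res <- build_clusters(tr)
  expect_identical(anyDuplicated(paste(res$members$individual_id,
                                       res$members$concat_pos)), 0L)
  expect_true(all(table(res$members$cluster_id) >= 2))
  expect_identical(sum(res$clusters$n), nrow(res$members))
  # observed clustered fraction is monotone in the threshold
  snv <- tr[tr$kind == "SNV", ]
  fr <- vapply(c(1e3, 5e3, 2e4, 1e5), function(thr)
    denovotrio:::fraction_within_threshold(snv$individual_id,
                                           snv$concat_pos, thr), numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("tandem events collapse adjoining pairs and reproduce the reference cohort rate", {
  # 54 isolated adjoining pairs among 17812 SNVs
  anchors <- seq(1e6, by = 1e6, length.out = 54)
  singles <- seq(2e8, by = 1e5, length.out = 17812 - 108)
  pos <- c(rbind(anchors, anchors + 1), singles)
  m <- records_from_positions(pos, rep("a", length(pos)))
  te <- tandem_events(m)
  expect_identical(te$n_events, 54L)
  expect_identical(te$n_adjoining_mutations, 108L)
  expect_equal(round(100 * te$rate, 2), 0.30)
  expect_equal(round(100 * te$ci[["low"]], 2), 0.23)
  expect_equal(round(100 * te$ci[["high"]], 2), 0.40)

  # distance 2 is not adjoining; a triple is one event of three
  m2 <- records_from_positions(c(500, 502), c("a", "a"))
  expect_identical(tandem_events(m2)$n_events, 0L)
  m3 <- records_from_positions(c(500, 501, 502, 9000), rep("a", 4))
  te3 <- tandem_events(m3)
  expect_identical(te3$n_events, 1L)
  expect_identical(te3$events$size, 3L)
})

test_that("subsampling thins the clustered fraction as analysis predicts", {
  set.seed(21)
  n_ind <- 40
  pos <- sort(runif(n_ind * 60, 0, 2.5e8))
  indiv <- sample(rep(seq_len(n_ind), 60))
  full <- denovotrio:::fraction_within_threshold(indiv, pos, 20000)
  half <- subsample_cluster_fraction(pos, indiv, 30, replicates = 400,
                                     seed = 3)
  expect_equal(half$keep_rate, 0.5)
  # for independent placements the pair count scales with keep_rate^2 but
  # the per-mutation fraction scales with keep_rate
  expect_equal(half$mean_fraction, full * 0.5, tolerance = 0.1)
  noop <- subsample_cluster_fraction(pos, indiv, 60, replicates = 5, seed = 4)
  expect_equal(noop$mean_fraction, full, tolerance = 1e-12)
  expect_error(subsample_cluster_fraction(pos, indiv, 61), "target mean")
})

test_that("read-backed phasing applies the 90% concordance rule", {
  mk <- function(n_cis, n_trans) {
    reads <- do.call(rbind, lapply(seq_len(n_cis + n_trans), function(i) {
      alle <- if (i <= n_cis) c("alt", "alt") else c("alt", "ref")
      data.frame(read_id = i, chrom = "chr1", pos = c(1000, 1005),
                 allele = alle)
    }))
    phase_by_reads(reads)
  }
  expect_identical(mk(10, 0)$verdict, "same_chromosome")
  expect_identical(mk(9, 1)$verdict, "same_chromosome")   # exactly 90%
  expect_identical(mk(11, 4)$verdict, "inconsistent")     # 73% vs 27%
  expect_identical(mk(0, 10)$verdict, "different")
  # reads covering a single site are uninformative: no pair emitted
  solo <- data.frame(read_id = 1:3, chrom = "chr1", pos = 1000,
                     allele = "alt")
  expect_identical(nrow(phase_by_reads(solo)), 0L)
})
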