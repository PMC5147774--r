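#' Average several replication-timing tracks
#'
#' Positionwise (here: per-bin) arithmetic mean of the input signals.
#' `policy = "any"` averages over the tracks that have data in a bin and
#' drops bins with no data at all; `policy = "all"` keeps only bins covered
#' by every track.
#'
#' @param replication data.frame `chrom`, `start`, `end`, `track1..trackK`.
#' @param policy `"any"` (default) or `"all"`.
#' @return data.frame `chrom`, `start`, `end`, `signal`.
#' @export
average_tracks <- function(replication, policy = c("any", "all")) {
  policy <- match.arg(policy)
  track_cols <- grep("^track", names(replication), value = TRUE)
  if (!length(track_cols)) stop("no replication tracks found")
  m <- as.matrix(replication[, track_cols, drop = FALSE])
  keep <- if (policy == "all") rowSums(is.na(m)) == 0
  else rowSums(!is.na(m)) > 0
  out <- replication[keep, c("chrom", "start", "end")]
  out$signal <- rowMeans(m[keep, , drop = FALSE], na.rm = TRUE)
  rownames(out) <- NULL
  out
}

#' Cohort callability summarised per genome bin
#'
#' For each depth-profile bin, the cohort sums of the expected per-position
#' SNV callability (`callable_perpos`) and of callability weighted by each
#' family's combined parental years (`callable_years_perpos`), plus the
#' bin's context-class composition. These are the position weights and rate
#' denominators of the replication-timing analyses.
#'
#' @param cohort A `trio_cohort`.
#' @param thresholds A [filter_thresholds()].
#' @param eps Base error rate (defaults to the cohort's).
#' @return data.frame: `chrom`, `start`, `end`, `n_CpG`, `n_strong`,
#'   `n_weak`, `callable_perpos`, `callable_years_perpos`.
#' @export
cohort_bin_callability <- function(cohort, thresholds = filter_thresholds(),
                                   eps = NULL) {
  if (is.null(eps)) eps <- cohort$config$base_error_rate
  prof <- cohort$depth_profile
  genome <- cohort$genome
  bw <- prof$end[1] - prof$start[1]
  ctx_bins <- context_bin_counts(genome, bw)
  dmax <- max(stats::qpois(1 - 1e-9, max(prof$dp_child, prof$dp_father,
                                         prof$dp_mother)), 30)
  fam <- cohort$families
  acc <- matrix(0, nrow(ctx_bins), 2)
  for (i in seq_len(nrow(fam))) {
    p <- prof[prof$family_id == fam$family_id[i], ]
    p <- p[order(match(p$chrom, genome$chrom_names), p$start), ]
    cf <- expected_callability_poisson(p$dp_child, p$dp_father, p$dp_mother,
                                       eps, thresholds, dmax)
    acc[, 1] <- acc[, 1] + cf
    acc[, 2] <- acc[, 2] + (fam$father_age[i] + fam$mother_age[i]) * cf
  }
  ctx_bins$callable_perpos <- acc[, 1]
  ctx_bins$callable_years_perpos <- acc[, 2]
  ctx_bins
}

#' Join replication signal onto callability bins
#'
#' Maps the averaged replication signal (binned at its own resolution) onto
#' the context/callability bins of [cohort_bin_callability()] by bin
#' midpoint, giving the single table the replication-timing analyses
#' consume. Bins without signal are dropped (sites without replication data
#' are disregarded).
#'
#' @param avg_track Output of [average_tracks()].
#' @param bin_callability Output of [cohort_bin_callability()].
#' @return `bin_callability` with a `signal` column.
#' @export
replication_bin_info <- function(avg_track, bin_callability) {
  mid <- (bin_callability$start + bin_callability$end) / 2
  bw <- avg_track$end[1] - avg_track$start[1]
  key <- paste(avg_track$chrom, avg_track$start %/% bw)
  idx <- match(paste(bin_callability$chrom, floor(mid) %/% bw), key)
  out <- bin_callability
  out$signal <- avg_track$signal[idx]
  out[!is.na(out$signal), ]
}

# Assign calls to bins of a bin table; returns row indices (NA if outside).
call_bin_index <- function(calls, bins) {
  bw <- bins$end[1] - bins$start[1]
  match(paste(calls$chrom, (calls$pos - 1) %/% bw),
        paste(bins$chrom, bins$start %/% bw))
}

#' Mutation rate by replication-timing decile
#'
#' Splits the genome into deciles of the replication signal, weighting each
#' bin by its callability-years, and reports the per-decile, per-context
#' per-position-per-year rate with Wilson CIs, together with the mean
#' signal per decile. High signal = early replication.
#'
#' @param calls SNV calls with `chrom`, `pos`, `context_class`.
#' @param bin_info Output of [replication_bin_info()].
#' @param level Confidence level.
#' @return data.frame: `decile` (1 = latest/lowest signal), `mean_signal`,
#'   `context`, `count`, `denominator_years`, `rate_pppy`, `ci_low`,
#'   `ci_high`.
#' @export
replication_decile_rates <- function(calls, bin_info, level = 0.95) {
  if (stats::sd(bin_info$signal) == 0)
    stop("replication signal is constant; deciles are undefined")
  w <- (bin_info$n_CpG + bin_info$n_strong + bin_info$n_weak) *
    bin_info$callable_perpos
  o <- order(bin_info$signal)
  cw <- cumsum(w[o]) / sum(w)
  dec_sorted <- pmax(pmin(ceiling(cw * 10 - 1e-9), 10L), 1L)
  decile <- integer(nrow(bin_info))
  decile[o] <- dec_sorted
  bi <- call_bin_index(calls, bin_info)
  out <- list()
  for (d in 1:10) {
    sel <- decile == d
    ms <- stats::weighted.mean(bin_info$signal[sel], w[sel])
    for (cx in c("CpG", "strong", "weak")) {
      denom <- sum(bin_info[[paste0("n_", cx)]][sel] *
                     bin_info$callable_years_perpos[sel])
      idx <- bi[!is.na(bi) & calls$context_class == cx]
      n <- sum(decile[idx] == d)
      ci <- if (denom > 0) wilson_ci(n, round(denom), level) else c(NA, NA)
      out[[paste(d, cx)]] <- data.frame(
        decile = d, mean_signal = ms, context = cx, count = n,
        denominator_years = denom,
        rate_pppy = if (denom > 0) n / denom else NA_real_,
        ci_low = ci[[1]], ci_high = ci[[2]], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Logistic regression of mutation occurrence on replication timing
#'
#' Aggregates mutated counts and callable (non-mutated) weight per rounded
#' signal value and context class, then fits a weighted logistic regression
#' of mutated-versus-callable on the signal with context-class indicator
#' covariates. A negative coefficient means more mutations at low signal
#' (late replication).
#'
#' @param calls SNV calls with `chrom`, `pos`, `context_class`.
#' @param bin_info Output of [replication_bin_info()].
#' @param signal_digits Signal rounded to this many decimals before
#'   aggregation (bounds the design size).
#' @return List: `coefficient`, `se`, `p_value`, `separation` (logical),
#'   `fit`.
#' @export
replication_association_test <- function(calls, bin_info,
                                         signal_digits = 2) {
  bi <- call_bin_index(calls, bin_info)
  ok <- !is.na(bi) & calls$context_class %in% c("CpG", "strong", "weak")
  agg <- list()
  for (cx in c("CpG", "strong", "weak")) {
    sig <- round(bin_info$signal, signal_digits)
    w <- bin_info[[paste0("n_", cx)]] * bin_info$callable_perpos
    cal <- tapply(w, sig, sum)
    mut_sig <- round(bin_info$signal[bi[ok & calls$context_class == cx]],
                     signal_digits)
    m <- table(factor(mut_sig, levels = names(cal)))
    agg[[cx]] <- data.frame(signal = as.numeric(names(cal)),
                            context = cx, mutated = as.integer(m),
                            callable = as.numeric(cal))
  }
  df <- do.call(rbind, agg)
  df <- df[df$callable > 0 | df$mutated > 0, ]
  fit <- suppressWarnings(
    stats::glm(cbind(mutated, round(pmax(callable - mutated, 0))) ~
                 signal + context,
               data = df, family = stats::binomial()))
  sep <- !fit$converged || any(abs(stats::coef(fit)) > 30)
  cf <- summary(fit)$coefficients
  list(coefficient = cf["signal", 1], se = cf["signal", 2],
       p_value = cf["signal", 4], separation = sep, fit = fit)
}

#' Cochran-Mantel-Haenszel combined odds ratio
#'
#' Combined odds ratio `sum(a_i d_i / n_i) / sum(b_i c_i / n_i)` over a list
#' of 2x2 tables (rows: mutated / callable-not-mutated; columns: late /
#' early), with a Robins-Breslow-Greenland confidence interval. Strata with
#' an empty margin contribute nothing to the sums.
#'
#' @param tables List of 2x2 matrices.
#' @param level Confidence level.
#' @return List: `or`, `ci_low`, `ci_high`, `n_strata`.
#' @examples
#' t1 <- matrix(c(10, 5, 5, 10), 2, byrow = TRUE)
#' cmh_or(list(t1, t1, t1))$or   # 4
#' @export
cmh_or <- function(tables, level = 0.95) {
  a <- vapply(tables, function(t) t[1, 1], numeric(1))
  b <- vapply(tables, function(t) t[1, 2], numeric(1))
  cc <- vapply(tables, function(t) t[2, 1], numeric(1))
  d <- vapply(tables, function(t) t[2, 2], numeric(1))
  n <- a + b + cc + d
  use <- n > 0
  R <- sum((a * d / n)[use]); S <- sum((b * cc / n)[use])
  if (S == 0 || R == 0)
    return(list(or = if (S == 0) Inf else 0, ci_low = NA_real_,
                ci_high = NA_real_, n_strata = sum(use)))
  or <- R / S
  # Robins-Breslow-Greenland variance of log(OR_MH)
  P <- ((a + d) / n)[use]; Q <- ((b + cc) / n)[use]
  Rk <- (a * d / n)[use]; Sk <- (b * cc / n)[use]
  var_log <- sum(P * Rk) / (2 * R^2) +
    sum(P * Sk + Q * Rk) / (2 * R * S) + sum(Q * Sk) / (2 * S^2)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or = or, ci_low = or * exp(-z * sqrt(var_log)),
       ci_high = or * exp(z * sqrt(var_log)), n_strata = sum(use))
}

#' Late-vs-early CMH odds ratios per clustering group
#'
#' Splits the genome at the callability-weighted median replication signal
#' into late (low signal) and early halves and, for each group of calls
#' (e.g. clustering-distance strata), forms one 2x2 table per context class
#' (mutated vs callable-non-mutated by late vs early) and combines them
#' with [cmh_or()]. OR > 1 means excess mutations in the late half.
#'
#' @param calls SNV calls with `chrom`, `pos`, `context_class`.
#' @param groups Factor/character grouping aligned with `calls` rows.
#' @param bin_info Output of [replication_bin_info()].
#' @param level Confidence level.
#' @return data.frame: `group`, `or`, `ci_low`, `ci_high`.
#' @export
clustered_cmh_or <- function(calls, groups, bin_info, level = 0.95) {
  w <- (bin_info$n_CpG + bin_info$n_strong + bin_info$n_weak) *
    bin_info$callable_perpos
  o <- order(bin_info$signal)
  med <- bin_info$signal[o][which(cumsum(w[o]) >= sum(w) / 2)[1]]
  late_bin <- bin_info$signal <= med
  bi <- call_bin_index(calls, bin_info)
  out <- lapply(unique(groups), function(g) {
    tabs <- lapply(c("CpG", "strong", "weak"), function(cx) {
      callable <- bin_info[[paste0("n_", cx)]] * bin_info$callable_perpos
      sel <- groups == g & calls$context_class == cx & !is.na(bi)
      a <- sum(late_bin[bi[sel]])
      b <- sum(!late_bin[bi[sel]])
      matrix(c(a, b, sum(callable[late_bin]) - a,
               sum(callable[!late_bin]) - b), 2, byrow = TRUE)
    })
    res <- cmh_or(tabs, level)
    data.frame(group = g, or = res$or, ci_low = res$ci_low,
               ci_high = res$ci_high, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Permutation test of mutation overlap with crossover bins
#'
#' Counts de novo calls falling inside a crossover bin of their own family
#' (half-open 0-based bins; a 1-based call at `p` overlaps `[start, end)`
#' iff `start < p <= end`), then permutes whole per-family bin lists across
#' families to obtain the chance expectation. Families without mapped
#' crossovers are excluded. The p-value uses the add-one convention with a
#' `>=` comparison.
#'
#' @param calls Calls with `individual_id` (family), `chrom`, `pos`.
#' @param crossovers data.frame `family_id`, `chrom`, `start`, `end`.
#' @param permutations Number of permutations (default 5000).
#' @param seed Integer seed.
#' @return List: `observed`, `expected` (median permuted count),
#'   `p_value`, `n_families`, `perm_counts`.
#' @export
crossover_overlap_test <- function(calls, crossovers, permutations = 5000,
                                   seed = 1) {
  fams <- sort(unique(crossovers$family_id))
  if (length(fams) < 2) stop("need crossover bins for at least 2 families")
  calls <- calls[calls$individual_id %in% fams, , drop = FALSE]
  mut_gr <- GenomicRanges::GRanges(calls$chrom,
                                   IRanges::IRanges(calls$pos, calls$pos))
  xo_gr <- GenomicRanges::GRanges(crossovers$chrom,
                                  IRanges::IRanges(crossovers$start + 1L,
                                                   crossovers$end))
  hits <- GenomicRanges::findOverlaps(mut_gr, xo_gr)
  pair <- unique(data.frame(
    mf = match(calls$individual_id[S4Vectors::queryHits(hits)], fams),
    bf = match(crossovers$family_id[S4Vectors::subjectHits(hits)], fams),
    mut = S4Vectors::queryHits(hits)))
  # count matrix: mutations of family i inside bins of family j
  K <- length(fams)
  cnt <- matrix(0L, K, K)
  if (nrow(pair)) {
    tab <- table(factor(pair$mf, levels = seq_len(K)),
                 factor(pair$bf, levels = seq_len(K)))
    cnt <- matrix(as.integer(tab), K, K)
  }
  observed <- sum(diag(cnt))
  set.seed(seed)
  perm_counts <- vapply(seq_len(permutations), function(i) {
    sigma <- sample.int(K)
    sum(cnt[cbind(seq_len(K), sigma)])
  }, numeric(1))
  list(observed = observed, expected = stats::median(perm_counts),
       p_value = (1 + sum(perm_counts >= observed)) / (1 + permutations),
       n_families = K, perm_counts = perm_counts)
}
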