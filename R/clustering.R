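#' Forward-scan nearest-mutation distances
#'
#' With all mutations sorted on the concatenated-genome axis, lists for each
#' mutation the distance to the next mutation in the sorted list (any
#' individual), the next mutation from the same individual, and the next
#' mutation from a different individual. Mutations without a successor of a
#' given kind contribute nothing to that list.
#'
#' @param concat_pos Sorted (non-decreasing) positions on the concatenated
#'   axis.
#' @param individual Individual labels aligned with `concat_pos`.
#' @return List with numeric vectors `any`, `same`, `different`.
#' @examples
#' nearest_distances(c(100, 150, 10050), c("a", "a", "a"))$any
#' @export
nearest_distances <- function(concat_pos, individual) {
  n <- length(concat_pos)
  if (n != length(individual)) stop("inputs must be aligned")
  if (is.unsorted(concat_pos)) stop("mutations must be sorted by concat_pos")
  if (n < 2) return(list(any = numeric(0), same = numeric(0),
                         different = numeric(0)))
  d_any <- diff(concat_pos)

  # next same-individual: consecutive differences within each individual
  d_same <- unlist(lapply(split(concat_pos, individual), diff),
                   use.names = FALSE)

  # next different-individual: advance candidate pointers past own runs
  cand <- seq_len(n) + 1L
  repeat {
    alive <- which(cand <= n)
    stuck <- alive[individual[cand[alive]] == individual[alive]]
    if (!length(stuck)) break
    cand[stuck] <- cand[stuck] + 1L
  }
  has <- cand <= n
  d_diff <- concat_pos[cand[has]] - concat_pos[has]
  list(any = as.numeric(d_any), same = sort(as.numeric(d_same)),
       different = as.numeric(d_diff))
}

# Fraction of mutations with another same-individual mutation strictly
# closer than `threshold` on the concatenated axis.
fraction_within_threshold <- function(individual, concat_pos, threshold) {
  n <- length(concat_pos)
  if (n < 2) return(0)
  o <- order(individual, concat_pos)
  iv <- individual[o]; ps <- concat_pos[o]
  near <- (diff(ps) < threshold) & (iv[-1] == iv[-n])
  mean(c(near, FALSE) | c(FALSE, near))
}

#' Observed vs permutation-expected clustered fraction
#'
#' Observed: the fraction of mutations with another mutation of the same
#' individual strictly less than `threshold` bp away on the concatenated
#' axis. Expected: the median of that fraction over random permutations of
#' the individual labels, which preserves the overall positional landscape
#' while breaking the within-individual linkage.
#'
#' @param concat_pos Concatenated-axis positions.
#' @param individual Individual labels.
#' @param threshold Distance threshold in bp (strict `<`).
#' @param permutations Number of label permutations (default 500).
#' @param seed Integer seed.
#' @return List: `observed`, `expected` (median permuted fraction),
#'   `perm_fractions`.
#' @export
permutation_expected_fraction <- function(concat_pos, individual,
                                          threshold = 20000,
                                          permutations = 500, seed = 1) {
  if (threshold <= 0) stop("threshold must be positive")
  set.seed(seed)
  observed <- fraction_within_threshold(individual, concat_pos, threshold)
  perm <- vapply(seq_len(permutations), function(i)
    fraction_within_threshold(sample(individual), concat_pos, threshold),
    numeric(1))
  list(observed = observed, expected = stats::median(perm),
       perm_fractions = perm)
}

#' Independence-null clustered fraction at cohort scale
#'
#' Simulates cohorts in which each individual's mutations are placed
#' independently and uniformly on a concatenated callable axis (counts
#' Poisson around `mean_per_individual`), and reports the per-replicate
#' fraction of mutations with a same-individual neighbour strictly closer
#' than `threshold`. The median over replicates is the independence
#' expectation against which an observed clustered fraction is judged.
#'
#' @param n_individuals Number of individuals.
#' @param mean_per_individual Mean mutations per individual (Poisson).
#' @param axis_length Length of the concatenated callable axis in bp.
#' @param threshold Distance threshold in bp (strict `<`).
#' @param replicates Number of simulated cohorts (default 500).
#' @param seed Integer seed.
#' @return List: `median` (fraction), `fractions` (per replicate), `ci`
#'   (2.5%/97.5% quantiles over replicates).
#' @export
independence_null_fraction <- function(n_individuals, mean_per_individual,
                                       axis_length, threshold = 5000,
                                       replicates = 500, seed = 1) {
  set.seed(seed)
  fr <- vapply(seq_len(replicates), function(r) {
    counts <- stats::rpois(n_individuals, mean_per_individual)
    total <- sum(counts)
    if (total < 2) return(0)
    indiv <- rep.int(seq_len(n_individuals), counts)
    pos <- stats::runif(total, 0, axis_length)
    fraction_within_threshold(indiv, pos, threshold)
  }, numeric(1))
  list(median = stats::median(fr), fractions = fr,
       ci = stats::quantile(fr, c(0.025, 0.975), names = FALSE))
}

#' Simulation null for nearest-mutation distance distributions
#'
#' Simulates random mutation sets in which each individual keeps its
#' observed number of mutations in each context class (CpG / non-CpG strong
#' / weak), with positions drawn within class proportionally to the mean
#' per-bin callability, then computes the three forward-scan distance lists
#' of [nearest_distances()] on the concatenated axis. Per-rank medians over
#' replicates give the null quantiles for QQ comparison with the observed
#' distances.
#'
#' @param counts_by_class Matrix or data.frame, one row per individual,
#'   columns `CpG`, `strong`, `weak`: mutation counts.
#' @param genome A `genome_model`.
#' @param callability_bins Optional data.frame `chrom`, `start`, `end`,
#'   `callability` of mean per-bin callability weights; uniform when `NULL`.
#' @param replicates Number of simulated sets (default 500).
#' @param seed Integer seed.
#' @return List: `medians` (per-rank medians for `any`, `same`,
#'   `different`), `n_replicates`.
#' @export
simulate_independence_null <- function(counts_by_class, genome,
                                       callability_bins = NULL,
                                       replicates = 500, seed = 1) {
  set.seed(seed)
  counts_by_class <- as.matrix(counts_by_class)
  stopifnot(all(c("CpG", "strong", "weak") %in% colnames(counts_by_class)))
  pool <- null_position_pool(genome, callability_bins)
  for (cx in colnames(counts_by_class)[colSums(counts_by_class) > 0]) {
    pw <- pool[[cx]]
    if (length(pw$pos) == 0 ||
        (!is.null(pw$w) && sum(pw$w) == 0))
      stop("context class ", cx, " has zero callability but nonzero counts")
  }
  reps <- lapply(seq_len(replicates), function(r) {
    d <- draw_null_set(pool, counts_by_class)
    nearest_distances(d$pos, d$individual)
  })
  med_by_rank <- function(key) {
    lists <- lapply(reps, function(r) sort(r[[key]]))
    L <- min(lengths(lists))
    if (L == 0) return(numeric(0))
    mat <- matrix(unlist(lapply(lists, function(x) x[seq_len(L)])),
                  nrow = L)
    apply(mat, 1, stats::median)
  }
  list(medians = list(any = med_by_rank("any"), same = med_by_rank("same"),
                      different = med_by_rank("different")),
       n_replicates = replicates)
}

# Per-class pools of concatenated positions (with optional callability
# weights) from which the independence null draws.
null_position_pool <- function(genome, callability_bins = NULL) {
  cls_pos <- class_positions(genome)
  lapply(c(CpG = "CpG", strong = "strong", weak = "weak"), function(cx) {
    cp <- unlist(lapply(genome$chrom_names, function(ch)
      concat_positions(rep(ch, length(cls_pos[[ch]][[cx]])),
                       cls_pos[[ch]][[cx]], genome$chrom_lengths)),
      use.names = FALSE)
    w <- NULL
    if (!is.null(callability_bins)) {
      bw <- callability_bins$end[1] - callability_bins$start[1]
      key <- paste(callability_bins$chrom, callability_bins$start %/% bw)
      pos_local <- unlist(lapply(genome$chrom_names, function(ch)
        cls_pos[[ch]][[cx]]), use.names = FALSE)
      chrom_rep <- rep(genome$chrom_names,
                       vapply(genome$chrom_names,
                              function(ch) length(cls_pos[[ch]][[cx]]),
                              integer(1)))
      w <- callability_bins$callability[
        match(paste(chrom_rep, (pos_local - 1) %/% bw), key)]
      if (any(is.na(w))) stop("callability bins do not cover the genome")
    }
    list(pos = cp, w = w)
  })
}

# One simulated mutation set: positions + individual labels, sorted.
draw_null_set <- function(pool, counts_by_class) {
  n_ind <- nrow(counts_by_class)
  pos <- list(); indiv <- list()
  for (cx in c("CpG", "strong", "weak")) {
    tot <- sum(counts_by_class[, cx])
    if (tot == 0) next
    pw <- pool[[cx]]
    draw <- if (is.null(pw$w))
      pw$pos[sample.int(length(pw$pos), tot, replace = TRUE)]
    else sample(pw$pos, tot, replace = TRUE, prob = pw$w)
    pos[[cx]] <- draw
    indiv[[cx]] <- rep.int(seq_len(n_ind), counts_by_class[, cx])
  }
  pos <- unlist(pos, use.names = FALSE)
  indiv <- unlist(indiv, use.names = FALSE)
  o <- order(pos)
  list(pos = pos[o], individual = indiv[o])
}

#' Group same-individual mutations into MNM clusters
#'
#' Single-linkage chaining: consecutive mutations of the same individual on
#' the same chromosome are linked when their gap is strictly below
#' `max_gap`; a cluster may therefore span more than `max_gap` in total.
#' With `strict_concat = TRUE` the same-chromosome requirement is dropped
#' and linking happens purely on the concatenated axis.
#'
#' @param mutations data.frame with `individual_id`, `chrom`, `pos`,
#'   `concat_pos`, `kind`.
#' @param max_gap Linking threshold in bp (default 20000, strict `<`).
#' @param include_indels Include indel mutations in the chaining.
#' @param strict_concat Link across chromosome boundaries on the
#'   concatenated axis.
#' @return List: `members` (input rows of clustered mutations plus
#'   `cluster_id`), `clusters` (per-cluster summary: `individual_id`,
#'   `n`, `n_snv`, `n_indel`, `span`), `size_histogram` (table).
#' @export
build_clusters <- function(mutations, max_gap = 20000,
                           include_indels = TRUE, strict_concat = FALSE) {
  mut <- mutations
  if (!include_indels) mut <- mut[mut$kind == "SNV", , drop = FALSE]
  mut <- mut[order(mut$individual_id, mut$concat_pos), , drop = FALSE]
  link <- rep(FALSE, nrow(mut))
  if (nrow(mut) > 1) {
    same_ind <- mut$individual_id[-1] == mut$individual_id[-nrow(mut)]
    gap_ok <- diff(mut$concat_pos) < max_gap
    if (!strict_concat)
      gap_ok <- gap_ok & (mut$chrom[-1] == mut$chrom[-nrow(mut)])
    link <- c(FALSE, same_ind & gap_ok)
  }
  comp <- cumsum(!link)
  sizes <- table(comp)
  keep <- comp %in% as.integer(names(sizes)[sizes >= 2])
  members <- mut[keep, , drop = FALSE]
  if (nrow(members)) {
    members$cluster_id <- paste0("C", match(comp[keep], unique(comp[keep])))
    agg <- lapply(split(members, members$cluster_id), function(m)
      data.frame(cluster_id = m$cluster_id[1],
                 individual_id = m$individual_id[1],
                 n = nrow(m), n_snv = sum(m$kind == "SNV"),
                 n_indel = sum(m$kind != "SNV"),
                 span = max(m$concat_pos) - min(m$concat_pos),
                 stringsAsFactors = FALSE))
    clusters <- do.call(rbind, agg)
    clusters <- clusters[order(as.integer(sub("^C", "", clusters$cluster_id))), ]
    rownames(clusters) <- NULL
  } else {
    members$cluster_id <- character(0)
    clusters <- data.frame(cluster_id = character(),
                           individual_id = character(), n = integer(),
                           n_snv = integer(), n_indel = integer(),
                           span = numeric(), stringsAsFactors = FALSE)
  }
  list(members = members, clusters = clusters,
       size_histogram = table(clusters$n))
}

#' Tandem mutation events
#'
#' Adjoining SNVs: same individual, same chromosome, positions exactly 1 bp
#' apart. Runs of mutually adjoining SNVs are collapsed into one event (an
#' isolated pair is an event of two; a triple is a single event of three).
#' The tandem rate is events over total SNVs, with a Wilson CI.
#'
#' @param mutations data.frame with `individual_id`, `chrom`, `pos`, `kind`.
#' @param level Confidence level.
#' @return List: `events` (data.frame `individual_id`, `chrom`, `start`,
#'   `size`), `n_adjoining_mutations`, `n_events`, `n_snv`, `rate`, `ci`.
#' @export
tandem_events <- function(mutations, level = 0.95) {
  snv <- mutations[mutations$kind == "SNV", , drop = FALSE]
  snv <- snv[order(snv$individual_id, snv$chrom, snv$pos), , drop = FALSE]
  n <- nrow(snv)
  adj <- if (n > 1)
    snv$individual_id[-1] == snv$individual_id[-n] &
      snv$chrom[-1] == snv$chrom[-n] & diff(snv$pos) == 1 else logical(0)
  run_id <- cumsum(!c(FALSE, adj))
  sizes <- table(run_id)
  ev_ids <- as.integer(names(sizes)[sizes >= 2])
  events <- do.call(rbind, lapply(ev_ids, function(id) {
    m <- snv[run_id == id, ]
    data.frame(individual_id = m$individual_id[1], chrom = m$chrom[1],
               start = min(m$pos), size = nrow(m), stringsAsFactors = FALSE)
  }))
  if (is.null(events))
    events <- data.frame(individual_id = character(), chrom = character(),
                         start = integer(), size = integer())
  n_events <- nrow(events)
  rate <- if (n > 0) n_events / n else NA_real_
  list(events = events,
       n_adjoining_mutations = if (n_events) sum(events$size) else 0L,
       n_events = n_events, n_snv = n, rate = rate,
       ci = if (n > 0) wilson_ci(n_events, n, level) else c(NA, NA))
}

#' Clustered fraction after subsampling to a target mutation load
#'
#' Bernoulli-thins each individual's mutations at rate
#' `target_mean / observed_mean` and recomputes the fraction of mutations
#' with a same-individual neighbour strictly under `threshold`; used to
#' compare clustering levels across studies with different mutation yields.
#'
#' @param concat_pos,individual Mutation set on the concatenated axis.
#' @param target_mean_per_individual Target mean mutations per individual.
#' @param threshold Distance threshold in bp (default 20000).
#' @param replicates Thinning replicates (default 200).
#' @param seed Integer seed.
#' @return List: `mean_fraction`, `ci` (2.5/97.5 percentiles), `fractions`,
#'   `keep_rate`.
#' @export
subsample_cluster_fraction <- function(concat_pos, individual,
                                       target_mean_per_individual,
                                       threshold = 20000, replicates = 200,
                                       seed = 1) {
  observed_mean <- length(concat_pos) / length(unique(individual))
  if (target_mean_per_individual > observed_mean)
    stop("target mean exceeds the observed mean per individual")
  keep_rate <- target_mean_per_individual / observed_mean
  set.seed(seed)
  fr <- vapply(seq_len(replicates), function(r) {
    keep <- stats::runif(length(concat_pos)) < keep_rate
    fraction_within_threshold(individual[keep], concat_pos[keep], threshold)
  }, numeric(1))
  list(mean_fraction = mean(fr),
       ci = stats::quantile(fr, c(0.025, 0.975), names = FALSE),
       fractions = fr, keep_rate = keep_rate)
}

#' Read-backed phasing of clustered mutation pairs
#'
#' For every pair of variant positions covered by at least one read (or read
#' pair), counts reads supporting the cis configuration (alternate alleles
#' of both variants on the same template: alt-alt or ref-ref) versus trans
#' (alt-ref / ref-alt). A pair is phased `same_chromosome` when at least
#' `min_concordance` of informative reads support cis, `different` when at
#' least that fraction support trans, and `inconsistent` otherwise.
#'
#' @param read_obs data.frame of per-read allele observations: `read_id`,
#'   `chrom`, `pos`, `allele` (`"ref"` or `"alt"`).
#' @param min_concordance Phasing concordance threshold (default 0.90,
#'   inclusive).
#' @return data.frame per position pair: `chrom`, `pos1`, `pos2`, `n_cis`,
#'   `n_trans`, `verdict`; pairs with zero informative reads are absent
#'   (no-call).
#' @examples
#' reads <- data.frame(read_id = rep(1:10, each = 2), chrom = "chr1",
#'                     pos = rep(c(100, 105), 10), allele = "alt")
#' phase_by_reads(reads)$verdict   # all cis
#' @export
phase_by_reads <- function(read_obs, min_concordance = 0.90) {
  stopifnot(all(read_obs$allele %in% c("ref", "alt")))
  out <- list()
  for (rd in split(read_obs, read_obs$read_id)) {
    if (nrow(rd) < 2) next
    rd <- rd[order(rd$pos), ]
    for (i in seq_len(nrow(rd) - 1)) {
      for (j in seq(i + 1, nrow(rd))) {
        key <- paste(rd$chrom[i], rd$pos[i], rd$pos[j])
        cis <- rd$allele[i] == rd$allele[j]
        if (is.null(out[[key]]))
          out[[key]] <- list(chrom = rd$chrom[i], pos1 = rd$pos[i],
                             pos2 = rd$pos[j], n_cis = 0L, n_trans = 0L)
        if (cis) out[[key]]$n_cis <- out[[key]]$n_cis + 1L
        else out[[key]]$n_trans <- out[[key]]$n_trans + 1L
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), pos1 = integer(),
                      pos2 = integer(), n_cis = integer(),
                      n_trans = integer(), verdict = character()))
  df <- do.call(rbind, lapply(out, as.data.frame))
  tot <- df$n_cis + df$n_trans
  df$verdict <- ifelse(df$n_cis / tot >= min_concordance, "same_chromosome",
                       ifelse(df$n_trans / tot >= min_concordance,
                              "different", "inconsistent"))
  rownames(df) <- NULL
  df[order(df$chrom, df$pos1, df$pos2), ]
}
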