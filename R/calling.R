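#' Thresholds of the trio de novo calling filter
#'
#' The seven criteria, in their fixed evaluation order:
#' 1. proband genotype likelihood ratio lik(AR)/lik(RR) > `child_lr`;
#' 2. both parents lik(RR)/lik(AR) > `parent_lr`;
#' 3. no outside individual (descendants of the proband excluded) has
#'    lik(AR)/lik(RR) or lik(AA)/lik(RR) > `pop_lr_max`;
#' 4. at least `min_child_depth` quality (base quality >= 20) reads in the
#'    proband and `min_parent_depth` in each parent;
#' 5. alternate reads are at least `min_alt_fraction` of the proband's
#'    quality reads;
#' 6. the alternate allele is seen on both strands in the proband;
#' 7. site quality metrics: ReadPosRankSum within `rank_sum_band`,
#'    MQRankSum within `mq_band`, FS below `max_fs`.
#'
#' Likelihood-ratio comparisons are strict (`>`); depth and alt-fraction are
#' "at least" (`>=`); rank-sum bands are inclusive. Indel calling uses the
#' same machinery with depth thresholds scaled by `indel_depth_multiplier`
#' (indels are harder to call than SNVs).
#'
#' @param child_lr,parent_lr,pop_lr_max Likelihood-ratio thresholds (natural
#'   scale).
#' @param min_child_depth,min_parent_depth Minimum quality-read depths.
#' @param min_alt_fraction Minimum proband alternate-read fraction.
#' @param rank_sum_band,mq_band Inclusive Z-score bands for ReadPosRankSum /
#'   MQRankSum.
#' @param max_fs Exclusive upper bound on the Phred-scaled strand-bias score.
#' @param indel_depth_multiplier Depth-threshold multiplier for indel sites.
#' @param crit3_pass,crit7_pass Depth-independent pass probabilities of
#'   criteria 3 and 7 used in the callability model.
#' @return List of class `filter_thresholds`.
#' @export
filter_thresholds <- function(child_lr = 1e10, parent_lr = 200,
                              pop_lr_max = 1e4,
                              min_child_depth = 15, min_parent_depth = 8,
                              min_alt_fraction = 0.30,
                              rank_sum_band = c(-6, 6),
                              mq_band = c(-6, 6),
                              max_fs = 20,
                              indel_depth_multiplier = 4 / 3,
                              crit3_pass = 1, crit7_pass = 1) {
  structure(as.list(environment()), class = "filter_thresholds")
}

# Scaled thresholds used for indel sites.
indel_thresholds <- function(th) {
  th$min_child_depth <- ceiling(th$min_child_depth * th$indel_depth_multiplier)
  th$min_parent_depth <- ceiling(th$min_parent_depth * th$indel_depth_multiplier)
  th
}

# Vectorised filter over an observation frame; returns 0 for accept or the
# index of the first violated criterion (evaluated in order 1..7).
first_failed_criterion <- function(obs, th = filter_thresholds()) {
  need <- c("gl_ar_child", "gl_rr_child", "gl_rr_father", "gl_ar_father",
            "gl_rr_mother", "gl_ar_mother")
  if (any(vapply(obs[need], function(x) any(!is.finite(x)), logical(1))))
    stop("missing or non-finite genotype likelihoods")
  alt_child <- obs$alt_fwd_child + obs$alt_rev_child
  crit <- cbind(
    obs$gl_ar_child - obs$gl_rr_child > log10(th$child_lr),
    (obs$gl_rr_father - obs$gl_ar_father > log10(th$parent_lr)) &
      (obs$gl_rr_mother - obs$gl_ar_mother > log10(th$parent_lr)),
    obs$pop_lr <= th$pop_lr_max,
    obs$dp_child >= th$min_child_depth &
      obs$dp_father >= th$min_parent_depth &
      obs$dp_mother >= th$min_parent_depth,
    alt_child >= th$min_alt_fraction * obs$dp_child & obs$dp_child > 0,
    obs$alt_fwd_child >= 1 & obs$alt_rev_child >= 1,
    obs$read_pos_rank_sum >= th$rank_sum_band[1] &
      obs$read_pos_rank_sum <= th$rank_sum_band[2] &
      obs$mq_rank_sum >= th$mq_band[1] &
      obs$mq_rank_sum <= th$mq_band[2] &
      obs$fs < th$max_fs)
  first_fail <- apply(!crit, 1, function(x) if (any(x)) which(x)[1] else 0L)
  as.integer(first_fail)
}

#' Apply the seven de novo calling criteria to one trio site
#'
#' @param obs List with per-member sublists `proband`, `father`, `mother`,
#'   each holding `quality_read_count`, `alt_fwd`, `alt_rev` and log10
#'   genotype likelihoods `gl_rr`, `gl_ar`, `gl_aa`.
#' @param metrics List with `read_pos_rank_sum`, `mq_rank_sum`, `fs`.
#' @param pop Numeric vector of per-outside-individual carrier likelihood
#'   ratios, i.e. max of lik(AR)/lik(RR) and lik(AA)/lik(RR) (natural scale);
#'   may be empty.
#' @param thresholds A [filter_thresholds()].
#' @return List with `accept` (logical) and `first_failed` (`NA` or
#'   `"criterion_k"`).
#' @examples
#' obs <- list(proband = list(quality_read_count = 20, alt_fwd = 5,
#'                            alt_rev = 4, gl_rr = -20, gl_ar = -6, gl_aa = -9),
#'             father = list(quality_read_count = 30, alt_fwd = 0, alt_rev = 0,
#'                           gl_rr = -0.1, gl_ar = -9, gl_aa = -70),
#'             mother = list(quality_read_count = 30, alt_fwd = 0, alt_rev = 0,
#'                           gl_rr = -0.1, gl_ar = -9, gl_aa = -70))
#' passes_filters(obs, list(read_pos_rank_sum = 0, mq_rank_sum = 0, fs = 5),
#'                pop = numeric(0))
#' @export
passes_filters <- function(obs, metrics, pop = numeric(0),
                           thresholds = filter_thresholds()) {
  row <- data.frame(
    dp_child = obs$proband$quality_read_count,
    alt_fwd_child = obs$proband$alt_fwd, alt_rev_child = obs$proband$alt_rev,
    gl_rr_child = obs$proband$gl_rr, gl_ar_child = obs$proband$gl_ar,
    gl_aa_child = obs$proband$gl_aa,
    dp_father = obs$father$quality_read_count,
    gl_rr_father = obs$father$gl_rr, gl_ar_father = obs$father$gl_ar,
    dp_mother = obs$mother$quality_read_count,
    gl_rr_mother = obs$mother$gl_rr, gl_ar_mother = obs$mother$gl_ar,
    pop_lr = if (length(pop)) max(pop) else 0,
    read_pos_rank_sum = metrics$read_pos_rank_sum,
    mq_rank_sum = metrics$mq_rank_sum, fs = metrics$fs)
  ff <- first_failed_criterion(row, thresholds)
  list(accept = ff == 0L,
       first_failed = if (ff == 0L) NA_character_ else paste0("criterion_", ff))
}

# P(depth-dependent child criteria pass | true het) for one child depth:
# alt reads ~ Binomial(d, 1/2) split uniformly over strands; criteria 1
# (likelihood ratio), 5 (alt fraction) and 6 (both strands).
child_pass_prob <- function(d, eps, th) {
  if (d < th$min_child_depth) return(0)
  a <- 0:d
  lr_ok <- d * log10(0.5) - (a * log10(eps) + (d - a) * log10(1 - eps)) >
    log10(th$child_lr)
  frac_ok <- a >= th$min_alt_fraction * d
  both_strands <- ifelse(a >= 1, 1 - 2 * 0.5^a, 0)
  sum(stats::dbinom(a, d, 0.5) * lr_ok * frac_ok * both_strands)
}

# P(parent criterion 2 passes | parent truly homozygous reference):
# alt reads ~ Binomial(d, eps).
parent_pass_prob <- function(d, eps, th) {
  if (d < th$min_parent_depth) return(0)
  a <- 0:d
  ok <- a * log10(eps) + (d - a) * log10(1 - eps) - d * log10(0.5) >
    log10(th$parent_lr)
  sum(stats::dbinom(a, d, eps) * ok)
}

#' Probabilistic callability of a site in one family
#'
#' The probability that a true de novo mutation at a site would pass the
#' depth-dependent calling criteria (1, 2, 4, 5, 6), conditional on the
#' quality-read depths of the three family members, under a binomial read
#' model: the proband's alternate reads are Binomial(depth, 1/2) and split
#' uniformly across strands, parental alternate reads are
#' Binomial(depth, `eps`), and genotype likelihoods follow the same model.
#' Criteria 3 and 7 enter as depth-independent pass probabilities
#' (`crit3_pass`, `crit7_pass` in the thresholds; both default 1). The genome
#' sum of these probabilities is the effective number of callable sites — the
#' denominator of the rate estimates.
#'
#' @param d_child,d_father,d_mother Quality-read depths (vectorised).
#' @param eps Per-read base error rate in (0, 0.5).
#' @param thresholds A [filter_thresholds()].
#' @return Callability values in `[0, 1]`, non-decreasing in each depth.
#' @examples
#' site_callability(40, 30, 30)
#' site_callability(0, 30, 30)   # criterion 4 can never pass
#' @export
site_callability <- function(d_child, d_father, d_mother, eps = 0.005,
                             thresholds = filter_thresholds()) {
  if (eps <= 0 || eps >= 0.5) stop("eps must lie in (0, 0.5)")
  stopifnot(all(d_child >= 0), all(d_father >= 0), all(d_mother >= 0))
  th <- thresholds
  cp <- vapply(unique(d_child), child_pass_prob, numeric(1), eps = eps, th = th)
  names(cp) <- unique(d_child)
  pp_depths <- unique(c(d_father, d_mother))
  pp <- vapply(pp_depths, parent_pass_prob, numeric(1), eps = eps, th = th)
  names(pp) <- pp_depths
  unname(cp[as.character(d_child)] * pp[as.character(d_father)] *
           pp[as.character(d_mother)] * th$crit3_pass * th$crit7_pass)
}

# Expected callability when member depths are Poisson around bin means;
# factorises over the three members.
expected_callability_poisson <- function(mu_child, mu_father, mu_mother,
                                         eps, th, dmax) {
  d <- 0:dmax
  cp <- vapply(d, child_pass_prob, numeric(1), eps = eps, th = th)
  pp <- vapply(d, parent_pass_prob, numeric(1), eps = eps, th = th)
  ec <- vapply(mu_child, function(m) sum(stats::dpois(d, m) * cp), numeric(1))
  ef <- vapply(mu_father, function(m) sum(stats::dpois(d, m) * pp), numeric(1))
  em <- vapply(mu_mother, function(m) sum(stats::dpois(d, m) * pp), numeric(1))
  ec * ef * em * th$crit3_pass * th$crit7_pass
}

# Per-bin context-class position counts for a genome.
context_bin_counts <- function(genome, bin_bp) {
  do.call(rbind, lapply(genome$chrom_names, function(ch) {
    cls <- context_classes(genome, ch)
    L <- genome$chrom_lengths[[ch]]
    idx <- ((seq_len(L) - 1L) %/% bin_bp) + 1L
    nb <- max(idx)
    tab <- function(which_cls) {
      v <- tabulate(idx[!is.na(cls) & cls == which_cls], nbins = nb)
      v
    }
    s <- (seq_len(nb) - 1L) * bin_bp
    data.frame(chrom = ch, start = s, end = pmin(s + bin_bp, L),
               n_CpG = tab("CpG"), n_strong = tab("strong"),
               n_weak = tab("weak"), stringsAsFactors = FALSE)
  }))
}

#' Call de novo mutations and compute family callability for a whole cohort
#'
#' Applies the seven calling criteria to every candidate site of every trio
#' (SNVs with the default thresholds, indels with depth thresholds scaled by
#' `indel_depth_multiplier`), and computes each family's effective number of
#' callable sites by summing the expected site callability over the genome,
#' using the family's binned depth profile (depths Poisson around the bin
#' mean). Context-stratified callable sums (CpG / non-CpG strong / weak) use
#' the reference sequence's per-bin context composition.
#'
#' @param cohort A `trio_cohort` from [simulate_cohort()], or a directory
#'   written by [write_cohort()].
#' @param thresholds A [filter_thresholds()].
#' @param eps Base error rate; defaults to the cohort's configured rate.
#' @return List with `calls` (data.frame of accepted sites, including
#'   `individual_id`, `context_class` and `concat_pos`) and `callability`
#'   (data.frame per family: `snv_callable_sum`, `indel_callable_sum`,
#'   `CpG`, `strong`, `weak`).
#' @export
cohort_call_and_callability <- function(cohort,
                                        thresholds = filter_thresholds(),
                                        eps = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (is.null(eps)) eps <- cohort$config$base_error_rate
  obs <- cohort$observations
  genome <- cohort$genome
  if (!all(cohort$families$family_id %in% cohort$depth_profile$family_id))
    stop("pedigree and depth profile disagree on family ids")

  is_snv <- obs$kind == "SNV"
  ff <- integer(nrow(obs))
  ff[is_snv] <- first_failed_criterion(obs[is_snv, , drop = FALSE], thresholds)
  if (any(!is_snv))
    ff[!is_snv] <- first_failed_criterion(obs[!is_snv, , drop = FALSE],
                                          indel_thresholds(thresholds))
  calls <- obs[ff == 0L, c("family_id", "chrom", "pos", "ref", "alt", "kind"),
               drop = FALSE]
  names(calls)[1] <- "individual_id"
  calls$context_class <- rep(NA_character_, nrow(calls))
  if (nrow(calls)) {
    snv <- calls$kind == "SNV"
    calls$context_class[snv] <- site_context(genome, calls$chrom[snv],
                                             calls$pos[snv])
  }
  calls$concat_pos <- concat_positions(calls$chrom, calls$pos,
                                       genome$chrom_lengths)
  calls <- calls[order(calls$concat_pos), ]
  rownames(calls) <- NULL

  th_ind <- indel_thresholds(thresholds)
  dmax <- max(stats::qpois(1 - 1e-9, max(cohort$depth_profile$dp_child,
                                         cohort$depth_profile$dp_father,
                                         cohort$depth_profile$dp_mother)), 30)
  ctx_bins <- context_bin_counts(genome, diff(
    c(cohort$depth_profile$start[1], cohort$depth_profile$end[1])))
  prof <- cohort$depth_profile
  fams <- unique(prof$family_id)
  callab <- do.call(rbind, lapply(fams, function(fam) {
    p <- prof[prof$family_id == fam, ]
    p <- p[order(match(p$chrom, genome$chrom_names), p$start), ]
    stopifnot(nrow(p) == nrow(ctx_bins))
    w <- p$end - p$start
    c_snv <- expected_callability_poisson(p$dp_child, p$dp_father,
                                          p$dp_mother, eps, thresholds, dmax)
    c_ind <- expected_callability_poisson(p$dp_child, p$dp_father,
                                          p$dp_mother, eps, th_ind, dmax)
    data.frame(family_id = fam,
               snv_callable_sum = sum(w * c_snv),
               indel_callable_sum = sum(w * c_ind),
               CpG = sum(ctx_bins$n_CpG * c_snv),
               strong = sum(ctx_bins$n_strong * c_snv),
               weak = sum(ctx_bins$n_weak * c_snv),
               stringsAsFactors = FALSE)
  }))
  rownames(callab) <- NULL
  list(calls = calls, callability = callab)
}
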