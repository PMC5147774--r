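#' Genotype log10-likelihoods under a binomial read model
#'
#' For a diploid site with `a` alternate reads out of `d` quality reads and a
#' per-read miscall probability `eps`, the (unnormalised) genotype
#' likelihoods are `lik(RR) = eps^a (1-eps)^(d-a)`, `lik(AR) = 0.5^d` and
#' `lik(AA) = (1-eps)^a eps^(d-a)`; the binomial coefficient cancels in every
#' ratio the calling filters use.
#'
#' @param a Alternate-read counts.
#' @param d Quality-read depths.
#' @param eps Base error rate in (0, 0.5).
#' @return Matrix with columns `gl_rr`, `gl_ar`, `gl_aa` (log10 scale).
#' @export
genotype_log10_lik <- function(a, d, eps) {
  stopifnot(eps > 0, eps < 0.5, all(a >= 0), all(a <= d))
  cbind(gl_rr = a * log10(eps) + (d - a) * log10(1 - eps),
        gl_ar = d * log10(0.5),
        gl_aa = a * log10(1 - eps) + (d - a) * log10(eps))
}

#' Per-family binned depth profile
#'
#' Sequencing depth varies smoothly along the genome; the generator models it
#' as piecewise-constant mean depth over `depth_bin_bp` bins, drawn
#' log-normally around `depth_mean` independently per family member. The
#' profile drives both the read depths of simulated observations and the
#' genome-wide callability sums.
#'
#' @param genome A `genome_model`.
#' @param families data.frame from [generate_families()].
#' @param config A [cohort_config()].
#' @return data.frame: `family_id`, `chrom`, `start` (0-based), `end`,
#'   `dp_child`, `dp_father`, `dp_mother` (mean depths).
#' @export
generate_depth_profile <- function(genome, families, config) {
  set.seed(config$seed + 3L)
  bins <- do.call(rbind, lapply(genome$chrom_names, function(ch) {
    L <- genome$chrom_lengths[[ch]]
    s <- seq(0, L - 1, by = config$depth_bin_bp)
    data.frame(chrom = ch, start = s, end = pmin(s + config$depth_bin_bp, L))
  }))
  sdlog <- 0.15
  out <- do.call(rbind, lapply(families$family_id, function(fam) {
    n <- nrow(bins)
    data.frame(family_id = fam, bins,
               dp_child = config$depth_mean * stats::rlnorm(n, -sdlog^2 / 2, sdlog),
               dp_father = config$depth_mean * stats::rlnorm(n, -sdlog^2 / 2, sdlog),
               dp_mother = config$depth_mean * stats::rlnorm(n, -sdlog^2 / 2, sdlog),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Mean depth of a member at given sites, looked up from the binned profile.
profile_depth_at <- function(profile, fam, chrom, pos, member) {
  col <- paste0("dp_", member)
  sub <- profile[profile$family_id == fam, ]
  key_sub <- paste(sub$chrom, sub$start %/% (sub$end - sub$start)[1])
  width <- (sub$end - sub$start)[1]
  key <- paste(chrom, (pos - 1) %/% width)
  sub[[col]][match(key, key_sub)]
}

#' Simulate per-trio site observations
#'
#' Emits one row per candidate site per trio: the family's truth mutations
#' plus `n_background_sites` non-mutated sites (a configurable fraction of
#' which carry an inherited population variant). Depths are Poisson around
#' the family's binned depth profile; at a true de novo site the proband's
#' alternate reads are Binomial(depth, 1/2) and parental alternate reads
#' arise only from base error; strand assignment of alternate reads is
#' uniform. Genotype likelihoods come from [genotype_log10_lik()]; GATK-style
#' site metrics (rank sums, strand-bias FS) and the population likelihood
#' ratio are drawn from null distributions under which true de novo sites
#' rarely fail the corresponding filters.
#'
#' @param mutations Truth mutations from [generate_mutations()].
#' @param families data.frame from [generate_families()].
#' @param config A [cohort_config()].
#' @param genome A `genome_model`.
#' @param depth_profile Optional profile from [generate_depth_profile()];
#'   generated on the fly when missing.
#' @return data.frame of site observations with truth label `is_denovo`.
#' @export
simulate_observations <- function(mutations, families, config, genome,
                                  depth_profile = NULL) {
  if (is.null(depth_profile))
    depth_profile <- generate_depth_profile(genome, families, config)
  set.seed(config$seed + 4L)
  eps <- config$base_error_rate
  res <- lapply(seq_len(nrow(families)), function(i) {
    fam <- families$family_id[i]
    mut <- mutations[mutations$family_id == fam, , drop = FALSE]
    nb <- config$n_background_sites
    bg_ch <- sample(genome$chrom_names, nb, replace = TRUE,
                    prob = genome$chrom_lengths)
    bg_pos <- vapply(bg_ch, function(ch)
      sample.int(genome$chrom_lengths[[ch]], 1L), integer(1))
    bg_ref <- mapply(function(c, p) ref_base(genome, c, p), bg_ch, bg_pos,
                     USE.NAMES = FALSE)
    bg_alt <- draw_alt(bg_ref, stats::runif(nb) < 0.6)
    sites <- data.frame(
      family_id = fam,
      chrom = c(mut$chrom, bg_ch),
      pos = c(mut$pos, bg_pos),
      ref = c(mut$ref, bg_ref),
      alt = c(mut$alt, bg_alt),
      kind = c(mut$kind, rep("SNV", nb)),
      is_denovo = c(rep(TRUE, nrow(mut)), rep(FALSE, nb)),
      stringsAsFactors = FALSE)
    n <- nrow(sites)
    polymorphic <- !sites$is_denovo &
      stats::runif(n) < config$background_polymorphic_fraction

    obs <- list()
    for (member in c("child", "father", "mother")) {
      mu <- profile_depth_at(depth_profile, fam, sites$chrom, sites$pos, member)
      d <- stats::rpois(n, mu)
      p_alt <- rep(eps, n)
      if (member == "child") {
        p_alt[sites$is_denovo | polymorphic] <- 0.5
      } else if (member == "father") {
        p_alt[polymorphic] <- 0.5   # inherited variants carried by the father
      }
      a <- stats::rbinom(n, d, p_alt)
      fwd <- stats::rbinom(n, a, 0.5)
      gl <- genotype_log10_lik(a, d, eps)
      obs[[member]] <- data.frame(dp = d, alt_fwd = fwd, alt_rev = a - fwd, gl)
      names(obs[[member]]) <- paste0(names(obs[[member]]), "_", member)
    }
    metrics <- data.frame(
      read_pos_rank_sum = stats::rnorm(n),
      mq_rank_sum = stats::rnorm(n),
      fs = stats::rexp(n, rate = 1 / 3),
      pop_lr = 10^stats::rnorm(n, ifelse(polymorphic, 8, 0), 1))
    cbind(sites, obs$child, obs$father, obs$mother, metrics)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
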