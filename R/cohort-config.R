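#' Configuration for the synthetic trio cohort generator
#'
#' Bundles every tunable parameter of the synthetic cohort. Defaults emulate
#' the statistical structure of a large population trio study: 283
#' trios averaging ~63 de novo SNVs and ~4.5 indels per proband, a paternal
#' age effect of 1.7 SNVs per year and a maternal effect of 0.34 SNVs per
#' year, a CpG/strong/weak transition-transversion spectrum, and a
#' multi-nucleotide-mutation (MNM) process placing ~3% of SNVs within 20 kb
#' of another mutation in the same individual.
#'
#' The default genome is desk-scale (50 Mb over two chromosomes) rather than
#' genome-scale; per-family mutation counts are governed by the age model,
#' not by genome length, so rate numerators match the emulated study while
#' denominators scale with `genome_length`.
#'
#' @param n_families Number of trios (default 283).
#' @param genome_length Total synthetic genome length in bp.
#' @param n_chromosomes Number of chromosomes the length is split over.
#' @param gc Genome GC fraction.
#' @param paternal_slope,maternal_slope Additional SNVs per year of paternal /
#'   maternal age at conception.
#' @param mean_snv Expected SNVs per proband at the mean parental ages.
#' @param mean_father_age,mean_mother_age Mean parental ages at conception
#'   (years).
#' @param sd_father_age,sd_mother_age Age standard deviations (years).
#' @param age_r2 Squared correlation between paternal and maternal ages.
#' @param min_age Lower truncation for ages (years).
#' @param mean_indel Expected indels per proband at the mean ages.
#' @param indel_paternal_slope,indel_maternal_slope Indel age effects per year.
#' @param deletion_insertion_ratio Expected deletions per insertion.
#' @param max_deletion_bp,max_insertion_bp Length caps for simulated indels.
#' @param spectrum Named numeric vector of SNV class weights over the six
#'   context-by-change classes (`CpG_ts`, `CpG_tv`, `strong_ts`, `strong_tv`,
#'   `weak_ts`, `weak_tv`). Defaults are proportional to the emulated study's
#'   observed class counts.
#' @param mnm_fraction Fraction of SNVs generated as part of multi-mutation
#'   (MNM) events.
#' @param mnm_distance_mixture List with weights `tandem`, `short`, `long` and
#'   ranges `short_range`, `long_range` for intra-event distances (bp):
#'   tandem = distance 1, short/long = log-uniform over the given range.
#' @param mnm_size_prob Success probability of the truncated geometric
#'   (support 2..8) for mutations per MNM event.
#' @param tandem_ca_boost Multiplier applied to the C>A class weight for
#'   tandem event pairs (polymerase-zeta-like tandem spectra; 1 disables).
#' @param depth_mean Mean sequencing depth (reads) per member.
#' @param depth_bin_bp Width of the constant-depth bins of the per-family
#'   depth profile.
#' @param base_error_rate Per-read base miscall probability.
#' @param n_background_sites Non-mutated candidate sites emitted per family by
#'   [simulate_observations()].
#' @param background_polymorphic_fraction Fraction of background sites that
#'   carry an inherited (population) variant rather than pure reference.
#' @param n_replication_tracks Number of replication-timing signal tracks.
#' @param replication_bin_bp Bin width of the replication signal.
#' @param crossovers_per_parent Mean number of crossover bins per parent.
#' @param crossover_bin_mean_bp Mean crossover bin length (bp; default 201 kb).
#' @param seed Integer seed; a fixed seed makes the whole cohort
#'   byte-reproducible.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @examples
#' cfg <- cohort_config(n_families = 20, genome_length = 2e6, seed = 1)
#' cfg$mean_snv
#' @export
cohort_config <- function(n_families = 283,
                          genome_length = 50e6,
                          n_chromosomes = 2,
                          gc = 0.41,
                          paternal_slope = 1.7,
                          maternal_slope = 0.34,
                          mean_snv = 62.9,
                          mean_father_age = 31.6,
                          mean_mother_age = 28.9,
                          sd_father_age = 5.5,
                          sd_mother_age = 5.0,
                          age_r2 = 0.65,
                          min_age = 15,
                          mean_indel = 4.53,
                          indel_paternal_slope = 0.1,
                          indel_maternal_slope = 0.01,
                          deletion_insertion_ratio = 2.6,
                          max_deletion_bp = 35,
                          max_insertion_bp = 8,
                          spectrum = c(CpG_ts = 2984, CpG_tv = 281,
                                       strong_ts = 4264, strong_tv = 3019,
                                       weak_ts = 4758, weak_tv = 2506),
                          mnm_fraction = 0.031,
                          mnm_distance_mixture = list(
                            tandem = 0.19, short = 0.37, long = 0.44,
                            short_range = c(2, 2000),
                            long_range = c(2000, 20000)),
                          mnm_size_prob = 0.6,
                          tandem_ca_boost = 3,
                          depth_mean = 35,
                          depth_bin_bp = 1e5,
                          base_error_rate = 0.005,
                          n_background_sites = 50,
                          background_polymorphic_fraction = 0.5,
                          n_replication_tracks = 5,
                          replication_bin_bp = 1e4,
                          crossovers_per_parent = 30,
                          crossover_bin_mean_bp = 201e3,
                          seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    n_families >= 1,
    genome_length >= 1000,
    n_chromosomes >= 1,
    gc > 0, gc < 1,
    paternal_slope >= 0, maternal_slope >= 0,
    mean_snv > 0, mean_indel > 0,
    mean_father_age > 0, mean_mother_age > 0,
    sd_father_age > 0, sd_mother_age > 0,
    age_r2 >= 0, age_r2 < 1,
    deletion_insertion_ratio > 0,
    all(spectrum >= 0), sum(spectrum) > 0,
    mnm_fraction >= 0, mnm_fraction <= 1,
    mnm_size_prob > 0, mnm_size_prob <= 1,
    depth_mean > 0,
    base_error_rate > 0, base_error_rate < 0.5,
    crossover_bin_mean_bp > 0
  )
  if (mean_father_age <= 0 || mean_mother_age <= 0)
    stop("parental age parameters must be positive")
  need <- c("CpG_ts", "CpG_tv", "strong_ts", "strong_tv", "weak_ts", "weak_tv")
  if (!all(need %in% names(cfg$spectrum)))
    stop("spectrum must name all six classes: ", paste(need, collapse = ", "))
  cfg$spectrum <- cfg$spectrum[need] / sum(cfg$spectrum[need])
  w <- cfg$mnm_distance_mixture
  stopifnot(w$tandem >= 0, w$short >= 0, w$long >= 0)
  tot <- w$tandem + w$short + w$long
  cfg$mnm_distance_mixture[c("tandem", "short", "long")] <-
    list(w$tandem / tot, w$short / tot, w$long / tot)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic trio cohort configuration\n")
  cat(sprintf("  %d families, %.1f Mb genome over %d chromosome(s)\n",
              x$n_families, x$genome_length / 1e6, x$n_chromosomes))
  cat(sprintf("  SNVs/proband at mean ages: %.1f (paternal %.2f/yr, maternal %.2f/yr)\n",
              x$mean_snv, x$paternal_slope, x$maternal_slope))
  cat(sprintf("  indels/proband: %.2f (del:ins %.1f), MNM fraction %.3f\n",
              x$mean_indel, x$deletion_insertion_ratio, x$mnm_fraction))
  cat(sprintf("  depth %.0fx, base error %.4f, seed %d\n",
              x$depth_mean, x$base_error_rate, x$seed))
  invisible(x)
}

# Intercept of the Poisson age model so that the expectation at the
# configured mean ages equals the configured cohort mean.
age_model_intercept <- function(mean_count, pat_slope, mat_slope,
                                mean_father_age, mean_mother_age) {
  mean_count - pat_slope * mean_father_age - mat_slope * mean_mother_age
}
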