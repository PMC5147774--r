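# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# Small end-to-end cohort: 30 trios on 4 Mb; enough mutations (~2000) for
# pipeline-level checks while keeping the run fast.
small_cohort <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- cohort_config(n_families = 30, genome_length = 4e6,
                         n_chromosomes = 2, n_background_sites = 20,
                         depth_bin_bp = 5e4, replication_bin_bp = 5e3,
                         crossovers_per_parent = 6,
                         crossover_bin_mean_bp = 3e4, seed = 42)
    .fixtures$small <- simulate_cohort(cfg)
  }
  .fixtures$small
}

small_callresult <- function() {
  if (is.null(.fixtures$small_call))
    .fixtures$small_call <- cohort_call_and_callability(small_cohort())
  .fixtures$small_call
}

# Truth-mutation record frame with concatenated positions, for clustering
# and spectra tests that work on the truth set directly.
truth_records <- function(cohort) {
  m <- cohort$mutations
  m$individual_id <- m$family_id
  m$concat_pos <- concat_positions(m$chrom, m$pos,
                                   cohort$genome$chrom_lengths)
  m[order(m$concat_pos), ]
}

# Rand index between two partitions given as label vectors (singletons get
# unique labels beforehand).
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  up <- upper.tri(same_a)
  mean(same_a[up] == same_b[up])
}

# Construct a mutation record frame from bare positions (single chromosome).
records_from_positions <- function(pos, individual,
                                   kind = rep("SNV", length(pos)),
                                   chrom = "chr1") {
  df <- data.frame(individual_id = individual, chrom = chrom, pos = pos,
                   kind = kind, concat_pos = pos, stringsAsFactors = FALSE)
  df[order(df$concat_pos), ]
}
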