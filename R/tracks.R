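#' Generate synthetic covariate tracks
#'
#' Produces (i) `n_replication_tracks` smooth replication-timing signals,
#' binned at `replication_bin_bp`, emulating wavelet-smoothed timing profiles
#' of several individuals (high signal = early replication, low = late), and
#' (ii) per-family, per-parent crossover bins with exponentially distributed
#' lengths around `crossover_bin_mean_bp` (the interval between flanking
#' heterozygous markers to which a meiotic crossover can be mapped).
#'
#' Each replication signal is a sum of low-frequency sinusoids (a shared
#' biology component plus a small per-individual perturbation), so the
#' per-bin increment is bounded by an analytic slope cap stored in
#' `attr(replication, "slope_cap")`.
#'
#' @param genome A `genome_model`.
#' @param families data.frame from [generate_families()].
#' @param config A [cohort_config()].
#' @return List of class `covariate_tracks` with elements `replication`
#'   (data.frame `chrom`, `start` 0-based, `end`, `track1..trackK`) and
#'   `crossovers` (data.frame `family_id`, `parent`, `chrom`, `start`
#'   0-based, `end`).
#' @export
generate_tracks <- function(genome, families, config) {
  set.seed(config$seed + 5L)
  K <- config$n_replication_tracks
  bw <- config$replication_bin_bp

  rep_list <- lapply(genome$chrom_names, function(ch) {
    L <- genome$chrom_lengths[[ch]]
    s <- seq(0, L - 1, by = bw)
    nb <- length(s)
    x <- seq_len(nb)
    n_harm <- 6
    freqs <- seq_len(n_harm) * 1.5 / nb
    shared_amp <- stats::runif(n_harm, 5, 15) / seq_len(n_harm)
    shared_phase <- stats::runif(n_harm, 0, 2 * pi)
    shared <- rowSums(sapply(seq_len(n_harm), function(k)
      shared_amp[k] * sin(2 * pi * freqs[k] * x + shared_phase[k])))
    tracks <- sapply(seq_len(K), function(t) {
      amp <- stats::runif(n_harm, 0.5, 1.5) / seq_len(n_harm)
      phase <- stats::runif(n_harm, 0, 2 * pi)
      pert <- rowSums(sapply(seq_len(n_harm), function(k)
        amp[k] * sin(2 * pi * freqs[k] * x + phase[k])))
      50 + shared + pert
    })
    colnames(tracks) <- paste0("track", seq_len(K))
    cap <- sum((shared_amp + 1.5 / seq_len(n_harm)) * 2 * pi * freqs)
    df <- data.frame(chrom = ch, start = s, end = pmin(s + bw, L),
                     stringsAsFactors = FALSE)
    list(df = cbind(df, tracks), cap = cap)
  })
  replication <- do.call(rbind, lapply(rep_list, `[[`, "df"))
  rownames(replication) <- NULL
  attr(replication, "slope_cap") <- max(vapply(rep_list, `[[`, numeric(1),
                                               "cap"))

  xo <- do.call(rbind, lapply(families$family_id, function(fam) {
    do.call(rbind, lapply(c("father", "mother"), function(par) {
      n <- stats::rpois(1, config$crossovers_per_parent)
      if (n == 0) return(NULL)
      ch <- sample(genome$chrom_names, n, replace = TRUE,
                   prob = genome$chrom_lengths)
      len <- pmax(round(stats::rexp(n, 1 / config$crossover_bin_mean_bp)), 1e3)
      start <- end <- numeric(n)
      for (j in seq_len(n)) {
        L <- genome$chrom_lengths[[ch[j]]]
        len[j] <- min(len[j], L - 1)
        start[j] <- sample.int(L - len[j], 1L) - 1L   # 0-based
        end[j] <- start[j] + len[j]
      }
      data.frame(family_id = fam, parent = par, chrom = ch,
                 start = start, end = end, stringsAsFactors = FALSE)
    }))
  }))
  rownames(xo) <- NULL
  structure(list(replication = replication, crossovers = xo,
                 bin_bp = bw), class = "covariate_tracks")
}
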