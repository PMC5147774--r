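#' Generate truth de novo mutations for a synthetic cohort
#'
#' Per-family SNV and indel counts are Poisson around an age-linear mean
#' (`intercept + paternal_slope * father_age + maternal_slope * mother_age`,
#' with the intercept solved so that the expectation at the configured mean
#' ages equals `mean_snv` / `mean_indel`). A configurable fraction of SNVs
#' (`mnm_fraction`) is laid down as multi-nucleotide mutation (MNM) events:
#' groups of 2-8 mutations whose consecutive gaps are drawn from a
#' tandem / short / long distance mixture capped at 20 kb. Independent SNVs
#' are placed by sampling a context-by-change class from the configured
#' spectrum and then a uniform position of that context class; clustered
#' mutations inherit whatever reference base their position carries. Indels
#' are deletions with odds `deletion_insertion_ratio`, with geometric lengths
#' capped at `max_deletion_bp` / `max_insertion_bp`.
#'
#' @param genome A `genome_model` from [generate_genome()].
#' @param families data.frame from [generate_families()].
#' @param config The [cohort_config()] used to generate both.
#' @return data.frame of truth mutations: `family_id`, `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `kind` (`SNV`/`insertion`/`deletion`),
#'   `cluster_id` (NA for independent mutations), `parent_of_origin`,
#'   `context_class` (SNVs only).
#' @export
generate_mutations <- function(genome, families, config) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "cohort_config"))
  set.seed(config$seed + 2L)
  cls_pos <- class_positions(genome)
  class_counts <- sapply(genome$chrom_names, function(ch)
    sapply(cls_pos[[ch]], length))  # 3 x nchrom matrix (CpG, strong, weak)
  if (any(rowSums(as.matrix(class_counts)) == 0))
    stop("genome too small: a context class has no positions")

  icept_snv <- age_model_intercept(config$mean_snv, config$paternal_slope,
                                   config$maternal_slope,
                                   config$mean_father_age,
                                   config$mean_mother_age)
  icept_ind <- age_model_intercept(config$mean_indel,
                                   config$indel_paternal_slope,
                                   config$indel_maternal_slope,
                                   config$mean_father_age,
                                   config$mean_mother_age)

  spec <- config$spectrum
  class3 <- c(CpG_ts = "CpG", CpG_tv = "CpG", strong_ts = "strong",
              strong_tv = "strong", weak_ts = "weak", weak_tv = "weak")
  ts_flag <- grepl("_ts$", names(spec))

  out <- vector("list", nrow(families) * 2L)
  k <- 0L
  for (i in seq_len(nrow(families))) {
    fam <- families$family_id[i]
    lam_snv <- max(icept_snv + config$paternal_slope * families$father_age[i] +
                     config$maternal_slope * families$mother_age[i], 0.1)
    n_snv <- stats::rpois(1, lam_snv)
    n_clustered_target <- stats::rbinom(1, n_snv, config$mnm_fraction)
    snvs <- place_family_snvs(genome, cls_pos, class_counts, spec, class3,
                              ts_flag, n_snv, n_clustered_target, config, fam)
    lam_ind <- max(icept_ind +
                     config$indel_paternal_slope * families$father_age[i] +
                     config$indel_maternal_slope * families$mother_age[i], 0.05)
    indels <- place_family_indels(genome, stats::rpois(1, lam_ind), config, fam)
    k <- k + 1L; out[[k]] <- snvs
    k <- k + 1L; out[[k]] <- indels
  }
  muts <- do.call(rbind, out[seq_len(k)])
  # drop the (rare) duplicate site within a family
  muts <- muts[!duplicated(muts[, c("family_id", "chrom", "pos")]), ]
  muts <- muts[order(muts$family_id, match(muts$chrom, genome$chrom_names),
                     muts$pos), ]
  rownames(muts) <- NULL
  muts
}

# Place one family's SNVs: independent draws by spectrum class plus
# MNM events with mixture-distributed gaps.
place_family_snvs <- function(genome, cls_pos, class_counts, spec, class3,
                              ts_flag, n_snv, n_clustered_target, config, fam) {
  n_indep <- n_snv - n_clustered_target
  rows <- list()

  if (n_indep > 0) {
    cls6 <- sample(names(spec), n_indep, replace = TRUE, prob = spec)
    ctx <- class3[cls6]
    chrom <- character(n_indep); pos <- integer(n_indep)
    for (cx in unique(ctx)) {
      idx <- which(ctx == cx)
      cnts <- class_counts[cx, , drop = TRUE]
      ch <- sample(genome$chrom_names, length(idx), replace = TRUE,
                   prob = cnts)
      chrom[idx] <- ch
      for (j in seq_along(idx)) {
        p <- cls_pos[[ch[j]]][[cx]]
        pos[idx[j]] <- p[sample.int(length(p), 1L)]
      }
    }
    rb <- mapply(function(c, p) ref_base(genome, c, p), chrom, pos,
                 USE.NAMES = FALSE)
    alt <- draw_alt(rb, ts_flag[match(cls6, names(spec))])
    rows$indep <- data.frame(family_id = fam, chrom = chrom, pos = pos,
                             ref = rb, alt = alt, kind = "SNV",
                             cluster_id = NA_character_,
                             stringsAsFactors = FALSE)
  }

  if (n_clustered_target >= 2) {
    sizes <- integer(0)
    while (sum(sizes) < n_clustered_target)
      sizes <- c(sizes, mnm_event_size(config$mnm_size_prob))
    ev <- lapply(seq_along(sizes), function(e) {
      place_mnm_event(genome, sizes[e], config,
                      sprintf("%s_M%03d", fam, e), fam)
    })
    rows$mnm <- do.call(rbind, ev)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(family_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      kind = character(), cluster_id = character(),
                      stringsAsFactors = FALSE)
  }
  if (nrow(res)) {
    res$parent_of_origin <- ifelse(stats::runif(nrow(res)) < 0.8,
                                   "father", "mother")
    res$context_class <- site_context(genome, res$chrom, res$pos)
  } else {
    res$parent_of_origin <- character(0)
    res$context_class <- character(0)
  }
  res
}

# Event size: geometric on {2,3,...} truncated at 8.
mnm_event_size <- function(p) {
  s <- 2L + stats::rgeom(1, p)
  while (s > 8L) s <- 2L + stats::rgeom(1, p)
  s
}

# Gap between consecutive mutations of one MNM event.
mnm_gap <- function(config) {
  m <- config$mnm_distance_mixture
  u <- stats::runif(1)
  if (u < m$tandem) return(1L)
  rng <- if (u < m$tandem + m$short) m$short_range else m$long_range
  as.integer(round(exp(stats::runif(1, log(rng[1]), log(rng[2])))))
}

place_mnm_event <- function(genome, size, config, cluster_id, fam) {
  gaps <- replicate(size - 1L, mnm_gap(config))
  span <- sum(gaps)
  ch <- sample(genome$chrom_names, 1L,
               prob = genome$chrom_lengths)
  L <- genome$chrom_lengths[[ch]]
  if (span + 2L >= L) stop("genome too small to place an MNM event")
  anchor <- sample.int(L - span - 1L, 1L)
  pos <- anchor + c(0L, cumsum(gaps))
  rb <- ref_base(genome, ch, pos)
  tandem <- size == 2L && gaps[1] == 1L
  alt <- vapply(rb, function(b) {
    if (tandem && b %in% c("C", "G") &&
        stats::runif(1) < ca_boost_prob(config)) {
      if (b == "C") "A" else "T"          # strand-collapsed C>A
    } else {
      draw_alt(b, stats::runif(1) < 0.6)  # ts:tv roughly 60:40 at non-class sites
    }
  }, character(1), USE.NAMES = FALSE)
  data.frame(family_id = fam, chrom = ch, pos = pos, ref = rb, alt = alt,
             kind = "SNV", cluster_id = cluster_id, stringsAsFactors = FALSE)
}

# Probability that a tandem-pair member at a C/G site is forced to C>A.
# Baseline C>A share among strong-site changes is ~1/2 of transversions;
# the boost multiplies it, capped at 0.9.
ca_boost_prob <- function(config) {
  min(0.2 * config$tandem_ca_boost, 0.9)
}

# Alternate allele given reference base and transition flag.
draw_alt <- function(ref, is_ts) {
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- list(A = c("C", "T"), G = c("C", "T"),
                 C = c("A", "G"), T = c("A", "G"))
  n <- length(ref)
  is_ts <- rep_len(is_ts, n)
  vapply(seq_len(n), function(i) {
    if (is_ts[i]) ts_map[[ref[i]]]
    else sample(tv_map[[ref[i]]], 1L)
  }, character(1))
}

place_family_indels <- function(genome, n_indel, config, fam) {
  if (n_indel == 0)
    return(data.frame(family_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      kind = character(), cluster_id = character(),
                      parent_of_origin = character(),
                      context_class = character(), stringsAsFactors = FALSE))
  p_del <- config$deletion_insertion_ratio /
    (1 + config$deletion_insertion_ratio)
  is_del <- stats::runif(n_indel) < p_del
  ch <- sample(genome$chrom_names, n_indel, replace = TRUE,
               prob = genome$chrom_lengths)
  ref <- alt <- character(n_indel)
  pos <- integer(n_indel)
  for (j in seq_len(n_indel)) {
    L <- genome$chrom_lengths[[ch[j]]]
    if (is_del[j]) {
      len <- min(1L + stats::rgeom(1, 0.45), config$max_deletion_bp)
      pos[j] <- sample.int(L - len - 1L, 1L)
      ref[j] <- ref_base(genome, ch[j], pos[j], width = len + 1L)
      alt[j] <- substr(ref[j], 1L, 1L)
    } else {
      len <- min(1L + stats::rgeom(1, 0.7), config$max_insertion_bp)
      pos[j] <- sample.int(L - 2L, 1L)
      anchor <- ref_base(genome, ch[j], pos[j])
      ref[j] <- anchor
      alt[j] <- paste0(anchor, paste(sample(c("A", "C", "G", "T"), len,
                                            replace = TRUE), collapse = ""))
    }
  }
  data.frame(family_id = fam, chrom = ch, pos = pos, ref = ref, alt = alt,
             kind = ifelse(is_del, "deletion", "insertion"),
             cluster_id = NA_character_,
             parent_of_origin = ifelse(stats::runif(n_indel) < 0.8,
                                       "father", "mother"),
             context_class = NA_character_, stringsAsFactors = FALSE)
}

#' Context class of arbitrary genome positions
#'
#' Vectorised over sites (possibly on different chromosomes): `CpG` for a C
#' followed by G or a G preceded by C, `strong` for other C/G, `weak` for
#' A/T, `NA` for N.
#'
#' @param genome A `genome_model`.
#' @param chrom,pos Site coordinates (1-based).
#' @return Character vector in `c("CpG","strong","weak")`.
#' @export
site_context <- function(genome, chrom, pos) {
  vapply(seq_along(pos), function(i) {
    b <- ref_base(genome, chrom[i], pos[i])
    if (b %in% c("A", "T")) return("weak")
    if (b == "N") return(NA_character_)
    nxt <- if (pos[i] < genome$chrom_lengths[[chrom[i]]])
      ref_base(genome, chrom[i], pos[i] + 1L) else ""
    prv <- if (pos[i] > 1L) ref_base(genome, chrom[i], pos[i] - 1L) else ""
    if ((b == "C" && nxt == "G") || (b == "G" && prv == "C")) "CpG" else "strong"
  }, character(1))
}
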