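#' Strand-collapsed classification of an SNV
#'
#' Collapses strands so that the reference base is always A or C (a G or T
#' reference is reverse-complemented together with its alternate allele and
#' flanks), yielding one of six change types (A>C, A>G, A>T, C>A, C>G, C>T),
#' the transition/transversion flag, the context class (CpG / non-CpG
#' strong / weak) and the collapsed-strand triplet (5' base, site, 3' base).
#'
#' @param ref,alt Single reference/alternate bases.
#' @param left,right 5' and 3' flanking bases on the plus strand.
#' @return List: `change` (e.g. `"C>T"`), `transition` (logical),
#'   `context_class`, `triplet` (e.g. `"TCA"`); `NULL` components when a
#'   flank contains N.
#' @examples
#' classify_snv("G", "A", "C", "T")$change   # collapses to C>T
#' @export
classify_snv <- function(ref, alt, left, right) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  stopifnot(ref %in% names(comp), alt %in% names(comp), ref != alt)
  if (ref %in% c("G", "T")) {
    new_left <- comp[[right]]
    right <- comp[[left]]
    left <- new_left
    ref <- comp[[ref]]
    alt <- comp[[alt]]
  }
  if (left == "N" || right == "N")
    return(list(change = paste0(ref, ">", alt),
                transition = is_transition(ref, alt),
                context_class = NA_character_, triplet = NA_character_))
  ctx <- if (ref == "A") "weak" else if (right == "G") "CpG" else "strong"
  list(change = paste0(ref, ">", alt),
       transition = is_transition(ref, alt),
       context_class = ctx,
       triplet = paste0(left, ref, right))
}

#' Classify called SNVs against a reference genome
#'
#' Vectorised wrapper around [classify_snv()] that pulls flanking bases from
#' the genome; sites whose flank contains N (or sits on a chromosome edge)
#' get `NA` context and are excluded from context analyses with a warning.
#'
#' @param calls data.frame with `chrom`, `pos`, `ref`, `alt` (SNVs).
#' @param genome A `genome_model`.
#' @return `calls` with columns `change`, `transition`, `context_class`,
#'   `triplet` added.
#' @export
classify_mutations <- function(calls, genome) {
  n <- nrow(calls)
  change <- triplet <- ctx <- rep(NA_character_, n)
  transition <- rep(NA, n)
  n_excluded <- 0L
  for (i in seq_len(n)) {
    L <- genome$chrom_lengths[[calls$chrom[i]]]
    p <- calls$pos[i]
    if (p <= 1L || p >= L) { n_excluded <- n_excluded + 1L; next }
    cl <- classify_snv(calls$ref[i], calls$alt[i],
                       ref_base(genome, calls$chrom[i], p - 1L),
                       ref_base(genome, calls$chrom[i], p + 1L))
    change[i] <- cl$change
    transition[i] <- cl$transition
    ctx[i] <- cl$context_class
    triplet[i] <- cl$triplet
    if (is.na(cl$triplet)) n_excluded <- n_excluded + 1L
  }
  if (n_excluded > 0)
    warning(n_excluded, " site(s) with undefined flank excluded from context")
  calls$change <- change
  calls$transition <- transition
  calls$context_class <- ctx
  calls$triplet <- triplet
  calls
}

snv_change_levels <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T")

#' Mutation-type spectra stratified by clustering distance
#'
#' Splits SNVs into bins of distance to the nearest same-individual mutation
#' (default strata: tandem `{1}`, `(1,10]`, `(10,100]`, `(100,2000]`,
#' `(2000,20000)` and non-clustered `>= 20000`; distances are integer bp and
#' the clustering cutoff is strict, so exactly 20 kb is non-clustered) and
#' tabulates the six strand-collapsed change types per bin, with Wilson CIs
#' on the proportions. Empty bins are reported with zero counts.
#'
#' @param changes Strand-collapsed change types (`"A>C"`, ... `"C>T"`).
#' @param nearest_same_distance Distance (bp) to the nearest same-individual
#'   mutation for each SNV (`Inf` when none).
#' @param breaks Inner bin edges (defaults to
#'   `c(1, 10, 100, 2000, 20000)`).
#' @param level Confidence level.
#' @return data.frame: `bin`, `change`, `count`, `proportion`, `ci_low`,
#'   `ci_high`.
#' @export
spectrum_by_distance_bin <- function(changes, nearest_same_distance,
                                     breaks = c(1, 10, 100, 2000, 20000),
                                     level = 0.95) {
  stopifnot(length(changes) == length(nearest_same_distance))
  k <- length(breaks)
  # integer distances; the final clustering threshold is strict (< breaks[k])
  edges <- c(0, breaks[-k] + 1, breaks[k], Inf)
  labels <- c(paste0("<=", breaks[1]),
              if (k > 2) paste0("(", breaks[1:(k - 2)], ",",
                                breaks[2:(k - 1)], "]"),
              paste0("(", breaks[k - 1], ",", breaks[k], ")"),
              paste0(">=", breaks[k]))
  bin <- cut(nearest_same_distance, edges, labels = labels, right = FALSE,
             include.lowest = TRUE)
  bin[is.na(changes)] <- NA   # unclassifiable sites (e.g. chromosome edge)
  out <- list()
  for (b in labels) {
    in_bin <- !is.na(bin) & bin == b
    tot <- sum(in_bin)
    for (ch in snv_change_levels) {
      k <- sum(in_bin & changes == ch)
      ci <- if (tot > 0) wilson_ci(k, tot, level) else c(low = NA, high = NA)
      out[[paste(b, ch)]] <- data.frame(
        bin = b, change = ch, count = k,
        proportion = if (tot > 0) k / tot else NA_real_,
        ci_low = ci[["low"]], ci_high = ci[["high"]],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fisher exact comparison of two mutation-type spectra
#'
#' Exact test on the 2-by-k table of type counts. Tables whose exact
#' network evaluation is infeasible fall back to a fixed-seed Monte-Carlo
#' p-value with at least 1e5 draws; the method used is reported.
#'
#' @param counts_a,counts_b Aligned count vectors over the mutation types.
#' @param mc_draws Monte-Carlo draws when simulation is used.
#' @param force_mc Force the Monte-Carlo path.
#' @return List: `p_value`, `method` (`"exact"` or `"monte_carlo"`).
#' @export
compare_spectra <- function(counts_a, counts_b, mc_draws = 1e5,
                            force_mc = FALSE) {
  stopifnot(length(counts_a) == length(counts_b))
  if (sum(counts_a) == 0 || sum(counts_b) == 0)
    stop("both count vectors must contain mutations")
  tab <- rbind(counts_a, counts_b)
  if (!force_mc) {
    ft <- tryCatch(stats::fisher.test(tab, workspace = 2e7),
                   error = function(e) NULL)
    if (!is.null(ft)) return(list(p_value = ft$p.value, method = "exact"))
  }
  ft <- stats::fisher.test(tab, simulate.p.value = TRUE, B = mc_draws)
  list(p_value = ft$p.value, method = "monte_carlo")
}

#' Polymerase-zeta tandem signature
#'
#' TRUE when an adjoining SNV pair changes its reference dinucleotide into
#' the alternate dinucleotide GC>AA or GA>TT, read 5'-3' on either strand
#' (equivalently, the plus-strand dinucleotide change is one of GC>AA,
#' GC>TT, GA>TT, TC>AA) — the signature of error-prone translesion
#' synthesis by polymerase zeta.
#'
#' @param ref_dinuc,alt_dinuc Two-base reference and alternate strings of an
#'   adjoining pair (positions exactly 1 bp apart).
#' @param pos1,pos2 Optional positions; when given, adjacency is checked.
#' @return Logical.
#' @examples
#' is_polzeta_signature("GC", "AA")   # TRUE
#' is_polzeta_signature("GC", "TT")   # TRUE (reverse complement of GC>AA)
#' is_polzeta_signature("CC", "TT")   # FALSE
#' @export
is_polzeta_signature <- function(ref_dinuc, alt_dinuc, pos1 = NULL,
                                 pos2 = NULL) {
  if (!is.null(pos1) && !is.null(pos2) && abs(pos2 - pos1) != 1)
    stop("pair is not adjoining (positions must be 1 bp apart)")
  stopifnot(nchar(ref_dinuc) == 2, nchar(alt_dinuc) == 2)
  revcomp2 <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    b <- strsplit(x, "")[[1]]
    paste0(comp[[b[2]]], comp[[b[1]]])
  }
  key <- paste0(ref_dinuc, ">", alt_dinuc)
  key_rc <- paste0(revcomp2(ref_dinuc), ">", revcomp2(alt_dinuc))
  sig <- c("GC>AA", "GA>TT")
  key %in% sig || key_rc %in% sig
}

# Motif membership of a collapsed-strand triplet (middle base C).
matches_tcw <- function(triplet) {
  substr(triplet, 1, 1) == "T" & substr(triplet, 3, 3) %in% c("A", "T")
}
matches_dch <- function(triplet) {
  substr(triplet, 1, 1) %in% c("A", "G", "T") &
    substr(triplet, 3, 3) %in% c("A", "C", "T")
}

#' Motif enrichment of clustered vs non-clustered cytosine mutations
#'
#' For C>G and C>T mutations, compares the fraction matching the APOBEC
#' target motif TCW (T-C-[A/T]), the broader DCH motif
#' ([A/G/T]-C-[A/C/T]: cytosines neither preceded by C nor followed by G)
#' and, for C>T transitions, the CpG context, between a clustered group
#' (typically 10 bp - 20 kb from the nearest same-individual mutation) and
#' the non-clustered group. Each motif gets per-group fractions with Wilson
#' CIs and a 2x2 Fisher exact p-value.
#'
#' @param changes,triplets Strand-collapsed change types and triplets.
#' @param clustered Logical: group membership per mutation.
#' @param level Confidence level.
#' @return data.frame: `motif`, `change_set`, per-group `k`/`n`/fraction and
#'   CI columns, `p_value`.
#' @export
motif_tests <- function(changes, triplets, clustered, level = 0.95) {
  stopifnot(length(changes) == length(triplets),
            length(changes) == length(clustered))
  ok <- !is.na(triplets)
  specs <- list(
    list(motif = "TCW", change_set = "C>G", test = matches_tcw),
    list(motif = "TCW", change_set = "C>T", test = matches_tcw),
    list(motif = "DCH", change_set = "C>G", test = matches_dch),
    list(motif = "CpG", change_set = "C>T",
         test = function(t) substr(t, 3, 3) == "G"))
  rows <- lapply(specs, function(s) {
    sel <- ok & changes == s$change_set
    if (sum(sel & clustered) == 0 || sum(sel & !clustered) == 0)
      stop("a group has no eligible ", s$change_set, " mutations")
    hit <- s$test(triplets[sel])
    grp <- clustered[sel]
    k1 <- sum(hit & grp); n1 <- sum(grp)
    k0 <- sum(hit & !grp); n0 <- sum(!grp)
    ci1 <- wilson_ci(k1, n1, level); ci0 <- wilson_ci(k0, n0, level)
    p <- stats::fisher.test(matrix(c(k1, n1 - k1, k0, n0 - k0), 2))$p.value
    data.frame(motif = s$motif, change_set = s$change_set,
               clustered_k = k1, clustered_n = n1,
               clustered_fraction = k1 / n1,
               clustered_ci_low = ci1[["low"]],
               clustered_ci_high = ci1[["high"]],
               other_k = k0, other_n = n0, other_fraction = k0 / n0,
               other_ci_low = ci0[["low"]], other_ci_high = ci0[["high"]],
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
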