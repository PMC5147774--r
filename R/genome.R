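#' Generate a synthetic reference genome
#'
#' Draws an i.i.d. nucleotide sequence with the configured GC content, split
#' over `n_chromosomes` equally sized chromosomes. The genome is a stand-in
#' for a real autosomal reference: large enough to place mutations, small
#' enough for desk-scale analysis; mutation counts are controlled by the
#' family age model rather than genome size.
#'
#' @param config A [cohort_config()].
#' @return A `genome_model` list with `chrom_names`, `chrom_lengths` (named
#'   integer vector) and `sequence` (named character vector of A/C/G/T
#'   strings).
#' @examples
#' g <- generate_genome(cohort_config(genome_length = 1e4, seed = 1))
#' g$chrom_lengths
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$genome_length < 1)
    stop("requested genome length must be positive")
  set.seed(config$seed)
  n <- config$n_chromosomes
  len <- floor(config$genome_length / n)
  lens <- rep.int(len, n)
  lens[n] <- config$genome_length - len * (n - 1)
  names(lens) <- paste0("chr", seq_len(n))
  p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
         G = config$gc / 2, T = (1 - config$gc) / 2)
  seqs <- vapply(lens, function(L) {
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  structure(list(chrom_names = names(lens),
                 chrom_lengths = lens,
                 sequence = seqs,
                 gc = config$gc),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosome(s), %.2f Mb total\n",
              length(x$chrom_names), sum(x$chrom_lengths) / 1e6))
  invisible(x)
}

#' Per-position sequence context classes
#'
#' Classifies every position of a chromosome into one of three
#' strand-symmetric context classes: `CpG` (a C directly followed by G, or a
#' G directly preceded by C), `strong` (other C or G) or `weak` (A or T).
#' Positions with `N` get `NA`. The three classes partition all non-N
#' positions.
#'
#' @param genome A `genome_model`.
#' @param chrom Chromosome name.
#' @return Factor vector (levels `CpG`, `strong`, `weak`) of length
#'   `chrom_lengths[chrom]`.
#' @export
context_classes <- function(genome, chrom) {
  bases <- strsplit(genome$sequence[[chrom]], "", fixed = TRUE)[[1]]
  n <- length(bases)
  cls <- rep(NA_character_, n)
  cls[bases %in% c("A", "T")] <- "weak"
  strong <- bases %in% c("C", "G")
  cls[strong] <- "strong"
  is_c <- bases == "C"
  is_g <- bases == "G"
  cpg_c <- is_c & c(is_g[-1], FALSE)        # C followed by G
  cpg_g <- is_g & c(FALSE, is_c[-n])        # G preceded by C
  cls[cpg_c | cpg_g] <- "CpG"
  factor(cls, levels = c("CpG", "strong", "weak"))
}

# List of per-class 1-based position indices for each chromosome.
class_positions <- function(genome) {
  out <- lapply(genome$chrom_names, function(ch) {
    cls <- context_classes(genome, ch)
    list(CpG = which(cls == "CpG"),
         strong = which(cls == "strong"),
         weak = which(cls == "weak"))
  })
  names(out) <- genome$chrom_names
  out
}

# Reference base(s) at given positions (vectorised over pos within one chrom).
ref_base <- function(genome, chrom, pos, width = 1L) {
  substring(genome$sequence[[chrom]], pos, pos + width - 1L)
}

#' Write a genome to FASTA
#'
#' @param genome A `genome_model`.
#' @param path Output FASTA path.
#' @export
write_genome_fasta <- function(genome, path) {
  dss <- Biostrings::DNAStringSet(genome$sequence)
  names(dss) <- genome$chrom_names
  Biostrings::writeXStringSet(dss, filepath = path)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA path.
#' @return A `genome_model`.
#' @export
read_genome_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(dss)
  names(seqs) <- names(dss)
  structure(list(chrom_names = names(seqs),
                 chrom_lengths = stats::setNames(nchar(seqs), names(seqs)),
                 sequence = seqs,
                 gc = NA_real_),
            class = "genome_model")
}

#' Positions on the concatenated-genome axis
#'
#' Maps (chrom, pos) pairs onto a single coordinate axis formed by
#' concatenating chromosomes in the genome's order with no gap, so that
#' nearest-neighbour distances are defined across the whole mutation set.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos 1-based positions.
#' @param chrom_lengths Named vector of chromosome lengths in concatenation
#'   order.
#' @return Numeric vector of concatenated positions.
#' @export
concat_positions <- function(chrom, pos, chrom_lengths) {
  offsets <- c(0, cumsum(as.numeric(chrom_lengths)))[seq_along(chrom_lengths)]
  names(offsets) <- names(chrom_lengths)
  if (!all(chrom %in% names(offsets)))
    stop("chromosome(s) not present in chrom_lengths")
  offsets[chrom] + pos
}
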