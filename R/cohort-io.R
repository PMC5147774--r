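#' Simulate a complete synthetic trio cohort
#'
#' One-shot driver for the generator: genome, families, truth mutations,
#' depth profile, site observations and covariate tracks, all reproducible
#' from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return List of class `trio_cohort` with elements `config`, `genome`,
#'   `families`, `mutations`, `depth_profile`, `observations`, `tracks`.
#' @examples
#' co <- simulate_cohort(cohort_config(n_families = 4, genome_length = 5e5,
#'                                     n_background_sites = 10, seed = 7))
#' nrow(co$mutations)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  genome <- generate_genome(config)
  families <- generate_families(config)
  mutations <- generate_mutations(genome, families, config)
  depth_profile <- generate_depth_profile(genome, families, config)
  observations <- simulate_observations(mutations, families, config, genome,
                                        depth_profile)
  tracks <- generate_tracks(genome, families, config)
  structure(list(config = config, genome = genome, families = families,
                 mutations = mutations, depth_profile = depth_profile,
                 observations = observations, tracks = tracks),
            class = "trio_cohort")
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf("trio_cohort: %d families, %d truth mutations (%d SNVs), %.1f Mb genome\n",
              nrow(x$families), nrow(x$mutations),
              sum(x$mutations$kind == "SNV"),
              sum(x$genome$chrom_lengths) / 1e6))
  invisible(x)
}

#' Write a synthetic cohort to standard file formats
#'
#' Writes: one VCF 4.2 per family (GT:DP:SAC:GL genotypes for
#' proband/father/mother; site metrics as INFO keys `RPRS`, `MQRS`, `FS`,
#' `POPLR`), a pedigree TSV, a truth-mutation TSV, a binned depth-profile
#' TSV, one bedGraph per replication-timing track, a BED file of crossover
#' bins (name column `family:parent`), the reference FASTA and a JSON config
#' snapshot. VCF positions are 1-based; bedGraph/BED intervals are half-open
#' 0-based.
#'
#' @param cohort A `trio_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  write_genome_fasta(cohort$genome, file.path(dir, "genome.fa"))

  ped <- data.frame(family_id = cohort$families$family_id,
                    proband_id = cohort$families$proband_id,
                    father_id = paste0(cohort$families$family_id, "_father"),
                    mother_id = paste0(cohort$families$family_id, "_mother"),
                    father_age = cohort$families$father_age,
                    mother_age = cohort$families$mother_age)
  utils::write.table(ped, file.path(dir, "pedigree.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$mutations, file.path(dir, "truth_mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$depth_profile, file.path(dir, "depth_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  vcf_dir <- file.path(dir, "vcf")
  dir.create(vcf_dir, showWarnings = FALSE)
  for (fam in cohort$families$family_id) {
    obs <- cohort$observations[cohort$observations$family_id == fam, ,
                               drop = FALSE]
    write_family_vcf(obs, cohort$genome, fam,
                     file.path(vcf_dir, paste0(fam, ".vcf")))
  }

  rep_df <- cohort$tracks$replication
  track_cols <- grep("^track", names(rep_df), value = TRUE)
  for (tc in track_cols) {
    f <- file.path(dir, paste0("replication_", tc, ".bedGraph"))
    con <- file(f, "w")
    writeLines(sprintf("track type=bedGraph name=%s", tc), con)
    utils::write.table(data.frame(rep_df$chrom, rep_df$start, rep_df$end,
                                  signif(rep_df[[tc]], 8)),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
  }

  xo <- cohort$tracks$crossovers
  utils::write.table(data.frame(xo$chrom, xo$start, xo$end,
                                paste0(xo$family_id, ":", xo$parent)),
                     file.path(dir, "crossovers.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  cfg <- unclass(cohort$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# One family's observations as a VCF 4.2 file with trio genotype columns.
write_family_vcf <- function(obs, genome, fam, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=denovotrio",
    sprintf("##contig=<ID=%s,length=%d>", genome$chrom_names,
            genome$chrom_lengths),
    "##INFO=<ID=RPRS,Number=1,Type=Float,Description=\"ReadPosRankSum Z-score\">",
    "##INFO=<ID=MQRS,Number=1,Type=Float,Description=\"MQRankSum Z-score\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled strand bias\">",
    "##INFO=<ID=POPLR,Number=1,Type=Float,Description=\"Max population carrier likelihood ratio\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Quality read depth\">",
    "##FORMAT=<ID=SAC,Number=4,Type=Integer,Description=\"Strand allele counts: refFwd,refRev,altFwd,altRev\">",
    "##FORMAT=<ID=GL,Number=3,Type=Float,Description=\"log10 genotype likelihoods RR,RA,AA\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           fam, "_child\t", fam, "_father\t", fam, "_mother")), con)
  if (nrow(obs) == 0) return(invisible(path))
  obs <- obs[order(match(obs$chrom, genome$chrom_names), obs$pos), ]
  info <- sprintf("RPRS=%.6g;MQRS=%.6g;FS=%.6g;POPLR=%.8g",
                  obs$read_pos_rank_sum, obs$mq_rank_sum, obs$fs, obs$pop_lr)
  sample_field <- function(member) {
    dp <- obs[[paste0("dp_", member)]]
    af <- obs[[paste0("alt_fwd_", member)]]
    ar <- obs[[paste0("alt_rev_", member)]]
    gl <- cbind(obs[[paste0("gl_rr_", member)]],
                obs[[paste0("gl_ar_", member)]],
                obs[[paste0("gl_aa_", member)]])
    gt_idx <- max.col(gl, ties.method = "first")
    gt <- c("0/0", "0/1", "1/1")[gt_idx]
    nref <- dp - af - ar
    sprintf("%s:%d:%d,%d,%d,%d:%.6g,%.6g,%.6g", gt, dp,
            ceiling(nref / 2), floor(nref / 2), af, ar,
            gl[, 1], gl[, 2], gl[, 3])
  }
  lines <- paste(obs$chrom, obs$pos, ".", obs$ref, obs$alt, ".", "PASS",
                 info, "GT:DP:SAC:GL",
                 sample_field("child"), sample_field("father"),
                 sample_field("mother"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

# Parse one of the package's per-family VCFs back into an observation frame.
read_family_vcf <- function(path, family_id = NULL) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (is.null(family_id))
    family_id <- sub("\\.vcf$", "", basename(path))
  empty <- data.frame(family_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      stringsAsFactors = FALSE)
  if (length(body) == 0) return(empty)
  fields <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  info_num <- function(key) {
    as.numeric(sub(sprintf(".*%s=([^;]+).*", key), "\\1", fields[, 8]))
  }
  parse_member <- function(col, member) {
    parts <- strsplit(fields[, col], ":", fixed = TRUE)
    dp <- as.integer(vapply(parts, `[`, character(1), 2))
    sac <- do.call(rbind, lapply(parts, function(p)
      as.integer(strsplit(p[3], ",", fixed = TRUE)[[1]])))
    gl <- do.call(rbind, lapply(parts, function(p)
      as.numeric(strsplit(p[4], ",", fixed = TRUE)[[1]])))
    out <- data.frame(dp = dp, alt_fwd = sac[, 3], alt_rev = sac[, 4],
                      gl_rr = gl[, 1], gl_ar = gl[, 2], gl_aa = gl[, 3])
    names(out) <- paste0(names(out), "_", member)
    out
  }
  ref <- fields[, 4]; alt <- fields[, 5]
  kind <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV",
                 ifelse(nchar(ref) > nchar(alt), "deletion", "insertion"))
  cbind(data.frame(family_id = family_id, chrom = fields[, 1],
                   pos = as.integer(fields[, 2]), ref = ref, alt = alt,
                   kind = kind, stringsAsFactors = FALSE),
        parse_member(10, "child"), parse_member(11, "father"),
        parse_member(12, "mother"),
        data.frame(read_pos_rank_sum = info_num("RPRS"),
                   mq_rank_sum = info_num("MQRS"),
                   fs = info_num("FS"),
                   pop_lr = info_num("POPLR")))
}

#' Read a written cohort directory
#'
#' Inverse of [write_cohort()]: reconstructs genome, pedigree, truth
#' mutations, depth profile, per-family observations (with the truth label
#' rejoined from the truth table) and covariate tracks.
#'
#' @param dir Directory written by [write_cohort()].
#' @return A list with the same elements as [simulate_cohort()] (minus
#'   `config`, which is returned as a plain list from the JSON snapshot).
#' @export
read_cohort <- function(dir) {
  genome <- read_genome_fasta(file.path(dir, "genome.fa"))
  ped <- utils::read.delim(file.path(dir, "pedigree.tsv"))
  families <- data.frame(family_id = ped$family_id,
                         proband_id = ped$proband_id,
                         father_age = ped$father_age,
                         mother_age = ped$mother_age)
  mutations <- utils::read.delim(file.path(dir, "truth_mutations.tsv"),
                                 colClasses = c(cluster_id = "character"))
  depth_profile <- utils::read.delim(file.path(dir, "depth_profile.tsv"))
  vcfs <- list.files(file.path(dir, "vcf"), pattern = "\\.vcf$",
                     full.names = TRUE)
  observations <- do.call(rbind, lapply(vcfs, read_family_vcf))
  key <- function(d) paste(d$family_id, d$chrom, d$pos)
  observations$is_denovo <- key(observations) %in% key(mutations)

  rep_files <- list.files(dir, pattern = "^replication_track.*\\.bedGraph$",
                          full.names = TRUE)
  rep_list <- lapply(rep_files, function(f)
    utils::read.delim(f, skip = 1, header = FALSE,
                      col.names = c("chrom", "start", "end", "value")))
  replication <- rep_list[[1]][, c("chrom", "start", "end")]
  for (i in seq_along(rep_list))
    replication[[paste0("track", i)]] <- rep_list[[i]]$value
  xo_raw <- utils::read.delim(file.path(dir, "crossovers.bed"), header = FALSE,
                              col.names = c("chrom", "start", "end", "name"))
  nm <- strsplit(xo_raw$name, ":", fixed = TRUE)
  crossovers <- data.frame(family_id = vapply(nm, `[`, character(1), 1),
                           parent = vapply(nm, `[`, character(1), 2),
                           chrom = xo_raw$chrom, start = xo_raw$start,
                           end = xo_raw$end, stringsAsFactors = FALSE)
  config <- jsonlite::read_json(file.path(dir, "config.json"),
                                simplifyVector = TRUE)
  list(config = config, genome = genome, families = families,
       mutations = mutations, depth_profile = depth_profile,
       observations = observations,
       tracks = structure(list(replication = replication,
                               crossovers = crossovers,
                               bin_bp = config$replication_bin_bp),
                          class = "covariate_tracks"))
}
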