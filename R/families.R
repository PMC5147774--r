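#' Generate synthetic trio families with correlated parental ages
#'
#' Parental ages at conception are drawn from a bivariate normal with the
#' configured means, standard deviations and squared correlation (`age_r2`),
#' truncated below at `min_age` by resampling. Assortative age pairing is
#' a robust demographic feature of trio cohorts and is what couples the
#' paternal- and maternal-age effects in the downstream regression.
#'
#' @param config A [cohort_config()].
#' @return data.frame with `family_id`, `proband_id`, `father_age`,
#'   `mother_age` (years, one row per trio).
#' @examples
#' fam <- generate_families(cohort_config(n_families = 5, seed = 1))
#' fam
#' @export
generate_families <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_families < 1) stop("n_families must be >= 1")
  set.seed(config$seed + 1L)
  n <- config$n_families
  r <- sqrt(config$age_r2)
  mu_f <- config$mean_father_age
  mu_m <- config$mean_mother_age
  sd_f <- config$sd_father_age
  sd_m <- config$sd_mother_age
  draw <- function(k) {
    z1 <- stats::rnorm(k)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(k)
    cbind(mu_f + sd_f * z1, mu_m + sd_m * z2)
  }
  ages <- draw(n)
  bad <- ages[, 1] < config$min_age | ages[, 2] < config$min_age
  while (any(bad)) {
    ages[bad, ] <- draw(sum(bad))
    bad <- ages[, 1] < config$min_age | ages[, 2] < config$min_age
  }
  data.frame(family_id = sprintf("F%04d", seq_len(n)),
             proband_id = sprintf("F%04d_child", seq_len(n)),
             father_age = round(ages[, 1], 1),
             mother_age = round(ages[, 2], 1),
             stringsAsFactors = FALSE)
}
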