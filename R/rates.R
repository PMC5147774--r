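#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes,trials Counts with `0 <= successes <= trials`,
#'   `trials >= 1`.
#' @param level Confidence level (default 0.95).
#' @return Named numeric `c(low, high)`, both in `[0, 1]`.
#' @examples
#' round(wilson_ci(54, 17812) * 100, 2)   # 0.23% - 0.40%
#' round(wilson_ci(0, 92)[2] * 100, 1)    # upper bound 4.0%
#' @export
wilson_ci <- function(successes, trials, level = 0.95) {
  if (trials < 1) stop("trials must be >= 1")
  if (successes < 0 || successes > trials)
    stop("successes must lie in [0, trials]")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  den <- 1 + z^2 / trials
  centre <- p + z^2 / (2 * trials)
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2))
  low <- if (successes == 0) 0 else max(0, (centre - half) / den)
  high <- if (successes == trials) 1 else min(1, (centre + half) / den)
  c(low = low, high = high)
}

new_rate_estimate <- function(numerator, denominator, level = 0.95) {
  if (denominator <= 0) stop("rate denominator must be positive")
  ci <- wilson_ci(numerator, round(denominator), level) # count CI at fixed denominator
  structure(list(numerator = numerator, denominator = denominator,
                 rate = numerator / denominator,
                 ci_low = ci[["low"]], ci_high = ci[["high"]],
                 level = level),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rate %.3g (%d%% CI %.3g-%.3g); %g mutations / %.4g effective positions\n",
              x$rate, round(100 * x$level), x$ci_low, x$ci_high,
              x$numerator, x$denominator))
  invisible(x)
}

#' Mutation rate per position per generation
#'
#' `sum(n_f) / (2 * sum(C_f))` where `n_f` is the de novo count and `C_f`
#' the callable-site sum of family `f`; the factor 2 counts the two parental
#' genome copies transmitted per generation. The Wilson CI is computed on
#' the count, with the denominator treated as fixed.
#'
#' @param counts Named (by family) or plain numeric vector of per-family
#'   mutation counts.
#' @param callable_sums Per-family callable-site sums, aligned with `counts`.
#' @param level Confidence level.
#' @return A `rate_estimate`.
#' @examples
#' rate_pppg(c(3, 5), c(1e6, 1e6))   # 8 / (2 * 2e6)
#' @export
rate_pppg <- function(counts, callable_sums, level = 0.95) {
  stopifnot(length(counts) == length(callable_sums))
  new_rate_estimate(sum(counts), 2 * sum(callable_sums), level)
}

#' Mutation rate per position per year
#'
#' `sum(n_f) / sum((p_f + m_f) * C_f)`, where `p_f` and `m_f` are the
#' paternal and maternal ages at conception (the generation intervals) of
#' family `f`. Each callable position is exposed for the combined parental
#' years of its family.
#'
#' @param counts Per-family mutation counts.
#' @param callable_sums Per-family callable-site sums.
#' @param father_ages,mother_ages Parental ages (years), aligned with
#'   `counts`.
#' @param level Confidence level.
#' @return A `rate_estimate`.
#' @examples
#' rate_pppy(6, 1e9, 30, 30)   # 6 / (60 * 1e9) = 1e-10
#' @export
rate_pppy <- function(counts, callable_sums, father_ages, mother_ages,
                      level = 0.95) {
  stopifnot(length(counts) == length(callable_sums),
            length(counts) == length(father_ages),
            length(counts) == length(mother_ages))
  if (any(!is.finite(father_ages)) || any(!is.finite(mother_ages)))
    stop("missing parental age")
  new_rate_estimate(sum(counts),
                    sum((father_ages + mother_ages) * callable_sums), level)
}

#' Joint regression of mutation counts on parental ages
#'
#' Ordinary least-squares fit of per-family de novo counts on paternal and
#' maternal age at conception jointly; because parental ages are strongly
#' correlated, the joint fit is what separates the paternal from the
#' maternal age effect. A Poisson log-link alternative is available via
#' `family = "poisson"` (slopes then on the log scale).
#'
#' @param counts Per-family mutation counts.
#' @param father_ages,mother_ages Ages (years).
#' @param family `"ols"` (default) or `"poisson"`.
#' @return List of class `parental_age_model`: `paternal` and `maternal`
#'   (each `estimate`, `se`, `p`), `intercept`, and the underlying `fit`.
#' @export
parental_age_regression <- function(counts, father_ages, mother_ages,
                                    family = c("ols", "poisson")) {
  family <- match.arg(family)
  if (length(counts) < 3) stop("need at least 3 families")
  if (stats::sd(father_ages) == 0 || stats::sd(mother_ages) == 0 ||
      abs(stats::cor(father_ages, mother_ages)) > 1 - 1e-12)
    stop("parental ages are constant or collinear")
  df <- data.frame(n = counts, fa = father_ages, ma = mother_ages)
  fit <- if (family == "ols") stats::lm(n ~ fa + ma, data = df)
  else stats::glm(n ~ fa + ma, data = df, family = stats::poisson())
  cf <- summary(fit)$coefficients
  structure(list(
    paternal = list(estimate = cf["fa", 1], se = cf["fa", 2], p = cf["fa", 4]),
    maternal = list(estimate = cf["ma", 1], se = cf["ma", 2], p = cf["ma", 4]),
    intercept = cf["(Intercept)", 1],
    family = family, fit = fit), class = "parental_age_model")
}

#' @export
print.parental_age_model <- function(x, ...) {
  cat(sprintf("parental-age model (%s):\n  paternal %+.3f /yr (SE %.3f, p = %.2g)\n  maternal %+.3f /yr (SE %.3f, p = %.2g)\n",
              x$family, x$paternal$estimate, x$paternal$se, x$paternal$p,
              x$maternal$estimate, x$maternal$se, x$maternal$p))
  invisible(x)
}

#' Context-stratified mutation-rate table
#'
#' Per-year rates for each mutation class: SNVs split by context class
#' (CpG / non-CpG strong / weak) and change type (transition /
#' transversion), plus insertions and deletions, each with a Wilson CI
#' computed on the class count over its context-specific callable
#' denominator. Also reports the deletion:insertion count ratio.
#'
#' @param calls Calls data.frame from [cohort_call_and_callability()] (needs
#'   `kind`, `context_class`, `ref`, `alt`, `individual_id`).
#' @param callability Per-family callability data.frame (same function).
#' @param families Families data.frame with `family_id`, `father_age`,
#'   `mother_age`.
#' @param level Confidence level.
#' @return List with `table` (data.frame: class, count, rate_pppy, ci_low,
#'   ci_high) and `deletion_insertion_ratio`.
#' @export
stratified_rate_table <- function(calls, callability, families,
                                  level = 0.95) {
  fam <- families[match(callability$family_id, families$family_id), ]
  years <- fam$father_age + fam$mother_age
  denom_ctx <- vapply(c("CpG", "strong", "weak"), function(cx)
    sum(years * callability[[cx]]), numeric(1))
  denom_indel <- sum(years * callability$indel_callable_sum)
  snv <- calls[calls$kind == "SNV" & !is.na(calls$context_class), ]
  is_ts <- is_transition(snv$ref, snv$alt)
  rows <- list()
  for (cx in c("CpG", "strong", "weak")) {
    if (denom_ctx[[cx]] <= 0) stop("zero callable denominator for ", cx)
    for (chg in c("transition", "transversion")) {
      n <- sum(snv$context_class == cx &
                 (if (chg == "transition") is_ts else !is_ts))
      ci <- wilson_ci(n, round(denom_ctx[[cx]]), level)
      rows[[paste(cx, chg)]] <- data.frame(
        context = cx, change = chg, count = n,
        rate_pppy = n / denom_ctx[[cx]],
        ci_low = ci[["low"]], ci_high = ci[["high"]])
    }
  }
  for (kind in c("insertion", "deletion")) {
    n <- sum(calls$kind == kind)
    ci <- wilson_ci(n, round(denom_indel), level)
    rows[[kind]] <- data.frame(context = kind, change = "all", count = n,
                               rate_pppy = n / denom_indel,
                               ci_low = ci[["low"]], ci_high = ci[["high"]])
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  n_del <- sum(calls$kind == "deletion")
  n_ins <- sum(calls$kind == "insertion")
  list(table = tab,
       deletion_insertion_ratio = if (n_ins > 0) n_del / n_ins else NA_real_)
}

# Transition = purine<->purine or pyrimidine<->pyrimidine single-base change.
is_transition <- function(ref, alt) {
  (ref %in% c("A", "G") & alt %in% c("A", "G")) |
    (ref %in% c("C", "T") & alt %in% c("C", "T"))
}
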