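#' Analytic power of the two-sided per-allele case-control test
#'
#' Under the log-additive alternative, the expected control allele
#' frequency is the population frequency `p` and the expected case
#' frequency is `p*OR / (1 - p + p*OR)`. The log-OR estimate has
#' approximate variance `1/(2 n_case p1 q1) + 1/(2 n_control p0 q0)` (2n
#' alleles per group), giving non-centrality `|log OR| / sd` and power
#' `pnorm(ncp - z) + pnorm(-ncp - z)` at the two-sided critical value `z`.
#'
#' @param maf allele frequency of the risk allele, in (0, 0.5].
#' @param or_alt per-allele odds ratio under the alternative (> 0).
#' @param n_cases,n_controls group sizes.
#' @param alpha two-sided significance level (default 0.05).
#' @return power as a fraction in `[alpha, 1)`. All arguments recycle.
#' @export
allele_test_power <- function(maf, or_alt, n_cases, n_controls,
                              alpha = 0.05) {
  stopifnot(all(maf > 0), all(maf <= 0.5), all(or_alt > 0),
            all(n_cases > 0), all(n_controls > 0),
            all(alpha > 0), all(alpha < 1))
  p0 <- maf
  p1 <- p0 * or_alt / (1 - p0 + p0 * or_alt)
  v <- 1 / (2 * n_cases * p1 * (1 - p1)) +
    1 / (2 * n_controls * p0 * (1 - p0))
  ncp <- abs(log(or_alt)) / sqrt(v)
  z <- qnorm(1 - alpha / 2)
  pnorm(ncp - z) + pnorm(-ncp - z)
}

#' Count catalog variants with adequate power
#'
#' Computes per-variant analytic power in each population (from that
#' population's allele frequency, reported OR and case/control counts) and
#' in the combined sample (allele frequency weighted by population sample
#' size, counts summed), and counts variants at or above the power
#' threshold.
#'
#' @param catalog locus catalog with `index_variant` and `reported_or`.
#' @param freqs matrix of risk-allele frequencies, rows = variants (ids in
#'   rownames), columns = populations.
#' @param n_cases,n_controls named per-population counts (names matching
#'   `colnames(freqs)`).
#' @param threshold power threshold (default 0.80).
#' @param alpha two-sided significance level.
#' @return list: `counts` (named, per population plus `combined`) and
#'   `table` (per-variant power in every scope).
#' @export
powered_fraction <- function(catalog, freqs, n_cases, n_controls,
                             threshold = 0.80, alpha = 0.05) {
  pops <- colnames(freqs)
  stopifnot(all(pops %in% names(n_cases)), all(pops %in% names(n_controls)))
  idx <- match(catalog$index_variant, rownames(freqs))
  missing <- catalog$index_variant[is.na(idx)]
  if (length(missing))
    warn2("no frequency for ", length(missing), " variant(s); skipped")
  keep <- !is.na(idx)
  f <- freqs[idx[keep], , drop = FALSE]
  or <- catalog$reported_or[keep]
  tab <- data.frame(variant_id = catalog$index_variant[keep],
                    reported_or = or, stringsAsFactors = FALSE)
  counts <- integer(0)
  for (pop in pops) {
    # power is computed for the risk allele as reported; fold to (0, 0.5]
    pw <- allele_test_power(pmin(pmax(fold_maf(f[, pop]), 1e-6), 0.5),
                            ifelse(f[, pop] <= 0.5, or, 1 / or),
                            n_cases[[pop]], n_controls[[pop]], alpha)
    tab[[paste0("power_", pop)]] <- pw
    counts[pop] <- sum(pw >= threshold)
  }
  n_tot <- vapply(pops, function(p) n_cases[[p]] + n_controls[[p]], 0)
  f_comb <- as.vector(f %*% n_tot / sum(n_tot))
  pw <- allele_test_power(pmin(pmax(fold_maf(f_comb), 1e-6), 0.5),
                          ifelse(f_comb <= 0.5, or, 1 / or),
                          sum(unlist(n_cases[pops])),
                          sum(unlist(n_controls[pops])), alpha)
  tab$power_combined <- pw
  counts["combined"] <- sum(pw >= threshold)
  list(counts = counts, table = tab, threshold = threshold)
}

#' Monte-Carlo power of the per-allele test
#'
#' Simulation oracle for [allele_test_power()]: draws case and control
#' genotypes from HWE genotype frequencies under the alternative, fits the
#' per-allele logistic model, and reports the rejection rate of the Wald
#' test.
#'
#' @inheritParams allele_test_power
#' @param reps number of replicates.
#' @param seed optional integer seed.
#' @return rejection-rate estimate.
#' @export
mc_allele_power <- function(maf, or_alt, n_cases, n_controls, alpha = 0.05,
                            reps = 5000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- maf; g <- 0:2
  fg <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  fcase <- fg * or_alt^g; fcase <- fcase / sum(fcase)
  zcrit <- qnorm(1 - alpha / 2)
  hits <- 0L
  y <- rep(c(1L, 0L), c(n_cases, n_controls))
  for (i in seq_len(reps)) {
    x <- c(sample(g, n_cases, TRUE, fcase), sample(g, n_controls, TRUE, fg))
    fit <- fit_logistic_wald(cbind(intercept = 1, dosage = x), y)
    if (fit$ok && abs(fit$beta / fit$se) > zcrit) hits <- hits + 1L
  }
  hits / reps
}
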