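#' Exact one-sided binomial tail for directional consistency
#'
#' Probability that at least `k` of `n` independent fair coin flips land
#' heads: the null chance of observing `k` or more of `n` index variants
#' with the reported effect direction when direction is random.
#'
#' @param k number of directionally consistent variants, `0 <= k <= n`.
#' @param n number of evaluated variants, `n >= 1`.
#' @return `P(X >= k)` for `X ~ Binomial(n, 1/2)`, exact.
#' @export
binomial_consistency <- function(k, n) {
  stopifnot(n >= 1, k >= 0, k <= n)
  pbinom(k - 1, n, 0.5, lower.tail = FALSE)
}

#' Is an oriented effect directionally consistent with the report?
#'
#' After orienting the estimated effect to the reported risk allele, the
#' effect is consistent when the oriented log-odds is strictly positive
#' (every reported OR exceeds 1 once expressed for the risk allele). An
#' oriented effect of exactly zero counts as inconsistent.
#'
#' @param beta estimated log-odds for the variant's effect allele.
#' @param orientation `+1`/`-1` from [align_to_catalog()]; `NA` = ambiguous.
#' @return logical; `NA` when the orientation is ambiguous.
#' @export
direction_consistent <- function(beta, orientation) {
  ifelse(is.na(orientation) | is.na(beta), NA, beta * orientation > 0)
}

#' Directional-consistency summary for one analysis scope
#'
#' Counts, among catalog index variants present in the scope's meta-analysis
#' table (i.e. passing the scope's MAF/INFO filters), how many have the
#' reported effect direction, and tests the count against the coin-flip
#' null with the exact one-sided binomial tail. Variants whose allele
#' orientation is ambiguous are excluded from `n` and logged.
#'
#' @param meta_table rows for one scope, with `variant_id`, `beta`, `p`,
#'   `orientation`.
#' @param catalog locus catalog (one row per reported index variant).
#' @param scope label for the summary row.
#' @param alpha nominal significance level for the consistent-and-nominal
#'   list.
#' @return list of class `consistency_summary`: `scope`, `n`, `k`,
#'   `fraction`, `p`, `nominal` (data frame of consistent variants with
#'   `p < alpha`), `detail` (per-variant table), `excluded` (ambiguous or
#'   absent variants).
#' @export
summarize_consistency <- function(meta_table, catalog, scope = "scope",
                                  alpha = 0.05) {
  idx <- meta_table[meta_table$variant_id %in% catalog$index_variant, ,
                    drop = FALSE]
  idx <- idx[!duplicated(idx$variant_id), , drop = FALSE]
  absent <- setdiff(catalog$index_variant, idx$variant_id)
  ambiguous <- idx$variant_id[is.na(idx$orientation)]
  eval_rows <- idx[!is.na(idx$orientation), , drop = FALSE]
  consistent <- direction_consistent(eval_rows$beta, eval_rows$orientation)
  n <- nrow(eval_rows); k <- sum(consistent)
  detail <- data.frame(variant_id = eval_rows$variant_id,
                       oriented_beta = eval_rows$beta * eval_rows$orientation,
                       p = eval_rows$p, consistent = consistent,
                       stringsAsFactors = FALSE)
  nominal <- detail[detail$consistent & detail$p < alpha, , drop = FALSE]
  structure(list(scope = scope, n = n, k = k,
                 fraction = if (n > 0) k / n else NA_real_,
                 p = if (n > 0) binomial_consistency(k, n) else NA_real_,
                 nominal = nominal, detail = detail,
                 excluded = data.frame(
                   variant_id = c(absent, ambiguous),
                   reason = rep(c("not_in_scope", "ambiguous_orientation"),
                                c(length(absent), length(ambiguous))),
                   stringsAsFactors = FALSE)),
            class = "consistency_summary")
}

#' @export
print.consistency_summary <- function(x, ...) {
  cat(sprintf("%s: %d of %d (%.1f%%) directionally consistent, binomial p = %.3g\n",
              x$scope, x$k, x$n, 100 * x$fraction, x$p))
  cat(sprintf("  %d consistent variants at nominal p < 0.05\n",
              nrow(x$nominal)))
  invisible(x)
}
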