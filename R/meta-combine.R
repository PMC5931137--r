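#' Fixed-effects inverse-variance meta-analysis
#'
#' Weights are `1/se^2`; the combined effect is the weighted mean, the
#' combined standard error `(sum w)^(-1/2)`, with a two-sided normal
#' p-value. Cochran's Q and the I-squared percentage are reported but never
#' used for filtering. The alternative sample-size-weighted z scheme
#' (`scheme = "samplesize"`) combines `z_i = beta_i/se_i` with weights
#' `sqrt(n_i)` and yields a p-value but no effect-scale estimate.
#'
#' @param beta per-study effects (log odds).
#' @param se per-study standard errors (> 0).
#' @param scheme `"stderr"` (default, effect-scale) or `"samplesize"`.
#' @param n per-study sample sizes (required for `"samplesize"`).
#' @return list: `beta`, `se`, `p`, `n_strata`, `q`, `i2` (percent),
#'   `scheme`; a single input is returned unchanged with `n_strata = 1`.
#' @export
inverse_variance_meta <- function(beta, se, scheme = c("stderr", "samplesize"),
                                  n = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(length(beta) == length(se), length(beta) >= 1, all(se > 0))
  k <- length(beta)
  if (scheme == "samplesize") {
    if (is.null(n)) stop2("sample sizes required for the samplesize scheme")
    w <- sqrt(n)
    z <- sum(w * beta / se) / sqrt(sum(w^2))
    return(list(beta = NA_real_, se = NA_real_, p = 2 * pnorm(-abs(z)),
                n_strata = k, q = NA_real_, i2 = NA_real_,
                scheme = scheme))
  }
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  q <- sum(w * (beta - b)^2)
  i2 <- if (k > 1) max(0, (q - (k - 1)) / q) * 100 else NA_real_
  list(beta = b, se = s, p = 2 * pnorm(-abs(b / s)), n_strata = k,
       q = q, i2 = i2, scheme = scheme)
}

meta_rows <- function(df, scope, population, scheme) {
  m <- inverse_variance_meta(df$beta, df$se, scheme = scheme, n = df$n)
  data.frame(variant_id = df$variant_id[1], scope = scope,
             population = population,
             effect_allele = df$effect_allele[1],
             beta = m$beta, se = m$se, p = m$p, or = exp(m$beta),
             n_strata = m$n_strata, n = sum(df$n),
             populations_present = paste(sort(unique(df$population)),
                                         collapse = ","),
             maf = sum(df$maf * df$n) / sum(df$n),
             q = m$q, i2 = m$i2,
             orientation = df$orientation[1],
             stringsAsFactors = FALSE)
}

#' Within-population meta-analysis over case-control strata
#'
#' @param assoc an `assoc_table` from [scan_associations()].
#' @param scheme passed to [inverse_variance_meta()].
#' @return data frame with one row per (population, variant):
#'   effect-scale pooled `beta`/`se`/`p`, `n_strata`, heterogeneity `q` and
#'   `i2`, and the stratum-consistent catalog `orientation`.
#' @export
population_meta <- function(assoc, scheme = "stderr") {
  parts <- split(assoc, list(assoc$population, assoc$variant_id), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(df)
    meta_rows(df, scope = "population", population = df$population[1],
              scheme = scheme)))
  rownames(out) <- NULL
  out
}

#' Cross-population (multiethnic) meta-analysis
#'
#' Two-stage fixed effects: strata are pooled within population first, then
#' the population-level estimates are pooled. Variants observed in fewer
#' than `min_populations` populations are excluded from the cross-ethnic
#' table; exclusions are logged in the `exclusions` attribute.
#'
#' @param assoc an `assoc_table`.
#' @param scheme passed to [inverse_variance_meta()].
#' @param min_populations minimum number of populations (default 2).
#' @return data frame with one row per eligible variant
#'   (`scope = "multiethnic"`).
#' @export
cross_ethnic_meta <- function(assoc, scheme = "stderr",
                              min_populations = 2L) {
  pm <- population_meta(assoc, scheme = scheme)
  parts <- split(pm, pm$variant_id)
  keep <- vapply(parts, nrow, 0L) >= min_populations
  excl <- data.frame(variant_id = names(parts)[!keep],
                     reason = rep("fewer_than_min_populations", sum(!keep)),
                     stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(parts[keep], function(df) {
    r <- meta_rows(df, scope = "multiethnic", population = "multiethnic",
                   scheme = scheme)
    r$n_strata <- sum(df$n_strata)
    r$populations_present <- paste(sort(df$population), collapse = ",")
    r
  }))
  if (is.null(out)) out <- pm[0, ]
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}
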