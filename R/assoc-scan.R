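#' Principal components from a random variant subset
#'
#' Columns are sampled from variants with folded MAF above `maf_min` and
#' call rate at or above `callrate_min`, mean-imputed, centered and
#' standardized; PCs are the leading left singular vectors (equivalently,
#' eigenvectors of the sample covariance of the standardized dosages),
#' ordered by decreasing eigenvalue and unit norm.
#'
#' @param dosages samples x variants matrix.
#' @param subset_size number of variants to sample (all eligible used, with
#'   a warning, when fewer are available).
#' @param maf_min minimum folded MAF for eligibility (exclusive).
#' @param callrate_min minimum call rate (inclusive).
#' @param k number of components.
#' @param seed optional integer seed for the variant subsample.
#' @return samples x k matrix with columns `PC1..PCk`, orthonormal.
#' @export
compute_pcs <- function(dosages, subset_size = 10000L, maf_min = 0.05,
                        callrate_min = 0.95, k = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  callrate <- colMeans(!is.na(dosages))
  freq <- colMeans(dosages, na.rm = TRUE) / 2
  maf <- fold_maf(freq)
  eligible <- which(!is.na(maf) & maf > maf_min & callrate >= callrate_min)
  if (length(eligible) < k)
    stop2("fewer eligible variants (", length(eligible),
          ") than requested components (", k, ")")
  if (length(eligible) < subset_size) {
    warn2("only ", length(eligible), " eligible variants; using all")
    sel <- eligible
  } else sel <- sample(eligible, subset_size)
  X <- dosages[, sel, drop = FALSE]
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  X <- scale(X)
  X <- X[, !is.na(colSums(X)) & apply(X, 2, function(c) any(c != 0)),
         drop = FALSE]
  sv <- svd(X, nu = k, nv = 0)
  pcs <- sv$u[, seq_len(k), drop = FALSE]
  colnames(pcs) <- paste0("PC", seq_len(k))
  rownames(pcs) <- rownames(dosages)
  pcs
}

# IRLS logistic fit with Wald statistics on the column named "dosage".
# Returns NULL coefficients flagged not-ok on separation / non-convergence.
# Constant covariate columns (e.g. sex inside a single-sex stratum) are
# dropped rather than allowed to make the fit rank-deficient.
fit_logistic_wald <- function(X, y, term = "dosage") {
  protected <- colnames(X) %in% c("intercept", term)
  const <- !protected & apply(X, 2, function(col) var(col) == 0)
  if (any(const)) X <- X[, !const, drop = FALSE]
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = glm.control(epsilon = 1e-8, maxit = 50L)))
  p <- ncol(X)
  ok <- fit$converged && fit$rank == p
  beta <- se <- pval <- NA_real_
  if (ok) {
    R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
    R[lower.tri(R)] <- 0
    cov <- tryCatch(chol2inv(R), error = function(e) NULL)
    if (is.null(cov)) ok <- FALSE else {
      cov <- cov[order(fit$qr$pivot), order(fit$qr$pivot), drop = FALSE]
      j <- match(term, colnames(X))
      beta <- fit$coefficients[j]
      se <- sqrt(cov[j, j])
      # runaway estimates signal (quasi-)separation
      if (!is.finite(se) || se > 100 || abs(beta) > 15) ok <- FALSE
      else pval <- 2 * pnorm(-abs(beta / se))
    }
  }
  list(beta = unname(beta), se = unname(se), p = unname(pval), ok = ok)
}

#' Per-variant log-additive logistic association
#'
#' Fits `status ~ dosage + covariates` by maximum likelihood (IRLS) and
#' returns the Wald estimate, standard error and two-sided p-value for the
#' dosage term. Samples with missing dosage are dropped for this variant
#' (complete-case per variant).
#'
#' @param dosage effect-allele dosage vector (`NA` = missing).
#' @param status 0/1 case indicator.
#' @param covariates optional numeric matrix/data frame of covariates
#'   (complete for analyzed samples).
#' @return list: `beta`, `se`, `p`, `or` (`exp(beta)`), `n`, `maf` (folded,
#'   over analyzed samples), `ok` (FALSE on separation or non-convergence).
#' @export
fit_snp_logistic <- function(dosage, status, covariates = NULL) {
  keep <- !is.na(dosage)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (anyNA(covariates[keep, , drop = FALSE]))
      stop2("missing covariate values among analyzed samples")
  }
  d <- dosage[keep]; y <- status[keep]
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_, or = NA_real_,
                n = length(y), maf = NA_real_, ok = FALSE))
  X <- cbind(intercept = 1, dosage = d)
  if (!is.null(covariates)) X <- cbind(X, covariates[keep, , drop = FALSE])
  res <- fit_logistic_wald(X, y)
  res$or <- exp(res$beta)
  res$n <- length(y)
  res$maf <- fold_maf(mean(d) / 2)
  res
}

scan_covariate_matrix <- function(samples, pcs) {
  cbind(age = samples$age, female = as.numeric(samples$sex == "F"),
        bmi = samples$bmi, pcs)
}

#' Association scan over strata with MAF and INFO filters
#'
#' For every case-control stratum, fits the per-variant log-additive
#' logistic model adjusted for age, sex, BMI and the first `k_pcs`
#' principal components (computed per population). Variants with folded
#' MAF below `maf_min` in a population (cases + controls pooled) are
#' excluded from that population's strata; variants with imputation INFO at
#' or below `info_min` in a stratum are excluded from that stratum. Effects
#' of catalog index variants are oriented to the reported risk allele.
#'
#' @param cohort a `chd_cohort`, or a list with `dosages`, `samples`,
#'   `variants`, `info`, `catalog`.
#' @param maf_min population MAF filter (inclusive lower bound).
#' @param info_min INFO filter (exclusive lower bound).
#' @param k_pcs number of principal components to adjust for.
#' @param pc_subset_size variant subset size for the PCA.
#' @return data frame of class `assoc_table` with one row per (stratum,
#'   passing variant): `variant_id`, `population`, `stratum`,
#'   `effect_allele`, `beta`, `se`, `p`, `or`, `n`, `maf`, `info`,
#'   `orientation`, `direction`; attribute `exclusions` logs every
#'   (variant, stratum, reason) drop.
#' @export
scan_associations <- function(cohort, maf_min = 0.01, info_min = 0.8,
                              k_pcs = 10L, pc_subset_size = 10000L) {
  samples <- cohort$samples; dosages <- cohort$dosages
  variants <- cohort$variants; info <- cohort$info
  catalog <- cohort$catalog
  stopifnot(all(samples$sample_id == rownames(dosages)))
  pops <- unique(samples$population)
  rows <- list(); excl <- list()
  for (pop in pops) {
    in_pop <- samples$population == pop
    Dp <- dosages[in_pop, , drop = FALSE]
    sp <- samples[in_pop, , drop = FALSE]
    pop_freq <- colMeans(Dp, na.rm = TRUE) / 2
    pop_maf <- fold_maf(pop_freq)
    pcs <- compute_pcs(Dp, subset_size = pc_subset_size, k = k_pcs)
    covars <- scan_covariate_matrix(sp, pcs)
    orient <- orient_catalog(catalog, variants, effect_freq = pop_freq)
    orient_of <- setNames(orient, catalog$index_variant)
    maf_fail <- is.na(pop_maf) | pop_maf < maf_min
    for (st in unique(sp$stratum)) {
      in_st <- sp$stratum == st
      if (sum(sp$status[in_st] == 1L) == 0 ||
          sum(sp$status[in_st] == 0L) == 0) {
        warn2("stratum ", st, " has no cases or no controls; skipped")
        next
      }
      info_st <- info[, st]
      for (j in seq_len(ncol(Dp))) {
        vid <- colnames(Dp)[j]
        if (maf_fail[j]) {
          excl[[length(excl) + 1L]] <-
            data.frame(variant_id = vid, stratum = st, reason = "maf_below_min")
          next
        }
        if (info_st[j] <= info_min) {
          excl[[length(excl) + 1L]] <-
            data.frame(variant_id = vid, stratum = st, reason = "info_below_min")
          next
        }
        fit <- fit_snp_logistic(Dp[in_st, j], sp$status[in_st],
                                covars[in_st, , drop = FALSE])
        if (!fit$ok) {
          excl[[length(excl) + 1L]] <-
            data.frame(variant_id = vid, stratum = st,
                       reason = "fit_failed_or_separated")
          next
        }
        ornt <- if (vid %in% names(orient_of)) orient_of[[vid]] else NA_integer_
        rows[[length(rows) + 1L]] <- data.frame(
          variant_id = vid, population = pop, stratum = st,
          effect_allele = variants$effect_allele[
            match(vid, variants$variant_id)],
          beta = fit$beta, se = fit$se, p = fit$p, or = fit$or,
          n = fit$n, maf = fit$maf, info = info_st[j],
          orientation = ornt,
          direction = if (is.na(ornt)) NA_integer_ else
            as.integer(sign(fit$beta * ornt)),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_id = character(), population = character(),
               stratum = character(), effect_allele = character(),
               beta = numeric(), se = numeric(), p = numeric(),
               or = numeric(), n = integer(), maf = numeric(),
               info = numeric(), orientation = integer(),
               direction = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(variant_id = character(), stratum = character(),
               reason = character())
  class(out) <- c("assoc_table", "data.frame")
  out
}
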