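#' Draw diverged per-population allele frequencies (Balding-Nichols)
#'
#' Population frequencies are drawn from a Beta law with mean equal to the
#' ancestral frequency `p` and variance `fst * p * (1 - p)`, i.e. shapes
#' `p(1-F)/F` and `(1-p)(1-F)/F`. `fst = 0` returns the ancestral frequency
#' unchanged for every population.
#'
#' @param ancestral_freq ancestral allele frequency, strictly in (0, 1).
#' @param fst divergence parameter in `[0, 1)`; scalar or one per population.
#' @param n_pops number of populations.
#' @param seed optional integer seed.
#' @param max_retry bound on redraws of degenerate (exactly 0 or 1) values.
#' @return numeric vector of length `n_pops`.
#' @export
simulate_frequencies <- function(ancestral_freq, fst, n_pops, seed = NULL,
                                 max_retry = 100L) {
  stopifnot(ancestral_freq > 0, ancestral_freq < 1, all(fst >= 0),
            all(fst < 1), n_pops >= 1)
  if (!is.null(seed)) set.seed(seed)
  fst <- rep_len(fst, n_pops)
  p <- ancestral_freq
  out <- numeric(n_pops)
  for (i in seq_len(n_pops)) {
    if (fst[i] == 0) { out[i] <- p; next }
    a <- p * (1 - fst[i]) / fst[i]
    b <- (1 - p) * (1 - fst[i]) / fst[i]
    x <- rbeta(1, a, b)
    tries <- 0L
    while ((x <= 0 || x >= 1) && tries < max_retry) {
      x <- rbeta(1, a, b)
      tries <- tries + 1L
    }
    if (x <= 0 || x >= 1)
      stop2("degenerate frequency persisted after ", max_retry,
            " redraws (ancestral_freq = ", p, ", fst = ", fst[i], ")")
    out[i] <- x
  }
  out
}

# P(Z1 < q1, Z2 < q2) for standard bivariate normal with correlation rho,
# by 1-D quadrature over the conditional normal CDF.
pnorm2 <- function(q1, q2, rho) {
  if (abs(rho) < 1e-12) return(pnorm(q1) * pnorm(q2))
  if (rho > 1 - 1e-10) return(pnorm(min(q1, q2)))
  if (rho < -1 + 1e-10) return(max(0, pnorm(q1) + pnorm(q2) - 1))
  s <- sqrt(1 - rho^2)
  f <- function(z) dnorm(z) * pnorm((q2 - rho * z) / s)
  integrate(f, -8.5, q1, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# Pearson correlation between the binary indicators 1(Z1 < q(f1)), 1(Z2 < q(f2))
binary_corr <- function(f1, f2, rho) {
  q1 <- qnorm(f1); q2 <- qnorm(f2)
  p11 <- pnorm2(q1, q2, rho)
  (p11 - f1 * f2) / sqrt(f1 * (1 - f1) * f2 * (1 - f2))
}

# Latent correlation delivering a target r^2 between thresholded indicators.
# Thresholding attenuates correlation, and unequal frequencies cap the
# attainable r^2; an unattainable target triggers a warning and the maximum.
calibrate_latent_rho <- function(target_r2, f1, f2) {
  if (target_r2 <= 0) return(list(rho = 0, achieved_r2 = 0))
  r_target <- sqrt(target_r2)
  rho_hi <- 0.99999
  r_max <- binary_corr(f1, f2, rho_hi)
  if (r_max^2 < target_r2) {
    warn2(sprintf(
      "target r^2 %.3f unattainable for frequencies %.3f / %.3f; achieved %.3f",
      target_r2, f1, f2, r_max^2))
    return(list(rho = rho_hi, achieved_r2 = r_max^2))
  }
  g <- function(rho) binary_corr(f1, f2, rho) - r_target
  rho <- uniroot(g, c(0, rho_hi), tol = 1e-9)$root
  list(rho = rho, achieved_r2 = binary_corr(f1, f2, rho)^2)
}

region_positions <- function(region) {
  round(seq(region$start, region$end, length.out = region$n_variants))
}

region_variant_ids <- function(region) {
  sprintf("%s_v%02d", region$region_id, seq_len(region$n_variants))
}

# Latent correlation matrix: exponential decay in distance, with the
# index-functional entry overridden by the calibrated value; eigenvalue
# clipping restores positive definiteness after the override.
region_latent_corr <- function(region, rho_if) {
  pos <- region_positions(region)
  C <- exp(-abs(outer(pos, pos, "-")) / region$ld_decay_length)
  i <- region$index_variant; j <- region$functional_variant
  if (i != j) C[i, j] <- C[j, i] <- rho_if
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    vals <- pmax(ev$values, 1e-8)
    C <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(C))
    C <- C / tcrossprod(d)
  }
  C
}

#' Simulate haplotypes for one region in one population
#'
#' Latent-Gaussian threshold model: haplotypes are rows of a zero-mean
#' Gaussian with correlation `exp(-distance / ld_decay_length)`, and the
#' allele at variant *j* is carried when the latent value falls below the
#' frequency quantile `qnorm(freq_j)`. The latent correlation between the
#' region's index and functional variants is calibrated by 1-D search so the
#' thresholded indicators hit the region's `target_r2`.
#'
#' @param region a [region_spec()].
#' @param pop_freqs per-variant allele frequencies in this population
#'   (length `n_variants`, each strictly in (0, 1)).
#' @param n_haplotypes even number of haplotypes (pairs form diploids).
#' @param seed optional integer seed.
#' @return 0/1 matrix `n_haplotypes x n_variants` with variant ids as
#'   column names; attribute `achieved_r2` carries the calibration result.
#' @export
simulate_haplotypes <- function(region, pop_freqs, n_haplotypes, seed = NULL) {
  stopifnot(length(pop_freqs) == region$n_variants,
            all(pop_freqs > 0), all(pop_freqs < 1))
  if (n_haplotypes %% 2L != 0L) stop2("n_haplotypes must be even")
  if (!is.null(seed)) set.seed(seed)
  cal <- if (region$index_variant != region$functional_variant) {
    calibrate_latent_rho(region$target_r2,
                         pop_freqs[region$index_variant],
                         pop_freqs[region$functional_variant])
  } else list(rho = 1, achieved_r2 = 1)
  C <- region_latent_corr(region, cal$rho)
  Z <- matrix(rnorm(n_haplotypes * region$n_variants),
              nrow = n_haplotypes) %*% chol(C)
  H <- sweep(Z, 2, qnorm(pop_freqs), "<") * 1L
  storage.mode(H) <- "integer"
  colnames(H) <- region_variant_ids(region)
  attr(H, "achieved_r2") <- cal$achieved_r2
  H
}

haplotypes_to_dosages <- function(H) {
  n <- nrow(H) %/% 2L
  D <- H[2L * seq_len(n) - 1L, , drop = FALSE] +
    H[2L * seq_len(n), , drop = FALSE]
  storage.mode(D) <- "double"
  D
}

#' Assign case/control status from a logistic disease model
#'
#' Disease labels are drawn from
#' `Bernoulli(plogis(baseline + effects . dosage + covariate terms))` over a
#' large simulated source population; cases and controls are then
#' subsampled to hit each stratum's target counts exactly, mimicking a
#' cohort-nested case-control design. Covariates enter centered at their
#' sample means so `baseline_log_odds` sets the source prevalence.
#'
#' @param dosages samples x variants dosage matrix.
#' @param effects named vector of per-variant log-odds (names must be
#'   columns of `dosages`); zero-length for a null model.
#' @param covariates data frame with columns `age`, `bmi`, `female`.
#' @param cov_betas list with `beta_age`, `beta_bmi`, `beta_female`.
#' @param baseline_log_odds intercept.
#' @param strata_targets data frame with columns `stratum`, `n_cases`,
#'   `n_controls`.
#' @param seed optional integer seed.
#' @return data frame `sample` (row index into `dosages`), `stratum`,
#'   `status` (1 = case); attribute `prevalence` records the realized
#'   pre-subsampling case fraction.
#' @export
assign_phenotypes <- function(dosages, effects, covariates, cov_betas,
                              baseline_log_odds, strata_targets, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(dosages)
  lp <- rep(baseline_log_odds, n)
  if (length(effects)) {
    miss <- setdiff(names(effects), colnames(dosages))
    if (length(miss)) stop2("effects refer to unknown variants: ",
                            paste(miss, collapse = ", "))
    G <- dosages[, names(effects), drop = FALSE]
    # risk terms enter centered (the intercept absorbs the shift) so that
    # baseline_log_odds sets the source prevalence regardless of the
    # number of effect variants
    lp <- lp + as.vector(sweep(G, 2, colMeans(G)) %*% effects)
  }
  lp <- lp + cov_betas$beta_age * (covariates$age - mean(covariates$age)) +
    cov_betas$beta_bmi * (covariates$bmi - mean(covariates$bmi)) +
    cov_betas$beta_female * (covariates$female - mean(covariates$female))
  y <- rbinom(n, 1L, plogis(lp))
  prevalence <- mean(y)
  cases <- sample(which(y == 1L))
  controls <- sample(which(y == 0L))
  need_cases <- sum(strata_targets$n_cases)
  need_controls <- sum(strata_targets$n_controls)
  if (length(cases) < need_cases || length(controls) < need_controls)
    stop2(sprintf(paste0("cannot reach target counts: need %d cases / %d ",
                         "controls, achieved %d / %d (prevalence %.3f)"),
                  need_cases, need_controls, length(cases), length(controls),
                  prevalence))
  out <- vector("list", nrow(strata_targets))
  ci <- 1L; ti <- 1L
  for (s in seq_len(nrow(strata_targets))) {
    nc <- strata_targets$n_cases[s]; nt <- strata_targets$n_controls[s]
    out[[s]] <- data.frame(
      sample = c(cases[ci:(ci + nc - 1L)], controls[ti:(ti + nt - 1L)]),
      stratum = strata_targets$stratum[s],
      status = rep(c(1L, 0L), c(nc, nt)),
      stringsAsFactors = FALSE)
    ci <- ci + nc; ti <- ti + nt
  }
  res <- do.call(rbind, out)
  attr(res, "prevalence") <- prevalence
  res
}

resolve_chip_plan <- function(chip_plan, samples, variant_ids, regions,
                              seed = NULL) {
  if (!length(chip_plan)) return(list())
  if (!is.null(seed)) set.seed(seed)
  default_block <- function() {
    k <- min(20L, length(regions))
    vapply(regions[seq_len(k)], function(r)
      region_variant_ids(r)[r$index_variant], "")
  }
  lapply(chip_plan, function(block) {
    vars <- if (is.null(block$variants)) default_block() else block$variants
    bad <- setdiff(vars, variant_ids)
    if (length(bad)) stop2("chip_plan references unknown variants: ",
                           paste(head(bad, 5), collapse = ", "))
    if (!is.null(block$samples)) {
      ids <- block$samples
      bad <- setdiff(ids, samples$sample_id)
      if (length(bad)) stop2("chip_plan references unknown samples: ",
                             paste(head(bad, 5), collapse = ", "))
    } else {
      pool <- samples$sample_id[samples$population %in% block$populations]
      if (!length(pool)) stop2("chip_plan references unknown populations: ",
                               paste(block$populations, collapse = ", "))
      ids <- sample(pool, round(block$fraction * length(pool)))
    }
    list(samples = ids, variants = vars)
  })
}

#' Apply chip missingness and imputation INFO scores
#'
#' Sets the designated sample-by-variant cells to missing (`NA`) and draws a
#' per-variant, per-stratum INFO score from the configured Beta law.
#'
#' @param dosages samples x variants dosage matrix with sample-id rownames.
#' @param samples sample table with `sample_id`, `population`, `stratum`.
#' @param chip_plan list of blocks, each with `samples` (ids) or
#'   `populations` + `fraction`, and `variants` (`NULL` = canonical block).
#' @param info_model `list(shape1, shape2)` for the Beta draw.
#' @param regions region list (used to resolve the default variant block).
#' @param seed optional integer seed.
#' @return `list(dosages =, info =, chip_missing =)`: the masked matrix, a
#'   variants x strata INFO matrix, and the resolved plan.
#' @export
apply_genotyping_artifacts <- function(dosages, samples, chip_plan,
                                       info_model = list(shape1 = 12,
                                                         shape2 = 1.2),
                                       regions = list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  plan <- resolve_chip_plan(chip_plan, samples, colnames(dosages), regions)
  for (block in plan)
    dosages[match(block$samples, rownames(dosages)), block$variants] <- NA
  strata <- unique(samples$stratum)
  info <- matrix(rbeta(ncol(dosages) * length(strata),
                       info_model$shape1, info_model$shape2),
                 nrow = ncol(dosages),
                 dimnames = list(colnames(dosages), strata))
  list(dosages = dosages, info = info, chip_missing = plan)
}

#' Simulate a complete multi-population case-control cohort
#'
#' Runs the full generator: Balding-Nichols per-population frequencies for
#' every variant, latent-Gaussian haplotypes per region and population,
#' diploid dosages, covariates, logistic phenotypes subsampled to the exact
#' stratum targets, chip missingness, INFO scores, and the locus catalog
#' (index variant per region, its effect allele as the reported risk
#' allele, and the configured reported odds ratio).
#'
#' @param config a [sim_config()].
#' @return an object of class `chd_cohort`: list with `samples`, `variants`,
#'   `dosages` (samples x variants, `NA` = missing), `info`
#'   (variants x strata), `catalog`, `truth`, `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pops <- config$pop_labels
  n_pops <- length(pops)
  regions <- config$regions

  # per-variant ancestral and diverged frequencies
  freq_list <- lapply(regions, function(r) {
    anc <- r$ancestral_freqs
    if (is.null(anc)) anc <- runif(r$n_variants, 0.05, 0.95)
    F <- t(vapply(anc, function(p)
      simulate_frequencies(p, config$fst_per_pop, n_pops), numeric(n_pops)))
    rownames(F) <- region_variant_ids(r)
    colnames(F) <- pops
    attr(F, "ancestral") <- anc
    F
  })
  freqs <- do.call(rbind, freq_list)
  variant_ids <- rownames(freqs)

  # fixed alleles per variant (effect allele = ALT); palindromic (A/T, C/G)
  # pairs are avoided so synthetic strand orientation is always resolvable
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, length(variant_ids), replace = TRUE)
  alt <- vapply(ref, function(b)
    sample(setdiff(bases, c(b, complement_allele(b))), 1), "")

  effects <- vapply(regions, function(r) log(r$or_functional), 0)
  names(effects) <- vapply(regions, function(r)
    region_variant_ids(r)[r$functional_variant], "")
  effects <- effects[effects != 0]

  samples_list <- list(); dosage_list <- list()
  achieved_r2 <- matrix(NA_real_, length(regions), n_pops,
                        dimnames = list(vapply(regions, `[[`, "", "region_id"),
                                        pops))
  prevalence <- setNames(numeric(n_pops), pops)
  for (i in seq_len(n_pops)) {
    n_target <- config$n_cases[i] + config$n_controls[i]
    n_source <- ceiling(config$source_multiplier * n_target)
    D <- matrix(0, n_source, 0)
    for (j in seq_along(regions)) {
      H <- simulate_haplotypes(regions[[j]], freq_list[[j]][, i],
                               2L * n_source)
      achieved_r2[j, i] <- attr(H, "achieved_r2")
      D <- cbind(D, haplotypes_to_dosages(H))
    }
    cv <- config$covariates
    covars <- data.frame(
      age = rnorm(n_source, cv$age_mean, cv$age_sd),
      bmi = rnorm(n_source, cv$bmi_mean, cv$bmi_sd),
      female = rbinom(n_source, 1L, cv$female_fraction))
    plan <- config$strata_plan[[pops[i]]]
    pheno <- assign_phenotypes(D, effects, covars, cv,
                               config$baseline_log_odds, plan)
    prevalence[i] <- attr(pheno, "prevalence")
    idx <- pheno$sample
    sid <- sprintf("%s_%05d", pops[i], seq_along(idx))
    Dsel <- D[idx, , drop = FALSE]
    rownames(Dsel) <- sid
    dosage_list[[i]] <- Dsel
    cond <- plan$prior_condition[match(pheno$stratum, plan$stratum)]
    samples_list[[i]] <- data.frame(
      sample_id = sid, population = pops[i], stratum = pheno$stratum,
      status = pheno$status, sex = ifelse(covars$female[idx] == 1L, "F", "M"),
      age = round(covars$age[idx], 1), bmi = round(covars$bmi[idx], 1),
      prior_condition = cond,
      has_claims = as.logical(
        rbinom(length(idx), 1L,
               ifelse(pheno$status == 1L, 0.95, config$claims_fraction))),
      stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, samples_list)
  rownames(samples) <- NULL
  dosages <- do.call(rbind, dosage_list)

  art <- apply_genotyping_artifacts(dosages, samples, config$chip_plan,
                                    config$info_model, regions)

  region_of <- rep(vapply(regions, `[[`, "", "region_id"),
                   vapply(regions, `[[`, 0L, "n_variants"))
  pos <- unlist(lapply(regions, region_positions), use.names = FALSE)
  chrom <- rep(vapply(regions, `[[`, "", "chrom"),
               vapply(regions, `[[`, 0L, "n_variants"))
  is_index <- variant_ids %in% vapply(regions, function(r)
    region_variant_ids(r)[r$index_variant], "")
  is_functional <- variant_ids %in% vapply(regions, function(r)
    region_variant_ids(r)[r$functional_variant], "")
  variants <- data.frame(
    variant_id = variant_ids, chrom = chrom, pos = pos,
    other_allele = unname(ref), effect_allele = unname(alt),
    region_id = region_of, is_index = is_index,
    is_functional = is_functional, stringsAsFactors = FALSE)
  for (p in pops) variants[[paste0("freq_", p)]] <- unname(freqs[, p])

  ancestral <- unlist(lapply(freq_list, attr, "ancestral"), use.names = FALSE)
  catalog <- do.call(rbind, lapply(regions, function(r) {
    iv <- region_variant_ids(r)[r$index_variant]
    data.frame(region_id = r$region_id, index_variant = iv,
               risk_allele = variants$effect_allele[match(iv, variant_ids)],
               reported_or = r$reported_or,
               risk_allele_freq = ancestral[match(iv, variant_ids)],
               chrom = r$chrom, start = r$start, end = r$end,
               source_population = "EUR", stringsAsFactors = FALSE)
  }))
  rownames(catalog) <- NULL

  structure(list(samples = samples, variants = variants,
                 dosages = art$dosages, info = art$info, catalog = catalog,
                 truth = list(freqs = freqs, effects = effects,
                              achieved_r2 = achieved_r2,
                              prevalence = prevalence,
                              chip_missing = art$chip_missing),
                 config = config),
            class = "chd_cohort")
}

#' @export
print.chd_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic cohort: %d samples (%d cases / %d controls), %d populations\n",
    nrow(x$samples), sum(x$samples$status == 1L),
    sum(x$samples$status == 0L), length(unique(x$samples$population))))
  cat(sprintf("  %d variants in %d regions, %d strata\n",
              nrow(x$variants), length(unique(x$variants$region_id)),
              length(unique(x$samples$stratum))))
  invisible(x)
}
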