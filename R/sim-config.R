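#' Describe one susceptibility region for the cohort simulator
#'
#' A region is a window of correlated variants containing a designated
#' *index* variant (the one a discovery GWAS would have reported) and a
#' *functional* variant (the one actually carrying the disease effect),
#' linked at a target squared correlation. Pairwise LD among the remaining
#' variants decays exponentially with physical distance.
#'
#' @param region_id character label, unique within a configuration.
#' @param chrom chromosome label.
#' @param start,end 1-based inclusive base-pair window, `start < end`.
#' @param n_variants number of variants in the region (>= 1).
#' @param ancestral_freqs ancestral (pre-divergence) allele frequencies of
#'   the effect alleles; scalar recycled, or vector of length `n_variants`,
#'   or `NULL` to draw uniformly on `[0.05, 0.95]` at simulation time.
#' @param ld_decay_length e-folding distance (bp) of the latent correlation.
#' @param index_variant,functional_variant indices (1-based, within region)
#'   of the index and functional variants; defaults put them adjacent near
#'   the middle of the region.
#' @param target_r2 target squared correlation between index and functional
#'   variants (applied in each population at that population's frequencies;
#'   the achieved value is reported in the simulation truth).
#' @param or_functional per-allele odds ratio carried by the functional
#'   variant (> 0; 1 = null region).
#' @param reported_or odds ratio the locus catalog will report for the index
#'   variant; defaults to `or_functional`.
#' @return an object of class `region_spec`.
#' @export
region_spec <- function(region_id, chrom = "1", start = 1e6, end = 2e6,
                        n_variants = 30, ancestral_freqs = NULL,
                        ld_decay_length = 1e5,
                        index_variant = NULL, functional_variant = NULL,
                        target_r2 = 0.9, or_functional = 1.12,
                        reported_or = or_functional) {
  stopifnot(length(region_id) == 1, n_variants >= 1, start < end,
            ld_decay_length > 0)
  if (!is.null(ancestral_freqs)) {
    ancestral_freqs <- rep_len(ancestral_freqs, n_variants)
    if (any(ancestral_freqs <= 0 | ancestral_freqs >= 1))
      stop2("ancestral_freqs must lie strictly in (0, 1)")
  }
  if (is.null(index_variant)) index_variant <- max(1L, n_variants %/% 2L)
  if (is.null(functional_variant))
    functional_variant <- if (n_variants > 1) index_variant + 1L else index_variant
  if (index_variant > n_variants || functional_variant > n_variants)
    stop2("index/functional variant index outside the region")
  if (target_r2 < 0 || target_r2 > 1) stop2("target_r2 must be in [0, 1]")
  if (or_functional <= 0 || reported_or <= 0) stop2("odds ratios must be > 0")
  structure(list(region_id = region_id, chrom = as.character(chrom),
                 start = start, end = end, n_variants = as.integer(n_variants),
                 ancestral_freqs = ancestral_freqs,
                 ld_decay_length = ld_decay_length,
                 index_variant = as.integer(index_variant),
                 functional_variant = as.integer(functional_variant),
                 target_r2 = target_r2, or_functional = or_functional,
                 reported_or = reported_or),
            class = "region_spec")
}

#' Build a default set of regions echoing a 65-region catalog
#'
#' @param n_regions number of regions.
#' @param n_variants variants per region.
#' @param or_functional per-allele odds ratio shared by the functional
#'   variants (scalar or vector of length `n_regions`).
#' @param target_r2 index-functional target squared correlation.
#' @param ld_decay_length latent-correlation e-folding distance in bp.
#' @return list of [region_spec()] objects.
#' @export
default_regions <- function(n_regions = 65, n_variants = 30,
                            or_functional = 1.12, target_r2 = 0.9,
                            ld_decay_length = 1e5) {
  or_functional <- rep_len(or_functional, n_regions)
  lapply(seq_len(n_regions), function(i)
    region_spec(region_id = sprintf("R%02d", i),
                chrom = as.character((i - 1L) %% 22L + 1L),
                start = 1e6 + (i - 1) * 3e6, end = 2e6 + (i - 1) * 3e6,
                n_variants = n_variants,
                ld_decay_length = ld_decay_length,
                target_r2 = target_r2, or_functional = or_functional[i]))
}

default_strata_plan <- function(pop_labels, n_cases, n_controls,
                                n_strata_per_pop = 6L) {
  conditions <- rep_len(c("breast", "prostate", "diabetes"), n_strata_per_pop)
  plan <- list()
  for (i in seq_along(pop_labels)) {
    nc <- even_split(n_cases[i], n_strata_per_pop)
    nt <- even_split(n_controls[i], n_strata_per_pop)
    plan[[pop_labels[i]]] <- data.frame(
      stratum = sprintf("%s.s%d", pop_labels[i], seq_len(n_strata_per_pop)),
      population = pop_labels[i],
      prior_condition = conditions,
      n_cases = nc, n_controls = nt,
      stringsAsFactors = FALSE)
  }
  plan
}

even_split <- function(n, k) {
  base <- n %/% k
  out <- rep(base, k)
  extra <- n - base * k
  if (extra > 0) out[seq_len(extra)] <- out[seq_len(extra)] + 1L
  as.integer(out)
}

#' Configuration for the synthetic multi-population cohort
#'
#' Defaults describe the study design the package is built around: three
#' non-European populations diverged from a common ancestral frequency
#' (Balding-Nichols), roughly 2,000 cases and 3,500 controls each, six
#' nested case-control strata per population (18 overall), 65 regions of 30
#' variants, and a chip plan under which a subset of samples in the first
#' and third populations is missing a fixed block of score variants
#' (emulating a Metabochip-style subset).
#'
#' @param pop_labels population labels.
#' @param n_cases,n_controls per-population target counts (same length as
#'   `pop_labels`).
#' @param fst_per_pop per-population divergence from the ancestral
#'   frequency, each in `[0, 1)`.
#' @param regions list of [region_spec()] objects.
#' @param n_strata_per_pop case-control strata per population.
#' @param strata_plan explicit plan (list of per-population data frames with
#'   columns stratum/population/prior_condition/n_cases/n_controls); default
#'   splits population totals evenly.
#' @param chip_plan list of blocks, each
#'   `list(populations =, fraction =, variants =)`; `variants = NULL` means
#'   the index variants of the first 20 regions (the canonical missing score
#'   block). `chip_plan = list()` disables chip missingness.
#' @param info_model `list(shape1 =, shape2 =)` Beta law for per-variant,
#'   per-stratum imputation INFO scores; the default (Beta(12, 1.2), mean
#'   0.91) leaves roughly a tenth of draws below the 0.8 filter so the
#'   filter is exercised.
#' @param covariates means/SDs and log-odds coefficients for age, BMI and
#'   sex (female indicator).
#' @param baseline_log_odds intercept of the logistic disease model at
#'   covariate means and zero risk dosage.
#' @param source_multiplier size of the simulated source population per
#'   population, as a multiple of `n_cases + n_controls` (cohort-nested
#'   subsampling happens from this pool).
#' @param claims_fraction fraction of controls carrying health-care claims
#'   records (drives the claims-restricted sensitivity filter).
#' @param seed integer master seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(pop_labels = c("african_american", "latino", "japanese"),
                       n_cases = c(2000L, 2000L, 2000L),
                       n_controls = c(3500L, 3500L, 3500L),
                       fst_per_pop = c(0.15, 0.08, 0.12),
                       regions = default_regions(),
                       n_strata_per_pop = 6L,
                       strata_plan = NULL,
                       chip_plan = list(list(populations = pop_labels[c(1, 3)],
                                             fraction = 0.3,
                                             variants = NULL)),
                       info_model = list(shape1 = 12, shape2 = 1.2),
                       covariates = list(age_mean = 60, age_sd = 8,
                                         bmi_mean = 27, bmi_sd = 4.5,
                                         female_fraction = 0.5,
                                         beta_age = 0.04, beta_bmi = 0.03,
                                         beta_female = -0.3),
                       baseline_log_odds = qlogis(0.4),
                       source_multiplier = 1.6,
                       claims_fraction = 0.74,
                       seed = 1L) {
  n_pops <- length(pop_labels)
  n_cases <- as.integer(rep_len(n_cases, n_pops))
  n_controls <- as.integer(rep_len(n_controls, n_pops))
  fst_per_pop <- rep_len(fst_per_pop, n_pops)
  if (any(n_cases <= 0) || any(n_controls <= 0)) stop2("counts must be > 0")
  if (any(fst_per_pop < 0 | fst_per_pop >= 1)) stop2("fst must be in [0, 1)")
  if (claims_fraction < 0 || claims_fraction > 1)
    stop2("claims_fraction must be in [0, 1]")
  if (anyDuplicated(vapply(regions, `[[`, "", "region_id")))
    stop2("duplicated region ids")
  if (is.null(strata_plan))
    strata_plan <- default_strata_plan(pop_labels, n_cases, n_controls,
                                       n_strata_per_pop)
  for (i in seq_len(n_pops)) {
    pl <- strata_plan[[pop_labels[i]]]
    if (is.null(pl)) stop2("strata_plan missing population ", pop_labels[i])
    if (sum(pl$n_cases) != n_cases[i] || sum(pl$n_controls) != n_controls[i])
      stop2("strata counts do not sum to population totals for ",
            pop_labels[i])
  }
  structure(list(pop_labels = pop_labels, n_cases = n_cases,
                 n_controls = n_controls, fst_per_pop = fst_per_pop,
                 regions = regions, strata_plan = strata_plan,
                 chip_plan = chip_plan, info_model = info_model,
                 covariates = covariates,
                 baseline_log_odds = baseline_log_odds,
                 source_multiplier = source_multiplier,
                 claims_fraction = claims_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}
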