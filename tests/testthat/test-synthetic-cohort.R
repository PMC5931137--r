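test_that("Balding-Nichols draws match the Beta moments and the zero-divergence identity", {
  expect_identical(simulate_frequencies(0.3, 0, 3), rep(0.3, 3))

  set.seed(101)
  x <- replicate(10000, simulate_frequencies(0.3, 0.1, 1))
  expect_equal(mean(x), 0.3, tolerance = 0.02)
  # Beta(p(1-F)/F, (1-p)(1-F)/F) variance = F p (1 - p) = 0.021
  expect_equal(var(x), 0.021, tolerance = 0.10)

  # strong divergence concentrates mass near fixation/loss
  set.seed(102)
  y <- replicate(2000, simulate_frequencies(0.5, 0.99, 1))
  expect_gt(mean(y < 0.05 | y > 0.95), 0.8)

  expect_error(simulate_frequencies(0, 0.1, 2))
  expect_error(simulate_frequencies(0.3, 1, 2))
})

test_that("latent-Gaussian haplotypes hit target frequencies and calibrated index-functional r2", {
  r <- region_spec("T1", start = 1e6, end = 1.1e6, n_variants = 2,
                   ancestral_freqs = 0.3, target_r2 = 0.8,
                   index_variant = 1, functional_variant = 2)
  H <- simulate_haplotypes(r, c(0.3, 0.3), 20000, seed = 7)
  expect_true(all(H %in% c(0L, 1L)))
  # column frequencies within 3 binomial SDs of the target
  sd3 <- 3 * sqrt(0.3 * 0.7 / 20000)
  expect_true(all(abs(colMeans(H) - 0.3) < sd3))
  r2 <- cor(H[, 1], H[, 2])^2
  expect_gte(r2, 0.75)
  expect_lte(r2, 0.85)

  # distance far beyond the decay length: independence
  rfar <- region_spec("T2", start = 1e6, end = 2e6, n_variants = 2,
                      ld_decay_length = 10,
                      index_variant = 1, functional_variant = 1)
  Hf <- simulate_haplotypes(rfar, c(0.4, 0.4), 20000, seed = 8)
  expect_lt(cor(Hf[, 1], Hf[, 2])^2, 0.002)

  # identical latent variable (zero effective distance): near-complete coupling
  expect_gt(binary_corr(0.3, 0.3, 0.99999)^2, 0.99)

  # infeasible target given a strong frequency mismatch: warn, report achieved
  expect_warning(cal <- calibrate_latent_rho(0.9, 0.05, 0.6),
                 "unattainable")
  expect_lt(cal$achieved_r2, 0.9)

  expect_error(simulate_haplotypes(r, c(0.3, 0.3), 101), "even")
})

test_that("phenotype assignment draws the logistic model and hits stratum targets exactly", {
  set.seed(9)
  n <- 6000
  D <- matrix(rbinom(n, 2, 0.3), ncol = 1,
              dimnames = list(NULL, "v1"))
  covars <- data.frame(age = rnorm(n, 60, 8), bmi = rnorm(n, 27, 4),
                       female = rbinom(n, 1, 0.5))
  betas <- list(beta_age = 0, beta_bmi = 0, beta_female = 0)
  targets <- data.frame(stratum = c("s1", "s2"),
                        n_cases = c(100L, 150L), n_controls = c(200L, 250L))
  ph <- assign_phenotypes(D, numeric(0), covars, betas,
                          baseline_log_odds = 0, targets, seed = 10)
  # null effects, baseline 0: source prevalence near logistic(0) = 1/2
  expect_equal(attr(ph, "prevalence"), 0.5, tolerance = 0.04)
  counts <- table(ph$stratum, ph$status)
  expect_identical(as.vector(counts[, "1"]), c(100L, 150L))
  expect_identical(as.vector(counts[, "0"]), c(200L, 250L))
  expect_false(anyDuplicated(ph$sample) > 0)

  # unreachable targets signal the achieved counts
  big <- data.frame(stratum = "s1", n_cases = n, n_controls = n)
  expect_error(assign_phenotypes(D, numeric(0), covars, betas, 0, big),
               "achieved")
  expect_error(assign_phenotypes(D, c(nope = 0.5), covars, betas, 0,
                                 targets), "unknown variants")
})

test_that("genotyping artifacts mask exactly the planned cells; the empty plan is an identity", {
  co <- test_cohort()
  samples <- co$samples
  D <- co$dosages
  D[is.na(D)] <- 1  # start from a complete matrix

  art0 <- apply_genotyping_artifacts(D, samples, chip_plan = list(),
                                     seed = 1)
  expect_identical(art0$dosages, D)

  ids <- samples$sample_id[samples$population == "latino"][1:10]
  vars <- colnames(D)[1:3]
  art <- apply_genotyping_artifacts(
    D, samples, chip_plan = list(list(samples = ids, variants = vars)),
    seed = 1)
  expect_true(all(is.na(art$dosages[ids, vars])))
  expect_identical(sum(is.na(art$dosages)), length(ids) * length(vars))
  expect_true(all(dim(art$info) == c(ncol(D),
                                     length(unique(samples$stratum)))))
  expect_true(all(art$info >= 0 & art$info <= 1))

  expect_error(apply_genotyping_artifacts(
    D, samples, chip_plan = list(list(samples = ids, variants = "nope"))),
    "unknown variants")
  expect_error(apply_genotyping_artifacts(
    D, samples, chip_plan = list(list(samples = "ghost", variants = vars))),
    "unknown samples")
})

test_that("the generator is deterministic and produces diploid dosages", {
  cfg <- small_config(seed = 77)
  a <- suppressWarnings(simulate_cohort(cfg))
  b <- suppressWarnings(simulate_cohort(cfg))
  expect_identical(a, b)
  d <- a$dosages
  expect_true(all(d[!is.na(d)] %in% c(0, 1, 2)))
  # strata plan respected exactly
  tab <- table(a$samples$stratum, a$samples$status)
  plan <- do.call(rbind, cfg$strata_plan)
  expect_identical(as.vector(tab[plan$stratum, "1"]), plan$n_cases)
  expect_identical(as.vector(tab[plan$stratum, "0"]), plan$n_controls)
  # chip plan: masked samples are missing the score block exactly
  blk <- a$truth$chip_missing[[1]]
  expect_true(all(is.na(d[blk$samples, blk$variants])))
  expect_false(anyNA(d[setdiff(rownames(d), blk$samples), ]))
})

test_that("realized population frequencies track the Balding-Nichols draws", {
  co <- test_cohort()
  for (pop in unique(co$samples$population)) {
    rows <- co$samples$sample_id[co$samples$population == pop]
    realized <- colMeans(co$dosages[rows, , drop = FALSE], na.rm = TRUE) / 2
    target <- co$truth$freqs[, pop]
    n_chrom <- 2 * length(rows)
    z <- abs(realized - target) / sqrt(target * (1 - target) / n_chrom)
    # ~99.7% of variants inside 3 binomial SDs
    expect_gt(mean(z < 3), 0.95)
  }
})
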