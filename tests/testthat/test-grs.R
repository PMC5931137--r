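toy_score_setup <- function() {
  variants <- data.frame(variant_id = c("v1", "v2"),
                         effect_allele = c("A", "C"),
                         other_allele = c("G", "T"),
                         stringsAsFactors = FALSE)
  dosages <- matrix(c(1, 0, 2, 2, 0, 1), nrow = 3,
                    dimnames = list(c("s1", "s2", "s3"), c("v1", "v2")))
  samples <- data.frame(sample_id = c("s1", "s2", "s3"),
                        population = "popA", stringsAsFactors = FALSE)
  def <- data.frame(region_id = c("R1", "R2"), variant_id = c("v1", "v2"),
                    risk_allele = c("A", "C"), mode = "base",
                    provenance = "test", stringsAsFactors = FALSE)
  list(variants = variants, dosages = dosages, samples = samples, def = def)
}

test_that("risk scores are risk-allele dosage sums with correct flips and bounds", {
  s <- toy_score_setup()
  prof <- build_score(s$dosages, s$def, s$variants, s$samples)
  expect_equal(prof$score, c(3, 0, 3))  # s1: 1 + 2; s2: 0 + 0; s3: 2 + 1
  expect_true(all(prof$score >= 0 & prof$score <= 4))

  # risk allele on the other strand of coding: dosage flips to 2 - d
  def_flip <- s$def
  def_flip$risk_allele <- c("G", "T")
  prof_flip <- build_score(s$dosages, def_flip, s$variants, s$samples)
  expect_equal(prof_flip$score, 4 - prof$score)

  bad <- s$def; bad$risk_allele[1] <- "T"
  expect_error(build_score(s$dosages, bad, s$variants, s$samples),
               "not an allele")
  bad2 <- s$def; bad2$variant_id[1] <- "ghost"
  expect_error(build_score(s$dosages, bad2, s$variants, s$samples),
               "absent")
})

test_that("scores are additive over definitions and invariant to sample order", {
  co <- test_cohort()
  cat1 <- co$catalog[1:3, ]; cat2 <- co$catalog[4:6, ]
  p1 <- build_score(co$dosages, score_definition(cat1), co$variants,
                    co$samples)
  p2 <- build_score(co$dosages, score_definition(cat2), co$variants,
                    co$samples)
  p12 <- build_score(co$dosages, score_definition(co$catalog[1:6, ]),
                     co$variants, co$samples)
  expect_equal(p12$score, p1$score + p2$score, tolerance = 1e-10)

  perm <- sample(nrow(co$dosages))
  pp <- build_score(co$dosages[perm, ], score_definition(cat1),
                    co$variants, co$samples[perm, ])
  expect_equal(pp$score[match(p1$sample_id, pp$sample_id)], p1$score,
               tolerance = 1e-10)
})

test_that("block missingness excludes samples and sporadic gaps are imputed at 2x frequency", {
  s <- toy_score_setup()
  D <- s$dosages
  D["s1", ] <- NA            # missing both score variants
  D["s2", "v2"] <- NA        # sporadic
  prof <- build_score(D, s$def, s$variants, s$samples, missing_exclude = 2L)
  expect_false(prof$included[1])
  expect_identical(prof$reason[1], "missing_score_block")
  expect_true(all(prof$included[2:3]))
  # within-population frequency of v2 from the remaining carrier: 1/2
  expect_equal(prof$score[2], 0 + 2 * (1 / 2), tolerance = 1e-10)
})

test_that("lead-SNP substitution follows the replication calls and observed effect signs", {
  co <- test_cohort()
  calls <- data.frame(region_id = co$catalog$region_id,
                      replicated = FALSE, best_proxy = NA_character_,
                      stringsAsFactors = FALSE)
  results <- data.frame(variant_id = co$variants$variant_id,
                        beta = 0.2, effect_allele = co$variants$effect_allele,
                        stringsAsFactors = FALSE)
  # no region replicated: identical to the base definition
  def0 <- substitute_leads(co$catalog, calls, results, co$variants)
  base <- score_definition(co$catalog)
  expect_identical(def0$variant_id, base$variant_id)
  expect_identical(def0$risk_allele, base$risk_allele)

  # one replicated region with a positive-effect proxy
  lead <- co$variants$variant_id[co$variants$region_id == "R02" &
                                   !co$variants$is_index][1]
  calls$replicated[calls$region_id == "R02"] <- TRUE
  calls$best_proxy[calls$region_id == "R02"] <- lead
  def1 <- substitute_leads(co$catalog, calls, results, co$variants)
  i <- which(def1$region_id == "R02")
  expect_identical(def1$variant_id[i], lead)
  expect_identical(def1$risk_allele[i],
                   co$variants$effect_allele[
                     match(lead, co$variants$variant_id)])
  expect_identical(def1$variant_id[-i], base$variant_id[-i])

  # a negative observed effect makes the other allele the risk allele
  results$beta[results$variant_id == lead] <- -0.3
  def2 <- substitute_leads(co$catalog, calls, results, co$variants)
  expect_identical(def2$risk_allele[i],
                   co$variants$other_allele[
                     match(lead, co$variants$variant_id)])
})

test_that("distribution comparison reproduces the closed-form Welch t statistic", {
  set.seed(71)
  samples <- data.frame(
    sample_id = sprintf("s%03d", 1:300),
    population = rep(c("pA", "pB"), each = 150),
    status = rep(rep(c(1L, 0L), each = 75), 2))
  profiles <- data.frame(sample_id = samples$sample_id,
                         score = rnorm(300, 67, 4) +
                           2 * (samples$population == "pB"),
                         n_missing = 0L, included = TRUE, reason = "")
  cmp <- compare_distributions(profiles, samples)
  for (i in seq_len(nrow(cmp$table))) {
    row <- cmp$table[i, ]
    sub <- merge(profiles, samples)[merge(profiles, samples)$population ==
                                      row$population, ]
    ca <- sub$score[sub$status == 1]; cn <- sub$score[sub$status == 0]
    tstat <- (mean(ca) - mean(cn)) /
      sqrt(var(ca) / length(ca) + var(cn) / length(cn))
    df <- (var(ca) / length(ca) + var(cn) / length(cn))^2 /
      ((var(ca) / length(ca))^2 / (length(ca) - 1) +
         (var(cn) / length(cn))^2 / (length(cn) - 1))
    expect_equal(row$t_p, 2 * pt(-abs(tstat), df), tolerance = 1e-10)
  }
  # histogram counts account for every included sample
  counts <- tapply(cmp$hist$count, cmp$hist$population, sum)
  expect_identical(as.vector(counts), c(150L, 150L))

  # separation by 5 SDs is decisive
  shifted <- profiles
  shifted$score[samples$status == 1] <- shifted$score[samples$status == 1] + 20
  cmp2 <- compare_distributions(shifted, samples)
  expect_true(all(cmp2$table$t_p < 1e-10))
})

test_that("risk-score association returns the reference quartile and a null continuous OR", {
  set.seed(72)
  n <- 2400
  samples <- data.frame(sample_id = sprintf("s%04d", 1:n),
                        population = "popA",
                        status = rbinom(n, 1, 0.4),
                        age = rnorm(n, 60, 8),
                        sex = rep(c("M", "F"), n / 2),
                        bmi = rnorm(n, 27, 4))
  profiles <- data.frame(sample_id = samples$sample_id,
                         score = rnorm(n, 67, 4.7),
                         n_missing = 0L, included = TRUE, reason = "")
  res <- grs_association(profiles, samples)
  q1 <- res[res$term == "Q1", ]
  expect_identical(q1$or, 1)  # exact reference contract
  cont <- res[res$term == "per_allele", ]
  expect_true(cont$ok)
  expect_equal(cont$or, 1, tolerance = 0.03)  # null score
  q4 <- res[res$term == "Q4", ]
  expect_true(is.finite(q4$or))
})
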