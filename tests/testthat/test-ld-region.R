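test_that("dosage r2 matches the haplotype-table formula on enumerable tables", {
  x <- c(0, 1, 2, 1, 0, 2, 1, 1)
  expect_equal(r2_from_dosages(x, x), 1)

  # perfectly coupled haplotypes AB/ab at 50/50
  v <- haplotype_vectors(50, 0, 0, 50)
  expect_equal(r2_from_dosages(v$x, v$y), 1)

  # four equifrequent haplotypes: linkage equilibrium
  v <- haplotype_vectors(25, 25, 25, 25)
  expect_equal(r2_from_dosages(v$x, v$y), 0)

  # textbook D^2/(pA pa pB pb) equivalence across haplotype tables
  set.seed(61)
  for (i in 1:20) {
    n <- sample(4, 50, replace = TRUE)
    tab <- as.vector(rmultinom(1, 200, c(0.4, 0.2, 0.1, 0.3)))
    if (any(c(tab[1] + tab[2], tab[3] + tab[4],
              tab[1] + tab[3], tab[2] + tab[4]) == 0)) next
    v <- haplotype_vectors(tab[1], tab[2], tab[3], tab[4])
    if (var(v$x) == 0 || var(v$y) == 0) next
    expect_equal(r2_from_dosages(v$x, v$y),
                 haplotype_r2(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
  }

  expect_warning(r2_from_dosages(rep(1, 10), rbinom(10, 2, 0.5)),
                 "monomorphic")
  expect_error(r2_from_dosages(c(1, NA), c(NA, 1)), "fewer than 2")
})

test_that("proxy sets use the inclusive threshold and match brute-force recomputation", {
  co <- test_cohort()
  panel <- co$dosages[co$samples$status == 0L, , drop = FALSE]
  region_vars <- co$variants$variant_id[co$variants$region_id == "R01"]
  index <- co$catalog$index_variant[co$catalog$region_id == "R01"]

  ps <- proxy_set(panel, index, r2_min = 0.4, candidate_ids = region_vars)
  expect_true(index %in% ps)
  # brute-force oracle
  brute <- region_vars[vapply(region_vars, function(v) {
    if (v == index) return(TRUE)
    ok <- !is.na(panel[, index]) & !is.na(panel[, v])
    r2 <- suppressWarnings(cor(panel[ok, index], panel[ok, v])^2)
    !is.na(r2) && r2 >= 0.4
  }, TRUE)]
  expect_setequal(ps, brute)

  # region where only the index exists
  expect_identical(proxy_set(panel, index, candidate_ids = index), index)
  expect_error(proxy_set(panel, "ghost"), "absent")
})

test_that("greedy tag bins partition the eligible set and handle the two degenerate extremes", {
  set.seed(62)
  # three near-copies: one bin
  base <- rbinom(300, 2, 0.4)
  flip <- function(x, k) { i <- sample(length(x), k); x[i] <- 2 - x[i]; x }
  panel1 <- cbind(a = base, b = flip(base, 3), c = flip(base, 4))
  bins1 <- greedy_tag_bins(panel1)
  expect_identical(bins1$n_tags, 1L)
  expect_setequal(bins1$bins[[1]], c("a", "b", "c"))

  # mutually independent variants: all singletons
  panel2 <- cbind(a = rbinom(300, 2, 0.3), b = rbinom(300, 2, 0.5),
                  c = rbinom(300, 2, 0.4), d = rbinom(300, 2, 0.2))
  bins2 <- greedy_tag_bins(panel2)
  expect_identical(bins2$n_tags, 4L)

  # partition and threshold monotonicity on simulated LD blocks
  co <- test_cohort()
  panel <- co$dosages[co$samples$status == 0L &
                        co$samples$population == "african_american", ,
                      drop = FALSE]
  for (region in unique(co$variants$region_id)[1:3]) {
    ids <- co$variants$variant_id[co$variants$region_id == region]
    res <- greedy_tag_bins(panel, candidate_ids = ids)
    members <- unlist(res$bins, use.names = FALSE)
    expect_setequal(members, res$eligible)        # full cover
    expect_identical(anyDuplicated(members), 0L)  # no overlap
    n_loose <- greedy_tag_bins(panel, r2_tag = 0.5,
                               candidate_ids = ids)$n_tags
    expect_lte(n_loose, res$n_tags)  # relaxing the threshold merges bins
  }
})

test_that("greedy binning matches an independent brute-force implementation", {
  set.seed(63)
  for (i in 1:10) {
    cfg_region <- region_spec(sprintf("B%d", i), start = 1e6,
                              end = 1e6 + 2e5,
                              n_variants = sample(3:10, 1),
                              ld_decay_length = sample(c(3e4, 1e5), 1),
                              target_r2 = 0.7)
    f <- runif(cfg_region$n_variants, 0.1, 0.9)
    H <- suppressWarnings(simulate_haplotypes(cfg_region, f, 800))
    panel <- haplotypes_to_dosages(H)
    ours <- greedy_tag_bins(panel)
    brute <- brute_tag_bins(panel)
    expect_identical(ours$n_tags, length(brute))
    expect_setequal(ours$tags, names(brute))
    for (tag in ours$tags)
      expect_setequal(ours$bins[[tag]], brute[[tag]])
  }
})

test_that("regional replication uses the tag-count-derived alpha threshold", {
  call1 <- regional_replication(c(v1 = 0.049), "v1", n_tags = 1)
  expect_true(call1$replicated)
  expect_equal(call1$alpha_region, 0.05)

  call2 <- regional_replication(c(v1 = 0.006, v2 = 0.2), c("v1", "v2"),
                                n_tags = 10)
  expect_false(call2$replicated)  # threshold 0.005
  expect_identical(call2$best_proxy, "v1")

  call3 <- regional_replication(c(v9 = 0.001), c("v1", "v2"), n_tags = 2)
  expect_identical(call3$status, "untestable")
  expect_true(is.na(call3$replicated))
})

test_that("region calls over a cohort are internally consistent", {
  co <- test_cohort()
  assoc <- test_assoc()
  cross <- suppressWarnings(cross_ethnic_meta(assoc))
  panel <- co$dosages[co$samples$status == 0L, , drop = FALSE]
  calls <- region_calls(cross, co$catalog, co$variants, panel)
  expect_identical(sort(calls$region_id), sort(co$catalog$region_id))
  expect_true(all(calls$alpha_region <= 0.05 + 1e-12))
  tested <- calls[calls$status == "tested", ]
  expect_true(all(tested$replicated == (tested$best_p < tested$alpha_region)))
})
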