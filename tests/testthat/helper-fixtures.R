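# shared small synthetic cohort, built once per test run
.fixture_env <- new.env(parent = emptyenv())

small_regions <- function(n_regions = 6, n_variants = 8, or = 1.0,
                          target_r2 = 0.8, span = 2.8e5) {
  lapply(seq_len(n_regions), function(i)
    region_spec(region_id = sprintf("R%02d", i),
                chrom = as.character(i),
                start = 1e6, end = 1e6 + span,
                n_variants = n_variants, ld_decay_length = 1e5,
                target_r2 = target_r2,
                or_functional = if (length(or) > 1) or[i] else or))
}

small_config <- function(seed = 42, or = 1.3, ...) {
  sim_config(n_cases = c(60L, 60L, 60L), n_controls = c(90L, 90L, 90L),
             regions = small_regions(or = or),
             n_strata_per_pop = 2L, seed = seed, ...)
}

test_cohort <- function() {
  if (is.null(.fixture_env$cohort))
    .fixture_env$cohort <- suppressWarnings(simulate_cohort(small_config()))
  .fixture_env$cohort
}

test_assoc <- function() {
  if (is.null(.fixture_env$assoc))
    .fixture_env$assoc <- suppressWarnings(
      scan_associations(test_cohort(), k_pcs = 4L, pc_subset_size = 40L))
  .fixture_env$assoc
}

# --- independent oracles -----------------------------------------------

# exact binomial upper tail by direct pmf summation
brute_binom_tail <- function(k, n) {
  if (k <= 0) return(1)
  sum(choose(n, k:n)) / 2^n
}

# greedy pairwise tag binning, written independently of the package:
# recompute coverage from scratch each round with pairwise correlations
brute_tag_bins <- function(panel, r2_tag = 0.8, maf_min = 0.01) {
  freq <- colMeans(panel, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  elig <- colnames(panel)[!is.na(maf) & maf > maf_min & maf > 0]
  pairwise_r2 <- function(a, b) {
    ok <- !is.na(panel[, a]) & !is.na(panel[, b])
    suppressWarnings(cor(panel[ok, a], panel[ok, b])^2)
  }
  remaining <- elig
  bins <- list()
  while (length(remaining)) {
    covered <- lapply(remaining, function(v)
      remaining[vapply(remaining, function(w) {
        r2 <- if (v == w) 1 else pairwise_r2(v, w)
        !is.na(r2) && r2 >= r2_tag
      }, TRUE)])
    sizes <- lengths(covered)
    cand <- remaining[sizes == max(sizes)]
    if (length(cand) > 1) {
      m <- maf[match(cand, colnames(panel))]
      pos <- match(cand, colnames(panel))  # id order as position stand-in
      cand <- cand[order(-m, pos, cand)]
    }
    tag <- cand[1]
    members <- covered[[match(tag, remaining)]]
    bins[[tag]] <- members
    remaining <- setdiff(remaining, members)
  }
  bins
}

# haplotype-table r^2: D^2 / (pA pa pB pb) from a 2x2 haplotype frequency table
haplotype_r2 <- function(n_AB, n_Ab, n_aB, n_ab) {
  n <- n_AB + n_Ab + n_aB + n_ab
  pAB <- n_AB / n
  pA <- (n_AB + n_Ab) / n
  pB <- (n_AB + n_aB) / n
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# expand a haplotype count table into paired 0/1 allele indicator vectors
haplotype_vectors <- function(n_AB, n_Ab, n_aB, n_ab) {
  x <- rep(c(1, 1, 0, 0), c(n_AB, n_Ab, n_aB, n_ab))
  y <- rep(c(1, 0, 1, 0), c(n_AB, n_Ab, n_aB, n_ab))
  list(x = x, y = y)
}
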