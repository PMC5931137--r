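#' Base (unweighted) score definition from the locus catalog
#'
#' One entry per catalog row: the index variant and its reported risk
#' allele, each contributing its risk-allele dosage to the score.
#'
#' @param catalog locus catalog.
#' @return data frame of class `score_definition` with columns `region_id`,
#'   `variant_id`, `risk_allele`, `mode`, `provenance`.
#' @export
score_definition <- function(catalog) {
  out <- data.frame(region_id = catalog$region_id,
                    variant_id = catalog$index_variant,
                    risk_allele = catalog$risk_allele,
                    mode = "base", provenance = "catalog_index",
                    stringsAsFactors = FALSE)
  class(out) <- c("score_definition", "data.frame")
  out
}

#' Substitute regionally significant lead SNPs into a score definition
#'
#' For every region whose replication call is positive, the index variant
#' is replaced by the region's best proxy; all other entries keep the
#' catalog index variant. The substituted risk allele is the allele with a
#' positive observed effect in the supplied results (the effect allele when
#' `beta > 0`, the other allele when `beta < 0`). Using population-scope
#' calls and results yields the "modified I" (ethnic-specific) score;
#' cross-ethnic calls and results yield "modified II".
#'
#' @param catalog locus catalog.
#' @param calls a `region_call_table` for the chosen scope.
#' @param results scope results with `variant_id`, `beta`, `effect_allele`.
#' @param variants variant table (for the non-effect allele).
#' @param mode label stored on the definition (`"modified_I"` or
#'   `"modified_II"`).
#' @return a `score_definition`.
#' @export
substitute_leads <- function(catalog, calls, results, variants,
                             mode = "modified_I") {
  def <- score_definition(catalog)
  def$mode <- mode
  for (i in seq_len(nrow(def))) {
    call <- calls[calls$region_id == def$region_id[i], , drop = FALSE]
    if (nrow(call) == 0 || is.na(call$replicated[1]) || !call$replicated[1])
      next
    lead <- call$best_proxy[1]
    row <- results[results$variant_id == lead, , drop = FALSE]
    if (nrow(row) == 0) next
    vi <- match(lead, variants$variant_id)
    risk <- if (row$beta[1] > 0) variants$effect_allele[vi] else
      variants$other_allele[vi]
    def$variant_id[i] <- lead
    def$risk_allele[i] <- risk
    def$provenance[i] <- sprintf("substituted_lead(beta=%.4f)", row$beta[1])
  }
  def
}

#' Per-sample unweighted genetic risk scores
#'
#' The score is the sum of risk-allele dosages over the definition's
#' variants. Samples missing `missing_exclude` or more score variants
#' (chip-level block missingness) are excluded with a reason; residual
#' sporadic missingness is imputed as twice the within-population
#' risk-allele frequency.
#'
#' @param dosages samples x variants effect-allele dosage matrix.
#' @param definition a `score_definition`.
#' @param variants variant table (effect/other alleles).
#' @param samples sample table (`sample_id`, `population`).
#' @param missing_exclude exclusion threshold on the per-sample count of
#'   missing score variants (default 20).
#' @return data frame of class `score_profile`: `sample_id`, `score`,
#'   `n_missing`, `included`, `reason`.
#' @export
build_score <- function(dosages, definition, variants, samples,
                        missing_exclude = 20L) {
  absent <- setdiff(definition$variant_id, colnames(dosages))
  if (length(absent))
    stop2("score variants absent from the dosage matrix: ",
          paste(absent, collapse = ", "))
  m <- nrow(definition)
  R <- matrix(NA_real_, nrow(dosages), m,
              dimnames = list(rownames(dosages), definition$variant_id))
  for (j in seq_len(m)) {
    vid <- definition$variant_id[j]
    vi <- match(vid, variants$variant_id)
    d <- dosages[, vid]
    risk <- definition$risk_allele[j]
    if (risk == variants$effect_allele[vi]) R[, j] <- d
    else if (risk == variants$other_allele[vi]) R[, j] <- 2 - d
    else stop2("risk allele ", risk, " is not an allele of ", vid)
  }
  n_missing <- rowSums(is.na(R))
  included <- n_missing < missing_exclude
  # impute sporadic missingness at 2 x within-population risk-allele freq
  for (pop in unique(samples$population)) {
    rows <- which(samples$population == pop)
    sub <- R[rows, , drop = FALSE]
    freq <- colMeans(sub, na.rm = TRUE) / 2
    for (j in which(colSums(is.na(sub)) > 0)) {
      nas <- is.na(sub[, j])
      sub[nas, j] <- 2 * freq[j]
    }
    R[rows, ] <- sub
  }
  score <- rowSums(R)
  out <- data.frame(sample_id = rownames(dosages), score = score,
                    n_missing = n_missing, included = included,
                    reason = ifelse(included, "",
                                    "missing_score_block"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_score_variants") <- m
  class(out) <- c("score_profile", "data.frame")
  out
}

#' Compare score distributions between cases and controls by population
#'
#' Welch two-sample t-tests of the case vs control score means within each
#' population, plus integer-binned histogram counts for plotting.
#'
#' @param profiles a `score_profile` (only `included` rows are used).
#' @param samples sample table with `sample_id`, `population`, `status`.
#' @return list: `table` (per-population case/control n, mean, SD, t-test
#'   p) and `hist` (long data frame of bin counts).
#' @export
compare_distributions <- function(profiles, samples) {
  df <- merge(profiles[profiles$included, c("sample_id", "score")],
              samples[, c("sample_id", "population", "status")],
              by = "sample_id")
  rows <- list(); hists <- list()
  for (pop in unique(df$population)) {
    sub <- df[df$population == pop, ]
    ca <- sub$score[sub$status == 1L]; co <- sub$score[sub$status == 0L]
    if (length(ca) < 2 || length(co) < 2)
      stop2("fewer than 2 cases or controls in ", pop)
    p <- if (sd(ca) == 0 && sd(co) == 0) NA_real_ else
      t.test(ca, co)$p.value
    rows[[pop]] <- data.frame(
      population = pop,
      case_n = length(ca), case_mean = round(mean(ca), 2),
      case_sd = round(sd(ca), 2),
      control_n = length(co), control_mean = round(mean(co), 2),
      control_sd = round(sd(co), 2),
      t_p = p, stringsAsFactors = FALSE)
    breaks <- seq(floor(min(sub$score)) - 0.5,
                  ceiling(max(sub$score)) + 0.5, by = 1)
    for (st in c(0L, 1L)) {
      h <- hist(sub$score[sub$status == st], breaks = breaks, plot = FALSE)
      hists[[paste(pop, st)]] <- data.frame(
        population = pop, status = st, bin_mid = h$mids, count = h$counts,
        stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
       hist = do.call(rbind, c(hists, make.row.names = FALSE)))
}

#' Association of a genetic risk score with disease
#'
#' Within each population: a continuous model (per-allele OR for the raw
#' score) and a quartile model (quartile cut-points from the full analyzed
#' within-population sample; lowest quartile as reference), both adjusted
#' for the supplied covariates.
#'
#' @param profiles a `score_profile` (only `included` rows are analyzed).
#' @param samples sample table with `sample_id`, `population`, `status`,
#'   `age`, `sex`, `bmi`.
#' @param covariates optional named list population -> extra covariate
#'   matrix (e.g. principal components), rows aligned with that
#'   population's samples in `samples` order.
#' @return data frame: `population`, `model` (`continuous` or
#'   `quartile`), `term`, `or`, `p`, `n`; the Quartile-1 row is the
#'   reference with `or = 1` exactly.
#' @export
grs_association <- function(profiles, samples, covariates = NULL) {
  rows <- list()
  for (pop in unique(samples$population)) {
    sp <- samples[samples$population == pop, , drop = FALSE]
    pr <- profiles[match(sp$sample_id, profiles$sample_id), , drop = FALSE]
    keep <- pr$included
    sp <- sp[keep, , drop = FALSE]; sc <- pr$score[keep]
    base_cov <- cbind(age = sp$age, female = as.numeric(sp$sex == "F"),
                      bmi = sp$bmi)
    if (!is.null(covariates) && !is.null(covariates[[pop]]))
      base_cov <- cbind(base_cov, covariates[[pop]][keep, , drop = FALSE])
    y <- sp$status
    # continuous (per risk allele)
    fit <- fit_logistic_wald(cbind(intercept = 1, dosage = sc, base_cov), y)
    rows[[length(rows) + 1L]] <- data.frame(
      population = pop, model = "continuous", term = "per_allele",
      or = exp(fit$beta), p = fit$p, n = length(y), ok = fit$ok,
      stringsAsFactors = FALSE)
    # quartiles of the analyzed within-population sample
    qcut <- quantile(sc, c(0.25, 0.5, 0.75))
    if (anyDuplicated(qcut)) {
      warn2("tied quartile cut-points in ", pop,
            "; quartile model flagged unusable")
      for (qi in 1:4)
        rows[[length(rows) + 1L]] <- data.frame(
          population = pop, model = "quartile", term = paste0("Q", qi),
          or = if (qi == 1) 1 else NA_real_, p = NA_real_, n = NA_integer_,
          ok = FALSE, stringsAsFactors = FALSE)
      next
    }
    qt <- cut(sc, breaks = c(-Inf, qcut, Inf), labels = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      population = pop, model = "quartile", term = "Q1",
      or = 1, p = NA_real_, n = sum(qt == 1), ok = TRUE,
      stringsAsFactors = FALSE)
    Qm <- cbind(Q2 = as.numeric(qt == 2), Q3 = as.numeric(qt == 3),
                Q4 = as.numeric(qt == 4))
    qfit <- suppressWarnings(
      glm.fit(cbind(intercept = 1, Qm, base_cov), y, family = binomial(),
              control = glm.control(epsilon = 1e-8, maxit = 50L)))
    pq <- ncol(Qm) + ncol(base_cov) + 1L
    okq <- qfit$converged && qfit$rank == pq
    covm <- if (okq) {
      R <- qfit$qr$qr[seq_len(pq), seq_len(pq), drop = FALSE]
      R[lower.tri(R)] <- 0
      cm <- chol2inv(R)
      cm[order(qfit$qr$pivot), order(qfit$qr$pivot), drop = FALSE]
    } else NULL
    for (qi in 2:4) {
      term <- paste0("Q", qi)
      no_cases <- sum(y[qt == qi]) == 0
      b <- if (okq) qfit$coefficients[term] else NA_real_
      se <- if (okq) sqrt(covm[qi, qi]) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        population = pop, model = "quartile", term = term,
        or = exp(unname(b)),
        p = if (okq && !no_cases) 2 * pnorm(-abs(b / se)) else NA_real_,
        n = sum(qt == qi), ok = okq && !no_cases,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out
}
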