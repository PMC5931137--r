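#' Squared allelic correlation from dosages
#'
#' Squared Pearson correlation of the two dosage vectors (the Rogers-Huff
#' composite estimator); on phased haplotype indicators it equals the
#' haplotype-based `D^2 / (pA pa pB pb)`.
#'
#' @param x,y dosage vectors of equal length (`NA` allowed; pairwise
#'   complete observations are used).
#' @return r-squared in `[0, 1]`; `NA` with a warning when either vector is
#'   monomorphic after filtering.
#' @export
r2_from_dosages <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < 2) stop2("fewer than 2 pairwise-complete observations")
  x <- x[keep]; y <- y[keep]
  if (var(x) == 0 || var(y) == 0) {
    warn2("monomorphic input; r^2 undefined")
    return(NA_real_)
  }
  cor(x, y)^2
}

panel_r2_matrix <- function(panel, ids = colnames(panel)) {
  C <- suppressWarnings(cor(panel[, ids, drop = FALSE],
                            use = "pairwise.complete.obs"))
  C^2
}

#' Proxy variants for an index SNP in a reference panel
#'
#' All panel variants with `r^2` to the index at or above `r2_min`
#' (inclusive threshold), the index itself always included (`r^2 = 1`).
#'
#' @param panel reference-panel dosage matrix (samples x variants).
#' @param index_id index variant id (must be a polymorphic panel column).
#' @param r2_min inclusive threshold (default 0.4).
#' @param candidate_ids variants to consider (default: all panel columns).
#' @return character vector of proxy ids.
#' @export
proxy_set <- function(panel, index_id, r2_min = 0.4,
                      candidate_ids = colnames(panel)) {
  if (!index_id %in% colnames(panel))
    stop2("index variant ", index_id, " absent from the panel")
  x <- panel[, index_id]
  if (var(x, na.rm = TRUE) == 0)
    stop2("index variant ", index_id, " is monomorphic in the panel")
  r2 <- vapply(candidate_ids, function(v) {
    if (v == index_id) return(1)
    suppressWarnings(r2_from_dosages(x, panel[, v]))
  }, 0)
  candidate_ids[!is.na(r2) & r2 >= r2_min]
}

#' Greedy pairwise tag-SNP binning
#'
#' Classic greedy pairwise tagging: among not-yet-tagged eligible variants
#' (panel MAF strictly above `maf_min`), repeatedly pick the one covering
#' the most untagged variants at `r^2 >= r2_tag` (itself included), make it
#' a tag, assign the covered variants to its bin, and remove them. Ties are
#' broken by higher MAF, then lower position, then id order. Every eligible
#' variant ends up in exactly one bin.
#'
#' @param panel reference-panel dosage matrix.
#' @param r2_tag inclusive tagging threshold (default 0.8).
#' @param maf_min exclusive MAF eligibility threshold (default 0.01).
#' @param candidate_ids variants to consider.
#' @param positions optional named base-pair positions for tie-breaking.
#' @return list: `n_tags`, `tags` (character), `bins` (named list
#'   tag -> member ids), `eligible`.
#' @export
greedy_tag_bins <- function(panel, r2_tag = 0.8, maf_min = 0.01,
                            candidate_ids = colnames(panel),
                            positions = NULL) {
  freq <- colMeans(panel[, candidate_ids, drop = FALSE], na.rm = TRUE) / 2
  maf <- fold_maf(freq)
  eligible <- candidate_ids[!is.na(maf) & maf > maf_min & maf > 0]
  if (!length(eligible))
    return(list(n_tags = 0L, tags = character(), bins = list(),
                eligible = character()))
  R2 <- panel_r2_matrix(panel, eligible)
  R2[is.na(R2)] <- 0
  diag(R2) <- 1
  pos <- if (is.null(positions)) setNames(seq_along(eligible), eligible) else
    positions[eligible]
  mafs <- setNames(maf[match(eligible, candidate_ids)], eligible)
  untagged <- eligible
  bins <- list()
  while (length(untagged)) {
    cover <- R2[untagged, untagged, drop = FALSE] >= r2_tag
    counts <- rowSums(cover)
    best <- which(counts == max(counts))
    if (length(best) > 1) {
      cand <- untagged[best]
      ord <- order(-mafs[cand], pos[cand], cand)
      tag <- cand[ord[1]]
    } else tag <- untagged[best]
    members <- untagged[cover[tag, ]]
    bins[[tag]] <- members
    untagged <- setdiff(untagged, members)
  }
  list(n_tags = length(bins), tags = names(bins), bins = bins,
       eligible = eligible)
}

#' Regional replication call from proxy p-values
#'
#' A region replicates when the smallest p-value among the index SNP's
#' proxies falls below the region-specific threshold `0.05 / n_tags`.
#' P-values must already be restricted to variants passing the INFO filter.
#'
#' @param pvals named vector of association/meta p-values, names = variant
#'   ids.
#' @param proxies proxy variant ids (from [proxy_set()]).
#' @param n_tags number of tag bins in the region (from
#'   [greedy_tag_bins()]).
#' @param alpha base significance level (default 0.05).
#' @return list: `n_tags`, `alpha_region`, `proxies`, `n_tested`,
#'   `best_proxy`, `best_p`, `replicated` (NA and
#'   `status = "untestable"` when no proxy has a usable p-value).
#' @export
regional_replication <- function(pvals, proxies, n_tags, alpha = 0.05) {
  stopifnot(length(proxies) >= 1, n_tags >= 1)
  alpha_region <- alpha / n_tags
  testable <- intersect(proxies, names(pvals)[!is.na(pvals)])
  if (!length(testable))
    return(list(n_tags = n_tags, alpha_region = alpha_region,
                proxies = proxies, n_tested = 0L,
                best_proxy = NA_character_, best_p = NA_real_,
                replicated = NA, status = "untestable"))
  p <- pvals[testable]
  best <- which.min(p)
  list(n_tags = n_tags, alpha_region = alpha_region, proxies = proxies,
       n_tested = length(testable), best_proxy = testable[best],
       best_p = unname(p[best]), replicated = unname(p[best]) < alpha_region,
       status = "tested")
}

#' Regional replication calls for every catalog region
#'
#' For each region: proxies of the index SNP(s) at `r2_proxy` in the proxy
#' panel (union over index SNPs when a region reports several), tag bins at
#' `r2_tag` in the tagging panel among the region's variants, and the
#' replication call from the scope's p-values. The two panels may be the
#' same matrix; the design mirrors using a European-ancestry panel for
#' proxy lookup and an African-ancestry panel for tag counting.
#'
#' @param results data frame with `variant_id` and `p` for one scope
#'   (already INFO-filtered by the scan).
#' @param catalog locus catalog.
#' @param variants variant table with `region_id`.
#' @param proxy_panel,tag_panel dosage matrices.
#' @param r2_proxy,r2_tag,maf_min,alpha thresholds.
#' @return data frame of class `region_call_table`: one row per region with
#'   `n_tags`, `alpha_region`, `n_proxies`, `best_proxy`, `best_p`,
#'   `replicated`, `status`.
#' @export
region_calls <- function(results, catalog, variants, proxy_panel,
                         tag_panel = proxy_panel, r2_proxy = 0.4,
                         r2_tag = 0.8, maf_min = 0.01, alpha = 0.05) {
  pvals <- setNames(results$p, results$variant_id)
  pos <- setNames(variants$pos, variants$variant_id)
  out <- lapply(split(catalog, catalog$region_id), function(entries) {
    region <- entries$region_id[1]
    region_vars <- variants$variant_id[variants$region_id == region]
    region_vars <- intersect(region_vars, colnames(proxy_panel))
    proxies <- unique(unlist(lapply(entries$index_variant, function(iv) {
      if (!iv %in% colnames(proxy_panel)) return(character())
      proxy_set(proxy_panel, iv, r2_min = r2_proxy,
                candidate_ids = region_vars)
    })))
    tags <- greedy_tag_bins(tag_panel, r2_tag = r2_tag, maf_min = maf_min,
                            candidate_ids = intersect(region_vars,
                                                      colnames(tag_panel)),
                            positions = pos)
    n_tags <- max(1L, tags$n_tags)
    call <- if (length(proxies))
      regional_replication(pvals, proxies, n_tags, alpha = alpha)
    else list(n_tags = n_tags, alpha_region = alpha / n_tags,
              n_tested = 0L, best_proxy = NA_character_,
              best_p = NA_real_, replicated = NA, status = "untestable")
    data.frame(region_id = region, index_variant = entries$index_variant[1],
               n_tags = call$n_tags, alpha_region = call$alpha_region,
               n_proxies = length(proxies), n_tested = call$n_tested,
               best_proxy = call$best_proxy, best_p = call$best_p,
               replicated = call$replicated, status = call$status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("region_call_table", "data.frame")
  out
}
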