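#' Default run configuration
#'
#' @param out_dir output directory for stage TSVs and the run log.
#' @param sim a [sim_config()] (the pipeline simulates its input cohort) or
#'   `NULL` with `cohort` supplied directly to [run_pipeline()].
#' @param claims_controls_only restrict controls to those with health-care
#'   claims records (sensitivity filter).
#' @param exclude_prior_condition drop samples from strata nested in cancer
#'   or diabetes case-control studies whose prior condition matches the
#'   given labels (e.g. `c("breast", "prostate", "diabetes")`); `NULL`
#'   disables the filter.
#' @param maf_min,info_min,r2_proxy,r2_tag,alpha analysis thresholds.
#' @param k_pcs,pc_subset_size principal-component settings.
#' @param missing_exclude GRS block-missingness exclusion threshold.
#' @param power_threshold adequate-power threshold.
#' @param seed integer seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("transloci_run_"),
                       sim = sim_config(),
                       claims_controls_only = FALSE,
                       exclude_prior_condition = NULL,
                       maf_min = 0.01, info_min = 0.8,
                       r2_proxy = 0.4, r2_tag = 0.8, alpha = 0.05,
                       k_pcs = 10L, pc_subset_size = 10000L,
                       missing_exclude = 20L, power_threshold = 0.80,
                       seed = 1L) {
  stopifnot(maf_min >= 0, maf_min < 0.5, info_min >= 0, info_min <= 1,
            r2_proxy >= 0, r2_proxy <= 1, r2_tag >= 0, r2_tag <= 1,
            alpha > 0, alpha < 1)
  structure(list(out_dir = out_dir, sim = sim,
                 claims_controls_only = claims_controls_only,
                 exclude_prior_condition = exclude_prior_condition,
                 maf_min = maf_min, info_min = info_min,
                 r2_proxy = r2_proxy, r2_tag = r2_tag, alpha = alpha,
                 k_pcs = k_pcs, pc_subset_size = pc_subset_size,
                 missing_exclude = missing_exclude,
                 power_threshold = power_threshold,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys map to [run_config()] arguments; an optional `sim` block
#' maps to [sim_config()] arguments (regions given as a list of
#' [region_spec()] argument sets).
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$sim)) {
    sim_args <- y$sim
    if (!is.null(sim_args$regions))
      sim_args$regions <- lapply(sim_args$regions, function(r)
        do.call(region_spec, r))
    sim <- do.call(sim_config, sim_args)
  }
  args <- y[setdiff(names(y), "sim")]
  if (!is.null(sim)) args$sim <- sim
  do.call(run_config, args)
}

apply_sample_filters <- function(cohort, config, log) {
  samples <- cohort$samples
  if (config$claims_controls_only) {
    drop <- samples$status == 0L & !samples$has_claims
    log(sprintf("claims filter: dropping %d controls without claims",
                sum(drop)))
    samples <- samples[!drop, , drop = FALSE]
  }
  if (!is.null(config$exclude_prior_condition)) {
    drop <- samples$prior_condition %in% config$exclude_prior_condition
    log(sprintf("prior-condition filter: dropping %d samples", sum(drop)))
    samples <- samples[!drop, , drop = FALSE]
  }
  cohort$samples <- samples
  cohort$dosages <- cohort$dosages[samples$sample_id, , drop = FALSE]
  cohort
}

#' Run the full locus-generalizability pipeline
#'
#' Stages: simulate (or accept) the cohort, apply sample filters,
#' association scan, within- and cross-population meta-analysis,
#' directional-consistency summaries, regional replication calls, the
#' three genetic risk scores with distribution comparisons and
#' case-control association, and analytic power over the catalog. Every
#' stage writes a TSV under `config$out_dir` and every exclusion is logged;
#' the returned bundle holds the same objects.
#'
#' @param config a [run_config()].
#' @param cohort optional pre-built `chd_cohort` (otherwise simulated from
#'   `config$sim`).
#' @return invisible list of class `pipeline_report`: `cohort`, `assoc`,
#'   `meta_pop`, `meta_cross`, `consistency`, `regions`, `grs`, `power`,
#'   `files`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)
  log <- function(msg) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                           "INFO", msg, "\n", file = log_path,
                           append = TRUE)
  tsv <- function(x, f) {
    write.table(x, file.path(config$out_dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
    f
  }
  set.seed(config$seed)
  files <- character()

  if (is.null(cohort)) {
    log("simulate: generating synthetic cohort")
    sim <- config$sim
    sim$seed <- config$seed
    cohort <- simulate_cohort(sim)
  }
  cohort <- apply_sample_filters(cohort, config, log)
  files <- c(files, tsv(cohort$samples, "samples.tsv"))

  log("scan: per-variant association within strata")
  assoc <- scan_associations(cohort, maf_min = config$maf_min,
                             info_min = config$info_min,
                             k_pcs = config$k_pcs,
                             pc_subset_size = config$pc_subset_size)
  files <- c(files, tsv(assoc, "assoc.tsv"),
             tsv(attr(assoc, "exclusions"), "exclusions.tsv"))

  log("meta: within- and cross-population fixed effects")
  meta_pop <- population_meta(assoc)
  meta_cross <- cross_ethnic_meta(assoc)
  files <- c(files, tsv(meta_pop, "meta_population.tsv"),
             tsv(meta_cross, "meta_multiethnic.tsv"))

  log("consistency: directional binomial tests")
  pops <- unique(cohort$samples$population)
  scopes <- c(setNames(lapply(pops, function(p)
    meta_pop[meta_pop$population == p, , drop = FALSE]), pops),
    list(multiethnic = meta_cross))
  consistency <- lapply(names(scopes), function(s)
    summarize_consistency(scopes[[s]], cohort$catalog, scope = s,
                          alpha = config$alpha))
  names(consistency) <- names(scopes)
  ctab <- do.call(rbind, lapply(consistency, function(x)
    data.frame(scope = x$scope, n = x$n, k = x$k, fraction = x$fraction,
               p = x$p, n_nominal = nrow(x$nominal),
               stringsAsFactors = FALSE)))
  files <- c(files, tsv(ctab, "consistency.tsv"))
  nominal <- do.call(rbind, lapply(consistency, function(x)
    if (nrow(x$nominal)) cbind(scope = x$scope, x$nominal) else NULL))
  if (!is.null(nominal)) files <- c(files, tsv(nominal, "nominal_snps.tsv"))

  log("regions: LD-proxy regional replication")
  # synthetic reference panels: first population's controls for tagging
  # (AFR-style), all controls for proxy lookup (EUR-style stand-in)
  panel_proxy <- cohort$dosages[cohort$samples$status == 0L, , drop = FALSE]
  panel_tag <- cohort$dosages[
    cohort$samples$status == 0L & cohort$samples$population == pops[1], ,
    drop = FALSE]
  regions <- lapply(names(scopes), function(s)
    region_calls(scopes[[s]], cohort$catalog, cohort$variants,
                 proxy_panel = panel_proxy, tag_panel = panel_tag,
                 r2_proxy = config$r2_proxy, r2_tag = config$r2_tag,
                 maf_min = config$maf_min, alpha = config$alpha))
  names(regions) <- names(scopes)
  rtab <- do.call(rbind, lapply(names(regions), function(s)
    cbind(scope = s, regions[[s]])))
  files <- c(files, tsv(rtab, "region_calls.tsv"))

  log("grs: building risk scores")
  defs <- list(base = score_definition(cohort$catalog))
  for (p in pops)
    defs[[paste0("modified_I_", p)]] <-
      substitute_leads(cohort$catalog, regions[[p]], scopes[[p]],
                       cohort$variants, mode = "modified_I")
  defs$modified_II <- substitute_leads(cohort$catalog, regions$multiethnic,
                                       scopes$multiethnic, cohort$variants,
                                       mode = "modified_II")
  grs <- list()
  for (nm in names(defs)) {
    prof <- build_score(cohort$dosages, defs[[nm]], cohort$variants,
                        cohort$samples,
                        missing_exclude = config$missing_exclude)
    cmp <- compare_distributions(prof, cohort$samples)
    ass <- grs_association(prof, cohort$samples)
    grs[[nm]] <- list(definition = defs[[nm]], profile = prof,
                      compare = cmp, association = ass)
    files <- c(files, tsv(defs[[nm]], sprintf("grs_definition_%s.tsv", nm)),
               tsv(cmp$table, sprintf("grs_distribution_%s.tsv", nm)),
               tsv(ass, sprintf("grs_association_%s.tsv", nm)))
  }

  log("power: analytic per-allele power over the catalog")
  freq_cols <- paste0("freq_", pops)
  freqs <- as.matrix(cohort$variants[, freq_cols, drop = FALSE])
  colnames(freqs) <- pops
  rownames(freqs) <- cohort$variants$variant_id
  counts <- table(cohort$samples$population, cohort$samples$status)
  n_cases <- setNames(as.list(counts[pops, "1"]), pops)
  n_controls <- setNames(as.list(counts[pops, "0"]), pops)
  power <- powered_fraction(cohort$catalog, freqs, n_cases, n_controls,
                            threshold = config$power_threshold,
                            alpha = config$alpha)
  files <- c(files, tsv(power$table, "power.tsv"))

  log("done")
  invisible(structure(list(cohort = cohort, assoc = assoc,
                           meta_pop = meta_pop, meta_cross = meta_cross,
                           consistency = consistency, regions = regions,
                           grs = grs, power = power, files = files,
                           config = config),
                      class = "pipeline_report"))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("locus-generalizability pipeline report\n")
  for (s in names(x$consistency)) print(x$consistency[[s]])
  rep_counts <- vapply(x$regions, function(r)
    sum(r$replicated, na.rm = TRUE), 0)
  cat("regions replicated:",
      paste(sprintf("%s=%d", names(rep_counts), rep_counts),
            collapse = ", "), "\n")
  cat("powered variants (>=", x$power$threshold, "):",
      paste(sprintf("%s=%d", names(x$power$counts), x$power$counts),
            collapse = ", "), "\n")
  invisible(x)
}
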