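#' Write a cohort's genotypes to VCF 4.2
#'
#' Hard calls go in GT (rounded dosage; missing as `./.`), dosages in DS,
#' and the across-strata mean imputation INFO in the INFO column under the
#' key `INFO`. Coordinates are 1-based, matching VCF throughout the package.
#'
#' @param variants variant table (`variant_id`, `chrom`, `pos`,
#'   `other_allele`, `effect_allele`).
#' @param dosages samples x variants matrix, `NA` = missing.
#' @param path output file.
#' @param info optional per-variant INFO values (variants x strata matrix or
#'   vector); the per-variant mean is written.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, dosages, path, info = NULL) {
  stopifnot(ncol(dosages) == nrow(variants))
  info_val <- if (is.null(info)) rep(1, nrow(variants)) else
    if (is.matrix(info)) rowMeans(info) else info
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Effect allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dosages)), collapse = "\t"))
  gt_of <- function(d) {
    g <- round(d)
    out <- rep("./.", length(d))
    out[!is.na(g) & g == 0] <- "0/0"
    out[!is.na(g) & g == 1] <- "0/1"
    out[!is.na(g) & g == 2] <- "1/1"
    out
  }
  rows <- vapply(seq_len(nrow(variants)), function(j) {
    d <- dosages[, j]
    cells <- paste0(gt_of(d), ":",
                    ifelse(is.na(d), ".", formatC(d, format = "g",
                                                  digits = 6)))
    paste(c(variants$chrom[j], variants$pos[j], variants$variant_id[j],
            variants$other_allele[j], variants$effect_allele[j], ".", "PASS",
            sprintf("INFO=%.4f", info_val[j]), "GT:DS", cells),
          collapse = "\t")
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

parse_gt_dosage <- function(gt) {
  # count of ALT alleles in a diploid GT string; "." anywhere -> missing
  clean <- gsub("\\|", "/", gt)
  out <- rep(NA_real_, length(gt))
  known <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
  hit <- clean %in% names(known)
  out[hit] <- known[clean[hit]]
  out
}

#' Read genotypes into the internal variant table + dosage matrix
#'
#' For VCF input, dosage is taken from the DS field when present, else from
#' GT allele counts; multi-allelic records and duplicated variant ids are
#' rejected. For TSV input, the file must have a `variant_id` column
#' followed by one column per sample holding dosages in `[0, 2]` (`NA` =
#' missing).
#'
#' @param path file path.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (by extension).
#' @return `list(variants = data.frame, dosages = samples x variants
#'   matrix)`; for VCF, `variants$info` carries the INFO-key value.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "tsv") {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(tab)[1] != "variant_id")
      stop2("dosage TSV must start with a variant_id column")
    if (anyDuplicated(tab$variant_id))
      stop2("duplicated variant id: ",
            tab$variant_id[duplicated(tab$variant_id)][1])
    D <- t(as.matrix(tab[, -1, drop = FALSE]))
    colnames(D) <- tab$variant_id
    if (any(D < 0 | D > 2, na.rm = TRUE))
      stop2("dosages outside [0, 2] in ", path)
    return(list(variants = data.frame(variant_id = tab$variant_id,
                                      stringsAsFactors = FALSE),
                dosages = D))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    stop2("multi-allelic records not supported: ",
          paste(head(fix$ID[multi], 5), collapse = ", "))
  if (anyDuplicated(fix$ID))
    stop2("duplicated variant id: ", fix$ID[duplicated(fix$ID)][1])
  info <- suppressWarnings(as.numeric(sub(".*(?:^|;)INFO=([^;]+).*", "\\1",
                                          fix$INFO)))
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    D <- apply(gt, 2, parse_gt_dosage)
    if (is.null(dim(D))) D <- matrix(D, nrow = nrow(gt),
                                     dimnames = dimnames(gt))
  } else {
    D <- ds
    gt <- tryCatch(vcfR::extract.gt(v, element = "GT"),
                   error = function(e) NULL)
    if (!is.null(gt)) {
      fill <- is.na(D)
      if (any(fill)) D[fill] <- parse_gt_dosage(gt[fill])
    }
  }
  rownames(D) <- fix$ID
  variants <- data.frame(variant_id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         other_allele = fix$REF, effect_allele = fix$ALT,
                         info = info, stringsAsFactors = FALSE)
  list(variants = variants, dosages = t(D))
}

#' Read a locus catalog TSV
#'
#' Expected columns: `region_id`, `index_variant`, `risk_allele`,
#' `reported_or`, and optionally `risk_allele_freq`, `chrom`, `start`,
#' `end`, `source_population`.
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_catalog <- function(path) {
  cat <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("region_id", "index_variant", "risk_allele", "reported_or")
  miss <- setdiff(need, names(cat))
  if (length(miss)) stop2("catalog is missing columns: ",
                          paste(miss, collapse = ", "))
  if (any(cat$reported_or <= 0)) stop2("reported_or must be > 0")
  cat
}

#' Write the full cohort bundle to a directory
#'
#' Emits `genotypes.vcf`, `samples.tsv`, `catalog.tsv`, `info.tsv`
#' (per-variant, per-stratum INFO) and `truth.tsv` (true frequencies,
#' effects and achieved index-functional r-squared).
#'
#' @param cohort a `chd_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  write_vcf(cohort$variants, cohort$dosages,
            file.path(dir, "genotypes.vcf"), info = cohort$info)
  tsv(cohort$samples, "samples.tsv")
  tsv(cohort$catalog, "catalog.tsv")
  tsv(data.frame(variant_id = rownames(cohort$info), cohort$info,
                 check.names = FALSE), "info.tsv")
  tr <- cohort$truth
  truth <- data.frame(variant_id = rownames(tr$freqs), tr$freqs,
                      effect = ifelse(rownames(tr$freqs) %in%
                                        names(tr$effects),
                                      tr$effects[rownames(tr$freqs)], 0),
                      check.names = FALSE)
  tsv(truth, "truth.tsv")
  invisible(dir)
}

complement_allele <- function(a) {
  ifelse(a %in% c("A", "C", "G", "T"), chartr("ACGT", "TGCA", a), a)
}

#' Orient a variant's effect allele against a catalog risk allele
#'
#' Returns `+1` when the effect allele is the reported risk allele, `-1`
#' when the other allele is (the effect sign must then be flipped), and
#' `NA` (ambiguous) when the call cannot be made. Strand-complement
#' matching is attempted for non-palindromic pairs. Palindromic (A/T, C/G)
#' pairs are resolved only when both the effect-allele and reported
#' risk-allele frequencies are below 0.40 (both minor, hence the same
#' physical allele); otherwise they are ambiguous.
#'
#' @param effect_allele,other_allele the variant's alleles.
#' @param risk_allele reported risk allele.
#' @param effect_freq frequency of the effect allele in the analyzed
#'   population (used only for palindromic pairs).
#' @param risk_freq reported risk-allele frequency (idem).
#' @return `+1L`, `-1L`, or `NA_integer_` for ambiguous.
#' @export
align_to_catalog <- function(effect_allele, other_allele, risk_allele,
                             effect_freq = NA_real_, risk_freq = NA_real_) {
  if (effect_allele == other_allele) stop2("degenerate variant alleles")
  palindromic <- identical(complement_allele(effect_allele), other_allele)
  if (!palindromic) {
    if (risk_allele == effect_allele) return(1L)
    if (risk_allele == other_allele) return(-1L)
    if (risk_allele == complement_allele(effect_allele)) return(1L)
    if (risk_allele == complement_allele(other_allele)) return(-1L)
    stop2(sprintf("no allele correspondence for %s/%s vs risk allele %s",
                  effect_allele, other_allele, risk_allele))
  }
  if (!risk_allele %in% c(effect_allele, other_allele))
    stop2(sprintf("no allele correspondence for %s/%s vs risk allele %s",
                  effect_allele, other_allele, risk_allele))
  if (!is.na(effect_freq) && !is.na(risk_freq) &&
      effect_freq < 0.40 && risk_freq < 0.40) return(1L)
  NA_integer_
}

# vectorized orientation of catalog entries against a variant table;
# per-population effect-allele frequency used for palindromic pairs
orient_catalog <- function(catalog, variants, effect_freq = NULL) {
  idx <- match(catalog$index_variant, variants$variant_id)
  out <- rep(NA_integer_, nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    if (is.na(idx[i])) next
    ef <- if (!is.null(effect_freq)) effect_freq[idx[i]] else NA_real_
    rf <- if (!is.null(catalog$risk_allele_freq))
      catalog$risk_allele_freq[i] else NA_real_
    out[i] <- align_to_catalog(variants$effect_allele[idx[i]],
                               variants$other_allele[idx[i]],
                               catalog$risk_allele[i], ef, rf)
  }
  out
}
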