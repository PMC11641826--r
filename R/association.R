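#' Uncorrected allelic chi-square test
#'
#' Pearson chi-square statistic (1 df, no Yates continuity correction) on
#' the 2x2 case/control by alt/ref allele-count table, with
#' `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`. The p-value is the
#' upper tail of the chi-square distribution with one degree of freedom.
#' A table with a zero margin (e.g. a monomorphic variant) has no finite
#' statistic and yields `NA` for both values rather than an error.
#'
#' @param t an [allele_count_table()].
#' @return Named numeric vector `c(chi2 = , p = )`.
#' @export
allelic_chi_square <- function(t) {
  stopifnot(inherits(t, "allele_count_table"))
  a <- t[["a"]]; b <- t[["b"]]; cc <- t[["c"]]; d <- t[["d"]]
  n <- a + b + cc + d
  margins <- c(a + b, cc + d, a + cc, b + d)
  if (n == 0 || any(margins == 0)) {
    return(c(chi2 = NA_real_, p = NA_real_))
  }
  chi2 <- n * (a * d - b * cc)^2 / prod(as.numeric(margins))
  c(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Allelic odds ratio
#'
#' Cross-product ratio `(a d) / (b c)` of the allele-count table, oriented
#' so the numerator carries the case alternate-allele odds
#' (keep-allele-order semantics: no minor-allele flipping). Undefined
#' (`NA`) exactly when `b * c = 0`; equal to 0 when `a * d = 0` with
#' `b * c > 0`.
#'
#' @param t an [allele_count_table()].
#' @return A single numeric odds ratio, or `NA` when undefined.
#' @export
allelic_odds_ratio <- function(t) {
  stopifnot(inherits(t, "allele_count_table"))
  a <- t[["a"]]; b <- t[["b"]]; cc <- t[["c"]]; d <- t[["d"]]
  if (b * cc == 0) return(NA_real_)
  (a * d) / (b * cc)
}

#' Group alternate-allele frequencies
#'
#' Alternate-allele frequency in cases (`F_A`) and controls (`F_U`),
#' reported for the alternate allele without minor-allele flipping.
#'
#' @param t an [allele_count_table()].
#' @return Named numeric vector `c(F_A = , F_U = )`; `NA` for a group with
#'   no genotyped samples.
#' @export
allele_frequencies <- function(t) {
  stopifnot(inherits(t, "allele_count_table"))
  a <- t[["a"]]; b <- t[["b"]]; cc <- t[["c"]]; d <- t[["d"]]
  c(
    F_A = if (a + b == 0) NA_real_ else a / (a + b),
    F_U = if (cc + d == 0) NA_real_ else cc / (cc + d)
  )
}

#' QC parameters for per-variant filtering
#'
#' Defaults follow the standard PLINK-style configuration for a small
#' unrelated cohort: per-variant missingness at most 0.1, pooled
#' minor-allele frequency at least 0.05, exact Hardy-Weinberg p-value at
#' least 1e-7, and a 0.05 significance level.
#'
#' @param max_missing_per_variant maximum tolerated fraction of missing
#'   calls per variant.
#' @param min_maf minimum pooled minor-allele frequency,
#'   `min(f, 1 - f)` over all genotyped samples.
#' @param hwe_p_threshold variants with exact Hardy-Weinberg p below this
#'   are removed.
#' @param alpha significance level carried through to reporting.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(max_missing_per_variant = 0.1, min_maf = 0.05,
                      hwe_p_threshold = 1e-7, alpha = 0.05) {
  x <- list(max_missing_per_variant = max_missing_per_variant,
            min_maf = min_maf, hwe_p_threshold = hwe_p_threshold,
            alpha = alpha)
  if (any(unlist(x) < 0) || any(unlist(x) > 1)) {
    stop("all QC parameters must lie in [0, 1]")
  }
  structure(x, class = "qc_params")
}

#' Per-variant quality-control filter
#'
#' Removes variants failing any of three rules, evaluated on all samples
#' pooled (no founder restriction in an unrelated cohort): missing-call
#' fraction above `max_missing_per_variant`, pooled minor-allele frequency
#' below `min_maf`, or exact Hardy-Weinberg p-value below
#' `hwe_p_threshold`. The first failing rule (in that order) is recorded
#' per removed variant.
#'
#' @param gt a [genotype_table()].
#' @param ph a [phenotype_map()] (unused by the pooled rules, accepted for
#'   interface symmetry with the association stage).
#' @param params a [qc_params()] object.
#' @return A list with `gt` (the filtered [genotype_table()]) and `log`, a
#'   data.frame with one row per input variant: `id`, `qc_pass`, `reason`.
#' @export
qc_filter <- function(gt, ph = NULL, params = qc_params()) {
  stopifnot(inherits(gt, "genotype_table"), inherits(params, "qc_params"))
  nvar <- nrow(gt$variants)
  reason <- rep(NA_character_, nvar)
  for (j in seq_len(nvar)) {
    dos <- gt$calls[, j]
    miss_frac <- mean(is.na(dos))
    if (miss_frac > params$max_missing_per_variant) {
      reason[j] <- "missingness"
      next
    }
    typed <- dos[!is.na(dos)]
    if (length(typed) == 0) {
      reason[j] <- "missingness"
      next
    }
    f <- sum(typed) / (2 * length(typed))
    if (min(f, 1 - f) < params$min_maf) {
      reason[j] <- "maf"
      next
    }
    p_hwe <- hwe_exact_test(sum(typed == 0L), sum(typed == 1L), sum(typed == 2L))
    if (p_hwe < params$hwe_p_threshold) reason[j] <- "hwe"
  }
  keep <- is.na(reason)
  list(
    gt = subset_variants(gt, keep),
    log = data.frame(id = gt$variants$id, qc_pass = keep,
                     reason = ifelse(keep, "", reason),
                     stringsAsFactors = FALSE)
  )
}

#' Multiple-testing adjustment
#'
#' Adjusts raw p-values by Bonferroni (`min(1, m p)`) or
#' Benjamini-Hochberg step-up with monotonicity enforcement, preserving
#' input order. Thin wrapper over [stats::p.adjust()] with input
#' validation.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Run the allelic association scan
#'
#' QC-filters the genotype table, computes per-variant allele frequencies,
#' the uncorrected allelic chi-square, its p-value and the allelic odds
#' ratio, then adjusts p-values across the tested variants.
#'
#' @param gt a [genotype_table()].
#' @param ph a [phenotype_map()].
#' @param params a [qc_params()] object.
#' @param adjust_method passed to [adjust_pvalues()].
#' @return A data.frame with one row per variant passing QC: `chrom`,
#'   `id`, `pos`, `ref`, `alt`, `F_A`, `F_U`, `chi2`, `p`, `p_adj`, `OR`,
#'   plus attribute `qc_log` carrying the per-variant QC record. Rows keep
#'   the input variant order; sort by `p` for a ranked report.
#' @export
run_association <- function(gt, ph, params = qc_params(),
                            adjust_method = "BH") {
  stopifnot(inherits(ph, "phenotype_map"))
  qc <- qc_filter(gt, ph, params)
  gt_f <- qc$gt
  nvar <- nrow(gt_f$variants)
  if (nvar == 0) {
    warning("no variants remain after QC")
    res <- data.frame(chrom = character(0), id = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), F_A = numeric(0), F_U = numeric(0),
                      chi2 = numeric(0), p = numeric(0), p_adj = numeric(0),
                      OR = numeric(0), stringsAsFactors = FALSE)
    attr(res, "qc_log") <- qc$log
    return(res)
  }
  stats_mat <- t(vapply(seq_len(nvar), function(j) {
    tab <- allele_counts(gt_f, ph, j)
    freq <- allele_frequencies(tab)
    cs <- allelic_chi_square(tab)
    c(freq, cs, OR = allelic_odds_ratio(tab))
  }, numeric(5)))
  res <- data.frame(
    chrom = gt_f$variants$chrom,
    id = gt_f$variants$id,
    pos = gt_f$variants$pos,
    ref = gt_f$variants$ref,
    alt = gt_f$variants$alt,
    F_A = stats_mat[, "F_A"],
    F_U = stats_mat[, "F_U"],
    chi2 = stats_mat[, "chi2"],
    p = stats_mat[, "p"],
    p_adj = adjust_pvalues(stats_mat[, "p"], adjust_method),
    OR = stats_mat[, "OR"],
    stringsAsFactors = FALSE
  )
  attr(res, "qc_log") <- qc$log
  res
}
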