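#' Genotype table
#'
#' A `genotype_table` holds diploid alternate-allele dosages for a cohort:
#' one row per sample, one column per biallelic variant. Dosages are 0, 1 or
#' 2 copies of the alternate allele; missing genotypes (including half
#' calls) are `NA`. Variants are keyed by `(chrom, pos, ref, alt)`; the `id`
#' column carries the rsID when one exists, otherwise the synthesized
#' `"REF > ALT"` label.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `id`. Positions are 1-based. Missing or `"."` ids are replaced by
#'   `"REF > ALT"`.
#' @param samples character vector of sample identifiers.
#' @param calls integer matrix, `length(samples)` rows by `nrow(variants)`
#'   columns, with values in `{0, 1, 2, NA}`.
#' @return An object of class `genotype_table`: a list with elements
#'   `variants`, `samples` and `calls`.
#' @export
genotype_table <- function(variants, samples, calls) {
  variants <- as.data.frame(variants)
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0) {
    stop("variants is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != length(samples) || ncol(calls) != nrow(variants)) {
    stop("calls must be a ", length(samples), " x ", nrow(variants), " matrix")
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) > 0 && (min(bad) < 0L || max(bad) > 2L)) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  if (any(variants$pos < 1)) stop("positions must be >= 1")
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  if (anyDuplicated(samples)) stop("duplicate sample identifiers")
  if (is.null(variants$id)) variants$id <- NA_character_
  variants$id <- ifelse(
    is.na(variants$id) | variants$id == "." | variants$id == "",
    paste(variants$ref, ">", variants$alt),
    variants$id
  )
  rownames(variants) <- NULL
  dimnames(calls) <- list(samples, NULL)
  structure(
    list(variants = variants, samples = as.character(samples), calls = calls),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$samples), "samples x",
      nrow(x$variants), "variants\n")
  n_missing <- sum(is.na(x$calls))
  cat("  missing calls:", n_missing,
      sprintf("(%.1f%%)\n", 100 * n_missing / max(1, length(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) c(length(x$samples), nrow(x$variants))

#' Subset a genotype table by variant index
#'
#' @param gt a [genotype_table()].
#' @param j integer or logical index over variants.
#' @return A `genotype_table` restricted to the selected variants.
#' @export
subset_variants <- function(gt, j) {
  stopifnot(inherits(gt, "genotype_table"))
  genotype_table(
    gt$variants[j, , drop = FALSE],
    gt$samples,
    gt$calls[, j, drop = FALSE]
  )
}

#' Case/control allele-count table
#'
#' The 2x2 table underlying every allelic association statistic:
#' `a`/`b` are alternate/reference allele counts in cases, `c`/`d` the
#' same in controls. Missing genotypes contribute no alleles, so `a + b`
#' is twice the number of genotyped cases.
#'
#' @param a,b,c,d non-negative integer allele counts.
#' @return An object of class `allele_count_table` (named integer vector).
#' @export
allele_count_table <- function(a, b, c, d) {
  x <- c(a = a, b = b, c = c, d = d)
  if (any(x < 0) || any(x != round(x))) {
    stop("allele counts must be non-negative integers")
  }
  if ((a + b) %% 2 != 0 || (c + d) %% 2 != 0) {
    stop("per-group allele totals must be even (diploid samples)")
  }
  structure(as.integer(x), names = names(x), class = "allele_count_table")
}
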