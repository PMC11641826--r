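#' Variants with alternate alleles exclusively in cases
#'
#' Keeps variants satisfying both filter rules: (a) every genotyped
#' (non-missing) control call is homozygous reference, and (b) at least
#' one case carries the alternate allele. Exclusivity is judged on
#' non-missing calls only — a missing control genotype is not evidence of
#' carriage — and the number of missing control calls is reported per
#' variant so that judgement is auditable.
#'
#' @param gt a [genotype_table()].
#' @param ph a [phenotype_map()].
#' @return data.frame with one row per retained variant: `chrom`, `id`,
#'   `pos`, `ref`, `alt`, `C_A` (alternate-allele count in cases) and
#'   `n_missing_controls`. Attribute `index` maps rows back to variant
#'   columns of `gt`.
#' @export
case_exclusive_variants <- function(gt, ph) {
  stopifnot(inherits(gt, "genotype_table"), inherits(ph, "phenotype_map"))
  status <- unclass(ph)[gt$samples]
  is_case <- status == "case"
  keep <- logical(nrow(gt$variants))
  C_A <- integer(nrow(gt$variants))
  miss_ctrl <- integer(nrow(gt$variants))
  for (j in seq_len(nrow(gt$variants))) {
    dos <- gt$calls[, j]
    ctrl <- dos[!is_case]
    case <- dos[is_case]
    ctrl_typed <- ctrl[!is.na(ctrl)]
    C_A[j] <- sum(case, na.rm = TRUE)
    miss_ctrl[j] <- sum(is.na(ctrl))
    keep[j] <- all(ctrl_typed == 0L) && C_A[j] >= 1L
  }
  out <- data.frame(
    chrom = gt$variants$chrom[keep],
    id = gt$variants$id[keep],
    pos = gt$variants$pos[keep],
    ref = gt$variants$ref[keep],
    alt = gt$variants$alt[keep],
    C_A = C_A[keep],
    n_missing_controls = miss_ctrl[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "index") <- which(keep)
  out
}

#' Prioritize case-exclusive variants
#'
#' Joins case-exclusive variants with their consequence annotations and
#' association statistics, keeps variants with raw `p < alpha`, and sorts
#' by (severity rank of the most severe consequence, ascending p). The
#' stricter `listing_alpha` cut used for headline reporting is returned as
#' a logical column rather than a second table.
#'
#' @param variants output of [case_exclusive_variants()].
#' @param annotations a `consequence_annotation` table
#'   (see [read_vep_table()]); variants lacking any annotation are
#'   retained with unknown severity and flagged.
#' @param results association results from [run_association()], matched by
#'   variant `id`, `chrom` and `pos`.
#' @param alpha significance level on the raw p-value (default 0.05).
#' @param listing_alpha stricter threshold flagged in the output
#'   (default 0.005).
#' @return data.frame with columns `chrom`, `id`, `pos`, `gene`, `C_A`,
#'   `consequence`, `severity_rank`, `chi2`, `p`, `passes_listing`,
#'   ordered by severity then p.
#' @export
prioritize <- function(variants, annotations, results,
                       alpha = 0.05, listing_alpha = 0.005) {
  if (alpha <= 0 || nrow(variants) == 0) {
    return(data.frame(chrom = character(0), id = character(0),
                      pos = integer(0), gene = character(0),
                      C_A = integer(0), consequence = character(0),
                      severity_rank = integer(0), chi2 = numeric(0),
                      p = numeric(0), passes_listing = logical(0),
                      stringsAsFactors = FALSE))
  }
  key <- function(chrom, pos, id) paste(chrom, pos, id, sep = ":")
  res_key <- key(results$chrom, results$pos, results$id)
  var_key <- key(variants$chrom, variants$pos, variants$id)

  rows <- lapply(seq_len(nrow(variants)), function(i) {
    ri <- match(var_key[i], res_key)
    if (is.na(ri)) return(NULL)  # removed by QC upstream
    ann <- annotations[annotations$variant_id == variants$id[i], , drop = FALSE]
    if (nrow(ann) == 0) {
      genes <- NA_character_
      cons <- NA_character_
      rank <- max(severity_table()$rank) + 1L
      message("variant ", variants$id[i], " has no consequence annotation; ",
              "retained with unknown severity")
    } else {
      cons <- most_severe(unlist(ann$terms))
      rank <- severity_rank(cons)
      genes <- paste(sort(unique(ann$gene)), collapse = ",")
    }
    data.frame(chrom = variants$chrom[i], id = variants$id[i],
               pos = variants$pos[i], gene = genes, C_A = variants$C_A[i],
               consequence = cons, severity_rank = rank,
               chi2 = results$chi2[ri], p = results$p[ri],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) return(prioritize(variants[0, ], annotations, results))
  out <- out[!is.na(out$p) & out$p < alpha, , drop = FALSE]
  out <- out[order(out$severity_rank, out$p, out$chrom, out$pos), , drop = FALSE]
  out$passes_listing <- out$p < listing_alpha
  rownames(out) <- NULL
  out
}
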