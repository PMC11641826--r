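#' Gene-level aggregation of case-exclusive variants
#'
#' Collapses prioritized case-exclusive variants to one row per gene,
#' modelling additive impairment: the per-variant case alternate-allele
#' counts are summed. A variant annotated to several genes contributes to
#' each of them. Aggregates are sorted by allele sum (descending), then
#' gene name.
#'
#' @param variants data.frame as returned by [prioritize()]: columns
#'   `gene` (comma-separated if multiple), `id`, `C_A`, `consequence`.
#' @return data.frame with columns `gene`, `n_variants`, `allele_counts`
#'   (comma-separated per-variant counts, descending), `allele_sum` and
#'   `consequences` (comma-separated, matching `allele_counts` order).
#' @export
aggregate_by_gene <- function(variants) {
  empty <- data.frame(gene = character(0), n_variants = integer(0),
                      allele_counts = character(0), allele_sum = integer(0),
                      consequences = character(0), stringsAsFactors = FALSE)
  if (nrow(variants) == 0) return(empty)
  # expand multi-gene annotations to one row per (variant, gene)
  expanded <- do.call(rbind, lapply(seq_len(nrow(variants)), function(i) {
    genes <- strsplit(variants$gene[i], ",", fixed = TRUE)[[1]]
    genes <- genes[!is.na(genes) & genes != ""]
    if (length(genes) == 0) return(NULL)
    data.frame(gene = genes, id = variants$id[i], C_A = variants$C_A[i],
               consequence = variants$consequence[i], stringsAsFactors = FALSE)
  }))
  if (is.null(expanded)) return(empty)
  # a variant may appear once per gene but never twice within a gene
  expanded <- expanded[!duplicated(expanded[c("gene", "id")]), , drop = FALSE]
  aggs <- lapply(split(expanded, expanded$gene), function(g) {
    ord <- order(-g$C_A, g$id)
    data.frame(gene = g$gene[1], n_variants = nrow(g),
               allele_counts = paste(g$C_A[ord], collapse = ","),
               allele_sum = sum(g$C_A),
               consequences = paste(g$consequence[ord], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, aggs)
  out <- out[order(-out$allele_sum, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Multi-variant co-occurrence filter
#'
#' Retains gene aggregates with at least `min_variants` case-exclusive
#' variants and a summed case alternate-allele count of at least
#' `min_allele_sum`. The defaults (2 variants, sum >= 10) define the
#' standard multi-variant route; `strict_preset = TRUE` switches to the
#' stricter 3-variant / sum >= 14 preset.
#'
#' @param aggs output of [aggregate_by_gene()].
#' @param min_variants minimum number of variants per gene.
#' @param min_allele_sum minimum summed case alternate-allele count.
#' @param strict_preset use the stricter (3, 14) preset instead of the
#'   supplied thresholds.
#' @return The filtered aggregate data.frame.
#' @export
multi_variant_genes <- function(aggs, min_variants = 2, min_allele_sum = 10,
                                strict_preset = FALSE) {
  if (strict_preset) {
    min_variants <- 3
    min_allele_sum <- 14
  }
  keep <- aggs$n_variants >= min_variants & aggs$allele_sum >= min_allele_sum
  out <- aggs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the genes-of-interest set
#'
#' Unions the single-variant route (genes carrying one significant
#' case-exclusive variant) with the multi-variant co-occurrence route.
#' The two routes must be disjoint by construction; an overlap indicates
#' the caller double-counted a gene and is an error.
#'
#' @param single_route character vector of gene symbols.
#' @param multi_route output of [multi_variant_genes()] (or a character
#'   vector of gene symbols).
#' @return A list of class `goi_set` with elements `single_variant_genes`,
#'   `multi_variant_genes` and `union` (sorted).
#' @export
genes_of_interest <- function(single_route, multi_route) {
  single <- sort(unique(as.character(single_route)))
  multi <- if (is.data.frame(multi_route)) multi_route$gene else multi_route
  multi <- sort(unique(as.character(multi)))
  overlap <- intersect(single, multi)
  if (length(overlap) > 0) {
    stop("gene(s) present in both routes: ", paste(overlap, collapse = ", "))
  }
  structure(
    list(single_variant_genes = single, multi_variant_genes = multi,
         union = sort(c(single, multi))),
    class = "goi_set"
  )
}

#' @export
print.goi_set <- function(x, ...) {
  cat("genes of interest:", length(x$union), "total\n")
  cat("  single-variant route:", length(x$single_variant_genes), "\n")
  cat("  multi-variant route: ", length(x$multi_variant_genes), "\n")
  invisible(x)
}
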