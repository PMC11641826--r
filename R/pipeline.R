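#' Pipeline configuration
#'
#' Bundles input paths and analysis thresholds for [run_panel_scan()] and
#' [run_full()]. Threshold defaults follow the analysis this package
#' implements: panel scan reports raw `p < 0.01`; the case-exclusive
#' filter keeps raw `p < 0.05` with a stricter `p < 0.005` listing cut;
#' the co-occurrence route requires at least 2 variants summing to at
#' least 10 case alternate alleles; the network is filtered at normalized
#' score 0.8.
#'
#' @param vcf,phenotypes paths to the genotype VCF and phenotype TSV.
#' @param vep_table path to the VEP-style annotation TSV (optional for the
#'   panel scan).
#' @param gene_regions path to a gene-region TSV, or `NULL` to use the
#'   packaged [gene_panel()].
#' @param string_links path to a STRING-style protein-links file, or
#'   `NULL` to skip the network stage.
#' @param qc a [qc_params()] object.
#' @param panel_alpha,exclusive_alpha,listing_alpha raw p-value thresholds.
#' @param min_variants,min_allele_sum co-occurrence route thresholds.
#' @param norm_threshold normalized interaction-score cutoff in `[0, 1]`.
#' @param flank locus flank in bp for the panel scan.
#' @param out_dir directory where [run_full()] writes its TSV reports.
#' @param seed integer seed recorded in the run manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, phenotypes, vep_table = NULL,
                            gene_regions = NULL, string_links = NULL,
                            qc = qc_params(),
                            panel_alpha = 0.01, exclusive_alpha = 0.05,
                            listing_alpha = 0.005, min_variants = 2,
                            min_allele_sum = 10, norm_threshold = 0.8,
                            flank = 5000, out_dir = NULL, seed = 1L) {
  thresholds <- c(panel_alpha, exclusive_alpha, listing_alpha)
  if (any(thresholds < 0) || any(thresholds > 1)) {
    stop("alpha thresholds must lie in [0, 1]")
  }
  if (norm_threshold < 0 || norm_threshold > 1) {
    stop("norm_threshold must lie in [0, 1]")
  }
  structure(list(vcf = vcf, phenotypes = phenotypes, vep_table = vep_table,
                 gene_regions = gene_regions, string_links = string_links,
                 qc = qc, panel_alpha = panel_alpha,
                 exclusive_alpha = exclusive_alpha,
                 listing_alpha = listing_alpha, min_variants = min_variants,
                 min_allele_sum = min_allele_sum,
                 norm_threshold = norm_threshold, flank = flank,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

.check_input <- function(path, what) {
  if (is.null(path)) return(invisible(NULL))
  if (!file.exists(path)) stop(what, " file not found: ", path)
  invisible(NULL)
}

.write_report <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.table(df, file.path(out_dir, name), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(NULL)
}

#' Panel scan over literature gene loci
#'
#' Restricts the cohort to the extended loci (gene body plus `flank` on
#' each side) of the configured gene panel, applies QC, runs the allelic
#' association test, and reports variants with raw `p < panel_alpha`,
#' ordered by p then position. When an annotation table is configured,
#' each reported variant carries its most severe consequence.
#'
#' @param config a [pipeline_config()].
#' @return data.frame: `chrom`, `id`, `pos`, `gene`, `F_A`, `F_U`,
#'   `consequence`, `chi2`, `p`, `p_adj`, `OR` (`NA` when undefined).
#' @export
run_panel_scan <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  .check_input(config$vcf, "VCF")
  .check_input(config$phenotypes, "phenotype")
  gt <- read_vcf(config$vcf)
  ph <- read_phenotypes(config$phenotypes)
  regions <- if (is.null(config$gene_regions)) gene_panel() else
    read_gene_regions(config$gene_regions)
  gt_panel <- extract_gene_loci(gt, regions, flank = config$flank)
  res <- run_association(gt_panel, ph, config$qc)
  res <- res[!is.na(res$p) & res$p < config$panel_alpha, , drop = FALSE]
  res <- res[order(res$p, res$pos), , drop = FALSE]

  # attach the overlapping panel gene(s) and, if available, consequences
  res$gene <- vapply(seq_len(nrow(res)), function(i) {
    hit <- regions$chrom == res$chrom[i] &
      res$pos[i] >= regions$start - config$flank &
      res$pos[i] <= regions$end + config$flank
    paste(sort(regions$gene[hit]), collapse = ",")
  }, character(1))
  res$consequence <- rep(NA_character_, nrow(res))
  if (!is.null(config$vep_table)) {
    ann <- read_vep_table(config$vep_table)
    res$consequence <- vapply(res$id, function(vid) {
      terms <- unlist(ann$terms[ann$variant_id == vid])
      if (length(terms) == 0) NA_character_ else most_severe(terms)
    }, character(1))
  }
  out <- res[c("chrom", "id", "pos", "gene", "F_A", "F_U", "consequence",
               "chi2", "p", "p_adj", "OR")]
  rownames(out) <- NULL
  out
}

#' Run the full prioritization pipeline
#'
#' Executes every stage on the configured inputs: panel scan, genome-wide
#' QC and association, case-exclusive filtering with consequence-severity
#' prioritization, gene-level co-occurrence aggregation, assembly of the
#' genes-of-interest set, and (when a protein-links file is configured)
#' normalized-score network filtering with seed-gene subnetwork extraction
#' and connected components. When `out_dir` is set, each stage's table is
#' written as TSV alongside a run manifest with per-stage row counts.
#'
#' @param config a [pipeline_config()].
#' @return A list with elements `panel`, `association`, `case_exclusive`,
#'   `aggregates`, `multi_variant`, `goi`, `subnetwork` (or `NULL`),
#'   `components` (or `NULL`) and `manifest`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  .check_input(config$vcf, "VCF")
  .check_input(config$phenotypes, "phenotype")
  .check_input(config$vep_table, "annotation")
  .check_input(config$string_links, "protein-links")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  }

  gt <- read_vcf(config$vcf)
  ph <- read_phenotypes(config$phenotypes)
  ann <- if (is.null(config$vep_table)) NULL else read_vep_table(config$vep_table)

  panel <- run_panel_scan(config)
  .write_report(panel, config$out_dir, "panel_scan.tsv")

  assoc <- run_association(gt, ph, config$qc)

  excl <- case_exclusive_variants(gt, ph)
  if (is.null(ann)) {
    ann <- structure(
      data.frame(variant_id = character(0), gene = character(0)),
      class = c("consequence_annotation", "data.frame")
    )
    ann$terms <- list(); ann$unknown_terms <- list()
  }
  prio <- prioritize(excl, ann, assoc,
                     alpha = config$exclusive_alpha,
                     listing_alpha = config$listing_alpha)
  .write_report(prio, config$out_dir, "case_exclusive.tsv")

  aggs <- aggregate_by_gene(prio)
  .write_report(aggs, config$out_dir, "gene_aggregates.tsv")
  multi <- multi_variant_genes(aggs, config$min_variants, config$min_allele_sum)
  .write_report(multi, config$out_dir, "multi_variant_genes.tsv")

  # single-variant route: genes whose only significant case-exclusive
  # variants pass the stricter listing cut and that are not multi-variant
  single_genes <- setdiff(
    unique(unlist(strsplit(prio$gene[prio$passes_listing], ",", fixed = TRUE))),
    multi$gene
  )
  single_genes <- sort(single_genes[!is.na(single_genes) & single_genes != ""])
  goi <- genes_of_interest(single_genes, multi)
  if (!is.null(config$out_dir)) {
    writeLines(goi$union, file.path(config$out_dir, "genes_of_interest.txt"))
  }

  subnet <- NULL
  comps <- NULL
  if (!is.null(config$string_links)) {
    g <- read_string_links(config$string_links)
    g <- normalize_scores(g)
    g <- filter_edges(g, config$norm_threshold, use_norm = TRUE)
    subnet <- extract_subnetwork(g, goi$union)
    comps <- connected_components(subnet)
    if (!is.null(config$out_dir)) {
      .write_report(subnet$edges, config$out_dir, "subnetwork_edges.tsv")
      node_attr <- subnet$node_route
      node_attr$route[node_attr$node %in% goi$single_variant_genes] <- "seed_single_variant"
      node_attr$route[node_attr$node %in% goi$multi_variant_genes] <- "seed_multi_variant"
      .write_report(node_attr, config$out_dir, "subnetwork_nodes.tsv")
      comp_df <- data.frame(
        component = rep(seq_along(comps), lengths(comps)),
        node = unlist(comps)
      )
      .write_report(comp_df, config$out_dir, "components.tsv")
    }
  }

  manifest <- data.frame(
    stage = c("panel_scan", "association", "case_exclusive",
              "gene_aggregates", "multi_variant_genes", "genes_of_interest",
              "subnetwork_nodes", "components"),
    rows = c(nrow(panel), nrow(assoc), nrow(prio), nrow(aggs), nrow(multi),
             length(goi$union),
             if (is.null(subnet)) NA_integer_ else length(subnet$selected_nodes),
             if (is.null(comps)) NA_integer_ else length(comps)),
    stringsAsFactors = FALSE
  )
  manifest_meta <- data.frame(
    stage = c("seed", "exclusive_alpha", "listing_alpha", "norm_threshold"),
    rows = c(config$seed, config$exclusive_alpha, config$listing_alpha,
             config$norm_threshold)
  )
  .write_report(rbind(manifest, manifest_meta), config$out_dir, "run_manifest.tsv")

  list(panel = panel, association = assoc, case_exclusive = prio,
       aggregates = aggs, multi_variant = multi, goi = goi,
       subnetwork = subnet, components = comps, manifest = manifest)
}
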