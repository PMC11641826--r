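#' Cohort simulation specification
#'
#' Defines a synthetic diploid case-control cohort. Defaults mirror the
#' study design this package targets: 12 cases and 11 controls, background
#' variants at a shared minor-allele frequency drawn uniformly from
#' `maf_range`, and planted case-exclusive variants whose case
#' alternate-allele counts fall in the 4-11 range typical of
#' carrier-exclusive rare variants in a cohort of this size.
#'
#' @param n_cases,n_controls sample counts.
#' @param n_null_variants number of background variants with identical
#'   allele frequency in both groups.
#' @param maf_range allele-frequency interval for background variants.
#' @param planted data.frame with columns `gene`, `C_A` (case
#'   alternate-allele count) and `consequence` (term string), one row per
#'   planted case-exclusive variant; `NULL` for none.
#' @param missing_rate per-call probability of a missing genotype.
#' @param protect_planted if `TRUE` (default), planted carrier calls are
#'   never erased by missingness, so the observable case count equals the
#'   specified `C_A`.
#' @param seed integer random seed for the draw.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 12, n_controls = 11,
                        n_null_variants = 100,
                        maf_range = c(0.05, 0.5),
                        planted = NULL,
                        missing_rate = 0,
                        protect_planted = TRUE,
                        seed = 1L) {
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must lie in [0, 1]")
  if (any(maf_range < 0) || any(maf_range > 1) || maf_range[1] > maf_range[2]) {
    stop("maf_range must be an interval within [0, 1]")
  }
  if (!is.null(planted)) {
    planted <- as.data.frame(planted)
    needed <- c("gene", "C_A", "consequence")
    missing_cols <- setdiff(needed, names(planted))
    if (length(missing_cols) > 0) {
      stop("planted is missing column(s): ", paste(missing_cols, collapse = ", "))
    }
    if (any(planted$C_A > 2 * n_cases)) {
      stop("planted C_A exceeds the number of case chromosomes (",
           2 * n_cases, ")")
    }
    if (any(planted$C_A < 1)) stop("planted C_A must be >= 1")
  }
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 n_null_variants = n_null_variants, maf_range = maf_range,
                 planted = planted, missing_rate = missing_rate,
                 protect_planted = protect_planted, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a case-control cohort
#'
#' Draws a synthetic [genotype_table()] and [phenotype_map()] from a
#' [cohort_spec()]. Background ("null") variants are sampled with the same
#' allele frequency in cases and controls (independent Bernoulli draws per
#' chromosome, i.e. binomial dosages); planted variants place exactly
#' `C_A` alternate alleles on randomly chosen case chromosomes and none in
#' controls. Missingness is applied afterwards, never erasing a planted
#' carrier when `protect_planted` is set. The truth manifest records each
#' planted variant for downstream recovery checks.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir if non-`NULL`, the cohort is also written there as
#'   `cohort.vcf`, `phenotypes.tsv` and `truth.tsv`.
#' @return A list with `gt` ([genotype_table()]), `ph`
#'   ([phenotype_map()]), and `truth` (data.frame: `id`, `chrom`, `pos`,
#'   `gene`, `C_A`, `consequence`; zero rows when nothing is planted).
#' @export
simulate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n_cases <- spec$n_cases
  n_controls <- spec$n_controls
  n <- n_cases + n_controls
  samples <- c(sprintf("case%02d", seq_len(n_cases)),
               sprintf("ctrl%02d", seq_len(n_controls)))
  status <- c(rep("case", n_cases), rep("control", n_controls))
  ph <- phenotype_map(samples, status)

  n_planted <- if (is.null(spec$planted)) 0L else nrow(spec$planted)
  nvar <- spec$n_null_variants + n_planted
  if (nvar == 0) stop("specification yields no variants")
  calls <- matrix(0L, nrow = n, ncol = nvar)
  planted_carrier <- matrix(FALSE, nrow = n, ncol = nvar)

  # planted case-exclusive variants occupy the first columns
  if (n_planted > 0) {
    for (j in seq_len(n_planted)) {
      chrom_idx <- sample(2L * n_cases, spec$planted$C_A[j])
      dosage <- tabulate((chrom_idx + 1L) %/% 2L, nbins = n_cases)
      calls[seq_len(n_cases), j] <- as.integer(dosage)
      planted_carrier[seq_len(n_cases), j] <- dosage > 0
    }
  }
  if (spec$n_null_variants > 0) {
    mafs <- stats::runif(spec$n_null_variants, spec$maf_range[1], spec$maf_range[2])
    for (k in seq_len(spec$n_null_variants)) {
      calls[, n_planted + k] <- stats::rbinom(n, 2L, mafs[k])
    }
  }
  if (spec$missing_rate > 0) {
    miss <- matrix(stats::runif(n * nvar) < spec$missing_rate, nrow = n)
    if (spec$protect_planted) miss[planted_carrier] <- FALSE
    calls[miss] <- NA_integer_
  }

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nvar, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  variants <- data.frame(
    chrom = "1",
    pos = 1000000L + 100L * seq_len(nvar),
    ref = ref, alt = alt,
    id = sprintf("var%04d", seq_len(nvar)),
    stringsAsFactors = FALSE
  )
  gt <- genotype_table(variants, samples, calls)

  truth <- if (n_planted > 0) {
    data.frame(id = variants$id[seq_len(n_planted)],
               chrom = variants$chrom[seq_len(n_planted)],
               pos = variants$pos[seq_len(n_planted)],
               gene = spec$planted$gene, C_A = spec$planted$C_A,
               consequence = spec$planted$consequence,
               stringsAsFactors = FALSE)
  } else {
    data.frame(id = character(0), chrom = character(0), pos = integer(0),
               gene = character(0), C_A = integer(0),
               consequence = character(0), stringsAsFactors = FALSE)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_vcf(gt, file.path(out_dir, "cohort.vcf"))
    utils::write.table(
      data.frame(sample = samples, code = ifelse(status == "case", 2L, 1L)),
      file.path(out_dir, "phenotypes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
    utils::write.table(truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(gt = gt, ph = ph, truth = truth)
}

#' Simulate VEP-style annotations for a cohort
#'
#' Planted variants receive their specified gene and consequence term;
#' background variants are assigned decoy genes and mostly noncoding terms
#' (`coding_fraction` of them get a missense call instead of an intronic
#' one).
#'
#' @param gt the simulated [genotype_table()].
#' @param truth the truth manifest from [simulate_cohort()].
#' @param n_decoy_genes number of decoy gene symbols to spread the
#'   background variants over.
#' @param coding_fraction fraction of background variants annotated with a
#'   coding consequence.
#' @param seed integer random seed.
#' @return A `consequence_annotation` data.frame (see [read_vep_table()]).
#' @export
simulate_annotations <- function(gt, truth, n_decoy_genes = 20,
                                 coding_fraction = 0.1, seed = 1L) {
  stopifnot(inherits(gt, "genotype_table"))
  set.seed(seed)
  ids <- gt$variants$id
  planted_idx <- match(truth$id, ids)
  gene <- character(length(ids))
  term <- character(length(ids))
  gene[planted_idx] <- truth$gene
  term[planted_idx] <- truth$consequence
  null_idx <- setdiff(seq_along(ids), planted_idx)
  if (length(null_idx) > 0) {
    gene[null_idx] <- sprintf("DECOY%03d",
                              sample(n_decoy_genes, length(null_idx), replace = TRUE))
    coding <- stats::runif(length(null_idx)) < coding_fraction
    term[null_idx] <- ifelse(coding, "missense_variant", "intron_variant")
  }
  out <- data.frame(variant_id = ids, gene = gene, stringsAsFactors = FALSE)
  out$terms <- lapply(strsplit(term, ",", fixed = TRUE), .normalize_term)
  out$unknown_terms <- lapply(out$terms, function(t) setdiff(t, severity_table()$term))
  structure(out, class = c("consequence_annotation", "data.frame"))
}

#' Write annotations as a VEP-style table
#'
#' @param ann a `consequence_annotation` data.frame.
#' @param path output path (tab-delimited, VEP-style header).
#' @return `path`, invisibly.
#' @export
write_vep_table <- function(ann, path) {
  tab <- data.frame(
    Uploaded_variation = ann$variant_id,
    Location = ".",
    SYMBOL = ann$gene,
    Consequence = vapply(ann$terms, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(tab), collapse = "\t")), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Interaction-graph simulation specification
#'
#' @param n_nodes number of background nodes (labelled `g001`, ...).
#' @param background_edge_prob probability of an edge between any two
#'   background nodes.
#' @param background_score mean and sd of the background score mode
#'   (scores drawn normal, rounded and clamped to `[1, 1000]`).
#' @param module_nodes character vector of planted high-confidence module
#'   nodes (added to the graph; fully connected among themselves).
#' @param module_score mean and sd of the module score mode.
#' @param seed integer random seed.
#' @return A list of class `graph_spec`.
#' @export
graph_spec <- function(n_nodes = 100, background_edge_prob = 0.05,
                       background_score = c(mean = 400, sd = 100),
                       module_nodes = character(0),
                       module_score = c(mean = 950, sd = 30),
                       seed = 1L) {
  structure(list(n_nodes = n_nodes,
                 background_edge_prob = background_edge_prob,
                 background_score = background_score,
                 module_nodes = module_nodes,
                 module_score = module_score,
                 seed = as.integer(seed)),
            class = "graph_spec")
}

#' Simulate a STRING-like interaction graph
#'
#' Background edges are sampled independently between background nodes at
#' `background_edge_prob` with scores from the low-confidence mode; the
#' planted module is a clique over `module_nodes` with scores from the
#' high-confidence mode, plus one low-score edge from each module node to
#' a random background node so the module is embedded rather than
#' floating. The result round-trips through [write_string_links()] /
#' [read_string_links()].
#'
#' @param spec a [graph_spec()].
#' @param out_path if non-`NULL`, the edge list is written there in
#'   STRING protein-links format.
#' @return A list with `graph` (a [ppi_graph()]) and `truth` (list:
#'   `module_nodes`, `module_edges` data.frame).
#' @export
simulate_ppi <- function(spec, out_path = NULL) {
  stopifnot(inherits(spec, "graph_spec"))
  set.seed(spec$seed)
  clamp_score <- function(x) pmin(1000L, pmax(1L, as.integer(round(x))))
  bg_nodes <- sprintf("g%03d", seq_len(spec$n_nodes))
  pairs <- if (spec$n_nodes >= 2) t(utils::combn(bg_nodes, 2)) else
    matrix(character(0), ncol = 2)
  keep <- stats::runif(nrow(pairs)) < spec$background_edge_prob
  bg <- data.frame(protein1 = pairs[keep, 1], protein2 = pairs[keep, 2],
                   stringsAsFactors = FALSE)
  bg$combined_score <- clamp_score(stats::rnorm(
    nrow(bg), spec$background_score[["mean"]], spec$background_score[["sd"]]))

  mod_edges <- data.frame(protein1 = character(0), protein2 = character(0),
                          combined_score = integer(0), stringsAsFactors = FALSE)
  if (length(spec$module_nodes) >= 2) {
    mp <- t(utils::combn(spec$module_nodes, 2))
    mod_edges <- data.frame(protein1 = mp[, 1], protein2 = mp[, 2],
                            stringsAsFactors = FALSE)
    mod_edges$combined_score <- clamp_score(stats::rnorm(
      nrow(mod_edges), spec$module_score[["mean"]], spec$module_score[["sd"]]))
    if (spec$n_nodes > 0) {
      anchors <- data.frame(
        protein1 = spec$module_nodes,
        protein2 = sample(bg_nodes, length(spec$module_nodes), replace = TRUE),
        stringsAsFactors = FALSE
      )
      anchors$combined_score <- clamp_score(stats::rnorm(
        nrow(anchors), spec$background_score[["mean"]],
        spec$background_score[["sd"]]))
      mod_edges <- rbind(mod_edges, anchors)
    }
  }
  g <- ppi_graph(rbind(bg, mod_edges))
  if (!is.null(out_path)) write_string_links(g, out_path)
  list(graph = g,
       truth = list(module_nodes = spec$module_nodes,
                    module_edges = mod_edges))
}
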