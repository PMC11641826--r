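#' Packaged consequence-severity table
#'
#' Returns the shipped severity ordering of sequence-ontology consequence
#' terms (rank 1 = most severe). The top block of ten terms — transcript
#' ablation, splice acceptor/donor, stop gained/lost, frameshift, start
#' lost, transcript amplification, feature elongation and feature
#' truncation — is the most-severe set used for prioritization; the
#' remainder follows the canonical VEP ordering.
#'
#' @return data.frame with columns `term` (lower_snake_case) and `rank`
#'   (unique positive integer, smaller = more severe).
#' @export
severity_table <- function() {
  path <- system.file("extdata", "consequence_severity.tsv",
                      package = "casexnet", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

.normalize_term <- function(x) {
  x <- tolower(trimws(x))
  gsub("[ -]+", "_", x)
}

#' Severity rank of consequence terms
#'
#' Maps terms to their packaged severity rank. Unknown terms are not an
#' error: they receive a rank one past the least severe packaged term, so
#' new ontology terms sort last instead of breaking the pipeline.
#'
#' @param terms character vector of consequence terms.
#' @return Integer vector of ranks.
#' @export
severity_rank <- function(terms) {
  tab <- severity_table()
  idx <- match(.normalize_term(terms), tab$term)
  out <- tab$rank[idx]
  out[is.na(idx)] <- max(tab$rank) + 1L
  out
}

#' Read a VEP-style annotation table
#'
#' Parses tab-delimited VEP output with (at least) the columns
#' `Uploaded_variation`, `SYMBOL` (or `Gene`) and `Consequence`.
#' Comma-separated multi-term consequence cells are split; terms are
#' normalized to lower_snake_case. One row of the result per
#' (variant, gene) pair.
#'
#' @param path path to the annotation file. Lines starting with `##` are
#'   skipped; the header may carry a leading `#`.
#' @return data.frame of class `consequence_annotation` with columns
#'   `variant_id`, `gene`, `terms` (list column of character vectors) and
#'   `unknown_terms` (list column of terms absent from the packaged
#'   severity table, usually empty).
#' @export
read_vep_table <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^##", lines)]
  if (length(lines) <= 1) {
    warning("annotation file has no data rows: ", path)
    return(structure(
      data.frame(variant_id = character(0), gene = character(0)),
      class = c("consequence_annotation", "data.frame")
    ))
  }
  lines[1] <- sub("^#", "", lines[1])
  tab <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  gene_col <- intersect(c("SYMBOL", "Gene"), names(tab))[1]
  needed <- c("Uploaded_variation", "Consequence")
  for (col in needed) {
    if (!col %in% names(tab)) stop("annotation file missing required column: ", col)
  }
  if (is.na(gene_col)) stop("annotation file missing required column: SYMBOL or Gene")
  known <- severity_table()$term
  term_lists <- lapply(strsplit(tab$Consequence, ",", fixed = TRUE),
                       .normalize_term)
  out <- data.frame(variant_id = tab$Uploaded_variation,
                    gene = tab[[gene_col]], stringsAsFactors = FALSE)
  out$terms <- term_lists
  out$unknown_terms <- lapply(term_lists, function(t) setdiff(t, known))
  n_unknown <- sum(lengths(out$unknown_terms))
  if (n_unknown > 0) {
    warning(n_unknown, " consequence term(s) not in the packaged severity table; ",
            "they will rank least severe")
  }
  structure(out, class = c("consequence_annotation", "data.frame"))
}

#' Most severe consequence of a variant
#'
#' Given all consequence terms annotated to one variant (across genes and
#' transcripts), returns the term with the smallest severity rank; ties
#' are broken by lexicographic term order so the result is deterministic.
#'
#' @param terms character vector of consequence terms for one variant.
#' @return A single consequence term.
#' @export
most_severe <- function(terms) {
  terms <- .normalize_term(unlist(terms))
  if (length(terms) == 0) stop("no consequence annotations supplied")
  ranks <- severity_rank(terms)
  candidates <- sort(unique(terms[ranks == min(ranks)]))
  candidates[1]
}

#' Coding-consequence predicate
#'
#' `TRUE` exactly for consequence terms that alter the coding sequence:
#' stop gained/lost, start lost, frameshift, inframe insertion/deletion,
#' missense, synonymous, protein altering, and the structural most-severe
#' block (transcript ablation/amplification, splice acceptor/donor,
#' feature elongation/truncation).
#'
#' @param term character vector of consequence terms.
#' @return Logical vector.
#' @export
is_coding <- function(term) {
  coding_set <- c(
    "stop_gained", "stop_lost", "start_lost", "frameshift_variant",
    "inframe_insertion", "inframe_deletion", "missense_variant",
    "synonymous_variant", "protein_altering_variant",
    "transcript_ablation", "splice_acceptor_variant",
    "splice_donor_variant", "transcript_amplification",
    "feature_elongation", "feature_truncation"
  )
  .normalize_term(term) %in% coding_set
}
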