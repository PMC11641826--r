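#' Construct a weighted interaction graph
#'
#' Validates and canonicalizes an undirected weighted edge list in the
#' STRING protein-links convention: integer `combined_score` on a 0-1000
#' confidence scale. Self-loops are dropped; duplicate unordered pairs are
#' merged keeping the maximum score.
#'
#' @param edges data.frame with columns `protein1`, `protein2`,
#'   `combined_score`.
#' @return data.frame of class `ppi_graph` with canonical (sorted) node
#'   pairs, one row per unordered pair.
#' @export
ppi_graph <- function(edges) {
  edges <- as.data.frame(edges)
  needed <- c("protein1", "protein2", "combined_score")
  missing_cols <- setdiff(needed, names(edges))
  if (length(missing_cols) > 0) {
    stop("edge list missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  s <- edges$combined_score
  bad <- which(is.na(s) | s != round(s) | s < 0 | s > 1000)
  if (length(bad) > 0) {
    stop("combined_score must be an integer in [0, 1000]; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  edges <- edges[edges$protein1 != edges$protein2, , drop = FALSE]
  u <- pmin(edges$protein1, edges$protein2)
  v <- pmax(edges$protein1, edges$protein2)
  key <- paste(u, v, sep = "\r")
  score <- tapply(edges$combined_score, key, max)
  keys <- names(score)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    protein1 = vapply(parts, `[`, character(1), 1),
    protein2 = vapply(parts, `[`, character(1), 2),
    combined_score = as.integer(score),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$protein1, out$protein2), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ppi_graph", "data.frame"))
}

#' Read a STRING-style protein-links file
#'
#' Parses a whitespace-delimited file with header
#' `protein1 protein2 combined_score` into a deduplicated undirected
#' [ppi_graph()]. When both orientations of a pair appear, the maximum
#' score is kept. A malformed score is reported with its line number.
#'
#' @param path path to the links file.
#' @return A `ppi_graph` edge list.
#' @export
read_string_links <- function(path) {
  if (!file.exists(path)) stop("protein-links file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "character"))
  needed <- c("protein1", "protein2", "combined_score")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0) {
    stop("protein-links file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  score <- suppressWarnings(as.numeric(tab$combined_score))
  bad <- which(is.na(score) | score != round(score) | score < 0 | score > 1000)
  if (length(bad) > 0) {
    stop("invalid combined_score at line ", bad[1] + 1L, " of ", path,
         " (must be an integer in [0, 1000])")
  }
  tab$combined_score <- as.integer(score)
  ppi_graph(tab)
}

#' Write a graph in STRING protein-links format
#'
#' @param g a [ppi_graph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_string_links <- function(g, path) {
  utils::write.table(g[c("protein1", "protein2", "combined_score")], path,
                     sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.graph_nodes <- function(g) sort(unique(c(g$protein1, g$protein2)))

.as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    g[c("protein1", "protein2")], directed = FALSE,
    vertices = .graph_nodes(g)
  )
}

#' Per-gene score normalization
#'
#' Rescales each edge's `combined_score` by the per-endpoint maxima so
#' that every gene retains its best interaction at full confidence: with
#' `M(x)` the maximum combined score over edges incident to `x`, edge
#' `(u, v)` gets `norm_score = s / min(M(u), M(v))` — equivalently the
#' larger of the two per-endpoint normalizations. Every non-isolated
#' node's strongest edge therefore has `norm_score = 1`, which prevents an
#' absolute score threshold from silently dropping genes whose best
#' interaction is modest.
#'
#' @param g a [ppi_graph()].
#' @return The graph with an added `norm_score` column in `(0, 1]`.
#' @export
normalize_scores <- function(g) {
  stopifnot(inherits(g, "ppi_graph"))
  if (nrow(g) == 0) {
    g$norm_score <- numeric(0)
    return(g)
  }
  node_max <- tapply(
    c(g$combined_score, g$combined_score),
    c(g$protein1, g$protein2),
    max
  )
  m_u <- node_max[g$protein1]
  m_v <- node_max[g$protein2]
  g$norm_score <- g$combined_score / pmin(m_u, m_v)
  g
}

#' Score distribution and threshold minimum
#'
#' Bins edge scores into a histogram of percent-of-total interactions and
#' locates the interior minimum from which the high-confidence mode rises:
#' the smallest-percentage interior bin that has larger bins on both
#' sides. When the histogram has no such interior minimum (e.g. a flat or
#' monotone profile) the minimum is reported as `NA` with a warning, and
#' the caller should fall back to the conventional thresholds (800 raw,
#' 0.8 normalized).
#'
#' @param g a [ppi_graph()], normalized first if `use_norm = TRUE`.
#' @param bin_width bin width: 25 score units (raw) or 0.025 (normalized)
#'   by default.
#' @param use_norm bin the `norm_score` column instead of `combined_score`.
#' @return A list with `histogram` (data.frame: `bin_low`, `bin_high`,
#'   `percent`) and `minimum` (score at the detected minimum bin's lower
#'   edge, or `NA`).
#' @export
score_distribution <- function(g, bin_width = if (use_norm) 0.025 else 25,
                               use_norm = FALSE) {
  stopifnot(inherits(g, "ppi_graph"))
  scores <- if (use_norm) {
    if (is.null(g$norm_score)) stop("graph has no norm_score; run normalize_scores() first")
    g$norm_score
  } else {
    g$combined_score
  }
  upper <- if (use_norm) 1 else 1000
  breaks <- seq(0, upper, by = bin_width)
  if (breaks[length(breaks)] < upper) breaks <- c(breaks, upper)
  if (length(breaks) - 1 < 3) stop("bin width too large: need at least 3 bins")
  counts <- graphics::hist(scores, breaks = breaks, plot = FALSE,
                           right = TRUE, include.lowest = TRUE)$counts
  pct <- 100 * counts / max(1, length(scores))
  hist_df <- data.frame(bin_low = breaks[-length(breaks)],
                        bin_high = breaks[-1], percent = pct)

  minimum <- NA_real_
  interior <- seq(2, length(pct) - 1)
  # interior bins below the global maximum on both sides qualify; pick the
  # lowest-percentage one (first on ties, scanning low to high)
  cand <- interior[vapply(interior, function(i) {
    any(pct[seq_len(i - 1)] > pct[i]) && any(pct[seq(i + 1, length(pct))] > pct[i])
  }, logical(1))]
  if (length(cand) > 0) {
    minimum <- hist_df$bin_low[cand[which.min(pct[cand])]]
  } else {
    warning("no interior minimum detectable in the score distribution; ",
            "fall back to the conventional threshold (800 raw / 0.8 normalized)")
  }
  list(histogram = hist_df, minimum = minimum)
}

#' Threshold filter on interaction confidence
#'
#' Keeps edges whose score meets the threshold: `norm_score >= threshold`
#' (threshold in `[0, 1]`) when `use_norm = TRUE`, otherwise
#' `combined_score >= threshold` (threshold in `[0, 1000]`). Nodes left
#' without edges are dropped from the node set.
#'
#' @param g a [ppi_graph()] (normalized first if `use_norm = TRUE`).
#' @param threshold score cutoff.
#' @param use_norm filter on the normalized score.
#' @return The filtered `ppi_graph`.
#' @export
filter_edges <- function(g, threshold, use_norm = FALSE) {
  stopifnot(inherits(g, "ppi_graph"))
  upper <- if (use_norm) 1 else 1000
  if (threshold < 0 || threshold > upper) {
    stop("threshold must lie in [0, ", upper, "]")
  }
  scores <- if (use_norm) {
    if (is.null(g$norm_score)) stop("graph has no norm_score; run normalize_scores() first")
    g$norm_score
  } else {
    g$combined_score
  }
  out <- g[scores >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Seed-gene subnetwork extraction
#'
#' Two-phase expansion around seed genes: first the seeds present in the
#' graph plus all their immediate neighbors (S1); then any further node
#' with at least two neighbors already in S1. The subnetwork is the
#' subgraph induced by the final node set — all edges of `g` with both
#' endpoints selected. The expansion is applied exactly once by default;
#' `iterate = TRUE` repeats the second phase to a fixpoint.
#'
#' @param g a [ppi_graph()].
#' @param seeds character vector of seed gene identifiers.
#' @param iterate repeat the two-neighbor expansion until no node is
#'   added.
#' @return A list of class `subnetwork` with `selected_nodes` (sorted),
#'   `seeds_found`, `edges` (induced `ppi_graph`), and `node_route`
#'   (data.frame labelling each node `seed`, `neighbor` or `expansion`).
#' @export
extract_subnetwork <- function(g, seeds, iterate = FALSE) {
  stopifnot(inherits(g, "ppi_graph"))
  nodes <- .graph_nodes(g)
  seeds_found <- intersect(unique(seeds), nodes)
  if (length(seeds_found) == 0) {
    warning("no seed gene present in the graph; subnetwork is empty")
    return(structure(list(
      selected_nodes = character(0), seeds_found = character(0),
      edges = g[0, , drop = FALSE],
      node_route = data.frame(node = character(0), route = character(0))
    ), class = "subnetwork"))
  }
  ig <- .as_igraph(g)
  neighbor_names <- function(vs) {
    unique(unlist(lapply(igraph::adjacent_vertices(ig, vs), igraph::as_ids)))
  }
  s1 <- union(seeds_found, neighbor_names(seeds_found))
  expand_once <- function(sel) {
    others <- setdiff(nodes, sel)
    if (length(others) == 0) return(sel)
    added <- others[vapply(others, function(v) {
      length(intersect(neighbor_names(v), sel)) >= 2
    }, logical(1))]
    union(sel, added)
  }
  s2 <- expand_once(s1)
  if (iterate) {
    repeat {
      s_next <- expand_once(s2)
      if (length(s_next) == length(s2)) break
      s2 <- s_next
    }
  }
  sel <- sort(s2)
  induced <- g[g$protein1 %in% sel & g$protein2 %in% sel, , drop = FALSE]
  rownames(induced) <- NULL
  route <- ifelse(sel %in% seeds_found, "seed",
                  ifelse(sel %in% s1, "neighbor", "expansion"))
  structure(list(
    selected_nodes = sel,
    seeds_found = sort(seeds_found),
    edges = induced,
    node_route = data.frame(node = sel, route = route, stringsAsFactors = FALSE)
  ), class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("subnetwork:", length(x$selected_nodes), "nodes,", nrow(x$edges),
      "edges (", length(x$seeds_found), "seeds )\n")
  invisible(x)
}

#' Connected components of a subnetwork
#'
#' Standard undirected connected components over the subnetwork's selected
#' nodes (isolated selected nodes form singleton components), ordered by
#' size descending with ties broken by the smallest node label, so
#' component 1 is always the largest.
#'
#' @param sub a `subnetwork` (see [extract_subnetwork()]).
#' @return A list of character vectors of node labels (each sorted), one
#'   per component.
#' @export
connected_components <- function(sub) {
  stopifnot(inherits(sub, "subnetwork"))
  if (length(sub$selected_nodes) == 0) return(list())
  ig <- igraph::graph_from_data_frame(
    sub$edges[c("protein1", "protein2")], directed = FALSE,
    vertices = sub$selected_nodes
  )
  comp <- igraph::components(ig)
  groups <- split(names(comp$membership), comp$membership)
  groups <- lapply(groups, sort)
  ord <- order(-vapply(groups, length, integer(1)),
               vapply(groups, `[`, character(1), 1))
  unname(groups[ord])
}
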