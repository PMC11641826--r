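edge_df <- function(...) {
  rows <- list(...)
  data.frame(protein1 = vapply(rows, `[[`, character(1), 1),
             protein2 = vapply(rows, `[[`, character(1), 2),
             combined_score = as.integer(vapply(rows, `[[`, character(1), 3)),
             stringsAsFactors = FALSE)
}

test_that("read_string_links dedups orientations, drops self-loops, keeps max", {
  path <- tempfile()
  writeLines(c("protein1 protein2 combined_score",
               "A B 900", "B A 900",
               "A A 950",
               "C D 900", "D C 850"), path)
  g <- read_string_links(path)
  expect_equal(nrow(g), 2)
  expect_equal(g$combined_score[g$protein1 == "A"], 900L)
  expect_equal(g$combined_score[g$protein1 == "C"], 900L)  # max-merge

  bad <- tempfile()
  writeLines(c("protein1 protein2 combined_score", "A B 900", "B C 1500"), bad)
  expect_error(read_string_links(bad), "line 3")
  bad2 <- tempfile()
  writeLines(c("protein1 protein2 combined_score", "A B x"), bad2)
  expect_error(read_string_links(bad2), "line 2")
})

test_that("normalize_scores gives every non-isolated node a norm-1 edge", {
  tri <- normalize_scores(ppi_graph(edge_df(
    c("A", "B", "900"), c("A", "C", "700"), c("B", "C", "600"))))
  score_of <- function(u, v) {
    tri$norm_score[(tri$protein1 == u & tri$protein2 == v) |
                     (tri$protein1 == v & tri$protein2 == u)]
  }
  expect_equal(score_of("A", "B"), 1)
  expect_equal(score_of("A", "C"), 1)          # C's best edge
  expect_equal(score_of("B", "C"), 600 / 700)  # min(M(B), M(C)) = 700

  single <- normalize_scores(ppi_graph(edge_df(c("X", "Y", "123"))))
  expect_equal(single$norm_score, 1)

  # star: center max 1000, leaves at 500 -> every leaf edge norms to 1
  star <- normalize_scores(ppi_graph(edge_df(
    c("hub", "top", "1000"),
    c("hub", "l1", "500"), c("hub", "l2", "500"), c("hub", "l3", "500"))))
  expect_true(all(star$norm_score == 1))

  # property: on random graphs, max norm_score per node is exactly 1
  set.seed(19)
  for (i in 1:10) {
    sim <- simulate_ppi(graph_spec(n_nodes = 30, background_edge_prob = 0.15,
                                   seed = i))
    g <- normalize_scores(sim$graph)
    per_node <- tapply(c(g$norm_score, g$norm_score),
                       c(g$protein1, g$protein2), max)
    expect_true(all(per_node == 1))
    expect_true(all(g$norm_score > 0 & g$norm_score <= 1))
  }
})

test_that("score_distribution locates the between-mode minimum", {
  sim <- simulate_ppi(graph_spec(
    n_nodes = 200, background_edge_prob = 0.2,
    background_score = c(mean = 400, sd = 60),
    module_nodes = sprintf("m%02d", 1:40),
    module_score = c(mean = 950, sd = 20), seed = 5))
  dist <- score_distribution(sim$graph, bin_width = 25)
  expect_false(is.na(dist$minimum))
  expect_gt(dist$minimum, 500)
  expect_lt(dist$minimum, 900)
  expect_equal(sum(dist$histogram$percent), 100, tolerance = 1e-9)

  # flat profile: no interior minimum, warning
  flat <- ppi_graph(data.frame(
    protein1 = sprintf("a%03d", 1:40), protein2 = sprintf("b%03d", 1:40),
    combined_score = as.integer(seq(13, 988, length.out = 40))))
  expect_warning(res <- score_distribution(flat, bin_width = 250), "no interior minimum")
  expect_true(is.na(res$minimum))

  expect_error(score_distribution(sim$graph, bin_width = 600), "3 bins")
})

test_that("filter_edges thresholds raw and normalized scores and is monotone", {
  tri <- normalize_scores(ppi_graph(edge_df(
    c("A", "B", "900"), c("A", "C", "700"), c("B", "C", "600"))))
  expect_equal(nrow(filter_edges(tri, 0)), 3)               # identity
  expect_equal(nrow(filter_edges(tri, 0.8, use_norm = TRUE)), 3)
  raw <- filter_edges(tri, 800)
  expect_equal(nrow(raw), 1)
  expect_equal(raw$combined_score, 900L)
  expect_error(filter_edges(tri, 1200), "threshold")

  set.seed(23)
  sim <- simulate_ppi(graph_spec(n_nodes = 60, background_edge_prob = 0.1,
                                 seed = 23))
  g <- normalize_scores(sim$graph)
  thresholds <- sort(stats::runif(6))
  for (i in seq_along(thresholds)[-1]) {
    lo <- filter_edges(g, thresholds[i - 1], use_norm = TRUE)
    hi <- filter_edges(g, thresholds[i], use_norm = TRUE)
    key <- function(x) paste(x$protein1, x$protein2)
    expect_true(all(key(hi) %in% key(lo)))
  }
})

test_that("extract_subnetwork applies the two-phase expansion once", {
  # path a-s-b with seed s; c adjacent to both a and b joins via phase 2
  g <- ppi_graph(edge_df(c("a", "s", "500"), c("s", "b", "500"),
                         c("a", "c", "500"), c("b", "c", "500"),
                         c("c", "d", "500")))
  sub <- extract_subnetwork(g, "s")
  expect_setequal(sub$selected_nodes, c("s", "a", "b", "c"))
  # d touches only c (one S1 member at most) and is not a seed -> excluded
  expect_false("d" %in% sub$selected_nodes)
  expect_equal(sub$node_route$route[sub$node_route$node == "c"], "expansion")

  # seed with no neighbors in the graph -> empty subnetwork with warning
  expect_warning(empty <- extract_subnetwork(g, "zzz"), "no seed")
  expect_length(empty$selected_nodes, 0)

  # iterate = TRUE may add further layers; once-only must not
  chain <- ppi_graph(edge_df(c("s", "x1", "500"), c("s", "x2", "500"),
                             c("x1", "y", "500"), c("x2", "y", "500"),
                             c("y", "z1", "500"), c("x1", "z1", "500")))
  once <- extract_subnetwork(chain, "s")
  fix <- extract_subnetwork(chain, "s", iterate = TRUE)
  expect_true("y" %in% once$selected_nodes)
  expect_false("z1" %in% once$selected_nodes)  # y entered only in phase 2
  expect_true("z1" %in% fix$selected_nodes)
})

test_that("extract_subnetwork equals brute-force construction on small graphs", {
  set.seed(29)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    pairs <- t(utils::combn(nodes, 2))
    keep <- stats::runif(nrow(pairs)) < 0.3
    if (!any(keep)) next
    g <- ppi_graph(data.frame(protein1 = pairs[keep, 1],
                              protein2 = pairs[keep, 2],
                              combined_score = 500L))
    seeds <- sample(nodes, sample(1:3, 1))
    got <- suppressWarnings(extract_subnetwork(g, seeds))
    expect_equal(got$selected_nodes, subnetwork_oracle(g, seeds),
                 info = paste("graph", i))
  }
})

test_that("connected_components matches the transitive-closure oracle", {
  # two disjoint triangles
  g <- ppi_graph(edge_df(c("a", "b", "500"), c("b", "c", "500"),
                         c("a", "c", "500"), c("x", "y", "500"),
                         c("y", "z", "500"), c("x", "z", "500")))
  sub <- extract_subnetwork(g, c("a", "x"))
  comps <- connected_components(sub)
  expect_length(comps, 2)
  expect_equal(lengths(comps), c(3L, 3L))
  expect_equal(comps[[1]], c("a", "b", "c"))  # size tie -> smallest label first

  empty <- suppressWarnings(extract_subnetwork(g, "none"))
  expect_length(connected_components(empty), 0)

  set.seed(37)
  for (i in 1:5) {
    sim <- simulate_ppi(graph_spec(n_nodes = 50, background_edge_prob = 0.03,
                                   seed = 100 + i))
    g <- sim$graph
    nodes <- sort(unique(c(g$protein1, g$protein2)))
    sub <- extract_subnetwork(g, nodes)  # select everything
    expect_equal(connected_components(sub), components_oracle(nodes, g))
  }
})

test_that("planted high-score module lands in the largest component", {
  seeds <- sprintf("m%02d", 1:8)
  sim <- simulate_ppi(graph_spec(n_nodes = 100, background_edge_prob = 0.02,
                                 module_nodes = seeds,
                                 module_score = c(mean = 950, sd = 20),
                                 seed = 41))
  g <- normalize_scores(sim$graph)
  g <- filter_edges(g, 0.8, use_norm = TRUE)
  sub <- extract_subnetwork(g, seeds)
  comps <- connected_components(sub)
  seeded <- seeds[seeds %in% c(g$protein1, g$protein2)]
  expect_true(all(seeded %in% comps[[1]]))
})
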