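# Independent oracles used across tests. Each deliberately takes a different
# route than the implementation it checks.

# HWE exact test by direct log-factorial enumeration (the implementation
# uses the ratio recurrence between adjacent heterozygote counts).
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  if (n == 0) return(1)
  n_alt <- 2 * naa + nAa
  n1 <- min(n_alt, 2 * n - n_alt)
  if (n1 == 0) return(1)
  n2 <- 2 * n - n1
  hs <- seq(n1 %% 2, n1, by = 2)
  lp <- vapply(hs, function(h) {
    h * log(2) + lfactorial(n) -
      lfactorial((n1 - h) / 2) - lfactorial(h) - lfactorial((n2 - h) / 2) +
      lfactorial(n1) + lfactorial(n2) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(lp)
  p_obs <- p[hs == nAa]
  min(1, sum(p[p <= p_obs * (1 + 1e-10)]))
}

# Pearson chi-square via expected counts (implementation uses the closed
# N(ad-bc)^2 form).
chi2_expected_oracle <- function(a, b, cc, d) {
  obs <- matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE)
  n <- sum(obs)
  expd <- outer(rowSums(obs), colSums(obs)) / n
  sum((obs - expd)^2 / expd)
}

# Two-phase seed expansion by explicit set computation on an adjacency list.
subnetwork_oracle <- function(edges, seeds) {
  nodes <- sort(unique(c(edges$protein1, edges$protein2)))
  nbr <- function(v) {
    unique(c(edges$protein2[edges$protein1 == v],
             edges$protein1[edges$protein2 == v]))
  }
  s0 <- intersect(seeds, nodes)
  if (length(s0) == 0) return(character(0))
  s1 <- union(s0, unique(unlist(lapply(s0, nbr))))
  s2 <- s1
  for (v in setdiff(nodes, s1)) {
    if (length(intersect(nbr(v), s1)) >= 2) s2 <- c(s2, v)
  }
  sort(s2)
}

# Connected components by transitive closure of the reachability matrix.
components_oracle <- function(nodes, edges) {
  n <- length(nodes)
  reach <- diag(n) > 0
  idx <- function(v) match(v, nodes)
  for (k in seq_len(nrow(edges))) {
    i <- idx(edges$protein1[k]); j <- idx(edges$protein2[k])
    reach[i, j] <- reach[j, i] <- TRUE
  }
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  seen <- rep(FALSE, n)
  comps <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    members <- which(reach[i, ])
    seen[members] <- TRUE
    comps[[length(comps) + 1]] <- sort(nodes[members])
  }
  ord <- order(-vapply(comps, length, integer(1)),
               vapply(comps, `[`, character(1), 1))
  comps[ord]
}

# Benjamini-Hochberg step-up worked by hand from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(1, adj)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Small VCF written in code; covers plain calls, a missing call, a half
# call, a multi-allelic site and an rsID-less indel.
write_fixture_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "./.", sep = "\t"),
    paste("1", "200", ".", "C", "A,T", ".", "PASS", ".", "GT",
          "1/2", "0/0", "0/2", sep = "\t"),
    paste("2", "300", ".", "TGAAA", "T", ".", "PASS", ".", "GT",
          "0/1", "./1", "1/1", sep = "\t")
  ), path)
  path
}

# Deterministic genotype table with prescribed case/control dosages.
make_gt <- function(case_dosages, ctrl_dosages, chrom = "1", pos = NULL) {
  case_dosages <- as.matrix(case_dosages)
  ctrl_dosages <- as.matrix(ctrl_dosages)
  stopifnot(ncol(case_dosages) == ncol(ctrl_dosages))
  nvar <- ncol(case_dosages)
  samples <- c(sprintf("case%02d", seq_len(nrow(case_dosages))),
               sprintf("ctrl%02d", seq_len(nrow(ctrl_dosages))))
  if (is.null(pos)) pos <- 1000L + seq_len(nvar)
  gt <- genotype_table(
    data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
               id = sprintf("v%03d", seq_len(nvar))),
    samples,
    rbind(case_dosages, ctrl_dosages)
  )
  ph <- phenotype_map(samples, c(rep("case", nrow(case_dosages)),
                                 rep("control", nrow(ctrl_dosages))))
  list(gt = gt, ph = ph)
}

# Case dosage vector carrying exactly C_A alternate alleles.
dosage_vector <- function(n_samples, total) {
  d <- integer(n_samples)
  full <- total %/% 2
  d[seq_len(full)] <- 2L
  if (total %% 2 == 1) d[full + 1] <- 1L
  d
}
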