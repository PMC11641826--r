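test_that("allelic chi-square reproduces the worked 2x2 tables", {
  # case-exclusive C_A = 11 of 24 case alleles vs 0 of 22
  cs <- allelic_chi_square(allele_count_table(11, 13, 0, 22))
  expect_equal(round(cs[["chi2"]], 2), 13.25)
  expect_equal(signif(cs[["p"]], 3), 0.000272)

  # shared variant, enriched in controls
  cs2 <- allelic_chi_square(allele_count_table(2, 20, 12, 10))
  expect_equal(round(cs2[["chi2"]], 2), 10.48)
  expect_equal(round(cs2[["p"]], 4), 0.0012)

  # balanced table: no association
  cs3 <- allelic_chi_square(allele_count_table(5, 5, 5, 5))
  expect_equal(cs3[["chi2"]], 0)
  expect_equal(cs3[["p"]], 1)

  # zero margin: flagged as NA rather than an error
  cs4 <- allelic_chi_square(allele_count_table(0, 24, 0, 22))
  expect_true(is.na(cs4[["chi2"]]) && is.na(cs4[["p"]]))
})

test_that("chi-square matches the expected-counts formulation on random tables", {
  set.seed(7)
  for (i in 1:200) {
    a <- sample(0:24, 1); b <- 24 - a
    cc <- sample(0:22, 1); d <- 22 - cc
    if (a + cc == 0 || b + d == 0) next
    got <- allelic_chi_square(allele_count_table(a, b, cc, d))[["chi2"]]
    expect_equal(got, chi2_expected_oracle(a, b, cc, d), tolerance = 1e-12)
  }
})

test_that("chi-square is symmetric under group and allele swaps; OR inverts", {
  set.seed(8)
  for (i in 1:50) {
    a <- sample(1:23, 1); b <- 24 - a
    cc <- sample(1:21, 1); d <- 22 - cc
    t0 <- allele_count_table(a, b, cc, d)
    grp <- allele_count_table(cc, d, a, b)     # case/control swap
    alle <- allele_count_table(b, a, d, cc)    # alt/ref swap
    expect_equal(allelic_chi_square(t0)[["chi2"]],
                 allelic_chi_square(grp)[["chi2"]], tolerance = 1e-12)
    expect_equal(allelic_chi_square(t0)[["chi2"]],
                 allelic_chi_square(alle)[["chi2"]], tolerance = 1e-12)
    or0 <- allelic_odds_ratio(t0)
    expect_equal(allelic_odds_ratio(grp), 1 / or0, tolerance = 1e-12)
  }
})

test_that("odds ratio follows keep-allele-order semantics with NA and 0 cases", {
  expect_equal(allelic_odds_ratio(allele_count_table(8, 14, 1, 21)), 12)
  expect_true(is.na(allelic_odds_ratio(allele_count_table(7, 15, 0, 22))))
  expect_equal(allelic_odds_ratio(allele_count_table(0, 24, 6, 16)), 0)
  expect_equal(allelic_odds_ratio(allele_count_table(3, 3, 3, 3)), 1)
})

test_that("allele frequencies are unflipped alternate-allele fractions", {
  f <- allele_frequencies(allele_count_table(2, 20, 12, 10))
  expect_equal(round(unname(f), 4), c(0.0909, 0.5455))
  f2 <- allele_frequencies(allele_count_table(0, 24, 6, 16))
  expect_equal(round(unname(f2), 4), c(0, 0.2727))
  f3 <- allele_frequencies(allele_count_table(24, 0, 0, 22))
  expect_equal(unname(f3), c(1, 0))
})

test_that("p is strictly decreasing in chi2 and chi2 = 0 gives p = 1", {
  chis <- seq(0, 30, by = 0.5)
  ps <- vapply(chis, function(x) stats::pchisq(x, 1, lower.tail = FALSE),
               numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_equal(allelic_chi_square(allele_count_table(6, 6, 6, 6))[["p"]], 1)
})

test_that("hwe_exact_test equals enumeration for all tables with <= 50 alleles", {
  for (n in 1:25) {  # n genotypes -> 2n <= 50 alleles
    for (nAa in 0:n) {
      for (naa in 0:(n - nAa)) {
        nAA <- n - nAa - naa
        expect_equal(hwe_exact_test(nAA, nAa, naa), hwe_oracle(nAA, nAa, naa),
                     tolerance = 1e-12,
                     info = sprintf("(%d,%d,%d)", nAA, nAa, naa))
      }
    }
  }
})

test_that("hwe_exact_test handles degenerate and extreme inputs", {
  expect_equal(hwe_exact_test(0, 0, 23), 1)  # monomorphic
  expect_equal(hwe_exact_test(0, 0, 0), 1)   # empty by convention
  # all-homozygote extreme: far tail, equal to the enumeration value
  expect_equal(hwe_exact_test(10, 0, 10), hwe_oracle(10, 0, 10))
  expect_lt(hwe_exact_test(10, 0, 10), 1e-5)
})

test_that("qc_filter applies missingness, MAF and HWE rules with reasons", {
  # variant 1: missing in 3 of 23 (13% > 10%)
  v1_case <- c(rep(NA_integer_, 3), rep(1L, 9))
  v1_ctrl <- rep(0L, 11)
  # variant 2: 2 alt alleles of 46 -> MAF 0.043 < 0.05
  v2_case <- c(2L, rep(0L, 11))
  v2_ctrl <- rep(0L, 11)
  # variant 3: passes everything
  v3_case <- c(rep(1L, 6), rep(0L, 6))
  v3_ctrl <- c(rep(1L, 5), rep(0L, 6))
  m <- make_gt(cbind(v1_case, v2_case, v3_case),
               cbind(v1_ctrl, v2_ctrl, v3_ctrl))
  out <- qc_filter(m$gt, m$ph, qc_params())
  expect_equal(out$log$reason, c("missingness", "maf", ""))
  expect_equal(nrow(out$gt$variants), 1L)
  expect_true(out$log$qc_pass[3])

  # HWE failure needs a more extreme cohort: 30 samples, all homozygous,
  # balanced alleles (exact p ~ 1.3e-9 < 1e-7)
  hwe_case <- rep(c(0L, 2L), 8)[1:15]
  hwe_ctrl <- rep(c(2L, 0L), 8)[1:15]
  m2 <- make_gt(cbind(hwe_case), cbind(hwe_ctrl))
  out2 <- qc_filter(m2$gt, m2$ph, qc_params())
  expect_equal(out2$log$reason, "hwe")
})

test_that("adjust_pvalues matches hand-worked BH and Bonferroni", {
  p <- c(0.001, 0.01, 0.03, 0.04)
  # step-up by hand: 0.001*4/1=0.004; 0.01*4/2=0.02; 0.03*4/3=0.04; 0.04*4/4=0.04
  expect_equal(adjust_pvalues(p, "BH"), c(0.004, 0.02, 0.04, 0.04))
  expect_equal(adjust_pvalues(p, "BH"), bh_oracle(p))
  expect_equal(adjust_pvalues(0.01, "BH"), 0.01)
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)
  # 13 tests at p = 0.004 are all nonsignificant after Bonferroni
  expect_equal(adjust_pvalues(rep(0.004, 13), "bonferroni"), rep(0.052, 13))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("adjustment ordering invariants hold on random p-vectors", {
  set.seed(9)
  for (i in 1:20) {
    p <- stats::runif(sample(3:40, 1))
    bh <- adjust_pvalues(p, "BH")
    bonf <- adjust_pvalues(p, "bonferroni")
    expect_true(all(bonf >= bh - 1e-12))
    expect_true(all(bh >= p - 1e-12))
    ord <- order(p)
    expect_true(all(diff(bh[ord]) >= -1e-12))
  }
})

test_that("run_association ranks a planted case-exclusive variant first", {
  spec <- cohort_spec(n_null_variants = 50,
                      planted = data.frame(gene = "G1", C_A = 11,
                                           consequence = "frameshift_variant"),
                      seed = 3)
  sim <- simulate_cohort(spec)
  res <- run_association(sim$gt, sim$ph)
  planted_row <- which(res$id == sim$truth$id[1])
  expect_length(planted_row, 1)
  expect_equal(round(res$chi2[planted_row], 2), 13.25)
  expect_equal(which.min(res$p), planted_row)
  expect_true(all(res$p_adj >= res$p - 1e-12))
})

test_that("label-swapped phenotypes leave chi2 unchanged and invert the OR", {
  spec <- cohort_spec(n_null_variants = 40, seed = 5)
  sim <- simulate_cohort(spec)
  swapped <- phenotype_map(names(sim$ph),
                           ifelse(unclass(sim$ph) == "case", "control", "case"))
  r1 <- run_association(sim$gt, sim$ph)
  r2 <- run_association(sim$gt, swapped)
  expect_equal(r1$chi2, r2$chi2, tolerance = 1e-12)
  defined <- !is.na(r1$OR) & !is.na(r2$OR) & r1$OR > 0
  expect_true(any(defined))
  expect_equal(r2$OR[defined], 1 / r1$OR[defined], tolerance = 1e-12)
})

test_that("zero variants after QC yields an empty result with a warning", {
  m <- make_gt(cbind(rep(NA_integer_, 12)), cbind(rep(NA_integer_, 11)))
  expect_warning(res <- run_association(m$gt, m$ph), "no variants")
  expect_equal(nrow(res), 0)
})

test_that("null-variant type-I error is within 3 SE of nominal 0.05", {
  spec <- cohort_spec(n_null_variants = 10000, seed = 123,
                      maf_range = c(0.05, 0.5))
  sim <- simulate_cohort(spec)
  ps <- vapply(seq_len(nrow(sim$gt$variants)), function(j) {
    allelic_chi_square(allele_counts(sim$gt, sim$ph, j))[["p"]]
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  frac <- mean(ps < 0.05)
  se3 <- 3 * sqrt(0.05 * 0.95 / length(ps))
  expect_lt(abs(frac - 0.05), se3)
})
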