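#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact conditional test of Hardy-Weinberg genotype proportions
#' given the observed allele counts. Conditional on the minor-allele total
#' `n1`, the heterozygote count `h` ranges over `{n1 mod 2, n1 mod 2 + 2,
#' ...}` up to `min(n1, n2)`; the p-value is the total probability of all
#' heterozygote counts whose conditional probability does not exceed that
#' of the observed count. Probabilities are computed by the standard
#' ratio recurrence between adjacent heterozygote counts, which is stable
#' for the cohort sizes this package targets.
#'
#' @param nAA,nAa,naa genotype counts: homozygous reference, heterozygous,
#'   homozygous alternate.
#' @return The exact two-sided p-value; 1 for an empty or monomorphic
#'   sample, where only one genotype configuration is possible.
#' @export
hwe_exact_test <- function(nAA, nAa, naa) {
  counts <- c(nAA, nAa, naa)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- nAA + nAa + naa
  if (n == 0) return(1)
  n_alt <- 2 * naa + nAa
  n_ref <- 2 * nAA + nAa
  n1 <- min(n_alt, n_ref)   # minor-allele total
  if (n1 == 0) return(1)    # monomorphic: single outcome

  h_values <- seq(n1 %% 2, n1, by = 2)
  # recurrence: P(h+2)/P(h) = [ (n1-h)(n2-h) ] / [ (h+2)(h+1) ] with
  # homozygote counts nA = (n1-h)/2, nB = (n2-h)/2 at each step
  n2 <- 2 * n - n1
  log_prob <- numeric(length(h_values))
  for (i in seq_along(h_values)[-1]) {
    h <- h_values[i - 1]
    log_prob[i] <- log_prob[i - 1] +
      log(n1 - h) + log(n2 - h) - log(h + 2) - log(h + 1)
  }
  prob <- exp(log_prob - max(log_prob))
  prob <- prob / sum(prob)

  obs <- nAa
  p_obs <- prob[h_values == obs]
  if (length(p_obs) == 0) stop("observed heterozygote count inconsistent with allele totals")
  min(1, sum(prob[prob <= p_obs * (1 + 1e-10)]))
}
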