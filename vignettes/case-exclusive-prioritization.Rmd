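---
title: "Case-exclusive variant prioritization: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-exclusive variant prioritization: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casexnet)
```

## The problem this package addresses

Very small exposed-cohort case-control studies — on the order of a dozen
cases and a dozen controls — cannot detect individual risk variants by
conventional association testing: after multiple-testing correction nothing
survives. `casexnet` implements the complementary strategy such studies use
instead: find variants whose alternate alleles are carried *only* by cases,
rank them by predicted functional severity, pool them per gene under an
additive-impairment model, and read off the biology from the interaction
network around the implicated genes. Every stage is an explicit, tested
function; nothing depends on an external service.

## The allelic association model

Each biallelic variant is summarized by the 2×2 table of allele counts,
$a$/$b$ alternate/reference in cases and $c$/$d$ in controls. Missing
genotypes contribute no alleles, so $a+b$ is twice the number of *genotyped*
cases — an important detail in small cohorts, where a single missing
genotype visibly changes the statistic (a case-exclusive variant carried on
10 of 22 genotyped case alleles gives χ² = 12.94; on 10 of 24 it would
not). The test is the uncorrected Pearson chi-square with one degree of
freedom,

$$\chi^2 = \frac{N\,(ad-bc)^2}{(a+b)(c+d)(a+c)(b+d)},$$

with the upper-tail p-value from the χ² distribution (via the regularized
incomplete gamma function in `stats::pchisq`). **No Yates continuity
correction is applied**: the correction would change the reproduced
statistics (13.25, 10.48, 8.324, …) and the allelic test convention this
package follows does not use it. Allele frequencies are reported for the
alternate allele without minor-allele flipping (keep-allele-order
semantics), and the odds ratio $ad/bc$ keeps the case alternate-allele odds
in the numerator: it is `NA` exactly when $bc = 0$ and 0 exactly when
$ad = 0$ with $bc > 0$, which is why a results table can contain both "NA"
and "0" odds ratios.

Both Bonferroni and Benjamini-Hochberg adjusted p-values are computed
(`adjust_pvalues`, a validated wrapper over `stats::p.adjust`), BH by
default. In cohorts of this size all adjusted values are expected to be
nonsignificant; the raw p-value thresholds below are therefore explicit,
documented screening levels, not claims of genome-wide significance.

## Quality control

`qc_filter` applies three per-variant rules, in order, on all samples pooled
(the cohort is unrelated, so no founder restriction applies):

| rule | default | meaning |
|---|---|---|
| missingness | > 0.10 removed | fraction of missing calls among all samples |
| MAF | < 0.05 removed | pooled minor-allele frequency, min(f, 1−f) |
| HWE | p < 1e-7 removed | exact conditional Hardy-Weinberg test |

Note the two distinct frequency conventions: QC uses the *folded* (minor)
frequency, while association output reports the *unfolded* alternate-allele
frequency. Both are deliberate and documented.

The Hardy-Weinberg test is the exact conditional test: given the observed
allele totals, the heterozygote count $h$ ranges over values of matching
parity, with conditional probability proportional to
$2^h\,n!/\big(n_{AA}!\,h!\,n_{aa}!\big)$; the two-sided p-value sums the
probabilities of all $h$ no more likely than the observed one.
Probabilities are computed by the stable ratio recurrence between adjacent
heterozygote counts, and the test suite verifies equality against an
independent log-factorial enumeration for every genotype configuration with
up to 50 alleles. A numerical guard multiplies the observed probability by
$(1+10^{-10})$ before the tail comparison so ties are never lost to
floating-point rounding.

## Severity ranking and the case-exclusive filter

Consequence terms are ranked by a packaged severity table
(`severity_table()`). Its top block of ten terms is the most-severe set used
for prioritization — transcript ablation, splice acceptor/donor, stop
gained/lost, frameshift, start lost, transcript amplification, feature
elongation and feature truncation — and the remainder follows the canonical
VEP ordering. Two of the block-one terms (feature elongation/truncation)
sit lower in recent VEP releases; this package keeps them in the top block
because the most-severe *set*, not the modern ordering, defines the
prioritization rule implemented here. Unknown terms are retained and rank
one past the least severe packaged term, so ontology growth cannot break a
run. A variant's severity is the minimum rank over all its annotations,
with lexicographic tie-breaking for determinism.

The case-exclusive filter keeps variants where (a) every *genotyped*
control is homozygous reference and (b) at least one case carries the
alternate allele. A missing control genotype is not treated as evidence of
carriage — the alternative (dropping any variant with a missing control)
would discard real signal at the 10% missingness QC allows — but the count
of missing controls is reported per variant so the judgement is auditable.
Prioritization keeps raw p < 0.05 (`alpha`), sorts by (severity rank,
ascending p), and flags the stricter p < 0.005 listing cut
(`listing_alpha`) used for headline reporting.

## Gene-level co-occurrence

`aggregate_by_gene` sums the case alternate-allele counts of a gene's
case-exclusive significant variants — a plain burden-style sum, not a
weighted test, because the model is additive impairment of one gene's
function. The multi-variant route keeps genes with ≥ 2 variants and allele
sum ≥ 10 by default. A stricter preset (≥ 3 variants, sum ≥ 14) is exposed
as `strict_preset = TRUE`; the default is the 2/10 rule because that is the
rule under which the published multi-variant gene set (ZNF92 at 6+6 = 12,
NUTM2D at 5+5 = 10) is internally consistent, while the 14 threshold
appears only in a narrative mention of the 3-plus-variant genes. A variant
annotated to several genes counts toward each of them, matching per-gene
annotation semantics. The genes-of-interest set is the union of the
single-variant route (genes whose variants pass the listing cut) and the
multi-variant route; the two routes are disjoint by construction and
`genes_of_interest` errors on overlap rather than silently deduplicating.

## Network analysis

STRING-style edges carry an integer `combined_score` in [0, 1000].
Ingestion drops self-loops and merges duplicate unordered pairs keeping the
maximum score (the conservative choice when both orientations of a pair are
listed with different scores).

Filtering on the absolute score excludes every gene whose best interaction
falls below the threshold — which can remove seed genes from the analysis
entirely. The per-gene normalization avoids that: with $M(x)$ the maximum
score over edges incident to $x$, each edge gets

$$\text{norm\_score}(u,v) = \frac{s(u,v)}{\min(M(u), M(v))},$$

the larger of the two per-endpoint normalizations, so every gene's
strongest edge has norm_score exactly 1 and survives any threshold ≤ 1.
The rule is stated per *edge*; a per-endpoint duplicate normalization
(keeping two directed copies) would be the alternative reading and is noted
here for completeness, but the min-of-maxima form is what guarantees each
gene keeps its best interaction with a single undirected edge set.

`score_distribution` bins edges (default width 25 score units, or 0.025
normalized) into percent-of-total counts and reports the interior minimum —
the lowest interior bin flanked by larger bins on both sides, ties going to
the lowest score. On real interactome-scale data the percentage declines
with score and rises again near the top; the minimum (around 800 raw / 0.8
normalized) separates the bulk from the high-confidence mode and is the
natural threshold. On a histogram with no interior minimum the function
warns and returns `NA`, and the documented fallback is the conventional
800 / 0.8.

Subnetwork extraction is a two-phase expansion applied exactly once: S1 =
seeds present in the graph plus all their neighbors; S2 = S1 plus every
node with at least two neighbors in S1; the result is the subgraph induced
by S2. Measuring the "distance one, two selected neighbors" rule against S1
rather than the raw seed set is the only reading under which the rule adds
nodes beyond immediate neighbors, and is what is implemented; an
`iterate = TRUE` option repeats phase two to a fixpoint for exploration but
is off by default. Components are ordered by size descending, ties by
smallest node label, so "component 1" is always the largest.

## The synthetic-data generator

`simulate_cohort` emulates the study conditions the analysis assumes: 12
cases and 11 controls by default; background variants drawn with the same
allele frequency in both groups (per-chromosome Bernoulli, i.e. binomial
dosages, frequency uniform on [0.05, 0.5]); planted case-exclusive variants
placing exactly `C_A` alternate alleles on randomly chosen case chromosomes
(the 4–11 range is what carrier-exclusive rare variants look like at this
cohort size); missingness applied afterwards, never erasing a planted
carrier unless `protect_planted` is switched off. The generator has no
linkage disequilibrium, no population structure, and no genotyping-error
model — the analysis under test treats variants independently, so these are
deliberately out of scope. Passing tests on this generator therefore
demonstrate correctness of the *method*, not robustness to LD-driven
confounding in real cohorts.

`simulate_ppi` embeds a planted high-score clique (mean 950, sd 30) in a
background Erdős–Rényi graph with low scores (mean 400, sd 100), each
module node anchored to the background by one low-score edge; the bimodal
design gives `score_distribution` a detectable between-mode minimum.

## Numerical and testing choices

* Worked-example statistics are asserted at the precision the source tables
  print (two to three decimals, four significant figures for p-values), not
  at machine epsilon.
* The chi-square implementation is cross-checked against an independent
  expected-counts formulation; the HWE test against full enumeration; the
  subnetwork builder against a brute-force set construction on all random
  graphs up to 12 nodes; components against a transitive-closure oracle.
* The type-I error of the allelic test on 10,000 simulated null variants is
  required to fall within 3 standard errors of the nominal 0.05; the
  empirical value at these allele counts is ≈ 0.053. The uniformity of null
  p-values is checked as a KS-style discrepancy with a documented tolerance
  of 0.10 — deliberately loose because the statistic is discrete at 46
  alleles, which lumps the p-value distribution.
* Simulation sizes in the suite (10,000 null variants; graphs of 30–200
  nodes; exhaustive small-graph checks at ≤ 12 nodes) were chosen so the
  full suite runs in well under a minute while still pinning the
  distributional properties.

## Known limitations

* The allelic test's asymptotics are approximate at 46 alleles; p-values
  near the screening thresholds should be read as ranks, not calibrated
  probabilities. No Fisher exact alternative is provided because the
  reproduced statistics are defined by the chi-square.
* Case-exclusivity is a filter, not a test: it conditions on controls being
  alt-free, and its false-positive behavior depends on control genotyping
  completeness. The per-variant missing-control count in the output is the
  honest disclosure of that dependence.
* Gene symbols are taken as given; no mapping between annotation symbols
  and network identifiers is attempted — callers must supply consistent
  identifiers to the network stage.
* The co-occurrence sum ignores phase: two variants in the same case could
  be in cis, impairing one haplotype only.
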