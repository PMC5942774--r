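# cibr — codon information bias analysis for bacterial genomes

Codon usage bias (CUB) — the unequal use of synonymous codons within a
coding sequence — separates fast-growing specialists from metabolically
flexible generalists, and leaves a measurable imprint of a strain's
habitat. `cibr` is for microbial comparative genomicists who want to
quantify that bias gene by gene and then compare it across strains,
functional categories and gene sets (conserved vs unique, chromosome vs
consortium), the way codon-usage studies of acidophilic biomining
communities are done.

## The statistic

The per-gene measure is the **codon information bias (CIB)**: the
Kullback–Leibler divergence of observed synonymous codon usage from equal
usage, rescaled by its composition-dependent maximum. With $p(a)$ the
amino-acid relative frequencies of the gene, $n(a)$ the degeneracy of amino
acid $a$, and $H_a$ the entropy of codon usage within $a$'s synonymous
family,

$$\mathrm{CIB} = \frac{\sum_a p(a)\,[\log n(a) - H_a]}
                      {\sum_a p(a)\,\log n(a)} \in [0, 1],$$

so CIB = 0 iff every synonymous family is used uniformly (no bias) and
CIB = 1 iff each amino acid is encoded by a single codon (maximal bias).

Around the statistic, the package provides the full comparative pipeline:

* **codon bookkeeping** — NCBI genetic-code tables 1/11, robust in-frame
  codon counting from CDS FASTA (ambiguity codons skipped, internal stops
  flagged, terminal stop excluded);
* **two-stage inference** — ties-adjusted two-sample Anderson–Darling test
  of distributional equality, then permutation tests for *stochastic
  dominance* (one-sided maximal ECDF gap; exhaustive enumeration for tiny
  samples, Monte-Carlo otherwise) with per-category verdicts;
* **grouping** — COG-category assignment from tabular alignment hits
  (e-value ≤ 1e-5, identity ≥ 40%, optional 90%-of-hit-length rule for
  metagenome fragments), ortholog-call intersection from two tools,
  conserved/unique gene partitions, group × category mean-CIB matrices and
  500-base gene-length bins;
* **clustering** — average-linkage dendrograms of strains over Pearson
  correlation distance between category profiles, exported as Newick;
* **synthetic ground truth** — a CDS simulator with a single bias knob
  β and closed-form population CIB, used by the test suite to validate
  every stage end to end.

## Worked example

Simulate a low-bias and a high-bias group of genes and ask whether the
first is stochastically less biased:

```r
library(cibr)
code <- load_genetic_code(11)

m_lo <- build_model(beta = 0.15, length_dist = list(kind = "fixed", codons = 250L))
m_hi <- build_model(beta = 0.45, length_dist = list(kind = "fixed", codons = 250L))
lo <- simulate_genes(m_lo, 120, group = "consortium_like", seed = 10)
hi <- simulate_genes(m_hi, 120, group = "reference_like",  seed = 20)

tab_lo <- cib_table(lo$sequences, code)
tab_hi <- cib_table(hi$sequences, code)
round(c(mean(tab_lo$cib), mean(tab_hi$cib)), 4)
#> [1] 0.1169 0.2688

compare_groups(list(ALL = tab_lo$cib), list(ALL = tab_hi$cib),
               alpha = 0.01, n_permutations = 10000, seed = 30)
#>   category n_x n_y ad_standardized         ad_p  dom_xy_p dom_yx_p                  verdict
#> 1      ALL 120 120        121.3491 8.869171e-49 9.999e-05        1 x_stochastically_smaller
```

The Anderson–Darling stage rejects equality outright (standardized
statistic 121.3), and the dominance stage finds the low-β group
stochastically smaller at the Monte-Carlo floor p = 1/10001, while the
opposite direction is hopeless (p = 1) — exactly the planted truth: the
β = 0.15 model has population CIB 0.022, the β = 0.45 model 0.178 (the
empirical means sit above both, the expected finite-length overshoot at
250 codons).

The package also ships a small curated table of published per-gene CIB
values for copper-resistance and oxidative-stress genes of five biomining
consortium strains and their counterpart strains:

```r
block_mean_cib(reported_biomining_cib())
#>    block  n mean_consortium mean_counterpart
#> 1 copper 12           0.186            0.232
#> 2    ros 23           0.236            0.264
```

In both functional blocks the consortium genes average visibly lower CIB
than their counterparts — the weaker codon bias associated with broad
environmental adaptability.

A thin subcommand wrapper for shell use lives at
`inst/cli/cib-pipeline.R` (`compute`, `compare`, `cluster`, `bins`,
`simulate`), each subcommand a direct call into the exported functions.

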