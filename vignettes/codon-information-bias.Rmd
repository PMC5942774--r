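---
title: "Measuring and comparing codon usage bias with CIB"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and comparing codon usage bias with CIB}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cibr)
```

## The statistic

Synonymous codons are not used equally often, and the strength of that
preference — codon usage bias — carries signal about translational
selection, growth strategy and habitat. `cibr` quantifies it per gene with
the codon information bias (CIB), a rescaled Kullback–Leibler divergence of
the observed within-family codon usage from equal synonymous usage, weighted
by the gene's amino-acid composition.

For a gene, let $p(a)$ be the relative frequency of amino acid $a$ among its
sense codons, $n(a)$ the degeneracy (size of the synonymous family), and
$q(c \mid a)$ the conditional frequency of codon $c$ within family $a$, with
within-family entropy $H_a = -\sum_{c \in a} q(c|a)\log q(c|a)$. Then

$$\mathrm{CIB} \;=\;
\frac{\sum_a p(a)\,\bigl[\log n(a) - H_a\bigr]}
     {\sum_a p(a)\,\log n(a)} .$$

The numerator is the average KL divergence of the family-conditional codon
distributions from uniform; the denominator is the largest value that
average can take given the amino-acid composition. Hence $0 \le \mathrm{CIB}
\le 1$, with the two characterizations the implementation treats as exact:
CIB is 0 **iff** every family is used uniformly, and 1 **iff** every amino
acid present is encoded by a single codon (and at least one family with
$n(a) > 1$ occurs). Both are property-tested.

Numerical conventions, all unit-tested:

* natural logarithm internally — the base cancels in the ratio;
* $0 \log 0 = 0$; amino acids absent from the gene drop out; families with
  $n(a) = 1$ (Met, Trp) contribute to neither sum;
* no pseudocounts: an unused synonymous codon is a true zero in $H_a$,
  which is what makes the value 1 attainable;
* a gene made solely of single-codon amino acids has denominator 0; its
  CIB is **undefined** — flagged `NA`, never an error, and counted when
  dropped downstream.

Codon counting takes the CDS at face value (frame from base 1, no ORF
calling), is case-insensitive, drops a trailing partial codon, skips codons
containing ambiguity characters, excludes a terminal stop by default, and
flags internal stops without aborting — draft genomes contain pseudogenes,
and a flag is more useful than an exception. The genetic code defaults to
NCBI table 11 (bacteria); its sense-codon degeneracy is identical to table
1, so CIB is the same under either, which is tested.

## Comparing groups of genes

Analyses of this kind ask whether one collection of genes (a strain, a COG
functional category, a conserved or unique gene set) is more or less biased
than another. `compare_groups()` uses a two-stage procedure per category:

1. **Equality stage.** The two-sample Anderson–Darling test (Scholz–Stephens
   $k = 2$, ties-adjusted midrank statistic, standardized with the exact
   finite-sample $\sigma_N$). The AD test is preferred over
   Kolmogorov–Smirnov for its tail sensitivity, which matters for the
   long-tailed CIB distributions genomes produce. P-values come from
   monotone (Hyman spline) interpolation of logit(p) against the published
   asymptotic percentiles of the standardized statistic (0.326, 1.225,
   1.960, 2.719, 3.752 at p = 0.25, 0.10, 0.05, 0.025, 0.01), with linear
   logit extrapolation outside the table; a label-permutation p-value is
   available when exactness matters more than speed. The implementation is
   validated against an independent reference implementation on frozen
   cases and against a direct double-sum evaluation of the continuous
   statistic.

2. **Ordering stage**, run only when stage 1 rejects at level `alpha`. Two
   one-sided permutation tests ask whether one group's values are
   *stochastically smaller* than the other's — $P(X > t) \le P(Y > t)$ at
   every threshold, i.e. CDFs that may touch but not cross. The statistic
   is the one-sided maximal ECDF gap $D = \max_t [\hat F_x(t) - \hat
   F_y(t)]$ (clipped at 0), its null distribution obtained by relabeling
   the pooled sample: exhaustively for combined $n \le 12$, otherwise by
   Monte Carlo with the add-one estimator $p = (1 + \#\{D^* \ge D\})/(1 +
   B)$, so $p \ge 1/(B+1)$ and is never 0. $D$ was chosen as the minimal
   statistic whose null and alternative match the touch-but-not-cross
   definition of dominance; being a rank functional, it shares the AD
   test's invariance under increasing transforms.

The verdict per category is `same`, `x_stochastically_smaller`,
`y_stochastically_smaller`, or `different_unordered` (distributions differ
but neither direction wins — crossing CDFs). Defaults: `alpha = 0.01`,
`n_permutations = 10000`, one documented integer seed from which
per-category child seeds are derived deterministically. No multiple-testing
correction is applied across categories — per-category p-values are the
convention this output mirrors — but `holm = TRUE` is available.

## Grouping, summaries, clustering

Functional labels come from standard 12/14-column tabular protein-alignment
hits, filtered at e-value ≤ 1e-5 and identity ≥ 40%, plus — for metagenome
proteins, where fragments are common — a covering-length requirement of at
least 90% of the hit length. Letters of all surviving hits of a gene are
unioned; a gene annotated "O,C" contributes its CIB to both O and C in
category summaries (the displayed convention in this literature; a
first-letter-only switch is easy to add at the call site by truncating the
assignment strings). Ortholog calls from two independent tools are
intersected as unordered pairs, and genes split into conserved (in any
surviving pair) versus unique sets; no reciprocal-best filtering is
re-applied here because that is the calling tools' job.

Group-by-category mean CIB pools all genes of the group (the alternative —
mean of per-species means — is available via `per_species_mean = TRUE`; on
balanced simulated data the two agree, and pooling was chosen as the
default because it weights genes, not genomes). Length summaries bin genes
into half-open intervals $(\ell - 500, \ell]$ bases.

Strain profiles (mean CIB per category) are clustered with unweighted
average linkage on Pearson correlation distance $1 - r$, computed with
pairwise deletion of missing categories; rows are not centered or scaled.
The linkage itself is delegated to `stats::hclust`; strain labels are
sorted first so the dendrogram is invariant under input order, and the
tree is exported as Newick with branch heights from the merge heights.
Zero-variance profiles make the correlation undefined and raise an error
naming the strain pair.

## The synthetic generator — what it does and does not emulate

Every statistical claim above is exercised against simulated coding
sequences with known truth. The model draws amino acids i.i.d. from a
distribution $p_{aa}$ (uniform over the 20 by default; a GC-skewed preset
exists) and, within each family, codons from the mixture

$$q(c \mid a) \;=\; \beta\,\mathbf 1[c = \mathrm{pref}(a)] \;+\;
\frac{1-\beta}{n(a)},$$

with one bias knob $\beta \in [0,1]$ and the alphabetically first codon as
the default preferred codon. A mixture rather than, say, a Dirichlet draw
was chosen deliberately: $q(\cdot|a)$ is closed-form, the population CIB is
computable exactly by `population_cib()`, and the endpoints are sharp —
$\beta = 0$ gives population CIB exactly 0 and $\beta = 1$ exactly 1,
matching the statistic's extremal characterizations. Population CIB is
strictly increasing in $\beta$, so the knob is identifiable. A TAA stop is
appended so generated FASTA records are valid CDS input. All randomness in
a call flows from one seed, recorded in the truth table; identical calls
are byte-identical.

The generator reproduces the statistical structure the inference machinery
assumes — per-gene codon frequencies varying around a group-level bias,
group and category labels, controllable length distributions — and it
reproduces the finite-length artefact that makes length binning necessary:
the plug-in entropy estimate is biased downward, so short genes *overshoot*
their population CIB (empirical CIB of unbiased 100-codon genes is visibly
positive, shrinking like $O(1/\mathrm{length})$). It does **not** emulate
operon structure, intragenomic GC gradients, tRNA-adaptation-driven
preference hierarchies, or expression-correlated bias; passing tests on
synthetic data therefore validate the estimator and the tests, not any
biological claim about real genomes.

## Validation workloads and their sizes

The shipped suite and the acceptance script rerun, at desk scale:

* block means of the curated copper-resistance/ROS gene table (12 and 23
  genes), which reproduce 0.186/0.232 and 0.236/0.264 at 3 decimals;
* CIB against an independent brute-force family-enumeration oracle on
  1,000 random count tables (agreement to 1e-12);
* the continuous AD statistic 2.4 on (1,2,3) vs (4,5,6) against a direct
  double-sum; the ties-adjusted standardized statistic against frozen
  reference values;
* exhaustive dominance p = 1/20 on the separated 3-vs-3 example, and
  Monte-Carlo agreement within 3 standard errors at $B = 10^5$;
* AD type-I error at $\alpha = 0.05$ over 200 replicate null pairs of
  $n = 50$;
* bias recovery with the Gly/Trp $\beta = 0.5$ model (population CIB
  0.2256) at $10^4$ codons, error < 0.02 and monotone in $\beta$;
* end-to-end ordering of $\beta = 0.1$ vs $\beta = 0.5$ groups
  ($n = 200$ genes of 300 codons, 20 replicates, $B = 10^4$);
* clade recovery from two planted templates (5 + 5 strains, noise
  sd 0.01) and a zero-height merge of identical profiles.

These sizes keep a full run in tens of seconds while leaving every
tolerance comfortably non-trivial; they are stated here so a reader can
scale them up when more precision is wanted.

## Known limitations

* CIB is a single-gene summary; it does not separate mutational bias from
  translational selection, and no expression-weighted reference set (CAI,
  tAI) is provided — other measures are out of scope by design.
* The asymptotic AD p-value is interpolated from five published percentile
  points; far outside the table (|T| large) it is an extrapolation, and at
  very small samples the permutation method is the better choice.
* The dominance statistic tests ordering against an exchangeable null;
  it is a test of "difference in the ordered direction", not a
  confirmation that CDFs never cross in the population.
* Multi-category genes are counted once per category, which double-counts
  genes in marginal totals; the per-assignment counts are reported so the
  effect is visible.
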