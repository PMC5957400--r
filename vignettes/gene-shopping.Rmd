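---
title: "Gene shopping for divergence-time estimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene shopping for divergence-time estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneshop)
```

## The problem

Phylogenomic datasets hold hundreds to thousands of gene alignments, far
more than Bayesian relaxed-clock dating can digest, and the genes vary
enormously in how fast and how clock-like they evolve. Fitting one complex
relaxed-clock model to all of them invites model mis-specification; fitting
each gene separately is intractable. *Gene shopping* takes a third route:
winnow the gene set down to a handful of genes whose properties make simple
clock models credible, then date with those.

`geneshop` implements the winnowing procedure and the machinery needed to
validate it. The procedure assumes two inputs: a focal species-tree
topology (inferred by whatever means) and rooted per-gene trees (rooting is
typically done with outgroups). Each gene is scored on three criteria:

1. **Concordance with the species tree.** Nontrivial bipartitions (splits)
   of the gene tree's unrooted topology are compared with those of the
   species tree after restricting both trees to their shared taxa. The
   score is the fraction of the gene tree's splits present in the species
   tree; 1 means full topological agreement.
2. **Clock-likeness.** On the rooted gene phylogram with outgroups removed,
   the variance of root-to-tip path lengths. An ultrametric tree has
   variance exactly 0; lineage-specific rate variation inflates it.
3. **Information content.** The total tree length in expected
   substitutions per site. Genes that evolve too slowly carry little
   signal, so among otherwise comparable genes longer trees are preferred.

Ranking is lexicographic: concordance (descending), then root-to-tip
variance (ascending), then tree length (descending). The top `n` genes
(three in the validation experiments) are selected and a concatenation
manifest with per-gene partitions is emitted for downstream dating.

## Tree statistics

Root-to-tip variance uses the **sample variance** (n−1 denominator). The
choice between the sample and population estimator does not change any
ranking — the two differ by a factor constant across genes of equal taxon
count — but absolute values do depend on it, so it is fixed and documented
here.

When outgroups are pruned before the clock statistics, the stem edge above
the ingroup root is retained (as the tree's `root.edge`) so that
root-to-tip path lengths of surviving taxa are unchanged by pruning; the
stem contributes a constant to every path and to the reported tree length,
and leaves the variance untouched.

Bipartition conventions: a split and its complement are one object,
canonicalized as the side not containing the lexicographically smallest
taxon; trivial splits (a side smaller than two taxa) are excluded; trees
with fewer than four shared taxa have no scorable splits. The denominator
of the concordance proportion is the **gene** tree's split count, which
stays well-defined when the gene tree misses taxa present in the species
tree (both trees are restricted to the shared taxon set first); the
species-tree denominator is available behind the `denominator` argument.
Polytomies are allowed in either tree and simply contribute fewer splits,
so collapsing a resolved edge can only reduce the shared count.

## The likelihood engine and the clock test

The standard molecular-clock test compares a gene's maximum-likelihood
score with free branch lengths against the maximum under a strict clock on
the same rooted topology; twice the difference is referred to a chi-square
distribution. A rooted binary tree on n taxa has 2n−3 identifiable free
branch lengths and n−1 clock node heights, giving **n−2 degrees of
freedom**. The default significance level is 0.05, configurable.

The engine is a Felsenstein-pruning implementation (in C++ via Rcpp) for
symmetric k-state substitution models with uniform stationary frequencies
and mean rate one, where the transition probabilities have the closed form
$P_{same}(t) = 1/k + \frac{k-1}{k}e^{-kt/(k-1)}$,
$P_{diff}(t) = (1-e^{-kt/(k-1)})/k$. For nucleotides this is Jukes–Cantor;
for amino acids the 20-state Poisson model. Empirical amino-acid
exchangeability matrices (WAG and kin) are deliberately not embedded: the
winnowing logic is model-agnostic, the engine stays exactly testable
against closed forms and brute-force enumeration, and the calibration
experiments use matched simulation/test models by construction. Supporting
empirical exchangeabilities is a straightforward extension point. Gaps and
ambiguity codes enter as partial likelihoods of one (missing data), the
same convention as the alignment container's contrast matrix. There is no
among-site rate variation, matching the simulation design.

Free branch lengths are optimized in two stages: a box-constrained
quasi-Newton pass (L-BFGS-B) driven by analytic per-branch derivatives
(one extra traversal yields the whole gradient), then per-branch Brent
sweeps against cached partial likelihoods until a full sweep improves the
log-likelihood by less than `tol` (default 1e-6). Clock optimization
parameterizes the n−1 node heights as the root height plus, per internal
node, its height as a proportion of its parent's height; the ordering
constraint becomes a simple box, one coordinate move rescales a whole
subtree, and the same two-stage scheme (chain-rule gradients, then
per-parameter Brent sweeps) applies. Branch lengths are bounded above by
`max_edge` (default 10 substitutions/site — effectively saturation) and
never go negative by construction. On a rooted topology only the sum of
the two root-adjacent branch lengths is identifiable; their split is
arbitrary and the log-likelihood, which is invariant to root placement
under these reversible models, is unaffected. A degenerate constant
alignment drives all branch lengths to the lower bound, and the LRT
statistic is clamped at zero so optimizer jitter can never produce a
negative test statistic.

## Simulators

The validation experiments rest on three simulators, all deterministic
functions of an explicit seed:

* **Yule chronograms** — forward pure-birth simulation from two lineages:
  with k lineages the waiting time to the next split is Exp(kλ) and the
  splitting lineage is uniform; simulation stops at the birth of the n-th
  lineage, so the expected root height is $\sum_{k=2}^{n-1} 1/(k\lambda)$
  (≈ 2.02 for n = 12, λ = 1). The degenerate n = 2 case runs a single
  waiting time at k = 2. Chronograms are rescaled to target root heights
  (0.25 / 0.5 / 0.75 in the simulation designs) by multiplying every
  branch.
* **Branch-rate decorations** mapping a chronogram to a phylogram:
  *strict* (one global rate), *noisy clock* (rate plus a zero-mean
  Gaussian per branch, redrawn until positive — negative rates are
  impossible, and the redraw policy matters once the noise standard
  deviation approaches the rate, as with rate 1, noise 0.75), and *UCLN*
  (independent lognormal rate per branch, parameters on the natural-log
  scale, so the mean branch rate is $e^{\mu + \sigma^2/2}$). The standard
  settings used throughout are rate 1 with noise 0.25 or 0.75, and
  mean.log −0.5 with stdev.log 0.5 or 1.0.
* **Sequence evolution** along the phylogram under the same symmetric
  models (root states from the stationary distribution, transitions by the
  closed-form probabilities), 1500 sites for nucleotide genes and 500 for
  amino-acid genes in the standard designs, gap-free.

What the generator emulates — and what it does not: simulated genes share
the true topology, are alignment-error-free, indel-free, and evolve
without among-site rate variation or selection. Passing validation
therefore demonstrates that the winnowing machinery ranks and selects
correctly when rate heterogeneity is the only confounder; it does not
certify behavior under topological conflict (incomplete lineage sorting),
alignment error, or compositional heterogeneity, all of which real data
add on top.

## Validation experiments

**Clock-test calibration.** Alignments simulated under a strict clock on a
fixed ultrametric tree are re-tested with the clock LRT at α = 0.05 using
the same model. The empirical false-rejection rate should sit near the
nominal 5%; the packaged calibration uses an 11-taxon Yule tree rescaled
to height 0.5, the Poisson amino-acid model, 500 sites, and 500
replicates, and is required to stay at or below 8%. (Nucleotide data of
the same design reject more often — stochastic variation accumulates with
more taxa and longer trees — which is one reason the ranking uses
root-to-tip variance, a descriptive measure of ultrametricity, rather than
the boolean test.)

**Rate-heterogeneity landscapes.** Pools of phylograms per condition
(clock, noisy clock, UCLN) are summarized as (tree length, root-to-tip
variance) scatters plus per-tip deviations from each gene's mean
root-to-tip path. Clock pools sit at variance ≈ 0 at every tree length;
mean variance increases monotonically in the noise standard deviation and
in stdev.log.

**Shopped versus random dating.** Per trial: one 12-taxon Yule chronogram
(rescaled to root height 0.5 — unrescaled Yule heights push Jukes–Cantor
sequences toward saturation, where branch lengths are unidentifiable, and
height 0.5 keeps per-gene tree lengths in the range empirical filtered
genes show); a pool of 200 genes, each with a global rate drawn
Uniform(0.5, 1.5) (tree-length heterogeneity) and a noise level drawn from
{0, 0.1, 0.25, 0.5, 0.75}; per-gene ML phylograms with branch lengths free
on the fixed true topology (within a simulation there is no topological
conflict, so concordance is 1 for every gene and selection is driven by
the clock-likeness and length criteria — exactly the mechanism under
test). Three winnowing-selected genes and three random genes are each
dated by joint ML strict-clock estimation and compared with the truth.

The dating step fixes the topology, shares one set of node heights across
genes, and profiles a scalar relative rate per gene ("a single molecular
clock, with gene-specific relative rates"). The root height is fixed at 1,
so results are relative ages; before computing error, the estimate's root
height is rescaled to the true height, and the error is the cumulative
absolute node-age difference across internal nodes. This point-estimate
metric was chosen because the package replaces Bayesian MCMC dating with
ML strict-clock dating: only point-age claims are reproduced, and
credible-interval (HPD-width) behavior of relaxed-clock posteriors is
explicitly out of scope. Across ≥ 50 trials the shopped arm's median
cumulative error must not exceed the random arm's (one-sided paired
rank test); with noise 0 everywhere the arms are indistinguishable.

## Numerical choices and degenerate inputs

* Ultrametricity tolerance: relative 1e-9 (configurable); rescaling and
  strict-rate decoration preserve it exactly.
* Optimizer tolerances: log-likelihood convergence 1e-6 by default; the
  gene-pool fits in the shopping experiment use 0.01, which is stricter
  than the default likelihood epsilon (0.1) of the standard ML gene-tree
  programs whose output the procedure normally consumes. Per-branch Brent
  tolerance scales with the overall tolerance.
* Ranking ties: the sort is stable, and statistic tables are emitted
  sorted by gene id, so equal records resolve to gene-id order —
  bit-reproducible output without a hidden tie-break key.
* Genes that cannot be rooted with the given outgroup, or that retain
  fewer than three taxa, are skipped with a warning and reported in the
  table's `skipped` attribute rather than failing the run.
* Newick round-trips preserve topology, labels and branch lengths to
  15 significant digits; duplicate or empty tip labels and negative branch
  lengths are rejected at parse time.
* A zero-height tree cannot be rescaled (error); a constant alignment
  yields all-zero ML branch lengths; the LRT statistic is clamped at 0.

## Problem sizes used by the validation suite

The packaged tests run the calibration at 500 amino-acid replicates
(11 taxa, 500 sites), oracle cross-checks on 500 random tree pairs and
exhaustive-enumeration likelihoods on ≤ 5-taxon, ≤ 3-site cases, Yule
height checks at 10,000 replicates, age-recovery at a 100,000-site
alignment, rate-dispersion monotonicity at 200 decorations per condition,
and the shopping comparison at 50 trials × 200 genes (plus a 20-trial
null). These sizes are the package's choices for routine verification;
all experiment functions accept larger values.

## Known limitations

* Substitution models are symmetric (JC / Poisson); no GTR, no empirical
  amino-acid matrices, no rate-across-sites. This is deliberate (see
  above) but means absolute likelihoods are not comparable with GTR+G
  analyses of real data.
* Dating is ML strict-clock on a fixed topology with relative ages; no
  fossil calibration, no credible intervals, no relaxed-clock posterior.
* Concordance is split-based; quartet methods and reconciliation
  (duplication/loss, ILS) are out of scope.
* The simulators produce substitution-only, gap-free data on a shared
  topology; conclusions about robustness to alignment error or gene-tree
  discordance cannot be drawn from them.
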