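---
title: "Detecting and placing ancient whole-genome duplications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and placing ancient whole-genome duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdinfer)
```

Paleopolyploidy — an ancient whole-genome duplication (WGD) — leaves three
partially independent signatures in a modern genome: a burst of equally aged
duplicate genes, a doubling of syntenic depth relative to an unduplicated
relative, and an excess of gene duplications mapping to one node of the
species phylogeny. `wgdinfer` implements all three detectors plus the
synthetic genome-evolution generator used to validate them. This vignette
explains the models, the defaults, and what the validation does and does not
establish.

## The synthetic generator: what it emulates

Every detector in the package is exercised on data from
`simulate_gene_tree()` / `simulate_polyploid_genome()` rather than on
downloaded genomes, so the generator's assumptions are the study conditions:

* **Gene families** evolve by a linear birth–death process inside an
  ultrametric species tree: each extant gene lineage duplicates at rate
  λ and dies at rate μ (events per gene per million years, My), one lineage
  entering the root. Default rates for the phylogenomic experiments are
  λ = μ = 0.002/gene/My, the scale typically estimated for plant gene-family
  turnover by count-based maximum likelihood.
* **WGDs** are episodic: at a `wgd_event()` every lineage alive on the
  carrying branch duplicates, and each *new* copy survives with the event's
  retention probability, independently per lineage. Retention is the single
  knob controlling how visible the event is; positive simulations use at
  least 0.2, the conventional lower bound for a detectable event.
* **The molecular clock** maps a duplication of age *a* to
  `Ks = 2 r_s a`, with multiplicative gamma noise of mean 1 and
  coefficient of variation 0.15 (`clock_params()`). The CV is a chosen
  default — empirical Ks distributions carry estimation noise of about this
  size — and is the one generator constant with no external anchor.
* **Polyploid gene orders** are produced by duplicating every chromosome
  (`multiplier` copies per round; 2 for WGD, 3 for a triplication), deleting
  each gene on the new copies with probability `loss_prob` (fractionation,
  default 0.3), and applying random rank-interval inversions (default 2 per
  chromosome). Gene ranks, not physical coordinates, are modelled, because
  collinearity statistics are measured in genes.

What the generator does **not** emulate: sequence-level evolution (no
rate variation across sites or lineages beyond the gamma noise), gene
conversion, tandem-duplication clustering, translocations between
chromosomes, and reciprocal-loss patterns that bias fractionation. Passing
tests therefore establish that the detectors recover the signal their models
assume; they do not establish robustness to every artefact of real
annotations.

## Ks age distributions and mixture peaks

`node_weighted_distribution()` gives each duplication node total weight 1,
split equally over its descendant pairs, so a large subfamily cannot
masquerade as a peak; raw per-pair weighting is available
(`node_weighted = FALSE`) because published distributions use both
conventions. The default window is Ks ∈ [0.01, 3]: below 0.01 the signal is
dominated by alleles and very recent tandem copies, above 3 synonymous sites
are effectively saturated; all peaks of interest here sit well below the
upper bound.

`fit_ks_mixture()` fits Gaussian mixtures to `log(Ks)` with observation
weights by EM (10 restarts from jittered weighted-quantile splits, relative
tolerance 1e-8, at most 500 iterations; the log-likelihood is asserted
non-decreasing at every iteration). Component count is chosen by a
sequential parametric-bootstrap likelihood-ratio test of k vs k+1 (200
replicates per test, α = 0.05, stopping at the first non-significant test or
`k_max = 4`). Two numerical choices matter:

* The observed LRT statistic is computed with the *same* reduced-effort EM
  (1 restart, 150 iterations, tolerance 1e-5) as the bootstrap replicates.
  Using a stronger optimiser on the observed data than on the replicates
  inflates the observed statistic relative to its reference distribution and
  makes the test anticonservative; with the symmetric procedure the test is
  calibrated (measured slightly conservative). The reported parameters
  always come from the full-effort fit.
* The bootstrap loop stops early once the accept/reject decision at level α
  is settled, which saves most replicates on clearly non-significant tests
  without changing any decision.

The "median Ks" of a peak is `exp(meanlog)` (the log-normal median); its
reported interval is the asymptotic 95% interval from the effective
per-component sample size. Degenerate components are prevented by a small
floor on the component standard deviation.

`ortholog_divergence_ks()` selects cross-genome pairs by reciprocal best
pairing with minimum Ks as the similarity proxy and summarises them by the
median with a 1000-replicate bootstrap interval. Which pair set published
analyses used (RBH vs syntenic orthologs) is generally unstated; RBH is the
package's choice and syntenic pair lists can be passed directly as a Ks
table. `classify_placement()` then applies interval logic: a peak wholly
above the ortholog divergence is `shared-ancestral`, wholly below is
`lineage-specific`, anything else `ambiguous`.

The self-contained Ks estimator `ng86_ks()` uses Nei–Gojobori (1986)
counting with Jukes–Cantor correction. It is oracle-testable (the suite
checks all 61×61 sense-codon pairs against brute-force enumeration) but
systematically underestimates high divergences relative to codon-model
maximum likelihood; users replicating a codon-model analysis should import
their Ks tables via `read_ks_table()`.

## Synteny blocks and depth ratios

Anchors are pairs of genes sharing a `family_id` (families with more than 10
members in either genome are skipped — a tandem-array guard; the cap is a
design choice, not an external constant). Chaining is maximal-cardinality
longest-increasing-chain dynamic programming per chromosome pair and
orientation, requiring at most 10 intervening genes between consecutive
anchors *on both genomes* (the stricter two-sided reading of a "distance
cut-off of ten genes") and at least 5 anchors per block. Chains are
extracted best-first with anchors consumed; ties go to the longer span, then
to the same orientation.

Depth is counted per gene as the number of covering block spans from the
other genome; the genome-pair ratio is the pair of modal nonzero depths,
reported unreduced (2:4, not 1:2) because the two multiplicities carry
independent information about each genome's history. Zero-depth genes stay
in the reported histograms so coverage can be inspected. Whether published
"depth ratios" are modes or percentile summaries of the depth histogram is
ambiguous; the mode is implemented, and it is robust to ≤ 30% fractionation
in the recovery experiments (1:2, 2:3 and 2:4 all recovered across ten seeds
at `loss_prob = 0.3`).

## MAPS-style duplication mapping

The species tree is a ladder: ingroup taxa ordered tip-to-root so each
internal node `N1..N(k-1)` defines one nested clade, with outgroups attached
below and used to root each gene tree (first outgroup tip by label). Each
gene-tree internal node maps to the species-tree node that is the LCA of its
leaf-species set, and is a duplication when its child species sets
intersect — the standard species-overlap criterion; the original method's
subtree-filtering rules live in its own references, so this criterion is a
stated interpretation, not a claimed re-implementation.

The counted unit per ladder node is the *maximal* gene-tree node mapping
there (its parent maps elsewhere). This matters: counting whole trees
instead inflates percentages below a WGD, because a retained WGD copy gives
a tree two chances to show an ordinary background duplication at the lower
nodes while the denominator stays fixed. With maximal-subtree counting a
retained copy adds one subtree to the denominator at each lower node, so
background percentages are unchanged and a 30%-retention WGD at node N2
shows ≈ 30% duplicated subtrees at N2 and background elsewhere.

The null is 3000 birth–death gene trees (coverage-filtered by rejection:
at least one tip per species, acceptance rate logged), the positive adds one
WGD at the tested node with retention ≥ 0.2, and per-node enrichment is a
one-sided Fisher's exact test at α = 0.05 with no cross-node correction
(each node is a separate a-priori hypothesis; flags must be read
accordingly). Uncertainty comes from resampling 1000 trees without
replacement 100 times. "Consistent with the positive simulation" means
Fisher-significant *and* reaching the positive arm's lower resampling bound.

Two behaviours of this design are worth knowing when reading flag tables.
First, a WGD casts a small duplication *shadow* on the node below it: a
retained copy whose descendants survive only in the two youngest taxa is,
from gene-tree data alone, indistinguishable from a duplication at `N1`, so
positive simulations elevate `N1` by a fraction of a percentage point. And
second, with one-sided tests at α = 0.05 and no cross-node correction, each
non-WGD node retains roughly its nominal false-flag probability against an
independent null simulation. Jointly these mean an occasional flag at the
node below a strong WGD is expected and should be read as the event's
shadow, not as evidence for a second event; the WGD node itself separates
from the null unambiguously (observed ≈ 38% vs ≈ 2% duplicated subtrees at
30% retention in the validation runs).

Rates for the null are estimated from gene counts by `estimate_bd_rates()`:
a single global (λ, μ) maximising the linear birth–death likelihood computed
by pruning over a truncated count space (truncation at 100 copies, reduced
automatically when observed counts are far smaller), with one gene at the
root and conditioning on family survival. Whether the original
implementation conditioned on survival in one or all species is unstated;
conditioning here is on at least one surviving gene anywhere, matching how
all-extinct families are unobservable.

## Problem sizes and known limitations

The validation experiments run at the sizes the analyses themselves use:
3500-point Ks mixtures, 2000-gene base genomes, 3000 gene trees per MAPS
arm, 3000 families for rate estimation; multi-seed claims (mixture recovery,
MAPS controls, depth-ratio recovery) use 10–20 seeds. These sizes were
chosen as the smallest at which the published-scale statistical behaviour is
stable.

Known limitations: the Ks estimator saturates (by design) near ps = 3/4;
the mixture model assumes log-normal peaks and will split strongly skewed
single cohorts at large n; depth ratios assume fractionation is unbiased
between copies; the MAPS duplication criterion does not model incomplete
lineage sorting or gene-tree estimation error (simulated trees are true
trees); and rate estimation assumes one global (λ, μ) across branches.
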