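---
title: "Methods: habitat specialists, diversity and co-occurrence networks"
author: "permanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: habitat specialists, diversity and co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permanet)
```

# Scope and data model

`permanet` implements the downstream statistical workflow applied to
16S-derived taxon abundance tables from contaminated-soil surveys: it takes
a genus- or OTU-level count matrix (taxa x samples) together with sample
metadata (site, permafrost layer, crude-oil contamination load) and
produces alpha-diversity summaries, relative-abundance profiles,
distance-based ordination with permutation tests, a multinomial habitat
specialist/generalist classification, and Spearman-screened co-occurrence
networks with keystone statistics. Upstream read processing (trimming,
alignment, chimera removal, OTU clustering) is out of scope; the package
starts from counts.

The canonical container is `abundance_table`, a named non-negative integer
matrix with taxa as rows. mothur "shared" files store samples as rows and
are transposed on read, so downstream code sees one orientation only.
Unknown lineage entries aggregate into an explicit `unclassified_<rank>`
bucket so rank-level aggregation conserves per-sample totals exactly.

# Alpha diversity

Shannon entropy is reported in nats (`H = -sum p_i log p_i`); the log base
is configurable because published tables rarely state it. Chao1 defaults to
the bias-corrected form `S_obs + F1(F1-1)/(2(F2+1))`, which stays finite
when no doubletons exist; the classical `S_obs + F1^2/(2 F2)` sits behind a
flag. ACE uses the conventional rare/abundant split at 10 reads; when the
rare group consists solely of singletons its coverage `C_ace = 1 - F1/N_rare`
is zero and the estimator is undefined, in which case the function falls
back to Chao1 (documented, and exercised in the tests).

Rarefaction is the exact hypergeometric expectation
`E[S_n] = sum_i (1 - C(N - N_i, n) / C(N, n))`, evaluated with `lchoose`
so depths of millions of reads cannot overflow; `C(N - N_i, n)` with
`N - N_i < n` correctly contributes a guaranteed detection. The tests pin
the closed form against exhaustive enumeration of all subsets at tiny `N`,
against `vegan::rarefy`, and against `1e4`-draw Monte-Carlo subsampling
(agreement within three standard errors).

# Profiles and heatmap structure

Relative abundance is plain column normalisation; rounding happens only at
presentation time. "Top k" taxa are ranked by *mean relative abundance*
across samples (not pooled counts), with lexicographic tie-breaking so the
ranking is deterministic. The clustered-heatmap structure uses Bray-Curtis
distance and average linkage by default - the published figure this
mirrors does not state its distance or linkage, so we chose the community
convention and left both configurable. Samples and taxa are both
clustered; taxon profiles use correlation distance, with constant profiles
placed at maximal distance.

# Ordination and PERMANOVA

Bray-Curtis dissimilarity `sum|x - y| / sum(x + y)` is computed from a
Manhattan-distance kernel and column totals. PCoA Gower-centres the squared
dissimilarities (`B = -1/2 J D^2 J`) and eigendecomposes; negative
eigenvalues - possible for semi-metric input - are reported but excluded
from coordinates and from "proportion explained".

PERMANOVA is single-factor by design: each published contrast (site,
contaminated-vs-uncontaminated, load) is a one-factor test, so multi-factor
partitioning was deliberately left out. Sums of squares come from squared
dissimilarities (`SS_total = sum_{i<j} d^2 / N`), the statistic is the
pseudo-F, and inference permutes group labels. Permuted statistics equal to
the observed one count toward the numerator, giving the conservative
`p = (1 + #[F_perm >= F_obs]) / (1 + n_perm)` with resolution
`1/(n_perm + 1)`. When all within-group distances vanish the statistic is
`+Inf` and the p-value still follows from permutation ties. The type-I
error of this construction is verified on 400 null communities (nominal
0.05, tolerance 0.02); F and R^2 are cross-checked against
`vegan::adonis2`.

# Habitat specialist classification

The multinomial classification takes each taxon's pooled counts
`(y_A, y_B)` over two habitats and asks whether its habitat share clears a
supermajority threshold `K` (default 2/3) *with confidence*. Sampling
effort is equalised through boundary success probabilities

```
p_A* = K N_A / (K N_A + (1 - K) N_B)
p_B* = (1 - K) N_A / ((1 - K) N_A + K N_B)
```

and four one-sided exact binomial tails on `y_A` given `t = y_A + y_B` at
level `alpha` (default `0.05/20`, the default of the reference
implementation of this scheme): specialist calls come from the two outer
tails, a generalist call requires *both* inner tails to reject (share
confidently inside `(1-K, K)`), and everything else is "too rare to
classify". We use exact tails rather than the normal approximation because
exactness is cheap at these counts; a brute-force enumeration of the
binomial pmf by forward recursion - an independent route - reproduces
every classification over all `y_A in [0, t]`, `t <= 60`, across a grid of
habitat totals, thresholds and alpha levels.

Counts at or below the coverage limit (default 30) are first multiplied by
their habitat's Good-Turing sample coverage `C_h = 1 - f1_h/N_h` and
rounded half-up - sparse counts in under-sampled habitats are discounted
before testing, the same direction of adjustment the reference
implementation applies to proportions. Taxa absent from both habitats are
excluded and reported separately.

Summaries report category counts and percentages both per taxon and
weighted by reads, since published percentage breakdowns of this kind are
typically read-weighted. Percentages round half-up to two decimals
("X% (n out of N)" labels), matching how such tables are printed; note
that `base::round` (half-to-even) differs on exact ties, which is why the
package carries its own `round_half_up`.

# Co-occurrence networks

The network stage follows the published filtering order: taxa below 0.01%
mean relative abundance are removed (strictly "less than", so a taxon at
exactly the floor survives); all remaining taxon pairs are screened by
Spearman's rho with the t-approximation p-value, passing on
`rho > 0.6 and p < 0.01` (both strict); then the taxon-sample affiliation
(two-mode) network - presence meaning count above a configurable floor,
default 0 - is projected onto taxa, keeping only screened pairs. The edge
weight (e-weight) is the number of samples in which both taxa are
detected, so it can never exceed the sample count, and the screened
network is a subgraph of the unscreened projection by construction.
Whether the original analysis screened before or after projection is
ambiguous; both orders are available (`project_affiliation(table)` vs
`project_affiliation(table, screen)`) and commute on the e-weights.

Degree analysis on "the upper half" keeps edges strictly above the median
e-weight; for an even edge count the median is the midpoint of the two
central values. Both conventions are documented because table
reproduction depends on them: with weights `{1,2,3}` only the 3 survives;
with `{1,1,5,5}` both 5s survive; equal-weight networks empty out. Node
summaries list, per taxon, the number of distinct partners and *all*
partners tied at the maximal e-weight (sorted lexicographically), the
layout of a keystone-taxon table; the chord matrix is the symmetric
e-weight adjacency whose row sums are sector widths. Spearman p-values are
deliberately not multiplicity-corrected by default - the screen's stated
rule is marginal - and a Benjamini-Hochberg step can be applied by the
caller on the screen's `p_value` column.

# The synthetic community generator

Because raw pyrosequencing data live upstream of this package, validation
uses a generator that emulates the *compiled design* of a permafrost
microcosm survey: 4 sites x {upper, deeper} layers x {0, 30, 50}% v/w
crude-oil loads (24 samples in the `paper_like` preset), genus-level
counts, and four planted taxon classes - contaminated-habitat
specialists, uncontaminated-habitat specialists, generalists, and rare
taxa - plus co-occurring guilds.

The mechanism: each taxon draws a log-normal baseline weight once;
specialists' weights are multiplied by `specialist_effect` in their
preferred habitat; members of a guild share one per-sample log-normal
latent factor with log-sd `guild_sdlog * guild_correlation` (a purely
shared factor - members decorrelate only through sampling noise - which
keeps the loading an interpretable tightness dial and is composition-safe;
copulas would add nothing here); per-sample composition is Dirichlet with
concentration 5000 around the expected weights; counts are multinomial at
a log-normal depth (default `meanlog = log(6300)`, `sdlog = 0.25`,
emulating per-sample 454 read counts varying by roughly a quarter around
their mean - the published pooled totals constrain only the mean, so the
spread is a modelling choice, not an estimate). Rare taxa are rescaled
deterministically so their maximal expected relative abundance stays below
half the 0.01% network filter.

Two calibration choices deserve a note. First, the Dirichlet
concentration (5000 for ~300 taxa) keeps pooled habitat counts close to
multinomial - the sampling regime the exact binomial classification
assumes - so the null false-call rate stays well under twice the per-test
alpha while per-sample compositions still fluctuate visibly. Strongly
overdispersed real communities would violate that assumption, and the
classifier's calls on such data should be read as anti-conservative; this
is a property of the method, not of the implementation. Second, shared
sequencing depth induces mild positive rank correlation between *all*
taxa (as it does in real count data), so guild recovery checks are
ordering checks (within-guild vs between-guild pairs), not
zero-correlation checks.

What passing tests show - and what they do not: recovery of planted
specialists (>= 90% at effect 50, 8 samples/habitat, depth 1e4) and of
planted guild edges (>= 80% within vs <= 5% between at loading 0.9)
demonstrates that the pipeline's decisions track the structure it claims
to detect under its own sampling model. They do not certify performance on
real communities, whose overdispersion, compositional effects and
phylogenetic correlation the generator intentionally omits (as it omits
chimeras, OTU-clustering noise and negative associations - the networks
here are co-occurrence only).

# Numerical and degenerate-input choices

* Classification, ranking and summaries break ties deterministically
  (lexicographic IDs), so identical inputs give byte-identical outputs.
* Identical seeds give bit-identical simulations; the generator derives
  per-stage substreams from the one design seed, so adding a stage never
  reshuffles another's draws.
* All-zero count vectors, zero-total samples, duplicate IDs, unknown taxa
  and single-sample clustering are hard errors naming the offending
  entity, never silent drops.
* Problem sizes in the validation suite (300-taxon communities, 100-400
  replicates, 199-999 permutations, `t <= 60` classification sweeps) were
  chosen so the full suite completes in about a minute on one core while
  keeping Monte-Carlo standard errors well inside the asserted tolerances.

# Known limitations

* One classification contrast at a time (two habitats); multi-habitat
  extensions are out of scope.
* PERMANOVA is one-factor, without strata; published multi-factor adonis
  formulas cannot be reproduced term-by-term.
* The Spearman screen's t-approximation is inaccurate below ~4 samples and
  is refused there.
* Network outputs retain isolated taxa; figures that silently drop them
  will differ in node count.
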