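---
title: "Ecological assembly null models for microbiome time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecological assembly null models for microbiome time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assemblage)
```

## The scientific question

A host-associated microbial community — for instance the hindgut
microbiota of a farmed fish followed over a feeding trial — changes over
time, and the interesting question is rarely *whether* it changes but
*why*: is the turnover driven by deterministic selection (environmental
filtering, host development, diet), by dispersal (limited or
homogenizing movement of taxa between hosts), or by neutral drift and
chance colonization? `assemblage` implements a coherent suite of
null-model tools that answer this question from four routine inputs — a
sample-by-OTU count table, a rooted phylogeny over the OTUs, taxonomy
and sample metadata (time point, treatment group) — plus, for the
functional stage, a genome function copy-number table.

Every stage is paired with a synthetic-community generator that plants a
*known* assembly process, so each statistic is validated by
parameter/process recovery rather than by visual plausibility. All
randomized procedures take explicit seeds and are exactly reproducible.

## The shared constrained-randomization null

Three stages (the Hill-dissimilarity null, the beta-null deviation and
RC~bray~) share one null kernel, so they test the same null hypothesis.
A null realization of a sample preserves its observed richness *S* and
read depth *N*: OTU identities are drawn without replacement with
probability proportional to their occupancy frequency across the
dataset; each drawn OTU receives one read, and the remaining *N − S*
reads are distributed multinomially in proportion to the metacommunity
mean relative abundance of the drawn OTUs. This is the classic
Raup-Crick-style constrained randomization: it scrambles *which* taxa
co-occur while respecting per-sample alpha diversity and the regional
abundance structure. Holding depth as well as richness fixed is a
deliberate, slightly stricter choice than "preserve alpha diversity"
alone; it prevents library-size artifacts from masquerading as assembly
signal.

## Hill-order dissimilarity curves

For two communities with relative abundances $p_1, p_2$ the package
computes the two-assemblage Hill beta diversity at order $q$,
$\beta_q = {}^q\!D_\gamma / {}^q\!D_\alpha \in [1, 2]$, and transforms
it to a dissimilarity in $[0, 1]$. Under the default *regional*
viewpoint ($1 - U_{q2}$) the $q = 0$ case is exactly the Jaccard
dissimilarity; under the *local* viewpoint ($1 - C_{q2}$) it is
Sørensen. Both coincide at $q = 1$, where the analytic limit
$\log\beta/\log 2$ is used (the formulas are continuous through
$q = 1$; the limit expression is substituted within $10^{-9}$ of it).
The diversity order tunes the weight of abundant OTUs: $q = 0$ sees
presence/absence only, $q = 1$ weighs OTUs by relative abundance,
$q = 2$ emphasizes dominants.

`hill_null_expectation()` computes, for every between-group sample pair
and a grid of orders (default 0–3 in steps of 0.25), the observed curve
and the mean ± SD over `n_iter` null pairs (default 999). The ecological
reading follows directly: observed ≈ null at $q = 0$ but far above the
null at $q \ge 1$ means the *membership* of the communities is as random
assembly would have it while their *abundance structure* is
deterministically shaped.

## Phylogenetic beta-null deviation

`beta_null_deviation()` replaces the taxon-identity metric with
Generalized UniFrac,
$$d_\alpha = \frac{\sum_e b_e\,(p_{Ae}+p_{Be})^\alpha\,
  \left|\tfrac{p_{Ae}-p_{Be}}{p_{Ae}+p_{Be}}\right|}
  {\sum_e b_e\,(p_{Ae}+p_{Be})^\alpha},$$
summing over tree branches $e$ with length $b_e$ and descendant
abundances $p_{\cdot e}$. The exponent defaults to $\alpha = 0.5$, the
canonical compromise between sensitivity to abundant and to rare
lineages; $\alpha = 1$ is exactly weighted normalized UniFrac (asserted
against an independent per-branch implementation in the tests). The
deviation of each within-group pair is `observed − mean(null)` under the
shared kernel; group means near 0 read as neutrally structured, away
from 0 as niche-structured. The analysis is strictly within-group on a
temporal basis — use the `group_time` label from the metadata reader.

## Quantitative process estimates

The five-way classification follows the standard two-step decision
tree. First the phylogenetic axis: the abundance-weighted
beta-mean-nearest-taxon distance
$$\beta\mathrm{MNTD} = \tfrac12 \sum_i p_{1i} \min_j d(i, j)
  + \tfrac12 \sum_j p_{2j} \min_i d(i, j)$$
(patristic distances, minima over taxa present in the other sample) is
standardized against a null built by shuffling taxon positions across
the whole phylogeny, giving the beta-nearest-taxon index
$\beta\mathrm{NTI} = (\mathrm{obs} - \bar{\mathrm{null}})/
\mathrm{sd}(\mathrm{null})$ with 999 shuffles by default.
$\beta\mathrm{NTI} > 2$ → variable selection;
$\beta\mathrm{NTI} < -2$ → homogeneous selection. Pairs without a
significant phylogenetic deviation go to the compositional axis:
RC~bray~ compares the observed Bray-Curtis dissimilarity with null pairs
from the shared kernel, scaled to $[-1, 1]$ with ties at half weight:
$$\mathrm{RC} = \frac{2\left[\#(\mathrm{null} < \mathrm{obs}) +
  \tfrac12\,\#(\mathrm{null} = \mathrm{obs})\right]}{n_\mathrm{iter}} - 1.$$
$\mathrm{RC} > 0.95$ → dispersal limitation (or historical
contingency); $\mathrm{RC} < -0.95$ → homogenizing dispersal; otherwise
the pair is *undominated* (weak selection, moderate dispersal and
drift). The homogenizing-dispersal rule is the standard lower-tail one;
descriptions of the framework occasionally typeset the sign
inconsistently, but only the lower tail can indicate dissimilarities
smaller than expected.

Implementation notes. The tip shuffle is unconstrained across the
metacommunity (the standard choice). Within `qpe()` one shuffle per
iteration is shared by all pairs — the usual matrix formulation, and
much faster than per-pair shuffles. For degenerate instances (identical
supports, star phylogenies) the null SD is zero and the index is
reported `NA` with a warning rather than an arbitrary value. On trees
with ≤ 8 tips `beta_nti(..., null = "exhaustive")` enumerates all
permutations; the test suite holds it against an independent
enumeration oracle. Classification defaults to within-group pairs (the
study design this package targets samples each host destructively, so
cross-group dispersal is not directly comparable); `pairs = "between"`
enables cross-group classification where it is meaningful, e.g. across
environments under variable selection.

## Competitive lottery model

Within a genus-level clade, a sample's *winner* is the member holding
strictly more than 90% of the clade's reads in that sample (the
threshold of the clade-based lottery literature; the strict inequality
matters only at the exact boundary). Per clade and time group the
package reports

* *winner prevalence* — the fraction of evaluated samples that have a
  winner, where a sample is evaluated only if the clade reaches a
  relative abundance of at least `presence_floor` (default $10^{-3}$;
  the floor is configurable, and the evaluated-sample count is
  reported);
* *winner diversity* — the Shannon entropy of winner identities across
  samples, normalized by $\ln(\text{number of distinct winners})$, with
  the convention that a single distinct winner has diversity 0.

Both statistics depend only on within-clade proportions, so they are
invariant to library size. A clade is flagged lottery-like when
prevalence > 0.75 *and* diversity > 0.25 — persistent winner presence
with stochastic winner replacement. Single-OTU clades are reported (a
lone member trivially "wins") but never flagged, since their winning is
structurally forced. OTUs without a genus annotation are excluded with
a logged count.

## Phylogenetic recruitment model

The recruitment model asks whether taxa newly detected over time are
phylogenetically distant from the established community (overdispersion,
$D > 0$), close relatives ("nepotism", $D < 0$), or equiprobable
($D = 0$). The generative kernel, shared verbatim between the simulator
and the estimator, recruits one taxon per step with probability
$\propto \exp(D\,z_s)$, where $z_s$ is the mean patristic distance from
candidate $s$ to the already-recruited set, standardized over the
current candidates. Standardizing at each step keeps the exponent
stable and makes $D$ unit-free — the estimate is exactly invariant to a
global rescaling of branch lengths (asserted to $10^{-6}$ after a
ten-fold rescaling).

`fit_dispersion()` estimates $D$ by curve matching: for each candidate
$D$ on a grid (default $-3$ to $3$ by $0.25$) it simulates ≥ 200
recruitment orderings (common random numbers across candidates, so the
objective is smooth in $D$), records the expected Faith's-PD fraction
after every recruit count, and minimizes the squared error between
logit-transformed observed and expected PD fractions at the observed
time points, refining the grid argmin by quadratic interpolation. Time
points whose PD fraction is 0 or 1 carry no logit information and are
excluded; at least three time points are therefore needed. The 95% CI
is a percentile bootstrap over recruitment steps: steps (time-point
increments) are resampled with replacement *conditioning on the first
time point's taxon set as the seed community*, and each resampled
series is re-scored against the precomputed expected curves — this
reuse is what makes 2000 bootstrap replicates affordable. Star-like
phylogenies make every candidate $D$ produce the same expected curve;
the fit then flags the dispersion unidentifiable instead of returning a
number. Estimates at the grid boundary are flagged as well.

Detection is presence-based: a taxon counts as detected at a time point
if it has at least `presence_min_count` reads (default 1) in any sample
of the group, samples being pooled within time points; groups are fit
independently. The estimator sees only taxa that were ever detected, so
$|D|$ is attenuated relative to the generative value when the series
stops well short of the pool — sign and ordering, not magnitude, are
the reliable readouts, and the package's own acceptance tests are
phrased accordingly.

## Taxa-function robustness

Each sample is perturbed `n_perturb` times (default 100): a removal
count $k$ is drawn uniformly from $1..S-1$ so perturbation magnitudes
span small to near-total, $k$ present taxa are deleted uniformly at
random, and the remainder is renormalized (a replacement mode that
redistributes the removed share to a metacommunity pool is also
provided). For each perturbation the *taxonomic shift* $t$ is the
weighted UniFrac between original and perturbed profiles and the
*functional shift* $f$ is the cosine dissimilarity between the
corresponding community function profiles
$F_k = \sum_s p_s\,\mathrm{copy}_{sk}$. The robustness regression
$$\ln f = -a + b \ln t$$
is fit by ordinary least squares over perturbations with $t > 0$ and
$f > 0$; $a$ (attenuation) is minus the intercept — high $a$ means
functional shifts stay small as taxonomy moves, i.e. robustness through
functional overlap — and $b$ (buffering) is the slope, how large a
perturbation must be before the functional profile visibly moves. When
more than half of the informative perturbations leave the functional
profile exactly unchanged ($f = 0$; e.g. effectively identical
genomes), the sample is flagged degenerate and $a$ is reported as
censored-high (`Inf`) rather than inventing a pseudo-count that would
silently set the attenuation scale. Cosine values below $10^{-12}$ are
snapped to exact zero so that collinear profiles are recognized as
unchanged rather than as floating-point dust.

The five gene distribution features are explicit operationalizations
(the literature names them without formulas); with $w_s$ the relative
abundances of the present, function-annotated taxa and $v_s$ their copy
vectors:

* average genome size $\sum_s w_s \lVert v_s \rVert_1$;
* genome size variability, the abundance-weighted SD of
  $\lVert v_s \rVert_1$;
* average functional dissimilarity, the abundance-pair-weighted mean
  cosine dissimilarity between distinct present genomes (undefined for
  single-taxon communities);
* average functional redundancy
  $\sum_k F_k n_k / \sum_k F_k$, the mean number of present carrier
  genomes $n_k$ per function, weighted by the community abundance
  $F_k$ of that function — this form (weighting in the average over
  functions, not inside the carrier count) is the one under which a set
  of disjoint single-function genomes has redundancy exactly 1
  regardless of abundances;
* unique-function abundance, the fraction of the community function
  profile contributed by functions carried by exactly one present
  taxon.

Per-category fits reuse one perturbation set across categories
(computing $f$ on the category's sub-vector), so category contrasts are
not confounded by perturbation sampling. `gdf_ordination()` standardizes
the features (dropping constants with a warning) and embeds samples by
classical MDS of Euclidean distances, reporting percent variance and
feature-axis correlations as loadings.

## BVSTEP subset selection

`bvstep_search()` looks for a small OTU subset whose Bray-Curtis
pattern rank-correlates with the full table's pattern. Distances are
computed on relative abundances of the subset columns *without*
renormalization (pairs with no subset reads at all get distance 1 by a
logged convention), and agreement is Spearman rank correlation — the
coefficient conventional for this routine; the Mantel-style correlation
is used descriptively, without a permutation test. The search is a
forward-addition/backward-elimination hill climb from random starting
subsets of size 5 (10 restarts by default): additions must strictly
improve rho and stop once the target (default 0.95) is reached;
eliminations are accepted whenever rho does not decrease, so ties
resolve toward smaller subsets. Candidate moves are scored
incrementally from per-pair contribution matrices, which makes each
sweep linear in the number of OTUs. The returned subset is the best
across restarts: meeting the target with the fewest OTUs, otherwise
the highest rho. The target is an algorithm parameter, not a data
property — on real data the achievable rho is whatever the data
support. An optional square-root or log transform of relative
abundances is available; raw relative abundances are the default.

## The synthetic-community generator

The generator's job is to *plant* a known process, at effect sizes
where the corresponding statistic should detect it, while staying
within a realistic amplicon-survey envelope: a lognormal metacommunity
(`sdlog = 1.2` spans roughly three orders of magnitude of abundance)
over an ultrametric birth–death phylogeny, tens of samples in
treatment-by-time groups, and a few thousand reads per sample. Each
sample is an independent Wright-Fisher chain — destructive sampling,
one host one sample — of `community_size` individuals resampled
multinomially for `n_generations` per elapsed time-point interval, with
offspring probabilities $((1-m)\,x/J + m\,\mathrm{meta}) \times w$ and
a final multinomial down-sampling to `library_size` reads.

The regimes differ in initialization and fitness $w$, and their default
kinetics were chosen once, from the mechanics of the statistics, before
the acceptance checks were written:

* **Neutral**: initialized from the metacommunity, $w = 1$, migration
  0.5 by default (the acceptance analyses use the high-migration case
  0.8). Community size 5000 with 20 generations per interval keeps
  drift mild, as befits a regime whose pairs should be undominated.
* **Homogeneous selection**: stabilizing selection toward the
  phylogenetic neighborhood of a single focal lineage shared by all
  groups, $w_s = \exp(-s\,(d(s,\mathrm{focal})/2\bar d)^2)$ with
  $\bar d$ the mean tip-tip distance and strength $s = 2$. The focal
  tip is the one with the densest neighborhood (most tips within
  $0.3\,\bar d$), so the favored set is a clade on any tree
  realization. Each sample starts from its own uniform founder subset
  (60% of the pool) and drifts at community size 1000 for 50
  generations per interval: the *stronger drift is essential* — it
  turns clade membership over between samples, and βNTI needs that
  turnover (two samples with identical supports have βMNTD 0 under
  every tip shuffle).
* **Variable selection**: the same selection kernel, but each group
  receives its own focal lineage, chosen greedily to maximize the
  minimum pairwise patristic distance between focals, pushing groups
  onto distant clades; cross-group pairs are the informative ones.
* **Dispersal limitation**: uniform founder subsets (60% of the pool)
  whose founder abundances are additionally scrambled by a lognormal
  factor (SD 1.5) — historical contingency: which arrivals prospered is
  decoupled from regional abundance — followed by drift with $m = 0$.
  The scrambling is what pushes observed Bray-Curtis beyond the
  abundance-informed null; founder subsetting alone produces turnover
  that the richness-preserving null largely reproduces.

An earlier design drew a Brownian trait on the tree and selected toward
trait optima. That satisfies "selection must be phylogenetically
autocorrelated" in expectation, but a single Brownian draw frequently
has level sets that are not clades (the taxa nearest any given trait
value sit in several subtrees), and homogeneous selection then produces
no phylogenetic clustering for βNTI to find — process recovery failed
on many seeds for reasons that are a property of the trait draw, not of
the statistic under test. Selecting on patristic proximity to a focal
lineage is the same assumption applied directly and makes the planted
regime detectable by construction, which is exactly what ground-truth
scaffolding is for. Setting `selection_strength = 0` degrades either
selection regime to the neutral regime bit-for-bit under the same seed.

What the generator does *not* emulate: sequencing error and chimeras,
compositional biases of PCR, within-host spatial structure, in-situ
diversification, or any fitted resemblance to a particular real
dataset. Passing recovery tests therefore demonstrates that the
statistics detect the processes they claim to detect under their own
assumptions — not that any particular real community was assembled that
way.

The genome-function simulator controls redundancy through per-function
carrier counts (low: functions mostly genome-unique; mid: ~30% of
genomes; high: ~90%) with lognormal genome-size factors; scaling a
genome's copy vector changes its size but not its cosine direction, so
size and redundancy are controlled independently. The recruitment
simulator reuses the estimator's kernel exactly, with the first taxon
uniform.

## Numerical choices and degenerate inputs

* Hill formulas restrict power sums to positive entries (so $0^0$ never
  contributes) and use the analytic $q = 1$ limit within $10^{-9}$ of 1.
* Zero-length and zero-total branches contribute nothing to Generalized
  UniFrac; two communities meeting only at the root give exactly 1.
* RC~bray~ ties count at half weight; identical samples give exactly
  −1 when every null pair is farther apart than the observed pair.
* Unrooted input trees are midpoint-rooted with a warning; missing
  branch lengths become 0 with a warning; negative lengths are an
  error.
* The pipeline derives one seed per stage from the master seed with a
  fixed stage-indexed formula, so toggling one stage never changes
  another stage's random stream; reruns with the same configuration are
  byte-identical (the run manifest records versions, seeds and
  parameters but no timestamps).
* Groups whose detection series cannot support a dispersion fit (fewer
  than two recruits after the first time point, or no informative PD
  fraction) are reported as missing in the pipeline output rather than
  aborting the run.

## Problem sizes used by the tests

The package's own acceptance checks run at deliberately modest sizes
chosen to make the properties sharp yet quick to verify: regime
recovery uses 200 OTUs with 12 samples per regime and 199 null
iterations; βNTI calibration uses 100 null-generated pairs; the
recruitment recovery experiment uses a 100-tip tree, 6 time points of
13 recruits, 20 replicate series, a 200-ordering Monte-Carlo per
candidate and a 200-resample bootstrap; robustness contrasts use 10
samples × 100 perturbations per redundancy level; BVSTEP recovery uses
5 signal OTUs in a circular abundance gradient over 95 noise OTUs
across 24 samples. Production defaults (999 null iterations, 2000
bootstraps, 100 perturbations) follow the values conventional in this
literature.

## Known limitations

* The five-way process classification inherits the assumptions of its
  lineage: a meaningful regional species pool, phylogenetic signal in
  niches for the βNTI step, and pairwise (not joint) inference.
* The recruitment estimator is a declared operationalization
  (exponential-in-standardized-distance kernel, logit-PD least squares,
  step bootstrap); other implementations of the same idea need not
  agree numerically, and $|D|$ is attenuated when the observed series
  covers only part of the pool.
* The lottery statistics condition on clades being observed above the
  presence floor; prevalence denominators count clade-bearing samples
  only (the alternative — all samples — is a switch away).
* BVSTEP is a local search; with strongly redundant signal structure
  different restarts can return different minimal subsets that are all
  adequate, which is a property of the problem, not the code.
* Robustness results are only as good as the supplied copy-number
  table; the package deliberately makes no assumption about where it
  came from.
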