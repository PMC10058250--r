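---
title: "Methods: painting-profile similarity, permutation tests and the downstream pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: painting-profile similarity, permutation tests and the downstream pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paintpop)
```

`paintpop` implements the downstream-analysis layer of haplotype-painting
population-structure studies. This vignette documents the statistical models
and procedures, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
conventions chosen where the methods literature is silent.

## Copying profiles and TVD similarity

Haplotype painting (e.g. ChromoPainter) expresses each recipient individual
as a mosaic of segments copied from donor haplotypes, and reports the
genome-wide matched chunk length per (recipient, donor) pair. Summing donors
within donor groups and normalising each recipient's row gives the copying
profile $f_i$, a point on the $K$-simplex. Genetic distance between two
recipients is the total variation distance

$$\mathrm{TVD}_{ij} = \tfrac12 \sum_{k=1}^{K} \lvert f_{ki} - f_{kj}\rvert,$$

a metric on the simplex in $[0, 1]$; $1 - \mathrm{TVD}$ is used as
similarity. `aggregate_to_groups()` excludes the structural zero self-column
when recipients also appear as donors, and errors on all-zero rows rather
than silently producing `NaN` profiles. TVD can be computed on chunk-length
or chunk-count matrices; both upstream dialects are accepted through the
same functions since only row proportions enter.

For principal components of a square painting matrix,
`prepare_pca_matrix()` fills each structural-zero diagonal entry with the
mean of that row's off-diagonal entries and then subtracts row means. The
"average of each row" convention is ambiguous about whether the zero itself
counts; the default excludes it, and `include_zero_diagonal = TRUE` gives
the other reading (the two differ by a factor $(n-1)/n$ on the fill and are
indistinguishable in practice for $n$ in the hundreds).

## Distinguishability permutation tests

Group A is *distinguishable* from group B when the mean intragroup
similarity of A, $G_A$, is significantly higher than the similarity of a
mixed group. Because a larger sample catches more of a group's diversity,
the test equalises sample sizes: per permutation the larger group is
downsampled so both have $n = \min(n_a, n_b)$ members, and a test group C is
drawn with $n/2$ members from each side without replacement (odd $n$:
$(n-1)/2$ from each plus one extra from a side chosen at random). The
p-value for A is the proportion of permutations whose mean within-C
similarity reaches $G_A$; likewise, separately, for B. The test is
deliberately asymmetric: a homogeneous A is easily diluted by B's members
(small $p_A$) even when a diverse B is not (large $p_B$).

Two conventions needed fixing where the procedure is usually stated loosely:

- **Tie rule.** The default counts ties ($\ge$) and applies the standard
  $+1$ correction, $p = (1 + \#\{\bar s_C \ge G\}) / (n_{\mathrm{perm}} +
  1)$, so p-values are valid and degenerate data (all similarities equal)
  give $p = 1$ rather than a spurious maximal significance. The literal
  strict-greater rule is available as `strict_gt = TRUE`.
- **Reference mean.** The permuted mean is compared against the full-group
  $G$ (the quantity the test reports), not the per-permutation downsampled
  group's mean; `reference = "downsampled"` gives the alternative reading.
  Under exchangeability both are calibrated; the full-group reference has
  lower Monte-Carlo noise.

Each comparison derives its RNG substream from the seed and the two member
sets, so results do not depend on the order in which pairs are run.
`n_perm` defaults to 100{,}000, the convention for published runs; the
calibration and power checks in this package use 500–2{,}000 permutations,
which bounds the attainable p-value at $1/(n_{\mathrm{perm}}+1)$ and is the
reason reported floors like $10^{-4}$ appear.

**Language-level variant.** Similarity within a language classification is
inflated by ethnic-group endogamy. `language_test()` therefore excludes
same-ethnic-group pairs from every mean — within languages, between them,
and within each permuted test group — and redraws permutations whose test
group contains fewer than two ethnic groups (no cross-ethnic pair, so its
score would be undefined); a redraw cap (`max_redraw_factor * n_perm`
attempts) turns a practically-impossible constraint into an explicit error.
A language containing a single ethnic group is reported as not testable
rather than given a p-value.

## Relatedness pruning

PI_HAT outliers are defined *relative to their populations*: pair $(i, k)$
is flagged when $\mathrm{PI\_HAT} > 0.15$ and

$$\mathrm{PI\_HAT} > \min\bigl(X_i + 3\max\{0.02, S_i\},\; Y_i +
3\max\{0.02, D_i\},\; X_k + 3\max\{0.02, S_k\},\; Y_k + 3\max\{0.02,
D_k\}\bigr)$$

with $X, Y, S, D$ the mean, median, SD and MAD of within-population PI_HAT.
This keeps low-diversity populations (where everyone is mildly related) from
being gutted by a fixed threshold. Populations with at most two sampled
individuals have undefined spread; any of their pairs above 0.15 is flagged
directly. The MAD scale constant defaults to 1 (raw MAD) and can be set to
1.4826 (the normal-consistent value R's `mad()` uses by default) — the
upstream convention is genuinely ambiguous, so it is exposed rather than
buried. Flagged pairs are resolved by stepwise greedy removal of the
individual in the most unresolved pairs (ties broken by smallest id, for
determinism); greedy vertex cover is within a factor of the optimum and the
tests verify validity and the greedy $\ge$ optimum bound against an
exhaustive oracle on small graphs. An absolute second pass (default 0.18)
then removes anything still highly related.

`prune_related()` runs duplicate resolution (PI_HAT $\ge$ 0.9 by default; a
seeded coin chooses the survivor, and discordant ethnic/birthplace metadata
marks the survivor as excluded from metadata analyses) *before* the formula
pass. A narrative order with duplicates handled last would let the formula
pass silently consume the near-1 pairs first; resolving them first keeps
each rule's effect observable while producing the same cover property. The
removal list carries a reason code per individual.

## Birthplace assignment and geography

An individual's analysis location is the spherical midpoint of the maternal
grandmother's and paternal grandfather's birthplaces when both are recorded
and within 150 km of each other; parents' midpoint when grandparent data are
missing; otherwise the individual's own birthplace, with the individual
excluded from birthplace-based analyses. The same 150 km rule is applied at
the parental level (the upstream description covers only grandparents; one
consistent rule beats a silent exception). Distances use the haversine
formula in its `atan2` form — accurate to antipodal separations, unlike the
`asin` form — on a sphere of radius 6371.0088 km (IUGG mean), exposed as an
argument rather than hidden in a library default. The midpoint is the
renormalised 3-D unit-vector mean: a geodesic midpoint, undefined (and an
error) for antipodal inputs; at sub-150-km separations it is
indistinguishable from any other mean convention.

## Isolation by distance

Pairs are assembled in three variants — different ethnic groups, same
ethnic group, or different ethnic groups with both members within 20 km of a
river polyline (minimum spherical point-to-segment distance) — honouring
the exclusion flags from birthplace assignment. Distances are grouped into
25-km bins; a bin is retained when it has strictly more pairs than the
variant's minimum (100 inter-ethnic, 20 intra-ethnic/corridor) and its pairs
do not all involve one individual. Bin mean similarity is regressed on the
bin midpoint by OLS, unweighted, and $R^2$ is reported ($R^2 \equiv 0$ when
the retained bin means are constant — a documented convention, since OLS
leaves it undefined).

One numerical caveat, which the parameter-recovery tests respect: with very
many pairs per bin the regression SE becomes tiny, and the difference
between the bin *midpoint* and the mean distance *within* the bin — a
property of the pair-distance density, e.g. triangular for individuals
scattered uniformly along a transect — becomes the dominant error term,
biasing the slope by up to ~1%. The recovery checks therefore draw pair
distances uniformly over the binned range, where the midpoint convention is
exactly unbiased; with strongly non-uniform geographies the slope should be
read with that (small) caveat in mind.

## IBD sharing summaries

Total sharing per unordered individual pair sums segment lengths at or
above 2 cM (the usual detection floor), aggregating haplotype pairs.
Length-bin decomposition assigns each segment to one bin; "2 to 6" and
">6" are implemented as $[2, 6)$ and $[6, \infty)$ — a segment of exactly
6 cM goes up, and the boundary is configurable. Bin totals therefore sum
exactly to pair totals. Cluster means count undetected pairs as zero so
they estimate sharing, not sharing-given-detection; singleton clusters are
an error rather than a silent `NaN`.

## Admixture-date harmonisation and the calendar

Each dating method carries its own retention rules: fastGLOBETROTTER
results need a one-date model fit `max_r2fit_1date` > 0.5; MOSAIC results
are dropped when expected genome-wide $r^2 < 0.5$ or source differentiation
$R_{st} < 0.01$; MALDER results need $p < 0.01$ (strict, the usual reading
of a "cutoff") and a date of at most 200 generations, beyond which
admixture LD carries little signal. Each rule can be disabled individually,
and removing one rule readmits exactly the events it alone rejected. MALDER
CIs are built as $g \pm 1.96\,\mathrm{SE}$, truncated below at zero
generations. Two admixture events are concluded only when two inferred
events have disjoint date CIs *and* disjoint amplitude CIs. Cross-method
CIs are merged as a true interval union (touching intervals merge) with the
convex hull also reported, since a displayed "union CI" can mean either; an
event is a single-method outlier when its CI is more than 3 generations
from every other method's.

Calendar conversion is $Y = D - 28(g + 1)$ with $D = 1968$ (mean sampling
birth year) and a 28-year generation. Years are astronomical internally
(year 0 exists); `format_year()` renders $Y \le 0$ as BCE at I/O only.
Prose year labels that round generations before converting can disagree
with the formula by a decade or two; this package always uses the formula.

## Demographic scenarios and MAF-matched downsampling

The expansion–bottleneck–expansion scenario is a piecewise-constant
effective-size schedule with changes at 100, 50 and 25 generations ago and
four sizes (ancestral, first expansion, bottleneck, second expansion) that
are required inputs — published scenario grids vary them, so the package
treats them as parameters with illustrative values in the examples.
Frequencies evolve by per-generation binomial resampling with the epoch's
$2N_e$ gene copies: a Wright–Fisher stand-in with the right drift variance
and martingale structure, chosen as the package's internal simulation
surface; a VCF adapter (`maf_from_vcf()`, `downsample_vcf()`) lets a
coalescent engine's output be slotted into the downsampling step instead.
No recombination or LD is modelled.

To mimic array data, simulated variants are downsampled so the count in
each 0.05-wide minor-allele-frequency bin matches a target histogram
(folded MAF, final bin closed so 0.5 is counted; monomorphic sites land in
the first bin and are flagged). When a bin's target exceeds availability,
all bin targets are scaled by the largest feasible common factor — keeping
the spectrum's *shape* — with a warning, rather than silently filling what
can be filled.

## The synthetic-data generator

`synth_config()` + the `generate_*()` functions produce the complete input
set with known ground truth: group copying profiles are Dirichlet draws
around configured mean profiles (concentration = tightness); birthplaces
scatter around group centres with a km-scale Gaussian; 5% of records (by
default) get missing grandparent fields and another 5% a grandfather
relocated > 150 km, so the exclusion rules always have work; kinship tables
plant duplicates (PI_HAT 1.0), parent-offspring and full sibs (0.5) and
half sibs (0.25) under truncated-normal noise over a background with
within-group inflation; IBD segment totals decay linearly with distance,
with Poisson segment counts and shifted-exponential lengths $\ge 2$ cM. All
generators derive named RNG substreams from one seed, so outputs are
byte-identical given a config.

What it does **not** emulate: linkage and recombination (profiles are
exchangeable draws, not mosaics), painting noise structure, genuine pedigree
consistency (planted relatives are marginal PI_HAT values), or spatially
structured profile gradients within a group. Passing tests therefore
demonstrate correctness of the downstream procedures under their stated
assumptions, not robustness to painting artefacts in real data.

## Problem sizes and determinism

The shipped checks use deliberately modest sizes chosen to exercise the
asymptotics that matter: 1{,}000 random simplex pairs/triples for the TVD
oracle and metric axioms; calibration of the permutation test on 200–500
replicate exchangeable cohorts of 15 + 15 at 2{,}000 permutations
(rejection at $\alpha = 0.05$ within a binomial band, KS distance to
uniform < 0.1); power on 100 replicates of 20 + 20 with Dirichlet means
0.1 apart in TVD; 50 replicates of the endogamy confound; 100 random
flag graphs (with an exhaustive vertex-cover oracle up to 10 nodes);
10{,}000-pair IBD conservation; a 500-individual isolation-by-distance
recovery; and 10{,}000-variant Wright–Fisher runs. Every stochastic step is
seeded; `scripts/acceptance.R` reruns all of it from one root seed.
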