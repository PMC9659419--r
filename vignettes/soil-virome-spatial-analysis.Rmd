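---
title: "Spatial structure and moisture response in soil viromes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial structure and moisture response in soil viromes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viroscape)
```

# Scope

`viroscape` implements the statistical core of a plot-scale soil-virome
study design: viral communities (vOTU coverage tables from viral-size-
fraction metagenomes) sampled on a two-block grid of field plots under two
precipitation regimes (100% and 50% of ambient) at two timepoints (T1, T2).
The package covers five linked analyses:

1. **Table hygiene** — singleton-vOTU removal, low-recovery virome removal,
   relative abundance, log transform.
2. **Spatial beta-diversity** — Bray–Curtis, PCoA, one-factor PERMANOVA,
   and distance–decay regressions with same-timepoint pair masking.
3. **Microdiversity** — per-sample consensus genotypes from allele-count
   pileups, pairwise consensus ANI, and per-vOTU ANI–distance correlations
   with Holm control.
4. **Indicator analysis** — two-group IndVal permutation tests contrasting
   the dry T2-50 samples against all others.
5. **Network trait enrichment** — the local-neighborhood hypergeometric
   scan on a protein-content gene-sharing network.

Upstream sequence processing (assembly, viral contig identification, vOTU
clustering, read mapping, coverage and breadth computation, network
construction) is out of scope: the package starts from the tabular products
of those tools, and a zero in a coverage table is taken to mean "not
detected after the upstream breadth filter".

# Models and procedures

## Beta-diversity and distance decay

Bray–Curtis dissimilarity is computed on log-transformed relative
abundances, `t(x) = ln(1 + 100 x)`. The transform's base and pseudocount
are not uniquely determined by convention; this form maps zeros to zero,
preserves ranks, and treats the argument as a percentage. Community
similarity `1 - BC` is regressed on the Euclidean distance between plot
centers over unordered sample pairs. All pairs mixing timepoints are
excluded, so with `n1` and `n2` samples per timepoint exactly
`n1(n1-1)/2 + n2(n2-1)/2` pairs enter the fit; the pair count is part of
the returned object. Pearson's r (two-sided) and the OLS slope are
reported, and the slope magnitude ratio between two fits expresses how much
faster one community type turns over in space than another.

PERMANOVA is one-factor (via `vegan::adonis2`): total SS of squared
distances partitioned into between- and within-group parts, pseudo-F
compared against seeded label permutations with the unbiased
`(b + 1)/(m + 1)` p estimator — the standard choice because it cannot
return zero. Multi-factor sequential models are intentionally not exposed.

PCoA retains positive-eigenvalue axes only and reports percent variance
over the positive part of the spectrum; no negative-eigenvalue correction
is applied (matching the default behavior of the classical implementation).
Axis signs are canonicalized so the largest-magnitude coordinate on each
axis is positive — classical scaling is sign-indeterminate, and a fixed
convention makes ordinations reproducible across platforms.

"Community overlap" is defined here as the Jaccard index of the detection
sets, as a percentage. The phrase "percentage of shared vOTUs" is also
consistent with normalizing by the smaller detection set; Jaccard was
chosen because it is symmetric, bounded, and standard. This is a
documented interpretation, not a derived fact.

Environmental distance z-scores each soil-chemistry variable (n−1
denominator) before Euclidean distance, so variables contribute equally
regardless of units; a constant variable is an error naming the column.

## Microdiversity

A position is *covered* at a minimum of 5 reads — the variant-calling
floor — and *polymorphic* when the second-most-common allele has at least 2
reads and at least 5% frequency. The minor-allele thresholds follow the
documented defaults of the standard strain-profiling tool; only the
coverage floor is fixed by the study design, and all three are arguments.
The consensus allele is the most common one, with ties broken by the fixed
order A < C < G < T for determinism.

Consensus ANI between two samples of one vOTU is the match fraction over
jointly covered positions (consensus-sequence semantics, i.e. all compared
positions count, not only variant sites). A pair is reported only when the
compared fraction of the genome *strictly exceeds* 0.25, mirroring the
`percent_genome_compared > 0.25` convention. Percent polymorphic uses
covered positions as the denominator rather than genome length: the
wording "in a vOTU sequence" is ambiguous, and the covered-position
denominator avoids a downward bias for partially covered genomes.

Per-vOTU ANI–distance correlations use the same cross-timepoint mask as
the community-level decay; vOTUs with no ANI variation are reported as such
and excluded from testing (they carry no information for a correlation),
and Holm's step-down controls the family-wise error across tested vOTUs.
Note that within-vOTU ANI ≥ 0.95 is a property of the upstream clustering
threshold, not enforced here; the generator respects it by construction.

## Indicator analysis

The group-size-corrected IndVal ("IndVal.g") is used: specificity
`A_g` from *group means* (so unequal group sizes do not bias it),
fidelity `B_g` as within-group occupancy, `IndVal_g = sqrt(A_g B_g)`, and
the statistic is the maximum over the two groups. This is the default
variant of the reference implementation; the non-corrected variant differs
only in using group totals. Significance is by label permutation with the
`(b + 1)/(m + 1)` estimator, 999 permutations by default, and calls use raw
p < 0.05 with no correction across vOTUs — deliberately mirroring the
conventional indicator-species workflow, where the output is a candidate
set rather than a confirmatory inference. The T2-50 group is always derived
from metadata (`timepoint == "T2" & treatment == "50"`), never supplied by
hand.

## Local-neighborhood trait enrichment

This is the package's centerpiece. Edge scores are −log10 P values of
protein-content overlaps; reciprocals turn them into path weights so
strong overlaps are short edges. After all-pairs Dijkstra:

- the neighborhood threshold is the **first percentile** of all *finite*
  unordered pairwise distances (self-pairs excluded). Unreachable pairs are
  excluded because infinite distances would otherwise dominate any
  percentile; the percentile uses linear order-statistic interpolation
  (`h = (n−1)p/100 + 1`), the default convention of the environment the
  procedure originated in (a nearest-rank alternative would differ only at
  small n).
- a node's neighborhood is every node at distance **strictly less than**
  the threshold ("shorter than"), including the focal node itself at
  distance 0. Inclusion of the focal node is not settled by the original
  wording; including it keeps membership symmetric
  (`u %in% N(v)` iff `v %in% N(u)`) and makes sizes well defined.
- neighborhoods with fewer than 10 nodes are excluded from testing (but
  reported), matching the published rule.
- each qualifying neighborhood is tested for each trait with an exact
  upper-tail hypergeometric probability `P(X >= k)`, with the universe `N`
  equal to all vOTU nodes in the network (reference-genome nodes are
  excluded from the universe). `P(X >= k)` is the standard enrichment
  convention; because `phyper(..., lower.tail = FALSE)` literally computes
  `P(X > q)`, and it is unknowable whether `k` or `k − 1` was passed
  historically, a `tail = "gt"` switch provides the alternative.
- Holm correction is applied per trait across the qualifying
  neighborhoods — the family actually "considered for the
  overrepresentation analyses". Applying it jointly across both traits
  would be more conservative; per-trait was chosen because the two traits
  are reported as separate analyses.

The significant subnetwork is the union of member sets of significant
neighborhoods; host-linkage annotation then reports, for each subnetwork
vOTU, the host taxa of directly adjacent reference genomes and the
fraction of reference-linked vOTUs whose links are exclusively one taxon.

# The synthetic-data generator

No sequencing data ship with the package; all inputs are simulated with
planted structure so that every analysis has a recoverable ground truth.

**Field layout.** Two rows of 1.8 m plots at 1.8 m center spacing — nine
upper, seven lower, rows 7.5 m apart — with half the plots assigned to the
50% regime, one or two subplots per plot, and two timepoints. Gravimetric
moisture is drawn around plausible grassland values (wet T1 ~0.22 g/g, dry
T2 ~0.12, drier T2-50 ~0.06).

**Abundances.** Each vOTU gets a random preferred location and a lognormal
baseline (meanlog log 20, sdlog 1); expected abundance decays with a
Gaussian kernel of width `decayScale` (default 2 m, i.e. strong turnover
at plot scale) times lognormal cell noise (sdlog 0.5). Indicator vOTUs are
multiplied by `exp(±treatmentLogEffect)` in T2-50 samples. A detection
floor zeroes values below the 20th percentile of nonzero values, so
occupancy spans a realistic range. The lognormal/Gaussian choices are the
generator's own: only the qualitative structure (decay, treatment shift,
variable occupancy) is asserted anywhere.

**Gene-sharing network.** A stochastic block model whose first block is
the planted module; by default the module is the densest region
(within-module edge probability 0.9 versus 0.1 in background blocks of 75,
0.005 between blocks, scores uniform on [1, 20]). The density asymmetry is
deliberate: real gene-sharing networks concentrate their sizeable local
neighborhoods in a few highly interconnected regions, and with ~500 nodes
the first-percentile threshold admits on average only ~1% of pairs, so a
module of uniform density would leave almost no neighborhood above the
10-node floor. Module members carry the "enriched" trait at 0.5 versus
0.05 elsewhere. When abundance truth is supplied, enriched-trait nodes
take planted indicator ids, linking the two generators for end-to-end
tests.

**Allele counts.** Each vOTU has a reference genotype, a set of variant
sites with one alternative allele each, and one shared uniform draw per
site. Sample `s` flips site `j` iff `u_j < q_s` with
`q_s = min(0.5, divergenceRate × distance-from-origin + noise)`. Coupling
the flips through shared uniforms makes the expected consensus mismatch
fraction between two samples exactly `|q_s − q_t|`, which grows with
spatial separation — independent per-sample flips would instead give
`q_s + q_t − 2 q_s q_t`, which is nearly uncorrelated with pairwise
distance and would not plant the ANI decay the analysis exists to detect.
Reads are Poisson around the mean coverage with a binomial minor-allele
share at variant sites. There is no linkage between sites.

**What the generator does not emulate.** Read-level error, uneven coverage
along genomes, compositionality artifacts of relative sequencing depth,
relic DNA, block-level confounding between treatment and space, and any
realistic protein-content evolution behind the network. Passing recovery
tests therefore demonstrates correctness of the statistical machinery
under the stated model, not robustness to every property of real soil
viromes.

# Numerical choices and degenerate inputs

- Permutation p values always use `(b + 1)/(m + 1)`; exact enumeration
  oracles (used in tests) use the plain fraction over all distinct
  assignments.
- Consensus ties break A < C < G < T; percentile interpolation is linear;
  the prevalence threshold is inclusive (`>= 90%`) while the
  most-variable-vOTU and compared-fraction thresholds are strict, each
  following its source wording.
- Degenerate inputs fail loudly with the offending label: zero-sum
  samples, constant chemistry variables, constant distance vectors, fewer
  than 3 retained pairs, all-zero vOTUs (flagged, not tested), groups of
  size 1.
- Bray–Curtis is a semimetric; the triangle inequality is neither assumed
  nor asserted, and PCoA's negative eigenvalues are reported unused.

# Problem sizes

The shipped tests and the acceptance script run entirely on simulated
data at sizes chosen to exercise every code path while completing a full
run in minutes on a laptop: abundance tables of 120–500 vOTUs × ~45
samples, networks of 500 nodes (20 recovery seeds, 200 null-calibration
seeds), allele profiles of 6–10 vOTUs × ~45 samples × 0.3–1 kb genomes,
and 100–200-replicate calibration loops for the permutation tests. The
published analyses these mirror ran on thousands of vOTUs; all algorithms
scale to that size (the scan's cost is dominated by all-pairs Dijkstra,
`O(V · E log V)`).

# Known limitations

- PERMANOVA is single-factor; no strata/blocking, no sequential SS.
- The IndVal machinery is specialized to two groups.
- The enrichment universe is the whole vOTU network; restricting the
  universe to, say, nodes with any detected trait would change K and N.
- The generator's treatment effect and spatial kernel act independently;
  at a 2 m kernel the spatial variance dominates and indicator recovery is
  weak at moderate effects — the moisture-arm fixtures therefore use a
  10 m kernel so the planted contrast dominates, and this is a property of
  the fixtures, not of the estimators.
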