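---
title: "Methods: MST-kNN clustering of expression metafeatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MST-kNN clustering of expression metafeatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstknn)
```

This vignette documents the models and procedures the package implements,
the parameters that matter, the numerical conventions, and the design
choices that were genuinely open — in enough detail that a user can judge
what a result does and does not mean.

## Metafeatures

A metafeature combines two measured features elementwise with one of four
operators (ratio, sum, difference, product), written `A/B`, `A+B`, `A-B`,
`A*B`. Each unordered pair contributes exactly one metafeature per
operator, oriented so the feature earlier in the matrix's row order comes
first. Two conventions are worth making explicit:

* **Orientation.** Difference and ratio depend on operand order. We always
  emit the `a`-before-`b` orientation. Downstream proximity uses
  `|Spearman|`, which is orientation-invariant, so this convention costs
  nothing; report tables show whichever orientation was generated.
* **No transformation of ratios.** Ratios are left on their natural scale.
  Spearman correlation is invariant under strictly monotone transforms, so
  a log-transform would change nothing downstream.

Positivity is enforced at the point of use: the ratio operator and the JSD
profiles require strictly positive values, whereas sums, differences and
products tolerate zeros, so loading a matrix with zeros is legal until a
positivity-requiring operation touches it.

Generation is blockwise (`block_size` rows at a time, with an optional
streaming callback) so the full metafeature matrix never has to be
materialized; at the scale this package targets (hundreds to a few
thousand base features) in-memory matrices are comfortable, and the
streaming contract is what would carry a larger deployment.

## Progression quantifiers

Each sample's expression vector over the signature features is treated as
a probability distribution after normalizing to unit sum. Divergence
between distributions is the Jensen–Shannon divergence with **natural
logarithms**, hence bounded by `ln 2 ≈ 0.6931`. The two progression scores
are the divergence of each sample's profile from the **mean of the
member profiles** of the control group and of the severe group.

Two choices here were open and are worth recording:

* *Per-sample sum-to-one normalization.* Microarray intensities are
  positive, and treating the signature vector as a composition is the
  natural reading; any global rescaling of a sample cancels out.
* *Mean of profiles, not profile of the mean.* Averaging the normalized
  profiles weights each member equally regardless of its overall
  intensity; averaging raw vectors first would let bright samples dominate
  the group profile. The mean of unit-sum vectors is unit-sum, so no
  renormalization is needed.

The base of the logarithm matters only for the absolute scale: the
clustering consumes ranks of the scores (Spearman), which are
base-invariant.

Braak stages I–VI are encoded 1–6; as an ordinal scale this is exactly
what a rank correlation needs.

## The clustering algorithm

### Distance and ranking

The dissimilarity is `d(i,j) = 1 − |Spearman(x_i, x_j)|`. The absolute
value is deliberate: marker clusters are expected to mix strongly positive
and strongly negative correlates (an inverted biomarker is as informative
as a direct one), which requires sign-blind proximity. Features with
constant expression have undefined correlation and are dropped with a
warning before clustering.

Every node's neighbour ranking — `f(a,b)` is the 1-based position of `b`
in `a`'s list of all other nodes sorted by distance, ties broken by the
smaller node index — is computed **once** from the full distance matrix
and reused for every component during the recursion. Only the threshold is
recomputed per component; re-ranking within components would change the
meaning of the edge annotations mid-recursion.

### Graph construction

Building the complete graph is avoided: the method uses the symmetrized
q-nearest-neighbour graph with starting value `q = ⌊ln n⌋ + 1`, the
smallest neighbourhood above `ln n`, the scale at which a kNN graph is
expected to contain the MST. A symmetrized qNN graph need not be
connected; `ensure_connected()` escalates `q` by 1 until it is (at
`q = n − 1` it is the complete graph). On data with tight, well-separated
modules the escalation can be substantial — every node's near
neighbourhood is intra-module, so cross-module edges appear only at large
`q`. The `q` actually used is logged and recorded in the result.

### MST and deterministic tie-breaking

The minimum spanning tree is computed with Kruskal's algorithm over edges
sorted by ascending weight, then smaller endpoint index, then larger
endpoint index. Rank-derived distances produce many exact ties; the fixed
sort order makes the tree — and therefore the whole clustering — a pure
function of the input matrix. The suite verifies the tree against an
exhaustive spanning-tree search on small graphs and against an independent
MST implementation on larger ones.

### Edge annotation and the partition recursion

Each tree edge carries `p(a,b) = min(f(a,b), f(b,a))`. The defining
property, verified by brute force in the tests, is that `p > k` holds
exactly when neither endpoint is among the other's `k` nearest
neighbours — the classical MST-kNN elimination rule. Components of size
`n_c` are processed with threshold `t = ⌊ln n_c⌋` (the worked 10-node
example gives `t = 2`):

| case | condition | action |
|------|-----------|--------|
| MINSIZE | `n_c ≤ 3` | terminal cluster |
| C1 | `p_max > t` | remove all edges with `p > t`, recurse |
| C3 | `p_max = 1` or `p_max = t` | terminal cluster |
| C2 | `1 < p_max < t` | remove all edges with `p = p_max`, recurse |

The cases are exhaustive and mutually exclusive. The C2 rule is the one
genuinely ambiguous point of the method's published description, whose
wording is garbled at exactly this criterion. We resolve it as *remove the
least-mutual edges* (`p = p_max`), which always removes at least one edge
and therefore terminates; the alternative literal reading (`p = p_max − 1`)
is exposed as `c2_policy = "pmax_minus_1"` (falling back to `p_max` when
no such edge exists, again to guarantee progress). This choice has a
visible consequence, discussed under *Limitations*.

`min_size` (default 3) and the `q` override are the remaining knobs; both
default to the published procedure.

## Cluster quality and FDR

* **Homogeneity** is the mean Pearson correlation between each member and
  its cluster centroid (the mean expression vector of the cluster).
  Singletons contribute 1 by convention — the recursion produces many
  small clusters, and excluding singletons would make H undefined on
  legitimate outputs; `singletons_as_one = FALSE` covers the other
  reading.
* **Separation** is the size-weighted mean Pearson correlation between
  cluster centroids (lower = better separated). Pearson on raw expression
  rows is the convention of the standard microarray clustering toolkit
  these definitions come from.
* **Permutation FDR.** For a marker screen, the marker vector is randomly
  permuted across samples (uniformly, seeded), the number of features
  passing each `|ρ|` threshold is counted, and the FDR estimate at a
  threshold is `mean null count / observed count`, capped at 1. The
  published protocol uses 1,000 permutations; the package default is
  adjustable and the test suite uses 200, which bounds the Monte-Carlo
  standard error of the null counts well below the decision margins being
  tested.

## Synthetic data: what it emulates and what it does not

`planted_expression()` draws one latent standard-normal factor per block
over samples; feature `i` of block `k` is `exp(a·z_k + ε_i)` with
`a = σ·sqrt(ρ/(1−ρ))`, so log-values of two same-block features have
expected Pearson correlation `ρ` (`rho_within`) and all values are
strictly positive with a log-normal, intensity-like skew. Markers from
`planted_marker()` blend the block latent with fresh orthogonalized noise,
calibrated so the expected correlation with block members is approximately
`rho_target`. All randomness sits behind a single integer seed; the same
seed reproduces the dataset byte for byte.

Defaults mirror the motivating study's shape: 17 samples, order 10²
features, `rho_within = 0.9`, `noise_sd = 0.3`. What the generator does
**not** model: probe-affinity differences, batch effects, heavy-tailed
outliers, correlated noise between blocks, and missingness. Passing the
planted-recovery tests therefore demonstrates that the algorithm separates
rank-correlation modules at realistic sample sizes — not that it is robust
to array-specific artifacts.

## Numerical conventions

* Internal arithmetic is full double precision. Expression writers print
  17 significant digits so write/read round trips are exact; report
  writers print correlations and JSD values with 6 decimals.
* Output ordering is lexicographic by feature id everywhere; cluster ids
  are renumbered contiguously from 0, ordered by each cluster's
  lexicographically smallest member. All writers are byte-deterministic.
* JSD values are clamped to `[0, ln 2]` to absorb rounding at the
  boundaries; profile sums are validated to 1e-9.
* Ranking ties (equal distances) break by smaller node index; member
  ranking ties (equal correlations) break lexicographically by id.
* Degenerate inputs: constant features are dropped (clustering) or
  flagged NA (marker scans) rather than erroring a whole run; a constant
  *marker* is an error, since every statistic downstream is undefined.

## Problem sizes

The test and validation runs use deliberately desk-scale instances: planted
datasets of 5 × 30 features × 17 samples for recovery, 500 features × 200
permutations for FDR calibration, exhaustive MST checks on graphs of up to
6 nodes (1,000 random instances), and pipeline runs on a few hundred
metafeatures. These sizes make the whole suite run in well under a minute
while still exercising every code path at the sample sizes the method is
designed for.

## Known limitations

* **C2 fragmentation.** On planted-block data the first C1 pass removes
  exactly the low-mutuality bridge edges and recovers the blocks cleanly
  (the suite checks that no final cluster mixes blocks). Inside a
  recovered block, however, `p_max` often falls strictly between 1 and
  `t`, so C2 keeps splitting: homogeneous modules emerge as several pure
  fragments rather than one cluster. Pair-counting agreement with the
  planted labels correspondingly sits below the level the block-purity
  result alone would suggest (the acceptance suite computes the exact
  values). This mirrors the method's tendency, on real data, to produce
  many small clusters. Users who want coarser output can raise
  `min_size` or stop at the first split level via the split log.
* The q-escalation rule guarantees connectivity but can push `q` far above
  `⌊ln n⌋ + 1` when modules are tight and far apart; the MST is then
  computed on a much denser graph (this only costs time, not
  correctness).
* Spearman at 17 samples is noisy (null |ρ| of ~0.2 on average); the
  permutation FDR exists precisely to quantify the resulting false
  discovery burden, and it should always be consulted alongside marker
  reports.
* Metafeature spaces are internally highly dependent (every feature
  appears in many pairs); clustering all metafeatures together can merge
  otherwise distinct modules through shared-operand bridges. The marker
  reports and FDR screen remain interpretable because they are computed
  per feature.
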