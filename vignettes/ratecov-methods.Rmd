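---
title: "Methods: evolutionary rate covariation in ratecov"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionary rate covariation in ratecov}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratecov)
```

## The model

ERC analysis asks whether two genes' evolutionary rates fluctuate
together across the branches of a species phylogeny. The inputs are one
branch-length table per orthogroup, each estimated on the *same* fixed
species topology pruned to the species that orthogroup covers (in
practice amino-acid substitution branch lengths from a program such as
PAML's `aaml`; in this package, equivalently, tables from the built-in
generator). Three stages follow.

**1. Branch identity.** Branches are matched across orthogroups by their
bipartitions: a branch is identified by the set of species on the side
not containing an anchor (the lexicographically smallest species), so
identity is independent of rooting or node rotation. Trees are treated
as unrooted throughout — the two edges incident to a degree-2 root
describe one branch and their lengths are summed — because substitution
branch lengths carry no root information. When a tree is pruned, each
pruned branch corresponds to a *path* of master-tree branches; the
package tracks this mapping explicitly so lengths can be compared across
orthogroups with different species content.

**2. Relative evolutionary rates.** The dataset-average tree holds, for
every master branch, the mean of that branch's length over the
orthogroups that resolve it one-to-one (branches merged into a longer
path by pruning are not decomposable per-edge and are excluded from the
mean, which keeps it unbiased). For a given orthogroup the expected
length of each of its branches is the path-sum of these means, and its
branch lengths are regressed on the expected lengths by
**through-origin ordinary least squares**, `b = r a`. The slope `r` is
the gene's overall rate; the residuals are the RERs, positive where the
gene evolved faster than expected. Published descriptions of this step
say only that observed lengths were "regressed against" the average
tree; the through-origin form on raw lengths is this package's choice —
it is the natural proportional-rates model, and because the next stage
is a *rank* correlation, monotone departures from that choice have
limited influence. A log-scale variant was considered and rejected as a
default because zero-length branches are legitimate data here.

**3. Pairwise ERC.** For each gene pair the computation is repeated on
the tree containing exactly the species the pair shares: both genes'
lengths are path-summed onto that pruned topology, expected lengths are
rebuilt there, RERs recomputed, and ERC is **Kendall's τ-b** between
them. τ-b (not τ-a) because ties are certain in this data — zero-length
branches and path-summing both create them. Recomputing on the shared
tree (rather than masking full-tree RERs) matches the stated procedure
for handling incomplete orthogroups and keeps every pair's regression
internally consistent.

A pair is *undefined* (reported `NA` with a reason code, never coerced
to 0) when fewer than 6 species are shared, fewer than 2 branches
survive the expected-length floor, either gene is degenerate, or either
RER vector is constant. Undefined pairs are excluded from percentile
denominators.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `min_species` | 6 | Minimum species per orthogroup, and per pair (shared); below this the RER regression has too few branches to be stable. Applied both as the ingest filter and pairwise. |
| `floor` | 1e-9 | Expected-length floor (substitutions/site). Branches whose dataset-average expectation is below it are dropped from the regression: a near-zero covariate would have unbounded leverage on the slope. |
| `threshold` | 0.4 | ERC hit threshold for focal rankings, the conventional cut used when building candidate lists. |
| `percentile` | `"all_pairs"` | Pool for "top x%" annotations. Published percentile claims are ambiguous between the focal gene's own row and all pairs; both are implemented and labeled (`"focal_row"` selects the other). |

## Numerical choices

* **Residual snapping.** Residuals smaller than `1e-12 × max(b)` are set
  to exactly 0. At that scale a residual is floating-point rounding, not
  signal, and — because τ is rank-based — leaving it in place would
  convert arithmetic noise into spurious correlations. The visible
  consequence: data that are exactly proportional to the species tree
  yield constant (all-zero) RER vectors and *undefined* τ, rather than a
  meaningless ±1.
* **Degenerate genes** (all-zero lengths) get slope 0 and are excluded
  downstream with a warning rather than an error, so one empty
  orthogroup cannot abort a dataset-scale run.
* **Exact vs approximate rank-sum.** `group_contrast()` enumerates all
  label assignments when the combined sample is ≤ 12 (exactness is cheap
  there; two-sidedness is distance of the rank sum from its null mean,
  which is tie-safe), and otherwise uses the normal approximation with
  tie-corrected variance and continuity correction. The approximation is
  accurate to well under 0.01 from permutation truth at ≥ 12 per group
  on continuous scores, which is the regime it is applied in; at very
  small n it is off by design, which is exactly why the exact branch
  exists.
* **MRP tie-breaking.** All search modes break equal-parsimony ties by
  the lexicographically smallest canonical Newick string (rooted next to
  the smallest leaf, subtrees sorted recursively), so outputs are
  deterministic and platform-independent. Baum–Ragan columns carry
  uniform weight — no weighting variant is described for the original
  supertree step, and uniform weights are the standard default.
  Exhaustive search is capped at 9 taxa ((2n−5)!! growth); the heuristic
  is NNI hill-climbing from greedy random-addition starts (default 10
  restarts), seeded.
* **Boundary conventions.** Migration classes are half-open with the top
  class closed: [0, 0.25) no migration, [0.25, 0.75) delayed,
  [0.75, 1] completed — the printed class limits overlap at 25% and 75%
  and do not resolve ties, so the package fixes the convention and
  documents it. Protrusion sector boundaries likewise go to the
  clockwise-starting sector (45° is middle, 135° rear, 225° middle,
  315° front). The nurse-cell normalization denominator is the *mean* of
  same-chamber NC peaks (`median` exposed as an option); the source
  description says "peak intensity values" without an aggregator.
* **Enrichment correction.** Benjamini–Hochberg across terms; the
  correction used by the original database-driven enrichment runs is not
  stated, and BH is the field default for exploratory term lists.

## What the generator emulates — and what it does not

`simulate_orthogroups()` draws, for gene *g* on master branch *e*,

```
b[g,e] = r_g * a_e * exp(sigma_shared * z[m(g),e] + sigma_noise * eps[g,e])
```

with `a` exponential(mean 0.1) master branch lengths, `r_g` uniform base
rates in `rate_range` (default 0.5–2), `z` one shared standard-normal
deviation per (module, branch), and `eps` independent gene-level noise.
Species drop out independently (default probability 0.1, redrawn until
`min_species` remain, so generated tables always pass the filter);
pruned-tree lengths are path-sums of the `b` values, exactly mirroring
how real pruned gene trees relate to the species tree. Defaults — 22
species, ≥ 6 species per orthogroup, `sigma_shared = 0.5`,
`sigma_noise = 0.1`, dropout 0.1 — encode the study conditions the
pipeline is validated under: a 22-taxon panel with a minority of genes
sharing a latent co-functional signal about five times stronger than
idiosyncratic noise. Multiplicative log-normal deviations keep lengths
positive without truncation; the exponential length scale is arbitrary
and cancels in the rank-based ERC.

What it deliberately does **not** emulate: sequence-level estimation
error (branch lengths are exact given the latent rates, whereas `aaml`
estimates carry sampling noise correlated with alignment length);
gene-tree/species-tree discordance (topologies are always the pruned
master); paralogy artifacts (the paralog filter is assumed upstream);
and non-modular correlation structure such as clade-specific rate
accelerations shared by *all* genes (the average tree absorbs those in
real data). Consequently, passing the planted-module recovery checks
shows the statistic and its plumbing are correct, not that real
proteomes will separate this cleanly; on real data the background τ
distribution is wider and threshold choice matters more.

`simulate_screen()` draws per-chamber migration fractions from a beta
distribution (mean = 0.85 baseline plus the gene's shift, concentration
10 — control clusters mostly complete migration, with realistic spread)
and disassociation flags Bernoulli. It models scoring variability only,
not imaging or genotype misclassification.

## Validation problem sizes

The shipped checks run, per seed: zero-noise identity on 40 orthogroups
× 22 species; residual orthogonality on 500 random regressions; τ-b
against an exhaustive O(n²) count on hundreds of tied vectors (n ≤ 50);
a 50-gene ERC matrix for symmetry and the shared-species contract;
planted-module recovery on 200 orthogroups × 22 species × 10 seeds
(focal row of 199 pairs computed exactly; background mean estimated
from 150 sampled non-module pairs per seed, whose sampling error is
negligible next to the ~0.8 separation); exhaustive MRP on 20 random
6-taxon instances against full 105-topology enumeration, with recovery
asserted on leave-one-out covers (three random 5-taxon subtrees can
leave several topologies tied through missing-data wildcards, so the
recovery fixture uses all six leave-one-out restrictions, which make
the source topology the unique optimum); rank-sum approximation
against 100,000-draw permutation oracles at 12–20 per group; and
screen-statistic recounts on 10,000-record fixtures. These sizes were
chosen so the full suite exercises every code path at ground-truth
scale in a couple of minutes on a single core.

## Known limitations

* ERC values are reported raw, without per-pair significance calibration
  — matching standard practice, but meaning τ values are comparable
  within a dataset, not across datasets with different species counts.
* The average tree treats orthogroups as exchangeable; a few extremely
  fast genes can still shift branch means (no robust/trimmed mean
  option yet).
* `aaml`-side questions — whether the original regression used raw or
  transformed lengths, and how subset branches were matched to the
  average tree — are not documented upstream; the choices here
  (through-origin OLS on raw lengths, path-summation) are this
  package's reconstruction and are stated as such, not asserted as the
  original implementation's.
* Exhaustive MRP beyond 8–9 taxa is impractical by design; heuristic
  mode makes no optimality guarantee (it is checked against the
  exhaustive optimum at small n).
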