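---
title: "Methods: 2-D/3-D neighboring and the Neighbor Preference Index"
author: "neighborpref"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 2-D/3-D neighboring and the Neighbor Preference Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neighborpref)
```

# The problem

Large chemical-structure databases precompute two complementary kinds of
"neighbor" relationships between compounds. *2-D neighboring* ("similar
compounds") compares substructure fingerprints — binary vectors recording the
presence of structural features such as element counts, ring systems, bonded
element pairs and atom environments — with the Tanimoto coefficient

$$T = \frac{N_{AB}}{N_A + N_B - N_{AB}},$$

where $N_A$, $N_B$ are the set-bit counts of the two fingerprints and
$N_{AB}$ the common-bit count; pairs with $T \ge 0.9$ are 2-D neighbors.
*3-D neighboring* ("similar conformers") compares conformer shapes with the
Gaussian-overlay model: a pair is a 3-D neighbor when some conformer pair has
shape-Tanimoto $ST \ge 0.8$ **and** color-Tanimoto $CT \ge 0.5$ at the
shape-optimized superposition, which guarantees a combo score
$ComboT = ST + CT \ge 1.3$.

The two schemes recognise different kinds of similarity: fingerprints find
close structural analogues (same scaffold), shape overlays find molecules of
similar form and feature layout regardless of scaffold. This package
implements both schemes, the dataset construction that makes them comparable,
and the per-compound statistic quantifying their complementarity — the
*Neighbor Preference Index*

$$NPI = \frac{N_{2D\text{-}only} - N_{3D\text{-}only}}{N_{total}} \in [-1, 1],$$

with $+1$ for compounds all of whose neighbors are 2-D-only, $-1$ for all
3-D-only, and $0$ for no preference. Common neighbors (found by both
schemes) enter through $N_{total}$ and pull the NPI toward zero. Compounds
with no neighbors have an undefined NPI; they are excluded from histograms
and reported separately, since the defining ratio has a zero denominator.

# The shape model

Each heavy atom contributes a spherical Gaussian $p\,e^{-\alpha r^2}$ with
$p = 2\sqrt{2}$ and $\alpha = \kappa/\sigma^2$, $\kappa = 2.41798793102$,
where $\sigma$ is the atom's van der Waals radius (C 1.70, N 1.55, O 1.52,
F 1.47, Si 2.10, P 1.80, S 1.80, Cl 1.75, Br 1.85, I 1.98 Å; configurable).
This is the standard parameterization that makes each atomic Gaussian
integrate to its hard-sphere volume $\tfrac{4}{3}\pi\sigma^3$. Overlap
volumes use the first-order pairwise sum

$$V_{AB} = \sum_{i \in A} \sum_{j \in B} p^2
  \left(\frac{\pi}{\alpha_i + \alpha_j}\right)^{3/2}
  e^{-\frac{\alpha_i \alpha_j}{\alpha_i + \alpha_j} d_{ij}^2},$$

which equals the $L^2$ inner product of the two summed densities.
Higher-order inclusion–exclusion corrections are deliberately omitted: the
pairwise form is the common analytic-mode choice and is exactly testable
against a grid-integration oracle (the test suite checks 1 % agreement on
randomized shapes). A useful consequence of the inner-product form is the
Cauchy–Schwarz bound $V_{AB} \le \sqrt{V_{AA} V_{BB}}$ at **any** pose, which
yields an exact upper bound on the optimal ST from self-overlap volumes
alone; the 3-D neighboring loop uses it to skip conformer pairs that cannot
reach the ST threshold. Because the bound is exact, the neighbor set is
identical to the unfiltered all-pairs scan (a property the tests verify).

## Superposition

The ST-optimized pose is found deterministically, without randomness:

1. center both shapes at their Gaussian-mass centroids,
2. diagonalize the Gaussian-weighted inertia tensor and align principal
   axes,
3. start from the four proper axis-flip combinations, and
4. refine each start with a relinearized steepest-ascent optimizer over the
   6 rigid-motion parameters (rotation about the moving centroid +
   translation), with backtracking line search, relative overlap tolerance
   $10^{-6}$ and at most 200 iterations.

CT and ComboT are evaluated at this shape-optimized pose only; a
feature-optimized superposition is not implemented because the neighboring
relation is defined on ST-optimized scores.

## Color features

Six feature types are perceived from the molecular graph with a documented
rule table (the field's standard force fields are proprietary, so the rules
are this package's own, configurable convention): donor = N/O bearing a
hydrogen; acceptor = N/O with formal charge $\le 0$ and fewer than four
substituents; cation/anion = positive/negative formal charge; hydrophobe =
contiguous groups of carbons with no heteroatom neighbor, merged at the
group centroid; ring = centroid of each basis ring. Color atoms are
Gaussians of radius 1 Å; CT sums same-type overlaps only. When both feature
sets are empty, CT is 0 with a degenerate flag — an empty feature set should
not make a pair similar.

# Data model and dataset construction

Structures are labelled graphs over heavy atoms (hydrogens are implicit
counts); covalent units are connected components. The raw ("series A")
datasets may contain salts and mixtures; because conformer models exist only
for single-component structures, such records can have 2-D but never 3-D
neighbors — a systematic bias. The collapsed ("series B") construction
removes it: every record maps to its *parent* (the carbon-containing unit
holding at least 70 % of the heavy atoms of all unique covalent units,
neutralized), families are deduplicated by canonical form with annotation
labels merged by union, and records failing conformer eligibility (single
component, organic elements, at most 15 rotatable bonds, at most 50 heavy
atoms) or lacking conformers are dropped.

Conventions that the source material leaves open, fixed here:

* **Canonical form** — deterministic canonical labelling of the graph
  (element, charge, H-count, bond orders) via BLISS, ignoring stereo flags;
  uniqueness of covalent units is a connectivity notion.
* **Neutralization** — positively charged N/O/S atoms carrying hydrogens are
  deprotonated, negatively charged N/O/S atoms are protonated; quaternary
  centres and metals stay charged.
* **Rotatable bond** — single, non-ring (bridge) bond whose endpoints both
  have another heavy neighbor; amide bonds are *not* excluded. This is the
  simplest defensible convention and is configurable.
* **Organic element set** — H, C, N, O, F, Si, P, S, Cl, Br, I.
* **"Available 3-D description"** — conformer eligibility plus at least one
  stored conformer.
* **Rings** — cycle-space basis rings (fundamental cycles closed through
  spanning-tree paths); adequate for the mono- and bicyclic structures this
  package generates and analyses, but not a smallest-set-of-smallest-rings
  algorithm for heavily fused polycycles.
* **Atom indexing** — 1-based everywhere (bonds, conformer rows, JSON-lines
  output), the native R convention; SDF is 1-based already.

The built-in fingerprint catalog is a versioned, simplified analogue of the
classic substructure key classes: element counts at thresholds, total-H
thresholds, ring counts by size, bonded element pairs by bond order,
ring-composition keys, and per-element environment keys (degree, H-bearing,
charge sign) — 437 defined positions in a vector that reserves the classic
881 length. It is *not* bit-compatible with any public fingerprint;
externally computed fingerprints can be imported from hex TSV instead.
Printed worked scores that depend on the exact public catalog are therefore
qualitative references here, not reproduction targets.

# Threshold comparability

Comparing neighbor counts across the two schemes is meaningful only if the
thresholds are comparably strict. Against random-pair score statistics
(2-D Tanimoto $0.42 \pm 0.13$; best ST-optimized ComboT $0.77 \pm 0.13$,
taken as inputs), the thresholds sit $z = (0.90-0.42)/0.13 = 3.7$ and
$z = (1.3-0.77)/0.13 = 4.1$ standard deviations above the means. Under a
normal-tail reading (implemented because it reproduces the printed
chances), the implied probabilities of two random structures being
neighbors are 0.0111 % (1 in 9 000) and 0.00228 % (1 in 43 825) — within a
factor of five of each other. Probabilities are computed from the
*unrounded* z-scores; note that the exact quotient of the two tails is
4.8696, so a two-decimal report of the ratio is 4.87.

```{r thresholds}
threshold_comparison()
```

# The synthetic population generator

No external corpus is downloaded; all pipeline stages are exercised on
seeded synthetic populations with *planted* similarity structure. A
population is a union of clusters of three kinds:

* **common** — members share one graph and one template geometry (plus
  Gaussian coordinate noise), so every within-cluster pair is both a 2-D
  and a 3-D neighbor;
* **2d_only** — members share one graph (fingerprint Tanimoto exactly 1)
  but each member's conformers sit on its own random fold of a long
  flexible chain, so within-cluster pairs fail the ST threshold;
* **3d_only** — members share one rigid skeleton geometry but carry
  different heteroatom decorations ({N,N}/{N,O}/{O,O} on two fixed adjacent
  slot pairs, plus a feature-less marker element) chosen so that every
  slot hosts a donor+acceptor in every member: fingerprints fall below 0.9
  while ST and CT stay near 1.

The scenario is a mixing weight over cluster kinds: *identical* = all
common, *disjoint* = none (alternating 2d_only/3d_only), *overlapping* =
0.7, *mixed* = 0.4. Cluster scaffolds sit on a geometric heavy-atom-count
ladder (roughly ×1.35 per step, rings as regular polygons, zig-zag chains,
terminal decorations) with cluster-specific feature-less signature elements,
so that cross-cluster pairs are neither 2-D nor 3-D neighbors; chains are
kept short enough that every structure passes conformer eligibility.
Defaults: 60 compounds, 6 clusters, 5 conformers per compound (noise
replicates of the member geometry, passed through the diverse ordering),
coordinate noise 0.1 Å, annotation fractions mesh 0.5 / protein3d 0.3 /
pharmact 0.25 / drug 0.2 with pharmact nested in mesh and a cluster
enrichment weight of 3 for the drug subset (curated drug sets are rich in
analogue series). 3d_only clusters are capped at their 9 decoration
variants, with members redistributed to other clusters.

What this emulates — and what it does not: the generator reproduces the
*statistical* structure the analysis assumes (planted 2-D/3-D cluster
overlap, nested annotation subsets, salt families over parents), not
medicinal chemistry. Bond geometries are idealised templates, conformers
are noise replicates rather than torsional ensembles, and populations are
five orders of magnitude smaller than a public corpus. Passing scenario
tests therefore demonstrates that the pipeline measures planted
complementarity correctly; it does not reproduce corpus-scale overlap
percentages or cross-dataset correlations, which depend on the real
database and are out of scope.

Randomness is controlled by a single mandatory seed that fans out to
per-stage child seeds (generation, annotation, salts) through a documented
linear derivation, so any stage is reproducible in isolation.

# Numerical choices and degenerate inputs

* ST is clipped to $[0,1]$ against floating-point overshoot; the optimized
  rotation is re-orthonormalized through an SVD before the pose is
  returned.
* Both-empty fingerprints score 0 with a degenerate flag (0/0 is
  undefined, and an empty-key molecule must not neighbor everything); the
  same convention applies to empty color sets.
* Histogram bins: 21 centres at $-1.0, -0.9, \dots, 1.0$, half-width 0.05,
  outermost bins truncated to $[-1.00,-0.95]$ and $[0.95,1.00]$; a value on
  a bin boundary goes to the bin whose centre is nearer zero (so 0.95
  counts as 0.9, keeping the extreme bins for genuinely extreme
  preferences).
* $R^2$ is the squared Pearson correlation of paired NPI values (not a
  regression through the origin); it errors on constant inputs.
* Problem sizes in the test suite — populations of 60 (scenario checks,
  matching the planted-structure defaults) and 100 (ComboT floor), 50
  grid-oracle shape pairs, 20 self-recovery cases — were chosen as the
  smallest sizes at which the checked properties are meaningful rather
  than vacuous.

# Known limitations

* The fingerprint catalog is deliberately simplified; absolute 2-D scores
  are not comparable with public-database scores, only the thresholded
  neighbor relation semantics.
* Ring perception uses a cycle basis, not SSSR, and will under-count rings
  in heavily fused systems.
* The diverse conformer ordering is a greedy maximin on $(1-ST)$ distance,
  a simple stand-in for published diverse-ordering algorithms.
* First-order overlap slightly overestimates volumes of strongly
  interpenetrating shapes; since both $V_{AB}$ and the self-overlaps are
  computed in the same approximation, ST remains internally consistent.
* The ST optimizer is local from four deterministic starts; pathological
  near-symmetric shapes can in principle lock onto a suboptimal flip,
  which the rigid-invariance tests bound in practice to within $10^{-3}$.
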