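---
title: "Feature-count-maximizing pharmacophore alignment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-count-maximizing pharmacophore alignment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g3ps)
```

## The alignment problem

A 3D pharmacophore abstracts a molecule into labelled interaction points:
hydrophobic contacts (`H`), aromatic rings (`AR`), hydrogen-bond acceptors
and donors (`HBA`, `HBD`), positive and negative ionizable groups (`PI`,
`NI`). Each feature $A_i$ carries a positional tolerance radius
$\mathrm{thresh}(A_i)$ (Å). Two features match under a rigid transform $t$
when their types are equal and

$$\lVert A_i - t(B_j)\rVert \;<\; \max\{\mathrm{thresh}(A_i),
\mathrm{thresh}(B_j)\},$$

with a strict inequality — a centre exactly on the tolerance boundary does
not match. Exclusion volumes are "anti-feature" spheres of the query; an
alignment is sterically admissible only when every atom $a$ of the aligned
molecule satisfies $\lVert t(a) - c_x\rVert > r_x$ for every sphere
$(c_x, r_x)$, again strictly.

The quantity that decides whether a screened molecule is a hit is the
**number of matched feature pairs** under the best rigid (rotation +
translation, no scaling, no reflection) transform — not the RMSD of some
pairing. RMSD only breaks ties between alignments with equal match counts.
Optimizing RMSD directly is actively misleading: any two models sharing one
feature type admit a three-pair superposition with tiny RMSD, so
RMSD-minimizing methods systematically favour small, tight matches over
large, looser ones and miss hits the model definition allows. The greedy
3-point search implemented here optimizes the match count directly.

Fit classes follow the screening vocabulary: *full* (all features of both
models pair), *maximum* (all query features pair into a larger model),
*partial* (at least $|A| - \#o$ query features pair, where $\#o$ is the
omitted-feature budget), *none* otherwise. A hit requires at least
$|A| - \#o$ matched features after all post-filters.

## Seeding: neighbourhood encodings and the dissimilarity matrix

Three pairs are the minimum that fixes an unambiguous rigid transform, so
the search starts from three-pair seed guesses. To rank candidate seeds
without knowing the transform, each feature is encoded by its
rigid-invariant surroundings: the list of (type, distance) entries to every
other feature of the same model.

Two encodings of equal owner type are compared by solving an optimal
assignment between their neighbour lists. A neighbour pair with different
labels costs 1; with equal labels it costs

$$\min\!\left(1,\; \frac{|d_p - d_q|}{\max\{\mathrm{thresh}(A_i) +
\mathrm{thresh}(A_p),\; \mathrm{thresh}(B_j) + \mathrm{thresh}(B_q)\}}
\right),$$

i.e. the encoded-distance difference relative to the larger of the two
pairs' summed tolerances — the natural scale on which both intra-model
distances could still vary while all four features match. Differences
beyond that scale carry no discriminative value and clamp at exactly 1.
Neighbour lists of unequal length are squared with dummy entries at the
maximal cost 1, since an unmatched neighbour is maximally dissimilar. The
total assignment cost, normalized by the feature count of the larger model,
fills one cell of the $|A| \times |B|$ dissimilarity matrix; cells of
type-incompatible features hold a sentinel and are never seeded from.
Owner types with different codes are incomparable rather than expensive —
this keeps every finite entry inside $[0, 1]$.

Seeds are then drawn three ways:

* **single best** — optimal assignment over the whole matrix, keep the
  three cheapest assigned pairs;
* **top-m** — enumerate every feasible three-pair combination (distinct
  rows, distinct columns, no sentinel), rank by summed cost, keep the $m$
  best. The enumeration is $O(n^6)$ but trivially cheap at pharmacophore
  sizes;
* **exhaustive** — every label-compatible three-pair combination, no
  matrix needed.

Presets `fast` ($m = 20$) and `accurate` ($m = 300$) are exposed; at
typical feature counts 20 guesses recover nearly all hits and 300 guesses
saturate the feasible combinations.

The assignment subproblems are solved exactly by a shortest-augmenting-path
solver with dual potentials (the Jonker–Volgenant scheme, $O(n^3)$),
written in plain R because the matrices never exceed a dozen rows; its
optimality is certified in the tests against exhaustive permutation
enumeration up to $n = 5$.

## Greedy refinement with a forbidden matrix

Each seed is grown into a maximal alignment:

1. Superpose the seed pairs with the Kabsch algorithm (SVD of the centred
   cross-covariance; a reflection in the raw solution is corrected by
   flipping the smallest singular direction, so the rotation always has
   determinant $+1$).
2. Initialize a boolean *forbidden* matrix $F$ over all $(i, j)$ feature
   pairs: type-incompatible pairs and the rows/columns of the seed pairs
   start marked.
3. Repeatedly take the unforbidden pair with the smallest centre distance
   under the current transform, tentatively add it, re-superpose, and
   re-validate **every** collected pair (the previous alignment is
   restored on failure, so the whole set is what must stay valid). If
   validation fails, a pure translation rescue is attempted (below). On
   success the pair joins the set and its entire row and column are
   forbidden; on failure just that cell is forbidden.
4. Stop when $F$ is exhausted, when every query feature is matched, or —
   opt-in — as soon as $|A| - \#o$ features are matched.

Every iteration marks at least one new cell of $F$ and marks are never
cleared, so the loop terminates within $|A|\,|B|$ iterations; the tests
assert the strict increase on every iteration. The whole search is
deterministic and RNG-free: candidate ties break lexicographically on
$(i, j)$, guess ranking ties break on sorted pair indices.

A guess whose three pairs are all contained in the collected set of an
earlier refinement is skipped — it would converge to the same solution.
Seeds with (nearly) collinear geometry leave the rotation undetermined;
`kabsch()` raises a degeneracy error for them and the guess loop skips such
seeds, since an exhaustive enumeration necessarily produces collinear
triples on any model with three roughly collinear features. Inside the
growth loop (four or more pairs) degeneracy checks are disabled: the SVD
solution is still RMSD-optimal there, merely non-unique, and aborting an
otherwise healthy refinement over it would help nobody.

**Translation rescue.** When adding a pair breaks some tolerance, a pure
shift $\delta$ may still bring every collected pair strictly inside its
sphere. Feasibility is the ball-intersection problem
$\min_\delta \max_k (\lVert r_k - \delta\rVert - \rho_k) < 0$ over the
pair residuals $r_k$ and tolerances $\rho_k$. The objective is convex, so
a deterministic Nelder–Mead descent from two starts (the residual
centroid and the worst residual) finds the minimum reliably; a cheap
necessary condition — every two balls must pairwise overlap — rejects
hopeless cases before the optimizer runs. Success requires a strictly
negative minimax excess, matching the strict match predicate. The rescue
is attempted only inside the growth loop, not on the initial seed
superposition, and seeds whose own geometry violates tolerances are not
discarded up front: refinement proceeds and the final tolerance-satisfying
subset is reported.

## Post-processing

**Exclusion dodging.** A raw alignment whose atoms clash with query
exclusion spheres is not discarded immediately: up to three (configurable)
dodging translations are applied, each the minimum-displacement shift
clearing all currently clashing atoms to radius $+\,10^{-3}$ Å. The
clearance objective alone is unbounded below (any huge shift clears a
finite clash set), so the search minimizes $\lVert\delta\rVert$ under a
feasibility penalty, starting from the resultant of the per-clash outward
pushes, then shrinks the shift to the smallest clearing scale along its
direction — minimal displacement maximizes the chance that the feature
tolerances survive. After a clash-free pose is reached, every matched pair
is re-validated and violating pairs are dropped; the alignment stays valid
only if the surviving count still reaches the caller's minimum. Persistent
clashes invalidate the alignment.

**Direction filters.** Matched pairs where both features carry unit
direction vectors must agree to within a configurable angle (default 45°,
the package's own choice — directed-feature angle conventions vary between
modelling tools). For plane-normal types (aromatic rings by default) the
angle is evaluated orientation-free, since a ring normal has no preferred
sign. Pairs failing the check become unmatched; if the survivor count
falls below $|A| - \#o$ the solution is discarded. Each pair is evaluated
independently, so the filter is order-independent.

## The baseline aligner

For head-to-head comparisons the package includes a faithful-behaviour
reimplementation of the classic histogram/assignment/superposition scheme
used in established screening pipelines: per-feature distance histograms
(one per neighbour type; bin width 1 Å over 0–20 Å, triangular
$[0.25, 0.5, 0.25]$ smoothing with edge-mirrored boundaries, which
conserves histogram mass exactly), a histogram-overlap cost
$1 - \mathrm{mean}_T\,\frac{\sum\min(h^1_T, h^2_T)}{\max(\sum h^1_T,
\sum h^2_T, 1)}$ over the union of neighbour types, one Hungarian
assignment, Kabsch superposition, and iterative removal of
tolerance-violating pairs until a stable assignment remains. Omitted
features are handled combinatorially: query subsets from size $|A|$ down
to $|A| - \#o$ are enumerated (largest first) and the first subset whose
alignment passes all filters wins. Bin width, range, kernel and cost
metric are configuration with the defaults above; none of them is
standardized anywhere, so they are documented choices, monotone in
histogram overlap, and the comparisons drawn from the baseline are on
match counts and operation counts only — never on wall-clock time, and the
module makes no claim of bit-compatibility with any proprietary
implementation.

Two structural consequences are worth spelling out because the test suite
asserts them. First, the one-shot assignment is a fixed-point iteration
with no search: when feature encodings are ambiguous — the extreme case
being models whose features all share one type, where every
distance-histogram looks alike — the assignment picks an essentially
arbitrary permutation, the superposition is poor, removal cascades below
three pairs, and no alignment is found at all, while the greedy search
aligns the same models. Second, the subset enumeration makes the
baseline's work grow as $\sum_k \binom{|A|}{k}$ with the omitted budget,
whereas the greedy search never consults $\#o$ during refinement. Its
per-entry Kabsch-invocation count is exposed as a hardware-independent
effort proxy.

## Screening

`screen()` aligns every library entry against the query, applies the
post-filters, and classifies hits per molecule (entries sharing a name are
conformers; the best conformer by match count, then RMSD, represents the
molecule). The full guess budget is refined for every entry regardless of
the omitted budget: the omitted budget enters hit classification only.
Early exit keyed on $|A| - \#o$ is available but off by default — tying
the refined-guess set to $\#o$ would make the search effort depend on a
parameter that, by design, only relaxes the acceptance threshold, and the
effort independence is one of the method's defining properties. No
pre-alignment pruning filters are applied; pruning is a separate concern
from alignment and deliberately out of scope here.

## Synthetic data: what it emulates and what it does not

All tests and the acceptance script run on synthetic pharmacophores; no
external data is needed. The generator emulates structure-based screening
models: 4–9 features drawn uniformly from the six standard types, uniform
positions in a 10 Å box with at least 1.5 Å separation (bonded-atom
scale), tolerance radii uniform in 1–2 Å — the range typical of screening
queries. Screening "actives" are rigid-motion copies of the query with
isotropic Gaussian positional noise (0.2–0.25 Å in the shipped suites,
emulating conformer-sampling spread well inside the tolerance scale),
optional random feature deletion, and randomly permuted feature order;
"decoys" are unrelated random models of the same size. Clash scenarios are
deterministic constructions: a 0.1 Å-deep clash with over 1 Å of tolerance
slack (fixable by a small dodge) and an atom at the matched-feature
centroid 5 Å inside a sphere (unfixable without destroying the match).

Real pharmacophores differ in ways these fixtures do not capture: feature
positions are correlated by chemistry rather than uniform, type
frequencies are skewed, tolerances are hand-tuned per feature, conformer
ensembles have structured rather than isotropic variation, and exclusion
shells contain dozens of spheres. Passing the shipped suites therefore
demonstrates the algorithmic properties — recovery, optimality against
enumeration, effort scaling, determinism — not screening enrichment on any
particular target.

Fixture randomness is locally seeded (identical specs give identical
fixtures, and the caller's RNG state is untouched); the aligners
themselves never draw random numbers.

## Numerical choices and edge cases

* Strict inequalities everywhere the model defines them: feature matching,
  exclusion clearance, rescue feasibility. Boundary equality fails.
* Rotations are validated to $R^\top R = I$ and $\det R = +1$ within
  $10^{-9}$; unit directions to $|\,\lVert d\rVert - 1| \le 10^{-9}$.
* Kabsch degeneracy: a point set whose second singular value is below
  $10^{-7}$ (relative to the largest, floored at 1) is treated as
  collinear/coincident.
* Queries where $|A| - \#o < 3$ are refused with a dedicated error
  condition: no unambiguous 3D alignment exists for fewer than three
  effective features.
* JSON I/O writes 17 significant digits (lossless round-trip); the phar
  text dialect writes 4 decimals (1 × 10⁻⁴ Å round-trip).
* Feature indices are 0-free: everything user-visible is 1-based R
  indexing.
* User-designated "optional" feature flags are stored and round-tripped
  but not treated specially by the aligner; omission is governed solely by
  the global budget $\#o$, whose semantics are well defined. Per-feature
  optionality interacts with seeding and scoring in ways no published
  specification pins down, so it is left to the caller.

## Problem sizes in the shipped suites

The test-suite and acceptance-script sizes are chosen to exercise every
claim at desk scale: 100–200 recovery instances per suite, 60–100 random
pairs for the enumeration-oracle and baseline comparisons (feature counts
4–6, where full mapping enumeration is exact and fast), 100–200-entry
screening libraries with 30–60 actives, and guess budgets spanning 1–300.
The brute-force mapping oracle used to certify the exhaustive search
enumerates every label-consistent one-to-one mapping of size ≥ 3 and
superposes each by Kabsch, followed by the same pure-translation
feasibility polish the refinement may apply — without that polish the
oracle would not bound the search from above, because a translation rescue
can validate poses outside the plain Kabsch family.

## Known limitations

* Direction vectors do not participate in the refinement loop itself; they
  are post-filters. Direction-aware refinement would detect doomed
  pairings earlier.
* Exclusion dodging searches pure translations only, and its candidate
  construction (minimum-displacement minimax) is a documented choice; no
  published specification defines the dodge directions.
* The baseline aligner is a behavioural reference, not a bit-exact
  reproduction of any specific commercial implementation.
* Conformer generation is out of scope; the package aligns pharmacophores
  it is given.
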