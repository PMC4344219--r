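---
title: "Methods: uncertainty-constrained regionalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uncertainty-constrained regionalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvregion)
```

## The problem and the model

Small-area survey estimates come with published margins of error (MOE), the
half-width of a 90% confidence interval, so `SE = MOE / 1.645`. The package
treats the published MOEs as the complete description of sampling
uncertainty: no design effects, no finite-population corrections, and no
covariances between variables or between areas (none of these are available
to a user of published tables). The dimensionless uncertainty currency is the
coefficient of variation, `CV = SE / estimate`.

Given `n` areas, `J` variables, and a target `c` (global, or a per-variable
vector), the method searches for a partition of the areas into contiguous
regions such that

1. every non-exempt variable in every region has `CV ≤ c` (plus optional
   region population bounds),
2. the number of regions `p` is maximal, and
3. among feasible `p`-region partitions, the within-region sum of squared
   deviations (SSD) of the areas' feature vectors from their region means is
   minimal.

Goal 2 minimizes the loss of spatial resolution; goal 3 avoids merging
dissimilar neighbourhoods ("breaking the map"). The two are lexicographic:
more regions always beats lower SSD.

### Error propagation

Region-level uncertainty follows the standard Census Bureau rules for
derived estimates:

* **counts** — estimates add, variances add:
  `SE = sqrt(Σ se_i²)`.
* **derived proportions** (numerator a subset of the denominator) —
  `SE = sqrt(se_num² − p²·se_den²) / den` with `p = num/den`. Published MOEs
  can make the radicand negative; the implementation then falls back to the
  ratio form below and counts the fallback in the run log.
* **ratio means** (numerator not a subset, e.g. aggregate income over
  population) — `SE = sqrt(se_num² + p²·se_den²) / den`.

Two zero conventions are fixed deliberately: an estimate of 0 with MOE 0 has
CV 0 (satisfied), matching the preprocessing reset described below; an
estimate of 0 with a positive MOE has CV `+Inf`, so feasibility fails loudly
rather than dividing silently by zero.

### The small-proportion exemption

CVs of proportions estimated below 5% are structurally unstable, so the CV
constraint is waived for `kind = "proportion"` variables whose **region-level
aggregated** estimate is below 0.05 (strict inequality). Region level, not
area level: evaluating the exemption on member areas would let an infeasible
region hide behind one small tract. Counts and means are never exempt.

## Preprocessing

The pipeline is fixed and order matters; `preprocess()` is the only path that
produces the optimizer's inputs, which is how the order is enforced:

1. **Zero-household filter.** Areas with no households (parks, water,
   institutions) are dropped; they would force divide-by-zero in derived
   ratios. The contiguity graph is restricted to the survivors.
2. **Zero-estimate MOE reset.** Published MOEs on zero estimates are a
   state-level filler constant, not a sampling quantity; `(0, MOE > 0)` cells
   become `(0, 0)`. The reset count is reported. Evaluation uses the reset
   table too — the resets are part of the data the method sees.
3. **z-scores.** Attributes arrive on incommensurable scales (dollars,
   shares, counts); each per-area point estimate column (counts verbatim,
   derived variables as their ratio) is standardized to mean 0, sample
   (n−1) sd 1. A zero-variance column is an error naming the column — a
   constant attribute carries no clustering information.
4. **Variance-weighted principal components.** Correlated attributes would
   count the same information twice in the SSD. All components of the
   standardized matrix are kept (100% of the variance); each component's
   scores are whitened to unit variance and multiplied by its explained
   variance share `w_c = λ_c / Σλ`. The weighting intent (more weight to
   components that explain more) admits several functional forms; this one
   was chosen because it makes a component's maximum possible SSD
   contribution proportional to its variance share, and it is recorded in
   the output metadata. Components with `λ ≤ 1e-10` (rank-deficient input)
   are dropped with a warning and the weights renormalized.

Features are computed once on the full retained table, not per candidate
region: the objective must compare areas in one common space.

## The two-phase heuristic

**Phase 1 (repeated `n_starts` times).** A seed area is drawn uniformly from
the unassigned areas. If it is not feasible alone, neighbours are added one
at a time, drawn uniformly from the current frontier ring; when a ring is
exhausted the frontier expands to the next ring (concentric growth, which
favours compact regions over gerrymanders). Growth stops at feasibility. A
seed whose growth exhausts its frontier without reaching feasibility is
dissolved back to unassigned and not re-seeded (with fewer available
neighbours it could only fail again). When no further feasible region can be
seeded, the leftovers are absorbed in random order: each joins the adjacent
region with the smallest SSD increase among regions that remain feasible
after absorption. A leftover adjacent to no region yet (all its neighbours
are leftovers) is deferred to the end of the queue; a full pass with no
progress — or a leftover with adjacent regions none of which can absorb it
feasibly — discards the entire attempt. Discarding rather than backtracking
keeps each attempt cheap, which is what makes many restarts affordable.

Across attempts the best partition is the one with the most regions, ties
broken by lowest SSD, remaining ties by earliest attempt (stable).

**Phase 2 (tabu search).** Single-area moves between adjacent regions are
evaluated; a move is admissible when the donor keeps at least one member,
stays connected (checked by traversal after tentative removal), and both
donor and receiver remain constraint-feasible — the region count never
changes in this phase. Each iteration applies the globally best admissible
non-tabu move, improving or not; reversing a move (the area re-entering its
source region) is tabu for `tabu_length` iterations, except when the move
would beat the best solution seen (aspiration). The search stops after
`max_swaps` iterations or `no_improve_stop` consecutive iterations without a
new best, and returns the best solution ever seen, so the returned SSD never
exceeds the phase-1 SSD. Ties among moves break deterministically (lowest
area index, then lowest target region index), which together with the single
RNG stream makes a run exactly reproducible from its seed.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cv` | — | CV target, dimensionless; 0.10–0.12 is a common "reasonable precision" band |
| `pop_min`, `pop_max` | none | bounds on region population (persons) |
| `n_starts` | 100 | phase-1 restarts; the heuristic's quality lever (production runs may use thousands) |
| `tabu_length` | 10 | iterations a reversed move stays forbidden |
| `max_swaps` | 10000 | hard cap on phase-2 iterations |
| `no_improve_stop` | 500 | phase-2 patience |
| `seed` | 1 | RNG seed; one stream drives seeding, growth, and leftover order |

## The synthetic generator

`generate_survey()` emulates the situation the method is built for: a
`rows × cols` lattice of unit-square areas, each belonging to a planted zone
(quadrants, horizontal bands, or arbitrary connected rectangular blocks).
Per area, a sample size `n_i` is drawn around `mean_sample` (default 135,
floor 10 — the scale of completed surveys per tract in a 5-year ACS pooling);
each variable's true value is its zone mean plus within-zone noise, and the
observed estimate adds sampling noise with `SE = sd / sqrt(n_i)`. Every
emitted MOE is exactly `1.645 · sd / sqrt(n_i)`, so the generated
uncertainties are internally consistent by construction, and the truth table
(zone labels, true values, per-cell sds, sample sizes) makes recovery
measurable. Proportion variables share the population denominator; their base
levels span 0.15–0.65, which at the default sample sizes yields area-level
CVs roughly between 0.05 and 0.4 — wide enough that CV targets between 0.40
and 0.05 produce the full range from near-singleton to heavily aggregated
partitions. The `effect` argument separates zone means in units of the
within-zone spread of observed estimates; 3 gives strongly separated zones,
0 plants no signal. `degrade_survey()` multiplies chosen areas' MOEs (and
rescales their sample sizes) to mimic tract-to-tract quality variation.

What the generator does **not** emulate: the real ACS sampling design
(weighting, systematic nonresponse), spatial autocorrelation of sampling
errors, irregular tract geometries, and correlated uncertainty across
variables. Gaussian noise is used throughout, consistent with the 1.645
interval convention. Passing tests on this generator therefore validates the
propagation algebra, the constraint logic, and the optimizer — not the
method's behaviour under design effects absent from published tables anyway.

Recovery of planted structure is scored by region **purity**: each region
contributes its largest single-zone contingent, summed and divided by `n`.
Purity 1 means no region straddles a planted boundary; an adjusted Rand index
against the zone labels is used as a cross-check in the tests (it is not the
headline score because regions are deliberately much smaller than zones,
which caps ARI well below 1 even for perfect nesting).

## Numerical choices and degenerate inputs

* Feasibility comparisons use `CV ≤ target + 1e-12`; SSD improvements must
  exceed `1e-12` to count. Running-sum updates in the optimizer clamp tiny
  negative variances (floating cancellation) at zero.
* The information-loss indicator `r = 1` iff `|a_ij − a_kj| < e_ij`
  (strict, as defined), with one convention added: a zero difference counts
  as within even when `e_ij = 0`. Without it a singleton region with a reset
  (zero) MOE would be scored as information loss, contradicting the
  statistic's meaning. `S_j` is defined only for proportion and mean
  variables — a region's count always exceeds its members' counts, so the
  comparison is meaningless for counts — and `S` averages only the evaluated
  variables.
* Region attribute values `a_kj` are re-aggregated ratios (summed numerators
  over summed denominators), never means of member ratios.
* Contiguity defaults to queen (a shared corner suffices) with rook
  available; queen is the permissive convention for tract-like polygons and
  avoids spurious islands at four-corner points. Geometry handling assumes
  polygons that tile the plane with matching boundary points, which is what
  census products and the generator provide; it is not a general-purpose
  geometry engine.
* Areas present in the geometry but not the attribute table (or vice versa)
  are a hard error: silent mismatch corrupts partitions.
* Region labels are dense integers ordered by first appearance; purely
  cosmetic.

## Design choices where the design was open

* **Within-ring order** during growth is uniform random: concentric growth
  is required for compactness, but randomizing within rings preserves
  restart diversity.
* **Leftover order** is randomized per attempt, and the receiving region is
  the least-SSD-increase one — biased toward homogeneity, consistent with
  goal 3. Deferring (rather than failing) leftovers whose neighbours are all
  still unassigned is a pragmatic reading of "joins an adjacent region": a
  region must exist before it can absorb anything.
* **Move evaluation** in phase 2 takes the single globally best admissible
  move per iteration (not per region pair), with the (area, source-region)
  pair as the tabu attribute.
* The **worked-example problem sizes** used by the tests and the acceptance
  script — 3×3 for exhaustive-oracle comparison (Bell(9) = 21147 partitions),
  12×12 for planted-zone recovery, 10×10 for the target and attribute
  sweeps, 200 seeded runs at `n_starts = 100` for the oracle rates — were
  chosen so that exhaustive enumeration stays exact and the full validation
  suite runs in minutes on one CPU while exercising every code path.

## Limitations

* The objective uses point estimates only; the MOEs gate feasibility but do
  not weight the SSD. An uncertainty-aware objective is an open problem.
* Exact region MOEs are unknowable from published tables (no microdata); the
  propagation formulas are the recommended approximation under an
  independence assumption.
* The heuristic is stochastic: different seeds give different (all feasible)
  partitions. On instances small enough to enumerate, it attains the maximum
  region count essentially always and the minimum SSD in the large majority
  of seeds (the acceptance script measures both rates); no such guarantee
  exists at realistic scale. Stability/consensus analysis across runs is out
  of scope.
* Maximizing the region count and then minimizing within-region SSD does not
  maximize between-region separation; alternatives that trade the two
  explicitly require a weighting the data cannot supply.
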