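---
title: "Models and methods behind scLineagePower"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scLineagePower}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scLineagePower)
```

`scLineagePower` estimates, by Monte-Carlo simulation, how the quality and
quantity of single-cell somatic-mutation data determine the ability to
answer three kinds of cell-lineage question: triplet topology
reconstruction, depth differences between cell groups, and separation of
subclones.  This vignette documents the models, the defaults and why they
were chosen, the numerical choices, and the known limitations — in
particular two statistical caveats that the package deliberately reports
rather than papers over.

## Mutation models

**STR (microsatellite) loci** follow the stepwise mutation model: at each
cell division a locus gains one repeat unit with probability `rate/2`,
loses one with probability `rate/2`, and is otherwise unchanged.  Repeat
counts are stored as signed offsets from the root value, with the root at
0; offsets are unbounded (no floor at a minimal repeat length) because the
stepwise model is symmetric and nothing in the simulated regimes drives a
locus anywhere near a physical boundary: at the highest rate considered
(1e-3) and 80 divisions, the offset standard deviation is about 0.28
repeat units.  Useful rate scales are `1e-3` (microsatellite-unstable
cancer cells), `1e-4` (long, mutable STRs in normal cells) and `1e-5`
(short STRs).

**SNV loci** are 4-state categorical (0 = reference, 1–3 alternatives): at
each division a base is replaced, with probability `rate` (`1e-7`–`1e-9`),
by one of the other three states uniformly.  Back-mutation is allowed,
since the per-division substitution law does not distinguish the
reference.

`propagate()` advances a genotype `k` divisions at once.  For STR it draws
the number of mutated divisions Binomial(`k`, `rate`) and splits them into
up/down steps Binomial(n, 1/2); for SNV it uses the exact `k`-step
transition probability of the symmetric 4-state chain,
`P(unchanged) = 1/4 + 3/4 (1 − 4·rate/3)^k`.  Both are distributionally
identical to the `k`-fold single-division loop (`method = "stepwise"`,
kept for cross-validation in the test suite) but make
100,000-locus × depth-40 × 1000-replicate experiments feasible on one
core.

## Genealogies of sampled cells

A full lineage tree to depth 40 would hold 2^40 cells, so only the
genealogy induced on the sampled cells is simulated.  The underlying
population is taken to double deterministically each generation, capped at
`cap` (default 2^20) cells.  Sampled cells receive distinct individual
indices in the final generation and ancestry is traced backwards: in the
doubling regime the parent of individual *i* is individual `floor(i/2)`,
so lineage collisions — coalescences — are exactly those of distinct
leaves sampled from the complete binary division tree.  This construction
guarantees strictly binary merges and integer branch lengths, and it *is*
the forward model, so no separate approximation argument is needed; the
test suite still cross-checks the pairwise coalescence-depth distribution
against an independent forward simulation.  In the capped regime each
lineage picks a uniform parent among `cap` cells (pairwise coalescence
probability exactly `1/cap` per generation); the astronomically rare
three-way collision there is redrawn to preserve binarity.  Heterochronous
sampling (groups at different depths) joins lineages into the backward
process at their own depth, with indices distinct from the lineages
already present — a sampled cell is never an ancestor of another sampled
cell.

Scenario geometry:

* `triplet_spec(X)`: root → internal node after `X` divisions; the two
  cherry leaves `X` divisions below it; the outgroup leaf `2X` divisions
  below the root.  All leaves are equidistant from the root.  The segment
  labeling of a triplet diagram admits other readings (e.g. different
  root–outgroup lengths); the symmetric reading was chosen so that every
  edge segment spans the same number of divisions and leaf depths are
  equal, and it is configurable simply by composing `propagate()` calls
  if a different geometry is wanted.
* `depth_groups_spec(X, Y, nA, nB)`: group A sampled at depth `X`, group
  B at `X + Y`, embedded in one shared genealogy.
* `subclone_spec(X, Y, nA, nB)`: two founders at depth `X` (coalescing
  within the first `X` divisions), each clone sampled `Y` divisions below
  its founder.

Each scenario has a matched null: `equal_depth_null_spec()` samples both
groups at the same depth from one genealogy and permutes the labels;
`mixed_clone_null_spec()` randomly splits one well-mixed clone.  The null
uses a *single* shared genealogy deliberately: with two independent
genealogies the mutations on each group's private trunk would not cancel
between groups, and the depth test's type-I error would be inflated well
above its nominal level even though no depth difference exists.  Random
labels on one tree keep the groups exchangeable, which is the null the
5% threshold is meant to control.

## Signal distortion: allele dropout and noise

The observed mutation table is the true table passed through dropout and
then noise (in that order — noise is a property of measured entries).

**Dropout.**  Entry `(i, j)` survives with probability `p_i q_j`: `p_i`
is the amplification quality of cell *i*, `q_j` the amplification bias of
locus *j*.  Given a binary signal table `x` from a calibration panel of
amplified single cells, `fit_dropout_ml()` maximizes

```
log L(P, Q; x) = Σ_ij log( x_ij p_i q_j + (1 − x_ij)(1 − p_i q_j) )
```

by simulated annealing: coordinate-wise Gaussian proposals (σ = 0.05)
reflected into [0, 1], geometric cooling (factor 0.995 from temperature
1), 20,000 proposals, 5 restarts from Uniform(0.2, 0.9) starts.  Only the
products `p_i q_j` are identifiable (the likelihood is invariant under
`(cP, Q/c)`), so the fit is returned in the canonical scale `max(q) = 1`
and restart agreement is reported on the product matrix
(`product_spread` attribute).  Likelihood terms are clamped at `1e-12`
before the log so boundary proposals keep finite energies.  In testing
the annealer matches a quasi-Newton reference optimizer to within a nat
on 50 × 200 panels; for larger panels scale `iterations` roughly with the
number of parameters (the 167 × 1000 recovery test uses 60,000).

A real calibration panel's `(P, Q)` are generally not available, so
`generate_calibration_fixture()` builds synthetic ones:
`p_i ~ Beta(8, 2)` (mean 0.8 — good but variable cells),
`q_j ~ Beta(5, 5)` (mean 0.5 — broadly spread locus quality), chosen once
as a realistic emulation of the wide quality spread of whole-genome
amplified cells; the default panel size of 167 cells matches the scale of
a typical ex-vivo calibration experiment.  The same Beta prior
(`dropout_prior()`) is the default dropout source in all power analyses,
with a fresh `(P, Q)` draw per simulated experiment.

On recovery accuracy: with `M` cells in the panel, each `q_j` rests on
`M` Bernoulli observations, so even *exact* maximum likelihood has a
product-matrix RMSE floor of roughly `mean(p)·sqrt(q(1−q)/M)` — about
0.07 for a 50-cell panel and about 0.04 at the default 167-cell scale.
Recovery targets tighter than this floor are unattainable for any
optimizer; the package's tests encode the floor explicitly.

**Noise.**  An observed STR entry shifts ±1 repeat (directions
equiprobable) with probability `str_shift_prob`; an observed SNV entry is
miscalled uniformly among the other categories with `snv_error_prob`
(default 1e-4, the scale of single-cell variant-calling error).  The STR
default 0.005 is a configurable placeholder on the plausible scale of
duplicate-inconsistency measurements; `estimate_str_noise()` computes the
inconsistency rate from duplicate tables when such data exist (note both
duplicates carry noise, so the rate is ≈ 2× the per-measurement shift
probability).

**Future enhancement** (`enhance_future()`): signal probabilities × 1.25
capped at 1, noise probabilities ÷ 2 — a projection of improved chemistry
and calling.  The cap is needed because a 25% relative increase can
exceed 1.

## Distances, classifiers, and their levels

The absolute distance between two cells averages `|T_il − T_jl|` over
loci observed in *both* cells; the denominator is the shared-loci count,
not the panel size, matching the convention of the worked three-cell
example in which `D(2,3) = (2+0+0)/3 = 2/3`.  (A `1/N` denominator would
shrink distances of poorly amplified cells toward 0 and confound dropout
with depth.)  For SNV, `|·|` is the 0/1 mismatch indicator.  A pair with
no shared observed locus has *undefined* distance and raises an error
rather than silently returning 0.

The cherry of a triplet is the pair with the smallest distance — for
three taxa, neighbor joining reduces to exactly this; ties are broken
uniformly at random, so an uninformative table yields each topology with
probability 1/3 (this is the random-reconstruction baseline, and tied
wins count as correct per draw).

The **depth test** compares the root distances (mean |offset| over a
cell's observed loci, root = all zeros with full signal) of the two
groups with a two-sided Welch t-test at α = 0.05.  Welch rather than the
pooled-variance test because groups at different depths have different
variances; two-sided because the direction is not known a priori.  In
power accounting a detection only counts when the deeper group also shows
the larger mean — sign errors are not credited.  Under the equal-depth
null this test holds its 5% level (measured 5.0% at 1000 replicates with
50-cell groups at depth 40, 5000 loci at rate 1e-4, default distortion).

The **clustering test** compares the within-group-A distances (unordered
distinct pairs) with the between-group distances (all A × B pairs), again
by Welch's t-test at 0.05.  *Caveat, reported deliberately:* the pairwise
distances entering this test are not independent — every cell
participates in many pairs — so the t-test's variance estimate is far too
small and the test fires on a randomly split single clone much more often
than the nominal 5%: about 28% under the package's default null
conditions (40 cells at depth 22, 5000 loci at rate 1e-4, 1000
replicates).  The nominal-level claim that accompanies this classifier in
the literature follows from the t-test threshold *only if* the distances
were independent; they are not, and the package reports the honest
empirical rate instead of assuming it.  Power numbers for the subclone
scenario should therefore be read against this inflated baseline, or the
classifier should be recalibrated (e.g. by a permutation of labels) — an
extension deliberately left out of scope since the package's purpose is
to characterize the stated statistic.

## Power grids, contours, and cost

`estimate_power()` repeats simulate → distort → classify over seeded
replicate streams (`derive_seed()` gives every replicate an independent,
reproducible substream, so grids are bit-reproducible from one master
seed).  `power_grid()` maps detection probability over a (cells × loci)
grid; `n_cells` is the *total* number of analyzed cells, split evenly
between groups, matching a cost model that charges per analyzed cell.
Grid proportions carry their replicate counts so Monte-Carlo error is
computable.

`extract_contour()` finds, for each cell count, the minimal loci reaching
a power level (default 0.95).  Raw Monte-Carlo grids are not exactly
monotone, so the grid is first smoothed by isotonic regression along the
loci axis and then along the cells axis before the crossing is located by
linear interpolation between adjacent loci values.  `optimize_cost()`
minimizes the linear cost `0.01 $/STR locus (0.0001 $/base) +
10 $/cell` — a 1:1000 cell:STR-locus cost ratio — along the contour,
breaking exact ties toward fewer cells (cells are usually the scarcer
resource).

Default study conditions follow the headline regime throughout: STR rate
1e-4, depth scenarios X = 40, Y = 10; subclones X = 2, Y = 20; classifier
threshold 0.05; 1000 replicates for reported rates.  The test suite runs
the same pipelines at reduced sizes (hundreds of replicates, a few
thousand loci) chosen to keep the full suite in the ten-minute range on
one core while leaving Monte-Carlo error well inside the asserted
tolerance bands; the acceptance script uses the full 1000 replicates.

## What the simulations do and do not show

The generator emulates: lineage-structured mutation accumulation under
the stepwise/SNV models, strongly heterogeneous dropout with separable
cell and locus effects, and unbiased ±1 measurement noise.  It does not
emulate: locus-specific or length-dependent STR rates, diploid/biallelic
signal, amplification-chemistry mechanisms (e.g. MDA bias correlated
between neighboring loci), read-level errors, cell death, or variable
division rates.  Passing tests therefore demonstrate correctness of the
stated models and the qualitative shape of the feasibility maps
(monotone in cells and loci, future-enhancement curves dominating current
ones), not quantitative predictions for any particular platform: headline
power values depend on the dropout calibration, and with the synthetic
Beta calibration used here they reproduce published-scale results only
qualitatively (e.g. triplet accuracy at X = 5 with 25,000 loci lands near
50%).

## Numerical and degenerate-input choices

* Likelihood terms clamped at 1e-12; annealing energies always finite.
* An all-zero signal table is flagged degenerate (products 0) with a
  warning rather than fit.
* Constant-and-equal groups give p = 1 (never flagged); constant but
  different groups give p = 0.
* Cells with zero observed loci are dropped from root-distance sets in
  the power pipelines (probability ~0 at realistic panel sizes); a pair
  with no shared locus is an explicit error.
* `cap` is rounded down to a power of two so each backward generation
  either halves or stays capped.
* Seeds derived via two combined polynomial hashes stay below 2^31.
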