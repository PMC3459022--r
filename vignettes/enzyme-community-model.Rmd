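---
title: "The exoenzyme community model: mechanics, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The exoenzyme community model: mechanics, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzcomm)
```

## The model

`enzcomm` simulates a community of bacteria that depend on extracellular
(exo-)enzymes to feed. Three nutrients — carbon, nitrogen, and phosphorus —
enter a 100 × 100 lattice (1 box = 1 µm³) only as polymeric *substrate*,
which is useless to a cell until an enzyme hydrolyzes it into diffusible
*product* (monomers). Enzymes are secreted into the environment, so they are
a public good: any neighbor, including one that produces nothing, can feed
on the products. Each microbe carries three binary loci, one per enzyme
type. Capital letters denote producer alleles, so `CNp` produces C- and
N-enzymes but no P-enzyme, `CNP` is the generalist producer, and `cnp` the
pure cheater; there are exactly eight genotypes.

Each box tracks nine concentrations (substrate, enzyme, product × C, N, P)
plus at most one resident microbe with internal C, N, P pools. Every
one-minute step executes eleven processes, process-major, in this order:
substrate input, substrate decay, product decay, product diffusion, enzyme
decay, enzyme diffusion, product formation, nutrient uptake and enzyme
production, microbial metabolism, death, and reproduction.

The core rates (all defaults of `scenario_config()`):

* **Input**: 0.1 / 0.01 / 0.001 fg of C / N / P substrate per box per
  minute. Nothing else enters the system.
* **Decay**: substrate, product, and enzyme pools all lose 1% per minute;
  the loss leaves the system and is tallied in a mass ledger.
* **Diffusion**: stochastic pairwise exchange. Each box, in a fresh random
  order, picks one random partner among its 8 neighbors (or uniformly over
  the whole grid in well-mixed mode) and moves `rate × dt × (high − low)`
  of the pool from the higher- to the lower-concentration box. Products use
  rate 0.5 /min, which makes a two-box pair equilibrate in a single
  one-minute step — this calibration is the reason the transfer fraction is
  interpreted as `rate × dt` times the concentration difference. Enzymes
  use the scenario's EDiff (the published sweep covers 10⁻⁴–10⁻²).
  Substrate never diffuses.
* **Product formation**: Michaelis–Menten,
  `ΔP = E · Vmax · S/(Km + S) · dt` with Vmax = 10 fg/fg/min and Km =
  0.001 fg/µm³, clipped at the available substrate. This flux — whether or
  not anything eats the product — is the *depolymerization* output.
* **Uptake**: surface-area scaled Michaelis–Menten,
  `ΔN = 0.1 · 0.0428 · biomass^{2/3} · 10 · P/(Km + P) · dt`, applied only
  to nutrients currently *in demand*.
* **Stoichiometric demand**: targets are C:N = 6 and C:P = 60. N is in
  demand when C:N is at or above 6, P when C:P is at or above 60, C when
  either ratio is at or below target. Equality counts as demand on both
  sides of a pair, so a perfectly balanced cell still feeds on everything —
  with strict inequalities a balanced cell would freeze.
* **Enzyme production**: every carried producer locus *must* emit
  EConstit × biomass fg of enzyme per minute (constitutive production;
  default 10⁻⁷ fg/fg/min). If the locus's nutrient is still in demand after
  uptake, up to 1% of this step's uptake of that nutrient additionally
  funds facultative production — a per-nutrient budget, because N- and
  P-enzyme budgets are accounted in N or P mass and converted to enzyme C
  mass at the enzyme stoichiometries C:N = 3.5, C:P = 200.
* **Metabolism, death, division**: basal respiration of 1.5 × 10⁻⁴ fg C
  per fg C per minute with proportional N and P leakage
  (`0.1 × ΔC / target ratio`), random mortality at 3 × 10⁻⁵/min, starvation
  death strictly below 30 fg C, division at 300 fg C into two equal
  daughters — one stays, one moves to a uniform random neighbor box and, if
  that box is occupied, a fair coin decides which of the two microbes dies.
  Mutation flips each locus of the dispersing daughter independently with
  probability 10⁻⁵ per division.

## Enzyme stoichiometry: one deliberate design decision

Enzymes are protein, so we give *every* enzyme type the same elemental
composition: secreting `E` fg of enzyme costs `(1 + 0.1) · E` carbon (the
secreted mass plus a 10% respiration overhead), `E/3.5` nitrogen, and
`E/200` phosphorus, regardless of which substrate the enzyme attacks. An
alternative reading — each enzyme costing only the elements of "its"
nutrient — is defensible from the prose, but it cannot reproduce the
model's published production cap: the cap formula

```
EnzProd = (CtoN_mic · N − C) / (CtoN_mic/CtoN_enz − 1 − Resp_enz)
```

is derived by requiring that production from a C-limited cell (which drains
N at the enzyme C:N of 3.5, faster than the cell ratio of 6) stops exactly
when C:N reaches 6. Under uniform protein composition exactly two
stoichiometric guards arise algebraically: this C:N form (protecting N from
being pushed into demand) and the analogous C:P form
`(C − CtoP_mic·P)/(1 + Resp_enz − CtoP_mic/CtoP_enz)` (protecting C, since
production burns carbon much faster than phosphorus). The engine applies,
per secretion event, the binding minimum of the facultative budget and
whichever guards protect nutrients not already in demand:

```{r cap}
balanced_production_cap(150, 26, scenario_config())
E <- balanced_production_cap(150, 26, scenario_config())
(150 - 1.1 * E) / (26 - E / 3.5)  # lands exactly on the C:N target
```

Constitutive production is mandatory and therefore not capped by
stoichiometry; when the internal pools cannot cover the elemental cost the
emission is scaled down to what can be paid — the model never borrows mass,
and a producer that chronically cannot pay shrinks toward the starvation
threshold.

## Randomness and reproducibility

All stochastic draws — initialization, diffusion partner choice, sweep
orders, per-box nutrient orders, mortality, division placement, contests,
and mutation — derive from one RNG stream per replicate:
`simulate_run()` seeds R's generator with `seed + replicate`, and the
compiled engine runs a dedicated xoshiro256++ stream seeded from R's
generator at entry, so whole runs are bit-reproducible from
`(config, replicate)`.
Processes whose per-box updates cannot interact (input, decay, product
formation, metabolism, mortality) sweep boxes in fixed order because the
result is independent of visiting order; the processes where order matters
(diffusion exchanges, uptake from shared pools, reproduction into shared
space) use a fresh random permutation each step, and uptake/production
randomizes the nutrient order within each microbe.

The lattice wraps toroidally by default (no edge artifacts; a bounded mode
is available via `torus = FALSE`). Diffusion transfers are applied
immediately in sweep order, which conserves pool totals to machine
precision; a per-nutrient ledger (inputs, decay losses, respiration, N and
P sequestered in secreted enzymes, depolymerization) lets
`mass_balance_error()` verify closure of every run. Enzyme pools are
carbon mass; the N and P built into secreted enzymes are booked as
sequestration sinks at emission.

## Outputs

`simulate_run()` records, every model hour: genotype counts, total density
(counts per µm² of grid), Simpson-type diversity `1 − Σ pᵢ²` (0 for an
extinct community, by convention), and per-nutrient depolymerization
(fg/h). Reported summaries average over the final 10,000 h window, clipped
to the run length. Genotype rasters (0 = empty, 1–8 = genotypes) are
snapshotted every 1,000 h — the time-slice unit of the spatial analysis —
and serialize to a plain-text format.

## Spatial association analysis

The analysis layer asks whether genotypes co-occur in space more than a
random arrangement would allow:

1. **Temporal independence.** Consecutive snapshots are autocorrelated.
   With `r_t` the fraction of boxes keeping the same label between
   consecutive slices, slices are sampled starting at the first, advancing
   by `ceiling((1 + r_t)/(1 − r_t))`, recomputed at each selected slice;
   a frozen pattern (`r_t = 1`) ends selection.
2. **Join counts.** For a neighborhood radius `r` (Chebyshev metric;
   radius 1 is the 8-neighbor convention; analysis graphs are bounded,
   not toroidal, by default), every pair of cells within distance `r` is a
   join. For each unordered pair of the nine categories (eight genotypes
   plus empty — empty boxes are a first-class category), the observed
   number of joins is compared with its expectation under *nonfree
   sampling*: a uniformly random permutation of the observed labels with
   category totals fixed. Expectation and variance are computed exactly
   from the category counts and the graph's join structure (counts of join
   pairs sharing 0 or 1 cells), giving `z = (obs − E)/√Var`. The same
   permutation engine that validates these moments in the tests is
   available as a fallback null (`null = "permutation"`).
3. **Aggregation.** Per pair and radius, z-statistics are squared and
   summed over all selected slices and replicates into a χ² statistic with
   degrees of freedom equal to the number of contributing slices; a pair
   is significant below the Bonferroni cutoff 0.05/45 ≈ 0.0011.
4. **Scores and complementation.** A pair's association score averages its
   mean z over the radii (default 1–5) with a significant positive
   association; averaging nested radii implicitly weights close neighbors
   more (a 1/x weighting, with x the radius — no explicit weights are
   used). Across different-genotype pairs, the score is correlated
   (Pearson) with the complementation score, the number of loci at which
   the two genotypes differ. Re-computing that correlation from the
   published 28-pair association table reproduces the published r:

```{r table2}
tab <- published_association_table()
complementation_correlation(tab$score, tab$complementation)$r
```

Degenerate cases are flagged rather than propagated: pairs with an absent
category or a null variance below 10⁻¹² are "not assessable" and contribute
neither z nor degrees of freedom; an aggregate with no contributing slice
is reported as not assessable; the complementation correlation requires at
least three cross-genotype pairs and nonzero variance on both sides.

## Synthetic fixtures

`generate_fixture_raster()` produces categorical rasters with controlled
structure — iid random labels, circular colonies on an empty background
(aggregation), a two-color checkerboard (maximal negative same-category
autocorrelation at radius 1), and thin alternating diagonal stripes
separated by empty stripes ("interwoven" filaments, the signature of
between-type coalitions). These exist so the statistics layer is testable
without any simulation: planted aggregation must give positive
same-category z, interwoven stripes must rank the cross pair above both
same pairs, and random labels must calibrate z to mean zero. They emulate
the *spatial* structure of simulation output, not its dynamics — passing
fixture tests validates the statistics, not the ecology.

## Scaled problem sizes

The published experiments run 35,000 h on a 100 × 100 grid with 5–11
replicates per scenario — cluster-scale work. The package supports those
sizes, but its own verification uses scaled runs chosen to keep a full
check affordable on a laptop. `regime_scenarios()` fixes the study
conditions on a 50 × 50 grid: generalist-producer dominance under low
diffusion and low constitutive cost, judged at 4,000 h (the community has
not finished sorting at 2,000 h); collapse under EConstit = 10⁻⁴ at
8,000 h, the horizon the original experiment used for that scenario
(the cheater sweep completes around 6,500–7,000 h at this grid size);
the well-mixed cheater sweep at EConstit = 10⁻⁵ over 8,000 h; and the
two-type versus eight-type contrast under high diffusion and production
at 5,000 h, with 2 seeds per scenario (4 for the eight-type survival
fraction). Ledger-closure checks run a 30 × 30 grid over 5,000 steps.
Two caveats follow. First, these regime checks probe the *direction* of
selection, not its published endpoint. In particular, the well-mixed
community is still mid-sweep at desk scale: by 8,000 h the generalist
producer is gone and cheaters are enriched well above their founding
share, and a 20,000 h probe shows the sweep continuing monotonically
(cheaters at 86% of the community), but completed extinction belongs to
the published 35,000 h horizon. The desk-scale check therefore asserts
the sweep's signature, not the final extinction. Relatedly, under the
highest constitutive cost (EConstit = 10⁻⁴) this implementation does not
always end in whole-community extinction: the cheaters and multi-enzyme
producers collapse, but because constitutive production is scaled down
to what a cell's internal pools can actually pay, a nutrient-starved
producer behaves like a facultative producer rather than bleeding
carbon to death, and a lean coalition of single-enzyme producers can
pass through the bottleneck and rebound. Whether the community dies or
rebounds at this grid size is seed-dependent. Second, quantitative
published values (the 64% survival fraction, the −0.45
diversity–depolymerization correlation) belong to the full-scale sweep
and are not reproduced at desk scale; the `run_sweep()`/`sweep_spec()`
defaults encode the full design for users with the compute budget.

## Known limitations

* Enzymes are never re-assimilated; their N and P leave the biological
  cycle at secretion (booked as sequestration).
* Cell stoichiometry is rigid outside the demand rules; there is no
  storage, dormancy, or variable quota.
* Alleles are binary; there is no continuous variation in production rate.
* The pairwise stochastic diffusion scheme *is* the model — it is not an
  approximation to a PDE, and its mixing behavior (not a diffusion
  coefficient in physical units) is what the rates calibrate.
* The spatial analysis matches the cited join-count framework
  (nonfree-sampling moments verified against enumeration and permutation
  oracles); it does not aim at bit-for-bit agreement with any particular
  spatial-statistics package.
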