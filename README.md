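# enzcomm

Individual-based simulation of exoenzyme-producing microbial communities,
with a join-count toolkit for detecting spatial associations between
genotypes.

## The problem

Most nutrients in soils and sediments are locked in polymers that microbes
cannot take up. Decomposition is gated by *extracellular enzymes*:
a cell secretes an enzyme, the enzyme hydrolyzes polymeric substrate into
diffusible monomers (products), and *any* nearby cell — including one that
never paid the cost of production — can eat the products. Exoenzymes are
therefore a public good, and enzyme-driven nutrient cycling is exposed to
cheating.

`enzcomm` implements a mechanistic, stochastic lattice model of this game
for three nutrients at once. Carbon, nitrogen, and phosphorus enter a
100 × 100 grid (one box = 1 µm³) only as substrate; separate enzymes
depolymerize each. A microbe carries three binary loci — one per enzyme —
written with capitals for producer alleles: `CNP` is the generalist
producer, `cnp` the pure cheater, and `CNp`, `CnP`, `cNp`, ... the partial
producers in between (8 genotypes). Nothing about fitness is specified
exogenously: cells pay real elemental costs for every secretion
(enzymes are protein: `(1+0.1)·E` carbon with respiration overhead,
`E/3.5` nitrogen, `E/200` phosphorus), feed by surface-area-scaled
Michaelis–Menten uptake of whatever products reach their box, balance
internal stoichiometry against targets C:N = 6 and C:P = 60, divide at
300 fg C, and die below 30 fg C or at random (3 × 10⁻⁵/min). Cooperation,
cheating, and *coalitions* — complementary partial producers feeding each
other (e.g. `CnP` with `cNp`) — all emerge from enzyme and product
diffusion.

The package is for modelers studying microbial public goods, diversity,
and decomposition: it exposes the full simulation engine (compiled, a
50 × 50 grid runs ≈ 25,000 steps/s), the community metrics (genotype
densities, Simpson diversity `1 − Σ pᵢ²`, per-nutrient depolymerization),
and the spatial statistics used to demonstrate coalitions: multi-category
join counts with exact nonfree-sampling (label-permutation) moments,
`z = (obs − E)/√Var`, aggregated over temporally independent snapshots
into χ² tests with a Bonferroni cutoff of 0.05/45, scored across
neighborhood radii 1–5, and correlated with genotype *complementation*
(number of differing loci).

## Worked example

Run a small scenario, look at the community, and test a spatial pattern:

```r
library(enzcomm)

cfg <- scenario_config(width = 30, height = 30, run_hours = 300,
                       enzyme_diffusion = 1e-3, EConstit = 1e-6,
                       seed = 42)
run <- simulate_run(cfg, replicate = 1)
run
#> <enz_run 300 h, replicate 1: pop 894, diversity 0.71, depoly C 9510 fg/h>

tail(run$metrics[, c("time_h", "total", "diversity", "depoly_C")], 2)
#>     time_h total diversity  depoly_C
#> 299    299   894 0.6931695  7995.323
#> 300    300   894 0.6925113 18028.703
```

894 of the 900 boxes are occupied after 300 h; diversity 0.69 means the
community is still a broad mixture of genotypes (0.875 would be eight
equal types), and 8–18 µg C of substrate is depolymerized per hour (the
flux through enzymes, whether or not anything eats the product — the last
hour's spike is a substrate hoard being hit by newly arrived enzyme).

Join-count statistics on a planted aggregation:

```r
set.seed(7)
ras <- generate_fixture_raster("aggregated", 8L, 12, 12,
                               n_colonies = 3, colony_radius = 2)
g <- build_neighbor_graph(12, 12, radius = 1)
zt <- join_count_z(ras, g)
zt[zt$pair == "CNP:CNP", c("observed", "expected", "z")]
#>   observed expected       z
#>        164  78.4359 13.5511
```

The colonies of `CNP` produce 164 same-genotype neighbor joins where a
random arrangement of the same labels expects 78 — a z-score of 13.6,
i.e. strong spatial aggregation.

The published association ranking of the 28 different-genotype pairs is
shipped as data; recomputing the complementation correlation:

```r
tab <- published_association_table()
ct <- complementation_correlation(tab$score, tab$complementation)
c(r = ct$r, p = ct$p)
#> r = 0.713  p = 2.1e-05
```

— complementary genotypes associate more strongly in space, the
coalition signature.

A thin CLI wraps the same functions
(`inst/cli/enzcomm simulate --config cfg.yaml --out DIR`, plus `sweep`,
`spatialstats`, and `fixtures` subcommands).

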