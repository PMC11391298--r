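# islesim

Spatially explicit eco-evolutionary simulation of biodiversity assembly on
a dynamic archipelago.

`islesim` is for macroecologists and theoreticians who want to study how
dispersal, competition and landscape structure interact to generate alpha,
beta, gamma and phylogenetic diversity over millions of years. The package
builds a procedural four-island landscape — oscillating sea level,
lapse-rate temperatures, a glacial land bridge, a late-emerging island —
and simulates three founding species whose populations disperse over
least-cost resistance paths, compete within sites, accumulate genetic
incompatibility while isolated, speciate, and go extinct.

## The model in brief

* **Thermal niche.** A population's growth response at environmental
  temperature `T_env` (normalized so 1 = 26 °C) is Gaussian,
  `n(T_env) = (1/ω) exp(−(T_env − T)² / (2ω²))`, with optimum `T` and
  range `ω`; the height `1/ω` imposes a specialist–generalist trade-off.
  The site growth rate is `r = g · n(Tmin) · n(Tmax)` with `g = 0.1`.
* **Ecology.** Within each 1-km² site, abundances follow Lotka–Volterra
  diffuse competition, `dN_f/dt / N_f = r_f − α_ff N_f − α_fh Σ_{k≠f} N_k`
  with `α_ff = 0.2` and `α_fh = 0.1(1 − l)` set by the tolerance trait
  `l`; the coexistence equilibrium is solved in closed form with
  sequential competitive exclusion.
* **Dispersal.** Events are Weibull(shape 2, scale `ψ = 1 + 49 d`) draws
  compared against least-cost distances (ocean 4/km, land 1/km + 0.1 per
  100 m of slope); successful arrivals found populations of size 0.05.
  Sites mutually reachable by dispersal form population clusters.
* **Speciation.** Isolated clusters accumulate +1 genetic incompatibility
  per 10-kyr step (−1 while connected); reaching the threshold `s = 65`
  (650 kyr) splits the species. Lineages are tracked and exportable as
  Newick trees.
* **Trait evolution.** Cluster-wide homogenization (abundance-weighted),
  Gaussian mutation (s.d. 0.001), and — in the `MET` model — a
  dispersal–competition trade-off surface `d + l ≤ 1` with random
  projection back to the boundary. `M0` freezes `d` and `l`; `ME` lets
  them evolve freely.

## Worked example

A single desk-scale run (78 × 186 km landscape, 80 sites per island,
251 steps covering the last 2.5 Myr) in the middle connectivity regime:

```r
library(islesim)

landscape <- generate_landscape(desk_landscape_config())
sim <- run_simulation(
  simulation_config("M0", d_init = 0.35, l_init = 1, rng_seed = 1),
  landscape
)
glance(sim)
#> # A tibble: 1 x 14
#>   model d_init l_init  seed regime gamma  beta alpha_mean pd_mean
#>   <chr>  <dbl>  <dbl> <int> <chr>  <int> <dbl>      <dbl>   <dbl>
#> 1 M0      0.35      1     1 k1         5  0.55       2.25    4.86
#> # i 5 more variables: speciation_prop <dbl>, extinction_prop <dbl>,
#> #   n_speciation_within <int>, n_speciation_between <int>, occupancy <dbl>
```

The run ends with `gamma = 5` species: the three founders plus two formed
by allopatric speciation across the A–B land bridge (`speciation_prop =
0.4` means 2 between-island events over the final richness of 5). Beta
turnover of 0.55 reflects islands C and D holding none of the A–B
radiation; `alpha_mean = 2.25` is the mean per-site richness over all
suitable sites, and `pd_mean = 4.86` the mean Faith's phylogenetic
diversity (Myr of branch length) of occupied-site communities. `tidy(sim)` returns the per-step time series,
`sim$events` the dated speciation/extinction log, and
`to_newick(sim$phylo, sim$n_steps)` the phylogeny.

Factorial experiments across dispersal and competition:

```r
exp <- run_experiment(landscape, models = c("M0", "MET"),
                      d_grid = seq(0.05, 1, by = 0.1), l_grid = c(0.1, 1),
                      seeds = 1:3)
autoplot(exp, metric = "gamma")   # dispersal-diversity curves per regime
```

Thin command-line wrappers live in `inst/scripts/` (`simulate.R`,
`experiment.R`).

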