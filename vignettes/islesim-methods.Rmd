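---
title: "Modelling dispersal, competition and landscape structure in an archipelago"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dispersal, competition and landscape structure in an archipelago}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(islesim)
```

`islesim` simulates the macro-eco-evolutionary assembly of biodiversity on a
dynamic four-island archipelago over millions of years. Three founding
species — one per static island — disperse, compete, adapt, speciate
allopatrically and go extinct while sea level, temperature and land
configuration change around them. This vignette explains the model, its
assumptions, the numerical choices, and what the package's synthetic
landscape does and does not capture.

## The landscape

The study system is a rectangular grid of 1 × 1 km sites. Three islands
(A, B, C) are smooth Gaussian cones on a flat seafloor at −115 m; a fourth
island (D) uplifts in discrete pulses from 1.5 Ma onwards. Island summits
span 600–803 m, and the cone widths are calibrated numerically so that each
island holds the configured number of suitable sites (default 250, 80 at
desk scale) at the 0-Ma sea level. A site is *suitable* exactly when its
elevation exceeds the current sea level.

Sea level follows a lowstand-biased 100-kyr oscillation,
$s(t) = -A(t)\,\tfrac{1 - \cos(2\pi t / 0.1\,\mathrm{Myr})}{2}$,
so every cycle tops out at the present-day (0 Ma) level and bottoms out at
$-A(t)$. The amplitude ramps smoothly from 50 m before the Quaternary to
100 m after ~2.6 Ma, so oscillations intensify exactly when the geological
record says they should and the lowest sea level of the run falls in the
Quaternary.

A narrow submarine ridge connects islands A and B. Its flat crest sits at
the saddle elevation (−65 m), so the land bridge is exposed *exactly* when
sea level drops below the saddle — five consecutive steps per glacial cycle
once the Quaternary amplitude is reached, and never in the pre-Quaternary
when the amplitude stays above −50 m. Islands C and D are separated from
everything by channels whose floors never emerge.

Site temperatures are driven by the sea-level phase (warm highstands, cold
lowstands) and decline with altitude at a lapse rate of 5.5 °C/km. The
seasonal spread $T_{max} - T_{min}$ grows linearly with elevation from 0 at
the 0-Ma shoreline to 5 °C at the highest summit. Two anchor temperatures
(warm sea-level, cold glacial) are calibrated by a short fixed-point
iteration so that the minimum and maximum temperature over *all suitable
sites and time steps* equal 9 and 26 °C exactly; the iteration converges
because the extremes are piecewise linear in the anchors. A configuration
whose parameters cannot span the target range aborts with a calibration
error.

Movement is resisted by the landscape: a step between suitable sites costs
1 per km plus 0.1 per 100 m of elevation difference; any step touching an
unsuitable (ocean) site costs 4 per km; diagonal steps count √2 km.
Least-cost distances between all suitable sites are computed with
Dijkstra's algorithm (via `igraph`) on the 8-neighbour grid graph, and are
cached per distinct geometry — sea-level phase × uplift pulse — so a
landscape object shared across simulation runs computes each matrix once.

### Geometry calibration

The facts the landscape reproduces directly are its headline values
(temperatures 9–26 °C, spread ≤ 5 °C, elevations −115 to 803 m,
501 steps, three islands at 5 Ma and four at 0 Ma) and the qualitative
structure (A–B land bridge at lowstands, island D emerging ~1.5 Ma,
isolated C and D). Everything else about the geometry — island spacing,
bridge length, saddle depth, channel widths — is open, and is treated as
a *calibration target*: the defaults were chosen
so that the three connectivity regimes emerge at the documented dispersal
bands (no inter-island colonization below d ≈ 0.15–0.25; A–B colonization
with maintained isolation in the middle band; all islands reachable at
high d) and so that diversity peaks at an interior dispersal value within
the A–B regime. Four points are geometrically impossible to make pairwise
equidistant in the plane; the centres form a rhombus whose four lateral
distances (A–C, A–D, B–C, B–D) are equal, which we read as the intended
"equally spaced" layout.

The bridge is the decisive element. Because dispersal events are drawn
per target per step, a colonization front advances a finite distance per
step (~1.8–2× the kernel scale); crossing the crest requires the front to
traverse it within one five-step exposure window, which sets the lower
regime boundary. Re-connection of the two island populations — which
erodes genetic incompatibility — requires the two fronts to meet, which
takes about twice as long; the number of steps the populations spend
connected per cycle therefore *decreases* with the bridge length and
*increases* with the kernel scale. A long crest (default 150 km at both
scales) makes mid-band dispersers cross occasionally but stay isolated
most of each cycle (net incompatibility gain ≈ +4 per cycle), while fast
dispersers reconnect for most of each window (net gain ≈ +2 per cycle,
too slow to reach the speciation threshold within the Quaternary) — the
mechanism behind the interior diversity peak.

## Populations and traits

A population is one species' occupancy of one site, with abundance $N_f$
(hundreds of implicit individuals per km²) and four evolving traits on
[0, 1]: thermal optimum $T$ (1 ⇔ 26 °C), thermal range $\omega$, dispersal
$d$ and heterospecific tolerance $l$. Temperatures are normalized by
$(T_{°C} - 9)/17$, so the trait scale's endpoints match the coldest and
warmest available site temperatures.

The growth response is Gaussian with a specialist–generalist trade-off:

$$n_f(T_{env}) = \frac{1}{\omega_f} \exp\!\left(-\frac{(T_{env} - T_f)^2}
{2\omega_f^2}\right), \qquad r_f = g \, n_f(T_{min}) \, n_f(T_{max})$$

with $g = 0.1$. The plain product is the default; a
`growth_combiner = "geometric_mean"` flag exposes the square-root variant.
Note that for $\omega < 1$ the height $1/\omega$ can push $r_f$ above
$g$; the formula is applied as written and not capped.

## Ecology

Within each site, abundances follow Lotka–Volterra diffuse competition

$$\frac{1}{N_f}\frac{dN_f}{dt} = r_f - \alpha_{ff} N_f -
\alpha_{fh} \sum_{k \neq f} N_k$$

with $\alpha_{ff} = 0.2$ for everyone and $\alpha_{fh} = 0.1\,(1 - l_f)$
(no heterospecific competition at $l = 1$). Once per 10-kyr step the
equilibrium is computed in closed form: writing $D_f = \alpha_{ff} -
\alpha_{fh,f}$,

$$N_{tot} = \frac{\sum_f r_f / D_f}{1 + \sum_f \alpha_{fh,f}/D_f}, \qquad
N_f = \frac{r_f - \alpha_{fh,f} N_{tot}}{D_f},$$

iteratively excluding (setting to zero) the single most negative candidate
and re-solving until all remaining abundances are positive. Ties are broken
on trait values, never on input order, so the equilibrium is permutation
invariant. The test suite verifies the closed form against forward Euler
integration of the differential equation to steady state for random
communities, including competitive-exclusion cases.

Populations whose equilibrium falls below the viability threshold
(`n_min`, default equal to the 0.05 arrival size — a population smaller
than a founding propagule is not considered viable) are removed; this is
also what makes a colonization "successful only if the arriving population
has a positive size after the ecological processes".

## Dispersal

Dispersal events are Weibull-distributed with shape 2 and scale
$\psi = 1 + 49\,\bar d$, where $\bar d$ is the species' population-size
weighted dispersal trait. Each unoccupied suitable site receives one event
per step, compared against the minimal least-cost distance from any
occupied site; success founds a population of size 0.05 that copies the
traits of the minimal-cost source (ties: most abundant source). Population
clusters — the units of gene flow — are the connected components of the
graph with an edge between occupied sites wherever an independent event
reaches the pairwise cost. The pairwise comparison is sampled as one
uniform against the Weibull tail probability $\exp(-(c/\psi)^2)$ (the same
event in distribution); pairs with probability below `p_min` ($10^{-12}$)
are skipped, and pairs already connected through earlier edges are skipped
because additional within-component edges cannot change the partition.

## Speciation

Isolation is bookkept at the level of *demes*: persistent groups of
populations that always sit inside one cluster. Pairwise genetic
incompatibility between demes increases by 1 per step while they are in
different clusters and decreases by 1 (floored at 0) while they share one.
When incompatibility between groups of demes reaches the threshold
$s = 65$ steps (650 kyr; sensitivity range 20–75), the species splits
along the components of the "still compatible" graph; the most abundant
component keeps the ancestral identity. Demes whose incompatibility decays
to zero inside one cluster merge (their rows collapse to the
abundance-weighted mean, rounded); a deme stretched over several clusters
splits, the parts inheriting the parent's row with zero mutual divergence.
The merge rule is a documented design choice of this package — divergence
must be compressed to deme level somehow, and the weighted mean is the
simplest abundance-respecting rule — and it is exposed to tests.

Lineages are recorded in a birth/death table exportable as Newick (Myr
branch lengths); the extant-pruned tree backs Faith's phylogenetic
diversity, computed by interval union along root paths and verified
against `picante::pd`.

## Trait evolution and the three models

After dispersal, traits are homogenized within clusters: every connected
population receives the population-size-weighted trait mean (`full`
homogenization, the default), or is pulled halfway towards it (`partial`),
which preserves within-cluster variation and suppresses the d → 0
within-island speciation artefact. Each trait then mutates by a
N(0, 0.001) increment, clipped to bounds (ω floored at $10^{-3}$ to keep
the niche response finite). The ambiguous mutation s.d. printed for the
competition coefficient is exposed as `alpha_mutation_sd` (applied on the
$\alpha_{fh}$ scale when set); the default mutates all traits with
s.d. 0.001 on the trait scale.

* **M0** – $d$ and $l$ never mutate: all populations keep the initial
  factorial values exactly.
* **ME** – all four traits evolve freely.
* **MET** – as ME, but `(d, l)` combinations above the trade-off boundary
  (default linear, $d + l = 1$; a concave power-law boundary is
  configurable) are orthogonally projected back onto the boundary with a
  small random tangential jitter (s.d. 0.01), at initialization and after
  every mutation step.

## The per-step loop

Each 10-kyr step executes: (0) the landscape advances; populations on
newly submerged sites are vacated; (1) divergence update and speciation
using the previous step's clusters; (2) colonization, then re-clustering
and deme bookkeeping; (3) homogenization, mutation and (MET) projection;
(4) ecological equilibria, viability filtering and extinction records. An
empty world is a fixed point. Runs are bit-reproducible given the seed.

## Scales, run times and what the tests show

The full-scale configuration (120 × 208 km, 250 sites per island,
501 steps = 5 Myr) is the study condition; the desk-scale preset
(78 × 186 km, 80 sites per island, 251 steps covering the last 2.5 Myr,
i.e. the oscillation-intensified period) keeps every rate, cost and
threshold identical and shrinks only the grid and the time span. The
package's statistical experiments (connectivity regimes, the
dispersal–diversity hump, the speciation–extinction regression) run at
desk scale; a single desk run takes seconds, so factorial experiments with
hundreds of runs complete in minutes.

Because the landscape is synthetic and smooth, passing tests demonstrate
that the *mechanisms* behave as specified — regimes emerge from cost
geometry, isolation accumulates on the documented clock, competition
shifts and lowers diversity — not that any real archipelago's diversity
is predicted. Features of real systems deliberately absent include rugged
topography, stochastic climate, plate tectonics and erosion, long-distance
dispersal tails, zoochory, and demographic stochasticity.

## Known limitations

* The connectivity-regime boundaries are properties of the calibrated
  geometry; other crest lengths or saddle depths move them.
* Extinction is rare in the calibrated system. Competitive exclusion
  requires one competitor's growth rate to fall below
  $\alpha_{fh}/\alpha_{ff} \le 1/2$ of the other's, but co-occurring
  species share local climate and trait divergence at mutation
  s.d. 0.001/step cannot open such gaps within a run; and thermally driven
  loss would require a normalized mismatch above ~0.8 at $\omega = 0.4$,
  while the glacial–interglacial swing is pinned near 0.56 by the 9–26 °C
  calibration. Speciation–extinction couplings estimated from this system
  therefore rest on very few events.
* Divergence bookkeeping is integer-valued at deme level; very large deme
  counts (fragmented ranges under partial homogenization) grow the
  pairwise matrix quadratically.
* The equilibrium assumes $\alpha_{ff} > \alpha_{fh}$; configurations
  violating it are rejected rather than integrated dynamically.
* With full homogenization and $d \to 0$, within-island fragmentation can
  produce occasional within-island speciation; the partial-homogenization
  option exists precisely to keep ranges cohesive in that limit.
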