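---
title: "Particle-based simulation of the yeast mating polarity circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Particle-based simulation of the yeast mating polarity circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarsim)
```

## The biological problem

During mating, budding yeast must orient a single "polarity site" — a
membrane patch of active, GTP-loaded Cdc42 — towards a partner cell. Before
committing, cells go through an *indecisive phase* in which Cdc42 clusters
erratically assemble, disassemble and relocate around the cortex. `polarsim`
implements a particle-based stochastic model of the circuits thought to
produce this behavior, together with the quantification pipeline needed to
analyze it:

* the **core polarity circuit**: inactive Cdc42 (cytosolic `Cdc42D_c`,
  membrane `Cdc42D_m`), active `Cdc42T`, and the scaffold-GEF complex
  Bem1-GEF, whose mutual activation with Cdc42 forms the primary positive
  feedback loop;
* the **receptor–Far1 circuit**: active pheromone receptors (`Ra_m`) recruit
  cytosolic Far1-GEF, which activates Cdc42 nearby; active Cdc42 in turn
  drives delivery of new receptors, a second, much slower positive feedback
  (receptor membrane residence is `1/k_10 ≈ 8.3` minutes versus seconds for
  Cdc42 and Bem1-GEF);
* their **combination**, and a **pheromone-binding variant** in which
  receptors are activated by explicit extracellular pheromone molecules
  rather than constitutively.

All rate constants, diffusion coefficients and abundances ship as plain-text
tables under `inst/extdata/` — the single source of truth from which
`build_circuit()` assembles every variant. G-protein intermediates, actin
cables and vesicle traffic are deliberately abstracted, following the model
this package implements: receptor delivery is a bimolecular event between a
cytosolic receptor and any membrane Cdc42-GTP, and endocytosis is a
first-order removal.

## The simulation algorithm

Molecules are volumeless point particles. Each time step `dt = 1e-4 s`:

1. **Diffusion** (Euler–Maruyama): each coordinate receives an independent
   Gaussian increment of standard deviation `sqrt(2 D dt)`. The plane is
   periodic in both directions. On the sphere, membrane particles take the
   Gaussian step in their local tangent plane and are re-projected to radius
   `R`; this is accurate because the step length (~0.7 nm for membrane
   species) is five orders of magnitude below the cell radius. Cytosolic
   particles diffuse inside the ball and reflect at the membrane.
2. **First-order reactions** fire with probability `1 - exp(-k dt)`.
   Dissociating complexes leave one product in place and put the other at
   `rho + 1e-5` um in a random direction — just beyond the binding radius, so
   the pair cannot re-associate in the very next step.
3. **Second-order reactions**: a reactant pair closer than the reactive
   radius `rho = 0.05` um reacts with probability `1 - exp(-lambda dt)`.
   Distances are minimum-image Euclidean on the periodic plane and Euclidean
   chord on the sphere. Each particle participates in at most one reaction
   per step; candidate pairs are processed in shuffled order so ties carry
   no positional bias.

The order (diffuse, then unimolecular, then bimolecular) follows the
convention of established particle-based simulation platforms; nothing in
the model output we examined is sensitive to it at `dt = 1e-4 s`.

### Geometry and the 2D/3D rate correspondence

The 2D model is a periodic square whose area equals the membrane of a 2.5-um
cell (`L = sqrt(4 pi 2.5^2) = 8.8623` um), with "cytosolic" species living on
the same plane but diffusing at the cytosolic rate. In 3D the cell is a
sphere: membrane species on the surface, cytosolic species inside. Rates
convert deterministically between the two pictures:

* first-order membrane association: `k_3D = (V_c / A_m) k_2D` (um/s);
* second-order cytosol–membrane reactions:
  `lambda_3D = (V_c / A_m) * (pi rho^2) / ((2/3) pi rho^3) * lambda_2D`,
  the factor being the ratio of the 2D reaction disc to the half-ball
  reaction volume available when one partner is membrane-bound;
* membrane–membrane and membrane-dissociation rates are unchanged.

`validate_rate_conversions()` applies these rules to every tabulated
reaction and confirms the shipped 3D column to printed precision — with the
single exception of the membrane complex-formation rate `lambda_4a`
(9.6 s⁻¹ in 2D, 40 s⁻¹ in 3D), which was tuned rather than converted so
that steady-state species counts agree between geometries. We therefore
store both columns verbatim and use the conversion rules only for
validation, never to populate the tables.

### Surface association in 3D

The um/s surface-association rates are realized as an equivalent first-order
conversion at rate `k_3D A_m / V_c` (algebraically equal to the 2D rate)
followed by a radial projection onto the membrane. Because a uniform
position in a ball has a uniformly distributed direction, radial projection
of a well-mixed cytosolic particle lands uniformly on the sphere *and*
preserves the particle's angular coordinate, so the scheme reproduces the
well-mixed association flux `k_3D * C * A_m` exactly and introduces no
angular bias. The well-mixed ODE oracle in the test suite (below) checks
this bookkeeping end to end.

### Performance-relevant internals

The engine is written in C++ (Rcpp): a xoshiro256+ stream with a ziggurat
normal sampler drives diffusion; bimolecular partners are found with a cell
grid rebuilt each step (counting sort on the plane, linked cells on the
sphere). Each bimolecular reaction is probed from its currently rarer
reactant species, so scan cost tracks the abundance of GEF-like species
(tens) rather than Cdc42 (thousands). First-order events use exact Binomial
thinning at the maximal per-species hazard. None of these choices alter the
sampled process; they only make a 4000-s cell affordable on a laptop.

## Quantifying polarity: the normalized K statistic

For `N` analyzed molecules (active Cdc42: `Cdc42T` plus the
Cdc42T–Bem1-GEF complex) we accumulate the distribution `P(r)` of all
`N(N-1)` ordered pairwise distances and its CDF. On the sphere,

`K(r) = 4 pi R^2 CDF(r) - 2 pi R^2 (1 - cos(r/R))`,

which vanishes identically for a uniform pattern (the uniform geodesic CDF
is `(1 - cos(r/R))/2`) and approaches `4 pi R^2 = 78.54` um² as all points
merge. On the periodic plane we use

`K(r) = sqrt((A / pi) CDF(r)) - r`.

The square root deserves a note: the corresponding formula without it,
`(A/pi) CDF(r) - r`, does **not** vanish for a uniform pattern — the uniform
minimum-image CDF is `pi r^2 / A` for `r <= L/2`, which makes the literal
expression `r^2 - r`, peaking above the polarity thresholds on this domain.
Only the square-root form satisfies both stated anchors of the statistic
(zero for uniform patterns, maximum `sqrt(A/pi) = 5.0` for a point mass) and
matches the normalization used by the prior work the statistic descends
from. We therefore default to the square-root form and keep the literal one
available behind `mode = "literal"`; a test pins the analytic `r^2 - r`
behavior of the literal form so the discrepancy stays visible rather than
silently resolved.

The scalar polarity measure `K` is the maximum of `K(r)` over the full
resolvable range (`r <= L/2` on the plane, `r <= pi R` on the sphere; 200
bins by default). Distance histograms on the plane are nevertheless
accumulated out to the maximal minimum-image distance `L/sqrt(2)` so that
`P` integrates to one. Thresholds: on the plane `K >= 1.5` is polarized and
`K >= 3` stable; on the sphere `K >= 30` and `K >= 50`.

### Polarity regimes

A run's regime is read off the distribution of K values recorded every 10 s
in the second half of the run: `delta = #(K >= 1.5) - #(K < 1.5)`. With `N`
samples, `|delta/N| <= 0.85` is the transient-polarity regime; above is
polarized, below unpolarized. Along an abundance axis `x`, mean delta is
fitted with `delta(x) = 2N / (1 + exp(-b(x - c))) - N` and regime boundaries
are `c ± log((1+alpha)/(1-alpha))/b`. Runs are launched from both uniform
and pre-polarized (sigma = 0.2 um) initial conditions, which probes both
basins of a bistable system without waiting for spontaneous switches.

## Cluster detection and dynamics

Clusters of active Cdc42 are detected per snapshot by Voronoi tessellation.
On the plane the tessellation is made periodic by replicating points within
a margin of each border before tessellating (`deldir`); on the sphere the
spherical Voronoi diagram is computed in compiled code from the convex-hull
Delaunay dual with geodesic polygon areas (no qhull-style backend is
assumed). The polygon-size threshold is calibrated against 50 uniform
negative controls of the same molecule count: control and sample polygon
sizes are binned on a common Freedman–Diaconis grid and the threshold is the
first crossing of the two densities above the sample's small-polygon mode.
Adjacent polygons below the threshold are grouped; groups pass if their
total polygon area is at most 0.785 um² (the area of the ~1-um polarity
site; the bound's direction is configurable since the area filter could be
read either way) and contain at least `count_min = 20` molecules. The count
filter default is a package choice — the original measurement it abstracts
is not printed in our sources — sized to be small against the ~3000-molecule
Cdc42 pool yet large enough to suppress singleton noise.

The 0/1/2+ cluster-count series yields occupancy fractions, a
row-stochastic transition matrix over observed consecutive pairs, and
dwell-time distributions; series can be resampled to 120-s intervals to
match experimentally scored movies, and `read_count_series()` ingests such
series from tabular text.

## The pheromone field

Gradient experiments place the receiver cell at the origin and an emitter
cell along +z (default gap 0.1 um between membranes). Pheromone molecules
(D = 150 um²/s) are emitted in a Poisson stream from the point on the
emitter facing the receiver, reflect off both cell bodies, and are absorbed
at a shell 7 um from the origin. Receptor binding is the bimolecular
reaction `Ri_m + pheromone -> Ra_m` with `lambda_11 = 1.8 s⁻¹`, chosen so
the receptor's equilibrium dissociation constant lands in the measured 6–7
nM range.

Two protocol details are worth making explicit:

* **Uniform baths.** Holding a *uniform* background against an absorbing
  shell by re-injecting absorbed molecules uniformly does not produce a
  uniform bath — fast absorption turnover sets up a steady diffusion profile
  roughly twice the nominal concentration near the cell (we verified this
  numerically). The uniform protocol therefore closes the domain: the outer
  shell reflects, the molecule count is fixed at
  `background_nM * N_A * V_domain`, and the equilibrium is exactly uniform.
* **Gradients over a background.** Point-source runs simulate only the
  emitted molecules explicitly; a uniform background is an independent
  equilibrium component and enters as an additive constant in measured ring
  profiles and in frozen-field binding rates. This matches the reported
  behavior of the modeled gradients, whose far-side concentration equals the
  background.

Concentrations at the receiver are measured in 16 equal-angle rings from the
source-facing pole, in a 0.15-um sampling shell above the membrane — thin
enough to resolve the near-source peak, wide enough to count molecules. With
these defaults the measured profiles span roughly 1.5–7 nM for 650
molecules/s over a 1.5 nM background and 0–1.1 nM for 150 molecules/s,
bracketing the reported 1.5–5.8 and 0–1.2 nM ranges; the peak value is
sensitive to the polar ring width, which our sources do not specify
numerically.

### Frozen-field mode

Explicit-pheromone runs resolve a fast extracellular species and are the
most expensive configuration. For scaled-down work, `frozen_gradient_field()`
converts a measured ring profile into a static position-dependent activation
rate for membrane receptors,
`lambda_11 * c(theta) * N_A * (2/3) pi rho^3` — the well-mixed expectation
of the explicit binding at local concentration `c(theta)`. This freezes
gradient shape and ignores pheromone depletion by binding (a small effect:
bound receptors hold well under 1% of the molecules in the domain at these
concentrations) and is flagged in run metadata as an approximation.

## Synthetic data: what it does and does not emulate

Every analysis component is testable without a simulation via the fixture
generators: area-uniform patterns on both geometries, wrapped or
tangent-plane Gaussian clusters of stated dispersion (exact von Mises–Fisher
sampling available behind `method = "vmf"`), immobile seed layouts, and
0/1/2+ count series from a known Markov chain. These fixtures reproduce the
*geometry* of polarized and unpolarized states and the *sampling structure*
of experimental cluster scoring (120-s intervals); they do not emulate
microscope noise, pixelation, or the spatial correlations of a genuinely
interacting particle system. Tests passing on fixtures therefore validate
the measurement pipeline, not the realism of the dynamics — that is what the
engine-level oracle tests (ODE comparison, diffusion law, two-state
membrane-exchange equilibrium) are for.

## Numerical choices and degenerate inputs

* Membrane positions on the sphere are held at `|x| = R` to within 1e-9 um
  by explicit re-projection after every move.
* Boundary reflections are specular (radial, through the surface). With a
  discrete time step this carries a known O(step/R) density bias within one
  step length of a curved boundary — about 7% for pheromone (D = 150
  um^2/s). Bath uniformity is therefore asserted on the bulk volume;
  near-membrane concentrations inherit the bias (a limitation shared by
  this class of discretized schemes at this `dt`).
* Cluster-detection thresholds are calibrated on the analysis window of a
  trajectory (post-transient snapshots), not on artificial initial
  configurations, since the calibration compares the sample's polygon-size
  density against uniform controls of the same molecule count.
* `K` is defined as 0 for fewer than two molecules (with a warning);
  cluster detection returns an empty set below three points (tessellation
  undefined); threshold calibration fails loudly when control and sample
  densities never intersect (degenerate or identical inputs).
* The dissociation offset `rho + 1e-5` um and the reaction-candidate
  shuffle are fixed, documented tie-breaks.
* "Time to stabilization" takes the first threshold crossing by default; a
  persistence window is available (`hold`) but defaults to zero since no
  hold time is specified by the protocols we reproduce.
* The logistic regime fit uses Levenberg–Marquardt (`minpack.lm`); a
  non-monotone delta profile is reported as a failed fit with undefined
  boundaries rather than extrapolated.

## Problem sizes used by the shipped tests

The packaged test suite and acceptance script run the physics unchanged
(`dt`, `rho`, rates, thresholds, abundances at their tabulated values) but
at reduced durations and replicate counts, sized to the phenomenon's own
timescales as established in pilot runs:

* Core-circuit regime checks use 3000 Cdc42 with 70/102/120 Bem1-GEF over
  50–150 s from both initial conditions. Dissipation of a pre-established
  site at 70 Bem1-GEF completes within ~100 s; at 102 and 120 the site
  persists over the same horizon while uniform starts remain unpolarized,
  so the pooled dual-init K values are bimodal — the transient-regime
  signature. Distinguishing the 102 (transient) from the 120 (polarized)
  *boundary* needs the full last-2000-s-of-4000-s protocol and is out of
  desk scope.
* Combined-circuit checks use the full 3000/170/30/2500 composition:
  receptor-seeded dissipation over 120 s (satellite clusters pass the
  20-molecule filter from ~90 s), receptor-clustered stabilization within
  50 s.
* Gradient stabilization runs the pheromone-binding circuit on the sphere
  in frozen-field mode for 50 s per replicate, five seed-paired replicates
  per gradient, comparing time-averaged K (a monotone surrogate for
  stabilization speed at a fixed horizon) by a one-sided exact signed-rank
  test.

Full-scale protocols (4000 s, 10 or more replicates, explicit pheromone)
run through exactly the same functions by raising `t_end`/`n_replicates` or
lowering the `experiment_config()` scale factor, and remain the
configuration of record for quantitative comparisons at published scale.

## Known limitations

* No excluded volume, actin cables, vesicle transport, or explicit G-protein
  dynamics — inherited simplifications of the modeled circuit.
* The receptor-delivery reaction places recruited receptors at the position
  of the recruiting Cdc42-GTP molecule, abstracting vesicle geometry.
* Frozen-field gradients ignore local pheromone depletion and temporal
  fluctuations of the field.
* The 2D "cytosol" is a planar projection; quantitative 2D/3D agreement is
  assessed at the level of steady-state molecule counts, not spatial
  microstructure.
* Spherical Voronoi areas assume points in general position; exactly
  coincident points make the tessellation degenerate and raise an error.
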