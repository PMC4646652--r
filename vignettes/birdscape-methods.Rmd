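---
title: "Methods: linking landowner decisions to grassland bird populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking landowner decisions to grassland bird populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(birdscape)
```

`birdscape` couples two models: an agent-based land-cover choice model
that turns conservation policy into landscape composition through
landowner value systems, and a full-annual-cycle population model that
turns landscape composition into grassland bird population growth. This
vignette documents the assumptions, parameters, numerical choices, and
limits of both, and explains the design decisions that were genuinely
open.

## 1. The landowner choice model

### Weights and utilities

Each of the three landowner archetypes holds a weight vector over five
objectives (grassland birds, carbon storage, water quality, financial
profit, biodiversity). The elicited weights for every
(landowner, policy) pair ship verbatim in
`system.file("extdata", "preference_weights.csv", package = "birdscape")`
and are retrieved with `apply_policy()`. Because they were elicited and
rounded to two decimals, rows sum to anywhere between 0.99 and 1.01;
`normalize_weights()` rescales to an exact unit sum while preserving
proportions. Shipping the raw values and normalizing at use keeps the
provenance visible.

Cover utilities `U(c, o)` on `[0, 1]` are *not* elicited data: the
package's defaults (`utility_matrix()`) encode the ordinal structure any
analyst of this system would impose — agriculture dominates profit
(1.0 vs 0.2–0.3), grassland dominates bird and biodiversity value
(0.9 vs 0.05–0.6), forest is intermediate with strong carbon value. They
are fully overridable through the config, and the calibration section
explains why they are *held fixed* during fitting.

### From utility maximization to cover probabilities

The framing requires both a rational reading (an owner picks the cover
maximizing utility) and a stochastic one (each pixel is assigned a cover
with policy-dependent probabilities). These are reconciled with a softmax
choice rule,

$$p(c) = \frac{e^{u(c)/\tau}}{\sum_{c'} e^{u(c')/\tau}},$$

whose temperature τ (default 0.15 on the 0–1 utility scale) makes
choice sharply — but not perfectly — rational: a utility gap of 0.15
shifts the odds by a factor *e*. The deterministic argmax is exposed as
`choice_model(deterministic = TRUE)` and is the τ → 0 limit (tested at
τ = 10⁻³). The default is documented as the package's own modelling choice, not as
an empirical claim about how real landowners decide. Softmax is computed after
subtracting the maximum utility, so it is overflow-safe and exactly
shift-invariant.

Each simulated landscape belongs to a single landowner type; mixed
mosaics are representable only by editing grids directly. An
experimental `stage_distributions` config hook can override the choice
model's distribution for specific annual-cycle stages (for instance a
wintering ground in a different jurisdiction); it is off by default and
exercised only by config-validation tests.

## 2. Landscapes

A landscape is a 40 × 40 grid of 30-m pixels (1.44 km²) holding one of
three covers per pixel; pixels are drawn i.i.d. from the cover
distribution, consuming one seeded RNG stream in row-major order, so a
(distribution, dimensions, seed) triple is bit-reproducible. Five such
landscapes — breeding, three stopovers, wintering — make a scenario.

Two geometric conventions are fixed rather than configurable:

* **The "one-hectare patch" is the 3 × 3 window** centred on a pixel
  (0.81 ha), the closest odd-sided square to one hectare given 30-m
  pixels. Forage quality is the mean cover quality over this window,
  focal pixel included.
* **Edges truncate.** Neighborhoods shrink at grid borders (a corner
  pixel has 3 Moore neighbors); there is no wraparound, because the
  grids represent bounded tracts, and no padding, because padding would
  invent cover. The Moore ring used for occupancy and edge effects
  excludes the focal pixel.

Grids round-trip through single-band ESRI ASCII rasters
(`read_ascii_grid()` / `write_ascii_grid()`, codes 1/2/3) bit-exactly.
Real projections and geodesy are out of scope.

## 3. The annual-cycle population model

The census point is the start of the breeding season:

$$N_t = N_{t-1}\,(1 + R_b)\,S_f\,S_w\,S_s.$$

The annual event order is breed → fall migration (three stopovers in
order) → winter → spring migration (the same stopovers, reversed).
Adults are assumed to survive the breeding season itself with
probability 1 — the recursion has no breeding-season mortality term —
and all mortality is carried by the three nonbreeding stages.

### Reproduction

Every grassland pixel contributes potential fledglings
`nest_density × fledglings_per_nest × nest_survival × (1 − edge_penalty · f_nonG)`,
where `f_nonG` is the non-grassland fraction of its Moore ring, and
`fledgling_potential()` sums this over the grid — reproduction responds
to both composition (how much grassland) and configuration (how
fragmented it is). Capacity enters as a nesting ceiling
`K_b = k_breeding × n_grass`: `min(N, K_b)` birds breed, producing the
corresponding share of the potential, so per-capita output
`R_b = F_pot / K_b` is *constant below capacity* and total output
saturates above it. The sub-capacity constancy is a deliberate design
choice: it makes the no-capacity dynamics exactly geometric
(`N_0 λ^t` with `λ = (1 + R_b) S_f S_w S_s`), which serves as the
model's closed-form oracle — the simulator is tested against it at
10⁻⁹ relative error over 30 years. An alternative reading, in which the
landscape's total output is fixed regardless of abundance, makes
per-capita reproduction density-*dependent* everywhere and admits no
such oracle; it was rejected for that reason.

### Stopover and winter survival

Stopover survivorship separates *occupancy* (is a pixel found and used?)
from *survivorship* (does a settled bird survive?). A pixel's occupancy
weight is `occupancy[cover] × mean(occupancy over the Moore ring)`;
birds settle proportionally to these weights up to the stop's capacity
`k_stopover × n_grass`, and a settled bird survives with its patch's
forage quality (the 3 × 3 mean of `stopover_survival[cover]`). Birds
over capacity — or all birds, if no pixel has positive occupancy —
survive at `matrix_survival_floor`. Winter is the same construction
minus every neighborhood term. Capacities are aggregate ceilings, not
per-pixel quotas: per-pixel quotas would make sub-capacity survival
depend on abundance and destroy the geometric regime above.

The three stopover survivals are evaluated *sequentially at the running
abundance* and multiplied; the flock shrinks between stops, so stop
order matters exactly when a stop's capacity binds — which is why fall
and spring traverse the stops in opposite orders rather than reusing a
single number.

Overflow survival is a soft ceiling rather than a hard cull: a hard cap
would make growth a discontinuous function of abundance and of the
landscape draw, and the replicate means the consequence table reports
would inherit those discontinuities.

### Scales and degenerate inputs

All rates are probabilities in `[0, 1]` (property-tested over random
landscapes and parameter sets); densities and capacities are per
grassland pixel. `N = 0` yields `R_b = 0` with no division error; a
trajectory that reaches zero has growth rate −1 by convention; an empty
grassland layer gives zero reproduction and floor-level survival.
Division by summed occupancy weights is guarded at 10⁻³⁰⁰ and the
all-zero case short-circuits to the floor.

Demography is expected-value (deterministic) by default, because the
replicate dispersion of interest comes from landscape generation;
demographic stochasticity (Poisson births, binomial stage survival) is a
config switch (`simulation.stochastic`), off by default.

## 4. Scenarios, replication, and seeds

A consequence-table cell (policy × landowner) is the mean over 100
replicate scenarios of the 30-year geometric mean growth rate, starting
from `N0 = 100` birds. All randomness descends from one base seed
through a documented integer-folding scheme (`derive_seed()`): cell
*ci*, replicate *r*, landscape slot *k* uses
`derive_seed(derive_seed(base, ci, r), k)`, so enlarging the replicate
count never perturbs existing replicates, and a single scenario rebuilt
with `derive_seed(base, ci, r)` reproduces a table replicate exactly
(this equality is tested).

Internally the batched runner computes, per landscape, a small set of
sufficient statistics — cover counts, the summed edge fraction over
grassland pixels, and 3 × 3 × 3 occupancy/quality contraction tensors —
from which every seasonal rate is a few matrix-vector products; the
30-year recursion then runs vectorized across all replicates. The
batched and per-pixel implementations are algebraically identical and
tested against each other, and the per-pixel ones against brute-force
enumeration.

## 5. Calibration

The demographic rates have no established values at the needed
granularity, so `calibrate_defaults()` fits them to the bundled
reference consequence table
(`reference_growth_table()`). The objective is the maximum absolute cell
error (Chebyshev — no cell may be sacrificed to improve the average)
plus a penalty of 10 per sign mismatch, making sign agreement an
effectively hard constraint; a best point that still mismatches any sign
is flagged as a calibration failure with a warning. The search is
Latin-hypercube screening over a bounded box
(`default_calibration_bounds()`, 15 parameters) followed by Nelder–Mead
restarts, all under fixed derived seeds; replicate landscapes are
generated once and reused, so the objective is deterministic and the
whole procedure is a pure function of its arguments. The packaged
calibrated set (`calibrated_demography()`) came from this procedure with
seed 20251 and 60 replicates per cell, reaching a maximum absolute cell
error of 0.0059 with all 21 signs reproduced.

Two aspects deserve honesty:

* **An identifiability floor.** Three policies carry *identical*
  profit-maximizer weight vectors, hence identical cover distributions
  and identical expected growth; the reference table nevertheless prints
  them 0.015 apart. No parameterization can separate those cells beyond
  replicate noise, so the maximum cell error cannot reach zero — the
  fitted 0.0059 is close to the floor this structure imposes, and the
  acceptance test that demands 0.005 everywhere documents the shortfall
  rather than hiding it.
* **The fit is phenomenological.** Utilities and the choice temperature
  are held fixed during calibration — they encode the ordinal preference
  structure, and freeing them mostly relabels the same landscape
  compositions while making the search space pathological. The fitted
  demographic values absorb whatever the underlying, unobserved functional
  forms did, and some land on bounds or in ecologically surprising
  places (e.g. stopover forage on agriculture fitted at 1.0, above
  grassland's 0.85). They should be read as a reproduction device for
  the reference table, not as field estimates.

## 6. What the generator does and does not emulate

Replicate landscapes are i.i.d. multinomial pixel fields. They share the
*composition* statistics of the system under study but none of the
spatial autocorrelation of real land cover — real parcels are contiguous,
follow soils and drainage, and change through autocorrelated decisions.
Edge and neighborhood effects in the bird model therefore operate on
salt-and-pepper fragmentation, which is the worst case for a given
composition. Passing tests show the coupled machinery is internally
correct and reproduces the reference table's structure under these
conditions; they do not validate predictions for any real landscape or
species. Likewise the three archetypes are hypothesized value systems,
not survey estimates, and policies act only by shifting weights — cost,
enforcement capacity, and interaction among policies are out of scope.

## 7. Problem sizes used by the shipped checks

The test suite and acceptance script run the study-scale configuration:
40 × 40 landscapes, 30-year horizon, 100 replicates per consequence cell,
an 11-step × 50-replicate grassland sweep, and a 1500-evaluation
calibration re-run at 60 replicates per cell. Brute-force oracles run on
small grids (2 × 2 to 12 × 12) where exhaustive enumeration is readable.

## 8. Known limitations

No age or stage structure; no density dependence beyond the capacity
ceilings; no dispersal among multiple breeding landscapes; no weather or
climate forcing; no landowner interaction, land sales, or temporal
dynamics in value systems; policies are evaluated one at a time, never
as portfolios. The consequence table ranks policies *within* a landowner
type; comparing absolute growth rates across landowner types inherits
every caveat above.
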