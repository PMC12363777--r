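---
title: "A Cellular Potts model of corneal epithelial homeostasis, injury and recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Cellular Potts model of corneal epithelial homeostasis, injury and recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`corneacpm` simulates a two-dimensional sagittal section of the corneal
limbus and peripheral cornea as a Cellular Potts
(Glazier--Graner--Hogeweg) model. Each cell is a connected-ish set of
pixels on a 200 x 90 voxel lattice (2 um per voxel edge, so 4 um^2 per
voxel and a 400 x 180 um tissue section). One Monte Carlo Step (MCS)
represents 6 minutes of biological time; 240 MCS make one simulated day.

The agents are the four epithelial cell types -- limbal epithelial stem
cells (LESCs), basal, wing and superficial cells -- plus frozen
environmental compartments: a one-pixel basement membrane row (a merged
representation of the epithelial basement membrane and Bowman's layer,
split into a low-stiffness limbal segment on the left 80 um and a
high-stiffness central segment), the stroma below it, lateral wall
columns, and the tear film above the tissue. The air above the tear is
inert medium.

### Movement: the effective energy

Pixel-copy dynamics minimize

$$\Delta H = \Delta H_{contact} + \Delta H_{links} + \Delta H_{volume} +
\Delta H_{surface} + \Delta H_{chemotaxis}$$

evaluated incrementally for each attempted copy of a source pixel's owner
onto an 8-neighbour target pixel. Per MCS, N attempts are made (N = number
of non-frozen lattice sites); a copy is accepted when it lowers the
energy, otherwise with Boltzmann probability $e^{-\Delta H/T}$.

* **Contact**: a symmetric per-type-pair energy `J` over the target
  pixel's 8-neighbourhood. Low `J` means strong adhesion. The default
  table encodes three orderings that the emergent tissue relies on:
  stem/basal cells wet the basement membrane while wing/superficial cells
  are expelled from it; the superficial sheet wets the tear film while
  wing cells hide behind it; and superficial--wing contact is mildly
  penalized so superficial cells sort to the apical surface instead of
  remaining buried.
* **Volume / surface**: quadratic constraints
  $\lambda_v (V - V_t)^2 + \lambda_s (S - S_t)^2$ with the target surface
  tied to the target volume, $S_t = f_\sigma \sqrt{V_t}$. Stem and basal
  cells get a larger surface factor (6.5 vs 4), making them flat cells
  that maintain broad membrane contact.
* **Chemotaxis**: $-\mu\,(c_{EGF}(target) - c_{EGF}(source))$ for the
  invading cell. Basal cells carry $\mu = 600$ by default: a bare
  basement membrane under EGF-rich tear is a strong attractor, which
  drives the centripetal colonization front during development and wound
  closure after injury; at homeostasis the term is negligible against the
  adhesion hierarchy because EGF gradients inside the stratified tissue
  are small.
* **Links**: optional adhesion springs (a hemidesmosome proxy) between a
  stem/basal cell's centre of mass and the membrane point it first
  attached to, broken permanently when that membrane pixel is destroyed.
  The default stiffness is zero -- the term is implemented and tested but
  inert, because the recurrent-erosion behaviour already emerges from the
  differentiation rule alone.

Cell connectivity is *not* enforced; fragmentation is monitored with
`count_fragmented()` instead.

### Growth, division, differentiation, shedding

Stem and basal cells grow by advancing their target volume once per MCS:

$$G_{total} = \delta \cdot \frac{EGF^4}{k_{m,EGF}^4 + EGF^4} \cdot
\frac{k_{m,d}^4}{k_{m,d}^4 + P^4},$$

where $EGF$ is the cell's mean EGF concentration, $P = \max(0,
\lambda_v(V_t - V))$ is the crowding pressure (the volume-constraint
response of a cell prevented from reaching its target; overshoot is
clamped so it never stimulates growth), and $\delta = 25/80$ px/MCS so
that an unconstrained cell doubles its 25-pixel volume in 80 MCS -- the
8-hour minimum doubling interval. At 50 pixels the cell divides through
its centre of mass: stem cells split with the plane normal along x
(daughters separate centripetally), basal cells with uniformly random
orientation. Daughters inherit the type, get the actual half-volumes as
new targets, and new ids (the parent id retires -- this matters for
turnover accounting below).

Differentiation is deterministic, immediate, and forward-only:

* stem -> basal when the cell no longer contacts the limbal membrane;
* basal -> wing when its membrane contact area falls to at most
  `omega_contact_basal = 5` boundary pixels (counted with the same
  8-neighbourhood as contact energies);
* wing -> superficial when its neighbour set contains tear film and wing
  cells and contains none of basal, stem, or central membrane. The
  printed form of this rule lists the intersection without an explicit
  "empty set"; we read it as "the intersection is empty", which is the
  only reading consistent with superficial cells forming the apical
  layer.

Superficial cells in tear contact shed with probability
$1/(3 \cdot 240) = 1/720$ per MCS (a 3-day mean tear-exposed lifetime);
shed pixels become tear film.

One MCS executes: field update -> chemical-death check -> growth ->
differentiation -> mitosis -> sloughing -> Metropolis dynamics -> tear
re-wetting. The order is fixed and logged; the model text does not
prescribe one.

### The EGF field

The tear film clamps EGF at 1.0 (normalized). The field obeys

$$\partial_t c = \nabla \cdot (D(x,y) \nabla c) - k_d\, c$$

with $k_d = 0.5$/MCS and a cell-type dependent coefficient: 20
voxel^2/MCS inside superficial cells (tight junctions) and the central
membrane, 0 in the limbal membrane, 186 voxel^2/MCS everywhere else.
Lateral walls are no-flux; the top and bottom lattice rows hold zero
concentration. The solver is operator-split implicit (Thomas algorithm
per row/column, harmonic-mean face coefficients, half the decay per
direction), unconditionally stable and positivity-preserving at any
coefficient; the accuracy contract is the analytic steady-state test (a
clamped column relaxes to $e^{-y/\ell}$, $\ell = \sqrt{D/k_d}$, within 5%
RMS), not a particular scheme. With pure decay one MCS multiplies the
field by $(1 + k_d/2n)^{-2n}$ with $n = 10$ substeps, within 0.6% of
$e^{-k_d}$; the discrete contract is what the unit tests pin down.
Magnitudes below 1e-12 are flushed to zero (a fully decayed toxicant
field otherwise drags the solver through subnormal arithmetic).

This geometry makes the superficial sheet an EGF barrier: basal cells
under an intact tissue see roughly 0.1--0.2 of the tear concentration,
which (with $k_{m,EGF} = 0.088$) throttles division to the rate that
balances sloughing. Remove the barrier -- by injury -- and EGF floods the
wound bed, driving proliferation and chemotactic closure. This single
feedback sets the homeostatic thickness: a thicker tissue starves its
basal layer of EGF and thins; a thinner one overgrows.

### Injury

Two mechanisms:

* **Ablation**: every epithelial cell whose centre of mass lies in a disc
  is removed instantly; its pixels become tear film (increased tear
  production fills the defect).
* **Chemical exposure**: a toxicant field with its own coefficients
  (default D = 30 voxel^2/MCS globally with the same 20/20/0 type map,
  decay 0.05/MCS) receives a droplet deposit
  $A\,e^{-\|p - c\|^2/2\sigma^2}$ (the $\sigma = 0$ limit puts the whole
  amplitude into the centre pixel) or a uniform surface dose. Each MCS,
  any epithelial cell whose mean concentration exceeds the kill threshold
  (0.14 a.u.) is marked dying: its target volume is set to zero and the
  volume constraint shrinks it away. Membrane pixels above the threshold
  convert permanently to a passive damaged state -- the model deliberately
  has no membrane regeneration.

With an instantaneous point deposit the peak concentration reaching depth
$r$ is bounded by $A/(\pi e r^2)$ (two-dimensional dilution), which is
why the three reference amplitudes grade cleanly by depth on the
homeostatic tissue: 750 a.u. at the surface pixel (100, 75) kills only
superficial and wing cells (*slight*), 1500 a.u. reaches basal cells
(*mild*), 2500 a.u. destroys membrane pixels under the wound
(*moderate*). Basal cells over destroyed membrane lose their contact
substrate, differentiate prematurely, and the re-closed epithelium
repeatedly breaks down -- recurrent-erosion-like dynamics that emerge
rather than being scripted.

## Calibration and the choices behind it

The printed constants of the model (lattice, clock, division volumes,
contact threshold, slough probability, EGF coefficients) are hard
defaults. Everything else -- the contact-energy table, temperature,
constraint stiffnesses, surface factors, the two Hill constants, the
chemotaxis coefficient, and the toxicant parameters -- is *calibrated*:
chosen once so that the emergent tissue reproduces the published
tissue-level outcomes, and tagged as such in `R/config.R`. The anchors
were, in order: a stable stratified tissue with a flat apical monolayer
and no fragmentation; ~50 um steady thickness with cross-segment
uniformity; stratification within a week and stability soon after;
limbal turnover about twice as slow as peripheral; and the
750/1500/2500 depth ladder.

Decisions worth knowing about:

* **Pressure formula.** The growth rule needs an "effective pressure from
  volume deviation"; we use the volume-constraint response
  $P = \max(0, \lambda_v (V_t - V))$, the standard Potts reading.
* **Two EGF Hill constants.** The growth law's half-saturation is
  per-cell; we expose one value for basal cells and a 1.45x larger one
  for stem cells. Slower stem cycling is what produces the limbal
  turnover lagging the periphery, and it keeps the limbal niche from
  over-producing.
* **Basal chemotaxis always on.** The source model switches chemotaxis on
  for wound-healing scenarios. Development from the day-0 stem seed *is*
  re-epithelialization of a bare membrane, so we keep one constant
  coefficient; at homeostasis it is inert by construction.
* **Stability detector.** "Stable" is operationalized as: every day in a
  5-day window, each of the four type counts (averaged per day) lies
  within max(10%, 2 cells) of its trailing 5-day mean, with all types
  present; the reported stability time is the day that window opens.
  The absolute 2-cell floor exists because the stem population is ~5-10
  cells: a relative band below integer granularity can never hold.
* **Turnover threshold.** "Nearly complete substitution" is read as the
  surviving baseline-cohort fraction reaching 5% (configurable). The
  cohort is the set of epithelial cell ids alive at the stability
  baseline with COM in the region (limbal: x < 40 voxels); ids vanish by
  division, sloughing, or injury death, never resurrect, so the survival
  curve is monotone.
* **Tear film bookkeeping.** The tear is one compartment whose pixel set
  is re-formed every MCS as a fixed 4-voxel layer over the current
  surface (tear production tracks the surface); air trapped under
  overhangs becomes tear; tear pockets enclosed in the tissue are left to
  the dynamics. The tear participates in Metropolis dynamics as the
  operative medium, the air does not.

## What the default scenario does and does not emulate

A homeostasis run from `build_initial_state()` contains only stem cells,
tear and membranes at day 0; all four epithelial types appear in correct
vertical order within the first simulated day (`stratification_time()`),
the colonization front covers the peripheral membrane by ~day 9-10, and
detected stability arrives around day 15-17 at ~50 um thickness. Three 45-day replicates
take a few minutes; the acceptance script uses exactly that campaign
(n = 3 seeds, 10,800 MCS each), a desk-scale stand-in for the published
six-month, many-replicate campaign, which the runner supports but no test
requires.

Two known quantitative limits, both structural rather than tunable:

* **Peripheral substitution time.** With shedding fixed at a 3-day mean
  surface lifetime, a column of $k$ suprabasal layers clears in about
  $3k$ days; at 50 um (4-6 small-cell layers) near-complete peripheral
  substitution takes ~15-20 simulated days, not ~7. The limbal time
  (~14-18 days) is consistent with the intended 14-day figure because
  the stem cohort also retires by slow division. A 7-day peripheral
  figure would require either much larger cells (fewer suprabasal
  layers) or a faster shedding clock than the stated 1/720.
* **Stability by day 15 is at the edge.** The colonization front is
  capped near 14-18 voxels/day by the 8-hour doubling limit, so coverage
  completes around day 9-10 and the wing/super compartments fill by day
  14-16; detected stability lands at day 15-17 depending on seed.

The generator also idealizes real corneas in the usual ways: 2D section,
a single merged membrane entity, no stromal cells, nerves, immune
response, tear-film dynamics or membrane regeneration, and one abstract
EGF field standing in for many signalling systems. Passing tests
demonstrate internal consistency with the stated rules and published
emergent outcomes, not predictive validity for any particular chemical
exposure.

## Numerical notes

* All randomness (Metropolis decisions, cleavage orientations, slough
  draws) flows from one 64-bit Mersenne Twister stream per run segment,
  seeded explicitly; runs are bit-reproducible for a given seed and
  configuration, which is the package's reproducibility mechanism (there
  is no checkpoint/restart).
* Division assigns pixels on the cleavage line to alternating daughters;
  a degenerate split (an empty daughter) is abandoned and retried at a
  later MCS.
* Dying cells keep their type label, but stop growing, dividing and
  differentiating; a cell whose last pixel is lost is removed from the
  registry immediately.
* Thickness is the plain difference of mean y-COMs (superficial minus
  basal/stem) times 2 um; no half-layer correction is applied. When a
  layer is absent the metric is `NA`, so injury transients remain
  representable.
* The mitosis threshold, contact threshold and segment boundaries are
  integer-valued by construction; the 10-segment analysis uses x in
  [0,19], [20,39], ..., [180,199] voxels.

## Reproducing the headline numbers

```{r}
library(corneacpm)
cfg <- cornea_config()
sims <- lapply(1:3, function(s) simulate_cornea(cfg, days = 45, seed = s))
m <- lapply(sims, metrics_series)

# thickness over the stable window, stability and stratification timing
sapply(m, function(x) mean(x$thickness_um[x$day >= 20 & x$day <= 30], na.rm = TRUE))
sapply(m, stability_time)
sapply(sims, stratification_time)

# injury ladder on the first replicate
st <- sims[[1]]$state
mild <- simulate_cornea(cfg, state = st, days = 10, seed = 99,
                        injuries = injury_spec("chemical_droplet",
                                               center = c(100, 75),
                                               amplitude = 1500,
                                               apply_at = st$mcs))
mild$injury_reports[[1]]
```

`scripts/acceptance.R` packages this campaign end-to-end and writes the
measured quantities as JSON.
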