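---
title: "Modeling targeted-ligand uptake at single-cell resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling targeted-ligand uptake at single-cell resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Whether a targeted drug or imaging conjugate works depends on two coupled
processes: its transport through the disorganized interstitial space of a
tumor (pharmacokinetics) and its engagement of receptors on individual cells
(pharmacodynamics). Compartmental PK/PD models average both over a whole
tissue and cannot say *which cells* acquire the agent, or why cells next to
a capillary sometimes end up less saturated than distant ones. `uptakesim`
works at the other extreme: every ligand molecule is an explicit particle,
every cell an explicit polygon, and every coarse-grained membrane receptor
an explicit binding site with its own position, affinity and capacity.

## The model

**Tissue.** A rectangular 2D domain (default 120 x 120 um) holds N
non-motile, non-proliferating cells (the simulated horizon is 6 hours, too
short for motility or division to matter). The left edge is a capillary:
molecules extravasate there. The right edge is absorbing: molecules crossing
it are cleared from the tissue and counted. Top and bottom edges reflect.
Cell membranes are impenetrable to free ligand.

**Receptors.** Each cell carries M pseudo-receptors on its boundary, each a
coarse-grained cluster of real receptors with coordinates on the membrane,
a binding probability (affinity) A in [0, 1], and a capacity B of ligand
slots (default 5). The default fixture allocates 286 receptors x 5 slots =
1,430 slots over 8 cells, proportional to cell circumference with
largest-remainder rounding so the total is exact.

**Transport.** Free molecules perform Brownian motion: per step each axis
receives an independent Gaussian displacement with s.d. sqrt(2 D dt). The
study grid uses D = 2.5e-6, 2.5e-5 and 2.5e-4 mm^2/s, spanning slowly
diffusing nanoparticle-like agents to small rapidly diffusing compounds;
values are converted internally to um^2/s.

**Binding.** A move is resolved in a fixed precedence: (1) domain
boundaries; (2) if the proposal lands within the capture radius `r_min` of a
receptor that has a free slot and a Bernoulli draw at its affinity succeeds,
the molecule snaps to the receptor and becomes bound; (3) otherwise, if the
move would cross a membrane or end inside a cell, the position stays
unchanged; (4) otherwise the proposal is accepted. Affinity levels are
labeled by a pseudo-association constant K_A = 100, 10, 1 mapping to binding
probabilities 1.0, 0.1, 0.01. There is no dissociation and no receptor
recycling: occupancy is append-only, so cumulative saturation is monotone by
construction.

**Endocytosis.** A bound complex is internalized once it has spent a minimum
residency of 20 minutes on the membrane, and the ligand is then placed
uniformly at random inside its cell (rejection sampling), mimicking
endosomal distribution. The residency is implemented as a hard threshold —
the simplest reading of a "minimum residency time"; an exponential delay on
top of the minimum would be easy to add but is not the default because no
data here constrains its scale.

**Release schemes.** The same dose enters over 1 minute ("fast", a
bolus/local injection) or 3 hours ("slow", continuous intravenous
extravasation), apportioned deterministically over steps by the
cumulative-floor rule (exact total, within one molecule of a constant rate).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `D` | 2.5e-5 mm^2/s | effective interstitial diffusivity of the agent |
| `K_A` | 100 | binding probability level (100 -> 1.0, 10 -> 0.1, 1 -> 0.01) |
| `L_total` | 5000 | molecules released (500-10,000 studied) |
| `scheme` | slow | release window: 60 s (fast) or 10,800 s (slow) |
| `dt` | 0.1 s | integration step |
| `r_min` | tissue-derived | capture radius (um) |
| `residency_s` | 1200 s | minimum membrane residency before endocytosis |
| `T_end` | 21,600 s | simulated horizon |

`r_min` is not a measured quantity; the default is half the inter-receptor
arc spacing of the most densely covered cell (floor 0.5 um), so that capture
disks tile the membrane without overlap — receptors then act as a contiguous
reactive membrane rather than isolated targets, and the choice introduces no
double-counting between neighbors. On the default fixture this gives
r_min of about 0.8 um.

At the default `dt` the per-step displacement is sqrt(2 D dt): about 0.7 um
at the calibrated D, but about 7 um at the largest studied D, which can step
across a capture zone or a narrow channel in one move (the engine warns when
the step length exceeds the smallest cell diameter). Binding tests the step
*endpoint*, matching the discrete binding condition of the underlying
model; a swept-segment capture mode is deliberately not the default since it
would change the effective association rate. Sensitivity studies should
lower `dt` rather than switch modes.

## Numerical choices

- **Update order** within a step is fixed: release, move all free molecules
  in molecule-id order, then internalize due complexes. Sequential binding
  resolution means two molecules cannot claim the same last slot in one
  step. The order is otherwise immaterial to the recorded observables.
- **Candidate receptor**: one binding attempt per molecule per step, against
  the nearest in-range receptor only; exact distance ties break toward the
  lowest (cell, receptor) index. The spatial hash used for the search is
  tested to agree exactly with exhaustive search.
- **Membrane test**: the step's chord (post-reflection endpoint vs current
  position) is tested against every cell's edges, with bounding-box
  prefilters; touching counts as crossing, so grazing moves are rejected
  conservatively.
- **A failed affinity draw does not reject the move**: the molecule simply
  continues in the interstitium (unless its path crosses a membrane). Only
  membrane crossings freeze the position.
- **RNG**: one seeded R RNG stream drives a whole run; replicate seeds are
  `seed + 0, 1, ..., n-1`. Identical (config, tissue, seed) gives bitwise
  identical output.
- **Fits**: one-phase association `B0 + (Bmax - B0)(1 - exp(-k t))`, the
  Hill curve `Bmax [L]^h / (K_D^h + [L]^h)` and the log-dose sigmoid
  `B0 + (Bmax - B0) / (1 + 10^(LogK_D - log10 [L]))` are fitted with
  bounded Levenberg-Marquardt least squares under multistart (rate constants
  initialized from a log-linear transform plus a fixed grid; lowest residual
  sum of squares wins, ties to the smaller rate). Constant series are
  flagged unidentifiable instead of being fitted.
- **B0 is free by default** in the association fit; `fix_b0 = 0` pins it
  when the physical zero intercept is wanted.

## What the fixture emulates — and what it does not

`generate_fixture_tissue()` stands in for a digitized intravital image: two
loose rows of 8 convex-ish cells (15-25 um across) separated by narrow 2-5
um channels, receptors spread uniformly along each membrane. It reproduces
the *structural motifs* that drive the interesting behavior — cells shading
one another from the vessel, narrow channels that slowly diffusing ligand
penetrates better than fast ligand, a finite 1,430-slot binding budget — and
it is deterministic per seed.

It does **not** reproduce: real membrane receptor clustering (fixture
affinity is uniform unless imported from an intensity image), irregular
concave cell shapes, stromal obstacles, 3D transport, vascular flow or
plasma kinetics, ligand degradation, or receptor recycling. Tests passing on
the fixture therefore validate the simulator's mechanics and its qualitative
parameter dependences, not quantitative predictions for any particular
tumor. For real geometries, `import_tissue_from_masks()` builds the tissue
from a label mask plus intensity image at a chosen receptor spacing.

## Degenerate inputs and edge cases

- A dose of 1 molecule, zero affinity, or zero diffusivity are all legal;
  conservation and monotonicity hold trivially.
- Receptors with distinct capacities are allowed (the fixture uses one
  reduced-capacity receptor when the slot total is not a multiple of 5).
- A proposal landing exactly at distance `r_min` does *not* bind (strict
  inequality); a point exactly on a membrane counts as interstitial.
- Reflection is resolved iteratively, so a pathological step longer than the
  domain still ends inside (or is cleared at the right edge first).

## Problem sizes used in the shipped analyses

The packaged tests and the acceptance script run the full 6-hour horizon at
`dt` = 0.1 s for the calibrated configuration and the seven-dose binding
curve (n = 3 replicates each), and the 2 x 2 affinity-diffusivity subset for
the fast-versus-slow comparison. These sizes were chosen as the smallest
runs that exercise every mechanism at the study's own parameter values;
engine unit tests use a few hundred molecules over 30 simulated minutes.

## Known limitations

- At D = 2.5e-4 mm^2/s and `dt` = 0.1 s the step length (~7 um) exceeds
  `r_min`, so binding rates at the highest diffusivity are resolution-limited;
  the inverse relation between diffusivity and saturation is robust to this
  (it persists at `dt` = 0.01 s) but absolute saturation levels at high D
  shift with `dt`.
- The left boundary reflects free molecules; re-entry into plasma is not
  modeled. During the release window this slightly overestimates the ligand
  pool near the vessel relative to a permeable-wall model.
- The membrane test uses the reflected chord, not the true reflected path;
  for cells at least ~1.5 um from the walls (guaranteed by the fixture) the
  difference is immaterial.
- Internalized ligand is inert: no intracellular trafficking, no signal
  model beyond counts.
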