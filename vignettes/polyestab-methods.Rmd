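---
title: "Modelling neopolyploid establishment with polyestab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling neopolyploid establishment with polyestab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`polyestab` simulates the origin and demographic establishment of
neotetraploid plant lineages inside a diploid population, on a bounded
lattice of square habitat patches (default 100 x 100 patches of 0.25 m²,
one plant per patch). The model is individual-based and spatially explicit
because the phenomena of interest — minority-cytotype exclusion, pollen
limitation, the triploid bridge, establishment at range margins — are all
driven by local interactions that deterministic, panmictic recursions
average away.

### Environment and fitness

Each patch carries five environmental variables: three "bioclimatic" layers
(V1–V3) that are nearly uniform at this micro scale, and two "soil" layers
(V4–V5) whose patchiness is what actually restricts the occupiable area. A
global seasonal factor, one Gaussian draw per generation (mean 1,
sd 10⁻³), multiplies V1–V3 for every patch of that generation, adding
intergenerational — not spatial — variability of order 0.1%. We read the
seasonal perturbation as a single global multiplier per generation rather
than an independent draw per patch; a global draw is the simplest
mechanism that produces between-year variability while leaving the spatial
structure of the landscape intact.

Every plant carries a five-component adaptive optimum (its *individual
adaptivity*, IA). On a patch with effective variables \(v_i\), the
per-variable fitness component is

\[ E_i = 2^{-|IA_i - v_i| / L_i}, \]

where \(L_i\) is the cytotype's tolerance half-width: a deviation equal to
the limit halves the component. Tetraploids use \(k \times L_i\) with the
tolerance multiplier \(k\) (1 by default; the swept variable of the
tolerance experiments). The five components combine into a single
environmental fitness \(E\) by geometric mean (configurable to product or
minimum); the geometric mean keeps \(E\) on the same scale as a single
component, so "founders hold E = 1" and "a deviation of one limit costs
half" remain true regardless of how many variables are active.

A patch is *ecologically suitable* for a genotype iff every per-variable
deviation is at most the limit (every \(E_i \ge 0.5\)). Suitability is a
hard establishment gate: seeds cannot recruit on unsuitable patches. This
makes the tolerance limit an actual range boundary, which is what produces
establishment of wide-tolerance tetraploids on the margins of the diploid
distribution.

### Demography

Plants are hermaphroditic perennials with overlapping generations. Each
cycle a plant dies with a flat 10% hazard; its lifespan is additionally
capped at \(\lceil 10 \times E_\mathrm{est} \rceil\) cycles, where
\(E_\mathrm{est}\) is its fitness at establishment — a plant established at
full fitness lives at most 10 cycles. The cap reproduces both stated facts
of the reference conditions (10-cycle life expectancy, 10% per-cycle
hazard) while letting marginal establishment shorten life. Fecundity is
age-structured: at most 3 offspring for one-year-olds, 6 for
two-year-olds, 10 afterwards; the realised ovule count is
Binomial(cap, E), which preserves the caps exactly at \(E = 1\), yields
integers, and adds demographic noise appropriate to an individual-based
model (the alternative, rounding cap × E, was rejected because it
eliminates establishment noise at small counts, which matters for
minority-cytotype dynamics).

Within one generation the order of operations is: seasonal draw and
fitness refresh; mortality; reproduction; dispersal; simultaneous
settlement; establishment detection; ageing. Ages increment after
reproduction so that one-year-old plants reproduce with their cap of 3;
incrementing before reproduction would make the age-1 fecundity class
unreachable. All seeds of a generation settle simultaneously, which is the
only ordering under which the "highest prospective fitness wins a
contested patch" rule is well defined.

### Reproduction and the gamete system

Gamete classes per cytotype: diploids make reduced \(x\) gametes and, once
unreduced-gamete production switches on (generation 200; earlier
generations are diploid burn-in to quasi-equilibrium), unreduced \(2x\)
gametes at the configured rate. Triploids make a mix of reduced \(x\),
reduced \(2x\), unreduced \(3x\) and aneuploid gametes; tetraploids make
reduced \(2x\) (and optionally unreduced \(4x\)) gametes. Aneuploid
gametes and any fusion above \(4x\) are inviable — the model tracks no
cytotype above tetraploid. Seeds that are triploid or have a triploid
parent survive with a single scalar viability (the triploid block); no
endosperm-dosage mechanism is modelled.

Each ovule independently chooses a pathway: selfing and apomixis with the
bearer cytotype's configured rates, otherwise outcrossing. Outcrossing
draws a pollen donor among living plants within 10 patches with weight
\(e^{-d/1.6}\) — about 95% of donor mass within 5 patches and a very small
fraction at 7–10, matching the stated neighborhood shape. An ovule with no
donor in range aborts (pollen limitation, one of the minority-cytotype
costs). An apomictic ovule develops into an exact maternal clone; the
apomictic pathway stands in for unreduced female gamete development without
fertilisation, so no separate gamete draw is made. Sexual offspring take
mid-parent trait values with optional Gaussian segregation noise
(default 0: pure blending, which deliberately removes drift in trait
values).

Seed dispersal distance is negative-exponential (mean 1.5 patches,
truncated at 20) with uniform direction; the workspace boundary is
absorbing (seeds displaced off-grid are lost) because the landscape is a
bounded range, not a torus. The kernel mean is a calibration knob (the
reference conditions state only that "most seeds establish very close" to
the mother).

### Polyploidization events and their fate

A *polyploidization event* is recorded when a neopolyploid individual
**establishes**: a triploid seed from lower-ploidy parents, or a
tetraploid seed whose parents are not both tetraploid, formed with at
least one unreduced gamete. Events are *bilateral* (two unreduced gametes)
or *unilateral* (exactly one); polyploids formed by two reduced gametes
(e.g. \(2x\)-dosage gametes from triploids or tetraploids) extend existing
lineages but are not unreduced-gamete events. Counting events at
establishment rather than at seed formation is a deliberate reading: the
reference event counts (~450 per run at the natural 0.6% rate) are
reproducible as establishment counts but would be over an order of
magnitude larger as seed counts, and the mapped quantity ("first
neopolyploid individuals") is an established plant.

Each tetraploid event founder receives a lineage tag inherited maternally
by tetraploid descendants (clones, selfed seeds, and 4x × 4x or bridge
crosses). An event becomes a *successful polyploidization event* (SPE)
when its living tagged tetraploids reach 50; events still pending at run
end are *unsuccessful* (UPE), so SPE + UPE = bilateral + unilateral always.
Triploid-formation events count (they are the unilateral channel of the
bridge) but can never themselves satisfy the 50-tetraploid criterion; a
tetraploid produced from a tagged triploid mother by reduced-gamete
fusion joins the mother's lineage, which is how a bridge lineage can
become an SPE.

Summary statistics per replicate: SPE, UPE, bilateral and unilateral
counts; GPIP, the generations from the formation of the first successful
event to its establishment; GuF, the generations from unreduced-gamete
onset to tetraploid fixation (4x proportion 1, with triploids counted in
the denominator); and the final 4x proportion. A replicate stops at
fixation or 1000 generations after onset.

## The synthetic environment and its calibration

The packaged generator builds each layer as a smoothed Gaussian random
field (white noise convolved with a Gaussian kernel): correlation length
~60 patches and small amplitude for the three bioclimatic layers (so they
are near-uniform across the workspace, relative sd < 1%), ~15 patches for
the two patchy soil layers. The soil layers additionally carry a radial
trend away from the grid centre. The trend supplies the large-scale
structure real soil maps have and stationary noise fields lack: without
it, a patch 40 cells away is as likely as not to resemble the range core,
and "shifting the optimum by 40 patches" would not mean shifting it
ecologically. With the trend, spatial and environmental distance are
coupled, the diploid range is a bounded core around the founder block,
and its margins are exactly where environmental values reach and exceed
the diploid tolerance limit. Fields are re-centred so the average over
the central founder block equals the layer mean, which guarantees the 30
diploid founders (placed on distinct patches of the central 20 x 20
block, optima copied from their patches, E = 1) sit inside the suitable
region. Because inheritance is blending, descendant optima can never
leave the convex hull of the founder optima; the founder block's IA
spread against the trend slope is therefore what bounds the achievable
range (~20 patches radius at the defaults).

Defaults were calibrated once, jointly with the tolerance limits, against
anchors of the reference conditions and then frozen: (i) the diploid
quasi-equilibrium census at the end of burn-in is on the order of 1000
plants (measured median ~1000 over environment seeds, anchor band
600–1400); (ii) at the natural 0.6% unreduced-gamete rate a full-length
run logs roughly 450 polyploidization events, which fixed the triploid
seed viability at 0.3; (iii) successful establishment at a 10%
unreduced-gamete rate is rare but non-zero while 20% drives reliable
fixation in ~60–110 post-onset generations, while mating-assurance and
tolerance levels at or below their thresholds produce none, which fixed
the triploid gamete class mix (29% x, 29% 2x, 5% 3x, 37% aneuploid) —
neither the mix nor the viability is printed in the reference and both
are marked as calibration targets. The fraction of the workspace suitable for at least
one founder genotype (`founderRangeMap()`) is ~13%: the population is
soil-restricted, as intended.

What the generator does *not* emulate: real rasters are anisotropic,
their soil variables are cross-correlated, and their gradients are not
radially symmetric about the founder site. Passing tests therefore
demonstrate the mechanisms (exclusion thresholds, mating and tolerance
effects, marginal establishment), not landscape-specific event counts;
exact reproduction of the reference table would additionally require the
original raster window and thousand-replicate sweeps.

## Experiment families

Five sweeps against the common baseline: unreduced-gamete rate
(0.6–20%), tetraploid selfing (10–100%), tetraploid apomixis (10–100%),
mixed mating, and environmental tolerance (k = 0.5–2.0) plus a
shifted-optimum variant (30 optimum patches at 5–40 patches distance; each
newly minted tetraploid founder's optimum is matched to a random one, and
inheritance proceeds unchanged from there). In the mixed family, selfing
*complements* apomixis (selfing = 1 − apomixis, no outcrossing at any
level): this is the only reading under which the mixed treatments behave
near-identically across levels and match the pure-selfing extreme, which
is the signature pattern of the reference results; setting both rates
equal to the level is infeasible above 50% and produces no establishment
at 10%. Treatment comparisons use one-way ANOVA plus all-pairs Tukey HSD
at α = 0.01 with a compact letter display assigned by insert-and-absorb on
the significance matrix (implemented in-package; the letters are a
deterministic function of the pairwise matrix).

The classical-comparison preset (`felberConfig()`) reproduces the
assumptions of the deterministic diploid/tetraploid gametic recursion
inside the agent-based model: triploid viability 0, fitness clamped to 1
everywhere, panmictic pollen. It runs by default on a uniform 32 x 32
workspace whose carrying capacity (~1000 plants) matches the census scale
of that comparison; the deterministic recursion itself
(`iterateRecursion()`, `findExclusionThreshold("deterministic")`) has the
known equal-fitness exclusion threshold \(3 - 2\sqrt{2} \approx 17.16\%\),
which the bisection reproduces to the fourth decimal.

## Numerical choices and degenerate inputs

* All randomness flows through R's RNG; one root seed per replicate fully
  determines it, and sweeps derive per-replicate seeds from a root seed by
  a fixed integer hash.
* Settlement ties (equal prospective E on one patch) break uniformly at
  random via reservoir choice; contention is otherwise strictly
  fitness-monotone.
* Truncated exponential dispersal uses rejection sampling (the truncation
  tail at the defaults is ~10⁻⁶, so rejection is essentially free).
* Zero-amplitude layers give exactly uniform grids; zero founders give an
  immediately stopping run with a zeroed summary; a fully saturated
  workspace admits no establishment.
* Zero residual variance in a treatment comparison (all replicates equal)
  is handled without an ANOVA: distinct means get distinct letters, equal
  means share one.

## Problem sizes used by the shipped checks

The packaged tests and the acceptance script run desk-scale versions of
the sweeps: 5–20 replicates per condition on the calibrated environment
(the reference design uses 1000), and the classical-comparison scan uses 5
replicates per 0.5% step on the 32 x 32 preset workspace. These sizes were
chosen so the full suite completes on a single CPU while keeping the
qualitative contrasts (zero vs non-zero SPE, threshold locations,
direction of fitness contrasts) overwhelmingly resolved; the
thousand-replicate design is reproducible with the same functions by
raising `replicates`.

## Known limitations

* Where successful lineages arise differs from the reference in one
  respect: at low unreduced-gamete rates this implementation's successful
  events grow almost exclusively by escaping to the range margin, where
  free patches are plentiful but fitness is low, so successful founders
  tend to carry *below*-average fitness (both absolute and relative to
  their diploid neighbours) rather than the above-average fitness the
  reference reports for its successful events. The corresponding
  acceptance check asserts the reference direction and fails honestly;
  event records carry both fitness measures so the comparison is
  transparent. The relaxation of the fitness filter under a doubled
  tetraploid tolerance is reproduced.

* No gene-level genetics: the adaptive optimum is a blended quantitative
  trait; with segregation sd 0 trait variance only erodes, so long-run
  trait diversity is maintained spatially (by local mating along
  environmental gradients), not mutationally.
* The triploid block is a single scalar viability; no endosperm dosage,
  no pollen competition beyond distance weighting, no seed bank or
  secondary dispersal.
* Cytotypes above 4x are treated as inviable fusions, so the model cannot
  address hexaploid formation.
* The shifted-optimum experiments inherit the dispersal truncation: shifts
  beyond the seed kernel's reach from the diploid margin are structurally
  unreachable, which is the intended mechanism for the collapse of
  establishment at the largest shift.
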