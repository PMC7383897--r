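---
title: "Modelling label-free mRBC purification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling label-free mRBC purification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiralsort)
```

# The process being modelled

In vitro erythropoiesis from CD34+ progenitors ends in a heterogeneous
suspension: enucleated manufactured red blood cells (mRBC, the product),
nucleated cells arrested at earlier stages (a leukemogenic hazard in a
transfusion product), and the free nuclei expelled at enucleation. All
three carry the same erythroid surface marker (CD235a), so a label-free
separation must exploit physical differences. Two are robust across
donors: nuclei are the smallest and stiffest objects in the sample, and
enucleated cells are the most deformable.

`spiralsort` models the two-stage purification built on those markers:

1. **Spiral inertial sorting.** In a spiral microchannel, particles focus
   at lateral equilibrium positions set by the balance of shear-gradient
   lift, wall lift and Dean drag; deformable particles feel an additional
   deformability-induced lift that shifts them toward the outer wall at
   elevated flow rates. Four balanced outlets section the 170 µm channel
   width into 42.5 µm bins (A at the outer wall through D at the inner
   wall), and the laminar flow divides equally between them.
2. **Membrane filtration** of the outlet-A fraction through a 3 µm
   track-etched membrane, removing almost all remaining nucleated cells at
   a substantial cost in enucleated yield.

# The focusing model is phenomenological

The package deliberately does **not** compute lift or drag forces. The
measured behaviour — per (cell class, flow rate) mean ± SD lateral
position — is the model (`defaultFocusingModel()`):

| class | 0.2 | 0.4 | 0.6 | 0.8 | 1.0 ml/min |
|---|---|---|---|---|---|
| enucleated | 100 ± 24 | 123 ± 22 | 131 ± 23 | 103 ± 33 | 36 ± 21 |
| nucleated | 110 ± 20 | 125 ± 15 | 134 ± 11 | — | 103 ± 32 |
| nucleus | — | 151 ± 23 | 156 ± 11 | 158 ± 11 | 154 ± 18 |

Positions are in µm from the outer wall. Missing cells of this table are
genuinely missing: `sampleLateralPositions()` raises a "no data" error for
them and `selectFlowRate()` reports the affected AUC as `NA`. We never
interpolate across flow rates — the enucleated trajectory is strongly
non-monotone (the 0.8 → 1.0 ml/min jump from 103 to 36 µm is the
deformability transition), so interpolation would invent physics.

Within an entry, positions are modelled as **normal**, truncated to the
physical channel `[0, width]` for sorting simulations and untruncated for
ROC work. Both choices are assumptions: the measured scatter is roughly
symmetric and unimodal, truncation at the printed parameters moves every
pairwise AUC by less than 0.01, and the untruncated closed form
`gaussianAuc()` = Φ(Δµ/√(σ₁²+σ₂²)) then serves as an independent oracle
for the empirical trapezoid AUC (they agree within 0.005 at n = 10⁵ in the
test suite).

**ROC orientation.** Positive = nearer the outer wall (position at or
below the cutoff). This is fixed, not configurable: it is the direction in
which the product (enucleated) separates from both contaminants at
1 ml/min, and it reproduces all quoted AUCs (0.96 vs nucleated, >0.99 vs
nuclei at 1 ml/min; 0.62 vs nucleated at 0.2 ml/min).

**Flow-rate selection** maximises the *minimum* available AUC over the
contaminant classes — the process is only as good as its worst
contaminant — and breaks exact ties toward the higher flow rate, since
throughput is otherwise free. With the default model this selects
1 ml/min.

# Synthetic populations

`generateEvents()` emulates real-time fluorescence and deformability
cytometry (RT-FDC) event tables. Per class: projected area (µm²) and
deformability are normal, fluorescence channels (DRAQ5-DNA, CD235a)
log-normal — a standard shape for cytometric intensities. Enucleated
events draw their DNA signal from the unstained background distribution,
encoding their DNA-negative phenotype. Diameter is defined as the
area-equivalent circle diameter, so `area = πd²/4` holds exactly.

**Preset calibration.** Absolute per-donor size parameters are not
published; what is published are the pairwise overlaps as two-sample AUCs.
The three presets are therefore calibrated so those AUCs are reproduced
(donor I enucleated-vs-nuclei ≈ 0.68; donor III enucleated-vs-nuclei
≈ 0.95 and enucleated-vs-nucleated ≈ 0.56), with means in a plausible
erythroid range (nuclei ≈ 40 µm², enucleated 36–71 µm² depending on donor,
nucleated ≈ 74–80 µm²). Donor II has the smallest, stiffest and least
abundant enucleated cells. Class fractions put enucleated cells at 10–35 %
of the starting sample (I: 30 %, II: 12 %, III: 35 %). Validity checks
enforce only the orderings that hold across donors — nuclei stiffest,
enucleated most deformable, nuclei smaller than nucleated cells — because
the size ranking of enucleated cells vs nuclei is explicitly
donor-dependent.

Debris (fragments at or below 15 µm²) is generated at a default 5 % of
events to exercise the debris gate; set `debrisFraction = 0` or
`includeDebris = FALSE` for clean tables.

**Seeding.** Every stochastic operation takes an explicit integer seed,
evaluates under a saved-and-restored RNG state, and derives sub-stream
seeds (kept below 2³¹) where one call needs several independent draws.
Identical (preset, n, seed) yield byte-identical CSV exports.

**What the generator does not emulate:** acquisition artifacts (doublets,
out-of-focus events, flow instabilities), spectral spillover, day-to-day
drift, donor replicates, or any correlation between size and fluorescence
within a class. Tests passing on these populations therefore demonstrate
correctness of the pipeline's logic under its stated statistical
assumptions, not robustness to real acquisition noise.

# Gating

The gate mirrors standard practice: debris excluded at or below
**15 µm²** (boundary inclusive on the debris side), then a DNA± split,
then an area split of DNA-positive events into nucleated cells (large) and
free nuclei (small). Conventions, all covered by tests:

* DNA-positive means `signal ≥ threshold`; raising the threshold can only
  grow the enucleated count (monotonicity).
* The DNA threshold defaults to the **0.995 quantile of an unstained
  control** (`fitDnaThreshold()`), placing at most 0.5 % of background
  events in the DNA+ region. Whether the original analysis used fixed
  values or per-experiment controls is unknown; per-experiment fitting is
  the reproducible choice.
* The nucleated-vs-nucleus area cut has no published value (it is drawn as
  rectangles on a scatter plot), so `defaultGates()` places it at the
  midpoint of the generating preset's nucleated and nucleus mean areas —
  consistent with any preset, overridable in `GateConfig`.
* CD235a is carried in every table but unused by the default gate, which
  operates on DNA × area only.

Composition summaries are reported over **non-debris** events; whether the
published compositions were computed before or after debris exclusion is
not stated, and after-exclusion is this package's convention.

# Channel design numbers

`hydraulicDiameter()`, `reynoldsNumber()`, `deanNumber()` and
`crowdingAlpha()` evaluate the standard expressions
(D<sub>h</sub> = 2HW/(H+W) = 51 µm at the default cross-section;
Re = ρUD<sub>h</sub>/µ; De = Re·√(D<sub>h</sub>/R); α = 6WH·VF/(πa²), with
VF = c·πa³/6 for spheres at number concentration c). Numerical notes:

* The quoted velocity table (0.65, 1.3, 1.9, 2.6, 3.3 m/s for 0.2–1.0
  ml/min) is not exactly `signif(U, 2)` of the computed velocities at one
  row (1.9608 → 2.0), and no single rounding rule regenerates the quoted
  Re column either. `operatingTable()` therefore reports the exact
  velocity, a 2-significant-figure convention column, Re from both, and
  accepts a `velocities` override so the quoted values can be supplied
  verbatim; with them it returns Re = 33, 66, 97, 133, 168 (the fourth row
  is within 1 of the quoted 132 — an artifact of rounding conventions, not
  of physics).
* The spiral's curvature radius is unpublished, so it defaults to unset
  and Dean numbers are only reported when it is configured. A single
  radius of **2.1 mm** regenerates the quoted De column (5, 10, 15, 21,
  26) exactly and is used as the configured example throughout.
* Direct evaluation of α at a = 5 µm and 3–4 × 10⁶ cells/ml gives
  0.077–0.102 — comfortably below the α = 1 crowding limit, though about
  half the quoted range (0.153–0.255), whose derivation (the volume
  fraction or diameter actually used) is unclear. The package reports the
  directly evaluated value.

# Sorting simulation and metrics

`simulateSort()` draws one truncated-normal position per event from its
true class's entry and bins it with half-open intervals
`[edge_i, edge_{i+1})`, last bin closed — a position exactly on an
interior edge goes to the inner neighbour (42.5 µm → outlet B). Events are
conserved exactly. Debris, which has no measured focusing entry, follows
the free-nuclei distribution by default (`debrisLike`): small rigid
fragments are the nearest physical analogue.

The metrics operate on class × outlet `CountTable`s: separation efficiency
(rows normalised to 1), purity (columns normalised to 100 %), and
enrichment as the outlet-to-inlet **concentration** ratio. Under the equal
4-way flow split each outlet holds a quarter of the inlet volume, so a
fully captured class is enriched 4×; counts and concentrations give
identical efficiencies and purities, which is why the implementation works
on counts and carries volumes only for enrichment. Degenerate inputs are
reported, not raised: an all-zero class has undefined efficiency (NA), an
empty outlet undefined purity (NA).

**A known, deliberate mismatch.** With the Gaussian 1 ml/min parameters,
about 58 % of enucleated mass falls in outlet A's 0–42.5 µm section,
whereas the reported separation efficiencies for good donors exceed 90 %.
The measured position distributions of presorted populations are evidently
skewed or narrower than mixed-sample scatter suggests; rather than guess a
distribution shape, the model is validated on the AUCs (which match to
±0.015) and outlet capture fractions are treated as calibratable, not
predicted. This is the package's main known limitation.

# Filtration and batch accounting

The membrane stage is a per-class Bernoulli passage
(`applyFilter()`), with an expected-value mode for deterministic reports
and a binomial mode that converges to it (3-SD agreement at n = 10⁵ in the
tests). Per-class passage probabilities are **calibrated knobs, not
measurements**: the defaults (enucleated 0.40, nucleated and nuclei 0.004)
are chosen so that filtering a ≈ 70/25/5 outlet-A composition reproduces
the reported aggregate outcomes — post-filter enucleated purity ≥ 99 % and
an enucleated loss inside the reported 50–70 % band. Membrane fouling and
time dependence are not modelled. Batch accounting subtracts the 1.5 ml
dead volume from each 10 ml batch and applies a configurable 5 %
sedimentation/dilution loss, giving a default usable recovery of
(8.5/10)·0.95 ≈ 80.8 %.

# Imaging

The cytospin module reconstructs a minimal "threshold, outline, classify"
analysis: global Otsu threshold (fixed-value override available) on dark
objects over a light background, connected components, a min-area filter
(default 15 µm², the debris boundary), then per-object features — centroid,
area, equivalent diameter, mean intensity and the internal dark fraction
(fraction of pixels below a nuclear-intensity cutoff, default 0.45).
Classification: small + dark → nucleus (default area ≤ 30 µm²); larger
objects are nucleated when their dark fraction reaches the cut (default
0.15, well below the ≈ 30 % dark-core fraction rendered for nucleated
cells) and enucleated otherwise. The original scripts' exact features and
cutoffs are unpublished; these rules are a faithful reconstruction of the
approach, not of the code.

The renderer draws enucleated cells as uniform mid-intensity disks,
nucleated cells with a darker concentric core (core diameter 0.55 of the
cell), nuclei as small dark disks, plus additive Gaussian noise; an
optional per-class area inflation emulates the cytospin spreading artifact
by which deformable cells flatten and appear larger than in suspension.
Constant or blank images segment to zero objects rather than erroring.

In-channel frames encode lateral position as the centroid's x distance
from a configured outer-wall pixel column; extraction is affine in the
wall coordinate (tested), and centroids converting to positions outside
`[0, width]` are flagged and excluded by default (`keepAll = TRUE` retains
them, used when a synthetic ROI deliberately extends past the channel).

# Problem sizes and test budget

The suite uses 10⁴–10⁵ events for distributional checks (AUC tolerances of
±0.015 need ≥ 10⁴ draws; 3-standard-error parameter recovery is checked at
10⁵), 200 planted blobs for position extraction (matching the event count
of the scatter data the model derives from), and 20–28 objects per
rendered field. These sizes keep the full suite under half a minute while
leaving every statistical tolerance comfortably above its Monte-Carlo
noise floor.

# Known limitations

* Outlet capture fractions are not predictive (see the Gaussian mismatch
  above); AUCs and the metric algebra are.
* Filter passage probabilities are calibrated, not measured; treat
  post-filter numbers as consistency checks of the calibration.
* Donor presets reproduce published overlap statistics, not absolute
  sizes; the supplement with per-donor tables was unavailable.
* No RT-FDC physics (deformation from contours), no CFD or force
  computation, no membrane fouling, no FCS file parsing (CSV tables only),
  and no modelling of differentiation kinetics upstream of the sorter.
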