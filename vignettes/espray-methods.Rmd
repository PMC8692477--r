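---
title: "Methods: device fields, droplet mechanics and assay quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: device fields, droplet mechanics and assay quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`espray` models the needle-plate electrospray device used to encapsulate
living cells in a polymer solution and quantifies the assays that surround
it. This vignette records the models, the numerical choices, and the
limits of what the synthetic-data tests demonstrate.

## The electrostatic model

The device is a stainless-steel capillary (18G: 0.838 mm bore, 1.27 mm
outer diameter) held at 10–15 kV, facing a grounded 60 × 60 × 1.5 mm
collector plate across a 70 mm air gap. With no free charge in the gap,
the potential obeys Laplace's equation with Dirichlet conditions on the
conductors; `solve_poisson()` also accepts a per-node charge density, in
which case the right-hand side of Poisson's equation is used.

The discretisation is a uniform-spacing finite-volume (five-point
finite-difference) scheme. Each pair of adjacent nodes is coupled by the
face conductance (face area over node distance):

* **axisymmetric mode** (default): radial faces carry `r_{i+1/2}`,
  vertical faces `r_i`; the control volume at `r = 0` is a disc of radius
  `h/2`, which yields the regularity condition on the axis. This is the
  physically faithful formulation for a rotationally symmetric device.
* **planar mode**: unit conductances on a full Cartesian cross-section
  `x ∈ [-W, W]`, provided for comparison — a 2-D slice model produces
  systematically weaker tip-field enhancement (the "needle" becomes an
  infinite blade), which matters when comparing against values obtained
  with unstated formulations.

Assumptions worth stating: the metal walls are equipotential; the fluid
column inside the bore is treated as free space (no dielectric contrast,
no meniscus shape); open boundaries are homogeneous Neumann
(`outer_boundary = "grounded"` switches the lateral and top edges to the
plate potential for sensitivity checks). The needle's exposed length is
not part of the device specification; the default protrusion is 30 mm
with the simulation box extending 30 mm laterally and 10 mm above the
needle entry. Tip-region fields are dominated by local geometry, and the
refinement audit quantifies what remains.

The resulting matrix is a symmetric M-matrix, so the discrete maximum
principle holds by construction and is asserted in the tests. The default
backend is a sparse Cholesky factorisation (`Matrix`); red-black SOR
(tolerance 1e-8 on the relative residual, cap 100,000 sweeps) is kept as
an independent iterative path and errors with the last residual attached
when it fails to converge.

```{r solve}
library(espray)
grid <- build_grid(device_geometry(), operating_potential(15e3),
                   spacing = 100e-6)
field <- compute_field(solve_poisson(grid))
tip_field_report(field)
```

### Sampling conventions and mesh registration

Field metrics are read at grid nodes, and near the needle rim that
matters: the 90-degree metal corner makes the continuum field singular,
so any "edge" value is really "the field at the free node nearest the
edge" and grows without bound under refinement. The conventions are
fixed and documented rather than hidden:

* `e_center` / `e_tip_axis`: the on-axis free node in the tip plane (the
  centre of the bore opening);
* `e_inner_edge`: the free node nearest `r = D_i/2` in the tip plane
  (19 um inside the wall at the default 100 um spacing);
* `e_near_plate`: the on-axis node one spacing above the plate;
* `e_axis_peak`: the maximum of the on-axis profile — the axis field
  rises for a few hundred micrometres beyond the shielded bore opening
  before decaying towards the plate, so the peak exceeds the tip-plane
  value by roughly 30% and is reported separately.

`refine_and_converge()` re-solves over decreasing spacings and flags
metrics that keep growing: at 100/71/50 um the mid-gap and near-plate
values move by under 1%, the bore-centre value by a few percent, while
`e_inner_edge` grows ~10% per step — the expected corner behaviour,
reported rather than suppressed. Formulation choice dominates even the
grid effect: planar values in the tip region are 3–5 times smaller than
axisymmetric ones on the same mesh, so tip-region comparisons across
implementations are only meaningful with the formulation, boundary
conditions, needle protrusion and sampling offsets pinned down.
Linearity, by contrast, is exact: scaling 15 kV to 10 kV scales every
metric by 2/3 to solver precision, which the tests assert to 0.1%.

The default grid is the study geometry at 100 um spacing (301 × 1116
nodes, about 5 s per solve); the spacing ceiling `D_i/8` guarantees at
least eight nodes across the bore.

## Drop mechanics at the capillary tip

Four order-of-magnitude scales govern drop formation on a meniscus of a
capillary with inner diameter `D_i`, outer diameter `D_o`, flow rate `Q`
and potential `phi`:

| scale | formula | value at 15 kV, 200 uL/min |
|---|---|---|
| electric | `eps0 * phi^2` | 1.99e-3 N |
| surface tension | `D_o * gamma` | 8.89e-5 N |
| gravity | `rho * D_o^3 * g` | 2.01e-5 N |
| flow momentum | `rho * Q^2 / D_i^2` | 1.58e-8 N |

The flow-momentum term is a momentum-flux scale rather than a force on a
specific body; it is reported alongside the forces without claiming a
net balance. The electric-to-surface-tension ratio (22.4 at 15 kV, 10.0
at 10 kV) drives the mode rule in `classify_mode()`: micro-dripping at
ratio ≥ 1, dripping below, with an optional user-set upper threshold for
oscillating micro-dripping (disabled by default — no quantitative upper
boundary is established for this device). The threshold of 1 is the
simplest dimensionally consistent criterion; both study operating points
classify as micro-dripping under it, consistent with the observed
operation, and the threshold is configuration-exposed. In micro-dripping
the droplet diameter falls in `[0.05, 0.85] · D_o` — 63.5 to 1079.5 um
for this nozzle, bracketing the observed 200–300 um droplets.

`exposure_report()` summarises what a cell experiences in transit: mean
exit velocity `Q / (pi (D_i/2)^2)` (6.04 mm/s at 200 uL/min), residence
time in the wetted bore (the wetted length defaults to the needle
protrusion and is override-able, since the true wetted length depends on
the syringe coupling), and the field along the path — its peak sits at
the bore rim in the tip plane, several-fold above the bore-centre value,
which is the quantitative sense in which exiting cells see a strongly
non-uniform field. Fluid properties default to water-like values
(density 1000 kg/m^3, surface tension 0.07 N/m) because the dilute
pullulan/gelatin/media solution is not otherwise characterised; both are
parameters of `fluid_properties()`.

## Image quantification

High-speed frames (512 × 1024 px at 7000 fps; `acquisition_params()`
reproduces the 142.86 us frame interval and 35,000-frame count of a 5 s
recording) are segmented by dark-object thresholding: Otsu's threshold
on the intensity range by default, connected components, border-touching
objects discarded, and a 120 um diameter floor separating droplets from
satellite outliers. Diameters are equivalent-circle diameters
`2 sqrt(A/pi)`.

Spheroid images are calibrated from their 500 um scale bar
(`locate_scale_bar()` finds the longest near-black horizontal run;
`scale_from_bar()` divides). Segmentation adds a morphological closing
(radius 2 px) before labelling. The inclusion rule is the study's area
rule made mechanical: masses of at least 3000 um^2 count
unconditionally; masses in the 2500–3000 um^2 borderline band count only
if round enough, operationalised as circularity `4 pi A / P^2 ≥ 0.4`.
The original criterion for borderline masses is an observer judgement
(cells orienting towards the mass); a circularity floor is a deliberate,
auditable stand-in, every record keeps its raw measurements so the rule
can be re-applied, and the floor is a parameter. Rasterised perimeters
make circularity noisy at small sizes, which is why the floor applies
only in the borderline band.

Degenerate inputs are defined, not errors: a featureless frame yields an
empty detection table; an uncalibrated frame refuses before any pixel
work; a single droplet reports sd 0 with an explicit
`sd_defined = FALSE` flag.

## Assay statistics

`viability_percent()` is the LDH lysate formula
`100 * mean(OD_sample) / mean(OD_control)`; it is invariant to common
rescaling of all ODs. `delta_delta_ct()` normalises to a reference gene
(GAPDH by convention) and a calibrator sample, returning
`2^(-ddCt)`; swapping treated and calibrator inverts the fold change
exactly, and technical replicates are averaged on the Ct scale.
`deg_filter()` reads "|fold change| > 1.5 and p < 0.05" symmetrically on
the ratio scale — up at `FC ≥ 1.5`, down at `FC ≤ 1/1.5` — with the
fold-change boundary inclusive and the p boundary strict (both
documented and tested; the thresholds are parameters).
`go_term_summary()` tallies a term's members by filter outcome; members
absent from the table count as unchanged, with a warning, and the
partition always sums to the term size. Absorbance wavelength (605 vs
650 nm appears inconsistently in assay write-ups) is carried as metadata
and never alters a computation. `group_compare()` is a thin,
deliberately non-novel convenience over `t.test()`, `aov()` and
`TukeyHSD()` with the p ≤ 0.05 significance convention.

## What the synthetic data does and does not show

Generators (`synth_droplet_frames()`, `synth_spheroid_image()`,
`synth_spheroid_study()`, `synth_od_table()`, `synth_ct_table()`,
`synth_deg_table()`) are deterministic under a fixed seed, emit ground
truth beside the data, and default to the study's conditions: droplet
diameters uniform on 200–300 um with optional sub-120 um satellites and
daughter droplets; spheroid areas log-normal with median ≈ 5000 um^2
plus sub-borderline debris, with a geometric per-day growth factor for
time courses; OD tables planting 90% / 70% viability at 10 / 15 kV; Ct
tables planting ACAN 8.7-fold and SOX9 6-fold (4.4 / 3 at 10 kV); DEG
tables planting that marker panel plus the up- and downregulated
collagen sets on a null background (log-normal fold changes, uniform
null p-values, effect p-values below threshold with configurable power),
including a 20-gene chondrocyte-development ontology term that tallies
17 up / 3 down. Noise models are the simplest adequate ones — Gaussian
pixel noise on constant backgrounds, Gaussian noise on log fold changes
— chosen because nothing richer is specified for these assays.

Passing round-trip tests therefore demonstrates that the quantification
rules are implemented correctly and recover planted parameters under
controlled imaging conditions. They do not demonstrate robustness to
uneven illumination, focus drift, overlapping or aggregating objects,
meniscus artefacts, or count-level RNA-seq noise: real brightfield and
high-speed material is harder than these renders, and the biological
effect sizes are inputs to the generators, not findings.

## Problem sizes and reproducibility

The shipped tests solve the full device twice at 100 um spacing and run
the refinement audit at 100/71/50 um (0.34–1.3 M nodes, the largest
solve ~30 s); image tests use 512 px frames. `scripts/acceptance.R`
re-solves the device at both potentials on the default grid and reports
the tip-region metrics; `run_paper_pipeline()` writes every artifact
(maps, profiles, reports, synthetic demonstrations) with a JSON manifest
so a run is reproducible from its config and seed alone.

## Known limitations

* No space charge, droplet charging, meniscus/Taylor-cone shape, or
  coupled fluid dynamics: the field model is electrostatic with bare
  electrodes, and the mode rule is a scale argument, not a stability
  analysis.
* Corner-adjacent field samples are mesh-registered by nature; compare
  them only under identical formulation, mesh and sampling conventions.
* The spheroid borderline rule replaces an observer judgement with a
  circularity floor; on real images the two can disagree.
* The synthetic image model renders idealised scenes; segmentation
  parameters tuned here should be re-validated on real material.
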