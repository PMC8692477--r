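# espray

Electrospraying delivers living cells in a polymer solution by ejecting
charged microdroplets from a high-voltage capillary, and the combination
of electric field and shear it applies can itself steer stem-cell
differentiation. `espray` is an R package for the quantitative side of
such experiments: it models the needle–plate device, classifies the
spraying regime, and implements the downstream quantification —
high-speed droplet sizing, spheroid area measurement, LDH viability,
ΔΔCt expression, and differential-expression filtering — with
synthetic-data generators standing in for every wet-lab input so the
whole pipeline is testable end to end.

It is aimed at biofabrication and bioprocess groups who need the
device-side physics and the assay-side statistics in one auditable,
scripted workflow.

## Models at the core

**Electrostatics.** The potential in the charge-free gap obeys
Laplace's equation, ∇²φ = 0 (a per-node charge density switches this to
Poisson's equation, ∇²φ = −ρ/ε₀), with Dirichlet conditions φ = V on
the needle and φ = 0 on the plate. `espray` discretises the device
cross-section with a uniform finite-volume five-point scheme — the
cylindrical Laplacian with the r = 0 regularity condition in the default
axisymmetric mode, a full Cartesian section in planar mode — and solves
the sparse symmetric system directly (red–black SOR is available as an
independent path). The field is E = −∇φ by central differences,
one-sided next to conductors. Tip-region metrics (bore-centre field,
inner-edge field, on-axis peak, near-plate field) are sampled at
documented grid nodes, and a refinement audit reports which of them are
mesh-registered (the metal corner is singular in the continuum limit).

**Drop mechanics.** Four scales govern drop formation on the meniscus:
electric F_e ~ ε₀φ², surface tension F_γ ~ D₀γ, gravity F_g ~ ρD₀³g,
and injected flow momentum Ṗ ~ ρQ²/D_i². The ratio F_e/F_γ classifies
the regime (micro-dripping at ratio ≥ 1), and in micro-dripping the
droplet diameter lies in [0.05, 0.85]·D₀.

**Quantification.** Otsu thresholding + connected components size dark
droplets (equivalent diameter 2√(A/π), 120 µm floor) and segment
brightfield spheroids calibrated from their 500 µm scale bar, with the
area rule: ≥ 3000 µm² counts, 2500–3000 µm² counts only at circularity
4πA/P² ≥ 0.4. Viability% = 100 · mean(OD_sample)/mean(OD_control);
fold change = 2^(−ΔΔCt) against a reference gene and calibrator; DEGs
are |FC| > 1.5 with p < 0.05, tallied per gene-ontology term.

## Worked example

```r
library(espray)

grid  <- build_grid(device_geometry(), operating_potential(15e3),
                    spacing = 100e-6)
field <- compute_field(solve_poisson(grid))
tip_field_report(field)
#> <espray tip field report> 15 kV applied, axisymmetric grid, h = 100 um
#>   bore centre (tip plane)     : 2.434 MV/m
#>   inner edge (r = 400 um)    : 3.492 MV/m
#>   edge / centre ratio         : 1.43
#>   on-axis peak (z = 0.30 mm)  : 3.155 MV/m
#>   near plate                  : 125.4 kV/m
```

The field a cell meets at the bore opening is megavolt-per-metre scale
and strongly non-uniform: ~43% higher at the bore's inner edge than at
its centre on this grid, decaying four-fold within the first millimetres
of the gap and to ~125 kV/m at the plate. Because the problem is linear,
re-solving at 10 kV scales every metric by exactly 2/3:

```r
grid10 <- build_grid(device_geometry(), operating_potential(10e3),
                     spacing = 100e-6)
scale_linearity_check(tip_field_report(field),
                      tip_field_report(compute_field(solve_poisson(grid10))))
#>         metric   value_a    value_b predicted_pct measured_pct   ok
#> 1   e_tip_axis 2433844.0 1622562.70      33.33333     33.33333 TRUE
#> 2     e_center 2433844.0 1622562.70      33.33333     33.33333 TRUE
#> 3 e_inner_edge 3492039.7 2328026.48      33.33333     33.33333 TRUE
#> ...
```

The force-scale analysis explains the observed operating regime:

```r
classify_mode(force_scales(fluid_properties(), operating_conditions(15e3)))
#> <espray mode> micro-dripping (electric/surface-tension force ratio = 22.4 >= threshold 1)
#>   droplet diameter bounds: 63.5 - 1079.5 um
```

The electric force outweighs surface tension 22-fold at 15 kV (10-fold
at 10 kV), so the device operates in micro-dripping, and the predicted
63.5–1079.5 µm diameter window brackets droplets that a synthetic
high-speed stack confirms by measurement:

```r
gen <- synth_droplet_frames(seed = 42)
det <- do.call(rbind, lapply(seq_along(gen$frames), function(i)
  detect_droplets(gen$frames[[i]], frame_index = i)))
droplet_diameter_stats(det)
#>    n     mean       sd      min      max polydispersity sd_defined
#> 1 60 256.2629 28.85246 201.8001 297.7553      0.1125893       TRUE
```

The whole computational study — both voltage solves, profiles, maps,
EHD reports and seeded quantification demonstrations with ground truth
— runs from configuration alone and writes a JSON manifest:

```r
run_paper_pipeline(espray_default_config(), out_dir = "espray-out")
```

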