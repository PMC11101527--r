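# dermafiber

Quantitative analysis of 3D dermal fiber microstructure and its relation to
uniaxial stretch mechanics.

Human dermis owes its J-shaped tensile response to a network of collagen and
elastin fibers. Multiphoton microscopy (SHG for collagen, TPEF
autofluorescence for elastin) images this network in 3D; tensile testing of
the same specimens yields stress–strain curves. `dermafiber` implements the
full quantitative chain between the two, for imaging/biomechanics groups who
want per-sample structural descriptors, curve characteristics, and
cohort-level dependence screens from calibrated z-stacks and tensile logs —
plus a synthetic-data generator so every stage can be validated against known
ground truth.

## What it computes

**3D fiber orientation.** Per voxel above an intensity threshold, an
11×11×11 window is max-intensity projected onto the *xy*, *xz*, *yz* planes.
In each projection, candidate directions *d* ∈ {1°,…,180°} through the
center are scored by *w(d) = L(d) · max(0, 1 − CV(d))* (chord length times
one minus the coefficient of variation of intensity along the
above-threshold run), and the projection angle is the doubled-angle weighted
vector sum ½·atan2(Σw sin2d, Σw cos2d). The in-plane angle θ comes from the
*xy* projection; the polar angle φ from the *xz*/*yz* angles β, γ via
tan²φ = 1/tan²β + 1/tan²γ (φ = 90° is in-plane).

**Directional statistics.** With b = |tan φ|, the axial center of mass is

  C̄ = ⟨ b/√(1+b²) · cos 2θ ⟩,  S̄ = ⟨ b/√(1+b²) · sin 2θ ⟩,
  Z̄ = ⟨ SI/√(1+b²) ⟩,  SI = sign(90° − φ) (and +1 at φ = 90°),

and the **3D orientation index** (3DOI) is the mean resultant length
√(C̄² + S̄² + Z̄²) ∈ [0, 1]: 0 for disordered, 1 for perfectly aligned
fibers. The main in-plane angle ½·atan2(S̄, C̄) is also reported folded into
[0°, 90°] (angle to the stretch axis).

**Angle distribution model.** The aggregate θ histogram is fit by a
two-family axial von Mises mixture

  ρ(θ) = b + w·exp{a₁cos 2(θ−α₁)}/(π I₀(a₁)) + (1−w)·exp{a₂cos 2(θ−α₂)}/(π I₀(a₂)),

by bounded least squares with multi-start initialization; `vm_sample()`
draws from it, `vm_density()` evaluates it.

**Fiber density.** Volume fraction above 0.45× the stack mean intensity
(`binary_mask()`, `fiber_density()`).

**Mechanics.** ε = ΔL/L₀ and nominal stress σ = F/(w₀·e₀) (MPa) from tensile
logs; toe/heel/linear segmentation (toe ends at 5% of σ_max; the linear
region is the widest locally linear run, moving-window R² ≥ 0.99, containing
the steepest point); characteristics E₁ (toe modulus), E₂ (linear modulus),
σ_max, ε_max, and ε_mid (strain at 50% σ_max). `upper_envelope()` recovers
the loading curve from stepwise-stretch records with relaxation drops.

**Dependence screening.** Distance correlation (V-statistic) between all
feature pairs with permutation p-values (2000 resamples by default),
complete-case filtering, and one-way ANOVA + Tukey HSD of 3DOI across
stress regions.

## Worked example

Recover two-family mixture parameters from 50,000 sampled angles
(w = 0.57, α₁ = 31.83°, a₁ = 0.51, α₂ = 135.35°, a₂ = 1.94):

```r
library(dermafiber)
truth <- vm_mixture(w = 0.57, alpha1 = 31.83, a1 = 0.51,
                    alpha2 = 135.35, a2 = 1.94)
th <- vm_sample(truth, 5e4, seed = 7)
bins <- ceiling(th); bins[bins == 0] <- 180
vm_fit(tabulate(bins, 180) / 5e4)
#> vm_fit (RSS 7.535e-02):
#>   vm_mixture: w = 0.558 | family 1: alpha = 32.51 deg, a = 0.525 |
#>               family 2: alpha = 135.69 deg, a = 1.872 | b = 0.0000
```

Both mean angles land within 1° of the generating values and the
concentrations within ~10%.

Run the full per-sample pipeline on synthetic data:

```r
ph <- gen_fiber_stack(fiber_phantom_spec(shape = c(24L, 96L, 96L),
                                         target_fill = 0.4, seed = 42))
gs <- gen_stress_strain(curve_spec(seed = 42))
entry <- list(sample_id = "SYN1", collagen = ph$stack,
              tensile = data.frame(displacement_mm = gs$curve$strain * 40,
                                   force_N = gs$curve$stress * 16),
              age = 80, thickness_collagen = 50)
res <- run_sample(entry, clip = FALSE)
res$features[, c("sample_id", "age", "E1", "E2", "sigma_max", "eps_mid",
                 "D_CO", "OI3D_CO", "main_theta_CO")]
#>   sample_id age    E1   E2 sigma_max eps_mid  D_CO OI3D_CO main_theta_CO
#> 1      SYN1  80 0.389 25.7      4.01   0.324 0.404   0.124            58
```

The density (0.404) matches the phantom's 0.4 fill; E₂, σ_max and ε_mid
come from the generated J-curve; the low 3DOI (0.12) reflects the
two-family, near-symmetric angle structure of the default phantom.

Screen a cohort for dependencies (one planted link, age → E₂):

```r
coh <- gen_cohort(24, dependency_spec = list(
  list(target = "E2", source = "age",
       link = function(a) 60 - 0.55 * a, noise_sd = 1.5)),
  missingness = TRUE, seed = 61)
out <- run_cohort(coh$table, n_resamples = 2000, seed = 9,
                  features = c("age", "E1", "E2", "sigma_max", "D_CO",
                               "OI3D_CO", "T_EL"))
out$n_complete
#> [1] 19
head(out$dependencies[order(out$dependencies$p_value), ], 2)
#>   feature_x feature_y   dc p_value n_used significant
#> 2       age        E2 0.95  0.0005     19        TRUE
#> 14       E2   OI3D_CO 0.54  0.0375     19        TRUE
```

The planted link is recovered at p = 1/2001; complete-case filtering of the
24-row table with the standard missingness pattern (3 missing E₁, 2 missing
the elastin block) keeps 19 rows.

## Package layout

| Area | Functions |
| --- | --- |
| Stack IO & calibration | `read_stack`, `write_stack`, `clip_fov`, `apply_depth_correction`, `clahe_enhance` |
| Orientation | `estimate_orientation`, `directional_summary`, `layer_histograms`, `polar_from_projections`, `fold_angle` |
| Mixture model | `vm_mixture`, `vm_density`, `vm_sample`, `vm_fit` |
| Density | `binary_mask`, `fiber_density` |
| Mechanics | `build_curve`, `segment_regions`, `extract_characteristics`, `upper_envelope`, `midpoint_group` |
| Dependence | `distance_correlation`, `dc_test`, `pairwise_dependencies`, `complete_cases`, `region_comparison` |
| Synthesis | `gen_fiber_stack`, `gen_stress_strain`, `gen_cohort` |
| Orchestration | `run_sample`, `run_cohort` |

The methods vignette (`vignettes/dermafiber-methods.Rmd`) documents the
model choices, defaults, and limitations in detail.
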