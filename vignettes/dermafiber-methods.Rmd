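---
title: "Methods: 3D fiber orientation, mixture modeling, and stretch mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D fiber orientation, mixture modeling, and stretch mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermafiber)
```

`dermafiber` links the 3D microstructure of dermal collagen/elastin
networks, imaged as two-channel multiphoton z-stacks, to the
characteristics of uniaxial tensile stress–strain curves. This vignette is
the package's account of its methods: the models, the defaults and their
units, the numerical choices, and what the validation on synthetic data
does and does not establish.

## Imaging geometry and calibration

Stacks are stored `(z, y, x)` with x the stretch axis; θ is measured from
+x in the imaging plane. The default acquisition geometry is a 500×500 µm
field of view at 0.5 µm/pixel laterally, centrally cropped to 400×400 µm
(`clip_fov()`) to discard the dark frame at the scan edges; for
odd-parity margins the crop offset is the floor of the margin. Because the
immersion oil (n₁ = 1.518) and tissue (n₂ = 1.37) refractive indices
differ, the actual focal displacement is half the apparent one; the
correction is stored as an explicit factor of 0.5 (`apply_depth_correction()`)
rather than recomputed from the indices, which are retained as metadata.
After correction the axial sampling is 0.5 µm/pixel, i.e. voxels are
isotropic, and the orientation estimator assumes they are (anisotropic
stacks should be resampled first).

Contrast enhancement (`clahe_enhance()`) is contrast-limited adaptive
histogram equalization applied per z-plane — volumes are enhanced as 2D
images, 3D CLAHE is not attempted. Defaults: 64-pixel tiles, clip limit
0.01 (fraction of the tile histogram). Neither value is prescribed by any
measurement; both are exposed. Enhancement equalizes local contrast, so it
helps *visibility* of dim structures (deep planes whose intensities occupy
a sliver of the stack range) but distorts mean-relative quantities:
fiber density therefore defaults to raw intensities, with an
`enhanced = TRUE` switch.

## Voxelwise 3D orientation by weighted vector summation

For every voxel brighter than 0.45× the stack mean whose 11×11×11 window
fits inside the volume, the window is max-intensity projected onto the
*xy*, *xz* and *yz* planes (MIP preserves the bright fiber chord against
dark background). In each projection, for candidate directions
*d* ∈ {1°,…,180°} through the window center, intensity is sampled along the
chord in 0.5-pixel steps (nearest neighbor, duplicates dropped) and the
direction is scored

&nbsp;&nbsp;*w(d) = L(d) · max(0, 1 − CV(d))*,

where *L(d)* is the length of the contiguous above-threshold run through
the center and *CV(d)* the coefficient of variation of intensity along
that run: long, uniformly bright chords are fiber-like; short or flickering
ones are not. The per-projection angle is the doubled-angle weighted vector
sum ½·atan2(Σw sin 2d, Σw cos 2d) — the axial-data analogue of a weighted
mean direction, far more noise-robust than an argmax over *d*. The weight
functional is the package's canonical choice for "weighted by length and
intensity fluctuation" and is deliberately simple; it is a pluggable
internal should alternatives be explored.

The *xy* angle is θ. The *xz* and *yz* angles β, γ determine the polar
angle by tan²φ = 1/tan²β + 1/tan²γ, with the limits: either projection
flat → φ = 90° (in-plane); both vertical → φ = 0° (along z). This formula
yields only the magnitude of the out-of-plane tilt (φ ≤ 90°). The sign is
recovered from which side the projections lean: taking the axial
representative with u_y ≥ 0, γ < 90° means the fiber climbs in +z and
γ > 90° that it descends (β plays this role, with the sign of cos θ, when
the fiber runs near the x axis, where the *yz* projection degenerates).
Downward tilts are reported as φ > 90°. Without the sign, the z-term of
the directional mean (below) could never cancel between opposite tilts,
and disordered volumes would show a spurious alignment floor of ≈ 0.5
instead of ≈ 0.

Border voxels (no full window), sub-threshold voxels, and degenerate
windows in which every direction has zero weight are invalid; no padding
is used, since padding would fabricate structure. All angle arithmetic is
degrees at the interface, radians internally.

## Directional statistics and the 3D orientation index

With b = |tan φ| the axial center of mass over valid voxels is

$$\bar C = \frac1n \sum_j \frac{b_j}{\sqrt{1+b_j^2}}\cos 2\theta_j,\qquad
  \bar S = \frac1n \sum_j \frac{b_j}{\sqrt{1+b_j^2}}\sin 2\theta_j,\qquad
  \bar Z = \frac1n \sum_j \frac{SI_j}{\sqrt{1+b_j^2}},$$

with SI = sign(90° − φ) and +1 at φ = 90°. Equivalently the summands are
(|sin φ| cos 2θ, |sin φ| sin 2θ, cos φ); the implementation follows the
b-form literally (with the φ = 90° limit handled exactly) and the test
suite checks it term-by-term against an independent evaluation. The 3D
orientation index is the mean resultant length √(C̄²+S̄²+Z̄²): 1 iff all
axial orientations coincide, ~0 for disordered fields, invariant to voxel
ordering and duplication, and equivariant under in-plane rotation. The
main angle ½·atan2(S̄, C̄) is reported both raw ([0°,180°)) and folded to
[0°,90°] (the angle to the stretch axis, `fold_angle()`).

Whether sub-threshold voxels should enter these sums is ambiguous in
principle ("all pixels" vs "fiber pixels"); the package sums over valid
(above-threshold) voxels only, which makes the index a property of the
fiber network rather than of the background fraction. The same 0.45×mean
threshold defines the density mask and the orientation validity mask, for
internal consistency.

Per-layer θ histograms (`layer_histograms()`) use 180 one-degree bins over
(0°,180°] (an angle of exactly 0 is axially identical to 180 and counted
there), each layer normalized to unit mass; layers without valid voxels
yield zero rows and are flagged. Stored layer order follows acquisition
order (z index 1 = first/deepest plane); display order is a plotting
concern.

## The two-family axial von Mises mixture

The aggregate θ distribution is modeled as

$$\rho(\theta) = b + w\,\frac{e^{a_1\cos 2(\theta-\alpha_1)}}{\pi I_0(a_1)}
 + (1-w)\,\frac{e^{a_2\cos 2(\theta-\alpha_2)}}{\pi I_0(a_2)},$$

π-periodic through the doubled angle, normalized over [0,π) when b = 0.
Density units are probability per radian, so the histogram (per-degree
frequencies) is converted by the bin width π/180 before fitting. The
exponentially scaled Bessel function keeps the kernel finite up to the
concentration bound a ≤ 100 (values at the bound are flagged).

Fitting is least squares on the binned density — the natural objective
when the data is a normalized histogram — with box constraints
(b, w ∈ [0,1], a ∈ [0,100]) and multi-start initialization: the two
highest circularly smoothed histogram peaks, their swapped assignment, and
concentration variants; mean angles are unconstrained during optimization
and wrapped afterwards, avoiding boundary sticking at 0°/180°. Families
are reported ordered α₁ ≤ α₂. Maximum likelihood on raw angles is not the
canonical path because the pipeline's input is the histogram. A fit is
flagged *degenerate* when the second family collapses (w outside
[0.02, 0.98], mean angles closer than 3°, or a concentration at the
bound) — single-family data produces exactly this signature, and such
parameters should be read as one-family fits.

Sampling (`vm_sample()`) requires b = 0, draws the family per
Bernoulli(w), then an axial draw: 2θ from a circular von Mises
(Best–Fisher rejection sampling), halved and wrapped into (0°,180°].
Noise-free density curves are recovered to 10⁻³; from 5·10⁴ sampled
angles, mean angles are typically recovered within 2° and concentrations
within 15%.

## Fiber density

`binary_mask()` thresholds at 0.45× the stack mean; `fiber_density()` is
the fraction of voxels above threshold. The comparison is strict (>),
except that a constant stack — where every voxel equals the mean — is
taken as all-fiber (≥), the sensible limit for a uniformly bright volume.
Density is invariant to uniform intensity rescaling (the threshold scales
with the mean) and is computed on whatever stack is supplied; the field-of-
view crop happens upstream. Whether to threshold raw or CLAHE-enhanced
intensities is a genuine choice; raw is the default because equalization
changes the mean that anchors the threshold.

## Stress–strain parameterization

`build_curve()` applies ε = ΔL/L₀ and σ = F/(w₀·e₀) (mm and N give MPa
directly; defaults L₀ = 40, w₀ = 20, e₀ = 0.8 mm), after a light moving
average on force (window 1% of the record, min 3 points). Only nominal
(engineering) quantities are used.

Segmentation (`segment_regions()`): the toe region ends where σ first
exceeds 5% of σ_max; the linear region is the widest contiguous run of
*locally linear* points — moving-window straight-line fit (half-width 2.5%
of the record) with R² ≥ 0.99 — containing the steepest locally linear
point; the heel is in between. The pointwise criterion is deliberate:
judging a candidate window by a single global R² lets it swallow the heel
and toe, because the steep branch dominates the total variance (numerical
experiments put the resulting E₂ bias at 6–12%); the pointwise rule keeps
the sharp-transition limit exact. Both thresholds (R² 0.99, toe 5%) are
arguments. The characteristics are E₁ (least-squares slope over the toe),
E₂ (slope over the linear region), σ_max, ε_max, and ε_mid (first linear
interpolated crossing of 0.5·σ_max; non-monotone crossings are flagged).

Two limitations are worth stating. First, the 5%-of-σ_max toe rule
presumes the toe stress plateau reaches 5% of σ_max before the heel; for
very compliant toes (E₁ ~ 0.1 MPa against σ_max ~ 4 MPa) it does not, the
nominal toe extends into the heel rise, and E₁ is upward-biased — such
fits should be read as an upper bound on E₁. Second, E₂ equals the
nominal linear modulus only if the curve actually attains its linear
regime within the record.

Stepwise-loading records (imaging pauses with stress relaxation) are
parameterized after `upper_envelope()` — the running maximum of stress
over strain — which recovers the loading envelope; continuous curves
bypass it. Midpoint-strain grouping (`midpoint_group()`) splits cohorts at
ε_mid = 0.27 into low (< 0.27) and high (≥ 0.27) groups.

## Dependence screening

`distance_correlation()` is the V-statistic estimator: double-centered
Euclidean distance matrices, dCov² the mean elementwise product,
normalized by the distance variances; 0 is returned (with a warning) for
constant inputs. The bias-corrected U-statistic variant is available
(`unbiased = TRUE`). The test (`dc_test()`) resamples by randomly
permuting the labels of one variable — the canonical independence null;
because double-centering commutes with relabeling, each permutation is a
re-indexing of the centered matrix, making 2000 resamples cheap. A
with-replacement bootstrap variant exists behind `method = "bootstrap"`
for users who prefer that convention. The p-value is
(1 + #{dc_perm ≥ dc_obs})/(1 + B), exact on the grid {1/(B+1), …}.

`pairwise_dependencies()` screens all feature pairs on complete cases at a
raw α = 0.05 per pair, with no multiple-testing correction by default —
the cohort-screening convention this mirrors — and a Benjamini–Hochberg
option off by default. `complete_cases()` drops rows with any missing
value among the requested features: with ~20 samples, imputation is
riskier than dropping. `region_comparison()` is one-way ANOVA with Tukey
HSD and conventional stars; 0.05 is the significance threshold throughout.

## Synthetic data: what it emulates and what it does not

`gen_fiber_stack()` rasterizes straight cylinders whose in-plane angles
follow a prescribed two-family mixture and whose polar angles follow an
axial von Mises concentrated at 90° (imaging volumes are thin, so fibers
lie nearly in-plane), with uniform anchors, maximum-intensity overlap
(SHG-like brightness, no additivity), additive Gaussian noise, and
iteration-capped fill control. Defaults: 45°/135° families, fill 0.4,
radius 2 px, fiber/background 200/10, noise SD 5. Crimp (waviness) is
deliberately absent: orientation estimation is local, so straight segments
validate it; a crimped-fiber option would test tortuosity metrics this
package does not compute.

`gen_stress_strain()` integrates a logistic stiffness switch:
E(ε) = E₁ + (E₂−E₁)·logistic((ε−c)/w), giving
σ(ε) = E₁ε + (E₂−E₁)·w·[softplus((ε−c)/w) − softplus(−c/w)] — monotone,
slope between E₁ and E₂ everywhere, and exactly the piecewise-linear sharp
J-curve as w → 0. (The superficially simpler form E₁ε + (E₂−E₁)·W(ε)·(ε−c)
dips negative before the heel, because the logistic tail multiplies a
negative strain offset; it was rejected for that reason.) When a target
σ_max is given the curve is rescaled so σ(ε_max) = σ_max, which rescales
the effective moduli; the returned nominal characteristics are computed
analytically from the *scaled* noiseless curve (ε_mid by root finding), so
recovery comparisons are self-consistent. Default heel width 0.015 strain:
narrow enough that the tangent modulus attains E₂ (within ~1%) over the
final quarter of the record, matching the visually linear terminal branch
of measured curves; with much wider heels the nominal E₂ is never realized
inside the record and "recovery" is ill-posed. Defaults E₁ = 0.1,
E₂ = 20 MPa, σ_max = 4 MPa, ε_max = 0.4 match cohort-scale averages for
human thigh dermis.

`gen_cohort()` draws the per-sample feature table from realistic marginals
(ages 61–95, densities 0.3–0.7 collagen / 0.002–0.45 elastin, 3DOI
0.06–0.25, moduli log-normal around the cohort means), overwrites targets
of planted links with link(source) + noise after an acyclicity check, and
optionally blanks 3 E₁ cells and 2 disjoint elastin blocks so that
complete-case filtering of 24 rows keeps 19 — the standard cohort
missingness pattern.

What passing tests on these phantoms shows: the estimator recovers known
orientation structure, fill fractions, curve characteristics and planted
dependencies under controlled conditions. What it does not show: real
tissue adds crimp, fiber-diameter dispersion, depth-dependent attenuation
and scattering, PSF anisotropy, and polarization-dependent SHG contrast —
none of which the phantoms model. One practical consequence observed on
phantoms carries over to real data: window-based estimation blurs the
angle histogram relative to the true fiber-axis distribution, so fitted
mixture concentrations are attenuated (means are recovered well; a-values
are lower bounds). Cohort-level conclusions should rest on the directional
summaries and the dependence screen, not on absolute concentration values.

## Numerical choices and degenerate inputs

* Chord sampling uses 0.5-px steps with nearest-neighbor lookup and
  duplicate removal; chord length is the geometric end-to-end distance +1.
* tan(90°) is treated by its limit everywhere (`tanpi` conventions);
  φ = 90° contributes exactly (cos 2θ, sin 2θ, 0) to the directional sums.
* The orientation core is compiled (Rcpp); a 24×96×96 stack at 30% fill
  takes a few seconds, and cost scales linearly in valid voxels.
* All-zero stacks yield an empty orientation field (warning) and an empty
  mask (warning); flat stress curves and sub-4-point dependence inputs are
  errors; single-point linear windows cannot occur (the window anchor is
  restricted to locally linear points).
* Problem sizes in the test suite (phantoms ≤ 24×96×96, 5·10⁴ mixture
  samples, 500×200 permutation calibration) were chosen as the smallest
  sizes at which the asserted tolerances are comfortably stable.
* Every stochastic routine takes an explicit seed; generators are
  deterministic given their spec.

## Known limitations

Beyond the phantom/real-data gap and the toe-rule bias noted above: the
estimator assigns one orientation per voxel, so crossing fibers within a
window blend; mixtures with more than two families, wrapped-Cauchy or
Bingham alternatives, and joint (θ, φ) spherical distributions are out of
scope; no constitutive (Fung/Ogden-type) modeling is attempted — the
descriptors are empirical curve characteristics; and registration across
stretch steps is not provided (successive stacks image overlapping but not
identical regions, so per-step comparisons are distributional, not
voxelwise).
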