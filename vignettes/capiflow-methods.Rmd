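---
title: "Methods: tracer-based angiography and flattened-vessel hemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracer-based angiography and flattened-vessel hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(capiflow)
```

This vignette is the package's account of its science and of the numerical
choices behind it: the synthetic movie model, each pipeline stage, the
profilometry estimators, the two hemodynamic solvers, and the places where a
design was genuinely open and a choice had to be made.

## 1. The imaging principle

In a transmission movie of thin perfused tissue, erythrocytes are dark,
moving absorbers on a bright, nearly static field. Two Z-projections of a
*registered* stack carry complementary information:

* **Minima.** `M(p) = min_t I_t(p)` keeps the darkest value ever observed at
  each pixel. Any pixel a red cell ever crossed is dark in `M`: the minima
  image is the lumen map of every perfused vessel, with no contrast agent.
* **Average.** `A(p) = mean_t I_t(p)` is monotone in mean tracer occupancy:
  a qualitative flux map (with the caveat that a stalled cell also darkens
  it).

Both fail without preprocessing, for four reasons the pipeline addresses in
order: the tissue moves (registration), half the frames are defocused by the
cardiac oscillation (blur rejection), cameras occasionally emit an aberrant
frame (outlier rejection), and — least obvious — registration itself locks
onto the coherently flowing erythrocytes and drifts with the flow
(decorrelation shuffle).

## 2. The synthetic movie generator

Every downstream stage is validated against movies with known ground truth,
so the generator is first-class code, not a test fixture.

**Scene.** A `vessel_network()` is a set of centerline polylines with lumen
radius, flattening factor `f ∈ [0, 1]` and mean tracer speed. Flattening
follows the constant-perimeter circle→stadium family (Section 5): the lumen
of diameter `D` at flattening `f` has gap `h = D(1 − 0.75 f)`, so `f = 1`
gives the fully flattened gap `D/4` and apparent width 1.43 `D`. The lumen
band ends flush at segment endpoints — only the centerline span is perfused,
so the ground-truth mask is exactly the region tracers can paint (a
straight segment's mask area is length × 2 radius).

**Tracers.** Cells advect along the centerline at the segment speed scaled
by `1 − 0.8 f` (flattened tips carry visibly less flux). Lateral position is
drawn with probability proportional to the local cross-section chord — cells
fill the lumen uniformly in 3D, and the 2D projection weights lateral offset
by optical path length. This is what makes the minima image obey the
chord law (Section 4). Each cell carries a lognormal speed factor
(σ = 0.12, resampled when it recirculates): real erythrocyte trains
disperse, and without dispersion the tracer pattern would translate rigidly
forever and *any* registration could lock onto it. The factor is
deliberately independent of lateral position: a transverse velocity profile
would make slow near-wall cells over-occupy the lumen edges and bias the
chord-law occupancy.

**Rendering.** Multiplicative (Beer–Lambert) absorption: a cell multiplies
the background by `1 − contrast` over an anti-aliased disc, so `n` stacked
cells transmit `(1 − c)^n` — overlapping tracers darken sub-linearly as in
transmission. The background is bright and *quasi*-uniform: a weak planar
gradient plus a static smooth texture (amplitude 5%, correlation ~2.5 px)
standing in for tissue granularity, plus a faint static attenuation of the
cell-free lumen (optical depth 0.1 at the thickest point) standing in for
plasma and wall. The texture matters: it is the static structure real
registration anchors to.

**Disturbances** (`motion_model()`): sinusoidal rigid jitter (default
amplitude 4 px, period 20 frames — a heartbeat at video rate; y component at
half amplitude, fixed phase offset), linear drift (0.02, 0.01) px/frame,
Gaussian defocus (σ = 2.5 px) on exactly `round(0.5 N)` frames at seeded
random positions, aberrant near-saturated frames at rate 0.005, additive
noise (σ = 0.005). Transforms are applied analytically — tracers are
stamped at shifted positions and the background evaluated in shifted
coordinates — so the per-frame ground-truth transform is exact, with no
interpolation error. The blur schedule holds the defocused fraction exactly
at its nominal value rather than drawing it i.i.d. per frame; an optical
configuration that is out of focus half the time defocuses half the frames
of any sufficiently long acquisition, and the fixed count makes "keeps
exactly 50%" a well-defined property of every seed.

**What it does not emulate.** No cell deformation, no hematocrit
segregation, no pulsatile velocity modulation, no non-rigid tissue motion,
no depth structure (a 2D scene with implied depth statistics). Tests passing
on these movies validate the *algorithms* under the stated disturbance
model; they do not certify performance on tissue whose motion is strongly
non-rigid.

## 3. Stack processing

**Decorrelation shuffle.** `shuffle_decorrelate()` reorders slots as
`1, H+1, 2, H+2, ...` with `H = ceiling(N/2)` (odd `N`: the first half is
the larger). Adjacent output frames are ≥ `H − 1` acquisition steps apart —
beyond the tracer decorrelation time — so consecutive frames show
independent cell configurations. The permutation is recorded and inverted by
`unshuffle()` at any later stage; frames discarded in between are simply
skipped, bookkeeping being by acquisition index throughout.

**Blur rejection** (`filter_blurred()`). Two criteria. The operator
criterion ranks frames by mean gray level in a small ROI over a crisp dark
feature: defocus diffuses light into it, so darker = sharper. The feature
must be smaller than the defocus kernel — a narrow capillary, a chimney
spot; the center of a wide saturated vessel is blur-invariant (convolution
preserves local means) and useless. The automatic criterion, default for
headless runs, ranks by mean squared gradient. The sharpest
`ceiling(keep_fraction · N)` frames are kept in order; `keep_fraction`
defaults to 0.5 to match the half-time-in-focus oscillation.

**Aberrant rejection** (`discard_aberrant()`). Normalized cross-correlation
with a reference frame; frames below 0.2 are dropped (a saturated glitch
frame correlates near 0, jittered-but-normal frames near 0.9). The
threshold is deliberately permissive — this stage removes gross outliers,
not marginal frames.

**Registration** (`register_stack()`). Translation (default) or translation
plus small-angle rotation search, estimated by windowed FFT correlation with
the integer peak refined on a 0.05 px grid by a local matrix DFT (an
upsampled evaluation of the band-limited correlation surface; a three-point
parabola is biased on broad peaks). Two normalizations are available:
plain cross-correlation (default) weights spectral components by energy and
stays anchored to the static scene; classic phase correlation (whitened
spectrum) is sharper on rigid feature-rich scenes but weights all
frequencies equally and can lock onto coherent tracer texture — measurably
worse on tracer movies, which is why it is not the default despite being
the textbook choice.

With a fixed reference (default), estimation is iterative: frames are
matched to the reference frame, then re-matched against the mean of the
aligned stack. Averaging washes the moving tracers out of the template, so
tracer texture in an individual frame acts as uncorrelated noise and cannot
bias the estimate; two passes reach ~0.2 px median, ~0.5 px worst-case
error on the synthetic benchmark. A `reference = "previous"` mode registers
each frame to its predecessor and accumulates — the behavior of
consecutive-frame plugin registration. In that mode each pairwise estimate
is biased the same way by the flow and the errors *add*: the unshuffled
stack drifts visibly (vessel-mask Dice drops from ~0.65 to ~0.45 on the
benchmark), while the shuffled stack does not. That contrast is the reason
the shuffle exists, and the package tests it explicitly.

Aligned frames are resampled bilinearly; pixels drawn from outside the
frame are filled with the frame median and *marked invalid*, and
projections skip invalid pixels — otherwise every border pixel's minima
would be the fill value. Featureless (zero-variance) frames fall back to
the identity transform and are flagged `low_confidence`.

**Projection and background.** `project()` computes minima or average over
valid contributions, recording per-pixel counts. `flatten_background()`
estimates the illumination as the grayscale closing with a disc much larger
than any vessel (the upper envelope: dark features narrower than the disc
vanish, smooth illumination is followed exactly) and subtracts it,
re-centered — the dark-on-bright equivalent of rolling-ball subtraction. It
is idempotent to within interpolation noise and reduces a planar gradient
by far more than the required tenfold.

`run_pipeline()` chains the stages in the canonical order — shuffle,
blur filter, aberrant filter, register, unshuffle, project, flatten — and
emits a manifest with per-stage frame counts and 16-bit-quantized image
checksums, so a saved configuration re-runs to identical outputs.

## 4. Absorption profilometry

If a long movie fills every lumen column completely at least once, the
minima image's optical density approximates the optical path length through
the vessel: `OD(x) = −log(I/I0) ∝` chord`(x)`. A cylinder of radius `R`
gives `OD ∝ 2√(R² − x²)`; a flattened (stadium) lumen gives a flat top with
cap roll-offs. Mean erythrocyte *flux* cannot be used for this — hematocrit
segregation concentrates cells unevenly — which is exactly why the minima,
not the average, image is profiled.

`extract_profile()` samples the image bilinearly along a line, estimates
`I0` per flank as the median of the outermost 20% of samples (the field is
assumed homogeneous outside the vessel) interpolated linearly across, and
floors OD at zero. An optional averaging band (`average_px`) averages the
ODs of parallel lines: the minima statistic is an extreme-value statistic
with pixel-scale fluctuations, and averaging along a straight vessel is the
cheap way to suppress them.

**Width.** Reported as the full width at 10% of the OD peak. The
conventional FWHM systematically underestimates the support of a chord
profile by 13% (`√3/2`), so FWHM *ratios* of profiles with different shapes
are biased — the flat/round apparent-width ratio would read 1.61 where the
geometry says 1.43. At the 10% level the width estimates the geometric
support for both shapes and the measured ratio lands within a few percent
of 1.43. The FWHM is reported alongside for comparability.

**Flatness.** The fraction of the half-maximum span where OD ≥ 0.9 of the
peak, with the peak taken as the 95th percentile of OD inside the span so a
single bright pixel cannot puncture a genuine plateau. Closed forms: 1 for
a rectangle, `√0.19/√0.75 ≈ 0.50` for a semicircular chord. On the rendered
benchmark flat segments score ≥ 0.8, cylindrical ones ~0.5, and the two
classes separate completely (AUC 1).

**Limitations.** Light-diffusion blunting is neglected (defensible at the
optical densities and vessel sizes in scope). The estimators assume a
single vessel under the line and a locally straight axis when the averaging
band is used.

## 5. Axial flow in a flattened tube

**Geometry.** Flattening a tube against two planes stretches its
cross-section at nearly constant wall perimeter. The model family is the
stadium: flat walls of length `L` joined by semicircular caps of diameter
`h`, with `L = π(D − h)/2` enforcing perimeter `πD`. Width `W = L + h`
interpolates from `D` (circle) through `1.428 D` at `h = D/4` to `πD/2`
when totally squeezed. The real flattened shape (an elastic contact
problem) is not exactly a stadium; the family reproduces its perimeter
invariant and all its printed geometric landmarks, and the resistance
target consequently carries a ±20% tolerance rather than a solver-accuracy
one.

**Problem.** Fully developed laminar flow: `μ ∇²w = dp/dz` on the section,
`w = 0` on the wall. One solve with unit forcing gives `w₁`; scaling by
`Q/∫w₁ dA` yields the velocity field at prescribed discharge and
`dp/dz = −μQ/∫w₁`. Linearity in `μ` and `Q` is exact and tested.

**Discretization.** Regular grid with spacing `gap/grid_resolution`
(default 48 cells across the gap). The wall is imposed by Shortley–Weller
stencils: at nodes whose neighbor lies outside, the stencil arm is
shortened to the exact boundary intersection, found by bisection on the
stadium's closed-form signed distance (distance to a segment minus `h/2`).
A plain staircase mask converges too slowly to meet a 1% target at
practical resolution; with the fractional stencils the circular section
reproduces `dp/dz = −128μQ/(πD⁴)` and wall shear `32Q/(πD³)` to ≈ 0.1% and
0.7% respectively at the default resolution, and the flattened-section
`dp/dz` changes by < 1% when the grid is doubled. The discharge integral
uses smeared cell fractions `clip(1/2 − sdf/δ)` near the wall.

**Wall shear.** `γ̇ = ∂w/∂n` sampled at analytic boundary points by
quadratic extrapolation through zero from `w` at 1.5δ and 3δ along the
inward normal. Samples are partitioned into caps and flat walls;
`shear_partition()` reports medians (and maxima) relative to the circular
baseline. Whether the reported gains are maxima or representative values
was left open in the source material; medians are the headline here
because the maxima depend on the cap–wall junction resolution.

**Results and oracle.** At `h = D/4`, equal `Q`: resistance ratio 15.3
(target ~17 ± 20%; the reported range itself spans 17–18), shear gains 7.6
(flat) and 4.4 (caps) against 8 and 4. The independent analytic oracle is
the rectangular-duct series
`Q = Gab³/12μ · [1 − 192b/(π⁵a) Σ tanh(nπa/2b)/n⁵]` for the rectangle of
the same width and gap, giving ratio 14.9 — the stadium, with its narrower
flat span, must sit just above it, and does. The series itself is checked
against the square-duct literature constant `|G| = 28.45 μQ/a⁴`. In the
slit limit (`h ≤ 0.1 D`) the solver lands within 10% of the series,
recovering the `1/h³` scaling.

## 6. Flux around a flattened arteriole tip

A dimensionless lattice model of an arteriole growing across a partially
flattened plexus. Conductivities by region: flattened capillaries 0.4,
cylindrical capillaries 1 (= 2.5 × 0.4), flat distal arteriole half 4,
cylindrical proximal half 10 (= 4 × 2.5) — the same 2.5 ratio between
cylindrical and flattened states in both vessel classes, reflecting that a
flattened *capillary* only multiplies resistance by ~2.5. Default lattice
26 × 41; the arteriole runs along the middle row from the inlet edge to a
tip at two thirds of the width, the distal half flat, with the flattened
capillary halo (radius 6 cells) around the flat segment. The boundary
conditions are not dictated by the source lattice description and are a
configuration choice here: Dirichlet `V = 1` at the arteriole inlet cell,
`V = 0` along the opposite (venous) edge, zero-flux borders elsewhere.

Fluxes are the one-sided differences `jx[i,j] = σ[i,j](V[i,j] − V[i−1,j])`
(and likewise in `j`), border fluxes zero; the sign convention follows the
update scheme (physical flux is `−σ∇V`; magnitudes are identical). The
potential relaxes by the explicit conservation update on free cells,

    V ← V + C · div(J) / s̄,   s̄ = mean of the four edge conductances,

iterated to a maximum cell divergence below 10⁻⁹ (the stopping rule is a
choice; "converged" is not otherwise quantified). Two facts forced the
normalization. Taken literally, an update of `V[i,j]` by the divergence
expression centered at the *same* index has a positive diagonal
(+2σ[i,j]) and diverges for any positive `C`; the conservative reading —
forward difference of the backward-differenced fluxes, the standard
five-point heterogeneous stencil — fixes the sign but is still explicit
with stability bound `C · Σσ_edges < 2`, violated at `C = 0.05` once σ
reaches 10. Normalizing by the local mean edge conductance makes the bound
`C < 0.5` independently of the conductivity map, and `C = 0.05` then
converges on the default scenario in ~6.6 × 10⁴ iterations — the order of
10⁵ expected for this lattice. The defining correctness property is
equivalence with the directly assembled sparse linear system
(`solve_potential_direct()`), to max |ΔV| ≤ 10⁻⁶, plus discrete
conservation, the maximum principle, and monotonicity of tip flux in the
tip conductivity.

The exclusion zone is quantified by `flux_region_means()`: mean |J| over
the flattened cells hugging the tip versus mean |J| over the plexus band
(3–7 rows off-axis) flanking the distal half — the path the flow swerves
through. Converged solutions show tip < swerve.

## 7. PIV

`piv_pass()` is ensemble block-matching: for each interrogation window the
cross-covariance surfaces of all frame pairs at `frame_step` are
accumulated — the right estimator for steady flow with sparse tracers —
and the displacement is the surface peak with parabolic subpixel
refinement. Correlation is computed zero-padded (linear, not circular) and
divided by the per-lag overlap count; without this unbiased normalization
the estimator shrinks displacements toward zero by ~10% at moderate lags.
The search is confined to half-window lags. Quality is the ratio of the
primary peak to the best peak outside its 3 × 3 neighborhood;
`median_filter_vectors()` flags (never deletes) vectors failing a
normalized local-median test with a 0.1 px/frame noise floor. Uniform
translation is recovered to < 0.05 px; reversing the stack negates the
field exactly.

## 8. Determinism and problem sizes

All randomness flows from explicit integer seeds through a
save/restore-scoped RNG, so generator calls are reproducible and leave the
session RNG untouched; identical seeds give bit-identical stacks, and the
pipeline manifest's checksums (computed after 16-bit quantization) are
stable across reruns. The standard study configurations are
`pipeline_benchmark()` — 300 frames, 176 × 120 px, jitter 4 px, half the
frames defocused — and `profile_benchmark()` — 220 motionless frames,
140 × 104 px, tracer density 4500 per 100 px at contrast 0.03, the
saturated regime profilometry assumes. The hemodynamics defaults are 48
grid cells across the gap (circular baseline) and 24 for the flattened
section; the validation suite exercises coarser grids for sweeps and
finer ones for convergence checks. These sizes are the package's reference
conditions; all quantitative claims in Sections 3–7 are computed at them
by the test suite, not quoted from elsewhere.

## 9. Known limitations

* Rigid registration only; tissue that deforms non-rigidly between frames
  is out of scope, as is fluorescence imaging — the method's point is that
  it is label-free.
* The viscosity is homogeneous Newtonian; the diameter dependence of
  apparent blood viscosity (at most a factor ~2 here) is not modeled.
* The stadium family is a geometric surrogate for the true elastic contact
  shape; resistance and shear targets inherit a geometric tolerance.
* The lattice flux model is dimensionless and deliberately uncoupled from
  the physical-units solver; it demonstrates topology, not magnitudes.
* Minima profilometry requires saturation ("filled at least once per
  column"); under-perfused vessels bias widths low and flatness high.
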