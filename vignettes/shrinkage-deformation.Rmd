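---
title: "Modeling slice shrinkage and the limits of linear z-correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling slice shrinkage and the limits of linear z-correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sliceshrink)
```

## The problem this package models

Fixed acute brain slices embedded in aqueous mounting medium under a
coverslip compress along the optical axis (z) and dilate moderately in the
slice plane. The compression is depth-dependent — strongest near the cut
surfaces, where slicing damage makes the tissue more compressible, and
mildest in the middle. Reconstructions traced from image stacks of such
slices inherit the deformation, so derived anatomical parameters (dendritic
length, landmark distances, spine densities) are biased. The widely used
remedy, rescaling all z-coordinates by the ratio of nominal to measured
slice thickness, implicitly assumes *uniform* compression and no lateral
change; this package makes the deformation explicit so that both the bias
and the limits of that correction can be quantified.

## The deformation model

Coordinates are micrometres throughout, with `z = 0` at the top imaged
surface and z increasing into the slice, which occupies `[0, T]`
(`T = 300` by default, the standard cut thickness). A
`deformation_profile` consists of

* a local shrinkage fraction `s(u)` of normalized depth `u = z/T`, with
  `s(u) < 1` everywhere so the depth map
  `z'(z) = ∫₀ᶻ (1 − s(ζ/T)) dζ` is strictly increasing (no fold-over), and
* an isotropic lateral scale `g` (`xy_dilation`) applied about the slice
  centre.

The deformed thickness is `T' = T(1 − ∫₀¹ s)`. Three profile families are
provided. The measurements the model is calibrated from cannot distinguish
a smooth from a stepwise depth dependence, so the family is a configuration
choice, not a claim:

* `profile_uniform(s)` — the control condition under which linear
  correction is exact;
* `profile_thirds(top, middle, bottom)` (and `profile_table()` for
  arbitrary breaks) — piecewise-constant, matching depth-stratified
  differential-shrinkage measurements directly;
* `calibrate_quadratic_profile(total, marginal20)` — a smooth symmetric
  parabola `s(u) = a + b(u − ½)²`. Both calibration constraints are linear
  in `(a, b)`: the mean of `(u − ½)²` is `1/12` over `[0, 1]` and `49/300`
  over the marginal 20% zones, so the solve is exact (closed form, checked
  to 1e-10 in tests). Calibrating to a 42.0% overall and 61.3% marginal
  shrinkage gives `a ≈ 0.219`, `b = 2.4125`, and predicts ≈ 24.1% mean
  shrinkage in the middle third — within one standard deviation of
  depth-stratified measurements of that quantity (30.4 ± 11.7%), which is
  the package's internal consistency check between the two calibration
  routes.

Nodes outside `[0, T]` are a hard error rather than being clamped: silent
clamping would corrupt every length metric downstream. The xy-dilation is
isotropic about the slice centre; only scalar landmark-distance changes are
available to calibrate it, so no anisotropic or position-dependent lateral
model is attempted. When a morphology is deformed, its xy centroid stands
in for the slice centre — the choice drops out of all length and density
metrics. The default `g` for conventional re-embedding, 1.073, is the ratio
implied by landmark distances moving from −2.9% (reference state, relative
to the recording chamber) to +4.2% (re-embedded without spacer):
1.042/0.971 ≈ 1.073.

## Linear correction and its residual

`correction_factor(nominal, measured)` is the quotient `T / T'`;
`apply_linear_z_correction()` scales z about `z = 0`, consistent with the
depth-map origin (scaling about the midplane would leave extents unchanged
but shift absolute coordinates). For any profile the corrected slice extent
equals the nominal thickness exactly; for a *uniform* profile with `g = 1`
every inter-node distance is restored to floating-point accuracy. For any
non-uniform profile the local corrected scale in a region with shrinkage
`s_k` is `(1 − s_k)·T/T'`, so `residual_error_by_depth()` reports
`(1 − s_k)·T/T' − 1` per depth bin: with the thirds profile
(0.451, 0.304, 0.443) and factor 300/180.2 this is −8.6% (top), +15.9%
(middle), −7.3% (bottom) — undercorrection at the surfaces, overcorrection
in the middle. Residuals are computed on matched segments (same node ids),
not on independently re-traced structures: tracing noise between two
reconstructions of the same cell is real but out of scope here.
A non-linear inverse correction is deliberately not offered: the analysis
this package supports concludes that prevention (spacers), not
compensation, is the remedy, and the correction implemented is exactly the
one in common use.

## Measurement procedures

*Depth-stratified differential shrinkage.* Unbranched segments whose chord
lies within 30° of the z-axis (configurable) are assigned to depth thirds
by the midpoint of their z-range **in the reference frame** — the minimally
shrunken state is the natural frame for depth assignment, though which
frame the original measurements used is not stated, so the threshold and
frame are explicit arguments. The statistic per segment is
`(z_before − z_after) / z_before`.

*Landmark distances.* All pairwise distances between labelled planar
points, each change normalized to its reference distance; under a pure
isotropic scaling `g` every pair changes by exactly `g − 1`.

*Spine densities.* Spines are modelled as attachment points on the shaft
with 3-D offset vectors to the spine tip. Projected counting
(`spine_density_projection`) declares a spine visible when the component of
its offset perpendicular to the projected shaft axis, in the chosen plane,
reaches a visibility threshold; density is visible count per projected
shaft length. This makes xy-projected density exactly invariant under pure
z-compression, while yz-projected density can only fall. The 3-D rule
(`spine_density_3d`) is an explicit stand-in model — the real
stack-counting procedure it emulates is not specified anywhere in a
reproducible form — declaring a spine countable when its lateral offset
reaches the lateral resolution OR its axial offset reaches the axial
resolution (defaults 0.25 and 0.7 µm, typical confocal values, simulation
parameters rather than measurements). A hard threshold was chosen over a
probabilistic visibility model so that every documented example is exactly
derivable. Shaft radius is carried but ignored in visibility geometry.

*Shrinkage kinetics.* The packaged time courses (three embedding methods,
shrinkage percent over days) are summarised by
`s(t) = s_inf (1 − e^{−t/τ})`. The fit profiles out `s_inf` (closed form
for fixed τ) and optimises τ by a coarse grid plus golden-section
refinement on log τ — deterministic on 3–4 point series where generic
nonlinear optimisers need luck with starting values. A τ pinned at the
search boundary (e.g. for a constant series) is flagged
(`flag = "degenerate_tau"`) rather than raised as an error. Noiseless
synthetic series are recovered to better than 1e-6 in both parameters. The
single-exponential form is a summary device, not a mechanistic claim: the
conventional-embedding series clearly contains a fast initial phase plus a
slow creep, so its fitted asymptote (≈ 38%) sits below the last observed
value (49.4%); the fitted asymptote *ordering* across methods
(metal < conventional < agar) is the robust, tested statement.

## Smoothing of traced trajectories

Traced neurite trajectories are ragged, far more so along the optical axis.
`gaussian_smooth()` applies an iterated 3-point kernel with weights
(¼, ½, ¼) — the binomial approximation of a Gaussian at window 3, the
natural reading of a "3-point Gaussian window" whose exact weights are
otherwise unspecified — separately to each unbranched path, with one pass
for x/y and 15 for z by default. Branch points and path endpoints are
anchored so topology-defining coordinates never move; smoothing per
unbranched path (rather than over a global node ordering) is the assumed
interpretation and keeps the operation well-defined on trees. The anchored
kernel has a closed-form behaviour on the path `z = (0, 1, 0)`: the
interior value decays as `0.5^k`, which the tests use as an oracle, along
with equivalence to direct discrete convolution for a single iteration.

## The exact paired test

`wilcoxon_signed_rank_exact()` enumerates the distribution of the
positive-rank sum over all `2^n` sign assignments — implemented as an exact
convolution over doubled mid-ranks, which is algebraically identical to
full enumeration and feasible to `n = 25` (beyond that it refuses rather
than silently approximating). Zero differences are dropped and counted
(`n_zero`); an all-zero sample returns `p = 1` with a flag. Ties receive
mid-ranks. The two-sided p-value is `min(1, 2·min(P(V ≤ v), P(V ≥ v)))`,
which yields `2/64 = 0.03125` for six concordant pairs and
`2/256 = 0.0078125` for eight — the values arising in the replication. The
zero-dropping convention is stated here rather than asserted to be the one
used in any particular original analysis, which is unverifiable. No
multiple-testing correction is applied within a report: the replication
reports a small set of planned paired comparisons.

## What the synthetic generator emulates — and what it does not

`generator_config()` fixes the study conditions: 300 µm slice, six neurons
per replication, isotropic growth directions (`orientation_bias = 0`;
1 forces strictly vertical neurites, useful for constructing exact
oracles), soma in the upper half of the slice as slices are mounted with
recorded somata toward the top surface, a 3-D spine density of 1.25 µm⁻¹
(the reference-state condition mean) with ~1 µm isotropic offsets, and
8 landmarks. Trees grow by a stochastic branching walk (normally
distributed ~6 µm steps, 6% per-step bifurcation probability, reflection
at the slice faces) to 400 nodes ≈ 2.4 mm of dendrite — a desk-scale
stand-in, deliberately smaller than a full pyramidal cell. Everything is
deterministic given the configuration and seed, with independent sub-seeds
per generator so adding spines never perturbs the trees.

The generator does **not** emulate: cell-type-specific branching
statistics, axons, tracing noise (two reconstructions of the same cell
never differ here), imaging physics (no point-spread function, no
deconvolution), or time-dependent deformation (the kinetics table is a
summary fixture, not a dynamic field). Passing replication tests therefore
show that the *deformation and measurement machinery* behaves as derived —
signs, exact scale factors, exact p-values under forced sign patterns —
not that effect magnitudes on real neurons are reproduced: magnitudes
depend on orientation statistics and are seed-dependent (in occasional
seeds a neuron near the strongly compressed surfaces can even end up net
negative after correction, weakening the corrected-arm p-value; the
direction of each mean effect is stable).

## Numerical choices and problem sizes

* Morphologies are stored in topological order (parents before children);
  SWC round trips preserve coordinates at 9 significant digits.
* Depth-map inversion uses bisection to 1e-10 µm; profile integrals are
  closed-form per family and are cross-checked against quadrature at 1e-9
  relative in tests.
* Degenerate inputs error early and specifically: nodes outside the slice
  volume (with ids), zero reference extents, mismatched landmark labels,
  mismatched tree topologies, infeasible generator parameters.
* Test and replication problem sizes — 6 neurons × 400 nodes, 45 vertical
  segments, 8 spine-bearing shafts of 40 µm, 2000-node trees for the
  isotropy check — were chosen so the whole suite runs in seconds while
  keeping Monte-Carlo checks comfortably inside 3-standard-error bands.

## Known limitations

Only scalar, depth-dependent axial compression plus isotropic lateral
dilation is modelled: no lateral position dependence, no anisotropy, no
time dependence. The 3-D spine-counting rule is a labelled stand-in. The
kinetics model is a two-parameter summary. The replication compares a
perfect reference state against a deformed one; the small (≤ 4%) residual
shrinkage of a real spacer-embedded reference is treated as zero by
default.
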