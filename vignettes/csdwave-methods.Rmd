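---
title: "Methods: firing-rate CSD waves on triangulated surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: firing-rate CSD waves on triangulated surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csdwave)
```

## The model

Cortical spreading depression (CSD) is a slow wave of neuronal
depolarisation thought to underlie migraine aura. `csdwave` models it at
the tissue scale with two state variables per cortical location: the mean
firing rate $u(x,t)$ (Hz) and a recovery variable $w(x,t)$
(dimensionless), coupled as a modified Rogers–McCulloch
(FitzHugh–Nagumo-type) reaction–diffusion system on a curved surface
$\Sigma \subset \mathbb{R}^3$:

$$
\partial_t u = -I(u, w) + \mathrm{div}_\Sigma (\delta \nabla_\Sigma u),
\qquad
\partial_t w = \eta_2\,(u - u_0 - \eta_3 w),
$$
$$
I(u, w) = G\,(u - u_0)\Big(1 - \frac{u}{u_{th}}\Big)\Big(1 - \frac{u}{u_p}\Big)
        + \eta_1 (u - u_0)\, w .
$$

The cubic makes $u_0$ (rest, 4 Hz), $u_{th}$ (threshold, 11.8 Hz) and
$u_p$ (peak, 64 Hz) literal fixed points of the local dynamics: tissue
pushed above threshold runs up to the 64 Hz plateau, stays there while
the slow recovery variable accumulates, and then returns to rest. On a
closed surface no boundary conditions are needed; on open fixture meshes
(sheets, ducts) the discretisation behaves as zero-flux.

`model_params()` carries the default calibration
(`G = 1.6`, `eta1 = 2.9227`, `eta2 = 2e-4`, `eta3 = 60`,
`delta = 0.7174` mm²/s, `dt = 0.6` s = 0.01 min). An alternative reading
of the cubic, $(1-(u-u_0)/u_{th})(1-(u-u_0)/u_p)$, is available as
`variant = "shifted"`; it moves the upper fixed point to $u_0 + u_p$ and
is not the default precisely because the default reading keeps the three
published rates as the literal rest/threshold/peak values.

### Units: the one decision that matters most

The calibration mixes time units and we fix the convention once: **the
rate constants $G$, $\eta_1$, $\eta_2$ are per minute**, while every
user-facing time (`dt`, `t_max`, activation times) is in seconds and
$\delta$ is in mm²/s. The package converts internally
(`dt` enters the reaction in minutes; $\delta\,\Delta t$ is
unit-consistent either way).

This is forced by the dynamics, not a taste choice. Reading the rates
per second makes the explicit reaction update unstable at the published
step $\Delta t = 0.01$ min: the linearised reaction rate near $u_p$ is
$\approx 6.6$ per time unit, so $\Delta t \cdot \lambda \approx 4$ per
second-reading — the space-clamped trajectory then overshoots to
$\sim 78$ Hz and oscillates below zero. Per minute,
$\Delta t \cdot \lambda \approx 0.066$: the scheme is stable, the
excitation plateaus within 1% of the 64 Hz peak, and plane waves travel
at $\approx 9.5$ mm/min — i.e. a cortex-scale traversal in tens of
minutes, which is the CSD regime this model is meant to reproduce. The
test suite measures all three facts.

One calibration claim does not survive either reading: with
$1/(\eta_2\eta_3) \approx 83$ min the space-clamped excitation stays
above threshold for roughly 100 minutes, not ~10. The package reports
the plateau duration (`excitation_episode()`) rather than asserting a
target for it.

## Discretisation

Space is discretised by P1 (piecewise-linear) finite elements on the
triangulation. The mass matrix assembles the exact element integrals
$(\text{area}/12)\,[[2,1,1],[1,2,1],[1,1,2]]$ (`mass_mode = "lumped"`
puts the row sums on the diagonal; wave speeds agree within 3% at the
reference resolution and the consistent form is the default). The
stiffness matrix is the intrinsic cotangent Laplace–Beltrami
discretisation, assembled triangle by triangle in each triangle's own
plane — valid because the diffusion tensor is isotropic
($D = \delta\,\mathrm{Id}$); anisotropic tensors are out of scope.
Degenerate triangles (area $\le 10^{-12}$ mm²) abort assembly rather
than being regularised.

Time stepping is implicit–explicit: the recovery ODE is advanced by its
closed-form exponential update with $u$ frozen, the reaction is
evaluated as $I(u^n, w^{n+1})$, and one solve of
$(M + \Delta t S)\,u^{n+1} = M u^n - \Delta t\, M I^{n+1}$ advances the
firing rate. The system matrix is symmetric positive definite and is
solved by conjugate gradients preconditioned with a zero-fill incomplete
Cholesky factor, at relative residual `1e-8` (configurable;
`1e-12` is used where a test compares against dense algebra). If the
incomplete factorisation breaks down the solver falls back to
unpreconditioned CG with a warning. The factor is built once per
simulation and each step warm-starts from the previous field.

Convergence choices were checked rather than assumed: halving `dt`
changes every wavefront-mediated activation time on the 6-region sphere
fixture by under 1%. The exception is documented: entries for regions
that share a boundary with the source activate *within the first step*
(crossing times of 0.2–0.35 s against a 0.6 s step), so their
interpolated crossing time is $O(\Delta t)$ by construction and cannot
converge at fixed threshold — those entries measure initial-condition
smoothing, not propagation.

## Simulation protocol and activation times

A single run depolarises one source region ($u = u_p$ on its vertices,
rest elsewhere, $w \equiv 0$ everywhere) and steps until every
non-excluded region is fully activated — every vertex has crossed the
activation threshold — or `t_max` (default 3600 s) is reached, in which
case the record is flagged incomplete with the unfinished regions named.
"Activated" is the first upward crossing of `activation_threshold`
(default $u_{th}$; the detection level is configurable because the
original convention is not stated), refined by linear interpolation
within the step. The all-sources protocol repeats this once per
non-excluded region and collects region-minimum and region-maximum
crossing times into $T_{min}$ and $T_{max}$ (rows = source, columns =
arrival). Atlas regions can be excluded as sources (e.g. a corpus
callosum label); excluded regions neither start waves nor appear in the
matrices.

Region rows/columns are ordered by lobe blocks, and within each lobe by
a deterministic greedy nearest-centroid chain starting from the region
closest to the (area-weighted) lobe centroid, ties broken toward the
lower region id.

## Quantities of interest

All operators act on the activation-time matrices:

* **Asymmetry** $A = T_{min} - T_{min}^\top$ (skew-symmetric; zero for
  perfectly symmetric propagation) and its normalised form
  $\hat A_{ij} = A_{ij} / (T_{min})_{ij}$ off-diagonal, which is
  invariant under rescaling all times.
* **Global asymmetry index**: sign of each column mean of $\hat A$,
  taken over off-diagonal entries (the diagonal is structurally zero;
  including it would only shrink every mean by the same factor — a
  switch exposes the alternative).
* **Residence and retention**: $D = T_{max} - T_{min}$ and the retention
  index $R_j = \sum_i D_{ij}$, the initial-condition-independent measure
  of how long the wavefront stays in region $j$.
* **Combined matrix**: two skew-symmetric asymmetry matrices from two
  meshes with name-matched regions are stacked as $|L|$ below and $|R|$
  above the diagonal without information loss.
* **Distance–time datasets**: all $k(k-1)$ ordered off-diagonal pairs of
  centroid distance versus activation time, with the Pearson coefficient
  computed by the two-pass textbook formula. Centroid distances are
  straight-line Euclidean — explicitly a proxy, never geodesic.

Region areas and centroids are defined on the vertex-labelled mesh by
majority vote of each triangle's vertex labels (ties to the lower region
id), which keeps areas an exact partition of the total surface; the
centroid of a region is the area-weighted mean of its triangles'
barycenters. Centroids therefore shift by $O(h)$ relative to the
continuum region — visible in coarse fixtures and covered by test
tolerances.

## Robust outlier detection

The $(\text{area}, \text{retention})$ dataset is screened for unusual
regions with squared Mahalanobis distances compared against the
$\chi^2_2$ quantile (97.5% by default), both classically (sample mean
and covariance) and robustly. The robust location and scatter are the
minimum covariance determinant estimates, computed by the FAST-MCD
strategy: `n_starts = 500` random $(p+1)$-subsets, concentration steps
until the support repeats, smallest determinant wins; the default subset
size $h = \lceil (n+p+1)/2 \rceil$ gives the maximal breakdown point.
The raw scatter is rescaled by the standard median consistency factor
$\mathrm{med}_i\, d_i^2 / \chi^2_{2,0.5}$ over all observations (the
rescaling can be switched off, which is how the tests compare the fit
against exhaustive enumeration of all $h$-subsets at $n \le 12$).
Reweighted MCD refinement is deliberately not applied. All subset draws
are seeded and the seed is recorded in the report. Datasets whose
best-subset scatter is numerically singular (e.g. constant retention on
a perfectly symmetric sphere fixture) are refused rather than forced.

## Synthetic geometry: what it does and does not emulate

No cortical mesh is distributed with the package, so the fixtures stand
in for one:

* `make_icosphere()` + `make_face_atlas()` — a closed manifold with six
  equal-area regions in three "lobes". On a sphere with isotropic
  diffusion, propagation between regions must be symmetric; the residual
  asymmetry of $T_{min}$ (under 2%) measures pure mesh discreteness and
  is the package's main correctness probe for the full pipeline.
* `make_seed_atlas()` — a deterministic nearest-seed partition into $k$
  regions (Fibonacci directions), the stand-in for a 34-region
  anatomical parcellation. The 34-region protocol fixture uses a
  radius-20 mm sphere so that each source patch exceeds the medium's
  critical nucleation radius ($\approx \delta/c \approx 4.5$ mm) — on a
  radius-10 sphere a 1/34 patch collapses instead of igniting, which is
  physics, not failure.
* `make_sheet()` — open flat sheets for plane-wave speed, the
  $\sqrt{\delta}$ speed-scaling law, collision/annihilation and
  sub-diffusion propagation checks.
* `make_duct()` — two rectangular legs joined by a sector that pivots
  around the inner corner; only the bend angle differs between
  comparison arms.

What these fixtures do **not** emulate: sulci and gyri (strong local
curvature), hemispheric anatomy, region shape irregularity, and the
flat corpus-callosum geometry. Passing tests therefore validate the
numerics and the operator definitions, not subject-specific cortical
results; quantities that depend on an individual cortical mesh
(specific correlation values, specific outlier lists, a specific maximal
asymmetry) are out of reach by construction.

### The bend-block experiment

The classical geometric effect — a wave failing to turn a sharp corner
that a gentle corner transmits — requires recovery on the timescale of
the corner transit. With the cortical calibration the recovery time
constant ($\approx 83$ min) exceeds any transit time, so the medium
behaves as bistable on those scales and trigger waves cannot be blocked
by geometry at any width or $\delta$ (both the critical pivot radius and
the front width scale as $\sqrt{\delta}$, so rescaling cannot change the
regime; a width/angle scan confirms universal transmission). The duct
demonstration therefore runs the same model in its fast-recovery pulse
regime (`eta2 = 0.02` per minute, all other parameters unchanged):
at matched $\delta$, width (3 mm), resolution and leg length, a 150°
bend transmits and a 30° bend blocks, with only the geometry differing
between the two arms.

## Problem sizes and determinism

The shipped tests use a subdivision-3 icosphere (642 vertices) for
sphere protocols, a subdivision-3, radius-20 sphere for the 34-region
protocol, 40 × 2 mm sheets at 0.5 mm resolution for wave-speed
measurements (0.1 mm at 100-fold-reduced diffusion, where the front is
ten times thinner), and ducts at 0.5 mm resolution — sizes at which the
wave speed is mesh-converged (halving the sheet spacing moves the
measured speed by well under 0.1%).

Simulations are deterministic; the only randomness in the package is the
MCD subset draw, which is seeded and restores the caller's RNG state.
Artifacts are written with 17-significant-digit, locale-independent,
LF-terminated text, so identical configurations produce byte-identical
files; the suite checks this by hashing.

## Known limitations

* Isotropic diffusion only; no DTI-informed anisotropy, no long-range
  connections, no inhibition, no synaptic plasticity, no ionic neuron
  models.
* No geodesic distances (the straight-line centroid proxy is part of
  the method definition).
* No mesh repair: invalid meshes are rejected with a pointer to the
  offending element, and only OFF/ASCII-PLY/CSV interchange is
  supported.
* First-step activation entries (regions touching the source) are
  $O(\Delta t)$ by construction; treat them as "immediate neighbours",
  not as converged travel times.
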