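# csdwave

Simulation of cortical spreading depression (CSD) — the slow
depolarisation wave behind migraine aura — on triangulated surface
meshes, with the full set of propagation statistics used to
characterise how geometry shapes the wave: activation-time matrices,
asymmetry and retention indices, distance–time correlations, and robust
outlier detection of regions. It is written for computational
neuroscientists and applied mathematicians who want to study
reaction–diffusion wave propagation on curved 2-manifolds (a cortex, a
sphere, a bent duct) without a full neural-field stack.

## The model

The tissue state is a firing rate $u$ (Hz) and a recovery variable $w$,
evolving as a modified Rogers–McCulloch reaction–diffusion system on a
surface $\Sigma$:

$$\partial_t u = -I(u,w) + \mathrm{div}_\Sigma(\delta \nabla_\Sigma u),
\qquad \partial_t w = \eta_2 (u - u_0 - \eta_3 w),$$

$$I(u,w) = G (u-u_0)\left(1-\tfrac{u}{u_{th}}\right)\left(1-\tfrac{u}{u_p}\right)
 + \eta_1 (u-u_0) w,$$

with rest $u_0 = 4$ Hz, threshold $u_{th} = 11.8$ Hz, peak
$u_p = 64$ Hz, $G = 1.6$, $\eta = (2.9227,\ 2\cdot10^{-4},\ 60)$
(rates per minute) and isotropic diffusion
$\delta = 0.7174\ \mathrm{mm^2 s^{-1}}$. Space is discretised by P1
surface finite elements (consistent mass, cotangent Laplace–Beltrami
stiffness) and time by an IMEX scheme: closed-form recovery update,
explicit reaction, implicit diffusion solved by incomplete-Cholesky
preconditioned conjugate gradients, $\Delta t = 0.01$ min. Waves travel
at ≈ 9.5 mm/min — the CSD regime. See the methods vignette
(`vignettes/csdwave-methods.Rmd`) for every numerical decision,
including why the rate constants are per minute.

## Worked example

Six equal regions on a sphere are the cleanest probe: with isotropic
diffusion on a perfect sphere, propagation between regions must be
symmetric, so every departure from symmetry measures mesh discreteness.

```r
library(csdwave)

mesh  <- make_icosphere(3, 10)        # closed manifold, radius 10 mm
atlas <- make_face_atlas(mesh)        # 6 cube-face regions, 3 lobes
mats  <- run_protocol(mesh, atlas, model_params())
round(mats$T_min, 1)                  # minimum activation times (s)
#>      +x   -x   +y   -y   +z   -z
#> +x  0.0 69.1  0.3  0.3  0.4  0.4
#> -x 69.1  0.0  0.3  0.3  0.4  0.4
#> +y  0.4  0.4  0.0 69.1  0.3  0.3
#> -y  0.4  0.4 69.1  0.0  0.3  0.3
#> +z  0.3  0.3  0.4  0.4  0.0 69.1
#> -z  0.3  0.3  0.4  0.4 69.1  0.0
```

Rows are source regions, columns arrival regions. Adjacent regions are
reached almost immediately (their boundaries touch the depolarised
source), while the antipodal region is reached in ≈ 69 s — a quarter
sphere at ≈ 9.5 mm/min. The matrix is symmetric to within 0.2%, as the
sphere demands.

```r
b <- qoi_bundle(mats, region_geometry(mesh, atlas))
b
#> qoi_bundle: 6 regions
#>   r(distance, T_min) = 0.9999   r(distance, T_max) = 0.9813
#>   r(area, retention) = 0.3763   max |asymmetry| = 0.0251 s
```

Activation times correlate almost perfectly with centroid distance
(3 distinct distances on a sphere), and the largest back-vs-forth
asymmetry is 25 ms — pure discretisation noise. The space-clamped
dynamics show the excitation episode itself:

```r
ep <- excitation_episode(model_params(), u_start = 13)
#> peak 63.49 Hz, plateau 101.7 min
```

A supra-threshold push rises to the 64 Hz plateau (within 1%) and
returns to rest once recovery accumulates.

A command-line interface wrapping the same functions (fixture
generation, single runs, the all-sources protocol, QoI extraction) is
installed at `system.file("cli", "csdwave", package = "csdwave")`.

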