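---
title: "Time-domain early-photon fluorescence molecular tomography with earlyfmt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-domain early-photon fluorescence molecular tomography with earlyfmt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The imaging problem

Fluorescence molecular tomography (FMT) reconstructs the three-dimensional
distribution of a fluorescent probe inside strongly scattering tissue from
light measured on the surface. Because multiply scattered photons blur the
inverse problem, time-gated acquisition keeps only the earliest-arriving
photons — those that underwent the fewest scattering events — and
reconstructs from the measurement at a single early time node (300 ps in
the default setup), which sharpens the attainable resolution at the cost
of a much larger time-domain computation.

`earlyfmt` implements the complete computational chain in R:

1. a Galerkin finite-element model of the coupled time-domain diffusion
   equations on tetrahedral meshes,
2. implicit time stepping with one precomputed sparse Cholesky
   factorization reused by every source, detector and time step,
3. batched detector-adjoint Green's functions,
4. a normalized-Born weight matrix assembled by temporal convolution with
   the fluorophore lifetime kernel, and
5. nonnegative algebraic reconstruction (relaxed Kaczmarz) at the gate.

## Forward model

Photon densities for excitation ($\Phi_x$) and emission ($\Phi_m$) obey
coupled diffusion equations

$$\frac{1}{c}\frac{\partial \Phi_v}{\partial t} + \mu_a \Phi_v
  - \nabla \cdot (D \nabla \Phi_v) = S_v, \qquad
  D = \frac{1}{3(\mu_a + \mu_s')},$$

with the impulsive surface source on the excitation side and the yield- and
lifetime-driven re-emission term $(\eta/\tau)\,\Phi_x * E$ on the emission
side, where $E(t) = e^{-t/\tau}$ and $*$ is temporal convolution. Robin
boundary conditions $\Phi + 2qD\,\partial\Phi/\partial n = 0$ encode the
refractive-index mismatch; $q$ is derived from an effective-reflectance fit
at the default $n = 1.37$. Optical properties are taken to be identical at
the excitation and emission wavelengths.

Galerkin discretisation over linear tetrahedra yields sparse symmetric
matrices $K$ (diffusion + absorption + boundary term) and $C$ (mass scaled
by $1/c$), assembled from closed-form element integrals (an independent
Gaussian-quadrature oracle backs them in the tests to $10^{-12}$). Implicit
Euler stepping

$$(K + C/\Delta t)\, G^{k+1} = (C/\Delta t)\, G^k + S^k$$

is unconditionally stable; the matrix $A = K + C/\Delta t$ is factorized
once and reused everywhere, which is the package's hardware-agnostic
reading of a precomputed-inverse scheme: detector fields advance as one
multi-column state, one time node at a time, then are restructured into
per-detector fields (`batched_detector_fields()`); a sequential reference
backend verifies equivalence to $10^{-12}$.

A unit load applied in the first time step represents a $\delta(t)$ source
of integrated strength $\Delta t$. The scale cancels in the normalized Born
ratio; the analytic-limit test divides by $\Delta t$ when comparing with
the infinite-medium kernel
$\Phi(r,t) = c\,(4\pi D c t)^{-3/2} e^{-r^2/(4Dct) - \mu_a c t}$.

## Weight matrix and normalized Born system

The first-order Born linearisation expresses the gated fluorescence
measurement as $\Phi_m(r_{sd}, t) = \int W(r_{sd}, r, t)\,\eta(r)\,dr^3$
with $W = G_s * E * G_d$. Discretely, `earlyfmt` uses the exact adjoint
identity of the implicit-Euler scheme,

$$W[(s,d),\,n] = \frac{c}{\tau\,\Delta t}
  \left(G_s[n,\cdot] * E * (C\,G_d)[n,\cdot]\right)\big|_{t_{gate}},$$

folding the $c/\tau$ coupling and the mass-matrix volume weighting into the
entries so that $W\eta$ reproduces the coupled two-pass simulation at the
gate to machine precision (the emission equation is linear in $\eta$, so
the "linearisation" is exact for fixed optical properties; the tests assert
agreement well inside 5%). Each matrix row is an independent per-node
convolution, the contract that makes this stage embarrassingly parallel.

Normalisation divides each pair's row and measurement by the gated
excitation $\Phi_x(r_{sd}, t_{gate})$, cancelling source strength and
coupling. Pairs whose gated excitation falls below $10^{-9}$ of the
maximum over pairs (or is nonpositive, which coarse meshes can produce at
early gates) are flagged unusable and excluded, never silently dropped.

## Reconstruction

The gated system $\Phi_{nB} = W^{nB}\eta$ is solved by relaxed Kaczmarz
iterations with nonnegativity clamping after every row update, starting
from $\eta = 0$, with $\lambda = 0.1$ and 100 sweeps in the default setup;
rows below a squared-norm floor ($10^{-30}$) are skipped and counted. Row
order is fixed (source-major, detector-minor); a seeded random order is
available.

Two numerical refinements, enabled by the pipeline and off by default in
`art_solve()` itself, address the geometry of Kaczmarz updates on locally
refined meshes:

* **Mass-variable reconstruction.** The Kaczmarz step distributes each
  update proportionally to the row entries, which scale with nodal volume
  shares; on a graded mesh this biases mass toward large, poorly resolving
  nodes. Solving for the nodal fluorophore mass $u_n = \eta_n V_n$
  (volume-scaled columns) makes the update geometry uniform across the
  mesh and is mathematically a diagonal preconditioner, not a change of
  model.
* **Valid-support restriction.** Nodes within one transport mean free path
  ($1/\mu_s' = 0.1$ cm at the background scattering) of the surface are
  excluded from the unknown set: the diffusion approximation — and hence
  the Born kernel — is invalid there, and the near-singular sensitivities
  of surface-adjacent nodes otherwise absorb reconstruction mass.

Quality metrics: the maximum node-wise relative error between two
reconstructions over the support of the reference (nodes at or above 1% of
its maximum — the formula is undefined where the reference is zero, and
nonnegative ART reconstructs exact zeros in the background); the Euclidean
distance between the half-maximum-thresholded, yield-weighted centroid and
the true target centre; and the fraction of volume-integrated recovered
mass within 0.5 cm of the truth.

## Synthetic phantom

The generator replaces a digital-atlas torso with a cylinder (radius
1.2 cm, height 3 cm, axis = rotation axis $z$) carrying three ellipsoidal
organ-like regions (heart, lung, liver) with the reference optical
properties

| region | $\mu_a$ (1/cm) | $\mu_s'$ (1/cm) |
|---|---|---|
| background | 0.1 | 10 |
| heart | 0.156 | 9.0 |
| lung | 0.516 | 21.2 |
| liver | 0.935 | 6.4 |

and a small cylindrical fluorescent target (radius 0.1 cm, height 0.2 cm)
centred at $(-0.31, -0.02, 1.93)$ cm. The mesh is a tensor-product
cylindrical grid (rings × azimuths × layers; prisms split into three
tetrahedra by a sorted-index rule that keeps the mesh conforming). Because
the per-node yield map is a binary indicator of the target, the grid is
locally refined around the target to cells of `target radius / 2.5`
(0.04 cm) so the indicator carries the target's volume; the refinement rule
is fixed a priori, and the total yield mass is within 10% of
$\eta \cdot \pi r^2 h$ at the default resolution. The default
characteristic edge of 0.24 cm yields about 4.6k nodes and 25k elements,
the problem scale at which the whole study runs in minutes on one CPU.

The acquisition emulates a rotation stage: 6 projections at 60°
increments (the frame rotates about the fixed mesh, which is equivalent to
rotating the object and exact for a synthetic phantom), a 120° detection
field of view centred on each source's antipode, a detector band of
±0.75 cm about the source height (1.93 cm, the target plane), and 60
detectors per projection by deterministic subsampling of the boundary
candidates — detector density on the coarse cylinder surface; the z band
and density are free parameters. Sources and detectors are displaced one
transport mean free path along the inward normal and snapped to the
nearest node (on the default mesh this snaps back to the boundary node,
which is why duplicated anchors are deduplicated with a warning).

What the phantom does *not* emulate: a realistic torso surface and organ
anatomy, instrument response functions, camera-pixel mapping, autofluorescence,
or model mismatch between simulation and reconstruction meshes (an
"inverse crime" shared by the simulation study it follows). Passing tests
therefore demonstrate internal consistency and numerical fidelity of the
chain, not performance on experimental data.

## Time grid, parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `dt_ps` | 10 ps | implicit-Euler step; 30 steps reach the gate |
| `t_end_ps`, `gate_ps` | 300 ps | early-photon gate at the final node |
| `tau_ps` | 560 ps | fluorophore lifetime (typical NIR dye scale) |
| `relaxation`, `n_iterations` | 0.1, 100 | ART settings of the study setup |
| `noise` | 10%, seed 42 | proportional Gaussian noise on gated data |
| `born_floor` | 1e-9 | relative validity floor on gated excitation |
| `support_depth_cm` | 0.1 | one background transport mean free path |
| `precision` | double | float32 rounding seam for the T4/T5 stages |

The gate snaps to the nearest time node (warning on mismatch). Noise is
multiplicative ("10% zero-mean Gaussian" applied proportionally, the
conventional reading for normalized data) and perturbs only the gated
fluorescence. The time-node indexing convention stores nodes at
$t = \Delta t, \dots, T\Delta t$ with the field zero at and before $t=0$;
the lifetime kernel is sampled on the lag grid starting at 0.

## Precision parameterization

The original acceleration strategy runs its two dominant stages — the
detector Green's functions and the weight matrix — in single precision,
with the remaining stages in double. `run_pipeline(..., precision =
"single")` mirrors that split: the multi-column detector state is rounded
to IEEE float32 after every step, as are the convolution intermediates,
weight rows and the normalized system, while assembly, excitation fields,
measurement synthesis and ART stay double. Both precision paths traverse
identical stage sequences and produce identically shaped outputs; the
acceptance script measures the maximum relative difference of the two
reconstructions over the support, which lands around $10^{-3}$–$10^{-4}$
percent — comfortably below the 0.15% reported for a GPU float32 pipeline,
as storage-level rounding is a milder perturbation than a full float32
arithmetic chain.

## Worked example

```{r, eval = FALSE}
library(earlyfmt)

run <- run_pipeline(fmt_config())
print(run)
#> <fmt_run> 4617 nodes, 360 pairs, double precision, accelerated backend
#>   localization error: 0.01996 cm; mass within 0.5 cm: 92.07 %
stage_report(run)
```

The six stages mirror the solver decomposition (T1 phantom/load, T2
assembly, T3 excitation Green's functions, T4 detector Green's functions,
T5 weight matrix, T6 reconstruction); T4 + T5 dominate the wall time, which
is precisely why they are the batched/precision-parameterized stages.

## Numerical choices and limitations

* Piecewise-constant coefficients per element (region-wise constants);
  nodal visualisation values are volume-weighted element averages.
* The boundary factor is $1/(2q)$ inside $K$, exactly as the Robin
  condition is stated; no separate boundary matrix is exposed.
* `temporal_convolve()` is the direct $O(T^2)$ causal double sum (exact
  match to the oracle is part of acceptance); the matrix form used for
  weight rows is verified against it.
* Degenerate inputs fail loudly: zero-volume elements, non-manifold faces,
  out-of-range connectivity, empty detector selections, all-unusable
  pairs, all-zero reconstructions.
* Consistent-mass FEM with a nodal impulse undershoots near the source at
  early steps (small negative field values); the gate-time far-field data
  are unaffected, and nonpositive gated excitation pairs are excluded.
* Single-gate reconstruction only by default; multi-gate stacking, other
  inverse solvers (regularized least squares, SART, CG), lifetime
  reconstruction, higher-order elements and radiative-transfer or
  telegraph-equation forward models are out of scope.
* Green's fields and measurements serialise as RDS; meshes and fields
  interchange as TetGen `.node`/`.ele` and legacy VTK; the gated system
  dumps as Matrix Market plus CSV.
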