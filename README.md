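# earlyfmt

Time-domain early-photon **fluorescence molecular tomography (FMT)** in R:
a finite-element forward model of the coupled time-domain diffusion
equations, Green's-function-based normalized-Born weight matrices, and
nonnegative algebraic reconstruction at a single early time gate.

FMT reconstructs the 3D distribution of a fluorescent probe in scattering
tissue from boundary light measurements. Gating on the earliest-arriving
photons (here, the 300 ps time node) uses the least-scattered light and
improves resolution, but forces a full time-domain computation. This
package is aimed at researchers prototyping time-domain diffuse optical
reconstruction methods on synthetic phantoms.

## Model

Excitation and emission photon densities obey coupled diffusion equations

```
(1/c) dPhi_v/dt + mu_a Phi_v - div(D grad Phi_v) = S_v,   D = 1/(3(mu_a + mu_s'))
```

with Robin boundary conditions `Phi + 2 q D dPhi/dn = 0`, the emission
source `(eta/tau) Phi_x * E` with lifetime kernel `E(t) = exp(-t/tau)`,
and `*` temporal convolution. Galerkin FEM over linear tetrahedra gives
sparse `K`, `C`; implicit Euler `(K + C/dt) G_{k+1} = (C/dt) G_k + S_k`
produces excitation (`G_s`) and detector-adjoint (`G_d`) Green's
functions, with one precomputed Cholesky factorization shared by every
source, detector and time step, and detector fields advanced as one
batched multi-column state. The gated Born weight matrix

```
W[(s,d), n] = c/(tau dt) * (G_s[n,] * E * (C G_d)[n,])[t_gate]
```

reproduces the coupled forward simulation exactly, and the normalized
system `Phi_m/Phi_x = W_nB eta` is solved by relaxed Kaczmarz (ART,
`lambda = 0.1`, 100 sweeps) with nonnegativity.

A synthetic heterogeneous phantom stands in for a small-animal torso: a
1.2 cm x 3 cm cylinder with heart/lung/liver-like ellipsoidal regions
(`mu_a` = 0.156/0.516/0.935, `mu_s'` = 9.0/21.2/6.4 1/cm over a 0.1/10
background), a 0.1 cm x 0.2 cm fluorescent target at (-0.31, -0.02, 1.93)
cm, 6 projections at 60 degree increments with a 120 degree detection FOV,
and 10% proportional Gaussian noise on the gated data.

## Worked example

```r
library(earlyfmt)

run <- run_pipeline(fmt_config())
print(run)
#> <fmt_run> 4617 nodes, 360 pairs, double precision, accelerated backend
#>   localization error: 0.01996 cm; mass within 0.5 cm: 92.07 %

stage_report(run)[, c("stage", "label", "seconds")]
#>   stage               label seconds
#> 1    T1 load data / phantom   0.748
#> 2    T2          assemble K   0.666
#> 3    T3             form Gs   2.405
#> 4    T4             form Gd   9.671
#> 5    T5              form W   1.649
#> 6    T6           solve eta   2.894
```

The default run meshes the phantom (~4.6k nodes), simulates noisy gated
measurements, builds the 360-pair normalized-Born system at 300 ps and
reconstructs the yield. The printed metrics say the recovered target
centroid lies 0.02 cm from the true centre and 92% of the recovered
fluorophore mass falls within 0.5 cm of it. Stage wall times are
informational; the detector Green's functions (T4) and weight matrix (T5)
dominate, which is why those two stages carry the batched and
precision-parameterized backends (`precision = "single"` rounds their
numerics to float32).

A thin command-line wrapper ships in `inst/scripts/`:

```sh
Rscript inst/scripts/earlyfmt all --config run.yaml --out out/
```

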