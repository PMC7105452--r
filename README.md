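# cardioem

Coupled cardiac electromechanics on simplicial meshes, in R with compiled
element kernels.

The package implements an orthotropic electro-viscoelastic tissue model:

* **Electrophysiology** — the monodomain equation
  `chi dv/dt - div(D(v, F, Pi) grad v) = g(v, r) + I_ext` with the
  four-variable minimal human ventricular cell model (epicardial constant
  set) for the reaction `g` and the gating kinetics of
  `r = (r1, r2, r3)`.
* **Mechanoelectrical feedback** — the conductivity
  `D = (D0 + D1 v) J C^-1 + (D0/2) J f0 (x) f0 + D2 J F^-1 Pi F^-t`
  carries geometric feedback (the Piola transform), porous-media
  self-diffusion (`D1`) and stress-assisted diffusion (`D2` against the
  Kirchhoff stress `Pi`).
* **Mechanics** — incompressible Holzapfel–Ogden orthotropic
  hyperelasticity with `(I4 - 1)+` compression gating, Kelvin–Voigt
  viscosity `sigma_visc = delta exp(beta tr(Bdot)) Bdot`, and either
  **active stress** (an orthotropic active Cauchy stress scaled by the
  tension `Ta`, itself a reaction–diffusion field driven by the calcium
  proxy `r3`) or **active strain** (the multiplicative split
  `F = F_E F_A` with `det F_A = 1` and shortening ODE
  `dxi/dt = K1/(1+r3) + K2 xi`).
* **Discretisation** — a stabilised three-field mixed-primal finite
  element scheme with the symmetric Kirchhoff stress (cell-wise
  discontinuous, degree `l`), displacement and pressure (continuous,
  degree `l+1`) on triangles/tetrahedra; the stress block is condensed
  exactly per element and re-enters the conductivity, which is the point
  of solving for it. Time stepping is semi-implicit operator splitting
  (explicit Rush–Larsen reaction, implicit lumped-mass diffusion,
  activation update, Newmark mechanics Newton solve).

Who it is for: numerical analysts and computational cardiology groups who
want a self-contained, scriptable reference implementation of
stress-assisted diffusion electromechanics with its verification and
benchmark suite, at desk scale.

## A worked example

A planar wave on the 12 mm slab used for conduction-velocity studies
(lowest-order elements, ~28k unknowns, Robin-supported viscoelastic
tissue, stress-assisted diffusion on):

```r
library(cardioem)
out <- cv_study(n = 44, dts = c(0.1), verbose = TRUE)
#> dt = 0.1 ms: CV = 0.9778 mm/ms
out$cv / 10      # on the reference table's printed scale
#> [1] 0.09778286
```

The wave crosses the probes on the line y = 7 mm at 0.98 mm/ms — the
coarse-mesh value; refining the time step moves it toward the ~1 mm/ms
range, and a fine-mesh 1D cable with the same constants propagates at
0.80 mm/ms, the physiological fibre velocity. The single-cell model
behaves like its published original:

```r
r0 <- run_0d(protocol = stimulus_protocol(stimulus(0, 3, 3)),
             T_end = 600, dt = 0.02)
r0$features
#> $peak
#> [1] 2.27507
#> $apd
#> [1] 269.3151
```

an action potential of 269 ms duration (APD90) from a 3 ms, amplitude-3
stimulus. Convergence of the steady coupled scheme:

```r
cv0 <- convergence_study(l = 0, levels = 5)
round(tail(cv0, 1)[, c("rate_Pi", "rate_u", "rate_p", "rate_v", "rate_Ta")], 3)
#>   rate_Pi rate_u rate_p rate_v rate_Ta
#> 5   0.998  1.007  0.976      1   0.999
```

first-order convergence for all fields at the lowest order, and
second-order with `l = 1` (see the methods vignette for the norms, the
verification material and the gating-variable treatment).

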