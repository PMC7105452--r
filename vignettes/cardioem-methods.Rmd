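---
title: "Methods: an orthotropic electro-viscoelastic model of cardiac tissue
  with stress-assisted diffusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orthotropic electro-viscoelastic cardiac electromechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`cardioem` simulates the two-way coupling between cardiac electrophysiology
and finite-strain tissue mechanics.

**Electrophysiology.** The transmembrane potential $v$ obeys the monodomain
equation in the reference configuration,
$$\chi\,\partial_t v - \nabla\cdot\{\mathbf D(v,\mathbf F,\boldsymbol\Pi)\nabla v\}
  = g(v,\vec r) + I_{\mathrm{ext}},\qquad
  \frac{d\vec r}{dt} = \vec m(v,\vec r),$$
with zero-flux boundaries and the four-variable minimal human ventricular
cell model supplying the reaction $g$ (the signed sum of a fast inward, a
slow outward and a slow inward current) and the kinetics of the gating
triple $\vec r = (r_1,r_2,r_3)$. Only the epicardial constant set ships;
the constants are exposed by name in `ionic_params_epi()` and the mapping
to the model's originally published symbols is the table in that help page.
Heaviside gates use the $H(0)=0$ convention, so $v=0$ carries no current.
Note two facts about "rest": the state $v=0$, $\vec r=(1,1,0)$ used as the
initial condition is quiescent in $v$, but $r_3$ relaxes to its
$\tanh$-shaped steady value $\approx 0.0215$, and the shortening law below
has a tonic equilibrium; the tests assert those behaviours rather than a
literal fixed point.

**Conductivity.** The diffusion tensor combines geometric feedback (the
Piola transform of an isotropic conductivity), a transversely isotropic
fibre term, porous-media self-diffusion, and stress-assisted diffusion
(SAD):
$$\mathbf D = (D_0 + D_1 v)\,J\mathbf C^{-1}
  + \tfrac{D_0}{2}\,J\,\mathbf f_0\otimes\mathbf f_0
  + D_2\,J\,\mathbf F^{-1}\boldsymbol\Pi\,\mathbf F^{-t},$$
with $\boldsymbol\Pi$ the *discrete* Kirchhoff stress of the mixed scheme
(this is the point of solving for the stress directly). The ambiguous
placement of $J$ in the printed fibre term is taken multiplicative, with a
`fibre_over_J` switch for the $D_0/(2J)$ reading. An ellipticity floor
clips eigenvalues of $\mathbf D$ at $10^{-6}D_0$ (configurable) and counts
clipped points instead of aborting, because diagnosing the loss of
ellipticity at large $D_2$ is itself a use case.

**Units.** Internally mm–ms–kPa. Stress-like moduli quoted in N/cm$^2$ are
stored $\times 10$. Diffusion constants are quoted in cm$^2$/s and
converted by `unit_scale = 0.1` to mm$^2$/ms; with the shipped constants a
fine-mesh planar wave travels at $\approx 0.8$ mm/ms along fibres, the
physiological scale. The reference conduction-velocity table that the
`cv_study()` driver reproduces prints its values on a scale consistent
with cm/ms (its coarse-mesh entry, 0.1032, corresponds to 1.03 mm/ms
here); the driver therefore reports both mm/ms and that printed scale. We
verified the alternative reading (numbers taken as mm$^2$/s) with an
independent 1D cable computation: its depolarisation front is then
$\sim 0.05$ mm wide and fails to propagate on any mesh coarser than
0.1 mm, including every mesh size the reference table lists, so that
reading is untenable.

**Mechanics.** Incompressible orthotropic Holzapfel–Ogden hyperelasticity
with the $(I_{4}-1)_+$ compression switch-off of the fibre/sheet terms
(strict inequality, one-sided gradient), optional Kelvin–Voigt viscosity
$\boldsymbol\sigma_{\rm visc} = \delta e^{\beta\,\mathrm{tr}\dot{\mathbf B}}\dot{\mathbf B}$
(with $\dot I_1 = \mathrm{tr}\,\dot{\mathbf B}$ and
$\dot{\mathbf B} = \dot{\mathbf F}\mathbf F^t + \mathbf F\dot{\mathbf F}^t$),
and two activation formalisms:

* *active stress*: an additive Cauchy stress with fibre, sheet–normal and
  normal–normal contributions weighted by the active tension $T_a$
  ($\kappa_{sn} = 0.6$, $\kappa_{nn} = 0.03$; no sheet–sheet diagonal
  term; in 2D only the fibre term survives);
* *active strain*: the multiplicative split
  $\mathbf F = \mathbf F_E\mathbf F_A$ with
  $\gamma_f=\xi$, $\gamma_s=(1+\xi)^{-1}(1+K_0\xi)^{-1}-1$,
  $\gamma_n=K_0\xi$, which gives $\det\mathbf F_A = 1$ identically. The
  elastic invariants are computed from $\mathbf F_E=\mathbf F\mathbf F_A^{-1}$
  directly; the printed modified-invariant formulas assume
  $\gamma_s=\gamma_n$, which the orthotropic law above does not satisfy in
  general, so they are kept only as a cross-check (a test verifies both
  agree when $\gamma_s=\gamma_n$ is imposed through $K_0$).

The Guccione transversally isotropic law is included for the cantilever
benchmark.

**Activation dynamics.** Active tension follows a reaction–diffusion law
$\partial_t T_a = \alpha_1 D_0\,\Delta T_a + \ell$. The printed reaction
$\ell = T_a - \alpha_2 r_3 + \alpha_3 I_{4f}$ is linearly *unstable* in
$T_a$ and incompatible with the bounded activation profiles the model is
meant to produce; the default is the relaxation form
$\ell = -T_a + \alpha_2 r_3 + \alpha_3 (I_{4f} - 1)$, with `literal_sign`
reproducing the printed form behind a divergence guard. Subtracting the
baseline from the stretch drive keeps the quiescent tissue at $T_a = 0$;
`stretch_offset = 0` gives the raw $I_{4f}$ drive. Within a time step the
$I_{4f}$ drive uses the last converged deformation. Shortening follows
$d\xi/dt = K_1(1+r_3)^{-1} + K_2\xi$, updated exponentially (exact for
frozen $r_3$) at quadrature points; note its resting equilibrium
$\xi^* = -K_1/K_2 = -0.1$ is not zero.

# Discretisation

**The three-field scheme.** The mechanical unknowns are the symmetric
Kirchhoff stress $\boldsymbol\Pi$, the displacement $\mathbf u$ and the
pressure $p$: a constitutive projection
$\int_\Omega [\boldsymbol\Pi - \mathcal G + pJ\mathbf I]:\boldsymbol\tau$,
the momentum balance
$\int_\Omega \boldsymbol\Pi\mathbf F^{-t}:\nabla\mathbf v$ with Robin
boundary springs $\int_{\partial\Omega}\eta\,\mathbf F^{-t}\mathbf u\cdot\mathbf v$,
and the incompressibility constraint $\int_\Omega (J-1)q$. On triangles and
tetrahedra, $\boldsymbol\Pi$ is a cell-wise discontinuous symmetric tensor
of degree $l$ and $\mathbf u$, $p$ are continuous of degree $l+1$,
$l\in\{0,1\}$. Because the $\boldsymbol\Pi$ test space is discontinuous,
its block of the system is block-diagonal and the stress is eliminated
exactly inside the element kernels (a cell-local $L^2$ projection of
$\mathcal G - pJ\mathbf I$); the projected stress — not the raw
constitutive one — enters the momentum residual and the SAD term, and is
recovered by `mech_stress()`. The equal-order pressure pair is stabilised
with the mesh-dependent term
$\zeta_{\rm stab}\sum_K h_K^2(\nabla p,\nabla q)_K$. Follower pressure
loads use Nanson's relation (traction $-p_N J\mathbf F^{-t}\mathbf n$,
pressure pushing into the domain — the sign that inflates a chamber and
lifts the benchmark beam); dead tractions and strong normal-displacement
constraints are also available.

**Time stepping.** One semi-implicit cycle per step, no sub-iterations:
explicit ionic reaction with a Rush–Larsen gate update; implicit
conductivity solve with an inner Newton over the self-diffusion, mass
lumped; the activation update; then the mechanics Newton solve with
Newmark inertia ($\beta=1/4$, $\gamma=1/2$; the time integrator is the
package's choice). The mechanics Newton reuses its factorised Jacobian
across iterations and steps, refreshing it when progress slows; Jacobians
are finite-difference element matrices (central differences, step
$10^{-6}$) assembled in compiled kernels.

**Numerical choices.** Quadrature of degree $2(l+1)+2$ for mechanics and
$2(l+1)$ for the monodomain operator (symmetric Gauss rules on triangles,
conical-product rules on tetrahedra); the longest cell edge defines
$h_K$; line searches accept on the residual 2-norm because the max-norm
can sit on the compression-gating kinks; a bounded-growth first step
accommodates the nonmonotone Newton path of the incompressible saddle
problem; Dirichlet rows are imposed by row substitution.

# The steady verification problem

A manufactured steady state of the full coupled system (active stress,
no viscosity) on the unit square checks the convergence orders: closed
forms for $\mathbf u$, $p$, $v$, $r$, $T_a$ with fibre frame
$\mathbf f_0=(0,1)$, $\mathbf s_0=(-1,0)$, simplified kinetics
$m = v - r^2$, $g = (v-1)vr$, $\ell = -T_a + r$, forcing terms computed
from the closed forms by central differences of the exact fluxes, exact
Dirichlet data for $\mathbf u$, $v$, $T_a$, the constraint $J = J_{ex}$,
and a mean-value multiplier pinning the pressure. Errors are measured in
$L^2$ for $\boldsymbol\Pi$ and $p$ and $H^1$ for the other continuous
fields; observed orders are $\approx l+1$ for all of them
(`convergence_study()`).

Three design points deserve a record:

* *Gating variable.* The weak form only asks $\vec r\in L^2$, and the
  steady gating relation $v - r^2 + f_r = 0$ is algebraic with a
  square-root branch structure: a continuous nodal discretisation of $r$
  degenerates on the manufactured field's zero lines (its Newton block is
  exactly singular there and the even nonlinearity invites branch flips).
  The driver therefore solves the relation pointwise at quadrature points
  on the branch of the exact field, consistent with how the transient
  solver stores internal variables. The square root maps an $O(h^{l+1})$
  potential error to an $O(h^{(l+1)/2})$ gating error inside a shrinking
  strip around the zero set; in $L^2$ the field still converges at
  $\approx l+1$ (slightly above, from the strip localisation), and that is
  the norm reported for $r$.
* *Verification material.* The manufactured deformation compresses fibres
  over part of the domain, so the $(I_4-1)_+$ kinks of the production law
  would cap the attainable smoothness of the exact stress at $H^{3/2}$ and
  with it the $l=1$ orders; dropping the gate but keeping the full
  anisotropy instead destabilises the compressive branches (the moduli are
  large enough that Newton limit-cycles). The verification problem
  therefore uses `ho_params_verification()`: the patient-specific constant
  set with the fibre/sheet moduli reduced a hundredfold and smooth
  (ungated) exponents — smooth, stable, still orthotropic. The production
  (gated, full-strength) law is exercised by the finite-difference energy
  tests and the mechanics benchmarks instead.
* *Stabilisation.* $\zeta_{\rm stab} = 0.25$ at lowest order; at second
  order the same constant visibly over-stabilises (the consistency error
  of the $h^2$-weighted term then dominates the pressure error), so the
  driver uses $\zeta_{\rm stab} = 0.002$ for $l=1$. The unit-square test
  is non-dimensional: the diffusion constants enter as printed, unlike
  the physical slab runs.

The ladder starts at $n=4$ subdivisions: on the $n=2$ mesh the exact
gating field vanishes at every vertex and the problem degenerates. Five
levels for $l=0$ ($n=4\dots64$) and four for $l=1$ ($n=4\dots32$) are run
by default — problem sizes chosen so the whole study stays in the minutes
range on one CPU.

# Experiments

* `cv_study()`: the 12 mm slab at $44\times44\times2$ triangles
  ($h=0.39$ mm, $\approx\!28$k unknowns at lowest order, Robin
  boundaries, $\zeta_{\rm stab}=2.5$), S1 from the left edge, probes on
  the line $y=7$ mm at $x = 3, 9$ mm, threshold $v^*=0.5$ with linear
  crossing interpolation. The reference table's exact mesh and probe
  layout are not published; these choices are the package's and are
  exposed as arguments.
* `cook_membrane()`: the tapered panel, clamped left edge, upward shear
  load $t=(0,100)$ read in kPa (the unit its section uses for the beam's
  pressure), constant $T_a = 0.7$ kPa, adaptive incremental loading.
* `land_beam()`: the $(0,10)\times(0,1)^2$ mm Guccione cantilever with
  follower pressure $p_N = 0.004$ kPa on its bottom face.
* `spiral_run()`: S1–S2 on the 50 mm slab with the printed timing
  (S2 at 330 ms over the bottom-left quadrant, both stimuli amplitude 3
  for 3 ms), with the persistence surrogate "share of nodes above
  $v=0.5$ stays within $(0.02, 0.9)$ over 400–500 ms".
* `viscosity_comparison()`: a planar wave on a 3D slab run with
  $\delta = 226$ kPa ms and $\delta = 0$, comparing peak displacement and
  peak Frobenius norm of $\boldsymbol\Pi$. The default geometry
  ($20\times20\times5$ mm at 2.5 mm resolution) is a scaled-down stand-in
  for the full $50\times50\times10$ mm study.

# What the synthetic conditions do and do not show

The drivers generate all inputs in code: structured slabs with constant
analytic fibre fields, the printed stimulus protocols, and the printed
constant sets. They emulate the tissue-level experiments of the source
model — planar and re-entrant propagation, benchmark loading — but not
patient-specific anatomy, rule-based fibre architectures, transmural
cell heterogeneity or pericardial contact; passing tests therefore
validate the discretisation and couplings, not organ-scale predictions.
Two quantitative caveats are recorded in the unit discussion above: the
conduction-velocity table is matched on its printed scale within a few
percent at the finer time steps but our splitting *damps* the front at
$\Delta t = 0.3$ ms where the reference's increases, and with the
physiological conduction velocity the printed 50 mm S1–S2 protocol
produces a transient broken wave rather than a compact sustained rotor
(the excitation wavelength, CV $\times$ APD $\approx 160$ mm, exceeds the
domain).

# Known limitations

Lowest-order dynamics only in 3D benchmarks by default; no quadrilateral
or hexahedral elements; no restitution-protocol automation or alternans
analysis; the stress-assisted window in $D_2$ is solver-dependent and
reported, not certified; $\rho_0 = 0.001$ is stored as printed (its unit
in the source table is a stress, which cannot be reconciled with a
density — inertial effects are correspondingly mild).

One further numerical observation: the Cook membrane is modelled as an
incompressible 2D continuum with no bending stiffness, and the compressed
band that the upward shear induces wrinkles at a mesh-dependent load
(roughly halving per uniform refinement). The refinement and
stabilisation-insensitivity studies therefore run at a sub-critical load
(5 kPa by default in the tests), where the tip deflection converges
cleanly; the printed benchmark load completes only at coarse resolution.
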