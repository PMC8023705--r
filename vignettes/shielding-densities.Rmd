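---
title: "Computing and decomposing nuclear magnetic shielding densities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing and decomposing nuclear magnetic shielding densities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shieldens)
```

## The model

An external magnetic field $\mathbf{B}$ induces a current density in a
closed-shell molecule. Because the induced current is linear in the field,
the natural object is its derivative, the current-density susceptibility
tensor (CDT)

$$\mathcal{T}_{\alpha\beta}(\mathbf{r}) \;=\;
  \frac{\partial J_\alpha(\mathbf{r})}{\partial B_\beta},$$

a $3\times 3$ tensor field. By the Biot–Savart law, the current at
$\mathbf{r}$ contributes to the magnetic field felt by nucleus $I$ at
$\mathbf{R}_I$, and hence to its NMR shielding tensor
$\sigma^I_{\alpha\beta}$. In Hartree atomic units (where the SI prefactor
$\mu_0/4\pi$ becomes $\alpha^2$, the squared fine-structure constant) the
*shielding density* for component $(\alpha,\beta)$ is

$$\varsigma^I_{\alpha\beta}(\mathbf{r}) \;=\;
  \alpha^2\,
  \frac{\big[\boldsymbol{\mathcal{T}}_{\cdot\beta}(\mathbf{r})
        \times \mathbf{u}\big]_\alpha}{|\mathbf{u}|^{3}},
  \qquad \mathbf{u} = \mathbf{r}-\mathbf{R}_I,$$

and $\sigma^I_{\alpha\beta} = \int \varsigma^I_{\alpha\beta}\,d^3r$.
Positive regions shield the nucleus, negative regions deshield it; the
sign at a point is set by the direction of the local current relative to
the studied nucleus, not by the tropicity of the global circulation. The
scalar field is reported in ppm bohr$^{-3}$ (values $\times 10^6$) and
its integral in ppm.

### The CDT from GIAO density matrices

Finite basis sets make magnetic properties gauge-origin dependent unless
the basis functions carry London phases (gauge-including atomic orbitals,
GIAOs). With a real solid-harmonic AO basis $\chi_\mu$ centered at
$\mathbf{R}_\mu$, a symmetric density matrix $D$, and perturbed matrices
$P^\beta = \mathrm{Im}\,(\partial D/\partial B_\beta)$ (real,
antisymmetric), differentiating the GIAO current density at $B=0$ gives
the expression implemented in `eval_cdt()`:

$$\mathcal{T}_{\alpha\beta}(\mathbf{r}) =
 -\sum_{\mu\nu} P^\beta_{\mu\nu}\,\chi_\mu \partial_\alpha \chi_\nu
 +\tfrac12 \sum_{\mu\nu} D_{\mu\nu}
   \big[(\mathbf{R}_\nu-\mathbf{R}_\mu)\times\mathbf{r}\big]_\beta
   \chi_\mu \partial_\alpha \chi_\nu
 -\tfrac12\,\epsilon_{\alpha\beta\gamma} \sum_{\mu\nu} D_{\mu\nu}
   \chi_\mu \chi_\nu\, (\mathbf{r}-\mathbf{R}_\nu)_\gamma .$$

The three terms are the paramagnetic response, the London-phase transfer
term, and the diamagnetic term. The derivation starts from
$\mathbf{J} = -\mathrm{Re}\,[\tilde\rho\,(\mathbf{p}+\mathbf{A})]$ with
$\tilde\chi_\mu = e^{-\frac{i}{2}(\mathbf{B}\times(\mathbf{R}_\mu-\mathbf{R}_O))\cdot\mathbf{r}}\chi_\mu$
and an arbitrary gauge origin $\mathbf{R}_O$; collecting first-order
terms, every occurrence of $\mathbf{R}_O$ cancels between the vector
potential and the phase derivatives, which is why no gauge-origin
parameter exists anywhere in the implementation. A single-center
closed-shell $s$ density with $P^\beta = 0$ collapses the expression to
the classical Larmor form
$-\tfrac12\rho(\mathbf{r})\,\epsilon_{\alpha\beta\gamma}(\mathbf{r}-\mathbf{R})_\gamma$,
whose isotropic Biot–Savart integral is the Lamb formula
$\sigma = \tfrac{\alpha^2}{3}\langle 1/r\rangle$ — the end-to-end oracle
used in the tests.

Two properties of this formulation are worth spelling out because the
test suite asserts them:

* **Gauge-origin independence.** The oracle in the tests evaluates the
  full complex finite-field current with an explicit, randomly placed
  gauge origin and differentiates numerically; agreement with the
  analytic expression to $10^{-10}$ at random points is therefore also a
  test of the cancellation.
* **Translation covariance.** The GIAO phases reference absolute shell
  centers, so a rigidly translated engine solution carries extra
  center-pair phases. To first order in $B$ the perturbed matrices of
  the translated system are
  $P'^\beta_{\mu\nu} = P^\beta_{\mu\nu} + \tfrac12 [(\mathbf{R}_\nu -
  \mathbf{R}_\mu)\times \mathbf{t}]_\beta D_{\mu\nu}$ for a shift
  $\mathbf{t}$. With this transformation the CDT field translates
  exactly; the tests verify covariance to machine precision.

### Engine interface

The electronic-structure problem itself (SCF/DFT and the
coupled-perturbed equations) is deliberately out of scope: any engine
that exposes $D$, $\partial D/\partial B$, the overlap matrix and the
basis can feed the pipeline through `adapt_engine()`, which permutes the
AO ordering to the canonical one (shells in input order, $m=-l..l$
within a shell), flips signs for engines that differentiate with respect
to $-\mathbf{B}$, and validates every invariant (density symmetric to
1e-10, perturbed matrices antisymmetric to 1e-8,
$\mathrm{tr}(DS)=n_{\mathrm{el}}$ to 1e-8). Bundles travel as a single
self-describing JSON container with full-precision (17 significant
digit) floats, so a write/read round trip is bit-identical.

## Quadrature

Shielding integrals are evaluated on standard multicenter molecular
grids:

* **Radial rule.** A trapezoidal rule on an exponentially mapped
  coordinate, $r_k = c\,(e^{kh}-1)$. On the pure exponential map the
  discretization error for Gaussian integrands
  $r^{2l+2}e^{-ar^2}$ is *scale invariant*; Poisson summation gives the
  relative error $2\,|\Gamma(l+\tfrac32 + i\pi/h)|/\Gamma(l+\tfrac32)$,
  which the implementation inverts for the step $h$ at the requested
  accuracy (default $10^{-12}$). The outermost node comes from the tail
  (an upper incomplete gamma) of the most diffuse exponent the grid must
  integrate, the innermost from the small-$r$ truncation error of the
  steepest; both default to per-element exponent ranges bracketing
  triple-zeta basis sets and are overridden by the actual basis when a
  bundle supplies one.
* **Angular rule.** Octahedrally symmetric Lebedev-type grids. The
  supported ladder (6, 14, 26, 38, 50, 86, 110, 146, 170, 194 points;
  algebraic degrees 3–23) was constructed by solving the spherical
  moment equations for the classical orbit compositions once
  (`data-raw/lebedev-solve.R`, a Levenberg–Marquardt solve with the
  weights eliminated by variable projection) and freezing the orbit
  parameters. The classical 74-point grid is omitted deliberately: its
  known solution carries a negative weight, which would violate the
  nonnegative-weight invariant of the atomic grids. Every shipped grid
  integrates all spherical harmonics up to its degree to round-off,
  which the test suite re-verifies.
* **Becke partitioning.** Space is divided into fuzzy atomic cells by
  the iterated smoothed step $s(\mu)$ with iteration order $k=3$,
  applied to the confocal coordinate of each atom pair. Weights sum to
  one at every point, so the atomic decomposition is exact by
  construction — only quadrature error remains. Cell radii are
  Bragg–Slater radii with Becke's heteronuclear size adjustment on by
  default and hydrogen set to 0.35 Å (Becke's recommendation); both
  choices are exposed in `becke_spec()` because the hydrogen radius
  visibly moves the H/C domain boundary in decomposition tables.

Default grid settings (`angular_order = 194`, `radial_accuracy =
1e-10`–`1e-12`) integrate a two-center Gaussian density to about
$10^{-6}$ relative and reproduce the Lamb shielding to well below
0.01 ppm; tests that only need partition-of-unity or topology checks run
at coarser settings to keep the suite fast.

### Singularity handling

The Biot–Savart kernel diverges as $|\mathbf{u}|^{-2}$ at the studied
nucleus. It is integrable: radial grids centered on atom $I$ place no
node at $r=0$, and any point within $10^{-10}$ bohr of $\mathbf{R}_I$ is
additionally excluded (the integrand treated as 0 there) for robustness
against user-supplied grids.

## Analytic models

Two closed-form current models serve as engine-free oracles and
qualitative stand-ins:

* `make_loop_provider()` — a toroidal ring current with a Gaussian
  cross-section (total circulation per unit field `strength`,
  cross-section width `width`). Azimuthal fields with axisymmetric
  magnitude are divergence-free by construction. In the thin-profile
  limit the induced field at the center approaches the textbook
  $\mu_0 I/2R$; at finite width the reference is a 1-d/2-d quadrature
  of the profile, carried out independently of the package's grids.
  A *diatropic* loop circulates so that its induced field at the loop
  center opposes the external field; with the package's sign
  convention (field along $+z$) its $\sigma_{zz}$ density at the center
  is positive, matching the convention that shielding regions plot blue.
* `make_vortex_provider()` — the Larmor diamagnetic current
  $-\tfrac12\rho(r)\,(\hat{\mathbf{e}}_\beta\times(\mathbf{r}-\mathbf{c}))$
  of a normalized Gaussian density, whose center shielding is the Lamb
  formula exactly.

`benzene_like_composite()` superimposes a diatropic perimeter loop, a
weaker paratropic inner loop, and six atomic vortices on a hexagonal
ring (ring radius 2.63 bohr, the carbon-ring radius of benzene). The
strengths (1 : 0.35) were chosen once so that the perimeter current
dominates, as in an aromatic ring; the model reproduces the qualitative
sign topology of aromatic shielding-density maps — shielding outside the
studied proton and on the far side of the ring, deshielding where the
diatropic current passes inside the proton, a near/far asymmetry from
the inner paratropic loop. It is used for map smoke tests only and is
never compared against ab initio numbers.

### What the synthetic fixtures do and do not show

The minimal response bundles (`make_min_bundle()`) are 1–2 $s$-type
centers with hand-chosen density matrices. They exercise every term of
the CDT expression (the finite-field oracle validates paramagnetic,
London and diamagnetic contributions together, at random gauge origins),
but they do not probe high angular momenta, large AO counts, or
linear-dependence pathologies of real triple-zeta basis sets. Likewise
the analytic models validate the Biot–Savart kernel, the grids and the
unit chain end to end, but a passing suite does not certify agreement
with any particular ab initio calculation — that comparison requires an
engine bundle and the quadrature-vs-analytic gates (0.1 ppm for
$^1$H, 0.5 ppm for $^{13}$C) built into the acceptance tests.

## Decomposition tables

`decompose_atomic()` integrates the shielding density separately over
every Becke cell. Each row carries the total, its pointwise positive and
negative parts (computed on the quadrature sum, so
positive + negative = total exactly; the split, unlike the total, is
mildly grid-dependent because the sign is evaluated pointwise), and the
percentage of the grand total. Percentages are computed from unrounded
values and may be negative for domains that deshield on balance. A
labeling map merges symmetry-equivalent atoms (ipso/ortho/meta/para) into
single rows; the default is one row per atom, since merged rows
presuppose symmetry knowledge the package cannot infer safely.

## Numerical choices and edge cases

* Internal units are atomic units throughout; shieldings are reported in
  ppm ($\times 10^6$), lengths in bohr (XYZ input converts from
  ångström with 1.8897261254578281 bohr/Å).
* Angular momenta up to $l=6$ are supported in the AO evaluator; the
  solid-harmonic polynomials are built by recursion and verified against
  the Laplace equation and sphere orthonormality rather than hard-coded
  tables.
* Points coinciding with a basis-function center are evaluated normally
  (Gaussians are smooth); only the kernel's own nucleus is excluded.
* A zero provider produces an all-zero decomposition; percentages are
  then reported as 0 with an explicit `degenerate` flag rather than NaN.
* All computations are deterministic: identical configurations produce
  byte-identical CSV outputs.
* Angular grids are unpruned (one angular order for all radial shells).
  Radial pruning would roughly halve the point counts at the cost of a
  second accuracy parameter; per-element point counts of the unpruned
  defaults are logged by `cmd_atoms()` so runs remain auditable.

## Known limitations

* No electronic-structure solver is bundled; all ab initio results
  require an external GIAO-capable engine behind `adapt_engine()`.
  Cartesian-AO engines must convert to solid-harmonic ordering in the
  adapter.
* The Becke split into atomic domains is one defensible choice among
  several; different cell functions or radii move the per-atom numbers
  (not the grand total).
* The angular ladder tops out at 194 points (degree 23). For very
  oscillatory integrands — currents far from all grid centers, or
  nuclei far outside the density — accuracy is limited by the angular
  rule, and adding pseudo-centers near the current distribution is the
  recommended workaround.
* Only the field-derivative (susceptibility) current is computed; there
  are no finite-field currents, no spin–spin couplings, and no
  magnetizability maps.
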