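---
title: "Modelling static compression damage in kiwifruit: methods and design notes"
author: "kiwifem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling static compression damage in kiwifruit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kiwifem)
```

kiwifem studies how a kiwifruit is damaged when it is squeezed between two
flat plates - the situation a fruit meets in grading lines, packed boxes
and stacked crates.  The package covers the whole chain of the analysis:
tissue-level material testing, a multiscale finite-element model of the
fruit (skin, flesh, core), displacement-controlled compression with
frictional plate contact, and the translation of the computed stress
fields into practical damage statements, including the maximum number of
fruits that can safely be stacked in a column.

This vignette explains the models, their assumptions, the tunable
parameters, and the numerical and design decisions - in the spirit of a
methods section, not a user manual.  Function-level documentation lives in
the help pages; the README shows a worked example.

## Tissue constitutive model

Fruit parenchyma under moderate monotonic compression is well described by
a *bilinear elastoplastic* idealization.  The stress-strain curve of a
specimen rises linearly with Young's modulus $E$ (the slope "Tan
$\alpha$" of the elastic interval) until the *bio-yield point*
$(\varepsilon_y, \sigma_y)$, where cell walls begin to rupture; beyond it
the curve continues with the shallower *tangent modulus* $E_t$ (the slope
"Tan $\beta$" of the plastic interval, measured on total strain).  In
three dimensions we use small-strain $J_2$ (Von Mises) plasticity with
linear isotropic hardening:

$$ q(\boldsymbol\sigma) \;=\; \sqrt{3 J_2} \;\le\; \sigma_y + H\,\bar\varepsilon^p,
\qquad H = \frac{E\,E_t}{E - E_t}, $$

where $\bar\varepsilon^p$ is the equivalent plastic strain.  The
conversion from the measured total-strain tangent $E_t$ to the plastic
hardening modulus $H$ makes the simulated uniaxial post-yield slope equal
$E_t$ exactly (`hardening_modulus()`; verified to $10^{-6}$ by a
strain-driven material-point loop in the tests).

The reference constants shipped with the package
(`default_materials()`) are the measured values for ripe "Xuxiang"
kiwifruit:

| tissue | $E$ (MPa) | $E_t$ (MPa) | $\sigma_y$ (MPa) | $\nu$ | density (g/cm³) |
|---|---|---|---|---|---|
| skin (tension) | 10.233 | - | 0.514 (rupture) | 0.30 | 0.99 |
| core | 4.499 | 1.381 | 1.306 | 0.30 | 1.154 |
| flesh, axial | 2.305 | 0.967 | 0.491 | 0.40 | 1.248 |
| flesh, radial | 1.346 | 0.642 | 0.292 | 0.40 | 1.248 |

Notes on these data:

* **Flesh anisotropy.**  The fibres of the flesh run along the
  stem-blossom axis, so the flesh is modelled as *transversely isotropic*:
  engineering constants $E_\text{axial}$, $E_\text{radial}$, one Poisson
  ratio $\nu = 0.40$ for both couplings, and - because no shear modulus
  was measured - the common closure
  $G = E_\text{radial} / (2(1+\nu))$ for both the in-plane and
  out-of-plane shear.  The assembled compliance is checked for positive
  definiteness at construction.
* **Flesh yield.**  The measurements provide separate axial and radial
  bio-yield/tangent pairs but no anisotropic yield surface.  We keep an
  isotropic $J_2$ surface and select the pair that matches the simulated
  loading direction (axial constants for axial compression, radial for
  radial).  A Hill-type anisotropic surface would need data that do not
  exist for this cultivar.
* **Skin.**  The skin is brittle: linear to a rupture stress of
  0.514 MPa with no plastic branch.  The fruit model treats it as linear
  elastic (rupture propagation is out of scope); the damage report instead
  flags skin area whose Von Mises stress exceeds the rupture stress.
* **Skin density.**  Two values are reported for the skin (0.551 in the
  tabulated data, 0.99 ± 0.03 g/cm³ in the accompanying text); the table
  unit (g/mm³) is physically implausible, so 0.99 g/cm³ is the default and
  the tabulated number ships as `density_alt`.  Density is unused by the
  quasi-static solver either way.

The radial-return update (`radial_return()`) is semi-implicit: the flow
direction is frozen at the trial normal and the plastic multiplier is
found by a scalar Newton iteration until the yield residual is below
$10^{-12}\sigma_y$.  For isotropic elasticity this reduces to the
classical one-step return
$\Delta\gamma = (q^\text{trial} - \sigma_y - H\bar\varepsilon^p)/(3G+H)$;
for the anisotropic flesh the iteration restores consistency exactly.

## Specimen analysis

`analyze_specimen()` converts a force-displacement record to
stress-strain by $\sigma = F/S$ and $\varepsilon = \Delta L / L$ and then
locates the bio-yield point by *two-segment piecewise-linear least
squares*: every admissible split of the samples is fitted with two
independent lines and the split with the smallest total squared error is
kept.  A breakpoint counts as a bio-yield point only if the post-break
slope drops by at least `min_drop` (default 25%) relative to the
pre-break slope; a negative post-break slope is classified as brittle
rupture (skin), and no qualifying slope change means "no yield point".
This operationalizes the definition of the two moduli as slopes of the
elastic and plastic intervals; the breakpoint estimate is the
intersection of the two fitted lines, which is exact for noiseless
bilinear data regardless of where the samples fall.

Fit windows are deliberate, configurable choices (no windows are given
with the published table): $E$ is the through-origin least-squares slope
on strains in $[0.2, 0.9]\,\varepsilon_y$ (staying clear of both the toe
region and the knee), and $E_t$ is the least-squares slope of the
post-yield samples up to the stress peak.  A configurable `toe_strain`
lets the user skip an initial compliant toe; it defaults to 0.

At 1% relative force noise the round-trip recovers $E$ within ±3% with
bias below 1% over 100 seeded replicates (tested), and the bio-yield
stress within 5%.

## Fruit geometry and meshing

The fruit solid is a parametric tri-axial ellipsoid (mean cohort
dimensions 65.83 × 55.43 × 51.16 mm) with an embedded ellipsoidal core
(52.42 × 18.41 × 9.79 mm) and the skin as a 0.5 mm membrane on the outer
surface.  A laser-scan-based geometry is out of scope; the
`"scanned_inferred"` preset adjusts the long-radial axis to 54.4 mm,
back-computed from the published loading-protocol displacement at the 10%
level, and is flagged as an inference.

Meshing is deterministic and structured (a *cubed-sphere* layout): an
inner cube block is wrapped in radial shell layers whose outermost nodes
lie exactly on the ellipsoid; each hexahedral cell is split into six
tetrahedra.  Three grading choices matter and are worth recording:

* mapping a *complete* cube grid onto the ball (either by radial
  projection or by the smooth polynomial cube-ball map) produces sliver
  elements at the cube corners whose quality degrades with refinement,
  because corner cells have seven of their eight vertices on the
  boundary.  The cubed-sphere topology avoids this; the minimum scaled
  Jacobian stays around 0.1 at every refinement level;
* the lattice is graded toward the cube-face centres
  ($u \mapsto u(1 - b + b u^2)$, $b = 0.4$), because the cube-sphere map
  is coarsest exactly at the six axis poles - where plate contact
  happens;
* shell layers are graded toward the surface (exponent 1.8), where the
  contact stress and damage gradients live.

Refinement level $r$ uses $n = 2(r+1)$ grid divisions and
$L = \lceil n/3 \rceil$ layers, giving exactly $(n+1)^3 + (6n^2+2)L$
nodes and $6(n^3 + 6n^2L)$ tetrahedra.  The default $r = 4$ (20,400
tetrahedra, ~11,000 degrees of freedom) is a desk-scale compromise: the
plate force at 2.5% axial strain changes by less than 5% between $r = 4$
and $r = 5$ (tested), and a full four-level compression sweep of one
direction runs in about a minute on one CPU.  Elements are tagged `core`
when their centroid falls inside the core ellipsoid; the core-flesh
interface is therefore non-conforming by one element - a documented
limitation consistent with the ~5% core volume fraction converging to its
analytic value.

## The compression solver

`solve_compression()` is an implicit quasi-static, displacement-driven
Newton solver: the lower plate is fixed, the upper plate advances in
equal increments (default: one per 0.5% strain) to the target strain
level, defined as plate travel over the initial plate-to-plate dimension.
The loading rate of the physical protocol (3 mm/min) is slow enough that
inertia is irrelevant, which is why an implicit static formulation
replaces explicit dynamics: it is deterministic, has no mass scaling, and
gives machine-precision equilibrium at every increment (upper and lower
plate reactions balance to the Newton tolerance).

*Elements.*  Linear tetrahedra for flesh and core (with the consistent
elastoplastic rank-one tangent), constant-strain membrane triangles
(plane stress, 0.5 mm) for the skin.  Linear tetrahedra at $\nu = 0.4$
carry a known risk of mild volumetric locking; this is accepted - the
Hertz benchmark below bounds the effect - and all element-level work is
vectorized over elements, so the solver is pure R plus sparse Cholesky
factorizations (supernodal CHOLMOD).

*Contact.*  Contact with the rigid plates went through three designs, and
the final one is worth explaining because the intermediate ones fail in
instructive ways:

1. *node-on-plane penalty* (one spring per surface node) makes the force
   jump as individual nodes pop in and out of contact: at desk
   resolution the contact patch spans only one or two surface elements,
   and the Hertz sphere benchmark scattered by ±25% between refinement
   levels;
2. *facet-quadrature penalty* (pressure sampled at three points per
   surface triangle) is smooth but over-constrains: about six gap
   samples per surface node lock the facets against the curvature of the
   rigid surface and overshoot the Hertz force by 40-50%;
3. the final scheme is a *mortar-style node-averaged penalty*: the gap is
   averaged per surface node over its facet ring with area weights (one
   smooth constraint per surface node), which removes both failure
   modes.

Two geometric corrections complete the contact model.  Gaps are measured
against the *exact* ellipsoid surface at each point's lateral position,
so the plates start exactly tangent to the fruit rather than to the
inscribed polyhedron; and the unmeshed sliver between a facet and the
exact surface (the sagitta, up to ~0.2 mm at default refinement) acts as
an elastic layer in series with the penalty, with the stiffness of a thin
material column (constrained modulus over height).  Treating that sliver
as rigid - the naive exact-gap formulation - inflates small-strain
contact forces appreciably.

*Friction.*  Coulomb friction (default $\mu = 0.428$) uses the
elastic-Coulomb regularization: tangential stick springs with the normal
penalty stiffness, slipping at $|t| = \mu p$.  Stick/slip switching is
non-smooth and can cycle within a Newton loop, so after three iterations
the friction forces are frozen for the rest of the increment and the
anchors are reconciled at commit.  The effect of friction on the
axial reaction is marginal in this geometry (< 0.3% on the fruit, < 3%
on the Hertz sphere - tested), matching the expectation for
near-Hertzian kinematics.

*Penalty parameter.*  The default penalty pressure stiffness is
$100\,C_\text{max}/h$ (stiffest modulus over surface element size), which
keeps penetrations near $10^{-3}$ mm - three orders below the imposed
travel - while leaving the system well conditioned.  External work
balances stored strain energy (solid + membrane + contact springs) to
0.05% in the elastic range (tested at 1% sphere compression).

*Rigid-body control.*  Frictionless plate contact leaves five rigid-body
modes; they are pinned by fixing the lateral components of the two
contact-pole nodes and one tangential component of an equatorial node -
all locations where symmetry makes the constrained reactions vanish.

## Verification ladder

The solver is verified bottom-up, each level against an independent
oracle:

1. single-tetrahedron stiffness against a Vandermonde-basis closed form
   ($10^{-12}$);
2. rigid-body modes in the stiffness kernel; affine patch test exact to
   $10^{-10}$ for both isotropic and transversely isotropic materials;
3. a block between frictionless plates carries exactly $F = E A
   \varepsilon$ (contact machinery, 1%);
4. elastic work balance (0.05%);
5. Hertz elastic-sphere contact: at 1% diametral compression the
   computed force sits 10-25% above the closed form
   $F = \tfrac43 E^* \sqrt R\,\delta^{3/2}$ depending on refinement.
   This is the accuracy frontier of the discretization: the contact
   patch radius $\sqrt{R\delta}$ spans barely one surface element at
   desk scale, and closing the gap to a few percent would need roughly
   forty grid divisions per cube edge (~600k tetrahedra), an order of
   magnitude beyond the intended problem size.  The remaining error is
   an overshoot, consistent with the known stiffness excess of linear
   tetrahedra in indentation;
6. mesh convergence of the whole-fruit force (< 5% across the last two
   refinement levels) and mirror symmetry of the Von Mises field across
   both transverse planes (< 5%, compared per parent hex on the subdomain
   whose hexes possess an exact mirror partner).  The six-tet split is
   not reflection-invariant: a curved-face hex and its mirror image are
   decomposed into slightly different regions, so no discrete mirror map
   exists for the shell cells and an element-level comparison there
   measures the pairing mismatch, not the field.  The planar-faced inner
   block - flesh interior and core - pairs exactly and is where the
   comparison is made.

## Damage assessment and stacking

An element is *damaged* when its Von Mises stress reaches the bio-yield
stress of its tissue (for flesh, the value matching the loading
direction; for skin, the rupture stress).  `classify_damage()` reports
volume-weighted damaged fractions per tissue and strain level, the
*onset strain* (smallest tested level whose flesh fraction exceeds
`onset_frac`, default 0.5% - a deliberate, configurable definition of
"noticeable damage"; the published analysis is qualitative and states no
fraction), and the *damage-threshold force*: the plate force at the 5%
strain level, below which no flesh damage is predicted.

`stacking_count()` turns the threshold force into the classic crate
question: under ideal vertical stacking the bottom fruit bears the
weight of the column above it, so the safe column height above the
bottom fruit is $\lfloor F_{5\%} / (m g) \rfloor$ fruit weights (mean
mass 97.11 g, $g = 9.81$ m/s²).  With the published threshold forces
(75.82 / 47.512 / 51.99 N) this gives 79 / 49 / 54 - two to three counts
above the published safe bounds of 77 / 48 / 53, whose exact arithmetic
(g value, mass percentile, safety margin) is not stated; the package
reports the computed count and checks it is at least as permissive as
the published bound.

## What the synthetic data do and do not emulate

`gen_specimen_record()` generates the uniaxial specimen records the
physical study measured: exact bilinear (flesh, core) or linear-brittle
(skin) curves mapped through the specimen geometry, plus i.i.d. Gaussian
force noise scaled to the peak force.  Only parameter means are
published, so the noise model is an assumption; it contains no serial
correlation, no toe-region artefacts (unless `toe_strain` is set), no
specimen-to-specimen biological variation, and no rate dependence.
Passing round-trip tests therefore demonstrates the *analysis pipeline*
is correct and noise-robust, not that real records look like this.

`gen_experiment_curve()` stands in for the whole-fruit validation
records: a Hertz-type power law $F = A d^{3/2}$ switching to a linear
post-yield segment at the knee, with multiplicative noise.  Its default
prefactor comes from the flesh modulus and the ellipsoid curvature at
the contact pole, i.e. from the same idealization the solver uses - so
curve-vs-curve validation against it checks internal consistency of
shape (correlations come out above 0.95), not agreement with physical
measurements.

## Known limitations

* **Geometry is the dominant model error.**  The published plate forces
  (36.74 N at 2.5%, 75.82 N at 5% axial) are roughly twice what the
  tri-axial ellipsoid with the measured tissue moduli can transmit: both
  our solver and a first-principles Hertz estimate with the same geometry
  and moduli give ~14 N and ~36 N.  The published force-displacement
  curves are close to linear from the origin, which is the signature of a
  much blunter contact region than an ellipsoid pole - real kiwifruit
  have nearly flat stem/blossom ends.  A scan-based geometry is out of
  scope here, so the package reports what the parametric model computes
  and documents the gap rather than tuning materials to compensate.  The
  same factor propagates to the predicted damage onset: flesh Von Mises
  just reaches bio-yield at the 10% axial level, but the 0.5%-volume
  onset definition is crossed only at 20%.
* Small-strain kinematics on the initial configuration: no geometric
  stiffening, bulging, or post-peak softening; results at the 20% level
  are indicative only.
* No viscoelasticity or rate dependence (quasi-static idealization of
  3 mm/min loading); no skin rupture propagation; seeds and tissue fluid
  ignored; the core-flesh interface is non-conforming by one element.
* The mortar penalty enforces contact in an averaged sense; local
  contact pressures are accurate to one surface element, not better.
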