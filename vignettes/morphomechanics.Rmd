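---
title: "Multi-scale morphomechanics of explosive pod shatter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale morphomechanics of explosive pod shatter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(podburst)
```

*Cardamine hirsuta* ("popping cress") disperses its seeds explosively: the
two fruit-valve halves detach, coil back in under three milliseconds, and
catapult seeds several metres at speeds of 5-10 m/s.  `podburst` models the
chain of mechanisms behind this movement at three scales -- the pressurized
exocarp cell, the trilayer valve wall, and the coiling organ with its seed
cargo -- and closes the loop with ballistic flight and the quantification
operators used on imaging data.  Because no raw data accompany the study
this package models, every input is produced by seeded synthetic-data
generators with known ground truth, which is what the test suite exercises.

## The valve as a prestressed trilayer

The valve wall is treated as three bonded layers: a stiff, lignified band
on the inner face (the secondary cell walls of the endocarp-b layer), a
passive middle tissue, and the outer exocarp whose cells actively shorten
under turgor.  The exocarp carries a rest axial strain of `-gamma` with
`gamma = 0.20`, the measured cell-length reduction between the flat
(attached) and coiled (detached) valve.  With axial strain
`eps(z) = eps0 + kappa z` through the thickness, the energy per unit length
is the quadratic

    U(eps0, kappa) = 1/2 * sum_i  E_i w a_i  Int_i (eps0 + kappa z - g_i)^2 dz,

whose layer integrals are evaluated in closed form
(`stack_resultants()`).  Minimizing out `eps0` (zero net axial force)
leaves an upward parabola in the longitudinal curvature whose vertex is the
coiled equilibrium; `landscape()` reports the equilibrium curvature, coil
count `L*kappa/(2*pi)`, and the energy released from the flat attached
state (`delta_E`).

Geometric parameters the source study does not print were fixed once:
valve 16 x 2 mm, lignified rod band 5 um at area fraction 0.5, middle
tissue 100 um, exocarp 20 um, lignin modulus 5 GPa.  The two tissue moduli
are calibration products, chosen so that the model reproduces the two
organ-scale observables at once -- three to four coils at equilibrium and
an energy drop of about 0.5 mJ: `E_exocarp = 55 MPa`, `E_middle = 10 MPa`.
The thicknesses are consistent with the roughly nine cell layers of the
valve wall.  A consequence worth stating plainly: with `gamma = 0.2` and a
16-mm valve, any linear trilayer that stores ~0.5 mJ must hold an exocarp
tension of several hundred millinewtons, an order of magnitude above the
tens of millinewtons measured by extensometry in the study this package
models.  The energy, coil count, coiling time and launch speeds form a
self-consistent set; the printed static forces do not fit inside the same
linear model, and `podburst` resolves the conflict in favour of the energy
scale (see "Known limitations").

### Hinged versus boxed endocarp-b walls

Cross-sectional flattening is the gate for coiling (the slap-bracelet
constraint).  With *hinged* lignified walls -- three stiff rods joined by
very thin hinges -- flattening costs almost nothing: a smeared rotational
hinge stiffness of 1e-6 N mm/rad^2 per mm makes the cost four orders of
magnitude below the release.  The *boxed* geometry (as in non-explosive
relatives and in transgenics with ectopic secondary walls, where the
endocarp-b box plus two adjacent layers lignify) is modeled as a 60-um
lignified sandwich: inner and outer plates at area fraction 0.9 joined by
a side-wall web at 0.2.  This raises the bending resultant so the
equilibrium has about one coil, and adds a transverse plate-bending cost
`1/2 D_t kappa_t^2 w L` to the flattening path.  The transverse plate pair
uses the per-cell depth (20 um), since lignified webs are discontinuous
between cell files, while the longitudinal stiffness integrates the full
sandwich, where the rods run continuously.

```{r}
p <- reference_params()
landscape(valve_model(p, "hinged"))
landscape(valve_model(p, "boxed"))
```

## Coiling dynamics and seed release

`simulate_release()` integrates a planar discrete elastic rod (velocity
Verlet; bending with intrinsic curvature equal to the landscape
equilibrium, near-inextensible axial springs, lumped mass) clamped at the
fruit end with the curl propagating from the free end.  Seeds are point
masses coupled by breakable Kelvin-Voigt tethers, the model of the pectic
adhesion observed in high-speed movies: tension `k delta + c ddelta/dt`
(never pushing), irreversible rupture at a critical extension.  The tether
constants (`k = 350 N/m`, `c = 2e-4 N s/m`, `delta_c = 175 um`) were fixed
once so that the reference run releases all ten seeds within 3 ms at a
mean speed near 5 m/s and a maximum near 10 m/s, mirroring how the source
study selected its adhesion model against measured launch statistics.

Numerical choices: the default step of 0.1 us sits well inside the axial
stability bound `sqrt(m_node h / EA)`; with zero damping the integrator
conserves total energy to better than 1 % over a run and aborts if energy
grows by 5 %.  Gravity is negligible over 3 ms (displacement under 0.05
um) and is left to the ballistics stage.  An optional mass-proportional
ambient damping and a Kelvin-Voigt internal bending viscosity are
available; both default to zero so the energy ledger stays conservative.

Tether rupture deliberately discards the adhesion energy stored in the
stretched pectic element (the strand snaps); the conservation guarantee
above is therefore a property of the rod integrator alone and is tested
without tethers.

One bookkeeping definition matters.  After the curl front has passed,
about a tenth of the released energy remains as undamped flexural ringing
of the coil; a strictly conservative rod never converts it.
`coiling_time()` therefore reports the time at which 95 % of the energy
the run ultimately releases has been released (and, by default, every
seed has detached) -- the duration of the observable coiling motion, which
is the quantity the high-speed measurement constrains.

## Seed ballistics

Released seeds follow `m dv/dt = m g - 1/2 rho Cd pi r^2 |v - w| (v - w)`,
integrated by fixed-step RK4 with a refined ground-crossing (vacuum ranges
are exact to 1e-6).  The discoid, tumbling seed is represented as a
drag-equivalent sphere: radius 0.8 mm, `Cd = 0.7`, mass 1 mg, values set
once from the seed's geometry; a smooth-sphere `Cd(Re)` correlation is
available behind `drag_model = "sphere_correlation"`.  Monte Carlo
dispersal resamples launch records with replacement, draws a uniform valve
azimuth and a uniform [0, 60] degree valve tilt, maps the in-plane launch
angle to an elevation about the vertical fruit axis, and flies each seed
from 0.2 m.  The plateau statistic of `distance_summary()` is the
coefficient of variation of histogram counts between the 25th and 75th
distance percentiles, compared in the tests against a same-size sample
from a Rayleigh fit.

## The pressurized exocarp cell

`inflate()` minimizes the total potential energy of an orthotropic
membrane (St. Venant-Kirchhoff plane stress on constant-strain triangles,
minus pressure times enclosed volume) over a triangulated box surface,
with an incremental pressure ramp and L-BFGS-B.  Each wall face uses the
two fruit axes it spans; anticlinal walls are doubled in thickness (they
are shared in tissue), the outer periclinal wall is four wall thicknesses
(outer epidermal walls are much thicker than anticlinal ones), and the
transverse end walls are constrained planar by default -- they are shared
with file neighbours, matching how the osmotic imaging was performed on
intact valve segments.  The cell-scale module computes internally in
um/MPa/uN/pJ for conditioning; all interfaces use the documented natural
units.

The wall moduli are calibration products: with `E_width = 40 MPa` fixed,
`calibrate_anisotropy()` adjusts the longitudinal:transverse ratio until
the inflation from 0 to 0.7 MPa gains 53 % volume (the measured osmotic
change), giving a ratio near 2.8.  Microindentation is emulated with the
pressure-shell contact model: the force to press a rigid probe into the
bulged outer wall equals turgor pressure times the flattened contact area,
the dominant term for a turgid cell; a membrane without bending stiffness
would fold around the edge of a small tip at vanishing force, so no
penalty-contact sphere is used.  Apparent stiffness rises with turgor,
with cell size at equal turgor, and with wall stiffness, as expected.

`file_tension_force()` models a file of cells with an explicitly shared
transverse wall (which carries membrane stress but no net pressure),
inflates it, then holds the end walls at the in-planta length -- the free
turgid length stretched by `1/(1 - gamma)` -- and reports the end reaction
scaled by the number of files across the valve width.

## Organ-scale elastica and the extension experiment

The excised, coiled valve is an inextensible planar elastica with uniform
intrinsic curvature, clamped at both ends along the pulling axis.  In two
dimensions the clamps fix the winding number, so tension tightens the
residual loops rather than removing them and the end-to-end distance
saturates below the contour length (`elastica_extension_limit()`); the
force-extension table is built by continuation from the natural coil, with
a stiff quadratic penalty closing the transverse gap.  Synthetic
extensometer curves append a taut phase -- further displacement loads only
the setup spring -- followed by a rupture collapse.
`correct_setup_compliance()` recovers the setup stiffness from the
pre-rupture linear tail (with a heteroscedasticity-robust standard error)
and removes it; `fit_bending_stiffness()` is then linear in the bending
stiffness (force scales with B at fixed intrinsic curvature).  Intervals
come from a seeded wild bootstrap with leverage-corrected residuals and a
t-quantile on the effective degrees of freedom -- the fit is dominated by
a few high-force points, and each bootstrap replicate also perturbs the
setup stiffness by its standard error.
`exocarp_from_valve()` inverts the layer-stack bending resultant for the
exocarp modulus and converts it to the pre-explosion tension
`E * (w t_exo) * gamma`.

## Quantification operators

`cell_deformation()` fits one affine deformation gradient per cell to
matched outline vertices (least squares on centred vertices, polar
decomposition), the standard principal-directions-of-growth computation
applied to shrinkage; `tension_map()` classifies the dominant axis.
`orientation_stats()` folds segment angles to [0, 90] degrees from the
fruit axis, bins them as longitudinal [0, 30), intermediate [30, 45) and
transverse [45, 90], and takes the principal orientation from the
structure-tensor mean of doubled angles, flagging isotropy when the
doubled-angle vector cancels.  Weighting by segment length is the default
where lengths are supplied.  `track_speeds()` uses central differences at
the camera frame rate.

## Synthetic data

Every consumer input has a generator with explicit seed, returned noise
specification, and ground truth sufficient to regenerate the clean
payload: tracked explosion movies (15,000 fps resampling of the rod
simulation plus Gaussian position noise), extensometer curves (50-um
increments, setup compliance, taut phase, rupture, multiplicative force
noise), osmotic/indentation bundles, pre/post outline pairs (random
star-shaped polygons under an affine contraction field), and landing
fields (uniform annulus by default).  Noise scales default to values of
the order seen in the corresponding figures and are tagged ASSUMED.  What
passing tests show is internal consistency -- parameters in, parameters
out -- not that real segmentation, tracking or load-cell artifacts are
captured; real data carry outliers, drift and correlated errors these
generators do not emulate.

## Problem sizes and tolerances

Default runs use 80 rod segments at dt = 0.1 us over 4-5 ms; cell meshes
at refinement 2 (about 1,400 elements for the mature cell; refinement 1
for calibration sweeps); 160 elastica segments; 1,000-sample dispersal
runs.  The membrane solver ramps pressure in 10 increments and accepts a
residual gradient below 1e-3 uN; bounding-dimension outputs at refinement
1 and 2 agree to about one percentage point in length, a few in volume
(the depth bulge converges more slowly).  The elastica force table is
interpolated in log-force over 60 continuation steps.

## Known limitations

* **Printed forces versus printed energy.**  The ~0.5 mJ energy release
  and the tens-of-millinewton exocarp tensions printed in the modeled
  study are mutually inconsistent within a linear trilayer at
  `gamma = 0.2` (released energy is bounded by roughly `F gamma L / 2`).
  The package anchors on the energy scale, which the dynamics and
  dispersal reproduce; its organ- and cell-route tensions are then
  consistent with each other (within a factor of ~1.5) but sit near half a
  newton.
* **Osmotic shape change of the anisotropic cell.**  Across wide scans of
  wall moduli, anisotropy ratios, Poisson ratio and wall-thickness
  factors, the membrane-walled box at +53 % volume yields about -4 %
  length and +75 to +100 % depth, not the measured -12 % and +40 %.
  Anisotropic faces bulge cylindrically along the stiff axis, so the
  longitudinal arc slack saturates; reproducing the measured pattern
  evidently needs wall bending stiffness (shell or solid elements) or the
  measured, non-box rest geometry.  An iterative tension-field variant
  (zeroing compressive principal stresses) was evaluated and shifts length
  by under one percentage point, so the shipped solver is the smooth
  membrane.
* **Conservative-rod ringing.**  Without internal dissipation ~10 % of the
  released energy keeps ringing in the coil; see the `coiling_time()`
  definition above.
* **Planar dynamics.**  No torsion, no coil self-contact, no aerodynamics
  on the valve; the 2D winding-number constraint in the elastica is an
  idealization of an experiment in which loops can escape the plane.
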