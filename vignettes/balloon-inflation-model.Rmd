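---
title: "Modelling non-compliant balloon inflation: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling non-compliant balloon inflation: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balloonmech)
```

## What this package models

Non-compliant balloons (PET/nylon-class, used in valvuloplasty, angioplasty
and transcatheter valve deployment) are inflated with contrast medium at a
prescribed flow rate; the clinically relevant behaviour is the coupled
relationship between injected volume, cavity pressure and balloon diameter,
free or pressed against a vessel-like conduit.  `balloonmech` provides a
desk-scale, fully testable counterpart of a bench validation campaign for
such a device: a forward mechanical model, the analysis equations used to
reduce bench data (tensile tests, compliance tests, biplane fluoroscopy),
validation metrics, and seeded synthetic generators standing in for every
experimental input.

The default device is a 23 mm balloon: cylindrical region 40 mm, total
length 75 mm, uniform membrane thickness 0.09 mm, pseudo-conical heads
tapering to a 3 mm catheter shaft.

## Constitutive model

The membrane is hyperelastic, isotropic, and modelled with a third-order
Ogden strain-energy function in deviatoric principal stretches
$\bar\lambda_i = J^{-1/3}\lambda_i$:

$$U = \sum_{i=1}^{N}\frac{2\mu_i}{\alpha_i^2}
      \left(\bar\lambda_1^{\alpha_i}+\bar\lambda_2^{\alpha_i}
            +\bar\lambda_3^{\alpha_i}-3\right)
    + \sum_{i=1}^{N}\frac{1}{\delta_i}\left(J^{el}-1\right)^{2i}.$$

The shipped coefficient set (`balloon_ogden_coefficients()`) is
$\mu = (-4715.57,\,2480.94,\,2479.35)$, $\alpha = (4.89,\,6.90,\,1.13)$,
$\delta = (1.38,\,0,\,0)$, Poisson ratio 0.45.  Two choices deserve
explanation:

* **Units.**  The coefficient table carries no unit statement, so the
  package fixes one, tagged on the model object: **MPa**.  The physics
  forces this choice: measured inflation pressures reach $\sim$0.57 MPa at
  15--19 % hoop strain, and Laplace equilibrium
  $\sigma_\theta = Pr/t$ with $r \approx 13$ mm, $t = 0.09$ mm then demands
  membrane stresses of tens of MPa.  The coefficients deliver that only on
  the MPa scale (the small-strain modulus is $3\sum\mu_i \approx 734$ MPa,
  the right order for a thin PET/nylon wall); a kPa reading would make the
  balloon about a thousand times too soft.  The assumption lives in exactly
  one place, the `units` tag of the shipped fixture.

* **Incompressibility.**  $\delta_2=\delta_3=0$ while $\delta_1>0$ and
  $\nu = 0.45$ is internally inconsistent compressibility information.  The
  membrane solver sidesteps it: thin membranes make through-thickness
  compressibility second order, so the solver enforces full
  incompressibility in plane stress, $\lambda_3 = 1/(\lambda_m
  \lambda_\theta)$, and the volumetric sum is inert.  $\nu$ is kept as
  metadata only.

The fitted coefficients of an Ogden model are famously non-unique:
`fit_ogden()` therefore multi-starts Levenberg--Marquardt from five
deterministic exponent seeds (with the linear-in-$\mu$ subproblem solved
exactly at each start), accepts only materially stable candidates
($\sum\mu_i>0$ and monotone predicted stress over the data range), and
documents that fit quality must be judged on the reproduced stress curve,
never on the coefficients.

Tensile data are interpreted as engineering (nominal) stress and strain,
the standard convention for dumb-bell tensile output; `ogden_uniaxial_stress()`
provides both conventions.

## The axisymmetric membrane solver

The full 3D membrane model (thousands of shell/membrane elements in a
general-purpose FE code) is re-expressed as a 1D meridian discretisation:
geometry, loads and boundary conditions are all axisymmetric, and the
reduction is what makes verification against closed forms possible at desk
scale.  Each two-node element carries a meridional stretch $\lambda_m =
L/L_0$ and a circumferential stretch $\lambda_\theta$ from the mean nodal
radius; fully integrated (not reduced) evaluation of the element energy is
trivial at this order.

**Volume-controlled loading.**  The bench controls injected volume, not
pressure, and treats the contrast as incompressible.  Fluid-cavity loading
therefore reduces to a constrained stationarity problem
$$\nabla_x\!\left[E_{\mathrm{int}}(x) - P\,V(x)\right] = 0,
  \qquad V(x) = V_{\mathrm{target}},$$
with the cavity pressure $P$ the Lagrange multiplier of the enclosed-volume
constraint.  $V(x)$ is the solid of revolution of the deformed meridian
(conical-frustum quadrature, exact for piecewise-linear meridians); the
same rule serves the imaging module, so solver and volumetry are mutually
consistent by construction.  The pressure load is the exact follower load
$-P\,\nabla V$.

**Statics, not explicit dynamics.**  The bench process is quasi-static, so
the static equations are solved directly: Newton iteration on the bordered
system, with continuation in volume (step cap 0.25 ml, automatic halving
on failure).  Two numerical details matter:

* The Jacobian is assembled by *central* finite differences with graph
  colouring (six colours for the 1D stencil, plus analytic pressure
  column/constraint row).  Forward differences are not accurate enough:
  near the stress-free state the radial stiffness is weak and the
  truncation error destroys the Newton rate.
* Damping uses the affine-invariant natural-monotonicity test (the
  simplified Newton correction under the current factorisation must
  shrink).  Raw residual-norm line searches mis-scale badly when stepping
  away from the zero-residual reference state.

Convergence requires the volume constraint to $10^{-8}$ relative (the
package contract is $10^{-6}$) and equilibrium to $10^{-7}$ of the current
force scale.  The solver contains no randomness: identical inputs give
bitwise-identical curves.

**Boundary conditions.**  The balloon extremities are fixed radially at the
shaft radius and free axially, with one axial pin removing the rigid-body
mode — matching a bench balloon suspended on holders with the shaft free to
draw in.

**Wrinkling.**  Membranes cannot carry compression.  Elements whose
biaxial stress would be compressive switch to a tension-field (relaxed)
energy — uniaxial in the taut direction — and the state is flagged
(`slack_flag` on the curve).  A small fraction (`reg`, default $10^{-3}$)
of the biaxial energy is retained on relaxed elements so slack regions keep
a well-posed tangent; its force contribution is negligible against taut
membrane and pressure forces.  Boundary elements that chatter between
regimes at numerically zero stress are frozen rather than iterated forever.
Reported curves keep all samples and carry the flag, which is more
informative than truncating to the first fully taut volume.

**Contact with the implantation-site phantom.**  The phantom is a
thin-walled linear-elastic cylinder: local radial compliance
$c = r_{in}^2/(Et)$ over its free length, rigid over the clamped end
bands.  Contact is frictionless and penalty-based, node-local
(Winkler-type): where the balloon radius exceeds the wall, the transmitted
pressure is $q = k\,(r-r_{p0})/(1+kc)$, the series combination of penalty
and wall springs, so as $k\to\infty$ the contact pressure converges to the
wall's Laplace pressure at its attained radius.  The penalty starts at
$10^3\times$ the membrane's radial stiffness scale and escalates tenfold
until penetration is below $10^{-3} r_p$ *and* (compliant walls) below 1 %
of the indentation.  Contact complementarity — zero pressure wherever a gap
is open — is asserted in the tests.

**Starting a constrained run.**  The bench crimps and deflates the balloon
before insertion.  A slack membrane below its reference volume has an
almost indeterminate shape — a degenerate numerical problem whose solution
carries no information — so the solver instead ramps the wall radially
inward onto the balloon at its (well-posed) reference state and then ramps
volume.  This is a declared replacement of the folding process, not an
approximation of it; the inflation curves beyond wall contact are
unaffected by the path taken to reach them, which is exactly the
quasi-static premise.

**Problem sizes.**  Default meshes use 100--200 meridian elements.  The
closed-form verification (long cylindrical balloon, heads shrunk to 5 % of
the length) runs 200 elements and matches the analytic membrane pressure
$P = \sigma_\theta t_0/(r_0\lambda_\theta^2\lambda_z)$ to a few parts in
$10^4$ over hoop stretches up to 1.15; mesh halving changes pressures by
well under 0.5 %; pressure work balances stored energy within 1 % on taut
paths.

## Vessel (Laplace-law) analysis

Compliance tests on printed cylinders are reduced exactly as practitioners
do: $r=\sqrt{V/(\pi l)}$, $\sigma_\theta = Pr/t$,
$\varepsilon=(r-r_{in})/r_{in}$, $E=\sigma_\theta/\varepsilon$, and
distensibility $D = \Delta V/(\Delta P\,V_{in})$ between the first and last
samples (the record window is configurable since the evaluation window is
otherwise a free choice).  The linearised closed form $D = 2r/(Et)$ ties
the two together; for the softest shipped composite (E = 0.55 MPa, r = 10
mm, t = 0.8 mm) it evaluates to $6.06\times10^{-3}$ mmHg$^{-1}$, matching
the measured $0.0060$ mmHg$^{-1}$ within 2 %.

One bias is worth knowing: the whole-volume radius conversion assumes a
uniform cylinder, while clamped end bands deform less.  With 10.6 mm bands
on a 60 mm sample the recovered modulus would read $\sim$20 % high.
Round-trip recovery checks therefore use band-free phantoms; the band
geometry is still modelled in `cylinder_pv_response()` (linear radius
taper across each band, the simplest shape meeting both boundary
conditions) because the contact solver needs it.

## Imaging analysis

Biplane fluoroscopy geometry is reduced with the two-bead-pair calibration
coefficient $w = b_{1,real}/(2b_{1,image}) + b_{2,real}/(2b_{2,image})$ —
the mean of two independent scale ratios, damping beam distortion.
Contours are extracted from thresholded grayscale images column by column
with sub-pixel linear interpolation of the threshold crossing (at
0.5 mm/pixel, whole-pixel boundaries would dominate every downstream
error); the revolution axis defaults to the least-squares symmetry axis of
the silhouette midline.  The "central section" is the axial midpoint of
the contour bounding box.  Volumes revolve the contour with the same
frustum rule as the solver; the injected-volume timeline is
$V(t)=V_0+\dot V\,(t-t_0)$ at the pump's 40 ml/h.

The column-wise tracer assumes an axially convex silhouette (one
super-threshold run per column), which balloon profiles satisfy; anything
else is rejected rather than mis-traced.

## Synthetic data: what it emulates and what it does not

All generators are pure functions of (parameters, seed), built on
`withr::with_seed` so they never disturb the caller's RNG stream.

* `gen_uniaxial()` — monotonic or cyclic tensile curves.  Cyclic mode
  inserts per-cycle residual-strain offsets (default ramping 3 % to 5 %
  across ten cycles to 10 % strain, the range rubber-like balloon membranes
  show).  Residual strain is *constructed*, not simulated: no elastoplastic
  law is implemented, matching the descriptive role the measurement plays.
* `gen_compliance()` — P--V records of phantom cylinders from the
  thin-wall response plus volume noise (default 0.01 ml).
* `gen_inflation_experiment()` — the forward solver plus instrument noise:
  Gaussian pressure noise (default 5 mmHg, a realistic bench strain-gauge
  transducer scale), optional manometer quantisation (clinical inflation
  devices quantise at 0.2 atm = 152 mmHg), and 0.5 mm diameter
  quantisation from the image resolution.  The clean curve is kept as
  ground truth, which makes the generator's round trips the integration
  tests of the whole pipeline.
* `gen_projections()` — anti-aliased biplane silhouettes at scale
  $1/w_{true}$ with bead markers whose image distances are quantised to the
  pixel grid; default arch distances of 120 and 160 mm span the field of
  view as a calibration arch would, keeping the quantisation-limited error
  in $w$ near 0.1 %.

What passing these round trips does **not** show: real balloons fold and
unfold with hysteresis, real membranes have non-uniform thickness, real
X-ray images have beam distortion beyond a scale factor, and a real
elastoplastic membrane accumulates set that this package only measures,
never predicts.  Agreement on synthetic data validates the *analysis
chain*, not the device.

## Validation metrics

Curves are compared "at equal volume": both are linearly interpolated onto
a 200-point uniform volume grid over the overlap of their ranges (the
pairing rule must be fixed somewhere; a uniform overlap grid is the least
arbitrary choice), then
$RMSE_P=\sqrt{\mathrm{mean}((P_{EXP}-P_{COMP})^2)}$ and likewise
$RMSE_d$.  Reports carry the pressure RMSE as an unrounded percentage of
the maximum experimental pressure and flag the diameter RMSE against the
0.5 mm image resolution — the floor below which diameter agreement is not
meaningful.

## Known limitations

* No 3D effects: folding, buckling into non-axisymmetric lobes, friction,
  and balloon burst are out of scope.
* The phantom is a Winkler-type thin-wall cylinder: axial coupling of wall
  bending near the contact edge is not modelled (the full 3D hex-mesh
  counterpart is deliberately replaced, with the thin-wall validation
  bounding the substitution).
* The Ogden fit is only trusted inside the fitted strain range; the
  shipped coefficient set misbehaves in uniaxial paths beyond roughly 20 %
  strain, so simulations keep stretches moderate.
* Pressure--volume behaviour below the reference volume is reported flat
  and flagged slack rather than resolved in detail.
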