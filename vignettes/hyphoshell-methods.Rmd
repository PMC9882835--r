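---
title: "Methods: wall-thickness mapping, wall mechanics, and the feedback model of tip growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wall-thickness mapping, wall mechanics, and the feedback model of tip growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyphoshell)
```

Filamentous fungi elongate at their hyphal tips by inflating a thin
polysaccharide wall under turgor pressure while exocytic vesicles (EVs)
deliver new wall material and remodeling enzymes to the apex. This package
implements, end to end, the quantitative machinery needed to study that
process on synthetic data with known ground truth: a two-channel imaging
phantom of the wall, a subresolution thickness estimator, thin-shell
mechanics and turgor estimation, a dynamical model of tip growth with
mechanical feedback, and the time-series statistics used on growth
recordings. This vignette explains each method, its assumptions, the
defaults, and the numerical choices; it states no result that the package's
tests and scripts do not themselves compute.

## Subresolution wall-thickness mapping

A mid-slice confocal image of a wall-labeled hypha shows two nearly
parallel intensity ridges: the plasma membrane lining the wall's inner face
(channel 1) and a lectin decorating the outer face (channel 2). The wall is
50--250 nm thick -- below the ~200 nm PSF -- so the two ridges blur into
broad overlapping bands *within each channel's image*, but because the two
labels are imaged in separate channels, the *distance between the two peak
centres* can be measured far below the diffraction limit, exactly as
bead-tracking localizes a single emitter to nanometres.

The pipeline (`map_thickness()`) proceeds as follows.

1. **Contour segmentation** (`segment_contour()`): Otsu threshold on the
   smoothed membrane channel, largest connected component, ordered boundary
   (EBImage), then subpixel refinement of every boundary point to the
   membrane ridge. The final refinement pass re-centres each point with the
   same peak model used for measurement (step 3); a plain ridge maximum is
   biased toward the brighter (cytoplasmic) side by roughly
   $0.2\,\sigma_{\mathrm{PSF}}$, which this removes.
2. **Normal profiles** (`sample_normal_profile()`): both channels are
   bilinearly sampled along the outward normal (tangent over ±5 contour
   points), half a pixel per step, ±max(3 PSF, 450) nm.
3. **Peak fitting** (`fit_peak()`): each profile is fit with
   $$I(x) = b_\mathrm{out} + (b_\mathrm{in} - b_\mathrm{out})\,
   \Phi\!\left(\frac{c - x}{w}\right) + A\,
   e^{-(x - c)^2 / 2 w^2},$$
   a Gaussian peak sharing its centre and width with an error-function
   step. The step is not a convenience: the cytoplasm (channel 1) and the
   lectin-containing medium (channel 2) put different plateaus on the two
   sides of each ridge, and a convolved step is exactly what a Gaussian PSF
   makes of that. Fitting the peak alone would bias the centre by tens of
   nanometres (the unit tests quantify this against a brute-force oracle);
   with the shared-centre step the estimator is unbiased to well under
   1 nm on noise-free data.
4. **Thickness** (`compute_thickness()`): $h = (c_2 - c_1) -
   \mathbf{s}\cdot\hat{\mathbf{n}}$, the centre distance minus the
   projection of the calibrated chromatic shift $\mathbf{s}$ onto the
   outward normal. Non-positive corrected distances and low-quality fits
   (R² < 0.8 or width outside 0.5--3 PSF) are flagged and excluded.
5. **Smoothing**: accepted thicknesses are Gaussian-smoothed along the
   arclength at a 500 nm scale -- the method's along-surface resolution --
   and indexed by the symmetrized arclength $s'$ from the tip (the point of
   maximal projection on the contour's major axis).

Under the default imaging model (65 nm pixels, 200 nm PSF, peak
200 expected counts, Poisson shot noise, 3-count read noise, chromatic
shift (30, −20) nm) the mean absolute error is about 5 nm per contour
point -- the acceptance script recomputes this over 50 phantoms -- safely
inside the 10--20 nm precision the live method is credited with.

## The synthetic phantom

`make_phantom()` builds a tube of radius ~1.2 µm with a hemispherical cap;
the inner face is the capsule boundary, the outer face its offset by the
local thickness $h(s)$ along the outward normal. That offset property *is*
the ground truth: the tests verify it against a brute-force
nearest-distance oracle between the two sampled curves, independent of any
rendering.

`render_image()` evaluates the expected image analytically from the signed
distance to each face: a Gaussian line-spread plus an error-function
background step per channel. For a locally straight wall this is the exact
PSF convolution; at the cap the wall curvature is ~6 PSF sigmas so the
approximation is mild. We chose the analytic route over raster convolution
to avoid grid/aliasing artifacts in a study whose target accuracy is a
third of a pixel. Backgrounds are expressed relative to the unit peak and
scaled by `photon_scale`, so expected counts are exactly linear in
`photon_scale` (a tested invariant). Noise is Poisson plus Gaussian read
noise from one seeded generator per call; fixed seed means bit-identical
images.

What the phantom deliberately does **not** emulate: out-of-focus light and
the third dimension (mid-slice only), label-layer thickness (both
fluorophores are treated as infinitely thin lines at the wall faces, as the
live method implicitly does when it reads the peak distance as $h$),
photobleaching, and multi-cell scenes. Passing tests therefore demonstrate
estimator correctness under the stated imaging model, not robustness to
every confound of real microscopy.

## Thin-shell mechanics and turgor

For a pressurized cylindrical shell the hoop force balance gives
$Y/P = R_1 / (h_\mathrm{side}\,\varepsilon_r)$ with
$\varepsilon_r = (R_1 - R_0)/R_0$ the elastic strain released by
depressurization; the hemispherical cap gives half that,
$Y/P = R_{t1} / (2 h_\mathrm{tip}\,\varepsilon_t)$. The factor two is also
why an isotropic wall relaxes twice as much radially as longitudinally --
the anisotropy diagnostic `anisotropy_ratio()` returns exactly 2 for an
isotropic tube. Strains are measured by segmenting a before/after image
pair and comparing radii (`contour_geometry()`; the length estimate
subtracts both end caps so that radius shrinkage does not leak into the
longitudinal strain).

Turgor comes from the osmotic chain (`turgor_from_osmotics()`): the
external molarity that shrinks the cell as much as ablation
(`iso_ablation_molarity()`, piecewise-linear interpolation, no
extrapolation) plus the medium molarity gives the zero-turgor internal
concentration $\bar c_0$; the Boyle-van 't Hoff relation with inaccessible
volume fraction $\beta$ (default 0.22) converts it to the turgid-state
concentration $\bar c_1 = \bar c_0 (V_0/V_1 - \beta)/(1-\beta)$; and
$P = (\bar c_1 - c_\mathrm{media}) R T$ at 298 K. With the measured inputs
(0.808 M, 0.112 M, $V_0/V_1 = 0.70$) this yields 1.1 MPa, or 1.3 MPa if
$\beta$ is taken as zero. Note that applying the $\bar c_1$ formula to
these inputs gives 0.566 M -- this, not any lower intermediate value, is
what reproduces 1.1 MPa.

## The tip-growth model

Three coupled ODEs describe the apex (`tip_derivatives()`):

$$\frac{dh}{dt} = \gamma\,EV - G h, \qquad
\frac{dEV}{dt} = \phi G - \alpha\,EV, \qquad
\frac{d(hc)}{dt} = \beta\,EV - G h c,$$

with the elastoplastic strain rate
$G = \mu c\,(PR/Yh - \epsilon)_+$ -- wall expansion proportional to the
remodeler concentration $c$ and to the elastic strain in excess of the
yield strain $\epsilon$, clamped at zero because plastic flow is
irreversible. Vesicles thicken the wall ($\gamma EV$), the wall thins as it
stretches ($-Gh$), and the vesicle pool is fed back in proportion to the
strain rate ($\phi G$) -- the mechanical feedback. Eliminating $c$ yields
an equivalent system in $(h, EV, G)$ whose $G$-equation involves
$\eta = \beta\mu PR/Y$ and $\theta = \epsilon Y/PR$; both formulations are
implemented and agree to $10^{-6}$ relative while $G > 0$ (a tested
equivalence -- the derived form is its own independent oracle). The
algebraic-$G$ form is the reference because it handles the yield clamp.

The growing fixed point is unique in closed form: $h^* = \gamma\phi/\alpha$
(thickness homeostasis -- independent of pressure and wall stiffness),
$c^* = \beta/\gamma$, $G^* = \eta\phi(1-\theta h^*)/(\alpha h^{*2})$,
$EV^* = \phi G^*/\alpha$, existing iff $\theta h^* < 1$.
`count_fixed_points()` confirms uniqueness by an independent sign-change
scan of the reduced equilibrium residual.

### Stability, and where the model lives in parameter space

Scaling the Jacobian at the fixed point by $G^*$ shows that stability
depends on just two numbers: $A = \alpha/G^*$ (vesicle turnover relative
to wall turnover) and $\rho = (2-\theta h^*)/(1-\theta h^*)$. The
characteristic polynomial is
$\lambda^3 + (3 + A - \rho)\lambda^2 + (2A + 2 - \rho)\lambda + A$
(with $\lambda = -G^*$ always one root), so by Routh--Hurwitz the feedback
stabilizes growth only when vesicle turnover is fast enough,
$A \gtrsim 1.2$ at the calibrated $\theta h^*$. Two facts worth stressing:

* **Without feedback** ($\phi G$ replaced by a constant source) the
  $(h, hc)$ subsystem is a saddle for every parameter choice
  ($\det \propto 2 - \rho < 0$): thickness homeostasis *requires* the
  feedback.
* **An elastic-strain feedback** (source $\propto PR/Yh$) has constant
  coefficient $A(3-\rho)$, negative whenever $\theta h^* > 1/2$ -- which
  the growth-arrest calibration pins at $\theta h^* = 1 - \Delta
  P_\mathrm{stop}/P \approx 0.55$. In the experimentally relevant regime
  this variant is always unstable.

These closed-form results define the parameter domain in which the
stability dichotomy is tested: observables drawn over the measured ranges
(tip thickness 50--90 nm, strain rate 0.1--0.3 min⁻¹, P 0.9--1.4 MPa,
Y 40--90 MPa, R 1--1.5 µm, stopping-pressure fraction 0.41--0.49) with
$A \in [2.5, 4.5]$.

### Calibration

`calibrate()` inverts the fixed point: given observed $(h^*, G^*, EV^*)$,
mechanics $(P, R, Y)$ and the smallest pressure drop that arrests growth,
it sets $\epsilon = (P - \Delta P_\mathrm{stop})R/(Yh^*)$ (yield reached
exactly at arrest) and solves for $\gamma, \phi, \beta$; $\alpha$ and
$\mu$ are gauge choices. The canonical set (`default_params()`) uses
$h^* = 65$ nm, $P = 1.1$ MPa, $Y = 64$ MPa, $R = 1.2$ µm, arrest at 0.2 M
sorbitol ($\Delta P = 0.496$ MPa, hence $\epsilon = 0.174$), $EV^* = 1$
(normalization), and $G^* = 0.25$ min⁻¹ with $\alpha = 1$ min⁻¹
($A = 4$). The last two are the package's considered choice of regime:
$G^*$ sets the relaxation rate of the wall composition, and
$G^* \approx 0.25$ min⁻¹ reproduces the observed 10--20 min approach to
steady growth at emerging branches; $A = \alpha/G^*$ controls both
stability ($A \gtrsim 1.2$) and the wall thickening during a growth arrest
(vesicles linger for $1/\alpha$ after $G$ hits zero, thickening the wall
by roughly $h^*/A$, i.e. ~25% at $A=4$, matching the observed 30--50%
within the model's semiquantitative remit). Slower turnover regimes that
match the thickening more closely are unstable and cannot hold steady
growth at all.

### Scenarios

`make_scenario()` encodes four perturbations (plus `steady`), each with a
documented schedule:

* **branching** -- de-novo growth: $h(0) = h^*$, vesicles *and* wall
  remodeler load at 10% of their steady values. Starting the remodeler
  load at exactly zero would make the vesicle pool dip before the feedback
  engages (the source $\phi G$ needs $G$ to build from nothing while the
  sink $\alpha EV$ acts immediately); the 10% start represents the
  vesicle patch that has already assembled when a branch becomes visible,
  and gives the observed monotone rise of EV and G to steady state in
  10--20 min at near-constant thickness.
* **osmotic_shock** -- a step turgor drop of the 0.2 M-sorbitol
  equivalent at t = 5 min, recovering exponentially with a 6-min time
  constant (so growth restarts within 10--15 min). Growth arrests
  instantly (strain falls below yield) while vesicles decay only at rate
  $\alpha$; the leftover synthesis thickens the wall transiently until
  turgor adaptation restores growth and $h$ relaxes back.
* **secretion_block** -- vesicle source and sink ramped down over 3 min to
  20% and 10% respectively. The factors are deliberately unequal, for a
  structural reason: scaling source and sink by the *same* factor leaves
  the fixed-point balance $\phi G^* = \alpha EV^*$ intact and the
  trajectory never moves; and a source-dominant block drives the wall to
  collapse, because once vesicles are gone the wall composition $c = w/h$
  is exactly conserved and $\dot h = -\mu c_0(\tau - \epsilon h) < 0$
  creeps the wall to zero thickness. Cutting the sink harder than the
  source raises the quasi-steady wall setpoint to
  $(m_\phi/m_\alpha)h^*$ while $G$ collapses underneath, which is the
  observed phenotype: vesicles disperse over 15--20 min, growth stops at
  ~14 min, and the wall thickens monotonically from 65 toward ~280 nm --
  of the order of the thickest walls seen after prolonged secretion
  arrest.
* **obstacle** -- a progressive partial turgor drop (22% over a 10-min
  ramp, 5-min hold, 10-min release), the effective load change of pushing
  on an elastic barrier. Because the ramp is slow compared with the
  relaxation times, the state tracks the moving fixed point, whose
  thickness does not depend on P at all: vesicles and growth dip to
  ~40% and recover, with under 10% thickness excursion. A deeper or
  faster drop crosses the yield threshold and reproduces the shock
  phenotype instead, which is not what a maintained elastic contact does.

Integration uses `deSolve::lsoda` at rtol $10^{-8}$/atol $10^{-10}$; the
first $G = 0$ crossing is recorded on the output grid. Trajectories abort
with a diagnostic if $h$ leaves the physical domain (which the unstable
variants do).

One caveat the tests make explicit: from very large perturbations (the
±50% convergence checks) a trajectory can transiently graze the yield
threshold and then crawl back at rate ~$G \approx 0$; convergence is then
complete well within five times the linearized time 10/|slowest
eigenvalue|, though not always within it.

## Time-series statistics

`relative_std()` is the sample coefficient of variation (n−1). The lagged
cross-correlation divides the mean centered product over the lag overlap
by the *full-series* standard deviations, so the zero-lag
autocorrelation is exactly 1 and the maximum lag is capped at n/3 to bound
the overlap shrinkage. `bleach_correct()` divides by a fixed-cell
reference normalized to its first frame. `fiducial_drift()` tracks a local
thickness extremum across kymograph frames with parabolic refinement and
reports its lab-frame slope; the model deposits wall only at the tip (no
advection term), and the simulated check recovers |drift| < 5% of tip
speed -- while a deliberately advected mark is recovered at its
constructed speed.

## Problem sizes and reproducibility

The shipped analyses use phantoms of 3--12 µm at 65 nm pixels
(~150--250 contour points, two peak fits each), 50-phantom precision
sweeps, 100-draw stability scans, and 40--120 min model integrations --
sizes chosen so that any single analysis completes in seconds to a couple
of minutes on one core. Every stochastic step takes an explicit integer
seed, one generator per call, and restores the caller's RNG state; fixed
seeds give bit-identical images and tables.

## Known limitations

* The estimator is validated on the stated imaging model; real images add
  focus drift, uneven labeling, and autofluorescence that the phantom does
  not emulate.
* The phantom treats both labels as lines exactly at the wall faces; a
  finite label-layer offset would add a constant bias that bead-style
  calibration would have to remove.
* The growth model is zero-dimensional (tip-averaged): no tip shape, no
  spatial wall mechanics, no advective wall flow, no stochasticity.
* Population statistics of real cells (distributions of thickness, moduli
  across strains and media) require real data and are outside what
  synthetic tests can establish.
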