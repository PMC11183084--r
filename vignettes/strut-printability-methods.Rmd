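---
title: "Models and methods behind strutkit"
author: "strutkit maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind strutkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strutkit)
```

`strutkit` quantifies the printability of extrusion-bioprinted strands
from optical measurements alone. This vignette explains the physical
models, the estimation choices, and what the synthetic validation does
and does not demonstrate.

## The parabolic strut

A freshly deposited strand on a flat plate is modelled as a parabolic
cap $h(x) = H\,(1 - (2x/a)^2)$, $|x| \le a/2$. Everything downstream
uses only two derived quantities: the vertex curvature
$\rho = 8H/a^2$ (the magnitude of the second derivative; the cap is
concave down) and the cross-section $\kappa = \tfrac{2}{3} H a$. The
parabola is an assumption, not a fit: strongly non-parabolic caps (e.g.
contact-line pinning, very high contact angles) are outside the model.
Geometry is kept in mm/mm²/mm³ throughout because the numbers come from
images; SI conversion happens exactly once, at the entry of the
force-balance computation (see below), which is where unit errors would
otherwise hide.

## Stripe-rotation optics

Seen from below, a transparent strut over a diagonally striped plate
rotates the stripes inside its footprint: the strut is a plano-convex
cylindrical lens. `strutkit` models this paraxially and thin: the
across-strut background coordinate is magnified by
$M = (1 - z\rho\,\Delta n)^{-1}$, so a stripe at true angle $\theta$
(vs. the strut axis) appears at $\tan\theta' = \tan\theta / M$. Three
consequences drive the implementation:

* $z$ and $\Delta n = n_\mathrm{strut} - n_\mathrm{medium}$ are not
  separately identifiable from one image; they enter only as the lumped
  product $z\,\Delta n$ (`lumped_zdn`, mm). This constant absorbs every
  unmodelled interface (flat strut bottom, plate glass) and **must be
  calibrated** against a strut of known geometry before absolute
  curvatures are quoted. The forward/inverse pair is exactly algebraic,
  so the calibration is a single multiplicative constant.
* The model fails at the focal condition $z\rho\,\Delta n \ge 1$
  (background inverted); the code refuses such inputs rather than
  returning a wrong sign. Freshly extruded, strongly curved strands can
  genuinely sit beyond focus — their first fraction of a second is
  simply not measurable by this method, and the synthetic spreading
  scenes start their ground truth at 0.45 s for that reason.
* Rotation is always toward the strut axis ($\theta' \le \theta$); an
  observation with $\theta' > \theta$ is inconsistent with the model and
  rejected.

The stripe angle itself is measured by the structure tensor of
derivative-of-Gaussian (DoG) gradients. DoG kernels (σ = 2 px) rather
than short difference stencils matter here: the anisotropic attenuation
of a 3-tap derivative biases orientation estimates by more than a degree
at realistic stripe pitches, while sampled DoG gradients are unbiased to
aliasing level, which the curvature inversion needs because at small
$\rho$ a 0.05° angle error is already a 2% curvature error.

## Spreading kinetics

After deposition the strut spreads. Two regimes are modelled, both with
a 1/7-power signature:

* complete wetting (water-based inks):
  $a(t) = K\,((t+t_0)/\mathrm{s})^{1/7}$, unbounded growth. The division
  by the unit second is deliberate — it makes $K$ carry mm.
* partial wetting (PBS-based inks):
  $a(t) = a_s (1 - e^{-B (t+t_0)})^{1/7}$, saturating at the final
  width $a_s$. Its first-order expansion $a_s B^{1/7} (t/\mathrm{s})^{1/7}$
  makes $a_s B^{1/7}$ directly comparable with $K$.

Fits use Levenberg-Marquardt (`minpack.lm::nlsLM`) with positivity
bounds, cost tolerance $10^{-12}$, closed-form initialisation for $K$
(the model is linear in $K$ at fixed $t_0$), and
$a_s^{(0)} = 1.05\,\max a$, $B^{(0)}$ from the time the series reaches
$(1-e^{-1})^{1/7} a_s^{(0)}$. Standard errors come from the Gauss-Newton
covariance at the optimum.

**Delay-time policy.** The default fixes $t_0 = 0$. On synthetic data
generated with $t_0 = 0$ the free-$t_0$ fit returns estimates smaller
than their own standard error (asserted over 100 seeded replicates in
the test suite), i.e. the parameter is not identified at realistic noise
— keeping it free only inflates variance. The free mode remains
available for diagnostics.

**Model choice.** Rather than hard-coding "water → complete, PBS →
partial", `model_selection()` fits both laws and compares small-sample
corrected AIC (AICc, both with $t_0$ fixed). On clearly growing data it
selects complete wetting, on saturating data ($B\,t_\max \gtrsim 3$)
partial wetting; on short, uninformative series the parameter-count
penalty favours the simpler complete-wetting law, and a `tie_margin`
controls when the difference is reported as a tie. Constant-width series
are flagged as degenerate instead of producing spurious parameters.

The auxiliary scalings — $K \sim \eta^{-1/7}$, the dilute-solution law
$\eta(c) = \eta_S (1 + [\eta] c / 3)^3$, and the full prefactor
$K = (\gamma_L \cdot 18 \cdot 7\, \kappa^3 / (\lambda \eta))^{1/7}$ —
are provided for consistency checks only. The wetting theory's constant
$\lambda$ has no published value and is a required user input; the
package never attempts to extract surface tension or viscosity from a
spreading fit, as $\gamma_L$, $\lambda$ and $\eta$ are not separable.

`cell_volume_fraction()` converts a cell loading (cells/ml) and mean
single-cell volume (µm³) into a volume percentage — the quick sanity
check for whether a loading can plausibly alter bulk rheology (at
10⁶ cells/ml and typical adherent-cell volumes it stays below half a
percent).

## The snapshot-as-time-series trick

When a meander finishes printing, the strand age varies linearly along
the path: zero at the nozzle, the full print duration at the start.
`width_series_from_snapshot()` therefore samples stations every 2 mm
along the path (the default spacing), measures the width perpendicular
to the local path direction, and assigns each station the elapsed time
(remaining path length)/$v_p$. Stations within 2 mm of a path corner,
and entire segments shorter than three corner margins (the serpentine's
vertical connectors), are excluded — corner flow is two-dimensional and
the strut-local optics model does not apply there. The width at a
station is read from the two edge-darkening dips of the perpendicular
intensity profile, averaged over ±3 px along the path and refined to
sub-pixel by a parabolic fit of each dip.

For strands embedded in a support gel there is no intensity edge at
all; `in_gel_strut_mask()` instead segments the strut from the local
stripe-orientation field. The phase discontinuity of the refracted
pattern produces a sharp spike of orientation deviation at the strut
boundary; the mask spans the outermost deviation spikes per image
column. The deviation-threshold alternative (mask = pixels whose
orientation deviates beyond a global threshold) was tried first and
discarded: the blur of the tensor window biases its area by 10-20%,
while the spike positions sit within about a pixel of the true edge.

## Hanging-strut force balance

Between nozzle and plate the strand is in elongational flow. Balancing
elongational stress and gravity on infinitesimal cylindrical elements,
and using volume continuity $v(s) = 4Q/(\pi d(s)^2)$, gives

$$\eta_E \;=\; \left(\frac{\rho_m g}{d\alpha/dx} -
\frac{2\gamma}{d(s)}\right) \frac{1}{dv/ds},$$

with mass density $\rho_m$ (never sharing a symbol with the vertex
curvature in this package: `density` vs `rho`), surface tension
$\gamma$, pitch angle $\alpha$ and strain rate
$\dot\varepsilon = dv/ds$. An equivalent arc-length form carries the
$\cos\alpha$ factor explicitly; both are implemented (`axis = "x"` /
`"s"`) and agree for a linear pitch angle.

Estimation choices:

* **Derivatives come from fitted parametric models**, not raw finite
  differences: the diameter profile is fit with an offset exponential
  $d(s) = d_\infty + (d_0 - d_\infty) e^{-s/s_c}$ (offset because real
  strands do not thin to zero), the pitch angle with a straight line in
  $x$. The strain rate then has the closed form
  $\dot\varepsilon = \tfrac{8Q}{\pi d^3} \tfrac{d_0-d_\infty}{s_c}
  e^{-s/s_c}$, which matches dense finite differences to $10^{-6}$.
  A pointwise Savitzky-Golay mode for $d\alpha/dx$ (`dalpha = "local"`)
  exists for visibly non-linear pitch profiles.
* **Viscous-regime restriction.** Measured diameter profiles are
  "parabolic-like": viscous stretching (thinning) near the nozzle
  followed by elastic recovery (re-thickening). Only the stretching
  phase obeys the purely viscous balance, so the analysis window ends at
  the minimum of the median-smoothed profile (window 5) and starts after
  a 2-point nozzle-exit exclusion zone (die swell/attachment); both are
  configurable. Monotone-increasing profiles raise an error — there is
  no viscous regime to analyse.
* **Units.** All inputs convert to SI at this boundary so $\eta_E$
  emerges in Pa·s; $\dot\varepsilon$ is scale-free in (mm, mm/s).
  Negative viscosities (possible when the surface-tension term dominates
  a thin strand) are reported with a warning flag, never silently
  dropped.

A structural point the implementation makes explicit: with a strictly
linear pitch angle, the force balance forces
$\eta_E \propto 1/\dot\varepsilon$ — a log-log slope of exactly −1.
Recovering a genuine power-law fluid $\eta_E = C \dot\varepsilon^{n-1}$
with $n \ne 0$ therefore requires a curved pitch-angle profile and the
local-derivative mode; the generator
`gen_trajectory_power_law()` constructs exactly such profiles by
integrating the force balance as an ODE, and the test suite recovers
the prescribed exponent from them within 10%.

## Synthetic fixtures: what they do and do not show

Every estimator is validated against generators whose ground truth is
known exactly and serialised alongside each render:

* spreading series on $t \in [0.5, 12]$ s (24 points), widths
  0.4–1.1 mm, Gaussian width noise of 10 µm;
* bottom views at 0.025 mm/px with sinusoidal stripes (pitch 0.8 mm,
  45°), the lens forward remap, edge darkening, and additive pixel
  noise (SD 0.01);
* side views with the nozzle bar drawn at its true 0.82 mm outer
  diameter (21G) so scale calibration is part of the round trip, the
  silhouette anti-aliased over one pixel, 1-px geometric jitter.

These sizes keep the full validation battery (including 100-replicate
recovery simulations and a ~1.9-megapixel meander render) at around ten
seconds on one core. Determinism is part of the contract: a fixed seed
reproduces arrays and images byte-for-byte.

The emulation is deliberately idealised: sinusoidal stripes (no
printing artefacts on the plate), exact parabolic/exponential ground
truths, additive Gaussian noise, no lens distortion, no perspective, no
illumination gradients, no cells rendered. Passing round trips
therefore demonstrate that the estimators are unbiased and correctly
inverted **under the stated models**, not that real phone-camera images
meet those models; on real data the lumped optical constant must be
calibrated, and deviations from the parabolic cap or exponential decay
become model error that no amount of image quality fixes. Renders are
written as 8-bit PNG; the quantisation step (1/255) is well below the
stated noise SDs and the round-trip tolerances.

## Known limitations

* No viscoelastic constitutive model: the elastic-recovery region is
  detected and excluded, not interpreted. The force balance is the
  simplest purely viscous one.
* No benchmark elongational-viscosity values exist to validate against
  in absolute terms; validation is internal consistency (analytic
  oracle, noise robustness, exponent recovery).
* The optics module assumes a single strut, locally straight, measured
  at its vertex; crossing strands, corners and multi-strut scenes are
  out of scope.
* Evaporation over the ~12 s observation window is neglected, matching
  the constancy of the recovered cross-sections along the strand.
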