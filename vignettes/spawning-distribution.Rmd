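---
title: "Modelling blue whiting spawning distributions from plankton-recorder presence/absence records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling blue whiting spawning distributions from plankton-recorder presence/absence records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Blue whiting (*Micromesistius poutassou*) larvae appear in Continuous
Plankton Recorder (CPR) samples collected by ships of opportunity in the
North-East Atlantic. Each silk square of the recorder corresponds to about
10 nautical miles of towing and records an abundance *category* (0, 1, 2, 3
larvae counted exactly; then ranges 4–11 and 12–25). The sampling is
irregular in space and time — ships follow commercial routes, coverage of
the Rockall region collapsed after the mid-1970s — and larvae are rare
(about 2% of samples). The scientific questions are where and when spawning
happens, whether there are two separable spawning components (a northern
one in the Rockall Trough and a southern one off the Porcupine Seabight,
conventionally split at 53°N), and how their abundances vary across years.

Because the categorical abundances above 3 larvae carry little metric
information, the data are reduced to presence/absence and modelled with a
Bernoulli generalised additive model (GAM) on the logit scale:

$$ y_i \sim \mathrm{Bernoulli}(p_i), \qquad
   \operatorname{logit} p_i = \beta_0 + \beta_{DN}\,DN_i +
   f(\mathit{east}_i, \mathit{north}_i, \mathit{doy}_i)
   \;[+\; s(\mathit{year}_i)] $$

where *east*/*north* are UTM zone-28 coordinates (one zone for the whole
domain), *doy* is the day of year, and *DN* is a day/night factor derived
from solar elevation (night: sun 6° or more below the horizon — the civil
dawn convention; a positive coefficient means larvae are more catchable by
day). Ten candidate structures for $f$ and the year term — from fully
additive to a full 3-D space–season tensor interaction, with the seasonal
and/or year smooths optionally conditioned on the component — are fitted
and ranked by AIC.

## The smoothing engine

The package implements its own penalized-spline engine rather than wrapping
a GAM library, so every ingredient is open to inspection and test:

* **Marginal bases.** Cubic B-splines (order 4) with interior knots at the
  data quantiles and a second-order difference penalty on the coefficients
  (P-splines). This stands in for classic cubic regression splines: the
  same function class and the same penalty rationale, with a simpler,
  numerically robust construction. Constants and linear coefficient
  patterns are unpenalized (null space dimension 2). The day-of-year basis
  is cyclic: uniform knots on [0, 365], boundary-overlapping basis
  functions wrapped so the function and its derivatives are continuous
  across New Year, with a circular difference penalty (null space:
  constants only). Basis dimensions are not dictated by the data; defaults
  are k = 10 for 1-D smooths, 8×8 for the 2-D spatial tensor and 6×6×8 for
  the 3-D tensor (the doy margin largest, as it carries the phenology),
  all configurable. `k` below 4 is rejected — an order-4 B-spline basis
  cannot be smaller.
* **Tensor products.** Row-wise Kronecker products of the marginal
  designs; each margin contributes its own expanded penalty
  $I \otimes S_m \otimes I$, hence its own smoothing parameter.
* **Identifiability.** Every smooth block is constrained to sum to zero
  over the training rows; the constraint is absorbed by a QR
  reparameterization that drops one column, and the global intercept is
  carried separately. By-component smooths are duplicated, masked per
  component, and constrained within each component; component mean-level
  differences are absorbed by the spatial term.
* **Fitting.** Penalized iteratively reweighted least squares (PIRLS) with
  step halving, so the penalized deviance is non-increasing. The
  coefficient covariance is the Bayesian posterior covariance
  $(X^TWX + \sum_j \lambda_j S_j)^{-1}$; the effective degrees of freedom
  (edf) are the trace of the influence matrix.
* **Smoothness selection.** A UBRE-type criterion,
  $D/n + 2\gamma\,\mathrm{edf}/n - 1$ (scale fixed at 1, appropriate for
  Bernoulli data), minimised over log smoothing parameters by
  derivative-free search (golden-section in one dimension, Nelder–Mead
  with an optional second start otherwise, a coarse log-grid as a
  fallback). The overfit-penalty multiplier $\gamma$ defaults to 1.4.
* **Model comparison.** Conditional AIC, $-2\ell + 2\,\mathrm{edf}$, using
  effective rather than raw degrees of freedom — required for penalized
  smooths. AUC is computed in-sample from average ranks (ties count ½);
  with ~2% presences it is optimistic, and is reported for comparability,
  not selection. ΔAIC is reported against the best one-component model and
  against the best model overall; ΔAIC > 20 is flagged ("essentially no
  empirical support") but never acted on automatically.

## Numerical choices

* PIRLS converges when the relative penalized-deviance change is below
  1e-8 (200 iterations cap); fitted probabilities are clamped away from 0
  and 1 at 1e-10; diverging linear predictors (|η| > 30) flag possible
  complete separation.
* Cholesky factorisations carry an escalating ridge fallback for
  near-singular systems.
* Log smoothing parameters are clamped to [-15, 15].
* Posterior draws use a Cholesky square root when the covariance is
  positive definite (deterministic and stable under archive round-trips)
  and an eigendecomposition otherwise, so an exactly zero covariance
  yields exactly degenerate draws.
* Points beyond a basis' knot range are evaluated by linear extension of
  the boundary value and slope; the count of extrapolated points is
  attached to the design.
* Component labels: an observation is northern iff its latitude is ≥ the
  dividing latitude (equality goes north). Elevation exactly -6° is night
  (the convention is inclusive).
* Feb 29 maps to day-of-year 60 (shared with Mar 1); the seasonal cycle is
  365 days everywhere.
* All timestamps are UTC; the reader rejects anything that is not ISO-8601
  (guessed timezones are the classic failure mode of ship-log data).

## Derived products

Model fits are turned into the scientific outputs on a regular
(east, north, doy) lattice per year, with the day/night state averaged
(the products do not condition on one state; "day", "night" are
available). All normalised products are per-component probability
densities — each component integrates to 1 over its own domain, so
**relative abundance must not be compared between components**. Annual
fields are normalised per year first and then averaged, so no single year
dominates.

* **Support masking.** Occurrence probabilities far from any sampled
  location are pure extrapolation: the unpenalized linear directions of a
  difference-penalized spline can grow toward unsampled corners of the
  bounding box, and a normalised density would concentrate there. Products
  are therefore restricted to the sampled domain: a fine (200×200)
  occupancy lattice recorded at fit time is dilated by a support radius
  (default 80 km), and each product cell is weighted by the *fraction* of
  its area inside the dilated region. Fractional weights make integrals
  stable under grid refinement, because every resolution integrates the
  same fixed fine indicator.
* **Spawning centres.** The centre of a component is estimated as the
  density-weighted centroid of its 75% highest-density region. The raw
  argmax cell is also reported, but on the broad plateau of a smooth
  density it is ill-determined (in synthetic experiments it wanders
  100–150 km at fixed truth while the trimmed centroid stays within a few
  tens of km); for a symmetric spawning bump the two coincide.
* **Peak-timing maps.** Per spatial cell, the day of year maximising the
  year-averaged probability; masked to the smallest cell set holding 75%
  of each component's spatial density (ties broken by cell index, so the
  mask is deterministic); cells with flat seasonal profiles are masked and
  counted.
* **Zonal marginals.** Eastings integrated out per component, normalised
  per component; the northing axis is reported with the latitude at the
  domain-centre easting for readability. Peak spawning days per component
  are read off the latitude-integrated seasonal profiles.
* **Annual index.** For each posterior coefficient draw, the probability
  integrated over space and season per year and component; the median and
  central 67% interval (±1 sd equivalent) are reported. Units are
  arbitrary but linear.
* Grid defaults (50×80 spatial cells, 5-day doy step) keep the refinement
  error of the integrals well below 1%.

## The synthetic world

Because the original observations are available only on request from the
curating foundation, the package carries a survey generator with a known
truth, and all parameter-recovery claims are made against it. The truth is
the simplest structure realising the two-component configuration: per
component, an isotropic Gaussian bump in projected space times a Gaussian
seasonal window on the circular doy axis, scaled by an amplitude plus a
component-specific year trend, on top of a rare-presence background, plus
a +0.17 logit day/night offset. The fitter never sees this functional
form.

Defaults state the world the tests assume, chosen once to match the survey
being emulated and then frozen:

* Southern component off the Porcupine Seabight (12.5°W, 50°N), spatial sd
  170 km, peak day 80, seasonal sd 30 d, amplitude 6.1, linearly declining
  trend; northern component in the Rockall Trough (9.5°W, 56.5°N), spatial
  sd 210 km, peak day 120 (a 40-day offset, inside the 30–45 day southern
  lead reported for the real stock), seasonal sd 38 d (more protracted),
  amplitude 7.6, sinusoidal trend. Background logit -6.6. With the default
  survey this yields ≈2% presences (the real figure is 1.9%) and a
  northern component of larger integrated abundance.
* The survey: seven criss-crossing routes west of Britain and Ireland,
  sampled every 10 nautical miles, one traversal per route per month with
  the start day drawn from a mid-month-peaked profile (the within-month
  sampling cycle) and instants advancing at 12 knots so traversals span
  day and night. The Rockall route is active only through 1974, emulating
  the loss of the ocean weather ship routes. Over 1950–2005 this gives
  ≈72k samples — the same order as the ≈59k real region-filtered records.
  The network is denser than a two-route sketch because centre recovery is
  only identifiable where routes actually cross the spawning centres; the
  real survey blankets the region far more densely still.
* Presence counts for simulated positives follow a geometric distribution
  (single larvae dominate), mapped through the category scheme; counts
  beyond the last range (12–25) are clamped into it. This choice is
  cosmetic: the pipeline models presence/absence only.

What a green recovery test establishes: with CPR-like sampling and a truth
of this family, the pipeline relocates spawning centres to a few tens of
km, recovers the seasonal offset to within days, covers the day/night
effect with its posterior interval, and prefers the two-component
structure exactly when the truth has one. What it does not establish:
robustness to oceanographic realism the generator lacks — advection,
bathymetry-linked habitat, gear saturation, species misidentification,
spatially correlated residuals.

## Design choices on open ground

* The sample timestamps' timezone is not documented for the real data; the
  package assumes UTC throughout and refuses ambiguous input rather than
  guessing.
* Basis dimensions and knot placements are not dictated by the source
  analysis; the defaults above are declared, not inferred, and
  configurable.
* Absolute AIC values are engine-specific (they depend on basis
  dimensions and the selection criterion's internals), so cross-engine
  comparisons are made on orderings and differences, never on absolute
  scores.
* The region-of-interest polygon of the original analysis is not published
  as coordinates; the default is the 20°W–10°E, 44–64°N box with the
  sparsely sampled Bay of Biscay and Norwegian Sea corners notched out,
  both configurable. Points exactly on the boundary are retained.
* The reference years behind the averaged distribution figures are not
  stated; the package averages the per-year normalised distributions over
  all fitted years.
* The ensemble's ΔAIC columns follow the published table: the
  one-component reference among models 1–6 only, the overall reference
  among all successfully fitted models; failed fits are recorded per row
  and excluded from the references.

## Known limitations

* In-sample AUC with rare presences is optimistic; no held-out skill is
  computed.
* The Bernoulli likelihood treats silk squares as independent; spatial or
  serial residual correlation along a tow is not modelled.
* Ordinal abundance modelling (continuation-ratio logits) is out of scope;
  the category detail beyond presence is used only by the simulator.
* Four-way space–season–year interactions are excluded — with ~2%
  presences they are not estimable.
* The smoothing-parameter search is derivative-free and budgeted; on very
  flat criteria the selected smoothness can differ slightly between runs
  with different budgets (fits are deterministic given settings).
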