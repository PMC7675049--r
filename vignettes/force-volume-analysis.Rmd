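---
title: "Depth-segmented nanomechanics and adhesion mapping of force-volume data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-segmented nanomechanics and adhesion mapping of force-volume data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fvmech)
```

## The measurement and the model

Force-distance (FD) curve based AFM records, at every pixel of a map, the
cantilever force while the tip approaches, indents, and retracts from a
living cell. Two very different signals live in one retraction curve:

* the **elastic contact response**, from which Young's moduli are extracted,
  and
* **single-molecule unbinding events**, when a ligand on the tip (here a
  cholesterol-binding toxin fragment on a PEG tether) has attached to the
  membrane and ruptures during retraction.

`fvmech` implements the full analysis chain for such data: baseline
correction, noise estimation, contact-point location, depth-segmented
elasticity, rupture detection with worm-like-chain (WLC) validation,
specificity classification, and map-level statistics, plus a synthetic
force-volume generator with complete ground truth so that every stage can be
verified quantitatively.

### Contact mechanics

For a spherical tip of radius $R$ indenting an incompressible elastic
half-space by $\delta$, the Hertz model gives

$$F = \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2},$$

linear in the prefactor once written against $\delta^{3/2}$. Cells are not
half-spaces: the shallow response (here $\delta \le 50$ nm) is dominated by
the plasma membrane (PM) and its immediate cortex attachment, the deeper
response (50-200 nm) by the actin cortex. `fvmech` separates the two by
**vertical segmentation** with a force-continuous two-layer model

$$F(\delta) = C_{pm}\, a(\delta) + C_{cx}\, b(\delta), \qquad
a(\delta) = \min(\delta, B)^{3/2},\quad
b(\delta) = \max(\delta^{3/2} - B^{3/2}, 0),$$

with the boundary $B = 50$ nm. Force continuity (stiffness switches, force
accumulates) avoids unphysical jumps at the boundary; it also means the
deep-window force is a cortex-slope term *plus a constant*, which is why the
independent per-window fits (`segmented_moduli(..., method = "window")`) use
a free intercept for the cortex window while the membrane window is
contact-anchored through the origin. The joint fit (`method = "joint"`, the
default) estimates both prefactors at once, which matters under noise: with
independent windows, a contact point located a few nanometres late leaks the
much stiffer cortex response into the membrane window and inflates $E_{pm}$
one-sidedly; in the joint fit those samples are explained by the cortex term.

For very shallow layers over a rigid support, the bottom-effect corrected
model is available:

$$F = \frac{16E}{9}\sqrt{R}\,\delta^{3/2}
\left(1 + 0.884\alpha + 0.781\alpha^2 + 0.386\alpha^3 + 0.0048\alpha^4\right),
\qquad \alpha = \frac{\sqrt{R\delta}}{h},$$

with layer thickness $h$ (config `layer_thickness_nm`, default 50 nm; what
"the layer" should mean for a cell - the membrane compartment or the whole
cell height - is genuinely ambiguous, so it is a configuration choice, with
the membrane-window interpretation as default and `bottom_effect` off unless
requested). As $\alpha \to 0$ the factor tends to 1 and the expression
reduces exactly to the Hertz law at $\nu = 0.5$.

### Fitting on the linear scale

The published convention linearizes the Hertz law as $F^{2/3}$ versus
$\delta$ and reads the modulus from the slope. `fvmech` fits the equivalent
regression of $F$ on $\delta^{3/2}$: noise-free the two give identical
estimates and are exactly scale-equivariant, but the $F$-scale regression
remains well defined when noise drives individual force samples negative
(where $F^{2/3}$ does not exist). The linearized form is retained as
`method = "linearized"` in `hertz_slope_fit()`.

### Contact point

The contact point is found by a deterministic two-piece scan on the approach
segment: each candidate split models everything before it as a constant and
everything after as the two-layer contact response in the
deflection-corrected depth $\delta = (z - z_0) - F/k$; the split minimizing
the total squared residual wins and is refined by parabolic interpolation.
Two design points matter:

* **the in-contact model must be the layered one.** A soft membrane over a
  stiffer cortex puts most of the contact-point information into the deeper
  force rise; a single-layer scan systematically places contact tens of
  nanometres late on such curves.
* **all candidates are scored on the same samples**, so an early split must
  explain the contact rise with the model toe and is penalized.

The scan runs on the approach because the retraction carries adhesion dips
near contact. The retraction (the segment the published convention fits) is
then analysed against the approach-located $z_0$; in this package's forward
model the two segments share the elastic response.

### Baseline handling

Raw FD curves carry tilt and bow; a second-degree polynomial is fitted to
the off-contact area (the fraction of samples farthest from the surface,
default 30%, widened once the contact point is roughly known) and
subtracted. Two numerical choices deserve explanation:

* **hold, don't extrapolate** (`baseline_extrapolate = "hold"`): the fitted
  polynomial is subtracted over its fit range and its edge value held beyond
  it. Extrapolating a quadratic fitted on noisy data into the contact region
  injects a smooth spurious force whose magnitude (several pN growing with
  distance) rivals the shallow-indentation signal of a soft membrane;
  holding the edge value leaves only the small true drift increment across
  the contact region. Full extrapolation is available and is exact for pure
  polynomial drift.
* **local contact anchoring**: just before mechanics fitting, the residual
  offset measured on the approach immediately before contact is removed, so
  the through-origin membrane term is not biased by the held offset. The
  approach is used because the retraction's pre-contact region may hold the
  tether.

The noise level is the SD of residuals about a straight-line fit of the
off-contact retraction, matching the convention of reporting noise levels
below 20 pN.

### Rupture events and WLC validation

Rupture candidates are local minima of the pairwise-mean retraction force
(averaging two samples keeps single-sample-wide tether dips visible while
reducing the noise floor by $\sqrt2$) below $3\sigma$, past the contact
point, that return toward baseline within 5 samples. Each candidate's
extension profile, from the contact crossing to the rupture, is fitted with
the WLC interpolation formula

$$F(x) = \frac{k_BT}{L_p}\left(\frac{1}{4}\left(1 - \frac{x}{L_c}\right)^{-2}
- \frac{1}{4} + \frac{x}{L_c}\right)$$

over $(L_p, L_c)$ with $k_BT$ at 310 K (the experiments run at 37 C).
Acceptance requires fit RMS below $2\max(\sigma, 0.1\ \mathrm{pN})$ (the
floor only matters for noise-free synthetic data) and a contour length in
5-60 nm (PEG linker plus protein). An event is **specific** when its rupture
force exceeds 80 pN, its rupture distance exceeds 5 nm, and the WLC
validation passed. Both gates use strict inequalities.

**Finite-sampling floor of the rupture force.** The tether breaks somewhere
between the last sampled point and the next; on a PEG-stiff tether the force
rises by roughly $k$-limited tens of pN per nm near rupture, so at ~0.9 nm
sampling the raw force minimum underestimates the rupture force by ~20 pN on
average. Accepted events therefore report the fitted tether force at the
last tethered sample plus the model-integrated expected rise over the
unobserved gap. This removes most of the bias; the residual mean absolute
error (~1.1 noise SD at 15 pN noise) is set by the within-sample randomness
of the break position and the endpoint uncertainty of the fit, and no
estimator can do much better at this sampling density. Consequences for
map-level statistics are discussed under *Limitations*.

### Map-level statistics

Per-pixel results assemble into multiparametric channels (height, $E_{pm}$,
$E_{cx}$, adhesion force, specificity mask, stratum). The **binding
probability** is the percentage of analysed pixels carrying a specific
event; pixels whose curve never exceeds `contact_min_snr` noise SDs are
excluded from the denominator (whole-field convention; no cell masking).
Domains are connected components of the specific mask, 8-connectivity by
default because the cholesterol-enriched assemblies are irregular and
diagonal contacts should not split them (4-connectivity is a config switch).
Pixels stratify as *cholesterol* (a specific rupture above 100 pN),
*non-adhesive* (nothing above 30 pN), or *indeterminate* (the 30-100 pN gap;
excluded from stratified statistics, since only the two extremes are
defined).

Group comparisons use one-way ANOVA with Tukey HSD for (near-)normal data
and a two-tailed Mann-Whitney U test otherwise, with the star convention
p < 0.05 (\*), < 0.01 (\*\*), < 0.005 (\*\*\*), < 0.001 (\*\*\*\*), strict
inequalities, "ns" above 0.05. The Mann-Whitney implementation enumerates
all group assignments exactly for $n_a + n_b \le 12$ (valid under ties) and
otherwise uses the normal approximation with tie and continuity corrections.
The unit of analysis for between-condition comparisons is the per-cell (here
per-map or per-group) mean.

### Pooled group fits

Per-curve modulus estimates at live-cell noise (15 pN against a soft
membrane whose entire 50-nm window generates <30 pN) are dominated by
contact-point uncertainty: the per-curve estimate correlates ~0.95 with the
contact-point error, giving relative errors of 50-150% per pixel, and any
truncation of non-physical negative estimates then biases a group mean
upward. When the quantity of interest is a *group* modulus (a cell, a
stratum, a condition), `pooled_moduli()` fits one pair of layer prefactors
to all curves of the group with per-curve contact points, alternating
shared-coefficient least squares, a global contact-shift line search (the
slow, strongly correlated likelihood mode), and per-curve contact
refinement. A shared nuisance intercept and ramp absorb residual baseline
drift. On synthetic maps this recovers group means across the 3.7-37.5 kPa
range within a few percent where the per-pixel average is tens of percent
off.

## The synthetic generator

`build_scene()` + `simulate_map()` produce maps with full ground truth:

* clustered domain masks grown from random connected blobs with a truncated
  power-law size distribution (sizes up to 64 pixels, exponent 1.8: small
  domains most abundant, heavy tail), grown until a target coverage;
* a two-valued PM elasticity field (inside/outside domains) over a uniform
  cortex, defaults 13.1/9.0 kPa over 15.9 kPa - the malignant-line stratum
  values - and coverage 27.5%;
* a two-layer, force-continuous contact response sampled on the piezo axis
  by inverting $z = z_0 + \delta + F/k$, turning around at the setpoint
  (default 750 pN, 512 samples per segment, k = 0.1 N/m, R = 65 nm, all
  within the instrument ranges used for such imaging);
* second-degree baseline drift (default $2 + 0.01 z + 2\times10^{-5} z^2$
  pN) and Gaussian force noise (default 15 pN, below the 20 pN ceiling);
* on domain pixels, with probability `p_bind` (default 1), a WLC tether
  ($L_p$ = 0.38 nm, $L_c \sim U(10, 40)$ nm) rupturing at a force drawn from
  $N(130, 35)$ pN truncated positive - the measured adhesion-force scale.

Every pixel draws from its own stream seeded by a documented hash of
(seed, row, col), so maps are reproducible and traversal-order independent.
A pixel's injected event is ground-truth *specific* when its drawn force and
distance pass the printed gates (`scene_specific_truth()`).

What the generator does **not** emulate: viscoelastic hysteresis between
approach and retract, PeakForce tapping dynamics and hydrodynamic drag,
surface topography (the contact height is flat), multiple tethers per pixel,
and spatial correlation of the moduli beyond the domain mask. Passing tests
on this generator therefore demonstrate the correctness and calibration of
the analysis under its stated noise model, not robustness to every artefact
of real instruments.

## Study sizes and verification results

The package's Monte-Carlo verification studies (in `tests/testthat/` and
`scripts/acceptance.R`) use these sizes, chosen to give stable statistics at
desk-scale runtimes:

* **modulus recovery**: the three published (PM, cortex) pairs - (5.3,
  37.5), (3.7, 20.5), (10.7, 15.9) kPa - as ground truth, 50 seeded 12x12
  maps each at 15 pN noise; the pooled group fit recovers each group mean
  with a median error well inside 10%.
* **rupture detection**: 500 curves with injected tethers at
  $N(130, 35)$ pN; sensitivity ~0.97 at a false-discovery rate ~0.02, with
  every reported specific event satisfying the printed gates by
  construction (asserted on every run).
* **binding probability**: 100 seeded maps per published coverage level
  (5.4%, 11.6%, 27.5%), compared against the exact binomial 99% interval
  around each scene's ground-truth specific fraction, at 24x24 pixels.

## Limitations

* **Binding-probability recovery is bounded by classification losses.** With
  a ~20 pN rupture-force measurement error at an 80 pN gate, events smear
  across the gate; because the force distribution is centred well above the
  gate, roughly ten times more events sit just above it than just below, and
  the net effect is a systematic ~5-8% relative loss of specific pixels.
  Tethers with short contour lengths (~10 nm) lose another few percent to
  the >= 10-sample WLC precondition, and ~1.5% of low-force events fall
  under the 3-sigma detection rule. The estimate therefore runs ~10%
  relatively below the true specific fraction - a property any pipeline with
  this noise floor shares - and exact binomial containment around the truth
  fails at high coverage where the interval is narrower than the loss. The
  package reports what it measures; no re-inflation is applied.
* **Rupture forces carry a ~1 sigma MAE floor** from the unobserved force
  rise between the last sampled point and the break (see above). Denser
  sampling, not better estimation, is the remedy.
* **Per-pixel moduli are noisy for soft membranes**; use the pooled fit for
  group-level numbers and treat per-pixel maps as qualitative. Negative
  per-pixel estimates are reported as absent rather than clipped, and the
  map mean is not a substitute for the pooled estimate.
* The elasticity model is purely elastic; viscoelastic indentation or
  conical tips are out of scope, as is parsing proprietary instrument files.

## A short tour

```{r, eval = FALSE}
library(fvmech)

# a synthetic malignant-cell-like scene with ground truth
scene <- build_scene(32, 32, coverage = 0.275, seed = 1)
map <- simulate_map(scene)

# the map-level fit
an <- analyze_map(map)
summary(an)
plot(an)

# headline numbers
binding_probability(an)          # percent of analysed pixels, specific
domain_sizes(an)                 # connected domains, sizes in px and nm^2
stratified_pm_elasticity(an)     # cholesterol vs non-adhesive E_pm + MW test

# group-level moduli, the precise way
pooled_moduli(map)

# persist and reload
write_dataset(map, "map.fvd")
identical_map <- read_dataset("map.fvd")

# end-to-end, config-driven
run_pipeline(list(simulate = list(rows = 32, cols = 32, coverage = 0.275,
                                  seed = 1),
                  seed = 1, out = "report.json"))
```
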