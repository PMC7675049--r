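# fvmech

Depth-segmented nanomechanics and adhesion mapping for AFM force-volume data.

## What this package is for

Force-distance (FD) curve based AFM maps living cells pixel by pixel: every
pixel holds an approach/retraction force curve from which one can extract
both the local elasticity and, with a ligand-functionalized tip, single
molecule unbinding events. `fvmech` implements the complete offline analysis
for such data, the workflow used to separate plasma-membrane (PM) from
cortical elasticity on breast epithelial cell lines and to map
cholesterol-enriched membrane domains with a toxin-derivatized tip:

* second-degree polynomial **baseline correction** of the off-contact area
  and **noise estimation** (SD about a linear fit of the off-contact
  retraction);
* deterministic **contact-point location** (two-piece least-squares scan
  with a layered in-contact model);
* **depth-segmented elasticity**: Hertz sphere contact
  `F = (4/3) E/(1-nu^2) sqrt(R) delta^(3/2)`, fitted on the linear
  `delta^(3/2)` scale, with the PM modulus from indentations below 50 nm and
  the cortex modulus from 50-200 nm via a force-continuous two-layer model;
  optional bottom-effect (finite layer thickness) correction
  `F = (16E/9) sqrt(R) delta^(3/2) (1 + 0.884a + 0.781a^2 + 0.386a^3 +
  0.0048a^4)`, `a = sqrt(R delta)/h`;
* **rupture-event detection** on the retraction, worm-like-chain validation
  of the tether extension profile (Marko-Siggia interpolation, kBT at 310 K),
  and **specificity classification** (force > 80 pN, distance > 5 nm,
  validated WLC);
* **map statistics**: binding probability (percent of analysed pixels with a
  specific event), connected-component domain sizes (~100 nm pixels),
  stratified PM elasticity (cholesterol-enriched, F > 100 pN, versus
  non-adhesive, F < 30 pN), before/after percent changes and fold changes;
* **group statistics**: one-way ANOVA + Tukey HSD, exact two-tailed
  Mann-Whitney U (full enumeration for small samples, tie-corrected normal
  approximation otherwise), and the star significance convention;
* a **synthetic force-volume generator** with complete ground truth
  (two-layer elastic response, clustered domains, WLC tethers rupturing at
  ~130 +/- 35 pN, second-degree drift, <20 pN Gaussian noise) so every stage
  is verifiable without instrument data;
* a single-file **container format** (`write_dataset()`/`read_dataset()`,
  uncompressed R serialization of a fixed hierarchical schema: acquisition,
  grid, curves, channels, truth) with TIFF+CSV channel export and a
  config-driven pipeline (`run_pipeline()`, plus a thin CLI in `inst/cli/`).

## Worked example

```r
library(fvmech)
scene <- build_scene(24, 24, coverage = 0.275, seed = 42)  # malignant-like scene
map   <- simulate_map(scene)                               # 576 curves, ground truth attached
an    <- analyze_map(map)                                  # the map-level fit
summary(an)
```

```
Force-volume analysis summary (24x24, 576 analysed pixels)
  median noise:        14.88 pN
  binding probability: 21.53%
  specific events:     124 of 157 candidates (force 142 +/- 35 pN)
  E_pm:           mean 11.4, sd 2.8, n = 576
  E_cortex:       mean 16, sd 0.31, n = 576
  adhesion_force: mean 30.5, sd 61, n = 576
  domains: 18 (sizes: 90, 6, 3, 3, 3 px)
PM elasticity by adhesion stratum
  cholesterol-enriched: n = 108, mean = 13.9 kPa
  non-adhesive:         n = 421, mean = 10.5 kPa
  Mann-Whitney U: p = 6.117e-29 (****)
```

The scene was built with 27.5% cholesterol-domain coverage, membrane moduli
of 13.1 kPa inside versus 9.0 kPa outside the domains over a 15.9 kPa
cortex, and 15 pN force noise. The analysis finds a binding probability of
21.5% (classification losses at the 80 pN specificity gate make this run
~10% relatively below the true specific fraction - see the vignette), an
adhesion-force distribution around 140 pN, a dominant 90-pixel domain among
small ones, and significantly stiffer membrane on cholesterol domains.
For group-level moduli use the pooled fit, which is far less sensitive to
per-curve contact-point noise:

```r
pooled_moduli(map, pixels = scene$domain_mask)
```

```
Pooled two-layer fit over 159 curves
  E_pm     = 13.1 kPa
  E_cortex = 16 kPa
  rms = 15.66 pN; nuisance offset 3.83 pN, ramp -0.0313 pN/nm
```

recovering the in-domain ground truth (13.1 kPa over 15.9 kPa) almost
exactly.

See `vignettes/force-volume-analysis.Rmd` for the models, the estimator
design choices, the generator's scope, and known limitations.

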