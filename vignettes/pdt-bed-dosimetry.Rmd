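---
title: "Methods: light dosimetry and outcome analysis for tumor-bed PDT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: light dosimetry and outcome analysis for tumor-bed PDT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdtbedkit)
```

# The problem

After surgical removal of a tumor node, residual cancer cells in the tumor
bed drive local recurrence. Post-operative photodynamic therapy (PDT) with
a topically applied chlorin-e6 gel is one candidate countermeasure, but its
effect depends on two depth profiles that behave very differently:

* the **photosensitizer (PS) concentration**, which enters the tissue by
  diffusion from the surface and decays roughly exponentially over a few
  hundred micrometers — and is strongly suppressed when a laser scalpel has
  coagulated ("caramelized") the surface into a 300–400 µm barrier layer;
* the **absorbed light dose**, which penetrates millimeters and whose shape
  depends on wavelength: chlorin e6 can be activated at either of its
  absorption peaks, 405 nm (blue, strong superficial deposition) or 660 nm
  (red, deeper and flatter).

Where light is present without PS, no therapeutic reactive-oxygen
production occurs, but low-dose light exposure on its own may *stimulate*
residual tumor cells. The package therefore quantifies three things: where
the light goes (Monte Carlo), where the PS goes (fluorescence tile-scan
analysis), and what happened to the animals (exact small-sample
statistics), plus an explicitly interpretive combination of the first two.

# Monte Carlo light transport

## Model

A homogeneous half-space of tissue with absorption coefficient $\mu_a$,
reduced scattering coefficient $\mu_s'$ and refractive index $n = 1.4$
under air ($n_0 = 1$), illuminated at normal incidence by a uniform broad
beam. Photon packets perform the standard hop–drop–spin walk: step lengths
$s = -\ln U/\mu_t$, weight deposition $w\,\mu_a/\mu_t$ per interaction,
scattering by an isotropic or Henyey–Greenstein phase function,
Fresnel/total-internal reflection when a packet returns to the top surface,
and Russian roulette below weight $10^{-4}$ with survival probability 0.1.
The deterministic specular loss $((n-n_0)/(n+n_0))^2 \approx 2.778\%$ is
removed analytically at launch.

The scored quantity is the accumulated absorbed weight per voxel,
$A(x,y,z,\lambda)$, reduced to the **in-depth absorbed-dose density**

$$\tilde A(z,\lambda) = \frac{\iint A(x,y,z,\lambda)\,dx\,dy}{N_{ph}\,\Delta z}
\quad [\mathrm{mm}^{-1}],$$

the fraction of launched energy absorbed per unit depth. Integrated over
depth it equals the absorbed fraction of the energy budget.

## Reference optical properties

| tissue | λ, nm | $\mu_a$, mm⁻¹ | $\mu_s'$, mm⁻¹ | $n$ |
|---|---|---|---|---|
| tumor  | 405 | 0.92 | 1.29 | 1.4 |
| tumor  | 660 | 0.18 | 0.67 | 1.4 |
| muscle | 405 | 0.57 | 1.17 | 1.4 |
| muscle | 660 | 0.07 | 0.58 | 1.4 |

Tumor tissue attenuates faster than muscle at both wavelengths (higher
blood content). These values are embedded as `default_tissue_models()` and
can be overridden through the JSON config.

## Design choices that were genuinely open

* **Anisotropy.** Only $\mu_s'$ is available for these tissues, not the
  anisotropy factor $g$. The default runs in the similarity regime:
  isotropic scattering with $\mu_s = \mu_s'$ ($g = 0$). Beyond roughly one
  transport mean free path the depth-resolved absorbed dose depends on
  $(\mu_a, \mu_s')$ only to first order, which the suite verifies directly
  (a $g = 0.9$ run with $\mu_s = \mu_s'/(1-g)$ agrees with the $g = 0$ run
  at depth). $g$ is exposed as an override; Henyey–Greenstein is used when
  $g \neq 0$.
* **Beam geometry.** "Uniform illumination" is realized as a laterally
  infinite uniform beam (periodic wrap in $x,y$), which matches the lateral
  integration in $\tilde A$ and removes edge effects; a 9-mm disc beam
  (matching the irradiation spot) is available, with laterally escaping
  weight counted as escaped. Which of the two produced the reference depth
  profiles is not recorded; for depth profiles at these depths the
  difference is small, and both are provided.
* **Boundaries.** Top surface: refractive mismatch 1.4/1.0 with full
  unpolarized Fresnel and TIR. Bottom (15 mm) and lateral boundaries:
  matched and absorbing, with the escaping weight tracked as transmitted —
  never silently lost.
* **Energy bookkeeping.** Russian roulette conserves weight only in
  expectation. The reported budget keeps the specular fraction at its
  analytic value and normalizes the stochastic tallies by the weight
  actually in play (launched weight after specular loss plus the net
  roulette boost), so specular + diffuse + absorbed + transmitted = 1
  *exactly on every run* while the roulette itself stays unbiased.
* **Grid and photon counts.** $\Delta z = 0.05$ mm over 15 mm: the
  crossover depths of interest are ≤ 2 mm, so they need fine axial
  resolution. Tests and the acceptance report use $10^6$ packets (seconds
  per run); $10^7$ reproduces the reference setting when wanted.
* **Caramelization layer.** Deliberately *not* modelled optically — the
  homogeneous models are read as qualitative estimates above it, matching
  how the underlying study treats them.

## Crossover depth

`crossover_depth` smooths both densities with a 3-bin moving average
(Monte Carlo noise near the crossing otherwise produces spurious sign
flips) and returns the linearly interpolated first depth at which the
405-nm density falls below the 660-nm one. With the reference properties
and $10^6$ packets this lands at ≈ 1.0 mm for tumor and ≈ 1.6 mm for
muscle; the tumor crossover is always the shallower one. Validation
anchors: a scattering-free run reproduces Beer–Lambert
($\tilde A = \mu_a e^{-\mu_a z}$) within 3 Monte Carlo standard errors per
bin, and the deep log-slope of the diffusive muscle/660 profile approaches
$\mu_\mathrm{eff} = \sqrt{3\mu_a(\mu_a+\mu_s')} \approx 0.37$ mm⁻¹.

# Fluorescence tile-scan analysis

Cryosections cut normal to the treated surface are imaged as tile scans:
6 serial confocal fields of view starting at the surface, 12 scans from 4
cryosections per animal, 5 animals per resection arm. The per-tile integral
intensity versus depth is the raw profile; per-sample profiles are the mean
over the sample's scans, group profiles the mean ± SD over animals
(averaged on intensities, not logs — the semi-log display is a plotting
choice, not an averaging one).

**Tile height.** The physical tile height is not recorded; the default is
212 µm — a plausible 40× confocal field — which makes the 636-µm reference
depth exactly three tile heights and lets 6 tiles span ≈ 1.3 mm,
consistent with the signal reaching its plateau at about 1 mm. It is a
configurable parameter, and every ratio the package reports is invariant
to it except through the depth labels themselves.

**Decay model.** $I(z) = I_0 e^{-z/\delta} + b$, fitted by `nls` (port
algorithm, non-negativity bounds) from a log-linear initialization. The
additive background $b$ captures the observed deep plateau; a pure
log-linear fit is available. Degenerate inputs (constant profiles) return a
flagged non-converged fit rather than an arbitrary number.

**Attenuation ratio.** The regime diagnostic is
$I(\text{surface tile}) / I(\text{636 µm deeper})$, with the reference
value interpolated log-linearly between tile centers (exact for
exponential samples). The reference depth is measured *from the first
sampling plane*: that is the only convention under which the closed forms
$e^{636/200} \approx 24$ (laser scalpel, > 20) and $e^{636/330} \approx
6.9$ (cold knife, < 7) hold independently of whether tiles are labelled by
centers or edges. Depth labels themselves use tile centers.

# Synthetic data: the stated world

`generate_fluor_stack` draws pixel intensities around
$(I_0 e^{-z/\delta} + b)\cdot T(x,y)$, where $z$ varies continuously down
each tile (pixel row → depth, so a tile integral is a true depth-bin
average), $T$ is a smooth multiplicative speckle field (relative SD 0.15,
correlation length 8 px) and the noise is Poisson-like (variance = mean)
plus additive Gaussian read noise (SD 0.5). The acquisition noise of the
real microscope is not characterized anywhere; these magnitudes are chosen
once as typical confocal behaviour and are all exposed in the spec object.
Presets: cold knife $\delta = 330$ µm, $I_0 = 100$, $b = 2$; laser scalpel
$\delta = 200$ µm, $I_0 = 40$, $b = 0.1$ (weaker signal and a nearly absent
plateau, reflecting blocked diffusion through the coagulated layer). The
preset decay lengths are chosen to land the attenuation ratios in the
published regimes (< 7 and > 20 respectively) — they are consistent with,
but not measurements of, the real tissue. The generator does **not**
emulate histological texture, vasculature, tile stitching artifacts or the
caramelization layer's own appearance; a green round-trip test therefore
establishes that the *analysis* recovers known ground truth under realistic
noise, not that the generator reproduces real tissue images.

`generate_ledger` produces the ten-group animal trial. In `expected` mode
it is deterministic: each group receives the integer recurrence count
closest (round half up) to its target percentage of evaluable animals. In
`sampled` mode outcomes are Bernoulli draws, for power-style exploration.

Two documented data inconsistencies surface here and are flagged rather
than hidden:

* the published per-group sizes (11,11,11,11,11 / 11,11,10,11,13) sum to
  111, although the source also prints a grand total of 113; the rows are
  the operative data (they are what the printed rates are computed from)
  and the generator reproduces them exactly;
* the printed 42% (11 evaluable) and 18% (10 evaluable after one death)
  correspond to no integer count — the nearest counts give 45% and 20% —
  so `generate_ledger` records both groups in its `discrepancies`
  attribute. The four irradiation-only group rates were never printed as
  numbers; the defaults (50, 27, 67, 90%) are synthetic choices consistent
  with the published ordinal statements (irradiation-only above the
  matching PDT group; 405-nm irradiation after cold knife comparable to
  its 92% control) and are marked `published = FALSE` in
  `paper_group_design()`.

# Trial statistics

Perioperative deaths (within ~2 h of the procedure, anesthesia
complications) are excluded from denominators: they carry no recurrence
information, and this policy is what reproduces 92% = 11/12 and
70% = 7/10 exactly. Reported rates are rounded half up to integer percent;
full precision is retained internally.

Clopper–Pearson intervals use the beta-quantile form of binomial tail
inversion; the suite checks them against an independent root-finding
oracle. Fisher's exact test sums hypergeometric probabilities of tables no
more probable than the observed one (two-sided probability method) and
reports the conditional-MLE odds ratio; both are checked against an
independent reference implementation across a table grid. No
multiple-testing correction is applied by default, since the reference
analysis reports rates without formal tests; pairwise comparisons are
provided as plumbing, clearly separable from the published results.

# Combined dose model (interpretive)

`combine_profiles` multiplies the light density by the surface-normalized
PS curve; `treatment_depth` reports where this proxy falls below 1% of its
surface value and the "PS-free light zone" where the PS has dropped below
5% of its surface value while light remains above 1% of its own. The 1%
and 5% thresholds are package choices, exposed as arguments. The proxy is
relative by construction — no singlet-oxygen kinetics, photobleaching or
oxygen depletion — and supports only ordinal conclusions: the product
decays faster than either factor; faster PS decay (laser scalpel) starts
the PS-free zone shallower; 660-nm light makes that zone larger than
405-nm light does. Every output of this module is labelled interpretive.

# Numerical and reproducibility notes

* All randomness flows through R's RNG (`set.seed`), including inside the
  C++ core via `unif_rand`, so any run is bitwise reproducible for a fixed
  seed and R version; the pipeline derives one stream per stage from a
  single root seed, and two runs with one seed yield byte-identical
  manifests.
* Depth is $z = 0$ at the cut surface, increasing downward; optics speak
  mm, fluorescence speaks µm, and conversions happen only at module
  boundaries (`combine_profiles`).
* Crossover interpolation is linear in the smoothed density difference;
  on an exponential difference this carries a curvature bias of order
  $(\Delta z)^2$, well below the Monte Carlo noise at the default grid.
* Tile stacks serialize as per-tile CSV matrices plus a JSON sidecar
  (plain text); a TIFF front end can be layered on without touching the
  analysis API.

# Known limitations

Homogeneous single-tissue models (no layered caramelization optics, no
skin); no polarization or time-resolved transport; no absolute fluorescence
calibration (arbitrary units throughout); no survival-time modelling —
recurrence is a 90-day binary endpoint; and the combined dose model is an
interpretive proxy, not dosimetry of photodynamic effect.
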