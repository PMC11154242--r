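# pdtbedkit

Computational toolkit for assessing **post-operative photodynamic therapy
(PDT) of the tumor bed** after surgical resection, comparing cold-knife and
laser-scalpel surgery. It is aimed at biophotonics and preclinical-oncology
groups who need to reason quantitatively about where, in depth, a topical
photosensitizer and the activating light actually meet.

The package implements four analysis stages plus the synthetic data needed
to test them end to end:

1. **Monte Carlo light dosimetry** (`simulate_transport`,
   `depth_dose_profile`, `crossover_depth`). Photon-packet transport in a
   homogeneous tissue half-space under broad-beam illumination, with
   weighted absorption, Fresnel/total-internal reflection at the
   index-mismatched surface and Russian-roulette termination. The 3-D
   absorbed-weight map A(x,y,z,λ) is reduced to the normalized in-depth
   absorbed-dose density

   &nbsp;&nbsp;&nbsp;&nbsp;Ã(z,λ) = ∬ A(x,y,z,λ) dx dy / (N_ph · Δz) [mm⁻¹],

   the fraction of launched energy absorbed per unit depth. Chlorin e6 has
   absorption peaks near 405 and 660 nm; blue light deposits more dose
   superficially, red light deeper, and `crossover_depth` locates the depth
   where the ordering flips (≈1 mm in tumor, ≈1.6 mm in muscle for the
   built-in optical properties).
2. **Photosensitizer penetration depth** (`integrate_tiles`,
   `aggregate_group`, `fit_decay`, `attenuation_ratio`). Serial confocal
   tile scans from the cut surface are integrated per tile, averaged across
   animals and fitted with I(z) = I₀·exp(−z/δ) + b. The surface-to-636-µm
   attenuation ratio separates the two resection regimes: > 20 after laser
   scalpel (the coagulated "caramelization" layer blocks diffusion),
   < 7 after cold knife.
3. **Recurrence statistics** (`summarize_groups`, `exact_binomial_ci`,
   `fisher_exact`, `recurrence_report`). Per-group 90-day recurrence rates
   over evaluable animals (perioperative deaths excluded from the
   denominator), Clopper–Pearson exact intervals and Fisher exact pairwise
   comparisons, for the ten-group cold-knife × laser-scalpel × treatment
   design.
4. **Combined dose model** (`combine_profiles`, `treatment_depth`). An
   explicitly interpretive pointwise product of the normalized light and PS
   depth curves, giving a relative PDT-intensity proxy and the "PS-free
   light zone" — depths that still receive light but hold no
   photosensitizer, the hypothesized substrate of light-stimulated
   recurrence.

Synthetic generators (`generate_fluor_stack`, `generate_ledger`) produce
tile stacks with known decay structure and per-animal trial ledgers
matching the reference group design, so every stage is testable with no
external data.

## Worked example

```r
library(pdtbedkit)

models <- default_tissue_models()          # tumor & muscle, 405/660 nm
cfg <- simulation_config(n_photons = 2e5, rng_seed = 17)

simulate_transport(models$tumor, 405, cfg)$budget
#> <energy_budget>
#>   specular reflected:     0.02778
#>   diffuse reflected:      0.06976
#>   absorbed:               0.90246
#>   transmitted or escaped: 0.00000

wavelength_comparison(models$tumor, cfg)$crossover_mm
#> [1] 1.05      # 405 nm out-deposits 660 nm down to ~1 mm in tumor

prof <- generate_sample_profile(fluor_preset("cold_knife", seed = 17),
                                group_label = "cold_knife")
fit_decay(prof)
#> <decay_fit> I0 = 4.163e+05, delta = 329.2 um, background = 8412, R^2 = 1.0000
attenuation_ratio(prof)      # 5.9 -> cold-knife regime (< 7)

led <- generate_ledger(trial_gen_spec(), mode = "expected")
summarize_groups(led)[c(5, 9, 10), c("group_id", "resection", "treatment",
                                     "n_evaluable", "n_recurrent",
                                     "rate_percent_reported")]
#>   group_id     resection treatment n_evaluable n_recurrent rate_percent_reported
#> 5        5 laser_scalpel      none          11           0                     0
#> 9        9    cold_knife   pdt_405          10           7                    70
#> 10      10    cold_knife      none          12          11                    92

exposure_time(irradiation_plan(150, 260))   # 660-nm session: 576.9 s
```

The specular value 0.02778 is the analytic normal-incidence Fresnel
reflectance for n = 1.4 tissue under air; the energy budget always sums to
1 exactly. The decay fit recovers the generator's ground truth
(δ = 330 µm); the recurrence table shows zero recurrence after
laser-scalpel-only surgery versus 92% after cold-knife-only surgery, cut to
70% by 405-nm PDT.

A full pipeline run (simulation → fluorescence → statistics → dose model,
with plots and a checksum manifest):

```r
run_pipeline(pipeline_config(rng_seed = 1, out_dir = "run1"))
```

or from the shell via the CLI launcher in `inst/cli/`:

```sh
pdt-bedkit simulate --tissue tumor --wavelength 405 --photons 1e6 --seed 17 --out profile.csv
pdt-bedkit synth ledger --mode expected --out ledger.csv
pdt-bedkit trial-stats --ledger ledger.csv --out report/
pdt-bedkit run --seed 1
```

## Vignette

`vignettes/pdt-bed-dosimetry.Rmd` documents the model assumptions,
parameter choices, what the synthetic generators do and do not emulate, and
known limitations.
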