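# paquant

Quantification of cell-delivered gold-nanorod (AuNR) accumulation in
tumors from multispectral photoacoustic (PA) imaging.

Endothelial colony-forming cells (ECFCs) loaded with gold nanorods are a
tumor-tropic contrast agent: the nanorods' longitudinal plasmon mode,
red-shifted to ≈900 nm by intracellular aggregation, gives them a strong
near-infrared PA fingerprint that can be separated from the endogenous
absorbers (oxygenated and deoxygenated hemoglobin, melanin). `paquant`
implements the full quantification chain for longitudinal studies of
this kind, for imaging scientists who want a transparent, scriptable
alternative to vendor unmixing tools:

- **Spectral unmixing.** Each voxel's multiwavelength signal
  `s ∈ R^W` is decomposed against a dictionary of unit-max reference
  spectra `R ∈ R^{W×C}` by non-negative least squares,
  `min_{a ≥ 0} ‖s − R a‖₂`, with the residual norm kept per voxel.
  Dictionaries can be built from parametric shape models or extracted
  from labeled regions of an acquisition.
- **ROI statistics.** Tumor masses are summarized with the *PA average
  threshold* — the mean of the top 10% of values inside the ROI — applied
  to the voxel-wise sum of the selected component abundances (typically
  AuNR-laden cells plus oxygenated hemoglobin), with optional
  normalization of each tumor's series to its own day-0 baseline.
- **Bayesian longitudinal model.** Per-tumor values `y` in group
  `g ∈ {treated, control}` at time `t ∈ {T0, T1, T2}` are modeled as
  `y ~ Normal(μ_{g,t}, σ_g)` with weakly informative priors
  `μ ~ Normal(0, 100)` and `σ ~ HalfNormal(50)`, the variance shared
  across time points within each group. The quantities of interest are
  the within-group change `Δ_t = μ_t − μ_0` (t = 1, 2) and the treatment
  effect `Effect_t = Δ_t^treated − Δ_t^control`, summarized by posterior
  means, equal-tailed intervals, 95% highest-density intervals (HDI) and
  P(Effect > 0). Sampling is by an in-package Metropolis-within-Gibbs
  sampler (exact conjugate draws for each μ, adaptive random-walk
  Metropolis on log σ), with rank-normalized split-R̂ and bulk effective
  sample size diagnostics.
- **Synthetic ground truth.** A phantom generator produces multispectral
  volumes from known component geometries (six in vivo wavelengths 680,
  730, 800, 924, 930, 968 nm; 203 µm slice spacing) and a cohort
  generator produces longitudinal measurement tables (8 treated + 2
  control tumors at days 0/1/3 by default), so every stage can be
  validated against known truth.

## Worked example

```r
library(paquant)

# dictionary at the six in vivo wavelengths
refs <- make_reference_spectra(wavelengths_in_vivo(),
                               default_spectrum_configs())

# phantom with a nanorod-cell sphere in a hemoglobin background
sim <- simulate_phantom_volume(refs, phantom_config(
  grid = c(8, 16, 16), noise_sd = 0.02, seed = 42,
  geometry = list(
    list(component = "aunr_cell", level = 1,
         region = region_sphere(c(4, 8, 8), 4)),
    list(component = "hbo2", level = 0.6,
         region = region_box(c(1, 8), c(1, 16), c(1, 8))))))
maps <- unmix_volume(sim$volume, refs)

roi <- array(1L, dim = c(8, 16, 16))
cumulative_component_signal(maps, roi, 1, c("aunr_cell", "hbo2"))
#> [1] 1.444837

# longitudinal cohort and treatment-effect model
cohort <- simulate_cohort(cohort_config(seed = 42))
fit <- sample_posterior(cohort, model_spec(),
                        sampler_config(chains = 4, tune = 1000,
                                       draws = 2000, seed = 1))
delta_and_effect(fit)
#> <effect_estimate> 95% intervals (equal-tailed and HDI)
#>        functional   mean  et_lower et_upper hdi_lower hdi_upper  p_gt0
#> 1 delta_treated_1  2.764  -0.07625    5.591   -0.1574     5.501 0.9716
#> 2 delta_control_1 -0.660 -15.64301   14.648  -14.1065    15.731 0.4427
#> 3        effect_1  3.424 -12.03679   18.778  -13.1046    17.108 0.7506
#> 4 delta_treated_2  5.032   2.21024    7.791    2.1669     7.724 0.9994
#> 5 delta_control_2 -2.030 -17.24081   13.381  -17.7800    12.543 0.3124
#> 6        effect_2  7.062  -8.56230   22.459   -8.3113    22.638 0.8928
```

The cumulative signal (1.44 a.u.) is the top-decile mean of the summed
AuNR-cell and HbO₂ abundances over the whole phantom, in the intensity
units of the acquisition. In the model output, `delta_treated_2` is the
posterior change of the treated group's mean signal from day 0 to day 3
(here the generator's truth is 31 − 27 = 4, inside the interval), and
`effect_2` is the treated-minus-control difference of those changes;
`p_gt0` is the posterior probability that the functional is positive.
Convergence for this fit: maximum split-R̂ 1.0043 over all eight
parameters, minimum bulk ESS 7458 across the six means.

A staged pipeline (`run_pipeline()`, YAML-configurable, see
`inst/extdata/config-desk.yaml`) and a thin command-line front end
(`inst/cli/paquant.R`, subcommands `simulate-phantom`, `simulate-cohort`,
`unmix`, `roi-stats`, `normalize`, `fit`, `report`) wrap the same
functions and write TIFF/CSV/JSON artifacts with run manifests.

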