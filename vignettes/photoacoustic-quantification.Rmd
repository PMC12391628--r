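---
title: "Quantifying nanorod-laden cell accumulation from multispectral photoacoustic volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nanorod-laden cell accumulation from multispectral photoacoustic volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paquant)
```

## The problem

Gold nanorods (AuNRs) carried into tumors by endothelial colony-forming
cells (ECFCs) act as a near-infrared photoacoustic contrast agent. Their
longitudinal plasmon resonance, red-shifted to roughly 900 nm by
endosomal aggregation, sits apart from the spectra of the endogenous
absorbers — oxygenated hemoglobin (rising into the NIR), deoxygenated
hemoglobin (broad peak near 756 nm) and melanin (monotonically
decaying). A multiwavelength acquisition therefore carries enough
information to separate the nanorod-cell contribution from the
physiological background, and a longitudinal series of such
acquisitions carries enough to ask whether the nanorod signal in
treated tumors rises over days while controls stay flat.

`paquant` implements that chain: per-voxel spectral unmixing, a
top-decile region-of-interest (ROI) summary per tumor, and a Bayesian
hierarchical model of the longitudinal group trajectories. Because raw
preclinical acquisitions of this kind are rarely public, the package
also includes a first-class synthetic generator for both the imaging
and the cohort arm, with known ground truth, which is what the test
suite exercises end to end.

## Spectral unmixing

A voxel's measurement at wavelengths $\lambda_1 < \dots < \lambda_W$ is
modeled as a non-negative linear mixture

$$ s(\lambda_w) = \sum_{c=1}^{C} a_c \, S_c(\lambda_w) + \varepsilon_w,
   \qquad a_c \ge 0, $$

where $S_c$ are reference spectra, unit-max normalized so that the
abundances $a_c$ carry the acquisition's intensity units. `unmix_voxel`
solves $\min_{a \ge 0} \lVert s - R a\rVert_2$ per voxel by
non-negative least squares (Lawson–Hanson active set, via
`pracma::lsqnonneg`; the residual norm is recomputed directly from the
solution). Noise is handled as an ordinary flat-spectrum dictionary
column rather than a special case, mirroring how air-bubble reference
regions are used in practice. There is no spatial regularization:
voxels are independent, so results are traversal-order invariant and
trivially parallelizable.

Key properties the suite verifies: exact recovery of dictionary atoms
and noiseless mixtures (mean absolute error below $10^{-6}$ on a
$16\times32\times32$ phantom with five components at six wavelengths),
agreement with an exhaustive grid-search oracle on random two-component
problems (within $2\times10^{-3}$ per component), scale equivariance,
and permutation covariance. With six wavelengths and five components
the system is overdetermined but close to square; strongly collinear
dictionaries (e.g. two nearly parallel spectra) make individual
abundances ill-determined even though the fit itself is stable — that
is a property of the physics, not of the solver, and is why the
nanorod-cell peak being spectrally distinct matters.

Reference spectra can also be extracted from labeled acquisitions
(`extract_reference_spectrum`): the plain per-wavelength mean over the
labeled voxels, unit-max normalized. The mean (not the top-decile
statistic) is deliberate: the top-10% rule is a tumor-signal summary,
not a spectrum estimator. `relative_spectral_difference` implements the
normalize-then-relative-difference convention
$(a_\mathrm{norm}-b_\mathrm{norm})/b_\mathrm{norm}$; the exact formula
used for such figure panels is not always printed, so
the convention is stated here explicitly and tested for its two
defining properties (zero at equality, invariance to global scale).

## ROI statistics

The per-tumor summary is the *PA average threshold*: the mean of the
top fraction (default 10%) of values in the ROI, with
$k = \lceil fN \rceil$ so that any non-empty ROI yields at least one
value. Ties at the cutoff rank are interchangeable, so the statistic is
order-independent. With $f = 1$ it reduces to the plain mean, and it is
monotone in every input — both properties are tested.

"Cumulative" signal over several components (typically
`aunr_cell + hbo2`, since those two spectra overlap most) is computed
by summing abundances voxel-wise *before* ranking, keeping the
statistic a single functional of the ROI; the alternative
(top-decile per component, then sum) is available via
`combine = "top-then-sum"` because the usual verbal description does not
disambiguate the two. Baseline normalization divides each tumor's
series by its own day-0 value (T0 rows become exactly 1); it feeds
descriptive fold-change plots only — the model consumes raw values,
since its baseline parameter $\mu_0$ already plays that role.

## The hierarchical longitudinal model

For group $g \in \{\text{treated}, \text{control}\}$ and time point
$t \in \{T0, T1, T2\}$ (days 0, 1, 3), per-tumor values are

$$ y_{i,g,t} \sim \mathcal N(\mu_{g,t}, \sigma_g), \qquad
   \mu_{g,t} \sim \mathcal N(0, 100), \qquad
   \sigma_g \sim \text{HalfNormal}(50), $$

with the variance shared across time points within a group. The
functionals of interest are
$\Delta_t = \mu_t - \mu_0$ for $t = 1, 2$ and
$\mathrm{Effect}_t = \Delta_t^{\text{treated}} -
\Delta_t^{\text{control}}$, computed per draw (the identities are
linear, hence exact per draw, not Monte-Carlo approximations).

Two readings of "shared variance" are defensible: one $\sigma$ per
group (shared over its time points) or a single pooled $\sigma$. The
default is per-group — the description sits inside a per-group model
paragraph, and treated and control tumors have no reason to share a
noise scale — but `model_spec(sigma_sharing = "pooled")` provides the
other reading. `Normal(0, 100)` is read as location 0, scale (standard
deviation) 100, the conventional weakly informative parameterization at
this signal scale.

### Sampler

`sample_posterior` uses Metropolis-within-Gibbs:

- each $\mu_{g,t}$ is drawn exactly from its Normal full conditional
  (conjugate given $\sigma_g$) — empty cells fall back to the prior;
- each $\log \sigma_g$ takes an adaptive random-walk Metropolis step
  (Jacobian included), the proposal scale adapted toward 0.4 acceptance
  by a Robbins–Monro schedule ($\gamma_i = i^{-0.6}$) during tuning and
  frozen afterwards.

Default budget: 1000 tuning iterations and 2000
kept draws per chain. Four chains are run (a chain count is rarely
printed; four is the field's default and the minimum for comfortable
split diagnostics), with per-chain seeds derived deterministically from
the master seed, so runs are exactly reproducible. Because the $\mu$
updates are exact conditional draws, their autocorrelation is near
zero and the bulk ESS of the six means lands near the total draw count
— this is what makes effective sample sizes above 2000 achievable at an
8000-draw budget, and it is what `scripts/acceptance.R` measures.
$\sigma$ mixes more slowly (random walk), which is acceptable since no
headline quantity is a $\sigma$ functional.

Initialization: $\mu$ at the prior mean, $\sigma$ at half the prior
scale; with conjugate $\mu$ draws the first Gibbs sweep already lands
in the data-supported region, so no burn-in beyond the tuning phase is
needed.

### Summaries and diagnostics

`summarize_posterior` reports the posterior mean, the equal-tailed
interval (empirical quantiles), the highest-density interval (shortest
contiguous window containing $\lceil 0.95\,n\rceil$ sorted draws), and
$P(>0)$. Both interval types are always reported because usage in the
literature mixes "credible interval" and "HDI" language; the HDI is the
headline for skewed effect posteriors. For unimodal samples the sorted
window HDI is standard; for multimodal posteriors a contiguous interval
over-covers (a known limitation, acceptable for this model's unimodal
conditionals).

`rhat_and_ess` implements rank-normalized split-$\widehat R$ (the
maximum of the rank-normalized and folded variants) and
autocorrelation-based bulk ESS with Geyer's initial monotone positive
sequence truncation, on split chains. The implementation was verified
against an independent reference implementation on fixed chains
(frozen values in the test suite agree to $10^{-6}$). Zero-variance
chains report $\widehat R = 1$ by convention and ESS `NA`, with a
degenerate flag. Pass gates default to $\widehat R \le 1.01$ and
ESS $\ge 400$.

## The synthetic generators

The phantom generator (`simulate_phantom_volume`) emulates the
acquisition geometry: six wavelengths (680, 730, 800, 924, 930,
968 nm), 203 µm slice spacing (in-plane spacing defaults to 75 µm, a
typical high-frequency PA in-plane resolution; it is configurable since
no printed value exists), component geometries as boxes and spheres
whose overlaps add (matching the linear forward model), additive
Gaussian noise, and clipping of negative post-noise intensities to zero
(PA amplitudes are non-negative). The spectral shapes are parametric
stand-ins — vendor tools ship tabulated chromophore spectra, but only
the shapes' qualitative separability matters for validating the
pipeline: hbo2 rises monotonically (geometric interpolation of two
anchors), hb is a broad 756 nm Lorentzian (120 nm FWHM), melanin decays
monotonically, aunr_cell is a Lorentzian at 900 nm (60 nm FWHM; on the
in vivo grid its maximum falls at 924 nm, the grid point nearest the
peak), and noise is flat. All shapes accept tabulated anchors for users
who want measured spectra.

The cohort generator (`simulate_cohort`) draws per-tumor values from
the exact data-generating process the model assumes: 8 treated and 2
control tumors at days 0/1/3, Normal within-group noise. Default means
are representative group trajectories (treated 0.27 → 0.31 a.u.,
control 0.18 → 0.17 a.u.) rescaled by 100 — descriptive group means in such
experiments are of order 0.3 a.u. while model-scale changes are of order
tens of "units", and the rescaling between the two scales is never
stated, so the generator adopts ×100 once (treated (27, 29, 31),
control (18, 17.5, 17); the control mid-point is
interpolated) and keeps the scale configurable. Within-group sd
defaults to 2, consistent with day-0 treated values being described as
narrowly distributed while later time points spread.

What the generators deliberately do **not** emulate: acoustic wave
propagation, wavelength-dependent fluence, depth-dependent attenuation,
reconstruction artifacts, motion, or tumor segmentation. Passing tests
therefore demonstrate that the *analysis* chain is correct under its
own model assumptions — not that the forward physics of a real
acquisition is captured. On real data, fluence coloration alone can
bias abundances; that correction is explicitly out of scope.

## Validation design and problem sizes

The suite validates each stage against an independent oracle: a
brute-force voxel loop for ROI spectrum extraction, an exhaustive
two-stage grid search for NNLS (coarse 0.01 sweep, then 0.001
refinement around the optimum — equivalent to a full 0.001 grid),
a sort-based rule for the top-decile statistic, the closed-form
Normal–Normal conjugate update for the sampler (with $\sigma$ fixed),
prior recovery on empty data, and frozen reference values for the
convergence diagnostics. Random two-component unmixing problems are
drawn from the spectral shape families themselves (a random-peak
Lorentzian against a random monotone ramp), i.e. the kind of distinct
chromophore pair a dictionary is built from, rather than arbitrary
near-collinear vectors for which per-component abundances are
physically unidentifiable.

Simulation-based calibration runs 200 synthetic cohorts with truths
drawn from the prior restricted to a realistic range
($|\mu| \le 100$, $\sigma \in [0.5, 20]$ — the unrestricted
HalfNormal(50) occasionally produces noise scales far above any
plausible signal, which would make the check uninformative) and asserts
that the 95% HDI for the treated T2 change covers its truth between 90%
and 99% of the time (the binomial band at 200 replicates). Per
replicate the sampler runs 2 chains × (300 tuning + 500 kept) draws —
HDI endpoints at that budget move by far less than the interval width,
so coverage is insensitive to it. Phantom validations use
$16\times32\times32$ grids (acceptance) and $4\times8\times8$ grids
(unit tests); end-to-end pipeline determinism is checked on the
default desk-scale configuration.

## Known limitations

- No fluence or depth correction; abundances are relative to local
  light delivery.
- The unmixing is per-voxel; no spatial prior, no partial-volume model.
- The HDI assumes a unimodal sample.
- The Gaussian likelihood has no per-tumor random effect: repeated
  measures of the same tumor are treated as exchangeable within the
  group-time cell; with 8 + 2
  tumors a richer hierarchy is hard to identify.
- The treatment-effect functional follows its definition
  ($\mathrm{Effect}_t = \Delta_t^{\text{treated}} -
  \Delta_t^{\text{control}}$) literally and exactly per draw;
  headline estimates stated elsewhere that are internally inconsistent with
  that identity cannot (and should not) be matched term by term.
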