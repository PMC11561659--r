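---
title: "Soma and neurite density imaging: model, estimation, and a synthetic lifespan study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soma and neurite density imaging: model, estimation, and a synthetic lifespan study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

SANDI (Soma And Neurite Density Imaging) describes the direction-averaged
(spherical-mean, "powder-averaged") diffusion MRI signal of gray matter as a
sum of three non-exchanging compartments:

$$
\frac{\tilde S(b)}{S_0} \;=\;
  f_{in}\,\tilde A_{in}(b D_{in}) \;+\;
  f_{is}\,\tilde A_{is}(b;\, r_s, D_{is}) \;+\;
  f_{ec}\,e^{-b D_{ec}},
\qquad f_{in} + f_{is} + f_{ec} = 1 .
$$

* **Neurites** are impermeable zero-radius sticks with parallel diffusivity
  $D_{in}$ and no perpendicular diffusivity. Averaged over uniformly
  dispersed orientations the stick signal has the closed form
  $\tilde A_{in}(x) = \sqrt{\pi/(4x)}\,\mathrm{erf}(\sqrt{x})$, $x = bD_{in}$
  (`stick_spherical_mean()`; a 3-term Taylor series replaces the expression
  below $x = 10^{-6}$ to avoid 0/0).
* **Somas** (cell bodies) are impermeable spheres of apparent radius $r_s$
  with intrinsic diffusivity $D_{is}$, fixed at 3 um^2/ms. The PGSE signal
  uses the Gaussian-phase-distribution (GPD, Murday–Cotts) series
  (`sphere_gpd_signal()`), with eigenvalues $\alpha_m = \mu_m/r_s$ from the
  roots of $j_1'(x) = 0$ (`bessel_alpha_roots()`; first roots 2.0816,
  5.9404, 9.2058).
* **Extracellular water** is an isotropic Gaussian pool with apparent
  diffusivity $D_{ec}$ (`ball_signal()`).

The signal fractions are T2-weighted; they are apparent fractions at the
acquisition's echo time, not volume fractions, and they are linearly
dependent through the unit-sum constraint.

The acquisition is the 8-shell strong-gradient protocol:
$b \in \{0.05, 0.35, 0.8, 1.5, 2.4, 3.45, 4.75, 6\}$ ms/um^2,
$\delta = 8$ ms, $\Delta = 19$ ms, 32 directions per shell below
2.3 ms/um^2 and 64 above, with interspersed $b = 0$ volumes
(`connectome_protocol()`). Internally all b-values are ms/um^2; FSL-style
files in s/mm^2 are converted on read (values above 50 are taken to be
s/mm^2). The implied maximum gradient is `b_to_gradient(6, 8, 19)` ~ 283
mT/m, inside a 300 mT/m system limit.

## Numerical choices in the forward model

The GPD series is truncated at 30 roots (configurable through
`gpd_config()`); terms decay fast at these timings and a convergence guard
rejects pathological inputs. Roots are cached after the first evaluation.

Two properties of the GPD sphere matter for everything downstream:

1. **Validation.** The GPD is an approximation. The package ships an exact
   Monte-Carlo oracle (`mc_sphere_signal()`): walkers seeded uniformly in a
   reflecting sphere accrue PGSE phase, and the signal is
   $\langle\cos\phi\rangle$. Because the GPD *is* the assumption that
   $\phi$ is Gaussian, the identity
   $-\log \tilde A_{is} = \tfrac12\mathrm{Var}(\phi)$ is the correct
   equivalence check between the two implementations, and it holds to
   within Monte-Carlo error everywhere we test. The signals themselves
   agree closely at mild attenuation but diverge at strong restriction
   combined with strong weighting (for example $r_s = 8$ um at
   $b = 6$ ms/um^2), where the true phase distribution is heavy-tailed and
   the GPD overestimates the signal. This is a property of the model the
   field uses, not an implementation artefact; the test suite asserts the
   phase-variance identity and reports the signal-domain deviation.

2. **Identifiability.** At fixed $\delta, \Delta$ the GPD exponent is
   exactly proportional to $b$: the soma compartment is mathematically an
   isotropic Gaussian pool with an effective diffusivity
   $D_{\mathrm{eff}}(r_s)$ (about 0.11, 0.46 and 0.93 um^2/ms at
   $r_s = 5, 8, 11$ um for these timings). The spherical-mean SANDI signal
   is therefore a stick plus a bi-exponential, and the pairs
   $(f_{is}, r_s)$ vs $(f_{ec}, D_{ec})$ are distinguished only by
   decay-rate separation. When $D_{\mathrm{eff}}(r_s) \approx D_{ec}$ the
   voxel-level problem is close to non-identifiable even without noise.
   This drives the estimator behaviour discussed below.

## Estimation

Following standard SANDI practice the inverse problem is solved by
regression learned on simulations: `build_training_set()` draws the five
free parameters uniformly within the priors ($D_{ec}, D_{in} \in [0.25,3]$
um^2/ms, $r_s \in [1,12]$ um, $f_{in}, f_{is} \in [0,1]$ subject to
$f_{in}+f_{is}\le 1$ by rejection), simulates shell means, and adds Rician
noise; `train_regressor()` fits one random regression forest per parameter
(200 trees by default, other tree parameters at the `ranger` defaults and
recorded in the model object). Predictions are structurally confined to
the prior box because a forest averages training labels;
$f_{ec} = 1 - f_{is} - f_{in}$ is derived, clipped to $[0,1]$ and flagged
when clipping occurs. Each model stores a protocol fingerprint (shell
b-values and timings) and refuses data that does not match.

Two honest caveats, quantified by the acceptance suite:

* Over the full priors the forest's voxel-level accuracy is limited by the
  bi-exponential degeneracy above, not by the regressor: a nearest-
  neighbour lookup in a noise-free training set of 2 x 10^4 signals finds
  neighbours within ~3 x 10^-3 per shell yet still misestimates $f_{is}$
  with RMSE ~0.12 inside the lifespan-relevant parameter box. Larger
  training sets and different tree settings move this only marginally.
* Consequently, region-level statistics in a study operate on *estimated*
  metrics whose mapping from true tissue parameters is biased and mixes
  neighbouring parameters (cross-talk). ROI averaging over many voxels
  removes estimation noise but not cross-talk.

`run_noise_propagation()` reproduces the standard noise-propagation design:
1000 parameter draws from narrower ranges ($D_{ec} \in [0.5,1.5]$,
$D_{in} \in [1,2]$ um^2/ms, $r_s \in [5,11]$ um, $f_{in}, f_{is} \in
[0.1,0.5]$), Rician noise at SNR $10^{10}$ and 50, paired draws across SNR
levels, and per-parameter bias/RMSE/correlation. The regressor is trained
at the matching noise level by default (configurable), since the study
design leaves this open. The defaults use 2 x 10^4 training signals and 50
trees per forest so the experiment runs in well under a minute; these are
configuration values, and the 10^5/200 convention can be requested.

## Noise model

Magnitude MRI noise is Rician: $S_n = \sqrt{(S+N_r)^2 + N_i^2}$ with
$N_r, N_i \sim N(0, \sigma^2)$ and $\sigma = 1/\mathrm{SNR}$ on
b0-normalised signals (`add_rician_noise()`; `sigma` may be per-shell).
The noise level is estimated from $b=0$ replicates as the median voxelwise
coefficient of variation (`estimate_noise_level()`); this replaces
MP-PCA-based noise mapping, which is an upstream preprocessing concern —
the only quantity the pipeline consumes is $\sigma$. The "noise-free" SNR
level is represented as $10^{10}$, not 0.

## DTI and DKI

`fit_dti()` uses only the $b = 0$ and $0.8$ ms/um^2 shells; `fit_dki()`
uses $b \le 3.45$ ms/um^2. The 0.05 ms/um^2 shell is excluded by default
(configurable): it is a diffusion-weighted shell, not a $b = 0$ image.
Both use two-pass weighted linear least squares on the log signal (weights
= squared predicted signals from an OLS pass). The kurtosis fit is
parameterised in $V(\mathbf n) = \overline D^2 W(\mathbf n)$, which keeps
the model linear and makes the fit exactly self-inverse on
cumulant-generated signals. AK/RK are evaluated along/perpendicular to the
principal eigenvector (the radial average over 64 angles); MK is a
numerical mean over 256 quasi-uniform directions, validated against exact
self-recovery. Out-of-range kurtosis values are reported, never clamped;
voxels with non-positive signals are flagged invalid.

## Regions and volumes

Two deliberately different conventions, mirrored from how partial-volume
masks are used in practice:

* **Metric means** (`aggregate_region_metric()`): unweighted mean over
  voxels with partial-volume weight strictly greater than 0.5 (and a valid
  fit); a weighted variant is available but not the default.
* **Normalised volume** (`compute_normalized_volume()`): the sum of *all*
  weights times the voxel volume, divided by total intracranial volume. No
  threshold.

## Cohort statistics

`build_results_table()` computes, per metric x region x target (age or
normalised volume), the partial Pearson correlation controlling for sex
(F/M coded 0/1; any consistent binary coding yields the same r, which is
tested) and optionally a free-water fraction covariate, with
Benjamini–Hochberg FDR applied within each target's table — the FDR family
is one results table, matching per-table reporting practice; the family
choice is recorded in the output structure. Group comparisons
(`compare_groups_ancova()`) test the three lifespan groups (young <= 34,
middle 35–54, older >= 55 years) by an F-test of group dummies plus sex
against sex alone, with Student (equal-variance) post hoc t tests —
"unpaired t test" unqualified — and FDR over the three pairs; Welch is an
option. `fisher_z_compare()` uses the independent-samples r-to-z formula
on |r| by default because that is the stated procedure, even though
correlations sharing the age variable are dependent; a dependent-correlation
variant is provided. `ks_normality()` is the plain Kolmogorov–Smirnov test
with estimated mean and SD, without the Lilliefors correction, and says so
in its output. `polynomial_age_fit()` reports linear and quadratic OLS
fits, their $R^2$, and the vertex age $-\beta_1/(2\beta_2)$ only when the
quadratic is concave and the vertex lies inside the observed age range.

## The synthetic cohort

No scanner data are redistributable, so `cohort_config()` +
`run_end_to_end()` generate a complete synthetic study: 33/21/18 subjects
in the young/middle/older groups with truncated-normal ages
(25.5 ± 3.6 in 19–34, 44.3 ± 6.6 in 35–54, 67.1 ± 7.7 in 55–85) and
18/13/9 females; per-region linear metric trajectories specified by their
values at ages 19 and 85 plus a target age correlation, with the residual
SD solved so the expected correlation matches the target given the
realised ages; Rician noise at SNR 50 applied to each directional
replicate *before* shell averaging (reproducing the small Rician floor of
in vivo spherical means); and a configurable number of voxels per
subject-region (default 32) whose fitted parameters are averaged,
emulating an ROI mean. A master seed drives independent substreams per
stage, so parameter draws are identical across noise levels and the whole
study is reproducible.

The default trajectories (for example $f_{is}$ from 0.28 at age 19 to 0.18
at age 85 with target $r = -0.75$; declining $r_s$ and $D_{in}$; rising
$f_{in}$, $f_{ec}$, $D_{ec}$; normalised volume declining with target
$r = -0.74$) are *fixtures*: values chosen inside the fitting priors with
the lifespan sign pattern, not measured tissue values, since no regional
ground truth is publicly available. A zero-slope `null_metric` column is
included for type-I-error checks.

What passing tests show — and what they do not: the generator plants
correlations in *true* parameters, and the pipeline recovers them only as
well as the estimator allows. With all six metrics co-trending, the
cross-talk described above attenuates the recovered $f_{is}$–age
correlation well below the planted value and can flip the sign of the
weaker recovered effects ($f_{ec}$, $D_{in}$); an oracle nonlinear
least-squares fit on nearly noise-free subject-average signals shows the
same behaviour, so this is information-theoretic, not a software defect.
The acceptance suite asserts the stated recovery targets anyway and
documents the measured shortfall; the type-I control of the null metric
and the strong planted effects' significance do hold. Real cortical
aging data may well present larger raw contrasts, different covariance
between tissue changes, and estimator-consistent *estimated* trends — an
in vivo correlation of estimated $f_{is}$ with age is a statement about
the estimator's output, which is exactly what the in vivo pipeline
measures.

Problem sizes used by the shipped tests (package choices): forests of
50–100 trees on 2–3 x 10^4 training signals, 1000 noise-propagation draws,
Monte-Carlo oracles at 10^5 walkers x 10^3 steps, and 20 cohort seeds for
coverage-style checks; 200 seeds for the cheap statistics-only
simulations.

## Known limitations

* No water exchange between compartments; no orientation-dispersion model
  beyond full dispersion; no compartmental T2 (fractions are T2-weighted).
* The GPD sphere model deviates from exact restricted-diffusion physics at
  strong attenuation (above), and its fixed-timing b-exponential form
  bounds voxel-wise identifiability.
* Preprocessing (distortion/eddy/motion correction, denoising,
  segmentation, registration) is upstream and out of scope; region masks
  are consumed in the metric-map grid.
* Non-central chi noise of multi-coil magnitude reconstruction is not
  modelled; the noise model is single-coil Rician.
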