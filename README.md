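# sandir

Soma And Neurite Density Imaging (SANDI) in R: forward simulation and
machine-learned inversion of the three-compartment gray-matter diffusion
MRI model, with the full analysis pipeline around it — Rician noise
modelling and noise-propagation experiments, DTI/DKI scalar metrics from
shell subsets, partial-volume ROI aggregation, the cohort statistics used
in lifespan microstructure studies, and a synthetic 72-subject cohort
generator so that every stage runs and is testable without scanner data.

It is written for researchers who analyse multi-shell diffusion MRI of
cortical gray matter and want a transparent, testable implementation of
the SANDI pipeline rather than a black box.

## The model

The direction-averaged (spherical-mean) signal at shell $b$, normalised by
the $b=0$ signal, is

$$\tilde S(b)/S_0 = f_{in}\,\tilde A_{in}(bD_{in})
 + f_{is}\,\tilde A_{is}(b;\,r_s, D_{is})
 + f_{ec}\,e^{-bD_{ec}},\qquad f_{in}+f_{is}+f_{ec}=1,$$

with sticks (neurites, powder-averaged:
$\tilde A_{in}(x)=\sqrt{\pi/4x}\,\mathrm{erf}\sqrt{x}$), impermeable
spheres of apparent radius $r_s$ (somas, Gaussian-phase-distribution /
Murday–Cotts series; $D_{is}$ fixed at 3 um²/ms), and an isotropic
Gaussian extracellular pool. Inversion follows the standard SANDI recipe:
a random-forest regressor trained on simulated signals drawn uniformly
from the priors, one forest per parameter, applied voxel-wise to the eight
b0-normalised shell means of the strong-gradient protocol
(b = 0.05…6 ms/um², δ = 8 ms, Δ = 19 ms). An exact Monte-Carlo
random-walk oracle for the restricted sphere ships with the package and
backs the test suite.

## A worked example

```r
library(sandir)

# the 8-shell acquisition and a cortical-like voxel
protocol <- connectome_protocol()
shells   <- group_shells(protocol)
voxel    <- sandi_params(f_in = 0.3, f_is = 0.3, r_s = 8, D_in = 2, D_ec = 1)
round(sandi_signal(voxel, shells = shells)$values, 4)
#>        [,1]   [,2]   [,3]   [,4]   [,5]   [,6]   [,7]   [,8]
#> [1,] 0.9639 0.7795 0.5815 0.3903 0.2561 0.1745 0.1229 0.0963
```

The eight numbers are the noise-free powder-averaged signals at
b = 0.05 … 6 ms/um²: the decay below 1 at the weakest shell reflects the
extracellular and neurite water, while the substantial signal remaining at
b = 6 is the hallmark of restricted (soma) water.

```r
# pooled demographics of the three lifespan groups
pooled_moments(n = c(33, 21, 18), mean = c(25.5, 44.3, 67.1),
               sd = c(3.6, 6.6, 7.7))
#> # A tibble: 1 x 3
#>       n  mean    sd
#>   <dbl> <dbl> <dbl>
#> 1    72  41.4  17.9

# is the soma-fraction-age correlation stronger than the volume-age one?
fisher_z_compare(r1 = -0.69, n1 = 72, r2 = -0.31, n2 = 72)
#> # A tibble: 1 x 2
#>       z       p
#>   <dbl>   <dbl>
#> 1  3.10 0.00194
```

A z of 3.10 (p ≈ 0.002) says the first correlation (soma signal fraction
vs age, r = −0.69) is significantly stronger in magnitude than the second
(cortical volume vs age, r = −0.31) at n = 72.

A complete synthetic study — demographics, age-dependent ground truth,
noisy signals, random-forest fitting, ROI means, correlation tables, group
ANCOVA and age-trend fits — runs with:

```r
study <- run_end_to_end(cohort_config(seed = 1))
study$recovery        # planted vs realised vs recovered age correlations
tidy(study)           # the metric x region x target correlation table
autoplot(study$results_table)
```

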