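# dsefficiency

Statistical efficiency of conventional distance sampling (CDS) on line
transects.

Distance sampling estimates the abundance *N* of animals (or plants, or any
objects) in a region from detections made along transect lines, allowing
for imperfect detection: the probability of detecting an object at
perpendicular distance *d* is modelled as a detection function *g*(*d*; θ)
with *g*(0) = 1, non-increasing in *d*, and zero beyond a truncation
distance *w*. The usual CDS estimator scales the *n* detections by the
coverage proportion *P* and the estimated mean detection probability
ḡ(θ̂) = *w*⁻¹∫₀ʷ *g*(*u*; θ̂) d*u*:

    N̂_CDS = n / (P ḡ(θ̂_CML)),

with θ̂ fitted by conditional maximum likelihood from the observed
distances. Having to *estimate* θ carries a hidden variance cost. This
package computes that cost exactly, in the form of the asymptotic penalty
factor

    F = 1 + h̄ᵀ Δ⁻¹ h̄ / (ḡ² (1 − P ḡ)) ≥ 1,

where h̄ is the mean of the parameter gradient *h* = ∂*g*/∂θ over [0, *w*]
and Δ = var(*h*(*D*)/*g*(*D*)) for a distance *D* drawn from the
detection-conditional density. The asymptotic variance of N̂_CDS is then
*F* times the variance of the idealized estimator that knows θ, namely
*N* *P*⁻¹ ḡ⁻¹ (1 − *P* ḡ), and the survey sample size needed for a target
coefficient of variation is E[*n*] = (1/*N* + CV²/*F*)⁻¹ (≈ *F*/CV² for
*n* ≪ *N*).

For survey designers and simulation studies the package provides:

* half-normal and hazard-rate detection families with analytic gradients,
  scale calibration to a target ḡ, and an extensible family interface;
* conditional-ML fitting (`fit_cml()`, a classed model object with
  `print`/`summary`/`coef`/`predict`/`plot`/`vcov`/`simulate` methods);
* Fisher-information and inverse-variance blocks, the penalty *F*, CV and
  sample-size calculators, and full penalty tables over grids of *P*, ḡ
  and shape;
* a replicate simulation harness comparing CDS, known-θ and strip-transect
  estimators under a Dirichlet-process overdispersed location model, with
  per-replicate reproducible seeding, empirical penalty ratios, RRMSE
  curves, MSE-optimal strip widths and strip-vs-CDS crossing ranges;
* a command line (`inst/cli/dsefficiency`) with `penalty`, `table`,
  `samplesize`, `simulate` and `fit` subcommands.

## Worked example

Simulate a survey with 20,000 objects uniformly placed up to 10 distance
units from the line, detect with a narrow-shoulder hazard-rate function
(θ = (0.448, 2), truncation *w* = 1, so coverage *P* = 0.1), and fit:

```r
library(dsefficiency)
set.seed(4)
pop <- draw_uniform_distances(20000, 10)$distances
d   <- thin_by_detection(pop, "hazard_rate", c(0.448, 2), w = 1)
fit <- fit_cml(d, "hazard_rate", P = 0.1)
fit
#> Conditional ML fit of a hazard_rate detection function
#>   n = 1262  w = 1
#>   theta_hat = ( 0.4655, 2.064 )
#>   gbar(theta_hat) = 0.6134  loglik = 163.938
#>   CDS abundance estimate (P = 0.1 ): 20572.5
```

The fit recovers the generating parameters and the abundance (truth
20,000) within sampling error. The asymptotic efficiency of that estimate:

```r
asymptotic_summary("hazard_rate", coef(fit), N = round(fit$N_cds), P = 0.1)
#> Asymptotic efficiency of the CDS abundance estimator
#>   family: hazard_rate  theta = ( 0.4655, 2.064 )  w = 1
#>   N = 20572   P = 0.1   E[n] = 1262
#>   gbar = 0.6134
#>   var(N_hat | theta known) = 314800
#>   penalty F = 2.505  -> var(N_hat_CDS) = 788500
#>   CV(N_hat_CDS) = 0.04316
```

Not knowing θ inflates the variance of the abundance estimate 2.5-fold
here. A survey wanting a 15% CV under this detection model would need
`sample_size(0.15, penalty_F("hazard_rate", coef(fit), 0.1))` ≈ 111
expected detections, not the 1/0.15² ≈ 44 that a known-θ calculation
suggests.

The same numbers from the shell:

```sh
Rscript inst/cli/dsefficiency penalty --family hazard_rate \
    --theta 0.448,2 --P 0.1
Rscript inst/cli/dsefficiency table --which table2 --out penalties.csv
```

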