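# morbcompress

Multimorbidity compression analysis for PASSI-style surveillance records:
a disability-weighted latent trait model turns five binary chronic-disease
indicators into a continuous multimorbidity index, and a zero/one-inflated
ordered beta regression with regional random intercepts relates that index
to socioeconomic covariates and the survey year. A negative year effect —
multimorbidity concentrating later in life as years pass — is the
operational signature of morbidity compression.

The package is aimed at epidemiologists and biostatisticians working with
cross-sectional behavioral-risk-factor surveillance data (adults 18–69,
self-reported diagnoses of diabetes, kidney failure, respiratory disease,
heart disease, and tumors, plus perceived health, sex, age, education,
economic status, year, region, and four behavioral risk factors). Because
such microdata are restricted, a synthetic-population generator with known
ground truth makes the full pipeline reproducible and testable.

## The model

**Measurement stage.** Disease indicators follow a two-parameter logistic
latent trait model with the trait z ~ N(0, 1):

    logit Pr(X_i = 1 | z) = beta0_i + beta1_i * z

The likelihood is weighted by severity: each reported disease gets a
GBD-style disability weight selected by perceived health (minimum of the
candidates for ratings 1–3, mean for 4, maximum for 5), weights combine as
D = 1 − prod(1 − W_i), and respondent j enters the likelihood with weight
w_j = (D_j + 1) N / (sum D + N), mean 1. Estimation is EM with fixed-node
quadrature (Bock–Aitkin); respondents are scored by the posterior mean
(EAP) and scores are rescaled to [0, 1].

**Regression stage.** The rescaled index y mixes a point mass at 0
(structurally, the all-zero disease pattern), a point mass at 1, and a
Beta-distributed interior. The default hurdle parameterization is

    Pr(y = 0)            = expit(X beta_zero)
    Pr(y = 1 | y > 0)    = expit(X beta − k2 + u_k)
    y | interior         ~ Beta(mean = expit(X beta + u_k), precision = psi)

with regional intercepts u_k ~ N(0, sigma_u²) integrated out by a Laplace
approximation. The single-predictor two-cutpoint (ordered beta) variant is
available as `variant = "canonical"`. Population-level predictions set
u = 0: y_hat = (1 − gamma_hat) * mu_hat. Risk-class stratified refits
(class = count of smoking, alcohol, poor diet, inactivity) rerun the
regression without random effects per stratum.

## Worked example

```r
library(morbcompress)

cfg <- pipeline_config(
  population = population_config(n_respondents = 20000, seed = 1),
  seed = 1
)
report <- run_pipeline(cfg)
report
```

```
Multimorbidity compression report
  seed: 1   config hash: 1d5f77d886cbf999ec72e9f14f7511e6
  latent trait fit: converged = TRUE loglik = -20831.64
  full-population year effect: -0.01005 (se 0.00252 )
  per-risk-class year effects:
 risk_class    n year_estimate     year_se
          0 3875  -0.014096044 0.005444299
          1 8180  -0.008034079 0.004050614
          2 6037  -0.009929916 0.004646258
          3 1750  -0.012368894 0.008138868
          4  158  -0.032266198 0.028688342
```

The default generator encodes a mild negative year trend on the latent
trait; the fitted conditional year coefficient (−0.010 per year, t ≈ −4.0)
recovers its sign in the full population and within every risk class — the
compression signature. The estimated item parameters mirror the
difficulty/discrimination layout (kidney failure rarest and most
discriminating):

```r
item_param_table(report$latent_fit)
#>       disease neg_beta0 beta1
#> 1    diabetes      3.47 1.367
#> 2      kidney      6.03 2.210
#> 3 respiratory      2.76 0.976
#> 4       heart      3.50 1.429
#> 5       tumor      3.08 0.915
```

Population-level predictions at age 69 in the first survey year show the
socioeconomic gradient (higher multimorbidity under low education and
economic difficulties):

```r
subset(report$predictions, year == 2008,
       select = c(sex, education, economic, y_hat))
#>      sex education     economic y_hat
#>   female      high         none 0.141
#>   female       low difficulties 0.179
#>     male      high         none 0.159
#>     male       low difficulties 0.200
```

Coefficient tables in the two-block (conditional / zero-inflation) layout
come from `summary(report$full_fit)`, regional empirical-Bayes predictions
from `blup(report$full_fit)`.

A thin command-line wrapper over the same functions lives at
`inst/cli/morbcompress.R` (subcommands `simulate`, `weights`, `fit-ltm`,
`fit-ordbeta`, `pipeline`).

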