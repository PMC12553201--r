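---
title: "Measuring multimorbidity compression with a weighted latent trait and ordered beta regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring multimorbidity compression with a weighted latent trait and ordered beta regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morbcompress)
```

## The scientific problem

Morbidity compression is the hypothesis that the onset of chronic disease is
being delayed faster than life expectancy grows, so the part of life spent in
poor health shrinks. Testing it on cross-sectional surveillance data requires
two ingredients: (i) a summary of each respondent's *cumulative* disease
burden — a count of diagnoses treats a mild and a severe condition alike —
and (ii) a regression that relates that summary to socioeconomic covariates
and, crucially, to the survey year, while respecting the summary's peculiar
distribution (a large healthy point mass at zero, a continuous bulk, and a
rescaled maximum at one).

`morbcompress` implements this analysis for PASSI-like records: five binary
non-communicable disease indicators (diabetes, kidney failure, respiratory
disease, heart disease, tumors), self-rated health on a 1–5 scale,
sex, age 18–69, education, economic status, survey year, and one of 19
regions. Because the underlying surveillance microdata are restricted, the
package ships a synthetic-population generator that reproduces the record
layout and the stated marginal structure, with ground truth retained for
testing.

## Stage 1: the disability-weighted latent trait

Each disease indicator $X_{ij}\in\{0,1\}$ is treated as a noisy measurement
of a single continuous multimorbidity trait $z_j \sim N(0,1)$ through a
two-parameter logistic model,

$$\operatorname{logit} \Pr(X_{ij}=1\mid z_j) = \beta_{0i} + \beta_{1i} z_j ,$$

so $\operatorname{expit}(\beta_{0i})$ is the disease's prevalence for an
average-burden person and $\beta_{1i}$ its loading on the trait.

Severity enters through the likelihood weights. Every disease carries a
catalogue of candidate disability weights in $(0,1)$ (GBD-style severity
scores; the packaged catalogue is synthetic but spans the published orders
of magnitude). Self-rated health selects the candidate — minimum for
ratings 1–3, mean for 4, maximum for 5 — and the selected weights combine
multiplicatively into the cumulative disability weight

$$D_j = 1 - \prod_i (1 - W_{ij}),$$

which is zero exactly when no disease is reported. The per-respondent
likelihood weights are

$$w_j = \frac{(D_j + 1)\,N}{\sum_j D_j + N},$$

mean one by construction, so a severe profile counts more without changing
the effective sample size.

Estimation maximizes the weighted marginal likelihood with the trait
integrated out on a fixed grid (61 equally spaced nodes on $[-6, 6]$ with
standard-normal masses renormalized to one; a Gauss–Hermite grid is
available via `quadrature_grid(type = "gauss_hermite")`). The EM iteration
collapses the data to at most $2^5 = 32$ response patterns, computes
per-pattern posterior node masses in the E-step, and solves one weighted
logistic regression per item by Newton's method in the M-step; convergence
is declared when no parameter moves by more than `1e-4` (default
`max_iter = 500`). The weighted marginal log-likelihood is monotone across
iterations, which the test suite checks. Since a 2PL is invariant to
flipping the trait's sign, slopes (and scores) are flipped after
convergence if their mean is negative. Standard errors use the empirical
cross-product of per-pattern score vectors obtained from Fisher's identity.

Respondents are scored by the posterior mean (EAP) of the trait given their
pattern — finite for every pattern, including the all-zero one, and
identical for identical patterns. The scoring rule and the quadrature
settings are conventions of this package; maximum-a-posteriori or
maximum-likelihood scoring would order patterns the same way but is not
provided.

### Rescaling and the structural zero

The regression stage uses $y_j = (z_j - z_{(1)})/(z_{(N)} - z_{(1)})$,
computed once on the pooled sample (not per year — pooling keeps one common
scale across the period). With all slopes positive the minimum EAP score is
attained exactly by the all-zero disease pattern, so $\{y = 0\}$ coincides
with the healthy pattern and the zero mass of $y$ is structural. Values
equal to 0 or 1 are therefore modelled as point masses, and interior values
are used untransformed — no boundary squeezing.

## Stage 2: zero/one-inflated ordered beta regression

The default ("hurdle") variant models, with $\eta = X\beta$ and
$\eta_0 = X\beta_0$ on the same covariates (sex, age, economic status,
education, years since the first survey wave, and sex × age):

* $\Pr(y=0) = \operatorname{expit}(\eta_0)$ — the zero part, no random
  effect;
* conditional on $y>0$: a one mass $\operatorname{expit}(\eta - k_2 + u_k)$
  and, on the interior, a Beta density with mean
  $\operatorname{expit}(\eta + u_k)$ and precision $\psi$, scaled by
  $1-\operatorname{expit}(\eta - k_2 + u_k)$;
* $u_k \sim N(0, \sigma_u^2)$, one intercept per region, entering the
  conditional components only.

The three probabilities sum to one by construction. This is the coherent
reading of a specification in which the zero line carries its own
coefficient vector and no random effect while the reported output has
distinct "conditional" and "zero-inflation" blocks; the single-predictor
two-cutpoint ("canonical") parameterization
($\Pr(y=0) = 1-\operatorname{expit}(\eta - k_1 + u_k)$,
$\Pr(y=1) = \operatorname{expit}(\eta - k_2 + u_k)$, $k_1 < k_2$) is kept as
`variant = "canonical"` and is verified in the test suite against an
independent mixed-model implementation of the same family (agreement to
about four decimals in coefficients and log-likelihood).

### Estimation

The hurdle likelihood factorizes exactly: the zero part is an ordinary
Bernoulli GLM on the indicator $\{y=0\}$ (fit by `stats::glm`, exact ML),
and the conditional part involves only the nonzero subset. The regional
random intercept is integrated out by a Laplace approximation: an inner
Newton iteration (analytic first and second derivatives in $u_k$,
vectorized across regions, warm-started between objective evaluations)
finds each region's mode, and the log-determinant correction is computed as
$\tfrac12\log(1 - \sigma_u^2 g_k'')$, a form that degenerates gracefully to
the no-random-effect likelihood as $\sigma_u \to 0$. Adaptive Gauss–Hermite
quadrature around the Laplace mode is available as a numerical cross-check
(`marginal_negloglik(..., method = "ghq")`); on small multi-region data the
two agree to well under 0.05 in log-likelihood.

The outer optimization is quasi-Newton (`nlminb`, parameter-scaled, central
finite-difference gradients) over $\beta$, $k_2$, $\log\psi$ and
$\log\sigma_u$, started from $k_2 = 1$ (the canonical variant starts from
$k_1 = -1$, $k_2 = 1$, with ordering enforced through
$k_2 = k_1 + e^\delta$), a logit-least-squares warm start for $\beta$,
$\psi = 5$ and $\sigma_u = 0.1$. Because survey designs with a raw-age ×
sex interaction are highly collinear, a damped Newton polish using the
full finite-difference Hessian (also reused for standard errors) follows;
the convergence flag requires a scaled gradient norm below $10^{-5}$.
Observations are sorted canonically before fitting so results are invariant
to input row order. Likelihood weights $w_j$ are *not* applied at this
stage by default — they belong to the measurement model — but a `weights`
argument exists.

Predictions at the population level set all random effects to zero:
$\hat y = (1-\hat\gamma)\hat\mu$ with $\hat\gamma$ the zero probability and
$\hat\mu$ the expected index given a nonzero outcome. Regional
empirical-Bayes predictions (`blup()`) return the inner modes with their
Laplace conditional standard deviations.

### Reduced fits at empty components

A stratum can lack exact ones (pooled rescaling puts $y=1$ only on the
sample-wide most severe pattern). `fit_ordered_beta` refuses such data by
default, advising the reduced model; with `boundary = "reduce"` it drops
the unobserved point mass — the maximum-likelihood limit $k_2 \to \infty$ —
which is how the pipeline's per-risk-class refits proceed.

## The pipeline and risk-class stratification

`run_pipeline()` chains: population (synthetic or CSV) → disability scores
→ weighted 2PL → EAP scores → pooled rescaling → full-population hurdle fit
with regional random intercept → per-risk-class refits *without* random
effects (risk class = count of smoking, alcohol, poor diet, physical
inactivity; the latent-trait scores are reused rather than refit per
stratum, since one common index is the point of the measurement model) →
population-level prediction grid → report with run metadata (seed,
configuration hash). Identical configuration and seed reproduce the report
exactly.

## The synthetic generator: what it emulates and what it does not

The generator draws covariates independently at the configured shares
(defaults 53.18% female, 60.17% high education, 52.77% economic
difficulties), ages uniformly on 18–69, years uniformly on 2008–2019, and
regions uniformly on 1–19. The latent trait is standard normal noise plus
configured covariate, year, and regional shifts, then re-standardized to a
mean-zero unit-variance marginal — the measurement model identifies the
trait on exactly that scale, so the generator must hand truth over on it.
Disease indicators are Bernoulli draws from the 2PL at the configured item
parameters (defaults equal to published estimates for the five PASSI
items); perceived health follows a proportional-odds link from the trait
(cutpoints placed at population shares 18/42/32/6.5/1.5%, slope 1.2 — the
survey's perceived-health/disease relationship is not documented, so this
link is a configurable stand-in); behaviors follow per-behavior logit
models with mild regional and year gradients so risk-class stratification
is non-degenerate. Ground truth (`z_true`) is written to a sidecar file by
`write_population()`, never to the observable table.

Deliberately *not* emulated: the real sampling design and nonresponse, the
exclusion of one region for participation reasons, correlation between
covariates (e.g. education by age), and any residual disease correlation
beyond the single latent factor. Passing tests therefore demonstrate that
the estimators recover the truth of *this* generative structure, not that
the substantive findings transfer to the restricted survey data.

## Numerical and design choices

* Quadrature: 61 rectangular nodes on $[-6,6]$; doubling the node count
  moves a converged log-likelihood by far less than $10^{-3}$ (tested).
* Candidate disability weights equal to 0 or 1 are rejected at catalogue
  load: a weight of 1 would force $D_j = 1$ and degenerate the weight rule.
* Sampling weights are recomputed per dataset — each $w_j$ couples to the
  sample total $\sum_j D_j$, so stored weights would go stale.
* Year is coded as an offset from the first survey year in the pipeline;
  with a free intercept this is a pure reparameterization (tested), but it
  conditions the optimizer far better than calendar years.
* The zero part keeps no random effect by default, following the model
  definition stage-1 output is regressed under; whether the published
  analysis shared the regional effect with the zero line is not documented.
* Cutpoints and the precision of the published regression are not
  reported, so published coefficient tables cannot be turned into
  predictions; all recovery checks are against synthetic truth.

## Problem sizes and the calibration study

Simulation-based checks run at desk scale, with sizes chosen so each check
is informative: generator calibration at $n = 100{,}000$ (binomial
standard errors ~0.16 percentage points); 2PL recovery at $n = 20{,}000$ —
note the rarest item (prevalence $\approx$ 0.23%) then carries only ~45
cases, so its parameters have sampling SD $\approx$ 0.3; ordered-beta
recovery at $n = 10{,}000$, 19 regions.

The year-effect ("compression") calibration is a designed sign-recovery
experiment: 20 signed replicates at $n = 6{,}000$ with a generative year
effect of $-0.10$ latent SD per year, item intercepts raised to
$(-1.6,\dots,-2.4)$ and flat behavior probabilities of 0.5, so the smallest
risk-class stratum (~6% of the sample) has expected $|t| \approx 3$–4 and
the sign is recovered with high probability in every stratum; and 20 null
replicates at $n = 4{,}000$ with a zero year effect, checking that $|t| < 2$
in at least 90% of runs. The signal is deliberately stronger than a
realistic compression trend: at survey scale (hundreds of thousands of
records) a subtle trend is detectable, at desk scale it is not, and a
sign-recovery study without power says nothing.

## Worked example

```{r, eval = FALSE}
library(morbcompress)

cfg <- pipeline_config(
  population = population_config(n_respondents = 20000, seed = 1),
  seed = 1
)
report <- run_pipeline(cfg)
report
summary(report$full_fit)
blup(report$full_fit)
```

## Known limitations

Five indicators bound what a unidimensional trait can resolve: the EAP
scores take at most 32 values, so the "continuous" index is continuous
only through the regression stage's smoothing. The Laplace approximation
is accurate here because regions are large; with very small clusters the
`"ghq"` cross-check should be consulted. The package deliberately omits
limited-information fit statistics beyond the analytic degrees-of-freedom
count, semi-parametric latent densities, Bayesian cutpoint priors, spatial
(neighborhood-structured) random effects, and any mortality or life-table
linkage.
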