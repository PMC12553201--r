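# Shared simulation helpers for the test suite.

disease_cols <- c("diabetes", "kidney", "respiratory", "heart", "tumor")
behavior_cols <- c("smoking", "alcohol", "poor_diet", "inactivity")

# Binary 2PL responses at given item parameters, latent trait standard normal.
sim_2pl <- function(n, beta0, beta1, seed) {
  set.seed(seed)
  z <- rnorm(n)
  X <- vapply(seq_along(beta0),
              function(i) rbinom(n, 1L, plogis(beta0[i] + beta1[i] * z)),
              integer(n))
  colnames(X) <- disease_cols[seq_along(beta0)]
  list(X = X, z = z)
}

# Calibration population for the year-effect sign/size studies: a clear
# compression signal with prevalent items and balanced behaviors, so that
# every risk-class stratum carries adequate information at desk scale.
calibration_config <- function(n, year_effect, seed) {
  population_config(
    n_respondents = n, seed = seed,
    item_params = data.frame(
      disease = disease_cols,
      beta0 = c(-1.6, -2.4, -1.2, -1.8, -1.4),
      beta1 = c(1.34, 2.08, 0.97, 1.65, 0.84)
    ),
    latent_effects = c(male = -0.15, age = 0.045, male_age = 0.012,
                       economic_none = -0.22, education_high = -0.20,
                       year = year_effect),
    region_effect_sd = 0.05,
    risk_behavior_logits = data.frame(
      behavior = behavior_cols,
      intercept = 0, region_slope = 0, year_slope = 0
    )
  )
}

# Default coefficient sets for ordered-beta simulations (survey-like design:
# intercept, male, age, economic none, education high, year_c, male:age).
ob_beta <- c(-1.0, -0.089, 0.007, -0.065, -0.075, -0.02, 0.004)
ob_beta_zero <- c(0.8, 0.5, -0.05, 0.3, 0.2, 0.005, -0.01)

# Truth mapped to the centered-age parameterization (age_c = age - 44).
center_age_truth <- function(b) {
  c(b[1] + 44 * b[3], b[2] + 44 * b[7], b[3], b[4], b[5], b[6], b[7])
}
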