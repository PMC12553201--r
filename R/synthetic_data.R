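# Synthetic PASSI-like populations.
#
# The generator emulates the record layout of the Italian PASSI behavioural
# surveillance system (adults 18-69, five self-reported chronic diseases,
# perceived health, socio-demographics, survey year 2008-2019, 19 regions)
# with a known ground-truth latent structure, so that every downstream
# estimation stage can be tested against truth without restricted microdata.

DISEASES <- c("diabetes", "kidney", "respiratory", "heart", "tumor")
BEHAVIORS <- c("smoking", "alcohol", "poor_diet", "inactivity")

#' Default item parameters of the disease measurement model
#'
#' Intercepts and slopes (logit scale) of the two-parameter logistic model
#' linking each disease indicator to the latent multimorbidity trait. The
#' defaults reproduce published estimates for the five PASSI disease items:
#' rare, high-slope kidney failure; prevalent, flatter respiratory disease
#' and tumours.
#'
#' @return data frame with columns `disease`, `beta0`, `beta1`.
#' @export
default_item_params <- function() {
  data.frame(
    disease = DISEASES,
    beta0 = c(-3.571, -6.082, -2.880, -3.924, -3.198),
    beta1 = c(1.340, 2.077, 0.974, 1.647, 0.840),
    stringsAsFactors = FALSE
  )
}

#' Packaged disability-weight catalogue
#'
#' A fixed, versioned catalogue of synthetic GBD-style candidate disability
#' weights per disease. It stands in for a curated mapping of survey disease
#' labels to published health-state weights: the values are invented but
#' match the order of magnitude and spread of published weights (mild forms
#' near 0.05, severe forms up to ~0.6). The same catalogue ships as a CSV at
#' `system.file("extdata", "gbd_like_synthetic_weights.csv",
#' package = "morbcompress")`.
#'
#' @return named list: disease -> ascending candidate weights in (0, 1).
#' @export
default_weight_catalogue <- function() {
  validate_weight_catalogue(list(
    diabetes    = c(0.049, 0.133, 0.211),
    kidney      = c(0.104, 0.376, 0.569),
    respiratory = c(0.019, 0.225, 0.408),
    heart       = c(0.041, 0.072, 0.179, 0.405),
    tumor       = c(0.049, 0.288, 0.451, 0.540)
  ))
}

#' Generate a disability-weight catalogue
#'
#' With `seed = NULL` returns the fixed packaged catalogue
#' ([default_weight_catalogue()]). With a seed, draws a random catalogue
#' (3-6 candidates per disease, uniform in (0.02, 0.7), sorted) — useful for
#' property tests that must not depend on the packaged values.
#'
#' @param seed integer or `NULL`.
#' @return named list: disease -> ascending candidate weights in (0, 1).
#' @export
generate_weight_catalogue <- function(seed = NULL) {
  if (is.null(seed)) {
    return(default_weight_catalogue())
  }
  with_seed(seed, {
    out <- lapply(DISEASES, function(d) {
      k <- sample(3:6, 1L)
      sort(stats::runif(k, 0.02, 0.7))
    })
    names(out) <- DISEASES
    validate_weight_catalogue(out)
  })
}

# Evaluate code under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Configuration for the synthetic population generator
#'
#' All generative quantities are explicit so that ground truth is known.
#' Defaults encode the survey structure being emulated: 19 regions, survey
#' years 2008-2019, covariate shares 53.18% female / 60.17% high education /
#' 52.77% economic difficulties, and the default disease item parameters.
#'
#' `latent_effects` shifts the mean of the latent trait by covariates before
#' the marginal is re-standardized to mean 0, variance 1 (the measurement
#' model identifies the trait as standard normal, so the generator must
#' respect that marginal). Units are latent-trait standard deviations; `age`
#' is per year of age centred at 44, `year` per survey year since the first.
#'
#' @param n_respondents positive integer, number of records.
#' @param n_regions positive integer, number of regions (default 19).
#' @param years inclusive integer range of survey years.
#' @param covariate_shares named numeric: probabilities of `female`,
#'   `high_education`, `economic_difficulties`.
#' @param latent_effects named numeric: coefficients of `male`, `age`,
#'   `male_age`, `economic_none`, `education_high`, `year` on the latent mean.
#' @param item_params data frame as [default_item_params()].
#' @param region_effect_sd nonnegative sd of the regional latent shift.
#' @param risk_behavior_logits data frame: per behavior an `intercept` plus
#'   `region_slope` (per unit of the centred, scaled region index) and
#'   `year_slope` (per year) on the logit of the behavior probability.
#' @param perceived_health_model list with `cutpoints` (4 increasing logit
#'   thresholds) and `slope` (loading of the latent trait), a
#'   proportional-odds link from the trait to the 1-5 self-rated health scale.
#' @param seed integer RNG seed.
#' @return an object of class `population_config`.
#' @export
population_config <- function(n_respondents = 10000L,
                              n_regions = 19L,
                              years = 2008:2019,
                              covariate_shares = c(
                                female = 0.5318,
                                high_education = 0.6017,
                                economic_difficulties = 0.5277
                              ),
                              latent_effects = c(
                                male = -0.15,
                                age = 0.045,
                                male_age = 0.012,
                                economic_none = -0.22,
                                education_high = -0.20,
                                year = -0.02
                              ),
                              item_params = default_item_params(),
                              region_effect_sd = 0.10,
                              risk_behavior_logits = default_behavior_logits(),
                              perceived_health_model = list(
                                cutpoints = stats::qlogis(c(0.18, 0.60, 0.92, 0.985)),
                                slope = 1.2
                              ),
                              seed = 1L) {
  cfg <- list(
    n_respondents = as.integer(n_respondents),
    n_regions = as.integer(n_regions),
    years = as.integer(years),
    covariate_shares = covariate_shares,
    latent_effects = latent_effects,
    item_params = item_params,
    region_effect_sd = region_effect_sd,
    risk_behavior_logits = risk_behavior_logits,
    perceived_health_model = perceived_health_model,
    seed = as.integer(seed)
  )
  class(cfg) <- "population_config"
  validate_population_config(cfg)
}

#' Default behavior generative model
#'
#' Mild regional and temporal gradients on the four risk behaviors so that
#' risk-class stratification is non-degenerate. Intercept probabilities are
#' typical adult shares (smoking ~30%, at-risk alcohol ~17%, poor diet ~55%,
#' physical inactivity ~35%).
#'
#' @return data frame with columns `behavior`, `intercept`, `region_slope`,
#'   `year_slope`.
#' @export
default_behavior_logits <- function() {
  data.frame(
    behavior = BEHAVIORS,
    intercept = stats::qlogis(c(0.30, 0.17, 0.55, 0.35)),
    region_slope = c(0.15, -0.15, 0.20, 0.25),
    year_slope = c(-0.03, -0.01, -0.02, 0.01),
    stringsAsFactors = FALSE
  )
}

validate_population_config <- function(cfg) {
  if (!inherits(cfg, "population_config")) stop_config("not a population_config")
  if (length(cfg$n_respondents) != 1L || is.na(cfg$n_respondents) || cfg$n_respondents < 1L) {
    stop_config("n_respondents must be a positive integer")
  }
  if (cfg$n_regions < 1L) stop_config("n_regions must be >= 1")
  if (length(cfg$years) == 0L || anyNA(cfg$years)) stop_config("year range must be nonempty")
  shares <- cfg$covariate_shares
  need <- c("female", "high_education", "economic_difficulties")
  if (!all(need %in% names(shares))) {
    stop_config(paste("covariate_shares must name:", paste(need, collapse = ", ")))
  }
  if (any(!is.finite(shares)) || any(shares < 0) || any(shares > 1)) {
    stop_config("covariate shares must be probabilities in [0, 1]")
  }
  if (!is.finite(cfg$region_effect_sd) || cfg$region_effect_sd < 0) {
    stop_config("region_effect_sd must be nonnegative")
  }
  ip <- cfg$item_params
  if (!all(c("disease", "beta0", "beta1") %in% names(ip)) || nrow(ip) != 5L) {
    stop_config("item_params must have 5 rows with disease, beta0, beta1")
  }
  cp <- cfg$perceived_health_model$cutpoints
  if (length(cp) != 4L || any(diff(cp) <= 0)) {
    stop_config("perceived-health cutpoints must be 4 increasing values")
  }
  cfg
}

#' Generate a synthetic PASSI-like population
#'
#' Draws respondent records under the configured ground truth:
#' covariates are sampled independently at the configured shares; the latent
#' multimorbidity trait is standard normal noise plus the configured
#' covariate and regional shifts, re-standardized so its marginal is mean 0,
#' variance 1; each disease indicator is Bernoulli with
#' `logit(p) = beta0 + beta1 * z`; perceived health follows the configured
#' proportional-odds model; behaviors follow their logit model. Identical
#' seeds give identical tables.
#'
#' The returned table carries the ground-truth trait in `z_true`; use
#' [write_population()] to persist observables and truth to separate files.
#'
#' @param config a [population_config()].
#' @return data frame, one row per respondent.
#' @export
generate_population <- function(config) {
  config <- validate_population_config(config)
  with_seed(config$seed, generate_population_impl(config))
}

generate_population_impl <- function(config) {
  n <- config$n_respondents
  shares <- config$covariate_shares

  region <- sample.int(config$n_regions, n, replace = TRUE)
  year <- sample(config$years, n, replace = TRUE)
  age <- sample(18:69, n, replace = TRUE)
  female <- stats::rbinom(n, 1L, shares[["female"]])
  edu_high <- stats::rbinom(n, 1L, shares[["high_education"]])
  econ_diff <- stats::rbinom(n, 1L, shares[["economic_difficulties"]])

  eff <- config$latent_effects
  coef_of <- function(nm) if (nm %in% names(eff)) eff[[nm]] else 0
  male <- 1L - female
  age_c <- age - 44
  year_c <- year - min(config$years)
  shift <- coef_of("male") * male +
    coef_of("age") * age_c +
    coef_of("male_age") * male * age_c +
    coef_of("economic_none") * (1L - econ_diff) +
    coef_of("education_high") * edu_high +
    coef_of("year") * year_c
  region_shift <- if (config$region_effect_sd > 0) {
    stats::rnorm(config$n_regions, 0, config$region_effect_sd)
  } else {
    rep(0, config$n_regions)
  }
  z_raw <- stats::rnorm(n) + shift + region_shift[region]
  # Re-standardize: the measurement model identifies the trait as marginal
  # standard normal, so the generator must hand truth over on that scale.
  z <- as.numeric(scale(z_raw))

  ip <- config$item_params
  disease <- matrix(0L, n, 5L, dimnames = list(NULL, ip$disease))
  for (i in seq_len(5L)) {
    disease[, i] <- stats::rbinom(n, 1L, expit(ip$beta0[i] + ip$beta1[i] * z))
  }

  phm <- config$perceived_health_model
  cum <- vapply(phm$cutpoints, function(k) expit(k - phm$slope * z), numeric(n))
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = n)
  u <- stats::runif(n)
  perceived_health <- 1L + rowSums(u > cum)

  bl <- config$risk_behavior_logits
  region_x <- (region - (config$n_regions + 1) / 2) / max(1, (config$n_regions - 1) / 2)
  behaviors <- matrix(0L, n, length(BEHAVIORS), dimnames = list(NULL, BEHAVIORS))
  for (b in seq_len(nrow(bl))) {
    p <- expit(bl$intercept[b] + bl$region_slope[b] * region_x + bl$year_slope[b] * year_c)
    behaviors[, bl$behavior[b]] <- stats::rbinom(n, 1L, p)
  }

  out <- data.frame(
    id = seq_len(n),
    region = region,
    year = year,
    age = age,
    sex = factor(ifelse(female == 1L, "female", "male"), levels = c("female", "male")),
    education = factor(ifelse(edu_high == 1L, "high", "low"), levels = c("low", "high")),
    economic = factor(ifelse(econ_diff == 1L, "difficulties", "none"),
                      levels = c("difficulties", "none")),
    perceived_health = perceived_health,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(disease), as.data.frame(behaviors))
  out$z_true <- z
  out
}

#' Write a population table and its ground-truth sidecar
#'
#' Observable columns go to `path`; ground-truth columns (`z_true`) go to a
#' sidecar `<path stem>_truth.csv`, keeping truth out of estimation inputs.
#'
#' @param pop table from [generate_population()].
#' @param path CSV path for the observable table.
#' @return invisibly, the two paths written.
#' @export
write_population <- function(pop, path) {
  truth_cols <- intersect("z_true", names(pop))
  obs <- pop[, setdiff(names(pop), truth_cols), drop = FALSE]
  utils::write.csv(obs, path, row.names = FALSE)
  truth_path <- sub("(\\.csv)?$", "_truth.csv", path)
  if (length(truth_cols)) {
    utils::write.csv(pop[, c("id", truth_cols), drop = FALSE], truth_path, row.names = FALSE)
  }
  invisible(c(population = path, truth = truth_path))
}
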