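# End-to-end multimorbidity-compression analysis.
#
# simulate (or load) -> disability weights -> weighted 2PL -> EAP scores ->
# rescale to [0, 1] -> full-population ordered beta with regional random
# intercept -> per-risk-class refits without random effects -> population
# level prediction grid -> report.

#' Risk class from the four behavior flags
#'
#' The cumulative count of present behaviors among smoking, alcohol
#' consumption, poor diet, and physical inactivity: 0 is the optimal
#' scenario, 4 the highest risk. Ex-smokers count as carrying the smoking
#' risk when the data encode smoking history that way.
#'
#' @param behaviors vector (or matrix / data frame with one row per
#'   respondent) of 4 binary flags.
#' @return integer class(es) in 0..4.
#' @examples
#' risk_class(c(0, 0, 0, 0)) # 0
#' risk_class(c(1, 1, 0, 1)) # 3
#' @export
risk_class <- function(behaviors) {
  if (is.data.frame(behaviors)) behaviors <- as.matrix(behaviors)
  if (is.null(dim(behaviors))) behaviors <- matrix(behaviors, nrow = 1L)
  if (ncol(behaviors) != 4L || anyNA(behaviors)) {
    stop_config("risk_class needs 4 non-missing binary behavior flags")
  }
  if (!all(behaviors %in% c(0, 1))) stop_config("behavior flags must be 0/1")
  as.integer(rowSums(behaviors))
}

#' Conditional risk-class frequencies by year and region
#'
#' For every (year, region) cell, the relative frequencies of risk classes
#' 0-4 (summing to one within the cell), plus pooled national frequencies
#' per year. Empty (year, region) cells are omitted with a notice.
#'
#' @param data data frame with `year`, `region`, and the four behavior
#'   columns (`smoking`, `alcohol`, `poor_diet`, `inactivity`).
#' @return list with data frames `by_region` (year, region, class, freq, n)
#'   and `national` (year, class, freq, n).
#' @export
conditional_behavior_frequencies <- function(data) {
  need <- c("year", "region", BEHAVIORS)
  if (!all(need %in% names(data))) {
    stop_config(paste("data must contain columns:", paste(need, collapse = ", ")))
  }
  cls <- risk_class(data[, BEHAVIORS])
  cls_f <- factor(cls, levels = 0:4)
  tab <- as.data.frame(table(year = data$year, region = data$region, class = cls_f))
  cell_n <- stats::aggregate(Freq ~ year + region, tab, sum)
  empty <- cell_n[cell_n$Freq == 0, , drop = FALSE]
  if (nrow(empty)) {
    message("omitting ", nrow(empty), " empty (year, region) cell(s)")
  }
  tab <- merge(tab, stats::setNames(cell_n, c("year", "region", "n")),
               by = c("year", "region"))
  tab <- tab[tab$n > 0, , drop = FALSE]
  tab$freq <- tab$Freq / tab$n
  by_region <- tab[order(tab$year, tab$region, tab$class),
                   c("year", "region", "class", "freq", "n")]
  nat <- as.data.frame(table(year = data$year, class = cls_f))
  nat_n <- stats::aggregate(Freq ~ year, nat, sum)
  nat <- merge(nat, stats::setNames(nat_n, c("year", "n")), by = "year")
  nat$freq <- nat$Freq / nat$n
  national <- nat[order(nat$year, nat$class), c("year", "class", "freq", "n")]
  rownames(by_region) <- NULL
  rownames(national) <- NULL
  list(by_region = by_region, national = national)
}

#' Configuration of a pipeline run
#'
#' @param population a [population_config()] (synthetic run) or a CSV path
#'   with respondent records.
#' @param catalogue disability-weight catalogue (default the packaged one).
#' @param grid quadrature grid for the latent trait fit.
#' @param variant ordered beta variant.
#' @param random_effect `"region"` or `"none"` for the full-population fit.
#' @param stratified fit the five per-risk-class refits (without random
#'   effects)?
#' @param prediction_years years to tabulate in the prediction grid.
#' @param prediction_age age at which population-level estimates are
#'   tabulated (default 69, where multimorbidity differences are widest).
#' @param seed seed for any pipeline-level randomness.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(population = population_config(),
                            catalogue = default_weight_catalogue(),
                            grid = quadrature_grid(),
                            variant = "hurdle",
                            random_effect = "region",
                            stratified = TRUE,
                            prediction_years = NULL,
                            prediction_age = 69L,
                            seed = 1L) {
  cfg <- list(
    population = population, catalogue = validate_weight_catalogue(catalogue),
    grid = grid, variant = variant, random_effect = random_effect,
    stratified = stratified, prediction_years = prediction_years,
    prediction_age = as.integer(prediction_age), seed = as.integer(seed)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full compression analysis
#'
#' Executes every stage of the analysis and returns a report: the weighted
#' latent trait fit, the rescaled index, the full-population ordered beta
#' fit (with regional random intercept by default), the per-risk-class
#' refits without random effects, the population-level prediction grid, the
#' regional BLUP table, and run metadata sufficient to reproduce the run.
#' Identical configuration and seed give an identical report.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory: every stage's outputs are persisted
#'   as CSV/JSON.
#' @return object of class `compression_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stage <- "load"
  report <- list(meta = list(
    seed = config$seed,
    config_hash = object_hash(config[setdiff(names(config), "seed")]),
    package_version = as.character(utils::packageVersion("morbcompress")),
    started = format(Sys.time(), tz = "UTC", usetz = TRUE)
  ))
  persist <- function(obj, name) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      if (is.data.frame(obj)) {
        utils::write.csv(obj, file.path(out_dir, paste0(name, ".csv")), row.names = FALSE)
      } else {
        jsonlite::write_json(obj, file.path(out_dir, paste0(name, ".json")),
                             auto_unbox = TRUE, digits = NA, force = TRUE)
      }
    }
  }
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  pop <- run_stage("population", {
    if (is.character(config$population)) {
      p <- utils::read.csv(config$population, stringsAsFactors = FALSE)
      p$sex <- factor(p$sex, levels = c("female", "male"))
      p$education <- factor(p$education, levels = c("low", "high"))
      p$economic <- factor(p$economic, levels = c("difficulties", "none"))
      p
    } else {
      generate_population(config$population)
    }
  })
  persist(pop[, setdiff(names(pop), "z_true")], "population")

  scores_dw <- run_stage("disability_weights", disability_scores(pop, config$catalogue))
  persist(scores_dw, "disability_weights")

  ltm <- run_stage("latent_trait", {
    X <- as.matrix(pop[, DISEASES])
    fit_weighted_2pl(X, w = scores_dw$w, grid = config$grid)
  })
  persist(item_param_table(ltm), "item_params")

  y <- run_stage("rescale", rescale_unit(ltm$z))
  scores <- data.frame(id = pop$id, z = ltm$z, y = y)
  persist(scores, "scores")

  model_data <- cbind(pop, y = y, year_c = pop$year - min(pop$year))
  full_spec <- ordered_beta_spec(variant = config$variant,
                                 random_effect = config$random_effect)
  full_fit <- run_stage("ordered_beta_full", fit_ordered_beta(model_data, full_spec))

  blups <- NULL
  if (config$random_effect == "region") {
    blups <- run_stage("blup", blup(full_fit))
    persist(blups, "blup")
  }

  class_fits <- NULL
  class_year <- NULL
  if (isTRUE(config$stratified)) {
    cls <- risk_class(pop[, BEHAVIORS])
    strat_spec <- ordered_beta_spec(variant = config$variant, random_effect = "none")
    class_fits <- run_stage("ordered_beta_by_class", {
      lapply(0:4, function(k) {
        sub <- model_data[cls == k, , drop = FALSE]
        if (nrow(sub) == 0L) return(NULL)
        fit_ordered_beta(sub, strat_spec, boundary = "reduce")
      })
    })
    names(class_fits) <- paste0("class_", 0:4)
    class_year <- do.call(rbind, lapply(0:4, function(k) {
      f <- class_fits[[k + 1L]]
      if (is.null(f)) return(NULL)
      data.frame(
        risk_class = k,
        n = f$n,
        year_estimate = unname(f$beta["year_c"]),
        year_se = unname(f$se_beta[which(names(f$beta) == "year_c")]),
        stringsAsFactors = FALSE
      )
    }))
    persist(class_year, "year_effect_by_class")
  }

  grid_years <- config$prediction_years
  if (is.null(grid_years)) {
    yrs <- sort(unique(pop$year))
    grid_years <- unique(c(min(yrs), max(yrs)))
  }
  profiles <- expand.grid(
    sex = factor(c("female", "male"), levels = c("female", "male")),
    education = factor(c("low", "high"), levels = c("low", "high")),
    economic = factor(c("difficulties", "none"), levels = c("difficulties", "none")),
    year = grid_years,
    age = config$prediction_age,
    KEEP.OUT.ATTRS = FALSE
  )
  profiles$year_c <- profiles$year - min(pop$year)
  predictions <- run_stage("predictions", predict_population(full_fit, profiles))
  persist(predictions, "predictions")

  behavior_freq <- run_stage("behavior_frequencies",
                             conditional_behavior_frequencies(pop))
  persist(behavior_freq$by_region, "behavior_frequencies_by_region")
  persist(behavior_freq$national, "behavior_frequencies_national")

  report$latent_fit <- ltm
  report$scores <- scores
  report$full_fit <- full_fit
  report$class_fits <- class_fits
  report$year_effects <- rbind(
    data.frame(
      risk_class = NA_integer_, n = full_fit$n,
      year_estimate = unname(full_fit$beta["year_c"]),
      year_se = unname(full_fit$se_beta[which(names(full_fit$beta) == "year_c")]),
      stringsAsFactors = FALSE
    ),
    class_year
  )
  report$blups <- blups
  report$predictions <- predictions
  report$behavior_frequencies <- behavior_freq
  report$config <- config
  class(report) <- "compression_report"
  persist(list(
    meta = report$meta,
    year_effects = report$year_effects,
    item_params = item_param_table(ltm)
  ), "report")
  report
}

#' @export
print.compression_report <- function(x, ...) {
  cat("Multimorbidity compression report\n")
  cat("  seed:", x$meta$seed, "  config hash:", x$meta$config_hash, "\n")
  cat("  latent trait fit: converged =", x$latent_fit$converged,
      "loglik =", format(x$latent_fit$loglik, digits = 8), "\n")
  cat("  full-population year effect:",
      format(x$year_effects$year_estimate[1], digits = 4),
      "(se", format(x$year_effects$year_se[1], digits = 3), ")\n")
  if (nrow(x$year_effects) > 1L) {
    cat("  per-risk-class year effects:\n")
    print(x$year_effects[-1L, ], row.names = FALSE)
  }
  invisible(x)
}
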