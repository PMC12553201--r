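# Composite disability weights and likelihood weights.
#
# Each reported disease carries a catalogue of candidate GBD-style disability
# weights; self-rated health picks one candidate per disease; the per-person
# weights combine multiplicatively into a cumulative disability weight D_j,
# which in turn defines the sampling weights w_j used by the latent trait
# likelihood.

#' Select a disability weight given perceived health
#'
#' A disease has several candidate disability weights (mild to severe forms).
#' Self-rated health (1 = excellent ... 5 = very bad) decides which candidate
#' applies: ratings 1-3 take the minimum candidate, 4 the arithmetic mean,
#' 5 the maximum.
#'
#' @param candidates numeric vector of candidate weights, ascending, each in
#'   the open unit interval.
#' @param perceived_health integer in 1..5.
#' @return a single disability weight.
#' @examples
#' select_weight(c(0.1, 0.3, 0.5), 2) # 0.1
#' select_weight(c(0.1, 0.3, 0.5), 4) # 0.3
#' @export
select_weight <- function(candidates, perceived_health) {
  if (length(candidates) == 0L) {
    stop_config("empty disability-weight candidate list")
  }
  if (any(!is.finite(candidates)) || any(candidates <= 0) || any(candidates >= 1)) {
    stop_config("disability-weight candidates must lie strictly in (0, 1)")
  }
  if (length(perceived_health) != 1L || !perceived_health %in% 1:5) {
    stop_config("perceived_health must be a single integer in 1..5")
  }
  if (perceived_health <= 3) {
    min(candidates)
  } else if (perceived_health == 4) {
    mean(candidates)
  } else {
    max(candidates)
  }
}

#' Cumulative disability weight for one respondent
#'
#' Combines the disability weights of the diseases a respondent reports into
#' a single burden score via the multiplicative rule
#' \deqn{D = 1 - \prod_i (1 - W_i),}
#' the convention used by the Global Burden of Disease project for comorbid
#' conditions. No reported disease gives \eqn{D = 0}.
#'
#' @param selected_weights numeric vector of weights for the diseases present
#'   (possibly empty), each in `[0, 1)`.
#' @return the cumulative disability weight, in `[0, 1)`.
#' @examples
#' composite_disability(numeric(0))   # 0
#' composite_disability(c(0.2, 0.3))  # 0.44
#' @export
composite_disability <- function(selected_weights) {
  if (length(selected_weights) == 0L) {
    return(0)
  }
  if (any(!is.finite(selected_weights)) || any(selected_weights < 0) ||
      any(selected_weights >= 1)) {
    stop_config("selected weights must lie in [0, 1); a weight of 1 is degenerate")
  }
  1 - prod(1 - selected_weights)
}

#' Likelihood weights from cumulative disability
#'
#' Converts cumulative disability weights into observation weights for the
#' latent-trait likelihood,
#' \deqn{w_j = (D_j + 1) N / (\sum_j D_j + N),}
#' so that respondents carrying more disability burden count more, while the
#' weights always sum to the sample size N (mean weight 1).
#'
#' @param D numeric vector of cumulative disability weights, each in `[0, 1)`.
#' @return numeric vector of weights summing to `length(D)`.
#' @examples
#' sampling_weights(c(0, 0, 0))    # all 1
#' sampling_weights(c(0.5, 0, 0))  # c(1.2857, 0.8571, 0.8571)
#' @export
sampling_weights <- function(D) {
  if (length(D) == 0L) {
    stop_config("empty disability vector")
  }
  if (any(!is.finite(D)) || any(D < 0) || any(D >= 1)) {
    stop_config("cumulative disability weights must lie in [0, 1)")
  }
  n <- length(D)
  (D + 1) * n / (sum(D) + n)
}

#' Per-respondent disability scores for a population table
#'
#' Applies the weight-selection rule and the multiplicative combination to
#' every respondent of a population table, then computes the likelihood
#' weights for the whole sample.
#'
#' @param pop data frame with the five disease indicator columns
#'   (`diabetes`, `kidney`, `respiratory`, `heart`, `tumor`) and
#'   `perceived_health`.
#' @param catalogue a disability-weight catalogue, see
#'   [default_weight_catalogue()].
#' @return data frame with columns `id` (if present in `pop`), `D` and `w`.
#' @export
disability_scores <- function(pop, catalogue) {
  catalogue <- validate_weight_catalogue(catalogue)
  diseases <- names(catalogue)
  missing_cols <- setdiff(c(diseases, "perceived_health"), names(pop))
  if (length(missing_cols)) {
    stop_config(paste("population table lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  ph <- pop$perceived_health
  # The selection rule maps each (disease, perceived health) pair to one
  # candidate; precompute the three summaries per disease.
  D <- numeric(nrow(pop))
  for (d in diseases) {
    cand <- catalogue[[d]]
    chosen <- ifelse(ph <= 3, min(cand), ifelse(ph == 4, mean(cand), max(cand)))
    present <- pop[[d]] == 1L
    D[present] <- 1 - (1 - D[present]) * (1 - chosen[present])
  }
  out <- data.frame(D = D, w = sampling_weights(D))
  if ("id" %in% names(pop)) out <- cbind(id = pop$id, out)
  out
}

#' Validate a disability-weight catalogue
#'
#' @param catalogue named list: disease -> ascending numeric candidates in (0,1).
#' @return the catalogue, with candidates sorted ascending.
#' @export
validate_weight_catalogue <- function(catalogue) {
  if (!is.list(catalogue) || is.null(names(catalogue)) || any(names(catalogue) == "")) {
    stop_config("catalogue must be a named list of candidate weight vectors")
  }
  for (d in names(catalogue)) {
    w <- catalogue[[d]]
    if (length(w) == 0L) stop_config(paste0("no candidate weights for disease '", d, "'"))
    if (any(!is.finite(w)) || any(w <= 0) || any(w >= 1)) {
      stop_config(paste0("candidate weights for '", d, "' must lie strictly in (0, 1)"))
    }
    catalogue[[d]] <- sort(w)
  }
  catalogue
}

#' Read / write a weight catalogue as two-column CSV
#'
#' The on-disk format is a plain CSV with columns `disease` and `weight`,
#' multiple rows per disease.
#'
#' @param path file path.
#' @return for `read_weight_catalogue`, a validated catalogue list.
#' @export
read_weight_catalogue <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("disease", "weight") %in% names(df))) {
    stop_config("catalogue CSV needs columns 'disease' and 'weight'")
  }
  validate_weight_catalogue(split(df$weight, factor(df$disease, levels = unique(df$disease))))
}

#' @rdname read_weight_catalogue
#' @param catalogue catalogue list to write.
#' @export
write_weight_catalogue <- function(catalogue, path) {
  catalogue <- validate_weight_catalogue(catalogue)
  df <- data.frame(
    disease = rep(names(catalogue), lengths(catalogue)),
    weight = unlist(catalogue, use.names = FALSE)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
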