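# Weighted two-parameter logistic (2PL) latent trait model.
#
# The five binary disease indicators are treated as manifest variables of a
# single continuous multimorbidity trait z ~ N(0, 1):
#
#   logit Pr(X_i = 1 | z) = beta0_i + beta1_i * z.
#
# The marginal likelihood integrates z out on a fixed quadrature grid
# (Bock-Aitkin) and each respondent's contribution is multiplied by the
# disability-derived sampling weight w_j, so severe disease profiles carry
# more information. Estimation is an EM whose M-step is one weighted
# logistic regression per item.

#' Quadrature grid for the latent trait
#'
#' Either equally spaced nodes on a symmetric interval with standard-normal
#' masses renormalized to one (the Bock-Aitkin convention, default), or
#' Gauss-Hermite nodes/weights transformed to the N(0, 1) density.
#'
#' @param n_nodes number of nodes (default 61).
#' @param type `"rectangular"` (default) or `"gauss_hermite"`.
#' @param bounds interval for the rectangular grid (default `c(-6, 6)`).
#' @return list with `nodes` (increasing) and `masses` (summing to 1).
#' @export
quadrature_grid <- function(n_nodes = 61L, type = c("rectangular", "gauss_hermite"),
                            bounds = c(-6, 6)) {
  type <- match.arg(type)
  if (type == "rectangular") {
    nodes <- seq(bounds[1], bounds[2], length.out = n_nodes)
    masses <- stats::dnorm(nodes)
    masses <- masses / sum(masses)
  } else {
    gh <- pracma::gaussHermite(n_nodes)
    nodes <- sqrt(2) * gh$x
    masses <- gh$w / sqrt(pi)
    masses <- masses / sum(masses)
  }
  list(nodes = nodes, masses = masses)
}

#' 2PL item response probability
#'
#' @param beta0 item intercept (logit scale).
#' @param beta1 item slope.
#' @param z latent trait value(s).
#' @return `plogis(beta0 + beta1 * z)`.
#' @examples
#' item_probability(0, 1, 0)           # 0.5
#' item_probability(-3.571, 1.340, 0)  # prevalence of an average-trait person
#' @export
item_probability <- function(beta0, beta1, z) {
  expit(beta0 + beta1 * z)
}

#' Item information function
#'
#' How much an item contributes to pinning down the latent trait at level
#' `z`: \eqn{I_i(z) = \beta_{1i}^2 p (1 - p)} with `p` the 2PL response
#' probability. Maximal, at value \eqn{\beta_{1i}^2/4}, where `p = 0.5`.
#'
#' @inheritParams item_probability
#' @return nonnegative information value(s).
#' @export
item_information <- function(beta0, beta1, z) {
  p <- item_probability(beta0, beta1, z)
  beta1^2 * p * (1 - p)
}

#' Degrees of freedom of the M2 limited-information statistic
#'
#' Univariate plus bivariate margins minus the free 2PL parameters:
#' `p + p(p-1)/2 - 2p`. For the five disease items this equals 5.
#'
#' @param n_items number of binary items, at least 3.
#' @return integer degrees of freedom.
#' @export
m2_degrees_of_freedom <- function(n_items) {
  n_items <- as.integer(n_items)
  if (length(n_items) != 1L || is.na(n_items) || n_items < 3L) {
    stop_config("M2 degrees of freedom require at least 3 items")
  }
  n_items + (n_items * (n_items - 1L)) %/% 2L - 2L * n_items
}

#' Rescale latent scores to the unit interval
#'
#' Affine map sending the sample minimum to 0 and the sample maximum to 1,
#' \eqn{y_j = (z_j - z_{(1)}) / (z_{(N)} - z_{(1)})}. Order preserving; the
#' zero point then corresponds to the least multimorbid response pattern.
#'
#' @param z numeric vector with at least two distinct values.
#' @return vector in `[0, 1]`.
#' @export
rescale_unit <- function(z) {
  if (!length(z) || any(!is.finite(z))) stop_config("scores must be finite")
  lo <- min(z)
  hi <- max(z)
  if (hi == lo) stop_config("cannot rescale a constant score vector")
  (z - lo) / (hi - lo)
}

# Collapse a binary response matrix into unique patterns with summed weights.
# Returns pattern matrix (patterns x items), total weight per pattern, and
# the index mapping rows to patterns.
collapse_patterns <- function(X, w) {
  key <- as.vector(X %*% 2^(seq_len(ncol(X)) - 1))
  idx <- match(key, sort(unique(key)))
  patterns <- rowsum(X, idx) / as.vector(table(idx))
  W <- as.vector(rowsum(w, idx))
  list(patterns = patterns, W = W, idx = idx)
}

# Pattern x node matrix of log conditional likelihoods given item params.
pattern_loglik <- function(patterns, beta0, beta1, nodes) {
  eta <- outer(beta1, nodes) + beta0          # items x nodes
  logp <- stats::plogis(eta, log.p = TRUE)
  logq <- stats::plogis(-eta, log.p = TRUE)
  patterns %*% logp + (1 - patterns) %*% logq # patterns x nodes
}

#' Fit the weighted 2PL latent trait model by EM
#'
#' Maximizes the weighted marginal log-likelihood
#' \deqn{\sum_j w_j \log \sum_q A_q \prod_i \pi_i(z_q)^{X_{ij}}
#'       (1-\pi_i(z_q))^{1-X_{ij}}}
#' over the item intercepts and slopes, where the nodes \eqn{z_q} and masses
#' \eqn{A_q} come from `grid`. The E-step computes per-pattern posterior
#' masses over nodes (weighted by `w`); the M-step is one Newton-solved
#' weighted logistic regression per item. Identification: the latent prior
#' is fixed at N(0, 1) and, after convergence, all slopes (and scores) are
#' flipped if their mean is negative.
#'
#' Standard errors come from the empirical cross-product of per-pattern
#' score contributions (Fisher's identity).
#'
#' @param X N x I binary matrix (or data frame) of disease indicators.
#' @param w positive sampling weights, length N (default all 1).
#' @param grid a [quadrature_grid()].
#' @param tol convergence tolerance on the max absolute parameter change.
#' @param max_iter maximum EM iterations.
#' @return object of class `latent_fit`: `item_params` (data frame with
#'   `disease`, `beta0`, `beta1`, `se_beta0`, `se_beta1`), `z` (EAP scores
#'   per respondent), `loglik`, `loglik_trace`, `iterations`, `converged`,
#'   `grid`.
#' @export
fit_weighted_2pl <- function(X, w = NULL, grid = quadrature_grid(),
                             tol = 1e-4, max_iter = 500L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  I <- ncol(X)
  if (n < 2L) stop_config("need at least two respondents")
  if (is.null(w)) w <- rep(1, n)
  if (length(w) != n || any(!is.finite(w)) || any(w <= 0)) {
    stop_config("weights must be strictly positive, one per respondent")
  }
  if (!all(X %in% c(0, 1))) stop_config("X must be binary")
  item_names <- colnames(X)
  if (is.null(item_names)) item_names <- paste0("item", seq_len(I))
  prev <- colSums(X * w) / sum(w)
  degenerate <- prev <= 0 | prev >= 1
  if (any(degenerate)) {
    stop_config(paste0(
      "item(s) without both responses observed: ",
      paste(item_names[degenerate], collapse = ", ")
    ))
  }

  cp <- collapse_patterns(X, w)
  patterns <- cp$patterns
  W <- cp$W
  nodes <- grid$nodes
  A <- grid$masses
  logA <- log(A)

  beta0 <- logit(prev)
  beta1 <- rep(1, I)
  loglik_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L

  repeat {
    iter <- iter + 1L
    ll_mat <- pattern_loglik(patterns, beta0, beta1, nodes)
    joint <- sweep(ll_mat, 2L, logA, "+")
    mx <- apply(joint, 1L, max)
    lik <- exp(joint - mx)
    marg <- rowSums(lik)
    loglik <- sum(W * (log(marg) + mx))
    loglik_trace <- c(loglik_trace, loglik)
    post <- lik / marg                      # patterns x nodes posteriors
    nq <- colSums(W * post)                 # expected counts per node
    old0 <- beta0
    old1 <- beta1
    for (i in seq_len(I)) {
      riq <- colSums(W * patterns[, i] * post)
      b <- newton_logistic(nodes, riq, nq, beta0[i], beta1[i])
      beta0[i] <- b[1]
      beta1[i] <- b[2]
    }
    delta <- max(abs(c(beta0 - old0, beta1 - old1)))
    if (delta < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  if (!converged) {
    warning("EM did not converge in ", max_iter,
            " iterations (last parameter change ", signif(delta, 3), ")")
  }
  # Sign identification: the trait direction is arbitrary in a 2PL.
  if (mean(beta1) < 0) beta1 <- -beta1

  ll_mat <- pattern_loglik(patterns, beta0, beta1, nodes)
  joint <- sweep(ll_mat, 2L, logA, "+")
  mx <- apply(joint, 1L, max)
  lik <- exp(joint - mx)
  marg <- rowSums(lik)
  loglik <- sum(W * (log(marg) + mx))
  post <- lik / marg

  # Empirical cross-product information from per-pattern score vectors
  # (Fisher identity: score of the marginal = posterior mean complete score).
  P <- expit(outer(beta1, nodes) + beta0)   # items x nodes
  n_pat <- nrow(patterns)
  scores <- matrix(0, n_pat, 2L * I)
  for (i in seq_len(I)) {
    resid <- post * (outer(patterns[, i], rep(1, length(nodes))) -
                       matrix(P[i, ], n_pat, length(nodes), byrow = TRUE))
    scores[, 2L * i - 1L] <- rowSums(resid)
    scores[, 2L * i] <- rowSums(sweep(resid, 2L, nodes, "*"))
  }
  info <- crossprod(scores * sqrt(W), scores * sqrt(W))
  ses <- rep(NA_real_, 2L * I)
  inv <- tryCatch(solve(info), error = function(e) NULL)
  if (!is.null(inv)) ses <- sqrt(pmax(diag(inv), 0))

  z_pat <- as.vector(post %*% nodes)
  fit <- list(
    item_params = data.frame(
      disease = item_names,
      beta0 = beta0,
      beta1 = beta1,
      se_beta0 = ses[seq(1L, 2L * I, by = 2L)],
      se_beta1 = ses[seq(2L, 2L * I, by = 2L)],
      stringsAsFactors = FALSE
    ),
    z = z_pat[cp$idx],
    loglik = loglik,
    loglik_trace = loglik_trace,
    iterations = iter,
    converged = converged,
    grid = grid,
    n = n
  )
  class(fit) <- "latent_fit"
  fit
}

# Newton iterations for one item's weighted logistic regression on the grid:
# maximize sum_q riq * log p_q + (nq - riq) * log(1 - p_q),
# p_q = plogis(b0 + b1 * z_q). Step-halving guards the ascent.
newton_logistic <- function(nodes, riq, nq, b0, b1, max_steps = 25L, tol = 1e-9) {
  obj <- function(b) {
    eta <- b[1] + b[2] * nodes
    sum(riq * stats::plogis(eta, log.p = TRUE) +
          (nq - riq) * stats::plogis(-eta, log.p = TRUE))
  }
  b <- c(b0, b1)
  f <- obj(b)
  for (s in seq_len(max_steps)) {
    p <- expit(b[1] + b[2] * nodes)
    g <- c(sum(riq - nq * p), sum((riq - nq * p) * nodes))
    v <- nq * p * (1 - p)
    H <- matrix(c(sum(v), sum(v * nodes), sum(v * nodes), sum(v * nodes^2)), 2L)
    step <- tryCatch(solve(H, g), error = function(e) g / max(diag(H)))
    repeat {
      b_new <- b + step
      f_new <- obj(b_new)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      step <- step / 2
      if (max(abs(step)) < 1e-12) {
        b_new <- b
        f_new <- f
        break
      }
    }
    moved <- max(abs(b_new - b))
    b <- b_new
    f <- f_new
    if (moved < tol) break
  }
  b
}

#' Expected a posteriori (EAP) latent scores
#'
#' Posterior mean of the latent trait given a response pattern, computed on
#' the quadrature grid under the fitted item parameters and the N(0, 1)
#' prior. Equal patterns always receive equal scores.
#'
#' @param X binary response matrix (or data frame).
#' @param item_params data frame with `beta0`, `beta1` (e.g. from a
#'   [fit_weighted_2pl()] fit).
#' @param grid a [quadrature_grid()].
#' @return numeric vector of scores, one per row of `X`.
#' @export
eap_scores <- function(X, item_params, grid = quadrature_grid()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  cp <- collapse_patterns(X, rep(1, nrow(X)))
  ll_mat <- pattern_loglik(cp$patterns, item_params$beta0, item_params$beta1, grid$nodes)
  joint <- sweep(ll_mat, 2L, log(grid$masses), "+")
  mx <- apply(joint, 1L, max)
  lik <- exp(joint - mx)
  post <- lik / rowSums(lik)
  z_pat <- as.vector(post %*% grid$nodes)
  z_pat[cp$idx]
}

#' @export
print.latent_fit <- function(x, ...) {
  cat("Weighted 2PL latent trait fit\n")
  cat("  respondents:", x$n, "  iterations:", x$iterations,
      "  converged:", x$converged, "\n")
  cat("  weighted marginal log-likelihood:", format(x$loglik, digits = 8), "\n\n")
  tab <- x$item_params
  tab$beta0 <- round(tab$beta0, 3)
  tab$beta1 <- round(tab$beta1, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Item parameter table in the conventional reporting layout
#'
#' Reports `-beta0` (so larger numbers mean rarer diseases) next to the
#' slope, mirroring the usual difficulty/discrimination presentation.
#'
#' @param fit a `latent_fit`.
#' @return data frame with columns `disease`, `neg_beta0`, `beta1`.
#' @export
item_param_table <- function(fit) {
  data.frame(
    disease = fit$item_params$disease,
    neg_beta0 = -fit$item_params$beta0,
    beta1 = fit$item_params$beta1,
    stringsAsFactors = FALSE
  )
}
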