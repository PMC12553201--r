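# Zero/one-inflated ordered beta regression with a regional random intercept.
#
# The rescaled multimorbidity index y in [0, 1] mixes point masses at 0 and 1
# with a Beta density on the interior. Two variants are provided:
#
#   * "hurdle" (default): the zero mass has its own coefficient vector (no
#     random effect); conditional on y > 0, the one mass is
#     expit(eta - k2 + u) and the interior carries a Beta(m * psi,
#     (1 - m) * psi) density with m = expit(eta + u). The three
#     probabilities sum to one by construction and the likelihood
#     factorizes exactly into a Bernoulli GLM for the zero part and a
#     conditional part on the nonzero subset.
#   * "canonical": the single-predictor ordered-cutpoint model with
#     Pr(y = 0) = 1 - expit(eta - k1 + u), Pr(y = 1) = expit(eta - k2 + u),
#     interior mass expit(eta - k1 + u) - expit(eta - k2 + u), k1 < k2.
#
# The regional random intercept u_k ~ N(0, sigma_u^2) is integrated out by a
# Laplace approximation (inner Newton on each region's mode plus a
# log-determinant correction); adaptive Gauss-Hermite quadrature is
# available as a cross-check.

#' Model specification for the ordered beta regression
#'
#' @param conditional two-sided formula for the conditional (nonzero) part;
#'   the left-hand side names the response.
#' @param zero one-sided formula for the zero part (hurdle variant only);
#'   defaults to the conditional right-hand side.
#' @param variant `"hurdle"` (default) or `"canonical"`.
#' @param random_effect `"region"` or `"none"`.
#' @param region_var name of the grouping column.
#' @return object of class `ordered_beta_spec`.
#' @export
ordered_beta_spec <- function(conditional = y ~ sex + age + economic + education +
                                year_c + sex:age,
                              zero = NULL,
                              variant = c("hurdle", "canonical"),
                              random_effect = c("region", "none"),
                              region_var = "region") {
  if (is.null(zero)) zero <- conditional[-2]
  spec <- list(
    conditional = conditional,
    zero = zero,
    variant = match.arg(variant),
    random_effect = match.arg(random_effect),
    region_var = region_var
  )
  class(spec) <- "ordered_beta_spec"
  spec
}

#' Probabilities of the three outcome components
#'
#' @param eta conditional linear predictor(s).
#' @param eta_zero zero-part linear predictor(s) (hurdle variant).
#' @param k1 lower cutpoint (canonical variant).
#' @param k2 upper cutpoint.
#' @param variant `"hurdle"` or `"canonical"`.
#' @return data frame with columns `pr0`, `pr_mid`, `pr1` summing to one.
#' @examples
#' component_probabilities(0, k1 = -1, k2 = 1, variant = "canonical")
#' @export
component_probabilities <- function(eta, eta_zero = NULL, k1 = NULL, k2,
                                    variant = c("hurdle", "canonical")) {
  variant <- match.arg(variant)
  if (variant == "canonical") {
    if (is.null(k1)) stop_config("canonical variant requires k1")
    if (any(k1 >= k2)) stop_config("cutpoints must satisfy k1 < k2")
    a1 <- expit(eta - k1)
    a2 <- expit(eta - k2)
    out <- data.frame(pr0 = 1 - a1, pr_mid = a1 - a2, pr1 = a2)
  } else {
    if (is.null(eta_zero)) stop_config("hurdle variant requires eta_zero")
    p0 <- expit(eta_zero)
    q <- expit(eta - k2)
    out <- data.frame(pr0 = p0, pr_mid = (1 - p0) * (1 - q), pr1 = (1 - p0) * q)
  }
  out
}

#' Interior Beta density of the ordered beta model
#'
#' Beta density in the mean/precision parameterization with mean
#' `m = expit(eta + u)` and precision `psi` (shapes `m * psi` and
#' `(1 - m) * psi`).
#'
#' @param y value(s) strictly inside (0, 1).
#' @param eta linear predictor.
#' @param u random-intercept value (default 0).
#' @param psi precision, positive.
#' @param log return log density?
#' @return density value(s).
#' @export
continuous_density <- function(y, eta, u = 0, psi, log = FALSE) {
  if (any(y <= 0 | y >= 1)) {
    stop_config("continuous_density is defined on the open interval (0, 1); point masses are handled by component_probabilities")
  }
  if (any(psi <= 0)) stop_config("precision psi must be positive")
  m <- expit(eta + u)
  stats::dbeta(y, m * psi, (1 - m) * psi, log = log)
}

# ---- internal likelihood machinery -----------------------------------------

MEAN_EPS <- 1e-10

# Per-observation conditional log-likelihood terms and first/second
# derivatives with respect to the region intercept u, hurdle variant
# (observations with y > 0 only).
hurdle_terms <- function(y, eta, k2, psi, u, deriv = TRUE) {
  one_mass <- is.finite(k2)
  ll <- numeric(length(y))
  d1 <- numeric(length(y))
  d2 <- numeric(length(y))
  is1 <- y == 1
  if (one_mass) {
    a <- eta - k2 + u
    s <- expit(a)
  } else {
    if (any(is1)) stop_config("observed ones are incompatible with a fit without a one mass")
    s <- numeric(length(y))
  }
  if (any(is1)) {
    ll[is1] <- stats::plogis(a[is1], log.p = TRUE)
    if (deriv) {
      d1[is1] <- 1 - s[is1]
      d2[is1] <- -s[is1] * (1 - s[is1])
    }
  }
  mid <- !is1
  if (any(mid)) {
    m <- pmin(pmax(expit(eta[mid] + u[mid]), MEAN_EPS), 1 - MEAN_EPS)
    ym <- y[mid]
    ll[mid] <- stats::dbeta(ym, m * psi, (1 - m) * psi, log = TRUE)
    if (one_mass) ll[mid] <- ll[mid] + stats::plogis(-a[mid], log.p = TRUE)
    if (deriv) {
      fp <- psi * (log(ym / (1 - ym)) - digamma(m * psi) + digamma((1 - m) * psi))
      fpp <- -psi^2 * (trigamma(m * psi) + trigamma((1 - m) * psi))
      mp <- m * (1 - m)
      mpp <- mp * (1 - 2 * m)
      sv <- s[mid]
      d1[mid] <- -sv + fp * mp
      d2[mid] <- -sv * (1 - sv) + fpp * mp^2 + fp * mpp
    }
  }
  list(ll = ll, d1 = d1, d2 = d2)
}

# log(exp(l1) - exp(l2)) for l1 > l2, stable.
log_diff_exp <- function(l1, l2) l1 + log1p(-exp(pmin(l2 - l1, -1e-16)))

# Canonical-variant per-observation terms (all observations).
canonical_terms <- function(y, eta, k1, k2, psi, u, deriv = TRUE) {
  a1 <- eta - k1 + u
  a2 <- eta - k2 + u
  s1 <- expit(a1)
  s2 <- expit(a2)
  ll <- numeric(length(y))
  d1 <- numeric(length(y))
  d2 <- numeric(length(y))
  is0 <- y == 0
  is1 <- y == 1
  mid <- !is0 & !is1
  if (any(is0)) {
    ll[is0] <- stats::plogis(-a1[is0], log.p = TRUE)
    if (deriv) {
      d1[is0] <- -s1[is0]
      d2[is0] <- -s1[is0] * (1 - s1[is0])
    }
  }
  if (any(is1)) {
    ll[is1] <- stats::plogis(a2[is1], log.p = TRUE)
    if (deriv) {
      d1[is1] <- 1 - s2[is1]
      d2[is1] <- -s2[is1] * (1 - s2[is1])
    }
  }
  if (any(mid)) {
    m <- pmin(pmax(expit(eta[mid] + u[mid]), MEAN_EPS), 1 - MEAN_EPS)
    ym <- y[mid]
    lmass <- log_diff_exp(stats::plogis(a1[mid], log.p = TRUE),
                          stats::plogis(a2[mid], log.p = TRUE))
    ll[mid] <- lmass + stats::dbeta(ym, m * psi, (1 - m) * psi, log = TRUE)
    if (deriv) {
      v <- s1[mid] - s2[mid]
      vp <- s1[mid] * (1 - s1[mid]) - s2[mid] * (1 - s2[mid])
      vpp <- s1[mid] * (1 - s1[mid]) * (1 - 2 * s1[mid]) -
        s2[mid] * (1 - s2[mid]) * (1 - 2 * s2[mid])
      fp <- psi * (log(ym / (1 - ym)) - digamma(m * psi) + digamma((1 - m) * psi))
      fpp <- -psi^2 * (trigamma(m * psi) + trigamma((1 - m) * psi))
      mp <- m * (1 - m)
      mpp <- mp * (1 - 2 * m)
      d1[mid] <- vp / v + fp * mp
      d2[mid] <- vpp / v - (vp / v)^2 + fpp * mp^2 + fp * mpp
    }
  }
  list(ll = ll, d1 = d1, d2 = d2)
}

# Laplace-approximate negative marginal log-likelihood of the random-effect
# part. `term_fun(u_obs, deriv)` returns per-observation ll/d1/d2 given each
# observation's u; `reg` is an integer region index 1..K; `w` observation
# weights. Returns the negloglik, region modes, and curvatures.
laplace_part <- function(term_fun, reg, K, sigma2, w, u_start = NULL,
                         max_iter = 60L, tol = 1e-9) {
  u <- if (is.null(u_start)) numeric(K) else u_start
  summarize <- function(u) {
    t <- term_fun(u[reg], deriv = TRUE)
    tmp <- rowsum(cbind(w * t$ll, w * t$d1, w * t$d2), reg)
    ridx <- as.integer(rownames(tmp))
    Fk <- G1 <- G2 <- numeric(K)
    Fk[ridx] <- tmp[, 1]
    G1[ridx] <- tmp[, 2]
    G2[ridx] <- tmp[, 3]
    list(F = Fk - u^2 / (2 * sigma2), G1 = G1 - u / sigma2, G2 = G2)
  }
  s <- summarize(u)
  for (it in seq_len(max_iter)) {
    if (max(abs(s$G1)) < tol) break
    d2F <- pmin(s$G2 - 1 / sigma2, -1e-8)
    step <- -s$G1 / d2F
    # per-region step halving keeps the inner ascent monotone
    for (h in 0:30) {
      u_new <- u + step
      s_new <- summarize(u_new)
      bad <- s_new$F < s$F - 1e-12
      if (!any(bad)) break
      step[bad] <- step[bad] / 2
    }
    moved <- max(abs(u_new - u))
    u <- u_new
    s <- s_new
    if (moved < tol) break
  }
  # log-determinant correction: 0.5 * log(sigma2 * H) = 0.5 * log1p(-sigma2 * G2)
  corr <- 0.5 * log1p(pmax(-sigma2 * s$G2, -1 + 1e-12))
  nll <- -sum(s$F) + sum(corr)
  list(nll = nll, u = u, H = 1 / sigma2 - s$G2)
}

# Adaptive Gauss-Hermite cross-check for the same marginal likelihood.
ghq_part <- function(term_fun, reg, K, sigma2, w, n_nodes = 15L) {
  lap <- laplace_part(term_fun, reg, K, sigma2, w)
  gh <- pracma::gaussHermite(n_nodes)
  nll <- 0
  for (k in seq_len(K)) {
    obs <- which(reg == k)
    H <- lap$H[k]
    delta <- sqrt(2 / H)
    ut <- lap$u[k] + delta * gh$x
    lf <- vapply(ut, function(uu) {
      uvec <- rep(uu, length(obs))
      t <- term_fun_subset(term_fun, reg, obs, uvec)
      sum(w[obs] * t) + stats::dnorm(uu, 0, sqrt(sigma2), log = TRUE)
    }, numeric(1))
    lw <- log(gh$w) + gh$x^2 + lf + log(delta)
    mx <- max(lw)
    nll <- nll - (mx + log(sum(exp(lw - mx))))
  }
  list(nll = nll, u = lap$u, H = lap$H)
}

# Evaluate term_fun's log-likelihood on a subset of observations. term_fun
# closes over full-length data vectors indexed by observation; we pass a
# full-length u with the subset's value and extract the subset.
term_fun_subset <- function(term_fun, reg, obs, uvec) {
  u_all <- numeric(length(reg))
  u_all[obs] <- uvec
  t <- term_fun(u_all, deriv = FALSE)
  t$ll[obs]
}

# Assemble design matrices and response from data + spec.
build_designs <- function(data, spec) {
  resp_var <- all.vars(spec$conditional[[2]])
  if (!resp_var %in% names(data)) {
    stop_config(paste0("response '", resp_var, "' not found in data"))
  }
  y <- data[[resp_var]]
  if (any(!is.finite(y)) || any(y < 0 | y > 1)) {
    stop_config("response values must lie in [0, 1]")
  }
  mf_c <- stats::model.frame(stats::delete.response(stats::terms(spec$conditional, data = data)), data)
  Xc <- stats::model.matrix(attr(mf_c, "terms"), mf_c)
  xlev_c <- stats::.getXlevels(attr(mf_c, "terms"), mf_c)
  if (spec$variant == "hurdle") {
    mf_z <- stats::model.frame(stats::terms(spec$zero, data = data), data)
    Xz <- stats::model.matrix(attr(mf_z, "terms"), mf_z)
    xlev_z <- stats::.getXlevels(attr(mf_z, "terms"), mf_z)
    terms_z <- attr(mf_z, "terms")
  } else {
    Xz <- NULL
    xlev_z <- NULL
    terms_z <- NULL
  }
  if (spec$random_effect == "region") {
    if (!spec$region_var %in% names(data)) {
      stop_config(paste0("grouping column '", spec$region_var, "' not found"))
    }
    region <- factor(data[[spec$region_var]])
  } else {
    region <- factor(rep(1L, length(y)))
  }
  list(
    y = y, Xc = Xc, Xz = Xz, region = region,
    terms_c = attr(mf_c, "terms"), xlev_c = xlev_c,
    terms_z = terms_z, xlev_z = xlev_z
  )
}

#' Negative marginal log-likelihood of the ordered beta model
#'
#' Computes the full-data negative log-likelihood at given natural-scale
#' parameters. With a regional random effect the per-region contribution
#' integrates over `u_k ~ N(0, sigma_u^2)` by a Laplace approximation
#' (`method = "laplace"`), or by adaptive Gauss-Hermite quadrature around
#' the Laplace mode (`method = "ghq"`) as a numerical cross-check.
#'
#' @param params named list: `beta` (conditional coefficients in design
#'   order), `beta_zero` (hurdle), `k1` (canonical), `k2`, `psi`,
#'   `sigma_u` (if `random_effect = "region"`).
#' @param data data frame containing the response and covariates.
#' @param spec an [ordered_beta_spec()].
#' @param method `"laplace"` or `"ghq"`.
#' @param n_ghq number of quadrature nodes for `"ghq"`.
#' @param weights optional positive observation weights.
#' @return the negative log-likelihood (scalar).
#' @export
marginal_negloglik <- function(params, data, spec = ordered_beta_spec(),
                               method = c("laplace", "ghq"), n_ghq = 15L,
                               weights = NULL) {
  method <- match.arg(method)
  d <- build_designs(data, spec)
  n <- length(d$y)
  w <- if (is.null(weights)) rep(1, n) else weights
  nll <- 0
  if (spec$variant == "hurdle") {
    eta_z <- as.vector(d$Xz %*% params$beta_zero)
    z_ind <- as.numeric(d$y == 0)
    nll <- nll - sum(w * (z_ind * stats::plogis(eta_z, log.p = TRUE) +
                            (1 - z_ind) * stats::plogis(-eta_z, log.p = TRUE)))
    nz <- d$y > 0
    if (any(nz)) {
      eta <- as.vector(d$Xc[nz, , drop = FALSE] %*% params$beta)
      ynz <- d$y[nz]
      wnz <- w[nz]
      if (spec$random_effect == "region") {
        reg <- as.integer(d$region)[nz]
        K <- nlevels(d$region)
        tf <- function(u_obs, deriv) hurdle_terms(ynz, eta, params$k2, params$psi, u_obs, deriv)
        part <- if (method == "laplace") {
          laplace_part(tf, reg, K, params$sigma_u^2, wnz)
        } else {
          ghq_part(tf, reg, K, params$sigma_u^2, wnz, n_ghq)
        }
        nll <- nll + part$nll
      } else {
        t <- hurdle_terms(ynz, eta, params$k2, params$psi, rep(0, sum(nz)), deriv = FALSE)
        nll <- nll - sum(wnz * t$ll)
      }
    }
  } else {
    if (params$k1 >= params$k2) stop_config("cutpoints must satisfy k1 < k2")
    eta <- as.vector(d$Xc %*% params$beta)
    if (spec$random_effect == "region") {
      reg <- as.integer(d$region)
      K <- nlevels(d$region)
      tf <- function(u_obs, deriv) canonical_terms(d$y, eta, params$k1, params$k2,
                                                   params$psi, u_obs, deriv)
      part <- if (method == "laplace") {
        laplace_part(tf, reg, K, params$sigma_u^2, w)
      } else {
        ghq_part(tf, reg, K, params$sigma_u^2, w, n_ghq)
      }
      nll <- nll + part$nll
    } else {
      t <- canonical_terms(d$y, eta, params$k1, params$k2, params$psi,
                           rep(0, n), deriv = FALSE)
      nll <- nll - sum(w * t$ll)
    }
  }
  nll
}

# Quasi-Newton minimization with parameter scaling and one polishing
# restart (clears spurious "singular convergence" exits on flat ridges).
minimize_nll <- function(fn, theta0, maxit, reltol) {
  scale <- 1 / pmax(0.01, abs(theta0))
  ctl <- list(iter.max = maxit, eval.max = 4L * maxit, rel.tol = reltol)
  opt <- stats::nlminb(theta0, fn, gradient = function(th) num_grad(fn, th),
                       scale = scale, control = ctl)
  opt2 <- stats::nlminb(opt$par, fn, gradient = function(th) num_grad(fn, th),
                        scale = 1 / pmax(0.01, abs(opt$par)), control = ctl)
  if (opt2$objective <= opt$objective) {
    opt2$iterations <- opt$iterations + opt2$iterations
    opt2
  } else {
    opt
  }
}

scaled_grad_crit <- function(g, theta, f) {
  max(abs(g) * pmax(1, abs(theta))) / max(1, abs(f))
}

# Damped Newton polish after the quasi-Newton phase: collinear designs leave
# long flat valleys where nlminb exits early; a few full Newton steps push
# the scaled gradient below tolerance. Returns the final point together with
# the gradient and the Hessian (reused for standard errors).
newton_polish <- function(fn, theta, f, max_steps = 3L, crit = 1e-5) {
  g <- num_grad(fn, theta)
  H <- NULL
  for (s in seq_len(max_steps)) {
    if (scaled_grad_crit(g, theta, f) < crit) break
    H <- num_hess(fn, theta)
    step <- tryCatch(-solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    improved <- FALSE
    for (h in 0:20) {
      theta_new <- theta + step
      f_new <- fn(theta_new)
      if (is.finite(f_new) && f_new <= f + 1e-10) {
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) break
    theta <- theta_new
    f <- f_new
    g <- num_grad(fn, theta)
    H <- NULL
  }
  if (is.null(H)) H <- num_hess(fn, theta)
  list(par = theta, objective = f, grad = g, hess = H)
}

num_grad <- function(f, x, h = NULL) {
  if (is.null(h)) h <- 1e-6 * pmax(1, abs(x))
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    e <- numeric(length(x))
    e[i] <- h[i]
    g[i] <- (f(x + e) - f(x - e)) / (2 * h[i])
  }
  g
}

num_hess <- function(f, x, h = NULL) {
  p <- length(x)
  if (is.null(h)) h <- 1e-4 * pmax(1, abs(x))
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    for (j in seq_len(p)) {
      if (j >= i) next
      ej <- numeric(p); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

#' Fit the ordered beta regression
#'
#' Maximum-likelihood estimation of the zero/one-inflated ordered beta
#' regression defined by `spec`. The hurdle variant factorizes exactly: the
#' zero part is a Bernoulli GLM on the indicator `y == 0` (fit by
#' [stats::glm()]); the conditional part (one-mass plus interior Beta, with
#' the optional regional random intercept integrated out by Laplace) is
#' maximized by quasi-Newton from documented starting values (cutpoint
#' `k2 = 1`, canonical `k1 = -1`; `beta` from a logit-least-squares warm
#' start on the interior values; `psi = 5`; `sigma_u = 0.1`). The canonical
#' variant is maximized jointly with the ordering enforced via
#' `k2 = k1 + exp(delta)`. Standard errors come from a central-difference
#' Hessian at the optimum; rows are sorted canonically before fitting so
#' the result is invariant to input row order.
#'
#' @param data data frame with the response, covariates, and grouping column.
#' @param spec an [ordered_beta_spec()].
#' @param weights optional positive observation weights (off by default:
#'   the disability-derived weights apply to the measurement model, not to
#'   this stage).
#' @param boundary what to do when a point-mass component has no
#'   observations: `"error"` (default) or, for the hurdle variant,
#'   `"reduce"` — drop the unobserved mass (its probability is fixed at
#'   zero, the maximum-likelihood limit), which is how the per-risk-class
#'   refits handle strata that contain no exact ones.
#' @param control list: `maxit`, `reltol` passed to the optimizer.
#' @return object of class `ordered_beta_fit`.
#' @export
fit_ordered_beta <- function(data, spec = ordered_beta_spec(), weights = NULL,
                             boundary = c("error", "reduce"), control = list()) {
  boundary <- match.arg(boundary)
  ctrl <- utils::modifyList(list(maxit = 500L, reltol = 1e-12), control)
  d <- build_designs(data, spec)
  n <- length(d$y)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(!is.finite(w)) || any(w <= 0)) {
    stop_config("weights must be strictly positive, one per observation")
  }

  has0 <- any(d$y == 0)
  has1 <- any(d$y == 1)
  hasmid <- any(d$y > 0 & d$y < 1)
  if (!hasmid || ((boundary == "error" || spec$variant == "canonical") &&
                  !(has0 && has1))) {
    stop_config(paste(
      "the response must contain zeros, ones, and interior values;",
      "fit a reduced model (plain beta regression or a binary model)",
      "for the components actually observed, or use boundary = 'reduce'",
      "with the hurdle variant"
    ))
  }
  one_mass <- has1
  zero_part <- has0

  # Canonical row order: estimates must not depend on how rows arrive.
  ord <- do.call(order, c(list(as.integer(d$region), d$y),
                          lapply(seq_len(ncol(d$Xc)), function(j) d$Xc[, j])))
  y <- d$y[ord]
  Xc <- d$Xc[ord, , drop = FALSE]
  Xz <- if (!is.null(d$Xz)) d$Xz[ord, , drop = FALSE]
  region <- droplevels(d$region[ord])
  w <- w[ord]
  K <- nlevels(region)
  pc <- ncol(Xc)

  # Warm start for beta: least squares on the logit of squeezed interior values.
  mid <- y > 0 & y < 1
  y_sq <- pmin(pmax(y[mid], 0.001), 0.999)
  beta_start <- tryCatch(
    unname(stats::lm.wfit(Xc[mid, , drop = FALSE], logit(y_sq), w[mid])$coefficients),
    error = function(e) rep(0, pc)
  )
  beta_start[!is.finite(beta_start)] <- 0

  zero_fit <- NULL
  if (spec$variant == "hurdle") {
    beta_zero <- NULL
    se_zero <- NULL
    zero_dev_ll <- 0
    if (zero_part) {
      z_ind <- as.numeric(y == 0)
      zero_fit <- withCallingHandlers(
        stats::glm.fit(Xz, z_ind, weights = w, family = stats::binomial()),
        warning = function(cnd) {
          if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(cnd))) {
            warning("possible separation in the zero part: some fitted zero probabilities are numerically 0 or 1",
                    call. = FALSE)
            invokeRestart("muffleWarning")
          }
        }
      )
      beta_zero <- stats::setNames(zero_fit$coefficients, colnames(Xz))
      qr_z <- zero_fit$qr
      vz <- tryCatch(chol2inv(qr_z$qr[seq_len(qr_z$rank), seq_len(qr_z$rank), drop = FALSE]),
                     error = function(e) matrix(NA_real_, ncol(Xz), ncol(Xz)))
      se_zero <- sqrt(pmax(diag(vz), 0))
      zero_dev_ll <- -zero_fit$deviance / 2
    }
    nz <- y > 0
    ynz <- y[nz]
    eta_base <- Xc[nz, , drop = FALSE]
    wnz <- w[nz]
    reg <- as.integer(region)[nz]
    re <- spec$random_effect == "region"
    # Parameter layout: beta, [k2 if the one mass is present], log psi,
    # [log sigma_u if the random effect is present].
    i_k2 <- if (one_mass) pc + 1L else 0L
    i_psi <- pc + 1L + as.integer(one_mass)
    i_sig <- i_psi + 1L
    ucache <- new.env(parent = emptyenv())
    ucache$u <- numeric(K)
    nll_cond <- function(theta) {
      beta <- theta[seq_len(pc)]
      k2 <- if (one_mass) theta[i_k2] else Inf
      psi <- exp(theta[i_psi])
      eta <- as.vector(eta_base %*% beta)
      if (re) {
        sigma2 <- exp(theta[i_sig])^2
        tf <- function(u_obs, deriv) hurdle_terms(ynz, eta, k2, psi, u_obs, deriv)
        part <- laplace_part(tf, reg, K, sigma2, wnz, u_start = ucache$u)
        ucache$u <- part$u
        part$nll
      } else {
        t <- hurdle_terms(ynz, eta, k2, psi, rep(0, length(ynz)), deriv = FALSE)
        -sum(wnz * t$ll)
      }
    }
    theta0 <- c(beta_start, if (one_mass) 1, log(5), if (re) log(0.1))
    opt <- minimize_nll(nll_cond, theta0, ctrl$maxit, ctrl$reltol)
    pol <- newton_polish(nll_cond, opt$par, opt$objective)
    theta <- pol$par
    nll_val <- pol$objective
    grad <- pol$grad
    converged <- scaled_grad_crit(grad, theta, nll_val) < 1e-5
    if (!converged) {
      warning("optimizer did not reach the scaled gradient tolerance; treat estimates with caution",
              call. = FALSE)
    }
    vcov_c <- tryCatch(solve(pol$hess),
                       error = function(e) matrix(NA_real_, length(theta), length(theta)))
    se <- sqrt(pmax(diag(vcov_c), 0))

    beta <- stats::setNames(theta[seq_len(pc)], colnames(Xc))
    k2 <- if (one_mass) theta[i_k2] else Inf
    psi <- exp(theta[i_psi])
    sigma_u <- if (re) exp(theta[i_sig]) else NA_real_
    # Region modes and curvature at the optimum for BLUPs.
    u_hat <- numeric(K)
    u_sd <- rep(NA_real_, K)
    if (re) {
      eta <- as.vector(eta_base %*% beta)
      tf <- function(u_obs, deriv) hurdle_terms(ynz, eta, k2, psi, u_obs, deriv)
      part <- laplace_part(tf, reg, K, sigma_u^2, wnz, u_start = ucache$u)
      u_hat <- part$u
      u_sd <- 1 / sqrt(part$H)
    }
    loglik <- zero_dev_ll - nll_val

    fit <- list(
      spec = spec,
      beta = beta,
      se_beta = se[seq_len(pc)],
      beta_zero = beta_zero,
      se_beta_zero = se_zero,
      k1 = NA_real_,
      k2 = k2,
      se_k2 = if (one_mass) se[i_k2] else NA_real_,
      psi = psi,
      se_log_psi = se[i_psi],
      sigma_u = sigma_u,
      se_log_sigma_u = if (re) se[i_sig] else NA_real_,
      u = stats::setNames(u_hat, levels(region)),
      u_sd = stats::setNames(u_sd, levels(region)),
      loglik = loglik,
      loglik_conditional = -nll_val,
      loglik_zero = zero_dev_ll,
      converged = converged && (is.null(zero_fit) || zero_fit$converged),
      n = n,
      n_nonzero = sum(nz),
      terms_c = d$terms_c, xlev_c = d$xlev_c,
      terms_z = d$terms_z, xlev_z = d$xlev_z,
      region_levels = levels(region),
      optim = list(iterations = opt$iterations, message = opt$message,
                   grad_norm = max(abs(grad)))
    )
  } else {
    re <- spec$random_effect == "region"
    reg <- as.integer(region)
    ucache <- new.env(parent = emptyenv())
    ucache$u <- numeric(K)
    nll_full <- function(theta) {
      beta <- theta[seq_len(pc)]
      k1 <- theta[pc + 1L]
      k2 <- k1 + exp(theta[pc + 2L])
      psi <- exp(theta[pc + 3L])
      eta <- as.vector(Xc %*% beta)
      if (re) {
        sigma2 <- exp(theta[pc + 4L])^2
        tf <- function(u_obs, deriv) canonical_terms(y, eta, k1, k2, psi, u_obs, deriv)
        part <- laplace_part(tf, reg, K, sigma2, w, u_start = ucache$u)
        ucache$u <- part$u
        part$nll
      } else {
        t <- canonical_terms(y, eta, k1, k2, psi, rep(0, n), deriv = FALSE)
        -sum(w * t$ll)
      }
    }
    theta0 <- c(beta_start, -1, log(2), log(5), if (re) log(0.1))
    opt <- minimize_nll(nll_full, theta0, ctrl$maxit, ctrl$reltol)
    pol <- newton_polish(nll_full, opt$par, opt$objective)
    theta <- pol$par
    grad <- pol$grad
    converged <- scaled_grad_crit(grad, theta, pol$objective) < 1e-5
    if (!converged) {
      warning("optimizer did not reach the scaled gradient tolerance; treat estimates with caution",
              call. = FALSE)
    }
    vcov_c <- tryCatch(solve(pol$hess),
                       error = function(e) matrix(NA_real_, length(theta), length(theta)))
    se <- sqrt(pmax(diag(vcov_c), 0))
    beta <- stats::setNames(theta[seq_len(pc)], colnames(Xc))
    k1 <- theta[pc + 1L]
    k2 <- k1 + exp(theta[pc + 2L])
    psi <- exp(theta[pc + 3L])
    sigma_u <- if (re) exp(theta[pc + 4L]) else NA_real_
    u_hat <- numeric(K)
    u_sd <- rep(NA_real_, K)
    if (re) {
      eta <- as.vector(Xc %*% beta)
      tf <- function(u_obs, deriv) canonical_terms(y, eta, k1, k2, psi, u_obs, deriv)
      part <- laplace_part(tf, reg, K, sigma_u^2, w, u_start = ucache$u)
      u_hat <- part$u
      u_sd <- 1 / sqrt(part$H)
    }
    fit <- list(
      spec = spec,
      beta = beta,
      se_beta = se[seq_len(pc)],
      beta_zero = NULL,
      se_beta_zero = NULL,
      k1 = k1,
      k2 = k2,
      se_k2 = NA_real_,
      psi = psi,
      se_log_psi = se[pc + 3L],
      sigma_u = sigma_u,
      se_log_sigma_u = if (re) se[pc + 4L] else NA_real_,
      u = stats::setNames(u_hat, levels(region)),
      u_sd = stats::setNames(u_sd, levels(region)),
      loglik = -pol$objective,
      loglik_conditional = -pol$objective,
      loglik_zero = NA_real_,
      converged = converged,
      n = n,
      n_nonzero = sum(y > 0),
      terms_c = d$terms_c, xlev_c = d$xlev_c,
      terms_z = d$terms_z, xlev_z = d$xlev_z,
      region_levels = levels(region),
      optim = list(iterations = opt$iterations, message = opt$message,
                   grad_norm = max(abs(grad)))
    )
  }
  class(fit) <- "ordered_beta_fit"
  fit
}

#' @export
logLik.ordered_beta_fit <- function(object, ...) {
  val <- object$loglik
  attr(val, "df") <- length(object$beta) + length(object$beta_zero) +
    sum(!is.na(c(object$k1, object$k2))) + 1L +
    as.integer(object$spec$random_effect == "region")
  class(val) <- "logLik"
  val
}

#' @export
coef.ordered_beta_fit <- function(object, component = c("conditional", "zero"), ...) {
  component <- match.arg(component)
  if (component == "conditional") object$beta else object$beta_zero
}

#' Coefficient tables in the two-block reporting layout
#'
#' @param object an `ordered_beta_fit`.
#' @param ... unused.
#' @return list with data frames `conditional` and `zero_inflation`
#'   (columns Estimate, Std. Error, t value, p value).
#' @export
summary.ordered_beta_fit <- function(object, ...) {
  mk <- function(est, se) {
    t <- est / se
    data.frame(
      Estimate = est, `Std. Error` = se, `t value` = t,
      `p value` = 2 * stats::pnorm(-abs(t)),
      check.names = FALSE, row.names = names(est)
    )
  }
  out <- list(
    variant = object$spec$variant,
    conditional = mk(object$beta, object$se_beta),
    zero_inflation = if (!is.null(object$beta_zero)) {
      mk(object$beta_zero, object$se_beta_zero)
    },
    cutpoints = c(k1 = object$k1, k2 = object$k2),
    psi = object$psi,
    sigma_u = object$sigma_u,
    loglik = object$loglik,
    converged = object$converged,
    n = object$n
  )
  class(out) <- "summary.ordered_beta_fit"
  out
}

#' @export
print.summary.ordered_beta_fit <- function(x, digits = 4, ...) {
  cat("Ordered beta regression (", x$variant, " variant), n = ", x$n, "\n", sep = "")
  cat("Conditional model\n")
  print(round(x$conditional, digits))
  if (!is.null(x$zero_inflation)) {
    cat("\nZero-inflation model\n")
    print(round(x$zero_inflation, digits))
  }
  cat("\ncutpoints:", paste(format(x$cutpoints[!is.na(x$cutpoints)], digits = digits),
                            collapse = " "),
      "  psi:", format(x$psi, digits = digits))
  if (!is.na(x$sigma_u)) cat("  sigma_u:", format(x$sigma_u, digits = digits))
  cat("\nlog-likelihood:", format(x$loglik, digits = 8),
      "  converged:", x$converged, "\n")
  invisible(x)
}

#' @export
print.ordered_beta_fit <- function(x, ...) {
  print(summary(x), ...)
  invisible(x)
}

#' Population-level predictions
#'
#' Combines the zero and conditional components with all random effects set
#' to zero: \eqn{\hat y = (1 - \hat\gamma) \hat\mu}, where \eqn{\hat\gamma}
#' is the zero probability and \eqn{\hat\mu} the expected index conditional
#' on a nonzero outcome (the one-mass times 1 plus the interior mass times
#' the Beta mean, renormalized).
#'
#' @param fit an `ordered_beta_fit`.
#' @param profiles data frame of covariate profiles (factor levels must
#'   match the fitted design).
#' @return `profiles` with columns `gamma_hat`, `mu_hat`, `y_hat` appended.
#' @export
predict_population <- function(fit, profiles) {
  mf_c <- stats::model.frame(stats::delete.response(fit$terms_c), profiles,
                             xlev = fit$xlev_c)
  Xc <- stats::model.matrix(stats::delete.response(fit$terms_c), mf_c)
  eta <- as.vector(Xc %*% fit$beta)
  if (fit$spec$variant == "hurdle") {
    if (!is.null(fit$beta_zero)) {
      mf_z <- stats::model.frame(fit$terms_z, profiles, xlev = fit$xlev_z)
      Xz <- stats::model.matrix(fit$terms_z, mf_z)
      gamma <- expit(as.vector(Xz %*% fit$beta_zero))
    } else {
      gamma <- rep(0, length(eta))
    }
    q1 <- if (is.finite(fit$k2)) expit(eta - fit$k2) else rep(0, length(eta))
    m <- expit(eta)
    mu <- q1 + (1 - q1) * m
  } else {
    pr <- component_probabilities(eta, k1 = fit$k1, k2 = fit$k2, variant = "canonical")
    gamma <- pr$pr0
    m <- expit(eta)
    mu <- (pr$pr1 + pr$pr_mid * m) / (pr$pr1 + pr$pr_mid)
  }
  out <- profiles
  out$gamma_hat <- gamma
  out$mu_hat <- mu
  out$y_hat <- (1 - gamma) * mu
  out
}

#' Empirical Bayes (BLUP-style) regional predictions
#'
#' Returns the mode of each region's random intercept given the data and the
#' estimated parameters, with the approximate conditional standard
#' deviation from the Laplace curvature.
#'
#' @param fit an `ordered_beta_fit` with `random_effect = "region"`.
#' @return data frame with columns `region`, `estimate`, `sd`.
#' @export
blup <- function(fit) {
  if (fit$spec$random_effect != "region") {
    stop_config("BLUPs require a fit with random_effect = 'region'")
  }
  data.frame(
    region = fit$region_levels,
    estimate = as.numeric(fit$u),
    sd = as.numeric(fit$u_sd),
    stringsAsFactors = FALSE
  )
}

#' Simulate from the ordered beta model
#'
#' Draws survey-style covariates (sex, age 18-69, economic status,
#' education, survey year with `year_c = year - min(year)`), regions
#' `1..K`, regional intercepts `u_k ~ N(0, sigma_u^2)`, and an outcome from
#' the hurdle or canonical ordered beta model. Coefficient vectors are in
#' the order of the default design: intercept, sex (male), age, economic
#' (none), education (high), year_c, male:age.
#'
#' @param n sample size.
#' @param K number of regions.
#' @param beta conditional coefficients (length 7).
#' @param beta_zero zero-part coefficients (hurdle; length 7).
#' @param k1 lower cutpoint (canonical).
#' @param k2 upper cutpoint.
#' @param psi Beta precision.
#' @param sigma_u regional random-intercept sd.
#' @param years survey years to sample from.
#' @param variant `"hurdle"` or `"canonical"`.
#' @param seed RNG seed.
#' @return data frame with covariates, `region`, `u_true`, and response `y`.
#' @export
simulate_ordered_beta <- function(n, K = 19L, beta, beta_zero = NULL,
                                  k1 = NULL, k2, psi, sigma_u = 0,
                                  years = 2008:2019,
                                  variant = c("hurdle", "canonical"),
                                  seed = 1L) {
  variant <- match.arg(variant)
  with_seed(seed, {
    region <- sample.int(K, n, replace = TRUE)
    sex <- factor(sample(c("female", "male"), n, TRUE), levels = c("female", "male"))
    age <- sample(18:69, n, TRUE)
    economic <- factor(sample(c("difficulties", "none"), n, TRUE),
                       levels = c("difficulties", "none"))
    education <- factor(sample(c("low", "high"), n, TRUE), levels = c("low", "high"))
    year <- sample(years, n, TRUE)
    year_c <- year - min(years)
    X <- cbind(1, sex == "male", age, economic == "none", education == "high",
               year_c, (sex == "male") * age)
    u <- if (sigma_u > 0) stats::rnorm(K, 0, sigma_u) else numeric(K)
    eta <- as.vector(X %*% beta)
    y <- numeric(n)
    if (variant == "hurdle") {
      p0 <- expit(as.vector(X %*% beta_zero))
      is0 <- stats::runif(n) < p0
      q1 <- expit(eta - k2 + u[region])
      is1 <- !is0 & stats::runif(n) < q1
      mid <- !is0 & !is1
      m <- expit(eta[mid] + u[region[mid]])
      y[is1] <- 1
      y[mid] <- stats::rbeta(sum(mid), m * psi, (1 - m) * psi)
    } else {
      pr <- component_probabilities(eta + u[region], k1 = k1, k2 = k2,
                                    variant = "canonical")
      v <- stats::runif(n)
      is0 <- v < pr$pr0
      is1 <- v >= pr$pr0 + pr$pr_mid
      mid <- !is0 & !is1
      m <- expit(eta[mid] + u[region[mid]])
      y[is1] <- 1
      y[mid] <- stats::rbeta(sum(mid), m * psi, (1 - m) * psi)
    }
    # Interior draws can round to exactly 0/1 in double precision; nudge them
    # back inside so the simulated component membership is preserved.
    y[mid & y == 0] <- 1e-12
    y[mid & y == 1] <- 1 - 1e-12
    data.frame(
      y = y, sex = sex, age = age, economic = economic, education = education,
      year = year, year_c = year_c, region = region, u_true = u[region],
      stringsAsFactors = FALSE
    )
  })
}
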