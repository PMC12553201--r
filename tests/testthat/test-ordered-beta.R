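test_that("component probabilities sum to one and match logistic evaluations", {
  pr <- component_probabilities(0, k1 = -1, k2 = 1, variant = "canonical")
  expect_equal(pr$pr0, 1 - plogis(1), tolerance = 1e-10)
  expect_equal(pr$pr1, plogis(-1), tolerance = 1e-10)
  expect_equal(pr$pr0, 0.26894, tolerance = 1e-4)
  expect_equal(pr$pr_mid, 0.46212, tolerance = 1e-4)
  set.seed(1)
  for (r in 1:50) {
    eta <- rnorm(1, 0, 2)
    k1 <- rnorm(1)
    k2 <- k1 + rexp(1)
    prc <- component_probabilities(eta, k1 = k1, k2 = k2, variant = "canonical")
    expect_equal(prc$pr0 + prc$pr_mid + prc$pr1, 1, tolerance = 1e-12)
    prh <- component_probabilities(eta, eta_zero = rnorm(1), k2 = k2, variant = "hurdle")
    expect_equal(prh$pr0 + prh$pr_mid + prh$pr1, 1, tolerance = 1e-12)
  }
  expect_error(component_probabilities(0, k1 = 1, k2 = 0, variant = "canonical"),
               "k1 < k2")
  # vanished zero mass: remaining mass splits by expit(eta - k2)
  pr <- component_probabilities(0.4, eta_zero = -40, k2 = 1.2, variant = "hurdle")
  expect_equal(pr$pr0, 0, tolerance = 1e-12)
  expect_equal(pr$pr1, plogis(0.4 - 1.2), tolerance = 1e-10)
})

test_that("a hurdle parameterization can reproduce any canonical probability triple", {
  eta <- 0.7; k1 <- -0.8; k2 <- 1.4
  can <- component_probabilities(eta, k1 = k1, k2 = k2, variant = "canonical")
  A <- plogis(eta - k1); B <- plogis(eta - k2)
  hur <- component_probabilities(qlogis(B / A) + k2, eta_zero = k1 - eta,
                                 k2 = k2, variant = "hurdle")
  expect_equal(hur$pr0, can$pr0, tolerance = 1e-12)
  expect_equal(hur$pr1, can$pr1, tolerance = 1e-12)
  expect_equal(hur$pr_mid, can$pr_mid, tolerance = 1e-12)
})

test_that("the interior Beta density is a proper, mean-parameterized density", {
  y <- seq(0.05, 0.95, by = 0.05)
  expect_equal(continuous_density(y, eta = 0, psi = 2), rep(1, length(y)))
  expect_equal(continuous_density(0.3, eta = 0, psi = 5),
               continuous_density(0.7, eta = 0, psi = 5))
  set.seed(2)
  for (r in 1:20) {
    eta <- rnorm(1); u <- rnorm(1, 0, 0.5); psi <- runif(1, 1, 20)
    total <- integrate(function(t) continuous_density(t, eta, u, psi),
                       0, 1, rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  expect_error(continuous_density(0, eta = 0, psi = 2), "open interval")
  expect_error(continuous_density(0.5, eta = 0, psi = -1), "positive")
})

test_that("the Laplace marginal likelihood matches degenerate and quadrature limits", {
  dat <- simulate_ordered_beta(150, K = 3, beta = ob_beta, beta_zero = ob_beta_zero,
                               k2 = 2.2, psi = 6, sigma_u = 0.4, seed = 5)
  p <- list(beta = ob_beta, beta_zero = ob_beta_zero, k2 = 2.2, psi = 6, sigma_u = 0.4)
  spec <- ordered_beta_spec()

  # sigma_u -> 0 degenerates to the no-random-effect likelihood
  p0 <- p; p0$sigma_u <- 1e-7
  no_re <- marginal_negloglik(p[names(p) != "sigma_u"], dat,
                              ordered_beta_spec(random_effect = "none"))
  expect_equal(marginal_negloglik(p0, dat, spec), no_re, tolerance = 1e-4)

  # single zero observation contributes exactly -log Pr(y = 0)
  d1 <- dat[dat$y == 0, ][1, ]
  xz <- c(1, d1$sex == "male", d1$age, d1$economic == "none",
          d1$education == "high", d1$year_c, (d1$sex == "male") * d1$age)
  expect_equal(marginal_negloglik(p, d1, spec),
               -plogis(sum(xz * ob_beta_zero), log.p = TRUE), tolerance = 1e-10)

  # independent adaptive Gauss-Hermite oracle, coded from the public pieces
  oracle <- 0
  for (k in sort(unique(dat$region))) {
    sub <- dat[dat$region == k, ]
    X <- cbind(1, sub$sex == "male", sub$age, sub$economic == "none",
               sub$education == "high", sub$year_c, (sub$sex == "male") * sub$age)
    eta <- as.vector(X %*% ob_beta)
    eta_z <- as.vector(X %*% ob_beta_zero)
    reg_ll <- function(u) {
      ll <- 0
      for (j in seq_len(nrow(sub))) {
        pr <- component_probabilities(eta[j] + u, eta_zero = eta_z[j],
                                      k2 = 2.2, variant = "hurdle")
        ll <- ll + if (sub$y[j] == 0) {
          log(pr$pr0)
        } else if (sub$y[j] == 1) {
          log(pr$pr1)
        } else {
          log(pr$pr_mid) + continuous_density(sub$y[j], eta[j], u, 6, log = TRUE)
        }
      }
      ll
    }
    # adaptive: center the 15-node rule at the per-region posterior mode
    mode <- optimize(function(u) reg_ll(u) + dnorm(u, 0, 0.4, log = TRUE),
                     c(-3, 3), maximum = TRUE)
    h <- 1e-4
    f2 <- (reg_ll(mode$maximum + h) + dnorm(mode$maximum + h, 0, 0.4, log = TRUE) -
             2 * mode$objective +
             reg_ll(mode$maximum - h) + dnorm(mode$maximum - h, 0, 0.4, log = TRUE)) / h^2
    sd_a <- sqrt(-1 / f2)
    gh <- pracma::gaussHermite(15)
    ut <- mode$maximum + sqrt(2) * sd_a * gh$x
    lw <- log(gh$w) + gh$x^2 +
      vapply(ut, function(u) reg_ll(u) + dnorm(u, 0, 0.4, log = TRUE), numeric(1)) +
      log(sqrt(2) * sd_a)
    oracle <- oracle - (max(lw) + log(sum(exp(lw - max(lw)))))
  }
  lap <- marginal_negloglik(p, dat, spec)
  expect_lt(abs(lap - oracle), 0.05)
  # the built-in quadrature cross-check agrees too
  expect_lt(abs(marginal_negloglik(p, dat, spec, method = "ghq") - oracle), 1e-3)
})

test_that("estimates are invariant to row order and to affine year recoding", {
  dat <- simulate_ordered_beta(1200, K = 5, beta = ob_beta, beta_zero = ob_beta_zero,
                               k2 = 2.3, psi = 7, sigma_u = 0.2, seed = 9)
  f1 <- fit_ordered_beta(dat)
  set.seed(1)
  f2 <- fit_ordered_beta(dat[sample(nrow(dat)), ])
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  expect_equal(f1$psi, f2$psi, tolerance = 1e-8)
  expect_equal(f1$sigma_u, f2$sigma_u, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)

  sp_raw <- ordered_beta_spec(conditional = y ~ sex + age + economic + education +
                                year + sex:age)
  f3 <- fit_ordered_beta(dat, sp_raw)
  expect_equal(f3$loglik, f1$loglik, tolerance = 1e-6)
  # same design order; only the intercept absorbs the year shift
  expect_equal(unname(f3$beta[-1]), unname(f1$beta[-1]), tolerance = 1e-5)
  expect_equal(unname(f3$beta_zero[-1]), unname(f1$beta_zero[-1]), tolerance = 1e-5)
})

test_that("the canonical variant agrees with an independent mixed-model implementation", {
  set.seed(3)
  n <- 2000; K <- 6
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.5); g <- sample(K, n, TRUE)
  u <- rnorm(K, 0, 0.3)
  eta <- 0.2 + 0.4 * x1 - 0.3 * x2 + u[g]
  pr <- component_probabilities(eta, k1 = -1, k2 = 1.5, variant = "canonical")
  v <- runif(n); y <- numeric(n)
  is0 <- v < pr$pr0
  is1 <- v >= pr$pr0 + pr$pr_mid
  mid <- !is0 & !is1
  y[is1] <- 1
  y[mid] <- rbeta(sum(mid), plogis(eta[mid]) * 7, (1 - plogis(eta[mid])) * 7)
  dat <- data.frame(y = y, x1 = x1, x2 = x2, region = g)
  f <- fit_ordered_beta(dat, ordered_beta_spec(conditional = y ~ x1 + x2,
                                               variant = "canonical"))
  ref <- glmmTMB::glmmTMB(y ~ x1 + x2 + (1 | region), data = dat,
                          family = glmmTMB::ordbeta())
  expect_equal(unname(f$beta), unname(glmmTMB::fixef(ref)$cond), tolerance = 1e-3)
  expect_equal(f$psi, glmmTMB::sigma(ref), tolerance = 1e-3)
  expect_equal(f$sigma_u, sqrt(glmmTMB::VarCorr(ref)$cond$region[1]), tolerance = 1e-3)
  expect_equal(f$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-4)
  cuts <- unname(ref$fit$par[names(ref$fit$par) == "psi"])
  expect_equal(c(f$k1, f$k2), cuts, tolerance = 1e-3)
})

test_that("population-level predictions combine the two components", {
  dat <- simulate_ordered_beta(4000, K = 4, beta = ob_beta, beta_zero = ob_beta_zero,
                               k2 = 2.3, psi = 7, sigma_u = 0, seed = 13)
  f <- fit_ordered_beta(dat, ordered_beta_spec(random_effect = "none"))
  prof <- expand.grid(
    sex = factor("female", levels = c("female", "male")),
    age = c(25, 45, 65),
    economic = factor("none", levels = c("difficulties", "none")),
    education = factor("high", levels = c("low", "high")),
    year_c = 0
  )
  pred <- predict_population(f, prof)
  expect_true(all(pred$gamma_hat >= 0 & pred$gamma_hat <= 1))
  expect_true(all(pred$mu_hat > 0 & pred$mu_hat <= 1))
  expect_equal(pred$y_hat, (1 - pred$gamma_hat) * pred$mu_hat, tolerance = 1e-12)
  # generative sign pattern: conditional age +, zero-part age - => y_hat rises
  expect_true(all(diff(pred$y_hat) > 0))
  bad <- prof
  bad$education <- factor("postdoc", levels = "postdoc")
  expect_error(predict_population(f, bad), "factor")
})

test_that("BLUPs are empirical-Bayes shrunken, centered, and need a random effect", {
  f0 <- fit_ordered_beta(
    simulate_ordered_beta(800, K = 4, beta = ob_beta, beta_zero = ob_beta_zero,
                          k2 = 2.3, psi = 7, sigma_u = 0, seed = 3),
    ordered_beta_spec(random_effect = "none")
  )
  expect_error(blup(f0), "random_effect")

  # null simulation: u == 0 generative, large-ish n => small BLUPs
  dat <- simulate_ordered_beta(12000, K = 6, beta = ob_beta, beta_zero = ob_beta_zero,
                               k2 = 2.3, psi = 7, sigma_u = 0, seed = 17)
  fn <- fit_ordered_beta(dat)
  b <- blup(fn)
  expect_lt(max(abs(b$estimate)), 0.05)
  expect_true(all(b$sd > 0 | is.na(b$sd)))

  # balanced design with real heterogeneity: BLUPs nearly center, and each
  # is no larger than the saturated per-region fixed offset
  dat2 <- simulate_ordered_beta(6000, K = 6, beta = ob_beta, beta_zero = ob_beta_zero,
                                k2 = 2.3, psi = 7, sigma_u = 0.25, seed = 19)
  fr <- fit_ordered_beta(dat2)
  b2 <- blup(fr)
  expect_lt(abs(sum(b2$estimate)), 6 * 0.05)
  sat <- fit_ordered_beta(
    dat2,
    ordered_beta_spec(conditional = y ~ sex + age + economic + education +
                        year_c + sex:age + factor(region),
                      zero = ~ sex + age + economic + education + year_c + sex:age,
                      random_effect = "none")
  )
  alpha <- c(0, unname(sat$beta[grep("factor\\(region\\)", names(sat$beta))]))
  offsets <- alpha - mean(alpha)
  expect_true(all(abs(b2$estimate) <= abs(offsets) + 0.02))
})

test_that("degenerate responses are refused or reduced as requested", {
  dat <- simulate_ordered_beta(500, K = 3, beta = ob_beta, beta_zero = ob_beta_zero,
                               k2 = 2.3, psi = 7, sigma_u = 0, seed = 23)
  no_ones <- dat[dat$y < 1, ]
  expect_error(fit_ordered_beta(no_ones, ordered_beta_spec(random_effect = "none")),
               "reduced model")
  f <- fit_ordered_beta(no_ones, ordered_beta_spec(random_effect = "none"),
                        boundary = "reduce")
  expect_true(is.infinite(f$k2))
  pred <- predict_population(f, data.frame(
    sex = factor("female", levels = c("female", "male")), age = 40,
    economic = factor("none", levels = c("difficulties", "none")),
    education = factor("high", levels = c("low", "high")), year_c = 5
  ))
  expect_true(pred$y_hat >= 0 && pred$y_hat <= 1)
  expect_error(fit_ordered_beta(dat[dat$y > 0 & dat$y < 1, ],
                                ordered_beta_spec(random_effect = "none"),
                                boundary = "reduce"),
               NA)
})
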