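test_that("item probability and information follow the 2PL closed forms", {
  expect_equal(item_probability(0, 1, 0), 0.5)
  # published diabetes parameters: prevalence of an average-trait person
  expect_equal(item_probability(-3.571, 1.340, 0), plogis(-3.571), tolerance = 1e-10)
  expect_equal(item_probability(-3.571, 1.340, 0), 0.02734, tolerance = 1e-3)
  # root of the linear predictor (kidney failure parameters)
  expect_equal(item_probability(-6.082, 2.077, 6.082 / 2.077), 0.5)

  expect_equal(item_information(0, 1, 0), 0.25)
  expect_equal(item_information(0, 0, 2), 0)
  # maximum of the information curve: beta1^2 / 4 at the p = 0.5 point
  opt <- optimize(function(z) item_information(-6.082, 2.077, z),
                  c(-6, 6), maximum = TRUE)
  expect_equal(opt$maximum, 6.082 / 2.077, tolerance = 1e-4)
  expect_equal(opt$objective, 2.077^2 / 4, tolerance = 1e-8)
})

test_that("M2 degrees of freedom count margins minus free parameters", {
  expect_identical(m2_degrees_of_freedom(5), 5L)
  expect_identical(m2_degrees_of_freedom(3), 0L)
  expect_identical(m2_degrees_of_freedom(4), 2L)
  expect_error(m2_degrees_of_freedom(2), "at least 3")
})

test_that("unit rescaling is an order-preserving affine map onto [0, 1]", {
  expect_equal(rescale_unit(c(1, 2, 3)), c(0, 0.5, 1))
  expect_equal(rescale_unit(c(-2, 2)), c(0, 1))
  set.seed(3)
  z <- rnorm(200)
  y <- rescale_unit(z)
  expect_equal(order(y), order(z))
  expect_equal(range(y), c(0, 1))
  expect_error(rescale_unit(rep(1, 5)), "constant")
})

test_that("quadrature grids are ordered with unit total mass", {
  for (g in list(quadrature_grid(), quadrature_grid(41, "gauss_hermite"))) {
    expect_true(all(diff(g$nodes) > 0))
    expect_equal(sum(g$masses), 1, tolerance = 1e-12)
    expect_true(all(g$masses >= 0))
  }
})

test_that("EAP scores are symmetric, pattern-monotone, and extremal at the corners", {
  # single-item symmetry
  p1 <- data.frame(disease = "a", beta0 = 0, beta1 = 1)
  z <- eap_scores(matrix(c(0, 1), ncol = 1), p1)
  expect_equal(z[1], -z[2], tolerance = 1e-10)

  ip <- default_item_params()
  patterns <- as.matrix(expand.grid(rep(list(0:1), 5)))
  colnames(patterns) <- ip$disease
  z <- eap_scores(patterns, ip)
  expect_equal(which.min(z), which(rowSums(patterns) == 0))
  expect_equal(which.max(z), which(rowSums(patterns) == 5))
  # dominance: turning any 0 into 1 never decreases the score
  for (r in seq_len(nrow(patterns))) {
    for (i in which(patterns[r, ] == 0)) {
      dom <- patterns[r, ]
      dom[i] <- 1
      r2 <- which(apply(patterns, 1, function(p) all(p == dom)))
      expect_gte(z[r2], z[r])
    }
  }
  # equal patterns always score equally
  X <- patterns[c(3, 7, 3, 3, 7), ]
  zz <- eap_scores(X, ip)
  expect_equal(zz[1], zz[3])
  expect_equal(zz[2], zz[5])
})

test_that("the EM increases the weighted marginal log-likelihood monotonically", {
  ip <- default_item_params()
  for (s in 1:3) {
    sim <- sim_2pl(1500, ip$beta0, ip$beta1, seed = 100 + s)
    w <- sampling_weights(runif(1500, 0, 0.8))
    fit <- fit_weighted_2pl(sim$X, w = w)
    expect_true(all(diff(fit$loglik_trace) > -1e-8))
    expect_true(fit$converged)
  }
})

test_that("unit weights reproduce the unweighted fit exactly", {
  ip <- default_item_params()
  sim <- sim_2pl(3000, ip$beta0, ip$beta1, seed = 11)
  w <- sampling_weights(rep(0, 3000))  # all-zero disability -> w = 1
  f1 <- fit_weighted_2pl(sim$X, w = w)
  f2 <- fit_weighted_2pl(sim$X)
  expect_equal(f1$item_params$beta0, f2$item_params$beta0, tolerance = 1e-10)
  expect_equal(f1$item_params$beta1, f2$item_params$beta1, tolerance = 1e-10)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("doubling the quadrature nodes barely moves the converged log-likelihood", {
  ip <- default_item_params()
  sim <- sim_2pl(2000, ip$beta0, ip$beta1, seed = 21)
  f1 <- fit_weighted_2pl(sim$X, grid = quadrature_grid(61))
  f2 <- fit_weighted_2pl(sim$X, grid = quadrature_grid(121))
  expect_lt(abs(f1$loglik - f2$loglik), 1e-3)
})

test_that("parameter bias shrinks with the sample size", {
  ip <- default_item_params()
  err <- sapply(c(2000, 20000), function(n) {
    sim <- sim_2pl(n, ip$beta0, ip$beta1, seed = 500)
    f <- fit_weighted_2pl(sim$X)
    mean(abs(c(f$item_params$beta0 - ip$beta0, f$item_params$beta1 - ip$beta1)))
  })
  expect_lt(err[2], err[1])
})

test_that("degenerate items are refused with the item named", {
  X <- cbind(diabetes = c(0L, 1L, 0L, 1L), kidney = c(0L, 0L, 0L, 0L),
             respiratory = c(1L, 0L, 1L, 0L))
  expect_error(fit_weighted_2pl(X), "kidney")
})

test_that("item parameter table mirrors the difficulty/discrimination layout", {
  ip <- default_item_params()
  sim <- sim_2pl(2000, ip$beta0, ip$beta1, seed = 77)
  f <- fit_weighted_2pl(sim$X)
  tab <- item_param_table(f)
  expect_equal(tab$neg_beta0, -f$item_params$beta0)
  expect_equal(tab$beta1, f$item_params$beta1)
  expect_equal(tab$disease, ip$disease)
})
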