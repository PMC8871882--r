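test_that("effective rates subtract the adjustment from the base rate", {
  p <- bench$params
  expect_equal(effective_rates(p, intervention(alpha1_bar = 0.03))$alpha1_star,
               0.005)
  expect_equal(effective_rates(p, intervention(gamma1_bar = -0.04))$gamma1_star,
               0.07)
  # no intervention: starred rates equal the base rates
  r0 <- effective_rates(p, intervention())
  expect_equal(unname(unlist(r0)),
               unname(unlist(p[c("alpha1", "alpha2", "gamma1", "gamma2",
                                 "theta", "tau")])))
})

test_that("out-of-range net rates are rejected with the offending name", {
  p <- bench$params
  expect_error(effective_rates(p, intervention(alpha1_bar = 0.05)),
               "alpha1_star", class = "i2s2r_validation_error")
  expect_error(effective_rates(p, intervention(tau_bar = -0.999)),
               "tau_star", class = "i2s2r_validation_error")
})

test_that("parameter and adjustment constructors enforce their ranges", {
  expect_error(model_parameters(alpha1 = 1.2, alpha2 = 0, beta1 = 0,
                                beta2 = 0, gamma1 = 0, gamma2 = 0,
                                theta = 0, tau = 0),
               "alpha1", class = "i2s2r_validation_error")
  expect_error(model_parameters(alpha1 = 0.1, alpha2 = 0.1, beta1 = 0.1,
                                beta2 = 0.1, gamma1 = 0.1, gamma2 = 0.1,
                                theta = 0.1, tau = 0.1, c = 0.1, g = 0.2),
               "equal", class = "i2s2r_validation_error")
  expect_error(intervention(theta_bar = 1.5), "theta_bar",
               class = "i2s2r_validation_error")
  expect_error(state(-0.1, 0.5, 0.1, 0, 0), "non-negative",
               class = "i2s2r_validation_error")
  expect_error(state(1, 0.5, 0.1, 0, 0), "total density",
               class = "i2s2r_validation_error")
})

test_that("benchmark derivatives match hand substitution", {
  r <- effective_rates(bench$params)
  d <- rumor_rhs(bench$initial, r, bench$params)
  expect_equal(unname(d[["I"]]), -0.01475, tolerance = 1e-12)
  expect_equal(unname(d[["ES"]]), 0.00463425, tolerance = 1e-12)
})

test_that("the empty system with no turnover is a fixed point", {
  p <- model_parameters(alpha1 = 0.1, alpha2 = 0.1, beta1 = 0.1, beta2 = 0.1,
                        gamma1 = 0.1, gamma2 = 0.1, theta = 0.1, tau = 0.1,
                        c = 0)
  d <- rumor_rhs(c(0, 0, 0, 0, 0), effective_rates(p), p)
  expect_equal(unname(d), rep(0, 5))
})

test_that("derivatives sum to the turnover law c - g*S for random inputs", {
  set.seed(11)
  for (i in 1:50) {
    p <- random_params()
    y <- stats::runif(5, 0, 0.2)
    d <- rumor_rhs(y, effective_rates(p), p)
    expect_equal(sum(d), p$c - p$g * sum(y), tolerance = 1e-12)
  }
})

test_that("a compartment at zero density is never driven negative", {
  set.seed(12)
  for (i in 1:20) {
    p <- random_params()
    for (j in 1:5) {
      y <- stats::runif(5, 0, 0.2)
      y[j] <- 0
      d <- rumor_rhs(y, effective_rates(p), p)
      expect_gte(d[[j]], 0)
    }
  }
})
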