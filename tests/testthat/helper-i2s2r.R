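# Shared fixtures and independent oracles.

bench <- benchmark_config()

# Central finite-difference Jacobian of the rhs (independent of the
# analytic rumor_jacobian).
fd_jacobian <- function(y, rates, params, h = 1e-6) {
  J <- matrix(0, 5, 5)
  for (j in 1:5) {
    up <- y; up[j] <- up[j] + h
    dn <- y; dn[j] <- dn[j] - h
    J[, j] <- (rumor_rhs(up, rates, params) - rumor_rhs(dn, rates, params)) /
      (2 * h)
  }
  J
}

# Random valid parameter set (rates in [0, 0.1], c = g) for property tests.
random_params <- function() {
  v <- stats::runif(8, 0, 0.1)
  model_parameters(alpha1 = v[1], alpha2 = v[2], beta1 = v[3], beta2 = v[4],
                   gamma1 = v[5], gamma2 = v[6], theta = v[7], tau = v[8],
                   c = stats::runif(1, 0, 0.01), k = stats::runif(1, 1, 60))
}

# Build a rumor_trajectory by hand (for summary-only tests).
fake_trajectory <- function(t, series) {
  df <- data.frame(t = t, I = 0, ES = 0, EA = 0, RS = 0, RA = 0)
  for (nm in names(series)) df[[nm]] <- series[[nm]]
  structure(df, class = c("rumor_trajectory", "data.frame"),
            grid_step = t[2] - t[1])
}
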