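#' Mean-field right-hand side of the I2S2R system
#'
#' Evaluates the time derivatives of the five compartment densities under the
#' net (post-intervention) rates. Transitions between engagers and their
#' immune classes are contact-driven (proportional to the product of the two
#' densities and the mean degree `k`), while the `beta` recoveries and the
#' population turnover are spontaneous. Summing the five components always
#' yields `c - g * (I + ES + EA + RS + RA)`: every interaction term appears
#' once with each sign, so the total density obeys a closed linear law.
#'
#' @param state a numeric vector `(I, ES, EA, RS, RA)` (an [state()] object or
#'   plain numeric of length 5).
#' @param rates an [effective_rates()] object.
#' @param params an [model_parameters()] object (supplies `beta1`, `beta2`,
#'   `c`, `g` and `k`).
#'
#' @return Named numeric vector of the five derivatives, per unit time.
#' @export
rumor_rhs <- function(state, rates, params) {
  y <- as_state_vector(state)
  I <- y[["I"]]; ES <- y[["ES"]]; EA <- y[["EA"]]
  RS <- y[["RS"]]; RA <- y[["RA"]]
  a1 <- rates$alpha1_star; a2 <- rates$alpha2_star
  g1 <- rates$gamma1_star; g2 <- rates$gamma2_star
  th <- rates$theta_star;  ta <- rates$tau_star
  b1 <- params$beta1; b2 <- params$beta2
  cc <- params$c; g <- params$g; k <- params$k
  c(I  = cc - a1 * I * ES * k - a2 * I * EA * k - g * I,
    ES = a1 * I * ES * k - g1 * ES * RS * k - b1 * ES +
         th * EA * ES * k + ta * RA * ES * k - g * ES,
    EA = a2 * I * EA * k - g2 * EA * RA * k - b2 * EA -
         th * EA * ES * k - g * EA,
    RS = g1 * ES * RS * k + b1 * ES - g * RS,
    RA = g2 * EA * RA * k + b2 * EA - ta * RA * ES * k - g * RA)
}

#' Analytic Jacobian of the I2S2R right-hand side
#'
#' Partial derivatives of the five derivative components with respect to the
#' five compartment densities, evaluated at `state`. Used by the equilibrium
#' solver (Newton steps) and the local-stability classification.
#'
#' @inheritParams rumor_rhs
#' @return A 5 x 5 numeric matrix, rows and columns in compartment order
#'   `I, ES, EA, RS, RA`.
#' @export
rumor_jacobian <- function(state, rates, params) {
  y <- as_state_vector(state)
  I <- y[["I"]]; ES <- y[["ES"]]; EA <- y[["EA"]]
  RS <- y[["RS"]]; RA <- y[["RA"]]
  a1 <- rates$alpha1_star; a2 <- rates$alpha2_star
  g1 <- rates$gamma1_star; g2 <- rates$gamma2_star
  th <- rates$theta_star;  ta <- rates$tau_star
  b1 <- params$beta1; b2 <- params$beta2
  g <- params$g; k <- params$k
  J <- matrix(0, 5, 5, dimnames = list(COMPARTMENTS, COMPARTMENTS))
  J["I", ] <- c(-a1 * ES * k - a2 * EA * k - g, -a1 * I * k, -a2 * I * k, 0, 0)
  J["ES", ] <- c(a1 * ES * k,
                 a1 * I * k - g1 * RS * k - b1 + th * EA * k + ta * RA * k - g,
                 th * ES * k, -g1 * ES * k, ta * ES * k)
  J["EA", ] <- c(a2 * EA * k, -th * EA * k,
                 a2 * I * k - g2 * RA * k - b2 - th * ES * k - g,
                 0, -g2 * EA * k)
  J["RS", ] <- c(0, g1 * RS * k + b1, 0, g1 * ES * k - g, 0)
  J["RA", ] <- c(0, -ta * RA * k, g2 * RA * k + b2, 0,
                 g2 * EA * k - ta * ES * k - g)
  J
}
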