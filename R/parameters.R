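#' @keywords internal
"_PACKAGE"

# Names of the five compartments, in the order used throughout the package.
COMPARTMENTS <- c("I", "ES", "EA", "RS", "RA")

# Base rates that an intervention can adjust, and the corresponding
# adjustment ("bar") fields.
ADJUSTABLE <- c("alpha1", "alpha2", "gamma1", "gamma2", "theta", "tau")
BAR_FIELDS <- paste0(ADJUSTABLE, "_bar")

validation_error <- function(msg) {
  stop(structure(class = c("i2s2r_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Model parameters of the I2S2R rumor-engagement system
#'
#' Bundles the base rates of the interactive-infection model: the per-contact
#' transmission probabilities between the ignorant class `I`, the supporter
#' engagers `ES`, the amplifier engagers `EA` and the two immune classes
#' `RS`/`RA`, together with the population-turnover rates and the mean network
#' degree. All probabilities and the turnover rates must lie in `[0, 1]`, and
#' the coming rate must equal the leaving rate (the public-opinion field is
#' assumed to be in demographic balance).
#'
#' @param alpha1 transmission probability ignorant -> supporter (per contact).
#' @param alpha2 transmission probability ignorant -> amplifier (per contact).
#' @param beta1 transmission probability supporter -> immune 1 due to contacts.
#' @param beta2 transmission probability amplifier -> immune 2 due to contacts.
#' @param gamma1 forgetting-transfer rate supporter -> immune 1 (per contact
#'   with immune 1).
#' @param gamma2 forgetting-transfer rate amplifier -> immune 2 (per contact
#'   with immune 2).
#' @param theta transmission probability amplifier -> supporter (per contact).
#' @param tau transmission probability immune 2 -> supporter (secondary
#'   supporter relapse, per contact).
#' @param c coming rate of new ignorants into the field (per unit time).
#' @param g leaving rate of the population (per unit time); must equal `c`.
#' @param k mean degree of the homogeneous contact network (positive).
#' @param N nominal population size used only when reporting absolute user
#'   numbers; it never enters the dynamics.
#'
#' @return An object of class `i2s2r_params` (a named list).
#' @seealso [benchmark_config()] for the calibrated benchmark values.
#' @export
model_parameters <- function(alpha1, alpha2, beta1, beta2, gamma1, gamma2,
                             theta, tau, c = 0.001, g = c, k = 50,
                             N = 100000) {
  p <- list(alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1, beta2 = beta2,
            gamma1 = gamma1, gamma2 = gamma2, theta = theta, tau = tau,
            c = c, g = g, k = k, N = N)
  for (nm in c("alpha1", "alpha2", "beta1", "beta2", "gamma1", "gamma2",
               "theta", "tau", "c", "g")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      validation_error(sprintf("parameter '%s' must be a single value in [0, 1], got %s",
                               nm, format(v)))
  }
  if (p$c != p$g)
    validation_error(sprintf("coming and leaving rates must be equal (c = %g, g = %g)",
                             p$c, p$g))
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0)
    validation_error("mean degree k must be a positive number")
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N <= 0)
    validation_error("population size N must be positive")
  structure(p, class = "i2s2r_params")
}

#' @export
print.i2s2r_params <- function(x, ...) {
  cat("I2S2R model parameters\n")
  cat(sprintf("  transmission: alpha1=%g alpha2=%g theta=%g tau=%g\n",
              x$alpha1, x$alpha2, x$theta, x$tau))
  cat(sprintf("  recovery:     beta1=%g beta2=%g gamma1=%g gamma2=%g\n",
              x$beta1, x$beta2, x$gamma1, x$gamma2))
  cat(sprintf("  turnover c=g=%g, mean degree k=%g, N=%g\n", x$c, x$k, x$N))
  invisible(x)
}

#' Intervention adjustments ("bars") for the six adjustable rates
#'
#' Each adjustment is subtracted from the corresponding base rate before
#' simulation; a positive bar hinders the targeted transition and a negative
#' bar (used for persuasion on the recovery rates) accelerates it. All bars
#' must lie in `[-1, 1]`; the zero vector is the benchmark (no intervention).
#'
#' @param alpha1_bar,alpha2_bar adjustments applied while ignorants are being
#'   recruited (psychological alarm-reaction stage).
#' @param gamma1_bar,gamma2_bar adjustments on the forgetting transfers
#'   (resistance stage); persuasion uses negative values here.
#' @param theta_bar adjustment on the amplifier -> supporter escalation
#'   (resistance stage).
#' @param tau_bar adjustment on the immune 2 -> supporter relapse
#'   (exhaustion stage).
#'
#' @return An object of class `i2s2r_intervention` (a named list).
#' @export
intervention <- function(alpha1_bar = 0, alpha2_bar = 0, gamma1_bar = 0,
                         gamma2_bar = 0, theta_bar = 0, tau_bar = 0) {
  a <- list(alpha1_bar = alpha1_bar, alpha2_bar = alpha2_bar,
            gamma1_bar = gamma1_bar, gamma2_bar = gamma2_bar,
            theta_bar = theta_bar, tau_bar = tau_bar)
  for (nm in names(a)) {
    v <- a[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < -1 || v > 1)
      validation_error(sprintf("adjustment '%s' must be a single value in [-1, 1], got %s",
                               nm, format(v)))
  }
  structure(a, class = "i2s2r_intervention")
}

#' @export
print.i2s2r_intervention <- function(x, ...) {
  nz <- Filter(function(v) v != 0, unclass(x))
  if (length(nz) == 0L) {
    cat("I2S2R intervention: none (benchmark)\n")
  } else {
    cat("I2S2R intervention:",
        paste(sprintf("%s=%g", names(nz), unlist(nz)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Net ("starred") rates after applying an intervention
#'
#' Subtracts each adjustment from its base rate. Because the starred values
#' act as transmission probabilities, any net rate falling outside `[0, 1]`
#' is rejected with an error naming the offending rate.
#'
#' @param params an [model_parameters()] object.
#' @param adj an [intervention()] object.
#'
#' @return An object of class `i2s2r_rates`: a named list with fields
#'   `alpha1_star`, `alpha2_star`, `gamma1_star`, `gamma2_star`,
#'   `theta_star`, `tau_star`.
#' @examples
#' p <- benchmark_config()$params
#' effective_rates(p, intervention(alpha1_bar = 0.03))$alpha1_star  # 0.005
#' @export
effective_rates <- function(params, adj = intervention()) {
  stopifnot(inherits(params, "i2s2r_params"), inherits(adj, "i2s2r_intervention"))
  star <- lapply(ADJUSTABLE, function(nm) params[[nm]] - adj[[paste0(nm, "_bar")]])
  names(star) <- paste0(ADJUSTABLE, "_star")
  for (nm in names(star)) {
    v <- star[[nm]]
    if (v < 0 || v > 1)
      validation_error(sprintf("net rate %s = %g falls outside [0, 1]; the intervention is stronger than the base rate allows",
                               nm, v))
  }
  structure(star, class = "i2s2r_rates")
}

#' @export
print.i2s2r_rates <- function(x, ...) {
  cat("I2S2R effective rates:",
      paste(sprintf("%s=%g", names(x), unlist(x)), collapse = ", "), "\n")
  invisible(x)
}

#' Construct and validate a compartment state
#'
#' A state holds the five compartment densities (fractions of the population)
#' at one time point. Components must be non-negative and the total density
#' must lie in `(0, 1 + tol]`.
#'
#' @param I,ES,EA,RS,RA compartment densities.
#' @param tol numerical slack allowed above a total density of 1.
#' @return A named numeric vector of length 5 with class `i2s2r_state`.
#' @export
state <- function(I, ES, EA, RS, RA, tol = 1e-8) {
  s <- c(I = I, ES = ES, EA = EA, RS = RS, RA = RA)
  if (any(!is.finite(s)))
    validation_error("state components must be finite")
  if (any(s < 0))
    validation_error(sprintf("state components must be non-negative (got %s = %g)",
                             names(s)[which(s < 0)[1]], s[s < 0][1]))
  tot <- sum(s)
  if (tot <= 0 || tot > 1 + tol)
    validation_error(sprintf("total density %g outside (0, 1 + %g]", tot, tol))
  structure(s, class = "i2s2r_state")
}

as_state_vector <- function(x) {
  v <- as.numeric(x)[seq_along(COMPARTMENTS)]
  names(v) <- COMPARTMENTS
  v
}
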