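# Eigenvalue-based classification of a linearization.
classify_eigen <- function(eig, tol = 1e-8) {
  mx <- max(Re(eig))
  if (abs(mx) <= tol) "marginal"
  else if (mx < 0) "locally-asymptotically-stable"
  else "unstable"
}

new_equilibrium_report <- function(y, rates, params, tol = 1e-8) {
  res <- rumor_rhs(y, rates, params)
  J <- rumor_jacobian(y, rates, params)
  eig <- eigen(J, only.values = TRUE)$values
  structure(list(state = y, residual = max(abs(res)), eigenvalues = eig,
                 classification = classify_eigen(eig, tol)),
            class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat("I2S2R equilibrium:",
      paste(sprintf("%s=%.6g", COMPARTMENTS, x$state), collapse = " "), "\n")
  cat(sprintf("  residual %.3g, %s\n", x$residual, x$classification))
  cat("  eigenvalue real parts:",
      paste(format(sort(Re(x$eigenvalues), decreasing = TRUE), digits = 4),
            collapse = ", "), "\n")
  invisible(x)
}

#' Rumor-free equilibrium and its local stability
#'
#' With no engagers (`ES = EA = 0`) every transmission term vanishes and the
#' system settles at `I = c/g` with empty engager and immune classes. The
#' report carries the (analytically zero) residual and the Jacobian
#' eigenvalues at that point; under the benchmark parameters the equilibrium
#' is unstable, which is what lets an arbitrarily small seeding of engagers
#' ignite an outbreak.
#'
#' @param params an [model_parameters()] object (requires `g > 0`).
#' @param adj an [intervention()] object.
#' @param tol tolerance on eigenvalue real parts for calling the
#'   classification marginal.
#' @return An `equilibrium_report`: list with `state`, `residual`,
#'   `eigenvalues` (complex, length 5) and `classification`.
#' @export
rumor_free_equilibrium <- function(params, adj = intervention(), tol = 1e-8) {
  stopifnot(params$g > 0)
  rates <- effective_rates(params, adj)
  y <- c(I = params$c / params$g, ES = 0, EA = 0, RS = 0, RA = 0)
  new_equilibrium_report(y, rates, params, tol)
}

# Damped Newton iteration on the rhs using the analytic Jacobian.
# Returns the root or NULL when the iteration fails to converge.
newton_root <- function(y0, rates, params, max_iter = 100, ftol = 1e-12) {
  y <- y0
  f <- rumor_rhs(y, rates, params)
  for (i in seq_len(max_iter)) {
    if (max(abs(f)) < ftol) break
    J <- rumor_jacobian(y, rates, params)
    d <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(d) || any(!is.finite(d))) return(NULL)
    lambda <- 1
    repeat {   # backtracking line search on ||f||
      y_new <- y - lambda * d
      f_new <- rumor_rhs(y_new, rates, params)
      if (max(abs(f_new)) < max(abs(f)) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    y <- y_new; f <- f_new
  }
  if (max(abs(f)) < ftol) y else NULL
}

#' Locate equilibria of the I2S2R system numerically
#'
#' Multi-start damped Newton iteration on the mean-field right-hand side,
#' started from seeded uniform random points in the unit box `[0, 1]^5`.
#' Converged roots are kept when they are physically admissible (all
#' components non-negative up to round-off and total density at most
#' `1 + 1e-6`), deduplicated at max-norm distance `1e-6`, and reported with
#' their residual and local stability classification. The closed-form
#' rumor-free equilibrium is always included as an additional start, and the
#' result is deterministic given `seed`.
#'
#' @inheritParams rumor_free_equilibrium
#' @param n_starts number of random starting points (at least 1).
#' @param seed integer seed for the starting points.
#' @return A list of `equilibrium_report`s sorted by decreasing `I`
#'   component; empty (with a message) when no start converged.
#' @export
find_equilibria <- function(params, adj = intervention(), n_starts = 40,
                            seed = 0, tol = 1e-8) {
  stopifnot(n_starts >= 1)
  rates <- effective_rates(params, adj)
  rng <- local({
    set.seed(seed)
    matrix(stats::runif(5 * n_starts), ncol = 5)
  })
  starts <- rbind(rng, c(params$c / params$g, 0, 0, 0, 0))
  roots <- list()
  for (i in seq_len(nrow(starts))) {
    r <- newton_root(starts[i, ], rates, params)
    if (is.null(r)) next
    if (any(r < -1e-9) || sum(r) > 1 + 1e-6) next
    r <- pmax(r, 0)
    if (any(vapply(roots, function(x) max(abs(x - r)) < 1e-6, logical(1))))
      next
    roots[[length(roots) + 1L]] <- r
  }
  if (length(roots) == 0L) {
    message("no equilibrium converged from ", n_starts, " starts")
    return(list())
  }
  roots <- roots[order(-vapply(roots, function(x) x[["I"]], numeric(1)))]
  lapply(roots, function(y) {
    names(y) <- COMPARTMENTS
    new_equilibrium_report(y, rates, params, tol)
  })
}
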