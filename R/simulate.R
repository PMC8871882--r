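#' Integrate the I2S2R system with an adaptive Runge-Kutta solver
#'
#' Solves the mean-field equations with the Dormand-Prince 4(5) pair
#' (`deSolve`'s `"ode45"` method, relative tolerance `1e-8`, absolute
#' tolerance `1e-10`) and samples the solution on a uniform output grid.
#' Small negative round-off values larger than `-1e-9` are clamped to zero.
#'
#' @param initial initial [state()] (or numeric vector of length 5).
#' @param params an [model_parameters()] object.
#' @param adj an [intervention()] object; defaults to no intervention.
#' @param horizon end time of the simulation (time is dimensionless; one unit
#'   is nominally a day for reporting).
#' @param grid_step spacing of the uniform output grid.
#'
#' @return A `rumor_trajectory`: a data frame with columns `t, I, ES, EA, RS,
#'   RA` and attributes `params`, `adjustments` and `grid_step`.
#' @examples
#' cfg <- benchmark_config()
#' traj <- integrate_model(cfg$initial, cfg$params, horizon = 100)
#' summarize_trajectory(traj)
#' @export
integrate_model <- function(initial, params, adj = intervention(),
                            horizon = 1000, grid_step = 0.1) {
  stopifnot(horizon >= grid_step, grid_step > 0)
  rates <- effective_rates(params, adj)
  y0 <- as_state_vector(initial)
  times <- seq(0, horizon, by = grid_step)
  deriv <- function(t, y, parms) list(rumor_rhs(y, rates, params))
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "ode45", rtol = 1e-8, atol = 1e-10)
  if (nrow(sol) < length(times)) {
    last_t <- if (nrow(sol) > 0) sol[nrow(sol), 1] else 0
    stop(sprintf("integration failed (step-size collapse); last valid time %g",
                 last_t))
  }
  m <- unclass(sol)
  vals <- m[, COMPARTMENTS, drop = FALSE]
  neg <- vals < 0
  if (any(vals[neg] < -1e-9))
    warning("integration produced negative densities below -1e-9")
  vals[neg] <- 0
  out <- data.frame(t = m[, "time"], vals)
  structure(out, class = c("rumor_trajectory", "data.frame"),
            params = params, adjustments = adj, grid_step = grid_step)
}

#' Fixed-step forward-Euler reference integrator
#'
#' A deliberately simple first-order scheme kept as an independent check on
#' the adaptive solver; it shares nothing with [integrate_model()] beyond the
#' right-hand side. Intended for validation at small step sizes, not for
#' production runs.
#'
#' @inheritParams integrate_model
#' @param step fixed Euler step; must be at most `1e-2`.
#' @return A `rumor_trajectory` sampled at every Euler step.
#' @export
euler_reference <- function(initial, params, adj = intervention(),
                            horizon, step = 1e-3) {
  stopifnot(step > 0, step <= 1e-2)
  rates <- effective_rates(params, adj)
  y <- as_state_vector(initial)
  n <- max(0L, as.integer(round(horizon / step)))
  out <- matrix(NA_real_, n + 1L, 5L, dimnames = list(NULL, COMPARTMENTS))
  out[1L, ] <- y
  if (n > 0L) for (i in seq_len(n)) {
    y <- y + step * rumor_rhs(y, rates, params)
    out[i + 1L, ] <- y
  }
  res <- data.frame(t = step * (0:n), out)
  structure(res, class = c("rumor_trajectory", "data.frame"),
            params = params, adjustments = adj, grid_step = step)
}

#' @export
print.rumor_trajectory <- function(x, ...) {
  cat(sprintf("I2S2R trajectory: %d grid points, t in [%g, %g]\n",
              nrow(x), x$t[1], x$t[nrow(x)]))
  cat("final state:",
      paste(sprintf("%s=%.6g", COMPARTMENTS,
                    unlist(x[nrow(x), COMPARTMENTS])), collapse = " "), "\n")
  invisible(x)
}

# Quadratic refinement of a grid maximum using the three bracketing points.
# Returns c(time, value); falls back to the raw grid point at the boundary
# or when the parabola is degenerate.
refine_peak <- function(t, v, i) {
  n <- length(v)
  if (i == 1L || i == n) return(c(t[i], v[i]))
  y1 <- v[i - 1L]; y2 <- v[i]; y3 <- v[i + 1L]
  denom <- y1 - 2 * y2 + y3
  if (denom >= 0) return(c(t[i], v[i]))   # not locally concave
  delta <- 0.5 * (y1 - y3) / denom
  h <- t[i + 1L] - t[i]
  c(t[i] + delta * h, y2 - 0.25 * (y1 - y3) * delta)
}

#' Summarize a trajectory per compartment
#'
#' For each compartment: the peak density (grid maximum refined by local
#' quadratic interpolation), the time at which it is first attained, the
#' extinction time (first grid time after the peak at which the density falls
#' below `extinction_threshold`; `NA` when never reached or when the
#' compartment never exceeded the threshold), and the density at the end of
#' the horizon. A mean descent rate,
#' `(peak_value - threshold) / (extinction_time - peak_time)`, is reported
#' for compartments that reach extinction.
#'
#' @param traj a `rumor_trajectory` from [integrate_model()] or
#'   [euler_reference()].
#' @param extinction_threshold density below which a compartment is
#'   considered extinct (default `1e-4`, i.e. a thirtieth of the initial
#'   engager density in the benchmark).
#'
#' @return A `trajectory_summary`: a data frame with one row per compartment
#'   and columns `compartment, peak_value, peak_time, extinction_time,
#'   descent_rate, final_value`.
#' @export
summarize_trajectory <- function(traj, extinction_threshold = 1e-4) {
  stopifnot(nrow(traj) > 0, extinction_threshold > 0)
  t <- traj$t
  rows <- lapply(COMPARTMENTS, function(cmp) {
    v <- traj[[cmp]]
    i <- which.max(v)
    pk <- refine_peak(t, v, i)
    ext <- NA_real_
    if (pk[2] >= extinction_threshold) {
      j <- which(t > pk[1] & v < extinction_threshold)
      if (length(j)) ext <- t[min(j)]
    }
    desc <- if (is.na(ext)) NA_real_ else
      (pk[2] - extinction_threshold) / (ext - pk[1])
    data.frame(compartment = cmp, peak_value = pk[2], peak_time = pk[1],
               extinction_time = ext, descent_rate = desc,
               final_value = v[length(v)])
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("trajectory_summary", "data.frame"),
            extinction_threshold = extinction_threshold,
            horizon = t[length(t)],
            grid_step = attr(traj, "grid_step"))
}

#' @export
print.trajectory_summary <- function(x, ...) {
  cat(sprintf("I2S2R trajectory summary (horizon %g, extinction threshold %g)\n",
              attr(x, "horizon"), attr(x, "extinction_threshold")))
  df <- as.data.frame(x)
  df$extinction_time <- ifelse(is.na(df$extinction_time), "not reached",
                               format(df$extinction_time))
  print.data.frame(df, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Write a trajectory to a delimited text file
#'
#' Columns `t, I, ES, EA, RS, RA`, comma-separated, full double precision.
#'
#' @param traj a `rumor_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)[, c("t", COMPARTMENTS)]
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
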