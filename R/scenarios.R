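# Registry of the 24 intervention scenarios: six modes (one adjustable rate
# each) at four intensity levels. Persuasion modes (3, 4) carry negative bars.
MODE_TARGET <- c("alpha1_bar", "alpha2_bar", "gamma1_bar",
                 "gamma2_bar", "theta_bar", "tau_bar")
MODE_LEVELS <- list(
  c(0.01, 0.02, 0.025, 0.03),       # mode 1: hinder ignorant -> supporter
  c(0.01, 0.02, 0.03, 0.04),        # mode 2: hinder ignorant -> amplifier
  c(-0.01, -0.02, -0.03, -0.04),    # mode 3: persuade supporter -> immune 1
  c(-0.01, -0.02, -0.03, -0.04),    # mode 4: persuade amplifier -> immune 2
  c(0.001, 0.002, 0.003, 0.004),    # mode 5: hinder amplifier -> supporter
  c(0.001, 0.002, 0.003, 0.004))    # mode 6: hinder immune 2 -> supporter
MODE_STAGE <- c("alarm-reaction", "alarm-reaction", "resistance",
                "resistance", "resistance", "exhaustion")
MODE_OBJECT <- c("Ignorant->Supporter", "Ignorant->Amplifier",
                 "Supporter->Immune1", "Amplifier->Immune2",
                 "Amplifier->Supporter", "Immune2->Supporter")
MODE_DIRECTION <- c("hindering", "hindering", "persuasion", "persuasion",
                    "hindering", "hindering")

#' Benchmark configuration of the I2S2R model
#'
#' The calibrated no-intervention configuration: transmission and recovery
#' rates estimated from the COVID-19 microblogging engagement case, turnover
#' `c = g = 0.001`, mean degree `k = 50`, nominal population 100,000, and the
#' initial state `(I, ES, EA, RS, RA) = (0.9, 0.003, 0.003, 0, 0)` (a mostly
#' ignorant field seeded with a small density of each engager type).
#'
#' @return A list with elements `params` ([model_parameters()]),
#'   `adjustments` (zero [intervention()]) and `initial` ([state()]).
#' @export
benchmark_config <- function() {
  list(params = model_parameters(alpha1 = 0.035, alpha2 = 0.075,
                                 beta1 = 0.03, beta2 = 0.005,
                                 gamma1 = 0.03, gamma2 = 0.005,
                                 theta = 0.005, tau = 0.005,
                                 c = 0.001, g = 0.001, k = 50, N = 100000),
       adjustments = intervention(),
       initial = state(0.9, 0.003, 0.003, 0, 0))
}

#' Look up one intervention scenario
#'
#' Returns the scenario for a given mode (1-6, selecting which transition is
#' adjusted) and intensity level (1-4, weakest to strongest). Scenario ids
#' run 1-24 in mode-major order.
#'
#' @param mode intervention mode, 1-6.
#' @param level intervention intensity, 1-4.
#' @return A `scenario_spec`: a list with fields `scenario_id`, `mode`,
#'   `level`, `stage`, `object`, `direction` and `adjustments` (an
#'   [intervention()] with exactly one nonzero bar).
#' @examples
#' scenario(1, 3)$adjustments$alpha1_bar  # 0.025
#' @export
scenario <- function(mode, level) {
  if (!(length(mode) == 1L && mode %in% 1:6))
    stop("mode must be an integer in 1..6")
  if (!(length(level) == 1L && level %in% 1:4))
    stop("level must be an integer in 1..4")
  bar <- MODE_LEVELS[[mode]][level]
  adj_args <- stats::setNames(list(bar), MODE_TARGET[mode])
  structure(list(scenario_id = (mode - 1L) * 4L + level,
                 mode = as.integer(mode), level = as.integer(level),
                 stage = MODE_STAGE[mode], object = MODE_OBJECT[mode],
                 direction = MODE_DIRECTION[mode],
                 adjustments = do.call(intervention, adj_args)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  bar <- unlist(x$adjustments)[MODE_TARGET[x$mode]]
  cat(sprintf("Scenario %d (mode %d, level %d): %s %s, %s = %g [%s stage]\n",
              x$scenario_id, x$mode, x$level, x$direction, x$object,
              MODE_TARGET[x$mode], bar, x$stage))
  invisible(x)
}

#' All 24 intervention scenarios
#'
#' @return A list of 24 `scenario_spec`s ordered by scenario id.
#' @export
scenario_table <- function() {
  unlist(lapply(1:6, function(m) lapply(1:4, function(l) scenario(m, l))),
         recursive = FALSE)
}

#' Run the benchmark and a set of intervention scenarios
#'
#' Integrates the benchmark configuration once and each scenario once
#' (identical horizon and grid), returning trajectories and summaries. The
#' result is deterministic given the configuration.
#'
#' @param specs list of `scenario_spec`s (default: all 24).
#' @param horizon,grid_step passed to [integrate_model()].
#' @param extinction_threshold passed to [summarize_trajectory()].
#' @return A `scenario_suite`: a list with `benchmark` (list of `trajectory`,
#'   `summary`) and `scenarios` (named `"1"`..., each a list of `spec`,
#'   `trajectory`, `summary`).
#' @export
run_suite <- function(specs = scenario_table(), horizon = 1000,
                      grid_step = 0.1, extinction_threshold = 1e-4) {
  cfg <- benchmark_config()
  bench_traj <- integrate_model(cfg$initial, cfg$params, cfg$adjustments,
                                horizon = horizon, grid_step = grid_step)
  bench <- list(trajectory = bench_traj,
                summary = summarize_trajectory(bench_traj, extinction_threshold))
  runs <- lapply(specs, function(sp) {
    stopifnot(inherits(sp, "scenario_spec"))
    traj <- tryCatch(
      integrate_model(cfg$initial, cfg$params, sp$adjustments,
                      horizon = horizon, grid_step = grid_step),
      error = function(e) stop(sprintf("scenario %d: %s", sp$scenario_id,
                                       conditionMessage(e))))
    list(spec = sp, trajectory = traj,
         summary = summarize_trajectory(traj, extinction_threshold))
  })
  names(runs) <- vapply(specs, function(sp) as.character(sp$scenario_id), "")
  structure(list(benchmark = bench, scenarios = runs,
                 horizon = horizon, grid_step = grid_step,
                 extinction_threshold = extinction_threshold),
            class = "scenario_suite")
}

#' @export
print.scenario_suite <- function(x, ...) {
  cat(sprintf("I2S2R scenario suite: benchmark + %d scenario(s), horizon %g\n",
              length(x$scenarios), x$horizon))
  invisible(x)
}

classify_change <- function(rel, labels, materiality) {
  # labels = c(positive, negative); NA relative change means both values were
  # missing in the same way -> unchanged.
  if (is.na(rel)) return("unchanged")
  if (abs(rel) < materiality) return("unchanged")
  if (rel > 0) labels[1] else labels[2]
}

#' Compare a scenario summary against the benchmark summary
#'
#' Computes, for the two engager compartments `ES` and `EA`, the relative
#' changes of peak density, peak time and extinction time against the
#' benchmark, and classifies each as unchanged when the relative change is
#' below the materiality threshold. When the benchmark never reaches
#' extinction but the scenario does, the extinction change is classified as
#' `"shortened"` (and vice versa as `"lengthened"`), with an `NA` numeric
#' change.
#'
#' @param summary,benchmark `trajectory_summary` objects computed on the same
#'   horizon and grid.
#' @param materiality relative change below which an effect counts as
#'   unchanged (default 1%).
#' @return An `effect_report` data frame with one row per engager
#'   compartment: numeric changes `peak_value_change`, `peak_time_change`,
#'   `extinction_time_change` and classifications `peak_value_class`
#'   (raised/lowered/unchanged), `peak_time_class`
#'   (delayed/advanced/unchanged), `extinction_class`
#'   (lengthened/shortened/unchanged).
#' @export
compare_to_benchmark <- function(summary, benchmark, materiality = 0.01) {
  stopifnot(inherits(summary, "trajectory_summary"),
            inherits(benchmark, "trajectory_summary"))
  if (!isTRUE(all.equal(attr(summary, "horizon"), attr(benchmark, "horizon"))) ||
      !isTRUE(all.equal(attr(summary, "grid_step"), attr(benchmark, "grid_step"))))
    stop("summaries were computed on different horizons or grids")
  rows <- lapply(c("ES", "EA"), function(cmp) {
    s <- summary[summary$compartment == cmp, ]
    b <- benchmark[benchmark$compartment == cmp, ]
    rel <- function(sv, bv) if (bv == 0) ifelse(sv == 0, 0, Inf) else (sv - bv) / bv
    pv <- rel(s$peak_value, b$peak_value)
    pt <- rel(s$peak_time, b$peak_time)
    if (is.na(s$extinction_time) && is.na(b$extinction_time)) {
      et <- NA_real_; et_class <- "unchanged"
    } else if (is.na(b$extinction_time)) {
      et <- NA_real_; et_class <- "shortened"
    } else if (is.na(s$extinction_time)) {
      et <- NA_real_; et_class <- "lengthened"
    } else {
      et <- rel(s$extinction_time, b$extinction_time)
      et_class <- classify_change(et, c("lengthened", "shortened"), materiality)
    }
    data.frame(compartment = cmp,
               peak_value_change = pv, peak_time_change = pt,
               extinction_time_change = et,
               peak_value_class = classify_change(pv, c("raised", "lowered"), materiality),
               peak_time_class = classify_change(pt, c("delayed", "advanced"), materiality),
               extinction_class = et_class)
  })
  structure(do.call(rbind, rows),
            class = c("effect_report", "data.frame"),
            materiality = materiality)
}

#' @export
print.effect_report <- function(x, ...) {
  cat(sprintf("I2S2R effect report vs benchmark (materiality %g%%)\n",
              100 * attr(x, "materiality")))
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Magnitude of a mode's targeted effect
#'
#' Each intervention mode aims at one trajectory feature: mode 1 delays the
#' supporter peak, mode 2 lowers the amplifier peak, mode 3 shortens the
#' supporter extinction, mode 4 shortens the amplifier extinction, mode 5
#' lowers the supporter peak, and mode 6 targets the relapse path (its
#' conclusion is a null effect, so its "magnitude" is the largest absolute
#' relative change observed). Extinction times that are never reached are
#' censored at the horizon so that shortening from "not reached" to a finite
#' time registers as a positive effect.
#'
#' @param suite a `scenario_suite` from [run_suite()].
#' @param mode intervention mode, 1-6.
#' @return Numeric vector of effect magnitudes for levels 1-4 (signed so that
#'   the intended direction of the mode is positive).
#' @export
targeted_effect <- function(suite, mode) {
  stopifnot(inherits(suite, "scenario_suite"), mode %in% 1:6)
  bench <- suite$benchmark$summary
  horizon <- suite$horizon
  get <- function(summary, cmp, col) {
    v <- summary[summary$compartment == cmp, col]
    if (col == "extinction_time" && is.na(v)) horizon else v
  }
  vapply(1:4, function(level) {
    id <- as.character((mode - 1L) * 4L + level)
    run <- suite$scenarios[[id]]
    if (is.null(run)) stop(sprintf("scenario %s not present in suite", id))
    s <- run$summary
    switch(mode,
      get(s, "ES", "peak_time") - get(bench, "ES", "peak_time"),
      get(bench, "EA", "peak_value") - get(s, "EA", "peak_value"),
      get(bench, "ES", "extinction_time") - get(s, "ES", "extinction_time"),
      get(bench, "EA", "extinction_time") - get(s, "EA", "extinction_time"),
      get(bench, "ES", "peak_value") - get(s, "ES", "peak_value"),
      {
        rep <- compare_to_benchmark(s, bench,
                                    materiality = .Machine$double.eps)
        max(abs(rep$peak_value_change), abs(rep$peak_time_change),
            abs(rep$extinction_time_change), na.rm = TRUE)
      })
  }, numeric(1))
}

#' Tabulate a suite's summaries and classifications
#'
#' One row per scenario and engager compartment, mirroring the scenario
#' registry columns plus the summary statistics and the three-way
#' classifications against the benchmark.
#'
#' @param suite a `scenario_suite`.
#' @param materiality passed to [compare_to_benchmark()].
#' @return A data frame.
#' @export
suite_table <- function(suite, materiality = 0.01) {
  stopifnot(inherits(suite, "scenario_suite"))
  bench <- suite$benchmark$summary
  bench_rows <- do.call(rbind, lapply(c("ES", "EA"), function(cmp) {
    b <- bench[bench$compartment == cmp, ]
    data.frame(scenario_id = 0L, mode = NA_integer_, level = NA_integer_,
               stage = "benchmark", direction = "none", compartment = cmp,
               peak_value = b$peak_value, peak_time = b$peak_time,
               extinction_time = b$extinction_time,
               peak_value_class = "unchanged", peak_time_class = "unchanged",
               extinction_class = "unchanged")
  }))
  rows <- lapply(suite$scenarios, function(run) {
    rep <- compare_to_benchmark(run$summary, bench, materiality)
    do.call(rbind, lapply(c("ES", "EA"), function(cmp) {
      s <- run$summary[run$summary$compartment == cmp, ]
      r <- rep[rep$compartment == cmp, ]
      data.frame(scenario_id = run$spec$scenario_id, mode = run$spec$mode,
                 level = run$spec$level, stage = run$spec$stage,
                 direction = run$spec$direction, compartment = cmp,
                 peak_value = s$peak_value, peak_time = s$peak_time,
                 extinction_time = s$extinction_time,
                 peak_value_class = r$peak_value_class,
                 peak_time_class = r$peak_time_class,
                 extinction_class = r$extinction_class)
    }))
  })
  out <- rbind(bench_rows, do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
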