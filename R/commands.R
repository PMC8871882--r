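# Command bodies backing the CLI wrapper (inst/cli/i2s2r). Each takes a
# run_config, writes its outputs under out_dir (or prints to stdout when
# out_dir is NULL) and returns its main result invisibly. Validation
# problems signal an "i2s2r_validation_error", which the wrapper maps to
# exit status 2.

out_path <- function(out_dir, name) {
  if (is.null(out_dir)) return(NULL)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(out_dir, name)
}

log_msg <- function(verbose, ...) if (verbose) message(...)

#' Run a single simulation from a configuration
#'
#' Integrates the configured model (benchmark or intervention scenario),
#' writes `trajectory.csv` and `summary.csv` under `out_dir` and logs the
#' effective (post-intervention) rates before integrating.
#'
#' @param config a [run_config()].
#' @param out_dir output directory; when `NULL` the summary is printed to
#'   standard output and nothing is written.
#' @param verbose emit progress messages on standard error.
#' @return Invisibly, a list with `trajectory` and `summary`.
#' @export
cmd_run <- function(config = run_config(), out_dir = NULL, verbose = TRUE) {
  config <- validate_run_config(config)
  params <- config_params(config)
  adj <- config_intervention(config)
  init <- config_initial(config)
  rates <- effective_rates(params, adj)
  log_msg(verbose, "effective rates: ",
          paste(sprintf("%s=%g", names(rates), unlist(rates)), collapse = " "))
  traj <- integrate_model(init, params, adj,
                          horizon = config$simulation$horizon,
                          grid_step = config$simulation$grid_step)
  summ <- summarize_trajectory(traj, config$simulation$extinction_threshold)
  tp <- out_path(out_dir, "trajectory.csv")
  if (!is.null(tp)) {
    write_trajectory(traj, tp)
    utils::write.csv(as.data.frame(summ), file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    log_msg(verbose, "wrote ", tp)
  } else {
    print(summ)
  }
  invisible(list(trajectory = traj, summary = summ))
}

#' Run the intervention-scenario suite from a configuration
#'
#' Integrates the benchmark plus the selected scenarios (all 24 by default),
#' writes one trajectory file per run and a single comparison table
#' `suite_summary.csv` with the classifications against the benchmark.
#'
#' @inheritParams cmd_run
#' @param modes intervention modes to include (default all six).
#' @return Invisibly, the `scenario_suite`.
#' @export
cmd_suite <- function(config = run_config(), out_dir = NULL, modes = 1:6,
                      verbose = TRUE) {
  config <- validate_run_config(config)
  specs <- Filter(function(sp) sp$mode %in% modes, scenario_table())
  log_msg(verbose, "running benchmark + ", length(specs), " scenario(s)")
  suite <- run_suite(specs, horizon = config$simulation$horizon,
                     grid_step = config$simulation$grid_step,
                     extinction_threshold = config$simulation$extinction_threshold)
  tab <- suite_table(suite, materiality = config$simulation$materiality)
  if (!is.null(out_dir)) {
    write_trajectory(suite$benchmark$trajectory,
                     out_path(out_dir, "trajectory_benchmark.csv"))
    for (run in suite$scenarios)
      write_trajectory(run$trajectory,
                       out_path(out_dir,
                                sprintf("trajectory_scenario_%02d.csv",
                                        run$spec$scenario_id)))
    utils::write.csv(tab, file.path(out_dir, "suite_summary.csv"),
                     row.names = FALSE)
    log_msg(verbose, "wrote ", file.path(out_dir, "suite_summary.csv"))
  } else {
    print(tab, row.names = FALSE)
  }
  invisible(suite)
}

#' Equilibrium and stability report from a configuration
#'
#' Locates equilibria by seeded multi-start Newton iteration and writes (or
#' prints) a structured text report with coordinates, residuals, eigenvalues
#' and the local stability classification; the closed-form rumor-free
#' equilibrium is reported first.
#'
#' @inheritParams cmd_run
#' @param n_starts number of random starts for [find_equilibria()].
#' @return Invisibly, the list of `equilibrium_report`s.
#' @export
cmd_stability <- function(config = run_config(), out_dir = NULL,
                          n_starts = 40, verbose = TRUE) {
  config <- validate_run_config(config)
  params <- config_params(config)
  adj <- config_intervention(config)
  reports <- find_equilibria(params, adj, n_starts = n_starts,
                             seed = config$seed)
  txt <- utils::capture.output({
    cat("I2S2R equilibrium report (", length(reports), " equilibria, seed ",
        config$seed, ")\n", sep = "")
    for (r in reports) print(r)
  })
  rp <- out_path(out_dir, "equilibria.txt")
  if (!is.null(rp)) {
    writeLines(txt, rp)
    log_msg(verbose, "wrote ", rp)
  } else {
    cat(txt, sep = "\n")
  }
  invisible(reports)
}

#' Role-cluster an engager table from a configuration
#'
#' Reads a per-user feature table (or synthesizes one with the configured
#' group sizes and seed), clusters it with DBSCAN and writes (or prints) the
#' role summary together with the percent contrasts of each cluster against
#' the advocate cluster.
#'
#' @inheritParams cmd_run
#' @param input path to a feature table; `NULL` synthesizes one.
#' @return Invisibly, a list with `summary` (a `role_cluster_summary`) and
#'   `contrasts`.
#' @export
cmd_cluster <- function(config = run_config(), input = NULL, out_dir = NULL,
                        verbose = TRUE) {
  config <- validate_run_config(config)
  clu <- config$clustering
  tab <- if (is.null(input)) {
    log_msg(verbose, "synthesizing engager table (",
            clu$n_advocates, "/", clu$n_supporters, "/", clu$n_amplifiers,
            ", seed ", config$seed, ")")
    generate_synthetic_engagers(clu$n_advocates, clu$n_supporters,
                                clu$n_amplifiers, seed = config$seed)
  } else {
    read_engager_table(input)
  }
  summ <- cluster_engagers(tab, eps = clu$eps, min_pts = clu$min_pts)
  adv <- summ[summ$label == "advocate", ]
  contrasts <- NULL
  if (nrow(adv) == 1L) {
    feats <- ENGAGER_FEATURES[1:4]
    rows <- summ[!summ$label %in% c("advocate", "noise"), ]
    contrasts <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
      vals <- vapply(feats, function(f)
        if (adv[[f]] > 0) percent_reduction(adv[[f]], rows[i, f]) else NA_real_,
        numeric(1))
      data.frame(label = rows$label[i], feature = feats,
                 percent_reduction_vs_advocate = vals)
    }))
  }
  if (!is.null(out_dir)) {
    utils::write.csv(as.data.frame(summ),
                     out_path(out_dir, "role_clusters.csv"), row.names = FALSE)
    if (!is.null(contrasts))
      utils::write.csv(contrasts, file.path(out_dir, "role_contrasts.csv"),
                       row.names = FALSE)
    log_msg(verbose, "wrote ", file.path(out_dir, "role_clusters.csv"))
  } else {
    print(summ)
    if (!is.null(contrasts)) print(contrasts, row.names = FALSE)
  }
  invisible(list(summary = summ, contrasts = contrasts))
}

#' Write a synthetic engager table from a configuration
#'
#' @inheritParams cmd_cluster
#' @param path output file (default `engagers.csv` under `out_dir`).
#' @return Invisibly, the generated table.
#' @export
cmd_synth <- function(config = run_config(), out_dir = ".", path = NULL,
                      verbose = TRUE) {
  config <- validate_run_config(config)
  clu <- config$clustering
  tab <- generate_synthetic_engagers(clu$n_advocates, clu$n_supporters,
                                     clu$n_amplifiers, seed = config$seed)
  if (is.null(path)) path <- out_path(out_dir, "engagers.csv")
  write_engager_table(tab, path)
  log_msg(verbose, "wrote ", path, " (", nrow(tab), " users)")
  invisible(tab)
}
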