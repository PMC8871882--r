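test_that("the benchmark configuration carries the calibrated values", {
  cfg <- benchmark_config()
  expect_equal(cfg$params$alpha2, 0.075)
  expect_equal(cfg$params$alpha1, 0.035)
  expect_equal(cfg$params$c, 0.001)
  expect_equal(cfg$params$k, 50)
  expect_equal(cfg$params$N, 100000)
  expect_equal(unname(unclass(cfg$initial)), c(0.9, 0.003, 0.003, 0, 0))
  expect_true(all(unlist(cfg$adjustments) == 0))
})

test_that("the scenario registry reproduces the 24 intervention settings", {
  expect_equal(scenario(1, 3)$adjustments$alpha1_bar, 0.025)
  expect_equal(scenario(4, 2)$adjustments$gamma2_bar, -0.02)
  expect_equal(scenario(6, 1)$adjustments$tau_bar, 0.001)
  specs <- scenario_table()
  expect_length(specs, 24L)
  expect_equal(vapply(specs, `[[`, 1L, "scenario_id"), 1:24)
  for (sp in specs) {
    bars <- unlist(sp$adjustments)
    expect_equal(sum(bars != 0), 1L)          # one adjustable rate per run
    nz <- bars[bars != 0]
    if (sp$direction == "persuasion") expect_lt(nz, 0) else expect_gt(nz, 0)
  }
  # intensity strictly increases with level inside every mode
  for (m in 1:6) {
    mags <- vapply(1:4, function(l) max(abs(unlist(scenario(m, l)$adjustments))),
                   numeric(1))
    expect_true(all(diff(mags) > 0))
  }
  expect_error(scenario(7, 1), "mode")
  expect_error(scenario(2, 0), "level")
})

test_that("suites run deterministically and degrade gracefully", {
  s0 <- run_suite(list(), horizon = 120, grid_step = 0.1)
  expect_length(s0$scenarios, 0L)
  expect_s3_class(s0$benchmark$summary, "trajectory_summary")
  rep <- compare_to_benchmark(s0$benchmark$summary, s0$benchmark$summary)
  expect_true(all(rep$peak_value_class == "unchanged"))
  expect_true(all(rep$peak_time_class == "unchanged"))
  expect_true(all(rep$extinction_class == "unchanged"))

  s2 <- run_suite(list(scenario(3, 2), scenario(3, 2)), horizon = 120,
                  grid_step = 0.1)
  expect_length(s2$scenarios, 2L)
  expect_equal(as.data.frame(s2$scenarios[[1]]$summary),
               as.data.frame(s2$scenarios[[2]]$summary))
})

test_that("early-stage hindering delays the supporter peak and raises the amplifier peak", {
  suite <- run_suite(list(scenario(1, 4)), horizon = 200, grid_step = 0.1)
  rep <- compare_to_benchmark(suite$scenarios[["4"]]$summary,
                              suite$benchmark$summary)
  expect_equal(rep$peak_time_class[rep$compartment == "ES"], "delayed")
  expect_equal(rep$peak_value_class[rep$compartment == "EA"], "raised")
})

test_that("suite tables cover benchmark and scenarios for both engager classes", {
  suite <- run_suite(list(scenario(2, 1), scenario(5, 3)), horizon = 150,
                     grid_step = 0.1)
  tab <- suite_table(suite)
  expect_equal(nrow(tab), 6L)                       # (benchmark + 2) x 2
  expect_setequal(tab$compartment, c("ES", "EA"))
  expect_true(all(tab$peak_value_class[tab$scenario_id == 0] == "unchanged"))
  expect_error(compare_to_benchmark(
    summarize_trajectory(integrate_model(bench$initial, bench$params,
                                         horizon = 50, grid_step = 0.1)),
    suite$benchmark$summary), "different horizons")
})
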