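test_that("total density follows the closed-form turnover solution", {
  traj <- integrate_model(bench$initial, bench$params, horizon = 300,
                          grid_step = 0.5)
  S <- rowSums(traj[, c("I", "ES", "EA", "RS", "RA")])
  expect_lt(max(abs(S - (1 + (0.906 - 1) * exp(-0.001 * traj$t)))), 1e-6)
})

test_that("a fully ignorant field stays ignorant", {
  traj <- integrate_model(c(1, 0, 0, 0, 0), bench$params, horizon = 50,
                          grid_step = 0.5)
  expect_lt(max(abs(traj$I - 1)), 1e-10)
  expect_equal(max(traj$ES, traj$EA, traj$RS, traj$RA), 0)
})

test_that("the Euler reference takes exact first-order steps", {
  h <- 0.01
  one <- euler_reference(bench$initial, bench$params, horizon = h, step = h)
  expect_equal(one$I[2], 0.9 + h * (-0.01475), tolerance = 1e-14)
  none <- euler_reference(bench$initial, bench$params, horizon = 0, step = h)
  expect_equal(nrow(none), 1L)
  expect_equal(unlist(none[1, c("I", "ES", "EA", "RS", "RA")]),
               unclass(bench$initial), ignore_attr = TRUE)
  expect_error(euler_reference(bench$initial, bench$params, horizon = 1,
                               step = 0.5))
})

test_that("Euler error vs the adaptive solution shrinks linearly in step", {
  traj <- integrate_model(bench$initial, bench$params, horizon = 20,
                          grid_step = 0.1)
  ref <- unlist(traj[which.min(abs(traj$t - 20)),
                     c("I", "ES", "EA", "RS", "RA")])
  err <- vapply(c(1e-2, 5e-3), function(h) {
    e <- euler_reference(bench$initial, bench$params, horizon = 20, step = h)
    max(abs(unlist(e[nrow(e), c("I", "ES", "EA", "RS", "RA")]) - ref))
  }, numeric(1))
  expect_lt(err[1], 5e-2)
  ratio <- err[1] / err[2]
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.8)
})

test_that("summaries handle degenerate and constructed series", {
  t <- seq(0, 10, by = 1)
  # constant-zero compartment: peak 0 at t = 0, extinction never reached
  s <- summarize_trajectory(fake_trajectory(t, list(ES = rep(0, 11))),
                            extinction_threshold = 1e-4)
  es <- s[s$compartment == "ES", ]
  expect_equal(es$peak_value, 0)
  expect_equal(es$peak_time, 0)
  expect_true(is.na(es$extinction_time))
  # symmetric triangle: refined peak stays on the middle grid point
  tri <- c(0:5, 4:0) / 5
  s2 <- summarize_trajectory(fake_trajectory(t, list(EA = tri)))
  ea <- s2[s2$compartment == "EA", ]
  expect_equal(ea$peak_time, 5)
  expect_equal(ea$peak_value, 1)
  # extinction: first grid time after the peak below the threshold
  expect_equal(ea$extinction_time, 10)
})

test_that("grid peaks agree with a dense-grid brute-force maximum", {
  coarse <- integrate_model(bench$initial, bench$params, horizon = 40,
                            grid_step = 0.1)
  dense <- integrate_model(bench$initial, bench$params, horizon = 40,
                           grid_step = 0.01)
  s <- summarize_trajectory(coarse)
  es <- s[s$compartment == "ES", ]
  expect_equal(es$peak_value, max(dense$ES), tolerance = 1e-6)
  expect_equal(es$peak_time, dense$t[which.max(dense$ES)], tolerance = 0.02)
})

test_that("summaries are stable under grid refinement", {
  a <- summarize_trajectory(integrate_model(bench$initial, bench$params,
                                            horizon = 60, grid_step = 0.1))
  b <- summarize_trajectory(integrate_model(bench$initial, bench$params,
                                            horizon = 60, grid_step = 0.05))
  # the supporter peak is broad and interpolates to full precision; the
  # amplifier peak is an order of magnitude sharper, so its refined value
  # carries a correspondingly larger interpolation error
  tol <- c(ES = 1e-6, EA = 1e-4)
  for (cmp in c("ES", "EA")) {
    ra <- a[a$compartment == cmp, ]; rb <- b[b$compartment == cmp, ]
    expect_lt(abs(ra$peak_value - rb$peak_value), tol[[cmp]])
    expect_lt(abs(ra$peak_time - rb$peak_time), 0.1)
  }
})

test_that("non-negativity holds along the benchmark trajectory", {
  traj <- integrate_model(bench$initial, bench$params, horizon = 200,
                          grid_step = 0.2)
  expect_true(all(as.matrix(traj[, c("I", "ES", "EA", "RS", "RA")]) >= 0))
})
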