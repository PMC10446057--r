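test_that("identical seeds reproduce the iteration table bitwise", {
  sc <- observed_scenario()
  a <- run_monte_carlo(sc, N = 50, seed = 123)
  b <- run_monte_carlo(sc, N = 50, seed = 123)
  expect_identical(a, b)
  c <- run_monte_carlo(sc, N = 50, seed = 124)
  expect_false(isTRUE(all.equal(a$shift_avg, c$shift_avg)))
  expect_error(run_monte_carlo(sc, N = 0), "N")
})

test_that("sampled determinants stay inside their distribution supports", {
  sc <- observed_scenario()
  r <- run_monte_carlo(sc, N = 200, seed = 5)
  expect_equal(nrow(r), 200)
  expect_true(all(r$V_room >= 1300 & r$V_room <= 1500))
  expect_true(all(r$AER >= 2 & r$AER <= 8))
  expect_true(all(r$V_NF >= 1 & r$V_NF <= 2))
  expect_true(all(r$beta_task1 >= 0.649 & r$beta_task1 <= 10))
  expect_true(all(r$G_task3 >= 1.85 & r$G_task3 <= 7.4))
  expect_true(all(r$G_task4 == 0))
  expect_true(all(r$avg_task1 > 0))
})

test_that("a degenerate point scenario equals a direct timeline solve", {
  sc <- point_scenario()
  r <- run_monte_carlo(sc, N = 1, seed = 9)
  sched <- realize_schedule(sc)
  geom <- zone_geometry(1.5, 1400)
  flow <- airflow_params(3.2, 5, 1400)
  tl <- simulate_timeline(sched[, c("duration", "G")], geom, flow,
                          grid = sum(sched$duration))
  ints <- attr(tl, "integrals")
  expect_equal(r$shift_avg, ints[["int_NF"]] / sum(sched$duration),
               tolerance = 1e-12)
  win <- attr(sched, "windows")
  expect_equal(r$dur_task1, win$end[1] - win$start[1])
  expect_equal(r$shift_duration, 56)
})

test_that("the shift average reconstructs from task averages", {
  r <- run_monte_carlo(observed_scenario(), N = 100, seed = 77)
  num <- r$avg_task1 * r$dur_task1 + r$avg_task2 * r$dur_task2 +
    r$avg_task3 * r$dur_task3 + r$avg_task4 * r$dur_task4
  den <- r$dur_task1 + r$dur_task2 + r$dur_task3 + r$dur_task4
  expect_equal(r$shift_avg, num / den, tolerance = 1e-9)
})

test_that("doubling every emission distribution doubles all concentrations", {
  sc <- observed_scenario()
  sc2 <- sc
  for (k in seq_along(sc2$tasks)) {
    g <- sc2$tasks[[k]]$G
    sc2$tasks[[k]]$G <- if (g$kind == "point") dist_point(2 * g$value)
      else dist_triangular(2 * g$min, 2 * g$mode, 2 * g$max)
  }
  a <- run_monte_carlo(sc, N = 30, seed = 42)
  b <- run_monte_carlo(sc2, N = 30, seed = 42)
  for (k in 1:4)
    expect_equal(b[[paste0("avg_task", k)]],
                 2 * a[[paste0("avg_task", k)]], tolerance = 1e-12)
  expect_equal(b$shift_avg, 2 * a$shift_avg, tolerance = 1e-12)
  expect_equal(b$dur_task2, a$dur_task2)  # durations untouched
})

test_that("the geometric mean is stable across seeds at full size", {
  sc <- observed_scenario()
  gm1 <- exp(mean(log(run_monte_carlo(sc, N = 4000, seed = 1)$shift_avg)))
  gm2 <- exp(mean(log(run_monte_carlo(sc, N = 4000, seed = 2)$shift_avg)))
  expect_lt(abs(gm1 / gm2 - 1), 0.02)
})

test_that("kept traces follow the realized schedule", {
  sc <- point_scenario()
  r <- run_monte_carlo(sc, N = 2, seed = 3, keep_traces = 1)
  traces <- attr(r, "traces")
  expect_length(traces, 1)
  tr <- traces[[1]]
  expect_equal(tr$time_min[1], 0)
  expect_true(all(diff(tr$time_min) > 0))
  expect_true(all(tr$C_NF >= 0 & tr$C_FF >= 0))
  expect_lte(max(tr$time_min), r$shift_duration[1])
})
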