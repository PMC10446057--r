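test_that("the packaged observed scenario reproduces the field parametrization", {
  sc <- observed_scenario()
  expect_s3_class(sc, "shift_spec")
  expect_equal(sc$V_room[c("kind", "min", "max")],
                   list(kind = "uniform", min = 1300, max = 1500))
  expect_equal(sc$AER[c("min", "max")], list(min = 2, max = 8))
  expect_equal(sc$V_NF[c("min", "max")], list(min = 1, max = 2))
  expect_equal(sc$beta[c("kind", "min", "mode", "max")],
                   list(kind = "triangular", min = 0.649, mode = 3.2,
                        max = 10))
  expect_equal(sc$Q_lev, 0)
  expect_length(sc$tasks, 4)
  expect_equal(vapply(sc$tasks, `[[`, integer(1), "n_repetitions"),
               c(4L, 10L, 17L, 1L))
  expect_equal(sc$tasks[[1]]$G[c("min", "mode", "max")],
               list(min = 0.43, mode = 0.87, max = 1.74))
  expect_equal(sc$tasks[[3]]$G[c("min", "mode", "max")],
               list(min = 1.85, mode = 3.7, max = 7.4))
  expect_equal(sc$tasks[[4]]$G$value, 0)
  expect_equal(sc$oelvs$TiO2, 10)
  expect_equal(sc$oelvs$MicroMica, 5)
  # mean realized durations: 4x23 + 10x2 + 17x1.5 + 10 = 147.5 min
  mean_dur <- sum(vapply(sc$tasks, function(tk)
    tk$n_repetitions * dist_mean(tk$t_pouring), numeric(1)))
  expect_equal(mean_dur, 147.5)
})

test_that("the full scenario library loads with the documented variants", {
  lib <- scenario_library()
  expect_named(lib, scenario_names())
  expect_equal(lib$beta_halved$beta[c("min", "mode", "max")],
               list(min = 0.33, mode = 1.6, max = 5))
  expect_equal(lib$g_widened$tasks[[1]]$G[c("min", "mode", "max")],
               list(min = 0.87, mode = 0.87, max = 3.48))
  expect_equal(lib$lev$Q_lev, 9.6)
  expect_equal(lib$small_room$V_room$value, 100)
  expect_equal(lib$large_room$V_room$value, 10000)
  expect_equal(lib$aer_reduced$AER[c("min", "max")],
               list(min = 0.4, max = 1.6))
  expect_equal(lib$worst_case$beta$min, 0.325)
  expect_equal(lib$worst_case$AER$max, 1.6)
})

test_that("configuration validation names the offending key", {
  cfg <- list(environment = list(V_room = 1400, AER = 5, V_NF = 1.5,
                                 beta = list(kind = "triangular", min = 5,
                                             mode = 3.2, max = 10)),
              tasks = list(list(name = "t", n_repetitions = 1,
                                t_pouring = 2, t_G = 1, G = 1)))
  expect_error(load_scenario(cfg), "min")
  cfg$environment$beta <- 3.2
  cfg$tasks[[1]]$G <- NULL
  expect_error(load_scenario(cfg), "'G'")
  cfg$tasks[[1]]$G <- 1
  cfg$environment$AER <- NULL
  expect_error(load_scenario(cfg), "'AER'")
})

test_that("omitted optional fields fall back to documented defaults", {
  cfg <- list(environment = list(V_room = 1400, AER = 5, V_NF = 1.5,
                                 beta = 3.2),
              tasks = list(list(name = "t", n_repetitions = 2,
                                t_pouring = 2, t_G = 1, G = 1)))
  sc <- load_scenario(cfg)
  expect_equal(sc$Q_lev, 0)
  expect_equal(sc$gap, 0)
  expect_equal(sc$scopes$beta, "per_repetition")
  expect_equal(sc$scopes$V_room, "per_shift")
  expect_equal(sc$tasks[[1]]$substance, "none")
})

test_that("emission-rate rescaling preserves the released mass", {
  expect_equal(rescale_emission(1.74, 0.5, 1.0), 0.87)
  expect_equal(rescale_emission(2.2, 3, 3), 2.2)
  expect_equal(rescale_emission(rescale_emission(1.3, 2, 5), 5, 2), 1.3)
  expect_error(rescale_emission(1, 0, 1), "emission times")
})

test_that("realized schedules expand repetitions into emit/pause segments", {
  sc <- observed_scenario()
  set.seed(11)
  sched <- realize_schedule(sc)
  win <- attr(sched, "windows")

  # task 2: point durations, t_G == t_pouring -> 10 pure emission segments
  t2 <- sched[sched$task == 2, ]
  expect_equal(nrow(t2), 10)
  expect_true(all(t2$duration == 2 & t2$emitting))

  # task 3: 1 emitting minute then a pause within each 1-2 min repetition
  t3 <- sched[sched$task == 3, ]
  expect_true(all(t3$duration[t3$emitting] == 1))
  expect_true(all(t3$G[!t3$emitting] == 0))

  # windows partition the shift: contiguous, no overlap, full coverage
  expect_equal(win$start[-1], win$end[-nrow(win)])
  expect_equal(win$start[1], 0)
  expect_equal(win$end[nrow(win)], sum(sched$duration))

  # per-task durations equal the summed pouring times
  for (k in 1:4)
    expect_equal(sum(sched$duration[sched$task == k]),
                 win$end[k] - win$start[k])
})

test_that("t_G longer than t_pouring is truncated with a warning", {
  sc <- shift_spec("trunc", 1400, 5, 1.5, 3.2, tasks = list(
    task_spec("bad", 1, t_pouring = 2, t_G = 5, G = 1)))
  expect_warning(sched <- realize_schedule(sc), "truncated")
  expect_equal(sum(sched$duration), 2)
  expect_true(all(sched$emitting))
})

test_that("inter-task gaps appear as unattributed zero-emission segments", {
  sc <- shift_spec("gapped", 1400, 5, 1.5, 3.2, gap = 3, tasks = list(
    task_spec("a", 1, t_pouring = 2, t_G = 2, G = 1),
    task_spec("b", 1, t_pouring = 2, t_G = 2, G = 1)))
  sched <- realize_schedule(sc)
  gaps <- sched[is.na(sched$task), ]
  expect_equal(nrow(gaps), 1)
  expect_equal(gaps$duration, 3)
  expect_equal(gaps$G, 0)
  expect_equal(sum(sched$duration), 7)
  win <- attr(sched, "windows")
  expect_equal(win$start[2] - win$end[1], 3)
})
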