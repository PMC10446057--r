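test_that("decay fits recover a pure exponential exactly", {
  tr <- data.frame(time_min = 0:10,
                   concentration_mg_m3 = 2 * exp(-0.5 * (0:10)))
  fit <- fit_decay(tr, c(0, 10))
  expect_equal(fit$lambda, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # scale invariance: lambda unchanged under C -> k C
  tr2 <- tr; tr2$concentration_mg_m3 <- 37 * tr2$concentration_mg_m3
  expect_equal(fit_decay(tr2, c(0, 10))$lambda, 0.5, tolerance = 1e-12)

  # background is removed before the log transform
  tr3 <- tr; tr3$concentration_mg_m3 <- tr3$concentration_mg_m3 + 0.3
  expect_equal(fit_decay(tr3, c(0, 10), background = 0.3)$lambda, 0.5,
               tolerance = 1e-10)
})

test_that("degenerate decay windows are rejected", {
  tr <- data.frame(time_min = 0:10,
                   concentration_mg_m3 = c(2 * exp(-0.5 * (0:9)), 0))
  expect_error(fit_decay(tr, c(0, 10)), "non-positive")
  expect_error(fit_decay(tr, c(0, 1)), "fewer than 3")
})

test_that("the OLS confidence interval covers the true decay rate", {
  set.seed(404)
  lambda <- 0.5
  t <- seq(0, 6, length.out = 30)
  hits <- 0
  n_rep <- 500
  for (i in seq_len(n_rep)) {
    conc <- 2 * exp(-lambda * t) * exp(rnorm(30, 0, log(1.1)))
    fit <- fit_decay(data.frame(time_min = t, concentration_mg_m3 = conc),
                     c(0, 6))
    ci <- fit$lambda + c(-1, 1) * qt(0.975, fit$n - 2) * fit$se_lambda
    if (lambda >= ci[1] && lambda <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.90)
})

test_that("NF decay rate converts to the inter-zonal airflow", {
  expect_equal(beta_from_decay(2.1333, 1.5), 3.2, tolerance = 1e-4)
  expect_error(beta_from_decay(-1, 1.5), "> 0")

  # round trip against the core model in the clean-far-field limit
  g <- zone_geometry(1.5, 1e8)
  a <- airflow_params(3.2, 60, 1e8)
  times <- seq(0, 1, by = 0.05)
  conc <- vapply(times[-1], function(t)
    propagate(zone_state(1, 0), g, a, 0, t)$C_NF, numeric(1))
  tr <- data.frame(time_min = times, concentration_mg_m3 = c(1, conc))
  fit <- fit_decay(tr, c(0, 1))
  expect_equal(beta_from_decay(fit$lambda, 1.5), 3.2, tolerance = 1e-6)
})

test_that("emission back-calculation inverts the forward model", {
  geom <- zone_geometry(1.5, 1400)
  flow <- airflow_params(3.2, 5, 1400)

  # steady-state reduction: G = C_NF / (1/Q + 1/beta)
  long <- data.frame(duration = 1e6, G = 1)
  G <- back_calculate_G(0.2793321, long, geom, flow)
  expect_equal(G, 0.87, tolerance = 1e-4)

  # linearity: doubling the observed mean doubles G
  expect_equal(back_calculate_G(2 * 0.2793321, long, geom, flow), 2 * G,
               tolerance = 1e-12)

  # noiseless synthetic task trace: forward then inverse is the identity
  sched <- do.call(rbind, replicate(4, data.frame(
    duration = c(12, 11), G = c(0.87, 0)), simplify = FALSE))
  tl <- simulate_timeline(sched, geom, flow, grid = 1)
  observed <- attr(tl, "integrals")[["int_NF"]] / sum(sched$duration)
  expect_equal(back_calculate_G(observed, sched, geom, flow), 0.87,
               tolerance = 1e-9)

  expect_error(back_calculate_G(0.3, data.frame(duration = 5, G = 0),
                                geom, flow), "no emitting")
  expect_error(back_calculate_G(-1, sched, geom, flow), "> 0")
})

test_that("trace CSV round trips through read and write", {
  tr <- data.frame(time_min = 0:5,
                   concentration_mg_m3 = c(1, 2, 1.5, 1.2, 1.1, 1.05))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back, tr)
  # timeline export picks the requested zone
  g <- zone_geometry(1.5, 1400)
  a <- airflow_params(3.2, 5, 1400)
  tl <- simulate_timeline(list(emission_segment(5, 1)), g, a)
  write_trace(tl, path, zone = "FF")
  expect_equal(read_trace(path)$concentration_mg_m3, tl$C_FF)
})
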