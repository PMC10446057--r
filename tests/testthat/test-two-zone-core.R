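geom <- zone_geometry(V_NF = 1.5, V_room = 1400)
flow <- airflow_params(beta = 3.2, AER = 5, V_room = 1400)

test_that("constructors enforce the model invariants", {
  expect_error(zone_geometry(2, 2), "V_NF")
  expect_error(zone_geometry(-1, 10), "V_NF")
  expect_error(airflow_params(0, 5, 1400), "beta")
  expect_error(airflow_params(3.2, 0, 1400), "AER")
  expect_error(airflow_params(3.2, 5, 1400, Q_lev = 200), "Q_lev")
  expect_equal(zone_geometry(1.5, 1400)$V_FF, 1398.5)
  expect_equal(airflow_params(3.2, 5, 1400)$Q, 5 * 1400 / 60)
})

test_that("steady state matches the closed form without local exhaust", {
  expect_equal(unlist(steady_state(0, geom, flow)),
               c(C_NF = 0, C_FF = 0))
  ss <- steady_state(0.87, geom, flow)
  expect_equal(ss$C_FF, 0.87 / (5 * 1400 / 60), tolerance = 1e-9)
  expect_equal(ss$C_FF, 0.0074571, tolerance = 1e-4)
  expect_equal(ss$C_NF, 0.0074571 + 0.87 / 3.2, tolerance = 1e-4)
  expect_error(steady_state(-1, geom, flow), "G")
})

test_that("a local exhaust shrinks the NF excess by beta/(beta + Q_lev)", {
  lev <- airflow_params(3.2, 5, 1400, Q_lev = 9.6)
  ss <- steady_state(0.87, geom, lev)
  expect_equal(ss$C_NF - ss$C_FF, 0.87 / 12.8, tolerance = 1e-9)
  ss0 <- steady_state(0.87, geom, flow)
  # 9.6 m^3/min of NF exhaust cuts the NF excess to a quarter
  expect_equal((ss$C_NF - ss$C_FF) / (ss0$C_NF - ss0$C_FF), 0.25,
               tolerance = 1e-9)
})

test_that("the steady state is a fixed point of propagate", {
  for (af in list(flow, airflow_params(3.2, 5, 1400, Q_lev = 9.6))) {
    ss <- steady_state(1.3, geom, af)
    nxt <- propagate(ss, geom, af, G = 1.3, dt = 17)
    expect_equal(nxt$C_NF, ss$C_NF, tolerance = 1e-9)
    expect_equal(nxt$C_FF, ss$C_FF, tolerance = 1e-9)
  }
})

test_that("NF decays single-exponentially when the far field stays clean", {
  g <- zone_geometry(1.5, 1e8)
  a <- airflow_params(1.5, 60, 1e8)  # enormous general ventilation
  out <- propagate(zone_state(1, 0), g, a, G = 0, dt = 1)
  expect_equal(out$C_NF, exp(-1), tolerance = 1e-6)
})

test_that("propagate converges to the steady state for large dt", {
  out <- propagate(zone_state(2, 1), geom, flow, G = 0.87, dt = 1e6)
  ss <- steady_state(0.87, geom, flow)
  expect_equal(out$C_NF, ss$C_NF, tolerance = 1e-9)
  expect_equal(out$C_FF, ss$C_FF, tolerance = 1e-9)
})

test_that("propagate agrees with an adaptive ODE oracle on random draws", {
  set.seed(314)
  worst <- 0
  for (i in 1:200) {
    cs <- random_two_zone_case()
    got <- propagate(cs$state, cs$geometry, cs$airflow, cs$G, cs$dt)
    ref <- lsoda_oracle(cs$state$C_NF, cs$state$C_FF, cs$geometry$V_NF,
                        cs$geometry$V_FF, cs$airflow$beta, cs$airflow$Q,
                        cs$airflow$Q_lev, cs$G, cs$dt)
    scale <- max(abs(ref), 1e-12)
    worst <- max(worst, abs(c(got$C_NF, got$C_FF) - ref) / scale)
  }
  expect_lt(worst, 1e-6)
})

test_that("propagate agrees with a fixed-step RK4 oracle", {
  set.seed(99)
  for (i in 1:5) {
    cs <- random_two_zone_case()
    got <- propagate(cs$state, cs$geometry, cs$airflow, cs$G, cs$dt)
    ref <- rk4_oracle(cs$state$C_NF, cs$state$C_FF, cs$geometry$V_NF,
                      cs$geometry$V_FF, cs$airflow$beta, cs$airflow$Q,
                      cs$airflow$Q_lev, cs$G, cs$dt)
    expect_equal(c(got$C_NF, got$C_FF), ref, tolerance = 1e-7)
  }
})

test_that("a single-segment timeline reproduces propagate on the grid", {
  tl <- simulate_timeline(list(emission_segment(10, 0.87)), geom, flow,
                          grid = 1)
  for (t in 1:9) {
    p <- propagate(zone_state(0, 0), geom, flow, 0.87, t)
    expect_equal(tl$C_NF[tl$time_min == t], p$C_NF, tolerance = 1e-12)
    expect_equal(tl$C_FF[tl$time_min == t], p$C_FF, tolerance = 1e-12)
  }
  expect_error(simulate_timeline(list(), geom, flow), "empty")
})

test_that("released mass is conserved across the whole timeline", {
  # task-1 mean schedule: 4 repetitions of 12 emitting + 11 still minutes
  segs <- do.call(rbind, replicate(4, data.frame(
    duration = c(12, 11), G = c(0.87, 0)), simplify = FALSE))
  for (af in list(flow, airflow_params(3.2, 5, 1400, Q_lev = 9.6))) {
    tl <- simulate_timeline(segs, geom, af, grid = 1)
    ints <- attr(tl, "integrals")
    final <- tl[nrow(tl), ]
    released <- sum(segs$duration * segs$G)
    expect_equal(released, 41.76)
    in_air <- geom$V_NF * final$C_NF + geom$V_FF * final$C_FF
    exhausted <- af$Q_lev * ints[["int_NF"]] +
      (af$Q - af$Q_lev) * ints[["int_FF"]]
    expect_equal(in_air + exhausted, released, tolerance = 1e-9)
  }
})

test_that("exact integrals agree with trapezoid quadrature of the trace", {
  segs <- data.frame(duration = c(12, 11), G = c(0.87, 0))
  tl <- simulate_timeline(segs, geom, flow, grid = 0.005)
  trap <- function(y) sum((y[-1] + y[-length(y)]) / 2) * 0.005
  ints <- attr(tl, "integrals")
  expect_equal(trap(tl$C_NF), ints[["int_NF"]], tolerance = 1e-5)
  expect_equal(trap(tl$C_FF), ints[["int_FF"]], tolerance = 1e-5)
})

test_that("concentrations are linear in the emission rate", {
  segs <- data.frame(duration = c(5, 3, 7), G = c(1.2, 0, 2.5))
  tl1 <- simulate_timeline(segs, geom, flow, grid = 0.5)
  segs2 <- segs; segs2$G <- 2 * segs2$G
  tl2 <- simulate_timeline(segs2, geom, flow, grid = 0.5)
  expect_equal(tl2$C_NF, 2 * tl1$C_NF, tolerance = 1e-12)
  expect_equal(tl2$C_FF, 2 * tl1$C_FF, tolerance = 1e-12)
})

test_that("steady concentrations respond monotonically to ventilation", {
  set.seed(55)
  for (i in 1:50) {
    V_room <- runif(1, 100, 3000); V_NF <- runif(1, 0.5, 5)
    AER <- runif(1, 0.5, 8); G <- runif(1, 0.1, 5)
    g <- zone_geometry(V_NF, V_room)
    b <- sort(runif(2, 0.3, 15))
    lo <- steady_state(G, g, airflow_params(b[1], AER, V_room))
    hi <- steady_state(G, g, airflow_params(b[2], AER, V_room))
    expect_lte(hi$C_NF, lo$C_NF)
    a2 <- sort(runif(2, 0.5, 10))
    s_lo <- steady_state(G, g, airflow_params(b[1], a2[1], V_room))
    s_hi <- steady_state(G, g, airflow_params(b[1], a2[2], V_room))
    expect_lte(s_hi$C_FF, s_lo$C_FF)
  }
})
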