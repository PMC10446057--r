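# Independent oracles and fixture builders for the two-zone model tests.

# Classic fixed-step RK4 integration of the two-zone ODE system; kept
# deliberately separate from the package's closed-form solver.
rk4_oracle <- function(C_NF0, C_FF0, V_NF, V_FF, beta, Q, Q_lev, G, t_end,
                       n_steps = 20000) {
  deriv <- function(x) c(
    (G + (beta + Q_lev) * (x[2] - x[1])) / V_NF,
    (beta * x[1] - (beta + Q) * x[2]) / V_FF)
  h <- t_end / n_steps
  x <- c(C_NF0, C_FF0)
  for (i in seq_len(n_steps)) {
    k1 <- deriv(x)
    k2 <- deriv(x + h / 2 * k1)
    k3 <- deriv(x + h / 2 * k2)
    k4 <- deriv(x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}

# Adaptive-step oracle (lsoda) for bulk random-draw comparisons.
lsoda_oracle <- function(C_NF0, C_FF0, V_NF, V_FF, beta, Q, Q_lev, G,
                         t_end) {
  f <- function(t, x, p) list(c(
    (G + (beta + Q_lev) * (x[2] - x[1])) / V_NF,
    (beta * x[1] - (beta + Q) * x[2]) / V_FF))
  out <- deSolve::lsoda(c(C_NF0, C_FF0), c(0, t_end), f, NULL,
                        rtol = 1e-11, atol = 1e-12)
  unname(out[2, 2:3])
}

random_two_zone_case <- function() {
  V_room <- runif(1, 50, 5000)
  V_NF <- runif(1, 0.5, min(10, V_room / 5))
  AER <- runif(1, 0.2, 10)
  beta <- runif(1, 0.3, 15)
  Q <- AER * V_room / 60
  Q_lev <- if (runif(1) < 0.3) runif(1, 0, 0.5 * Q) else 0
  list(geometry = zone_geometry(V_NF, V_room),
       airflow = airflow_params(beta, AER, V_room, Q_lev),
       G = runif(1, 0, 10),
       state = zone_state(runif(1, 0, 2), runif(1, 0, 0.5)),
       dt = runif(1, 0.05, 30))
}

# Tiny deterministic scenario (all point distributions) for exactness
# checks of the Monte-Carlo plumbing.
point_scenario <- function(G1 = 0.87) {
  shift_spec(
    name = "point",
    V_room = 1400, AER = 5, V_NF = 1.5, beta = 3.2,
    tasks = list(
      task_spec("pour", 2, t_pouring = 23, t_G = 12, G = G1,
                substance = "TiO2"),
      task_spec("clean", 1, t_pouring = 10, t_G = 10, G = 0,
                substance = "TiO2")))
}
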