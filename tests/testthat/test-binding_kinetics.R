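test_that("Langmuir equilibrium occupancy behaves as an isotherm", {
  expect_equal(langmuir_equilibrium(730e-9, 730e-9), 0.5)
  # fitted constants predict the 1 uM equilibrium response magnitude
  expect_equal(1.393 * langmuir_equilibrium(1e-6, 730e-9), 0.805,
               tolerance = 5e-4)
  expect_equal(langmuir_equilibrium(1, 730e-9), 1, tolerance = 1e-6)
  expect_equal(langmuir_equilibrium(0, 730e-9), 0)
  cc <- 10^seq(-9, -4, by = 0.5)
  expect_true(all(diff(langmuir_equilibrium(cc, 730e-9)) > 0))
  expect_error(langmuir_equilibrium(-1e-9, 730e-9), "non-negative")
})

test_that("association transient rises at k_on c + k_off", {
  r <- tdna_rates()
  eq <- -0.805
  expect_equal(association_response(0, r, 1e-6, eq), 0)
  expect_equal(association_response(1e7, r, 1e-6, eq), eq)
  # half-rise time ln2 / (k_on c + k_off) ~ 218.7 s at 1 uM
  t_half <- log(2) / (r$k_on * 1e-6 + r$k_off)
  expect_equal(t_half, 218.74, tolerance = 1e-4)
  expect_equal(association_response(t_half, r, 1e-6, eq), eq / 2)
  expect_error(association_response(-1, r, 1e-6, eq), "non-negative")
})

test_that("dissociation transient is continuous at t_d and halves at ln2/k_off", {
  r <- tdna_rates()
  expect_equal(dissociation_response(1800, 1800, r$k_off, -0.7), -0.7)
  t_half <- log(2) / r$k_off
  expect_equal(t_half, 512.0, tolerance = 1e-3)
  expect_equal(dissociation_response(1800 + t_half, 1800, r$k_off, -0.7),
               -0.35)
  expect_error(dissociation_response(1799, 1800, r$k_off, -0.7), "t >= t_d")
})

test_that("pulse-shape parameters match independent hand evaluation", {
  # independent re-evaluation of the current-domain formulas on a fixed
  # arbitrary parameter set
  set.seed(101)
  for (i in 1:5) {
    k_on <- runif(1, 100, 5000); k_off <- runif(1, 1e-4, 1e-2)
    c_avg <- 10^runif(1, -7.5, -5.5); k_t <- 10^runif(1, 8, 12)
    q <- -8.3e-7
    kd <- k_off / k_on
    eq <- -1.0 * langmuir_equilibrium(c_avg, kd)
    m <- pulse_model(kinetic_rates(k_on, k_off), c_avg, k_t,
                     response_scale(eq, -1.0, q), t_a = 0, t_d = 60)
    p <- pulse_params(m)
    n_eq <- eq / q
    alpha_hand <- (k_on * c_avg * n_eq) / (k_off * n_eq + k_t * c_avg)
    beta_hand <- (k_on * c_avg + k_off) /
      (1 + (k_off * n_eq) / (k_t * c_avg))
    gamma_hand <- (c_avg + kd) * n_eq / c_avg + k_t / k_on
    expect_equal(p$alpha, alpha_hand)
    expect_equal(p$beta, beta_hand)
    expect_equal(p$gamma, gamma_hand)
    expect_gt(p$alpha, 0)
    expect_gt(p$beta, 0)
  }
})

test_that("fast-transport limit of the pulse parameters", {
  m_inf <- make_model(k_t = 1e18)
  p <- pulse_params(m_inf)
  r <- tdna_rates()
  expect_lt(p$alpha, 1e-6)
  expect_equal(p$beta, r$k_on * 1e-6 + r$k_off, tolerance = 1e-5)
  expect_gt(p$gamma, 1e10)  # diverges with k_t
})

test_that("pulse response starts at zero and plateaus at the isotherm", {
  m <- make_model(k_t = 1e9, t_d = 30)
  # W0(alpha e^alpha) = alpha makes the response vanish at t_a
  expect_equal(pulse_response(m$t_a, m), 0)
  expect_equal(pulse_response(c(-50, -1), m), c(0, 0))
  # a very long pulse reaches the equilibrium response of the isotherm
  m_long <- make_model(k_t = 1e9, t_d = 1e5)
  plateau <- pulse_response(9.9e4, m_long)
  expect_equal(plateau, m$response$delta_i_eq, tolerance = 1e-6)
})

test_that("pulse response magnitude is bounded and phase-monotone", {
  for (k_t in c(3e8, 1e10, 1e12)) {
    m <- make_model(k_t = k_t, t_d = 120)
    tg <- seq(0, 900, by = 1)
    y <- pulse_response(tg, m)
    expect_true(all(abs(y) <= abs(m$response$delta_i_sat) + 1e-12))
    mag <- abs(y)
    assoc <- tg >= 0 & tg <= 120
    expect_true(all(diff(mag[assoc]) >= -1e-12))
    expect_true(all(diff(mag[tg > 120]) <= 1e-12))
  }
})

test_that("fast transport collapses the pulse model onto pure kinetics", {
  r <- tdna_rates()
  m <- make_model(k_t = 1e16, t_d = 300)
  tg <- seq(0, 2000, by = 2)
  y <- pulse_response(tg, m)
  eq <- m$response$delta_i_eq
  ref <- ifelse(tg <= 300, association_response(tg, r, 1e-6, eq),
                dissociation_response(
                  pmax(tg, 300), 300, r$k_off,
                  association_response(300, r, 1e-6, eq)))
  expect_lt(max(abs(y - ref)) / max(abs(ref)), 1e-3)
})

test_that("closed form agrees with the ODE oracle across a parameter grid", {
  for (k_t in c(1e8, 1e9, 1e10, 1e12)) {
    for (c_avg in c(3e-7, 1e-6, 3e-6)) {
      for (t_d in c(30, 300)) {
        m <- make_model(k_t = k_t, c_avg = c_avg, t_d = t_d)
        tg <- seq(0, t_d + 600, by = 2)
        y_cf <- pulse_response(tg, m)
        y_ode <- ode_reference_response(tg, m)
        expect_lt(max(abs(y_cf - y_ode)) / max(abs(y_cf)), 1e-5)
      }
    }
  }
})

test_that("ODE oracle respects conservation and the null input", {
  m <- make_model(k_t = 1e9, t_d = 60)
  tg <- seq(0, 500, by = 1)
  y <- ode_reference_response(tg, m)
  n <- y / m$response$q_factor
  n_max <- pulse_params(m)$n_max
  expect_true(all(n >= -1e-6 * n_max & n <= n_max * (1 + 1e-6)))
  # no pulse window inside the grid -> identically zero
  y0 <- ode_reference_response(tg, m, schedule = data.frame(on = 1e6,
                                                            off = 1e6 + 30))
  expect_equal(max(abs(y0)), 0)
})

test_that("model constructors validate their inputs", {
  r <- tdna_rates()
  expect_error(kinetic_rates(-1, 1e-3), "positive")
  expect_error(response_scale(-2, -1.393, -8e-7), "exceed")
  expect_error(response_scale(-0.8, 1.393, -8e-7), "sign")
  expect_error(pulse_model(r, 1e-6, 1e9,
                           response_scale(-0.8, -1.393, -8e-7),
                           t_a = 30, t_d = 10), "t_d")
  m <- make_model()
  expect_error(pulse_response(c(3, 1, 2), m), "sorted")
})
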