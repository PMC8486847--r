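test_that("EDL and series gate capacitance reproduce the device stack", {
  # golden values use the conventionally rounded Debye lengths
  cgr <- edl_capacitance(4e3, lambda_d_nm = 0.77)
  expect_equal(cgr, 3.68, tolerance = 1e-3)
  cq <- quantum_capacitance(fet_stack())
  expect_equal(cq, 8e-2)
  expect_equal(gate_capacitance(cgr, cq), 7.83e-2, tolerance = 1e-3)
  cgr_dil <- edl_capacitance(4e3, lambda_d_nm = 7.75)
  expect_equal(cgr_dil, 0.3656, tolerance = 1e-3)
  expect_equal(gate_capacitance(cgr_dil, cq), 6.58e-2, tolerance = 1e-2)
  # linearity in area; full-precision electrolyte route
  el <- electrolyte(0.150)
  expect_equal(edl_capacitance(8e3, el), 2 * edl_capacitance(4e3, el))
})

test_that("series combination is symmetric, bounded and Inf-absorbing", {
  expect_equal(gate_capacitance(0.4, 0.4), 0.2)
  set.seed(11)
  for (i in 1:20) {
    cs <- runif(3, 0.01, 10)
    g <- gate_capacitance(cs[1], cs[2], cs[3])
    expect_lt(g, min(cs))
    expect_equal(g, gate_capacitance(cs[3], cs[1], cs[2]))
  }
  # an infinite term drops out
  expect_equal(gate_capacitance(3.68, 0.08, Inf),
               gate_capacitance(3.68, 0.08))
  expect_error(gate_capacitance(0, 0.08), "positive")
})

test_that("screened molecular charge decays over the Debye length", {
  pr <- oligo_probe()
  expect_equal(effective_charge(pr, lambda_d_nm = 0.77), 5.42e-20,
               tolerance = 1e-3)
  expect_equal(effective_charge(pr, lambda_d_nm = 7.75), 1.943e-18,
               tolerance = 1e-3)
  # unscreened limit: full backbone charge
  expect_equal(effective_charge(pr, lambda_d_nm = Inf),
               18 * 1.602176634e-19)
  # monotone in Debye length and in base count
  q1 <- effective_charge(pr, lambda_d_nm = 2)
  q2 <- effective_charge(pr, lambda_d_nm = 4)
  expect_lt(q1, q2)
  # monotone in base count in the weak-screening regime (r < lambda_D)
  expect_lt(effective_charge(oligo_probe(n_bases = 12), lambda_d_nm = 50),
            effective_charge(oligo_probe(n_bases = 24), lambda_d_nm = 50))
})

test_that("CNP-shift surface density is the direct quotient", {
  # direct evaluation with the device stack inputs (~2.4e4 um^-2)
  n <- surface_density_from_cnp_shift(66, 7.83e-2, 5.42e-20, 4e3)
  expect_equal(n, 66e-3 * 7.83e-11 / (5.42e-20 * 4e3), tolerance = 1e-12)
  expect_equal(n, 2.38e4, tolerance = 5e-3)
  expect_equal(surface_density_from_cnp_shift(0, 7.83e-2, 5.42e-20, 4e3), 0)
  expect_equal(surface_density_from_cnp_shift(132, 7.83e-2, 5.42e-20, 4e3),
               2 * n)
  expect_error(surface_density_from_cnp_shift(66, 7.83e-2, 0, 4e3),
               "positive")
})

test_that("transduction factor and count/current conversion are exact", {
  q <- transduction_factor(-28.0, 1.94e-18, 6.58e-2)
  expect_equal(q, -28.0 * 1.94e-18 / 6.58e-11)
  expect_equal(q, -8.255e-7, tolerance = 1e-3)
  expect_equal(transduction_factor(-28.0, 0, 6.58e-2), 0)
  expect_equal(transduction_factor(28.0, 1.94e-18, 6.58e-2), -q)
  # equilibrium response maps to ~1e6 bound receptors
  expect_equal(current_to_bound(-0.805, q), -0.805 / q)
  expect_gt(current_to_bound(-0.805, q), 0)
  # exact round trip
  set.seed(3)
  di <- rnorm(50)
  expect_equal(current_to_bound(bound_to_current(di, q), q), di)
  expect_equal(current_to_bound(0, q), 0)
  expect_error(current_to_bound(1, 0), "nonzero")
})

test_that("receptor ceiling inverts the isotherm", {
  expect_equal(n_r_max(1e-6, 0.746e-6, 1000), 1746)
  expect_equal(n_r_max(1e-6, 0, 1000), 1000)
  expect_equal(n_r_max(5e-7, 5e-7, 1000), 2000)
  expect_error(n_r_max(0, 1e-6, 1000), "positive")
})

test_that("wire half-area matches the reference electrode estimate", {
  expect_equal(wire_half_area(10, 0.5), 7.85e6, tolerance = 1e-3)
})
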