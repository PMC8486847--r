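test_that("moving mean preserves constants and spreads an impulse", {
  tr_const <- fet_trace(0:99, rep(31.25, 100))
  expect_equal(moving_mean(tr_const, 21)$current, rep(31.25, 100))
  # unit impulse on a 1-s grid -> rectangle of height 1/21
  x <- numeric(101); x[51] <- 1
  f <- moving_mean(fet_trace(0:100, x), 21)$current
  expect_equal(f[41:61], rep(1 / 21, 21))
  expect_equal(sum(f), 1)  # mass conserved away from edges
  # one-sample window is the identity
  tr <- fet_trace(0:9, rnorm(10))
  expect_equal(moving_mean(tr, 1)$current, tr$current)
  expect_warning(out <- moving_mean(tr, 0.2), "shorter")
  expect_equal(out$current, tr$current)
  # trailing alignment is causal: output at t never depends on samples
  # after t
  x2 <- c(rep(0, 50), rep(1, 51))
  f2 <- moving_mean(fet_trace(0:100, x2), 21, align = "trailing")$current
  expect_equal(f2[1:50], rep(0, 50))
  expect_equal(moving_mean(tr_const, 21, align = "trailing")$current,
               rep(31.25, 100))
})

test_that("decision sampling hits every interval endpoint", {
  spec <- transmission_spec(rep(c(1, 0), 10), 60, 30)
  tr <- fet_trace(seq(0, 1300), sin(seq(0, 1300) / 100))
  s <- sample_decisions(tr, spec, delay_s = 0)
  expect_length(s$values, 21)
  expect_equal(s$times, seq(0, 1200, by = 60))
  # L = 1: the two endpoints of the single interval
  s1 <- sample_decisions(tr, transmission_spec(1, 60, 30), 0)
  expect_length(s1$values, 2)
  # shifting trace times and delay together leaves samples unchanged
  tr_shift <- fet_trace(tr$time + 37, tr$current)
  s2 <- sample_decisions(tr_shift, spec, delay_s = 37)
  expect_equal(s2$values, s$values)
  expect_error(sample_decisions(fet_trace(0:100, rnorm(101)), spec, 0),
               "outside")
})

test_that("difference detector decodes falling intervals as ones", {
  expect_equal(difference_detect(c(5, 4, 3, 2)), c(1L, 1L, 1L))
  expect_equal(difference_detect(rep(2, 5)), c(0L, 0L, 0L, 0L))
  # exact ties decode to 0; strictly positive affine rescaling is a no-op
  set.seed(21)
  for (i in 1:20) {
    r <- cumsum(rnorm(11))
    a <- runif(1, 0.1, 10); b <- rnorm(1, 0, 30)
    expect_equal(difference_detect(r), difference_detect(a * r + b))
  }
  expect_error(difference_detect(3), "two samples")
})

test_that("bit error rate is the mismatch fraction", {
  b <- prbs(20, seed = 4)
  expect_equal(bit_error_rate(b, b), 0)
  expect_equal(bit_error_rate(b, 1L - b), 1)
  sent <- rep(0L, 60); got <- sent; got[c(3, 30, 59)] <- 1L
  expect_equal(bit_error_rate(sent, got), 0.05)
  expect_error(bit_error_rate(1:3, 1:4), "equal length")
})

test_that("noiseless 20-bit transmission decodes perfectly at long intervals", {
  m <- make_model(k_t = 1e10)
  for (seed in c(1, 7, 13)) {
    bits <- prbs(20, seed = seed)
    spec <- transmission_spec(bits, 360, 30)
    sim <- gen_transmission_trace(spec, m, baseline_uA = 31.25,
                                  noise = NULL, tail_s = 360)
    dec <- difference_detect(sample_decisions(sim$trace, spec, 0))
    expect_equal(bit_error_rate(bits, dec), 0)
    # causal filtering never flips a noiseless decision
    filt <- moving_mean(sim$trace, 21, align = "trailing")
    expect_equal(difference_detect(sample_decisions(filt, spec, 0)), dec)
  }
})

test_that("delay estimation recovers a known shift", {
  m <- make_model(k_t = 1e10)
  bits <- prbs(8, seed = 2)
  true_delay <- 55
  spec_tx <- transmission_spec(bits, 120, 30, t_transmit_s = true_delay)
  tg <- seq(0, 8 * 120 + 240, by = 1)
  rx <- received_signal(spec_tx, m, tg)
  spec_rx <- transmission_spec(bits, 120, 30, t_transmit_s = 0)
  expect_equal(estimate_delay(rx, spec_rx, m, delays = seq(0, 90, by = 5)),
               true_delay)
})
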