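test_that("afferent rate and locking functions evaluate per the input model", {
  expect_equal(am_rate(300), 171)
  expect_equal(am_rate(0), 180)
  expect_equal(am_rate(1200), 144)
  expect_error(am_rate(7000), "negative")

  expect_equal(am_vs(2000), 0)
  expect_equal(am_vs(300), 0.65 * tanh(1.7), tolerance = 1e-12)
  expect_equal(am_vs(300), 0.6080, tolerance = 1e-4)
  expect_equal(am_vs(0), 0.65 * tanh(2), tolerance = 1e-12)
  expect_equal(am_vs(3000), 0)  # clipped, never negative

  expect_equal(level_rate(20), 150)
  expect_equal(level_rate(35), 30 + 240 / (1 + exp(-2.5)), tolerance = 1e-12)
  expect_equal(level_rate(35), 251.8, tolerance = 1e-3)
  s <- level_rate(seq(-40, 100, by = 5))
  expect_true(all(diff(s) > 0))
  expect_gt(s[1], 30 - 1e-6)
  expect_lt(s[length(s)], 270)
})

test_that("von Mises concentration inverts the Bessel ratio", {
  expect_equal(vs_to_kappa(0), 0)
  for (v in seq(0.1, 0.9, by = 0.1)) {
    expect_equal(kappa_to_vs(vs_to_kappa(v)), v, tolerance = 1e-9)
  }
  k <- vs_to_kappa(0.6080)
  expect_equal(besselI(k, 1) / besselI(k, 0), 0.6080, tolerance = 1e-9)
  expect_error(vs_to_kappa(1), "\\[0, 1\\)")
})

test_that("generated trains have the requested rate and phase locking", {
  expect_length(generate_fiber_train(fiber_drive(0), 1000, seed = 1)$times, 0)

  # homogeneous: count within 4 sd of the Poisson expectation
  tr <- generate_fiber_train(fiber_drive(171), 20000, seed = 42)
  expect_lt(abs(length(tr$times) - 171 * 20), 4 * sqrt(171 * 20))
  expect_true(all(diff(tr$times) > 0))

  # modulated: cycle-averaged rate equals the nominal rate and the pooled
  # empirical vector strength matches the request within 0.01 over 40 s
  drv <- fiber_drive(am_rate(300), am_vs(300), 300)
  pooled <- unlist(lapply(1:10, function(i)
    generate_fiber_train(drv, 40000, seed = 100 + i)$times))
  expect_lt(abs(length(pooled) / 10 - 171 * 40), 4 * sqrt(171 * 40 * 10) / 10)
  expect_lt(abs(vector_strength(pooled, 300) - am_vs(300)), 0.01)

  # locking phase shifts the spike phases but not the rate
  shifted <- generate_fiber_train(fiber_drive(171, 0.6, 300, phase = 90),
                                  40000, seed = 9)
  expect_lt(abs(vector_strength(shifted, 300) - 0.6), 0.02)
})

test_that("fiber substreams are reproducible and distinct", {
  a <- generate_input_trains(fiber_drive(100), fiber_drive(30), 1000, seed = 5)
  b <- generate_input_trains(fiber_drive(100), fiber_drive(30), 1000, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$exc[[1]]$times, a$exc[[2]]$times))
  expect_length(a$exc, 20)
  expect_length(a$inh, 8)
})

test_that("alpha-function conductance traces match the kernel sum", {
  pE <- synapse_params("excitatory")
  g <- conductance_trace(spike_train(0, 2), pE, dt = 0.002, duration = 2)
  expect_equal(max(g), pE$A_syn, tolerance = 1e-9)
  expect_equal((which.max(g) - 1) * 0.002, pE$tau_syn)
  expect_equal(g[round(2 * pE$tau_syn / 0.002) + 1], pE$A_syn * 2 / exp(1),
               tolerance = 1e-9)

  # two coincident spikes double the trace exactly
  g2 <- conductance_trace(spike_train(c(0, 0), 2), pE, 0.002, 2)
  expect_equal(g2, 2 * g, tolerance = 1e-12)

  # exponential recursion vs direct kernel-sum oracle on an irregular train
  set.seed(77)
  dt <- 0.002
  times <- round(sort(runif(25, 0, 8)) / dt) * dt
  pI <- synapse_params("inhibitory")
  g3 <- conductance_trace(spike_train(times, 10), pI, dt, 10)
  grid <- (0:5000) * dt
  expect_equal(g3, alpha_sum_oracle(times, pI$A_syn, pI$tau_syn, grid),
               tolerance = 1e-9)
  expect_true(all(g3 >= 0))

  expect_equal(max(abs(conductance_trace(spike_train(numeric(0), 10),
                                         pE, dt, 10))), 0)
})

test_that("synaptic current follows the driving force", {
  expect_equal(synaptic_current(5, -75, -75), 0)
  expect_equal(synaptic_current(3.5, -60, 0), 210)
  expect_equal(synaptic_current(12, -60, -75), -180)
  expect_error(synaptic_current(-1, -60, 0), "non-negative")
})
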