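no_input <- list(exc = numeric(0), inh = numeric(0))

test_that("all variants are quiescent at rest without input", {
  for (v in model_variants()) {
    res <- simulate_lso(v, no_input, duration = 10, record_voltage = TRUE)
    expect_length(res$spikes$times, 0)
    v_rest <- resting_potential(lso_params(v))
    # the exponential variants carry a ~0.03 pA standing spike current at
    # rest, so allow a sub-0.01 mV equilibrium offset
    expect_lt(max(abs(res$voltage$values - v_rest)), 0.01)
  }
})

test_that("passive membrane follows the closed-form RC step response", {
  # 100 pA step from rest; tau_m = C/g_L = 24/26.4 ~ 0.909 ms
  dur <- 6
  dt <- 0.002
  res <- simulate_lso("PLk", no_input, dur, dt = dt, i_inj = 100,
                      record_voltage = TRUE, spiking = FALSE)
  tt <- trace_times(res$voltage)
  expected <- rc_step_oracle(tt, 100, 24, 26.4, -60)
  expect_lt(max(abs(res$voltage$values - expected)), 0.05)
  # steady-state deflection I/g_L
  expect_equal(res$voltage$values[length(tt)], -60 + 100 / 26.4,
               tolerance = 1e-3)
})

test_that("active membrane settles at the KLVA-balanced resting potential", {
  alk <- lso_params("ALk")
  res <- simulate_lso("ALk", no_input, duration = 30, record_voltage = TRUE,
                      v0 = -60, d0 = klva_steady_state(-60)$d_inf)
  expect_lt(abs(res$state$V - resting_potential(alk)), 0.05)
})

test_that("output spike trains respect the refractory floor", {
  for (v in model_variants()) {
    inp <- generate_input_trains(fiber_drive(500), fiber_drive(0), 2000,
                                 seed = 21)
    res <- simulate_lso(v, inp, 2000)
    expect_gt(length(res$spikes$times), 20)
    expect_gte(min(diff(res$spikes$times)), lso_params(v)$T_ref - 1e-9)
    expect_true(all(diff(res$spikes$times) > 0))
    expect_true(all(res$spikes$times >= 0 & res$spikes$times <= 2000))
  }
})

test_that("strong constant drive gives regular firing at the refractory limit", {
  res <- simulate_lso("PLk", no_input, 500, i_inj = 2000)
  isi <- diff(res$spikes$times)
  expect_true(all(isi >= 2.0 - 1e-9))
  expect_lt(sd(isi), 1e-6)  # deterministic drive -> perfectly regular
})

test_that("passive subthreshold responses superpose linearly", {
  dur <- 20
  dt <- 0.002
  n <- round(dur / dt)
  set.seed(3)
  i1 <- 40 * sin(2 * pi * 100 * (0:(n - 1)) * dt / 1000)
  i2 <- rep(c(30, -20), each = n / 2)
  v_of <- function(i) {
    simulate_lso("PLk", no_input, dur, dt = dt, i_inj = i,
                 record_voltage = TRUE, spiking = FALSE)$voltage$values
  }
  lhs <- v_of(i1 + i2) + 60
  rhs <- (v_of(i1) + 60) + (v_of(i2) + 60)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("KLVA gating stays within [0, 1] under strong drive", {
  inp <- generate_input_trains(fiber_drive(400), fiber_drive(200), 1000,
                               seed = 8)
  for (v in c("ALk", "ASp", "AEx")) {
    res <- simulate_lso(v, inp, 1000, record_voltage = TRUE)
    expect_true(all(res$gating >= 0 & res$gating <= 1))
  }
})

test_that("halving the Euler step changes 10-s spike counts by < 2%", {
  inp <- generate_input_trains(fiber_drive(level_rate(35)), fiber_drive(100),
                               10000, seed = 13)
  for (v in c("PLk", "ALk")) {
    n2 <- length(simulate_lso(v, inp, 10000, dt = 0.002)$spikes$times)
    n1 <- length(simulate_lso(v, inp, 10000, dt = 0.001)$spikes$times)
    expect_lt(abs(n1 - n2) / n2, 0.02)
  }
  expect_error(simulate_lso("PLk", inp, 10, dt = 0.05), "0.01")
})

test_that("identical inputs yield matching subthreshold trajectories", {
  inp <- generate_input_trains(fiber_drive(80), fiber_drive(30), 200,
                               seed = 4)
  v_plk <- simulate_lso("PLk", inp, 200, record_voltage = TRUE,
                        spiking = FALSE)$voltage$values
  # PSp without spikes is the same dynamical system as PLk
  v_psp <- simulate_lso("PSp", inp, 200, record_voltage = TRUE,
                        spiking = FALSE)$voltage$values
  expect_equal(v_psp, v_plk, tolerance = 1e-12)
  # PEx deviates only through the (tiny) subthreshold exponential current
  v_pex <- simulate_lso("PEx", inp, 200, record_voltage = TRUE,
                        spiking = FALSE)$voltage$values
  expect_lt(max(abs(v_pex[v_plk < -55] - v_plk[v_plk < -55])), 0.3)
})

test_that("simulations are bit-for-bit reproducible from the seed", {
  run <- function() {
    inp <- generate_input_trains(fiber_drive(171, 0.6, 300),
                                 fiber_drive(171, 0.6, 300, phase = -135),
                                 1000, seed = 99)
    simulate_lso("ALk", inp, 1000)$spikes$times
  }
  expect_identical(run(), run())
})
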