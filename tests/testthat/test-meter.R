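test_that("sine_fit recovers a clean sinusoid essentially exactly", {
  t <- seq(0, 0.5 - 1e-4, by = 1e-4)
  w <- waveform(1 * sin(2 * pi * 15 * t + pi / 6) + 0.2, fs = 1e4)
  f <- sine_fit(w, 15)
  expect_equal(f$amplitude, 1, tolerance = 1e-6)
  expect_equal(f$frequency, 15, tolerance = 1e-6)
  expect_equal(f$phase_deg, 30, tolerance = 1e-6)
  expect_equal(f$offset, 0.2, tolerance = 1e-6)
  expect_lt(f$residual_rms, 1e-9)
  # frequency is genuinely free: recover a detuned tone from a coarse hint
  w2 <- waveform(sin(2 * pi * 15.6 * t + 1), fs = 1e4)
  expect_equal(sine_fit(w2, 15)$frequency, 15.6, tolerance = 1e-4)
  # preconditions
  expect_error(sine_fit(waveform(sin(t[1:100]), fs = 1e4), 15), "cycles")
  expect_error(sine_fit(w, 6000), "sampling rate")
})

test_that("sine_fit phase error stays below 0.1 degree at 40 dB SNR", {
  set.seed(7)
  t <- seq(0, 0.5 - 1e-4, by = 1e-4)
  errs <- replicate(100, {
    phi <- runif(1, -pi, pi)
    # SNR 40 dB: noise SD = RMS(signal) / 100
    x <- sin(2 * pi * 15 * t + phi) + rnorm(length(t), 0, 1 / sqrt(2) / 100)
    f <- sine_fit(waveform(x, 1e4), 15)
    abs(toothEIS:::wrap_deg(f$phase_deg - phi * 180 / pi))
  })
  expect_lt(max(errs), 0.1)
})

test_that("sine_fit rejects residual odd harmonics of the stimulus", {
  t <- seq(0, 0.5 - 1e-4, by = 1e-4)
  set.seed(21)
  for (i in 1:5) {
    phi <- runif(1, -pi, pi)
    x <- sin(2 * pi * 15 * t + phi) +
      10^(-30 / 20) * (sin(2 * pi * 45 * t + runif(1, -pi, pi)) +
                         sin(2 * pi * 75 * t + runif(1, -pi, pi)))
    f <- sine_fit(waveform(x, 1e4), 15)
    expect_lt(abs(toothEIS:::wrap_deg(f$phase_deg - phi * 180 / pi)), 0.5)
  }
})

test_that("the emulated meter reproduces closed-form impedances", {
  # pure resistor, noiseless: modulus exact, phase at numerical zero
  cfg0 <- acquisition_config(noise_sd = 0, n_repeats = 1)
  m <- measure_impedance(3e5, cfg0)
  expect_equal(m$z_mod, 3e5, tolerance = 1e-4)
  expect_lt(abs(m$z_phase), 0.05)  # quantization-only error
  # parallel RC at the validation geometry: phase = atan(wRC)
  R <- 5e5; C <- 18.2e-9; w <- 2 * pi * 15
  mrc <- measure_impedance(list(r = R, c = C),
                           acquisition_config(n_repeats = 3))
  expect_equal(mrc$z_phase, atan(w * R * C) * 180 / pi, tolerance = 1e-2)
  expect_equal(mrc$z_mod, R / sqrt(1 + (w * R * C)^2), tolerance = 1e-2)
  # demineralized tooth circuit: cross-module agreement with the forward model
  mdm <- measure_impedance(dm_params(), acquisition_config(n_repeats = 3))
  expect_lt(abs(mdm$z_phase - phase_positive(circuit_impedance(dm_params(), 15))),
            0.5)
  # determinism and repeat bookkeeping
  m2 <- measure_impedance(3e5, cfg0)
  expect_identical(m$z_phase, m2$z_phase)
  m10 <- measure_impedance(3e5, acquisition_config(n_repeats = 10))
  expect_length(m10$per_repeat_phases, 10)
  expect_equal(m10$z_phase, mean(m10$per_repeat_phases))
  expect_gte(m10$phase_sd, 0)
})

test_that("ADC clipping raises an error naming the overloaded channel", {
  expect_error(measure_impedance(1e3, acquisition_config()), "current")
  expect_error(measure_impedance(3e5, acquisition_config(v_gain = 1e3)),
               "stimulus")
})

test_that("meter classification hands the averaged phase to the neuron", {
  cfg <- acquisition_config(n_repeats = 3)
  rdm <- meter_classify(measure_impedance(dm_params(), cfg))
  expect_equal(rdm$label, "DM")
  rnd <- meter_classify(measure_impedance(nd_params(), cfg))
  expect_equal(rnd$label, "ND")
  m65 <- structure(list(z_mod = 1e5, z_phase = 65, f_est = 15,
                        per_repeat_phases = 65, phase_sd = 0),
                   class = "phase_measurement")
  expect_equal(meter_classify(m65)$index, 50)
})
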