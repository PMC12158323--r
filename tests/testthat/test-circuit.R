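test_that("CPE impedance matches its closed form and limiting elements", {
  # n = 1: ideal unit capacitor, Z = 1/(jwC); at w = 1 this is -1i
  expect_equal(cpe_impedance(q = 1, n = 1, f = 1 / (2 * pi)),
               complex(imaginary = -1), tolerance = 1e-12)
  # ideal-capacitor closed form at arbitrary (C, f)
  C <- 4.7e-8; f <- 123
  expect_equal(cpe_impedance(C, 1, f), 1 / (2i * pi * f * C),
               tolerance = 1e-14)
  # n = 0: pure resistor 1/q at any frequency
  expect_equal(cpe_impedance(q = 0.5, n = 0, f = 3), 2 + 0i)
  expect_equal(cpe_impedance(q = 0.5, n = 0, f = 7777), 2 + 0i)
  # demineralized-enamel CPE at 15 Hz: phase exactly -n*90, magnitude 1/(q w^n)
  z <- cpe_impedance(2.1e-7, 0.86, 15)
  expect_equal(Mod(z), 1 / (2.1e-7 * (2 * pi * 15)^0.86), tolerance = 1e-12)
  expect_equal(Mod(z), 95478.9, tolerance = 1e-5)
  expect_equal(Arg(z) * 180 / pi, -0.86 * 90, tolerance = 1e-12)
  expect_error(cpe_impedance(-1, 0.8, 10), "positive")
  expect_error(cpe_impedance(1e-7, 0.8, -5), "positive")
})

test_that("circuit impedance matches the independent complex-arithmetic oracle", {
  p <- nd_params()
  for (f in c(0.1, 1, 15, 1e3, 1e4))
    expect_equal(circuit_impedance(p, f),
                 oracle_impedance(p$r1, p$r2, p$q, p$n, f), tolerance = 1e-13)
  # frozen oracle values at the classification frequency
  z15 <- circuit_impedance(p, 15)
  expect_equal(Mod(z15), 77446.0, tolerance = 1e-5)
  expect_equal(phase_positive(z15), 69.983, tolerance = 1e-4)
  zdm <- circuit_impedance(dm_params(), 15)
  expect_equal(Mod(zdm), 133755.5, tolerance = 1e-5)
  expect_equal(phase_positive(zdm), 44.090, tolerance = 1e-4)
  # asymptotes: resistive r1 at high f, r1 + r2 at low f
  expect_equal(Mod(circuit_impedance(p, 1e9)), p$r1, tolerance = 1e-3)
  expect_lt(phase_positive(circuit_impedance(p, 1e9)), 0.1)
  expect_equal(Mod(circuit_impedance(p, 1e-9)), p$r1 + p$r2, tolerance = 1e-3)
})

test_that("phase stays in (0, 90) deg and |Z| is non-increasing in f", {
  set.seed(11)
  grid <- log_frequency_grid()
  for (i in 1:100) {
    p <- circuit_params(10^runif(1, 2, 6), 10^runif(1, 5, 8),
                        10^runif(1, -8, -6), runif(1, 0.5, 1))
    z <- circuit_impedance(p, grid)
    ph <- phase_positive(z)
    expect_true(all(ph > -1e-9 & ph < 90))
    expect_true(all(diff(Mod(z)) <= 1e-9 * Mod(z)[-1]))
  }
})

test_that("the standard grid has 26 log-uniform points including endpoints", {
  g <- log_frequency_grid()
  expect_length(g, 26)
  expect_equal(g[1], 0.1)
  expect_equal(g[26], 1e4)
  expect_equal(diff(log10(g)), rep(0.2, 25), tolerance = 1e-12)
  expect_false(15 %in% g)  # the classification frequency is off-grid
})

test_that("simulate_spectrum is pointwise circuit_impedance with valid invariants", {
  p <- dm_params()
  s <- simulate_spectrum(p)
  expect_s3_class(s, "impedance_spectrum")
  expect_length(s$z, 26)
  expect_equal(s$z, circuit_impedance(p, s$frequency))
  expect_true(all(Im(s$z) <= 0))        # capacitive circuit
  expect_true(all(Mod(s$z) > 0))
  expect_true(all(diff(Mod(s$z)) < 0))  # monotone magnitude
  s1 <- simulate_spectrum(p, frequency = 15)
  expect_equal(s1$z, circuit_impedance(p, 15))
  expect_error(simulate_spectrum(p, frequency = numeric(0)), "empty")
})

test_that("phase_at_frequency is exact on grid points and interpolates off-grid", {
  s <- nd_spectrum()
  expect_equal(phase_at_frequency(s, 10), phase_positive(s$z[s$frequency == 10]))
  # constant-phase spectrum: interpolation of a constant
  zc <- complex(modulus = 10^(6:1), argument = rep(-70 * pi / 180, 6))
  sc <- impedance_spectrum(10^(0:5), zc)
  expect_equal(phase_at_frequency(sc, 33.7), 70, tolerance = 1e-12)
  # interpolation error at 15 Hz below 0.5 deg against direct evaluation
  direct <- phase_positive(circuit_impedance(nd_params(), 15))
  expect_lt(abs(phase_at_frequency(s, 15) - direct), 0.5)
  expect_error(phase_at_frequency(s, 1e5), "outside")
  expect_error(phase_at_frequency(s, 0.01), "outside")
})

test_that("parameter and spectrum validation rejects bad input", {
  expect_error(circuit_params(-1, 1, 1e-7, 0.8), "r1")
  expect_error(circuit_params(1, 1, 1e-7, 1.2), "n")
  expect_error(circuit_params(1, 1, 1e-7, 0), "n")
  expect_error(impedance_spectrum(c(2, 1), c(1 + 0i, 1 + 0i)), "increasing")
  expect_error(impedance_spectrum(c(1, 2), c(1 + 0i)), "lengths")
  expect_error(impedance_spectrum(1, 0 + 0i), "magnitude")
  expect_error(impedance_spectrum(1, 1 + 0i, label = "XX"), "label")
})
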