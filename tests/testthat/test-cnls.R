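test_that("initial guess reads the spectrum asymptotes sensibly", {
  g <- initial_guess(nd_spectrum())
  expect_gt(g$r1, 3.9e3 / 2)
  expect_lt(g$r1, 3.9e3 * 2)
  expect_equal(g$n, 0.8)
  # flat resistor-like spectrum: r1 recovered, r2 flagged low-confidence
  sR <- impedance_spectrum(log_frequency_grid(),
                           complex(real = rep(1e5, 26), imaginary = -1e-9))
  gR <- initial_guess(sR)
  expect_equal(gR$r1, 1e5, tolerance = 1e-6)
  expect_true(attr(gR, "low_confidence_r2"))
  # guess respects bounds
  b <- fit_config()$bounds
  for (s in list(nd_spectrum(), dm_spectrum(), sR)) {
    gg <- initial_guess(s, b)
    expect_true(gg$r1 >= b$r1[1] && gg$r1 <= b$r1[2])
    expect_true(gg$q >= b$q[1] && gg$q <= b$q[2])
  }
  short <- impedance_spectrum(c(1, 2, 3), circuit_impedance(nd_params(), c(1, 2, 3)))
  expect_error(initial_guess(short), "decades")
})

test_that("noiseless round trips recover both reference parameter sets to <0.1%", {
  for (cond in c("sound", "demineralized")) {
    p <- enamel_reference_params(cond)
    fit <- fit_spectrum(simulate_spectrum(p))
    expect_true(fit$converged)
    expect_lt(rel_err(fit$params$r1, p$r1), 1e-3)
    expect_lt(rel_err(fit$params$r2, p$r2), 1e-3)
    expect_lt(rel_err(fit$params$q, p$q), 1e-3)
    expect_lt(rel_err(fit$params$n, p$n), 1e-3)
    expect_lt(fit$cost, 1e-12)
  }
})

test_that("fits are deterministic given the config seed", {
  s <- simulate_spectrum(nd_params())
  f1 <- fit_spectrum(s, fit_config(seed = 7))
  f2 <- fit_spectrum(s, fit_config(seed = 7))
  expect_identical(f1$params, f2$params)
})

test_that("r2 is recovered within 10% median error under replicate-level noise", {
  p <- nd_params()
  g <- log_frequency_grid()
  z0 <- circuit_impedance(p, g)
  set.seed(42)
  errs <- replicate(20, {
    z <- toothEIS:::perturb_spectrum_z(z0, 0.02, 1)
    fit <- fit_spectrum(impedance_spectrum(g, z))
    rel_err(fit$params$r2, p$r2)
  })
  expect_lt(median(errs), 0.10)
})

test_that("unit-weighting fit scales equivariantly with impedance rescaling", {
  s <- simulate_spectrum(dm_params())
  cfg <- fit_config(weighting = "unit")
  f1 <- fit_spectrum(s, cfg)
  cc <- 3.7
  f2 <- fit_spectrum(impedance_spectrum(s$frequency, s$z * cc), cfg)
  expect_equal(f2$params$r1 / f1$params$r1, cc, tolerance = 1e-6)
  expect_equal(f2$params$r2 / f1$params$r2, cc, tolerance = 1e-4)
  expect_equal(f2$params$q * cc, f1$params$q, tolerance = 1e-4)
  expect_equal(f2$params$n, f1$params$n, tolerance = 1e-6)
})

test_that("goodness_of_fit reproduces the optimizer cost and tracks noise", {
  s <- simulate_spectrum(nd_params())
  fit <- fit_spectrum(s)
  rep <- goodness_of_fit(fit, s)
  expect_equal(rep$cost, fit$cost, tolerance = 1e-9)
  expect_lt(rep$rms_relative, 1e-7)
  expect_true(all(rep$per_decade$rms_relative < 1e-7))
  expect_equal(sum(rep$per_decade$n_points), 26)
  # noise strictly increases the cost of the noiseless-fit parameters
  set.seed(1)
  zn <- toothEIS:::perturb_spectrum_z(s$z, 0.02, 1)
  sn <- impedance_spectrum(s$frequency, zn)
  rep_n <- goodness_of_fit(fit, sn)
  expect_gt(rep_n$cost, rep$cost)
  # mismatched lengths rejected
  s5 <- impedance_spectrum(s$frequency[1:5], s$z[1:5])
  expect_error(goodness_of_fit(fit, s5), "lengths")
})

test_that("modulus weighting balances relative residuals across decades", {
  # under modulus weighting the high-frequency decade must be fitted to
  # a comparable relative accuracy as the low-frequency one
  set.seed(5)
  g <- log_frequency_grid()
  z <- toothEIS:::perturb_spectrum_z(circuit_impedance(nd_params(), g), 0.02, 1)
  s <- impedance_spectrum(g, z)
  fit <- fit_spectrum(s, fit_config(weighting = "modulus"))
  per <- goodness_of_fit(fit, s)$per_decade
  expect_lt(max(per$rms_relative) / min(per$rms_relative), 50)
})
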