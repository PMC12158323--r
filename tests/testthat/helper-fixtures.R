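# Shared fixtures: reference circuits and noiseless forward spectra.

nd_params <- function() enamel_reference_params("sound")
dm_params <- function() enamel_reference_params("demineralized")

nd_spectrum <- function() simulate_spectrum(nd_params())
dm_spectrum <- function() simulate_spectrum(dm_params())

# Independent oracle: direct complex evaluation of the circuit equation,
# written without the package's forward-model code path.
oracle_impedance <- function(r1, r2, q, n, f) {
  zc <- 1 / ((complex(imaginary = 2 * pi * f))^n * q)
  r1 + r2 * zc / (r2 + zc)
}

rel_err <- function(a, b) abs(a / b - 1)
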