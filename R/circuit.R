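#' Equivalent-circuit parameters for a tooth impedance spectrum
#'
#' Container for the four element values of the first-order equivalent
#' circuit used to model tooth impedance spectra: a series resistance
#' `r1` in series with the parallel combination of a charge-transfer
#' resistance `r2` and a constant-phase element (CPE) with coefficient
#' `q` and exponent `n`. The circuit impedance is
#' \deqn{Z(f) = R_1 + \frac{R_2 \, Z_{CPE}(f)}{R_2 + Z_{CPE}(f)},
#'       \quad Z_{CPE}(f) = \frac{1}{(j 2 \pi f)^N Q}.}
#'
#' `r1` lumps the solution resistance and the electrode-tooth interface
#' resistance; the two contributions are not separately identifiable
#' from a spectrum and are deliberately not modelled apart.
#'
#' @param r1 series resistance, ohm (> 0).
#' @param r2 parallel (charge-transfer) resistance, ohm (> 0).
#' @param q CPE coefficient, s^n/ohm (> 0).
#' @param n CPE exponent, dimensionless, in (0, 1]. `n = 1` is an ideal
#'   capacitor; fitted enamel values are typically around 0.8.
#' @return An object of class `circuit_params`.
#' @examples
#' p <- circuit_params(r1 = 3.9e3, r2 = 2.6e7, q = 3.3e-7, n = 0.81)
#' circuit_impedance(p, 15)
#' @export
circuit_params <- function(r1, r2, q, n) {
  stop_if_not_scalar_pos(r1, "r1")
  stop_if_not_scalar_pos(r2, "r2")
  stop_if_not_scalar_pos(q, "q")
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0 || n > 1)
    stop("`n` must be in (0, 1]", call. = FALSE)
  structure(list(r1 = r1, r2 = r2, q = q, n = n), class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("Equivalent-circuit parameters (R1 + R2 || CPE):\n")
  cat(sprintf("  r1 = %.4g ohm\n  r2 = %.4g ohm\n  q  = %.4g s^n/ohm\n  n  = %.3f\n",
              x$r1, x$r2, x$q, x$n))
  invisible(x)
}

#' Reference circuit parameters for sound and demineralized enamel
#'
#' Representative fitted element values for human incisor enamel before
#' and after in vitro demineralization, used as class centres by the
#' synthetic-data generator and as worked-example inputs.
#'
#' Note that the reported series resistance is *larger* for the
#' demineralized condition (7.5e4 vs 3.9e3 ohm), while demineralization
#' is physically expected to lower the high-frequency impedance
#' magnitude (which this element dominates); the two conditions may have
#' been transposed in the source estimates. The values are used exactly
#' as reported. Class separation by the 15 Hz phase, which drives the
#' single-neuron classifier, holds under either assignment.
#'
#' @param condition `"sound"` (non-demineralized, ND) or
#'   `"demineralized"` (DM).
#' @return A [circuit_params] object.
#' @examples
#' enamel_reference_params("sound")
#' @export
enamel_reference_params <- function(condition = c("sound", "demineralized")) {
  condition <- match.arg(condition)
  if (condition == "sound")
    circuit_params(r1 = 3.9e3, r2 = 2.6e7, q = 3.3e-7, n = 0.81)
  else
    circuit_params(r1 = 7.5e4, r2 = 3.4e7, q = 2.1e-7, n = 0.86)
}

#' Logarithmically spaced frequency grid
#'
#' Builds the standard acquisition grid: frequencies 10^(k/points_per_decade)
#' Hz with both endpoints included. The default 0.1 Hz to 10 kHz at 5
#' points per decade gives 26 points.
#'
#' @param f_min,f_max grid endpoints, Hz; must be exact powers of
#'   10^(1/points_per_decade) for the grid to include them (the defaults
#'   are).
#' @param points_per_decade number of points per frequency decade.
#' @return Strictly increasing numeric vector of frequencies in Hz.
#' @examples
#' length(log_frequency_grid())  # 26
#' @export
log_frequency_grid <- function(f_min = 0.1, f_max = 1e4, points_per_decade = 5) {
  stop_if_not_scalar_pos(f_min, "f_min")
  stop_if_not_scalar_pos(f_max, "f_max")
  if (f_max <= f_min) stop("`f_max` must exceed `f_min`", call. = FALSE)
  k_min <- round(log10(f_min) * points_per_decade)
  k_max <- round(log10(f_max) * points_per_decade)
  10^(seq(k_min, k_max) / points_per_decade)
}

#' Constant-phase-element impedance
#'
#' \deqn{Z_{CPE}(f) = \frac{1}{(j 2 \pi f)^N Q}}
#' The phase is exactly \eqn{-N \cdot 90} degrees at every frequency and
#' the magnitude is \eqn{1 / (Q (2 \pi f)^N)}. `n = 1` reduces to an
#' ideal capacitor with capacitance `q`; `n = 0` reduces to a resistor
#' `1/q` (allowed here as a degenerate limit although excluded from the
#' fitted parameter space).
#'
#' @param q CPE coefficient, s^n/ohm (> 0).
#' @param n CPE exponent in \[0, 1\].
#' @param f frequency in Hz (> 0); may be a vector.
#' @return Complex impedance in ohm, same length as `f`.
#' @examples
#' cpe_impedance(q = 1, n = 1, f = 1 / (2 * pi))  # -1i: unit capacitor at w = 1
#' @export
cpe_impedance <- function(q, n, f) {
  stop_if_not_scalar_pos(q, "q")
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 0 || n > 1)
    stop("`n` must be in [0, 1]", call. = FALSE)
  if (!is.numeric(f) || length(f) < 1L || any(!is.finite(f) | f <= 0))
    stop("`f` must be positive and finite", call. = FALSE)
  1 / ((2i * pi * f)^n * q)
}

#' Impedance of the tooth equivalent circuit
#'
#' Series resistance plus the parallel combination of `r2` and the CPE:
#' `r1 + r2 * Z_cpe / (r2 + Z_cpe)`. At high frequency the CPE shorts
#' the parallel branch and the impedance tends to `r1` (resistive); at
#' low frequency it tends to `r1 + r2`.
#'
#' @param p a [circuit_params] object.
#' @param f frequency in Hz (> 0); may be a vector.
#' @return Complex impedance in ohm, same length as `f`.
#' @export
circuit_impedance <- function(p, f) {
  stopifnot(inherits(p, "circuit_params"))
  zc <- cpe_impedance(p$q, p$n, f)
  p$r1 + p$r2 * zc / (p$r2 + zc)
}

#' Impedance spectrum container
#'
#' A frequency grid with the measured (or simulated) complex impedance
#' at each point, plus replicate / tooth bookkeeping and an optional
#' class label.
#'
#' @param frequency strictly increasing positive frequencies, Hz.
#' @param z complex impedance values, ohm; same length as `frequency`,
#'   all magnitudes > 0.
#' @param replicate_id small integer identifying the acquisition
#'   replicate.
#' @param tooth_id optional integer identifying the sample.
#' @param label optional class label, `"ND"` or `"DM"`.
#' @return An object of class `impedance_spectrum`.
#' @export
impedance_spectrum <- function(frequency, z, replicate_id = 1L,
                               tooth_id = NA_integer_, label = NULL) {
  if (length(frequency) < 1L) stop("empty frequency grid", call. = FALSE)
  if (any(!is.finite(frequency) | frequency <= 0))
    stop("frequencies must be positive and finite", call. = FALSE)
  if (is.unsorted(frequency, strictly = TRUE))
    stop("frequencies must be strictly increasing", call. = FALSE)
  z <- as.complex(z)
  if (length(z) != length(frequency))
    stop("`z` and `frequency` lengths differ", call. = FALSE)
  if (any(is.na(z)) || any(Mod(z) <= 0))
    stop("impedance values must be finite with positive magnitude",
         call. = FALSE)
  if (!is.null(label)) {
    label <- as.character(label)
    if (!label %in% c("ND", "DM"))
      stop('`label` must be "ND" or "DM"', call. = FALSE)
  }
  structure(list(frequency = as.numeric(frequency), z = z,
                 replicate_id = as.integer(replicate_id),
                 tooth_id = as.integer(tooth_id), label = label),
            class = "impedance_spectrum")
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf("Impedance spectrum: %d points, %.3g-%.3g Hz", length(x$frequency),
              min(x$frequency), max(x$frequency)))
  if (!is.null(x$label)) cat(sprintf(", label %s", x$label))
  cat("\n")
  invisible(x)
}

#' Simulate a noiseless spectrum from circuit parameters
#'
#' Vectorized forward evaluation of [circuit_impedance] over a grid.
#'
#' @param p a [circuit_params] object.
#' @param frequency frequency grid in Hz (default: the standard
#'   0.1 Hz-10 kHz grid at 5 points per decade).
#' @param ... passed to [impedance_spectrum] (replicate / label fields).
#' @return An [impedance_spectrum].
#' @examples
#' s <- simulate_spectrum(enamel_reference_params("sound"))
#' phase_at_frequency(s, 15)  # about 70 degrees
#' @export
simulate_spectrum <- function(p, frequency = log_frequency_grid(), ...) {
  if (length(frequency) < 1L) stop("empty frequency grid", call. = FALSE)
  impedance_spectrum(frequency, circuit_impedance(p, frequency), ...)
}

#' Impedance phase at an arbitrary frequency
#'
#' Returns the phase (positive-degrees convention) at `f`. Grid points
#' return the stored value; off-grid frequencies are linearly
#' interpolated in log10(f), which is accurate because the circuit's
#' phase is smooth in log-frequency. The classification frequency
#' (15 Hz) falls between the standard grid points 10 and 15.85 Hz.
#'
#' @param s an [impedance_spectrum].
#' @param f frequency in Hz, inside the grid range.
#' @return Phase in degrees (positive convention).
#' @export
phase_at_frequency <- function(s, f) {
  stopifnot(inherits(s, "impedance_spectrum"))
  stop_if_not_scalar_pos(f, "f")
  if (f < min(s$frequency) || f > max(s$frequency))
    stop(sprintf("frequency %g Hz outside grid range [%g, %g]",
                 f, min(s$frequency), max(s$frequency)), call. = FALSE)
  ph <- phase_positive(s$z)
  idx <- which(s$frequency == f)
  if (length(idx) == 1L) return(ph[idx])
  stats::approx(log10(s$frequency), ph, xout = log10(f))$y
}
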