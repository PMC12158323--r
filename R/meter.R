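#' Sampled waveform container
#'
#' @param samples numeric vector of voltage samples.
#' @param fs sampling rate, samples per second.
#' @param t0 start time, seconds.
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, fs, t0 = 0) {
  stop_if_not_scalar_pos(fs, "fs")
  if (length(samples) < 1L || any(!is.finite(samples)))
    stop("samples must be finite and non-empty", call. = FALSE)
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0),
            class = "waveform")
}

waveform_times <- function(w) w$t0 + (seq_along(w$samples) - 1) / w$fs

#' Acquisition settings of the single-frequency meter emulation
#'
#' Mirrors the signal chain of a microcontroller-based phase meter: a
#' sinusoidal stimulus of a few tens of millivolts, a trans-impedance
#' amplifier converting the circuit current to a voltage, both channels
#' offset to mid-scale and digitized by a unipolar 16-bit ADC, then
#' sine-fitted. Ten repeated phase measurements are averaged to reduce
#' noise.
#'
#' @param f0 stimulus frequency, Hz, within about \[1, 100\].
#' @param v_amp stimulus amplitude, volts.
#' @param fs ADC sampling rate, samples/s.
#' @param duration record length per repeat, s (about 2 s of total
#'   acquisition at the defaults).
#' @param adc_bits ADC resolution (>= 8).
#' @param adc_range unipolar ADC full-scale range, volts.
#' @param tia_gain trans-impedance gain, V/A; the default keeps a 10 mV
#'   stimulus across loads from about 25 kOhm to beyond 500 kOhm inside
#'   the unipolar ADC window (a tooth at 15 Hz falls in this span).
#' @param v_gain stimulus-channel voltage gain before the ADC.
#' @param noise_sd additive Gaussian noise at the ADC input, volts.
#' @param n_repeats phase measurements averaged per reading.
#' @param seed integer seed.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(f0 = 15, v_amp = 0.01, fs = 1e4,
                               duration = 0.25, adc_bits = 16,
                               adc_range = 3.3, tia_gain = 4e6,
                               v_gain = 120, noise_sd = 2e-4,
                               n_repeats = 10, seed = 0) {
  stopifnot(f0 >= 1, f0 <= 110, v_amp > 0, fs > 2 * f0, duration > 0,
            adc_bits >= 8, adc_range > 0, tia_gain > 0, v_gain > 0,
            noise_sd >= 0, n_repeats >= 1)
  structure(list(f0 = f0, v_amp = v_amp, fs = fs, duration = duration,
                 adc_bits = as.integer(adc_bits), adc_range = adc_range,
                 tia_gain = tia_gain, v_gain = v_gain, noise_sd = noise_sd,
                 n_repeats = as.integer(n_repeats), seed = seed),
            class = "acquisition_config")
}

# Three-parameter (fixed-frequency) linear sine fit: A sin + B cos + C.
sine_fit_fixed <- function(t, x, f) {
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t), 1)
  cf <- stats::lm.fit(X, x)$coefficients
  amp <- sqrt(cf[1]^2 + cf[2]^2)
  phase <- atan2(cf[2], cf[1])  # x ~ amp * sin(2 pi f t + phase) + C
  list(amplitude = amp, phase_deg = wrap_deg(rad2deg(phase)),
       frequency = f, offset = cf[3])
}

#' Four-parameter sine fit
#'
#' Least-squares fit of `A * sin(2 pi f t + phi) + C` to a sampled
#' waveform with the frequency free, initialized from a linear
#' three-parameter fit at `f_hint` and refined by Levenberg-Marquardt.
#' Fitting the full model (rather than correlating at a fixed
#' frequency) rejects residual harmonics of the stimulus generation and
#' small frequency errors, which is what makes the phase estimate
#' robust. The result is normalized to `amplitude >= 0` with the phase
#' wrapped into (-180, 180] degrees.
#'
#' If the non-linear refinement diverges, an error of class
#' `toothEIS_sine_fit_error` is signalled whose condition carries the
#' fixed-frequency fallback result in `$fallback`.
#'
#' @param w a [waveform] containing at least 3 cycles of `f_hint`,
#'   sampled above the Nyquist rate.
#' @param f_hint approximate frequency, Hz.
#' @return List with `amplitude` (volts), `phase_deg` (degrees),
#'   `frequency` (Hz), `offset` (volts), and `residual_rms`.
#' @examples
#' t <- seq(0, 0.5, by = 1e-4)
#' w <- waveform(1.0 * sin(2 * pi * 15 * t + pi / 6), fs = 1e4)
#' sine_fit(w, 15)
#' @export
sine_fit <- function(w, f_hint) {
  stopifnot(inherits(w, "waveform"))
  stop_if_not_scalar_pos(f_hint, "f_hint")
  if (w$fs <= 2 * f_hint)
    stop("sampling rate must exceed twice the target frequency",
         call. = FALSE)
  t <- waveform_times(w)
  if ((max(t) - min(t)) * f_hint < 3)
    stop("record must contain at least 3 cycles of `f_hint`", call. = FALSE)
  x <- w$samples
  init <- sine_fit_fixed(t, x, f_hint)
  par0 <- c(A = unname(init$amplitude), f = f_hint,
            phi = deg2rad(unname(init$phase_deg)), C = unname(init$offset))
  model_resid <- function(p) x - (p[1] * sin(2 * pi * p[2] * t + p[3]) + p[4])
  nl <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = model_resid,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  ok <- !is.null(nl) && all(is.finite(nl$par)) && nl$par[2] > 0 &&
    abs(nl$par[2] - f_hint) < 0.5 * f_hint
  if (!ok) {
    fallback <- c(init, list(residual_rms = sqrt(mean(
      (x - (init$amplitude * sin(2 * pi * f_hint * t +
                                   deg2rad(init$phase_deg)) +
              init$offset))^2))))
    cond <- structure(
      class = c("toothEIS_sine_fit_error", "error", "condition"),
      list(message = "four-parameter sine fit diverged; fallback attached",
           call = sys.call(), fallback = fallback))
    stop(cond)
  }
  p <- nl$par
  A <- p[1]; phi <- p[3]
  if (A < 0) { A <- -A; phi <- phi + pi }
  list(amplitude = unname(A),
       phase_deg = unname(wrap_deg(rad2deg(phi))),
       frequency = unname(p[2]),
       offset = unname(p[4]),
       residual_rms = sqrt(mean(nl$fvec^2)))
}

adc_quantize <- function(x, bits, vrange, channel) {
  if (any(x < 0 | x > vrange))
    stop(sprintf("ADC clipping on the %s channel", channel), call. = FALSE)
  lsb <- vrange / (2^bits - 1)
  round(x / lsb) * lsb
}

#' Emulated single-frequency impedance measurement
#'
#' Runs the full meter chain in software: synthesize the stimulus,
#' compute the exact steady-state current through the circuit, apply
#' the trans-impedance gain, add the mid-scale offset and Gaussian
#' noise on both channels, quantize with the unipolar ADC, sine-fit
#' both records, and form the impedance from the two phasors
#' (`|Z| = (A_v / v_gain) / (A_i / tia_gain)`, phase =
#' current phase minus voltage phase, i.e. the positive-degrees
#' convention for a capacitive load). The measurement is repeated
#' `n_repeats` times with independent noise and the phases averaged.
#'
#' @param p circuit description: a [circuit_params] object, a single
#'   resistance in ohm, or `list(r = , c = )` for a parallel RC.
#' @param cfg an [acquisition_config].
#' @return An object of class `phase_measurement`: `z_mod` (ohm),
#'   `z_phase` (degrees, positive convention, mean over repeats),
#'   `f_est` (Hz), `per_repeat_phases`, `phase_sd`.
#' @examples
#' m <- measure_impedance(3e5, acquisition_config(n_repeats = 2))
#' m$z_mod  # about 300 kOhm, phase about 0 degrees
#' @export
measure_impedance <- function(p, cfg = acquisition_config()) {
  stopifnot(inherits(cfg, "acquisition_config"))
  z <- impedance_of(p, cfg$f0)
  t <- seq(0, cfg$duration - 1 / cfg$fs, by = 1 / cfg$fs)
  mid <- cfg$adc_range / 2
  v_clean <- cfg$v_amp * sin(2 * pi * cfg$f0 * t) * cfg$v_gain + mid
  i_amp <- cfg$v_amp / Mod(z)
  i_clean <- i_amp * sin(2 * pi * cfg$f0 * t - Arg(z)) * cfg$tia_gain + mid
  res <- with_local_seed(cfg$seed, {
    lapply(seq_len(cfg$n_repeats), function(r) {
      nv <- if (cfg$noise_sd > 0) stats::rnorm(length(t), 0, cfg$noise_sd) else 0
      ni <- if (cfg$noise_sd > 0) stats::rnorm(length(t), 0, cfg$noise_sd) else 0
      va <- adc_quantize(v_clean + nv, cfg$adc_bits, cfg$adc_range, "stimulus")
      ia <- adc_quantize(i_clean + ni, cfg$adc_bits, cfg$adc_range, "current")
      fv <- sine_fit(waveform(va, cfg$fs), cfg$f0)
      fi <- sine_fit(waveform(ia, cfg$fs), cfg$f0)
      list(z_mod = (fv$amplitude / cfg$v_gain) / (fi$amplitude / cfg$tia_gain),
           z_phase = wrap_deg(fi$phase_deg - fv$phase_deg),
           f_est = fi$frequency)
    })
  })
  phases <- vapply(res, `[[`, numeric(1), "z_phase")
  structure(list(
    z_mod = mean(vapply(res, `[[`, numeric(1), "z_mod")),
    z_phase = mean(phases),
    f_est = mean(vapply(res, `[[`, numeric(1), "f_est")),
    per_repeat_phases = phases,
    phase_sd = if (length(phases) > 1) stats::sd(phases) else 0),
    class = "phase_measurement")
}

#' @export
print.phase_measurement <- function(x, ...) {
  cat(sprintf("|Z| = %.4g ohm, phase = %.2f deg (SD %.3f deg over %d repeats)\n",
              x$z_mod, x$z_phase, x$phase_sd, length(x$per_repeat_phases)))
  invisible(x)
}

#' Classify a meter measurement with the single-neuron classifier
#'
#' Hands the averaged phase of a [measure_impedance] result to
#' [demineralization_index], exactly as the firmware feeds its phase
#' reading to the classifier.
#'
#' @param m a `phase_measurement`.
#' @param cfg a [neuron_config].
#' @return A `classification_result`.
#' @export
meter_classify <- function(m, cfg = neuron_config()) {
  stopifnot(inherits(m, "phase_measurement"), inherits(cfg, "neuron_config"))
  classification_result(demineralization_index(m$z_phase, cfg), m$z_phase, cfg)
}
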