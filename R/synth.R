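#' Class-conditional population model for circuit parameters
#'
#' Describes how circuit parameters vary across teeth within each class.
#' `r1`, `r2`, `q` are drawn log-normally around the class centre with a
#' common geometric spread; `n` is Gaussian around its centre and
#' clipped into (0, 1]. The default centres are the reference values for
#' sound and demineralized enamel; the default geometric SD of 1.6 makes
#' the classes overlap slightly in parameter space (real tooth
#' classifiers are imperfect) while the 15 Hz phase still separates them
#' most of the time.
#'
#' @param nd_center,dm_center [circuit_params] class centres for
#'   non-demineralized and demineralized teeth.
#' @param log_sd geometric spread for `r1`, `r2`, `q`: draws are
#'   `center * exp(N(0, log(log_sd)))`. `log_sd = 1` means no spread.
#' @param n_sd additive Gaussian SD for `n`.
#' @param seed integer seed; the ND and DM streams are derived from it
#'   independently.
#' @return An object of class `population_model`.
#' @export
population_model <- function(nd_center = enamel_reference_params("sound"),
                             dm_center = enamel_reference_params("demineralized"),
                             log_sd = 1.6, n_sd = 0.04, seed = 0) {
  stopifnot(inherits(nd_center, "circuit_params"),
            inherits(dm_center, "circuit_params"),
            log_sd >= 1, n_sd >= 0)
  structure(list(nd_center = nd_center, dm_center = dm_center,
                 log_sd = log_sd, n_sd = n_sd, seed = seed),
            class = "population_model")
}

#' Replicate-level measurement noise model
#'
#' Multiplicative magnitude noise and additive phase noise applied
#' independently at every frequency of every replicate, emulating the
#' tight but visibly non-identical repeated acquisitions of a
#' potentiostat triplicate.
#'
#' @param mag_rel_sd relative SD of the multiplicative magnitude noise
#'   per point.
#' @param phase_sd additive phase noise SD per point, degrees.
#' @param n_replicates acquisitions per tooth (3 by default).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(mag_rel_sd = 0.02, phase_sd = 1, n_replicates = 3) {
  stopifnot(mag_rel_sd >= 0, phase_sd >= 0, n_replicates >= 1)
  structure(list(mag_rel_sd = mag_rel_sd, phase_sd = phase_sd,
                 n_replicates = as.integer(n_replicates)),
            class = "noise_model")
}

#' Draw circuit parameters for one class
#'
#' @param m a [population_model].
#' @param label `"ND"` or `"DM"`.
#' @param k number of draws.
#' @return List of `k` [circuit_params] objects. Deterministic given
#'   `m$seed`; the two label streams are independent.
#' @export
sample_parameters <- function(m, label, k) {
  stopifnot(inherits(m, "population_model"), k >= 1)
  if (!label %in% c("ND", "DM")) stop('`label` must be "ND" or "DM"',
                                      call. = FALSE)
  center <- if (label == "ND") m$nd_center else m$dm_center
  salt <- if (label == "ND") 1L else 2L
  sdlog <- log(m$log_sd)
  with_local_seed(derive_seed(m$seed, salt), {
    lapply(seq_len(k), function(i) {
      circuit_params(
        r1 = center$r1 * exp(stats::rnorm(1, 0, sdlog)),
        r2 = center$r2 * exp(stats::rnorm(1, 0, sdlog)),
        q  = center$q  * exp(stats::rnorm(1, 0, sdlog)),
        n  = min(1, max(1e-3, stats::rnorm(1, center$n, m$n_sd))))
    })
  })
}

# Apply per-point magnitude/phase noise to a complex impedance vector.
perturb_spectrum_z <- function(z, mag_rel_sd, phase_sd) {
  npt <- length(z)
  mod <- Mod(z) * (1 + stats::rnorm(npt, 0, mag_rel_sd))
  mod <- pmax(mod, .Machine$double.eps)
  ph <- Arg(z) + deg2rad(stats::rnorm(npt, 0, phase_sd))
  complex(modulus = mod, argument = ph)
}

#' Generate a labeled synthetic dataset of impedance spectra
#'
#' Draws per-tooth circuit parameters from the population model,
#' simulates each tooth's spectrum on the grid, and produces
#' `noise$n_replicates` noisy replicates per tooth (magnitude scaled by
#' `1 + eps`, phase shifted by `delta`, independently per point). The
#' generating parameters of every tooth are recorded as provenance.
#'
#' @param m a [population_model].
#' @param noise a [noise_model].
#' @param n_per_class teeth per class (the dataset is balanced).
#' @param frequency frequency grid, Hz.
#' @return An object of class `labeled_dataset`: list with `spectra`
#'   (one [impedance_spectrum] per tooth x replicate, labelled and
#'   carrying `tooth_id` / `replicate_id`) and `provenance` (data frame
#'   `tooth_id`, `label`, `r1`, `r2`, `q`, `n`).
#' @examples
#' d <- generate_labeled_dataset(n_per_class = 3)
#' d$provenance
#' @export
generate_labeled_dataset <- function(m = population_model(),
                                     noise = noise_model(),
                                     n_per_class = 12,
                                     frequency = log_frequency_grid()) {
  stopifnot(inherits(m, "population_model"), inherits(noise, "noise_model"),
            n_per_class >= 1)
  spectra <- list()
  prov <- NULL
  tooth <- 0L
  for (label in c("ND", "DM")) {
    pars <- sample_parameters(m, label, n_per_class)
    noise_seed <- derive_seed(m$seed, if (label == "ND") 3L else 4L)
    with_local_seed(noise_seed, {
      for (i in seq_len(n_per_class)) {
        tooth <- tooth + 1L
        p <- pars[[i]]
        prov <- rbind(prov, data.frame(
          tooth_id = tooth, label = label,
          r1 = p$r1, r2 = p$r2, q = p$q, n = p$n))
        z0 <- circuit_impedance(p, frequency)
        for (r in seq_len(noise$n_replicates)) {
          z <- if (noise$mag_rel_sd == 0 && noise$phase_sd == 0) z0
               else perturb_spectrum_z(z0, noise$mag_rel_sd, noise$phase_sd)
          spectra[[length(spectra) + 1L]] <- impedance_spectrum(
            frequency, z, replicate_id = r, tooth_id = tooth, label = label)
        }
      }
    })
  }
  structure(list(spectra = spectra, provenance = prov,
                 model = m, noise = noise),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  labs <- vapply(x$spectra, function(s) s$label, character(1))
  tid <- vapply(x$spectra, function(s) s$tooth_id, integer(1))
  cat(sprintf("Labeled dataset: %d teeth (%d spectra incl. replicates)\n",
              length(unique(tid)), length(x$spectra)))
  print(table(labs[!duplicated(tid)]))
  invisible(x)
}

#' Synthesize stimulus and current waveforms for a circuit at one frequency
#'
#' Produces the time-domain pair the single-frequency meter digitizes:
#' a sinusoidal voltage stimulus `v(t) = v_amp sin(2 pi f0 t)` and the
#' exact steady-state current through the circuit,
#' `i(t) = v_amp / |Z(f0)| * sin(2 pi f0 t - Arg Z(f0))` plus optional
#' Gaussian noise. For a capacitive circuit (`Arg Z < 0`) the current
#' leads the voltage by the impedance phase, so the stimulus/current
#' phasor ratio reproduces `Z(f0)` exactly by construction.
#'
#' @param p a [circuit_params] object, or a single resistance in ohm,
#'   or `list(r = , c = )` for a parallel RC.
#' @param f0 stimulus frequency, Hz.
#' @param v_amp stimulus amplitude, volts (10 mV default).
#' @param fs sampling rate, samples/s; must exceed `2 * f0`.
#' @param duration record length, s; must cover at least 5 cycles.
#' @param noise_sd additive Gaussian noise SD on the current waveform,
#'   in amperes.
#' @param seed integer seed; same seed gives bit-identical waveforms.
#' @return List with `stimulus` and `current`, each a [waveform].
#' @export
generate_waveforms <- function(p, f0, v_amp = 0.01, fs = 1e4, duration = 0.5,
                               noise_sd = 0, seed = 0) {
  stop_if_not_scalar_pos(f0, "f0")
  stop_if_not_scalar_pos(fs, "fs")
  if (fs <= 2 * f0)
    stop("sampling rate must exceed twice the stimulus frequency (aliasing)",
         call. = FALSE)
  if (duration * f0 < 5)
    stop("record must cover at least 5 stimulus cycles", call. = FALSE)
  z <- impedance_of(p, f0)
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  v <- v_amp * sin(2 * pi * f0 * t)
  i0 <- v_amp / Mod(z) * sin(2 * pi * f0 * t - Arg(z))
  i <- if (noise_sd > 0)
    with_local_seed(seed, i0 + stats::rnorm(length(i0), 0, noise_sd))
  else i0
  list(stimulus = waveform(v, fs), current = waveform(i, fs))
}

# Closed-form impedance of the circuit descriptions accepted by the
# meter and waveform generator.
impedance_of <- function(p, f0) {
  if (inherits(p, "circuit_params")) return(circuit_impedance(p, f0))
  if (is.numeric(p) && length(p) == 1L) {
    stop_if_not_scalar_pos(p, "resistance")
    return(complex(real = p))
  }
  if (is.list(p) && all(c("r", "c") %in% names(p))) {
    stop_if_not_scalar_pos(p$r, "r")
    stop_if_not_scalar_pos(p$c, "c")
    zc <- 1 / (2i * pi * f0 * p$c)
    return(p$r * zc / (p$r + zc))
  }
  stop("unsupported circuit description", call. = FALSE)
}
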