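#' Single-neuron classifier configuration
#'
#' Parameters of the single-perceptron classifier operating on the
#' impedance phase at one frequency: input bias `ib` (degrees), weight
#' `w`, sigmoid gain `g` (per degree), decision threshold on the
#' demineralization index (percent), and the classification frequency
#' `f0`. The defaults are the calibrated operating point: `ib = 65`
#' (mean DM phase plus 1.5 standard deviations), `w = 1`, `g = 2`,
#' threshold 50 percent, `f0 = 15` Hz.
#'
#' @param ib input bias, degrees.
#' @param w input weighting factor, dimensionless.
#' @param g sigmoid gain, per degree (> 0).
#' @param threshold decision cut on the index, percent, in (0, 100).
#' @param f0 classification frequency, Hz (> 0).
#' @return An object of class `neuron_config`.
#' @export
neuron_config <- function(ib = 65, w = 1, g = 2, threshold = 50, f0 = 15) {
  stopifnot(is.finite(ib), is.finite(w), g > 0,
            threshold > 0, threshold < 100, f0 > 0)
  structure(list(ib = ib, w = w, g = g, threshold = threshold, f0 = f0),
            class = "neuron_config")
}

#' Demineralization index of a phase measurement
#'
#' Inverted-sigmoid perceptron output:
#' \deqn{I(\phi) = \frac{100}{1 + \exp(g (w \phi - ib))}}
#' in percent. The index is strictly decreasing in the phase (sound
#' teeth have high capacitive phase at 15 Hz, hence an index near 0;
#' demineralized teeth have low phase, index near 100) and equals 50
#' exactly at the decision boundary `w * phase = ib`. It saturates
#' smoothly at 0 and 100 for extreme inputs.
#'
#' @param phase impedance phase in degrees, positive convention; may be
#'   a vector.
#' @param cfg a [neuron_config].
#' @return Index in percent, within \[0, 100\].
#' @examples
#' demineralization_index(65)  # exactly 50 at the boundary
#' demineralization_index(c(70, 44))  # sound vs demineralized
#' @export
demineralization_index <- function(phase, cfg = neuron_config()) {
  stopifnot(inherits(cfg, "neuron_config"), all(is.finite(phase)))
  100 / (1 + exp(cfg$g * (cfg$w * phase - cfg$ib)))
}

classification_result <- function(index, input_phase, cfg) {
  label <- if (index >= cfg$threshold) "DM" else "ND"
  structure(list(index = index, label = label, input_phase = input_phase),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("phase %.2f deg -> demineralization index %.2f%% -> %s\n",
              x$input_phase, x$index, x$label))
  invisible(x)
}

#' Classify a spectrum with the single-neuron classifier
#'
#' Extracts the phase at the classification frequency (interpolating in
#' log-frequency if needed) and applies [demineralization_index]. An
#' index greater than or equal to the threshold is labelled `"DM"`; the
#' tie goes to `"DM"`, favouring sensitivity in a screening context.
#'
#' @param s an [impedance_spectrum] whose grid covers `cfg$f0`.
#' @param cfg a [neuron_config].
#' @return A `classification_result`: list with `index` (percent),
#'   `label`, and `input_phase` (degrees).
#' @examples
#' s <- simulate_spectrum(enamel_reference_params("demineralized"))
#' classify_spectrum(s)
#' @export
classify_spectrum <- function(s, cfg = neuron_config()) {
  stopifnot(inherits(s, "impedance_spectrum"), inherits(cfg, "neuron_config"))
  phase <- phase_at_frequency(s, cfg$f0)
  classification_result(demineralization_index(phase, cfg), phase, cfg)
}

#' Per-tooth mean phase of a labeled dataset
#'
#' Extracts the phase at `f0` from every spectrum and averages the
#' replicates of each tooth, giving the per-tooth phase the calibration
#' rule and the classifier accuracy summaries operate on.
#'
#' @param d a [labeled_dataset].
#' @param f0 frequency in Hz.
#' @return Data frame with `tooth_id`, `label`, `phase` (degrees,
#'   positive convention).
#' @export
tooth_phases <- function(d, f0 = 15) {
  ph <- vapply(d$spectra, phase_at_frequency, numeric(1), f = f0)
  tid <- vapply(d$spectra, function(s) s$tooth_id, integer(1))
  lab <- vapply(d$spectra, function(s) s$label, character(1))
  agg <- stats::aggregate(ph, by = list(tooth_id = tid), FUN = mean)
  lab1 <- lab[match(agg$tooth_id, tid)]
  data.frame(tooth_id = agg$tooth_id, label = lab1, phase = agg$x)
}

#' Calibrate the single-neuron classifier on a labeled dataset
#'
#' Reproduces the statistical calibration rule: the input bias is the
#' mean 15 Hz phase of the demineralized teeth plus 1.5 times their
#' phase standard deviation (sample SD over per-tooth mean phases,
#' replicates averaged first); `w = 1`; the gain is chosen from
#' `g_grid` to minimise the training error rate, ties resolved toward
#' the smaller (smoother) gain; the threshold stays at 50 percent.
#'
#' @param training a [labeled_dataset] containing both classes.
#' @param g_grid candidate sigmoid gains.
#' @param f0 classification frequency, Hz.
#' @return A [neuron_config], with attribute `training_accuracy`.
#' @export
calibrate_neuron <- function(training, g_grid = c(0.5, 1, 2, 4), f0 = 15) {
  stopifnot(inherits(training, "labeled_dataset"), length(g_grid) >= 1)
  tp <- tooth_phases(training, f0)
  if (length(unique(tp$label)) < 2L)
    stop("training set must contain both ND and DM teeth", call. = FALSE)
  dm <- tp$phase[tp$label == "DM"]
  ib <- mean(dm) + 1.5 * stats::sd(dm)
  g_grid <- sort(g_grid)
  errs <- vapply(g_grid, function(g) {
    cfg <- neuron_config(ib = ib, w = 1, g = g, f0 = f0)
    idx <- demineralization_index(tp$phase, cfg)
    pred <- ifelse(idx >= cfg$threshold, "DM", "ND")
    mean(pred != tp$label)
  }, numeric(1))
  g_best <- g_grid[which.min(errs)]  # which.min takes the first: smallest g on ties
  cfg <- neuron_config(ib = ib, w = 1, g = g_best, f0 = f0)
  attr(cfg, "training_accuracy") <- 1 - min(errs)
  cfg
}
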