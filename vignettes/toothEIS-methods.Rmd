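---
title: "toothEIS: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{toothEIS: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toothEIS)
```

## The physical model

Enamel demineralization dissolves hydroxyapatite, opens inter-crystalline
pores, and lets ion-rich fluid reach the tissue, so the electrical
impedance of the tooth surface falls and its phase response shifts. A
tooth spectrum measured between 0.1 Hz and 10 kHz behaves as a
single-time-constant (first-order) system: resistive at high frequency,
capacitive-like at low frequency. `toothEIS` models it with three
elements — a series resistance `r1` (electrolyte plus electrode–tooth
interface, frequency-independent), in series with a charge-transfer
resistance `r2` in parallel with a constant-phase element:

$$Z(f) = R_1 + \frac{R_2\,Z_{CPE}}{R_2 + Z_{CPE}},\qquad
  Z_{CPE} = \frac{1}{(j\,2\pi f)^{N} Q}.$$

The CPE generalizes a capacitor to distributed (rough, porous)
interfaces: its phase is exactly $-90N$ degrees at every frequency.
Assumptions worth making explicit:

* one time constant — no second arc; multi-process circuits are out of
  scope by design;
* `r1` is treated as a single lumped element. Its decomposition into
  solution and interface resistance is not identifiable from a spectrum
  and is deliberately not modelled;
* `n` is restricted to (0, 1] in the fitted space (enamel fits give
  `n` near 0.8); the degenerate resistor limit `n = 0` is allowed in the
  forward CPE evaluation only.

The bundled reference element values
(`enamel_reference_params()`) are representative fits for sound and
demineralized incisor enamel. One oddity is documented rather than
hidden: the sound column carries the *smaller* series resistance
(3.9 kΩ vs 75 kΩ), although demineralization is physically expected to
*lower* the high-frequency magnitude that `r1` dominates; the two
columns of the source estimates may have been transposed. The values are
used exactly as given — the 15 Hz phase contrast that drives the
classifier (≈70° sound vs ≈44° demineralized) holds either way.

## Phase conventions

Internally every impedance is a true complex number, so capacitive
phases are negative. Every user-facing phase — classifier input, polar
CSV files, meter output — uses the positive-degrees convention
(`phase_positive(z) = -Arg(z)·180/π`), which is natural for an
instrument that only ever sees capacitive loads. The conversion happens
exactly once at each interface boundary.

In the time domain the current through a capacitive load *leads* the
stimulus voltage: $i(t) = \frac{V}{|Z|}\sin(2\pi f t - \arg Z)$ with
$\arg Z < 0$. The waveform generator and the meter emulation implement
this physical sign; it is what makes the meter's phasor ratio
$Z = V/I$ agree with the forward model including sign, and the relative
phase magnitude (≈44° for the demineralized reference circuit at 15 Hz)
is what the classifier consumes.

## The frequency grid and interpolation

The standard acquisition grid is $10^{k/5}$ Hz for $k = -5,\dots,20$:
five points per decade from 0.1 Hz to 10 kHz with *both endpoints
included*, 26 points, matching common potentiostat behaviour. The
classification frequency 15 Hz is not a grid point (neighbours 10.0 and
15.85 Hz), so `phase_at_frequency()` interpolates linearly in
$\log_{10} f$. The circuit's phase is smooth in log-frequency; the
interpolation error at 15 Hz is below 0.1° for the reference circuits
(tested against direct evaluation, tolerance 0.5°).

## CNLS fitting

`fit_spectrum()` minimizes the stacked real/imaginary weighted sum of
squares $\sum_f w_f\,|Z_{meas}(f) - Z_{model}(f)|^2$ by
Levenberg–Marquardt (`minpack.lm::nls.lm`) with box bounds. Numerical
choices:

* **Modulus weighting** $w_f = 1/|Z_{meas}(f)|^2$ by default: spectra
  span ~4 orders of magnitude, and unweighted least squares would fit
  only the low-frequency megaohm region. Unit weighting remains an
  option (and is what makes the scaling-equivariance property exact).
* **Log-parameterization** of `r1`, `r2`, `q`: enforces positivity and
  conditions the Jacobian across the kΩ–tens-of-MΩ range; `n` is
  box-bounded directly.
* **Initialization** from the spectrum's asymptotes: `r1` ← |Z| at the
  highest frequency, `r1 + r2` ← |Z| at the lowest (with `r2` floored at
  1 % of `r1` for flat spectra, flagged low-confidence), `n = 0.8`, and
  `q` set so the CPE corner frequency matches the phase-extremum
  frequency of the data.
* **Multistart**: 5 additional starts with ±50 % log-uniform
  perturbations of the guess (±10 % of that scale, additively, for `n`),
  under a fixed seed; the best final cost wins. Non-convergence is
  reported as a flag, never an exception — a screening pipeline should
  degrade, not die.
* Convergence tolerances default to 1e-10 (relative) with 200
  iterations per start; noiseless round trips recover all four
  parameters to machine precision, and the identifiability property
  (50 random draws within a factor of 10 of the reference values,
  recovery < 0.5 %) is part of the test suite.

One caveat the tests make visible: with the reference values the CPE
corner frequency sits near or below the 0.1 Hz grid edge, so `r2` is the
least-identified parameter under noise (median relative error ≈6 % at
2 % magnitude / 1° phase noise — still inside the 10 % contract).

## The synthetic-data generator

No public tooth-spectrum dataset exists, so the generator *is* the study
population for testing. It emulates, at the statistical level:

* **class structure**: per-tooth parameters drawn log-normally around
  the sound/demineralized centres (`r1`, `r2`, `q`; geometric SD 1.6)
  with Gaussian `n` (SD 0.04, clipped to (0, 1]). The spread is chosen
  so the classes overlap slightly in parameter space — real classifiers
  on tooth data reach ~85–88 % accuracy, not 100 % — while the 15 Hz
  phase still separates classes most of the time;
* **replicate structure**: three acquisitions per tooth, with per-point
  multiplicative magnitude noise (2 % SD) and additive phase noise
  (1° SD), matching visually tight potentiostat triplicates;
* **waveforms**: exact steady-state sinusoids at the stimulus frequency
  (10 mV amplitude, 10 kHz sampling, 0.5 s records) for the meter path.

What it does **not** emulate: electrode-contact drift, autoranging
artefacts, inter-tooth anatomical covariates (age, tooth type), or any
mechanistic link between acid exposure time and parameter shift. Passing
tests therefore demonstrate the *pipeline's* correctness and its
behaviour under the assumed statistics — not clinical performance on
real teeth.

Every stochastic operation takes an integer seed and runs on a local RNG
stream (the caller's RNG state is untouched); per-label and per-stage
sub-streams are derived with an LCG-style hash kept below $2^{31}$, so a
dataset is exactly reproducible from `(seed, config)` and its provenance
table.

## The single-neuron classifier

The decision function is the inverted sigmoid
$I(\phi) = 100/(1+\exp(G(W\phi - IB)))$, in percent. The functional form
was chosen so that (a) the index *decreases* with phase — sound teeth,
high phase, index near 0 — and (b) with $W = 1$ the bias $IB$ is the
midpoint phase where $I = 50$, which is what makes its statistical
derivation (mean demineralized phase + 1.5 SD ⇒ 65°) meaningful in the
phase domain. The standard deviation in the calibration rule uses the
sample ($n-1$) denominator, computed over per-tooth mean phases
(replicates averaged first). The gain is selected from a small grid by
minimum training error with ties resolved toward the smaller, smoother
gain; an index exactly at the threshold classifies as DM, favouring
sensitivity in a screening setting. The decision boundary $\phi = IB/W$
is independent of the gain, which only sets the sharpness of the index.

## The MLP classifier

A $(p \to 3 \to 2 \to 1)$ network with tanh hidden units. Choices the
architecture description leaves open were resolved as follows:

* **output layer**: a single sigmoid unit with cross-entropy loss, so
  the network emits a DM probability and an ROC curve is well defined;
* **solver**: the weights are optimized with base R
  `optim(method = "L-BFGS-B")` over an analytic backpropagation
  gradient. (A quoted "adaptive learning rate α = 1e-4" cannot apply to
  L-BFGS, which has no learning rate; it is treated as a reporting
  artefact and not implemented.) No installed R package offers a
  two-hidden-layer tanh MLP, so the forward pass and gradient are
  package code — small, explicit, and unit-tested;
* **regularization**: L2 penalty 1e-4 on weights (not biases),
  `max_iter` 2000 — mild shrinkage appropriate for tens of samples;
* **normalization**: min–max to [0, 1], fitted on training data only;
  test values may fall outside [0, 1] and are deliberately not clipped
  (a leakage guard is part of the test suite);
* **splits**: stratified by class at the tooth level, so replicates of
  one tooth can never straddle train and test; 5-fold CV likewise
  stratified;
* **features**: `r1`, `r2`, `q` by default; the CPE exponent is
  excluded because its variation does not track class, and the test
  suite asserts that adding it does not improve CV accuracy.

## The phase-meter emulation

The emulated instrument measures impedance at one frequency
(1–100 Hz) the way the hardware prototype does: sine stimulus, exact
circuit current, trans-impedance amplifier, mid-scale offset, additive
Gaussian noise, 16-bit unipolar ADC quantization, four-parameter sine
fit of both channels, phasor division, and averaging of 10 repeated
phase readings (≈2.5 s of signal at the defaults).

* The **four-parameter sine fit** (amplitude, frequency, phase, offset;
  frequency free) is initialized by a linear three-parameter fit at the
  frequency hint and refined by Levenberg–Marquardt. Leaving the
  frequency free both mirrors the prototype's estimator and rejects
  residual odd harmonics of a PWM-generated stimulus; the harmonics
  themselves are emulated as additive tones when needed rather than by
  modelling the PWM filter chain, which is hardware detail with no
  algorithmic content. If the refinement diverges, the error condition
  carries the fixed-frequency fallback estimate.
* The **front-end gains** are package choices (none were specified):
  stimulus channel ×120 (10 mV → 1.2 V) and trans-impedance gain
  4×10⁶ V/A on a 3.3 V ADC. A fixed gain cannot put both 100 kΩ and
  500 kΩ loads above a quarter of full scale without clipping the low
  end — the 5× load span caps the high-resistance end at ~20 % of range
  — so the gain was set to use ~24 % of full scale (peak-to-peak) at
  100 kΩ while accepting loads down to ≈25 kΩ, covering synthetic sound
  teeth whose 15 Hz magnitude falls below the 100 kΩ validation floor.
  Clipping raises an error naming the overloaded channel.
* At these settings the emulated phase uncertainty stays below 0.6° for
  pure resistors and below 2° for the 100–500 kΩ parallel-RC validation
  grid (18.2 nF), the bounds reported for the hardware; quantization
  alone contributes ≪0.05°.

## Metrics

DM is the positive class everywhere. The ROC sweep groups tied scores
into single threshold steps, which makes the trapezoidal AUC coincide
exactly (to 1e-12, tested on 200 random sets) with the Mann–Whitney
pair-counting statistic exported as `auc_rank()`; `pROC` serves as an
independent cross-check in the test suite, not as the implementation.
Scores with zero denominators are reported as `NA` and flagged, never
silently zeroed.

## Problem sizes

The test suite and acceptance script run at desk scale by choice:
26-point spectra; 24-tooth balanced datasets (12 per class, triplicate);
80-tooth datasets for MLP split/CV checks; 50-draw identifiability and
20-draw noise-recovery Monte Carlos; 100-trial sine-fit studies; 100
repeated meter readings per averaging condition. The full suite
completes in well under a minute.

## Known limitations

* Statistical, not mechanistic, realism: the generator cannot validate
  clinical sensitivity/specificity claims.
* `r2` identifiability degrades when the CPE corner falls below the
  lowest measured frequency; extending the grid downward would help at
  the cost of acquisition time.
* Exact numeric agreement with any particular commercial CNLS
  implementation is not promised: weighting schemes and convergence
  criteria differ between tools, and only synthetic round trips have a
  ground truth.
* The single-frequency meter inherits the single-time-constant
  assumption; a tooth with a second dispersion in the 1–100 Hz window
  would bias its phase reading.
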