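# toothEIS

Impedance-spectroscopy assessment of early tooth demineralization.

Dental caries always begins with enamel demineralization: acid attack
dissolves the hydroxyapatite lattice, the enamel becomes porous, ion-rich
fluid fills the inter-crystalline spaces, and the electrical impedance of
the tooth surface drops. Electrochemical impedance spectroscopy (EIS) —
a small sinusoidal voltage stimulus swept over frequency while the
current is measured — detects this change non-invasively and without
ionizing radiation. `toothEIS` is for researchers and instrument
developers working on impedance-based caries screening: it implements
the full analysis chain from spectra to a binary sound/demineralized
(ND/DM) call, plus a software emulation of a single-frequency handheld
phase meter, and a synthetic-data generator so every stage can be
exercised and validated without measured tooth data.

## The model

A tooth spectrum between 0.1 Hz and 10 kHz behaves as a first-order
system and is modelled by a series resistance R1 (solution + electrode
interface) in series with the parallel combination of a charge-transfer
resistance R2 and a constant-phase element (CPE) representing the
double-layer capacitance of the enamel interface:

    Z(f) = R1 + R2 · Z_CPE / (R2 + Z_CPE),   Z_CPE = 1 / ((j 2π f)^N · Q)

with Q the CPE coefficient (s^N/Ω) and N ∈ (0, 1] its exponent (N = 1 is
an ideal capacitor; enamel fits give N ≈ 0.8). Spectra are fitted by
complex non-linear least squares (CNLS): real and imaginary residuals
are stacked and weighted by 1/|Z|² so every decade of a spectrum that
spans four orders of magnitude counts.

Two classifiers act on the results:

* **Single-neuron classifier** — a perceptron with an inverted sigmoid
  acting on one number, the impedance phase φ at 15 Hz (where the
  ND/DM phase contrast is largest), returning a demineralization index

      I(φ) = 100 / (1 + exp(G · (W·φ − IB)))   (percent),

  with IB = 65° (mean DM phase + 1.5 SD), W = 1, G = 2, and a 50 %
  decision threshold. Sound teeth (φ ≈ 70°) score ≈ 0 %, demineralized
  teeth (φ ≈ 44°) score ≈ 100 %.
* **MLP classifier** — a (3 → 2)-hidden-layer tanh network on the fitted
  (R1, R2, Q1) after min–max normalization, trained by L-BFGS with a
  70/30 stratified split and 5-fold cross-validation. The CPE exponent
  is excluded: its small changes do not track demineralization.

The phase-meter emulation reproduces the measurement chain of a
microcontroller prototype: sine stimulus, trans-impedance amplifier,
16-bit unipolar ADC with noise and quantization, four-parameter sine fit
of both channels (frequency free, which also rejects residual stimulus
harmonics), impedance from the phasor ratio, and averaging of 10
repeated phase readings.

## Worked example

```r
library(toothEIS)

p <- enamel_reference_params("demineralized")
s <- simulate_spectrum(p)          # 26-point spectrum, 0.1 Hz - 10 kHz
classify_spectrum(s)
#> phase 44.04 deg -> demineralization index 100.00% -> DM

fit_spectrum(s)                    # CNLS round trip recovers the elements
#> CNLS fit (modulus weighting): cost 5.706e-30, converged after 9 iterations
#> Equivalent-circuit parameters (R1 + R2 || CPE):
#>   r1 = 7.5e+04 ohm
#>   r2 = 3.4e+07 ohm
#>   q  = 2.1e-07 s^n/ohm
#>   n  = 0.860

measure_impedance(p, acquisition_config())   # emulated handheld meter
#> |Z| = 1.338e+05 ohm, phase = 44.09 deg (SD 0.003 deg over 10 repeats)
```

The phase of 44° sits far below the 65° decision boundary, so the index
saturates at 100 % and the tooth is called demineralized; the emulated
meter agrees with the forward model to well under a degree.

A synthetic balanced 24-tooth study, classified by the single neuron:

```r
d  <- generate_labeled_dataset(n_per_class = 12)   # triplicate spectra
tp <- tooth_phases(d, 15)
pred <- ifelse(demineralization_index(tp$phase) >= 50, "DM", "ND")
classification_scores(confusion_matrix(tp$label, pred))
#>   accuracy     0.917
#>   f1           0.923
#>   recall       1.000
#>   specificity  0.833
#>   precision    0.857
#>   npv          1.000
```

A command-line interface covering the whole pipeline (`simulate`, `fit`,
`classify`, `calibrate`, `train-mlp`, `evaluate`, `meter`) is available
through `eis_cli()` or the `inst/cli/toothEIS` wrapper script.

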