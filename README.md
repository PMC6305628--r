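# hrpwm

Switched-excitation design and thermal-lesion prediction for
high-intensity focused ultrasound (HIFU).

HIFU transmitters have traditionally paired every transducer element with
a linear power amplifier: clean spectra, but bulky, inefficient and
expensive.  Switched (transistor bridge) drives fix the size and
efficiency problem, yet the obvious two-level square wave carries strong
odd harmonics — the third and fifth sit only about 10 and 15 dB below the
fundamental — inside the band of a resonant therapy transducer, where they
become acoustic energy with unwanted consequences (focal distortion,
transducer heating, cavitation-prone waveform transients).

This package implements **harmonic-reduction pulsewidth modulation
(HRPWM)** for a five-level bridge, together with the full analysis chain
needed to evaluate a switched drive against the linear-amplifier ideal:

* **Waveform design** (`design_switching_angles`, `synthesize`,
  `apodisation_set`): quarter-wave-symmetric switching-angle optimisation.
  With switching angles `a_k` and level steps `s_k` (rail step `V`), the
  Fourier series of the staircase is

  ```
  b_n = (4 V / (n pi)) * sum_k s_k cos(n a_k),   n odd
  ```

  The solver fixes the fundamental, `sum_k s_k cos(a_k) = 2 m` (modulation
  index `m`, normalised to the full staircase maximum `8V/pi`), and forces
  `sum_k s_k cos(n a_k) = 0` for each nulled harmonic `n` — one pulse per
  half cycle (two angles, H3 nulled) for `m` in `[0.433, 0.866]`, two
  pulses (four angles, H3/H5/H7 nulled) outside.  Amplitude control from
  fixed supply rails is what enables array apodisation without per-element
  adjustable supplies.
* **Harmonic spectroscopy** (`harmonic_levels`, `suppression_check`):
  exact-integer-cycle DFT levels in dB relative to the fundamental.
* **Gate sequencing** (`compile_gates`, `validate_gates`,
  `write_gate_table`): compiles a five-level waveform to the six bridge
  gate lines (`nA2p, nA1p, nA0p, A0n, A1n, A2n`) with dead-time insertion,
  shoot-through/dead-time/on-time validation and an FPGA-ready 0/1 table.
* **True electrical power** (`power_spectrum`, `total_true_power`):
  `P(f) = Re(V(f) I(f)*)` with an exact Parseval normalisation and
  band-limited integration (default 500 kHz – 10 MHz).
* **Acoustic field** (`transducer_model`, `compute_field`): linear
  per-harmonic model of a 64 mm / 63 mm focused bowl at 1.1 MHz — an FIR
  band-shape that rejects harmonic 4 and above, and an exact
  spherical-wave-expansion evaluation of the bowl's Rayleigh integral with
  power-law attenuation through a water/tissue layer stack.
* **Thermal dose** (`heating_rate`, `pennes_solve`, `cem43`,
  `lesion_metrics`): absorption heating `Q = sum_h alpha_h p_h^2 / (rho c)`,
  explicit axisymmetric Pennes bioheat solution, Sapareto–Dewey CEM43 and
  lesion thresholding at 240 equivalent minutes.
* **Cavitation detection** (`detect_events`, `classify_exposure`,
  `emission_spectrum`): the segmented trigger (380 mV threshold, 50 ms
  hold-off, 250 µs segments, 256-segment budget, mechanical if > 10
  events) and harmonic/ultraharmonic line labelling above a 5 MHz
  high-pass.
* **Fixtures, configuration, CLI** (`make_vi_trace`, `make_pcd_trace`,
  `load_config`, `run_comparison`, `inst/cli/hrpwm.R`): seeded synthetic
  signals, YAML-configurable end-to-end comparison runs, and an umbrella
  command-line tool (`design / spectrum / gates / power / simulate /
  compare / pcd`).

## Worked example

Design the HRPWM drive at the 70 % operating point and inspect its
spectrum:

```r
library(hrpwm)
spec <- excitation_spec("hrpwm", centre_frequency = 1.1e6,
                        modulation_index = 0.70,
                        sample_rate = 64 * 1.1e6, n_cycles = 4L)
w <- synthesize(spec)
harmonic_levels(w, 6)
#> <harmonic_spectrum>  f0 = 1100000 Hz
#>  order frequency_Hz amplitude_V level_dB
#>      1      1100000    52.65200     0.00
#>      2      2200000     0.00000     -Inf
#>      3      3300000     0.42247   -41.91
#>      4      4400000    0.00000      -Inf
#>      5      5500000   13.93500    -11.55
#>      6      6600000    0.00000      -Inf
```

The third harmonic, which a bi-level drive would leave at −9.5 dB, is
down at the −42 dB quantisation floor; the residual fifth harmonic lies
above the transducer's pass band and is rejected by its band-shape.  For
comparison, `synthesize(excitation_spec("bilevel", ...))` yields H3/H5 at
−9.5 / −14.0 dB — the closed-form square-wave series.

Run the scheme comparison at 26 W calibrated acoustic power (0.5 mm
thermal grid, 20 s exposure + 10 s cooling from 37 °C):

```r
report <- run_comparison(default_config())
report
#> <comparison_report>
#>   26 W calibrated acoustic power (drive convention), grid 0.5 mm [scaled down]
#>   sine     area  111.50 mm^2  (  +0.0% vs sine)  Tpeak 143.4 C
#>   bilevel  area  115.50 mm^2  (  +3.6% vs sine)  Tpeak 171.1 C
#>   hrpwm    area  105.50 mm^2  (  -5.4% vs sine)  Tpeak 137.2 C
```

The HRPWM lesion is a few percent smaller than the sine reference because
the drive parks about 6 % of its calibrated power in its fifth/seventh
harmonics, which the transducer's stop-band removes.  The bi-level lesion
comes out *larger* under this linear model: its third harmonic radiates,
focuses more tightly and is absorbed more strongly at the focus than the
path attenuation can offset — see the methods vignette
(`vignettes/hrpwm-methods.Rmd`) for why this differs from nonlinear
full-wave predictions and what that implies about the model's domain of
validity.

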