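---
title: "Switched HIFU excitation and lesion prediction: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Switched HIFU excitation and lesion prediction: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hrpwm)
```

This vignette records the models behind the package, the parameters that
matter, and the design decisions taken where the design was genuinely
open.  Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Waveform design

A five-level bridge can output the levels $\{-2,-1,0,+1,+2\}$ mapped to
rails $\pm V_2, \pm V_1$ and a ground clamp (equal steps $V_2 = 2V_1$ by
default).  We design quarter-wave-symmetric staircases: within the first
quarter cycle the level changes by $s_k \in \{+1,-1\}$ at angles
$\alpha_k \in [0, \pi/2]$, and the rest of the cycle follows by mirror
and sign symmetry.  Only odd harmonics survive, with sine coefficients

$$ b_n = \frac{4V_1}{n\pi} \sum_k s_k \cos(n \alpha_k), \qquad n\ \text{odd}. $$

**Modulation-index normalisation.** $m = 1$ is defined as the maximum
fundamental of the un-nulled full staircase (all angles at zero), i.e.
$b_1^{max} = 8V_1/\pi$.  The operating point used throughout is
$m = 0.70$: the value named "70 % duty cycle" in the transmit-scheme
literature is ambiguous between a carrier duty and a modulation index,
and we adopt the index reading as the default mapping; it is an ordinary
function argument, not a constant.

**Feasible bands and escalation.** With two angles and the third harmonic
nulled ($\cos 3\alpha_1 + \cos 3\alpha_2 = 0$,
$\cos\alpha_1 + \cos\alpha_2 = 2m$) solutions exist for
$m \in [\sqrt3/4, \sqrt3/2] \approx [0.433, 0.866]$, on the two branches
$\alpha_2 = \pi/3 \pm \alpha_1$.  Outside this band the solver escalates
to four angles (two pulses per half cycle).  Four unknowns against a
fundamental constraint leave three degrees of freedom, so the four-angle
system nulls harmonics $\{3,5,7\}$ — a superset of the two-angle design's
$\{3\}$ — which makes the Newton system square and deterministic.  The
solver is a damped Newton iteration with eight deterministic multi-starts,
tolerance $10^{-9}$, 100-iteration cap; an infeasible request (e.g.
$m = 1$ with H3 nulled, impossible because $\cos\alpha \le 1$) raises an
error naming the feasible band rather than returning a partial solution.

**Sampling and quantisation.** Waveforms are sampled at
$\ge 32$ samples/cycle (64 by default).  Switching instants are snapped
to the sample lattice by enumerating the floor/ceil candidate for every
angle and keeping the combination that best preserves the fundamental
while holding each designed null at least 23 dB below the fundamental
(3 dB of margin under the 20 dB relevance floor used for suppression
checks); remaining exact ties quantise to the earlier sample.  This
bounds the fundamental error to about 2 % at 64 samples/cycle — naive
per-instant rounding can err by 5–7 % at unlucky modulation indices.  A
transition that lands exactly on a sample takes its new level at that
sample, so the sampled sequence is half-wave antisymmetric exactly and
quarter-wave symmetric up to one sample per switching angle.

## 2. Harmonic spectroscopy

Harmonic levels are computed by a DFT over an exact integer number of
cycles with a rectangular window: every test signal is periodic and
synchronous, so leakage is handled by the integer-cycle precondition
rather than by windowing, and the dB levels
($20\log_{10}|A_n/A_1|$) are exact.  A non-integer record is an error,
not a warning.  $-80$ dB is the declared numerical floor for "absent".

## 3. Gate compilation

Level-to-path mapping: $+2 \to$ `nA2p`, $+1 \to$ `nA1p`, $0 \to$ the
clamp pair `nA0p`+`A0n`, $-1 \to$ `A1n`, $-2 \to$ `A2n`.  The active-low
pMOS lines conduct at 0, the active-high nMOS lines at 1; exported gate
tables hold these physical levels in a fixed column order.

Three hardware constraints are enforced: mutual exclusion (at most one
conducting path per sample), a dead gap of at least the configured dead
time between distinct paths, and the $\approx$ 1 ms on-time bound of the
capacitively level-shifted rail gates (the clamp pair is exempt; it can
idle indefinitely).  Dead time defaults to 100 ns — a typical MOSFET
driver scale; it is not dictated by the modelled hardware and is recorded
in the schedule.  The compiler treats the clamp as the resting state:
transitioning clamp→rail releases the clamp early, rail→clamp engages it
late, rail→rail delays the incoming gate, so the output floats only
inside dead gaps and decompiling recovers the input levels at every
conducting sample.  Whether the physical bridge interleaves the clamp
with every transition is a convention of this compiler, not a claim about
any fabricated board.

## 4. True electrical power

$P(f) = \mathrm{Re}\{V(f) I(f)^\ast\}$ as a one-sided density normalised
so that the trapezoidal integral over the full band equals the
time-domain mean of $v\cdot i$ exactly (the discrete Parseval identity
fixes the normalisation; every bin carries the one-sided factor two,
which exactly compensates the half weight the trapezoid gives the band
endpoints, with one extra factor at the edge bin of odd-length records).
Band-limited totals integrate over 500 kHz – 10 MHz by default.  No
window is applied; 100-cycle synchronous records are the intended input,
and band-edge leakage on non-synchronous records is the caller's risk.

## 5. Acoustic field: a linear per-harmonic surrogate

The transducer is a concave bowl, 64 mm aperture, 63 mm radius of
curvature, 1.1 MHz centre frequency.  Its electromechanical band-shape is
a 50-order FIR low-pass realised by Kaiser-windowed design at a 20 MHz
design rate with cutoff midway between $3f_0$ and $4f_0$; only the
magnitude contract is normative — unit gain (normalised) across
$f_0..3f_0$ and $\ge 40$ dB rejection at $4f_0$ and above.  Surface
pressure per harmonic is $p_h = |A_h|\,|H(h f_0)|\,k_{cal}$ with a single
volts-to-pascals calibration constant.

Propagation is **linear and per-harmonic**: each harmonic is radiated as
an independent monochromatic field of the uniformly driven bowl.  The
implementation evaluates the Rayleigh–Sommerfeld integral over the
spherical cap through its spherical-wave (addition-theorem) expansion
about the geometric focus; the series is numerically converged, matching
the O'Neil closed form on axis to machine precision and brute-force
surface quadrature off axis to the quadrature's own accuracy (both are
independent oracles in the test suite).  Accuracy degrades only in a thin
shell of field points at distance $\approx F$ from the focus — next to
the transducer face, inside the water path where no heat is deposited.
The focal $-6$ dB beamwidth of this model at $f_0$ is $\approx 1.85$ mm,
matching hydrophone measurements of the modelled transducer (a datasheet
figure of 1.33 mm is not reproducible by any linear diffraction model of
this geometry).

Attenuation uses per-layer power laws
$\alpha(f) = \alpha_0 (f/\mathrm{MHz})^b$ in dB/cm, applied as
$e^{-\alpha_h z_{path}}$ along the axial path; refraction between layers
is neglected and the diffraction pattern is computed at the coupling
(water) sound speed.  The default stack is 43 mm of water followed by
45 mm of tissue, placing the focus 20 mm deep in tissue — the lesioning
depth of the experimental protocol this emulates.  The tissue stand-ins
($c = 1547$ m/s, $\rho = 1060$ kg/m³,
$\alpha_0 = 0.52$ dB cm⁻¹ MHz⁻¹·¹, $b = 1.1$) are literature
chicken-muscle values; the source tissue table was not available, so all
of them are configuration keys.

What the surrogate deliberately omits: nonlinear harmonic generation and
prefocal shock losses, scattering, standing waves, absorbing boundaries.
Harmonics exist only where the drive puts them.

## 6. Heating, bioheat and dose

Absorption heating sums the first six harmonics,
$Q = \sum_{h=1}^{6} \alpha_h p_h^2 / (\rho c)$, with $\alpha_h$ taken
equal to the propagation attenuation (the attenuation is not split into
absorption and scattering; all of it heats).  The Pennes equation

$$ \rho C_p \frac{\partial T}{\partial t} =
   k_t \nabla^2 T - w_b \rho_b C_b (T - T_b) + Q $$

is integrated by an explicit finite-volume scheme on the axisymmetric
grid: the cell-centred radial operator makes the axis a natural zero-flux
face, outer boundaries are insulated, and the scheme conserves energy
exactly up to time discretisation.  The time step must satisfy the
stability bound (checked, with the maximum stable step named in the
error); an implicit solver was rejected in favour of something directly
verifiable against closed forms (equilibrium, conduction-free linear
ramp, heat-kernel spread).  Thermal dose is Sapareto–Dewey CEM43
($R = 0.5$ at or above 43 °C, $0.25$ below), accumulated at every solver
step, and the lesion is the region with $\ge 240$ equivalent minutes.
Lesion cross-section area counts each half-plane cell twice (both sides
of the axis), matching how a sliced lesion is photographed and measured.
Perfusion defaults to zero to emulate ex-vivo tissue; a nonzero value is
one configuration key away.

## 7. The scheme comparison and its calibration convention

`run_comparison` drives the whole chain for sine, bi-level and HRPWM at
equal calibrated acoustic power (26 W default), 20 s on + 10 s cooling
from 37 °C, and reports lesion areas and percentage changes against the
sine reference.

**Calibration convention.**  Two conventions are implemented.  The
default, `calibrate = "drive"`, normalises the total power carried by the
drive spectrum at the source surface *before* the transducer band-shape,
mirroring an equal-electrical-power protocol (the practical way a bench
comparison is normalised, since electrical true power is what a current
probe measures); the transducer then decides how much of each harmonic
radiates.  The alternative, `"radiated"`, normalises the post-transfer
spectrum.  The distinction matters: with a fully effective stop-band the
radiated spectra of HRPWM and sine are identical, so under `"radiated"`
their lesions are identical by construction, whereas under `"drive"`
HRPWM pays for the $\approx 6\%$ of its power parked in H5/H7 that the
transducer rejects — the mechanism by which low-distortion switched
drives can still lose a little lesioning efficacy.

**Numerical sizes.**  The comparison runs on a 0.5 mm thermal grid
(64 × 78 mm half-plane, 9 984 cells) with the pressure field evaluated on
a two-fold supersampled grid and the heating rate block-averaged down, so
the narrow third-harmonic focal spot deposits the correct integrated
power; the Pennes step is 25 ms against a $\approx 0.4$ s stability
bound, and drives are synthesised at 256 samples/cycle for the spectral
stage.  These sizes keep a full three-scheme comparison near ten seconds
on one CPU; the native 112 µm field grid of the emulated study remains
available through `solver$grid_spacing` for users who want it.

**What the linear surrogate predicts — and what it cannot.**  At these
settings HRPWM comes out a few percent smaller than sine (the H5/H7
mechanism above).  Bi-level, however, comes out a few percent *larger*,
not the tens-of-percent smaller that nonlinear full-wave simulation and
ex-vivo experiments report.  The reason is structural: in a linear lossy
model the radiated third harmonic focuses with diffraction gain
proportional to frequency and is absorbed $3^{1.1} \approx 3.3\times$
more strongly at the focus, which outweighs its extra 2–4 dB of path
attenuation at any plausible target depth, so concentrated H3 deposition
enlarges the simulated lesion.  Reversing that verdict requires either an
implausibly long absorbing path ($\alpha_0 \cdot L \gtrsim 5.5$ dB·cm⁻¹ ×
cm, roughly 10 cm of muscle) or the prefocal nonlinear losses that this
surrogate explicitly excludes.  Users should therefore read bi-level
comparisons from this package as a lower bound on harmonic-related harm:
the model captures energy bookkeeping across the transducer band, not
nonlinear propagation, cavitation or waveform-transient effects.

## 8. Cavitation detection

The trigger emulates a segmented-acquisition oscilloscope: absolute value
above 380 mV (broadband emissions are bipolar, and no polarity is implied
by the emulated hardware), 50 ms hold-off, 250 µs segments, at most 256 —
so the count for well-separated bursts is exactly $\min(K, 256)$ — and
more than 10 events classifies the exposure as mechanically rather than
thermally formed.  The receive high-pass (stopband $\ge 60$ dB below
5 MHz, linear phase) removes the drive's first three harmonics before
spectral analysis.  Emission spectra use an averaged periodogram (up to
16 sub-segments) so that the 6 dB line-labelling prominence floor has a
negligible false-alarm rate on pure noise; peaks within half a bin of
$n f_0$ or $(2n+1) f_0/2$ are labelled harmonic or ultraharmonic.  A
broadband burst can legitimately exceed the prominence floor at a line
frequency by chance; the strongest labelled line is the robust readout.

## 9. Synthetic fixtures and what passing tests show

All test inputs are generated in code: drive waveforms through a lumped
RLC load (exact periodic steady-state current, per-bin admittance),
Gaussian-noise PCD traces with enveloped broadband bursts and optional
coherent lines, all bit-reproducible from a seed.  They emulate the
*structure* of bench signals — synchronous records, known line content,
stationary noise — not their pathologies: no probe de-skew, amplifier
droop, impedance drift, asynchronous sampling or non-stationary noise.
Passing tests therefore demonstrate correctness of the algorithms under
their stated preconditions, not robustness to uncalibrated hardware.

## 10. Known limitations

* Linear propagation only; no boiling, no cavitation-enhanced heating,
  no temperature-dependent tissue properties (peak temperatures above
  100 °C are reported as computed and should be read as "beyond the
  model").
* The expansion field is inaccurate in a thin shell near the transducer
  face (water path, no heating consequence).
* Tissue parameters are literature stand-ins; every one is a
  configuration key.
* The comparison's bi-level verdict excludes the nonlinear mechanisms
  that dominate it in full-wave models (Section 7).
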