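---
title: "High-pass phase distortion of LFP cross-correlations: model, simulation and correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-pass phase distortion of LFP cross-correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpphase)
```

## The problem

Every extracellular acquisition system AC-couples its input: an analog
high-pass stage with a cutoff somewhere in the 0.1–1 Hz range sits in front
of the digitizer. Around and below its cutoff such a stage does two things
to each frequency component: it attenuates it by the gain $|H(\omega)|$ and
it shifts its phase by $\arg H(\omega)$ — for a first-order high-pass,
$\arg H = \arctan(\omega_0/\omega)$, a phase *lead* that reaches 45° at the
cutoff and is still ~6° a decade above it. Local field potentials carry
most of their power exactly where this happens, so any waveform estimate
built from LFP — in particular the spike-triggered LFP average (stLFP),
which equals the spike–LFP cross-correlation — inherits the distortion.
The characteristic signature is that a purely monophasic correlation
(a single trough at zero lag) acquires a delayed positive rebound: the
causal high-pass "discharges" after the trough, producing a biphasic shape
with a peak a few hundred milliseconds after the trough that is easily
mistaken for biology.

This package provides the machinery to (i) model and measure amplifier
transfer functions, (ii) synthesize signal pairs whose true correlation is
known exactly, (iii) filter and phase-correct signals in the frequency
domain, and (iv) quantify the resulting correlation shapes.

## Transfer functions

`filter_model()` describes analog prototypes (Butterworth high-/low-pass
stages and cascades); `evaluate_model()` evaluates their exact frequency
response from the pole product, which keeps the phase naturally unwrapped.
Filters are represented by frequency response only — never by time-domain
recursion — because all filtering and correction here is done
spectrally, and because it sidesteps digital-design ambiguity entirely.

The sign convention throughout: **positive phase means the output leads
the input**, which is what a high-pass stage does at low frequencies.

Three named presets stand in for common systems: `"cerebus-like"`
(first-order high-pass at 0.3 Hz), `"openephys-1hz"` and
`"openephys-0.1hz"` (first-order at 1 and 0.1 Hz), each cascaded with a
first-order 7.5 kHz low-pass. The true topology and order of commercial
front-ends are not published, and nominally equal cutoffs can hide very
different phase behaviour — bench measurements show a nominal 0.1 Hz
system can shift phase *more* than a nominal 0.3 Hz one — so first order
is a documented assumption, not a claim about the hardware, and the
calibration module exists precisely so that a real system is measured
rather than presumed.

Tabulated transfer functions (from calibration or CSV) are interpolated
linearly in (log-frequency, dB-gain) and (log-frequency, phase)
coordinates, the natural geometry for grids spanning three decades
(0.03–30 Hz). Outside the tabulated range, endpoint values are held
constant.

## Calibration

`synthesize_calibration()` emulates the bench procedure: a sine of known
amplitude and frequency into the head-stage, markers at the extrema of the
input (the role of a function generator's TTL line), white noise on the
output. `estimate_point()` fits in-phase, quadrature and offset regressors
at the known frequency by least squares — exact on noiseless input, robust
to non-integer period counts, and invariant to DC offsets — and references
phase to the markers: zero phase means an undistorted sine whose positive
peaks fall on alternate markers. Whether the first marker is a maximum or
a minimum is decided by the sign of the fitted waveform there, which is
unambiguous while the phase shift stays inside ±90°, as it does for the
filter classes modelled here.

The default grid is 7 log-spaced frequencies from 0.03 to 30 Hz. The
package's own checks run each record for 10 periods (at least 10 s) at
1 kHz with noise at 5% of the input amplitude; under those conditions 100
replicate sweeps recover gain within 1% and phase within 0.01 rad at every
grid frequency. Cycle counts and noise levels in a real calibration are
the experimenter's choice; the analytic scaling is the usual
$\mathrm{SE} \propto \sigma\sqrt{2/N}$ of a sine fit, relative to the
*output* amplitude, so low-frequency points of a high-pass system need the
most data.

## The signal-pair generator

Pairs $x(t), y(t)$ are built directly in the frequency domain from a
target one-sided power spectrum $P(\omega)$ and magnitude coherence
$C(\omega) \le 1$:
$X(\omega) = P^{1/2}(\omega)e^{i\varphi(\omega)}$ with phases drawn
uniformly and independently per positive-frequency bin, and
$Y(\omega) = -C(\omega)X(\omega) + Y_2(\omega)$, where $Y_2$ carries power
$(1-C^2)P$ with its own independent phases. Negative-frequency bins are
conjugate-symmetric, the DC bin is zero (signals are zero-mean by
construction) and the Nyquist bin is real with random sign. Two
consequences matter:

* the realized magnitude coherence equals $C(\omega)$ exactly in
  expectation, because $y$'s power is $C^2P + (1-C^2)P = P$;
* the cross-spectrum $-C(\omega)P(\omega)$ is real and non-positive, so
  the pair's true cross-correlation is symmetric with a central trough —
  the clean "ground truth" that filtering then distorts.

Amplitudes are deterministic ($P^{1/2}$, not Rayleigh-distributed), which
makes spectral estimates of short records tight. The one-sided PSD is
normalized so that $\int P\,df$ equals the signal variance; Welch
comparisons in the package use the same convention.

### Default conditions

`make_spectral_spec()` defaults describe the cortical-LFP-like regime in
which the artefact is prominent:

| parameter | default | meaning |
|---|---|---|
| `amplitude` | 5000 µV²/Hz | plateau of the knee power law |
| `knee_hz`, `exponent` | 0.7 Hz, 3 | spectrum flat below the knee, $f^{-3}$ above |
| `osc_amp`, `osc_freq_hz`, `osc_bw_hz` | 50 µV²/Hz, 5 Hz, 3 Hz | broad slow rhythm, as in rodent cortex |
| `hf_floor` | 1 µV²/Hz | wideband background |
| `c_max`, `band_lo_hz`, `band_hi_hz` | 0.9, 2 Hz, 20 Hz | coherence plateau and raised-cosine rolloff |
| `lf_mult`, `mult_lo_hz`, `mult_hi_hz` | 1, 0.5 Hz, 2 Hz | low-frequency power multiplier and its band |

Together these give ~70 µV RMS signals whose cross-correlation is a
symmetric trough a few hundred milliseconds wide. The defaults were tuned
once, against the package's own deterministic cross-spectral integrals, so
that the full set of qualitative properties holds simultaneously with
margin at 600 s × 1 kHz: the unfiltered pair classifies as non-biphasic;
each high-pass preset turns it biphasic with a peak offset of a few
hundred milliseconds; phase-only correction reverts the classification;
and the artefact grows monotonically with low-frequency power. Notes on
the individual pieces:

* the **wideband floor** contributes ~2% of the variance but most of the
  fast fluctuations, so that 99th-percentile upward crossings occur at a
  few Hz — multi-unit-like rates — rather than once every several seconds;
* the **5 Hz bump** supplies coherent power in the 1 Hz filter's passband.
  Without it, the gain attenuation that phase-only correction deliberately
  retains leaves a corrected curve whose symmetric sidelobes sit close to
  the biphasic classifier's ratio threshold; with it they sit well below.
  Its 3 Hz width keeps its own correlation ringing confined to lags where
  the central trough dominates;
* the **low-frequency multiplier** acts fully below 0.5 Hz and not at all
  above 2 Hz, so a sweep member's band power below 0.5 Hz scales *exactly*
  by `lf_mult` while power above 2 Hz is *exactly* fixed — a clean "more
  slow power, same fast power" manipulation. Because the coherent bulk of
  the spectrum lies below 2 Hz, applying the multiplier to the shared spec
  (both signals) is what makes the artefact growth clearly monotone; an
  alternative `spec_y` argument to `generate_pair()` varies only $y$'s
  spectrum at fixed coherence, which scales the cross-power by
  $\sqrt{\texttt{lf\_mult}}$ instead and is the gentler manipulation.

### What the generator does not emulate

The surrogate is purely spectral: stationary, Gaussian-ish, with no
biophysics (no dipole geometry, no conductances, no spike waveforms
leaking into the LFP band), no nonstationarity (no state switches, no
drifting rhythms), and spikes are threshold crossings of the same process
rather than point processes with refractoriness. Passing tests therefore
demonstrate the *filter-side* claims — what high-pass phase shifts do to
any correlation and that phase-only correction undoes exactly the phase
part — not that any particular biological stLFP is artefactual. That
question is settled per recording, by calibrating the amplifier and
correcting the data.

## Filtering and correction

Both operations act on the whole record with a single FFT:

* `apply_tf()` multiplies each positive-frequency bin by
  $|H|e^{i\arg H}$ (forward distortion, $V_{out} = H V_{in}$);
* `phase_correct()` multiplies by $e^{-i\arg H}$, the phase-only inverse:
  $V_{corr}(\omega) = e^{-i\arg H(\omega)}V_{out}(\omega)$.

The correction leaves every bin's power untouched — including the
low-frequency attenuation. Inverting the gain as well (`invert_gain =
TRUE`) divides out $|H|$, but amplifying bins the amplifier suppressed
also amplifies their noise, which is why the power loss is retained by
default and why `phase_correct(apply_tf(v, H), H)` equals gain-only
filtering *exactly* (to ~1e-13 relative in the test suite) rather than
recovering `v`.

Numerical conventions, chosen once and applied consistently so that the
exact identity above holds bin for bin:

* **DC bin**: a high-pass filter's phase is undefined at 0 Hz; `apply_tf`
  multiplies DC by the gain at the lowest available frequency with zero
  phase, and `phase_correct` leaves it untouched.
* **Nyquist bin**: multiplied by its gain with zero phase, keeping the
  spectrum conjugate-symmetric and the output real.
* **Circularity**: a single whole-record FFT treats the record as
  periodic. For records much longer than the filter's slowest time
  constant (seconds, for sub-Hz cutoffs) the wrap-around is negligible;
  `pad_mirror = TRUE` mirror-pads short records first. The default is off
  because the package's own demonstrations use 600 s records.
* Signals are processed in double precision regardless of storage
  precision (files store float32).

## Estimators and diagnostics

`cross_correlate()` computes the unbiased, edge-truncated estimate
$c(\tau) = \langle x(t)\,y(t+\tau)\rangle_t$ after mean subtraction, via
zero-padded FFTs; positive lag means $y$ after $x$. `st_average()` averages
mean-subtracted LFP windows around spike times and reports per-spike µV —
not a correlation coefficient — matching how stLFPs are plotted; when
spikes are upward threshold crossings of a companion signal, the classical
triggered-correlation result makes the stLFP proportional to the
continuous cross-correlation, which the suite verifies at $r > 0.95$.

`biphasic_index()` operationalizes "biphasic": trough = minimum within
±100 ms of zero lag; peak = maximum at later lags; the curve is biphasic
when peak/|trough| exceeds 0.2 *and* the peak trails the trough by
0.05–1 s. The thresholds are configurable; the defaults encode "a rebound
of at least a fifth of the trough, offset by a perceptible fraction of a
second", which matches the published examples of the shape. The companion
`asymmetry_index()` (normalized squared difference between the two lag
signs) separates genuinely asymmetric curves from symmetric ones whose
sidelobes merely trip the ratio.

`welch_psd()` / `welch_coherence()` are standard Welch estimators (Hann
taper, 50% overlap, mean-removed segments, 10 s segments by default for
0.1 Hz resolution) used as the independent empirical check that generated
pairs realize their spectral spec. Magnitude coherence of independent
signals is biased upward at finite segment counts (≈ $K^{-1/2}$ for $K$
segments), which the tests account for by using hundreds of segments
when asserting "coherence ≈ 0".

## Problem sizes

The package's checks use 600 s at 1 kHz (the scale at which the artefact
demonstrations are run), 10-period calibration records at 1 kHz with 100
replicate sweeps, and 50 random signal/filter pairs for the exactness of
the correction identity; the unit tests exercise the same code paths at
30–150 s and 200–500 Hz.

## Known limitations

* Correction quality on real data is limited by the calibration, not by
  the algorithm: the phase is undone only as accurately as $\arg H$ was
  measured, and interpolation holds endpoint values outside the calibrated
  band.
* No real-time/causal variant: the correction is offline by design
  (a phase-only inverse is non-causal).
* No vendor-format readers (Blackrock NSx, Open Ephys continuous); the
  float32-plus-JSON-sidecar format is the interchange point, and readers
  for vendor formats are deliberately out of scope.
* The biphasic classifier is a shape heuristic for simulation summaries,
  not a statistical test; near its thresholds, inspect the curves.
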