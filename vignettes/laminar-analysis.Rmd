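---
title: "Laminar signal-flow analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar signal-flow analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamflow)
```

`lamflow` analyzes recordings from linear multi-contact ("laminar") probes in
primary visual cortex: 16 contacts at 150 µm spacing spanning the cortical
depth, recorded while gratings of six diameters (0.5°–15°) are flashed for
500 ms after a 500 ms blank. This vignette explains each stage's model, the
parameters that matter, and the choices made where the methods literature
leaves the design open. It states no empirical result that the package's
tests and acceptance script do not themselves compute.

## Signal conditioning

Two signals are derived from the broadband extracellular recording:

* **LFP** — 0.75–300 Hz, 3rd-order Butterworth, then decimation to 1 kHz.
* **MUAe** — the multi-unit band (0.6–9 kHz at a 32 kHz acquisition rate),
  full-wave rectified, low-passed at 200 Hz, decimated to 1 kHz. The MUAe is
  an envelope of aggregate spiking near the contact; it is non-negative
  before z-scoring.

All filters are applied forward–backward (zero phase). The filter chain
specification does not pin down phase handling; zero-phase is chosen so that
group delay cannot bias latency estimates. The 0.75–300 Hz band is far wider
than the 4–55 Hz analysis bands, so the effect of this choice on the
connectivity analyses is negligible — but it is a choice, and single-pass
causal filtering would shift absolute latencies by a few milliseconds.

Two numerical caveats worth knowing:

* The 0.75 Hz high-pass corner at 8–32 kHz puts filter poles extremely close
  to the unit circle. The band is therefore realized as a high-pass/low-pass
  cascade rather than one band-pass polynomial, and linearity of the chain
  holds to ~1e-7 relative (not machine precision) because rounding is
  amplified near those poles.
* Decimation is plain subsampling after the anti-alias low-pass; the target
  rate must divide the raw rate exactly (8000 → 1000 by default). The
  deposited-data convention of ~1 kHz is stated in one place as 1017 Hz;
  1000 Hz is the default here and any divisor rate can be configured.

Epochs use the half-open window `[-500, 500)` ms around stimulus onset with
0-based sample indexing, so one epoch at 1 kHz is exactly 1000 samples and
the onset sample is not double-counted. Baseline z-scoring pools the mean
and SD over all trials and all samples of the `[-300, 0)` ms window.

## Bipolar referencing

The raw LFP volume-conducts across the whole probe, so layer-resolved
spectral and connectivity analyses use the bipolar LFP: at contact *i*,
`LFPbp(i) = LFP(i−1) − LFP(i+1)`, contacts ordered top to bottom. The
"difference of the neighboring contacts" can also be read as a
successive-pair difference; the centered form is the default because it
keeps the result assigned to a contact-centered depth and uses both
flanking neighbors symmetrically, and the successive form is available via
`bipolar_reference(method = "successive")`. End contacts have no two
neighbors and are marked unusable.

## Inverse CSD and laminar alignment

The current source density is the standard finite-difference inverse:

$$\mathrm{CSD}(z) = -\sigma\,\frac{\phi(z+h) - 2\phi(z) + \phi(z-h)}{h^2}$$

with conductivity σ = 0.3 S/m, spacing h = 150 µm, potentials in volts
internally so the result is in A/m³. Boundary contacts are regained by
duplicating the boundary potentials (the Vaknin method). **The sign
convention is sink-positive**: a current sink appears as a positive value.
The opposite convention is common elsewhere; every consumer in this package
(alignment, QC, normalization) assumes sink-positive.

Sessions are aligned across experiments at the early layer-4c current sink:
the channel whose maximal sink-positive CSD within 35–55 ms after onset is
largest defines depth 0 µm, and `depth(ch) = (alignment − ch) × 150 µm`, so
three contacts above the alignment channel sit at +450 µm (supragranular)
and three below at −450 µm (infragranular). The window conventions differ
slightly between uses in the source methods (35–55 ms for the search,
40–70 ms for sink-peak normalization); both are configurable and those are
the defaults. Session QC automates two inclusion rules — an identifiable
early sink peaking by 50 ms, and an alignment channel between the seventh
and twelfth contact — and records the third (overall CSD-pattern
consistency) as a manual flag that is never auto-decided. The QC wording
says "current source" where the alignment section says "current sink"; the
implementation uses the early sink-positive peak detector for both,
recorded here as an interpretation.

### The forward model and current conservation

The synthetic generator needs potentials whose CSD is a planted map. The
discrete Vaknin-extended CSD operator is singular: depth-constant potentials
are invisible to it, and every CSD it can produce sums to zero across depth
(current conservation). The forward model therefore solves the operator
under a zero-mean-potential gauge; charge-balanced CSD maps round-trip
through `compute_icsd()` to machine precision, and unbalanced input is
projected onto the balanced subspace with a warning. Physically meaningful
laminar CSD maps are charge-balanced, so the generator only plants balanced
profiles (a depth-Gaussian sink with its return currents).

## Response latency

The phasic MUAe response (0–200 ms, z-scored to baseline) is fit with the
sum of two normalized Gaussians and a cumulative Gaussian:

$$R(t) = \frac{G_1}{\sqrt{2\pi}\sigma_1} e^{-\tfrac{(t-\mu_1)^2}{2\sigma_1^2}}
       + \frac{G_2}{\sqrt{2\pi}\sigma_2} e^{-\tfrac{(t-\mu_2)^2}{2\sigma_2^2}}
       + \frac{G_3}{2}\left(1 + \mathrm{erf}\frac{t-\mu_3}{\sqrt{2}\sigma_3}\right)$$

Because of the Gaussian normalization the amplitudes $G_{1,2}$ are areas
(z·ms); $G_3$ is the plateau height in z. Latency is the earliest time the
*fitted model* exceeds z = 3, evaluated on a 0.1 ms grid — an absolute
criterion, so responses of different sizes are compared on the same scale.
Fitting is Levenberg–Marquardt with box bounds (means inside the window,
σ ∈ [1, 100] ms, amplitudes free-signed to allow suppression transients)
and five jittered restarts from a data-driven start (μ₁ at the peak, μ₃ at
the half-rise, σ = 10 ms); the surface is multimodal and the restart count
is a compromise between robustness and the ~100 fits a full session needs.
Fits use trial-averaged traces per condition, consistent with one transient
per channel; single-trial latency estimation is out of scope. Compartment
summaries average two adjacent channels at ±450/±600 µm for the
supra/infragranular compartments and use the alignment channel for the
granular one.

## Induced spectral power

Spectrograms use a 100 ms Hanning window stepped by 10 ms, demeaned per
window, zero-padded to a 1024-point FFT. Window centers define timestamps,
which makes the 200–500 ms sustained-window selection deterministic. The
per-window demeaning attenuates frequencies below the ~10 Hz window
resolution, so white-noise spectra are flat only above ~15 Hz — relevant
when interpreting the theta band, whose absolute power estimates lean on
the window's low-frequency response.

The iSP ("induced spectral power") expresses stimulus-period power relative
to the 300 ms pre-stimulus baseline. The source description — "z-score
relative to spontaneous activity" — does not determine the estimator, and
the two natural readings serve different purposes, so both are computed:

* `z_amp`: trial-mean power minus the mean of per-trial baseline means,
  over the SD of per-trial baseline means. It scales with the power change,
  so band-power size tuning and the gamma peak frequency read it. Its null
  spread is wider than N(0, 1), because the numerator carries single-window
  variance while the denominator is the spread of 300 ms baseline averages.
* `z` (paired): each trial's power against its own baseline mean, reduced
  by a one-sample statistic. Its null is standard normal at realistic trial
  counts (the calibration the tests verify), but it *saturates* near
  √n·(mean/SD of an exponential-like variate) for any strong effect and
  carries no spectral-shape information. Detection masks use it.

Band definitions are θ 4–8, α 8–13, β 14–25, γ 35–55 Hz for power; the
phase-triggered averaging stage uses its own printed γ band of 30–55 Hz.
Each consumer keeps its own printed band rather than harmonizing them.

## Phase-triggered averaging

For each band, the reference contact's LFPbp is band-passed (zero-phase,
3rd order) to give the phase-providing signal; its troughs inside the
sustained window are alignment points, and the broadband LFPbp of every
contact is averaged within ±120 (θ), ±80 (α), ±80 (β) or ±25 (γ) ms of each
trigger, pooled across the trials of one stimulus size. Troughs are strict
local minima with no amplitude threshold — noise triggers average out — with
one numerical guard: a filtered signal whose amplitude is below 1e-4 of the
trace scale is treated as having no phase at all, so constant input yields
zero triggers rather than round-off artifacts. The per-channel lag is the
local trough nearest lag 0 (trough-triggered averaging makes a coupled
channel's trough the matched-sign extremum); negative lags mean the target
leads the reference.

## Spectral Granger causality and the reversal control

Directed coupling between contact pairs is quantified on the sustained
response: 256 bins from 200 ms after onset, per trial. A bivariate VAR of
fixed order 50 (~50 ms of history at ~1 kHz) is estimated by multi-trial
least squares after per-trial demeaning, and Geweke's frequency-domain
measure is computed from the transfer function and innovation covariance
with the standard partialing of the instantaneous covariance; the
implementation evaluates `log1p` of the causal-to-intrinsic power ratio, so
the index is non-negative by construction. Band values are the *mean* of
the GC index over band bins — "integration" without a stated convention is
read as the grid-density-invariant mean — and the net index is forward
minus backward, exactly antisymmetric under pair swap.

The reverse-Granger test (RGT) guards against spurious directionality from
instantaneously mixed common noise: time-reversing every trial flips a
genuine lagged interaction's dominant direction but leaves lag-zero
covariance (hence mixing artifacts) untouched. The named test has no
published decision rule, so the rule here is: pass when the sign of the
band net GC flips under reversal *and* both magnitudes exceed a floor.
The floor is a significance requirement — about two trial-bootstrap
standard errors of the net index. The bootstrap resamples whole trials
with the channel pairing intact, so it reflects the sampling variability
that instantaneous mixing itself induces in the net index; a
pairing-destroying shuffle null would understate exactly that variability
and under-floor the scenario the test exists to reject. Both the flip
status and the magnitudes are reported, so stricter across-session
criteria can be applied downstream.

Model order 50 with 20 trials × 256 bins leaves ~40 observations per
parameter — enough for least squares, and the package warns below a
10-observations-per-parameter margin. Conditional (multivariate) GC is out
of scope.

## Cluster-mass permutation statistics

Depth × time (or depth × frequency) condition differences across sessions
use a cluster-mass permutation test: a pixelwise paired statistic
(signed-rank z by default; paired t available) thresholded at two-sided
p < 0.05, 4-connected clustering, cluster mass = Σ|statistic|, and a null
from random per-session sign flips with the maximum cluster mass recorded.
With ≤ 12 sessions all 2ⁿ sign patterns are enumerated and the test is
exact. The cluster-forming statistic and threshold are not stated in the
methods this follows; both are configurable and the defaults are recorded
here so results are reproducible. FDR correction is Benjamini–Hochberg
(the default reading of "FDR-corrected"), and paired comparisons use the
Wilcoxon signed-rank test, enumerated exactly for n ≤ 12 even under ties.

## The synthetic generator

Because the deposited recordings are tens of gigabytes of proprietary-format
data, validation rests on a generator that emulates the study conditions
with full ground truth: 16 channels at 150 µm; 8 kHz raw rate by default
(32 kHz available; the multi-unit band scales as 600 Hz–0.45·fs so the same
filter chain is exercised at desk-scale cost); 20 trials per diameter of
500 ms blank + 500 ms stimulus; an early sink at channel 8 peaking at 45 ms
planted through the exact forward model; per-layer MUAe rate profiles
generated from R(t) itself (granular 45 ms < infragranular 52 ms <
supragranular 60 ms at the smallest size, latency growing 3–5 ms and
amplitudes suppressed 12–35% toward the largest size, strongest
superficially); band-limited oscillations with directed γ-band coupling
layer 5 → layer 6 → supragranular (channels 11 → 13 → 5, 5 ms lags,
strength 0.8); a narrowband γ oscillator at the sink channel whose peak
frequency falls 45 → 38 Hz and whose amplitude grows with stimulus size;
and an optional instantaneously mixed common-noise source with
channel-specific weights (weights vary across channels so that bipolar
referencing does not cancel the shared source exactly, keeping the
reversal-test scenario non-degenerate).

Choices worth explaining:

* **Lagged-oscillator latents.** Each latent is an AR(2) resonator at its
  band center plus lagged, scaled copies of its parents, then band-limited
  by a zero-phase pass of its own band. The final filter is linear and
  time-invariant, so the planted lag survives exactly (the cross-correlation
  of two coupled latents peaks at the planted lag to within one sample),
  while the resonator's spectral skirts — which would otherwise make a
  "γ-band" coupling Granger-visible at theta — are removed. The network is
  required to be acyclic per band, which guarantees stability from the
  resonator poles alone.
* **MUAe calibration.** The carrier's amplitude envelope must be scaled so
  that the *processed, z-scored* MUAe tracks the planted R(t) in z units.
  Rather than an analytic rectified-Gaussian calculation that would have to
  model the whole filter chain, the generator measures the baseline mean
  and single-sample SD of a 20 s unmodulated carrier run through the same
  MUAe chain and sets the modulation gain to their ratio. Ground-truth
  latency is defined on the noiseless R(t) via a 0.1 ms grid, so it is
  independent of this calibration and of any estimator.
* **Background noise** is independent per channel and band-limited below
  300 Hz, so the multi-unit band contains only the carrier and the MUAe
  calibration stays exact.
* **What the generator does not emulate:** 1/f spectral shape, eye
  movements and microsaccadic modulation, spike waveforms and refractory
  structure, nonstationary oscillation bursts, electrode drift, line noise.
  Passing tests therefore demonstrate that the estimators recover planted
  structure under realistic amplitudes and trial counts — not that real
  V1 data contain such structure.

Problem sizes used by the validation suite (chosen as desk-scale defaults):
latency recovery over 50 noise seeds; iSP calibration over ≥1000
decorrelated null bins; GC oracle comparison at 400 trials × 256 bins;
reversal-test discrimination over 100 simulations per scenario at 20 trials
each; cluster-test calibration over 500 null replicates of 12 sessions;
pipeline-level γ-routing recovery over 20 generated sessions.

## Known limitations

* The latency model's cumulative-Gaussian term and second Gaussian are
  nearly collinear for weak plateaus; individual parameter estimates are
  then poorly identified even when the latency (a functional of the fit)
  is stable. The `converged` flag is honest, not a guarantee of parameter
  identifiability.
* Order-50 VAR on short segments is variance-heavy; band means smooth much
  of this, but single-pair GC spectra at 20 trials are noisy. The
  trial-shuffled RGT floor absorbs most of the resulting false directions.
* The amplitude iSP (`z_amp`) is not variance-stabilized; comparing values
  across frequencies with very different baseline power levels compares
  ratios to different references.
* The cluster-mass test assumes exchangeability of the paired difference
  maps across sign flips; session-specific scale differences violate this
  only mildly (the statistic is rank-based by default).
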