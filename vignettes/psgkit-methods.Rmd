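---
title: "Methods: stage-time-aware sleep EEG analysis with psgkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-time-aware sleep EEG analysis with psgkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind psgkit, in the spirit of a methods section: what each stage of
the pipeline assumes, which parameters matter and why their defaults
are what they are, what the synthetic data generator does and does not
emulate, and where the design was genuinely open.

## The two time axes

Sleep EEG carries two time axes. Chronological time is the recording's
sample clock. Stage time is induced by the hypnogram: the sequence of
sleep stages (W, N1, N2, N3, REM, plus movement and unscored epochs)
assigned to consecutive 30-s scoring epochs. psgkit's core abstraction
is a restriction engine over both axes at once. A `stage_selection`
holds a stage set, an optional chronological window, and an optional
*stage-time limit* ("the first N minutes of selected-stage time").
`select_stage_time()` applies them in a fixed order:

1. the chronological window is intersected first — an epoch survives
   only if it lies wholly inside the window;
2. the stage filter keeps epochs whose stage is in the selected set;
3. artifact-flagged epochs are dropped;
4. the stage-time limit then keeps surviving epochs in chronological
   order until the limit is reached.

Epochs are atomic: restrictions never split one, because a stage
notation is a per-epoch fact. The stage-time limit must therefore be a
multiple of the epoch length (0.5 min at 30-s epochs). Under this
reading, "the first 30 min of N2 or N3" counts only selected-stage
time and keeps exactly 60 epochs when the night has that many. Whether
the combined restriction should instead count clock time was an open
design point; we chose stage-time counting because it is the reading
under which the phrase "30 minutes *of* N2 or N3 sleep" is literally
true, and we document rather than assert that choice.

Adjacent surviving epochs are merged into segments, the segments are
concatenated, and the seam positions (`boundary_samples`) are carried
with the result. Seams are non-physical discontinuities, so windowed
analyses downstream must not straddle them; band filtering happens
*before* restriction (step 9 before step 10 in the pipeline), so no
filter transient is ever created at a seam.

## File dialects

The stage-notation parsers accept four text dialects: `generic_csv`
(`epoch,stage` at minimum), `hume_csv` (numeric stage codes, with the
legacy R&K codes 3 and 4 both mapping to N3), `remlogic_txt`
(tab-separated event rows with `SLEEP-S0`…`SLEEP-REM` labels and clock
times, converted to seconds from the file's own start-time header,
wrapping past midnight), and `twin_txt` (1-based epoch/label rows).
The exact vendor export formats are not published, so these are
documented stand-in grammars chosen to exercise the real contract —
many dialects, one canonical model — and each parser is verified by a
write/parse round-trip law. Recordings come in via EDF (16-bit) or
BrainVision (`INT_16` / `IEEE_FLOAT_32`, multiplexed or vectorized);
both readers normalize to microvolts, the single amplitude unit used
throughout (spindle thresholds and artifact thresholds are amplitude
thresholds, so one unit matters).

Intermediate results persist in a small self-describing container:
magic bytes, a format version, payload length, serialized payload and
a checksum. Loading verifies all four, so truncation and corruption
fail loudly and round trips are bit-exact.

## Preprocessing chain

The common preprocessing chain runs once per participant, in a fixed,
provenance-audited order: import → downsample → stage-marker embedding
→ montage → custom hook → re-reference → ICA slot → bad-channel
interpolation; then, per frequency band: band filter → stage-time
restriction → module analysis. The ICA slot is deliberately a named
no-op that can invoke external tooling: decomposition algorithms are
out of scope here, but the slot keeps the chain order auditable.

Numerical choices:

* **Downsampling** applies a Chebyshev II anti-alias low-pass (order
  8, 60 dB stopband starting at the new Nyquist, passband to roughly
  0.45 × the target rate) forward–backward, then decimates (integer
  ratios) or polyphase-resamples (rational ratios). Duration is
  preserved within one sample.
* **Band filters.** Default band table: delta 0.5–4 Hz, theta 4–8 Hz,
  sigma 12–16 Hz, all user-overridable. Delta and sigma use an order-4
  Butterworth band-pass applied forward–backward (zero phase,
  effective order doubled). Theta uses a Chebyshev II design with
  stopband edges 1 Hz outside the passband and 40 dB attenuation:
  during deep sleep, delta activity is an order of magnitude larger
  than theta, and the steeper stopband keeps it out of the theta
  estimate. The Chebyshev parameters are configurable defaults, not
  a reproduction of any particular lab's filter. Designs are checked
  for pole radii before use; an unstable design (very narrow band at a
  high sampling rate) is rejected with a suggestion to downsample
  first — which the pipeline order encourages anyway.
* **Re-referencing** supports average, linked (e.g. mastoids), single
  channel, or none. Average referencing forces each sample's channel
  sum to zero, an algebraic identity the tests assert.
* **Bad-channel interpolation** uses spherical splines (order-4
  Legendre kernel summed to degree 50, ridge regularization 1e-5 on
  the kernel diagonal) over the located good channels, requiring at
  least four. The montage is a proportional spherical 10-20 model:
  each 10% arc step is 18° of inclination, so C3 sits 36° from Cz and
  the outer ring at 72°; F3/F4/P3/P4 are spherical midpoints of their
  neighboring electrodes. On this model a constant field interpolates
  exactly and a smooth dipolar field reconstructs a held-out central
  electrode to within a few percent RMS.
* **Artifact rejection** is per-band, per-channel, per-epoch maximum
  absolute amplitude against a threshold in µV. The method is
  deliberately the simplest one consistent with per-band thresholds;
  anything smarter (spectral novelty, adaptive thresholds) belongs in
  a custom hook.

## Spectra

`amplitude_spectrum()` is a Welch estimator over the restricted
segment set: Hamming-tapered windows (default 5 s — long enough to
resolve the 0.5 Hz delta edge, short enough that a 30-s epoch holds
several windows) with 50% overlap, placed only inside individual
segments so no window crosses a seam. Amplitude convention: per-window
squared magnitudes are corrected for the taper's coherent gain,
averaged, square-rooted and doubled for the one-sided spectrum, so a
sinusoid of amplitude A whose frequency falls on a bin reads A at that
bin. Whether a sleep lab plots amplitude or power is a convention
choice; we report amplitude (µV) because the spindle and artifact
thresholds are amplitude-scaled, and power is one `^2` away.
`group_average_spectra()` refuses mismatched frequency axes or channel
orders rather than silently reordering.

## Envelopes and time-frequency

The filter-Hilbert envelope is the magnitude of the FFT-based analytic
signal of an already band-filtered recording; the first and last 2 s
are flagged unreliable (transform edge effects). Whether downstream
comparisons use amplitude or squared amplitude is left to the caller;
summaries report amplitude. `envelope_summary()` aggregates over a
stage selection per channel and per named channel group (the
frontocentral set F3/F4/C3/C4 being the conventional example), and
returns a decimated full-bout trace (≤ 10 000 points per channel) with
per-epoch ribbon colors for plotting; statistics always use full
resolution. The ribbon color code is fixed: cyan = N1, grey = N2,
blue = N3, green = REM, white = wake or movement; unscored epochs
default to white with a hatch flag so they stay distinguishable.

`morlet_tfr()` convolves with complex Morlet wavelets normalized to
unit energy, defaults log-spaced 0.5–30 Hz with
`n_cycles = max(3, f/2)` — the standard trade-off between temporal
resolution at low frequencies and spectral resolution at high ones.

## Spindle detection

The detector is the classic dual amplitude-threshold scheme, stated
here operationally because every constant is a tunable parameter
(`spindle_params()`): per channel, (1) band-pass to sigma (12–16 Hz);
(2) rectify; (3) form the upper envelope by linear interpolation
through the rectified signal's local maxima; (4) baseline = mean
rectified amplitude over the selected stages' artifact-free epochs
(N2/N3 by default); (5) candidates = maximal intervals with envelope
> lower × baseline (lower = 2); (6) accept if the envelope peak >
upper × baseline (upper = 6) and the duration lies in 0.5–3 s;
(7) events not overlapping the selected stages are discarded. The
duration gate is our addition (disable it by setting the bounds to 0
and Inf): it prevents degenerate one-sample events on noisy baselines.
Because both thresholds are baseline-relative, the event list is
invariant to global amplitude rescaling — asserted as a test. Baselines
are computed per channel from artifact-free selected-stage epochs
only, since artifacts inflate the mean and would suppress detection.

## Cluster-based permutation tests

`cluster_permutation()` compares two independent groups over channels
(or channels × frequency bins). Per feature, Welch's *t*; features
with |t| above the two-sided α = 0.05 critical value (Welch degrees of
freedom) are clustered by adjacency, positive and negative effects
separately so opposite-signed neighbors never merge; cluster mass is
the summed *t*; the null is the maximum |mass| over random group
relabelings; p = (1 + #{null ≥ |mass|}) / (n_perm + 1), which bounds p
away from zero at the permutation resolution. Channel adjacency is
angular distance on the unit sphere ≤ 40° by default, which connects
each standard 10-20 electrode to its immediate ring and midline
neighbors. All knobs (cluster-forming α, tail handling, permutation
count, adjacency angle) are exposed, since the canonical references
leave them to the analyst. Monte-Carlo checks in the test suite show
family-wise error at the nominal 5% under the null (500 simulations ×
200 permutations, n = 10 + 10 over 19 channels) and reliable recovery
of a 2-SD effect injected over a four-channel neighborhood. One
calibration note: with these design choices, the probability that
*every* injected channel individually clears the cluster-forming
threshold is about 0.95 — a supra-threshold cluster covering the
neighborhood is found essentially always, but demanding all four
memberships simultaneously sits at that boundary by construction.

## The synthetic generator

`generate_recording()` builds each channel as white Gaussian noise
(default SD 5 µV) plus per-stage sinusoids at each band's center
frequency (amplitude switching at epoch boundaries, phase continuous
across the night, one uniform random phase per channel × band) plus
injected spindle bursts. Default stage plan: a compact one-hour night
(W 4, N1 6, N2 40, N3 30, N2 20, REM 16, W 4 epochs) whose 90 NREM
epochs make restrictions up to 45 min of N2/N3 satisfiable; default
band amplitudes encode the canonical pattern — delta highest in N3
(40 µV), sigma highest in N2 (12 µV), modest elsewhere. The sampling
rate (128 Hz) comfortably exceeds twice the highest band edge.

Spindle bursts are Hann-tapered sinusoids at the sigma center
frequency, injected *in phase* with the channel's ongoing sigma
background so amplitudes add coherently and the realized rectified
peak equals `peak_multiplier ×` the channel's baseline — where the
baseline is the mean rectified sigma-filtered amplitude of the
*pre-injection* signal over N2/N3 epochs. Computing the baseline on
the pre-injection signal keeps the ground truth independent of the
detector; we compute it numerically for the realized noise draw rather
than from a closed form, because the mean rectified amplitude of a
tone-plus-noise mixture across mixed stages has no tractable exact
expression and an approximation would re-introduce model dependence.
With the default amplitudes the baseline is ≈ 7.2 µV, the steady N2
sigma envelope (≈ 12 µV) stays below the 2× lower threshold
(≈ 14.4 µV), a 3× distractor (≈ 21.7 µV) exceeds the lower but not the
6× upper threshold (≈ 43 µV), and a 7× spindle (≈ 50 µV) exceeds both:
the three regimes the detector must separate are all represented.

What the generator does *not* emulate: 1/f background spectra (the
noise is white, which keeps spectral flatness checks exact),
K-complexes, arousals, stage-transition dynamics, EOG/EMG channels, or
inter-channel correlation structure beyond shared stage amplitudes. Passing tests on this data therefore
demonstrate algorithmic correctness — thresholds, restrictions,
round-trips, error control — not clinical validity on real recordings.

## Problem sizes and determinism

The test suite and the acceptance script use a one-hour, six-channel
synthetic night at 128 Hz (≈ 0.5 M samples per channel), 100–200
random hypnograms for round-trip and mask-oracle properties, and 500
null simulations × 200 permutations for the error-control study —
sizes chosen so the whole suite runs in about a minute and a half on
one CPU while every statistical check retains enough replicates to be
meaningful. Every stochastic component takes an explicit seed:
identical `synth_spec`s produce bit-identical recordings, seeded
permutation tests reproduce exactly, and the pipeline writes its
resolved configuration next to its outputs so a run can be repeated
byte-for-byte.

## Known limitations

* EDF+ discontinuous records, vendor binary annotation streams, and
  BrainVision writing are out of scope.
* The stage dialects are documented stand-ins, not byte-level vendor
  replicas; real exports may need a preprocessing pass or a new parser
  (adding one means adding a label table and a reader function).
* The spindle detector is amplitude-based; oscillation-counting or
  phase-based refinements are not implemented.
* Paired (within-subject) cluster permutation is limited to treating
  the design as two independent groups; a sign-flip variant is a
  documented but untested extension point.
* ICA is a hook, not an implementation.
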