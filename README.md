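# psgkit

Stage-time-aware analysis of sleep EEG recordings in R.

## The problem

Overnight polysomnography (PSG) is scored into discrete sleep stages —
wake (W), NREM stages N1–N3, and REM — at fixed 30-s epochs. Those
stage notations form a second time axis ("stage time") that most sleep
analyses care about more than clock time: spectral power is computed
over N3 only, spindles are counted in N2, and restrictions like *"the
first 30 minutes of N2 or N3 sleep"* mix both axes. General-purpose
EEG toolchains make this painful: every stage-restricted analysis
requires manual epoching, masking and re-concatenation, and every
sleep-scoring program exports its stage notations in a different file
dialect.

psgkit addresses this for R users. It imports recordings (EDF,
BrainVision `.vhdr/.vmrk/.eeg`) and stage notations in four text
dialects (Hume-style numeric codes, RemLogic-style event lists,
TWin-style epoch tables, and a generic CSV), normalizes everything
into one canonical model, embeds the stages as per-epoch signal
markers, and exposes a restriction engine that selects data jointly by
stage set, chronological window, and a stage-time limit. On top of
that engine it provides:

* **Welch amplitude spectra** per channel, seam-aware (analysis windows
  never span the joins between non-adjacent pieces of the night), with
  group averaging;
* **filter-Hilbert amplitude envelopes** (band-pass + analytic-signal
  magnitude) with per-stage and per-channel-group summaries;
* **Morlet wavelet time-frequency decomposition**;
* **sleep spindle detection** by the classic dual amplitude-threshold
  scheme: the sigma-band (12–16 Hz) signal is rectified, its
  local-maxima envelope is compared against a *lower* threshold (2 ×
  the mean rectified sigma amplitude over the selected stages, marking
  event onset/offset) and an *upper* threshold (6 × baseline, which
  the event's peak must exceed), with a 0.5–3 s duration gate;
* **cluster-based permutation tests** comparing two groups over scalp
  topography (and optionally frequency), with Welch *t*
  cluster-forming, summed-*t* cluster mass, and a max-statistic
  relabeling null;
* a **synthetic PSG generator** producing ground-truthed nights
  (stage-dependent band amplitudes, injected spindle bursts with known
  onsets and peak multiples, matching hypnogram files in every
  dialect) so the whole pipeline is testable without clinical data;
* a **batch pipeline** (`run_pipeline()` + a thin CLI at
  `inst/cli/psgkit.R`) that runs the documented common-preprocessing
  chain — import → downsample → stage markers → montage → custom hook
  → re-reference → ICA slot → bad-channel interpolation — once per
  participant and then filter → restrict → analysis per frequency
  band, recording every step in an auditable provenance trail.

## Worked example

Simulate a ground-truthed night, restrict to the first 30 minutes of
N2/N3, and detect spindles:

```r
library(psgkit)

spec0  <- synth_spec(seed = 42)                 # 120 epochs, 6 channels
events <- place_spindle_events(spec0$hypnogram, n = 12,
                               channels = c("C3", "C4"),
                               peak_multiplier = 7)
spec   <- synth_spec(spindle_events = events, seed = 42)
gen    <- generate_recording(spec)
gen$recording
#> <psg_recording> 6 channels x 460800 samples @ 128 Hz (3600.0 s)
#>   channels: F3 F4 C3 C4 O1 O2

marked <- embed_stage_markers(gen$recording, gen$truth$hypnogram)
sel    <- stage_selection(c("N2", "N3"), stage_time_limit_min = 30)
select_stage_time(marked, sel)
#> <segment_set> 1 segments, 230400 samples (1800.0 s) @ 128 Hz

det <- detect_spindles(gen$recording, marked)   # lower 2x, upper 6x
head(det[, c("channel", "onset_s", "offset_s",
             "peak_amplitude_uv", "stage")], 4)
#>   channel  onset_s offset_s peak_amplitude_uv stage
#> 1      C3 344.5781 345.4141          50.02552    N2
#> 2      C4 404.5781 405.4141          50.91687    N2
#> 3      C3 464.5781 465.4062          49.84702    N2
#> 4      C4 524.5938 525.4219          49.16280    N2

dens <- spindle_density(det, gen$truth$hypnogram)
dens[dens$channel %in% c("C3", "C4"), ]
#>   channel n_events stage_minutes density_per_min mean_duration_s mean_peak_uv
#> 3      C3        6            45       0.1333333       0.8515625     50.06994
#> 4      C4        6            45       0.1333333       0.8671875     50.09040
```

The restriction keeps exactly 60 epochs (1800 s) of N2/N3; the twelve
injected bursts (six per central channel) are all recovered, each with
a ~0.86 s supra-threshold duration and a peak near 50 µV — 7 × the
~7.2 µV mean rectified sigma baseline the generator reports in
`gen$truth$baseline_uv`. Stage minutes (45 = 90 NREM epochs × 0.5 min)
are the density denominator.

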