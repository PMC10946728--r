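---
title: "astmeg: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{astmeg: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`astmeg` simulates and analyses a three-stream auditory short-term memory
(ASTM) MEG experiment at the sensor level. This vignette documents the
underlying models, every tunable parameter that matters, the numerical
choices, and what the synthetic data do and do not establish about real
recordings.

## The experimental design

Each trial presents a 2500-ms *encoding* scene of three simultaneous
tone-pip streams at 3, 7 and 19 Hz (tone durations 166.5, 71.45 and
26.15 ms; onset asynchronies 333, 142.9 and 52.3 ms — the printed design
values, used verbatim, which are deliberately not exactly `1000/rate`),
followed by a 2000-ms silent *maintenance* stage and a 2000-ms probe.
Carriers are drawn per trial, without replacement, from a fixed pool of 11
values between 200 and 2799 Hz and paired randomly with the three rates. On
"same" trials the probe duplicates a scene stream; on "different" trials it
pairs a scene carrier with a scene rate the carrier did not have. Schedules
are balanced: `n_per_cell` trials (56 in the full design, 336 total) for
each probe-rate x class cell, shuffled, with inter-trial intervals uniform
on 700-2000 ms in 100-ms steps. Tones carry 5-ms raised-cosine ramps counted
inside the tone duration; a tone that cannot complete before the scene or
probe ends is omitted entirely (no partial tones).

Note two deliberate literalisms: the carrier pool is "logarithmically
spaced" only approximately (successive ratios vary), and the 19-Hz SOA of
52.3 ms differs from 1000/19 = 52.63 ms. Both are treated as ground truth
for the design and reproduced exactly.

## The synthetic-data generator

An epoch (channels x time, -1000 to 6000 ms) is a sum of planted components
and structured noise. The sensor array is a Fibonacci lattice on the upper
unit hemisphere; adjacency connects channels within a distance threshold
calibrated so the median degree is 6-8, with every channel guaranteed at
least two neighbours.

**Sustained evoked field** (`erf_sustained`): a spatial topography times a
smoothed boxcar (250-ms raised-cosine edges). The default window runs from
scene onset through the end of the epoch: probe stimulation and the motor
response keep evoked activity elevated after maintenance, and ending the
boxcar at 4500 ms would make its offset ramp repeat identically across
trials, creating spurious lines at exact 0.5-Hz multiples (which include 3,
7 and 19 Hz) in the maintenance-stage concatenated spectrum — contradicting
the target structure of no maintenance peaks. The condition contrast
(default amplitudes 2.2 correct / 1.5 incorrect, arbitrary units) spans
encoding and maintenance either way. The topography is dipolar (two
opposite-polarity Gaussian-in-angle lobes), as an axial gradiometer array
over a tangential source would measure.

**Steady-state response** (`steady_state`): the default model convolves the
tone-onset impulse train of each stream with a per-tone evoked kernel (a
~120-ms monophasic lobe plus a weaker ~70-ms biphasic deflection), gated
smoothly to zero at scene offset. This produces energy at each stream's
rate *and its harmonics*, as frequency-tagged auditory responses do. An
alternative `envelope_bandpass` model (the stimulus envelope band-passed
around the rate) is available but cannot produce even harmonics: the pip
trains have an exact 50% duty cycle, so the envelope's even Fourier
coefficients vanish — the onset-kernel model is the default for that
reason. Default amplitudes are 2.4 / 1.6 / 1.1 for 3 / 7 / 19 Hz — dominant
at 3 Hz in the time domain. (Neighbour-normalized *SNR* readouts can still
favour 19 Hz, where the 1/f floor is low; this is a property of the
normalization, not of the planted amplitudes.) Steady-state amplitudes are
identical across conditions by default: the target structure has no
correct/incorrect difference in stimulus tracking.

**Band-limited oscillations** (`band_power`): Gaussian noise band-limited
by FFT masking, multiplied by an envelope that rises from a baseline of 1
to the condition amplitude (default 2.1 correct / 1.2 incorrect) inside the
effect window. The shipped windows mirror the qualitative findings the
pipeline must recover: theta 1560-2410 ms (encoding), alpha 1500-2500 and
2500-3650 ms, beta 646-1281, 2632-3340 and 3766-4510 ms. The planted
passbands sit inside the physiological core of each band (theta 4.5-6.5,
alpha 8.5-12.5, beta 14.5-19.5 Hz) rather than filling the analysis bands
edge-to-edge: a 400-ms Hanning taper smears power by roughly ±2 Hz, and
brick-wall plants touching a band edge leak visibly into the neighbouring
analysis band.

**Noise**: 20 latent 1/f sources (exponent 1.0) mixed through random smooth
topographies (spatial correlation for DSS to exploit); a 50-Hz line
component with fixed topography and random phase per trial; three
integrated-random-walk drift sources; and a white sensor floor. Scales
(1.0, 0.3, 0.5, 0.2 SD units respectively) were chosen once so that planted
effects are present but not trivially visible at single-trial level.

**Trial-to-trial variability**: phase-locked components are scaled per
trial by `exp(N(0, trial_sd))` (default 0.2; half that SD for the ERF).
This matters for the concatenated-spectrum analysis: identical repeated
segments put all phase-locked energy on the trial-period comb (multiples of
1/2.5 s = 0.4 Hz), whereas amplitude variability moves part of it into a
continuous peak at the stimulation frequency itself, as real evoked
responses show. Per-participant random effects scale each effect's
amplitude by `exp(N(0, participant_sd))` (default 0.15).

**Behaviour**: responses are drawn from per-rate P(respond "same")
parameters — defaults 0.72/0.66/0.62 (same trials) and 0.32/0.22/0.20
(different trials) plus a 3-Hz bias increment of 0.13 applied in both
classes, which yields ~71% accuracy and the characteristic excess of "same"
responses to 3-Hz probes. RTs are log-normal with outcome-ordered locations
TP < TN < FN < FP (870/1000/1090/1140 ms medians, sdlog 0.25) and a small
3-Hz modulation (faster "same" responses, slower true negatives). These are
free generator parameters, not measured quantities. `simulate_study`
redraws a participant whose drawn behaviour has fewer correct than
incorrect trials, mirroring the exclusion of participants unable to perform
the task; the equating step requires a correct majority.

## The analysis pipeline

Preprocessing runs in a fixed order: power-based trial rejection (mean
± 2 SD of per-trial mean squared amplitude; ties and zero-variance sets
reject nothing; rejecting all trials is an error) → DSS cleaning → 500-ms
prestimulus baseline → RT outlier filter → accuracy split → equating.

**DSS.** Both covariances are computed over the encoding-stage bias window
after per-trial channel demeaning. `C0` is whitened by eigendecomposition
with eigenvalues below `1e-9` of the largest truncated (rank-deficient data
beyond that truncation is a hard error with a diagnostic); the whitened
`C1` is then eigendecomposed, giving scores in [0, 1] that are invariant to
global rescaling of the data. Artifact cleaning keeps the top 80% of the
rank (config `cleanup_keep_frac`) — non-reproducible drift and line
components concentrate in the low-score tail — while the PSD stage projects
onto exactly the first two components (`dss_keep_psd`), determined from the
encoding stage and applied to the whole trial. Patterns are the
pseudo-inverse of the filters on the retained subspace, so keep-all
round-trips are exact to numerical precision.

**Equating** sorts correct trials by RT ascending (ties broken by trial
index, for determinism) and keeps the fastest `n_incorrect`, so both
averages carry identical trial counts.

**RMS bootstrap.** The participant-level RMS difference time courses are
resampled over participants with replacement (10,000 iterations at full
scale); a time point is significant when >= 95% of iteration means share a
sign. Resample means exactly zero count toward neither direction. An
exhaustive enumeration oracle (`enumerate_sign_consistency`, all `n^n`
ordered resamples for n <= 6) validates the Monte-Carlo fractions. No
temporal-contiguity requirement is imposed on the significance mask.

**Cluster permutation.** The cluster-forming threshold is the two-sided
paired-t critical value at `alpha_cf = 0.05` (df = n-1) — the common
default of the toolboxes this procedure comes from; the minimum of 3
distinct channels per cluster is enforced identically on observed and
permuted maps; p-values use the `(1 + exceedances) / (1 + n_perm)`
estimator, so no cluster reports p = 0. Zero-variance nodes get t = 0 with
a warning (conservative). Channel x time clustering links spatial
neighbours at the same window centre and consecutive centres of the same
channel.

**TFR.** 400-ms single-Hanning segments every 50 ms (the slide step is not
part of the printed design; 50 ms resolves the shortest planted window
comfortably), zero-padded to `fs / 0.5` samples so the grid lands exactly
on 0.5-Hz steps from 1-30 Hz. A single 400-ms Hanning taper has a natural
smoothing bandwidth of roughly 2.5 Hz, so a nominal "1-Hz smoothing" figure
cannot be realized with this window; the implementation documents the
single-taper reading. Each segment is demeaned before tapering — otherwise
sustained fields leak through the taper's DC lobe into the delta band and
masquerade as oscillatory condition effects. Baseline normalization is
relative change `(P - B)/B` on trial-averaged power (dB available by
config), with the baseline window given by *window centres* in
[-400, -200] ms, i.e. data from -600 to 0 ms. Band edges are inclusive on
the 0.5-Hz grid; alpha is 8-13 Hz (the sensor-level definition; a source
variant uses 8-14 Hz and is not adopted) and beta 14-20 Hz.

**PSD.** Stage segments of all trials are concatenated in trial order
(20 encoding epochs at 600 Hz give 30,000 samples and hence 0.02-Hz
resolution); one Hanning taper spans the whole series; power bins from 1-21
Hz are each divided by the mean of their 3rd-20th neighbours on both sides
(edge bins use the available side only). Two readout subtleties deserve
note. First, concatenating identical-length segments concentrates
phase-locked energy on the trial-period comb — multiples of 0.4 Hz for the
2.5-s encoding stage — which contains no bin at exactly 3.0, 7.0 or 19.0
Hz; peaks are therefore read within ±0.25 Hz of the nominal rate (argmax
bin for peak values, window mean for presence checks) rather than at the
single nearest bin. Second, the per-channel neighbour ratio has a positive
Jensen bias on flat spectra (~+6% with a Hann taper, whose periodogram bins
are locally correlated, reducing the 36-bin neighbour mean's effective dof
to ~18); the bias is condition- and stage-common and cancels from all
contrasts, and the channel-averaged normalized spectrum is unbiased to well
within 5%. Peak-presence statistics ("is there a 3-Hz peak during
maintenance?") are computed from unprojected sensor spectra: after a rank-2
DSS projection every channel shares two time courses, and single normalized
bins become too variable for a stable absence check — the projected route
is kept for peak values and the condition x rate ANOVA, matching the
analysis the peaks feed.

**Behavioural statistics.** The RT outlier filter is a single pass (not
iterated) within participant x outcome cells by default; the alternative
participant x (rate x class) cell definition is a config switch, since
"condition" is ambiguous between the two. The within-subject ANOVA tests
each effect against its subject x effect interaction stratum with no
sphericity correction, matching the uncorrected dfs the design implies
((3,66), (2,44), (6,132) at 23 participants).

## Statistical validation and its limits

The test suite checks three layers: exact design reproduction; calibration
(cluster-test family-wise error in [0.02, 0.10] over 200 null datasets;
ANOVA type-I error at its nominal rate; bootstrap fractions against the
enumeration oracle); and end-to-end parameter recovery at a reduced scale —
8 participants, 64 channels, 150 Hz, 60 trials (36 for the 20 null-run
replicates), 200 permutations, 2000 bootstrap iterations — chosen so the
full suite runs in minutes while each planted contrast remains detectable.
Recovery means a significant cluster of the right sign in the planted band
and stage whose time span overlaps the planted window by at least 50%
(either direction of the overlap ratio); for the dipolar ERF, clusters of
either sign count when their members fall in the matching-polarity lobe of
the planted topography, since a dipolar field difference necessarily
produces one positive and one negative t-lobe.

What passing these tests shows: the pipeline's statistics are calibrated
under its own null, and effects of the planted kind, size and extent are
recovered where they were planted. What it does not show: performance on
real MEG. The generator's noise is stationary and Gaussian, head position
does not move, there are no eye-blink or cardiac artifacts, forward-model
geometry is idealized (Gaussian/dipolar lobes on a hemisphere), neural
nonstationarity is reduced to lognormal amplitude scaling, and behavioural
RTs are conditionally independent of the neural signal given the outcome.
Adjacent-band taper leakage is real but only controlled, not absent:
strongly planted alpha activity measurably elevates the lower beta bins.

## Parameter reference

| Parameter | Default (full scale) | Meaning |
|---|---|---|
| `fs_hz` | 600 | sampling rate, Hz |
| `n_channels` | 274 | sensors on the helmet lattice |
| `n_per_cell` | 56 | trials per probe-rate x class cell (336 total) |
| `n_participants` | 23 | simulated cohort size |
| `z_thresh` | 2 | trial-power rejection threshold, SD |
| `rt_k` | 2.5 | RT outlier threshold, SD |
| `cleanup_keep_frac` | 0.8 | DSS rank fraction kept at cleaning |
| `dss_keep_psd` | 2 | DSS components for the PSD stage |
| `baseline_ms` | [-500, 0) | ERF baseline window |
| `n_boot`, `boot_criterion` | 10000, 0.95 | bootstrap iterations, sign criterion |
| `n_perm`, `min_channels`, `alpha_cf` | 1000, 3, 0.05 | cluster test settings |
| `tfr_window_ms`, `tfr_step_ms` | 400, 50 | spectrogram taper and slide |
| `tfr_baseline_ms` | [-400, -200] | TFR baseline (window centres) |
| `bands` | delta 1-4, theta 4-7, alpha 8-13, beta 14-20 | analysis bands, Hz |
| `psd_f_range`, `psd_k` | [1, 21], 10 | PSD range, channels per peak |

All of these live in `default_config()`, round-trip through YAML, and the
`"reduced"` preset changes only the scale parameters, never the scientific
ones.
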