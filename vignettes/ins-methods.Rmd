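---
title: "Wavelet-coherence INS analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-coherence INS analysis: models, parameters, and design choices}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(insync)
```

## The problem this package addresses

In an fNIRS hyperscanning experiment two interacting people are recorded
simultaneously; the question is whether, where, and *when* their cortical
hemodynamics couple. `insync` implements the full analysis chain for
turn-taking dialogue paradigms in which two interlocutors (A and C)
communicate through an interpreter under different interpreting modes —
consecutive (CI), simultaneous (SI), and mother-tongue retelling (CC) —
each with a matched resting baseline (`rest_rain` for CI, because rain
sounds mask speech in that condition; plain `rest` for SI and CC).

The quantity of interest is interpersonal neural synchronization (INS):
the wavelet transform coherence (WTC) between one channel of A and one
channel of C, Fisher-z transformed, averaged over the task period, and
baselined by subtracting the matched rest. Because an interpreter
introduces a transmission delay, coupling may be *time-lagged*: the whole
analysis is repeated with C's series shifted by −26 … +26 s in 1 s steps.

## The coherence model

For a signal $x$ sampled at rate $f_s$ (10 Hz throughout), the Morlet
CWT at scale $s$ is computed by FFT convolution with the analytic Morlet
wavelet ($\omega_0 = 6$). Scales form a geometric grid, by default 106
scales from 0.3 s to 128 s; the Fourier period of a scale is
$s \cdot 4\pi/(\omega_0 + \sqrt{2+\omega_0^2}) \approx 1.033\,s$.

Squared coherence is

$$R^2(s,t) = \frac{|S(W_{xy}/s)|^2}{S(|W_x|^2/s)\,S(|W_y|^2/s)},$$

where $S$ smooths in time with a Gaussian of SD equal to the scale $s$
(in seconds) and across scales with a 0.6-octave boxcar — the smoothing
conventions of the standard wavelet-coherence toolbox. The widths are
not free styling: with a time-lagged coupling the cross-wavelet phase
winds across frequency as $2\pi\,\delta f$ per lag $\delta$, and a
scale window much wider than ~half an octave averages that winding
phase to zero, suppressing genuine in-band coherence and scattering
ripple artifacts near $1/\delta$ Hz. Without $S$ the estimator is
identically 1 (the test-suite asserts this to guard the smoothing step).
Coherence values are converted as $z = \operatorname{atanh}(\sqrt{R^2})$
— the correlation-analogy convention; `fisher_z(..., square_root =
FALSE)` gives the alternative reading ($\operatorname{atanh}(R^2)$), and
per-scale task averages are computed as means of $z$ values
(z-then-average; the order matters only mildly and averaging the
variance-stabilised quantity is the defensible default).

### Numerical choices that matter

* **Zero padding.** The CWT pads to the next power of two *past the
  support of the largest wavelet* (three times the maximum scale). With
  the textbook "next power of two" rule alone, a record whose length
  falls just under a power of two receives almost no padding, the
  convolution becomes circular at large scales, and the two ends of the
  record contaminate each other. That bias is invisible in a single
  analysis but produces spurious jumps in a lag scan, where the record
  length changes with every lag.
* **Demeaning.** Coherence inputs are demeaned before transforming, so
  an offset cannot leak through the zero padding; together with the
  ratio form of $R^2$ this makes coherence invariant to per-channel gain
  and offset (asserted to 1e-6 in the tests).
* **Edge renormalisation.** Both smoothing kernels are normalised
  against the smoothed all-ones field, so a constant field passes
  through the smoother unchanged and no separate edge correction is
  needed.
* **Cone of influence.** The COI (max trustworthy period per time point,
  from the $\sqrt2 s$ e-folding of the Morlet envelope) is computed and
  stored, but task averaging does not exclude it by default;
  `task_average(..., exclude_coi = TRUE)` enables exclusion. Rest and
  task maps have comparable COI footprints, so the subtraction removes
  most of its bias.
* **Scale-boxcar unit.** The boxcar width is configured in octaves
  (`scale_width_oct`, default 0.6) and converted to grid steps
  internally; the grid itself is spaced in decades.
* **Smoothing-operator cache.** Kernel FFTs and masks depend only on
  (grid, rate, record length); a lag scan re-uses them across dyads via
  an internal memo cache (reset beyond ~300 MB).

## Preprocessing

Each recording is trimmed by 30 s at both edges (instrument settling),
linearly detrended (OLS; the detrending choice is exposed because only
"detrending" is conventionally specified), and motion-corrected with
temporal derivative distribution repair (TDDR). No band-pass filter is
applied before coherence — frequency selection happens after, on the
wavelet scale axis.

TDDR here is a two-stage robust repair of the temporal derivative:

1. the detrended signal is split at 0.5 Hz (zero-phase Butterworth,
   order 3) and the *fluctuation* component's first differences are
   iteratively reweighted with Tukey's biweight ($c = 4.685$, MAD scale
   1.4826, tolerance 1e-8 on the weights, ≤ 50 iterations), then
   cumulated back;
2. a *gross-trim* pass hard-rejects derivative outliers beyond the same
   $c \cdot \mathrm{MAD}$ bound on the unsplit signal.

The second stage exists because a one-sample spike keeps roughly 10% of
its amplitude below any 0.5 Hz cutoff; a purely banded repair therefore
cannot suppress it by more than ~90%. The trim pass removes that
residue while being exactly inert for any sample within the Tukey bound:
constants, ramps, and clean slow sinusoids pass through unchanged (the
robust mean is kept in the reconstruction, so all-unit weights give the
identity exactly). A channel whose derivative has zero robust scale is
returned unchanged — with nothing to down-weight, the repair is the
identity, not an error. `tddr_params(component = "low", gross_trim =
FALSE)` reproduces the orientation that targets slow drift instead.

## The synthetic dyad generator

No public accession exists for the study data, so the generator is a
first-class module: every downstream stage is tested against cohorts
with known ground truth.

Each channel is a standardized mixture of $1/f$ background (spectral
synthesis, default exponent 1), sinusoidal cardiac (1 Hz, amplitude
0.25), respiratory (0.3 Hz, 0.2) and Mayer-wave (0.1 Hz, 0.3) components
with random phases, and white noise (SD 0.2) — the standard fNIRS
confound structure. Inter-brain coupling is injected as a *band-limited
Gaussian process* (white noise shaped by a Gaussian spectral window),
added to one channel of A and, delayed by an integer number of samples,
to the matched channel of C, with mixing weights $\sqrt{1-\rho}$ and
$\sqrt{\rho}$ so the shared component carries exactly the variance
fraction $\rho$. Rest recordings share the noise model but never the
couplings. Motion artifacts (single-sample spikes, persisting steps)
arrive as per-channel Poisson events.

### Why the coupling bandwidth is 0.010 Hz

The spectral width of the shared component controls its temporal
correlation: $\sigma_t \approx 1/(2\pi\,\mathrm{bw})$. A very narrow
window (0.005 Hz, $\sigma_t \approx 32$ s) makes the *lag* of a
40 s-period coupling ill-determined — the coherence profile over lags is
flat across ±10 s, and no estimator can localise the peak to ±2 s. A
much wider window fails the other way: at a 17 s lag the cross-wavelet
phase $2\pi\,\delta f$ winds across the coupling's own band and its
*unlagged* coherence cancels, so the band-selection stage (which runs
before the lag scan) loses the band. The default TPJ-like coupling uses
0.010 Hz ($\sigma_t \approx 16$ s): sharp enough that the injected
17 s lag is identifiable, concentrated enough that band selection finds
it near 0.02–0.032 Hz. The IFG-like time-aligned coupling uses 0.065 Hz
centre, 0.015 Hz width.

Between-dyad variability enters as Gaussian jitter (SD 0.1 by default)
on each coupling's nominal strength, shared across that coupling's
conditions; behavioural scores synthesised from the realized strengths
give the score–INS correlation stage a meaningful target.

What the generator does **not** emulate: real hemodynamic response
shapes convolved with behaviour, shared physiological drivers
(systemic blood-pressure coupling between co-present people),
scalp/superficial contamination, channel-specific optode coupling
quality, or non-stationary coupling within a session. Passing tests
demonstrate that the pipeline recovers the *statistical* structure it
assumes — band-limited, lagged, condition-dependent shared variance —
not that it is robust to every physiological confound of real data.

## Statistics

* **Band selection.** Per scale, a one-way repeated-measures F across
  conditions over dyads (dyads = repeated-measures unit; with two
  conditions $F = t^2$). The null shuffles condition labels *within*
  each dyad independently, 1000 times by default; the null statistic is
  the maximum F across scales (family-wise control over the frequency
  axis; a pointwise variant sits behind `family = "pointwise"`). The
  threshold is the 99th percentile of the null maxima — the upper tail,
  since F is one-tailed. Contiguous supra-threshold scales form
  clusters; clusters separated by fewer than `merge_gap = 2` scale
  steps merge into single bands. Degenerate 0/0 scales return F = 0
  with a warning.
* **Group test.** Paired t per (channel pair, lag) on band-averaged INS
  increases, two-sided, Bonferroni-corrected with
  $m = n_\text{pairs} \times n_\text{lags}$ (the full default scan:
  $676 \times 53 = 35\,828$). Zero-variance cells give $t = 0, p = 1$
  when the mean difference is also zero.
* **Validation.** The pseudo-dyad null: participant A of each dyad is
  re-paired with C of another, the group-mean condition difference at
  the target pair/lag is recomputed per pairing, and the observed
  statistic is located in that distribution (two-tailed area 5% by
  default, 1% available). For ≤ 8 dyads and enough permutations the
  null is enumerated exhaustively (the identity pairing included);
  beyond the number of distinct re-pairings, sampling is with
  replacement and says so. A channel-shuffle null is *not* the default:
  re-pairing non-interacting people is the standard hyperscanning null.
* **Phase analysis.** Turn-taking phases are averaged with windows
  shifted by the ~6 s hemodynamic delay-to-peak; a lagged sample pair
  enters a window only when *both* timelines fall inside it, which makes
  exchanging the roles of A and C exactly equivalent to negating the lag
  (asserted to 1e-9). Phase values pool across turns into one value per
  dyad per phase type before correlating with interpretation scores
  (Pearson, two-sided).

## Problem sizes used in the tests

The suite exercises the defaults (106 scales, 0.3–128 s) for the
algebraic identities, and scaled-down grids for simulation studies: a
48-scale 2–80 s grid for band-selection cohorts, a 16-scale 20–80 s grid
for lag scans, 10-dyad cohorts of 2-channel montages with session-length
records (960 s, two consecutive-interpreting blocks), 10 replicate
cohorts for the band-recovery rate, and 200–400 direct null-table
replicates for type-I calibration. These sizes were chosen so each simulated question
is answered with comfortable statistical margin by a single-core run.

## Known limitations

* Reweighting the fluctuation derivative injects a small random-walk
  perturbation into noisy channels (any derivative-reweighting repair
  does); it is far below the physiological noise floor but measurable
  on noiseless synthetic signals.
* The discrete argmax over lags inherits the temporal resolution of the
  coupling itself; for processes narrower than ~0.01 Hz the lag profile
  is too flat for metre-precision claims, and the package reports the
  profile rather than pretending otherwise.
* Band edges are reported as the frequencies of the outermost scales in
  a cluster; with coarse grids the printed edges quantise accordingly.
* `read_recording()` supports the native TSV + JSON sidecar format
  only; there is no HDF5/SNIRF reader in this build.
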