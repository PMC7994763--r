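---
title: "Methods: simulating and measuring rTMS phase entrainment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring rTMS phase entrainment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Different cortical areas oscillate at different intrinsic ("natural")
frequencies — roughly alpha (~10 Hz) over visual cortex and low beta
(~20 Hz) over motor cortex. Short trains of repetitive transcranial magnetic
stimulation (rTMS) delivered at or near a region's natural frequency are
hypothesized to *phase-entrain* the ongoing oscillation: each pulse pulls the
oscillation phase toward a pulse-locked target, so phase alignment across
trials builds up over the train and outlasts the last pulse by a few cycles.
`entrainlock` implements the full measurement chain for this question —
from raw multi-trial TMS-EEG epochs through artifact preprocessing, wavelet
phase extraction, inter-trial phase-locking statistics and a nonparametric
statistical battery — together with a synthetic data generator that realizes
the three regimes of interest (no effect, single-pulse phase reset,
progressive entrainment) with known ground truth, so every stage is testable
without access to recorded data.

## The generator: a pulsed phase oscillator

Each cortical source is a noisy phase oscillator. Between pulses

$$\varphi(t + \Delta) = \varphi(t) + 2\pi f_0 \Delta + \varepsilon,
  \qquad \varepsilon \sim \mathcal N(0, \sigma_\varphi^2 \Delta),$$

with natural frequency $f_0$ and phase-diffusion scale $\sigma_\varphi$
(rad/$\sqrt{\mathrm s}$; the intrinsic coherence time is roughly
$1/\sigma_\varphi^2$ s). At each pulse the directly stimulated source
receives a phase pull toward a fixed pulse-locked target phase $\psi_p = 0$:

$$\varphi \leftarrow \varphi + \kappa \,\mathrm{wrap}(\psi_p - \varphi),
  \qquad \kappa \in [0, 1],$$

where `wrap` maps to $(-\pi, \pi]$. $\kappa = 1$ is a full single-pulse
phase reset, $0 < \kappa < 1$ partial pull — repeated pulses then produce the
progressive, cumulative phase alignment that defines entrainment — and
$\kappa = 0$ (or a sham protocol) leaves the dynamics untouched. We use the
linear phase pull rather than a sinusoidal coupling term because the package
treats "full reset at $\kappa = 1$, in one pulse" as the defining boundary
case of the generator; a sine map only approaches the target asymptotically.
The qualitative entrainment behaviour (an Arnold tongue widening with
$\kappa$, explored by `arnold_map()`) is the same for both maps.

Pulse updates propagate to remote sources through explicit network entries
(gain, lag), but only between sources whose natural frequencies differ by at
most 3 Hz — this encodes frequency-specific long-range coupling and gives
the topographic analyses a known ground truth.

Sensor signals are a Gaussian-leadfield projection (FWHM 60° of arc) of
$a\cos\varphi$ per source, plus:

* **1/f background noise** per channel, spatially smoothed across the scalp
  (FWHM 40°). The smoothing matters: background EEG is itself
  volume-conducted, and a spatially *white* noise floor would be amplified
  by the surface-Laplacian stage (a spatial high-pass) out of all proportion
  to the smooth source topographies.
* an optional **pulse-evoked damped sinusoid** with fixed latency and
  polarity (decay 100 ms). This deliberately produces the "spurious phase
  locking" that evoked components cause, so analyses can be stress-tested
  against it. Whether evoked amplitude attenuates over a train is unknown;
  it is exposed as `evoked_attenuation` and constant by default.
* a large **decay artifact** ($\tau$ = 2 ms, 10× the largest source
  amplitude) in the first ~8 ms after each pulse, for real (non-sham)
  stimulation only. The trigger sample itself stays clean.

Defaults emulate the target experiment: 63 scalp channels on an idealized
spherical 10/10 layout plus earlobe references A1/A2, 5-pulse trains at
5/11/23 Hz (or a single pulse), 30 trials per block, epochs from 2 s before
the first to 3 s after the last pulse, visual source at Oz with
$f_0 = 10.5$ Hz, motor source at C3 with $f_0 = 21$ Hz, $\kappa = 0.4$,
$\sigma_\varphi = 1.5$ rad/$\sqrt{\mathrm s}$. The montage is an idealized
sphere parameterized by arc fractions, not digitized electrode positions;
channel adjacency uses a great-circle threshold of 0.40 rad, the smallest
value at which every scalp channel on this layout has at least two
neighbours (each then has 2–11).

## Preprocessing

The artifact pipeline runs in a fixed order, enforced by `preprocess()`:
re-reference to the linked earlobes, linear interpolation of the pulse
windows, ICA decay-artifact suppression, amplitude-based trial rejection,
spherical-spline current source density (CSD), downsampling.

* **Interpolation** replaces the `round(interp_ms/1000 · fs)` samples after
  each pulse onset (40 samples = 8 ms at 5 kHz; 60 = 12 ms fallback) with
  the line joining the onset sample to the first post-window sample.
* **ICA**: a seeded deflation FastICA (tanh contrast) is fit on the
  epoch-concatenated data after reduction to the principal components
  carrying 99.9% of variance. Components whose *trial-averaged* time course,
  standardized against the component's full-epoch single-trial mean and SD,
  exceeds |z| > 1.65 anywhere within 0–100 ms after any pulse are
  subtracted from the data. The standardization scale matters: averaging
  over $N$ trials shrinks non-phase-locked activity by $\sqrt N$, so
  ongoing oscillations and noise stay well below 1.65 while pulse-locked
  transients (the decaying artifact, large evoked components) stand out; a
  z-score taken against the averaged waveform's own SD would flag every
  component. Deflation-mode extraction is used deliberately: strongly
  non-Gaussian components converge in a few iterations, while directions in
  the near-Gaussian background have a vanishing fixed-point update and no
  preferred rotation — such directions are accepted as an orthonormal
  residual basis and flagged (`converged = FALSE`) in the report.
* **Trial rejection** drops trials exceeding 200 µV on any scalp channel
  within 1 s before the first / after the last pulse.
* **CSD** applies the Perrin spherical-spline surface Laplacian (spline
  order m = 4, λ = 1e−5, 50 Legendre terms, head radius 92 mm), computed
  once as a channel × channel linear operator. Output is reference-free and
  annihilates spatially constant maps; on spherical harmonics of degree
  $l$ it reproduces the closed form $l(l+1) Y_l / R^2$ (correlation
  > 0.99 at 63 channels for $l = 2, 3$).
* **Downsampling** to 1000 Hz applies a zero-phase Butterworth low-pass at
  400 Hz (forward–backward, so phase — the measurand — is undistorted)
  before integer decimation; a ratio of 1 is the identity.

## Phase extraction and phase-locking statistics

The Morlet wavelet at center frequency $f$ has $\sigma_t = m/(2\pi f)$ and
$\sigma_f = f/m$ with $m = 3$, so $\sigma_t \sigma_f = 1/(2\pi)$
everywhere. (A spectral width of $4f/m$ sometimes quoted alongside this
$\sigma_t$ violates the Fourier uncertainty product; the package uses
$f/m$.) The grid is 3–45 Hz in 1 Hz steps — the coarsest grid resolving 5,
11 and 23 Hz exactly. Support is truncated at $\pm 4\sigma_t$; samples whose
support leaves the epoch are masked, never zero-padded, because padding
fabricates phase. Amplitude is normalized so a unit sinusoid at $f$ has
modulus 1.

Across trials $n = 1 \dots N$ the phase-locking factor at electrode $m$ is

$$\mathrm{PLF}_m(f, t) = \Bigl|\tfrac 1N \sum_{n=1}^N
   e^{i \varphi_{m,n}(f,t)}\Bigr|, \qquad
  \mathrm{ZPLF} = N \cdot \mathrm{PLF}^2 .$$

ZPLF is the Rayleigh-Z statistic: under uniform phase its expectation is ~1
*independently of N*, which is what makes blocks comparable after unequal
trial rejection. `zplf_norm_freq()` standardizes ZPLF across the 3–45 Hz
axis per (channel, time) — used for the per-pulse frequency profiles at the
stimulated electrode — and `zplf_norm_time()` across the epoch per
(channel, frequency) — used for the individual-alpha-frequency analyses.
Per-pulse profiles average the standardized ZPLF over ±0.5 cycles of each
profiled frequency around each pulse; the baseline (`ctrl`) is the mean from
5 to 2 *stimulation-frequency* cycles before the first pulse (the window is
defined in stimulation cycles for every profiled frequency). Post-train
persistence is the longest criterion-satisfying run starting at the last
pulse, in units of the stimulation period.

One analytic guard: the wavelet's Gaussian envelope places only
`leakage_fraction(wavelet_spec(3), 1)` ≈ 1.8% of its mass more than one
period from its center (the cutoff is $2\pi/m$ envelope SDs, frequency
independent), so phase locking observed more than a cycle after the last
pulse cannot be temporal smearing of the pulse response.

## Statistics

Real and sham conditions are compared per participant with elementwise
paired t maps over (channel, frequency, time), thresholded at uncorrected
two-tailed p < 0.05. Suprathreshold samples of equal sign form clusters,
connected over ±1 frequency bin, ±1 time bin, and montage-adjacent channels
at the same bin; each cluster is scored by its summed t. The null
distribution of the maximum (minimum) cluster score comes from flipping
condition labels within participants — sign flips of the paired differences,
enumerated exhaustively with a warning when $2^n$ does not exceed the
requested 500 permutations — and a cluster is significant beyond the 97.5th
percentile of its signed null (two-tailed 5%). Family-wise error under an
exchangeable null is the test's defining property and is checked by Monte
Carlo calibration in the test suite.

Electrodes inside significant clusters are counted per (frequency, time);
counts at the stimulation frequency versus another frequency are compared
with an exact two-sided binomial test against p₀ = 0.5 (minimum-likelihood
two-sided rule, which at p₀ = 0.5 equals doubling the smaller tail). The
per-pulse profile values at the stimulated electrode enter a one-way
fixed-effects ANOVA over levels (ctrl, pulse 1…5) — df (5, 6(n−1)) — with
Dunnett many-to-one comparisons of each pulse against ctrl (two-sided,
family-corrected via the multivariate t with correlation 1/2, integrated by
seeded quasi-Monte-Carlo), and a Pearson correlation of value against pulse
index tests the linear build-up over the train.

## Numerical and design choices

* Clustering uses graph components over a vectorized edge list; permutation
  t maps for all permutations are computed in one matrix product, since the
  per-voxel sum of squared differences is invariant under sign flips.
* `dunnett_vs_ctrl()` saves and restores the RNG state around the
  quasi-Monte-Carlo integral so results are reproducible without disturbing
  the caller's random stream; integration error is held below ~1e−4.
* Degenerate inputs (zero-variance slices, fully masked windows, all trials
  rejected) are masked with warnings or raise errors naming the offending
  unit; ties in peak-frequency searches resolve toward the lower frequency.
* The trialset container round-trips through R serialization
  (`write_trialset()`/`read_trialset()`); it is a runtime artifact, not an
  exchange format.
* The end-to-end driver `run_cohort()` treats each synthetic participant's
  real/sham ZPLF map pair as the paired unit, mirroring the within-
  participant permutation of the emulated design. Figure rendering is
  limited to simple `image()` methods and is never load-bearing; all
  results are numeric tables.

## Problem sizes used by the tests

The test and acceptance suites run at desk scale, chosen once: unit tests
use toy montages and short epochs; the permutation-calibration suite uses
200 null runs on 10-channel × 10-frequency × 50-time maps with 8
participants and 100 permutations; Dunnett calibration uses 1000 simulated
14 × 6 tables; the end-to-end cohort analysis uses 14 synthetic
participants, 12 trials per block and a 1 kHz native rate with the wavelet
stack evaluated at the stimulated electrode (unit tests exercise the 5 kHz
interpolation arithmetic separately). These sizes keep the full suite
runnable on one CPU while leaving every statistical property measurable.

## What passing tests do and do not show

The generator realizes the *hypothesized* dynamics: if entrainment of the
stated form is present, the pipeline recovers it (correct frequency, growing
per-pulse profile, nothing in sham). Passing does not certify the biological
claim on real data: real TMS-EEG carries auditory/somatosensory evoked
components with richer structure than the damped sinusoid, muscle and ocular
artifacts the pipeline does not address (no EOG-based rejection, no channel
repair, no line-noise notch), non-stationary natural frequencies, and a
genuinely unknown coupling mechanism for which the linear phase pull is a
minimal stand-in. The montage is an idealized sphere, and no
volume-conductor head model is used.
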