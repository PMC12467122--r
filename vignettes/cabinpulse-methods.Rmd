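---
title: "Two-stage radar heart-rate estimation: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage radar heart-rate estimation: models, parameters, design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement problem

A frequency-modulated continuous-wave (FMCW) radar looking at a seated
person resolves the chest wall in range and observes its micro-motion
through the phase of the reflected signal. A chirp sweeping from
$f_\mathrm{start}$ to $f_\mathrm{end}$ (bandwidth $B$) turns a target at
range $R$ into a baseband beat tone at $f_b = 2BR/(cT_c)$, and a chest
displacement $\Delta R$ moves the phase of the target's range bin by

$$\Delta\varphi = \frac{4\pi}{\lambda_c}\,\Delta R,$$

with $\lambda_c$ the wavelength at the sweep centre. At 60 GHz
($\lambda_c \approx 5$ mm) a 0.1 mm heartbeat displacement is a 14.4°
phase shift — easily measurable, but buried under respiration (4–12 mm,
0.1–0.5 Hz), road-induced body vibration (0.5–5 Hz), and noise. The
package estimates heart rate (HR) from 5 s windows of this phase signal,
using two estimation stages fused over time by a sequential Kalman filter
(SKF).

`cabinpulse` implements the full chain — scene simulation, pre-processing,
coarse estimation, fine estimation, fusion, evaluation — for a
single-channel radar with one chirp per 50 ms frame (20 Hz slow-time
rate), 128 samples per chirp at 3 MHz, sweeping 58–63.5 GHz.

# Pre-processing

`range_fft()` applies a Hann window across each chirp and a one-sided FFT.
`clutter_filter()` removes static reflections per range bin along slow
time: the temporal mean is subtracted and a zero-phase order-4 Butterworth
high-pass at 0.1 Hz is applied. `select_range_bin()` takes the bin with
the largest time-averaged amplitude in a 0.2–1.5 m search range (sun-visor
to chest geometry), once per recording — the driver is assumed seated.
`extract_phase()` unwraps the angle of the complex slow-time series at
that bin; `bandpass_hr()` restricts it to 0.5–3.0 Hz (30–180 bpm);
`hilbert_kalman()` applies robust smoothing; `phase_difference()` takes
the first difference, which is the working signal of both stages.

Numerical choices worth knowing:

* All filters are Butterworth order 4 run forward–backward (zero phase).
  `signal::filtfilt` alone leaves large startup transients at the very low
  normalized clutter cutoff (0.1 Hz at 20 Hz sampling), so the package
  extends the signal by an odd reflection before filtering. Recordings
  shorter than three settling times ($3/f_c = 30$ s) carry a warning flag.
* The simulator writes the beat tone with the *start-frequency* phase
  convention $\varphi_0 = 4\pi f_\mathrm{start} R/c$. The windowed range
  FFT evaluates the chirp at its centre, which adds
  $2\pi f_b (N{-}1)/(2f_s)$; the recovered bin phase is then exactly the
  $4\pi R/\lambda_c$ law above. Writing $4\pi R/\lambda_c$ into the tone
  directly would make the recovered phase $\approx B/2f_c \approx 4.5\%$
  too large.
* The robust smoother is a constant-velocity scalar Kalman filter whose
  innovation $\nu$ is scaled by the Huber-type weight
  $w = \min(1, \delta\sqrt{S}/|\nu|)$ ($\delta = 1.5$ by default), so
  outliers are not excessively weighted; the envelope of the analytic
  signal scales the measurement-noise variance, trusting weak-return
  samples less. Its exact formulation in the original signal chain is not
  fully specified, so the stage is pluggable
  (`preprocess$hilbert_kalman = FALSE` disables it).
* The phase difference has length $n-1$; the pipeline front-pads one
  sample so a 90 s recording yields exactly eighteen 5 s chunks.

# Stage 1 — coarse estimation

Each 100-sample chunk is decomposed with a 3-level discrete wavelet
transform. At 20 Hz, the level-3 approximation A3 covers 0–1.25 Hz and the
level-3 detail D3 covers 1.25–2.5 Hz; reconstructing from A3 and D3 alone
(zeroing D1, D2) keeps exactly the 0–150 bpm band. The wavelet is
Daubechies-4 (compact support suits 100-sample chunks; `db2` and `haar`
are available). The transform is periodized with zero-padding to a
multiple of $2^\mathrm{levels}$, making it an orthogonal map whose adjoint
is its exact inverse — reconstruction is exact to rounding, which the test
suite asserts at $10^{-8}$.

The band-limited chunk is fitted with an autoregressive model by Burg's
method (`stats::ar.burg`), chosen for its resolution on short records, and
the AR spectrum

$$P(f) = \frac{\sigma_e^2}{\left|1 + \sum_{k=1}^{p}\alpha_k
  e^{-j2\pi f k/f_s}\right|^2}$$

is evaluated on a 512-point grid over 0.5–2.5 Hz. **Model order.** The
default is $p = 16$. With $p = 12$ the pole budget — two tones (cardiac
fundamental and second harmonic, both emphasized by the differencing
step's $|2\sin(\pi f/f_s)|$ gain) plus the vibration continuum — is too
tight, and on simulated drives the fundamental's peak location is biased
by up to 0.2 Hz, defeating the harmonic-pair logic; $p = 16$ roughly
doubled the per-chunk hit rate in those experiments while staying well
below the $n/2$ identifiability bound.

Spectral peaks (local maxima with topographic prominence at least 5% of
the spectrum maximum) form patterns that a rule table maps to the coarse
estimate $f_0$:

* one peak: select it;
* two peaks with $f_2/f_1 \in [1.65, 2.35]$: a fundamental/second-harmonic
  pair — both $f_1$ and $f_2/2$ estimate the fundamental, and their mean
  is used (the harmonic peak is often the sharper of the two after
  differencing). The window is wider than the textbook $[1.8, 2.2]$
  because Burg peak locations on 100-sample windows scatter by several
  percent;
* two peaks with near-equal amplitudes (ratio < 1.25): their mean;
  otherwise the stronger peak;
* three or four peaks: harmonic pruning low-to-high (drop peaks within
  ±10% of twice a lower retained peak), then the two-peak rules on the two
  largest survivors;
* more than four peaks: nearest to the history median, or the strongest
  when no history exists.

When a history of accepted estimates exists, ambiguous (non-harmonic)
patterns are resolved toward peaks within the plausible jump range of the
history median — a stronger peak outside that range would be rejected by
the plausibility gate anyway, so this keeps the chunk informative instead
of discarding it.

The plausibility gate itself rejects estimates deviating from the median
of the last three accepted values by more than 15 bpm (a physiological
slew bound over 5 s); rejected chunks hand control to Stage 2.

# Stage 2 — fine estimation

The same phase-difference chunk is modelled as a sparse combination of
sine/cosine atoms on a 200-point frequency grid spanning 0.5–2.5 Hz
(inclusive endpoints): $\Phi \in \mathbb{R}^{100\times400}$ with
$\Phi_{n,m} = \sin(2\pi f_m t_n)$ for $m \le M$ and
$\cos(2\pi f_{m-M} t_n)$ above. The inverse problem $y = \Phi x +
\epsilon$ is solved by a relevance vector machine: automatic relevance
determination with per-weight precisions updated by evidence maximization
($\alpha_m \leftarrow \gamma_m/\mu_m^2$,
$\gamma_m = 1 - \alpha_m\Sigma_{mm}$), pruning at $\alpha > 10^9$,
convergence at $10^{-6}$ on $\Delta\log\alpha$, at most 500 iterations,
noise variance re-estimated from the residual with a $10^{-12}$ floor. The
posterior moments are computed through the $N \times N$ Woodbury form, so
the cost is governed by the chunk length, not the 400-atom dictionary.
There is no random initialization; fits are bit-reproducible.

The per-frequency energy $P(f_m) = \mu_m^{(\sin)2} + \mu_m^{(\cos)2}$
is searched within ±12.5 bpm (0.208 Hz) of the Stage 1 estimate; the fine
estimate $f_1$ is the mean of the two strongest local maxima there (one
peak: that peak). If the window holds no peak, $f_1 = f_0$ is kept with a
fallback flag that makes the fusion stage inflate its noise variance
fourfold. The upstream description of this fallback references a "target
energy value" that is never defined; the package does not guess at it.
When Stage 1 is invalid the window centres on the previous fused estimate,
and when none exists the full band is searched with $f_1$ the mean of the
two globally strongest peaks. The grid is treated as endpoint-inclusive
(`seq(0.5, 2.5, length.out = 200)`).

# Fusion and track management

The per-chunk pair $(f_0, f_1)$ measures one HR state, modelled as a
scalar random walk ($A = H = 1$, units bpm). The SKF applies the two
scalar updates in sequence — first $f_0$ with variance $R_0$, then $f_1$
with $R_1$ — which is algebraically identical to one batch update with the
stacked 2-vector measurement (asserted to $10^{-9}$ in the tests).
Defaults: $Q = 0.5$ bpm² per chunk, $R_0 = 25$, $R_1 = 9$ bpm²
(the fine stage is weighted as the more reliable), $P_0 = 100$ bpm².
These are surrogates tuned on the simulator, not physical constants; all
are configurable.

Per-chunk spectra are ambiguous often enough that a plain causal filter
can lock onto a harmonic or a vibration line at start-up and stay there.
The pipeline therefore manages the track explicitly:

* **Acquisition** — the history starts only when a coarse estimate agrees
  with one of the previous three within the 15 bpm jump limit; the SKF
  initializes at the median of that pair.
* **Re-lock** — three mutually consistent rejections within the last eight
  chunks replace the history and re-inflate the fused covariance by
  $P_0$ (the tracker admits its state was wrong).
* **Self-confirmation guard** — an $f_1$ from a window centred on the
  fused prior is partially circular and is applied with the inflated
  $R_1$.
* **Backcast** — recordings are processed offline, so chunks before the
  first lock report the first locked estimate rather than an unconfirmed
  single-chunk guess.

On 30 simulated 90 s drives these rules reduced the fused mean absolute
error from ≈7 bpm to ≈2 bpm, almost entirely by preventing or shortening
wrong initial locks.

# The scene simulator

`simulate_recording()` emulates a driver's thorax at 0.5 m: a
raised-cosine cardiac pulse train (peak-to-peak 0.4 mm by default, duty
0.3, instantaneous frequency following the configured HR trace; the pulse
shape deliberately carries the second-harmonic energy that real cardiac
displacement shows), a sinusoidal respiratory component (8 mm
peak-to-peak at 0.25 Hz), band-limited Gaussian vehicle vibration
(0.5–5 Hz, 0.1 mm RMS), and white baseband noise at 20 dB SNR. Cardiac
and respiratory amplitudes sit mid-range of the published physiological
bands; vibration RMS and SNR have no published values and were fixed once
at levels that make the cardiac line clearly present but not trivially
dominant. The seed fixes every random draw; identical configurations give
bit-identical cubes.

What the simulator does *not* emulate — and what passing tests therefore
do not show about real data: clothing attenuation and decoupling, body
and limb motion, bin migration from posture changes, multi-person
reflections, RF interference, and real (non-Gaussian, non-stationary)
road vibration spectra. The vibration model is a band-limited stand-in,
not a claim of realism. Published accuracy figures from real drives are
not reproducible from this simulator and are out of scope; the package's
quantitative claims are about the simulator's controlled conditions,
where the problem sizes used throughout (10 drives × 90 s × 18 chunks)
keep the full test suite and the acceptance script within a few minutes
on one CPU.

# Degenerate inputs and edge cases

Zero-amplitude range bins fail with the frame index named; recordings
shorter than one chunk are rejected; a constant reference trace makes the
Pearson correlation undefined (reported as `NA`) and switches the
out-of-SD error gate to a 1 bpm absolute tolerance with a degeneracy
flag. The trailing remainder of a recording that does not fill a 5 s
chunk is dropped and counted. Chunk indices are 0-based with half-open
`[start, start + 5)` second intervals.

# Known limitations

* The peak-decision rule table is a documented, configurable surrogate:
  the upstream description shows outcomes, not rules, and explicitly
  leaves their clarification to future work.
* A wrong lock can still survive a full recording when the decoy line is
  persistent and the true line rarely surfaces; the re-lock rule needs
  three consistent rejections to fire.
* HR traces with genuine fast changes (> 15 bpm per 5 s) are actively
  suppressed by the plausibility gate — arrhythmia is out of scope.
* The evaluation module's out-of-SD columns can be read per recording or
  pooled; both are computed because the original wording is ambiguous.
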