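# cabinpulse

Contactless heart-rate (HR) estimation from a 60 GHz FMCW radar observing
a seated person — the in-cabin driver-monitoring setting, where a radar in
the sun visor watches the thorax from ~0.5 m through clothing, independent
of lighting. The package is aimed at researchers in radar vital-sign
monitoring who need a complete, testable reference chain: a physics-based
scene simulator, the estimation pipeline, and agreement metrics against a
chest-strap-style reference trace.

## The method

Chest micro-motion modulates the phase of the target's range bin:
a displacement ΔR produces Δφ = 4π ΔR / λ_c (14.4° per 0.1 mm at 60 GHz).
After range FFT, slow-time clutter removal (0.1 Hz high-pass), range-bin
selection, phase extraction, 0.5–3 Hz band-pass, robust (Huber-weighted)
Kalman smoothing and differencing, the 20 Hz phase-difference signal is
processed in 5 s chunks (100 samples):

- **Stage 1 (coarse, f0):** a 3-level discrete wavelet transform isolates
  0–2.5 Hz (A3: 0–1.25 Hz, D3: 1.25–2.5 Hz ≙ 0–150 bpm); a Burg AR model
  gives the spectrum P(f) = σ²ₑ / |1 + Σ αₖ e^(−j2πfk/fs)|², and a
  pattern-based rule table (harmonic pairs, near-equal peaks, harmonic
  pruning) picks f0, gated by a ±15 bpm plausibility check against the
  recent history.
- **Stage 2 (fine, f1):** the chunk is decomposed over a 100×400
  sine/cosine dictionary on a 200-point 0.5–2.5 Hz grid by a relevance
  vector machine (sparse Bayesian regression); the energy spectrum
  P(fₘ) = μₘ² + μₘ₊ₘ² is searched within ±12.5 bpm (0.208 Hz) of f0 and
  f1 is the mean of the two strongest peaks.
- **Fusion:** a sequential Kalman filter treats (f0, f1) as two noisy
  measurements of one scalar HR state (random walk), applying the two
  scalar updates per chunk — algebraically identical to the batch
  two-measurement update.

The simulator generates raw ADC frame cubes (58–63.5 GHz sweep, 128
samples/chirp at 3 MHz, 50 ms frames) for a thorax with cardiac
(0.2–0.6 mm), respiratory (4–12 mm) and road-vibration (0.5–5 Hz) motion,
plus a 1 Hz ground-truth HR trace. Evaluation reports MAE, MRE,
out-of-1/2-SD error rates, Bland–Altman limits of agreement
(bias ± 1.96·SD) and Pearson correlation.

## Worked example

```r
library(cabinpulse)

cfg <- radar_config(duration = 90)           # 58-63.5 GHz, 20 Hz slow time
sc  <- scene_config(hr_bpm = 72, seed = 5)   # driver at 72 bpm, road vibration
rec <- simulate_recording(cfg, sc)           # raw cube + 1 Hz truth trace

res <- run_pipeline(rec$cube)
res
#> HR pipeline result: 18 chunks, range bin 19
#>   chunk_index t_start_s    f0_bpm    f1_bpm hr_skf_bpm
#> 1           0         0  61.95205  57.73869   69.53147
#> 2           1         5 121.11546 124.37186   69.53147
#> 3           2        10  65.23973  71.60804   69.53147
#> 4           3        15  69.05577  70.70352   69.90193
#> 5           4        20  73.91389  71.30653   70.67004
#> 6           5        25  68.93836  74.02010   71.28480
#>   ...

evaluate_pipeline(res, rec$truth)
#> Agreement report (18 chunk pairs)
#>   MAE  1.38 bpm   MRE  1.92 %
#>   out-of-1SD 10 (56 %)   out-of-2SD 10 (56 %)   ref SD 0.00 bpm
#>   Bland-Altman bias -1.38 bpm, LoA [-3.00, 0.23] bpm
#>   Pearson r NA (p = NA)
```

Reading the output: the radar resolved the chest at range bin 19
(≈ 0.49 m). Chunk 1's coarse estimate jumped to the second harmonic
(121 bpm) and was rejected by the plausibility gate; the fused trace
(`hr_skf_bpm`) stays near the true 72 bpm, ending with a mean absolute
error of 1.38 bpm. The reference is constant here, so its SD is 0 — the
out-of-SD gate then counts every deviation beyond an absolute 1 bpm
tolerance and the Pearson correlation is undefined (`NA`) by design.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/cabinpulse run-all --out-dir out/ --seed 5
```

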