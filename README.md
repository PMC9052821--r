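# binsrm

Blind equalization–cancellation (EC) modeling of binaural speech
intelligibility and **spatial release from masking (SRM)** under interaural
processing-latency offsets ("reference ITDs").

## The problem

In asymmetric treatment of hearing loss (e.g. a hearing aid on one ear and a
cochlear implant on the other) the two ears' processing latencies differ, so
even a frontal source carries a static interaural time offset of several
milliseconds.  This package models how such a reference ITD degrades the
benefit of spatially separating speech and noise — the SRM, defined as

```
SRM = SRT(S0N0) − SRT(S0N90)
```

where the speech reception threshold (SRT) is the SNR at which a criterion
intelligibility is reached, for a masker collocated with the target (S0N0)
or at 90° azimuth (S0N90).  The interaural cues can be manipulated to carry
both ITDs and ILDs (condition A), ITDs only (B), or ILDs only (C).

## The model

For each two-ear mixture: a 30-band gammatone filterbank (ERB-spaced,
150–8500 Hz); for bands up to 1500 Hz an EC stage that *blindly* estimates a
per-band equalization delay τ̂ (cross-correlation argmax) and level α̂ (RMS
difference) from the mixture, applies them with Gaussian processing jitter

```
σ_δ = σ_δ0 (1 + |τ̂|/τ0)          σ_δ0 = 65 µs,  τ0 = 1.6 ms
σ_ε = σ_ε0 (1 + (|α̂|/α0)^p)      σ_ε0 = 0.25,   α0 = 13 dB,  p = 1.6
```

and subtracts (level-minimization) or adds (level-maximization) the
equalized ears; a blind modulation analysis (SRMR: low-rate over high-rate
envelope modulation energy) selects the better path, and selects the better
ear for the bands above 1500 Hz.  The selected transformations are applied
unchanged to the clean speech and noise shadow paths, which are resynthesized
and scored by the critical-band **Speech Intelligibility Index** (SII).
Averaging the SII over sentences and Monte-Carlo jitter draws on a 21-point
SNR grid gives a psychometric curve; SRTs are read off at a calibrated
reference SII.  Because σ_δ grows with |τ̂|, a large reference ITD destroys
ITD-based unmasking while leaving ILD-based unmasking intact — the model's
central prediction.

Stimuli are synthetic: speech-spectrum (LTASS) noise, a 4-Hz
envelope-modulated speech-like target, and a parametric binaural impulse
response generator (0.70 ms ITD and a 12-dB head-shadow shelf at 90°, plus an
optional diffuse reverberant tail with configurable T60).  External
two-channel WAV impulse responses can be used instead (`read_wav()`).

## Worked example

ITD-only condition (B) with a 3.5 ms reference ITD, at a small demonstration
scale (3 sentences × 3 Monte-Carlo runs, 2-dB grid):

```r
library(binsrm)
cfg   <- binsrm_config()
grid  <- seq(-16, -4, by = 2)
scene <- scene_spec(masker_azimuth_deg = 90, condition = "B_ITD_ONLY",
                    ref_itd_ms = 3.5)
curve <- simulate_condition(scene, cfg, n_sentences = 3, n_mc = 3,
                            grid = grid, seed = 1)
curve
#> <psychometric_curve: 7 SNRs in [-16, -4] dB, 63 evals, SII 0.086..0.430>

cal  <- simulate_condition(scene_spec(0, "A_BOTH", 0), cfg, n_sentences = 3,
                           n_mc = 3, grid = grid, seed = 1)
ref  <- calibrate_reference_sii(cal, -7)     # reference SII at the calibration SRT
round(ref, 4)
#> [1] 0.2285

srt0  <- srt_from_curve(cal, ref)$srt_db     # -7    dB SNR (collocated)
srt90 <- srt_from_curve(curve, ref)$srt_db   # -10.64 dB SNR (separated)
compute_srm(srt0, srt90)
#> [1] 3.64
```

Reading: with only ITD cues and an already-degraded 3.5 ms reference ITD,
separating the masker still lowers the SRT by 3.6 dB; at 0 ms the same
condition yields ≈ 6 dB, and at 10 ms the benefit collapses toward 0 — the
model's reference-ITD effect.  `run_experiment()` sweeps all conditions ×
reference ITDs × azimuths (× environments) and returns a tidy table with one
row per cell; `plot_srm()` draws SRM against reference ITD per condition.
A thin command-line front end is in `inst/cli/binsrm.R`
(`binsrm.R run --config exp.yaml --out results/ --seed 1 --reduced`).

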