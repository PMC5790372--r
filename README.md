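# speechtrack

Cerebro-acoustic speech tracking analysis for MEG, in R.

During connected speech, the acoustic amplitude envelope carries the
syllabic rhythm (~7 Hz in Italian). Neural populations phase-align to
these slow fluctuations, and the strength of that alignment —
**cerebro-acoustic coherence** — can be imaged from MEG recordings. This
package implements a complete, tested pipeline for such analyses, aimed
at auditory/neural-signal researchers who want every stage reproducible
and verifiable by parameter recovery:

- **Stimulus tools** — WAV I/O and a noise **vocoder** (1- or 8-channel,
  logarithmically spaced bands) that destroys spectral detail while
  preserving the envelope, the classic intelligibility manipulation.
- **Envelope extraction** — nine Butterworth bands (100–1000 Hz) spaced
  equally along the basilar membrane (Greenwood map), zero-phase
  filtering, Hilbert analytic amplitude, summed and scaled to max 1.
- **Preprocessing** — zero-phase 1 Hz high-pass / 170 Hz low-pass,
  50/100/150 Hz line-noise removal, anti-aliased downsampling to 256 Hz,
  1 s epoching, robust variance/range artifact screening; the stimulus
  envelope runs through the identical chain.
- **Coherence** — Hanning-tapered cross-spectral densities (1–30 Hz,
  1 Hz steps), magnitude coherence with the envelope, Fisher z
  (`atanh`).
- **Source imaging** — analytic spherical-conductor MEG forward model on
  an 8 mm grid; **DICS** beamformer maps of source–envelope coherence
  (6 ± 2 and 7 ± 2 Hz windows averaged into one 4–9 Hz image); **LCMV**
  virtual sensors with SVD orientation reduction.
- **Connectivity** — phase-locking value spectra (0–50 Hz, 2 s padding)
  with theta-band (4–8 Hz) summaries, and the **phase slope index**
  (±5 Hz band, jackknife-normalized) for directionality:
  `psi > 0` means the first series leads.
- **Inference** — pseudo-t maps with 15 mm FWHM variance smoothing,
  **TFCE** (compiled union-find sweep), and max-statistic permutation
  FWE correction (group shuffles or paired sign flips), including the
  group-by-intelligibility interaction contrast.
- **Synthetic study generator** — speech-like stimuli, envelope-coupled
  cortical dipoles (strength α, lag τ) on pink-noise backgrounds,
  sensor projection at a chosen SNR, and a two-group ×
  three-condition cohort with embedded ground truth.

The statistic at the core is the magnitude coherence between sensor (or
beamformed source) signals and the speech envelope,

    coh(f) = |S_xe(f)| / sqrt(S_xx(f) * S_ee(f)),   z = atanh(coh),

with S the trial-averaged Hanning-tapered cross-spectra of 1 s epochs,
localized by DICS filters `w = S⁻¹l / (lᵀS⁻¹l)` and tested at the group
level with TFCE + permutation max statistics.

## Worked example

```r
library(speechtrack)

# 1. A 7 Hz speech-like stimulus and its unintelligible vocoded version
stim <- synth_stimulus(rate_hz = 7, duration_s = 20, seed = 1)
voc1 <- vocode(stim, vocoder_spec(n_channels = 1, noise_seed = 2))
cor(extract_speech_envelope(stim)$samples,
    extract_speech_envelope(voc1)$samples)   # 0.842  (envelope survives)
cor(stim$samples, voc1$samples)              # -0.0011 (fine structure gone)

# 2. One synthetic subject: an envelope-coupled source in STG (alpha = 0.5)
cfg <- simulation_config(
  n_trials_per_condition = 60, conditions = "nat",
  n_subjects = c(EB = 1, SI = 1),
  coupling_alpha = list(STG = list(EB = c(nat = 0.5), SI = c(nat = 0.5))),
  source_positions = rbind(STG = c(0.056, -0.008, 0.016)),
  n_sensors = 64, snr_db = 0, seed = 5)
ep <- synth_subject(cfg, "EB", subject_seed = 42)
#> <epoch_set> 60 trials x 64 channels x 256 samples at 256 Hz

# 3. Where does the brain track the envelope, and at what rate?
prof <- sensor_coherence_spectrum(ep, roi = seq_len(64))
prof$peak_hz                                  # 7  (the syllabic rate)
max(prof$z)                                   # 1.342

grid <- make_grid(spacing = 0.008, conductor_radius = 0.09)
lf <- sphere_leadfield(grid, ep$sensors)
map <- source_coherence_map(ep, lf)           # DICS, 4-9 Hz image
grid$points[which.max(map$values), ] * 1000   # 56 -8 16 (mm) = the source
```

The coherence spectrum peaks at the stimulus' 7 Hz syllable rate, and the
DICS map's maximum falls on the simulated source position exactly (0 mm
error at 0 dB SNR with 60 trials).

A full cohort analysis — simulation, sensor coherence, per-condition DICS
maps, STG–CS connectivity (PLV + PSI), and the TFCE-corrected interaction
contrast — runs end to end via

```r
run_pipeline(list(seed = 1), out_dir = "run1")   # writes manifest.json
```

or `Rscript scripts/run_pipeline.R config.yaml --out run1`. Artifacts are
hashed into the manifest; identical configurations reproduce identical
hashes.

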