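---
title: "Cerebro-acoustic speech tracking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cerebro-acoustic speech tracking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

During connected speech, the amplitude envelope — the slow (< ~30 Hz)
fluctuation of acoustic energy — carries the syllabic rhythm of the signal
(~7 Hz for Italian). Neural populations in auditory cortex phase-align to
these fluctuations, and the strength of this *cerebro-acoustic coherence*
can be imaged with MEG. `speechtrack` implements the full analysis chain
used to ask where in the brain such speech tracking occurs, how it depends
on intelligibility (manipulated by noise vocoding), how two groups (e.g.
early-blind and sighted listeners) differ, and in which direction
information flows between the implicated regions. Because real MEG
recordings of this kind are not redistributable, the package includes a
first-class synthetic-data generator with known ground truth, so every
stage can be validated by parameter recovery at desk scale.

## Stimuli and the noise vocoder

`vocode()` implements a classic channel vocoder: the waveform is split
into `n_channels` logarithmically spaced bands (default 70–9000 Hz, a
Shannon-style speech range), each band's envelope is extracted by
half-wave rectification followed by a zero-phase low-pass at 30 Hz
(retaining syllabic and prosodic modulations), refilled with band-limited
Gaussian noise, RMS-matched per band to the original, and summed. One
channel renders speech unintelligible while an 8-channel version remains
intelligible; both preserve the broadband envelope, which is the premise
the whole design rests on. Because the band filters' skirts overlap, a
single per-band gain does not make the *summed* output match the input
band RMS exactly; `vocode()` therefore runs four Jacobi-style gain
iterations, after which measured band RMS matches to well under 1%.
Carriers come from a seeded generator, so vocoding is bit-reproducible.
The Hilbert-based envelope of this module's sibling (`envelope`) is
deliberately *not* used inside the vocoder: rectification + low-pass is
the classic vocoder recipe, and keeping the two envelope definitions
separate mirrors how the analysis chain is specified.

## Envelope extraction

`extract_speech_envelope()` filters the audio into nine bands between 100
and 1000 Hz whose edges are equally spaced along the human basilar
membrane, i.e. images of an arithmetic sequence of cochlear positions
under the Greenwood map \(F(p) = A\,(10^{a p} - k)\) with the standard
human constants \(A = 165.4\), \(a = 2.1\), \(k = 0.88\). Each band is
filtered with a fourth-order Butterworth applied forward and backward
(zero phase), the analytic amplitude is taken as the modulus of the
Hilbert transform, and the nine band envelopes are summed and scaled to a
maximum of 1. The envelope is computed on the whole stimulus before any
epoching so that Hilbert edge effects stay confined to the stimulus
boundaries. `align_envelope_to_recording()` then passes the envelope
through exactly the same filter chain and downsampling as the sensor data
— including the line-noise (DFT) filters; running the envelope through
notches it cannot contain is harmless and keeps "processed identically"
literally true — so envelope and MEG samples live on one grid.

## Preprocessing

`apply_standard_filters()` applies a zero-phase Butterworth high-pass at
1 Hz and low-pass at 170 Hz plus removal of 50/100/150 Hz line components
by subtracting their least-squares sinusoid fit over the whole record (the
"DFT filter"). Filter orders are not part of the chain's definition; we
use order 4 everywhere for consistency with the envelope filterbank.
`downsample()` inserts an extra anti-alias low-pass at
\(0.8 \times \text{target}/2\) (≈ 102 Hz for 256 Hz output) before spline
interpolation onto the new grid, because the 170 Hz low-pass alone would
alias the 128–170 Hz band. Epoching cuts non-overlapping 1 s segments
(trailing partial segments discarded), which fixes the spectral resolution
at 1 Hz. `screen_artifacts()` replaces interactive artifact inspection
with a fully automatic robust screen: per-trial/per-channel variance and
range are summarized, and trials or channels whose median/MAD z-score
exceeds 5 (default) are dropped. This is reproducible and recovers planted
outliers exactly; it does not emulate an expert's eye for unusual artifact
morphologies.

### Zero-phase filtering internals

All filtering uses Butterworth designs kept in second-order sections
(analog prototype poles + bilinear transform) and applied forward and
backward with odd-reflection padding and step steady-state initial
conditions. The SOS form matters: a 1 Hz high-pass on 1 kHz data has poles
so close to the unit circle that the expanded polynomial form is
numerically fragile, and naive forward–backward filtering without initial
states leaves second-scale DC transients. With this implementation a
constant input passes a high-pass as exact zeros, and passband sinusoids
are preserved to better than 2%.

## Cerebro-acoustic coherence

`compute_csd()` applies a Hanning taper to each 1 s epoch, Fourier
transforms every channel together with the aligned envelope, and averages
cross-terms over trials on the integer grid 1–30 Hz (1 Hz steps; the 1 s
epochs make finer steps meaningless, and the code refuses them rather than
padding silently). Coherence is the magnitude form
\(|S_{xy}| / \sqrt{S_{xx} S_{yy}}\), variance-stabilized as
\(z = \operatorname{atanh}(\text{coh})\). Under independence the expected
coherence is \(\sqrt{\pi} / (2\sqrt{n})\) for \(n\) trials, which the test
suite verifies to within 20% for \(n \in \{10, 50, 200\}\), and the whole
estimator is checked against a brute-force explicit-DFT implementation to
1e-10.

## Forward model

The imaging grid is an axis-aligned lattice (default 8 mm spacing) masked
to the inner 90% of a spherical conductor (default radius 9 cm). Sensors
are ideal point magnetometers on a Fibonacci-spiral upper hemisphere
(default 102 sensors at 12 cm), radially oriented. Fields come from the
closed-form solution for a current dipole in a homogeneous conducting
sphere. This analytic model replaces the realistic single-shell anatomy a
clinical pipeline would use: it is dependency-free, exact, and supplies
hard test oracles — radial dipoles and dipoles at the center are
magnetically silent, and the far field converges to the free-space
magnetic-dipole form with moment \(\tfrac12\, r_q \times Q\) (the
point-dipole error decays like source offset over distance, so the 1%
agreement is checked with a deep source at ten sphere radii). The
beamformer code is agnostic to which forward model supplies the leadfield.

## Beamforming

Because the radial source orientation in a spherical conductor is silent,
every leadfield is first reduced to its rank-2 tangential subspace; all
filters live there. `source_coherence_map()` (DICS) band-averages the CSD
over two windows, 6 ± 2 and 7 ± 2 Hz, builds per-voxel scalar filters
\(w = S^{-1} l\,/\,(l^\top S^{-1} l)\) along the dominant orientation (the
direction maximizing minimum-variance output power, from a 2×2
eigenproblem), computes source–envelope coherence per window, applies
`atanh`, and averages the two z-maps into a single 4–9 Hz image. Averaging
the *z*-maps (not raw coherence) keeps the combination on the
variance-stabilized scale on which the downstream statistics operate. The
regularization default is 5% of mean sensor power — a common beamforming
default, exposed as a parameter since the appropriate value depends on
sensor count and SNR. `lcmv_virtual_sensor()` computes one common
time-domain filter per subject from the trial-averaged covariance, applies
it to every trial, and reduces the two tangential components to one series
via SVD of the concatenated component-by-time matrix, fixing the sign so
the retained component correlates positively with its largest-weight
sensor (SVD signs are otherwise arbitrary, which would scramble
between-subject averaging).

## Connectivity

`plv_spectrum()` zero-pads each 1 s virtual-sensor epoch to 2 s (0.5 Hz
bins, 0–50 Hz), applies a Hanning taper, and averages the
amplitude-normalized cross-spectrum over trials — the phase-locking value,
insensitive to joint power fluctuations; `band_mean()` averages the
z-transformed PLV over theta (4–8 Hz, nine bins). `phase_slope_index()`
uses the same spectral pipeline to form the complex coherency \(C(f)\) and
computes \(\Psi = \operatorname{Im} \sum_f C^*(f)\, C(f + \delta f)\) over
a ±5 Hz band around 6 Hz (the syllabic-rate frequency of interest, with
the band clipped at 1 Hz; \(\delta f\) is one bin). The sign convention —
positive means the first argument temporally leads — is pinned by a
delayed-copy simulation. \(\Psi\) is normalized by its leave-one-trial-out
jackknife standard error. One caveat discovered during validation and
worth knowing: at the exact null the PSI is a *degenerate* (zero-gradient)
statistic, and the jackknife then overestimates its standard deviation by
a roughly constant factor (~1.5, independent of trial count), so
\(|\Psi / \widehat{se}| > 2\) occurs in well under 5% of null simulations.
The normalized PSI is therefore conservative as a null test while fully
informative about direction — with a 20 ms lag the correct sign is
recovered in 100/100 simulations at 60 trials.

## Group statistics

`pseudo_t_map()` computes voxelwise two-sample (independent) or paired
(dependent) t statistics with the variance map Gaussian-smoothed at
15 mm FWHM before forming the ratio — variance smoothing suppresses
high-spatial-frequency noise that beamformer maps inherit, and MEG source
images are smooth enough that 15 mm (larger than typical fMRI kernels) is
appropriate. `tfce()` integrates \(e(h)^E h^H\,dh\) over thresholds
(defaults E = 0.5, H = 2, 100 integration steps per map, 26-connectivity —
the canonical TFCE settings, since none are dictated by the method
itself), handling negative lobes on the negated map. The compiled
union-find sweep is verified against a pure-R threshold/BFS oracle.
`permutation_fwe()` relabels group membership (independent) or flips
within-subject condition differences (dependent; sign flipping is exact
under the paired null), recomputes pseudo-t → TFCE each time, records the
max |enhanced| statistic over an optional small-volume mask, and returns
\(p_v = (1 + \#\{\max_\text{perm} \ge |E_v|\}) / (1 + n_\text{perm})\).
When fewer distinct relabellings exist than requested permutations, all
are enumerated. The interaction of group × intelligibility is computed by
`interaction_contrast()` as an independent-design comparison of
per-subject (natural − 1-channel) difference maps.

## The synthetic study

`synth_cohort()` generates the full experiment: a speech-like stimulus
(band-limited noise carrier × a jittered syllable train — gamma-shaped
bursts at 7 Hz with 15% CV interval jitter), its 8-channel and 1-channel
vocoded versions, and per-subject continuous sensor data. Each cortical
source follows
\(s(t) = \alpha\, g\!\left(\text{env}_\theta(t - \tau)\right) +
\sqrt{1 - \alpha^2}\,\eta(t)\),
where \(\text{env}_\theta\) is the stimulus envelope band-passed 4–9 Hz
(coupling is injected only in the analysis band, keeping \(\alpha\)
interpretable as the coupled fraction of source SD), \(g\) standardizes to
unit variance, and \(\eta\) is pink (1/f) noise, the generic spectral
profile of neural mass signals. Sources (10 nA·m tangential dipoles) are
projected through the spherical leadfield, white sensor noise is added at
0 dB SNR (sensor-level signal and noise power equal — a deliberately hard
but realistic operating point), and the continuous record (512 Hz) runs
through the full preprocessing chain. The default effect structure places
envelope coupling at STG in everyone (α = 0.5), at parieto-occipital
cortex only in the EB group (α = 0.4, all conditions), and at calcarine
sulcus only in EB × natural speech (α = 0.4) — the planted
group-by-intelligibility interaction; all lags default to 20 ms. Group
sizes default to 17 + 16 subjects and three conditions. What the generator
does *not* emulate: phonetic content, anatomical cortical geometry,
correlated inter-source background activity, eye/cardiac artifacts, and
head movement — so passing recovery tests demonstrates the correctness of
the estimators, not robustness to every property of real recordings.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations are scaled for a single
CPU: beamformer recovery uses 200 trials × 102 sensors at 20 (tests) or 5
(script) random source positions on the full 8 mm grid; FWER calibration
uses 8 subjects per group, 500 permutations and 200 (tests) or 100
(script) replicate null datasets on a 12 mm grid; the end-to-end
interaction recovery uses 8 + 8 subjects, 30 trials per condition, 32
sensors, a 12 mm grid and 500 permutations over 20 (tests) or 6 (script)
replicate cohorts. These sizes are the package's validation conditions;
all are parameters, and nothing in the implementation depends on them.

## Known limitations

- The forward model is a homogeneous sphere; no realistic single-shell or
  BEM head models, gradiometer pickup integration, or MRI handling.
- Artifact screening is statistical only; no ICA, cHPI or vendor formats
  (audio I/O is WAV; interchange containers are R serialization + JSON).
- The PSI null test is conservative (see above); directional inference is
  unaffected.
- Coherence is single-taper Hanning at 1 Hz resolution by design; no
  multitaper or time-resolved variants.
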