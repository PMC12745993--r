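---
title: "Unsupervised sleep staging with feature-weighted kernel densities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised sleep staging with feature-weighted kernel densities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Manual sleep scoring assigns one of five AASM stages (Wake, N1, N2, N3,
REM) to every 30-s epoch of an overnight EEG recording. `aisleep` does
this without any labeled training data, from a single channel, in four
moves:

1. **Spectral features.** Each 30-s epoch is summarized by its Welch power
   spectral density in dB. One night becomes a matrix of a few hundred
   rows (epochs) by 251 frequency bins (0–50 Hz at 0.2 Hz).
2. **Embedding.** The PSD rows restricted to 0.2–30 Hz are projected into
   a 2-D plane with UMAP. Epochs of the same stage form clusters; the
   staging logic reads *only* the 2-D coordinates.
3. **Feature-weighted density carving.** For each stage in turn, a
   per-epoch feature known to characterize that stage (gamma power,
   spindle power, slow-oscillation coverage, oscillatory strength) is
   converted into non-negative weights $w_i$, and a weighted kernel
   density estimate
   $$p(x) = \frac{1}{n\,b_1 b_2}\sum_{i=1}^{n} w_i\,
     K_2\!\left(\frac{x - x_i}{b}\right)$$
   is evaluated on the embedding ($K_2$ the bivariate standard Gaussian,
   bandwidth from Scott's rule $b = n^{-1/(4+d_x)}$ with $d_x = 2$).
   Epochs where the density is high — above 10% of its global maximum, or
   above a competing density — receive that stage's label. Each step only
   converts epochs still *Unknown*; labels are never overwritten (the one
   documented exception is the N3 step's candidate reassignment, below).
4. **Temporal resolution of N1 vs REM.** What remains after Wake, N2 and
   N3 are carved out is low-amplitude mixed-frequency activity, which N1
   and REM share almost exactly in the spectrum. They are separated by
   run-length and context rules, not by spectral content.

The cascade is: open-eye Wake (gamma power, Otsu threshold, weighted KDE,
10%-of-maximum rule) → N2N3 (personalized spindle power, zero split, two
competing KDEs) → N3 (slow-oscillation coverage, 10% rule plus a
proximity test) → closed-eye Wake (oscillatory strength, two competing
KDEs, only Unknown epochs) → N1/REM (provisional REM, uniform smoothing
of the stage curve, short runs near the low-stage side flip to N1).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| Welch segment / overlap | 5 s / 50% | — | 0.2 Hz resolution; the embedding's stated lower edge is 0.2 Hz |
| IRASA resampling set $h$ | 1.1–1.9 step 0.05 | — | the standard published parameterization |
| smoothing $\sigma$ | 1 epoch × 0.5 Hz | — | just enough to stabilize per-epoch peak frequencies |
| gamma band | 25–50 | Hz | open-eye wakefulness marker |
| spindle search / target / preferred | 5–20 / 14 / 12–16 | Hz | fast-spindle personalization |
| density fraction | 0.1 | — | "exceeds 10% of the global density maximum" selection rule |
| SO weight floor | 0.10 | — | weights are $\max(\text{SO\%} - 0.10,\, 0)$ |
| smoothing kernel | 20 epochs | — | 10-minute window for the N1/REM rule |
| REM minimum duration | 20 epochs | — | runs of 10 min or longer always stay REM |
| artifact guard | 500 | µV | epochs above this are excluded from SO weighting |
| UMAP | n_neighbors 15, min_dist 0.1, seed 42 | — | library defaults; only structure matters downstream |

All of these live in `ais_config()` and can be overridden from a YAML
file (`--config`).

## Numerical and design choices

**Sign of the density rule.** The algorithm tables print
`S[p < max(p)*0.1]` for the Wake and N3 selections, but the prose and the
figures select the *high*-density region. We implement
`p >= 0.1 * max(p)`; `staging$literal_sign = TRUE` restores the printed
comparison for anyone who wants it.

**Spindle-power source.** The spindle power is the mean dB of the raw PSD
over the personalized band (center ± 1 Hz), exactly as the cascade defines
it. An alternative reading uses the IRASA oscillatory residual instead
(`psp$source = "psd_osc"`), but we found the residual to be near zero mean
with small variance for *every* non-spindle stage, so its zero split
degenerates: almost no epochs fall below zero and the N2N3 step swallows
N1 and REM. On the raw PSD in dB, zero corresponds to 1 µV²/Hz — a
meaningful boundary between spindle-band activity and background at
12–16 Hz — and the split is robust. This is the package's default.

**IRASA validity range.** Resampling by $h$ compresses the spectrum; the
$h$-resampled series carries no information above $f_s/(2h)$. The fractal
fit is therefore only valid below $f_s/(2 h_{max})$ (≈ 26.3 Hz at the
defaults) and the decomposition grid is truncated there. Every consumer
of the oscillatory component works at or below 20 Hz. The residual's
per-bin magnitude on pure 1/f input (~1 dB mean absolute) reflects Welch
estimator variance at 11 segments per epoch, not bias.

**Distance to a point set.** The N3 step assigns each high-SO-density
candidate to N3 or Wake by comparing distances to the already-labeled
point sets. The set of spindle-stage epochs is *bi-modal by construction*
(it covers both the N2 and the N3 clusters), so its centroid lies between
the clusters and is not representative; with centroid distance, genuine
N3 candidates were systematically pushed to Wake. The default is
therefore nearest-member distance; `centroid` and `median_pairwise`
remain options.

**Zero-phase filtering.** The slow-oscillation detector band-passes at
0.5–2.0 Hz with a centred, symmetric windowed-sinc FIR (transition width
0.2 Hz) applied in a single pass — a symmetric centred kernel has exactly
zero phase, which the deflection-duration criteria require. Candidate
waves run between consecutive negative-going zero crossings, negative
deflection first; the five amplitude/duration criteria are applied per
wave.

**Degenerate inputs.** Silent epochs are floored at 1e-12 µV²/Hz before
the dB conversion; constant feature distributions make a carving step
skip with a warning rather than fail; a constant sample in a Gaussian fit
gets σ floored at 1e-6; ties in the Otsu scan resolve to the lowest
threshold; a smoothed stage value of exactly 2.5 keeps an epoch REM
(strict inequality).

**Determinism.** Everything downstream of the embedding is a pure
function of its inputs. The embedding runs single-threaded with a fixed
seed, so `stage` twice with the same configuration writes byte-identical
hypnograms.

## What the synthetic generator emulates — and what it does not

`night_spec()` / `simulate_night()` produce ground-truthed nights whose
per-stage recipes mirror the phenomenology the staging features key on:

* a 1/f^1.5 background common to all stages, plus a stage-specific
  low-frequency (< 6 Hz) component (amplitudes: N3 > N2 > N1/REM/Wake).
  The broadband floor is deliberately stage-independent: real amplitude
  differences between sleep stages live at low frequencies, and a
  stage-dependent gamma floor would fabricate extra modes in the gamma
  histogram that real data do not show;
* open-eye Wake: broadband 25–50 Hz elevation (~10 µV RMS). Wake runs
  are eyes-open first, then eyes-closed (coherent drowsy blocks with
  ~10 Hz, 25 µV alpha bursts), as in pre-sleep wakefulness;
* N2: 3–8 spindle bursts per epoch (0.7–1.5 s, 25 µV) at a per-night
  center frequency drawn from 12–16 Hz; N3: the same but sparser, plus
  0.5–1.2 Hz slow-oscillation trains with 120 µV peak-to-peak covering
  about half of each epoch — every N3 epoch passes the five detector
  criteria by construction;
* N1 and REM: identical low-amplitude theta-tinged recipes. This is the
  point: nothing spectral distinguishes them, so any recovered REM/N1
  split is attributable to the temporal logic alone;
* stage sequencing from a semi-Markov chain (geometric run lengths, mean
  30 epochs for N2, 24 for REM, 16 for N3, 4 for N1 — N1 capped at 10
  epochs since the stage lasts 1–5 minutes in practice), beginning and
  ending in Wake.

A green end-to-end test therefore establishes that the cascade recovers
stages whose defining features are present and separable — it does not
establish performance on real polysomnography, where artifacts, age
effects, sleep disorders, scorer noise and channel choice all matter.
The generator has no EOG/EMG, no movement artifacts beyond an optional
amplitude guard case, and stage transitions sharper than real hypnograms.

## Known limitations

* A night with very little N3 (a handful of epochs) can over-carve: the
  few slow-oscillation-rich epochs do not form their own embedding
  cluster, so their weighted density spreads over the whole spindle
  cluster and the 10% rule selects it wholesale. This is a property of
  the density-carving rule itself (the same happens with the centroid
  distance), and a reason hypnograms from such nights deserve a look at
  the returned `densities`.
* N1 recall is intrinsically weak (as for every method in this family):
  the stage is brief, spectrally ambiguous, and recovered only through
  the run-length heuristic.
* The personalized spindle band assumes *some* 12–16 Hz activity exists;
  a night with none falls back to 14 Hz with a warning.
* Recordings are assumed (or resampled) to 100 Hz; all band edges assume
  a 50 Hz Nyquist.
* Trimming to "30 min around sleep" requires labels an unsupervised tool
  does not have; `--trim START END` accepts explicit bounds instead, and
  the default is to stage the full recording.
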