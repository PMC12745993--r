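# aisleep

Unsupervised, interpretable sleep staging from a single EEG channel.

Sleep laboratories score overnight EEG manually, 30 seconds at a time,
into the five AASM stages (Wake, N1, N2, N3, REM) — about two hours of
expert work per night. `aisleep` automates this without any labeled
training data, which makes it usable on recordings from portable,
home-based devices where no scorer and no training distribution exist.

## Method in brief

For every 30-s epoch the Welch power spectral density (dB) is computed;
the PSD rows (0.2–30 Hz) are embedded into a 2-D plane with UMAP, where
epochs of the same stage cluster. Stages are then carved out
sequentially by *feature-weighted kernel density estimation*: a
per-epoch feature characteristic of one stage becomes the weights
$w_i$ of

$$p(x) = \frac{1}{n\,b^2}\sum_{i=1}^{n} w_i\,K_2\!\Big(\frac{x-x_i}{b}\Big),
\qquad b = n^{-1/(4+d_x)},\ d_x = 2,$$

and high-density epochs receive that stage's label:

| step | stage | feature | weighting |
|---|---|---|---|
| 1 | Wake (eyes open) | gamma power (25–50 Hz) | Otsu split, percentile-rank weights, `p ≥ 0.1·max(p)` |
| 2 | N2N3 | personalized fast-spindle power (peak ± 1 Hz) | Gaussian-CDF weights from the zero split, two competing KDEs |
| 3 | N3 | slow-oscillation coverage | `max(SO% − 0.10, 0)`, 10% rule + proximity test; rest of N2N3 → N2 |
| 4 | Wake (eyes closed) | oscillatory strength (IRASA residual, 5–20 Hz) | Gaussian-CDF weights, two competing KDEs |
| 5 | N1 / REM | — | remaining epochs → REM; short runs near the low-stage side of the smoothed hypnogram → N1 |

The spindle band is personalized per night (density peak of per-epoch
oscillatory peak frequencies closest to 14 Hz); the oscillatory residual
comes from an IRASA fractal/oscillatory decomposition; slow oscillations
are detected with the standard five amplitude/duration criteria
(0.5–2 Hz, PTP > 75 µV, deflection durations, peak signs). See
`vignette("aisleep-methods")` for assumptions, parameters and numerical
choices.

## Worked example

The package ships a seedable generator of ground-truthed synthetic
nights (stage-conditioned spectra: gamma for open-eye wake, alpha bursts
for closed-eye wake, spindle bursts for N2/N3, high-amplitude slow
oscillations for N3, low-amplitude mixed frequency for N1/REM):

```r
library(aisleep)

spec <- night_spec(n_epochs = 240, seed = 3)   # a 2-h synthetic night
sim  <- simulate_night(spec)
res  <- run_aisleep(sim$recording, verbose = TRUE)
#> open-eye Wake: 15 epochs
#> N2N3: 194 epochs
#> N3: 57 epochs (N2: 137)
#> closed-eye Wake: 15 additional epochs
#> N1: 2, REM: 14

res
#> <aisleep_result>
#> <hypnogram> 240 epochs: W=30 N1=2 N2=137 N3=57 REM=14 ?=0
#>   spindle band: 13.40-15.40 Hz; 579 slow oscillations

sc <- score(confusion(sim$hypnogram, res$hypnogram))
sprintf("accuracy %.3f | macro F1 %.3f | kappa %.3f",
        sc$accuracy, sc$macro_f1, sc$kappa)
#> "accuracy 0.992 | macro F1 0.918 | kappa 0.986"
round(sc$recall, 2)
#>   W  N1  N2  N3 REM
#> 1.0 0.5 1.0 1.0 1.0
```

Reading: the cascade labeled 30 wake epochs (15 by gamma, 15 by alpha),
carved 194 spindle-stage epochs into 137 N2 + 57 N3 using the 579
detected slow oscillations, and resolved the remainder into N1/REM by
the temporal rule. Against the generator's ground truth it recovers
every stage except (as expected) part of the brief N1 — the hard stage
for every method of this family. Accuracy on *real* polysomnography is
lower (the published figure for this approach is ~82% on young healthy
subjects); the synthetic world is noiseless and artifact-free.

## Command line

```sh
Rscript exec/aisleep simulate --seed 7 --n-epochs 960 \
        --out-edf night.edf --out-hypnogram truth.txt
Rscript exec/aisleep stage --edf night.edf --channel "synthetic Fpz-Cz" \
        --seed 42 --out-hypnogram pred.txt --out-features feats/
Rscript exec/aisleep evaluate --ref truth.txt --pred pred.txt
```

`stage` writes the resolved configuration next to the hypnogram for
provenance; `evaluate --align-clusters` additionally solves the optimal
cluster-to-stage assignment (for scoring unlabeled clusterings).
Recordings are EDF (16-bit), hypnograms single-column text (codes 0–5 or
tokens `W/N1/N2/N3/REM`), features tab-separated tables.

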