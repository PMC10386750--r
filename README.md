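# radarvitals

Non-contact vital-sign monitoring with ultra-wideband (UWB) pulse radar,
reconstructed as a fully synthetic, testable pipeline. The package is aimed
at researchers in biomedical signal processing who want a reproducible
reference implementation of a radar vitals chain — signal model, vitals
extraction, deep-learning heart-rate correction, and RR-interval anomaly
detection with a latency statistic — without access to the private subject
data such systems are usually built on.

## What it implements

**Chest-motion signal model.** The chest surface sits at baseline distance
`d0` from the radar and oscillates with respiration and heartbeat,

    d(t) = d0 + mb sin(2π fb t) + mh sin(2π fh t),

with respiration at 0.1–0.3 Hz (4–12 mm) and heartbeat at 1–2 Hz
(0.2–0.5 mm). Displacement from baseline modulates the echo phase as
`θ = 4π x / λ` (carrier band 6.5–8.1 GHz). `synthesize_phase_series()`
composes these with Gaussian phase noise and optional gross body-motion
transients; `estimate_rates()` recovers breaths/min and BPM from
band-restricted spectral peaks; `motion_energy()` and
`classify_motion_status()` implement the four-level motion state
(stillness → continuous motion) via three energy thresholds; distance is
`R = c tD / 2`.

**Calibrated correction dataset.** A latent-Gaussian factor model generates
records of eight measurement-condition factors (direction, angle, gender,
height, weight, age, distance, motion status) together with a reference
(oximeter) and a radar heart rate. Loadings are calibrated by per-factor
bisection so that the Kendall tau-b between each factor and the absolute
heart-rate error matches published coefficients (weight −0.274, motion
status 0.219, …), while the mean absolute error is anchored at 21.5 BPM.

**Heart-rate correction network.** A fully connected net (9 inputs →
64 → 128 → 256 → 128 → 1; PReLU on the hidden layers; dropout
0.2/0.3/0.4) trained with mean-squared-error loss and Adagrad updates
(`G ← G + g²; θ ← θ − η g/√(G+ε)`), implemented from scratch on base
matrices.

**RR-interval anomaly detector.** A 1-D CNN (two conv → batch-norm → ReLU →
average-pool blocks, fully connected head with dropout) classifies sliding
1024-interval windows as normal/abnormal, trained with cross-entropy and
Adam. For an abnormal segment starting at interval `i ≥ 1024`, the latency
value `k` is the offset of the first flagged window end at or after `i`
(clamped to ≥ 1); detection succeeds when `k ≤ 10`.

## Worked example

Correction experiment (10,400 records, 80/20 split):

```r
library(radarvitals)
cal <- calibrate_dependence(seed = 11)     # match published tau-b targets
df  <- generate_correction_dataset(10400, cal, seed = 5)
ae  <- abs(df$radar_hr - df$oximeter_hr)
kendall_tau_b(df$weight, ae)               # -0.282  (target -0.274)
kendall_tau_b(df$motion_status, ae)        #  0.218  (target  0.219)
mean(ae)                                   # 21.4 BPM before correction

ev <- evaluate_correction(df, correction_net_config(epochs = 40), seed = 99)
ev$measured                    # MAE 21.42  MSE 465.67  MRE 0.29  (n = 2080)
ev$corrected                   # MAE  2.50  MSE   9.76  MRE 0.03  (n = 2080)
round(ev$reduction_pct, 2)     # mae 88.31  mse 97.91  mre 88.12  (all > 85)
```

Anomaly-detection experiment (1600-interval sequence, six inserted
tachyarrhythmia-like segments):

```r
corpus   <- make_detector_corpus(n_seq = 20, seed = 4)
detector <- train_detector(corpus$windows, corpus$labels,
                           detector_net_config(epochs = 10))
base   <- generate_rr_sequence(1600, seed = 5)
seq_ab <- insert_abnormal_segments(
  base, lapply(c(350, 315, 450, 350, 299.5, 502),
               function(m) list(mean_rr = m, length = NA)), seed = 6)
evaluate_latency_experiment(detector, seq_ab)
#  segment average_rr_ms latency_k  result
#        1      352.7761         1 success
#        2      314.9997         1 success
#        3      453.7270         1 success
#        4      349.6828         1 success
#        5      303.4082         1 success
#        6      504.2453         1 success
# 6/6 segments detected with k <= 10 (max k = 1)
```

Every abnormal segment is flagged within one interval of its onset; the
detector sees clean synthetic separations, so its latencies are lower than
a detector facing clinical recordings would achieve (see the methods
vignette for what these numbers do and do not establish).

A command-line interface wraps the same steps
(`inst/scripts/radarvitals simulate|extract|gen-data|gen-rr|train-corrector|correct|train-detector|detect|eval-latency|evaluate|correlate|run-all`),
and `run_pipeline()` executes both experiment chains from one seed, writing
a manifest with file hashes.

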