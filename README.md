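# plinet

Phase-lag-index functional brain networks from multichannel EEG, with
small-world graph metrics and group statistics.

## What it is for

Task and state changes (fatigue, attention, emotional valence) reshape
how cortical regions synchronize. A standard way to quantify this from
scalp EEG is to build a *functional brain network*: electrodes are
nodes, and the edge weight between two channels is the **phase lag
index**

    PLI = | < sign(Δφ(t)) > | ,   Δφ wrapped to (−π, π],

the absolute time-average of the sign of the instantaneous phase
difference (from the Hilbert analytic signal). PLI is 0 for symmetric
phase-difference distributions — including identical, volume-conducted
signals, its main selling point — and 1 for a perfect constant-sign
lag. The PLI matrix is thresholded proportionally (keeping the
strongest s·N(N−1)/2 connections for sparsities s = 5%…40%) and each
binary graph is summarized by clustering coefficient C, characteristic
path length L (harmonic mean, so disconnected graphs stay finite),
global efficiency E_g, nodal/mean local efficiency NE_loc / E_loc, and
the normalized small-world indices

    γ = C / C_random,   λ = L / L_random,   σ = γ / λ,

where the null values come from degree-preserving Maslov–Sneppen
rewired references (σ > 1 ⇒ small-world topology). Range-averaged
metrics are compared between conditions with two-sample t-tests and
Cohen's d, including ROI aggregation of NE_loc by lobe and hemisphere.

Because studies of this design rarely deposit raw EEG, the package also
ships a **synthetic-EEG generator**: six mental-state coupling profiles
(resting, fatigue, attentive, inattentive, positive, negative) with
controllable per-band, per-region phase coupling, so the entire chain
runs — and is tested — end-to-end with known ground truth. It is aimed
at researchers prototyping EEG connectivity pipelines or teaching
network neuroscience methods.

## Worked example

Simulate a resting-vs-fatigue cohort (6 subjects per state, 30 s at
250 Hz), run the full chain in both bands, and compare the low-band
metrics:

```r
library(plinet)
cfg <- pipeline_config(profile_a = "resting", profile_b = "fatigue",
                       n_per_group = 6, duration = 30,
                       n_random_realizations = 5, seed = 42)
bundle <- run_pipeline(cfg)
subset(bundle$comparisons, band == "low",
       select = c(metric, mean_a, mean_b, t, p, d))
```

```
   metric mean_a mean_b       t      p       d
    sigma 1.0574 0.1126 16.5055 0.0000  9.5294
    gamma 1.1191 0.1135 15.3493 0.0000  8.8619
   lambda 1.0449 1.0122  4.7358 0.0008  2.7342
      E_g 0.4933 0.4881  0.7773 0.4550  0.4488
    E_loc 0.4167 0.0730 22.7196 0.0000 13.1172
  NE_left 0.6351 0.1524 21.7963 0.0000 12.5841
 NE_right 0.4822 0.0091 16.8270 0.0000  9.7151
```

Group `a` is resting, `b` is fatigue. The fatigued state's dense but
unstructured low-band coupling (mean PLI 0.51 vs 0.14 at rest) washes
out clustered topology, so its σ and γ drop sharply — the direction
such analyses report for fatigue — while raw global efficiency E_g
barely moves (proportional thresholding fixes the edge count, so E_g
reacts to topology, not density). Local efficiency and both
hemispheric NE_loc means collapse with the loss of ROI structure.
`run_pipeline(cfg, "out/")` additionally writes the condition-mean PLI
matrices, per-subject metric tables, the comparison table and a JSON
run manifest; with the same config and seed the outputs are
byte-identical.

Lower-level entry points: `generate_state_recording()`,
`process_recording()` (preprocess → band-pass → phase → PLI),
`threshold_by_sparsity()`, `sparsity_sweep()`, `random_reference()`,
`compare_conditions()`, `label_state()`.

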