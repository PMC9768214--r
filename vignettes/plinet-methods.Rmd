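---
title: "Methods: PLI functional brain networks and their small-world metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PLI functional brain networks and their small-world metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plinet)
```

## The analysis chain

`plinet` turns multichannel EEG into functional brain networks and
compares their topology between mental states. The chain is:

1. **Preprocess** — per-channel mean removal and a zero-phase 1–45 Hz
   broadband filter.
2. **Band-pass** — a low band pooling theta and alpha (4–13 Hz) and a
   high band covering beta (14–30 Hz). Delta is excluded by design: it
   is tied to sleep, deep anesthesia and pathology rather than task
   states.
3. **Instantaneous phase** — the analytic signal
   $\psi(t) = S(t) + i\tilde S(t)$ via the Hilbert transform;
   $\varphi(t) = \arg\psi(t)$, $A(t) = |\psi(t)|$.
4. **Connectivity** — the phase lag index between channels $n,m$:
   $\mathrm{PLI} = \left|\langle \operatorname{sign}\,
   \Delta\varphi(t)\rangle\right|$, with
   $\Delta\varphi = \varphi_n - \varphi_m$ wrapped to $(-\pi,\pi]$.
   PLI is 0 when the phase-difference distribution is symmetric around
   zero (including identical, volume-conducted signals) and 1 under a
   perfect constant-sign lag.
5. **Graphs** — proportional thresholding keeps the
   $\operatorname{round}(s\,N(N-1)/2)$ strongest connections at each
   sparsity $s$ in a 5–40% grid (5% steps).
6. **Metrics** — clustering coefficient $C$, characteristic path
   length $L$, global efficiency $E_g$, nodal and mean local efficiency
   $NE_{loc}, E_{loc}$, and the normalized indices
   $\gamma = C/C_{rand}$, $\lambda = L/L_{rand}$,
   $\sigma = \gamma/\lambda$ against degree-preserving rewired
   references. $\sigma > 1$ indicates small-world topology.
7. **Statistics** — per-subject metrics are averaged over the sparsity
   grid and compared between conditions with a pooled-variance
   two-sample t-test and Cohen's d.

## Numerical and design choices

**Filtering.** Both filters are zero-phase frequency-domain filters
whose gain is the squared magnitude response of an order-8 Butterworth
band-pass (what a forward–backward IIR pass realizes), applied to a
reflection-padded signal to suppress circular wrap-around. Order 8 keeps
a 10 Hz tone inside the 4–13 Hz band within 2% of its amplitude while
attenuating a tone one octave outside any edge by far more than 20 dB;
a lower-order response loses over 10% of in-band amplitude near the band
edge, which would bias connectivity toward mid-band rhythms. Zero phase
matters because PLI is built entirely from phase.

**Edges of the analytic transform.** The first and last second of each
recording are flagged and excluded from PLI: the FFT-based Hilbert
transform is unreliable there.

**Epoching.** PLI is estimated in contiguous 4 s epochs (≥ 16 cycles at
4 Hz) and averaged. The epoch mean of $|\langle\cdot\rangle|$ has a
known upward noise floor for uncoupled channels: a 4 s epoch of 4–13 Hz
activity carries only ~36 independent phase-difference samples, so the
expected epoch-mean PLI of independent channels is ≈ 0.12, while the
pooled estimate over 58 s is ≈ 0.03. Contrasts between conditions are
unaffected (the floor is common to all states), but absolute PLI values
close to 0.1 should be read against this floor. `pli_matrix(...,
epoch_length = NULL)` pools all samples instead.

**Path length on disconnected graphs.** At 5% sparsity a 30-node graph
is almost surely disconnected, so the default $L$ is the harmonic mean
$N(N-1)/\sum_{i\neq j} L_{ij}^{-1} = 1/E_g$, which stays finite by
letting disconnected pairs contribute zero. The arithmetic mean over
connected pairs is available via `method = "arithmetic"`; the two
disagree in general and the harmonic form is the one that makes the
5–40% sweep well defined everywhere.

**Random references.** Each reference is a Maslov–Sneppen rewiring
(double-edge swaps, 10 × |E| successful swaps) preserving the degree
sequence exactly; 20 realizations by default, explicitly seeded. Graphs
that admit no valid swap fall back to a density-matched Erdős–Rényi
draw with a warning. $\sigma$ is computed per sparsity and then
averaged over the grid.

**Edge-count rounding and ties.** The edge count is round-half-up of
$s\,N(N-1)/2$; ties at the weight cutoff break by lexicographic channel
order, so thresholding is deterministic and, for tie-free weights,
nested across the grid.

**Conventions.** $C_i = 0$ and $NE_{loc} = 0$ for nodes of degree < 2;
$\operatorname{sign}(0) = 0$, which makes self-PLI exactly 0.

**Statistics.** Pooled-variance (Student) t is the default, Welch via
`welch = TRUE`; no multiple-testing correction is applied by default,
mirroring how such metric panels are conventionally reported; tests are
unpaired. Cohen's d uses the pooled n−1-weighted standard deviation.

## The synthetic-EEG generator

No public EEG accompanies this analysis problem, so the package ships a
generator whose cohorts drive every downstream stage with known ground
truth. Each channel is a sum of band-limited sources plus white noise:

* a **global** source shared by all channels,
* a **left-ROI** source shared by {F3, F7, FC1, FC5, C3, T7},
* a **right-ROI** source shared by {F4, F8, FC2, FC6, C4, T8},
* a **frontal–occipital** source shared by those two lobes,
* an independent per-channel oscillator.

Every channel receives its group sources with a fixed channel-specific
phase offset, golden-ratio-scrambled over [0.45, 2.7] rad. The offsets
make the shared component appear with a *non-zero constant lag* in each
pair — necessary because PLI is blind to zero-lag coupling — and the
scrambling decorrelates the offset difference of a pair from its class,
so no pair class is structurally favored. Source amplitudes follow
$a = \sqrt{c}$ increments of the profile's class couplings $c$; the
square root keeps weak couplings above the PLI noise floor while
preserving the class ordering, and additive increments guarantee that a
pair's total shared amplitude is monotone in its class coupling.

The six shipped profiles encode the qualitative contrasts the evoked
states are known for: *fatigue* has dense global low-band coupling;
*attentive* strengthens frontal–occipital coupling; *inattentive* is
weakly coupled throughout; *positive*/*negative* flip right/left
hemispheric dominance; *resting* has moderate, ROI-structured coupling.
The coupling magnitudes themselves are package calibration constants —
the source analyses report these contrasts only qualitatively
("denser", "sparser") — chosen once so that (i) the low-band mean PLI
of fatigue exceeds resting by > 0.1, (ii) class-mean PLI ranks exactly
like each profile's couplings at 60 s, and (iii) the hemispheric
asymmetry of the positive/negative profiles is recovered in ≥ 90% of
seeds. Defaults: 250 Hz sampling (a parameter; tests need no more), 30
channels in a standard 10–20 montage, unit-relative broadband noise.

What the generator does **not** emulate: volume conduction and a
forward head model (shared sources stand in for cortical coupling
directly), ocular/muscle artifacts, 1/f background spectra beyond the
two analysis bands, non-stationarity within a recording, and inter-
subject anatomical variability. Passing tests therefore demonstrate
that the *pipeline* recovers known coupling structure, not that it is
robust to every pathology of real scalp EEG.

## Verified properties and problem sizes

The test suite verifies, among others (sizes are package choices that
keep the suite fast while leaving each property well-powered):

* PLI boundary cases exactly (constant lag → 1, zero lag → 0) through
  the full signal chain, and the $3/\sqrt{n}$ bound for uniform phase
  differences;
* graph metrics against brute-force triangle-enumeration and
  Floyd–Warshall oracles (100 random graphs, N ≤ 12, 1e-10) and against
  igraph;
* Watts–Strogatz graphs (N = 30, k = 4, p = 0.1) yield σ > 1 in ≥ 95%
  of 100 seeds, and matched Erdős–Rényi graphs a mean σ within 10% of
  1, under 20 rewired references;
* the full chain's type-I error at α = 0.05 over 200 null cohorts
  (two groups of 13 drawn from the same profile, 20 s recordings, low
  band, 8-point sparsity grid) lies in [0.01, 0.10] — run without
  random-reference normalization, which under the null affects no
  rejection decision, on the range-averaged global efficiency;
* the shipped fatigue-vs-resting σ contrast and the positive-vs-negative
  hemispheric NE_loc contrast are recovered with the correct sign in
  ≥ 90% of 20 seeds at 13 subjects per group (20 s recordings, 5
  rewired references for σ);
* state labeling is total, deterministic and first-match over all
  5^6 = 15,625 subjective-scale vectors.

## Known limitations

* Synthetic σ values sit near or below 1 for most shipped profiles: the
  phase-offset geometry of the generator does not produce strongly
  clustered graphs, so σ contrasts between states are meaningful while
  absolute σ levels are not representative of cortical networks.
* The epoch-mean PLI noise floor (above) biases weak connectivity
  upward; use pooled estimation for absolute density statements.
* Recordings shorter than ~6 s leave no usable epoch after edge
  exclusion with the defaults.
* EDF input is not supported; recordings are CSV + JSON sidecar.
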