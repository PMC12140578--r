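---
title: "Alpha-band imaginary-coherence networks and divergent-thinking scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alpha-band imaginary-coherence networks and divergent-thinking scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icnet)
```

## The analysis problem

Noninvasive brain stimulation studies of creativity ask whether a
stimulation-induced change in behavior is accompanied by a change in
large-scale cortical communication. `icnet` implements one complete analysis
chain for this question in a within-subject crossover design: every subject
is recorded at rest before and after stimulation, once under active
stimulation (tRNS over the bilateral dorsolateral prefrontal cortex) and once
under sham, while performing two verbal divergent-thinking tasks — the
alternative-uses task (AUT) and the associative-fluency task (AFT).

The chain is:

1. **Signal conditioning** — zero-phase band-pass filtering, average
   referencing, segmentation of eyes-closed stretches.
2. **Spectral estimation** — Welch-averaged auto- and cross-spectra
   (1 s Hann windows, 50% overlap, 1 Hz resolution).
3. **Connectivity** — imaginary coherence per scout pair, averaged over the
   alpha band (8–12 Hz inclusive).
4. **Network metrics** — weighted node degree (wND), z-normalisation over
   the 62 scouts, frontal-region averaging, and the difference-of-differences
   change score `(post − pre)_tRNS − (post − pre)_sham`.
5. **Statistics** — baseline paired t-tests, edge-wise sign-flip permutation
   t-tests with Benjamini–Hochberg FDR, and backward-elimination regressions
   of the frontal wND change on the behavioral change scores.
6. **Behavioral scoring** — fluency, originality by statistical infrequency,
   and flexibility from word-embedding distances.

A synthetic-data module generates scout-level recordings and verbal-response
tables with known ground truth, so every downstream stage is testable without
any recorded data.

## Imaginary coherence

For scouts $x$ and $y$ with auto-spectra $S_{xx}(f)$, $S_{yy}(f)$ and
cross-spectrum $S_{xy}(f)$, the package computes

$$\mathrm{IC}_{xy}(f) \;=\; \left|\,\mathrm{Im}\!\left(
  \frac{S_{xy}(f)}{\sqrt{S_{xx}(f)\,S_{yy}(f)}}\right)\right| \in [0, 1].$$

The quantity inside the absolute value is the imaginary part of coherency.
An instantaneous (zero-lag, real) mixture of sources — the volume-conduction
/ source-leakage confound — produces a purely *real* coherency, so nonzero
IC cannot be explained by mixing alone. This is the property the synthetic
generator exercises explicitly: its leakage matrix applies exactly such a
zero-lag mixture, and the packaged tests verify that mixed-but-independent
sources stay below a surrogate-derived noise ceiling.

Finite data give positively biased IC estimates (order $1/\sqrt{n_\mathrm{windows}}$),
so the package never interprets raw IC against zero. Instead
`ic_noise_ceiling()` simulates independent white-noise pairs *through the
same Welch/IC path at the same data length* and returns a quantile of that
null distribution.

Band aggregation averages per-frequency IC over the inclusive 8–12 Hz bins
(five bins at 1 Hz resolution), taking the absolute value per bin *before*
averaging. The alternative — coherence of band-averaged spectra — is not
used because IC is defined per frequency and in [0, 1] per bin.

## Network metrics and change scores

The weighted node degree of scout $i$ is the row sum
$w_i = \sum_{j \ne i} \mathrm{IC}_{ij}$ of the zero-diagonal band-IC matrix.
wND values are z-scored across scouts — the sample standard deviation
($n-1$) is used; the choice is documented because the convention is
otherwise ambiguous — and region values are unweighted means of the
*z-scores* (z first, then averaging). All-equal wND is a degenerate input:
`z_normalize()` raises a typed error and the pipeline records missing
values.

The packaged atlas emulates a 62-scout cortical parcellation (31 regions per
hemisphere). The frontal region sets include all frontal-lobe scouts of a
hemisphere — motor and orbitofrontal scouts included — because the
stimulation montage plausibly affects the whole frontal lobe; the membership
ships as an editable JSON file, not code, since reasonable alternatives
(e.g. excluding orbitofrontal scouts) exist.

An important numerical property, found while characterising the synthetic
generator: because the z-transform renormalises by the across-scout spread,
the region-mean z response to a *focal* increase in coupling saturates — as
the injected effect grows, the z-pattern approaches a fixed shape and the
region mean stops growing. Recovery of *between-subject* effect-magnitude
differences is therefore best in the small-to-moderate coupling regime; the
packaged brain–behavior recovery simulations inject deltas around 0.2 for
this reason, while pure edge-detection simulations use 0.4.

## Permutation statistics

Edge-wise inference uses the paired t statistic on the per-subject
difference of condition deltas, with a sign-flip permutation null: each
permutation flips the sign of whole subjects' difference vectors, with flips
shared across all 1891 edges so the edge correlation structure is preserved.
This is the exact exchangeability scheme for a paired design under the null
of no condition effect. The Monte-Carlo p-value uses the +1 correction
$p = (1 + \#\{|t^*| \ge |t|\}) / (1 + n_\mathrm{perm})$ so p-values are
always positive and valid; 5000 draws is the reference default.
Benjamini–Hochberg FDR is applied across all edges (the
Benjamini–Yekutieli variant is available by flag); whether the original
analysis corrected over all edges or a subset is unstated, so all-edges is
the default and documented here.

## Behavioral scoring

Answers are casefolded, punctuation-stripped and whitespace-collapsed; no
stemming is applied (German-safe). Scoring then distinguishes three
measures, each computed per item and averaged over the session's three
items:

* **Fluency** — the number of valid answers: distinct after normalization,
  and for the AUT also excluding the prompt's stated common use. The precise
  validity norms of the original scoring manual are not enumerated in the
  source material, so the predicate is deliberately small and configurable.
* **Originality** — statistical infrequency: one minus the answer's relative
  frequency in the pool of all valid answers for that item across all
  participants and both sessions, after synonym canonicalization. The
  inversion `1 − rel_freq` (rather than, say, `max_count − count`) keeps
  scores in [0, 1]; a unique answer in a pool of $N$ scores $1 - 1/N$, a
  universal answer scores 0.
* **Flexibility** — the mean pairwise cosine distance among the distinct
  canonical answer vectors of a response set; synonymous answers share one
  vector and contribute once. A consecutive-pair variant is available since
  the exact formula of the referenced embedding-based scorer is not
  reproduced in the source; the pairwise mean is the common
  operationalization and the default. Multi-word answers fall back to the
  mean of in-vocabulary word vectors; fully out-of-vocabulary answers are
  excluded from flexibility (but kept for fluency and originality).

## The synthetic generator

`gen_scout_signals()` realises oscillators as band-pass-filtered noise
carriers: a coupled pair shares one narrowband carrier, with the second
scout receiving a phase-shifted copy constructed from the analytic signal.
This gives direct, exact control of the phase lag — the quantity imaginary
coherence detects — which coupled-ODE oscillator models do not. Leakage is a
fixed dense instantaneous mixing matrix applied after coupling
(`leakage_matrix()`, off-diagonal weights uniform in [0.05, 0.30] by
default), i.e. precisely the confound IC is claimed to reject. The eye-state
track alternates 35 s open/closed blocks, mirroring the acquisition protocol
the pipeline targets; short recordings (shorter than one block) are marked
fully closed so that reduced-size simulations remain analysable.

`gen_study()` produces the 2 × 2 crossover (40 subjects by default, 5 min
recordings at 250 Hz scaled down in tests), perturbing only the tRNS-post
cell by the design's effect edges. Each subject's injected delta is the
nominal delta times a subject factor (normal, mean 1, configurable sd,
truncated at 0.1): this between-subject spread is what makes brain–behavior
coupling identifiable.

`gen_behavior()` samples ordered answers from a long-tailed (Zipf) per-item
vocabulary. The subject's latent behavioral effect is a mixing weight
between the standardized injected connectivity magnitude and independent
noise (`behavior_link` 0 = pure noise, 1 = deterministic). In the tRNS
session the sampling weights are tempered — raised to an exponent below 1 in
proportion to the latent effect — which pushes answers into the long tail
and raises scored originality; embeddings are built so that frequent answers
cluster near an item-specific center while tail answers disperse, so
flexibility rises too. Fluency is left null by design (the same answer-count
distribution in both conditions) and serves as the negative control in the
regression recovery tests. What the generator does *not* emulate: realistic
head geometry or channel-level acquisition, 1/f spectra and non-stationarity
of real EEG, semantic structure of real answer corpora, or rater-based
scoring — passing tests demonstrate internal consistency of the estimators
and the recovery of injected effects, not performance on recorded data.

## Problem sizes used in the packaged simulations

The distributional tests run at deliberately reduced size, chosen as the
smallest instances that still exercise every stage: null calibration uses
500 replicate studies of 12 subjects × 10 scouts × 10 s at 64 Hz with 500
permutation draws; edge recovery uses 20 replicates of 40 subjects × 16
scouts × 16 s; brain–behavior recovery uses 20 replicates of 40 subjects ×
16 scouts × 48 s at 50 Hz (longer recordings because the regression needs
low-noise per-subject estimates, lower rate because the window count — not
the sampling rate — sets the estimator's precision). Full-scale geometry
(62 scouts, 250 Hz, 5 min) is used wherever a single recording suffices.

## Numerical and design choices

* Zero-phase (forward–backward Butterworth) filtering, because phase
  distortion would corrupt the pipeline's core quantity; the passband
  contract (±1 dB at band center, ≥ 20 dB one octave outside) is asserted on
  the realized response in the tests.
* Welch taper: Hann; detrend: per-window mean removal. Both are unstated in
  the reference analysis; they are the defaults of the toolchain it used.
* A 1 s guard is trimmed from each eye-state segment boundary (configurable)
  to suppress transition artifacts; segments shorter than one window are
  dropped with a warning. Eyes-closed segments are treated as separate
  epochs whose windows are pooled — whether the original analysis
  concatenated them is unstated; pooling avoids spurious coherence across
  segment joins.
* Backward elimination removes the predictor with the largest p-value while
  it exceeds 0.10 (configurable; `removal_p = 1` keeps the full model,
  `0` reduces to intercept-only). Standardized coefficients are
  `B · sd(x)/sd(y)`, equal to the slopes on z-scored variables.
* Monte-Carlo seeds: every stochastic function takes an explicit seed;
  a study design's master seed derives all per-recording seeds, so equal
  seeds reproduce a dataset bit for bit.

## Known limitations

* The pipeline starts from clean scout-level signals: no artifact handling,
  source estimation or forward modeling is included, by scope.
* The surrogate noise ceiling assumes stationary signals with matched data
  length; strongly non-stationary data would need segment-matched
  surrogates.
* Statistical-infrequency originality is unstable in small samples — rare
  answers are overestimated; scores from pools of tens of participants
  should be interpreted comparatively, not absolutely.
* The BH step-up map is not idempotent; adjusted p-values are reported once
  and never re-adjusted.
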