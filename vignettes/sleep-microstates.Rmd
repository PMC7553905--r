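---
title: "EEG microstates in sleep and wake: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG microstates in sleep and wake: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepstates)
```

## The model

Multichannel EEG does not wander continuously through topography space:
over stretches of roughly 50–100 ms the scalp potential map stays
quasi-stable, then switches abruptly to another configuration.  These
*microstates* are summarized by a small set of template maps plus, per
recording, the temporal statistics of their alternation.  `sleepstates`
implements the complete analysis chain for a paired two-condition design
(e.g. NREM sleep vs. resting wake, or dream-experience vs. no-experience
awakenings within sleep):

1. **Preprocessing** — zero-phase 1–50 Hz band-pass, downsampling,
   spherical-spline interpolation of bad channels, common average
   reference, extraction of fixed-length (typically 30 s) epochs.
2. **Clustering** — maps at local maxima of the Global Field Power (the
   spatial SD across channels; its peaks are the moments of highest
   topographic signal-to-noise) are clustered by a *polarity-invariant*
   modified k-means, first within subject, then across subjects on the
   pooled subject templates.
3. **Choice of K** — seven cluster-validity criteria are evaluated over a
   K range and merged into a *meta-criterion*: the median of the
   per-criterion optima.
4. **Back-fitting** — every sample is labelled with the template of
   highest absolute spatial correlation (winner-takes-all), yielding per
   map the global explained variance (GEV), mean duration, occurrence and
   coverage.
5. **Spectral profile** — Morlet-wavelet power, averaged over the samples
   of each microstate and over channels, summarized in the canonical
   Delta (1–4), Theta (4.5–8), Alpha (8.5–12), Beta (12.5–25) and Gamma
   (25.5–40 Hz) bands.
6. **Statistics** — 2×K fully-within-subject ANOVA with unconditional
   Greenhouse–Geisser correction and partial η², Bonferroni post-hocs, and
   paired sign-flip randomization tests.
7. **Sources** — a generic distributed linear inverse (weighted minimum
   norm) on a user-supplied or toy lead field, per-point temporal
   standardization, per-microstate averaging, 95th-percentile masking and
   voxelwise paired randomization.

Polarity is ignored throughout (`|spatial correlation|` everywhere):
topographies of opposite sign arise from oscillation of the same
generators, so a map and its negation are the same microstate.

## Why the synthetic generator is first-class

No suitable human sleep data set is bundled; instead the package carries a
generator whose planted ground truth makes every stage testable.
`simulate_recording()` emits, per epoch, a semi-Markov state sequence:
segment durations are gamma distributed (shape 2 by default, truncated at
2 samples — a right-skewed distribution consistent with sub-second
microstate phenomenology; nothing in the package depends on this being the
true duration law, and it is configurable), and segment states follow a
jump chain with uniform off-diagonal structure,
\(Q_{ij} = \pi_j / (1-\pi_i)\).  That chain's stationary distribution is
*not* \(\pi\) in general, so the per-state mean durations are scaled as
\(d_i = \bar d\,\pi_i/\nu_i\) (with \(\nu\) the jump chain's stationary
vector), which makes the long-run time coverage exactly the requested
\(\pi\) and keeps the segment-weighted mean duration exactly \(\bar d\).
Within a segment the data are `template × carrier × ±1 + noise`: the
carrier is band-limited noise (band-pass-filtered white noise, unit RMS;
a pure-tone mode exists for analytic tests), the per-segment sign models
polarity inversions, and spatially white sensor noise is scaled so that
RMS(signal)/RMS(noise) equals the configured `snr` (linear amplitude
ratio; 6 dB ≡ 2).

`simulate_group()` adds the two features group inference needs: exact
inter-subject topography jitter (each subject map is the group map plus an
orthogonal unit perturbation weighted to hit a target correlation, 0.9 by
default) and an exact planted coverage shift between conditions
(±Δ/2 on designated maps, so condition differences are +Δ and −Δ by
construction — the classic double dissociation plants +Δ on map 3 and −Δ
on map 4).

What the generator does *not* emulate: spatially correlated sensor noise,
1/f background spectra, sleep graphoelements (spindles, K-complexes),
artifacts, or electrode-position error.  Passing tests therefore show the
*algorithms* are correct on data obeying the microstate model, not that
the model fits any particular recording.

## Numerical and design choices

* **Modified k-means update.**  Each template is the dominant eigenvector
  of \(\sum_t x_t x_t^\top\) over its assigned (average-referenced,
  raw-amplitude) maps.  Using raw amplitudes means each update maximizes
  the cluster's GEV (the maps' squared GFP enters as the weight), so total
  GEV is non-decreasing over iterations — asserted in tests.  The sign of
  the eigenvector is canonicalized (largest-magnitude entry positive) for
  determinism; it is meaningless for the model.  Defaults: 100 restarts,
  tolerance 1e-6 on GEV, all seeds explicit; empty clusters are reseeded
  from the worst-fitting map.
* **Validity-criterion variants.**  The seven criteria exist in many
  variants; the package fixes: Goodman–Kruskal Γ on all
  (within, between) pair combinations with ties counted for neither;
  Rousseeuw silhouettes (singletons contribute 0); Davies–Bouldin with
  centroid = cluster template; Milligan–Cooper point-biserial;
  Dunn = single-linkage separation over complete-linkage diameter;
  Krzanowski–Lai with W = summed squared dissimilarities to the cluster
  template (defined only at interior K of the tested grid); and a
  predictive-residual cross-validation criterion
  \(\sigma^2\,((C-1)/(C-K-1))^2\), undefined when \(K \ge C-1\).  All
  criteria operate on the polarity-invariant metric
  \(d = \sqrt{2(1-|r|)}\).  Every variant is pinned by a brute-force
  oracle test at 1e-8.
* **Meta-criterion median rule.**  For an even number of available optima
  the *lower* middle value is used: it is always an actually-attained K
  and biases toward parsimony.
* **Filtering.**  The band-pass is a 4th-order Butterworth applied
  forward–backward (zero phase, so topographies are not distorted), per
  epoch to prevent bleed across concatenation boundaries; provenance of
  the choice lives here rather than in any claim about how the original
  recordings were filtered.  Downsampling requires an integer rate ratio
  and applies an 8th-order zero-phase anti-alias low-pass at 80% of the
  target Nyquist.
* **Spherical splines.**  Perrin-type interpolation with order m = 4,
  Legendre series to degree 50, and 1e-5 Tikhonov regularization; an
  all-one-hemisphere good-channel set triggers a warning and a
  regularized solve.
* **Wavelet convention.**  The mother wavelet is specified by its
  time-domain FWHM at 1 Hz (default 3 s) and scales as 1/f.  Power is
  normalized so a unit sinusoid yields its RMS power (0.5) at its own
  frequency bin.  Samples within FWHM/2 of an epoch edge are excluded
  per frequency from band-power summaries (exclusion, not mirroring, to
  avoid biasing label-conditioned averages).
* **Wavelet resolution vs. state duration.**  A carrier band can only be
  attributed to a state whose segments are long relative to the wavelet
  width at that band's frequencies: an 80 ms segment holds less than half
  a delta cycle, and the 1–4 Hz wavelets integrate over seconds, so
  band-specific contrasts between 80 ms states are physically smeared.
  The spectral-attribution tests therefore plant 1000 ms states; this is
  a resolution statement about time–frequency analysis, not a tuning of
  the generator defaults (which stay at 80 ms).
* **ANOVA.**  Direct sums-of-squares decomposition for the balanced
  fully-within 2×K design; Greenhouse–Geisser ε from the covariance of
  orthonormalized effect scores, applied unconditionally (no
  data-dependent sphericity gate); both p values are reported.  Because
  unconditional GG is deliberately conservative when sphericity actually
  holds, the null-calibration test measures the type-I error of the
  *uncorrected* interaction test, which is exact under the simulated
  exchangeable null (measured ≈ 0.048); the GG-corrected rate under the
  same null is ≈ 0.034, i.e. conservative, as intended.  Results are
  cross-checked against an independent general-purpose implementation
  (`car::Anova`) in the test suite.
* **Randomization tests.**  Sign-flip null on paired differences;
  exhaustive enumeration when \(2^n \le 4096\) (exact proportion,
  computed with the same summation order as the observed statistic so
  tie patterns compare bit-exactly), otherwise seeded Monte-Carlo with the
  add-one estimator \((c+1)/(N+1)\) so p is never 0.
* **Inverse solution.**  The operator is a generic weighted minimum norm
  \(W L^\top (L W L^\top + \lambda I)^{-1}\) with depth weighting
  (per-point column-norm normalization) by default and an optional
  nearest-neighbour smoothness weighting as a local-autoregressive-style
  surrogate; results are labelled generic distributed inverse.  λ defaults
  to \(\mathrm{tr}(LWL^\top)/(C\,\mathrm{snr}^2)\) with snr = 3.  Current
  density is summarized by the moment-vector norm (polarity-free).
  Percentile masking uses a strictly-above tie convention, so an
  all-equal map yields an empty mask.
* **Toy lead field.**  Homogeneous single conducting sphere, evaluated by
  the classical Legendre-series expansion truncated at degree 300
  (accurate for source radii ≤ 0.9).  A source at the exact centre has no
  radial direction; it is emitted as zero gain and flagged degenerate
  rather than given the analytic centre limit, keeping degenerate
  geometry out of every downstream computation.
* **Coordinates.**  All on-disk formats use 0-based, half-open sample
  intervals; channel positions are unit-sphere 3-D coordinates.

## Problem sizes used in validation

The end-to-end checks run on desk-scale instances chosen as the smallest
at which the properties are stable: 64 channels (instead of 256), 20
subjects, 8–20 s of data per recording at 100–250 Hz, 2–12 tested K, and
20 seeded replicates for rate-style claims.  Under those conditions the
pipeline recovers planted group templates at mean |r| ≈ 0.99 (SNR 6 dB),
the meta-criterion returns the planted K = 5 in ≈ 90% of runs, back-fit
label accuracy is ≈ 92%, and the planted ±0.10 coverage double
dissociation yields a significant condition×map interaction with correct
post-hoc directions in 20/20 replicates.  `scripts/acceptance.R`
recomputes all of these from scratch.

## Known limitations

* ICA-based artifact removal and sleep staging are out of scope; an
  epoch-level artifact mask (choosing which epochs to extract) is the
  supported substitute.
* The EDF reader handles continuous 16-bit recordings with one sampling
  rate; the delimited dialect is the bit-exact interchange format.
* Back-fitting labels every sample by default; optional
  minimum-correlation rejection exists but temporal smoothing /
  minimum-duration merging is not implemented.
* The meta-criterion inherits the variance of its seven constituents at
  low SNR or short recordings; with very fragmented data several criteria
  drift toward larger K.
* Source results depend entirely on the supplied lead field; with the toy
  sphere they validate the *estimator*, not any anatomical claim.
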