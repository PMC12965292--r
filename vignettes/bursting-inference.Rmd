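---
title: "Inferring promoter bursting kinetics from MS2/MCP traces"
author: "ms2burst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring promoter bursting kinetics from MS2/MCP traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ms2burst)
```

## The problem

The MS2/MCP reporter makes nascent transcription visible in living tissue: an
array of RNA stem-loops inserted into a gene's transcription unit is bound
co-transcriptionally by a fluorescent coat protein, so every engaged RNA
polymerase II contributes a quantum of fluorescence at the transcription site
for as long as its transcript remains there. A per-nucleus fluorescence trace
is therefore a noisy, kernel-smeared readout of the underlying sequence of
Pol II initiation events, and those events in turn reflect the switching of
the promoter between transcriptionally competent and silent states.

`ms2burst` implements the full quantitative chain for Notch-target genes
imaged in *Drosophila* follicle cells: trace quality control and
segmentation, absolute calibration of fluorescence to mRNA counts against
smFISH, deconvolution of calibrated traces into discrete initiation events,
multi-exponential survival analysis of inter-initiation waiting times with
promoter-state model selection and rate inversion, and quantification of
coactivator (Mastermind) hub enrichment and its temporal relationship to
transcription. Because the study's raw imaging data are not deposited, the
package also contains a first-class synthetic-data module that generates
every input with known ground truth; all tests and the acceptance analysis
run against it.

## The promoter model

The core model is a nonsequential three-state continuous-time Markov chain:
one ON state and two OFF states, each connected to ON only
(ON &harr; OFF1, ON &harr; OFF2). Five rates parameterize it:

* `k_ini` — Pol II initiations per second while ON;
* `k1_minus`, `k1_plus` — entry to and exit from the short-lived OFF1;
* `k2_minus`, `k2_plus` — entry to and exit from the long-lived OFF2.

Mean OFF dwell times are `1/k1_plus` and `1/k2_plus`, and the stationary ON
probability is `p_on = 1 / (1 + k1_minus/k1_plus + k2_minus/k2_plus)`. The
sequential alternative (ON &harr; OFF1 &harr; OFF2) is exposed by the
simulator's rate parameterization but is not an inversion target: it implies
a mechanistic coupling between the two silent states for which there is no
independent support.

Treating initiation as absorption gives the waiting time between successive
initiations a phase-type law: with `Q` the 3x3 sub-generator on
(ON, OFF1, OFF2) and absorption at rate `k_ini` from ON,
`S(t) = e_ON' exp(Qt) 1 = A1 e^{l1 t} + A2 e^{l2 t} + A3 e^{l3 t}`,
with `sum(A_i) = 1` and `l_i < 0`. `phase_type_survival()` computes this
closed form by eigen-decomposition; `infer_kinetics()` inverts it using five
moment and characteristic-polynomial identities (the constraint
`sum(A_i) = 1` leaves exactly five free fitted quantities, matching the five
rates), and reports infeasibility when no nonnegative-rate solution exists.
The mean waiting time obeys `E[tau] = 1 / (p_on * k_ini)`, the identity used
for the steady-state check.

### Default kinetic regime

`default_kinetics()` encodes the regime characteristic of these promoters:
OFF dwell times of about 6 s and 145 s, `k_ini = 0.25 /s`, and ON-exit rates
(`k1_minus = 0.15`, `k2_minus = 0.01`) chosen once so that active periods
show bursty fine structure, a stationary ON probability near 0.3, and peak
nascent-transcript counts in the mid-30s — consistent with a detection floor
of three molecules and a maximum of ~35 RNAs at the height of activity.

## Synthetic data

`simulate_promoter_path()` is an exact Gillespie simulation (exponential
sojourns, competing exits from ON); `sample_initiations()` adds a Poisson
process at `k_ini` restricted to ON segments. `render_ms2_trace()` convolves
events with a single-polymerase kernel: zero until the polymerase reaches
the loop cassette, a linear ramp to exactly one molecule-equivalent while
the cassette is transcribed, a plateau through the remaining gene body plus
a terminal retention time, then release. Two presets place the cassette near
the transcription start (`"loops-near-TSS"`) or near the 3' end
(`"loops-near-3p"`); elongation rate (45 bp/s) and retention (30 s) are
modelling assumptions with no claim of measurement. Noise is additive
Gaussian on traces (detection-limited imaging) and multiplicative log-normal
on smFISH spot intensities (median-preserving, so the single-molecule
calibration stays centered).

Hub traces are generated as a zero-phase (forward-backward) exponentially
smoothed transform of the ON indicator, advanced by `lead_lag_s` (default
120 s) — the simplest mechanism that makes hub changes precede transcription
while remaining exactly recoverable: one-sided smoothing would add its own
filter delay to the planted lead. Correlating a hub trace against a rendered
MS2 trace shows an extra 2–3 frames of delay beyond the planted lead,
contributed by the reporter's transcription and retention times; the planted
value is recovered exactly against the promoter-activity indicator.

Image scenes plant a Gaussian locus spot whose integrated intensity is
scaled so that the mean of the 30x30-pixel quantification ROI equals
`fold_enrichment x background` exactly, making the planted fold the ground
truth for `roi_enrichment()`. Nuclei are drawn much larger than the ROI so
that locus and reference ROIs fit fully inside the nuclear mask; random
reference ROIs additionally exclude a margin around the locus so they are
free of spot signal. What the generator does *not* emulate: photobleaching,
blinking, 3D point-spread functions, nuclear movement, or segmentation and
tracking errors — so green tests demonstrate correctness of the analysis
chain, not robustness to those upstream artifacts.

## Trace processing rules

The QC and segmentation rules are boundary-exact and tested against a
brute-force run-length oracle:

* tracks kept only with **more than five** detected frames (>= 6) and no
  internal gap of more than two frames; traces that begin with their
  nucleus track or end at its last frame are dropped as boundary-censored;
* gaps of **fewer than five** missing frames (<= 4) inside active stretches
  are filled with the mean of the flanking frames;
* ON runs separated by **fewer than 21** OFF frames (<= 20, ~7 min at 20-s
  frames) merge into one active period; durations are quoted only for
  periods flanked by inactivity on both sides, and inactive periods only
  between two active ones;
* the proportion of active nuclei is the fraction whose first onset falls
  in each 5-min bin over at most 60 min; onset-aligned averages assign 0
  after a trace ends, with all traces in the SEM denominator.

Frames are 0-based and periods half-open `[start, end)`. The ON-call
threshold defaults to 3 molecule-equivalents (the detection floor); it is a
configuration value, not a measured constant.

## Calibration

The single-molecule intensity is the median of thresholded smFISH spot
intensities; ATS counts are total intensity divided by that unit. MS2
arbitrary units are related to molecule counts by quantile–quantile
matching: both samples are reduced to `min(n1, n2)` equally spaced
quantiles (linear interpolation between order statistics) and an ordinary
least-squares line is fitted. Samples from multiple genes are pooled into
one fit, since the relationship is reporter- not gene-specific. Calibrated
counts are floored at zero and flagged below the three-molecule detection
floor.

## Deconvolution

`deconvolve()` seeks the set of unit-amplitude initiation events whose
rendered trace minimizes the squared residual. The search is greedy matching
pursuit with local refinement (each event re-placed at its best candidate
time; events that stop paying for themselves are dropped); on traces of up
to 30 frames with up to 3 events it attains the exhaustive-search optimum,
which is the tested contract. Placement stops when the best single-event
residual reduction falls below `2 x noise_sd x ||kernel||`.

Two numerical choices matter at 20-s sampling:

* **Placement grid.** Candidate times subdivide the frame interval by
  `grid_oversample = 2`. The loop-cassette ramp spans ~1.5 frames, so
  inter-frame increments localize an event to about half a frame but no
  further; a finer grid invents unsupported structure, while whole-frame
  placement quantizes waiting times to the frame interval.
* **Within-cell dispersal.** Sub-cell timing is unidentifiable, and events
  sharing a cell would otherwise produce spurious zero waits. Each event
  therefore receives a seeded uniform offset within its cell — the
  conditional law of Poisson arrivals given cell counts. This is why the
  deconvolution is deterministic *given a seed*.

## Survival analysis and model selection

Waiting times are collected within active periods only (no cross-period
intervals, no censoring model; boundary intervals are simply excluded). The
empirical survival is the product-limit estimate with pointwise Greenwood
variance and normal 95% bands clipped to [0, 1]; at the largest wait the
estimate is exactly zero and the variance undefined, so that step is
excluded from band-coverage judgments.

Bi- and triexponential models `S(t) = sum(A_i e^{l_i t})` with
`sum(A_i) = 1`, `l_i < 0` are fitted by Levenberg–Marquardt on the mean
squared deviation, initialized by a cumulative-integral linear solve (a sum
of n exponentials satisfies an n-th order linear ODE; n-fold integration
converts rate estimation into one least-squares problem whose
characteristic-polynomial roots are the rates). Each candidate is also
started from the previous candidate's fit plus a small fast component,
keeping the lower-MSD *physically interpretable* result (survival
nonincreasing, nonnegative amplitudes), which enforces MSD nesting without
letting degenerate local minima displace invertible fits.

Model selection takes the smallest candidate passing two gates: the fitted
curve must lie within the pointwise Greenwood band, and the
Kolmogorov–Smirnov test (computed with fitted parameters, hence an
approximate p-value) must not reject at `alpha = 0.05`, with MSD as the
tie-break. On the band gate: with a thousand or more distinct waits, even
the true model is expected to exit a pointwise 95% band at isolated steps,
so a literal every-step requirement rejects every model at realistic sample
sizes. The default `ci_fraction = 0.98` requires coverage at 98% of defined
steps — far above the ~93–95% typical of an underspecified biexponential
fit in this regime, and robust to isolated excursions; `ci_fraction = 1`
restores the literal reading.

The steady-state check estimates the mean inter-initiation interval in
sliding 4-frame (80-s) windows with bootstrap percentile intervals, and
calls the kinetics stable when the confidence interval of the trend slope
contains zero. The *pooled* interval (all waits, not window-truncated) is
the estimator compared against `1/(p_on * k_ini)`: window truncation would
systematically discard the rare long waits that carry a quarter of the
mean.

## Hub quantification and correlation

Enrichment is the locus-ROI pixel mean over the mean of random ROIs placed
fully inside the same nuclei, making the measure exactly 1 on uniform
nuclei and invariant to global intensity scaling. ATS counting thresholds
within nuclear masks, keeps at most the brightest connected component per
nucleus, and divides by the number of masks. Focus pairing is
mutual-nearest-neighbor within 1 um. Cross-correlation is Pearson
correlation of overlapping segments at integer-frame lags (no zero
padding — traces are tens of frames long), mean-subtracted by construction,
with the documented sign convention that a negative peak lag means the hub
leads transcription; r² is reported alongside signed r, whose sign
disambiguates the lead direction. The secondary-peak threshold in
autocorrelation is `3/sqrt(n)`. Detrending before correlation is off by
default (mean subtraction only) and available as an option.

## Problem sizes and verification

The test suite and the acceptance analysis use: 50 traces x 60 min at 20-s
frames for end-to-end parameter recovery (about 12,000 waits); 20 seeded
replicates of ~2,000 generator waits for model-selection frequency; 10^5
nuclei for the two-allele detection ratio; and 320x320-pixel scenes with
four nuclei for enrichment recovery. Under those conditions the pipeline
recovers `k_ini` within ~10–15%, the initiation flux `p_on * k_ini` within
~5% by the pooled-interval route (and within ~25% through the full fit
inversion), selects three states in >= 80% of replicates without
over-selecting on Poisson data, recovers planted correlation lags exactly
(and within one frame at signal-to-noise 5), and recovers planted image
fold-enrichments within 10%.

## Known limitations

* The slow OFF dwell time (`1/k2_plus`) is the least identifiable quantity
  from one-hour traces: few waits visit the long OFF state, and
  deconvolution blurs the tail, so its point estimate can be off severalfold
  even when `k_ini` and the initiation flux are accurate.
* Sub-frame event timing is imputed, not measured; the short-wait portion
  of the survival curve inherits the dispersal assumption.
* The KS p-value uses fitted parameters and is therefore anti-conservative;
  it is one of two gates, not a calibrated test.
* Calibration assumes a common linear intensity–count relationship across
  genes; a gene-specific departure would bias absolute counts but not the
  kinetic shape analysis.
* The image module quantifies a single z-slice (or a provided projection);
  no 3D PSF or nuclear motion is modelled.
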