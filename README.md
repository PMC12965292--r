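# ms2burst

Transcriptional bursting inference from MS2/MCP live-imaging traces.

## What this package is for

Live imaging with the MS2/MCP reporter turns nascent transcription into a
per-nucleus fluorescence time series: RNA stem-loops in a nascent transcript
bind fluorescent coat protein, so each engaged RNA polymerase II adds one
quantum of signal at the transcription site until its transcript is
released. `ms2burst` implements the quantitative analysis chain used to
study Notch-target transcription in *Drosophila* follicle cells with such
traces:

* **Trace processing** — track retention rules, short-gap interpolation,
  active/inactive-period segmentation with the ~7-min merge window,
  proportion of nuclei switching on per 5-min bin, onset-aligned averages,
  background subtraction and median filtering.
* **Absolute calibration** — single-molecule intensity from smFISH spots
  (median of thresholded particles) and a pooled quantile–quantile linear
  fit relating MS2 arbitrary units to mRNA counts.
* **Deconvolution** — matching-pursuit inversion of a calibrated trace into
  discrete Pol II initiation events under a single-polymerase kernel
  (ramp–plateau–release), deterministic given a seed.
* **Kinetic inference** — product-limit survival of inter-initiation
  waiting times with Greenwood confidence bands; constrained bi/tri-
  exponential fits (`S(t) = sum A_i e^{l_i t}`, `sum A_i = 1`) initialized
  by a cumulative-integral linear solve; model selection by a
  band-coverage gate plus Kolmogorov–Smirnov with mean-squared-deviation
  tie-break; closed-form inversion of a three-component fit into the five
  rates of the nonsequential three-state promoter model (ON, two OFFs);
  steady-state checks of the mean inter-initiation interval
  `<tau> = 1/(p_ON * k_ini)` in 4-frame (80-s) windows with bootstrap
  confidence intervals.
* **Hub quantification and correlation** — locus ROI enrichment against
  random nuclear ROIs, ATS counting in nuclear masks, 1-um
  mutual-nearest-neighbor focus pairing, min–max normalization, 10x10-grid
  persistence scoring, and lagged cross/auto-correlation of paired hub and
  transcription traces (negative lag = hub leads).
* **Synthetic data** — exact Gillespie simulation of the promoter chain and
  generators for every input the pipeline consumes (traces, hub channels,
  two-allele populations, smFISH spot tables, locus-image scenes), with
  known ground truth and seed determinism.

## Worked example

Simulate a promoter in the default bursting regime (OFF dwell times ~6 s
and ~145 s), collect inter-initiation waiting times, select the number of
promoter states, and invert the fit into rates:

```r
library(ms2burst)

k <- default_kinetics()
path <- simulate_promoter_path(k, duration_s = 28000, seed = 1)
events <- sample_initiations(path, k$k_ini, seed = 2)
curve <- empirical_survival(waiting_times(events))
sel <- select_model(curve)
sel
#> <model_selection> 3 promoter states (gates passed)
sel$fits[["3"]]
#> <multiexp_fit> 3 components; MSD 1.46e-05; KS 0.01 (p 0.976); CI pass
#>   A1 = 0.4591, lambda1 = -0.4718 /s (1/|l| = 2.12 s)
#>   A2 = 0.511, lambda2 = -0.08181 /s (1/|l| = 12.2 s)
#>   A3 = 0.02993, lambda3 = -0.005029 /s (1/|l| = 199 s)
infer_kinetics(sel$fits[["3"]])
#> Nonsequential 3-state promoter kinetics (per second):
#>   k_ini = 0.2586  k1- = 0.1426  k1+ = 0.145  k2- = 0.007363  k2+ = 0.005178
#>   p_ON = 0.2937; mean OFF durations 6.897 s and 193.1 s
```

The biexponential fit fails the Greenwood-band gate while the
triexponential passes, so three promoter states are selected; the inversion
recovers the planted initiation rate (`k_ini = 0.25/s`) and ON probability
(`p_ON = 0.299`) closely, with the long OFF dwell the least certain
quantity. The steady-state check confirms stationarity:

```r
steady_state_tau(events, window_frames = 4, frame_interval_s = 20, seed = 3)
#> <steady_state_check> 997 windows of 80 s; pooled tau 12.2 s; stable
1 / (k$p_on * k$k_ini)
#> [1] 13.4
```

The same analysis runs from a rendered fluorescence trace through
deconvolution:

```r
kern <- kernel_preset("loops-near-TSS", frame_interval_s = 20)
trace <- render_ms2_trace(events, kern, duration_s = 28000, noise_sd = 0.5,
                          seed = 3)
dec <- deconvolve(trace, kern, noise_sd = 0.5)
periods <- periods_to_seconds(segment_active_periods(trace, threshold = 3))
waits <- waiting_times(dec$events, periods)
```

`run_pipeline(run_config(...))` executes the whole chain (simulate,
calibrate against generated smFISH spots, deconvolve, fit, correlate) and
writes CSV artifacts plus a JSON summary stamped with the configuration
hash and seed; `inst/scripts/ms2burst.R` is a thin command-line wrapper.

## Vignette

`vignettes/bursting-inference.Rmd` documents the promoter model and its
inversion, the kernel geometry, every tunable parameter with its default
and rationale, the numerical choices in deconvolution and survival fitting,
what the synthetic generator does and does not emulate, and known
limitations.
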