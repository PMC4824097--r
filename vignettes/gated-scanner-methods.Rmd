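---
title: "The gated-scanner model: simulation and analysis methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The gated-scanner model: simulation and analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatedscanner)
```

## The model

AddAB is a bacterial helicase-nuclease that resects double-stranded DNA
breaks. While translocating it scans the 3'-terminated strand for the
recombination-hotspot sequence Chi; recognition switches the enzyme from a
degradative mode into a recombination-promoting mode (the "AddAB*" state)
with slower translocation, attenuated nuclease activity, and a long-lived
footprint on the Chi-containing strand. The gated-scanner picture is a
two-state stochastic model of that switch, and this package implements it as
a seeded simulator plus the analysis pipelines of the assays used to
characterise it experimentally.

A molecule enters the substrate at position 0 and translocates at `v_pre`
(bp/s). Three things can interrupt scanning:

1. **Chi engagement.** At each Chi coordinate, with probability `p_pause`
   per encounter, the enzyme forms a *stalled encounter complex*. The dwell
   is gamma distributed with integer shape `pause_shape` and scale
   `pause_scale` — the sum of `pause_shape` sequential exponential kinetic
   steps, reflecting that measured dwell histograms are not exponential. A
   dwell ends in *commitment* to the Chi-modified state with probability
   `p_commit` (translocation resumes at `v_post` and further Chi sites are
   ignored), otherwise scanning resumes at `v_pre`.
2. **Spontaneous isomerization.** Independently of Chi, the scanning state
   converts to the Chi-modified state at hazard `k_iso` per second of
   pre-Chi translocation. This is the signature of the latch-destabilised
   mutant (E129A): a gate that normally opens only upon Chi binding opens
   stochastically when its closed conformation is destabilised. The hazard
   is clocked in time, not base pairs, because the transition is a protein
   conformational event; at fixed `v_pre` the two parameterizations are
   equivalent. Spontaneous switching emits no pause (whether it should is
   unresolved experimentally; we chose the simpler reading).
3. **Detachment.** A hazard `k_detach` ends the run (processivity). The
   enzymes studied here are highly processive, so the packaged sets use 0;
   the parameter exists for sensitivity analyses.

A single dwell law covers both failed and successful recognition attempts,
with `p_commit` deciding the outcome; the experiments cannot distinguish
separate laws, so we did not introduce one.

Off the DNA, the mature enzyme:Chi complex dissociates at `k_off_chi` (per
minute); the exonuclease-chase assay reads this out as the exponential decay
of the protected Chi fragment.

## Packaged parameter sets and their calibration

`make_default_params()` carries one parameter set per enzyme variant and
temperature regime; `?make_default_params` tabulates every default against
its empirical anchor. The calibration logic, in order of directness:

* **Rates.** `v_pre` = 300 bp/s (22 °C) and 1000 bp/s (37 °C) are measured
  mean translocation rates. Temperature is handled purely as alternative
  parameter sets, not as an Arrhenius model.
* **Post-Chi rate.** At 22 °C the tweezers traces show only a slightly
  decreased rate after Chi: `v_post = 0.75 v_pre`. For the 37 °C
  (stopped-flow) sets we use `v_post = 0.5 v_pre`: the triplex-displacement
  transients resolve a clearly delayed second phase whose separation is
  dominated by slower translocation beyond Chi, which requires a
  substantially slower converted state; with a 0.75 ratio the two phases
  blend and no biphasic decomposition (ours or the original) could report
  the amplitudes it does.
* **Dissociation.** `k_off_chi = ln 2 / t_half` with measured half-lives of
  3 min (wild type), 45 min (E129A), 0.8 min (F68A) and 13 min
  (F68A+E129A). The F210A-containing sets carry placeholder magnitudes (the
  assay was not reported for them) and are flagged as such in the docs.
* **Pause probability and dwell scale (22 °C).** The reported locus-level
  pause frequencies (66% wild type, 57% E129A over a ten-Chi locus) are
  frequencies of *detected* pauses, and the reported medians (1.45 s /
  1.00 s) are medians over detected events, i.e. censored at the 0.33 s
  instrument resolution. We therefore calibrated through the full
  measurement model: `pause_scale` is set so that the complete
  simulate → render (60 Hz, 30 bp noise) → filter (3 Hz) → detect pipeline
  returns the printed censored median (final values 0.632 s and 0.4075 s;
  the closed-form censored-gamma inversion, `calibrate_pause_scale()`,
  over-shoots by ~10–15% because adjacent-Chi merging and finite bandwidth
  inflate detected durations). `p_pause` is the per-site detected
  probability `1-(1-f)^(1/10)` divided by the fraction of dwells above the
  censor and by the measured near-censor detector efficiency (0.93 / 0.87).
* **Commitment (37 °C).** On a substrate with three Chi sequences ~50% of
  the wild-type population converts, giving per-Chi commitment
  `1 - 0.5^(1/3)` (`p_commit = 1` at this temperature; the data constrain
  only the product). The same joint logic sets the 37 °C dwell scale from
  the 4/38 detectable-pause frequency, and the E129A 37 °C `p_pause` from
  its ~70% conversion once `k_iso` is accounted for.
* **Isomerization.** `k_iso = 0.1 /s` for E129A at 37 °C emulates the
  distance-dependent loss of first-phase amplitude on Chi-free DNA; the
  paper-level rate is not printed, so the value is ours. The 22 °C sets use
  `k_iso = 0`, where no spontaneous slowdown was reported.
* **Chi-binding mutants.** F68A and F210A reduce the per-encounter response
  ~2.5- and ~15-fold (implemented in `p_pause`, since these mutations
  eliminate pausing); the latch double mutants raise `p_commit` 2–2.5×,
  restoring F68A+E129A yield to wild-type levels.

Chi spacing within the ten-Chi locus is not printed; we default to 30 bp
from 4588 bp. Positions are 0-based base pairs from the entry end, distances
half-open in `[0, length_bp)`.

## What the synthetic data emulate — and what they do not

`render_trace()` adds independent Gaussian noise (default SD 30 bp per 60 Hz
sample, ≈10 nm at 0.33 nm/bp) to the piecewise-linear path: at 3 Hz this
gives traces that look like filtered bead recordings. Real traces also
contain drift, bead-tether fluctuations with non-white spectra, and tracking
artefacts; none are modelled, and the analysis entry points deliberately
accept plain position-versus-time tables so real (pre-corrected) data can be
analyzed identically. Chase series use independent binomial aliquots per
timepoint with mean-one lognormal densitometry noise; gel backgrounds and
partial digestion are not modelled. Triplex curves are arrival-time
ensembles convolved with an exponential displacement step (default 10 /s);
photophysics and instrument dead time are not. Passing tests therefore
demonstrate correct recovery of the model's own parameters through realistic
sampling noise — not robustness to every artefact of real recordings.

## Trace analysis

Raw traces are reduced by non-overlapping block averages to 3 Hz. Local
velocity is a sliding least-squares slope over a centred `velocity_window_s`
(default 0.67 s ≈ 2 filtered samples). Pauses are maximal runs of samples
with velocity below `pause_velocity_frac` of the trace's pre-Chi mean
velocity, lasting at least `min_pause_s = 0.33` s — the instrument
resolution; shorter events are never reported.

Two numerical choices matter here:

* **Threshold fraction 0.5.** A sample's velocity falls below a fraction
  `f` of the running rate only when more than `1-f` of its window overlaps
  the plateau, so a below-threshold run under-covers the true plateau by
  `(1-2f) × window`. At `f = 0.5` the run length is an unbiased duration
  estimator and the minimum detectable plateau equals the 0.33 s censor;
  for other thresholds the detector applies the geometric correction
  explicitly. With default noise the threshold sits >5 SD below the running
  velocity and >5 SD above a plateau, so misclassification is negligible.
* **Sub-sample boundaries.** Run edges are refined by interpolating the
  velocity's threshold crossing, so durations are continuous rather than
  multiples of 1/3 s; otherwise the reported medians move on a coarse grid
  (a third of the E129A median!).

The pre-Chi reference velocity is computed from entry up to the
(interpolated) first crossing into the Chi window, excluding samples whose
velocity window could touch it, so at-Chi dwells never deflate the
reference. An event is at-Chi when its mean position falls inside
`chi_window_bp`; the default window starts one Chi spacing *below* the
first site because plateau-edge averaging reports dwell positions a few bp
upstream. Events straddling the window edge count as at-Chi if their mean
is inside. Closely spaced Chi dwells separated by less than the window
merge into one event — as they do in the real instrument.

Dwell statistics (`pause_statistics()`) report the frequency of traces with
at least one at-Chi event and the censored summaries (median, mean,
quartiles, range) over detected events only. Sample medians over ~40 events
carry ~12% relative sampling error; recovery tests and tolerances are set
with that in mind. `moods_median_test()` compares two dwell samples by the
counts above versus not-above the pooled grand median (ties count as "not
above"), with a continuity-corrected chi-square on the 2×2 table — the
appropriate nonparametric choice given skewed, censored dwell data at small
n. The continuity correction makes the test conservative at these sample
sizes (its measured type-I error at α = 0.05 is ~0.04).

## Ensemble kinetics

* **Chase decay.** `fit_exponential_decay()` fits `f0 exp(-k t)` by
  unweighted least squares (the densitometry error structure is unknown)
  and reports `t_half = ln 2 / k` with a residual-resampling bootstrap
  interval; non-decaying series are refused rather than reported.
* **Triplex transients.** `fit_biphasic()` fits a sum of two offset rising
  exponentials. The objective is multimodal in the offsets, so the fit is
  multistarted (default 8 starts; offsets seeded at the 10% and 60% signal
  times, rates at the inverse rise time, amplitudes spread across starts).
  Phase 1 is the smaller-offset phase, ties broken by the larger rate, and
  a phase carrying <2% of the amplitude is treated as degenerate so
  single-phase data report `a1 ≈ 1`. Whether the two phases share one rate
  is not settled by the source material; both free (default) and
  constrained (`equal_rates = TRUE`) variants are exposed. For transients
  too complex to decompose (the latch mutant on Chi-containing DNA) only
  `amplitude_at_time()` — the crude fixed-time amplitude read — is
  reported, following the original analysis choice.
* **Inversions.** `fit_dose_response()` inverts first-phase amplitudes
  against Chi number via `a1(n) = (1-c)^n`; `fit_isomerization()` inverts a
  Chi-free distance series via `a1(L) = exp(-k_iso L / v_pre)` (log-linear
  regression through the origin). The distance-series design matters: when
  the switch position is continuous, molecules converting close to the
  reporter are barely delayed and the biphasic fit absorbs them into phase
  1. At reporter distances of 1–4 kb with a fast displacement step the
  residual bias on `k_iso` is ~5–10%; at 4–12 kb it approaches 20%. The
  packaged distance-series scenario uses 1–4 kb.

## Scenarios and reproducibility

Every stochastic entry point takes an explicit seed, and identical seeds
give identical outputs. `run_scenario()` executes a YAML-defined batch of
assay blocks; blocks without their own seed get one derived from the global
seed by a fixed counter scheme (`seed × 1009 + block index`, folded into the
32-bit range), so each block is independently reproducible. Bundles carry a
config hash, the expanded seeds, and the package version. Outputs are plain
CSV with JSON sidecars so that written artefacts re-enter the analysis
functions unchanged.

Problem sizes in the packaged scenarios mirror the study design: 48 and 44
traces at 22 °C, chase series of 500 molecules with 5% noise over two
half-lives, triplex ensembles of 2000–5000 molecules. These are the sizes
at which the recovery tolerances in the test suite were set.

## Known limitations

* No mechanical DNA model: force and rise-per-bp are metadata; noise is
  white Gaussian in base pairs.
* Chi sites are coordinates, not sequence matches; "Chi-like" promiscuous
  recognition is representable only through `k_iso`.
* The pause detector is a single velocity-threshold design; changepoint or
  HMM detectors are extension points, not implemented.
* Dwell medians at the study's trace counts carry double-digit-percent
  sampling error; run-to-run variation of that size is expected, not a bug.
* Nuclease cleavage positions, gel densitometry, and limited-proteolysis
  readouts are out of scope.
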