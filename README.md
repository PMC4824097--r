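# gatedscanner

Simulation and analysis of Chi recombination-hotspot recognition by the
bacterial AddAB helicase-nuclease, modelled as a two-state *gated scanner*.

AddAB resects double-stranded DNA breaks while scanning for the short Chi
hotspot sequence. Recognition converts the enzyme into a slower,
recombination-promoting state (AddAB\*) that footprints the Chi-containing
strand. This package implements that conversion as a stochastic
single-molecule model and regenerates, from synthetic data, the quantitative
observables of the assays used to characterise it:

* **Translocation model.** An enzyme moves at rate `v_pre`; each Chi
  encounter arrests it with probability `p_pause` in a gamma-distributed
  dwell (shape *m*, scale *θ* — *m* sequential kinetic steps), resolved by
  commitment to the slow state (probability `p_commit`, rate `v_post`
  thereafter) or release. Spontaneous isomerization at hazard `k_iso`
  (the latch-mutant signature) and detachment at `k_detach` compete during
  scanning. The mature enzyme:Chi complex dissociates at `k_off_chi`, so
  Chi-fragment survival under an exonuclease chase decays as
  `exp(-k_off_chi · t)`.
* **Single-molecule pipeline.** 60 Hz bead traces with Gaussian positional
  noise, 3 Hz block-average filtering, sliding least-squares velocimetry,
  velocity-threshold pause detection with the 0.33 s instrument censor,
  censored dwell statistics, Mood's median test, and velocity-versus-position
  profiles.
* **Ensemble pipeline.** Single-exponential chase fits with bootstrap
  half-life intervals; biphasic offset-exponential decomposition of
  triplex-displacement transients; Chi-dose inversion `a1(n) = (1-c)^n`;
  Chi-free distance-series inversion `a1(L) = exp(-k_iso L / v_pre)`;
  Chi-fragment yield fold changes.

Packaged parameter sets (`make_default_params()`) cover the wild type, the
latch mutant E129A, the Chi-binding mutants F68A/F210A and their double
mutants, at 22 °C and 37 °C. The methods vignette
(`vignettes/gated-scanner-methods.Rmd`) explains the model, every default,
and the calibration choices.

## Worked example

Simulate the 22 °C single-molecule experiment — 48 wild-type and 44
latch-mutant traces on a 7.7 kb substrate with a ten-Chi locus at 4588 bp —
and run the full pause analysis:

```r
library(gatedscanner)

make_default_params("wildtype")
#> Gated-scanner parameters [wildtype]
#>   v_pre 300 bp/s, v_post 225 bp/s
#>   pause: p = 0.1218 per Chi, gamma(shape 2, scale 0.632 s), p_commit 0.35
#>   k_off_chi 0.231 /min (t1/2 3 min), k_iso 0 /s, k_detach 0 /s

run_scenario(default_scenario("tweezers_22C"))
#> Scenario result bundle [tweezers_22C], config 1b67da2e
#>  - traces wildtype (seed 2201 ): freq 0.77, median 1.6 s, v_pre 299.9 bp/s
#>  - traces E129A (seed 2202 ): freq 0.52, median 0.907 s, v_pre 300.3 bp/s
```

`freq` is the fraction of traces with at least one detected pause at the Chi
locus and `median` the censored median dwell; for this seed the wild type
pauses in 77% of traces with a 1.6 s median dwell and the latch mutant in
52% with 0.91 s — scattered, as expected at ~40 events, around the encoded
66%/1.45 s and 57%/1.00 s.

Dissociation of the hyper-stable latch-mutant complex from Chi, via a
simulated exonuclease chase (500 molecules per lane, 5% densitometry noise):

```r
series <- simulate_chase(make_default_params("E129A"),
                         seq(0, 90, length.out = 8), n_molecules = 500,
                         noise_cv = 0.05, seed = 42)
fit_exponential_decay(series, seed = 43)
#> Exponential decay fit: f0 = 1.01, k = 0.0157 /min, t1/2 = 44.1 min (95% CI 40.7-47.4)
```

The fitted half-life of ~44 min recovers the encoded 45 min — roughly
15-fold more stable than the wild type's 3 min.

A thin command-line wrapper over the same functions lives in
`inst/cli/gatedscanner.R` (`simulate`, `analyze-traces`, `fit-chase`,
`fit-triplex`, `dose-response`, `distance-series`, `run-scenario`,
`compare-pauses`, `list-variants`).

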