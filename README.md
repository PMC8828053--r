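# cosmofret

Simulation and analysis of single-molecule FRET / colocalization
(CoSMoS) data for eukaryotic replicative-helicase loading.

## The problem

Origin licensing loads two Mcm2-7 helicases head-to-head around origin
DNA. Single-molecule experiments monitor this on individual
surface-tethered DNAs by alternating-excitation TIRF microscopy: a
donor-labeled ORC and acceptor-labeled Mcm2-7 (or Cdt1) report arrivals,
departures, and — through apparent FRET efficiency

```
E = I_Aem / (I_Aem + I_Dem)        (donor excitation)
```

— two specific interfaces: the C-terminal **OM** interface active during
each helicase recruitment, and the inverted **MO** interface formed when
a single ORC, tethered to the first helicase, flips over it to recruit
the second. Analyzing such data means turning noisy three-channel,
2.4-s-resolution intensity records into presence intervals, intensity
steps, FRET intervals, classified loading events, and censored
dwell-time statistics.

`cosmofret` implements that entire measurement chain *and* a kinetic
simulator that generates synthetic data with the statistical structure
the analysis assumes — stochastic state trajectories under the ORC-flip
mechanism (plus failure branches, two-ORC pathways, loss-of-function
mutants, and the re-FRET / ORC-exchange alternatives), Bernoulli
fluorophore labeling, FRET-dependent emission splitting, donor PIFE,
stepwise acceptor counting, per-exposure photobleaching, and additive
background noise — so every stage of the pipeline is exercised and
validated without microscope data. An optional image layer renders
traces into small synthetic TIRF movies and recovers them by spot
detection and colocalization.

Audience: single-molecule biophysicists and method developers who need a
tested, seedable reference implementation of CoSMoS/FRET trace analysis,
or a ground-truthed benchmark generator for their own detectors.

## A worked example

Simulate a small cohort under the standard OM-labeling design
(0.5 nM ORC / 15 nM Cdt1-Mcm2-7 conditions, 0.88 ORC labeling), analyze
it, and fit the first OM dwell:

```r
library(cosmofret)

cfg <- run_config("fig1", n_dna = 60, seed = 7,
                  p_mo_given_first_mcm = 1, p_second_given_mo = 1)
tc  <- simulate_experiment(cfg)     # trajectories -> labels -> traces
res <- analyze_traces(tc, cfg)      # detection + event classification

head(res$events[, c("dna_id", "m1_time", "m2_time", "success")])
#>   dna_id m1_time m2_time success
#> 1      1     8.4    90.0    TRUE
#> 2      2    22.8    97.2    TRUE
#> 3      3    32.4    63.6    TRUE
#> 4      4    27.6    54.0    TRUE
#> 5      5    25.2    75.6    TRUE
#> 6      6    46.8    97.2    TRUE

om <- recover_om_dwells(n_dna = 400, seed = 1)
om$first
#> <rate_fit> mean = 34.4 +/- 1.8 s (n = 279, 0 censored)
om$second
#> <rate_fit> mean = 50.7 +/- 3 s (n = 295, 0 censored)
```

`m1_time`/`m2_time` are the two detected Mcm2-7 arrival steps (seconds,
quantized to the 2.4-s cycle); `success` applies the > 48 s double
retention rule for a completed double hexamer. The two fits are
censored-exponential maximum-likelihood means of the detected first and
second OM-FRET interval durations (left-truncation corrected for the
detection floor, with bootstrap errors), recovering the 30 s / 56 s
ground truth the cohort was simulated with to within two standard
errors — this particular seed draws a high first-OM cohort.

Population helpers mirror the arithmetic used for published fractions:

```r
expected_two_label_fraction(0.88)       # 0.7744  (two labeled ORCs if two were needed)
proportion_with_se(37, 82)$p            # 0.4512195
conditional_fraction(0.18, 0.02, 0.23, 0.02)$ratio  # 0.7826087
pattern_frequency_test(c(25, 21, 22, 22),
                       model_profile_expectation("orc_flip"))$p_value
```

A thin CLI over the same functions lives at `inst/cli/cosmofret.R`
(`simulate` / `analyze` / `report`).

## Layout

- `R/params.R`, `R/presets.R` — parameter objects, validation, named
  experiment presets (fig1, fig2-mixedMcm, ..., bleach-control)
- `R/simulate.R` — the kinetic state simulator and labeling
- `R/render.R` — the trace forward model and photobleaching
- `R/movie.R` — synthetic TIRF movies, spot detection, colocalization
- `R/analyze.R` — background correction, presence/step/FRET detection
- `R/events.R` — event assembly, ORC counting, profile typing
- `R/stats.R` — survival curves, censored MLE, bleach decomposition,
  fraction algebra, G tests, offset histograms
- `R/recovery.R`, `R/pipeline.R` — recovery experiments and the
  simulate/analyze/report commands
- `vignettes/methods.Rmd` — the full model and methods account
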