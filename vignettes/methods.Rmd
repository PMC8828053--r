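---
title: "Models and methods behind cosmofret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cosmofret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosmofret)
```

# The biological system and the measurement

Eukaryotic replication origins are licensed by loading two Mcm2-7
helicases around DNA as a head-to-head double hexamer. The origin
recognition complex (ORC) binds the origin, and with Cdc6 and Cdt1
recruits the two helicases one at a time. In colocalization single-molecule
spectroscopy (CoSMoS) versions of this reaction, surface-tethered origin
DNAs are imaged by alternating-excitation TIRF microscopy: every 2.4-s
cycle holds one 1-s donor-excited exposure and one 1-s acceptor-excited
exposure separated by 0.2-s dead times, repeated 600 times (~24 min).
Donor-labeled ORC and acceptor-labeled Mcm2-7 (or Cdt1) report arrivals and
departures through direct excitation, and apparent FRET efficiency

$$E = \frac{I_{\mathrm{Aem}}}{I_{\mathrm{Aem}} + I_{\mathrm{Dem}}}
\quad (\text{donor excitation, background-corrected})$$

reports specific protein-protein interfaces. Two labeled interfaces matter
here: the *OM* interface between the Orc5 C-terminus and the Mcm2
C-terminus, active during each helicase recruitment, and the *MO* interface
between the Orc6 C-terminus and the Mcm3 N-terminus, active in the
inverted intermediate in which ORC, tethered to the first helicase, has
flipped to face its N-terminal side before recruiting the second helicase.

`cosmofret` provides (i) a continuous-time stochastic simulator of this
loading reaction on independent DNA molecules, (ii) a forward model that
renders state trajectories into the three recorded channels, (iii) an
optional synthetic image layer, (iv) the per-molecule detection layer
(presence intervals, intensity steps, E series, high-FRET intervals),
(v) event assembly and classification, and (vi) the population statistics
(censored survival analysis, exponential MLE with bootstrap, bleach-rate
decomposition, multinomial model tests).

# The kinetic state model

Each DNA hosts at most one loading attempt, drawn from the helicase-tethered
ORC-flip state machine:

1. ORC arrives at rate `orc_arrival_rate` (exponential waiting time), or is
   prebound at $t = 0$ in staged designs.
2. A first Mcm2-7/Cdt1 arrives at rate `mcm_arrival_rate`; the first OM
   interaction starts at this arrival.
3. The first OM interaction lasts Exp(`mean_first_om_s` = 30 s) and ends
   *exactly* at the first Cdt1 release — a model assumption mirroring the
   observed coincidence of the two events at the 2.4-s resolution.
4. With probability `p_mo_given_first_mcm` = 0.23 the MO complex forms
   after a lag Exp(`mean_mo_delay_s` = 8.3 s); otherwise ORC departs
   (Exp(10 s) lag, a free parameter) and the unstabilized helicase leaves
   with median lifetime `median_m1_release_s` = 11 s
   (rate $\ln 2 / \mathrm{median}$).
5. Given MO, with probability `p_second_given_mo` = 0.79 a second Mcm2-7
   arrives (rate `mcm_arrival_rate` from MO onset), carries the second OM
   interaction for Exp(`mean_second_om_s` = 56 s) ending with second Cdt1
   release and ORC departure, and the MO interval ends
   Exp(`mean_mo_end_after_m2_s` = 9.7 s) after the second arrival, at the
   onset of double-hexamer interactions. The MO interval therefore always
   brackets the second arrival. Failed MO events release the first helicase
   with median `median_m1_with_mo_s` = 35 s and may show a short-lived
   (< 48 s) second association (`p_abortive_second`, exponential
   conditioned below 48 s — the class is defined only by the threshold).
6. ORC usage is a mixture: one ORC (0.81), two sequential ORCs (8/166),
   two overlapping ORCs (14/166), remainder a nonspecific background of
   short extra ORC visits (Poisson count, 15-s dwells).

All dwells are exponential (the dwell-time survival curves of this system
are well described by single exponentials); the sampler is pluggable.
Mechanism modes re-wire which molecule carries each interaction:
`re_fret` attaches both OM periods to the first helicase and has no MO
interval; `orc_exchange` swaps two ORCs within one frame time so a single
ORC appears continuously present; `two_orc_independent` forces visibly
sequential two-ORC events. In a sequential two-ORC event the first ORC
releases once the first helicase is loaded and the MO delay is dominated
by the second ORC's arrival from solution — a consequence is that only
events whose inter-ORC gap exceeds two cycles (~79% at the default
arrival rate) are recognizable as two-ORC, a resolution limit the
classifier tests acknowledge.

Mutants: `mcm5RA` blocks Cdt1 release, so its OM interaction ends only
through a composite fluorophore-loss process (photobleach or the complex
sliding off the DNA end) with mean `mean_5ra_loss_s` = 156 s; `orc6dN119`
suppresses MO formation to `p_mo_dn119` = 0.012 (the residual observed
frequency, 5/418).

Parameters the source experiments do not constrain — the two arrival
rates (0.05 /s each, putting typical attempt starts within the first
minute of a 24-min record), the ORC departure lag after failed attempts
(10 s), the abortive-second probability (0.5) and dwell (20 s) — were
fixed once at values realistic for the sub-nM protein concentrations of
these assays and are ordinary configuration, not fitted quantities.

# The trace forward model

Labeling plans assign each molecule a dye class independently (ORC donor
at Orc5-C, Orc6-C, or Orc1-N; Mcm2-7 acceptor at Mcm2-C, Mcm4-N, or
Mcm3-N; Cdt1 acceptor at either terminus; or unlabeled, e.g. the measured
0.88 ORC labeling fraction). FRET requires the correct geometry: an OM
interaction is high-FRET only for the Orc5-C/Mcm2-C pair (set-points 0.72
and 0.79 for first and second), the MO interaction only for
Orc6-C/Mcm3-N (0.73). Donor/acceptor coexistence without an engaged
interface renders at the 0.08 no-interaction set-point; labeled Cdt1
contributes its control values (0.358 for Orc5-C with Cdt1-N, 0.10 for
Orc6-C with Cdt1-C) and raises an engaged OM to the composite 0.83 when
Cdt1-N is present. Composite states are single effective set-points, not
explicit three-dye kinetics — only the composite values are known.

During donor-excited frames the noiseless split is
$I_\mathrm{Aem} = E\,T$, $I_\mathrm{Dem} = (1-E)\,T$ with
$T = \texttt{unit\_intensity} \times \texttt{pife\_factor}$ while an OM
interaction is active (protein-induced fluorescence enhancement of the
donor dye; the effect is qualitative in the source data, so the 1.3
default is configurable) and $T = \texttt{unit\_intensity}$ otherwise.
Acceptor-excited intensity is one unit per present, unbleached acceptor
and is independent of FRET state. State occupancy is integrated over each
1-s exposure, so a transition inside an exposure scales emission linearly
by time-in-state (the camera integrates photons). Noise is additive
zero-mean Gaussian per recorded channel: traces model already
background-corrected records.

The background SD defaults to 150 units (per-frame SNR ~6.7 for one
acceptor, ~4.7 on the summed donor channel). Exact magnitudes are not
published; the value was calibrated once against the detection layer's
own contract — at the 0.4 FRET threshold the baseline E-noise must
false-qualify rarely enough that ≥ 95% of OM/MO intervals of three or
more frames are recovered with endpoint errors of at most one frame.

Photobleaching is per-dye and per-illuminated-exposure (Bernoulli,
probability `bleach_prob_per_exposure` times the design's
`laser_exposure_factor`), so the observed fluorophore-loss rate
decomposes as $k_\mathrm{obs}(f) = k_\mathrm{intrinsic} + f\,k_\mathrm{bleach}$,
which `estimate_bleach_rate()` inverts from fits at the two exposure
conditions (1 and 2.4).

# The detection layer

**Background correction** subtracts, per DNA and channel, the median of
frames outside detected presence, iterated once. Because rendered traces
are nominally pre-corrected, presence is detected about zero; this removes
residual offsets smaller than the detection threshold. A channel occupied
in essentially every frame has no empty cluster to anchor on and is left
unchanged, flagged.

**Presence intervals** use hysteresis thresholding on the donor-excited
*total* emission (conserved under FRET, so donor presence is detected
independently of FRET state) or on the acceptor-excited channel: an
interval needs one frame at ≥ 4 noise SDs and extends over frames at
≥ 2 SDs, tolerating one sub-threshold frame; ends at the trace end are
right-censored. Event times follow the convention that a time is the
start of the first frame in the new state; interval ends are the start of
the frame after the last qualifying frame, so durations are quantized to
the 2.4-s cycle.

**Steps** are located by binary segmentation on the acceptor series:
the candidate split maximizes the CUSUM statistic and is accepted by a
two-sample z test (α = 0.001) using the global robust noise scale
(median absolute deviation of first differences). A per-segment Welch
variance was rejected deliberately: segments adjacent to an early or
late event can be a handful of frames, where Welch has essentially no
power even against five-sigma steps. Statistically significant but
physically implausible changepoints — mean shifts below three noise
SDs, as arise on long flat stretches — are merged away, as are
same-direction sub-steps one frame apart (camera integration splits any
physical transition that lands inside an exposure). Down-steps whose size
matches the current level are departures; otherwise down-steps at 35–65%
of the preceding up-step are half losses (release of one of two
co-arrived acceptors, i.e. Cdt1); up-steps are arrivals.

**E series and high-FRET intervals.** E is computed on donor-excited
frames where both a donor and at least one acceptor are present; the
ratio is emitted as-is (no clamping), and histogram-style summaries
exclude |E| > 2. High-FRET intervals are runs of valid frames with
E ≥ 0.4 — the midpoint between the 0.08 baseline and the ~0.72 engaged
states, a stand-in for the unpublished "above background noise" onset
rule — with one-frame gap tolerance, a per-frame donor-emission floor
(frames straddling a donor departure otherwise contribute pure-noise
ratios), and acceptor presence confirmed within 4.8 s of the onset.
Single-frame intervals count: requiring two frames would left-truncate
the dwell sample and, by memorylessness, bias exponential means upward
by roughly the truncation length. Intervals shorter than about two
cycles can fall entirely between donor exposures of the alternation
scheme and are invisible in principle.

# Event assembly and classification

Events are assembled per DNA from arrival steps: the first two arrivals
are the two helicase recruitments; retention runs to the next
departure-classified step (censored at trace end); success requires both
retentions > 48 s (20 frames). ORC counting classifies donor presence
intervals against the recruitment window (one spanning interval;
two sequential; two overlapping; three or more; or unlabeled — excluded
from FRET analyses). FRET profiles attribute each high-FRET onset to an
arrival within ±4.8 s (the observed attribution spread, with one 6-s
outlier, motivates the window; wider lags flag the event anomalous rather
than being silently attributed), giving two-peak / first-only /
second-only / none, which under mixed C/N labeling maps onto the CC / CN /
NC / NN double-hexamer types. Coincidence calls use the ±2.4-s cycle as
the temporal resolution.

# Population statistics

Dwell-time survival uses the product-limit estimator with Greenwood
variance (via the survival package; linear-scale 95% bands, collapsing
where S reaches zero). The censored-exponential MLE is the closed form
$\hat\tau = \sum d_i / n_\mathrm{uncensored}$, with uncertainty from a
seeded nonparametric bootstrap over events (B = 1000 by default; events,
not frames, are the independent unit). Detection-limited dwell samples
are left-truncated (intervals shorter than about one exposure are never
recorded), which by memorylessness inflates the naive mean by the
effective floor; `fit_exponential_mle(..., t_min)` applies the exact
correction — drop observations below `t_min`, subtract `t_min` from the
rest — and the recovery experiments use `t_min` of two cycles, safely
above the floor. Fractions carry Wald binomial SEs
to match the reported "± SE" convention — whether the source's SEs are
Wald is not stated, so Wilson intervals are reported alongside — and
ratios of fractions propagate first-order errors with an optional
correlation term. Model discrimination uses a likelihood-ratio G test
against model-expected profile proportions (flip: $q^2$, $q(1-q)$,
$q(1-q)$, $(1-q)^2$ at coupled-label fraction $q$; re-FRET: $q$, 0, 0,
$1-q$), with structural-zero violations rejecting outright and an
optional Monte-Carlo exact p value for small n. Offset histograms use
2.4-s bins with one bin centered on zero.

# What the simulator does and does not emulate

It reproduces the statistical structure the analysis assumes: alternating
excitation timing, state-dependent emission splitting, PIFE, stepwise
acceptor counting with Cdt1 co-arrival and release, incomplete labeling,
per-exposure bleaching, additive Gaussian background, and the full event
taxonomy including failure branches, mutants, and mechanistic
alternatives. It does not emulate spectral crosstalk or bleed-through,
spatial variation of laser excitation (the simulated field is flat),
stage drift, dye blinking, non-Gaussian camera noise, multiple sequential
loading attempts on one DNA, or diffusive sliding of intermediates. Tests
passing on these simulations therefore validate the analysis logic and
its estimators, not robustness to optical artifacts absent from the
forward model.

# Reproducibility, problem sizes, and file formats

Every stage is seeded; per-stage sub-seeds derive deterministically from
one master seed, so a run is bit-for-bit reproducible from (config,
seed). The validation experiments use cohorts of 330–1000 DNAs at 600
cycles — a few hundred analyzable events per quantity, matching the scale
of the source datasets (82–418 events) while keeping each experiment in
the minutes range on one CPU. Traces, ground truth, intervals and events
interchange as CSV; statistics as JSON; configurations as YAML snapshots;
movies export as multi-page TIFF. CSV is deliberately the one trace
container: it is lossless for this schema and keeps the pipeline free of
binary artifacts. The legacy Matlab "intervals" dialect of the public
archives is out of scope (`read_intervals_archive()` documents the
pointer).

# Known limitations

- Event times are quantized to the 2.4-s cycle, and lags between
  quantities detected on the donor and acceptor grids (offset by half a
  cycle) can carry sub-cycle systematic offsets below the reported
  uncertainties.
- Dwell samples are detection-limited: intervals shorter than about one
  exposure are invisible, handled by the truncation-corrected MLE above;
  a small residual (< 1 s) from whole-cycle edge frames remains. Fused
  first/second OM intervals across sub-resolution gaps are excluded from
  the first-OM dwell sample rather than charged to it; the gap is
  independent of the first-OM duration, so the exclusion is unbiased.
- The window-mean E after a first arrival is reported over frames within
  the detected OM interval. A literal all-frames window mean under
  exponential 30-s dwells mixes in post-release baseline frames
  (~15% weight) and underestimates the engaged-state value that the
  published window statistic evidently reports (its spread implies < 5%
  baseline contamination).
- Ratio-of-noisy-intensities bias inflates mean E by
  $\sigma^2 (2E - 1) / T^2$ (about +0.006 at defaults); this is visible
  in estimator tests and negligible against reported uncertainties.
- Two-ORC recognition is resolution-limited (see above); the classifier
  reports, and the tests assert, the physically attainable fraction.
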