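#' Kinetic parameters for the helicase-loading state model
#'
#' Rates, mean dwells, and branch probabilities of the stochastic
#' helicase-loading model: ORC binds origin DNA, recruits a first
#' Mcm2-7/Cdt1 via a C-terminal "OM" interaction that ends at first Cdt1
#' release, then (with probability `p_mo_given_first_mcm`) flips over the
#' first helicase to form the inverted "MO" complex from which a second
#' Mcm2-7 is recruited (with probability `p_second_given_mo`), completing
#' the head-to-head double hexamer. Failure branches, short-lived
#' ("abortive") second associations, two-ORC pathways, nonspecific extra
#' ORC visits, and two loss-of-function mutants are included.
#'
#' All dwell and lag distributions are exponential (dwell-time survival
#' curves of this system are well described by single exponentials);
#' median-parameterised lifetimes are converted internally via
#' rate = ln(2) / median. A different sampler can be plugged in through
#' `dwell_sampler`, a `function(n, mean_s)`.
#'
#' @param orc_arrival_rate ORC arrivals per second per DNA.
#' @param mcm_arrival_rate Mcm2-7/Cdt1 arrivals per second per receptive DNA
#'   (ORC-bound for the first helicase, MO-bound for the second).
#' @param mean_first_om_s Mean duration (s) of the first OM interaction;
#'   ends at first Cdt1 release.
#' @param mean_second_om_s Mean duration (s) of the second OM interaction.
#' @param mean_mo_delay_s Mean lag (s) from first Cdt1 release to MO onset.
#' @param mean_mo_end_after_m2_s Mean lag (s) from second Mcm2-7 arrival to
#'   the end of the MO interaction (onset of double-hexamer interactions).
#' @param p_mo_given_first_mcm Probability a first-Mcm2-7 binding event goes
#'   on to form the MO complex.
#' @param p_second_given_mo Probability an MO complex recruits a stable
#'   second Mcm2-7.
#' @param median_m1_release_s Median lifetime (s) on DNA of a lone first
#'   Mcm2-7 after ORC departure when no MO interaction formed.
#' @param median_m1_with_mo_s Median lifetime (s) of a first Mcm2-7 after MO
#'   onset when no second Mcm2-7 is recruited.
#' @param p_abortive_second Probability that an MO complex that fails to
#'   recruit a stable second Mcm2-7 nevertheless shows a short-lived
#'   (< 48 s) second association.
#' @param mean_abortive_dwell_s Mean dwell (s) of abortive second
#'   associations (exponential conditioned below 48 s).
#' @param p_one_orc,p_two_orc_sequential,p_two_orc_overlap Mixture weights
#'   over ORC-usage pathways; the remainder is the "nonspecific extra ORC"
#'   class (a Poisson background of short ORC visits on top of a one-ORC
#'   event).
#' @param mean_orc_depart_after_om1_s Mean lag (s) from the end of a first
#'   OM interaction to ORC departure when no MO forms.
#' @param mean_5ra_loss_s Mean (s) of the composite fluorophore-loss process
#'   (photobleach or complex sliding off the DNA end) that terminates OM
#'   interactions of the Cdt1-release-defective Mcm5-R549A mutant.
#' @param p_mo_dn119 Residual MO-formation probability of the Orc6
#'   N-terminal-domain deletion mutant (near zero).
#' @param extra_orc_poisson_mean,mean_extra_orc_dwell_s Poisson mean for the
#'   number of additional nonspecific ORC visits (beyond one) and their mean
#'   dwell (s), in the nonspecific class.
#' @param mechanism One of `"orc_flip"` (default), `"re_fret"`,
#'   `"orc_exchange"`, `"two_orc_independent"`: which molecule carries each
#'   OM/MO interaction.
#' @param mutant One of `"wildtype"`, `"mcm5RA"` (no Cdt1 release, hence no
#'   OM end by release, no MO, no second Mcm2-7), `"orc6dN119"` (MO
#'   formation suppressed to `p_mo_dn119`).
#' @param dwell_sampler Optional `function(n, mean_s)` replacing the
#'   exponential dwell sampler.
#' @return An object of class `kinetic_params` (a validated list).
#' @export
kinetic_params <- function(orc_arrival_rate = 0.05,
                           mcm_arrival_rate = 0.05,
                           mean_first_om_s = 30,
                           mean_second_om_s = 56,
                           mean_mo_delay_s = 8.3,
                           mean_mo_end_after_m2_s = 9.7,
                           p_mo_given_first_mcm = 0.23,
                           p_second_given_mo = 0.79,
                           median_m1_release_s = 11,
                           median_m1_with_mo_s = 35,
                           p_abortive_second = 0.5,
                           mean_abortive_dwell_s = 20,
                           p_one_orc = 0.81,
                           p_two_orc_sequential = 8 / 166,
                           p_two_orc_overlap = 14 / 166,
                           mean_orc_depart_after_om1_s = 10,
                           mean_5ra_loss_s = 156,
                           p_mo_dn119 = 0.012,
                           extra_orc_poisson_mean = 0.3,
                           mean_extra_orc_dwell_s = 15,
                           mechanism = c("orc_flip", "re_fret", "orc_exchange",
                                         "two_orc_independent"),
                           mutant = c("wildtype", "mcm5RA", "orc6dN119"),
                           dwell_sampler = NULL) {
  mechanism <- match.arg(mechanism)
  mutant <- match.arg(mutant)
  p <- list(
    orc_arrival_rate = orc_arrival_rate,
    mcm_arrival_rate = mcm_arrival_rate,
    mean_first_om_s = mean_first_om_s,
    mean_second_om_s = mean_second_om_s,
    mean_mo_delay_s = mean_mo_delay_s,
    mean_mo_end_after_m2_s = mean_mo_end_after_m2_s,
    p_mo_given_first_mcm = p_mo_given_first_mcm,
    p_second_given_mo = p_second_given_mo,
    median_m1_release_s = median_m1_release_s,
    median_m1_with_mo_s = median_m1_with_mo_s,
    p_abortive_second = p_abortive_second,
    mean_abortive_dwell_s = mean_abortive_dwell_s,
    p_one_orc = p_one_orc,
    p_two_orc_sequential = p_two_orc_sequential,
    p_two_orc_overlap = p_two_orc_overlap,
    mean_orc_depart_after_om1_s = mean_orc_depart_after_om1_s,
    mean_5ra_loss_s = mean_5ra_loss_s,
    p_mo_dn119 = p_mo_dn119,
    extra_orc_poisson_mean = extra_orc_poisson_mean,
    mean_extra_orc_dwell_s = mean_extra_orc_dwell_s,
    mechanism = mechanism,
    mutant = mutant,
    dwell_sampler = dwell_sampler
  )
  validate_kinetic_params(p)
  class(p) <- "kinetic_params"
  p
}

validate_kinetic_params <- function(p) {
  rates <- c("orc_arrival_rate", "mcm_arrival_rate")
  means <- c("mean_first_om_s", "mean_second_om_s", "mean_mo_delay_s",
             "mean_mo_end_after_m2_s", "median_m1_release_s",
             "median_m1_with_mo_s", "mean_abortive_dwell_s",
             "mean_orc_depart_after_om1_s", "mean_5ra_loss_s",
             "mean_extra_orc_dwell_s")
  for (f in c(rates, means)) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("kinetic_params: `", f, "` must be a single positive number",
           call. = FALSE)
    }
  }
  probs <- c("p_mo_given_first_mcm", "p_second_given_mo", "p_abortive_second",
             "p_one_orc", "p_two_orc_sequential", "p_two_orc_overlap",
             "p_mo_dn119")
  for (f in probs) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("kinetic_params: `", f, "` must be a probability in [0, 1]",
           call. = FALSE)
    }
  }
  w <- p$p_one_orc + p$p_two_orc_sequential + p$p_two_orc_overlap
  if (w > 1 + 1e-12) {
    stop("kinetic_params: ORC-pathway mixture weights must sum to <= 1",
         call. = FALSE)
  }
  invisible(p)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params> mechanism =", x$mechanism, "| mutant =", x$mutant, "\n")
  cat(sprintf("  OM means %.3g / %.3g s; MO delay %.3g s; MO end lag %.3g s\n",
              x$mean_first_om_s, x$mean_second_om_s, x$mean_mo_delay_s,
              x$mean_mo_end_after_m2_s))
  cat(sprintf("  p(MO | first Mcm) = %.3g; p(second | MO) = %.3g\n",
              x$p_mo_given_first_mcm, x$p_second_given_mo))
  invisible(x)
}

# Label-class vocabularies. Donor dyes sit on ORC (Orc5-C, Orc6-C, or
# Orc1-N); acceptor dyes sit on Mcm2-7 (Mcm2-C, Mcm4-N, Mcm3-N) or Cdt1
# (N- or C-terminal). "dark" = unlabeled.
ORC_LABELS <- c("5C", "6C", "1N", "dark")
MCM_LABELS <- c("2C", "4N", "3N", "dark")
CDT1_LABELS <- c("N649", "C650", "dark")

#' Experiment design: sample size, acquisition length, and labeling plans
#'
#' @param n_dna Number of DNA molecules (spots) to simulate.
#' @param duration_cycles Number of 2.4-s acquisition cycles (default 600,
#'   ~24 min).
#' @param orc_label_plan Named probability vector over ORC label classes
#'   `c("5C","6C","1N","dark")`. Default: Orc5-C donor with the measured
#'   0.88 labeling fraction.
#' @param mcm_label_plan Named probability vector over Mcm2-7 label classes
#'   `c("2C","4N","3N","dark")`.
#' @param cdt1_label_plan Named probability vector over Cdt1 label classes
#'   `c("N649","C650","dark")`.
#' @param staged_prebound If `TRUE`, ORC/Cdc6 is prebound to the DNA before
#'   imaging starts and free ORC is withheld: ORC arrivals occur only at
#'   t = 0.
#' @param laser_exposure_factor Relative laser exposure (1.0 for alternating
#'   excitation; 2.4 for the continuous-illumination photobleaching
#'   control). Scales the per-exposure bleaching probability.
#' @return Object of class `experiment_design`.
#' @export
experiment_design <- function(n_dna = 64,
                              duration_cycles = 600,
                              orc_label_plan = c("5C" = 0.88, dark = 0.12),
                              mcm_label_plan = c("2C" = 1),
                              cdt1_label_plan = c(dark = 1),
                              staged_prebound = FALSE,
                              laser_exposure_factor = 1) {
  d <- list(
    n_dna = as.integer(n_dna),
    duration_cycles = as.integer(duration_cycles),
    orc_label_plan = check_plan(orc_label_plan, ORC_LABELS, "orc_label_plan"),
    mcm_label_plan = check_plan(mcm_label_plan, MCM_LABELS, "mcm_label_plan"),
    cdt1_label_plan = check_plan(cdt1_label_plan, CDT1_LABELS,
                                 "cdt1_label_plan"),
    staged_prebound = isTRUE(staged_prebound),
    laser_exposure_factor = laser_exposure_factor
  )
  if (d$n_dna < 1L) stop("experiment_design: n_dna must be >= 1", call. = FALSE)
  if (d$duration_cycles < 1L) {
    stop("experiment_design: duration_cycles must be >= 1", call. = FALSE)
  }
  if (!is.numeric(laser_exposure_factor) || laser_exposure_factor <= 0) {
    stop("experiment_design: laser_exposure_factor must be > 0", call. = FALSE)
  }
  class(d) <- "experiment_design"
  d
}

check_plan <- function(plan, allowed, what) {
  if (is.null(names(plan)) || any(!names(plan) %in% allowed)) {
    stop(what, ": names must be among {", paste(allowed, collapse = ", "), "}",
         call. = FALSE)
  }
  if (any(plan < 0) || abs(sum(plan) - 1) > 1e-8) {
    stop(what, ": probabilities must be non-negative and sum to 1",
         call. = FALSE)
  }
  full <- stats::setNames(numeric(length(allowed)), allowed)
  full[names(plan)] <- plan
  full
}

#' Frame timing of the alternating-excitation acquisition
#'
#' One 2.4-s cycle holds a 1-s donor-excited exposure and a 1-s
#' acceptor-excited exposure separated by 0.2-s dead times.
#'
#' @param cycle_s Cycle duration (s).
#' @param donor_exposure_s,acceptor_exposure_s Exposure durations (s).
#' @param dead_s Dead time between frames (s).
#' @param n_cycles Number of cycles.
#' @return Object of class `frame_timing`.
#' @export
frame_timing <- function(cycle_s = 2.4, donor_exposure_s = 1,
                         acceptor_exposure_s = 1, dead_s = 0.2,
                         n_cycles = 600) {
  if (abs(cycle_s - (donor_exposure_s + acceptor_exposure_s + 2 * dead_s)) >
      1e-9) {
    stop("frame_timing: cycle_s must equal donor + acceptor exposures + ",
         "2 * dead_s", call. = FALSE)
  }
  structure(list(cycle_s = cycle_s,
                 donor_exposure_s = donor_exposure_s,
                 acceptor_exposure_s = acceptor_exposure_s,
                 dead_s = dead_s,
                 n_cycles = as.integer(n_cycles)),
            class = "frame_timing")
}

#' Photophysical parameters of the trace forward model
#'
#' Apparent-FRET set-points are the measured state means of the system:
#' 0.72 and 0.79 for the first and second OM interactions, 0.73 for the MO
#' interaction, 0.08 for donor/acceptor coexistence without interaction,
#' 0.83 for an OM interaction with an additional N-terminally
#' acceptor-labeled Cdt1, 0.358 for the Orc5-C donor with only Cdt1-N
#' labeled, and 0.10 for the Orc6-C donor with a C-terminally labeled Cdt1.
#'
#' @param unit_intensity Arbitrary units emitted per active fluorophore per
#'   1-s exposure.
#' @param background_sd SD of the zero-mean additive background noise after
#'   correction, in the same arbitrary units. The default gives a per-frame
#'   SNR of about 7 for one acceptor fluorophore (4.7 on the summed
#'   donor-excited channel), calibrated once so that interval detection at
#'   the default 0.4 FRET threshold meets the >= 95% recovery fidelity the
#'   analysis layer promises.
#' @param efret_om_first,efret_om_second,efret_mo,efret_baseline
#'   Apparent-FRET set-points (dimensionless, in \[0, 1\]).
#' @param efret_om_with_cdt1N Composite OM set-point with labeled Cdt1-N.
#' @param efret_cdt1N_control,efret_cdt1C_control Baseline set-points for
#'   donor + labeled Cdt1 without an OM/MO interaction (Orc5-C/Cdt1-N and
#'   Orc6-C/Cdt1-C pairs respectively).
#' @param pife_factor Multiplier on donor-excited total emission during OM
#'   interactions (protein-induced fluorescence enhancement of the donor
#'   dye; the effect is qualitative in the source data, default 1.3).
#' @param bleach_prob_per_exposure Per-dye bleaching probability per
#'   illuminated 1-s frame at laser exposure factor 1.
#' @return Object of class `photophysics_params`.
#' @export
photophysics_params <- function(unit_intensity = 1000,
                                background_sd = 150,
                                efret_om_first = 0.72,
                                efret_om_second = 0.79,
                                efret_mo = 0.73,
                                efret_baseline = 0.08,
                                efret_om_with_cdt1N = 0.83,
                                efret_cdt1N_control = 0.358,
                                efret_cdt1C_control = 0.10,
                                pife_factor = 1.3,
                                bleach_prob_per_exposure = 5e-4) {
  p <- list(unit_intensity = unit_intensity,
            background_sd = background_sd,
            efret_om_first = efret_om_first,
            efret_om_second = efret_om_second,
            efret_mo = efret_mo,
            efret_baseline = efret_baseline,
            efret_om_with_cdt1N = efret_om_with_cdt1N,
            efret_cdt1N_control = efret_cdt1N_control,
            efret_cdt1C_control = efret_cdt1C_control,
            pife_factor = pife_factor,
            bleach_prob_per_exposure = bleach_prob_per_exposure)
  es <- grep("^efret_", names(p), value = TRUE)
  for (f in es) {
    if (p[[f]] < 0 || p[[f]] > 1) {
      stop("photophysics_params: `", f, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  if (p$pife_factor < 1) {
    stop("photophysics_params: pife_factor must be >= 1", call. = FALSE)
  }
  if (p$bleach_prob_per_exposure < 0 || p$bleach_prob_per_exposure > 1) {
    stop("photophysics_params: bleach_prob_per_exposure must be in [0, 1]",
         call. = FALSE)
  }
  if (p$unit_intensity <= 0 || p$background_sd < 0) {
    stop("photophysics_params: unit_intensity > 0 and background_sd >= 0 ",
         "required", call. = FALSE)
  }
  class(p) <- "photophysics_params"
  p
}

#' Analysis thresholds used by the detection layer
#'
#' @param k_on,k_off Hysteresis thresholds for presence detection, in units
#'   of the channel noise SD (`k_on > k_off`).
#' @param max_gap_frames Number of consecutive sub-threshold frames
#'   tolerated inside a presence or FRET interval.
#' @param fret_threshold High-FRET threshold on apparent FRET efficiency;
#'   default 0.4, the midpoint between the 0.08 baseline and the ~0.72 high
#'   state.
#' @param fret_min_frames Minimum qualifying frames for a FRET interval
#'   (1: a detection minimum above one frame left-truncates the dwell
#'   sample and biases exponential fits upward by the truncation point).
#' @param confirm_window_s Window (s) within which acceptor presence must be
#'   confirmed around a FRET-interval onset.
#' @param step_alpha Significance level of the per-step Welch test in the
#'   changepoint (binary-segmentation) step detector.
#' @param success_min_s Minimum retention (s) of each Mcm2-7 for a
#'   double-hexamer event to be called successful (> 48 s, i.e. 20 frames).
#' @param coincidence_window_s Temporal resolution (s) used for coincidence
#'   calls; one acquisition cycle.
#' @param attribution_window_s Window (s) for attributing a FRET peak to an
#'   Mcm2-7 arrival.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(k_on = 4, k_off = 2, max_gap_frames = 1,
                            fret_threshold = 0.4, fret_min_frames = 1,
                            confirm_window_s = 4.8, step_alpha = 1e-3,
                            success_min_s = 48, coincidence_window_s = 2.4,
                            attribution_window_s = 4.8) {
  if (k_on <= k_off || k_off <= 0) {
    stop("analysis_config: need k_on > k_off > 0", call. = FALSE)
  }
  if (fret_threshold <= 0 || fret_threshold >= 1) {
    stop("analysis_config: fret_threshold must lie in (0, 1)", call. = FALSE)
  }
  structure(list(k_on = k_on, k_off = k_off,
                 max_gap_frames = as.integer(max_gap_frames),
                 fret_threshold = fret_threshold,
                 fret_min_frames = as.integer(fret_min_frames),
                 confirm_window_s = confirm_window_s,
                 step_alpha = step_alpha,
                 success_min_s = success_min_s,
                 coincidence_window_s = coincidence_window_s,
                 attribution_window_s = attribution_window_s),
            class = "analysis_config")
}
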