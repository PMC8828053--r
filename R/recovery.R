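# In-silico parameter-recovery experiments: simulate a cohort under a
# preset, run the full detection/classification pipeline, and re-estimate
# the generating quantity. These back the package's validation suite.

#' Parameter-recovery experiments
#'
#' Each function simulates a seeded cohort with the study-condition
#' parameters, renders traces (photobleaching disabled so that dwell ends
#' reflect chemistry, as in the source analyses), runs the full pipeline,
#' and recovers one population quantity:
#' \describe{
#'   \item{recover_om_dwells}{Censored-exponential MLE of the first and
#'     second OM interaction durations from detected high-FRET intervals
#'     attributed to the two Mcm2-7 arrivals (conditioned double-hexamer
#'     cohort, OM labeling).}
#'   \item{recover_mo_end_lag}{Mean detected lag from the second Mcm2-7
#'     arrival step to the end of the MO-FRET interval (MO labeling).}
#'   \item{recover_cdt1_mo_lag}{Mean detected lag from the first Cdt1
#'     release (half-loss step) to MO-FRET onset (MO labeling plus
#'     C-terminally labeled Cdt1).}
#'   \item{recover_5ra_om}{Censored-exponential MLE of OM-FRET durations
#'     for the Cdt1-release-defective Mcm5-R549A mutant, whose OM end is
#'     the composite fluorophore-loss process.}
#'   \item{recover_efret_window}{Grand mean apparent FRET over the 10-s
#'     windows after first Mcm2-7 arrivals, restricted to frames inside
#'     the detected OM interval (the interval mean is the state value the
#'     window statistic reports), with the +/- 2 exclusion rule.}
#'   \item{recover_conversion_fraction}{Fraction of detected first-Mcm2-7
#'     binding events converting to stable (> 48 s) second recruitment
#'     under the study branch probabilities.}
#'   \item{recover_lone_mcm_median}{Median detected lifetime of the first
#'     Mcm2-7 after ORC departure with the MO branch suppressed.}
#' }
#'
#' @param n_dna Cohort size (DNA molecules).
#' @param seed Integer seed; all stage seeds derive from it.
#' @return A list with the recovered quantity (see each function), the
#'   event count `n` used, and intermediate fits where applicable.
#' @name recovery
NULL

cohort <- function(preset_name, n_dna, seed, conditioned = TRUE, ...) {
  extra <- list(...)
  args <- c(list(preset_name = preset_name, n_dna = n_dna, seed = seed),
            if (conditioned) {
              list(p_mo_given_first_mcm = 1, p_second_given_mo = 1,
                   p_one_orc = 1, p_two_orc_sequential = 0,
                   p_two_orc_overlap = 0)
            },
            extra)
  cfg <- do.call(run_config, args)
  tc <- simulate_experiment(cfg)  # bleach = FALSE by default
  list(cfg = cfg, tc = tc, res = analyze_traces(tc, cfg$analysis))
}

# High-FRET intervals attributed to an arrival time, over a cohort.
# A first-OM interval whose detected end reaches past the second arrival
# is a fusion of the two OM periods across a sub-resolution gap; such
# intervals are excluded rather than charged to the first dwell. The gap
# is independent of the first-OM duration (the state chain is
# memoryless), so the exclusion does not bias the dwell sample.
attributed_intervals <- function(res, which = c("m1", "m2"), window = 4.8) {
  which <- match.arg(which)
  ev <- res$events
  d <- numeric(); cens <- logical()
  for (a in res$analyses) {
    e <- ev[ev$dna_id == a$dna_id, ]
    if (!nrow(e)) next
    t_ref <- e[[paste0(which, "_time")]]
    if (is.na(t_ref)) next
    fi <- a$fret_intervals
    if (!nrow(fi)) next
    k <- which(abs(fi$t_start - t_ref) <= window)
    if (which == "m1" && length(k) && !is.na(e$m2_time) &&
        fi$t_end[k[1]] > e$m2_time) {
      next  # fused with the second OM period
    }
    if (length(k)) {
      d <- c(d, fi$t_end[k[1]] - fi$t_start[k[1]])
      cens <- c(cens, fi$right_censored[k[1]])
    }
  }
  list(durations = d, censored = cens)
}

#' @rdname recovery
#' @export
recover_om_dwells <- function(n_dna = 400, seed = 1L) {
  co <- cohort("fig1", n_dna, seed)
  om1 <- attributed_intervals(co$res, "m1")
  om2 <- attributed_intervals(co$res, "m2")
  # t_min = two cycles: safely above the detection floor, so the fitted
  # means are free of the left-truncation bias of undetectable dwells
  list(first = fit_exponential_mle(om1$durations, om1$censored,
                                   bootstrap_B = 500,
                                   rng_seed = sub_seed(seed, 21L),
                                   t_min = 4.8),
       second = fit_exponential_mle(om2$durations, om2$censored,
                                    bootstrap_B = 500,
                                    rng_seed = sub_seed(seed, 22L),
                                    t_min = 4.8),
       n = c(first = length(om1$durations), second = length(om2$durations)),
       cohort = co)
}

#' @rdname recovery
#' @export
recover_mo_end_lag <- function(n_dna = 360, seed = 2L) {
  co <- cohort("fig5-MO", n_dna, seed)
  ev <- co$res$events
  lags <- numeric()
  for (a in co$res$analyses) {
    e <- ev[ev$dna_id == a$dna_id, ]
    if (!nrow(e) || is.na(e$m2_time)) next
    fi <- a$fret_intervals
    if (!nrow(fi)) next
    k <- which(fi$t_start < e$m2_time & fi$t_end > e$m2_time - 2.4 &
                 !fi$right_censored)
    if (length(k)) lags <- c(lags, fi$t_end[k[1]] - e$m2_time)
  }
  list(mean_lag_s = mean(lags), se = stats::sd(lags) / sqrt(length(lags)),
       n = length(lags))
}

#' @rdname recovery
#' @export
recover_cdt1_mo_lag <- function(n_dna = 360, seed = 3L) {
  co <- cohort("fig6-cdt1C", n_dna, seed)
  ev <- co$res$events
  lags <- numeric()
  for (a in co$res$analyses) {
    e <- ev[ev$dna_id == a$dna_id, ]
    if (!nrow(e) || is.na(e$m2_time)) next
    hl <- a$steps[a$steps$classification %in% "half_loss", ]
    hl <- hl$time_s[hl$time_s > e$m1_time & hl$time_s < e$m2_time]
    if (!length(hl)) next
    fi <- a$fret_intervals
    k <- which(fi$t_start < e$m2_time & fi$t_end > e$m2_time - 2.4)
    if (!length(k)) next
    lags <- c(lags, fi$t_start[k[1]] - hl[1])
  }
  list(mean_lag_s = mean(lags), se = stats::sd(lags) / sqrt(length(lags)),
       n = length(lags))
}

#' @rdname recovery
#' @export
recover_5ra_om <- function(n_dna = 330, seed = 4L) {
  co <- cohort("fig4-5RA", n_dna, seed, conditioned = FALSE,
               p_one_orc = 1, p_two_orc_sequential = 0,
               p_two_orc_overlap = 0)
  om <- attributed_intervals(co$res, "m1")
  list(fit = fit_exponential_mle(om$durations, om$censored,
                                 bootstrap_B = 500,
                                 rng_seed = sub_seed(seed, 23L),
                                 t_min = 4.8),
       n = length(om$durations))
}

#' @rdname recovery
#' @param exclude E values with magnitude above this are excluded.
#' @param cohort_obj Optionally reuse an already-simulated cohort (as
#'   returned internally); `NULL` simulates afresh.
#' @export
recover_efret_window <- function(n_dna = 150, seed = 5L, exclude = 2,
                                 cohort_obj = NULL) {
  co <- cohort_obj %||% cohort("fig1", n_dna, seed)
  ev <- co$res$events
  vals <- numeric()
  n_events <- 0L
  for (a in co$res$analyses) {
    e <- ev[ev$dna_id == a$dna_id, ]
    if (!nrow(e) || is.na(e$m2_time)) next
    fi <- a$fret_intervals
    k <- which(abs(fi$t_start - e$m1_time) <= 4.8)
    if (!length(k)) next
    n_events <- n_events + 1L
    sel <- a$efret$valid & !is.na(a$efret$E) &
      a$efret$time_s >= e$m1_time & a$efret$time_s < e$m1_time + 10 &
      a$efret$time_s >= fi$t_start[k[1]] &
      a$efret$time_s + 2.4 <= fi$t_end[k[1]] + 1e-9
    v <- a$efret$E[sel]
    vals <- c(vals, v[abs(v) <= exclude])
  }
  list(mean_efret = mean(vals),
       sem = stats::sd(vals) / sqrt(length(vals)),
       n_frames = length(vals), n_events = n_events)
}

#' @rdname recovery
#' @param eligible_before_s First-arrival cutoff (s) so that conversion
#'   has room to occur before the trace ends.
#' @export
recover_conversion_fraction <- function(n_dna = 1000, seed = 6L,
                                        eligible_before_s = 1080) {
  co <- cohort("fig5-MO", n_dna, seed, conditioned = FALSE)
  ev <- co$res$events
  elig <- ev[ev$m1_time < eligible_before_s, ]
  pr <- proportion_with_se(sum(elig$success), nrow(elig))
  c(pr, list(events = elig))
}

#' @rdname recovery
#' @export
recover_lone_mcm_median <- function(n_dna = 330, seed = 7L) {
  co <- cohort("fig1", n_dna, seed, conditioned = FALSE,
               p_mo_given_first_mcm = 0, p_one_orc = 1,
               p_two_orc_sequential = 0, p_two_orc_overlap = 0)
  lags <- numeric()
  for (a in co$res$analyses) {
    di <- a$donor_intervals
    ai <- a$acceptor_intervals
    if (!nrow(di) || !nrow(ai)) next
    if (di$right_censored[1] || ai$right_censored[1]) next
    lag <- ai$t_end[1] - di$t_end[1]
    if (lag > 0) lags <- c(lags, lag)
  }
  list(median_s = stats::median(lags), n = length(lags))
}
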