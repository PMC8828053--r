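#' Assemble double-hexamer (and abortive) loading events
#'
#' Builds candidate events from the acceptor-channel step record of each
#' DNA: the first two arrival steps are the first and second Mcm2-7
#' arrivals. Retention of each helicase runs from its arrival to the first
#' subsequent departure-classified down-step (departures between the two
#' arrivals are charged to the first helicase; after the second arrival
#' the first departure is charged to the second helicase), right-censored
#' at trace end. An event is a successful double hexamer when both
#' retentions exceed `success_min_s` (> 48 s, i.e. 20 or more acquisition
#' frames); events with a short-lived second association are recorded as
#' unsuccessful.
#'
#' @param analyses A list of `dna_analysis` objects (see [analyze_dna()]),
#'   or a single one.
#' @param config An [analysis_config()].
#' @param t_total Trace duration (s) used for censoring.
#' @return A data frame of `event_record` rows (one per DNA with at least
#'   one Mcm2-7 arrival): `dna_id`, `m1_time`, `m2_time`, `m1_retention`,
#'   `m2_retention`, `m1_censored`, `m2_censored`, `n_arrivals`, `success`.
#' @export
find_double_hexamer_events <- function(analyses, config = analysis_config(),
                                       t_total = 1440) {
  if (inherits(analyses, "dna_analysis")) analyses <- list(analyses)
  rows <- lapply(analyses, function(a) {
    st <- a$steps
    ups <- st[st$direction == "up" & st$classification %in% "arrival", ,
              drop = FALSE]
    if (!nrow(ups)) return(NULL)
    downs <- st[st$direction == "down" &
                  st$classification %in% "departure", , drop = FALSE]
    m1 <- ups$time_s[1]
    m2 <- if (nrow(ups) >= 2L) ups$time_s[2] else NA_real_
    ret <- function(from, upto = Inf) {
      d <- downs$time_s[downs$time_s > from & downs$time_s <= upto]
      if (length(d)) c(d[1] - from, FALSE) else c(t_total - from, TRUE)
    }
    if (is.na(m2)) {
      r1 <- ret(m1)
      return(data.frame(dna_id = a$dna_id, m1_time = m1, m2_time = NA_real_,
                        m1_retention = r1[1], m2_retention = NA_real_,
                        m1_censored = as.logical(r1[2]), m2_censored = NA,
                        n_arrivals = nrow(ups), success = FALSE))
    }
    d_between <- downs$time_s[downs$time_s > m1 & downs$time_s <= m2]
    d_after <- downs$time_s[downs$time_s > m2]
    if (length(d_between)) {
      r1 <- c(d_between[1] - m1, FALSE)
    } else if (length(d_after) >= 2L) {
      r1 <- c(d_after[2] - m1, FALSE)
    } else {
      r1 <- c(t_total - m1, TRUE)
    }
    r2 <- if (length(d_after)) c(d_after[1] - m2, FALSE)
          else c(t_total - m2, TRUE)
    success <- r1[1] > config$success_min_s & r2[1] > config$success_min_s
    data.frame(dna_id = a$dna_id, m1_time = m1, m2_time = m2,
               m1_retention = r1[1], m2_retention = r2[1],
               m1_censored = as.logical(r1[2]),
               m2_censored = as.logical(r2[2]),
               n_arrivals = nrow(ups), success = success)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(dna_id = integer(), m1_time = numeric(),
                      m2_time = numeric(), m1_retention = numeric(),
                      m2_retention = numeric(), m1_censored = logical(),
                      m2_censored = logical(), n_arrivals = integer(),
                      success = logical())
  }
  rownames(out) <- NULL
  out
}

#' Count ORC molecules engaged over a loading event
#'
#' Classifies ORC usage from donor presence intervals relative to the two
#' Mcm2-7 arrival times: class `"1"` when a single ORC interval spans the
#' whole recruitment window; `"2_sequential"` when the first interval ends
#' before a second begins, both before the second arrival; `"2_overlap"`
#' when a second ORC joins while the first persists; `"3+"` otherwise.
#' Events with no overlapping ORC interval are flagged `"unlabeled"` and
#' are excluded from FRET analyses.
#'
#' @param event One row of the event table ([find_double_hexamer_events()]).
#' @param orc_intervals Donor presence intervals for that DNA.
#' @param tol_s Matching tolerance (s), one cycle by default.
#' @return Character scalar: `"1"`, `"2_sequential"`, `"2_overlap"`,
#'   `"3+"`, or `"unlabeled"`.
#' @export
count_orc <- function(event, orc_intervals, tol_s = 2.4) {
  m1 <- event$m1_time
  m2 <- if (is.na(event$m2_time)) event$m1_time else event$m2_time
  iv <- orc_intervals
  if (is.null(iv) || !nrow(iv)) return("unlabeled")
  ov <- iv[iv$t_end > m1 - tol_s & iv$t_start < m2 + tol_s, , drop = FALSE]
  n <- nrow(ov)
  if (n == 0L) return("unlabeled")
  if (n == 1L) return("1")
  if (n == 2L) {
    ov <- ov[order(ov$t_start), ]
    if (ov$t_end[1] <= ov$t_start[2] + tol_s) return("2_sequential")
    return("2_overlap")
  }
  "3+"
}

#' Classify the OM-FRET profile of a loading event
#'
#' A high-FRET interval is attributed to Mcm2-7 arrival i when its onset
#' lies within the attribution window (default 4.8 s) of that arrival.
#' Profiles are `two_peak`, `first_only`, `second_only`, or `none`;
#' intervals attributable to neither arrival flag the event anomalous.
#' Under a mixed C/N acceptor-labeling design the profile maps onto the
#' double-hexamer type: two peaks = CC, first-only = CN, second-only = NC,
#' none = NN (C = the FRET-coupled label position).
#'
#' @param event One event row.
#' @param fret_intervals High-FRET intervals for that DNA.
#' @param config An [analysis_config()].
#' @param infer_type If `TRUE`, also return the inferred CC/CN/NC/NN type.
#' @return A list: `profile`, `inferred_type`, `anomalous`.
#' @export
classify_fret_profile <- function(event, fret_intervals,
                                  config = analysis_config(),
                                  infer_type = TRUE) {
  w <- config$attribution_window_s
  iv <- fret_intervals
  near <- function(t) {
    !is.na(t) && !is.null(iv) && nrow(iv) &&
      any(abs(iv$t_start - t) <= w)
  }
  p1 <- near(event$m1_time)
  p2 <- near(event$m2_time)
  anomalous <- FALSE
  if (!is.null(iv) && nrow(iv)) {
    attributed <- vapply(iv$t_start, function(on) {
      (!is.na(event$m1_time) && abs(on - event$m1_time) <= w) ||
        (!is.na(event$m2_time) && abs(on - event$m2_time) <= w)
    }, logical(1))
    anomalous <- any(!attributed)
  }
  profile <- if (p1 && p2) "two_peak" else if (p1) "first_only"
    else if (p2) "second_only" else "none"
  type <- if (infer_type) {
    switch(profile, two_peak = "CC", first_only = "CN",
           second_only = "NC", none = "NN")
  } else NA_character_
  list(profile = profile, inferred_type = type, anomalous = anomalous)
}

#' Coincidence call between two event times
#'
#' Two times are simultaneous when their lag is within the temporal
#' resolution of the acquisition (one 2.4-s cycle by default).
#'
#' @param time_a,time_b Event times (s); `NA` yields an undefined call.
#' @param window_s Coincidence window (s).
#' @return A list: `call` (`"simultaneous"`, `"a_first"`, `"b_first"`, or
#'   `NA`) and signed `lag_s` (`time_b - time_a`).
#' @export
coincidence <- function(time_a, time_b, window_s = 2.4) {
  if (is.na(time_a) || is.na(time_b)) {
    return(list(call = NA_character_, lag_s = NA_real_))
  }
  lag <- time_b - time_a
  call <- if (abs(lag) <= window_s) "simultaneous"
    else if (lag > 0) "a_first" else "b_first"
  list(call = call, lag_s = lag)
}

#' Classify a whole cohort of analyzed DNAs
#'
#' Convenience wrapper combining [find_double_hexamer_events()],
#' [count_orc()] and [classify_fret_profile()] over a list of analyses.
#'
#' @param analyses List of `dna_analysis` objects.
#' @param config An [analysis_config()].
#' @param t_total Trace duration (s).
#' @return The event table with `orc_class`, `fret_profile`,
#'   `inferred_type` and `anomalous` columns appended.
#' @export
classify_events <- function(analyses, config = analysis_config(),
                            t_total = 1440) {
  ev <- find_double_hexamer_events(analyses, config, t_total)
  if (!nrow(ev)) {
    ev$orc_class <- character()
    ev$fret_profile <- character()
    ev$inferred_type <- character()
    ev$anomalous <- logical()
    return(ev)
  }
  byid <- stats::setNames(analyses,
                          vapply(analyses, `[[`, numeric(1), "dna_id"))
  ev$orc_class <- NA_character_
  ev$fret_profile <- NA_character_
  ev$inferred_type <- NA_character_
  ev$anomalous <- NA
  for (i in seq_len(nrow(ev))) {
    a <- byid[[as.character(ev$dna_id[i])]]
    ev$orc_class[i] <- count_orc(ev[i, ], a$donor_intervals,
                                 tol_s = config$coincidence_window_s)
    cf <- classify_fret_profile(ev[i, ], a$fret_intervals, config)
    ev$fret_profile[i] <- cf$profile
    ev$inferred_type[i] <- cf$inferred_type
    ev$anomalous[i] <- cf$anomalous
  }
  ev
}
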