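#' Background-correct a trace set
#'
#' For each DNA and channel, subtracts a baseline estimated as the median
#' of frames outside detected presence (a coarse threshold pass), iterated
#' once after re-detection on the corrected series. If a channel is
#' occupied in essentially all frames, a global robust baseline (overall
#' median) is used and the channel is flagged.
#'
#' Simulated traces model already background-corrected records, so on them
#' this is a no-op to within noise; the operation matters for externally
#' supplied traces with offsets.
#'
#' @param traceset A `trace_set`.
#' @return The `trace_set` with corrected intensities and a `baselines`
#'   data frame (`dna_id`, `channel`, `baseline`, `global_fallback`).
#' @export
correct_background <- function(traceset) {
  stopifnot(inherits(traceset, "trace_set"))
  df <- traceset$traces
  rows <- list()
  for (id in unique(df$dna_id)) {
    sel <- df$dna_id == id
    sub <- df[sel, ]
    dsel <- sub$frame_kind == "donor_ex"
    for (ch in c("I_Dex_Dem", "I_Dex_Aem", "I_Aex_Aem")) {
      fsel <- if (ch == "I_Aex_Aem") !dsel else dsel
      x <- sub[[ch]][fsel]
      bl <- baseline_of(x)
      df[[ch]][sel][fsel] <- x - bl$baseline
      rows[[length(rows) + 1L]] <- data.frame(
        dna_id = id, channel = ch, baseline = bl$baseline,
        global_fallback = bl$global_fallback)
    }
  }
  traceset$traces <- df
  traceset$baselines <- do.call(rbind, rows)
  traceset
}

# Baseline = median of frames outside detected presence, iterated once.
# Traces are nominally background-corrected already, so presence is
# detected about zero and the outside-frame median removes residual
# offsets (valid while |offset| stays below the k_off detection
# threshold; larger offsets need an explicit baseline). A channel
# occupied in every frame falls back to the global median, flagged.
baseline_of <- function(x) {
  sig <- stats::mad(diff(x)) / sqrt(2)
  if (sig == 0) sig <- max(abs(x)) * 1e-9 + 1e-12  # noiseless limit
  cfg <- analysis_config()
  pass <- function(v) {
    iv <- presence_from_series(v, seq_along(v), cfg, noise_sd = sig,
                               cycle = 1)
    outside <- !in_any_interval(seq_along(v), iv)
    if (sum(outside) < 3L) {
      # Channel occupied in essentially every frame: no per-trace empty
      # cluster exists. Traces are nominally pre-corrected, so leave the
      # channel untouched rather than subtract its signal level.
      return(list(b = 0, fallback = TRUE))
    }
    list(b = stats::median(v[outside]), fallback = FALSE)
  }
  p1 <- pass(x)
  if (p1$fallback) return(list(baseline = 0, global_fallback = TRUE))
  p2 <- pass(x - p1$b)
  list(baseline = p1$b + if (p2$fallback) 0 else p2$b,
       global_fallback = FALSE)
}

# Extract one detection series for a DNA. The donor series is the
# donor-excited *total* emission (D_em + A_em), which is conserved under
# FRET and therefore reports donor presence independently of FRET state;
# the acceptor series is the acceptor-excited emission.
channel_series <- function(traceset, dna_id,
                           channel = c("donor", "acceptor")) {
  channel <- match.arg(channel)
  sub <- traceset$traces[traceset$traces$dna_id == dna_id, ]
  if (channel == "donor") {
    sub <- sub[sub$frame_kind == "donor_ex", ]
    list(x = sub$I_Dex_Dem + sub$I_Dex_Aem, time_s = sub$time_s,
         dem = sub$I_Dex_Dem, aem = sub$I_Dex_Aem)
  } else {
    sub <- sub[sub$frame_kind == "acceptor_ex", ]
    list(x = sub$I_Aex_Aem, time_s = sub$time_s)
  }
}

#' Detect presence intervals in one channel of one DNA
#'
#' Hysteresis thresholding: an interval must contain at least one frame at
#' or above `k_on` noise SDs and extends over contiguous frames at or above
#' `k_off` SDs, tolerating up to `max_gap_frames` consecutive sub-threshold
#' frames. Interval end times are the start of the first frame after the
#' last qualifying frame (one-cycle quantization); intervals touching the
#' trace end are flagged right-censored.
#'
#' @param traceset A background-corrected `trace_set`.
#' @param dna_id DNA to analyze.
#' @param channel `"donor"` (donor-excited total emission) or `"acceptor"`
#'   (acceptor-excited emission).
#' @param config An [analysis_config()].
#' @param noise_sd Channel noise SD; estimated robustly from first
#'   differences when `NULL`.
#' @return Data frame with `channel`, `t_start`, `t_end`,
#'   `right_censored`.
#' @export
detect_presence <- function(traceset, dna_id, channel = "donor",
                            config = analysis_config(), noise_sd = NULL) {
  ser <- channel_series(traceset, dna_id, channel)
  iv <- presence_from_series(ser$x, ser$time_s, config, noise_sd,
                             cycle = traceset$timing$cycle_s)
  if (nrow(iv)) iv <- cbind(channel = channel, iv)
  else iv <- data.frame(channel = character(), t_start = numeric(),
                        t_end = numeric(), right_censored = logical())
  iv
}

presence_from_series <- function(x, time_s, config, noise_sd = NULL,
                                 cycle = 2.4) {
  if (is.null(noise_sd)) noise_sd <- robust_sd(x)
  if (!is.finite(noise_sd) || noise_sd <= 0) {
    # noiseless series (e.g. background_sd = 0 renders): any nonzero
    # signal clears an arbitrarily small threshold
    noise_sd <- max(abs(x)) * 1e-9 + 1e-12
  }
  on <- x >= config$k_on * noise_sd
  off <- x >= config$k_off * noise_sd
  runs <- qualifying_runs(off, config$max_gap_frames)
  out <- list()
  for (r in runs) {
    if (!any(on[r[1]:r[2]])) next
    out[[length(out) + 1L]] <- data.frame(
      t_start = time_s[r[1]],
      t_end = time_s[r[2]] + cycle,
      right_censored = r[2] == length(x))
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(t_start = numeric(), t_end = numeric(),
                  right_censored = logical())
}

robust_sd <- function(x) stats::mad(diff(x)) / sqrt(2)

# Runs of TRUE allowing gaps of up to max_gap FALSE frames inside a run.
qualifying_runs <- function(flag, max_gap) {
  n <- length(flag)
  idx <- which(flag)
  if (!length(idx)) return(list())
  runs <- list()
  s <- idx[1]; e <- idx[1]
  for (i in idx[-1]) {
    if (i - e - 1L <= max_gap) e <- i
    else { runs[[length(runs) + 1L]] <- c(s, e); s <- i; e <- i }
  }
  runs[[length(runs) + 1L]] <- c(s, e)
  runs
}

#' Apparent FRET efficiency series
#'
#' Computes `E = I_Dex_Aem / (I_Dex_Aem + I_Dex_Dem)` on donor-excited
#' frames. Values are defined only where the validity mask holds (a donor
#' present AND at least one acceptor present, from the supplied presence
#' intervals); on masked-valid frames the ratio is emitted as-is even when
#' the denominator is non-positive, so values outside \[0, 1\] occur and are
#' never clamped. Histogram-style exports exclude values below -2 or above
#' +2 via [efret_values()].
#'
#' @param traceset A background-corrected `trace_set`.
#' @param dna_id DNA to analyze.
#' @param donor_intervals,acceptor_intervals Presence-interval data frames
#'   (see [detect_presence()]).
#' @return An `efret_series` data frame: `time_s`, `E`, `valid`.
#' @export
compute_efret <- function(traceset, dna_id, donor_intervals,
                          acceptor_intervals) {
  ser <- channel_series(traceset, dna_id, "donor")
  valid <- in_any_interval(ser$time_s, donor_intervals) &
    in_any_interval(ser$time_s, acceptor_intervals,
                    shift = -1.2)  # acceptor frames trail donor frames
  E <- ifelse(valid, ser$aem / (ser$aem + ser$dem), NA_real_)
  structure(data.frame(time_s = ser$time_s, E = E, valid = valid,
                       donor_total = ser$dem + ser$aem),
            class = c("efret_series", "data.frame"))
}

in_any_interval <- function(t, intervals, shift = 0) {
  if (is.null(intervals) || !nrow(intervals)) return(rep(FALSE, length(t)))
  out <- rep(FALSE, length(t))
  for (r in seq_len(nrow(intervals))) {
    out <- out | (t >= intervals$t_start[r] + shift &
                    t < intervals$t_end[r])
  }
  out
}

#' @rdname compute_efret
#' @param series An `efret_series`.
#' @param exclude Magnitude beyond which values are excluded (default 2).
#' @return `efret_values`: the vector of valid E values with |E| <=
#'   `exclude`.
#' @export
efret_values <- function(series, exclude = 2) {
  v <- series$E[series$valid]
  v[!is.na(v) & abs(v) <= exclude]
}

#' Detect stepwise intensity changes
#'
#' Changepoints in the acceptor-excited series are located by binary
#' segmentation on frame means with a per-split Welch two-sample test at
#' `step_alpha`. Down-steps whose magnitude is 35-65% of the preceding
#' up-step are classified `half_loss` (release of one of two co-arrived
#' acceptors, e.g. Cdt1); down-steps matching the full current intensity
#' are `departure`; up-steps are `arrival`. Step times follow the
#' convention that an event time is the start of the first frame in the
#' new state.
#'
#' @param traceset A background-corrected `trace_set`.
#' @param dna_id DNA to analyze.
#' @param config An [analysis_config()].
#' @param noise_sd Optional known noise SD (unused by the Welch test but
#'   kept for API symmetry).
#' @return Data frame: `time_s`, `channel`, `direction`, `magnitude`,
#'   `classification`.
#' @export
detect_steps <- function(traceset, dna_id, config = analysis_config(),
                         noise_sd = NULL) {
  ser <- channel_series(traceset, dna_id, "acceptor")
  steps_from_series(ser$x, ser$time_s, config$step_alpha, noise_sd)
}

steps_from_series <- function(x, time_s, alpha = 1e-3, noise_sd = NULL,
                              min_step_sd = 3) {
  if (is.null(noise_sd)) noise_sd <- robust_sd(x)
  if (!is.finite(noise_sd) || noise_sd <= 0) {
    noise_sd <- max(abs(x)) * 1e-9 + 1e-12  # noiseless limit
  }
  cps <- sort(binseg(x, 1L, length(x), alpha, sigma = noise_sd))
  empty <- data.frame(time_s = numeric(), channel = character(),
                      direction = character(), magnitude = numeric(),
                      classification = character())
  if (!length(cps)) return(empty)
  # Merge away statistically significant but physically implausible
  # changepoints (mean shifts below min_step_sd noise SDs): long flat
  # stretches otherwise yield small spurious steps, and single physical
  # transitions landing inside an exposure split into two sub-steps.
  repeat {
    bounds <- c(0L, cps, length(x))
    seg_means <- vapply(seq_len(length(bounds) - 1L), function(i) {
      mean(x[(bounds[i] + 1L):bounds[i + 1L]])
    }, numeric(1))
    if (!length(cps)) return(empty)
    deltas <- abs(diff(seg_means))
    worst <- which.min(deltas)
    if (deltas[worst] >= min_step_sd * noise_sd) break
    cps <- cps[-worst]
  }
  # A physical transition inside one exposure splits into two
  # same-direction sub-steps around the partial frame; keep the earlier
  # boundary (the partial frame belongs to the new state).
  repeat {
    bounds <- c(0L, cps, length(x))
    seg_means <- vapply(seq_len(length(bounds) - 1L), function(i) {
      mean(x[(bounds[i] + 1L):bounds[i + 1L]])
    }, numeric(1))
    if (length(cps) < 2L) break
    d <- diff(seg_means)
    adj <- which(diff(cps) == 1L & sign(d[-length(d)]) == sign(d[-1]))
    if (!length(adj)) break
    cps <- cps[-(adj[1] + 1L)]
  }
  out <- empty
  last_up <- NA_real_
  for (i in seq_along(cps)) {
    mag <- seg_means[i + 1L] - seg_means[i]
    dir <- if (mag > 0) "up" else "down"
    cls <- NA_character_
    if (dir == "up") {
      cls <- "arrival"
      last_up <- mag
    } else {
      level <- seg_means[i]
      ratio_up <- if (!is.na(last_up) && last_up > 0) -mag / last_up else NA
      if (level > 0 && -mag >= 0.8 * level) {
        cls <- "departure"  # takes the channel to (near) zero
      } else if (!is.na(ratio_up) && ratio_up >= 0.35 && ratio_up <= 0.65) {
        cls <- "half_loss"
      }
    }
    out <- rbind(out, data.frame(
      time_s = time_s[cps[i] + 1L], channel = "acceptor",
      direction = dir, magnitude = abs(mag), classification = cls))
  }
  out
}

# Binary segmentation: candidate split by the CUSUM statistic, then a
# two-sample z test at the chosen split using the global robust noise
# scale (first differences are insensitive to the steps themselves).
# Per-segment variance estimates are not used: segments adjacent to an
# early or late event can be only a few frames long, where a Welch test
# has essentially no power even against a five-sigma step.
binseg <- function(x, lo, hi, alpha, sigma, min_seg = 1L) {
  n <- hi - lo + 1L
  if (n < 2L * min_seg) return(integer())
  xs <- x[lo:hi]
  cs <- cumsum(xs)
  ks <- min_seg:(n - min_seg)
  n1 <- ks; n2 <- n - ks
  m1 <- cs[ks] / n1
  m2 <- (cs[n] - cs[ks]) / n2
  cusum <- abs(m2 - m1) * sqrt(n1 * n2 / n)
  best <- which.max(cusum)
  z <- (m2[best] - m1[best]) /
    (sigma * sqrt(1 / n1[best] + 1 / n2[best]))
  p <- 2 * stats::pnorm(-abs(z))
  if (!is.finite(p) || p >= alpha) return(integer())
  cp <- lo + ks[best] - 1L
  c(binseg(x, lo, cp, alpha, sigma, min_seg), cp,
    binseg(x, cp + 1L, hi, alpha, sigma, min_seg))
}

#' Detect high-FRET intervals
#'
#' Contiguous runs of masked-valid frames with `E >= fret_threshold`
#' (default 0.4, midway between the 0.08 no-interaction baseline and the
#' ~0.72 engaged state), tolerating `max_gap_frames` sub-threshold frames
#' and requiring `fret_min_frames` qualifying frames. Onsets are accepted
#' only when acceptor presence is confirmed within `confirm_window_s` of
#' the onset in the acceptor-excitation record.
#'
#' @param efret An `efret_series` from [compute_efret()].
#' @param acceptor_intervals Acceptor presence intervals used for the
#'   confirmation rule (`NULL` skips the rule).
#' @param config An [analysis_config()].
#' @param cycle Acquisition cycle (s).
#' @return Data frame: `t_start`, `t_end`, `right_censored`.
#' @export
detect_fret_intervals <- function(efret, acceptor_intervals = NULL,
                                  config = analysis_config(), cycle = 2.4) {
  thr <- config$fret_threshold
  if (thr <= 0 || thr >= 1) {
    stop("detect_fret_intervals: threshold must lie in (0, 1)", call. = FALSE)
  }
  qual <- efret$valid & !is.na(efret$E) & efret$E >= thr
  if (!is.null(efret$donor_total)) {
    # a high-FRET frame needs genuine donor emission: frames straddling a
    # donor departure otherwise contribute pure-noise ratios
    tot <- efret$donor_total
    sig <- robust_sd(tot)
    if (!is.finite(sig) || sig <= 0) sig <- max(abs(tot)) * 1e-9 + 1e-12
    qual <- qual & tot > 2 * sig
  }
  runs <- qualifying_runs(qual, config$max_gap_frames)
  out <- list()
  n <- nrow(efret)
  for (r in runs) {
    if (sum(qual[r[1]:r[2]]) < config$fret_min_frames) next
    onset <- efret$time_s[r[1]]
    if (!is.null(acceptor_intervals)) {
      ok <- nrow(acceptor_intervals) &&
        any(acceptor_intervals$t_start <= onset + config$confirm_window_s &
              acceptor_intervals$t_end >= onset - config$confirm_window_s)
      if (!ok) next
    }
    out[[length(out) + 1L]] <- data.frame(
      t_start = onset, t_end = efret$time_s[r[2]] + cycle,
      right_censored = r[2] == n)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(t_start = numeric(), t_end = numeric(),
                  right_censored = logical())
}

#' Full per-DNA analysis
#'
#' Runs the measurement layer for one DNA: donor and acceptor presence,
#' acceptor-channel steps, the FRET series, and high-FRET intervals.
#'
#' @param traceset A background-corrected `trace_set`.
#' @param dna_id DNA to analyze.
#' @param config An [analysis_config()].
#' @return A list (`dna_analysis`) with `donor_intervals`,
#'   `acceptor_intervals`, `steps`, `efret`, `fret_intervals`.
#' @export
analyze_dna <- function(traceset, dna_id, config = analysis_config()) {
  don <- detect_presence(traceset, dna_id, "donor", config)
  acc <- detect_presence(traceset, dna_id, "acceptor", config)
  steps <- detect_steps(traceset, dna_id, config)
  ef <- compute_efret(traceset, dna_id, don, acc)
  fr <- detect_fret_intervals(ef, acc, config,
                              cycle = traceset$timing$cycle_s)
  structure(list(dna_id = dna_id, donor_intervals = don,
                 acceptor_intervals = acc, steps = steps, efret = ef,
                 fret_intervals = fr, config = config),
            class = "dna_analysis")
}

#' Export detected intervals and steps as a tidy table
#'
#' @param analyses A list of `dna_analysis` objects.
#' @return Data frame: `dna_id`, `kind`, `t_start_s`, `t_end_s`,
#'   `censored`, `magnitude`.
#' @export
intervals_table <- function(analyses) {
  rows <- lapply(analyses, function(a) {
    out <- list()
    for (nm in c("donor_intervals", "acceptor_intervals", "fret_intervals")) {
      iv <- a[[nm]]
      if (nrow(iv)) {
        out[[nm]] <- data.frame(
          dna_id = a$dna_id,
          kind = sub("_intervals", "", nm),
          t_start_s = iv$t_start, t_end_s = iv$t_end,
          censored = iv$right_censored, magnitude = NA_real_)
      }
    }
    if (nrow(a$steps)) {
      out$steps <- data.frame(
        dna_id = a$dna_id,
        kind = paste0("step_", ifelse(is.na(a$steps$classification), "other",
                                      a$steps$classification)),
        t_start_s = a$steps$time_s, t_end_s = NA_real_,
        censored = FALSE, magnitude = a$steps$magnitude)
    }
    if (length(out)) do.call(rbind, out) else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(dna_id = integer(), kind = character(),
                      t_start_s = numeric(), t_end_s = numeric(),
                      censored = logical(), magnitude = numeric())
  }
  rownames(out) <- NULL
  out
}
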