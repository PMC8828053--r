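# Build a trace_set directly from per-frame channel vectors.
synthetic_traceset <- function(dem, aem, aex, cycle = 2.4) {
  n <- length(aex)
  tD <- (seq_len(n) - 1) * cycle
  tA <- tD + 1.2
  df <- data.frame(
    dna_id = 1L, cycle = rep(seq_len(n), each = 2L),
    frame_kind = rep(c("donor_ex", "acceptor_ex"), n),
    time_s = as.vector(rbind(tD, tA)),
    I_Dex_Dem = NA_real_, I_Dex_Aem = NA_real_, I_Aex_Aem = NA_real_)
  dsel <- df$frame_kind == "donor_ex"
  df$I_Dex_Dem[dsel] <- dem
  df$I_Dex_Aem[dsel] <- aem
  df$I_Aex_Aem[!dsel] <- aex
  structure(list(traces = df, timing = frame_timing(n_cycles = n),
                 phys = photophysics_params(), trajectories = NULL,
                 bleach_log = data.frame()),
            class = "trace_set")
}

test_that("background correction removes a constant offset and preserves steps", {
  set.seed(101)
  n <- 600
  noise <- function() rnorm(n, 0, 200)
  # noise-only channels with +100 offset
  tc <- synthetic_traceset(noise() + 100, noise() + 100, noise() + 100)
  cor <- correct_background(tc)
  for (ch in c("I_Dex_Dem", "I_Dex_Aem", "I_Aex_Aem")) {
    v <- cor$traces[[ch]]
    v <- v[!is.na(v)]
    expect_lt(abs(mean(v)), 4 * 200 / sqrt(n))
  }
  # offset atop a real event: magnitude unchanged after correction
  sig <- c(rep(0, 200), rep(1000, 200), rep(0, 200))
  tc2 <- synthetic_traceset(noise(), noise(), sig + noise() + 250)
  cor2 <- correct_background(tc2)
  x <- cor2$traces$I_Aex_Aem
  x <- x[!is.na(x)]
  mag <- mean(x[201:400]) - mean(x[c(1:200, 401:600)])
  expect_lt(abs(mag - 1000), 50)
})

test_that("correction is a no-op on simulator traces (already corrected)", {
  cfg <- conditioned_config("fig1", n_dna = 4, seed = 71)
  tc <- simulate_experiment(cfg)
  cor <- correct_background(tc)
  expect_true(all(abs(cor$baselines$baseline) < 80))
})

test_that("apparent FRET follows the intensity ratio and its validity mask", {
  n <- 20
  dem <- rep(30, n); aem <- rep(70, n)
  dem[1] <- 50; aem[1] <- 0
  tc <- synthetic_traceset(dem, aem, rep(1000, n))
  don_iv <- data.frame(t_start = 0, t_end = 48, right_censored = FALSE)
  acc_iv <- data.frame(t_start = 1.2, t_end = 24, right_censored = FALSE)
  ef <- compute_efret(tc, 1L, don_iv, acc_iv)
  expect_equal(ef$E[1], 0)          # I_Aem = 0, I_Dem = 50
  expect_equal(ef$E[2], 0.7)        # 70 / (70 + 30)
  # acceptor absent after 24 s: masked invalid, dropped from histograms
  expect_false(any(ef$valid[ef$time_s >= 24]))
  expect_true(all(is.na(ef$E[!ef$valid])))
  # out-of-range values are not clamped but are excluded at +/- 2
  dem2 <- rep(-40, n); aem2 <- rep(30, n)
  ef2 <- compute_efret(synthetic_traceset(dem2, aem2, rep(1000, n)),
                       1L, don_iv, acc_iv)
  expect_equal(ef2$E[2], -3)        # 30 / (30 - 40): emitted as-is
  expect_false(any(abs(efret_values(ef2)) > 2))
})

test_that("presence detection has the promised false-positive and recovery behaviour", {
  set.seed(7)
  # noise only: fewer than 1 false interval per 600 frames on average
  n_false <- 0
  for (r in 1:20) {
    x <- rnorm(600, 0, 200)
    iv <- cosmofret:::presence_from_series(x, (0:599) * 2.4,
                                           analysis_config(), 200)
    n_false <- n_false + nrow(iv)
  }
  expect_lt(n_false / 20, 1)
  # a 100-s dwell is recovered with endpoints within one cycle
  x <- rnorm(600, 0, 200)
  x[101:142] <- x[101:142] + 1000   # frames 101..142: 100.8 s
  iv <- cosmofret:::presence_from_series(x, (0:599) * 2.4,
                                         analysis_config(), 200)
  expect_equal(nrow(iv), 1L)
  expect_lt(abs(iv$t_start - 100 * 2.4), 2.5)
  expect_lt(abs(iv$t_end - 143 * 2.4), 2.5)
  expect_false(iv$right_censored)
  # truncation at trace end is flagged as right-censored
  x2 <- rnorm(600, 0, 200)
  x2[580:600] <- x2[580:600] + 1000
  iv2 <- cosmofret:::presence_from_series(x2, (0:599) * 2.4,
                                          analysis_config(), 200)
  expect_true(iv2$right_censored[nrow(iv2)])
})

test_that("step detection finds a staircase and classifies half losses", {
  set.seed(8)
  stair <- c(rep(0, 100), rep(1000, 100), rep(2000, 400)) + rnorm(600, 0, 200)
  st <- cosmofret:::steps_from_series(stair, (0:599) * 2.4)
  ups <- st[st$direction == "up", ]
  expect_equal(nrow(ups), 2L)
  expect_true(all(ups$classification == "arrival"))
  expect_lt(abs(ups$time_s[1] - 100 * 2.4), 2.5)
  expect_lt(abs(ups$time_s[2] - 200 * 2.4), 2.5)
  # 2 units -> 1 unit at a known release time: half_loss at that time
  rel <- c(rep(0, 50), rep(2000, 150), rep(1000, 300), rep(0, 100)) +
    rnorm(600, 0, 200)
  st2 <- cosmofret:::steps_from_series(rel, (0:599) * 2.4)
  hl <- st2[st2$classification %in% "half_loss", ]
  expect_equal(nrow(hl), 1L)
  expect_lt(abs(hl$time_s - 200 * 2.4), 2.5)
  dep <- st2[st2$classification %in% "departure", ]
  expect_equal(nrow(dep), 1L)
  # flat occupied trace: no steps at all
  flat <- rep(1500, 600) + rnorm(600, 0, 200)
  expect_equal(nrow(cosmofret:::steps_from_series(flat, (0:599) * 2.4)), 0L)
})

test_that("high-FRET intervals are recovered with the acceptor-confirmation rule", {
  set.seed(9)
  n <- 600
  E_true <- rep(0.08, n)
  E_true[101:113] <- 0.72           # 31.2 s high-FRET window
  Etot <- 1000
  aem <- E_true * Etot + rnorm(n, 0, 120)
  dem <- (1 - E_true) * Etot + rnorm(n, 0, 120)
  tc <- synthetic_traceset(dem, aem, rep(1000, n))
  don_iv <- data.frame(t_start = 0, t_end = 1440, right_censored = TRUE)
  acc_iv <- data.frame(t_start = 100 * 2.4, t_end = 1440,
                       right_censored = TRUE)
  ef <- compute_efret(tc, 1L, don_iv, acc_iv)
  fr <- detect_fret_intervals(ef, acc_iv, analysis_config())
  expect_equal(nrow(fr), 1L)
  expect_lt(abs((fr$t_end - fr$t_start) - 31.2), 2.5)
  # all-baseline series: no intervals
  aem0 <- 0.08 * Etot + rnorm(n, 0, 120)
  dem0 <- 0.92 * Etot + rnorm(n, 0, 120)
  ef0 <- compute_efret(synthetic_traceset(dem0, aem0, rep(1000, n)),
                       1L, don_iv, acc_iv)
  expect_equal(nrow(detect_fret_intervals(ef0, acc_iv)), 0L)
  # onsets without confirmed acceptor presence nearby are rejected
  acc_late <- data.frame(t_start = 1000, t_end = 1440, right_censored = TRUE)
  ef1 <- compute_efret(tc, 1L, don_iv,
                       data.frame(t_start = 0, t_end = 1440,
                                  right_censored = TRUE))
  fr1 <- detect_fret_intervals(ef1, acc_late, analysis_config())
  expect_equal(nrow(fr1), 0L)
  expect_error(detect_fret_intervals(ef, acc_iv,
                                     analysis_config(fret_threshold = 0.4)),
               NA)
  expect_error(analysis_config(fret_threshold = 1.4), "fret_threshold")
})

test_that("noiseless traces reproduce ground truth to frame quantization", {
  cfg <- conditioned_config("fig1", n_dna = 10, seed = 81)
  cfg$phys <- photophysics_params(background_sd = 0)
  tc <- simulate_experiment(cfg)
  res <- analyze_traces(tc, cfg)
  ev <- res$events
  for (a in res$analyses) {
    tr <- tc$trajectories$trajectories[[a$dna_id]]
    m1_true <- tr$events$time_s[tr$events$event_kind == "mcm1_arrive"]
    if (!length(m1_true)) next
    e <- ev[ev$dna_id == a$dna_id, ]
    expect_lt(abs(e$m1_time - m1_true), 2.4 + 1e-9)
    om1 <- tr$interactions[tr$interactions$kind == "om1", ]
    # intervals shorter than two cycles can fall entirely between donor
    # exposures of the alternation scheme and are legitimately invisible
    if (om1$t_end - om1$t_start < 4.8 || om1$t_end > 1435) next
    k <- which(abs(a$fret_intervals$t_start - e$m1_time) <= 4.8)
    expect_gte(length(k), 1L)
    det <- a$fret_intervals[k[1], ]
    expect_lt(abs(det$t_start - om1$t_start), 2.4 + 1e-9)
    expect_lt(abs(det$t_end - om1$t_end), 2.4 + 1e-9)
  }
})

test_that("detection fidelity at default SNR meets the recovery contract", {
  # >= 95% of simulated OM/MO intervals lasting >= 3 frames are recovered
  # with endpoint errors <= 1 frame
  cfg <- conditioned_config("fig1", n_dna = 60, seed = 82)
  tc <- simulate_experiment(cfg)
  res <- analyze_traces(tc, cfg)
  n_tot <- 0; n_ok <- 0
  for (a in res$analyses) {
    tr <- tc$trajectories$trajectories[[a$dna_id]]
    om_all <- tr$interactions[tr$interactions$kind %in% c("om1", "om2"), ]
    # the low-FRET gap between the two OM periods must itself be
    # resolvable (>= 2 cycles), otherwise the intervals merge by design
    gap_ok <- if (nrow(om_all) == 2L) {
      (max(om_all$t_start) - min(om_all$t_end)) >= 4.8
    } else TRUE
    for (kind in c("om1", "om2")) {
      ia <- tr$interactions[tr$interactions$kind == kind, ]
      if (!nrow(ia)) next
      if (ia$t_end - ia$t_start < 3 * 2.4 || ia$t_end > 1435) next
      if (!gap_ok) next
      n_tot <- n_tot + 1
      fi <- a$fret_intervals
      if (!nrow(fi)) next
      k <- which(abs(fi$t_start - ia$t_start) <= 2.4 + 1e-9)
      if (length(k) && abs(fi$t_end[k[1]] - ia$t_end) <= 2.4 + 1e-9) {
        n_ok <- n_ok + 1
      }
    }
  }
  expect_gt(n_tot, 60)
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("the E estimator is unbiased over simulated high-FRET windows", {
  cfg <- conditioned_config("fig1", n_dna = 40, seed = 83)
  tc <- simulate_experiment(cfg)
  res <- analyze_traces(tc, cfg)
  ev <- res$events
  vals <- c()
  for (a in res$analyses) {
    e <- ev[ev$dna_id == a$dna_id, ]
    if (!nrow(e) || is.na(e$m2_time)) next
    fi <- a$fret_intervals
    k <- which(abs(fi$t_start - e$m1_time) <= 4.8)
    if (!length(k)) next
    sel <- a$efret$valid & a$efret$time_s >= fi$t_start[k[1]] &
      a$efret$time_s + 2.4 <= fi$t_end[k[1]]
    vals <- c(vals, a$efret$E[sel])
  }
  vals <- vals[!is.na(vals) & abs(vals) <= 2]
  expect_gt(length(vals), 200)
  # mean within 2 SEM of the set-point, allowing the small ratio-of-noisy-
  # intensities bias (~ sigma^2 (2E - 1) / T^2, about +0.01 here)
  expect_lt(abs(mean(vals) - 0.72),
            2 * sd(vals) / sqrt(length(vals)) + 0.012)
})

test_that("intervals table gathers intervals and steps tidily", {
  cfg <- conditioned_config("fig1", n_dna = 3, seed = 84)
  tc <- simulate_experiment(cfg)
  res <- analyze_traces(tc, cfg)
  it <- res$intervals
  expect_named(it, c("dna_id", "kind", "t_start_s", "t_end_s", "censored",
                     "magnitude"))
  expect_true(all(c("donor", "acceptor", "fret") %in% it$kind |
                    startsWith(it$kind, "step_")))
})
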