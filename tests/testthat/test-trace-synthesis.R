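test_that("unlabeled molecules render as zero-mean noise in every channel", {
  mols <- rbind(mol_row("orc1", "orc", 10, 100, "dark"),
                mol_row("mcm1", "mcm", 20, 120, "dark"))
  ts <- manual_trajectory_set(mols, ia_row("om1", 20, 60, "orc1", "mcm1"))
  tc <- render_traces(ts, frame_timing(n_cycles = 100),
                      photophysics_params(background_sd = 50), rng_seed = 1)
  for (ch in c("I_Dex_Dem", "I_Dex_Aem", "I_Aex_Aem")) {
    v <- tc$traces[[ch]]
    v <- v[!is.na(v)]
    expect_lt(abs(mean(v)), 3 * 50 / sqrt(length(v)))
  }
})

test_that("noiseless emission split reproduces the FRET set-point exactly", {
  phys <- photophysics_params(background_sd = 0)
  mols <- rbind(mol_row("orc1", "orc", 0, 240, "5C"),
                mol_row("mcm1", "mcm", 0, 240, "2C"))
  ts <- manual_trajectory_set(mols, ia_row("om1", 0, 240, "orc1", "mcm1"))
  tc <- render_traces(ts, frame_timing(n_cycles = 100), phys, 1)
  don <- tc$traces[tc$traces$frame_kind == "donor_ex" &
                     tc$traces$time_s < 230, ]
  E <- don$I_Dex_Aem / (don$I_Dex_Aem + don$I_Dex_Dem)
  expect_equal(unique(round(E, 12)), 0.72)
  # PIFE: total donor-excited emission enhanced during the OM interaction
  expect_equal(unique(round(don$I_Dex_Dem + don$I_Dex_Aem, 9)),
               phys$unit_intensity * phys$pife_factor)
})

test_that("donor-excited total emission is conserved across FRET states", {
  phys <- photophysics_params(background_sd = 0)
  mols <- rbind(mol_row("orc1", "orc", 0, 240, "5C"),
                mol_row("mcm1", "mcm", 0, 240, "3N"),
                mol_row("mcm2", "mcm", 0, 240, "2C"))
  # same geometry, different E states across time: om then baseline
  ts <- manual_trajectory_set(mols, ia_row("om2", 0, 120, "orc1", "mcm2"))
  tc <- render_traces(ts, frame_timing(n_cycles = 100), phys, 1)
  don <- tc$traces[tc$traces$frame_kind == "donor_ex", ]
  tot <- don$I_Dex_Dem + don$I_Dex_Aem
  inside <- don$time_s + 1 <= 120
  outside <- don$time_s >= 120
  expect_equal(unique(round(tot[inside], 9)),
               phys$unit_intensity * phys$pife_factor)
  # outside the OM interval: baseline E, no PIFE; total equals one unit
  expect_equal(unique(round(tot[outside & don$time_s < 230], 9)),
               phys$unit_intensity)
})

test_that("acceptor-excited intensity counts acceptors and ignores FRET", {
  phys <- photophysics_params(background_sd = 0)
  mols <- rbind(mol_row("orc1", "orc", 0, 240, "5C"),
                mol_row("mcm1", "mcm", 0, 240, "2C"),
                mol_row("cdt1_1", "cdt1", 0, 120, "N649"))
  ts <- manual_trajectory_set(mols, ia_row("om1", 0, 60, "orc1", "mcm1"))
  tc <- render_traces(ts, frame_timing(n_cycles = 100), phys, 1)
  acc <- tc$traces[tc$traces$frame_kind == "acceptor_ex", ]
  # two acceptors before the Cdt1 release, one after: 2 -> 1 units
  expect_equal(unique(round(acc$I_Aex_Aem[acc$time_s + 1 <= 120], 9)),
               2 * phys$unit_intensity)
  expect_equal(unique(round(acc$I_Aex_Aem[acc$time_s >= 120 &
                                            acc$time_s < 230], 9)),
               phys$unit_intensity)
})

test_that("composite and control set-points select on label geometry", {
  phys <- photophysics_params(background_sd = 0)
  E_of <- function(mols, ia, t) {
    ts <- manual_trajectory_set(mols, ia)
    tc <- render_traces(ts, frame_timing(n_cycles = 100), phys, 1)
    don <- tc$traces[tc$traces$frame_kind == "donor_ex", ]
    k <- which(don$time_s <= t & t < don$time_s + 1)[1]
    don$I_Dex_Aem[k] / (don$I_Dex_Aem[k] + don$I_Dex_Dem[k])
  }
  # OM pair with N-labeled Cdt1 present: composite 0.83
  m1 <- rbind(mol_row("orc1", "orc", 0, 240, "5C"),
              mol_row("mcm1", "mcm", 0, 240, "2C"),
              mol_row("cdt1_1", "cdt1", 0, 240, "N649"))
  expect_equal(E_of(m1, ia_row("om1", 0, 240, "orc1", "mcm1"), 48.2), 0.83)
  # Orc5-C donor with only Cdt1-N: control 0.358
  m2 <- rbind(mol_row("orc1", "orc", 0, 240, "5C"),
              mol_row("cdt1_1", "cdt1", 0, 240, "N649"))
  expect_equal(E_of(m2, ia_row("om1", 0, 240, "orc1", "mcm1")[0, ], 48.2),
               0.358)
  # MO pair: 0.73; mismatched labels give the 0.08 baseline
  m3 <- rbind(mol_row("orc1", "orc", 0, 240, "6C"),
              mol_row("mcm1", "mcm", 0, 240, "3N"))
  expect_equal(E_of(m3, ia_row("mo", 0, 240, "orc1", "mcm1"), 48.2), 0.73)
  m4 <- rbind(mol_row("orc1", "orc", 0, 240, "6C"),
              mol_row("mcm1", "mcm", 0, 240, "2C"))
  expect_equal(E_of(m4, ia_row("mo", 0, 240, "orc1", "mcm1"), 48.2), 0.08)
})

test_that("rendered E converges to the set-point as noise vanishes", {
  cfg <- conditioned_config("fig1", n_dna = 12, seed = 21)
  ts <- assign_labels(cfg$design,
                      simulate_trajectories(cfg$kinetic, cfg$design, 21), 22)
  phys <- photophysics_params(background_sd = 20)
  tc <- render_traces(ts, cfg$timing, phys, 23)
  Es <- c()
  for (tr in ts$trajectories) {
    om <- tr$interactions[tr$interactions$kind == "om1", ]
    if (!nrow(om)) next
    don <- tc$traces[tc$traces$dna_id == tr$dna_id &
                       tc$traces$frame_kind == "donor_ex", ]
    sel <- don$time_s >= om$t_start & don$time_s + 1 <= min(om$t_end, 1440)
    Es <- c(Es, don$I_Dex_Aem[sel] / (don$I_Dex_Aem[sel] +
                                        don$I_Dex_Dem[sel]))
  }
  expect_gt(length(Es), 50)
  expect_lt(abs(mean(Es) - 0.72), 2 * stats::sd(Es) / sqrt(length(Es)) + 0.002)
})

test_that("zero bleach probability leaves traces untouched", {
  cfg <- conditioned_config("fig1", n_dna = 4, seed = 31)
  tc <- simulate_experiment(cfg)
  phys0 <- tc$phys
  phys0$bleach_prob_per_exposure <- 0
  expect_identical(apply_photobleaching(tc, phys0, 99)$traces, tc$traces)
})

test_that("bleach hazard scales with laser exposure factor", {
  # immortal dye: molecule present for the whole trace; observed loss is
  # bleaching only, so the per-cycle hazard ratio must approach 2.4
  base <- manual_trajectory_set(mol_row("orc1", "orc", 0, Inf, "5C"),
                                ia_row("om1", 0, 1, "orc1", "none")[0, ],
                                n_cycles = 400)
  hazard <- function(factor, seed) {
    des <- base$design
    des$laser_exposure_factor <- factor
    trs <- base
    trs$design <- des
    trs$trajectories <- rep(trs$trajectories, 300)
    for (i in seq_along(trs$trajectories)) trs$trajectories[[i]]$dna_id <- i
    phys <- photophysics_params(bleach_prob_per_exposure = 2e-3)
    tc <- render_traces(trs, frame_timing(n_cycles = 400), phys, seed)
    tc <- apply_photobleaching(tc, phys, seed + 1)
    bl <- tc$bleach_log
    n_frames <- vapply(seq_len(300), function(i) {
      t <- if (i %in% bl$dna_id) bl$bleach_time_s[bl$dna_id == i] else 960
      ceiling(t / 2.4)
    }, numeric(1))
    sum(seq_len(300) %in% bl$dna_id) / sum(n_frames)
  }
  h1 <- hazard(1, 51)
  h24 <- hazard(2.4, 53)
  expect_gt(h24 / h1, 1.8)
  expect_lt(h24 / h1, 3.2)
})

test_that("donor bleach silences donor-excited channels while direct acceptor excitation persists", {
  phys <- photophysics_params(background_sd = 0,
                              bleach_prob_per_exposure = 0.05)
  mols <- rbind(mol_row("orc1", "orc", 0, 240, "5C"),
                mol_row("mcm1", "mcm", 0, 240, "2C"))
  ts <- manual_trajectory_set(mols, ia_row("om1", 0, 240, "orc1", "mcm1"))
  tc <- render_traces(ts, frame_timing(n_cycles = 100), phys, 1)
  tc <- apply_photobleaching(tc, phys, 2)
  bl <- tc$bleach_log
  don_bleach <- bl$bleach_time_s[bl$molecule_id == "orc1"]
  expect_length(don_bleach, 1L)  # deterministic under the fixed seed
  don <- tc$traces[tc$traces$frame_kind == "donor_ex", ]
  after <- don$time_s >= don_bleach + 2.4
  expect_true(all(abs(don$I_Dex_Dem[after] + don$I_Dex_Aem[after]) < 1e-9))
  acc <- tc$traces[tc$traces$frame_kind == "acceptor_ex", ]
  acc_bleach <- bl$bleach_time_s[bl$molecule_id == "mcm1"]
  upto <- if (length(acc_bleach)) acc_bleach else 230
  still <- acc$time_s + 1 <= upto
  expect_true(all(acc$I_Aex_Aem[still] > 0.99 * phys$unit_intensity))
})

test_that("trace CSV round trip preserves the schema", {
  cfg <- conditioned_config("fig1", n_dna = 2, seed = 61)
  tc <- simulate_experiment(cfg)
  f <- tempfile(fileext = ".csv")
  write_traces_csv(tc, f)
  back <- read_traces_csv(f, cfg$timing, cfg$phys)
  expect_equal(back$traces$I_Aex_Aem, tc$traces$I_Aex_Aem, tolerance = 1e-8)
  expect_error(read_traces_csv({
    g <- tempfile(fileext = ".csv")
    utils::write.csv(data.frame(a = 1), g, row.names = FALSE)
    g
  }), "schema mismatch")
})
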