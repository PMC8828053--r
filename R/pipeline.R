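#' Run configuration
#'
#' A fully serializable bundle of every knob in the pipeline: kinetic
#' parameters, experiment design, frame timing, photophysics, analysis
#' thresholds, and the master RNG seed. A run is reproducible bit-for-bit
#' from (config, seed): every stage derives its own sub-seed from the
#' master seed by a fixed scheme (stage index k maps to
#' `(seed * 48271 + 1000003 k) mod (2^31 - 1)`).
#'
#' @param preset_name A [preset()] name, or `NULL` to use the supplied
#'   components.
#' @param n_dna Number of DNAs.
#' @param seed Master seed.
#' @param kinetic,design,timing,phys,analysis Component objects; preset
#'   components are used where these are `NULL`.
#' @param bleach If `TRUE`, [apply_photobleaching()] is part of simulation.
#' @param ... Kinetic-parameter overrides forwarded to [preset()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(preset_name = "fig1", n_dna = 64, seed = 1L,
                       kinetic = NULL, design = NULL, timing = NULL,
                       phys = NULL, analysis = NULL, bleach = FALSE, ...) {
  base <- if (!is.null(preset_name)) preset(preset_name, n_dna = n_dna, ...)
    else list(name = "custom", kinetic = kinetic_params(...),
              design = experiment_design(n_dna = n_dna),
              timing = frame_timing(), phys = photophysics_params())
  structure(list(preset = base$name,
                 kinetic = kinetic %||% base$kinetic,
                 design = design %||% base$design,
                 timing = timing %||% base$timing,
                 phys = phys %||% base$phys,
                 analysis = analysis %||% analysis_config(),
                 bleach = isTRUE(bleach),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> preset =", x$preset, "| n_dna =", x$design$n_dna,
      "| seed =", x$seed, "| bleach =", x$bleach, "\n")
  invisible(x)
}

config_to_list <- function(cfg) {
  strip <- function(o) {
    o <- unclass(o)
    o$dwell_sampler <- NULL
    o
  }
  des <- strip(cfg$design)
  # named vectors lose their names in YAML; maps (lists) do not
  for (f in c("orc_label_plan", "mcm_label_plan", "cdt1_label_plan")) {
    des[[f]] <- as.list(des[[f]])
  }
  list(preset = cfg$preset, seed = cfg$seed, bleach = cfg$bleach,
       kinetic = strip(cfg$kinetic), design = des,
       timing = strip(cfg$timing), phys = strip(cfg$phys),
       analysis = strip(cfg$analysis))
}

#' Rebuild a run configuration from a YAML snapshot
#'
#' @param path Path to a `config.yaml` written by [cmd_simulate()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  kin <- do.call(kinetic_params, y$kinetic)
  for (f in c("orc_label_plan", "mcm_label_plan", "cdt1_label_plan")) {
    y$design[[f]] <- unlist(y$design[[f]])
  }
  des <- do.call(experiment_design, y$design)
  tim <- do.call(frame_timing, y$timing)
  phys <- do.call(photophysics_params, y$phys)
  ana <- do.call(analysis_config, y$analysis)
  cfg <- run_config(preset_name = NULL, n_dna = des$n_dna, seed = y$seed,
                    kinetic = kin, design = des, timing = tim, phys = phys,
                    analysis = ana, bleach = y$bleach)
  cfg$preset <- y$preset
  cfg
}

#' Simulate an experiment end to end
#'
#' Trajectories -> labels -> traces (-> photobleaching), all seeded from
#' the config's master seed.
#'
#' @param config A [run_config()].
#' @return A `trace_set`.
#' @export
simulate_experiment <- function(config) {
  ts <- simulate_trajectories(config$kinetic, config$design,
                              sub_seed(config$seed, 1L))
  ts <- assign_labels(config$design, ts, sub_seed(config$seed, 2L))
  tc <- render_traces(ts, config$timing, config$phys, sub_seed(config$seed, 3L))
  if (config$bleach) tc <- apply_photobleaching(tc, config$phys,
                                                sub_seed(config$seed, 4L))
  tc
}

#' Analyze every DNA of a trace set
#'
#' Background correction, per-DNA detection, and event classification.
#'
#' @param traceset A `trace_set`.
#' @param config An [analysis_config()] (or a [run_config()], whose
#'   `analysis` element is used).
#' @return List: `analyses` (per-DNA), `events`, `intervals`.
#' @export
analyze_traces <- function(traceset, config = analysis_config()) {
  if (inherits(config, "run_config")) config <- config$analysis
  tc <- correct_background(traceset)
  ids <- unique(tc$traces$dna_id)
  analyses <- lapply(ids, function(id) analyze_dna(tc, id, config))
  t_total <- tc$timing$n_cycles * tc$timing$cycle_s
  events <- classify_events(analyses, config, t_total)
  list(analyses = analyses, events = events,
       intervals = intervals_table(analyses))
}

#' Pipeline command: simulate
#'
#' Writes `traces.csv`, `ground_truth.csv`, `bleach_log.csv` and a
#' `config.yaml` snapshot to `out_dir`. Re-running with the same config
#' and seed is byte-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the `trace_set`.
#' @export
cmd_simulate <- function(config, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cmd_simulate: cannot create output directory ", out_dir,
         call. = FALSE)
  }
  tc <- simulate_experiment(config)
  write_traces_csv(tc, file.path(out_dir, "traces.csv"))
  utils::write.csv(ground_truth_log(tc$trajectories),
                   file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  utils::write.csv(tc$bleach_log, file.path(out_dir, "bleach_log.csv"),
                   row.names = FALSE)
  yaml::write_yaml(config_to_list(config), file.path(out_dir, "config.yaml"))
  invisible(tc)
}

#' Pipeline command: analyze
#'
#' Reads the simulation products of [cmd_simulate()] (or accepts a
#' `trace_set` directly), runs the analysis chain, and writes
#' `intervals.csv`, `events.csv` and `stats.json`.
#'
#' @param in_dir Directory written by [cmd_simulate()].
#' @param traceset Optional in-memory `trace_set` (skips the CSV read).
#' @param config Optional `run_config`; read from `config.yaml` otherwise.
#' @return Invisibly, the [analyze_traces()] result.
#' @export
cmd_analyze <- function(in_dir, traceset = NULL, config = NULL) {
  config <- config %||% read_run_config(file.path(in_dir, "config.yaml"))
  if (is.null(traceset)) {
    traceset <- read_traces_csv(file.path(in_dir, "traces.csv"),
                                timing = config$timing, phys = config$phys)
  }
  res <- analyze_traces(traceset, config$analysis)
  utils::write.csv(res$intervals, file.path(in_dir, "intervals.csv"),
                   row.names = FALSE)
  utils::write.csv(res$events, file.path(in_dir, "events.csv"),
                   row.names = FALSE)
  jsonlite::write_json(summary_stats(res$events),
                       file.path(in_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

summary_stats <- function(events) {
  n <- nrow(events)
  n_dh <- sum(!is.na(events$m2_time))
  n_succ <- sum(events$success)
  succ <- if (n > 0) proportion_with_se(n_succ, n) else
    list(p = NA_real_, se = NA_real_)
  orc_tab <- as.list(table(events$orc_class))
  prof_tab <- as.list(table(events$fret_profile))
  list(n_events = n, n_two_arrival = n_dh, n_success = n_succ,
       success_fraction = succ$p, success_se = succ$se,
       orc_class_counts = orc_tab, fret_profile_counts = prof_tab)
}

#' Pipeline command: report
#'
#' Renders a short human-readable summary of an analyzed run; when
#' `expected` values (with tolerances) are supplied, appends a check table
#' flagging each quantity pass/fail.
#'
#' @param in_dir Directory holding `events.csv` (from [cmd_analyze()]).
#' @param expected Optional data frame: `quantity`, `expected`,
#'   `tolerance`.
#' @param file Connection or path for the text output ("" = stdout).
#' @return Invisibly, the summary list.
#' @export
cmd_report <- function(in_dir, expected = NULL, file = "") {
  events <- utils::read.csv(file.path(in_dir, "events.csv"))
  s <- summary_stats(events)
  lines <- c(
    "== helicase-loading run report ==",
    sprintf("events (>= 1 Mcm arrival): %d", s$n_events),
    sprintf("two-arrival events:        %d", s$n_two_arrival),
    sprintf("successful double hexamers: %d (fraction %.3f +/- %.3f)",
            s$n_success, s$success_fraction, s$success_se),
    paste0("ORC count classes: ",
           paste(names(s$orc_class_counts), unlist(s$orc_class_counts),
                 sep = "=", collapse = ", ")),
    paste0("FRET profiles: ",
           paste(names(s$fret_profile_counts),
                 unlist(s$fret_profile_counts), sep = "=", collapse = ", ")))
  checks <- NULL
  if (!is.null(expected) && nrow(expected)) {
    vals <- list(success_fraction = s$success_fraction,
                 n_events = s$n_events, n_success = s$n_success)
    checks <- expected
    checks$value <- vapply(checks$quantity, function(q) {
      v <- vals[[q]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
    checks$pass <- !is.na(checks$value) &
      abs(checks$value - checks$expected) <= checks$tolerance
    lines <- c(lines, "-- checks --",
               sprintf("%-20s value=%.4g expected=%.4g tol=%.3g  %s",
                       checks$quantity, checks$value, checks$expected,
                       checks$tolerance,
                       ifelse(checks$pass, "PASS", "FAIL")))
  }
  writeLines(lines, con = if (identical(file, "")) stdout() else file)
  invisible(list(summary = s, checks = checks))
}
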