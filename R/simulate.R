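#' Simulate helicase-loading state trajectories
#'
#' Draws continuous-time state trajectories of ORC-mediated Mcm2-7 loading
#' on independent DNA molecules. Each DNA hosts at most one loading attempt:
#' ORC arrives (or is prebound), a first Mcm2-7/Cdt1 arrives and engages the
#' C-terminal OM interface, and the attempt then branches into MO formation,
#' second-helicase recruitment, abortive second associations, or failure,
#' according to the configured probabilities. The mechanism mode controls
#' which molecule carries each OM/MO interaction: under `"re_fret"` both OM
#' periods attach to the first Mcm2-7 and no MO interval exists; under
#' `"orc_exchange"` two ORC molecules swap within one frame time; under
#' `"two_orc_independent"` the two recruitments are mediated by two ORCs
#' separated by a visible gap.
#'
#' Event times are exact continuous times and may exceed the acquisition
#' window; the trace renderer truncates and flags censoring. Times are
#' non-decreasing within a DNA; the end of the first OM interaction ties
#' exactly with the first Cdt1 release in wild-type trajectories (a model
#' assumption of the state machine).
#'
#' @param params A [kinetic_params()] object.
#' @param design An [experiment_design()] object.
#' @param rng_seed Integer seed.
#' @return An object of class `trajectory_set`: a list with elements
#'   `trajectories` (one `state_trajectory` per DNA), `params`, `design`,
#'   and `labeled` (FALSE until [assign_labels()] is applied).
#' @seealso [assign_labels()], [render_traces()], [ground_truth_log()]
#' @export
simulate_trajectories <- function(params, design, rng_seed = 1L) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(design, "experiment_design"))
  with_seed(rng_seed, {
    trajs <- lapply(seq_len(design$n_dna), function(i) {
      sim_one_dna(params, design, dna_id = i)
    })
  })
  structure(list(trajectories = trajs, params = params, design = design,
                 labeled = FALSE, rng_seed = rng_seed),
            class = "trajectory_set")
}

#' @rdname simulate_trajectories
#' @param dna_id Identifier for the single simulated DNA.
#' @export
simulate_trajectory <- function(params, design, rng_seed = 1L, dna_id = 1L) {
  with_seed(rng_seed, sim_one_dna(params, design, dna_id))
}

draw_dwell <- function(params, mean_s, n = 1L) {
  if (is.null(params$dwell_sampler)) rexp_mean(n, mean_s)
  else params$dwell_sampler(n, mean_s)
}

# One DNA. Times are continuous; Inf t_off means "present at trace end".
sim_one_dna <- function(params, design, dna_id) {
  t_total <- design$duration_cycles * 2.4
  ev <- list()
  mol <- list()
  ia <- list()
  add_ev <- function(kind, time, id) {
    ev[[length(ev) + 1L]] <<- list(event_kind = kind, time_s = time,
                                   molecule_id = id)
  }
  add_mol <- function(id, species, on, off) {
    mol[[length(mol) + 1L]] <<- list(molecule_id = id, species = species,
                                     t_on = on, t_off = off)
  }
  add_ia <- function(kind, s, e, donor, acc, reason) {
    ia[[length(ia) + 1L]] <<- list(kind = kind, t_start = s, t_end = e,
                                   donor_id = donor, acceptor_id = acc,
                                   end_reason = reason)
  }
  finish <- function() {
    events <- if (length(ev)) {
      df <- do.call(rbind, lapply(ev, as.data.frame))
      df$label_class <- NA_character_
      df[order(df$time_s), , drop = FALSE]
    } else {
      data.frame(event_kind = character(), time_s = numeric(),
                 molecule_id = character(), label_class = character())
    }
    molecules <- if (length(mol)) do.call(rbind, lapply(mol, as.data.frame))
      else data.frame(molecule_id = character(), species = character(),
                      t_on = numeric(), t_off = numeric())
    molecules$label_class <- NA_character_
    interactions <- if (length(ia)) do.call(rbind, lapply(ia, as.data.frame))
      else data.frame(kind = character(), t_start = numeric(),
                      t_end = numeric(), donor_id = character(),
                      acceptor_id = character(), end_reason = character())
    structure(list(dna_id = dna_id, events = events, molecules = molecules,
                   interactions = interactions, t_total = t_total),
              class = "state_trajectory")
  }

  mech <- params$mechanism
  t_orc <- if (design$staged_prebound) 0 else rexp_mean(1, 1 / params$orc_arrival_rate)
  if (t_orc >= t_total) return(finish())
  add_ev("orc_arrive", t_orc, "orc1")

  t_m1 <- t_orc + rexp_mean(1, 1 / params$mcm_arrival_rate)
  if (t_m1 >= t_total) {
    # ORC-only visit; ORC remains to trace end (no attempt started).
    add_mol("orc1", "orc", t_orc, Inf)
    return(finish())
  }
  add_ev("mcm1_arrive", t_m1, "mcm1")
  add_mol("mcm1", "mcm", t_m1, NA)  # t_off filled below
  add_mol("cdt1_1", "cdt1", t_m1, NA)

  is_5ra <- params$mutant == "mcm5RA"
  d1 <- if (is_5ra) draw_dwell(params, params$mean_5ra_loss_s)
        else draw_dwell(params, params$mean_first_om_s)
  om1_end <- t_m1 + d1
  add_ev("om_start", t_m1, "mcm1")
  add_ev("om_end", om1_end, "mcm1")

  if (is_5ra) {
    # Cdt1 release is blocked: the OM interaction persists until the
    # composite fluorophore-loss process removes the whole complex.
    add_ev("orc_depart", om1_end, "orc1")
    add_ev("mcm_depart", om1_end, "mcm1")
    add_mol("orc1", "orc", t_orc, om1_end)
    set_off <- function(id, off) {
      for (k in seq_along(mol)) if (mol[[k]]$molecule_id == id) mol[[k]]$t_off <<- off
    }
    set_off("mcm1", om1_end); set_off("cdt1_1", om1_end)
    add_ia("om1", t_m1, om1_end, "orc1", "mcm1", "loss")
    return(finish())
  }

  add_ev("cdt1_release", om1_end, "cdt1_1")
  set_off <- function(id, off) {
    for (k in seq_along(mol)) if (mol[[k]]$molecule_id == id) mol[[k]]$t_off <<- off
  }
  set_off("cdt1_1", om1_end)

  p_mo <- if (params$mutant == "orc6dN119") params$p_mo_dn119
          else params$p_mo_given_first_mcm
  mo_forms <- stats::runif(1) < p_mo

  # ORC-usage pathway. Mechanism modes override the mixture.
  pathway <- if (mech == "orc_exchange") "exchange"
    else if (mech == "two_orc_independent") "two_seq"
    else {
      w <- c(one = params$p_one_orc, two_seq = params$p_two_orc_sequential,
             two_overlap = params$p_two_orc_overlap)
      extra <- max(0, 1 - sum(w))
      sample(c(names(w), "extra"), 1, prob = c(w, extra))
    }

  if (!mo_forms) {
    # Failed attempt: ORC leaves, then the lone unstabilized first Mcm2-7
    # is released with a short (median-parameterised) lifetime.
    orc_off <- om1_end + draw_dwell(params, params$mean_orc_depart_after_om1_s)
    m1_off <- orc_off + draw_dwell(params, params$median_m1_release_s / log(2))
    add_ev("orc_depart", orc_off, "orc1")
    add_ev("mcm_depart", m1_off, "mcm1")
    add_mol("orc1", "orc", t_orc, orc_off)
    set_off("mcm1", m1_off)
    add_ia("om1", t_m1, om1_end, "orc1", "mcm1", "cdt1_release")
    add_extra_orc_visits(pathway, params, t_orc, orc_off, add_ev, add_mol)
    return(finish())
  }

  second_stable <- stats::runif(1) < params$p_second_given_mo

  # Which ORC mediates the first vs second recruitment, and when the MO
  # tether forms. In a sequential two-ORC event the first ORC releases
  # once the first helicase is loaded and the MO delay is dominated by
  # the arrival of the second ORC from solution; in all other pathways
  # the tethered flip of the resident ORC sets the delay.
  orc_a <- "orc1"
  orc_b <- "orc1"
  if (pathway %in% c("two_seq", "exchange")) orc_b <- "orc2"
  if (pathway == "two_seq") {
    orc2_arrival <- om1_end + rexp_mean(1, 1 / params$orc_arrival_rate)
    mo_start <- orc2_arrival + rexp_mean(1, 2)
  } else {
    orc2_arrival <- NA_real_
    mo_start <- om1_end + draw_dwell(params, params$mean_mo_delay_s)
  }

  if (second_stable) {
    t_m2 <- mo_start + rexp_mean(1, 1 / params$mcm_arrival_rate)
    d2 <- draw_dwell(params, params$mean_second_om_s)
    om2_end <- t_m2 + d2
    mo_end <- t_m2 + draw_dwell(params, params$mean_mo_end_after_m2_s)
    add_ev("mcm2_arrive", t_m2, "mcm2")
    add_mol("mcm2", "mcm", t_m2, Inf)
    add_mol("cdt1_2", "cdt1", t_m2, om2_end)
    if (mech != "re_fret") {
      add_ev("mo_start", mo_start, "mcm1")
      add_ev("mo_end", mo_end, "mcm1")
      add_ia("mo", mo_start, mo_end, orc_b, "mcm1", "dh_form")
    }
    add_ev("om_start", t_m2, "mcm2")
    add_ev("om_end", om2_end, "mcm2")
    add_ev("cdt1_release", om2_end, "cdt1_2")
    add_ev("dh_form", mo_end, "mcm2")
    om2_acc <- if (mech == "re_fret") "mcm1" else "mcm2"
    add_ia("om2", t_m2, om2_end, orc_b, om2_acc, "orc_depart")
    set_off("mcm1", Inf)
    orc_b_off <- om2_end
    add_ev("orc_depart", orc_b_off, orc_b)
    if (orc_b == "orc1") {
      add_mol("orc1", "orc", t_orc, orc_b_off)
    } else {
      # Sequential two-ORC: the first ORC releases once the first helicase
      # is loaded; the second arrives later from solution. Under
      # orc_exchange the swap happens within one frame time.
      if (pathway == "exchange") {
        orc1_off <- max(mo_start - 0.1, om1_end)
        orc2_on <- orc1_off
      } else {
        orc2_on <- orc2_arrival
        orc1_off <- min(om1_end + 0.1, orc2_on)
      }
      add_ev("orc_depart", orc1_off, "orc1")
      add_ev("orc_arrive", orc2_on, "orc2")
      add_mol("orc1", "orc", t_orc, orc1_off)
      add_mol("orc2", "orc", orc2_on, orc_b_off)
    }
    add_ia("om1", t_m1, om1_end, orc_a, "mcm1", "cdt1_release")
    add_extra_orc_visits(pathway, params, t_orc, om2_end, add_ev, add_mol)
    if (pathway == "two_overlap") {
      v_on <- om1_end + stats::runif(1) * max(t_m2 - om1_end, 0.1)
      v_off <- v_on + rexp_mean(1, 30)
      add_ev("orc_arrive", v_on, "orc_x")
      add_ev("orc_depart", v_off, "orc_x")
      add_mol("orc_x", "orc", v_on, v_off)
    }
    return(finish())
  }

  # MO formed but no stable second recruitment: the first Mcm2-7 (and the
  # tethered ORC) is eventually released; optionally a short-lived second
  # association occurs first.
  m1_off <- mo_start + draw_dwell(params, params$median_m1_with_mo_s / log(2))
  mo_end <- m1_off
  if (mech != "re_fret") {
    add_ev("mo_start", mo_start, "mcm1")
    add_ev("mo_end", mo_end, "mcm1")
    add_ia("mo", mo_start, mo_end, orc_b, "mcm1", "mcm_depart")
  }
  add_ev("mcm_depart", m1_off, "mcm1")
  set_off("mcm1", m1_off)
  if (stats::runif(1) < params$p_abortive_second) {
    t_ab <- mo_start + rexp_mean(1, 1 / params$mcm_arrival_rate)
    if (t_ab < mo_end) {
      dwell <- rexp_mean_below(1, params$mean_abortive_dwell_s, 48)
      add_ev("mcm2_arrive", t_ab, "mcm2")
      add_ev("mcm_depart", t_ab + dwell, "mcm2")
      add_mol("mcm2", "mcm", t_ab, t_ab + dwell)
      add_mol("cdt1_2", "cdt1", t_ab, t_ab + dwell)
      om2_acc <- if (mech == "re_fret") "mcm1" else "mcm2"
      if (mech != "re_fret") {
        add_ia("om2", t_ab, t_ab + dwell, orc_b, om2_acc, "mcm_depart")
        add_ev("om_start", t_ab, "mcm2")
        add_ev("om_end", t_ab + dwell, "mcm2")
      }
    }
  }
  orc_b_off <- mo_end
  add_ev("orc_depart", orc_b_off, orc_b)
  if (orc_b == "orc1") {
    add_mol("orc1", "orc", t_orc, orc_b_off)
  } else {
    if (pathway == "exchange") {
      orc1_off <- max(mo_start - 0.1, om1_end)
      orc2_on <- orc1_off
    } else {
      orc2_on <- orc2_arrival
      orc1_off <- min(om1_end + 0.1, orc2_on)
    }
    add_ev("orc_depart", orc1_off, "orc1")
    add_ev("orc_arrive", orc2_on, "orc2")
    add_mol("orc1", "orc", t_orc, orc1_off)
    add_mol("orc2", "orc", orc2_on, orc_b_off)
  }
  add_ia("om1", t_m1, om1_end, orc_a, "mcm1", "cdt1_release")
  add_extra_orc_visits(pathway, params, t_orc, orc_b_off, add_ev, add_mol)
  finish()
}

# Nonspecific extra-ORC background: short visits layered over the event
# span (the "three ORC" class attributed to nonspecific DNA binding).
add_extra_orc_visits <- function(pathway, params, span_start, span_end,
                                 add_ev, add_mol) {
  if (pathway != "extra") return(invisible())
  n <- 1L + stats::rpois(1, params$extra_orc_poisson_mean)
  span_end <- max(span_end, span_start + 1)
  for (i in seq_len(n)) {
    on <- stats::runif(1, span_start, span_end)
    off <- on + rexp_mean(1, params$mean_extra_orc_dwell_s)
    id <- paste0("orc_ns", i)
    add_ev("orc_arrive", on, id)
    add_ev("orc_depart", off, id)
    add_mol(id, "orc", on, off)
  }
  invisible()
}

#' Assign fluorophore label classes to molecules
#'
#' Each molecule instance is independently assigned a label class drawn
#' from its species' labeling plan (ORC donors: Orc5-C, Orc6-C, Orc1-N, or
#' unlabeled; Mcm2-7 acceptors: Mcm2-C, Mcm4-N, Mcm3-N, or unlabeled;
#' Cdt1: N- or C-terminal acceptor or unlabeled). Assignments are recorded
#' in the ground truth (molecule table and event log).
#'
#' @param design An [experiment_design()] whose plans are sampled.
#' @param trajectories A `trajectory_set` from [simulate_trajectories()].
#' @param rng_seed Integer seed.
#' @return The `trajectory_set` with `labeled = TRUE` and label classes
#'   filled in.
#' @export
assign_labels <- function(design, trajectories, rng_seed = 1L) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  plans <- list(orc = design$orc_label_plan, mcm = design$mcm_label_plan,
                cdt1 = design$cdt1_label_plan)
  with_seed(rng_seed, {
    trajectories$trajectories <- lapply(trajectories$trajectories, function(tr) {
      m <- tr$molecules
      if (nrow(m)) {
        m$label_class <- vapply(m$species, function(sp) {
          pl <- plans[[sp]]
          sample(names(pl), 1, prob = pl)
        }, character(1))
        tr$molecules <- m
        idx <- match(tr$events$molecule_id, m$molecule_id)
        tr$events$label_class <- m$label_class[idx]
      }
      tr
    })
  })
  trajectories$design <- design
  trajectories$labeled <- TRUE
  trajectories
}

#' Combined ground-truth event log
#'
#' @param trajectories A `trajectory_set`.
#' @return A data frame with columns `dna_id`, `event_kind`, `time_s`,
#'   `molecule_id`, `label_class` across all DNAs.
#' @export
ground_truth_log <- function(trajectories) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  out <- lapply(trajectories$trajectories, function(tr) {
    if (!nrow(tr$events)) return(NULL)
    cbind(dna_id = tr$dna_id, tr$events)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(dna_id = integer(), event_kind = character(),
                      time_s = numeric(), molecule_id = character(),
                      label_class = character())
  }
  rownames(out) <- NULL
  out
}

#' @export
print.trajectory_set <- function(x, ...) {
  n_ev <- sum(vapply(x$trajectories, function(t) nrow(t$events), integer(1)))
  cat("<trajectory_set>", length(x$trajectories), "DNAs,", n_ev, "events,",
      if (x$labeled) "labeled" else "unlabeled", "\n")
  invisible(x)
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat("<state_trajectory> dna", x$dna_id, "-", nrow(x$events), "events\n")
  if (nrow(x$events)) print(utils::head(x$events, 12))
  invisible(x)
}
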