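# Shared fixture builders. Everything is generated in code at test time.

# Fully labeled OM-pair design with deterministic pathway (one ORC, every
# attempt converts), used wherever a clean double-hexamer cohort is needed.
conditioned_config <- function(preset_name = "fig1", n_dna = 20, seed = 1,
                               ...) {
  cfg <- run_config(preset_name, n_dna = n_dna, seed = seed,
                    p_mo_given_first_mcm = 1, p_second_given_mo = 1,
                    p_one_orc = 1, p_two_orc_sequential = 0,
                    p_two_orc_overlap = 0, ...)
  donor <- if (cfg$preset %in% c("fig5-MO", "fig5-dN119", "fig5-prebound",
                                 "fig6-cdt1C")) "6C" else "5C"
  plan <- c("5C" = 0, "6C" = 0, "1N" = 0, dark = 0)
  plan[donor] <- 1
  cfg$design$orc_label_plan <- plan
  cfg
}

# A hand-built single-DNA trajectory set with exact interval geometry, for
# renderer unit tests. Times in seconds; labels fully specified.
manual_trajectory_set <- function(molecules, interactions, events = NULL,
                                  design = experiment_design(n_dna = 1),
                                  n_cycles = 100) {
  if (is.null(events)) {
    events <- data.frame(event_kind = character(), time_s = numeric(),
                         molecule_id = character(),
                         label_class = character())
  }
  tr <- structure(list(dna_id = 1L, events = events, molecules = molecules,
                       interactions = interactions,
                       t_total = n_cycles * 2.4),
                  class = "state_trajectory")
  design$duration_cycles <- as.integer(n_cycles)
  structure(list(trajectories = list(tr), params = kinetic_params(),
                 design = design, labeled = TRUE, rng_seed = 0L),
            class = "trajectory_set")
}

mol_row <- function(id, species, on, off, label) {
  data.frame(molecule_id = id, species = species, t_on = on, t_off = off,
             label_class = label)
}

ia_row <- function(kind, s, e, donor, acc) {
  data.frame(kind = kind, t_start = s, t_end = e, donor_id = donor,
             acceptor_id = acc, end_reason = "test")
}
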