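#' Experiment presets
#'
#' Named experimental designs matching the labeling schemes used in the
#' single-molecule helicase-loading study conditions:
#' \describe{
#'   \item{fig1}{OM-FRET pair: Orc5-C donor (0.88 labeled), Mcm2-C acceptor;
#'     0.5 nM ORC / 15 nM Cdt1-Mcm2-7 design.}
#'   \item{fig2-mixedMcm}{OM pair with an equimolar mix of Mcm2-C and Mcm4-N
#'     acceptor-labeled Mcm2-7 (7.5 nM each).}
#'   \item{fig3-mixedORC}{Equimolar mix of Orc5-C and Orc1-N donor-labeled
#'     ORC (0.25 nM each) with Mcm2-C acceptor.}
#'   \item{fig4-cdt1}{OM pair plus N-terminally acceptor-labeled Cdt1.}
#'   \item{fig4-5RA}{OM pair with the Cdt1-release-defective Mcm5-R549A
#'     mutant helicase.}
#'   \item{fig5-MO}{MO-FRET pair: Orc6-C donor, Mcm3-N acceptor.}
#'   \item{fig5-dN119}{MO pair with the Orc6 N-terminal-deletion mutant.}
#'   \item{fig5-prebound}{MO pair, ORC/Cdc6 prebound and free ORC withheld.}
#'   \item{fig6-cdt1C}{MO pair plus C-terminally acceptor-labeled Cdt1.}
#'   \item{bleach-control}{Donor-labeled ORC with unlabeled Mcm2-7 (5RA) for
#'     photobleaching-rate determination; set `laser_exposure_factor` to 1
#'     or 2.4.}
#' }
#'
#' @param name Preset name (see Details).
#' @param n_dna Number of DNA molecules.
#' @param ... Overrides passed to [kinetic_params()].
#' @return A list with elements `kinetic` ([kinetic_params()]),
#'   `design` ([experiment_design()]), `timing` and `phys`.
#' @export
#' @examples
#' p <- preset("fig1", n_dna = 4)
#' p$kinetic$mean_first_om_s
preset <- function(name, n_dna = 64, ...) {
  name <- match.arg(name, preset_names())
  kin <- switch(name,
    "fig4-5RA" = kinetic_params(mutant = "mcm5RA", ...),
    "fig5-dN119" = kinetic_params(mutant = "orc6dN119", ...),
    kinetic_params(...)
  )
  des <- switch(name,
    "fig1" = experiment_design(n_dna = n_dna),
    "fig2-mixedMcm" = experiment_design(
      n_dna = n_dna, mcm_label_plan = c("2C" = 0.5, "4N" = 0.5)),
    "fig3-mixedORC" = experiment_design(
      n_dna = n_dna, orc_label_plan = c("5C" = 0.44, "1N" = 0.44, dark = 0.12)),
    "fig4-cdt1" = experiment_design(
      n_dna = n_dna, cdt1_label_plan = c("N649" = 1)),
    "fig4-5RA" = experiment_design(n_dna = n_dna),
    "fig5-MO" = experiment_design(
      n_dna = n_dna, orc_label_plan = c("6C" = 0.88, dark = 0.12),
      mcm_label_plan = c("3N" = 1)),
    "fig5-dN119" = experiment_design(
      n_dna = n_dna, orc_label_plan = c("6C" = 0.88, dark = 0.12),
      mcm_label_plan = c("3N" = 1)),
    "fig5-prebound" = experiment_design(
      n_dna = n_dna, orc_label_plan = c("6C" = 0.88, dark = 0.12),
      mcm_label_plan = c("3N" = 1), staged_prebound = TRUE),
    "fig6-cdt1C" = experiment_design(
      n_dna = n_dna, orc_label_plan = c("6C" = 0.88, dark = 0.12),
      mcm_label_plan = c("3N" = 1), cdt1_label_plan = c("C650" = 1)),
    "bleach-control" = experiment_design(
      n_dna = n_dna, mcm_label_plan = c(dark = 1))
  )
  if (name == "bleach-control" && kin$mutant == "wildtype") {
    kin <- kinetic_params(mutant = "mcm5RA", ...)
  }
  list(name = name, kinetic = kin, design = des,
       timing = frame_timing(n_cycles = des$duration_cycles),
       phys = photophysics_params())
}

#' @rdname preset
#' @export
preset_names <- function() {
  c("fig1", "fig2-mixedMcm", "fig3-mixedORC", "fig4-cdt1", "fig4-5RA",
    "fig5-MO", "fig5-dN119", "fig5-prebound", "fig6-cdt1C", "bleach-control")
}
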