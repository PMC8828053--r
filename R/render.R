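#' Render state trajectories into three-channel fluorescence traces
#'
#' Converts labeled trajectories into per-frame intensities under the
#' alternating-excitation scheme: each 2.4-s cycle holds one 1-s
#' donor-excited exposure and one 1-s acceptor-excited exposure. During
#' donor-excited frames with an interacting donor/acceptor pair the
#' noiseless emission split is `I_Aem = E * T` and `I_Dem = (1 - E) * T`
#' with `T = unit_intensity * pife_factor` while an OM interaction is
#' active (protein-induced fluorescence enhancement of the donor dye) and
#' `T = unit_intensity` otherwise; `E` is the apparent-FRET set-point of
#' the active state. When a donor coexists on the DNA with labeled
#' acceptor(s) but no interaction is active, the low "no-interaction"
#' set-point applies (0.08, or the Cdt1-specific control values).
#' Acceptor-excited intensity counts present, unbleached acceptors and is
#' independent of FRET state (direct excitation only). State occupancy is
#' integrated over each exposure, so transitions inside an exposure scale
#' emission by fractional occupancy. Zero-mean Gaussian background noise is
#' added to every recorded channel (traces model background-corrected
#' records).
#'
#' @param trajectories A labeled `trajectory_set` (see [assign_labels()]).
#' @param timing A [frame_timing()] object.
#' @param phys A [photophysics_params()] object.
#' @param rng_seed Integer seed (noise stream).
#' @return An object of class `trace_set`: a list with `traces` (one row
#'   per DNA x frame: `dna_id`, `cycle`, `frame_kind`, `time_s`,
#'   `I_Dex_Dem`, `I_Dex_Aem`, `I_Aex_Aem`; donor-excited channels are `NA`
#'   on acceptor-excited frames and vice versa), `timing`, `phys`, the
#'   embedded ground-truth `trajectories`, and `bleach_log`.
#' @export
render_traces <- function(trajectories, timing = frame_timing(),
                          phys = photophysics_params(), rng_seed = 1L) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  if (!isTRUE(trajectories$labeled)) {
    stop("render_traces: trajectories must be labeled (see assign_labels)",
         call. = FALSE)
  }
  render_core(trajectories, timing, phys, rng_seed, bleach_log = NULL)
}

#' Apply stochastic photobleaching to a rendered trace set
#'
#' Each dye bleaches independently with a fixed probability per illuminated
#' exposure, scaled by the design's `laser_exposure_factor`; traces are
#' re-rendered with dye activity truncated at the sampled bleach times, and
#' bleach events are recorded. The observed fluorophore-loss rate is then
#' the intrinsic departure rate plus the bleach rate times the exposure
#' factor, which is the basis of the bleach-rate decomposition in
#' [estimate_bleach_rate()].
#'
#' @param traceset A `trace_set` from [render_traces()].
#' @param phys A [photophysics_params()]; `bleach_prob_per_exposure = 0`
#'   returns the input unchanged.
#' @param rng_seed Integer seed (bleach draws and fresh noise stream).
#' @return A `trace_set` with a populated `bleach_log` (data frame:
#'   `dna_id`, `molecule_id`, `label_class`, `bleach_time_s`).
#' @export
apply_photobleaching <- function(traceset, phys = NULL, rng_seed = 1L) {
  stopifnot(inherits(traceset, "trace_set"))
  phys <- phys %||% traceset$phys
  if (phys$bleach_prob_per_exposure == 0) return(traceset)
  trajset <- traceset$trajectories
  timing <- traceset$timing
  q <- min(1, phys$bleach_prob_per_exposure *
             trajset$design$laser_exposure_factor)
  t_total <- timing$n_cycles * timing$cycle_s
  log_rows <- list()
  with_seed(sub_seed(rng_seed, 11L), {
    for (tr in trajset$trajectories) {
      m <- tr$molecules
      if (!nrow(m)) next
      for (k in seq_len(nrow(m))) {
        lab <- m$label_class[k]
        if (is.na(lab) || lab == "dark") next
        kind <- if (m$species[k] == "orc") "donor_ex" else "acceptor_ex"
        starts <- frame_starts(timing, kind)
        expo <- if (kind == "donor_ex") timing$donor_exposure_s
                else timing$acceptor_exposure_s
        s <- max(0, m$t_on[k])
        e <- min(t_total, if (is.finite(m$t_off[k])) m$t_off[k] else t_total)
        lit <- which(overlap_frac(s, e, starts, expo) > 0)
        if (!length(lit)) next
        g <- stats::rgeom(1, q) + 1L
        if (g <= length(lit)) {
          bt <- starts[lit[g]] + 0.5 * expo
          log_rows[[length(log_rows) + 1L]] <- data.frame(
            dna_id = tr$dna_id, molecule_id = m$molecule_id[k],
            label_class = lab, bleach_time_s = bt)
        }
      }
    }
  })
  bl <- if (length(log_rows)) do.call(rbind, log_rows)
        else data.frame(dna_id = integer(), molecule_id = character(),
                        label_class = character(), bleach_time_s = numeric())
  render_core(trajset, timing, phys, sub_seed(rng_seed, 12L), bleach_log = bl)
}

frame_starts <- function(timing, kind) {
  base <- (seq_len(timing$n_cycles) - 1L) * timing$cycle_s
  if (kind == "donor_ex") base
  else base + timing$donor_exposure_s + timing$dead_s
}

render_core <- function(trajset, timing, phys, rng_seed, bleach_log = NULL) {
  t_total <- timing$n_cycles * timing$cycle_s
  tD <- frame_starts(timing, "donor_ex")
  tA <- frame_starts(timing, "acceptor_ex")
  nC <- timing$n_cycles
  out <- vector("list", length(trajset$trajectories))
  with_seed(rng_seed, {
    for (i in seq_along(trajset$trajectories)) {
      tr <- trajset$trajectories[[i]]
      cuts <- NULL
      if (!is.null(bleach_log) && nrow(bleach_log)) {
        cuts <- bleach_log[bleach_log$dna_id == tr$dna_id, , drop = FALSE]
      }
      sig <- render_one_dna(tr, timing, phys, t_total, tD, tA, cuts)
      noise <- function(n) stats::rnorm(n, 0, phys$background_sd)
      df <- data.frame(
        dna_id = tr$dna_id,
        cycle = rep(seq_len(nC), each = 2L),
        frame_kind = rep(c("donor_ex", "acceptor_ex"), nC),
        time_s = as.vector(rbind(tD, tA)),
        I_Dex_Dem = NA_real_, I_Dex_Aem = NA_real_, I_Aex_Aem = NA_real_)
      dsel <- df$frame_kind == "donor_ex"
      df$I_Dex_Dem[dsel] <- sig$dem + noise(nC)
      df$I_Dex_Aem[dsel] <- sig$aem + noise(nC)
      df$I_Aex_Aem[!dsel] <- sig$aex + noise(nC)
      out[[i]] <- df
    }
  })
  structure(list(traces = do.call(rbind, out), timing = timing, phys = phys,
                 trajectories = trajset,
                 bleach_log = bleach_log %||% data.frame(
                   dna_id = integer(), molecule_id = character(),
                   label_class = character(), bleach_time_s = numeric())),
            class = "trace_set")
}

# Active (presence AND unbleached) interval of one molecule row.
mol_active <- function(m, k, t_total, cuts) {
  s <- max(0, m$t_on[k])
  e <- min(t_total, if (is.finite(m$t_off[k])) m$t_off[k] else t_total)
  if (!is.null(cuts) && nrow(cuts)) {
    hit <- cuts$bleach_time_s[cuts$molecule_id == m$molecule_id[k]]
    if (length(hit)) e <- min(e, hit[1])
  }
  c(s, e)
}

render_one_dna <- function(tr, timing, phys, t_total, tD, tA, cuts) {
  nC <- timing$n_cycles
  dem <- numeric(nC); aem <- numeric(nC); aex <- numeric(nC)
  m <- tr$molecules
  if (!nrow(m)) return(list(dem = dem, aem = aem, aex = aex))
  lab <- m$label_class
  lab[is.na(lab)] <- "dark"
  act <- lapply(seq_len(nrow(m)), function(k) mol_active(m, k, t_total, cuts))
  names(act) <- m$molecule_id

  # Direct acceptor excitation: one unit per present, unbleached acceptor.
  acc_rows <- which(m$species %in% c("mcm", "cdt1") & lab != "dark")
  for (k in acc_rows) {
    a <- act[[k]]
    if (a[2] > a[1]) {
      aex <- aex + phys$unit_intensity *
        overlap_frac(a[1], a[2], tA, timing$acceptor_exposure_s)
    }
  }

  donor_rows <- which(m$species == "orc" & lab %in% c("5C", "6C", "1N"))
  if (!length(donor_rows)) return(list(dem = dem, aem = aem, aex = aex))

  acc_union <- iv_union(do.call(rbind, c(list(iv_make(numeric(), numeric())),
    lapply(acc_rows, function(k) iv_make(act[[k]][1], act[[k]][2])))))
  cdt1_rows <- which(m$species == "cdt1" & lab != "dark")

  ia <- tr$interactions
  for (dk in donor_rows) {
    did <- m$molecule_id[dk]
    dlab <- lab[dk]
    P <- iv_make(act[[dk]][1], act[[dk]][2])
    if (!nrow(P)) next
    segs <- list()  # each: list(iv = matrix, E = set-point)
    my_ia <- if (nrow(ia)) ia[ia$donor_id == did, , drop = FALSE] else ia
    pife_iv <- iv_make(numeric(), numeric())
    if (nrow(my_ia)) {
      om_rows <- which(my_ia$kind %in% c("om1", "om2"))
      if (length(om_rows)) {
        pife_iv <- iv_intersect(P, iv_union(
          iv_make(my_ia$t_start[om_rows], my_ia$t_end[om_rows])))
      }
      for (r in seq_len(nrow(my_ia))) {
        acc_id <- my_ia$acceptor_id[r]
        ak <- match(acc_id, m$molecule_id)
        if (is.na(ak)) next
        alab <- lab[ak]
        iv <- iv_intersect(P, iv_make(my_ia$t_start[r], my_ia$t_end[r]))
        iv <- iv_intersect(iv, iv_make(act[[ak]][1], act[[ak]][2]))
        if (!nrow(iv)) next
        kind <- my_ia$kind[r]
        if (kind %in% c("om1", "om2") && dlab == "5C" && alab == "2C") {
          E0 <- if (kind == "om1") phys$efret_om_first else phys$efret_om_second
          # Composite set-point while the co-arrived N-labeled Cdt1 is there.
          cd_id <- if (kind == "om1") "cdt1_1" else "cdt1_2"
          ck <- match(cd_id, m$molecule_id)
          if (!is.na(ck) && lab[ck] == "N649") {
            civ <- iv_intersect(iv, iv_make(act[[ck]][1], act[[ck]][2]))
            if (nrow(civ)) {
              segs[[length(segs) + 1L]] <- list(iv = civ,
                                                E = phys$efret_om_with_cdt1N)
              iv <- iv_subtract(iv, civ)
            }
          }
          if (nrow(iv)) segs[[length(segs) + 1L]] <- list(iv = iv, E = E0)
        } else if (kind == "mo" && dlab == "6C" && alab == "3N") {
          segs[[length(segs) + 1L]] <- list(iv = iv, E = phys$efret_mo)
        }
      }
    }
    high_iv <- if (length(segs)) iv_union(do.call(rbind,
      lapply(segs, `[[`, "iv"))) else iv_make(numeric(), numeric())
    # Baseline: donor present with labeled acceptor(s) but no coupled state.
    base_iv <- iv_subtract(iv_intersect(P, acc_union), high_iv)
    if (nrow(base_iv)) {
      # Cdt1-control set-points take precedence over the generic 0.08.
      special <- iv_make(numeric(), numeric())
      for (ck in cdt1_rows) {
        eS <- if (dlab == "5C" && lab[ck] == "N649") phys$efret_cdt1N_control
          else if (dlab == "6C" && lab[ck] == "C650") phys$efret_cdt1C_control
          else NA_real_
        if (is.na(eS)) next
        civ <- iv_intersect(base_iv, iv_make(act[[ck]][1], act[[ck]][2]))
        if (nrow(civ)) {
          segs[[length(segs) + 1L]] <- list(iv = civ, E = eS)
          special <- iv_union(rbind(special, civ))
        }
      }
      rest <- iv_subtract(base_iv, special)
      if (nrow(rest)) segs[[length(segs) + 1L]] <- list(iv = rest,
                                                        E = phys$efret_baseline)
    }
    dark_iv <- iv_subtract(iv_subtract(P, high_iv), base_iv)
    if (nrow(dark_iv)) segs[[length(segs) + 1L]] <- list(iv = dark_iv, E = 0)

    for (sg in segs) {
      for (pife_on in c(TRUE, FALSE)) {
        iv <- if (pife_on) iv_intersect(sg$iv, pife_iv)
              else iv_subtract(sg$iv, pife_iv)
        if (!nrow(iv)) next
        Tf <- phys$unit_intensity * if (pife_on) phys$pife_factor else 1
        for (r in seq_len(nrow(iv))) {
          fr <- overlap_frac(iv[r, 1], iv[r, 2], tD, timing$donor_exposure_s)
          dem <- dem + (1 - sg$E) * Tf * fr
          aem <- aem + sg$E * Tf * fr
        }
      }
    }
  }
  list(dem = dem, aem = aem, aex = aex)
}

#' @export
print.trace_set <- function(x, ...) {
  nd <- length(unique(x$traces$dna_id))
  cat("<trace_set>", nd, "DNAs x", x$timing$n_cycles, "cycles",
      sprintf("(%.0f s)", x$timing$n_cycles * x$timing$cycle_s), "\n")
  invisible(x)
}

#' Write / read a trace set as CSV
#'
#' One row per DNA x frame; the schema is the `traces` data frame of
#' [render_traces()]. Reading back returns a bare `trace_set` without the
#' embedded ground truth.
#'
#' @param traceset A `trace_set`.
#' @param path Output CSV path.
#' @return `write_traces_csv` returns `path` invisibly; `read_traces_csv`
#'   returns a `trace_set`.
#' @export
write_traces_csv <- function(traceset, path) {
  utils::write.csv(traceset$traces, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @param timing,phys Acquisition metadata to attach on read.
#' @export
read_traces_csv <- function(path, timing = frame_timing(),
                            phys = photophysics_params()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dna_id", "cycle", "frame_kind", "time_s",
            "I_Dex_Dem", "I_Dex_Aem", "I_Aex_Aem")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("trace CSV schema mismatch; missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  timing$n_cycles <- max(df$cycle)
  structure(list(traces = df, timing = timing, phys = phys,
                 trajectories = NULL,
                 bleach_log = data.frame()),
            class = "trace_set")
}
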