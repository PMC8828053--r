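#' Map DNA positions in a synthetic TIRF field
#'
#' Draws sub-pixel DNA spot coordinates in a small pixel field with a
#' minimum pairwise spacing of 4 PSF sigmas (so neighbouring spots do not
#' blend at the default PSF width).
#'
#' @param n_spots Number of DNA positions.
#' @param size_px Field side length in pixels (default 64).
#' @param psf_sigma PSF sigma in pixels (default 1.2).
#' @param rng_seed Integer seed.
#' @param dna_ids Identifiers to attach (default `1:n_spots`).
#' @return Object of class `field_map`: data frame `positions`
#'   (`dna_id`, `x`, `y`), plus `size_px` and `psf_sigma`.
#' @export
field_map <- function(n_spots, size_px = 64, psf_sigma = 1.2, rng_seed = 1L,
                      dna_ids = seq_len(n_spots)) {
  min_sep <- 4 * psf_sigma
  margin <- 4 * psf_sigma
  xs <- numeric(0); ys <- numeric(0)
  with_seed(rng_seed, {
    tries <- 0L
    while (length(xs) < n_spots) {
      x <- stats::runif(1, margin, size_px - margin)
      y <- stats::runif(1, margin, size_px - margin)
      if (!length(xs) || all((xs - x)^2 + (ys - y)^2 >= min_sep^2)) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
      tries <- tries + 1L
      if (tries > 10000L * n_spots) {
        stop("field_map: could not place spots with the required spacing",
             call. = FALSE)
      }
    }
  })
  structure(list(positions = data.frame(dna_id = dna_ids, x = xs, y = ys),
                 size_px = size_px, psf_sigma = psf_sigma),
            class = "field_map")
}

# Integrated 2-D Gaussian PSF: fraction of unit flux landing in each pixel.
psf_patch <- function(x0, y0, sigma, size_px, halfwidth) {
  ix <- max(1L, floor(x0 - halfwidth)):min(size_px, ceiling(x0 + halfwidth))
  iy <- max(1L, floor(y0 - halfwidth)):min(size_px, ceiling(y0 + halfwidth))
  px <- stats::pnorm((ix + 0.5 - x0) / sigma) -
    stats::pnorm((ix - 0.5 - x0) / sigma)
  py <- stats::pnorm((iy + 0.5 - y0) / sigma) -
    stats::pnorm((iy - 0.5 - y0) / sigma)
  list(ix = ix, iy = iy, w = outer(px, py))
}

#' Render a trace set into a synthetic movie
#'
#' Each DNA spot is drawn as an integrated 2-D Gaussian whose total flux in
#' every frame equals that DNA's (noiseless re-rendered) trace intensity in
#' the corresponding channel, plus per-pixel Gaussian noise. The stack
#' holds `2 * n_cycles` frames (one donor-excited and one acceptor-excited
#' frame per cycle), each with the two emission fields of the donor-excited
#' frame kept separate.
#'
#' @param traceset A `trace_set`.
#' @param fieldmap A [field_map()] covering every `dna_id` in the traces.
#' @param psf_sigma PSF sigma in pixels.
#' @param rng_seed Seed for the pixel noise.
#' @param pixel_noise_sd Per-pixel noise SD (arbitrary units).
#' @return Object of class `movie_stack`: arrays `Dex_Dem`, `Dex_Aem`,
#'   `Aex_Aem` of dimension `size_px x size_px x n_cycles`, plus timing and
#'   field metadata. Frame count is `2 * n_cycles`.
#' @export
render_movie <- function(traceset, fieldmap, psf_sigma = fieldmap$psf_sigma,
                         rng_seed = 1L, pixel_noise_sd = 30) {
  stopifnot(inherits(traceset, "trace_set"), inherits(fieldmap, "field_map"))
  df <- traceset$traces
  ids <- unique(df$dna_id)
  pos <- fieldmap$positions
  if (!all(ids %in% pos$dna_id)) {
    stop("render_movie: unmapped dna_id in trace set", call. = FALSE)
  }
  nC <- traceset$timing$n_cycles
  sz <- fieldmap$size_px
  hw <- ceiling(5 * psf_sigma)
  chans <- c("Dex_Dem", "Dex_Aem", "Aex_Aem")
  stacks <- lapply(chans, function(ch) array(0, dim = c(sz, sz, nC)))
  names(stacks) <- chans
  for (id in ids) {
    sub <- df[df$dna_id == id, ]
    p <- pos[pos$dna_id == id, ]
    patch <- psf_patch(p$x, p$y, psf_sigma, sz, hw)
    don <- sub[sub$frame_kind == "donor_ex", ]
    acc <- sub[sub$frame_kind == "acceptor_ex", ]
    for (ch in chans) {
      flux <- if (ch == "Aex_Aem") acc$I_Aex_Aem else don[[paste0("I_", ch)]]
      for (k in seq_len(nC)) {
        if (is.na(flux[k]) || flux[k] == 0) next
        stacks[[ch]][patch$ix, patch$iy, k] <-
          stacks[[ch]][patch$ix, patch$iy, k] + flux[k] * patch$w
      }
    }
  }
  if (pixel_noise_sd > 0) {
    with_seed(rng_seed, {
      for (ch in chans) {
        stacks[[ch]] <- stacks[[ch]] +
          array(stats::rnorm(sz * sz * nC, 0, pixel_noise_sd),
                dim = c(sz, sz, nC))
      }
    })
  }
  structure(c(stacks,
              list(size_px = sz, psf_sigma = psf_sigma,
                   pixel_noise_sd = pixel_noise_sd,
                   timing = traceset$timing, fieldmap = fieldmap,
                   n_frames = 2L * nC)),
            class = "movie_stack")
}

#' Detect fluorescent spots in a single frame
#'
#' Local maxima above `threshold_sd` noise SDs, refined to a sub-pixel
#' centroid over a small window; duplicate candidates within 2 sigma keep
#' only the brightest. Flux is the background-free sum over a 6-sigma box.
#'
#' @param frame A pixel matrix.
#' @param threshold_sd Detection threshold in noise SDs.
#' @param noise_sd Known noise scale; estimated robustly when `NULL`.
#' @param psf_sigma PSF sigma in pixels.
#' @return Data frame: `x`, `y`, `flux` (possibly empty).
#' @export
detect_spots <- function(frame, threshold_sd = 5, noise_sd = NULL,
                         psf_sigma = 1.2) {
  if (is.null(noise_sd)) noise_sd <- stats::mad(frame)
  thr <- threshold_sd * noise_sd
  nr <- nrow(frame); nc <- ncol(frame)
  if (!is.finite(thr)) return(data.frame(x = numeric(), y = numeric(),
                                         flux = numeric()))
  cand <- which(frame >= thr, arr.ind = TRUE)
  cand <- cand[cand[, 1] > 1 & cand[, 1] < nr & cand[, 2] > 1 &
                 cand[, 2] < nc, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    keep[i] <- frame[r, c] == max(frame[(r - 1):(r + 1), (c - 1):(c + 1)])
  }
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(data.frame(x = numeric(), y = numeric(),
                                     flux = numeric()))
  w <- max(2L, ceiling(2 * psf_sigma))
  box <- ceiling(3 * psf_sigma)
  out <- lapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]
    ix <- max(1, r - w):min(nr, r + w)
    iy <- max(1, c - w):min(nc, c + w)
    patch <- pmax(frame[ix, iy], 0)
    tot <- sum(patch)
    x <- sum(ix * rowSums(patch)) / tot
    y <- sum(iy * colSums(patch)) / tot
    fx <- max(1, round(x) - box):min(nr, round(x) + box)
    fy <- max(1, round(y) - box):min(nc, round(y) + box)
    data.frame(x = x, y = y, flux = sum(frame[fx, fy]),
               peak = frame[r, c])
  })
  out <- do.call(rbind, out)
  # Deduplicate within 2 sigma, keeping the brighter peak.
  out <- out[order(-out$peak), ]
  sel <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!sel[i]) next
    if (i < nrow(out)) {
      d2 <- (out$x[-(1:i)] - out$x[i])^2 + (out$y[-(1:i)] - out$y[i])^2
      sel[-(1:i)][d2 < (2 * psf_sigma)^2] <- FALSE
    }
  }
  out <- out[sel, c("x", "y", "flux")]
  rownames(out) <- NULL
  out
}

#' Extract traces from a movie by colocalization with mapped DNA positions
#'
#' Integrates pixel intensities in a fixed box around each mapped DNA
#' position for every frame and channel; optionally flags frames in which
#' a detected spot lies within `radius_px` of the DNA position.
#'
#' @param movie A `movie_stack`.
#' @param fieldmap A [field_map()] (defaults to the one embedded in the
#'   movie).
#' @param radius_px Colocalization radius in pixels (> 0).
#' @param detect If `TRUE`, run [detect_spots()] per frame and add a
#'   `colocalized` flag on acceptor frames.
#' @param threshold_sd Spot-detection threshold when `detect = TRUE`.
#' @return A `trace_set` with the standard `traces` schema (plus
#'   `colocalized` when requested); ground truth is not carried over.
#' @export
colocalize_and_extract <- function(movie, fieldmap = movie$fieldmap,
                                   radius_px = 2, detect = FALSE,
                                   threshold_sd = 5) {
  stopifnot(inherits(movie, "movie_stack"))
  if (radius_px <= 0) {
    stop("colocalize_and_extract: radius_px must be > 0", call. = FALSE)
  }
  pos <- fieldmap$positions
  nC <- dim(movie$Aex_Aem)[3]
  sz <- movie$size_px
  box <- ceiling(3 * movie$psf_sigma)
  tD <- frame_starts(movie$timing, "donor_ex")[seq_len(nC)]
  tA <- frame_starts(movie$timing, "acceptor_ex")[seq_len(nC)]
  out <- vector("list", nrow(pos))
  for (i in seq_len(nrow(pos))) {
    x0 <- pos$x[i]; y0 <- pos$y[i]
    ix <- max(1, round(x0) - box):min(sz, round(x0) + box)
    iy <- max(1, round(y0) - box):min(sz, round(y0) + box)
    sums <- lapply(c("Dex_Dem", "Dex_Aem", "Aex_Aem"), function(ch) {
      apply(movie[[ch]][ix, iy, , drop = FALSE], 3, sum)
    })
    df <- data.frame(
      dna_id = pos$dna_id[i],
      cycle = rep(seq_len(nC), each = 2L),
      frame_kind = rep(c("donor_ex", "acceptor_ex"), nC),
      time_s = as.vector(rbind(tD, tA)),
      I_Dex_Dem = NA_real_, I_Dex_Aem = NA_real_, I_Aex_Aem = NA_real_)
    dsel <- df$frame_kind == "donor_ex"
    df$I_Dex_Dem[dsel] <- sums[[1]]
    df$I_Dex_Aem[dsel] <- sums[[2]]
    df$I_Aex_Aem[!dsel] <- sums[[3]]
    if (detect) {
      df$colocalized <- NA
      hit <- vapply(seq_len(nC), function(k) {
        sp <- detect_spots(movie$Aex_Aem[, , k], threshold_sd,
                           noise_sd = movie$pixel_noise_sd,
                           psf_sigma = movie$psf_sigma)
        nrow(sp) > 0 &&
          any((sp$x - x0)^2 + (sp$y - y0)^2 <= radius_px^2)
      }, logical(1))
      df$colocalized[!dsel] <- hit
    }
    out[[i]] <- df
  }
  timing <- movie$timing
  timing$n_cycles <- nC
  structure(list(traces = do.call(rbind, out), timing = timing,
                 phys = NULL, trajectories = NULL,
                 bleach_log = data.frame()),
            class = "trace_set")
}

#' Write a movie stack as multi-page TIFF files
#'
#' One TIFF per channel, frames as pages, intensities scaled to \[0, 1\]
#' by the stack maximum. Requires the `tiff` package.
#'
#' @param movie A `movie_stack`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the written paths.
#' @export
write_movie_tiff <- function(movie, dir, prefix = "movie") {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("write_movie_tiff requires the `tiff` package", call. = FALSE)
  }
  paths <- character()
  for (ch in c("Dex_Dem", "Dex_Aem", "Aex_Aem")) {
    arr <- movie[[ch]]
    rng <- max(abs(arr), 1e-9)
    pages <- lapply(seq_len(dim(arr)[3]), function(k) {
      pmin(pmax(arr[, , k] / rng, 0), 1)
    })
    p <- file.path(dir, paste0(prefix, "_", ch, ".tif"))
    tiff::writeTIFF(pages, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @export
print.movie_stack <- function(x, ...) {
  cat("<movie_stack>", x$size_px, "x", x$size_px, "px,", x$n_frames,
      "frames (", dim(x$Aex_Aem)[3], "cycles )\n")
  invisible(x)
}
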