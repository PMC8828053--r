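#' Product-limit survival curve with Greenwood confidence bounds
#'
#' Kaplan-Meier estimator of the dwell-time survival function with
#' pointwise 95% confidence bounds from the Greenwood variance formula
#' (linear scale). Censored observations contribute to the risk set only.
#' Without censoring the estimator equals one minus the empirical CDF.
#'
#' @param durations Dwell times (s), n >= 1.
#' @param censored Logical right-censoring flags (same length).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `survival_curve`: `time`, `surv`, `lower`,
#'   `upper` (all starting at S(0) = 1), `n`, `n_censored`, and the
#'   underlying `survival::survfit` object as `fit`.
#' @export
survival_curve <- function(durations, censored = rep(FALSE, length(durations)),
                           conf_level = 0.95) {
  if (!length(durations)) stop("survival_curve: empty input", call. = FALSE)
  stopifnot(length(censored) == length(durations))
  fit <- survival::survfit(
    survival::Surv(durations, !censored) ~ 1,
    conf.type = "plain", conf.int = conf_level)
  lo <- pmax(0, fit$lower)
  hi <- pmin(1, fit$upper)
  # where S hits 0 the Greenwood variance degenerates; the band collapses
  lo[is.na(lo)] <- fit$surv[is.na(lo)]
  hi[is.na(hi)] <- fit$surv[is.na(hi)]
  structure(list(time = c(0, fit$time),
                 surv = c(1, fit$surv),
                 lower = c(1, lo),
                 upper = c(1, hi),
                 n = length(durations),
                 n_censored = sum(censored),
                 fit = fit),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("<survival_curve> n =", x$n, "(", x$n_censored, "censored )\n")
  invisible(x)
}

#' @rdname survival_curve
#' @param x A `survival_curve`.
#' @param t Times at which to evaluate S(t).
#' @export
surv_at <- function(x, t) {
  stopifnot(inherits(x, "survival_curve"))
  idx <- findInterval(t, x$time)
  x$surv[pmax(idx, 1L)]
}

#' Censored-exponential maximum-likelihood fit
#'
#' For exponential dwell times with right censoring the MLE of the mean is
#' the total observation time divided by the number of uncensored events.
#' Uncertainty is estimated by nonparametric bootstrap over events
#' (resampling whole observations, B resamples).
#'
#' Dwells below a detection limit are never recorded, which left-truncates
#' the sample and, by memorylessness, shifts the naive mean up by the
#' effective floor. Setting `t_min` above the floor restores an unbiased
#' estimate: observations shorter than `t_min` are dropped and `t_min` is
#' subtracted from the rest before the MLE (exact for exponential dwells).
#'
#' @param durations Dwell times (s).
#' @param censored Logical right-censoring flags.
#' @param bootstrap_B Number of bootstrap resamples (default 1000).
#' @param rng_seed Integer seed for the bootstrap.
#' @param t_min Left-truncation point (s); 0 disables the correction.
#' @return Object of class `rate_fit`: `mean_s`, `se`, `rate`, `n`,
#'   `n_censored`, `loglik`, `boot_means`, `t_min`.
#' @export
fit_exponential_mle <- function(durations,
                                censored = rep(FALSE, length(durations)),
                                bootstrap_B = 1000, rng_seed = 1L,
                                t_min = 0) {
  stopifnot(length(censored) == length(durations))
  if (t_min > 0) {
    keep <- durations >= t_min
    durations <- durations[keep] - t_min
    censored <- censored[keep]
  }
  n_unc <- sum(!censored)
  if (n_unc == 0L) {
    stop("fit_exponential_mle: all observations censored; mean dwell is ",
         "not identifiable", call. = FALSE)
  }
  mle <- function(d, c) sum(d) / sum(!c)
  m <- mle(durations, censored)
  ll <- -sum(!censored) * log(m) - sum(durations) / m
  boot <- numeric(0)
  se <- NA_real_
  if (bootstrap_B > 0) {
    n <- length(durations)
    with_seed(rng_seed, {
      boot <- vapply(seq_len(bootstrap_B), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        if (all(censored[idx])) return(NA_real_)
        mle(durations[idx], censored[idx])
      }, numeric(1))
    })
    se <- stats::sd(boot, na.rm = TRUE)
  }
  structure(list(mean_s = m, se = se, rate = 1 / m, n = length(durations),
                 n_censored = sum(censored), loglik = ll, boot_means = boot,
                 t_min = t_min),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> mean = %.3g +/- %.2g s (n = %d, %d censored)\n",
              x$mean_s, x$se, x$n, x$n_censored))
  invisible(x)
}

#' Decompose an observed fluorophore-loss rate into bleaching and
#' intrinsic components
#'
#' Dwell-time fits at two relative laser exposures obey
#' `k_obs(f) = k_intrinsic + f * k_bleach`; the two-condition design
#' (alternating excitation, f = 1, versus continuous excitation, f = 2.4)
#' determines both unknowns by a linear solve, with first-order SE
#' propagation from the fitted means.
#'
#' @param fit_low,fit_high `rate_fit` objects at the two exposures.
#' @param exposure_low,exposure_high Relative laser exposure factors.
#' @return List: `k_bleach`, `k_bleach_se`, `k_intrinsic`,
#'   `k_intrinsic_se` (all per second; `k_bleach` per unit exposure).
#' @export
estimate_bleach_rate <- function(fit_low, fit_high, exposure_low = 1,
                                 exposure_high = 2.4) {
  if (exposure_low == exposure_high) {
    stop("estimate_bleach_rate: identical exposure factors give a singular ",
         "system", call. = FALSE)
  }
  k1 <- 1 / fit_low$mean_s
  k2 <- 1 / fit_high$mean_s
  se_k1 <- fit_low$se / fit_low$mean_s^2
  se_k2 <- fit_high$se / fit_high$mean_s^2
  df <- exposure_high - exposure_low
  kb <- (k2 - k1) / df
  ki <- k1 - exposure_low * kb
  a <- 1 + exposure_low / df   # d ki / d k1
  b <- -exposure_low / df      # d ki / d k2
  list(k_bleach = kb,
       k_bleach_se = sqrt(se_k1^2 + se_k2^2) / abs(df),
       k_intrinsic = ki,
       k_intrinsic_se = sqrt((a * se_k1)^2 + (b * se_k2)^2))
}

#' Probability that both of two independently labeled molecules carry a dye
#'
#' With per-molecule labeling probability p, two independent molecules are
#' both labeled with probability p^2 (e.g. 0.88^2 = 0.77, the expected
#' two-ORC visibility if two ORCs were required).
#'
#' @param p_label Labeling probability in \[0, 1\].
#' @return p^2.
#' @export
expected_two_label_fraction <- function(p_label) {
  if (!is.numeric(p_label) || any(p_label < 0 | p_label > 1)) {
    stop("expected_two_label_fraction: p_label must lie in [0, 1]",
         call. = FALSE)
  }
  p_label^2
}

#' Binomial fraction with standard error
#'
#' Wald SE `sqrt(p (1 - p) / n)` to match fractions reported as value
#' +/- SE; a Wilson 95% interval is returned alongside.
#'
#' @param k Successes (0 <= k <= n).
#' @param n Trials (> 0).
#' @return List: `p`, `se`, `wilson_lower`, `wilson_upper`, `k`, `n`.
#' @export
proportion_with_se <- function(k, n) {
  if (n <= 0) stop("proportion_with_se: n must be positive", call. = FALSE)
  if (k < 0 || k > n) stop("proportion_with_se: need 0 <= k <= n",
                           call. = FALSE)
  p <- k / n
  z <- stats::qnorm(0.975)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(p = p, se = sqrt(p * (1 - p) / n),
       wilson_lower = max(0, centre - half),
       wilson_upper = min(1, centre + half), k = k, n = n)
}

#' Ratio of two fractions with propagated standard error
#'
#' First-order (delta-method) propagation for `p_num / p_den`. The two
#' fractions are treated as independent unless a correlation is supplied;
#' for a ratio of a quantity to itself the correlation is 1 and the SE is
#' zero.
#'
#' @param p_num,se_num Numerator fraction and its SE.
#' @param p_den,se_den Denominator fraction (> 0) and its SE.
#' @param correlation Correlation between numerator and denominator
#'   estimates (default 0).
#' @return List: `ratio`, `se`.
#' @export
conditional_fraction <- function(p_num, se_num, p_den, se_den,
                                 correlation = 0) {
  if (p_den <= 0) stop("conditional_fraction: zero or negative denominator",
                       call. = FALSE)
  r <- p_num / p_den
  rel2 <- (se_num / p_num)^2 + (se_den / p_den)^2 -
    2 * correlation * se_num * se_den / (p_num * p_den)
  list(ratio = r, se = abs(r) * sqrt(max(rel2, 0)))
}

#' Expected FRET-profile proportions under a loading mechanism
#'
#' For a mixed labeling design in which a fraction `q` of the relevant
#' protein carries the FRET-coupled (C-terminal) label: under the ORC-flip
#' mechanism the first and second recruitments are independent draws, so
#' profiles (two peaks, none, first-only, second-only) occur at
#' `(q^2, (1-q)^2, q(1-q), q(1-q))`; under the re-FRET mechanism both
#' peaks are carried by the first helicase, giving `(q, 1-q, 0, 0)`.
#'
#' @param model `"orc_flip"` or `"re_fret"`.
#' @param q Fraction carrying the coupled label (default 0.5, equimolar).
#' @return Named numeric vector over
#'   `c("two_peak", "none", "first_only", "second_only")`.
#' @export
model_profile_expectation <- function(model = c("orc_flip", "re_fret"),
                                      q = 0.5) {
  model <- match.arg(model)
  if (model == "orc_flip") {
    c(two_peak = q^2, none = (1 - q)^2, first_only = q * (1 - q),
      second_only = q * (1 - q))
  } else {
    c(two_peak = q, none = 1 - q, first_only = 0, second_only = 0)
  }
}

#' Multinomial goodness-of-fit (likelihood-ratio G) test
#'
#' Tests observed profile counts against model-expected proportions. Cells
#' with a structural zero expectation but a positive observed count reject
#' the model outright (p = 0, flagged). The p value uses the chi-squared
#' reference distribution for G with k - 1 degrees of freedom; an exact
#' Monte-Carlo multinomial p value can be requested for small n.
#'
#' @param observed Named or unnamed non-negative counts.
#' @param expected_prop Model proportions (same length; summing to 1).
#' @param simulate_p If `TRUE`, add a Monte-Carlo multinomial p value.
#' @param B Monte-Carlo replicates.
#' @param rng_seed Seed for the Monte-Carlo p value.
#' @return List: `G`, `df`, `p_value`, `p_mc` (or `NA`),
#'   `structural_violation`.
#' @export
pattern_frequency_test <- function(observed, expected_prop,
                                   simulate_p = FALSE, B = 2000,
                                   rng_seed = 1L) {
  stopifnot(length(observed) == length(expected_prop), all(observed >= 0))
  if (abs(sum(expected_prop) - 1) > 1e-8) {
    stop("pattern_frequency_test: expected proportions must sum to 1",
         call. = FALSE)
  }
  n <- sum(observed)
  viol <- any(expected_prop == 0 & observed > 0)
  if (viol) {
    return(list(G = Inf, df = length(observed) - 1L, p_value = 0,
                p_mc = if (simulate_p) 0 else NA_real_,
                structural_violation = TRUE))
  }
  keep <- expected_prop > 0
  exp_n <- n * expected_prop[keep]
  obs <- observed[keep]
  pos <- obs > 0
  G <- 2 * sum(obs[pos] * log(obs[pos] / exp_n[pos]))
  df <- length(observed) - 1L
  p <- stats::pchisq(G, df, lower.tail = FALSE)
  p_mc <- NA_real_
  if (simulate_p) {
    with_seed(rng_seed, {
      sims <- stats::rmultinom(B, n, expected_prop)
      gs <- apply(sims, 2, function(o) {
        pos <- o > 0 & expected_prop > 0
        2 * sum(o[pos] * log(o[pos] / (n * expected_prop[pos])))
      })
      p_mc <- (1 + sum(gs >= G - 1e-12)) / (B + 1)
    })
  }
  list(G = G, df = df, p_value = p, p_mc = p_mc,
       structural_violation = FALSE)
}

#' Histogram of signed lags in acquisition-cycle bins
#'
#' Bins are one cycle wide (2.4 s) and aligned so that one bin is centered
#' on zero lag, matching the temporal-resolution convention for
#' coincidence calls.
#'
#' @param lags Finite signed lags (s).
#' @param bin_s Bin width (s).
#' @return List: `breaks`, `mid`, `count`, `fraction`, `se`,
#'   `central_fraction` (fraction of lags in the zero-centered bin, with
#'   `central_se`), `n`.
#' @export
offset_histogram <- function(lags, bin_s = 2.4) {
  lags <- lags[is.finite(lags)]
  n <- length(lags)
  if (!n) {
    return(list(breaks = numeric(), mid = numeric(), count = integer(),
                fraction = numeric(), se = numeric(),
                central_fraction = NA_real_, central_se = NA_real_, n = 0L))
  }
  kmax <- max(1, ceiling((max(abs(lags)) + bin_s / 2) / bin_s))
  breaks <- (seq(-kmax, kmax) + 0.5) * bin_s
  breaks <- c(-(kmax + 0.5) * bin_s, breaks)
  cnt <- as.integer(table(cut(lags, breaks, include.lowest = TRUE)))
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  frac <- cnt / n
  se <- sqrt(frac * (1 - frac) / n)
  central <- which.min(abs(mid))
  list(breaks = breaks, mid = mid, count = cnt, fraction = frac, se = se,
       central_fraction = frac[central], central_se = se[central], n = n)
}
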