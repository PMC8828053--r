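# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
rexp_mean <- function(n, mean_s) {
  stopifnot(mean_s > 0)
  stats::rexp(n, rate = 1 / mean_s)
}

# Exponential draw conditioned below `upper` (inverse-CDF; used for the
# short-lived second-association class which is defined only by a threshold).
rexp_mean_below <- function(n, mean_s, upper) {
  u <- stats::runif(n)
  -mean_s * log(1 - u * (1 - exp(-upper / mean_s)))
}

# Deterministic sub-seed scheme: every stage draws its own seed from the
# master seed so that adding a stage never perturbs another stage's stream.
# Kept below 2^31 - 1 (R integer range).
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1000003 * k) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  expr
}

# Overlap (seconds) of interval [s, e] with each window [starts, starts + width].
overlap_frac <- function(s, e, starts, width) {
  pmax(0, pmin(e, starts + width) - pmax(s, starts)) / width
}

# Minimal interval algebra on two-column matrices (start, end), rows sorted,
# used by the trace renderer to split a donor's presence into emission states.
iv_make <- function(s, e) {
  keep <- is.finite(s) & e > s
  cbind(start = s[keep], end = e[keep])
}

iv_intersect <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(iv_make(numeric(), numeric()))
  out_s <- numeric()
  out_e <- numeric()
  for (i in seq_len(nrow(a))) {
    s <- pmax(a[i, 1], b[, 1])
    e <- pmin(a[i, 2], b[, 2])
    ok <- e > s
    out_s <- c(out_s, s[ok])
    out_e <- c(out_e, e[ok])
  }
  iv_make(out_s, out_e)
}

iv_union <- function(a) {
  if (nrow(a) <= 1L) return(a)
  a <- a[order(a[, 1]), , drop = FALSE]
  s <- a[1, 1]; e <- a[1, 2]
  out_s <- numeric(); out_e <- numeric()
  for (i in seq_len(nrow(a))[-1]) {
    if (a[i, 1] > e) {
      out_s <- c(out_s, s); out_e <- c(out_e, e)
      s <- a[i, 1]; e <- a[i, 2]
    } else e <- max(e, a[i, 2])
  }
  iv_make(c(out_s, s), c(out_e, e))
}

iv_subtract <- function(a, b) {
  if (nrow(a) == 0L) return(a)
  if (nrow(b) == 0L) return(a)
  b <- iv_union(b)
  out_s <- numeric(); out_e <- numeric()
  for (i in seq_len(nrow(a))) {
    s <- a[i, 1]; e <- a[i, 2]
    segs_s <- s; segs_e <- e
    for (j in seq_len(nrow(b))) {
      ns <- numeric(); ne <- numeric()
      for (k in seq_along(segs_s)) {
        cs <- segs_s[k]; ce <- segs_e[k]
        bs <- b[j, 1]; be <- b[j, 2]
        if (be <= cs || bs >= ce) { ns <- c(ns, cs); ne <- c(ne, ce); next }
        if (bs > cs) { ns <- c(ns, cs); ne <- c(ne, bs) }
        if (be < ce) { ns <- c(ns, be); ne <- c(ne, ce) }
      }
      segs_s <- ns; segs_e <- ne
    }
    out_s <- c(out_s, segs_s); out_e <- c(out_e, segs_e)
  }
  iv_make(out_s, out_e)
}
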