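#' Lag-grid specification for the photon correlator
#'
#' The correlator evaluates G on a multi-tau style quasi-logarithmic grid:
#' the finest octaves are sampled at the macrotime tick resolution and the
#' photon times are coarsened by a factor 2 per octave before pair
#' counting, with `points_per_octave` lags per octave. The default grid
#' spans one macrotime tick (12.5 ns at 80 MHz) to a tenth of the trace
#' duration, which covers the usual FCS display range.
#'
#' @param points_per_octave lags per factor-2 of correlation time
#'   (default 16).
#' @param max_lag_s largest correlation time in seconds; `NULL` means
#'   `duration / 10` of the stream being correlated.
#' @return A list of class `lag_scheme`.
#' @export
lag_scheme <- function(points_per_octave = 16, max_lag_s = NULL) {
  stopifnot(points_per_octave >= 1)
  structure(list(m = as.integer(2 * points_per_octave),
                 max_lag_s = max_lag_s),
            class = "lag_scheme")
}

resolve_max_lag <- function(stream, scheme) {
  max_lag_s <- scheme$max_lag_s
  if (is.null(max_lag_s)) return(stream$duration_s / 10)
  if (max_lag_s > stream$duration_s) {
    warning("lag grid exceeds the trace duration; truncated to duration",
            call. = FALSE)
    max_lag_s <- stream$duration_s
  }
  max_lag_s
}

new_correlation_curve <- function(lags_s, G, G_err, n_pairs, lag_ticks,
                                  coarsening, stream, n_segments = 1L) {
  structure(list(lags_s = lags_s, G = G, G_err = G_err, n_pairs = n_pairs,
                 lag_ticks = lag_ticks, coarsening = coarsening,
                 mean_rate = mean_count_rate(stream),
                 duration_s = stream$duration_s,
                 n_photons = n_photons(stream),
                 n_segments = n_segments,
                 label = stream$label),
            class = "correlation_curve")
}

empty_curve <- function(stream) {
  new_correlation_curve(numeric(0), numeric(0), numeric(0), numeric(0),
                        numeric(0), numeric(0), stream)
}

# shared estimator arithmetic applied to pair/count tables returned by the
# C++ counters: symmetric (finite-trace) normalization, fluctuation
# convention.  Lags with an empty left or right photon window are
# undefined and flagged NA.
curve_from_counts <- function(counts, stream) {
  denom <- counts$NL * counts$NR
  G <- ifelse(denom > 0, counts$pairs * (counts$M - counts$k) / denom - 1,
              NA_real_)
  new_correlation_curve(
    lags_s = counts$lag_ticks * stream$tick_s,
    G = G,
    G_err = rep(NA_real_, nrow(counts)),
    n_pairs = counts$pairs,
    lag_ticks = counts$lag_ticks,
    coarsening = counts$u,
    stream = stream)
}

#' Photon-mode autocorrelation of a photon stream
#'
#' Computes the normalized intensity autocorrelation G(t_c) directly from
#' the photon arrival times (no intermediate binned intensity trace), on
#' the quasi-logarithmic grid of [lag_scheme()]. Symmetric normalization
#' over the windows `[0, T - tau)` and `[tau, T)` removes the finite-trace
#' bias, so for a homogeneous Poisson stream the expected G is 0 at every
#' lag (fluctuation convention). Lags whose normalization windows contain
#' no photons are reported as `NA` rather than zero-filled.
#'
#' @param stream a `photon_stream` (typically after [apply_gate()]).
#' @param scheme a [lag_scheme()].
#' @return A `correlation_curve`: fields `lags_s`, `G`, `G_err` (NA here;
#'   see [segment_errors()]), `n_pairs`, `mean_rate`, `duration_s`,
#'   `n_photons`. A stream with fewer than 2 photons gives an empty curve
#'   with a warning.
#' @export
correlate <- function(stream, scheme = lag_scheme()) {
  stopifnot(inherits(stream, "photon_stream"), inherits(scheme, "lag_scheme"))
  if (n_photons(stream) < 2) {
    warning("fewer than 2 photons; returning an empty correlation curve",
            call. = FALSE)
    return(empty_curve(stream))
  }
  max_lag_s <- resolve_max_lag(stream, scheme)
  T_ticks <- max(ceiling(stream$duration_s / stream$tick_s),
                 max(stream$macro_ticks) + 1)
  max_lag_ticks <- floor(max_lag_s / stream$tick_s)
  if (max_lag_ticks < 1) {
    warning("maximum lag below one macrotime tick; empty curve",
            call. = FALSE)
    return(empty_curve(stream))
  }
  counts <- .multi_tau_count(stream$macro_ticks, T_ticks, scheme$m,
                             max_lag_ticks)
  curve_from_counts(counts, stream)
}

#' Brute-force pair-counting autocorrelation (test oracle)
#'
#' Direct O(N^2) evaluation of the same estimator as [correlate()]: photon
#' times are coarsened exactly as in the multi-tau grid and ordered pairs
#' are counted by a naive double loop. Intended as an independent oracle
#' for small streams; it shares only the estimator definition, not the
#' counting code, with [correlate()].
#'
#' @param stream a `photon_stream` with at most ~1e5 photons.
#' @param scheme a [lag_scheme()]; alternatively pass explicit integer
#'   `lag_ticks` (with coarsening 1) to probe individual lag bins.
#' @param lag_ticks optional explicit vector of lags in macrotime ticks.
#' @return A `correlation_curve` on the same grid as [correlate()].
#' @export
brute_force_correlate <- function(stream, scheme = lag_scheme(),
                                  lag_ticks = NULL) {
  stopifnot(inherits(stream, "photon_stream"))
  if (n_photons(stream) < 2) {
    warning("fewer than 2 photons; returning an empty correlation curve",
            call. = FALSE)
    return(empty_curve(stream))
  }
  if (n_photons(stream) > 1e5)
    stop("brute_force_correlate is restricted to streams of <= 1e5 photons",
         call. = FALSE)
  T_ticks <- max(ceiling(stream$duration_s / stream$tick_s),
                 max(stream$macro_ticks) + 1)
  if (is.null(lag_ticks)) {
    max_lag_ticks <- floor(resolve_max_lag(stream, scheme) / stream$tick_s)
    grid <- .multi_tau_lags(scheme$m, max_lag_ticks)
  } else {
    grid <- data.frame(k = as.numeric(lag_ticks),
                       u = rep(1, length(lag_ticks)))
  }
  counts <- .brute_force_count(stream$macro_ticks, T_ticks, grid$k, grid$u)
  curve_from_counts(counts, stream)
}

#' Autocorrelation with segment-based error bars
#'
#' Splits the acquisition into `n_segments` equal intervals, correlates
#' each independently, and reports the per-lag mean and standard error
#' over segments. This is the standard FCS practice for obtaining fit
#' weights from a single trace. Segments with fewer than 2 photons are
#' dropped with a warning.
#'
#' @param stream a `photon_stream`.
#' @param n_segments number of segments, at least 2.
#' @param scheme a [lag_scheme()]; the default maximum lag is a tenth of
#'   the segment (not trace) duration.
#' @return A `correlation_curve` with populated `G_err`.
#' @export
segment_errors <- function(stream, n_segments = 10, scheme = lag_scheme()) {
  stopifnot(inherits(stream, "photon_stream"))
  if (n_segments < 2)
    stop("n_segments must be at least 2", call. = FALSE)
  seg_dur <- stream$duration_s / n_segments
  seg_ticks <- seg_dur / stream$tick_s
  curves <- vector("list", n_segments)
  for (s in seq_len(n_segments)) {
    lo <- (s - 1) * seg_ticks
    hi <- s * seg_ticks
    keep <- stream$macro_ticks >= lo & stream$macro_ticks < hi
    seg <- stream
    seg$macro_ticks <- stream$macro_ticks[keep] - floor(lo)
    seg$microtimes_ns <- stream$microtimes_ns[keep]
    seg$duration_s <- seg_dur
    if (sum(keep) < 2) {
      warning(sprintf("segment %d has fewer than 2 photons; dropped", s),
              call. = FALSE)
      curves[[s]] <- NULL
    } else {
      curves[[s]] <- correlate(seg, scheme)
    }
  }
  curves <- Filter(Negate(is.null), curves)
  if (!length(curves))
    stop("no segment had enough photons to correlate", call. = FALSE)
  Gmat <- sapply(curves, function(cv) cv$G)
  if (is.null(dim(Gmat))) Gmat <- matrix(Gmat, ncol = length(curves))
  n_used <- rowSums(!is.na(Gmat))
  Gbar <- rowMeans(Gmat, na.rm = TRUE)
  Gsd <- apply(Gmat, 1, stats::sd, na.rm = TRUE)
  Gerr <- ifelse(n_used >= 2, Gsd / sqrt(n_used), NA_real_)
  pairs <- rowSums(sapply(curves, function(cv) cv$n_pairs))
  ref <- curves[[1]]
  out <- new_correlation_curve(ref$lags_s, Gbar, Gerr, pairs, ref$lag_ticks,
                               ref$coarsening, stream,
                               n_segments = length(curves))
  out
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf(
    "<correlation_curve> %d lags in [%.3g, %.3g] s; <F> = %.4g kHz, %d photons / %.3g s\n",
    length(x$lags_s),
    if (length(x$lags_s)) min(x$lags_s) else NA,
    if (length(x$lags_s)) max(x$lags_s) else NA,
    x$mean_rate / 1e3, x$n_photons, x$duration_s))
  invisible(x)
}

#' @export
as.data.frame.correlation_curve <- function(x, ...) {
  data.frame(lag_s = x$lags_s, G = x$G, G_err = x$G_err, n_pairs = x$n_pairs)
}

#' Write a correlation curve as CSV
#'
#' Columns `lag_s, G, G_err`; header comment lines (prefixed `#`) carry
#' the mean count rate, duration, photon count and label.
#'
#' @param curve a `correlation_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# mean_rate_hz: %.10g", curve$mean_rate),
    sprintf("# duration_s: %.10g", curve$duration_s),
    sprintf("# n_photons: %d", curve$n_photons),
    sprintf("# label: %s", curve$label),
    "lag_s,G,G_err"), con)
  if (length(curve$lags_s))
    writeLines(paste(sprintf("%.10g", curve$lags_s),
                     sprintf("%.10g", curve$G),
                     sprintf("%.10g", curve$G_err), sep = ","), con)
  invisible(path)
}
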