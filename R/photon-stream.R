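#' Construct a TCSPC photon stream
#'
#' A photon stream is the raw product of a time-correlated single photon
#' counting (TCSPC) acquisition: one record per detected photon, holding the
#' macroscopic arrival time within the measurement and the microscopic delay
#' relative to the excitation pulse. Macrotimes are stored on an integer tick
#' grid (default: one tick per excitation period) so that downstream photon
#' correlation is exact in integer arithmetic; microtimes are stored in
#' nanoseconds as the forward delay since the preceding excitation pulse.
#'
#' Some TCSPC hardware records the reverse start-stop delay (time to the
#' *next* pulse). Importers of such data should convert with
#' `microtime_fwd = period - microtime_rev` before constructing a stream;
#' gating semantics in this package are always relative to the preceding
#' pulse.
#'
#' @param macro_ticks numeric vector of integer-valued macrotime ticks,
#'   non-decreasing. One tick equals `tick_s` seconds.
#' @param microtimes_ns numeric vector, same length as `macro_ticks`; delay
#'   since the preceding excitation pulse in nanoseconds, each in
#'   `[0, 1e9 / rep_rate_hz)`.
#' @param rep_rate_hz excitation repetition rate in Hz (default 80 MHz).
#' @param duration_s total acquisition length in seconds; must cover the
#'   last photon.
#' @param tick_s macrotime tick length in seconds; defaults to the
#'   excitation period `1 / rep_rate_hz`.
#' @param channel_ns TCSPC microtime channel width in ns; `0` means
#'   microtimes are continuous (e.g. simulated).
#' @param label free-text provenance tag.
#'
#' @return An object of class `photon_stream`.
#' @seealso [apply_gate()], [lifetime_histogram()], [read_photon_stream()]
#' @export
photon_stream <- function(macro_ticks, microtimes_ns,
                          rep_rate_hz = 8e7,
                          duration_s,
                          tick_s = 1 / rep_rate_hz,
                          channel_ns = 0,
                          label = "") {
  stopifnot(is.numeric(macro_ticks), is.numeric(microtimes_ns))
  x <- structure(
    list(
      macro_ticks  = as.numeric(macro_ticks),
      microtimes_ns = as.numeric(microtimes_ns),
      rep_rate_hz  = as.numeric(rep_rate_hz),
      duration_s   = as.numeric(duration_s),
      tick_s       = as.numeric(tick_s),
      channel_ns   = as.numeric(channel_ns),
      label        = as.character(label)
    ),
    class = "photon_stream"
  )
  validate_photon_stream(x)
}

#' Validate a photon stream's invariants
#'
#' Checks monotone macrotimes, microtimes within the excitation period,
#' and that the stated duration covers the last photon. Called by
#' [photon_stream()] and by the readers; exported for use on streams
#' assembled by hand.
#'
#' @param x a `photon_stream`.
#' @return `x`, invisibly unchanged, or an error describing the first
#'   violated invariant (with the offending index where applicable).
#' @export
validate_photon_stream <- function(x) {
  stopifnot(inherits(x, "photon_stream"))
  n <- length(x$macro_ticks)
  if (length(x$microtimes_ns) != n)
    stop("macrotime and microtime vectors differ in length", call. = FALSE)
  if (!is.finite(x$rep_rate_hz) || x$rep_rate_hz <= 0)
    stop("rep_rate_hz must be positive", call. = FALSE)
  if (!is.finite(x$tick_s) || x$tick_s <= 0)
    stop("tick_s must be positive", call. = FALSE)
  if (!is.finite(x$duration_s) || x$duration_s < 0)
    stop("duration_s must be non-negative", call. = FALSE)
  if (n > 0) {
    bad <- which(diff(x$macro_ticks) < 0)
    if (length(bad))
      stop(sprintf("macrotimes not non-decreasing at record %d", bad[1] + 1L),
           call. = FALSE)
    period <- excitation_period_ns(x)
    bad <- which(x$microtimes_ns < 0 | x$microtimes_ns >= period)
    if (length(bad))
      stop(sprintf(
        "microtime %.4g ns at record %d outside [0, %.4g) ns excitation period",
        x$microtimes_ns[bad[1]], bad[1], period), call. = FALSE)
    if (x$macro_ticks[n] * x$tick_s > x$duration_s + 1e-12)
      stop("duration_s is shorter than the last macrotime", call. = FALSE)
  }
  invisible(x)
}

#' Excitation period of a stream, in nanoseconds
#' @param x a `photon_stream` (or a rep rate in Hz).
#' @return period in ns (12.5 ns at 80 MHz).
#' @export
excitation_period_ns <- function(x) {
  rate <- if (inherits(x, "photon_stream")) x$rep_rate_hz else as.numeric(x)
  1e9 / rate
}

#' Number of photons in a stream
#' @param x a `photon_stream`.
#' @return integer photon count.
#' @export
n_photons <- function(x) {
  stopifnot(inherits(x, "photon_stream"))
  length(x$macro_ticks)
}

#' Macrotimes in seconds
#' @param x a `photon_stream`.
#' @return numeric vector, `macro_ticks * tick_s`.
#' @export
macrotimes_s <- function(x) {
  stopifnot(inherits(x, "photon_stream"))
  x$macro_ticks * x$tick_s
}

#' Mean detected count rate
#' @param x a `photon_stream`.
#' @return photons per second over the stated duration.
#' @export
mean_count_rate <- function(x) {
  stopifnot(inherits(x, "photon_stream"))
  if (x$duration_s <= 0) return(0)
  n_photons(x) / x$duration_s
}

#' @export
print.photon_stream <- function(x, ...) {
  cat(sprintf(
    "<photon_stream> %d photons over %.3g s (%.3g kHz), rep rate %.4g MHz\n",
    n_photons(x), x$duration_s, mean_count_rate(x) / 1e3, x$rep_rate_hz / 1e6))
  if (nzchar(x$label)) cat("  label:", x$label, "\n")
  invisible(x)
}

#' Define a detection gate on the microtime axis
#'
#' A gate keeps photons whose TCSPC microtime (delay after the excitation
#' pulse) falls in the half-open window `[t_start, t_end)` nanoseconds.
#' Raising `t_start` preferentially keeps long-lifetime photons from the
#' centre of a CW-STED observation spot.
#'
#' @param t_start gate opening, ns (the gate delay often written T_g).
#' @param t_end gate closing, ns; must satisfy
#'   `0 <= t_start < t_end <= period`.
#' @param period_ns excitation period used to validate `t_end`
#'   (default 12.5 ns, i.e. 80 MHz).
#' @return An object of class `gate_window`.
#' @export
gate_window <- function(t_start, t_end, period_ns = 12.5) {
  t_start <- as.numeric(t_start); t_end <- as.numeric(t_end)
  if (!is.finite(t_start) || !is.finite(t_end))
    stop("gate bounds must be finite", call. = FALSE)
  if (t_start < 0 || t_start >= t_end || t_end > period_ns + 1e-9)
    stop(sprintf("need 0 <= t_start < t_end <= period (%g ns); got [%g, %g)",
                 period_ns, t_start, t_end), call. = FALSE)
  structure(list(t_start = t_start, t_end = t_end), class = "gate_window")
}

#' @export
print.gate_window <- function(x, ...) {
  cat(sprintf("<gate_window> [%.4g, %.4g) ns\n", x$t_start, x$t_end))
  invisible(x)
}

#' Apply a microtime gate to a photon stream
#'
#' Retains exactly the photons with `t_start <= microtime < t_end`. The
#' macrotimes of retained photons and the acquisition duration are left
#' untouched, so gated and ungated correlation curves share a time base;
#' only the mean count rate drops. Gating is idempotent and disjoint gates
#' partition the photon set.
#'
#' @param stream a `photon_stream`.
#' @param gate a `gate_window` (validated against the stream's period).
#' @return A `photon_stream` containing the retained photons.
#' @export
apply_gate <- function(stream, gate) {
  stopifnot(inherits(stream, "photon_stream"), inherits(gate, "gate_window"))
  period <- excitation_period_ns(stream)
  if (gate$t_end > period + 1e-9)
    stop("gate end exceeds the excitation period of the stream", call. = FALSE)
  keep <- stream$microtimes_ns >= gate$t_start &
          stream$microtimes_ns <  gate$t_end
  out <- stream
  out$macro_ticks   <- stream$macro_ticks[keep]
  out$microtimes_ns <- stream$microtimes_ns[keep]
  out
}

#' Fluorescence lifetime histogram of a photon stream
#'
#' Histograms the microtimes over the excitation period. The final bin is
#' truncated at the period when `bin_width_ns` does not divide it, so the
#' bins always span exactly `[0, period)` and counts conserve the photon
#' number.
#'
#' @param stream a `photon_stream`.
#' @param bin_width_ns histogram bin width in ns; must be positive and
#'   smaller than the excitation period.
#' @return An object of class `lifetime_histogram` with fields
#'   `bin_edges_ns` (length `nbins + 1`) and `counts`.
#' @export
lifetime_histogram <- function(stream, bin_width_ns = 0.1) {
  stopifnot(inherits(stream, "photon_stream"))
  period <- excitation_period_ns(stream)
  if (!is.finite(bin_width_ns) || bin_width_ns <= 0)
    stop("bin_width_ns must be positive", call. = FALSE)
  if (bin_width_ns >= period)
    stop("bin_width_ns must be smaller than the excitation period",
         call. = FALSE)
  edges <- seq(0, period, by = bin_width_ns)
  if (edges[length(edges)] < period) edges <- c(edges, period)
  idx <- findInterval(stream$microtimes_ns, edges,
                      rightmost.closed = FALSE, left.open = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(bin_edges_ns = edges, counts = as.integer(counts)),
            class = "lifetime_histogram")
}

#' @export
print.lifetime_histogram <- function(x, ...) {
  cat(sprintf("<lifetime_histogram> %d bins over [0, %.4g) ns, %d photons\n",
              length(x$counts), max(x$bin_edges_ns), sum(x$counts)))
  invisible(x)
}
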