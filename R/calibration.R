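#' Observation-spot FWHM from a transit-time ratio
#'
#' For free 2D diffusion the transit time scales with the spot area, so
#' the effective spot diameter at a given depletion power follows from
#' the transit-time ratio against a confocal reference:
#'
#' \deqn{\mathrm{FWHM}(P) = \mathrm{FWHM}(0)\sqrt{\tau_D(P)/\tau_D(0)}}
#'
#' @param tau_D transit time at the condition of interest, seconds.
#' @param tau_D0 confocal reference transit time, seconds.
#' @param fwhm0 confocal spot FWHM in nm. This is a user-supplied
#'   calibration (from bead imaging or theory); the package default of
#'   240 nm corresponds to 488 nm excitation at NA 1.4 and should be
#'   replaced by the instrument's own value.
#' @return FWHM in nm.
#' @export
fwhm_from_transit <- function(tau_D, tau_D0, fwhm0 = 240) {
  if (any(!is.finite(tau_D)) || any(tau_D <= 0))
    stop("tau_D must be positive", call. = FALSE)
  if (!is.finite(tau_D0) || tau_D0 <= 0)
    stop("tau_D0 must be positive", call. = FALSE)
  if (!is.finite(fwhm0) || fwhm0 <= 0)
    stop("fwhm0 must be positive", call. = FALSE)
  fwhm0 * sqrt(tau_D / tau_D0)
}

#' Build a spot-size calibration from confocal and STED fits
#'
#' Averages the confocal transit time over the (by default QC-passing)
#' reference fits, then converts every STED-stage fit to an effective
#' spot FWHM via [fwhm_from_transit()]. Uncertainties are propagated to
#' first order (delta method) on the square root from the replicate
#' spread of both the confocal reference and the per-power transit
#' times.
#'
#' @param confocal_fits list of `fcs_fit_result` at zero depletion power.
#' @param sted_fits data pairs: either a list of `list(power=, fit=)` or
#'   a data.frame-free list; each entry one STED-stage fit with its
#'   depletion power (mW or percent, any consistent unit).
#' @param fwhm0 confocal FWHM in nm (see [fwhm_from_transit()]).
#' @param qc_only use only QC-passing confocal fits (default TRUE).
#' @return A `spot_calibration`: `fwhm0`, `tau_D0` (mean, sd, n) and a
#'   data.frame `entries` with one row per power
#'   (`power, tau_D_mean, tau_D_sd, n, fwhm_nm, fwhm_sd_nm`).
#' @export
build_calibration <- function(confocal_fits, sted_fits = list(),
                              fwhm0 = 240, qc_only = TRUE) {
  if (qc_only) {
    kept <- qc_filter(confocal_fits,
                      bounds = if (length(confocal_fits))
                        confocal_fits[[1]]$qc_bounds else c(0.8, 1.2))
  } else kept <- confocal_fits
  if (!length(kept))
    stop("no QC-passing confocal reference fit; cannot calibrate",
         call. = FALSE)
  tau0 <- vapply(kept, function(r) r$params$tau_D, numeric(1))
  tau_D0 <- mean(tau0)
  tau_D0_sd <- if (length(tau0) >= 2) stats::sd(tau0) else 0

  entries <- data.frame(power = numeric(0), tau_D_mean = numeric(0),
                        tau_D_sd = numeric(0), n = integer(0),
                        fwhm_nm = numeric(0), fwhm_sd_nm = numeric(0))
  if (length(sted_fits)) {
    powers <- vapply(sted_fits, function(e) as.numeric(e$power), numeric(1))
    taus <- vapply(sted_fits, function(e) e$fit$params$tau_D, numeric(1))
    for (p in sort(unique(powers))) {
      tt <- taus[powers == p]
      m <- mean(tt)
      s <- if (length(tt) >= 2) stats::sd(tt) else 0
      f <- fwhm_from_transit(m, tau_D0, fwhm0)
      # delta method on fwhm0 * sqrt(tau/tau0):
      # var_f = f^2/4 * (var_tau/tau^2 + var_tau0/tau0^2)
      fsd <- f / 2 * sqrt((s / m)^2 + (tau_D0_sd / tau_D0)^2)
      entries <- rbind(entries, data.frame(
        power = p, tau_D_mean = m, tau_D_sd = s, n = length(tt),
        fwhm_nm = f, fwhm_sd_nm = fsd))
    }
  }
  structure(list(fwhm0 = fwhm0, tau_D0 = tau_D0, tau_D0_sd = tau_D0_sd,
                 n_confocal = length(tau0), entries = entries),
            class = "spot_calibration")
}

#' @export
print.spot_calibration <- function(x, ...) {
  cat(sprintf(
    "<spot_calibration> fwhm0 = %.3g nm; tau_D0 = %.4g +/- %.2g s (n=%d)\n",
    x$fwhm0, x$tau_D0, x$tau_D0_sd, x$n_confocal))
  if (nrow(x$entries)) print(x$entries)
  invisible(x)
}

#' Aggregate fits over a laser-power series
#'
#' Summarises replicate fits recorded at a series of excitation (or
#' depletion) powers into per-power mean and standard deviation of the
#' transit time and of the molecular brightness, the standard way of
#' screening dye performance (photobleaching shortens apparent transits
#' at high power; brightness saturates). With `normalize = TRUE` the
#' transit times are divided by the mean transit time at the lowest
#' power.
#'
#' @param fits list of `list(power=, fit=)` entries as in
#'   [build_calibration()].
#' @param normalize divide tau_D by its mean at the lowest power.
#' @param qc_only use QC-passing fits only (default FALSE: power series
#'   deliberately include conditions that break the free-diffusion QC).
#' @return A `power_series`: data.frame `summary` with columns
#'   `power, n, tau_D_mean, tau_D_sd, cpm_mean, cpm_sd` sorted by
#'   ascending power, plus the normalization flag.
#' @export
aggregate_power_series <- function(fits, normalize = FALSE,
                                   qc_only = FALSE) {
  if (!length(fits)) stop("need at least one power level", call. = FALSE)
  powers <- vapply(fits, function(e) as.numeric(e$power), numeric(1))
  keep <- if (qc_only)
    vapply(fits, function(e) isTRUE(e$fit$qc_pass), logical(1))
  else rep(TRUE, length(fits))
  if (!any(keep)) stop("no fits retained for the power series", call. = FALSE)
  powers <- powers[keep]; fits <- fits[keep]
  taus <- vapply(fits, function(e) e$fit$params$tau_D, numeric(1))
  cpms <- vapply(fits, function(e) e$fit$cpm, numeric(1))
  lv <- sort(unique(powers))
  smry <- do.call(rbind, lapply(lv, function(p) {
    i <- powers == p
    data.frame(power = p, n = sum(i),
               tau_D_mean = mean(taus[i]),
               tau_D_sd = if (sum(i) >= 2) stats::sd(taus[i]) else 0,
               cpm_mean = mean(cpms[i]),
               cpm_sd = if (sum(i) >= 2) stats::sd(cpms[i]) else 0)
  }))
  if (normalize) {
    ref <- smry$tau_D_mean[1]
    smry$tau_D_mean <- smry$tau_D_mean / ref
    smry$tau_D_sd <- smry$tau_D_sd / ref
  }
  structure(list(summary = smry, normalized = normalize),
            class = "power_series")
}

#' @export
print.power_series <- function(x, ...) {
  cat(sprintf("<power_series> %d power level(s)%s\n", nrow(x$summary),
              if (x$normalized) ", tau_D normalised to lowest power" else ""))
  print(x$summary)
  invisible(x)
}

#' Write a spot calibration as CSV
#' @param cal a `spot_calibration`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration_csv <- function(cal, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fwhm0_nm: %.10g", cal$fwhm0),
               sprintf("# tau_D0_s: %.10g", cal$tau_D0),
               sprintf("# tau_D0_sd_s: %.10g", cal$tau_D0_sd)), con)
  utils::write.table(cal$entries, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
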